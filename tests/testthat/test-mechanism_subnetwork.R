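fixed_profile <- function(freq) {
  structure(list(freq = freq, seeds = seed_set(names(freq)[1]),
                 params = walk_parameters(), iterations = 0L, residual = 0),
            class = "diffusion_profile")
}

test_that("top_k_entities ranks by frequency with id tie-breaks", {
  prof <- fixed_profile(c(a = 0.2, b = 0.5, c = 0.3))
  expect_equal(top_k_entities(prof, 5), c("b", "c", "a"))
  uni <- fixed_profile(c(d = 0.25, b = 0.25, c = 0.25, a = 0.25))
  expect_equal(top_k_entities(uni, 2), c("a", "b"))
  withr::with_seed(6, {
    f <- runif(20); names(f) <- sprintf("n%02d", sample(20))
    prof <- fixed_profile(f / sum(f))
    oracle <- names(sort(prof$freq, decreasing = TRUE))[1:7]
    expect_equal(top_k_entities(prof, 7), oracle)
  })
})

sub_fixture <- function(k = 3L, association = "reachability") {
  net <- multiscale_network(
    ppi = data.frame(from = c("P1", "P2", "P4"), to = c("P2", "P3", "P5")),
    annotation = data.frame(from = c("P1", "P3"), to = c("F1", "F1"))
  )
  disease <- disease_context("DIS", c("P2", "P3"), population_size = 5L)
  params <- walk_parameters()
  op <- build_transition_matrix(net, params)
  profile_ing <- compute_diffusion_profile(net, seed_set(c("P1", "P4")),
                                           params, operator = op)
  profile_dis <- compute_diffusion_profile(net, seed_set(c("P2", "P3")),
                                           params, operator = op)
  list(net = net, disease = disease, ing = profile_ing, dis = profile_dis,
       params = subnetwork_parameters(k = k, association = association))
}

test_that("direct disease-protein targets produce both link edges", {
  fx <- sub_fixture(k = 1L)
  sub <- build_subnetwork(fx$net, "ING", c("P2"), fx$disease, fx$ing, fx$dis,
                          fx$params)
  expect_true("P2" %in% sub$nodes$id)
  expect_true(any(sub$edges$layer == "targets" & sub$edges$to == "P2"))
  expect_true(any(sub$edges$layer == "disease_link" & sub$edges$to == "P2"))
})

test_that("targets unreachable from disease-related nodes are excluded", {
  fx <- sub_fixture(k = 3L)
  # P4/P5 form a component disconnected from the disease proteins
  sub <- build_subnetwork(fx$net, "ING", c("P1", "P4"), fx$disease,
                          fx$ing, fx$dis, fx$params)
  expect_true("P4" %in% sub$dropped_targets)
  expect_false("P4" %in% sub$nodes$id)
  expect_true("P1" %in% sub$nodes$id)
})

test_that("exclusion is a no-op when every target is adjacent to a disease protein", {
  fx <- sub_fixture(k = 3L)
  sub <- build_subnetwork(fx$net, "ING", c("P1", "P2"), fx$disease,
                          fx$ing, fx$dis, fx$params)
  expect_length(sub$dropped_targets, 0)
  sub_adj <- build_subnetwork(
    fx$net, "ING", c("P1", "P2"), fx$disease, fx$ing, fx$dis,
    subnetwork_parameters(k = 3L, association = "adjacency"))
  expect_length(sub_adj$dropped_targets, 0)
})

test_that("node set matches a brute-force recomputation on a synthetic network", {
  cfg <- synthetic_config(n_proteins = 20L, n_functions = 10L,
                          disease_module_size = 4L, n_herbs = 5L,
                          rng_seed = 17L)
  st <- generate_study(cfg)
  params <- walk_parameters()
  op <- build_transition_matrix(st$network, params)
  ing <- st$catalog$ingredients[1]
  targets <- intersect(ingredient_targets(st$catalog, ing),
                       network_node_ids(st$network))
  p_ing <- compute_diffusion_profile(st$network, seed_set(targets), params,
                                     operator = op)
  p_dis <- compute_diffusion_profile(st$network, seed_set(st$disease$proteins),
                                     params, operator = op)
  k <- 5L
  sub <- build_subnetwork(st$network, ing, targets, st$disease, p_ing, p_dis,
                          subnetwork_parameters(k = k))

  # brute-force set algebra from the two sorted profiles
  topk <- function(pr) {
    ord <- order(-pr$freq, names(pr$freq), method = "radix")
    names(pr$freq)[ord][1:k]
  }
  expected <- union(union(topk(p_ing), topk(p_dis)),
                    union(targets, intersect(st$disease$proteins,
                                             union(topk(p_ing), topk(p_dis)))))
  expected <- setdiff(expected, sub$dropped_targets)
  expect_setequal(setdiff(sub$nodes$id, c(ing, "DISEASE")), expected)

  # node-count bound: 2k + direct targets + disease proteins + 2 pseudo-nodes
  expect_lte(nrow(sub$nodes),
             2 * k + length(targets) + length(st$disease$proteins) + 2)
})

test_that("SIF export has one line per edge and round-trips", {
  fx <- sub_fixture(k = 2L)
  sub <- build_subnetwork(fx$net, "ING", "P2", fx$disease, fx$ing, fx$dis,
                          fx$params)
  d <- withr::local_tempdir()
  p <- file.path(d, "sub.sif")
  export_subnetwork(sub, p, "sif")
  expect_length(readLines(p), nrow(sub$edges))
  back <- import_subnetwork(p, "sif")
  expect_setequal(back$nodes, unique(c(sub$edges$from, sub$edges$to)))
  key <- function(e) sort(paste(e$from, e$to, e$layer))
  expect_identical(key(back$edges), key(sub$edges))
})

test_that("GraphML export round-trips node and edge sets with attributes", {
  fx <- sub_fixture(k = 3L)
  sub <- build_subnetwork(fx$net, "ING", c("P1", "P2"), fx$disease,
                          fx$ing, fx$dis, fx$params)
  d <- withr::local_tempdir()
  p <- file.path(d, "sub.graphml")
  export_subnetwork(sub, p, "graphml")
  back <- import_subnetwork(p, "graphml")
  expect_setequal(back$nodes$name, sub$nodes$id)
  expect_setequal(back$nodes$role[back$nodes$name == "ING"], "ingredient")
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to),
                                e$layer))
  expect_identical(key(back$edges), key(sub$edges))
})

test_that("identical inputs give byte-identical SIF output", {
  fx <- sub_fixture(k = 3L)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.sif"); p2 <- file.path(d, "b.sif")
  for (p in c(p1, p2)) {
    sub <- build_subnetwork(fx$net, "ING", c("P1", "P2"), fx$disease,
                            fx$ing, fx$dis, fx$params)
    export_subnetwork(sub, p, "sif")
  }
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
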