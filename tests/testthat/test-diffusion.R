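test_that("transition rows normalize class weights over outgoing pairs", {
  net <- multiscale_network(
    ppi = data.frame(from = "P", to = "Q"),
    annotation = data.frame(from = "P", to = "F")
  )
  op <- build_transition_matrix(net, walk_parameters(w_pp = 1, w_pf = 2))
  Tm <- as.matrix(op$T)
  dimnames(Tm) <- list(op$nodes, op$nodes)
  expect_equal(Tm["P", "Q"], 1 / 3)
  expect_equal(Tm["P", "F"], 2 / 3)
  expect_equal(unname(Matrix::rowSums(op$T)[match("P", op$nodes)]), 1)
})

test_that("function rows split between parent and child under equal weights", {
  net <- multiscale_network(
    hierarchy = data.frame(from = c("F", "H"), to = c("G", "F"))
  )
  op <- build_transition_matrix(
    net, walk_parameters(w_up = 1, w_down = 1, w_fp = 0))
  Tm <- as.matrix(op$T)
  dimnames(Tm) <- list(op$nodes, op$nodes)
  expect_equal(Tm["F", "G"], 1 / 2)
  expect_equal(Tm["F", "H"], 1 / 2)
})

test_that("zeroing cross-layer weights reduces to a plain PPI walk", {
  net <- random_msnet(12, 5, seed = 5)
  params <- walk_parameters(w_pf = 0, w_fp = 0, w_up = 0, w_down = 0)
  op <- build_transition_matrix(net, params)
  # oracle: operator on the PPI subgraph alone
  ppi_only <- multiscale_network(ppi = network_edges(net, "ppi"))
  op_ppi <- build_transition_matrix(ppi_only, walk_parameters())
  prot <- op_ppi$nodes
  sub <- as.matrix(op$T)[match(prot, op$nodes), match(prot, op$nodes)]
  expect_equal(unname(sub), unname(as.matrix(op_ppi$T)), tolerance = 1e-12)
})

test_that("alpha = 1 returns the seed distribution exactly", {
  net <- tiny_network()
  seeds <- seed_set(c("A", "C"))
  prof <- compute_diffusion_profile(net, seeds,
                                    walk_parameters(restart_probability = 1))
  expect_identical(unname(prof$freq[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(prof$freq), 1)
})

test_that("single-node network concentrates all mass on that node", {
  net <- multiscale_network(proteins = "only")
  prof <- compute_diffusion_profile(net, seed_set("only"),
                                    walk_parameters(restart_probability = 0.3))
  expect_equal(unname(prof$freq["only"]), 1)
})

test_that("power iteration matches the dense closed-form solve", {
  for (seed in 1:8) {
    net <- random_msnet(sample(5:14, 1), sample(0:5, 1), seed = seed)
    params <- walk_parameters(restart_probability = 0.17, tolerance = 1e-12)
    op <- build_transition_matrix(net, params)
    seeds <- seed_set(sample(network_proteins(net), 2))
    prof <- compute_diffusion_profile(net, seeds, params, operator = op)
    s <- seed_vector_for(net, seeds)
    oracle <- rwr_dense_oracle(op, s, 0.17)
    expect_lt(max(abs(prof$freq - oracle)), 1e-8)
    expect_lt(abs(sum(prof$freq) - 1), 1e-9)
  }
})

test_that("dangling nodes restart to the seeds and conserve mass", {
  net <- multiscale_network(ppi = data.frame(from = "A", to = "B"),
                            proteins = c("Z"))
  params <- walk_parameters(restart_probability = 0.2)
  prof <- compute_diffusion_profile(net, seed_set("Z"), params)
  expect_equal(sum(prof$freq), 1, tolerance = 1e-9)
  # Z only restarts to itself, so it keeps all mass
  expect_equal(unname(prof$freq["Z"]), 1, tolerance = 1e-9)
})

test_that("restart pull is monotone: larger alpha moves r closer to s", {
  net <- random_msnet(10, 4, seed = 9)
  seeds <- seed_set(network_proteins(net)[1:2])
  s <- seed_vector_for(net, seeds)
  dist <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(a) {
    prof <- compute_diffusion_profile(net, seeds,
                                      walk_parameters(restart_probability = a))
    sum(abs(prof$freq - s))
  }, numeric(1))
  expect_true(all(diff(dist) < 0))
})

test_that("profiles are equivariant under node relabeling", {
  net <- random_msnet(10, 4, seed = 13)
  params <- walk_parameters()
  seeds_ids <- network_proteins(net)[c(1, 4)]
  prof <- compute_diffusion_profile(net, seed_set(seeds_ids), params)

  ren <- function(x) paste0("N", x, "X")
  e <- net$edges
  net2 <- multiscale_network(
    ppi = data.frame(from = ren(e$from[e$layer == "ppi"]),
                     to = ren(e$to[e$layer == "ppi"])),
    annotation = data.frame(from = ren(e$from[e$layer == "annotation"]),
                            to = ren(e$to[e$layer == "annotation"])),
    hierarchy = data.frame(from = ren(e$from[e$layer == "hierarchy"]),
                           to = ren(e$to[e$layer == "hierarchy"])),
    proteins = ren(network_proteins(net)), functions = ren(network_functions(net))
  )
  prof2 <- compute_diffusion_profile(net2, seed_set(ren(seeds_ids)), params)
  expect_equal(unname(prof2$freq[ren(names(prof$freq))]),
               unname(prof$freq), tolerance = 1e-12)
})

test_that("seed nodes retain at least alpha times their seed mass", {
  net <- random_msnet(12, 4, seed = 21)
  alpha <- 0.17
  seeds <- seed_set(network_proteins(net)[1:3])
  prof <- compute_diffusion_profile(
    net, seeds, walk_parameters(restart_probability = alpha))
  expect_true(all(prof$freq[names(seeds)] >= alpha * as.numeric(seeds) - 1e-12))
  expect_true(all(prof$freq[names(seeds)] > 0))
})

test_that("seed sets disjoint from the network raise an error listing ids", {
  net <- tiny_network()
  expect_error(compute_diffusion_profile(net, seed_set(c("q1", "q2"))),
               "q1, q2")
})

test_that("top_mass_fraction sums the k largest frequencies", {
  net <- multiscale_network(proteins = sprintf("n%02d", 1:10))
  prof <- compute_diffusion_profile(
    net, seed_set(sprintf("n%02d", 1:10)),
    walk_parameters(restart_probability = 1))
  expect_equal(top_mass_fraction(prof, 5), 0.5)
  expect_equal(top_mass_fraction(prof, 99), 1.0)

  # random profile: brute-force sort-and-sum oracle
  withr::with_seed(3, {
    f <- runif(length(prof$freq))
    prof$freq[] <- f / sum(f)
  })
  expect_equal(top_mass_fraction(prof, 4),
               sum(sort(prof$freq, decreasing = TRUE)[1:4]))
})

test_that("non-convergence carries the residual in the error", {
  net <- random_msnet(10, 3, seed = 2)
  params <- walk_parameters(restart_probability = 0.01, tolerance = 1e-15,
                            max_iterations = 3L)
  expect_error(
    compute_diffusion_profile(net, seed_set(network_proteins(net)[1]), params),
    "failed to converge"
  )
})

test_that("profile TSV serialization writes frequencies and metadata sidecar", {
  net <- tiny_network()
  prof <- compute_diffusion_profile(net, seed_set("A"), walk_parameters())
  d <- withr::local_tempdir()
  p <- file.path(d, "prof.tsv")
  write_profile(prof, p)
  tab <- read.table(p, sep = "\t")
  expect_equal(nrow(tab), length(prof$freq))
  expect_equal(sum(tab$V2), 1, tolerance = 1e-9)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$restart_probability, 0.17)
})
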