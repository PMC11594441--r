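make_profile <- function(freq) {
  structure(list(freq = freq, seeds = seed_set(names(freq)[1]),
                 params = walk_parameters(), iterations = 0L, residual = 0),
            class = "diffusion_profile")
}

test_that("correlation score is 1 for identical profiles and errors on zero variance", {
  f <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(correlation_score(make_profile(f), make_profile(f)), 1.0)
  uni <- c(a = 1 / 3, b = 1 / 3, c = 1 / 3)
  expect_error(correlation_score(make_profile(uni), make_profile(f)),
               "zero variance")
})

test_that("correlation matches the direct covariance formula on toy vectors", {
  a <- c(n1 = 0.40, n2 = 0.25, n3 = 0.15, n4 = 0.12, n5 = 0.08)
  b <- c(n1 = 0.35, n2 = 0.10, n3 = 0.30, n4 = 0.05, n5 = 0.20)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlation_score(make_profile(a), make_profile(b)), hand)
})

test_that("profiles over different universes align on the union with zeros", {
  a <- c(x = 0.6, y = 0.4)
  b <- c(y = 0.5, z = 0.5)
  av <- c(0.6, 0.4, 0); bv <- c(0, 0.5, 0.5)
  expect_equal(correlation_score(make_profile(a), make_profile(b)),
               cor(av, bv))
})

test_that("hypergeometric overlap reproduces exact combinatorial values", {
  expect_equal(hypergeometric_overlap(0, 5, 10, 100), 1.0)
  expect_equal(hypergeometric_overlap(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeometric_overlap(2, 10, 10, 100),
               hyper_upper_bruteforce(2, 10, 10, 100))
  expect_error(hypergeometric_overlap(6, 5, 10, 100), "infeasible")
})

test_that("upper tail is monotone non-increasing in k and consistent with enrichment", {
  N <- 60; K <- 12; n <- 15
  p <- vapply(0:min(n, K), function(k) hypergeometric_overlap(k, n, K, N),
              numeric(1))
  expect_true(all(diff(p) <= 1e-15))
  for (k in 0:min(n, K)) {
    e <- enrichment_value(k, n, K, N)
    expect_equal(e > 1, (k / n) > (K / N))
  }
})

test_that("enrichment value is the overlap fraction over the background fraction", {
  expect_equal(enrichment_value(5, 50, 10, 100), 1.0)
  expect_equal(enrichment_value(0, 50, 10, 100), 0.0)
  # cross-row consistency: the background fraction implied by one printed
  # row (overlap 5/50 at fold enrichment 118.36) reproduces the other rows
  p0 <- (5 / 50) / 118.36
  expect_equal(round(enrichment_value(4, 50, background_fraction = p0), 2), 94.69)
  expect_equal(round(enrichment_value(4, 48, background_fraction = p0), 2), 98.63)
  expect_equal(round(enrichment_value(3, 31, background_fraction = p0), 2), 114.54)
  expect_equal(round(enrichment_value(3, 30, background_fraction = p0), 2), 118.36)
})

test_that("a non-significant entity is never prioritized regardless of score", {
  net <- random_msnet(20, 5, seed = 31)
  prots <- network_proteins(net)
  disease <- disease_context("D", prots[1:4], population_size = 20L)
  params <- walk_parameters()
  dis_prof <- compute_diffusion_profile(net, seed_set(prots[1:4]), params)
  prof <- compute_diffusion_profile(net, seed_set(prots[5]), params)
  rec <- rank_entities(list(E1 = prof), list(E1 = prots[5]), disease, dis_prof)
  expect_false(rec$prioritized)
  expect_gte(rec$hypergeom_p, 0.05)
})

test_that("herb-level prioritization requires enough significant ingredients", {
  net <- random_msnet(20, 5, seed = 32)
  prots <- network_proteins(net)
  disease <- disease_context("D", prots[1:4], population_size = 20L)
  params <- walk_parameters()
  dis_prof <- compute_diffusion_profile(net, seed_set(prots[1:4]), params)
  prof <- compute_diffusion_profile(net, seed_set(prots[1:4]), params)
  # overlap 4/4 against K=4, N=20: p = 1/C(20,4) < 0.05, enrichment = 5
  rec4 <- rank_entities(list(H = prof), list(H = prots[1:4]), disease,
                        dis_prof,
                        significant_ingredient_counts = c(H = 4L))
  rec5 <- rank_entities(list(H = prof), list(H = prots[1:4]), disease,
                        dis_prof,
                        significant_ingredient_counts = c(H = 5L))
  expect_lt(rec4$hypergeom_p, 0.05)
  expect_false(rec4$prioritized)
  expect_true(rec5$prioritized)
})

test_that("ranking output is invariant to entity input order", {
  net <- random_msnet(15, 5, seed = 33)
  prots <- network_proteins(net)
  disease <- disease_context("D", prots[1:3], population_size = 15L)
  params <- walk_parameters()
  dis_prof <- compute_diffusion_profile(net, seed_set(prots[1:3]), params)
  profs <- compute_diffusion_profiles(
    net, list(E1 = seed_set(prots[2]), E2 = seed_set(prots[7]),
              E3 = seed_set(prots[10])), params)
  tsets <- list(E1 = prots[2], E2 = prots[7], E3 = prots[10])
  r1 <- rank_entities(profs, tsets, disease, dis_prof)
  r2 <- rank_entities(rev(profs), rev(tsets), disease, dis_prof)
  expect_identical(r1, r2)
})

test_that("core targets count herbs through full ingredient target sets", {
  cat <- herb_catalog(
    data.frame(herb = c("H1", "H2", "H3", "H3"),
               ingredient = c("a", "b", "c", "d")),
    data.frame(ingredient = c("a", "b", "c", "d"),
               target = c("P1", "P1", "P1", "P2"))
  )
  ct <- core_targets(cat, c("H1", "H2", "H3"), min_herbs = 3)
  expect_equal(ct$target, "P1")
  expect_equal(ct$n_herbs, 3L)
  all_t <- core_targets(cat, c("H1", "H2", "H3"), min_herbs = 1)
  expect_setequal(all_t$target, c("P1", "P2"))
})

test_that("core targets equal brute-force membership counting on random catalogs", {
  withr::with_seed(44, {
    hi <- data.frame(herb = rep(sprintf("H%d", 1:6), each = 3),
                     ingredient = sprintf("i%02d", 1:18))
    it <- data.frame(ingredient = sample(hi$ingredient, 60, replace = TRUE),
                     target = sample(sprintf("P%02d", 1:12), 60, replace = TRUE))
    cat <- herb_catalog(hi, it)
    herbs <- sprintf("H%d", 1:6)
    ct <- core_targets(cat, herbs, min_herbs = 2)
    for (p in sprintf("P%02d", 1:12)) {
      n_hit <- sum(vapply(herbs, function(h) p %in% herb_targets(cat, h),
                          logical(1)))
      if (n_hit >= 2) {
        expect_true(p %in% ct$target)
        expect_equal(ct$n_herbs[ct$target == p], n_hit)
      } else {
        expect_false(p %in% ct$target)
      }
    }
  })
})
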