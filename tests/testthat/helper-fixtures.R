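# Hand-built 5-protein / 3-function interactome used across module tests.
tiny_network <- function() {
  multiscale_network(
    ppi = data.frame(from = c("A", "A", "B", "C"),
                     to = c("B", "C", "C", "D")),
    annotation = data.frame(from = c("A", "B", "D"),
                            to = c("F1", "F1", "F2")),
    hierarchy = data.frame(from = c("F1", "F2"), to = c("F3", "F3")),
    proteins = "E"
  )
}

tiny_catalog <- function() {
  herb_catalog(
    herb_ingredient = data.frame(
      herb = c("H1", "H1", "H1", "H2", "H2", "H3"),
      ingredient = c("i1", "i2", "i3", "i4", "i5", "i6")
    ),
    ingredient_target = data.frame(
      ingredient = c("i1", "i1", "i2", "i3", "i4", "i6"),
      target = c("A", "B", "B", "C", "A", "D")
    )
  )
}

# Random multiscale network independent of the package's generator; used as
# input for diffusion oracle checks.
random_msnet <- function(n_prot, n_fun, p_edge = 0.15, seed = 1L) {
  withr::with_seed(seed, {
    prots <- sprintf("p%02d", seq_len(n_prot))
    funs <- if (n_fun > 0L) sprintf("f%02d", seq_len(n_fun)) else character()
    pairs <- t(combn(prots, 2))
    keep <- runif(nrow(pairs)) < p_edge
    ppi <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
    ann <- NULL
    hier <- NULL
    if (n_fun > 0L) {
      ann <- data.frame(from = sample(prots, max(1L, n_prot), replace = TRUE),
                        to = sample(funs, max(1L, n_prot), replace = TRUE))
      if (n_fun >= 2L) {
        parent <- vapply(2:n_fun, function(i) sample.int(i - 1L, 1L),
                         integer(1))
        hier <- data.frame(from = funs[2:n_fun], to = funs[parent])
      }
    }
    multiscale_network(ppi = ppi, annotation = ann, hierarchy = hier,
                       proteins = prots, functions = funs)
  })
}

# Dense closed-form RWR solve: r = alpha (I - (1-alpha) T_eff')^{-1} s with
# dangling rows of T replaced by the seed distribution. Independent of the
# package's power iteration.
rwr_dense_oracle <- function(operator, s, alpha) {
  Tm <- as.matrix(operator$T)
  if (any(operator$dangling))
    Tm[operator$dangling, ] <- matrix(s, nrow = sum(operator$dangling),
                                      ncol = length(s), byrow = TRUE)
  n <- length(s)
  as.vector(alpha * solve(diag(n) - (1 - alpha) * t(Tm), s))
}

seed_vector_for <- function(net, seeds) {
  ids <- net$nodes$id
  s <- stats::setNames(numeric(length(ids)), ids)
  s[names(seeds)] <- as.numeric(seeds)
  s
}

# Brute-force upper-tail hypergeometric by explicit pmf summation.
hyper_upper_bruteforce <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
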