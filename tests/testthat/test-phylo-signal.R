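test_that("phylogenetic covariance equals shared root-to-tip path lengths", {
  C <- phylo_vcv(balanced4())
  expected <- matrix(c(2, 1, 0, 0,
                       1, 2, 0, 0,
                       0, 0, 2, 1,
                       0, 0, 1, 2), 4, 4,
                     dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_equal(C, expected)

  st <- star_tree(4, depth = 1)
  expect_equal(unname(phylo_vcv(st)), diag(4))
  tr <- simulate_tree(12, seed = 3)
  expect_equal(diag(phylo_vcv(tr)),
               setNames(ape::node.depth.edgelength(tr)[1:12], tr$tip.label))
})

test_that("K matches the explicit-inverse oracle on the balanced 4-tip tree", {
  tr <- balanced4()
  C <- phylo_vcv(tr)
  suppressWarnings({
    expect_equal(blomberg_k(c(A = 0, B = 0, C = 10, D = 10), tr)$estimate,
                 1.8, tolerance = 1e-10)
    expect_equal(blomberg_k(c(A = 0, B = 10, C = 0, D = 10), tr)$estimate,
                 0.6, tolerance = 1e-10)
    expect_equal(k_oracle(c(0, 0, 10, 10), C), 1.8, tolerance = 1e-12)
    expect_equal(k_oracle(c(0, 10, 0, 10), C), 0.6, tolerance = 1e-12)
  })
})

test_that("K equals the oracle on random small trees", {
  for (seed in 1:5) {
    tr <- simulate_tree(8, seed = seed)
    x <- simulate_traits(tr, "bm", seed = seed + 100)[, 1]
    suppressWarnings(
      expect_equal(blomberg_k(x, tr)$estimate,
                   k_oracle(unname(x), phylo_vcv(tr)), tolerance = 1e-10))
  }
})

test_that("K is exactly 1 on an equal-depth star tree", {
  st <- star_tree(16, depth = 3)
  set.seed(4)
  for (i in 1:3) {
    x <- setNames(rnorm(16), st$tip.label)
    suppressWarnings(expect_equal(blomberg_k(x, st)$estimate, 1,
                                  tolerance = 1e-10))
  }
})

test_that("K is invariant to affine transforms of the trait", {
  tr <- simulate_tree(40, seed = 8)
  x <- simulate_traits(tr, "bm", seed = 9)[, 1]
  k0 <- blomberg_k(x, tr)$estimate
  expect_equal(blomberg_k(3.2 * x + 17, tr)$estimate, k0, tolerance = 1e-12)
  expect_equal(blomberg_k(-x, tr)$estimate, k0, tolerance = 1e-12)
})

test_that("degenerate traits and bad input are rejected", {
  tr <- simulate_tree(10, seed = 1)
  x <- setNames(rep(1, 10), tr$tip.label)
  expect_error(suppressWarnings(blomberg_k(x, tr)), "degenerate")
  y <- setNames(rnorm(9), tr$tip.label[1:9])
  expect_error(blomberg_k(y, tr), "missing")
})

test_that("zero standard errors reduce the error-aware K to the plain K", {
  tr <- simulate_tree(30, seed = 2)
  x <- simulate_traits(tr, "bm", seed = 5)[, 1]
  se0 <- setNames(rep(0, 30), names(x))
  expect_equal(blomberg_k(x, tr, se0)$estimate, blomberg_k(x, tr)$estimate)
})

test_that("error-aware K agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(60, seed = 13)
  x <- simulate_traits(tr, "bm", seed = 14)[, 1]
  se <- setNames(rep(0.4, 60), names(x))
  ours <- blomberg_k(x, tr, se)
  ph <- phytools::phylosig(tr, x, method = "K", se = se)
  expect_equal(ours$estimate, as.numeric(ph$K), tolerance = 0.01)
  expect_equal(blomberg_k(x, tr)$estimate,
               as.numeric(phytools::phylosig(tr, x, method = "K")),
               tolerance = 1e-8)
})

test_that("accounting for observation noise pulls K back toward 1 under BM", {
  tr <- simulate_tree(80, seed = 21)
  noise_sd <- 1
  set.seed(22)
  n_rep <- 60
  naive <- aware <- numeric(n_rep)
  X <- simulate_traits(tr, "bm", sigma2 = 1, n_traits = n_rep, seed = 23)
  for (i in seq_len(n_rep)) {
    x <- X[, i] + rnorm(80, 0, noise_sd)
    se <- setNames(rep(noise_sd, 80), rownames(X))
    naive[i] <- blomberg_k(x, tr)$estimate
    aware[i] <- tryCatch(blomberg_k(x, tr, se)$estimate, error = function(e) NA)
  }
  expect_lt(mean(naive), 0.9) # noise dilutes the naive K
  expect_gt(mean(aware, na.rm = TRUE), mean(naive)) # correction recovers it
  expect_equal(mean(aware, na.rm = TRUE), 1, tolerance = 0.2)
})

test_that("tip randomization flags clade-structured traits as significant", {
  tr <- simulate_tree(64, seed = 31)
  # strongly clustered: a genuine clade of 15-30 tips shifted far from the rest
  parts <- ape::prop.part(tr)
  sizes <- lengths(parts)
  node <- which(sizes >= 15 & sizes <= 30)[1]
  clade <- attr(parts, "labels")[parts[[node]]]
  set.seed(32)
  x <- setNames(rnorm(64, 0, 0.2), tr$tip.label)
  x[clade] <- x[clade] + 10
  res <- permutation_test(x, tr, n_perm = 500, seed = 99)
  expect_true(res$significant)
  expect_gt(res$estimate, res$perm_quantiles[2])
  expect_equal(res$perm_count, 500L)

  # identical seed, identical permutation distribution
  res2 <- permutation_test(x, tr, n_perm = 500, seed = 99)
  expect_identical(res$permutations, res2$permutations)

  expect_error(permutation_test(x, tr, n_perm = 0), "n_perm")
})

test_that("value-se pairs are shuffled jointly in the permutation test", {
  tr <- simulate_tree(24, seed = 41)
  x <- simulate_traits(tr, "bm", seed = 42)[, 1]
  se <- setNames(runif(24, 0.05, 0.3), names(x))
  res <- permutation_test(x, tr, se = se, n_perm = 100, seed = 7)
  expect_true(res$se_used)
  expect_length(res$permutations, 100)
  expect_true(all(is.finite(res$permutations)))
})
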