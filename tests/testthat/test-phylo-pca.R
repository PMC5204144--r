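test_that("standardization gives mean-zero unit-variance columns", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  rownames(X) <- paste0("g", 1:3)
  Z <- standardize_traits(X)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(Z), c(a = 0, b = 0))
  expect_equal(apply(Z, 2, sd), c(a = 1, b = 1))
  # idempotence
  expect_equal(standardize_traits(Z), Z, ignore_attr = TRUE)
  X[, 2] <- 5
  expect_error(standardize_traits(X), "constant")
  X[1, 1] <- NA
  expect_error(standardize_traits(X), "missing")
})

test_that("PPCA with C = I reproduces ordinary PCA", {
  set.seed(1)
  n <- 25
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("g", 1:n), paste0("t", 1:4)))
  Z <- standardize_traits(X)
  st <- star_tree(n, depth = 1)
  st$tip.label <- rownames(Z)
  fit <- ppca(Z, tree = st)
  ref <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  expect_equal(fit$eigenvalues, unname(ref$sdev^2), tolerance = 1e-10)
  # loadings agree up to the fixed sign convention
  for (j in 1:4) {
    v <- ref$rotation[, j]
    k <- which.max(abs(v))
    if (v[k] < 0) v <- -v
    expect_equal(unname(fit$loadings[, j]), unname(v), tolerance = 1e-10)
  }
})

test_that("variance proportions sum to one and loadings are orthonormal", {
  tr <- simulate_tree(40, seed = 12)
  X <- simulate_traits(tr, "bm", n_traits = 5, seed = 13)
  fit <- ppca(standardize_traits(X), tree = tr)
  expect_equal(sum(fit$proportion_variance), 1, tolerance = 1e-10)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_equal(crossprod(fit$loadings), diag(5), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("two proportional traits load entirely on the first axis", {
  tr <- simulate_tree(30, seed = 14)
  x <- simulate_traits(tr, "bm", seed = 15)[, 1]
  X <- cbind(t1 = x, t2 = 2 * x)
  fit <- ppca(standardize_traits(X), tree = tr)
  expect_equal(fit$proportion_variance[1], 1, tolerance = 1e-10)
})

test_that("the 4-genus 2-trait instance matches an explicit-inverse oracle", {
  tr <- balanced4()
  C <- phylo_vcv(tr)
  Z <- cbind(t1 = c(-1.2, -0.4, 0.4, 1.2), t2 = c(0.5, -0.5, -1, 1))
  rownames(Z) <- LETTERS[1:4]
  invC <- solve(C)
  ones <- rep(1, 4)
  a <- drop(t(ones) %*% invC %*% Z) / drop(t(ones) %*% invC %*% ones)
  Zc <- sweep(Z, 2, a)
  S <- t(Zc) %*% invC %*% Zc / 3
  fit <- ppca(Z, tree = tr)
  expect_equal(fit$evolutionary_covariance, S, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(fit$eigenvalues, eigen(S, symmetric = TRUE)$values,
               tolerance = 1e-12)
})

test_that("PPCA agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(35, seed = 16)
  X <- simulate_traits(tr, "bm", n_traits = 4, seed = 17)
  Z <- standardize_traits(X)
  fit <- ppca(Z, tree = tr)
  ph <- phytools::phyl.pca(tr, Z, method = "BM", mode = "cov")
  expect_equal(fit$eigenvalues, unname(diag(ph$Eval)), tolerance = 1e-6)
  for (j in 1:4) {
    expect_equal(abs(unname(fit$loadings[, j])),
                 abs(unname(ph$Evec[, j])), tolerance = 1e-6)
  }
})

test_that("ppca rejects more traits than taxa and unknown genera", {
  tr <- balanced4()
  Z <- matrix(rnorm(20), 4, 5, dimnames = list(LETTERS[1:4], paste0("t", 1:5)))
  expect_error(ppca(Z, tree = tr), "more traits")
  Z2 <- matrix(rnorm(8), 4, 2, dimnames = list(c("A", "B", "C", "X"), c("t1", "t2")))
  expect_error(ppca(Z2, tree = tr), "absent")
})
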