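# Phylogenetic signal statistics.
#
# Blomberg's K compares the observed ratio of trait variance (ignoring the
# tree) to GLS variance (weighting by the phylogenetic covariance C) against
# the same ratio expected under Brownian motion on that tree; K = 1 under
# BM, K -> 0 as trait values become independent of phylogeny. The
# error-aware variant absorbs per-tip measurement error (intrageneric
# standard errors) into the working covariance. Pagel's lambda rescales the
# off-diagonal of C and is estimated by maximum likelihood.

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared root-to-tip path length of tips i and j; the
#' diagonal holds root-to-tip distances. Under Brownian motion trait
#' covariance is proportional to C.
#'
#' @param tree rooted `phylo` with positive branch lengths, unique tips.
#' @return tip-labelled n x n matrix in tree tip order.
#' @export
phylo_vcv <- function(tree) {
  check_tree(tree)
  ape::vcv.phylo(tree)
}

# Precompute the pieces of the K statistic for a fixed working covariance.
k_prepare <- function(C) {
  R <- tryCatch(chol(C), error = function(e) abort("singular covariance matrix"))
  invC <- chol2inv(R)
  n <- nrow(C)
  sum_inv <- sum(invC)
  list(
    invC = invC, n = n, sum_inv = sum_inv,
    expected = (sum(diag(C)) - n / sum_inv) / (n - 1),
    logdet = 2 * sum(log(diag(R)))
  )
}

# K for one trait vector or the columns of a matrix, given k_prepare() output.
k_statistic <- function(X, prep) {
  X <- as.matrix(X)
  A <- prep$invC %*% X
  a <- colSums(A) / prep$sum_inv
  R <- sweep(X, 2, a)
  mse0 <- colSums(R^2)
  mse <- colSums(R * (prep$invC %*% R))
  unname((mse0 / mse) / prep$expected)
}

match_tips <- function(x, tree, what = "trait") {
  tips <- tree$tip.label
  if (is.null(names(x))) {
    if (length(x) != length(tips)) {
      abort(sprintf("unnamed %s vector must have one value per tip", what))
    }
    names(x) <- tips
    return(x)
  }
  missing <- setdiff(tips, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s values missing for tip(s): %s", what,
                  paste(head(missing, 5), collapse = ", ")))
  }
  x[tips]
}

new_signal_result <- function(statistic_name, estimate, sigma2, se_used, n_tips,
                              ...) {
  structure(
    c(list(statistic_name = statistic_name, estimate = estimate,
           sigma2 = sigma2, se_used = se_used, n_tips = n_tips), list(...)),
    class = "phylodem_signal"
  )
}

#' @export
print.phylodem_signal <- function(x, ...) {
  cat(sprintf("<phylodem_signal> %s = %.4f (n_tips = %d, sigma2 = %.4g%s)\n",
              x$statistic_name, x$estimate, x$n_tips, x$sigma2,
              if (isTRUE(x$se_used)) ", with tip SE" else ""))
  if (!is.null(x$significant)) {
    cat(sprintf("  permutations: %d, 2.5-97.5%% band [%.4f, %.4f], significant: %s\n",
                x$perm_count, x$perm_quantiles[1], x$perm_quantiles[2],
                x$significant))
  }
  if (!is.null(x$log_likelihood)) {
    cat(sprintf("  logLik = %.4f, lambda_max = %.4f, LRT p (vs lambda = 0) = %.4g\n",
                x$log_likelihood, x$lambda_max, x$lrt_p))
  }
  invisible(x)
}

# Gaussian log-likelihood of x under N(a1, sigma2*C + D), a profiled by GLS.
gls_loglik <- function(x, C, D, sigma2) {
  V <- sigma2 * C
  if (!is.null(D)) V <- V + D
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  invV <- chol2inv(R)
  a <- sum(invV %*% x) / sum(invV)
  r <- x - a
  -0.5 * (drop(crossprod(r, invV %*% r)) + 2 * sum(log(diag(R))) +
            length(x) * log(2 * pi))
}

#' Blomberg's K, optionally accounting for per-tip standard errors
#'
#' Without `se`, K is the classic GLS formulation on C. With `se`
#' (intrageneric standard errors), the Brownian rate sigma^2 is estimated by
#' maximum likelihood under covariance `sigma2 * C + diag(se^2)` and K is
#' computed on the working covariance `C + diag(se^2) / sigma2_hat`, which
#' discounts tips whose values are poorly estimated.
#'
#' @param x named trait vector (names = tip labels) or unnamed vector in
#'   tip order.
#' @param tree rooted `phylo` with branch lengths.
#' @param se optional per-tip standard errors (named like `x`); zeros
#'   allowed.
#' @return a `phylodem_signal` object (statistic `"K"`).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' blomberg_k(c(A = 0, B = 0, C = 10, D = 10), tr)
#' @export
blomberg_k <- function(x, tree, se = NULL) {
  C <- phylo_vcv(tree)
  x <- match_tips(x, tree)
  n <- length(x)
  if (n < 4) warn("fewer than 4 tips: K is unreliable")
  else if (n < 20) warn("fewer than 20 tips: K has low power")
  if (var(x) == 0) abort("degenerate trait: all tip values identical")

  if (is.null(se)) {
    prep <- k_prepare(C)
    K <- k_statistic(x, prep)
    a <- sum(prep$invC %*% x) / prep$sum_inv
    r <- x - a
    sigma2 <- drop(crossprod(r, prep$invC %*% r)) / (n - 1)
    return(new_signal_result("K", K, sigma2, FALSE, n))
  }

  se <- match_tips(se, tree, "se")
  if (any(!is.finite(se)) || any(se < 0)) abort("se must be finite and >= 0")
  if (all(se == 0)) return(blomberg_k(x, tree))
  D <- diag(se^2, n)
  # ML for sigma2 on the log scale; bracket spans far below/above the naive
  # GLS rate so the optimum is interior unless the signal is degenerate
  prep0 <- k_prepare(C)
  a0 <- sum(prep0$invC %*% x) / prep0$sum_inv
  s2_naive <- max(drop(crossprod(x - a0, prep0$invC %*% (x - a0))) / n, 1e-12)
  obj <- function(ls2) -gls_loglik(x, C, D, exp(ls2))
  opt <- optimize(obj, log(s2_naive) + c(-18, 6), tol = 1e-9)
  sigma2 <- exp(opt$minimum)
  if (sigma2 < 1e-10 * s2_naive || sigma2 < 1e-14) {
    abort("signal indistinguishable from noise: sigma2 MLE at zero")
  }
  C_star <- C + D / sigma2
  K <- k_statistic(x, k_prepare(C_star))
  new_signal_result("K", K, sigma2, TRUE, n,
                    log_likelihood_sigma2 = -opt$objective)
}

#' Tip-randomization significance test for Blomberg's K
#'
#' Shuffles trait values (jointly with their standard errors, which belong
#' to the same genus) across the tips of the tree `n_perm` times, recomputes
#' K each time, and flags the observed K as significant when it falls
#' outside the 2.5-97.5 percentile band of the permuted values.
#'
#' @inheritParams blomberg_k
#' @param n_perm number of tip randomizations (>= 100; 1000 is standard).
#' @param seed integer seed; drawn and recorded if missing.
#' @return a `phylodem_signal` with `significant`, `perm_quantiles`,
#'   `p_value`, `perm_count`, `seed` and the permuted K values.
#' @export
permutation_test <- function(x, tree, se = NULL, n_perm = 1000, seed = NULL) {
  if (!is.numeric(n_perm) || n_perm < 100) abort("n_perm must be >= 100")
  n_perm <- as.integer(n_perm)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  observed <- blomberg_k(x, tree, se)
  x <- match_tips(x, tree)
  n <- length(x)

  set.seed(seed)
  if (is.null(se)) {
    prep <- k_prepare(phylo_vcv(tree))
    P <- replicate(n_perm, x[sample.int(n)])
    perm_k <- k_statistic(P, prep)
  } else {
    se <- match_tips(se, tree, "se")
    perm_k <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      blomberg_k(setNames(x[idx], names(x)), tree,
                 setNames(se[idx], names(se)))$estimate
    }, numeric(1))
  }
  band <- unname(quantile(perm_k, c(0.025, 0.975), type = 7))
  p_two <- 2 * min((1 + sum(perm_k >= observed$estimate)) / (n_perm + 1),
                   (1 + sum(perm_k <= observed$estimate)) / (n_perm + 1))
  new_signal_result(
    "K", observed$estimate, observed$sigma2, observed$se_used, n,
    perm_count = n_perm, perm_quantiles = band,
    significant = observed$estimate < band[1] | observed$estimate > band[2],
    p_value = min(p_two, 1), seed = seed, permutations = perm_k
  )
}

# lambda transform: scale off-diagonal entries of C, keep the diagonal
lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# largest lambda keeping C(lambda) positive definite, by bisection on a
# Cholesky test; capped at `upper` (well beyond the Brownian value of 1)
lambda_upper_bound <- function(C, upper = 4, tol = 1e-6) {
  pd <- function(l) !is.null(tryCatch(chol(lambda_transform(C, l)),
                                      error = function(e) NULL))
  if (pd(upper)) return(upper)
  lo <- 0
  hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pd(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Pagel's lambda by maximum likelihood
#'
#' Multiplies the off-diagonal of C by lambda (diagonal unchanged) and
#' maximizes the Gaussian likelihood jointly over lambda and the Brownian
#' rate sigma^2. lambda = 1 recovers Brownian motion, lambda = 0 a star-like
#' absence of covariance; the search runs over [0, lambda_max] where
#' lambda_max is the largest value keeping C(lambda) positive definite
#' (computed, not assumed to be 1). A likelihood-ratio test against
#' lambda = 0 is reported.
#'
#' @inheritParams blomberg_k
#' @return a `phylodem_signal` (statistic `"lambda"`) with
#'   `log_likelihood`, `lambda_max`, `lrt_stat` and `lrt_p`.
#' @export
pagel_lambda <- function(x, tree, se = NULL) {
  C <- phylo_vcv(tree)
  x <- match_tips(x, tree)
  n <- length(x)
  if (var(x) == 0) abort("degenerate trait: all tip values identical")
  D <- NULL
  if (!is.null(se)) {
    se <- match_tips(se, tree, "se")
    if (any(!is.finite(se)) || any(se < 0)) abort("se must be finite and >= 0")
    if (any(se > 0)) D <- diag(se^2, n)
  }
  lam_max <- lambda_upper_bound(C)

  profile <- function(lambda) {
    Cl <- lambda_transform(C, lambda)
    if (is.null(D)) {
      # closed-form ML rate given lambda
      prep <- tryCatch(k_prepare(Cl), error = function(e) NULL)
      if (is.null(prep)) return(list(ll = -Inf, sigma2 = NA_real_))
      a <- sum(prep$invC %*% x) / prep$sum_inv
      r <- x - a
      q <- drop(crossprod(r, prep$invC %*% r))
      s2 <- q / n
      list(ll = -0.5 * (n * log(s2) + prep$logdet + n + n * log(2 * pi)),
           sigma2 = s2)
    } else {
      obj <- function(ls2) -gls_loglik(x, Cl, D, exp(ls2))
      opt <- optimize(obj, c(-25, 15), tol = 1e-8)
      list(ll = -opt$objective, sigma2 = exp(opt$minimum))
    }
  }

  opt <- optimize(function(l) -profile(l)$ll, c(0, lam_max), tol = 1e-6)
  if (!is.finite(opt$objective)) {
    abort(sprintf("lambda optimization failed on [0, %.4f]", lam_max))
  }
  # optimize() never evaluates the interval ends: check them explicitly
  cand <- c(opt$minimum, 0, lam_max)
  lls <- c(-opt$objective, profile(0)$ll, profile(lam_max)$ll)
  best <- which.max(lls)
  lambda_hat <- cand[best]
  at_best <- profile(lambda_hat)
  ll0 <- lls[2]
  lrt <- max(2 * (at_best$ll - ll0), 0)
  new_signal_result(
    "lambda", lambda_hat, at_best$sigma2, !is.null(D), n,
    log_likelihood = at_best$ll, lambda_max = lam_max,
    lrt_stat = lrt, lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  )
}
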