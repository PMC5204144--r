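# Phylogenetic principal component analysis.
#
# Ordinary PCA of a genus x trait matrix treats genera as independent; a
# phylogenetic PCA replaces the sample covariance with the evolutionary
# covariance, computed GLS-style with the phylogenetic covariance C, so
# trait correlations induced purely by shared ancestry do not masquerade as
# functional axes.

#' Standardize trait columns to mean zero, unit variance
#'
#' Uses ordinary (non-phylogenetic) column means and sample standard
#' deviations, so every trait contributes equally to the subsequent PPCA.
#'
#' @param X numeric genus x trait matrix (rownames = genera), complete cases
#'   only.
#' @return standardized matrix.
#' @export
standardize_traits <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) abort("trait matrix has missing cells; keep complete-trait genera only")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant trait column: %s",
                  paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Phylogenetic PCA
#'
#' Computes the GLS (phylogenetic) mean vector
#' \eqn{a = (1' C^{-1} 1)^{-1} 1' C^{-1} Z}, the evolutionary covariance
#' \eqn{S = (Z - 1a)' C^{-1} (Z - 1a) / (n - 1)}, and its eigendecomposition.
#' Scores are \eqn{(Z - 1a) V}. Each loading column is flipped so its
#' largest-magnitude element is positive, for deterministic output.
#'
#' @param Z genus x trait matrix (typically from [standardize_traits()]),
#'   rownames matching the tips of `tree`.
#' @param tree rooted `phylo`; alternatively pass a precomputed covariance
#'   via `C`.
#' @param C optional phylogenetic covariance matrix overriding `tree`.
#' @return a `phylodem_ppca` object: `loadings`, `scores`, `eigenvalues`,
#'   `proportion_variance`, `n_genera`, `traits_used`.
#' @export
ppca <- function(Z, tree = NULL, C = NULL) {
  Z <- as.matrix(Z)
  if (is.null(C)) {
    if (is.null(tree)) abort("supply `tree` or `C`")
    C <- phylo_vcv(tree)
  }
  if (is.null(rownames(Z))) abort("Z needs rownames (genera)")
  missing <- setdiff(rownames(Z), rownames(C))
  if (length(missing) > 0) {
    abort(sprintf("genera absent from the phylogeny: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  C <- C[rownames(Z), rownames(Z)]
  n <- nrow(Z)
  p <- ncol(Z)
  if (p > n) abort("more traits than genera")
  invC <- tryCatch(chol2inv(chol(C)), error = function(e) abort("singular covariance matrix"))
  ones <- rep(1, n)
  a <- drop(crossprod(ones, invC %*% Z)) / sum(invC)
  Zc <- sweep(Z, 2, a)
  S <- crossprod(Zc, invC %*% Zc) / (n - 1)
  eig <- eigen(S, symmetric = TRUE)
  V <- eig$vectors
  # deterministic sign: largest-|.| element of each column positive
  for (j in seq_len(p)) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  ev <- pmax(eig$values, 0)
  dimnames(V) <- list(colnames(Z), paste0("PPCA", seq_len(p)))
  scores <- Zc %*% V
  structure(
    list(loadings = V, scores = scores, eigenvalues = ev,
         proportion_variance = ev / sum(ev), n_genera = n,
         traits_used = colnames(Z), phylo_mean = a,
         evolutionary_covariance = S),
    class = "phylodem_ppca"
  )
}

#' @export
print.phylodem_ppca <- function(x, ...) {
  cat(sprintf("<phylodem_ppca> %d genera, %d traits\n", x$n_genera,
              length(x$traits_used)))
  pv <- round(100 * x$proportion_variance, 1)
  cat("  % variance:", paste(pv, collapse = ", "), "\n")
  cat("  traits:", paste(x$traits_used, collapse = ", "), "\n")
  invisible(x)
}
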