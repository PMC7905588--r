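#' Canonical correlation analysis of two variable blocks
#'
#' Classical CCA implemented from the covariance algebra: blocks are z-scored,
#' and the canonical correlations are the singular values of the whitened
#' cross-covariance \eqn{\Sigma_{xx}^{-1/2} \Sigma_{xy} \Sigma_{yy}^{-1/2}}.
#' Canonical variates are normalized to unit sample variance.  The sign of
#' each dimension is fixed so that the largest-magnitude structure loading of
#' the X-block variate is positive (the paired Y-variate is flipped together
#' with it, so correlations stay non-negative).
#'
#' Intended use here: X = tongue colour parameters, Y = pulse sphygmogram
#' parameters of the same subjects, to quantify the overall tongue-pulse
#' association in a study group.
#'
#' @param X,Y numeric matrices or data.frames with the same number of rows
#'   (subjects); no constant columns; requires `nrow > ncol(X) + ncol(Y)`.
#' @return an object of class `cca_result` with components
#'   `cor` (canonical correlations, descending, in `[0, 1]`),
#'   `x_coef`, `y_coef` (variate coefficient matrices on the standardized
#'   scale), `x_loadings`, `y_loadings` (per-variable correlations with the
#'   own-block variates), `wilks`, `chisq`, `df`, `p_value` (Bartlett test per
#'   dimension), and `n`, `p`, `q`, `x_names`, `y_names`.
#' @export
fit_cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.numeric(X) || !is.numeric(Y)) stop("blocks must be numeric")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n <= p + q) {
    stop(sprintf("need n > p + q subjects (n = %d, p = %d, q = %d)", n, p, q))
  }
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(p))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%d", seq_len(q))
  sx <- apply(X, 2L, stats::sd); sy <- apply(Y, 2L, stats::sd)
  if (any(sx == 0)) stop("constant column(s) in X: ",
                         paste(colnames(X)[sx == 0], collapse = ", "))
  if (any(sy == 0)) stop("constant column(s) in Y: ",
                         paste(colnames(Y)[sy == 0], collapse = ", "))
  Xs <- scale(X); Ys <- scale(Y)

  Sxx <- crossprod(Xs) / (n - 1)
  Syy <- crossprod(Ys) / (n - 1)
  Sxy <- crossprod(Xs, Ys) / (n - 1)

  isqrt <- function(S, block) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < max(e$values) * 1e-10) {
      stop(block, " block is (numerically) rank deficient; ",
           "remove collinear or redundant columns")
    }
    e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*%
      t(e$vectors)
  }
  Wx <- isqrt(Sxx, "X"); Wy <- isqrt(Syy, "Y")
  sv <- svd(Wx %*% Sxy %*% Wy, nu = min(p, q), nv = min(p, q))
  m <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(m)], 0), 1)

  A <- Wx %*% sv$u          # a' Sxx a = I -> unit-variance variates
  B <- Wy %*% sv$v
  U <- Xs %*% A
  V <- Ys %*% B
  xl <- stats::cor(Xs, U)
  yl <- stats::cor(Ys, V)

  for (k in seq_len(m)) {
    j <- which.max(abs(xl[, k]))
    if (xl[j, k] < 0) {
      A[, k] <- -A[, k]; B[, k] <- -B[, k]
      xl[, k] <- -xl[, k]; yl[, k] <- -yl[, k]
    }
  }
  dimnames(A) <- list(colnames(X), paste0("U", seq_len(m)))
  dimnames(B) <- list(colnames(Y), paste0("V", seq_len(m)))
  dimnames(xl) <- dimnames(A); dimnames(yl) <- dimnames(B)

  bart <- bartlett_stats(r, n, p, q)
  structure(list(cor = r, x_coef = A, y_coef = B,
                 x_loadings = xl, y_loadings = yl,
                 wilks = bart$wilks, chisq = bart$chisq, df = bart$df,
                 p_value = bart$p_value,
                 n = n, p = p, q = q,
                 x_names = colnames(X), y_names = colnames(Y)),
            class = "cca_result")
}

bartlett_stats <- function(r, n, p, q) {
  m <- length(r)
  wilks <- rev(cumprod(rev(1 - r^2)))      # Lambda_k = prod_{i>=k} (1 - r_i^2)
  scale <- n - 1 - (p + q + 1) / 2
  chisq <- -scale * log(pmax(wilks, .Machine$double.xmin))
  df <- (p - seq_len(m) + 1) * (q - seq_len(m) + 1)
  pval <- stats::pchisq(chisq, df, lower.tail = FALSE)
  list(wilks = wilks, chisq = chisq, df = df, p_value = pval)
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> n = %d, p = %d, q = %d\n", x$n, x$p, x$q))
  cat(sprintf("  first canonical correlation: %.3f (Bartlett p = %.4g)\n",
              x$cor[1L], x$p_value[1L]))
  invisible(x)
}

#' Structure loadings of the first canonical dimension
#'
#' The structure loading of a variable is its sample correlation with the
#' first canonical variate of its own block; these are the per-parameter
#' "canonical correlation coefficients" reported alongside a tongue-pulse
#' CCA.  Rows are sorted by absolute loading, descending.
#'
#' @param result a fitted [fit_cca()] object.
#' @param X,Y optional data blocks; if supplied, loadings are recomputed from
#'   them (columns must match the fit), otherwise the stored loadings are
#'   used.  A constant column yields an `NA` loading with a warning.
#' @param dimension canonical dimension to report (default 1).
#' @return data.frame with columns `variable`, `block`, `loading`, `rank`.
#' @export
structure_loadings <- function(result, X = NULL, Y = NULL, dimension = 1L) {
  stopifnot(inherits(result, "cca_result"))
  k <- as.integer(dimension)
  stopifnot(k >= 1L, k <= length(result$cor))
  if (!is.null(X) && !is.null(Y)) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    U <- scale(X) %*% result$x_coef[, k]
    V <- scale(Y) %*% result$y_coef[, k]
    xl <- suppressWarnings(as.numeric(stats::cor(X, U)))
    yl <- suppressWarnings(as.numeric(stats::cor(Y, V)))
    if (anyNA(c(xl, yl))) warning("constant column(s): loading undefined, reported as NA")
  } else {
    xl <- result$x_loadings[, k]
    yl <- result$y_loadings[, k]
  }
  out <- data.frame(variable = c(result$x_names, result$y_names),
                    block = rep(c("x", "y"), c(result$p, result$q)),
                    loading = c(xl, yl))
  out <- out[order(-abs(out$loading)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Significance of canonical dimensions
#'
#' Bartlett's chi-square approximation on Wilks' lambda, applied sequentially
#' to dimensions 1..min(p, q); optionally a distribution-free permutation test
#' of the first canonical correlation (rows of Y permuted, CCA refitted).
#'
#' @param result a fitted [fit_cca()] object.
#' @param method `"bartlett"` (default) or `"permutation"`.
#' @param X,Y data blocks, required for the permutation test.
#' @param n_perm number of permutations (default 499).
#' @return for `"bartlett"`, a data.frame with one row per dimension
#'   (`dimension`, `cor`, `wilks`, `chisq`, `df`, `p_value`); for
#'   `"permutation"`, a one-row data.frame (`cor`, `p_value`, `n_perm`).
#' @export
cca_significance <- function(result, method = c("bartlett", "permutation"),
                             X = NULL, Y = NULL, n_perm = 499L) {
  stopifnot(inherits(result, "cca_result"))
  method <- match.arg(method)
  if (result$n <= result$p + result$q) stop("n too small for significance test")
  if (method == "bartlett") {
    m <- length(result$cor)
    return(data.frame(dimension = seq_len(m), cor = result$cor,
                      wilks = result$wilks, chisq = result$chisq,
                      df = result$df, p_value = result$p_value))
  }
  if (is.null(X) || is.null(Y)) stop("permutation test requires X and Y")
  X <- as.matrix(X); Y <- as.matrix(Y)
  obs <- result$cor[1L]
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(Y))
    rb <- fit_cca(X, Y[perm, , drop = FALSE])$cor[1L]
    if (rb >= obs) exceed <- exceed + 1L
  }
  data.frame(cor = obs, p_value = (1 + exceed) / (n_perm + 1),
             n_perm = n_perm)
}
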