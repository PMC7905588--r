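# Independent brute-force oracle for cohesion / contraction / IMC, coded on
# plain adjacency matrices with a hand-rolled BFS (no igraph, no package
# internals), used to cross-check the implementation.

oracle_bfs_dist <- function(A) {
  n <- nrow(A)
  A <- A > 0
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  visited <- diag(TRUE, n)
  frontier <- diag(TRUE, n)
  step <- 0L
  while (any(frontier)) {
    step <- step + 1L
    nxt <- (frontier %*% A) > 0
    nxt <- nxt & !visited
    if (!any(nxt)) break
    D[nxt] <- step
    visited <- visited | nxt
    frontier <- nxt
  }
  D
}

oracle_cohesion <- function(W, threshold = 0) {
  stopifnot(nrow(W) >= 2)
  deg <- rowSums(W > 0)
  str <- rowSums(W)
  s <- sum((str / deg)[deg > 0])
  D <- oracle_bfs_dist(W > threshold)
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  stopifnot(length(fin) > 0)
  1 / (s * mean(fin))
}

oracle_contract <- function(W, v) {
  nb <- which(W[v, ] > 0)
  merged <- union(v, nb)
  keep <- setdiff(seq_len(nrow(W)), setdiff(merged, v))
  vi <- match(v, keep)
  W2 <- W[keep, keep, drop = FALSE]
  for (u in setdiff(seq_along(keep), vi)) {
    W2[vi, u] <- W2[u, vi] <- sum(W[merged, keep[u]])
  }
  if (length(vi)) W2[vi, vi] <- 0
  W2
}

oracle_imc <- function(W, v, threshold = 0) {
  base <- oracle_cohesion(W, threshold)
  W2 <- oracle_contract(W, v)
  if (nrow(W2) < 2 || all(W2 == 0)) return(1)
  1 - base / oracle_cohesion(W2, threshold)
}

# independent CCA route: generalized-eigenvalue form on plain covariance
# inverses (no whitening/SVD)
oracle_cca_cor <- function(X, Y) {
  X <- scale(as.matrix(X)); Y <- scale(as.matrix(Y))
  n <- nrow(X)
  Sxx <- crossprod(X) / (n - 1)
  Syy <- crossprod(Y) / (n - 1)
  Sxy <- crossprod(X, Y) / (n - 1)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  ev <- sort(Re(eigen(M)$values), decreasing = TRUE)
  sqrt(pmin(pmax(ev[seq_len(min(ncol(X), ncol(Y)))], 0), 1))
}
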