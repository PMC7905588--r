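# graph-construction helpers shared across test files

# conet from a weighted adjacency matrix; codes V01, V02, ... (index order ==
# lexicographic order, so oracle indices and network codes align)
net_from_adj <- function(W) {
  n <- nrow(W)
  codes <- sprintf("V%02d", seq_len(n))
  ij <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  tr <- if (nrow(ij)) data.frame(from = codes[ij[, 1L]], to = codes[ij[, 2L]],
                                 weight = W[ij]) else NULL
  conet(codes, tr)
}

adj_from_net <- function(net) {
  codes <- net$nodes$code
  W <- matrix(0, length(codes), length(codes),
              dimnames = list(codes, codes))
  if (nrow(net$triples)) {
    W[cbind(net$triples$from, net$triples$to)] <- net$triples$weight
    W[cbind(net$triples$to, net$triples$from)] <- net$triples$weight
  }
  W
}

quick_net <- function(codes, from, to, weight = 1) {
  conet(codes, data.frame(from = from, to = to, weight = weight))
}

is_connected_adj <- function(A) {
  all(is.finite(oracle_bfs_dist(A > 0)))
}

# all labeled connected graphs on n nodes (unit weights), as adjacency
# matrices; feasible up to n = 5 (<= 1024 edge subsets)
all_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    if (sum(sel) < n - 1L) next
    W <- matrix(0, n, n)
    W[pairs[sel, , drop = FALSE]] <- 1
    W <- W + t(W)
    if (is_connected_adj(W)) out[[length(out) + 1L]] <- W
  }
  out
}

# random connected weighted graph: random spanning tree + extra edges,
# integer weights in 1..9
random_connected_adj <- function(n, extra = n) {
  W <- matrix(0, n, n)
  for (i in 2:n) {
    j <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
    W[i, j] <- W[j, i] <- sample.int(9L, 1L)
  }
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2L)
    if (W[ij[1L], ij[2L]] == 0) {
      W[ij[1L], ij[2L]] <- W[ij[2L], ij[1L]] <- sample.int(9L, 1L)
    }
  }
  W
}
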