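#' Parameters for weighted network cohesion
#'
#' Cohesion of a weighted network WG is defined as
#' \deqn{\partial(WG) = 1 / (s \times l)}
#' where `s` aggregates node strengths and `l` is the average shortest hop
#' distance of the unweighted graph obtained by keeping edges above a weight
#' threshold.  Two aggregation rules for `s` are supported:
#' `"strength_over_degree"` (the default) sums each node's strength divided by
#' its number of neighbours; `"degree_weighted"` sums degree times strength.
#' The two rules coincide only on special graphs; the default follows the
#' verbal definition of `s` as the sum of per-node average strengths, the
#' alternative keeps the degree-weighted form for sensitivity checks.
#'
#' @param strength_aggregation `"strength_over_degree"` or `"degree_weighted"`.
#' @param edge_threshold minimum edge weight (strictly greater than) for an
#'   edge to enter the unweighted distance graph. Default 0: any positive
#'   co-occurrence forms an edge.
#' @param disconnected_policy how to average shortest distances when the
#'   thresholded graph is disconnected: `"finite_pairs_only"` averages over
#'   pairs with a finite distance; `"component_restricted"` averages the
#'   per-component mean distances (components of size >= 2), unweighted.
#' @return a list of class `cohesion_params`.
#' @export
cohesion_params <- function(strength_aggregation = c("strength_over_degree",
                                                     "degree_weighted"),
                            edge_threshold = 0,
                            disconnected_policy = c("finite_pairs_only",
                                                    "component_restricted")) {
  stopifnot(is.numeric(edge_threshold), edge_threshold >= 0)
  structure(list(strength_aggregation = match.arg(strength_aggregation),
                 edge_threshold = edge_threshold,
                 disconnected_policy = match.arg(disconnected_policy)),
            class = "cohesion_params")
}

#' Node strength
#'
#' Strength of a node in a weighted network: the sum of the weights of its
#' incident edges (the weighted-graph analogue of degree).  Isolated nodes
#' have strength 0.
#'
#' @param net a [conet].
#' @param v optional node code(s); default all nodes.
#' @return named numeric vector of strengths.
#' @export
node_strength <- function(net, v = NULL) {
  stopifnot(inherits(net, "conet"))
  codes <- node_codes(net)
  s <- stats::setNames(numeric(length(codes)), codes)
  if (nrow(net$triples)) {
    inc <- tapply(c(net$triples$weight, net$triples$weight),
                  c(net$triples$from, net$triples$to), sum)
    s[names(inc)] <- inc
  }
  if (is.null(v)) return(s)
  if (!all(v %in% codes)) stop("unknown node: ",
                               paste(setdiff(v, codes), collapse = ", "))
  s[v]
}

#' Node degree (number of neighbours)
#'
#' @inheritParams node_strength
#' @return named integer vector.
#' @export
node_degree <- function(net, v = NULL) {
  stopifnot(inherits(net, "conet"))
  codes <- node_codes(net)
  d <- stats::setNames(integer(length(codes)), codes)
  if (nrow(net$triples)) {
    inc <- table(c(net$triples$from, net$triples$to))
    d[names(inc)] <- as.integer(inc)
  }
  if (is.null(v)) return(d)
  if (!all(v %in% codes)) stop("unknown node: ",
                               paste(setdiff(v, codes), collapse = ", "))
  d[v]
}

# hop-distance matrix of the thresholded unweighted graph (Inf off-component)
hop_distances <- function(net, edge_threshold = 0) {
  codes <- node_codes(net)
  tr <- net$triples[net$triples$weight > edge_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(tr[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = codes))
  igraph::distances(g, weights = NA)[codes, codes, drop = FALSE]
}

#' Weighted network cohesion
#'
#' Computes \eqn{\partial(WG) = 1/(s \times l)}: the reciprocal of the product
#' of aggregate node strength `s` and average shortest unweighted distance
#' `l`.  Higher cohesion means a tighter network.  A single-node network has
#' cohesion `Inf` by convention; a network whose nodes are all isolated has no
#' defined average distance and raises an error.
#'
#' @param net a [conet].
#' @param params a [cohesion_params()] object.
#' @return a positive number, possibly `Inf`.
#' @export
cohesion <- function(net, params = cohesion_params()) {
  stopifnot(inherits(net, "conet"), inherits(params, "cohesion_params"))
  n <- nrow(net$nodes)
  if (n == 0L) stop("empty network")
  if (n == 1L) return(Inf)
  if (nrow(net$triples) == 0L) stop("network has no edges; cohesion undefined")

  str <- node_strength(net)
  deg <- node_degree(net)
  pos <- deg > 0L
  s <- switch(params$strength_aggregation,
              strength_over_degree = sum(str[pos] / deg[pos]),
              degree_weighted = sum(deg[pos] * str[pos]))

  D <- hop_distances(net, params$edge_threshold)
  off <- D[upper.tri(D)]
  fin <- off[is.finite(off)]
  if (!length(fin)) stop("all nodes isolated after thresholding; cohesion undefined")
  if (params$disconnected_policy == "finite_pairs_only") {
    l <- mean(fin)
  } else {
    tr <- net$triples[net$triples$weight > params$edge_threshold, , drop = FALSE]
    g <- igraph::graph_from_data_frame(tr[, c("from", "to")], directed = FALSE,
                                       vertices = data.frame(name = node_codes(net)))
    comp <- igraph::components(g)
    ls <- c()
    for (ci in seq_len(comp$no)) {
      members <- which(comp$membership == ci)
      if (length(members) < 2L) next
      sub <- D[members, members]
      ls <- c(ls, mean(sub[upper.tri(sub)]))
    }
    l <- mean(ls)
  }
  1 / (s * l)
}

#' Contract a node with its neighbourhood
#'
#' Node contraction merges a node `v` and all of its neighbours into a single
#' super-node (which keeps `v`'s code).  Edges from the merged set to an
#' outside node are replaced by one edge whose weight is the sum of the
#' replaced weights, so total co-occurrence mass between the merged set and
#' the rest is conserved; edges internal to the merged set vanish.
#'
#' @param net a [conet].
#' @param v node code to contract.
#' @return a [conet] with `|N(v)|` fewer nodes.
#' @export
contract_node <- function(net, v) {
  stopifnot(inherits(net, "conet"), length(v) == 1L)
  codes <- node_codes(net)
  if (!v %in% codes) stop("unknown node: ", v)
  tr <- net$triples
  nb <- unique(c(tr$to[tr$from == v], tr$from[tr$to == v]))
  merged <- c(v, nb)

  keep_nodes <- net$nodes[!net$nodes$code %in% nb, , drop = FALSE]
  if (nrow(tr)) {
    from <- ifelse(tr$from %in% merged, v, tr$from)
    to <- ifelse(tr$to %in% merged, v, tr$to)
    ok <- from != to
    if (any(ok)) {
      a <- pmin(from[ok], to[ok])
      b <- pmax(from[ok], to[ok])
      agg <- rowsum(tr$weight[ok], group = paste(a, b, sep = "\r"))
      pairs <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
      tr2 <- data.frame(from = pairs[, 1L], to = pairs[, 2L],
                        weight = as.numeric(agg))
    } else {
      tr2 <- NULL
    }
  } else {
    tr2 <- NULL
  }
  conet(keep_nodes, tr2)
}

#' Node importance by contraction (IMC)
#'
#' \deqn{IMC(V_i) = 1 - \partial(WG) / \partial(WG * V_i)}
#' where \eqn{\partial(WG * V_i)} is the cohesion of the network after
#' contracting node \eqn{V_i}.  Contracting an important hub tightens the
#' network strongly, so its post-contraction cohesion is much larger and IMC
#' approaches 1.  When contraction collapses the network to a single node (or
#' leaves no edges), the post-contraction cohesion is `Inf` and IMC = 1 by
#' the limit convention.  IMC is never greater than 1.
#'
#' @param net a [conet].
#' @param v node code.
#' @param params a [cohesion_params()].
#' @param .base optional precomputed cohesion of `net` (used by [rank_core()]
#'   to avoid recomputation).
#' @return a number <= 1.
#' @export
imc <- function(net, v, params = cohesion_params(), .base = NULL) {
  base <- if (is.null(.base)) cohesion(net, params) else .base
  cn <- contract_node(net, v)
  if (nrow(cn$nodes) < 2L || nrow(cn$triples) == 0L) return(1)
  1 - base / cohesion(cn, params)
}

#' Rank nodes by IMC and select the core set
#'
#' Evaluates IMC for every node (each contraction is applied to the original
#' network, one at a time) and ranks nodes by IMC descending, breaking ties by
#' strength descending and then by code.  The first `k` nodes form the core
#' set used to build core symptom / index networks.
#'
#' @param net a [conet].
#' @param params a [cohesion_params()].
#' @param k core size (default 10, the size of the published core tables).
#' @return a list with `table` (data.frame of class `importance_table`:
#'   `code`, `label`, `imc`, `rank`, `strength`, `degree`) and `core`
#'   (character vector of the top `min(k, n)` codes).
#' @export
rank_core <- function(net, params = cohesion_params(), k = 10L) {
  stopifnot(inherits(net, "conet"), k >= 1)
  base <- cohesion(net, params)
  codes <- node_codes(net)
  vals <- vapply(codes, function(v) imc(net, v, params, .base = base),
                 numeric(1L))
  str <- node_strength(net)
  deg <- node_degree(net)
  ord <- order(-vals, -str, codes)
  tab <- data.frame(code = codes[ord],
                    label = net$nodes$label[ord],
                    imc = unname(vals[ord]),
                    rank = seq_along(codes),
                    strength = unname(str[ord]),
                    degree = unname(deg[ord]))
  class(tab) <- c("importance_table", "data.frame")
  if (k > nrow(tab)) {
    warning(sprintf("requested core of %d nodes but network has only %d",
                    as.integer(k), nrow(tab)))
  }
  list(table = tab, core = utils::head(tab$code, min(as.integer(k), nrow(tab))))
}

#' Extract the induced core subnetwork
#'
#' Induced subgraph on the union of one or two core node sets; edges keep
#' their raw co-occurrence weights.  With two sets (e.g. core symptoms and
#' core indexes), each edge is tagged `within` or `cross` so the combined
#' symptom-index network can highlight cross-block interaction edges.
#'
#' @param net a [conet].
#' @param core character vector of node codes.
#' @param core2 optional second set of node codes.
#' @return a [conet]; with two sets its triples gain an `edge_type` column.
#' @export
extract_core_subnetwork <- function(net, core, core2 = NULL) {
  stopifnot(inherits(net, "conet"))
  all_core <- unique(c(core, core2))
  unknown <- setdiff(all_core, node_codes(net))
  if (length(unknown)) stop("unknown node: ", paste(unknown, collapse = ", "))
  nodes <- net$nodes[net$nodes$code %in% all_core, , drop = FALSE]
  tr <- net$triples[net$triples$from %in% all_core &
                      net$triples$to %in% all_core, , drop = FALSE]
  out <- conet(nodes, if (nrow(tr)) tr else NULL)
  if (!is.null(core2) && nrow(out$triples)) {
    in1 <- out$triples$from %in% core & out$triples$to %in% core
    in2 <- out$triples$from %in% core2 & out$triples$to %in% core2
    out$triples$edge_type <- ifelse(in1 | in2, "within", "cross")
  }
  out
}
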