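#' Weighted co-occurrence networks
#'
#' A `conet` stores an undirected weighted network as a node table plus a
#' triple table `[Vi, Vj, Wij]`, the representation used throughout the
#' package: nodes are symptoms or clinical indexes, and the weight of an edge
#' is the number of subjects in whom both features were abnormal
#' simultaneously.
#'
#' @param nodes data.frame with columns `code` (unique identifier), and
#'   optionally `label` (human-readable name) and `block` (`"symptom"` or
#'   `"index"`). A character vector of codes is also accepted.
#' @param triples data.frame with columns `from`, `to` (node codes) and
#'   `weight` (positive). Each unordered pair may appear once; self-loops are
#'   rejected. May have zero rows (network of isolated nodes).
#' @param integer_weights if `TRUE`, require weights to be whole numbers
#'   (co-occurrence counts).
#' @return an object of class `conet` with components `nodes` and `triples`;
#'   triples are stored canonically (`from` < `to` lexicographically, rows
#'   sorted by pair).
#' @export
conet <- function(nodes, triples = NULL, integer_weights = FALSE) {
  if (is.character(nodes)) nodes <- data.frame(code = nodes)
  stopifnot(is.data.frame(nodes), "code" %in% names(nodes))
  nodes$code <- as.character(nodes$code)
  if (anyDuplicated(nodes$code)) stop("duplicate node codes")
  if (any(!nzchar(nodes$code))) stop("empty node code")
  if (is.null(nodes$label)) nodes$label <- nodes$code
  if (is.null(nodes$block)) nodes$block <- rep(NA_character_, nrow(nodes))
  nodes <- nodes[, c("code", "label", "block")]
  rownames(nodes) <- NULL

  if (is.null(triples) || nrow(as.data.frame(triples)) == 0L) {
    triples <- data.frame(from = character(), to = character(),
                          weight = numeric())
  } else {
    triples <- as.data.frame(triples)
    stopifnot(all(c("from", "to", "weight") %in% names(triples)))
    triples$from <- as.character(triples$from)
    triples$to <- as.character(triples$to)
    triples$weight <- as.numeric(triples$weight)
    unknown <- setdiff(c(triples$from, triples$to), nodes$code)
    if (length(unknown)) {
      stop("triples reference unknown nodes: ", paste(unknown, collapse = ", "))
    }
    if (any(triples$from == triples$to)) stop("self-loops are not allowed")
    if (any(!is.finite(triples$weight)) || any(triples$weight <= 0)) {
      stop("edge weights must be positive and finite")
    }
    if (integer_weights && any(triples$weight != round(triples$weight))) {
      stop("co-occurrence weights must be whole numbers")
    }
    swap <- triples$from > triples$to
    tmp <- triples$from[swap]
    triples$from[swap] <- triples$to[swap]
    triples$to[swap] <- tmp
    key <- paste(triples$from, triples$to, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edge for pair(s): ",
                                 paste(unique(key[duplicated(key)]), collapse = "; "))
    triples <- triples[order(triples$from, triples$to),
                       c("from", "to", "weight")]
    rownames(triples) <- NULL
  }
  structure(list(nodes = nodes, triples = triples), class = "conet")
}

#' @export
print.conet <- function(x, ...) {
  cat(sprintf("<conet> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$triples)))
  if (nrow(x$triples)) {
    cat(sprintf("  weights: min %g, max %g\n",
                min(x$triples$weight), max(x$triples$weight)))
  }
  invisible(x)
}

node_codes <- function(net) net$nodes$code

#' Build a co-occurrence network from a binary subject-by-feature matrix
#'
#' For every pair of features (i, j), the edge weight Wij is the number of
#' subjects in whom both features are present (bit 1).  Pairs that never
#' co-occur are omitted; features with no co-occurrences remain as isolated
#' nodes so the node set matches the feature catalog.
#'
#' @param mat numeric or integer matrix of 0/1 values, subjects in rows,
#'   features in columns; column names are feature codes.
#' @param features optional data.frame with columns `code`, `label`, `block`
#'   giving metadata for (a superset of) the matrix columns.
#' @param blocks optional character vector: keep only features whose `block`
#'   is among these (e.g. `"symptom"`) before building the network.
#' @return a [conet] with integer edge weights.
#' @export
build_network <- function(mat, features = NULL, blocks = NULL) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("F%03d", seq_len(ncol(mat)))
  }
  if (!all(mat %in% c(0, 1))) stop("matrix must be binary (0/1)")
  storage.mode(mat) <- "integer"

  nodes <- data.frame(code = colnames(mat))
  if (!is.null(features)) {
    features <- as.data.frame(features)
    idx <- match(nodes$code, features$code)
    if ("label" %in% names(features)) nodes$label <- features$label[idx]
    if ("block" %in% names(features)) nodes$block <- features$block[idx]
  }
  if (!is.null(blocks)) {
    if (is.null(nodes$block)) stop("block filter requires feature metadata")
    keep <- nodes$block %in% blocks
    nodes <- nodes[keep, , drop = FALSE]
    mat <- mat[, keep, drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("need at least 2 features to build a network")

  cross <- crossprod(mat)              # t(X) %*% X: co-occurrence counts
  ut <- upper.tri(cross)
  w <- cross[ut]
  ij <- which(ut, arr.ind = TRUE)
  keep <- w > 0L
  triples <- data.frame(from = colnames(mat)[ij[keep, 1L]],
                        to = colnames(mat)[ij[keep, 2L]],
                        weight = as.numeric(w[keep]))
  conet(nodes, triples, integer_weights = TRUE)
}

#' Normalize co-occurrence weights into an association table
#'
#' Divides every edge weight by the network-wide maximum weight so the
#' strongest pair scores exactly 1.000 (the convention of the core-symptom
#' association tables).  Rows are sorted by normalized weight descending,
#' ties broken by raw weight then by pair code.
#'
#' @param net a [conet] with at least one edge.
#' @return data.frame of class `assoc_table` with columns `pair_a`, `pair_b`,
#'   `block_a`, `block_b`, `raw_weight`, `normalized_weight`.
#' @export
normalize_weights <- function(net) {
  stopifnot(inherits(net, "conet"))
  if (nrow(net$triples) == 0L) stop("network has no edges to normalize")
  tr <- net$triples
  blk <- stats::setNames(net$nodes$block, net$nodes$code)
  tab <- data.frame(pair_a = tr$from, pair_b = tr$to,
                    block_a = unname(blk[tr$from]),
                    block_b = unname(blk[tr$to]),
                    raw_weight = tr$weight,
                    normalized_weight = tr$weight / max(tr$weight))
  tab <- tab[order(-tab$normalized_weight, -tab$raw_weight,
                   tab$pair_a, tab$pair_b), ]
  rownames(tab) <- NULL
  class(tab) <- c("assoc_table", "data.frame")
  tab
}

#' Filter an association table
#'
#' @param tab an association table from [normalize_weights()].
#' @param mode `"threshold"` keeps pairs with normalized weight strictly
#'   greater than `value`; `"top_k"` keeps the first `value` rows of the
#'   sorted table.
#' @param value threshold in `[0, 1)` or a positive integer k.
#' @param pair_type restrict to `"within"`-block pairs (both nodes in the same
#'   block) or `"cross"`-block pairs (e.g. symptom-index), applied before the
#'   threshold / top-k selection. Requires block metadata.
#' @return the filtered association table, order preserved.
#' @export
filter_associations <- function(tab, mode = c("threshold", "top_k"), value,
                                pair_type = c("all", "within", "cross")) {
  stopifnot(inherits(tab, "data.frame"))
  mode <- match.arg(mode)
  pair_type <- match.arg(pair_type)
  if (pair_type != "all") {
    if (all(is.na(tab$block_a)) || all(is.na(tab$block_b))) {
      stop("pair_type filter requires block metadata")
    }
    same <- tab$block_a == tab$block_b
    tab <- tab[if (pair_type == "within") same else !same, , drop = FALSE]
  }
  if (mode == "threshold") {
    if (!is.numeric(value) || value < 0 || value >= 1) {
      stop("threshold must lie in [0, 1)")
    }
    out <- tab[tab$normalized_weight > value, , drop = FALSE]
  } else {
    if (!is.numeric(value) || value < 1) stop("top_k value must be >= 1")
    k <- as.integer(value)
    if (k > nrow(tab)) {
      warning(sprintf("requested top %d pairs but only %d available", k,
                      nrow(tab)))
      k <- nrow(tab)
    }
    out <- utils::head(tab, k)
  }
  rownames(out) <- NULL
  out
}

#' Write a network in Pajek .NET format
#'
#' Writes `*Vertices n` with 1-based ids and double-quoted labels (the node
#' codes), then `*Edges` lines `i j w`.  Isolated nodes are written so that
#' the vertex count matches the feature catalog.
#'
#' @param net a [conet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(net, path) {
  stopifnot(inherits(net, "conet"))
  codes <- node_codes(net)
  idx <- stats::setNames(seq_along(codes), codes)
  lines <- c(sprintf("*Vertices %d", length(codes)),
             sprintf('%d "%s"', seq_along(codes), codes))
  lines <- c(lines, "*Edges")
  if (nrow(net$triples)) {
    tr <- net$triples
    lines <- c(lines, sprintf("%d %d %s", idx[tr$from], idx[tr$to],
                              format(tr$weight, scientific = FALSE,
                                     trim = TRUE, digits = 15)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pajek .NET file
#'
#' Accepts the undirected dialect written by [write_pajek()]: a `*Vertices`
#' header, quoted vertex labels, and a single `*Edges` section.  Directed
#' `*Arcs` sections are rejected.  Parse errors name the offending line.
#'
#' @param path path to a `.net` file.
#' @return a [conet]; vertex labels become node codes.
#' @export
read_pajek <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty Pajek file: ", path)
  first <- nonblank[1L]
  m <- regmatches(lines[first],
                  regexec("^\\*[Vv]ertices[[:space:]]+([0-9]+)[[:space:]]*$",
                          lines[first]))[[1L]]
  if (length(m) != 2L) {
    stop(sprintf("line %d: expected '*Vertices n' header, got '%s'",
                 first, lines[first]))
  }
  n <- as.integer(m[2L])
  codes <- character(n)
  seen <- logical(n)
  i <- first + 1L
  section <- "vertices"
  edges <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (grepl("^\\*", ln)) {
      kw <- tolower(sub("[[:space:]].*$", "", ln))
      if (kw == "*arcs") {
        stop(sprintf("line %d: '*Arcs' section found; only undirected networks ('*Edges') are supported", i))
      }
      if (kw == "*edges") {
        section <- "edges"
        i <- i + 1L
        next
      }
      stop(sprintf("line %d: unsupported section '%s'", i, ln))
    }
    if (section == "vertices") {
      vm <- regmatches(ln, regexec('^([0-9]+)[[:space:]]+"(.*)"[[:space:]]*$', ln))[[1L]]
      if (length(vm) != 3L) {
        stop(sprintf("line %d: malformed vertex line '%s'", i, ln))
      }
      id <- as.integer(vm[2L])
      if (id < 1L || id > n) {
        stop(sprintf("line %d: vertex id %d outside 1..%d", i, id, n))
      }
      if (seen[id]) stop(sprintf("line %d: duplicate vertex id %d", i, id))
      codes[id] <- vm[3L]
      seen[id] <- TRUE
    } else {
      parts <- strsplit(ln, "[[:space:]]+")[[1L]]
      if (length(parts) < 2L || length(parts) > 3L) {
        stop(sprintf("line %d: malformed edge line '%s'", i, ln))
      }
      a <- suppressWarnings(as.integer(parts[1L]))
      b <- suppressWarnings(as.integer(parts[2L]))
      w <- if (length(parts) == 3L) suppressWarnings(as.numeric(parts[3L])) else 1
      if (is.na(a) || is.na(b) || is.na(w)) {
        stop(sprintf("line %d: malformed edge line '%s'", i, ln))
      }
      if (a < 1L || a > n || b < 1L || b > n) {
        stop(sprintf("line %d: vertex index outside 1..%d", i, n))
      }
      edges[[length(edges) + 1L]] <- c(a, b, w)
    }
    i <- i + 1L
  }
  if (!all(seen)) {
    # Pajek allows omitting vertex lines; fall back to numeric labels
    codes[!seen] <- as.character(which(!seen))
  }
  tr <- NULL
  if (length(edges)) {
    em <- do.call(rbind, edges)
    key <- paste(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    if (anyDuplicated(key)) {
      stop("duplicate edge in Pajek file for vertex pair ",
           key[duplicated(key)][1L])
    }
    tr <- data.frame(from = codes[em[, 1L]], to = codes[em[, 2L]],
                     weight = em[, 3L])
  }
  conet(codes, tr)
}
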