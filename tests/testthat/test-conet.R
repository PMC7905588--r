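test_that("edge weights count simultaneous occurrences, checked by brute force", {
  rows <- c("110", "110", "011", "111", "000")
  mat <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  colnames(mat) <- c("A", "B", "C")
  net <- build_network(mat)
  w <- function(a, b) {
    hit <- net$triples$from == min(a, b) & net$triples$to == max(a, b)
    if (any(hit)) net$triples$weight[hit] else 0
  }
  expect_equal(w("A", "B"), 3)
  expect_equal(w("B", "C"), 2)
  expect_equal(w("A", "C"), 1)
  # brute force over all pairs and subjects
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(w(colnames(mat)[i], colnames(mat)[j]),
                 sum(mat[, i] & mat[, j]))
  }
})

test_that("single-positive subjects add no edges; zero pairs are omitted; isolated nodes kept", {
  mat <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  colnames(mat) <- c("A", "B", "C")
  net <- build_network(mat)
  expect_equal(nrow(net$triples), 1L)      # only A-B co-occur (subject 3)
  expect_equal(net$triples$weight, 1)
  expect_true("C" %in% net$nodes$code)     # isolated feature kept as node
  expect_error(build_network(rbind(c(1, 2), c(0, 1))), "binary")
})

test_that("network construction is invariant to subject order and equivariant to relabeling", {
  set.seed(11)
  mat <- matrix(rbinom(300, 1, 0.4), 30, 10,
                dimnames = list(NULL, LETTERS[1:10]))
  net1 <- build_network(mat)
  net2 <- build_network(mat[sample(30), ])
  expect_identical(net1$triples, net2$triples)
  perm <- sample(10)
  net3 <- build_network(mat[, perm])
  expect_identical(net1$triples[order(net1$triples$from, net1$triples$to), ],
                   net3$triples[order(net3$triples$from, net3$triples$to), ])
})

test_that("triple invariants hold on random cohorts", {
  set.seed(12)
  for (rep in 1:5) {
    mat <- matrix(rbinom(40 * 8, 1, runif(1, 0.2, 0.6)), 40, 8,
                  dimnames = list(NULL, letters[1:8]))
    net <- build_network(mat)
    tr <- net$triples
    expect_true(all(tr$from != tr$to))
    expect_true(all(tr$weight >= 1))
    marg <- colSums(mat)
    expect_true(all(tr$weight <= pmin(marg[tr$from], marg[tr$to])))
    # conservation: total edge weight == sum over subjects of C(positives, 2)
    expect_equal(sum(tr$weight), sum(choose(rowSums(mat), 2)))
  }
})

test_that("normalization divides by the global maximum and is exactly invertible", {
  net <- quick_net(c("A", "B", "C"), c("A", "B"), c("B", "C"), c(4, 2))
  tab <- normalize_weights(net)
  expect_equal(tab$normalized_weight, c(1.0, 0.5))
  expect_equal(tab$normalized_weight * max(tab$raw_weight), tab$raw_weight)
  one <- quick_net(c("A", "B"), "A", "B", 7)
  expect_equal(normalize_weights(one)$normalized_weight, 1)
  expect_error(normalize_weights(conet(c("A", "B"))), "no edges")
})

test_that("association filtering by threshold, top-k, and pair type", {
  net <- quick_net(c("A", "B", "C", "D"),
                   c("A", "A", "B"), c("B", "C", "C"), c(10, 6, 4))
  tab <- normalize_weights(net)
  expect_equal(tab$normalized_weight, c(1.0, 0.6, 0.4))
  expect_equal(nrow(filter_associations(tab, "threshold", 0.5)), 2L)
  expect_equal(nrow(filter_associations(tab, "top_k", 2)), 2L)
  expect_warning(all6 <- filter_associations(tab, "top_k", 10), "only 3")
  expect_equal(nrow(all6), 3L)
  expect_error(filter_associations(tab, "threshold", 1.2), "\\[0, 1\\)")
  expect_error(filter_associations(tab, "top_k", 0), ">= 1")
})

test_that("cross-block filtering keeps exactly the symptom-index pairs", {
  set.seed(13)
  nodes <- data.frame(code = c(paste0("S", 1:4), paste0("I", 1:3)),
                      block = rep(c("symptom", "index"), c(4, 3)))
  mat <- matrix(rbinom(50 * 7, 1, 0.5), 50, 7,
                dimnames = list(NULL, nodes$code))
  net <- build_network(mat, features = nodes)
  tab <- normalize_weights(net)
  expect_warning(
    cross <- filter_associations(tab, "top_k", 100, pair_type = "cross"),
    "available")
  # brute-force pair-type check
  expected <- sum(xor(startsWith(tab$pair_a, "S"), startsWith(tab$pair_b, "S")))
  expect_gt(expected, 0)
  expect_equal(nrow(cross), expected)
  expect_true(all(cross$block_a != cross$block_b))
  expect_warning(
    within <- filter_associations(tab, "top_k", 100, pair_type = "within"),
    "available")
  expect_equal(nrow(within) + nrow(cross), nrow(tab))
})

test_that("sort order is strict: normalized weight, raw weight, then pair code", {
  net <- quick_net(c("B", "A", "D", "C"),
                   c("B", "A", "A"), c("D", "C", "D"), c(3, 3, 5))
  tab <- normalize_weights(net)
  expect_equal(tab$raw_weight, c(5, 3, 3))
  expect_equal(tab$pair_a[2:3], c("A", "B"))   # ties broken lexicographically
})

test_that("Pajek files round-trip exactly, including spaces in labels and isolated vertices", {
  net <- conet(c("white coating", "head ache", "lonely node"),
               data.frame(from = "white coating", to = "head ache",
                          weight = 2))
  path <- withr::local_tempfile(fileext = ".net")
  write_pajek(net, path)
  back <- read_pajek(path)
  expect_equal(back$nodes$code, net$nodes$code)
  expect_equal(back$triples, net$triples)
  # writing the reread network reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".net")
  write_pajek(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("Pajek parser rejects directed, malformed, and inconsistent files", {
  p <- withr::local_tempfile(fileext = ".net")
  writeLines(c("*Vertices 2", '1 "a"', '2 "b"', "*Arcs", "1 2 1"), p)
  expect_error(read_pajek(p), "Arcs")
  writeLines(c("*Network foo", "*Vertices 2"), p)
  expect_error(read_pajek(p), "header")
  writeLines(c("*Vertices 2", '1 "a"', '2 "b"', "*Edges", "1 3 1"), p)
  expect_error(read_pajek(p), "outside 1..2")
  writeLines(c("*Vertices 2", '1 "a"', '2 "b"', "*Edges", "1 2 1", "2 1 4"), p)
  expect_error(read_pajek(p), "duplicate edge")
  writeLines(c("*Vertices 2", '1 "a"', "oops", "*Edges"), p)
  expect_error(read_pajek(p), "line 3")
})
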