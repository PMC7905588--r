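test_that("node strength sums incident edge weights", {
  star <- quick_net(c("C", "L1", "L2", "L3"), rep("C", 3),
                    c("L1", "L2", "L3"), c(1, 2, 3))
  expect_equal(unname(node_strength(star, "C")), 6)
  iso <- conet(c("A", "B", "Z"), data.frame(from = "A", to = "B", weight = 4))
  expect_equal(unname(node_strength(iso, "Z")), 0)
  tri <- quick_net(c("A", "B", "C"), c("A", "A", "B"), c("B", "C", "C"))
  expect_equal(unname(node_strength(tri)), c(2, 2, 2))
  expect_error(node_strength(tri, "Q"), "unknown node")
})

test_that("cohesion matches hand computations", {
  # two nodes joined by weight-2 edge: s = 2 + 2, l = 1
  expect_equal(cohesion(quick_net(c("A", "B"), "A", "B", 2)), 0.25)
  # unit triangle: s = 3, l = 1
  expect_equal(cohesion(quick_net(c("A", "B", "C"), c("A", "A", "B"),
                                  c("B", "C", "C"))), 1 / 3)
  # unit path: s = 1 + 1 + 1, l = 4/3
  expect_equal(cohesion(quick_net(c("A", "B", "C"), c("A", "B"),
                                  c("B", "C"))), 0.25)
})

test_that("cohesion handles degenerate networks by convention", {
  expect_equal(cohesion(conet("A")), Inf)
  expect_error(cohesion(conet(c("A", "B"))), "no edges")
  expect_error(cohesion(conet(character(0))), "empty")
  # thresholding can isolate everything
  k2 <- quick_net(c("A", "B"), "A", "B", 2)
  expect_error(cohesion(k2, cohesion_params(edge_threshold = 5)), "isolated")
})

test_that("degree-weighted aggregation variant computes sum(degree * strength)", {
  # unit path A-B-C: degrees 1,2,1; strengths 1,2,1 -> s = 1 + 4 + 1 = 6
  path <- quick_net(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  got <- cohesion(path, cohesion_params("degree_weighted"))
  expect_equal(got, 1 / (6 * (4 / 3)))
})

test_that("contraction merges the closed neighbourhood and conserves outside mass", {
  star <- quick_net(c("C", "L1", "L2"), c("C", "C"), c("L1", "L2"))
  expect_equal(nrow(contract_node(star, "C")$nodes), 1L)
  path <- quick_net(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  expect_equal(nrow(contract_node(path, "B")$nodes), 1L)
  wp <- quick_net(c("A", "B", "C"), c("A", "B"), c("B", "C"), c(2, 5))
  got <- contract_node(wp, "A")
  expect_equal(sort(got$nodes$code), c("A", "C"))
  expect_equal(got$triples$weight, 5)
  # parallel edges into the merged set sum
  sq <- quick_net(c("A", "B", "C", "D"), c("A", "A", "B", "C"),
                  c("B", "C", "D", "D"), c(1, 2, 3, 4))
  got2 <- contract_node(sq, "A")       # merges A, B, C; D outside
  expect_equal(got2$triples$weight, 3 + 4)
  expect_error(contract_node(wp, "Q"), "unknown node")
})

test_that("IMC boundary conventions: full collapse gives 1, isolated node gives 0", {
  star <- quick_net(c("C", "L1", "L2", "L3"), rep("C", 3),
                    c("L1", "L2", "L3"))
  expect_identical(imc(star, "C"), 1)
  # an isolated node's contraction changes nothing at all
  iso <- conet(c("A", "B", "Z"), data.frame(from = "A", to = "B", weight = 1))
  expect_equal(imc(iso, "Z"), 0)
})

test_that("IMC never exceeds 1 and matches the oracle on random weighted graphs", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(3:7, 1)
    W <- random_connected_adj(n)
    net <- net_from_adj(W)
    for (v in seq_len(n)) {
      got <- imc(net, sprintf("V%02d", v))
      expect_lte(got, 1)
      expect_equal(got, oracle_imc(W, v), tolerance = 1e-12)
    }
  }
})

test_that("IMC is invariant under node relabeling and equal on automorphic nodes", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 3; W[1, 3] <- W[3, 1] <- 3
  W[2, 4] <- W[4, 2] <- 1; W[3, 4] <- W[4, 3] <- 1
  net <- net_from_adj(W)                    # nodes 2 and 3 are automorphic
  expect_equal(imc(net, "V02"), imc(net, "V03"), tolerance = 1e-12)
  # relabel: swap codes of nodes 2 and 4
  codes <- c("V01", "X", "V03", "Y")
  net2 <- conet(codes, data.frame(
    from = c("V01", "V01", "X", "V03"), to = c("X", "V03", "Y", "Y"),
    weight = c(3, 3, 1, 1)))
  expect_equal(imc(net2, "X"), imc(net, "V02"), tolerance = 1e-12)
})

test_that("in a unit star the center is at least as important as any leaf", {
  star <- quick_net(c("C", "L1", "L2", "L3", "L4"), rep("C", 4),
                    paste0("L", 1:4))
  ic <- imc(star, "C")
  for (l in paste0("L", 1:4)) expect_gte(ic, imc(star, l))
})

test_that("ranking sorts by IMC with documented tie-break and warns when k exceeds n", {
  set.seed(22)
  W <- random_connected_adj(6)
  net <- net_from_adj(W)
  rc <- rank_core(net, k = 3)
  vals <- vapply(seq_len(6), function(v) oracle_imc(W, v), numeric(1))
  str <- rowSums(W)
  ord <- order(-vals, -str, sprintf("V%02d", 1:6))
  expect_equal(rc$table$code[1:3], sprintf("V%02d", ord[1:3]))
  expect_equal(rc$core, rc$table$code[1:3])
  expect_equal(rc$table$rank, 1:6)
  expect_warning(rc_all <- rank_core(net, k = 99), "only 6")
  expect_equal(length(rc_all$core), 6L)
})

test_that("core subnetwork extraction induces the right edges and tags cross-set pairs", {
  set.seed(23)
  W <- random_connected_adj(8, extra = 12)
  net <- net_from_adj(W)
  # identity when the core is everything
  all_net <- extract_core_subnetwork(net, net$nodes$code)
  expect_equal(all_net$triples, net$triples)
  # two disjoint singletons with no connecting edge
  no_edge <- which(W == 0 & upper.tri(W), arr.ind = TRUE)[1, ]
  pair <- sprintf("V%02d", no_edge)
  got <- extract_core_subnetwork(net, pair[1], pair[2])
  expect_equal(nrow(got$nodes), 2L)
  expect_equal(nrow(got$triples), 0L)
  expect_error(extract_core_subnetwork(net, "nope"), "unknown node")
})

test_that("cross-set edge count in a combined network matches brute force", {
  set.seed(24)
  nodes <- data.frame(code = c(paste0("S", 1:6), paste0("I", 1:6)),
                      block = rep(c("symptom", "index"), each = 6))
  mat <- matrix(rbinom(80 * 12, 1, 0.35), 80, 12,
                dimnames = list(NULL, nodes$code))
  net <- build_network(mat, features = nodes)
  core_s <- paste0("S", 1:4)
  core_i <- paste0("I", 1:4)
  comb <- extract_core_subnetwork(net, core_s, core_i)
  n_cross <- sum(comb$triples$edge_type == "cross")
  # brute force: symptom-index pairs inside the union with W >= 1
  brute <- 0
  for (s in core_s) for (i in core_i) {
    if (sum(mat[, s] & mat[, i]) >= 1) brute <- brute + 1
  }
  expect_equal(n_cross, brute)
})

test_that("cohesion reduces to the unweighted reciprocal form on unit-weight graphs", {
  set.seed(25)
  for (rep in 1:5) {
    W <- random_connected_adj(6); W[W > 0] <- 1
    net <- net_from_adj(W)
    # all weights 1: every node's strength/degree ratio is 1, so s = n and
    # cohesion is 1 / (n * average shortest distance)
    D <- oracle_bfs_dist(W)
    l <- mean(D[row(D) != col(D)])
    expect_equal(cohesion(net), 1 / (6 * l), tolerance = 1e-12)
  }
})
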