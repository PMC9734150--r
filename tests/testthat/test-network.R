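path_graph <- function(n, len = 1) {
  residue_graph(data.frame(i = paste0("n", seq_len(n - 1)),
                           j = paste0("n", seq_len(n - 1) + 1),
                           length = len),
                nodes = paste0("n", seq_len(n)))
}

test_that("residue-graph construction applies contact, occupancy and correlation filters", {
  # 3 residues in permanent contact with |C| = 0.9, 0.5, 0.1
  coords <- array(0, dim = c(4, 3, 3))
  coords[, 2, 1] <- 3; coords[, 3, 1] <- 5.5
  coords[, 3, 2] <- 1
  base <- ensemble_trajectory(coords + array(rnorm(36, 0, 1e-3), dim = dim(coords)),
                              c("a", "b", "c"))
  cm <- diag(3)
  cm[1, 2] <- cm[2, 1] <- 0.9
  cm[2, 3] <- cm[3, 2] <- 0.5
  cm[1, 3] <- cm[3, 1] <- 0.1
  dccm <- correlation_matrix(cm, c("a", "b", "c"))
  g <- build_residue_graph(base, dccm, contact_cutoff = 6, occupancy_min = 0.5,
                           corr_min = 0.05)
  expect_equal(nrow(g$edges), 3L)
  len <- setNames(g$edges$length, paste(g$edges$i, g$edges$j))
  expect_equal(unname(len["a b"]), -log(0.9))
  expect_equal(unname(len["b c"]), -log(0.5))
  expect_equal(unname(len["a c"]), -log(0.1))
  expect_true(len["a b"] < len["b c"] && len["b c"] < len["a c"])

  # one separated frame breaks a occupancy_min = 1 edge
  far <- base
  far$coords[4, 3, 1] <- 50
  g2 <- build_residue_graph(far, dccm, contact_cutoff = 6, occupancy_min = 1,
                            corr_min = 0.05)
  expect_false(any(g2$edges$i == "b" & g2$edges$j == "c"))

  # corr_min floor removes the weak pair
  g3 <- build_residue_graph(base, dccm, corr_min = 0.2)
  expect_equal(nrow(g3$edges), 2L)
})

test_that("graph edges equal a brute-force recomputation on a random ensemble", {
  set.seed(19)
  cov <- network_covariance(build_toy_network(matrix(runif(36, 0, 9), ncol = 3,
                                                     dimnames = list(paste0("r", 1:12), NULL)),
                                              cutoff = 7), mode = "scalar")
  tr <- sample_ensemble(cov, 200, seed = 41)
  dc <- compute_dccm(tr, superpose = FALSE)
  g <- build_residue_graph(tr, dc, contact_cutoff = 6, occupancy_min = 0.5,
                           corr_min = 0.05)
  # oracle: direct loop over pairs and frames
  expected <- 0L
  for (i in 1:11) for (j in (i + 1):12) {
    dij <- sqrt(rowSums((tr$coords[, i, ] - tr$coords[, j, ])^2))
    if (mean(dij <= 6) >= 0.5 && abs(dc$values[i, j]) >= 0.05) {
      expected <- expected + 1L
      row <- g$edges[g$edges$i == tr$labels[i] & g$edges$j == tr$labels[j], ]
      expect_equal(nrow(row), 1L)
      expect_equal(row$length, -log(abs(dc$values[i, j])))
    }
  }
  expect_equal(nrow(g$edges), expected)
})

test_that("shortest paths take the cheaper multi-hop route and report unreachable pairs", {
  g <- residue_graph(data.frame(i = c("A", "B", "A"), j = c("B", "C", "C"),
                                length = c(1, 1, 3)))
  sp <- shortest_path(g, "A", "C")
  expect_equal(sp$path, c("A", "B", "C"))
  expect_equal(sp$length, 2)

  single <- residue_graph(data.frame(i = "A", j = "B", length = 0.7))
  expect_equal(shortest_path(single, "A", "B")$length, 0.7)

  disc <- residue_graph(data.frame(i = c("A", "C"), j = c("B", "D"),
                                   length = 1), nodes = c("A", "B", "C", "D"))
  res <- shortest_path(disc, "A", "D")
  expect_false(res$reachable)
  expect_equal(res$length, Inf)
})

test_that("Dijkstra agrees with exhaustive enumeration and igraph on random graphs", {
  set.seed(97)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    g <- random_graph(n)
    ig <- as_igraph(g)
    dmat <- igraph::distances(ig, weights = igraph::E(ig)$weight)
    mine <- allonet:::all_pairs_shortest(g)$dist
    expect_equal(unname(mine[g$nodes, g$nodes]),
                 unname(dmat[g$nodes, g$nodes]), tolerance = 1e-10)
    # spot-check one pair against the simple-path enumeration oracle
    pick <- sample(g$nodes, 2)
    expect_equal(shortest_path(g, pick[1], pick[2])$length,
                 brute_shortest(g, pick[1], pick[2]), tolerance = 1e-10)
  }
})

test_that("equal-length ties resolve to the lexicographically smallest path", {
  # two equal routes A->B->D and A->C->D
  g <- residue_graph(data.frame(i = c("A", "B", "A", "C"),
                                j = c("B", "D", "C", "D"),
                                length = 1))
  expect_equal(shortest_path(g, "A", "D")$path, c("A", "B", "D"))
  expect_equal(shortest_path(g, "D", "A")$path, c("D", "B", "A"))
})

test_that("SPM usage concentrates on bottleneck edges and normalizes to 1", {
  # P4: the middle edge serves the most pairs
  s <- compute_spm(path_graph(4))
  mid <- s$edges$usage[s$edges$i == "n2" & s$edges$j == "n3"]
  expect_equal(mid, 1)
  expect_true(all(s$edges$usage <= 1))
  expect_true(all(s$edges$usage[s$edges$i == "n1"] < 1))

  # bridge between two triangles gets usage 1
  tri <- data.frame(i = c("a1", "a1", "a2", "b1", "b1", "b2", "a3"),
                    j = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"),
                    length = 1)
  sb <- compute_spm(residue_graph(tri))
  bridge <- sb$edges$usage[sb$edges$i == "a3" & sb$edges$j == "b1"]
  expect_equal(bridge, 1)
  # oracle: the bridge carries every cross pair = 2 * 3 * 3 ordered pairs,
  # more than any intra edge can serve
  expect_true(all(sb$edges$usage[!(sb$edges$i == "a3" & sb$edges$j == "b1")] < 1))

  # threshold 0 admits every used edge
  s0 <- compute_spm(path_graph(4), threshold = 0)
  expect_true(all(s0$edges$in_spm == (s0$edges$usage > 0)))

  # edges off every shortest path have zero usage
  gx <- residue_graph(data.frame(i = c("A", "B", "A"), j = c("B", "C", "C"),
                                 length = c(1, 1, 10)))
  sx <- compute_spm(gx)
  expect_equal(sx$edges$usage[sx$edges$i == "A" & sx$edges$j == "C"], 0)
})

test_that("single-pair SPM mode traces only the first-to-last route", {
  g <- path_graph(5)
  s <- compute_spm(g, pairs = "endpoints")
  expect_true(all(s$edges$usage == 1))
})

test_that("CPL matches closed forms and the exhaustive oracle", {
  expect_equal(characteristic_path_length(path_graph(3))$cpl, 4 / 3)
  k4 <- residue_graph(data.frame(i = c("a", "a", "a", "b", "b", "c"),
                                 j = c("b", "c", "d", "c", "d", "d"),
                                 length = 1))
  expect_equal(characteristic_path_length(k4)$cpl, 1)

  set.seed(17)
  for (rep in 1:20) {
    g <- random_graph(sample(4:7, 1))
    expect_equal(characteristic_path_length(g)$cpl, brute_cpl(g), tolerance = 1e-10)
  }
})

test_that("scaling all edge lengths scales CPL but leaves the SPM ranking alone", {
  set.seed(3)
  g <- random_graph(7)
  g2 <- g
  g2$edges$length <- g$edges$length * 4.2
  expect_equal(characteristic_path_length(g2)$cpl,
               4.2 * characteristic_path_length(g)$cpl, tolerance = 1e-9)
  expect_equal(compute_spm(g2)$edges$usage, compute_spm(g)$edges$usage)
  # triangle property on sampled triples
  d <- allonet:::all_pairs_shortest(g)$dist
  for (rep in 1:20) {
    abc <- sample(g$nodes, 3)
    expect_lte(d[abc[1], abc[3]], d[abc[1], abc[2]] + d[abc[2], abc[3]] + 1e-12)
  }
})

test_that("node weakening ranks, flags disconnections, and matches recomputation", {
  star <- residue_graph(data.frame(i = "hub", j = paste0("leaf", 1:4), length = 1))
  nw <- node_weakening(star, candidates = "hub")
  expect_true(nw$table$disconnects[1])
  expect_true(is.na(nw$table$cpl_without[1]))

  p4 <- path_graph(4)
  nw2 <- node_weakening(p4)
  row_n2 <- nw2$table[nw2$table$node == "n2", ]
  expect_true(row_n2$disconnects)
  # remainder n1 | n3-n4: only reachable pair n3-n4 at length 1
  expect_equal(row_n2$cpl_without, 1)

  # removing a node used by no shortest path leaves CPL untouched
  gx <- residue_graph(data.frame(i = c("A", "B", "A", "A"),
                                 j = c("B", "C", "C", "X"),
                                 length = c(1, 1, 10, 20)))
  # X is a pendant; its removal changes only pairs through X
  nwx <- node_weakening(gx, candidates = "X")
  base_abc <- characteristic_path_length(residue_graph(
    data.frame(i = c("A", "B", "A"), j = c("B", "C", "C"), length = c(1, 1, 10))))$cpl
  expect_equal(nwx$table$cpl_without[1], base_abc)

  # oracle recomputation on random graphs
  set.seed(31)
  for (rep in 1:5) {
    g <- random_graph(6)
    nw3 <- node_weakening(g)
    for (r in seq_len(nrow(nw3$table))) {
      if (!nw3$table$disconnects[r] || !is.na(nw3$table$cpl_without[r])) {
        g2 <- allonet:::drop_node(g, nw3$table$node[r])
        if (nrow(g2$edges)) {
          expect_equal(nw3$table$cpl_without[r], brute_cpl(g2), tolerance = 1e-10)
        }
      }
    }
    expect_true(all(diff(abs(nw3$table$delta_cpl[!is.na(nw3$table$delta_cpl)])) <= 1e-12))
  }
})

test_that("regulator binding recruits inter-subunit edges into the SPM", {
  nets <- dimer_pair()
  cov_a <- network_covariance(nets$apo, mode = "scalar")
  cov_b <- network_covariance(nets$bound, mode = "scalar")
  tr_a <- sample_ensemble(cov_a, 5000, seed = 61)
  tr_b <- sample_ensemble(cov_b, 5000, seed = 62)
  g_a <- build_residue_graph(tr_a, compute_dccm(tr_a, superpose = FALSE))
  g_b <- build_residue_graph(tr_b, compute_dccm(tr_b, superpose = FALSE))
  expect_gt(count_cross_spm(g_b), count_cross_spm(g_a))
})
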