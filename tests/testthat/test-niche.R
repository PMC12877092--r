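# Spot labeling, lattice adjacency, neighbor-pair profiles, similarity and
# temporal alignment.

test_that("spots are labeled by argmax with flagged ties", {
  ab <- abundance_matrix(matrix(c(0.7, 0.2, 0.1,
                                  0.5, 0.5, 0.0,
                                  0.1, 0.3, 0.6), 3, 3, byrow = TRUE,
                                dimnames = list(c("s1", "s2", "s3"),
                                                c("T1", "T2", "T3"))))
  lab <- label_spots(ab)
  expect_equal(unname(lab$labels), c("T1", "T1", "T3"))
  expect_equal(unname(lab$tie_flag), c(FALSE, TRUE, FALSE))
  lab_last <- label_spots(ab, tie_rule = "last")
  expect_equal(unname(lab_last$labels[2]), "T2")
})

test_that("labeling equals an independent per-row maximum scan", {
  set.seed(21)
  v <- matrix(runif(60), 20, 3,
              dimnames = list(sprintf("s%d", 1:20), c("A", "B", "C")))
  lab <- label_spots(abundance_matrix(v))
  manual <- character(20)
  for (i in 1:20) {
    best <- 1
    for (j in 2:3) if (v[i, j] > v[i, best]) best <- j
    manual[i] <- colnames(v)[best]
  }
  expect_equal(unname(lab$labels), manual)
})

test_that("all-zero spots become unassigned and leave pair counting", {
  v <- matrix(c(1, 0, 0, 0, 0, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("T1", "T2")))
  expect_message(lab <- label_spots(abundance_matrix(v)), "unassigned")
  expect_equal(unname(lab$labels[2]), "unassigned")
  grid <- build_adjacency(make_line_grid(3))
  grid$spots <- c("a", "b", "c")
  names(lab$labels) <- names(lab$tie_flag) <- c("a", "b", "c")
  expect_warning(pp <- count_neighbor_pairs(grid, lab), "no adjacency edges")
  # both edges touch the unassigned middle spot
  expect_equal(pp$n_edges, 0)
  expect_equal(pp$n_excluded, 2L)
  expect_true(all(pp$freq == 0))
})

test_that("hex adjacency has degree 6 at the center and 1 edge for a pair", {
  g <- build_adjacency(hex_grid_for_tests(1))
  expect_equal(nrow(g$adjacency), 12)   # 6 center spokes + 6 ring edges
  two <- build_adjacency(spot_grid(c("a", "b"), c(0L, 0L), c(0L, 1L),
                                   c(0, 1), c(0, 0)))
  expect_equal(nrow(two$adjacency), 1)
  expect_error(build_adjacency(spot_grid(c("a", "b"), c(0L, 0L), c(0L, 0L),
                                         c(1, 1), c(1, 1))),
               class = "mbstage_geometry_error")
})

test_that("adjacency on jittered lattices equals the all-pairs oracle", {
  set.seed(31)
  for (rep in 1:5) {
    grid <- random_jittered_grid(sample(2:3, 1))
    got <- build_adjacency(grid)$adjacency
    want <- oracle_adjacency(grid)
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
})

test_that("pair counting matches hand enumeration on a chain", {
  grid <- build_adjacency(make_line_grid(3))
  lab <- make_labeling(stats::setNames(c("A", "B", "A"), grid$spots),
                       types = c("A", "B"))
  pp <- count_neighbor_pairs(grid, lab)
  expect_equal(pp$pair_counts["A", "B"], 2)
  expect_equal(unname(pp$freq["A|B"]), 1)
  expect_equal(pp$n_edges, 2)
})

test_that("homogeneous labels put all mass on the diagonal pair", {
  grid <- build_adjacency(hex_grid_for_tests(2))
  lab <- make_labeling(stats::setNames(rep("A", length(grid$spots)),
                                       grid$spots), types = c("A", "B"))
  pp <- count_neighbor_pairs(grid, lab)
  expect_equal(unname(pp$pair_counts["A", "A"]), nrow(grid$adjacency))
  expect_equal(unname(pp$freq["A|A"]), 1)
})

test_that("pair counting conserves edges on random grids", {
  set.seed(41)
  for (rep in 1:10) {
    grid <- build_adjacency(random_jittered_grid(sample(2:4, 1)))
    labels <- sample(c("A", "B", "C", "unassigned"), length(grid$spots),
                     replace = TRUE, prob = c(1, 1, 1, 0.2))
    lab <- make_labeling(stats::setNames(labels, grid$spots),
                         types = c("A", "B", "C"))
    pp <- count_neighbor_pairs(grid, lab)
    expect_identical(pp$n_edges + pp$n_excluded, nrow(grid$adjacency))
    ut <- upper.tri(pp$pair_counts, diag = TRUE)
    expect_equal(sum(pp$pair_counts[ut]), pp$n_edges)
  }
})

test_that("pair counts equal the brute-force oracle", {
  set.seed(51)
  for (rep in 1:8) {
    grid <- build_adjacency(random_jittered_grid(sample(2:3, 1)))
    labels <- sample(c("A", "B", "unassigned"), length(grid$spots),
                     replace = TRUE, prob = c(1, 1, 0.15))
    lab <- make_labeling(stats::setNames(labels, grid$spots),
                         types = c("A", "B"))
    got <- profile_as_keys(count_neighbor_pairs(grid, lab))
    want <- oracle_pair_counts(grid, labels)
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})

test_that("similarity follows the 1 - D/max(D) contract", {
  p1 <- make_profile(c("A|A" = 1, "A|B" = 0, "B|B" = 0), c("A", "B"))
  p2 <- make_profile(c("A|A" = 0, "A|B" = 0, "B|B" = 1), c("A", "B"))
  p3 <- make_profile(c("A|A" = 0.5, "A|B" = 0, "B|B" = 0.5), c("A", "B"))
  sim <- sample_similarity(list(s1 = p1, s2 = p2, s3 = p3))
  expect_equal(sim$D["s1", "s2"], sqrt(2))
  expect_equal(sim$S["s1", "s2"], 0)    # most dissimilar pair scores 0
  expect_true(isSymmetric(sim$S))
  expect_equal(unname(diag(sim$S)), rep(1, 3))
  expect_true(all(sim$S >= 0 & sim$S <= 1))
  expect_equal(min(sim$S[upper.tri(sim$S)]), 0)
  expect_warning(sample_similarity(list(a = p1, b = p1)), "identical")
})

test_that("similarity is invariant to spot and type reordering", {
  cfg <- synthetic_config(seed = 13, grid_radius = 4L)
  s <- generate_tissue_sample(cfg, sample_meta("t", "tissue", 11))
  g <- build_adjacency(s$grid)
  lb <- label_spots(s$abundance)
  base <- count_neighbor_pairs(g, lb)
  set.seed(1)
  ix <- sample(length(g$spots))
  g2 <- build_adjacency(spot_grid(g$spots[ix], g$array_row[ix],
                                  g$array_col[ix], g$x[ix], g$y[ix]))
  lb2 <- structure(list(labels = lb$labels[g2$spots],
                        tie_flag = lb$tie_flag[g2$spots],
                        types = rev(lb$types)),
                   class = "spot_labeling")
  shuf <- count_neighbor_pairs(g2, lb2)
  expect_identical(base$pair_counts[lb$types, lb$types],
                   shuf$pair_counts[lb$types, lb$types])
  expect_warning(sim1 <- sample_similarity(list(a = base, b = shuf)),
                 "identical")
  expect_equal(sim1$D["a", "b"], 0)
})

fake_similarity <- function(S) {
  structure(list(ids = rownames(S), S = S, D = 1 - S),
            class = "similarity_matrix")
}

test_that("temporal alignment is the similarity-weighted timepoint mean", {
  ids <- c("q", "t7", "t11", "t17")
  meta <- list(sample_meta("t7", "tissue", 7),
               sample_meta("t11", "tissue", 11),
               sample_meta("t17", "tissue", 17))
  S <- diag(4); dimnames(S) <- list(ids, ids)
  S["q", c("t7", "t11", "t17")] <- c(0, 1, 0)
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  expect_equal(temporal_alignment(fake_similarity(S), "q",
                                  meta)$estimated_timepoint, 11)
  S["q", c("t7", "t11", "t17")] <- c(0.5, 0, 0.5)
  expect_equal(temporal_alignment(fake_similarity(S), "q",
                                  meta[c(1, 3)])$estimated_timepoint, 12)
  S["q", c("t7", "t11", "t17")] <- c(0.2, 0.3, 0.5)
  al <- temporal_alignment(fake_similarity(S), "q", meta)
  expect_equal(al$estimated_timepoint, 0.2 * 7 + 0.3 * 11 + 0.5 * 17)
  expect_equal(sum(al$weights), 1)
  S["q", c("t7", "t11", "t17")] <- 0
  expect_error(temporal_alignment(fake_similarity(S), "q", meta),
               class = "mbstage_degenerate_error")
})

test_that("replicates of one timepoint average at the similarity level", {
  ids <- c("q", "t11_r1", "t11_r2", "t17_r1")
  meta <- list(sample_meta("t11_r1", "tissue", 11, replicate = "r1"),
               sample_meta("t11_r2", "tissue", 11, replicate = "r2"),
               sample_meta("t17_r1", "tissue", 17))
  S <- diag(4); dimnames(S) <- list(ids, ids)
  S["q", c("t11_r1", "t11_r2", "t17_r1")] <- c(0.8, 0.4, 0.6)
  al <- temporal_alignment(fake_similarity(S), "q", meta)
  # mean(0.8, 0.4) = 0.6 for 11 PCW, 0.6 for 17 PCW -> midpoint
  expect_equal(al$estimated_timepoint, 14)
})
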