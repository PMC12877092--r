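# Cluster-graph lineage extraction, HVG selection, PC1 pseudotime and binned
# profiles.

test_that("union kNN graphs match the brute-force oracle", {
  expect_equal(build_knn_graph(cbind(c(0, 1)), k = 1),
               matrix(c(1L, 2L), 1))
  # three collinear points, k = 1: middle connects to both ends
  e <- build_knn_graph(cbind(c(0, 1, 2)), k = 1)
  expect_equal(unname(e), rbind(c(1L, 2L), c(2L, 3L)))
  set.seed(201)
  sort_edges <- function(e) unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
  for (rep in 1:3) {
    emb <- matrix(rnorm(100 * 3), 100)
    k <- sample(2:6, 1)
    expect_equal(sort_edges(build_knn_graph(emb, k)),
                 sort_edges(oracle_knn(emb, k)))
  }
  expect_error(build_knn_graph(cbind(c(0, 1)), k = 2),
               class = "mbstage_parameter_error")
})

test_that("cluster connectivity counts inter-edges over the smaller degree", {
  # two 2-cell clusters, fully bipartite, no intra edges
  edges <- rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  cg <- cluster_connectivity(edges, c("A", "A", "B", "B"))
  expect_equal(cg$edges$weight, 1)    # 4 / min(4, 4)
  # no inter-cluster edges -> no edge entry (weight 0)
  cg0 <- cluster_connectivity(rbind(c(1, 2), c(3, 4)),
                              c("A", "A", "B", "B"))
  expect_equal(nrow(cg0$edges), 0)
  # renaming clusters leaves weights unchanged
  cg2 <- cluster_connectivity(edges, c("x2", "x2", "x1", "x1"))
  expect_equal(cg2$edges$weight, cg$edges$weight)
})

test_that("pruning keeps w = 0.05 and drops w = 0.049", {
  cg <- make_cluster_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
                                      weight = c(0.05, 0.049)))
  expect_equal(prune_and_path(cg, "a", "b")$path, c("a", "b"))
  err <- tryCatch(prune_and_path(cg, "a", "c"), error = function(e) e)
  expect_s3_class(err, "mbstage_degenerate_error")
  expect_match(conditionMessage(err), "disconnected")
  expect_match(conditionMessage(err), "component")
})

test_that("trivial and waypoint paths behave as specified", {
  cg <- make_cluster_graph(data.frame(
    from = c("r", "r", "m", "w", "m"), to = c("m", "w", "w", "e", "e"),
    weight = c(0.9, 0.9, 0.9, 0.9, 0.9)))
  expect_equal(prune_and_path(cg, "r", "r")$path, "r")
  # direct shortest path skips the waypoint; forcing it reroutes
  free <- prune_and_path(cg, "r", "e")
  forced <- prune_and_path(cg, "r", "e", waypoint = "w")
  expect_equal(length(free$path), 3)
  expect_true("w" %in% forced$path)
  expect_equal(forced$path, c("r", "w", "e"))
  expect_error(prune_and_path(cg, "r", "zz"),
               class = "mbstage_parameter_error")
})

test_that("member cells attach to the path clusters", {
  cg <- make_cluster_graph(data.frame(from = "a", to = "b", weight = 0.5))
  labels <- c("a", "b", "a", "zz")
  lp <- prune_and_path(cg, "a", "b", labels = c("a", "b", "a", "b"))
  expect_equal(nrow(lp$cells), 4)
  expect_setequal(unique(lp$cells$cluster), c("a", "b"))
})

test_that("constrained shortest paths equal the exhaustive oracle", {
  set.seed(211)
  for (rep in 1:120) {
    cg <- random_test_graph(sample(4:10, 1))
    ids <- cg$clusters$cluster
    rt <- sample(ids, 2)
    want <- oracle_best_path(cg, rt[1], rt[2])
    got <- tryCatch(prune_and_path(cg, rt[1], rt[2])$path,
                    error = function(e) NULL)
    expect_identical(got, want)
  }
})

test_that("HVG selection is intersect-within, union-across timepoints", {
  hv <- suppressWarnings(
    select_hvg(list(r1 = c("a", "b", "c"), r2 = c("b", "c", "d"),
                    r3 = c("c", "e")),
               timepoint = c("t1", "t1", "t2"), n_hvg = 3))
  expect_setequal(hv$per_timepoint$t1, c("b", "c"))
  expect_setequal(hv$per_timepoint$t2, c("c", "e"))
  expect_setequal(hv$final, c("b", "c", "e"))
  # disjoint replicate sets contribute nothing
  hv0 <- select_hvg(list(r1 = c("a", "b"), r2 = c("c", "d")),
                    timepoint = c("t1", "t1"), n_hvg = 2)
  expect_length(hv0$per_timepoint$t1, 0)
  # single replicate, single timepoint: its own set
  hv1 <- select_hvg(list(r1 = c("x", "y")), "t1", n_hvg = 2)
  expect_setequal(hv1$final, c("x", "y"))
  expect_warning(select_hvg(list(r1 = c("a", "b")), "t1", n_hvg = 5),
                 "exceeds")
})

test_that("adding a timepoint can only grow the final HVG set", {
  set.seed(221)
  for (rep in 1:5) {
    pool <- sprintf("g%02d", 1:30)
    reps <- lapply(1:6, function(i) sample(pool, 10))
    tps <- rep(c("t1", "t2", "t3"), each = 2)
    partial <- select_hvg(reps[1:4], tps[1:4], n_hvg = 10)
    full <- select_hvg(reps, tps, n_hvg = 10)
    expect_true(all(partial$final %in% full$final))
  }
})

test_that("per-replicate HVGs come from a dispersion ranking of lognorm", {
  set.seed(231)
  # gene 'hot' has inflated dispersion at a matched mean scale
  base <- matrix(rpois(50 * 20, 20), 50, 20,
                 dimnames = list(sprintf("c%d", 1:50), sprintf("g%d", 1:20)))
  base[, 1] <- rnbinom(50, mu = 20, size = 0.4)
  cm <- lognormalize(count_matrix(base))
  hv <- select_hvg(list(r1 = cm), "t1", n_hvg = 3)
  expect_true("g1" %in% hv$final)
})

test_that("PC1 pseudotime recovers a one-dimensional gradient", {
  t0 <- seq(0, 1, length.out = 30)
  ln <- cbind(g1 = 2 * t0, g2 = -t0 + 1, g3 = 0.5 * t0)
  rownames(ln) <- sprintf("c%02d", 1:30)
  cm <- cm_with_layer(ln)
  ct <- rep(c("early", "late"), each = 15)
  pt <- pc1_pseudotime(cm, colnames(ln), ct, root_cells = t0 < 0.2)
  expect_equal(cor(pt$pseudotime, t0, method = "spearman"), 1)
  expect_equal(unname(pt$pseudotime[1]), 0)
  expect_equal(unname(pt$pseudotime[30]), 1)
  # flipping the sign of every gene leaves pseudotime unchanged
  pt2 <- pc1_pseudotime(cm_with_layer(-ln), colnames(ln), ct,
                        root_cells = t0 < 0.2)
  expect_equal(pt2$pseudotime, pt$pseudotime)
  # two cleanly separated cell types along PC1 -> adjusted R^2 near 1
  sep <- rbind(matrix(0, 10, 3), matrix(5, 10, 3)) +
    matrix(rnorm(60, sd = 0.01), 20, 3)
  dimnames(sep) <- list(sprintf("s%d", 1:20), c("a", "b", "c"))
  pt3 <- pc1_pseudotime(cm_with_layer(sep), colnames(sep),
                        rep(c("T1", "T2"), each = 10),
                        root_cells = rep(c(TRUE, FALSE), each = 10))
  expect_gte(pt3$adj_r_squared, 0.99)
  ident <- matrix(1, 5, 3, dimnames = list(sprintf("i%d", 1:5),
                                           c("a", "b", "c")))
  expect_error(pc1_pseudotime(cm_with_layer(ident), c("a", "b", "c"),
                              rep("T", 5), rep(TRUE, 5)),
               class = "mbstage_degenerate_error")
})

test_that("bin profiles use equal-width bins over the trimmed range", {
  n <- 200
  pt <- seq(0, 1, length.out = n)
  ln <- cbind(up = 6 * pt, flat = rep(1, n))
  rownames(ln) <- sprintf("c%03d", seq_len(n))
  cm <- cm_with_layer(ln)
  bp <- bin_profiles(pt, cm, n_perm = 1999, seed = 1)
  edges <- attr(bp, "bin_edges")
  expect_equal(length(edges), 6)
  expect_equal(diff(edges), rep(diff(edges)[1], 5), tolerance = 1e-9)
  # trimming removes the extreme 1% on both sides
  expect_equal(attr(bp, "n_cells"), sum(pt >= quantile(pt, 0.01) &
                                        pt <= quantile(pt, 0.99)))
  up <- bp[bp$gene == "up", ]
  means <- as.numeric(up[paste0("bin", 1:5)])
  expect_true(all(diff(means) > 0))
  expect_equal(up$call, "up")
  expect_true(all(means >= min(ln[, "up"]) & means <= max(ln[, "up"])))
  expect_equal(bp[bp$gene == "flat", "call"], "none")
})

test_that("bin means match hand-computed values on ten cells", {
  pt <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85, 0.95)
  ln <- cbind(g = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  rownames(ln) <- sprintf("c%02d", 1:10)
  bp <- bin_profiles(pt, cm_with_layer(ln), trim = c(0, 100),
                     n_perm = 299, seed = 1)
  # equal-width bins over [0.05, 0.95]: two cells per bin
  expect_equal(as.numeric(bp[paste0("bin", 1:5)]),
               c(1.5, 3.5, 5.5, 7.5, 9.5))
})
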