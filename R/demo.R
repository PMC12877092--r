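# End-to-end demonstration pipeline on synthetic data plus a machine-readable
# self-check report. The demo generates tissue analogs at 7/11/17 PCW and
# three organoids interpolating them, runs every stage of the package, and
# verifies the pipeline's core contracts (oracle equivalences, similarity
# contract, alignment recovery, permutation-test calibration, ...) at a scale
# that completes in a few minutes on one CPU.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- internal brute-force oracles (independent code paths used only for
# ---- self-checks; the test suite carries its own copies) ----

brute_pair_counts <- function(grid, labels, tol = 1.05) {
  xy <- cbind(grid$x, grid$y)
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  pitch <- min(d[d > 0])
  cnt <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > tol * pitch) next
    if (labels[i] == "unassigned" || labels[j] == "unassigned") next
    key <- paste(sort(c(labels[i], labels[j])), collapse = "|")
    cnt[[key]] <- (cnt[[key]] %||% 0) + 1
  }
  unlist(cnt)
}

profile_counts_as_keys <- function(profile) {
  pc <- profile$pair_counts
  ut <- which(upper.tri(pc, diag = TRUE) & pc > 0, arr.ind = TRUE)
  if (!nrow(ut)) return(numeric(0))
  keys <- apply(ut, 1, function(ij)
    paste(sort(c(rownames(pc)[ij[1]], colnames(pc)[ij[2]])), collapse = "|"))
  stats::setNames(pc[ut], keys)
}

# DFS enumeration of all simple root->end paths, then the same tie-break
# rules prune_and_path documents (min hops, max bottleneck, lexicographic).
enum_best_path <- function(cg, root, endpoint) {
  keep <- cg$edges$weight >= cg$prune_threshold
  e <- cg$edges[keep, , drop = FALSE]
  nbrs <- function(v) {
    rows <- e$from == v | e$to == v
    data.frame(to = ifelse(e$from[rows] == v, e$to[rows], e$from[rows]),
               w = e$weight[rows])
  }
  paths <- list(); walk <- function(p, wmin) {
    v <- p[length(p)]
    if (v == endpoint) { paths[[length(paths) + 1]] <<- list(p = p, w = wmin); return() }
    nb <- nbrs(v)
    for (k in seq_len(nrow(nb))) if (!nb$to[k] %in% p)
      walk(c(p, nb$to[k]), min(wmin, nb$w[k]))
  }
  walk(root, Inf)
  if (!length(paths)) return(NULL)
  len <- vapply(paths, function(x) length(x$p), numeric(1))
  paths <- paths[len == min(len)]
  wmin <- vapply(paths, `[[`, numeric(1), "w")
  paths <- paths[wmin >= max(wmin) - 1e-12]
  keys <- vapply(paths, function(x) paste(x$p, collapse = "\r"), character(1))
  paths[[order(keys)[1]]]$p
}

random_cluster_graph <- function(n_nodes, p_edge = 0.4) {
  ids <- sprintf("k%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2))
  on <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(from = ids[pairs[on, 1]], to = ids[pairs[on, 2]],
                      weight = round(stats::runif(sum(on)), 3))
  structure(list(clusters = data.frame(cluster = ids, size = 1L,
                                       degree = NA_real_),
                 edges = edges, prune_threshold = 0.05),
            class = "cluster_graph")
}

random_labeled_grid <- function(radius, types, jitter = 0.02) {
  h <- hex_lattice(radius, "rg")
  g <- spot_grid(h$barcode, h$array_row, h$array_col,
                 h$x + stats::runif(nrow(h), -jitter, jitter),
                 h$y + stats::runif(nrow(h), -jitter, jitter))
  labels <- sample(c(types, "unassigned"), nrow(h), replace = TRUE,
                   prob = c(rep(1, length(types)), 0.15))
  labeling <- structure(list(labels = stats::setNames(labels, g$spots),
                             tie_flag = stats::setNames(
                               rep(FALSE, nrow(h)), g$spots),
                             types = types),
                        class = "spot_labeling")
  list(grid = g, labeling = labeling)
}

square_grid <- function(nr, nc) {
  rc <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  spot_grid(sprintf("sq_%d_%d", rc$row, rc$col), rc$row, rc$col,
            rc$col, rc$row)
}

# Full niche pipeline for one generated sample.
niche_profile_of <- function(sample) {
  grid <- build_adjacency(sample$grid)
  labeling <- label_spots(sample$abundance)
  count_neighbor_pairs(grid, labeling)
}

# Alignment of organoids mixing two tissues at the given alphas; returns the
# estimated PCW per alpha.
alignment_curve <- function(seed, alphas, pcw = c(11, 17), n_rep = 2) {
  cfg <- synthetic_config(seed = seed)
  tissues <- list(); metas <- list()
  for (tp in pcw) for (r in seq_len(n_rep)) {
    meta <- sample_meta(sprintf("tissue_%dpcw_r%d", tp, r), "tissue", tp,
                        replicate = sprintf("r%d", r))
    tissues[[meta$sample_id]] <- generate_tissue_sample(cfg, meta)
    metas[[meta$sample_id]] <- meta
  }
  ta <- tissues[[sprintf("tissue_%dpcw_r1", pcw[1])]]$truth
  tb <- tissues[[sprintf("tissue_%dpcw_r1", pcw[2])]]$truth
  profiles <- lapply(tissues, niche_profile_of)
  est <- vapply(alphas, function(a) {
    org <- generate_organoid_sample(
      cfg, ta, tb, a, sample_meta(sprintf("org_a%.2f", a), "organoid", 40))
    pr <- c(profiles, list(query = niche_profile_of(org)))
    names(pr)[length(pr)] <- "query"
    sim <- sample_similarity(pr)
    temporal_alignment(sim, "query", unname(metas))$estimated_timepoint
  }, numeric(1))
  stats::setNames(est, sprintf("alpha_%g", alphas))
}

#' Run the end-to-end demonstration pipeline with self-checks
#'
#' Generates three synthetic tissue sections (7/11/17 PCW analogs) and three
#' organoids interpolating them, runs every stage of the package on them
#' (niche profiling, similarity, temporal alignment, maturation-path trends,
#' Moran's I screening, lineage extraction with PC1 pseudotime, binned
#' profiles, module scoring with the resampled permutation test, pseudobulk
#' correlation), and verifies the pipeline's core contracts with independent
#' brute-force checks at a reduced simulation scale. The returned report is
#' machine-readable; pass `out` to also write it as JSON.
#'
#' @param seed Master seed.
#' @param out Optional path for the JSON report.
#' @param n_oracle_grids Random grids for the pair-counting oracle check.
#' @param n_null_sims Simulations for the permutation-null calibration
#'   checks.
#' @param n_power_sims Simulations per effect size for the power check.
#' @param n_path_graphs Random cluster graphs for the path oracle check.
#' @param quiet Suppress progress messages?
#' @return The report, invisibly: `properties` (named list of pass flags and
#'   measured numbers), `pipeline` (headline numbers of the demo run),
#'   `all_pass`, `elapsed_sec`.
#' @export
run_demo <- function(seed = 0, out = NULL, n_oracle_grids = 60,
                     n_null_sims = 200, n_power_sims = 100,
                     n_path_graphs = 100, quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  props <- list()
  seed <- as.integer(seed)

  ## ---- demo pipeline on three tissues + three organoids ----
  say("generating synthetic study (seed %d)...", seed)
  cfg <- synthetic_config(seed = seed)
  tissue_meta <- list(sample_meta("tissue_7pcw", "tissue", 7),
                      sample_meta("tissue_11pcw", "tissue", 11),
                      sample_meta("tissue_17pcw", "tissue", 17))
  tissues <- lapply(tissue_meta, function(m) generate_tissue_sample(cfg, m))
  names(tissues) <- vapply(tissue_meta, `[[`, character(1), "sample_id")
  t7 <- tissues[[1]]$truth; t11 <- tissues[[2]]$truth; t17 <- tissues[[3]]$truth
  orgs <- list(
    organoid_d40 = generate_organoid_sample(
      cfg, t7, t11, 0.9, sample_meta("organoid_d40", "organoid", 40)),
    organoid_d70 = generate_organoid_sample(
      cfg, t11, t17, 0.6, sample_meta("organoid_d70", "organoid", 70)),
    organoid_d120 = generate_organoid_sample(
      cfg, t11, t17, 0.7, sample_meta("organoid_d120", "organoid", 120)))

  say("niche profiling and temporal alignment...")
  profiles <- lapply(c(tissues, orgs), niche_profile_of)
  sim <- sample_similarity(profiles)
  alignments <- vapply(names(orgs), function(q)
    temporal_alignment(sim, q, tissue_meta)$estimated_timepoint, numeric(1))

  ## property 2: similarity contract + permutation invariance
  S <- sim$S
  off <- S[upper.tri(S)]
  shuf <- {
    smp <- tissues[[3]]
    g <- build_adjacency(smp$grid)
    lb <- label_spots(smp$abundance)
    p1 <- count_neighbor_pairs(g, lb)
    ix <- sample(length(g$spots))
    g2 <- spot_grid(g$spots[ix], g$array_row[ix], g$array_col[ix],
                    g$x[ix], g$y[ix])
    g2 <- build_adjacency(g2)
    ty <- sample(lb$types)
    lb2 <- structure(list(labels = lb$labels[g2$spots],
                          tie_flag = lb$tie_flag[g2$spots], types = ty),
                     class = "spot_labeling")
    p2 <- count_neighbor_pairs(g2, lb2)
    identical(p1$pair_counts[lb$types, lb$types],
              p2$pair_counts[lb$types, lb$types])
  }
  props$similarity_contract <- list(
    pass = isSymmetric(S) && all(diag(S) == 1) &&
      all(off >= 0 & off <= 1) && min(off) == 0 && shuf,
    min_off_diagonal = min(off))

  ## property 1: pair-count oracle equivalence on random grids
  say("pair-counting oracle check (%d grids)...", n_oracle_grids)
  set.seed(mb_seed(seed, "oracle-grids"))
  ok1 <- TRUE
  for (i in seq_len(n_oracle_grids)) {
    rg <- random_labeled_grid(sample(2:4, 1), c("A", "B", "C"))
    got <- profile_counts_as_keys(
      count_neighbor_pairs(build_adjacency(rg$grid), rg$labeling))
    want <- brute_pair_counts(rg$grid, rg$labeling$labels)
    ok1 <- ok1 && length(got) == length(want) &&
      all(sort(names(got)) == sort(names(want))) &&
      all(got[names(want)] == want)
  }
  props$pair_count_oracle <- list(pass = ok1, n_grids = n_oracle_grids)

  ## property 3: temporal-alignment recovery in mix_alpha
  say("alignment recovery across mixing weights...")
  alphas <- c(0, 0.25, 0.5, 0.75, 1)
  curves <- do.call(rbind, lapply(seed + 1:3, alignment_curve,
                                  alphas = alphas))
  # the recovery property concerns the estimator's expectation: the
  # seed-averaged curve must be nondecreasing, and every seed must order the
  # endpoints correctly (adjacent quarter-steps differ by less than the
  # profile sampling noise on a single lattice)
  mono <- all(diff(colMeans(curves)) >= -1e-9) &&
    all(curves[, 1] < curves[, ncol(curves)])
  mid <- mean(vapply(seed + 1:5, function(s)
    alignment_curve(s, 0.5)[[1]], numeric(1)))
  props$alignment_recovery <- list(
    pass = mono && abs(mid - 14) <= 1.5,
    monotone = mono, mean_estimate_alpha_half = mid,
    mean_curve = as.list(stats::setNames(colMeans(curves),
                                         colnames(curves))))

  ## property 4: Moran's I
  say("Moran's I checks (%d null simulations)...", n_null_sims)
  g22 <- build_adjacency(square_grid(2, 2))
  chk <- generate_field(g22, "checkerboard")
  I_chk <- morans_i(g22, chk, n_perm = 99, seed = seed)$I
  const_err <- inherits(tryCatch(
    morans_i(g22, generate_field(g22, "constant")),
    error = function(e) e), "mbstage_degenerate_error")
  gh <- build_adjacency(hex_grid(3, "m"))
  set.seed(mb_seed(seed, "moran-null"))
  rej <- mean(vapply(seq_len(n_null_sims), function(i)
    morans_i(gh, stats::rnorm(length(gh$spots)), n_perm = 99,
             seed = mb_seed(seed, paste0("mn", i)))$p_perm <= 0.05,
    logical(1)))
  ex_g <- build_adjacency(square_grid(1, 5))
  vals5 <- c(0.3, -1.2, 0.5, 2.1, -0.7)
  p_ex <- morans_i(ex_g, vals5, exhaustive = TRUE)$p_perm
  perms <- permutations_of(5)
  a5 <- ex_g$adjacency[, 1]; b5 <- ex_g$adjacency[, 2]
  i5 <- function(v) { z <- v - mean(v)
    (5 / (2 * nrow(ex_g$adjacency))) * 2 * sum(z[a5] * z[b5]) / sum(z^2) }
  e5 <- -1 / 4
  p_brute <- mean(abs(apply(perms, 1, function(ix) i5(vals5[ix])) - e5) >=
                  abs(i5(vals5) - e5) - 1e-12)
  props$morans_i <- list(
    pass = abs(I_chk - (-1)) < 1e-12 && const_err &&
      rej >= 0.01 && rej <= 0.09 && abs(p_ex - p_brute) < 1e-12,
    checkerboard_I = I_chk, null_rejection = rej)

  ## property 5: permutation / rank-sum exactness and calibration
  say("permutation-test checks (%d null simulations)...", n_null_sims)
  set.seed(mb_seed(seed, "perm-exact"))
  ok_ex <- TRUE
  for (na in 2:4) {
    vals <- round(stats::rnorm(8), 2)
    a <- vals[seq_len(na)]; b <- vals[(na + 1):8]
    splits <- utils::combn(8, na)
    t_obs <- abs(mean(a) - mean(b))
    t_all <- apply(splits, 2, function(ix)
      abs(mean(vals[ix]) - mean(vals[-ix])))
    want <- (1 + sum(t_all >= t_obs - 1e-12)) / (1 + ncol(splits))
    got <- perm_p_mean_diff(a, b, n_perm = 999)
    ok_ex <- ok_ex && abs(got - want) < 1e-12
  }
  rs_want <- 2 / choose(4, 2)
  rs_got <- ranksum_compare(c(1, 2), c(3, 4))
  set.seed(mb_seed(seed, "perm-null"))
  rej5 <- mean(vapply(seq_len(n_null_sims), function(i)
    perm_p_mean_diff(stats::rnorm(8), stats::rnorm(8), n_perm = 99) <= 0.05,
    logical(1)))
  power <- vapply(c(0.25, 0.5, 1), function(eff) {
    set.seed(mb_seed(seed, paste0("power", eff)))
    mean(vapply(seq_len(n_power_sims), function(i)
      perm_p_mean_diff(stats::rnorm(15), stats::rnorm(15, eff),
                       n_perm = 99) <= 0.05, logical(1)))
  }, numeric(1))
  props$permutation_tests <- list(
    pass = ok_ex && abs(rs_got - rs_want) < 1e-9 &&
      rej5 >= 0.01 && rej5 <= 0.09 && all(diff(power) >= 0),
    null_rejection = rej5, power = as.list(stats::setNames(
      power, c("eff_0.25", "eff_0.5", "eff_1"))))

  ## property 6: moving average
  ma <- moving_average(c(1, 2, 3, 4, 5), 3)
  vals_r <- stats::rnorm(40)
  sm <- moving_average(vals_r, 7)
  props$moving_average <- list(
    pass = all(abs(ma - c(1.5, 2, 3, 4, 4.5)) < 1e-12) &&
      all(abs(moving_average(vals_r, 100) - mean(vals_r)) < 1e-12) &&
      min(sm) >= min(vals_r) && max(sm) <= max(vals_r))

  ## property 7: lineage path oracle + pseudotime recovery
  say("lineage path oracle (%d graphs) and pseudotime recovery...",
      n_path_graphs)
  set.seed(mb_seed(seed, "path-graphs"))
  ok7 <- TRUE
  for (i in seq_len(n_path_graphs)) {
    cg <- random_cluster_graph(sample(4:10, 1))
    ids <- cg$clusters$cluster
    rt <- sample(ids, 2)
    want <- enum_best_path(cg, rt[1], rt[2])
    got <- tryCatch(prune_and_path(cg, rt[1], rt[2])$path,
                    error = function(e) NULL)
    ok7 <- ok7 && identical(got, want)
  }
  prune_cg <- structure(list(
    clusters = data.frame(cluster = c("a", "b", "c"), size = 1L,
                          degree = NA_real_),
    edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                       weight = c(0.05, 0.049)),
    prune_threshold = 0.05), class = "cluster_graph")
  boundary_ok <- identical(
    tryCatch(prune_and_path(prune_cg, "a", "b")$path,
             error = function(e) NULL), c("a", "b")) &&
    inherits(tryCatch(prune_and_path(prune_cg, "b", "c"),
                      error = function(e) e), "mbstage_degenerate_error")
  rho <- vapply(seed + 1:2, function(s) {
    cfg_sc <- synthetic_config(seed = s, n_cells = 800L)
    sc <- generate_single_cell_dataset(cfg_sc)
    cm <- lognormalize(sc$counts)
    reps <- split(seq_len(nrow(sc$cells)),
                  paste(sc$cells$timepoint, sc$cells$replicate))
    rep_cms <- lapply(reps, function(ix)
      lognormalize(count_matrix(cm$counts[ix, , drop = FALSE])))
    tp_of <- vapply(strsplit(names(reps), " "), `[[`, character(1), 1)
    hvg <- select_hvg(rep_cms, tp_of, n_hvg = 100)
    pt <- pc1_pseudotime(cm, hvg, sc$cells$cell_type,
                         sc$cells$cluster == "c1")
    abs(stats::cor(pt$pseudotime, sc$truth$pseudotime, method = "spearman"))
  }, numeric(1))
  props$lineage <- list(pass = ok7 && boundary_ok && all(rho >= 0.9),
                        pseudotime_spearman = mean(rho))

  ## property 8: HVG set algebra
  hv <- select_hvg(list(r1 = c("a", "b", "c"), r2 = c("b", "c", "d"),
                        r3 = c("c", "e")),
                   timepoint = c("t1", "t1", "t2"), n_hvg = 3)
  hv2 <- select_hvg(list(r1 = c("a", "b", "c"), r2 = c("b", "c", "d"),
                         r3 = c("c", "e"), r4 = c("f", "g")),
                    timepoint = c("t1", "t1", "t2", "t3"), n_hvg = 3)
  props$hvg_scheme <- list(
    pass = setequal(hv$final, c("b", "c", "e")) &&
      all(hv$final %in% hv2$final))

  ## property 9: pseudobulk correlation
  say("pseudobulk checks...")
  prof <- matrix(c(1, 2, 3, 6, 1, 2, 3, 6, 5, 4, 3, 0), 3, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), paste0("x", 1:4)))
  pb_fix <- structure(list(groups = rownames(prof), genes = colnames(prof),
                           means = prof, n_cells = c(1L, 1L, 1L),
                           layer = "lognorm"), class = "pseudobulk_table")
  r_fix <- correlation_matrix(pb_fix)
  interp_ok <- all(vapply(seed + 1:3, function(s) {
    cfg_i <- synthetic_config(seed = s)
    A <- generate_tissue_sample(cfg_i, sample_meta("A", "tissue", 7))
    C <- generate_tissue_sample(cfg_i, sample_meta("C", "tissue", 17))
    B <- generate_organoid_sample(cfg_i, A$truth, C$truth, 0.5,
                                  sample_meta("B", "organoid", 70))
    counts <- rbind(A$counts$counts, B$counts$counts, C$counts$counts)
    rownames(counts) <- sprintf("s%04d", seq_len(nrow(counts)))
    cmb <- lognormalize(count_matrix(counts))
    grp <- rep(c("A", "B", "C"), c(length(A$grid$spots),
                                   length(B$grid$spots),
                                   length(C$grid$spots)))
    r <- correlation_matrix(pseudobulk_means(cmb, grp, cmb$genes))
    r["B", "A"] > r["A", "C"] && r["B", "C"] > r["A", "C"]
  }, logical(1)))
  props$pseudobulk <- list(
    pass = abs(r_fix["g1", "g2"] - 1) < 1e-12 &&
      abs(r_fix["g1", "g3"] - (-1)) < 1e-12 && interp_ok)

  ## ---- remaining pipeline stages on the demo samples ----
  say("maturation path, Moran screening, lineage and module stages...")
  smp <- tissues$tissue_17pcw
  grid17 <- build_adjacency(smp$grid)
  cm17 <- lognormalize(smp$counts)
  poly <- cbind(c(0, 0), range(grid17$y))  # vertical line through the lattice
  path_spots <- order_spots_on_polyline(grid17, poly, radius = 1.2)
  gm <- gene_model(cfg)
  mat_gene <- gm$maturation_genes[1]
  prof_path <- path_expression_profile(cm17, path_spots, mat_gene,
                                       window = 11)
  trend <- path_trend_test(prof_path$value, seq_along(path_spots),
                           n_perm = 499, seed = seed)
  lr <- neighbor_lr_score(grid17, cm17$layers$lognorm[, gm$maturation_genes[1]],
                          cm17$layers$lognorm[, gm$maturation_genes[2]])
  maps <- cbind(lr_pair = lr,
                gradient = generate_field(grid17, "smooth_gradient"),
                noise = generate_field(grid17, "iid_noise", seed = seed + 7))
  moran_rank <- rank_pairs_by_moran(grid17, maps, n_perm = 199, seed = seed)

  sc <- generate_single_cell_dataset(synthetic_config(seed = seed,
                                                      n_cells = 800L))
  cm_sc <- lognormalize(sc$counts)
  X <- cm_sc$layers$lognorm
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  emb <- stats::prcomp(X, center = TRUE, scale. = TRUE, rank. = 10)$x
  knn <- build_knn_graph(emb, k = 10)
  cg <- cluster_connectivity(knn, sc$cells$cluster)
  lin <- prune_and_path(cg, "c1", "c5", labels = sc$cells$cluster)
  reps <- split(seq_len(nrow(sc$cells)),
                paste(sc$cells$timepoint, sc$cells$replicate))
  rep_cms <- lapply(reps, function(ix)
    lognormalize(count_matrix(cm_sc$counts[ix, , drop = FALSE])))
  hvg_sc <- select_hvg(rep_cms,
                       vapply(strsplit(names(reps), " "), `[[`,
                              character(1), 1), n_hvg = 100)
  pt <- pc1_pseudotime(cm_sc, hvg_sc, sc$cells$cell_type,
                       sc$cells$cluster == "c1")
  bins <- bin_profiles(pt$pseudotime, cm_sc,
                       c(unlist(sc$modules), sc$truth$trend_genes),
                       n_perm = 1999, seed = seed)
  mst <- activation_score(cm_sc, sc$modules, groups = sc$cells)
  perm_res <- resampled_permutation_test(mst, sc$cells$timepoint, "t1", "t2",
                                         n_perm = 499, n_resample = 25,
                                         seed = seed)
  tp_prof <- timepoint_profile(pt$pseudotime, sc$cells$timepoint)
  wilcox_p <- ranksum_compare(pt$pseudotime[sc$cells$timepoint == "t1"],
                              pt$pseudotime[sc$cells$timepoint == "t2"])

  pipeline <- list(
    alignment_pcw = as.list(alignments),
    similarity_tissue_7_vs_17 = S["tissue_7pcw", "tissue_17pcw"],
    path_trend_rho = trend$statistic,
    path_trend_p = trend$p_value,
    top_moran_map = moran_rank$pair[1],
    top_moran_I = moran_rank$I[1],
    lineage_path = paste(lin$path, collapse = "->"),
    pseudotime_adj_r_squared = pt$adj_r_squared,
    n_hvg_final = length(hvg_sc$final),
    n_genes_called = sum(bins$call != "none"),
    module_mean_p = as.list(stats::setNames(perm_res$mean_p,
                                            perm_res$module)),
    pseudotime_wilcoxon_p = wilcox_p,
    timepoint_means = as.list(stats::setNames(tp_prof$summary$mean,
                                              tp_prof$summary$group)))

  report <- list(seed = seed,
                 properties = props,
                 all_pass = all(vapply(props, `[[`, logical(1), "pass")),
                 pipeline = pipeline,
                 elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    say("report written to %s", out)
  }
  say("demo complete in %.1f s; all properties pass: %s",
      report$elapsed_sec, report$all_pass)
  invisible(report)
}
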