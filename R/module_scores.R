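# Gene-module activation scores and the resampled two-sided permutation
# comparison between cell groups, plus per-timepoint distribution summaries
# and rank-sum comparisons of pseudotime.

#' Gene-module activation scores
#'
#' The activation score of a module in a cell is the mean log-normalized
#' expression of the module's genes in that cell. Genes absent from the
#' expression matrix are dropped with a warning; modules left empty are
#' dropped with a warning.
#'
#' @param cm A [count_matrix()] with a `"lognorm"` layer.
#' @param modules Named list of gene-id vectors.
#' @param groups Optional data.frame of per-cell group labels (e.g. dataset,
#'   timepoint, cell type), one row per entity of `cm`.
#' @return An object of class `module_score_table`: `scores` (cell x module
#'   matrix), `modules` (retained gene sets), `groups`.
#' @export
activation_score <- function(cm, modules, groups = NULL) {
  if (is.null(cm$layers$lognorm))
    stop_param("lognorm layer missing; call lognormalize() first")
  if (!length(modules) || is.null(names(modules)))
    stop_param("modules must be a non-empty named list")
  if (!is.null(groups) && nrow(groups) != length(cm$entities))
    stop_validation("groups must have one row per cell")
  retained <- list()
  for (nm in names(modules)) {
    genes <- intersect(modules[[nm]], cm$genes)
    dropped <- setdiff(modules[[nm]], cm$genes)
    if (length(dropped))
      mb_warn(sprintf("module '%s': %d genes absent and dropped", nm,
                      length(dropped)))
    if (!length(genes)) {
      mb_warn(sprintf("module '%s' has no retained genes; module dropped", nm))
      next
    }
    retained[[nm]] <- genes
  }
  if (!length(retained)) stop_param("no module has retained genes")
  scores <- vapply(retained, function(genes)
    rowMeans(cm$layers$lognorm[, genes, drop = FALSE]),
    numeric(length(cm$entities)))
  scores <- matrix(scores, nrow = length(cm$entities),
                   dimnames = list(cm$entities, names(retained)))
  structure(list(scores = scores, modules = retained, groups = groups),
            class = "module_score_table")
}

# All C(n, k) splits of 1..n taking k as group A; columns are combinations.
group_splits <- function(n, k) utils::combn(n, k)

# Two-sided permutation p for |mean_a - mean_b| on pooled values.
# Exhaustive when total <= max_exhaustive; sampled otherwise. Both modes
# apply the +1 correction on numerator and denominator so p is never 0.
perm_p_mean_diff <- function(a, b, n_perm, max_exhaustive = 10) {
  # sort the pool so the permutation draw depends only on the value multiset,
  # never on which group was labeled "a"
  pooled <- sort(c(a, b))
  na <- length(a); n <- length(pooled)
  t_obs <- abs(mean(a) - mean(b))
  if (n <= max_exhaustive) {
    splits <- group_splits(n, na)
    t_perm <- apply(splits, 2, function(ix)
      abs(mean(pooled[ix]) - mean(pooled[-ix])))
    (1 + sum(t_perm >= t_obs - 1e-12)) / (1 + ncol(splits))
  } else {
    ix_mat <- vapply(seq_len(n_perm), function(i) sample.int(n, na),
                     integer(na))
    sums <- if (na > 1) colSums(matrix(pooled[ix_mat], na)) else pooled[ix_mat]
    tot <- sum(pooled)
    t_perm <- abs(sums / na - (tot - sums) / (n - na))
    (1 + sum(t_perm >= t_obs - 1e-12)) / (1 + n_perm)
  }
}

#' Resampled two-sided permutation test on module scores
#'
#' For each module, compares the activation scores of two cell groups with a
#' two-sided one-way permutation test (statistic: absolute difference of
#' group means). When group sizes differ, the larger group is subsampled
#' without replacement to the smaller group's size `n_resample` times and the
#' mean permutation p over resamples is reported; equal-sized groups use a
#' single pass. P-values are +1-corrected (never exactly 0), enumeration is
#' exhaustive when the compared cells number at most 10, and the mean p is
#' Benjamini-Hochberg-adjusted across modules. Significance tiers: `***`
#' p_adj < 0.001, `**` < 0.01, `*` < 0.05, `ns` otherwise.
#'
#' @param mst A [activation_score()] result (or a cell x module score matrix).
#' @param group Per-cell group labels (vector over cells).
#' @param group_a,group_b The two labels to compare.
#' @param n_perm Label permutations per test (default 10,000).
#' @param n_resample Resamples of the larger group (default 100).
#' @param seed RNG seed.
#' @return data.frame (module, statistic, mean_p, p_adj, tier) with the
#'   per-resample p-values as an attribute `"p_resample"`.
#' @export
resampled_permutation_test <- function(mst, group, group_a, group_b,
                                       n_perm = 10000, n_resample = 100,
                                       seed = 1L) {
  scores <- if (inherits(mst, "module_score_table")) mst$scores else as.matrix(mst)
  if (length(group) != nrow(scores))
    stop_validation("group labels must cover all cells")
  if (n_perm < 99) stop_param("n_perm must be >= 99")
  ia <- which(group == group_a); ib <- which(group == group_b)
  if (!length(ia) || !length(ib)) stop_param("both groups must be non-empty")
  n_small <- min(length(ia), length(ib))
  if (n_small < 2) stop_param("smaller group must have >= 2 cells")
  equal <- length(ia) == length(ib)
  if (equal) {
    message("equal group sizes: single pass, no subsampling")
    n_res <- 1L
  } else n_res <- n_resample
  # which group is subsampled depends only on sizes, so the procedure is
  # symmetric in the labels (a, b)
  small <- if (length(ia) <= length(ib)) ia else ib
  large <- if (length(ia) <= length(ib)) ib else ia
  p_mat <- matrix(NA_real_, n_res, ncol(scores),
                  dimnames = list(NULL, colnames(scores)))
  stat <- numeric(ncol(scores))
  for (j in seq_len(ncol(scores))) {
    v <- scores[, j]
    stat[j] <- abs(mean(v[ia]) - mean(v[ib]))
    set.seed(mb_seed(seed, paste0("permtest:", colnames(scores)[j])))
    for (r in seq_len(n_res)) {
      sub <- if (equal) large else sample(large, n_small)
      p_mat[r, j] <- perm_p_mean_diff(v[small], v[sub], n_perm)
    }
  }
  mean_p <- colMeans(p_mat)
  p_adj <- stats::p.adjust(mean_p, method = "BH")
  tier <- ifelse(p_adj < 0.001, "***",
                 ifelse(p_adj < 0.01, "**",
                        ifelse(p_adj < 0.05, "*", "ns")))
  out <- data.frame(module = colnames(scores), statistic = stat,
                    mean_p = mean_p, p_adj = p_adj, tier = tier,
                    row.names = NULL)
  attr(out, "p_resample") <- p_mat
  out
}

#' Per-timepoint distribution summaries of a score
#'
#' Mean, standard deviation and a Gaussian kernel density (Silverman's
#' bandwidth) of a per-cell score within each group (e.g. dataset x
#' timepoint). Densities are evaluated on a fixed grid spanning all groups
#' and integrate to 1 (trapezoid rule) within 1e-3.
#'
#' @param values Per-cell numeric scores.
#' @param group Per-cell group labels.
#' @param n_grid Density evaluation grid size.
#' @return List with `summary` (data.frame: group, n, mean, sd) and
#'   `density` (data.frame: group, x, y).
#' @export
timepoint_profile <- function(values, group, n_grid = 512) {
  if (length(values) != length(group))
    stop_validation("values and group lengths differ")
  groups <- unique(as.character(group))
  summ <- do.call(rbind, lapply(groups, function(g) {
    v <- values[group == g]
    if (!length(v)) stop_param(sprintf("empty group '%s'", g))
    s <- if (length(v) > 1) stats::sd(v) else {
      mb_warn(sprintf("group '%s' has a single cell; sd reported as 0", g))
      0
    }
    data.frame(group = g, n = length(v), mean = mean(v), sd = s)
  }))
  rng <- range(values)
  pad <- max(diff(rng), 1e-8) * 0.3
  dens <- do.call(rbind, lapply(groups, function(g) {
    v <- values[group == g]
    if (length(v) < 2 || stats::sd(v) == 0) {
      # degenerate group: narrow Gaussian peak at the group value
      bw <- max(diff(rng), 1e-8) / 100
      d <- stats::density(v, bw = bw, from = rng[1] - pad, to = rng[2] + pad,
                          n = n_grid)
    } else {
      d <- stats::density(v, bw = "nrd0", from = rng[1] - pad,
                          to = rng[2] + pad, n = n_grid)
    }
    data.frame(group = g, x = d$x, y = d$y)
  }))
  list(summary = summ, density = dens)
}

#' Two-sided rank-sum comparison
#'
#' Wilcoxon rank-sum test: exact when the smaller sample has at most 8
#' observations and there are no ties, otherwise the normal approximation
#' with tie correction (no continuity correction, so it matches the
#' closed-form z statistic).
#'
#' @param values_a,values_b Numeric samples.
#' @return Two-sided p-value.
#' @export
ranksum_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop_param("both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  use_exact <- min(length(values_a), length(values_b)) <= 8 && !ties
  res <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                             exact = use_exact,
                                             correct = FALSE))
  res$p.value
}
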