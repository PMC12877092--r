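# Ordering spots along an annotated maturation path and running-average
# expression trends, plus a permutation trend test. The trend test is a
# documented substitute for cell-type-decomposed differential expression
# along the path (which requires the deconvolution model and is out of
# scope): it tests monotone association of expression with path position.

#' Order spots along an annotated polyline path
#'
#' Spots within `radius` of the polyline are kept and ordered by the
#' arc-length of their orthogonal projection onto it; ties are broken by
#' distance to the line, then by spot id.
#'
#' @param grid A [spot_grid()].
#' @param polyline Numeric matrix of vertices (n >= 2 rows, columns x, y).
#' @param radius Positive capture radius around the polyline.
#' @return Character vector of spot ids in path order.
#' @export
order_spots_on_polyline <- function(grid, polyline, radius) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stop_param("polyline needs >= 2 vertices")
  if (!is.numeric(radius) || radius <= 0) stop_param("radius must be > 0")
  p <- cbind(grid$x, grid$y)
  seg_start <- polyline[-nrow(polyline), , drop = FALSE]
  seg_vec <- diff(polyline)
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum_len <- c(0, cumsum(seg_len))
  best_d <- rep(Inf, nrow(p)); best_arc <- rep(NA_real_, nrow(p))
  for (s in seq_len(nrow(seg_start))) {
    v <- seg_vec[s, ]; L2 <- sum(v^2)
    rel <- sweep(p, 2, seg_start[s, ])
    tt <- if (L2 > 0) pmin(1, pmax(0, (rel %*% v)[, 1] / L2)) else 0
    proj <- seg_start[s, 1] + tt * v[1]
    projy <- seg_start[s, 2] + tt * v[2]
    d <- sqrt((p[, 1] - proj)^2 + (p[, 2] - projy)^2)
    upd <- d < best_d
    best_arc[upd] <- cum_len[s] + tt[upd] * seg_len[s]
    best_d[upd] <- d[upd]
  }
  keep <- best_d <= radius
  if (!any(keep)) stop_geometry("no spot within radius of the polyline")
  ord <- order(best_arc[keep], best_d[keep], grid$spots[keep])
  grid$spots[keep][ord]
}

#' Running average along a path
#'
#' Centered moving average with end truncation (never padding): position i
#' averages positions `max(1, i - floor(w/2)) .. min(n, i + floor(w/2))`.
#' The default window of 50 spots matches the scale at which expression
#' trends along a maturation path are summarized.
#'
#' @param values Numeric vector in path order.
#' @param window Target window size (>= 1).
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(values, window = 50) {
  n <- length(values)
  if (!n) stop_param("empty input")
  if (!is.numeric(window) || window < 1) stop_param("window must be >= 1")
  half <- floor(window / 2)
  cs <- c(0, cumsum(values))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Permutation trend test along a path
#'
#' Statistic: Spearman correlation of the values with their path rank.
#' Two-sided p-value by permuting positions; exhaustive enumeration over all
#' n! orderings when n <= 7, otherwise `n_perm` sampled permutations with the
#' +1-corrected p `(1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_perm)`.
#' Constant values give an undefined statistic and p = 1 by convention.
#'
#' @param values Numeric vector of per-spot values in path order.
#' @param positions Path positions; default the ordering index.
#' @param n_perm Number of permutations when sampling (>= 99).
#' @param seed Seed for the sampled permutations.
#' @return List with `statistic` (Spearman rho), `p_value`, `n_perm` and
#'   `method` (`"exhaustive"` or `"sampled"`).
#' @export
path_trend_test <- function(values, positions = seq_along(values),
                            n_perm = 999, seed = 1L) {
  n <- length(values)
  if (n < 5) stop_param("need >= 5 spots for the trend test")
  if (n_perm < 99) stop_param("n_perm must be >= 99")
  if (stats::sd(values) == 0) {
    mb_warn("constant values: trend statistic undefined, p = 1")
    return(list(statistic = NA_real_, p_value = 1, n_perm = 0L,
                method = "degenerate"))
  }
  rv <- rank(values)
  rp <- rank(positions)
  rho_obs <- stats::cor(rv, rp)
  if (n <= 7) {
    perms <- permutations_of(n)
    rho_all <- apply(perms, 1, function(ix) stats::cor(rv, rp[ix]))
    p <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
    list(statistic = rho_obs, p_value = p, n_perm = nrow(perms),
         method = "exhaustive")
  } else {
    set.seed(seed)
    R <- vapply(seq_len(n_perm), function(i) rp[sample.int(n)],
                numeric(n))
    rho_perm <- as.numeric(stats::cor(rv, R))
    p <- (1 + sum(abs(rho_perm) >= abs(rho_obs) - 1e-12)) / (1 + n_perm)
    list(statistic = rho_obs, p_value = p, n_perm = n_perm,
         method = "sampled")
  }
}

# All n! permutations of 1..n as rows (small n only).
permutations_of <- function(n) {
  if (n > 8) stop_param("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Smooth expression of genes along a maturation path
#'
#' Convenience wrapper: orders the log-normalized expression of selected
#' genes along an ordered spot list and applies [moving_average()].
#'
#' @param cm A [count_matrix()] with a `"lognorm"` layer.
#' @param ordered_spots Spot ids in path order (e.g. from
#'   [order_spots_on_polyline()]).
#' @param genes Genes to profile.
#' @param window Window size passed to [moving_average()].
#' @return Long-format data.frame: gene, position, spot, value, smoothed.
#' @export
path_expression_profile <- function(cm, ordered_spots, genes, window = 50) {
  if (is.null(cm$layers$lognorm))
    stop_param("lognorm layer missing; call lognormalize() first")
  missing_spots <- setdiff(ordered_spots, cm$entities)
  if (length(missing_spots)) stop_validation("path spots missing from counts")
  genes <- intersect(genes, cm$genes)
  if (!length(genes)) stop_param("no requested gene present")
  do.call(rbind, lapply(genes, function(g) {
    v <- cm$layers$lognorm[ordered_spots, g]
    data.frame(gene = g, position = seq_along(ordered_spots),
               spot = ordered_spots, value = as.numeric(v),
               smoothed = moving_average(as.numeric(v), window))
  }))
}
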