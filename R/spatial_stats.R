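# Moran's I with a permutation null for per-spot scores, and a simple
# neighbor ligand-receptor score. The neighbor score is a transparent
# stand-in for optimal-transport signaling inference (out of scope): it only
# measures local ligand/receptor co-occurrence, feeding the Moran's I ranking.

#' Moran's I spatial autocorrelation with a permutation null
#'
#' Binary neighbor weights (1 for adjacent spots, no row standardization):
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centered values z.
#' The two-sided permutation p-value relabels values over spots and compares
#' `|I - E[I]|` with `E[I] = -1/(n-1)`; exhaustive enumeration over all n!
#' labelings when `exhaustive = TRUE` (n <= 8), otherwise `n_perm` sampled
#' relabelings with the +1-corrected p.
#'
#' @param grid A [spot_grid()] with adjacency built.
#' @param values Numeric vector over the grid's spots (non-constant).
#' @param n_perm Number of permutations (sampled mode).
#' @param seed RNG seed for the permutations.
#' @param exhaustive Enumerate all labelings (n <= 8)?
#' @return An object of class `moran_result`: `I`, `n`, `S0`, `expected_I`,
#'   `p_perm`, `n_perm`.
#' @export
morans_i <- function(grid, values, n_perm = 999, seed = 1L,
                     exhaustive = FALSE) {
  if (is.null(grid$adjacency))
    stop_param("adjacency not built; call build_adjacency() first")
  n <- length(grid$spots)
  if (n < 3) stop_param("Moran's I needs n >= 3 spots")
  if (length(values) != n) stop_validation("values length != number of spots")
  if (stats::sd(values) == 0) stop_degenerate("constant field")
  a <- grid$adjacency[, 1]; b <- grid$adjacency[, 2]
  S0 <- 2 * nrow(grid$adjacency)
  i_of <- function(v) {
    z <- v - mean(v)
    (n / S0) * 2 * sum(z[a] * z[b]) / sum(z^2)
  }
  I_obs <- i_of(values)
  e_i <- -1 / (n - 1)
  if (exhaustive) {
    perms <- permutations_of(n)
    I_all <- apply(perms, 1, function(ix) i_of(values[ix]))
    p <- mean(abs(I_all - e_i) >= abs(I_obs - e_i) - 1e-12)
    np <- nrow(perms)
  } else {
    set.seed(seed)
    z <- values - mean(values)
    denom <- sum(z^2)
    Z <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
    I_perm <- (n / S0) * 2 * colSums(Z[a, , drop = FALSE] *
                                     Z[b, , drop = FALSE]) / denom
    p <- (1 + sum(abs(I_perm - e_i) >= abs(I_obs - e_i) - 1e-12)) /
      (1 + n_perm)
    np <- n_perm
  }
  structure(list(I = I_obs, n = n, S0 = S0, expected_I = e_i,
                 p_perm = p, n_perm = np),
            class = "moran_result")
}

#' @exportS3Method base::print
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, n = %d), permutation p = %.4g\n",
              x$I, x$expected_I, x$n, x$p_perm))
  invisible(x)
}

#' Neighbor ligand-receptor score
#'
#' Per-spot score of local signaling potential:
#' `score(s) = ligand(s) * mean(receptor over neighbors of s)`. Isolated
#' spots score 0. This is a deliberately simple local co-occurrence score,
#' not a signaling-flow inference.
#'
#' @param grid A [spot_grid()] with adjacency built.
#' @param ligand,receptor Numeric vectors over the grid's spots.
#' @return Numeric per-spot scores (named by spot).
#' @export
neighbor_lr_score <- function(grid, ligand, receptor) {
  if (is.null(grid$adjacency))
    stop_param("adjacency not built; call build_adjacency() first")
  n <- length(grid$spots)
  if (length(ligand) != n || length(receptor) != n)
    stop_validation("ligand/receptor length != number of spots")
  adj <- grid$adjacency
  nb_sum <- numeric(n); nb_deg <- numeric(n)
  if (nrow(adj)) {
    for (col in 1:2) {
      other <- 3 - col
      s <- tapply(receptor[adj[, other]], adj[, col], sum)
      ix <- as.integer(names(s))
      nb_sum[ix] <- nb_sum[ix] + s
      d <- table(adj[, col])
      nb_deg[as.integer(names(d))] <- nb_deg[as.integer(names(d))] + d
    }
  }
  score <- ifelse(nb_deg > 0, ligand * nb_sum / nb_deg, 0)
  names(score) <- grid$spots
  score
}

#' Rank per-spot score maps by spatial autocorrelation
#'
#' Computes Moran's I with a permutation p-value for each score map (e.g.
#' one per ligand-receptor pair), adjusts the p-values across maps with
#' Benjamini-Hochberg, and sorts by I descending. Constant maps are dropped
#' with a warning.
#'
#' @param grid A [spot_grid()] with adjacency built.
#' @param score_table Numeric matrix, spots in rows, one column per score map
#'   (column names = pair ids), or a named list of per-spot vectors.
#' @param n_perm,seed Passed to [morans_i()].
#' @return data.frame (pair, I, p, p_adj) sorted by I descending.
#' @export
rank_pairs_by_moran <- function(grid, score_table, n_perm = 999, seed = 1L) {
  if (is.list(score_table) && !is.matrix(score_table))
    score_table <- do.call(cbind, score_table)
  score_table <- as.matrix(score_table)
  if (!ncol(score_table)) stop_param("need at least one score map")
  keep <- apply(score_table, 2, function(v) stats::sd(v) > 0)
  if (any(!keep))
    mb_warn(sprintf("%d constant score maps dropped", sum(!keep)))
  if (!any(keep)) {
    mb_warn("all score maps constant; empty ranking")
    return(data.frame(pair = character(), I = numeric(), p = numeric(),
                      p_adj = numeric()))
  }
  score_table <- score_table[, keep, drop = FALSE]
  res <- lapply(seq_len(ncol(score_table)), function(j)
    morans_i(grid, score_table[, j], n_perm = n_perm, seed = seed))
  out <- data.frame(pair = colnames(score_table),
                    I = vapply(res, `[[`, numeric(1), "I"),
                    p = vapply(res, `[[`, numeric(1), "p_perm"))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(-out$I), , drop = FALSE]
}
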