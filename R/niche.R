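# Spot labeling by greatest deconvolved abundance, neighbor-pair profiles,
# inter-sample similarity in [0, 1], and temporal alignment of organoids to
# tissue timepoints.

#' Spot-by-cell-type abundance matrix
#'
#' Container for the output of an external spot deconvolution (one row per
#' spot, one column per cell type, nonnegative abundances).
#'
#' @param values Numeric matrix, spots in rows (rownames = spot barcodes),
#'   cell types in columns (colnames = type ids).
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("abundance matrix needs spot and type names")
  if (ncol(values) < 2) stop_validation("need at least 2 cell types")
  if (any(values < 0)) stop_validation("abundances must be >= 0")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop_validation("duplicate spot or type ids")
  structure(list(spots = rownames(values), types = colnames(values),
                 values = values),
            class = "abundance_matrix")
}

#' Label spots by their most abundant cell type
#'
#' Each spot is labeled with the cell type the deconvolution estimates it to
#' contain in the greatest abundance. Ties are broken by `tie_rule` and
#' flagged; spots with all-zero abundances are labeled `"unassigned"` and
#' later excluded from pair counting.
#'
#' @param ab An [abundance_matrix()].
#' @param tie_rule `"first"` (default: first type in declared column order)
#'   or `"last"`.
#' @return An object of class `spot_labeling`: list with `labels` (named
#'   character), `tie_flag` (logical) and `types` (the type universe).
#' @export
label_spots <- function(ab, tie_rule = c("first", "last")) {
  tie_rule <- match.arg(tie_rule)
  v <- ab$values
  mx <- apply(v, 1, max)
  n_max <- rowSums(v == mx)
  tie <- n_max > 1
  pick <- if (tie_rule == "first") {
    apply(v == mx, 1, which.max)
  } else {
    apply(v == mx, 1, function(z) max(which(z)))
  }
  labels <- ab$types[pick]
  zero <- mx == 0
  if (any(zero)) {
    labels[zero] <- "unassigned"
    message(sprintf("%d spots with all-zero abundance labeled 'unassigned'",
                    sum(zero)))
  }
  tie[zero] <- TRUE
  names(labels) <- ab$spots
  names(tie) <- ab$spots
  structure(list(labels = labels, tie_flag = tie, types = ab$types),
            class = "spot_labeling")
}

#' Build the spot lattice adjacency
#'
#' Two spots are neighbors iff their physical center distance is at most
#' `scale_tolerance` times the minimum pairwise center distance; on a regular
#' hexagonal lattice this yields the six lattice neighbors.
#'
#' @param grid A [spot_grid()].
#' @param scale_tolerance Multiplier on the minimum pitch; default 1.05
#'   tolerates small lattice jitter.
#' @return The grid with its `adjacency` filled in (two-column matrix of spot
#'   indices, i < j).
#' @export
build_adjacency <- function(grid, scale_tolerance = 1.05) {
  n <- length(grid$spots)
  if (n < 2) stop_geometry("need at least 2 spots to build adjacency")
  d <- as.matrix(stats::dist(cbind(grid$x, grid$y)))
  pos <- d[upper.tri(d)]
  if (all(pos == 0)) stop_geometry("all spots coincident")
  pitch <- min(pos[pos > 0])
  hit <- which(upper.tri(d) & d <= scale_tolerance * pitch & d > 0,
               arr.ind = TRUE)
  grid$adjacency <- validate_adjacency(hit, n)
  grid
}

#' Count neighboring cell-type pairs
#'
#' Every adjacency edge contributes one count to the unordered pair of its
#' endpoint labels (diagonal = same-type adjacencies). Edges touching
#' `"unassigned"` spots are excluded from both numerator and denominator.
#' Frequencies are counts divided by retained edges, so the profile is a
#' composition comparable across samples of different sizes.
#'
#' @param grid A [spot_grid()] with adjacency built.
#' @param labeling A [spot_labeling()] covering the grid's spots.
#' @return An object of class `pair_profile`: `types`, symmetric K x K
#'   `pair_counts`, upper-triangle-with-diagonal `freq` vector (names
#'   `"A|B"`), `n_edges` retained and `n_excluded`.
#' @export
count_neighbor_pairs <- function(grid, labeling) {
  if (is.null(grid$adjacency))
    stop_param("adjacency not built; call build_adjacency() first")
  if (!all(grid$spots %in% names(labeling$labels)))
    stop_validation("labeling does not cover all spots")
  types <- labeling$types
  K <- length(types)
  counts <- matrix(0L, K, K, dimnames = list(types, types))
  lab <- labeling$labels[grid$spots]
  adj <- grid$adjacency
  n_excl <- 0L
  if (!is.null(adj) && nrow(adj)) {
    la <- lab[adj[, 1]]; lb <- lab[adj[, 2]]
    keep <- la != "unassigned" & lb != "unassigned"
    n_excl <- sum(!keep)
    ia <- match(la[keep], types); ib <- match(lb[keep], types)
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    tab <- tabulate((hi - 1L) * K + lo, nbins = K * K)
    upper <- matrix(tab, K, K)          # counts landed in upper triangle
    counts <- upper + t(upper)
    diag(counts) <- diag(upper)
    dimnames(counts) <- list(types, types)
  }
  ut <- upper.tri(counts, diag = TRUE)
  freq_counts <- counts[ut]
  pair_names <- outer(types, types, function(a, b) paste(a, b, sep = "|"))[ut]
  total <- sum(freq_counts)
  if (total == 0) {
    mb_warn("no adjacency edges after exclusions; all-zero pair profile")
    freq <- freq_counts * 0
  } else freq <- freq_counts / total
  names(freq) <- pair_names
  structure(list(types = types, pair_counts = counts, freq = freq,
                 n_edges = total, n_excluded = n_excl),
            class = "pair_profile")
}

# Re-express a pair profile's freq vector on a shared ordered type basis
# (absent pairs = 0).
profile_on_basis <- function(profile, types) {
  K <- length(types)
  counts <- matrix(0, K, K, dimnames = list(types, types))
  old <- intersect(profile$types, types)
  counts[old, old] <- profile$pair_counts[old, old]
  ut <- upper.tri(counts, diag = TRUE)
  v <- counts[ut]
  names(v) <- outer(types, types, function(a, b) paste(a, b, sep = "|"))[ut]
  if (sum(v) > 0) v / sum(v) else v
}

#' Inter-sample niche similarity
#'
#' Euclidean distances between the samples' neighbor-pair frequency vectors
#' (on the union type basis), inverted and normalized to \[0, 1\]:
#' `S = 1 - D / max(D)` over off-diagonal pairs, so the most dissimilar pair
#' scores exactly 0 and identical samples score 1.
#'
#' @param profiles List of [count_neighbor_pairs()] results.
#' @param ids Sample ids (default: names of `profiles`).
#' @return An object of class `similarity_matrix`: `ids`, similarity `S` and
#'   distance `D` matrices.
#' @export
sample_similarity <- function(profiles, ids = names(profiles)) {
  if (length(profiles) < 2) stop_param("need at least 2 samples")
  if (is.null(ids) || length(ids) != length(profiles) || anyDuplicated(ids))
    stop_param("profiles need unique sample ids")
  types <- unique(unlist(lapply(profiles, `[[`, "types")))
  F <- do.call(rbind, lapply(profiles, profile_on_basis, types = types))
  rownames(F) <- ids
  D <- as.matrix(stats::dist(F))
  off <- D[upper.tri(D)]
  mx <- max(off)
  if (mx == 0) {
    mb_warn("all pair profiles identical; similarity set to 1 everywhere")
    S <- matrix(1, nrow(D), ncol(D), dimnames = dimnames(D))
  } else {
    S <- 1 - D / mx
    diag(S) <- 1
  }
  structure(list(ids = ids, S = S, D = D), class = "similarity_matrix")
}

#' Temporal alignment of a query sample to tissue timepoints
#'
#' Per tissue timepoint, the similarity of the query is averaged over that
#' timepoint's replicates; the normalized similarities are used as weights in
#' a weighted average of the timepoints, giving the query's estimated
#' gestational age.
#'
#' @param sim A [sample_similarity()] result covering the query and the
#'   tissue samples.
#' @param query_id Sample id of the (organoid) query.
#' @param tissue_meta List of [sample_meta()] (kind `"tissue"`) for the
#'   tissue samples present in `sim`.
#' @return An object of class `temporal_alignment`: `query_id`, `weights`
#'   (named by timepoint, summing to 1), `per_timepoint_similarity` and
#'   `estimated_timepoint` (PCW).
#' @export
temporal_alignment <- function(sim, query_id, tissue_meta) {
  ids <- vapply(tissue_meta, `[[`, character(1), "sample_id")
  kinds <- vapply(tissue_meta, `[[`, character(1), "kind")
  tps <- vapply(tissue_meta, `[[`, numeric(1), "timepoint_value")
  if (any(kinds != "tissue")) stop_param("tissue_meta must all be tissue samples")
  if (query_id %in% ids) stop_param("query must not be a tissue sample")
  if (!query_id %in% sim$ids) stop_param("query not in similarity matrix")
  if (!all(ids %in% sim$ids)) stop_param("tissue samples missing from similarity matrix")
  if (length(unique(tps)) < 2) stop_param("need >= 2 distinct tissue timepoints")
  s <- sim$S[query_id, ids]
  per_tp <- tapply(s, tps, mean)
  if (all(per_tp == 0))
    stop_degenerate("query has zero similarity to every timepoint; alignment undefined")
  w <- per_tp / sum(per_tp)
  t_vals <- as.numeric(names(per_tp))
  est <- sum(w * t_vals)
  structure(list(query_id = query_id, weights = w,
                 per_timepoint_similarity = per_tp,
                 estimated_timepoint = est),
            class = "temporal_alignment")
}

#' @exportS3Method base::print
print.temporal_alignment <- function(x, ...) {
  cat(sprintf("temporal_alignment: %s -> %.2f PCW\n", x$query_id,
              x$estimated_timepoint))
  print(round(x$weights, 3))
  invisible(x)
}
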