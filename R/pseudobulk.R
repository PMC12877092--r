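# Group-level mean expression over the HVG set and the pairwise Pearson
# correlation matrix used to stage in-vitro samples against fetal timepoints.

#' Pseudobulk mean-expression profiles
#'
#' Mean per-cell expression per group (dataset x timepoint) over a gene set,
#' computed from any per-cell value layer (log-normalized by default; a
#' batch-corrected layer can be supplied instead and the layer used is
#' recorded). Groups with no cells are dropped with a warning.
#'
#' @param cm A [count_matrix()] with the requested layer.
#' @param group Per-cell group labels.
#' @param genes Gene set (e.g. the `final` set of [select_hvg()]).
#' @param layer Layer name, default `"lognorm"`.
#' @return An object of class `pseudobulk_table`: `groups`, `genes`, `means`
#'   (group x gene), `n_cells`, `layer`.
#' @export
pseudobulk_means <- function(cm, group, genes, layer = "lognorm") {
  if (is.null(cm$layers[[layer]]))
    stop_param(sprintf("layer '%s' missing", layer))
  genes <- intersect(as.character(genes), cm$genes)
  if (!length(genes)) stop_param("empty gene set")
  if (length(group) != length(cm$entities))
    stop_validation("group labels must cover all cells")
  x <- cm$layers[[layer]][, genes, drop = FALSE]
  groups <- unique(as.character(group))
  n_cells <- vapply(groups, function(g) sum(group == g), integer(1))
  if (any(n_cells == 0)) {
    mb_warn(sprintf("%d empty groups dropped", sum(n_cells == 0)))
    groups <- groups[n_cells > 0]
    n_cells <- n_cells[n_cells > 0]
  }
  means <- t(vapply(groups, function(g)
    colMeans(x[group == g, , drop = FALSE]), numeric(length(genes))))
  dimnames(means) <- list(groups, genes)
  structure(list(groups = groups, genes = genes, means = means,
                 n_cells = n_cells, layer = layer),
            class = "pseudobulk_table")
}

#' Pairwise Pearson correlation of pseudobulk profiles
#'
#' Symmetric group x group Pearson correlation matrix of the pseudobulk mean
#' profiles; groups with a constant profile are dropped with a warning.
#'
#' @param pb A [pseudobulk_means()] result.
#' @return Correlation matrix (diagonal 1, entries in \[-1, 1\]).
#' @export
correlation_matrix <- function(pb) {
  if (length(pb$groups) < 2) stop_param("need >= 2 groups")
  sds <- apply(pb$means, 1, stats::sd)
  if (any(sds == 0))
    mb_warn(sprintf("%d constant-profile groups dropped", sum(sds == 0)))
  m <- pb$means[sds > 0, , drop = FALSE]
  if (nrow(m) < 2) stop_param("fewer than 2 non-constant groups")
  r <- stats::cor(t(m))
  diag(r) <- 1
  r
}

#' Average-linkage clustering of a correlation matrix
#'
#' Presentation helper: hierarchical clustering (average linkage) on
#' 1 - correlation, for ordering heatmap rows/columns.
#'
#' @param r A correlation matrix from [correlation_matrix()].
#' @return An `hclust` object.
#' @export
correlation_hclust <- function(r) {
  stats::hclust(stats::as.dist(1 - r), method = "average")
}
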