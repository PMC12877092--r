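# Lineage reconstruction on a pruned cluster-abstraction graph: kNN cell
# graph, inter-cluster connectivity, shortest root-to-endpoint path with an
# optional waypoint, per-replicate HVG selection (intersect within timepoint,
# union across), an oriented-PC1 pseudotime proxy, and trimmed five-bin
# expression profiles with start-vs-end change calls.
#
# The cluster connectivity statistic is a transparent substitute for the
# published graph-abstraction statistic (inter-cluster edges over the smaller
# cluster's total degree, clipped to [0, 1]); the pruning threshold of 0.05
# is carried over. The start-vs-end call replaces a GAM-based test with a
# permutation difference-of-bin-means test at the same thresholds.

#' Union k-nearest-neighbor cell graph
#'
#' Undirected graph with an edge whenever either cell lists the other among
#' its k nearest neighbors by Euclidean distance; distance ties are broken by
#' cell index.
#'
#' @param embedding Numeric cell x dims matrix.
#' @param k Neighbors per cell (1 <= k < n).
#' @return Two-column integer matrix of cell-index edges (i < j).
#' @export
build_knn_graph <- function(embedding, k = 10) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k < 1) stop_param("k must be >= 1")
  if (k >= n) stop_param("k must be < number of cells")
  if (any(!is.finite(embedding))) stop_validation("embedding must be finite")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ], seq_len(n))[seq_len(k)]
    edges[[i]] <- cbind(pmin(i, nb), pmax(i, nb))
  }
  unique(do.call(rbind, edges))
}

#' Cluster-graph connectivity from a cell graph
#'
#' Edge weight between clusters A and B: observed inter-cluster edges divided
#' by the smaller of the two clusters' total degrees, clipped to \[0, 1\];
#' zero when no inter-cluster edge exists.
#'
#' @param cell_graph Two-column integer matrix of cell-index edges.
#' @param labels Per-cell cluster labels.
#' @param prune_threshold Stored pruning threshold (default 0.05) used later
#'   by [prune_and_path()].
#' @return An object of class `cluster_graph`: `clusters` (ids with sizes),
#'   `edges` (data.frame from, to, weight), `prune_threshold`.
#' @export
cluster_connectivity <- function(cell_graph, labels, prune_threshold = 0.05) {
  labels <- as.character(labels)
  if (any(is.na(labels))) stop_validation("every cell must be labeled")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop_param("need >= 2 clusters")
  deg <- tabulate(factor(c(cell_graph[, 1], cell_graph[, 2]),
                         levels = seq_along(labels)),
                  nbins = length(labels))
  cl_deg <- tapply(deg, factor(labels, levels = clusters), sum, default = 0)
  la <- labels[cell_graph[, 1]]; lb <- labels[cell_graph[, 2]]
  inter <- la != lb
  ca <- pmin(la[inter], lb[inter]); cb <- pmax(la[inter], lb[inter])
  key <- paste(ca, cb, sep = "\r")
  cnt <- table(key)
  edges <- do.call(rbind, lapply(names(cnt), function(k) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1]]
    denom <- min(cl_deg[ab[1]], cl_deg[ab[2]])
    w <- if (denom > 0) min(1, as.numeric(cnt[[k]]) / denom) else 0
    data.frame(from = ab[1], to = ab[2], weight = w,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  sizes <- as.integer(table(factor(labels, levels = clusters)))
  structure(list(clusters = data.frame(cluster = clusters, size = sizes,
                                       degree = as.numeric(cl_deg)),
                 edges = edges, prune_threshold = prune_threshold),
            class = "cluster_graph")
}

# Adjacency list of the pruned graph (strict w < threshold removed).
pruned_adjacency <- function(cg) {
  keep <- cg$edges$weight >= cg$prune_threshold
  e <- cg$edges[keep, , drop = FALSE]
  adj <- stats::setNames(vector("list", nrow(cg$clusters)),
                         cg$clusters$cluster)
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- rbind(adj[[e$from[i]]],
                              data.frame(to = e$to[i], w = e$weight[i]))
    adj[[e$to[i]]] <- rbind(adj[[e$to[i]]],
                            data.frame(to = e$from[i], w = e$weight[i]))
  }
  adj
}

# All hop-minimal paths a -> b on the pruned graph; among them pick the one
# with the largest minimum edge weight, then the lexicographically smallest
# cluster-id sequence. Errors with the component memberships if disconnected.
shortest_path_one <- function(cg, from, to) {
  nodes <- cg$clusters$cluster
  adj <- pruned_adjacency(cg)
  if (from == to) return(from)
  # BFS distances from `from`
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (u in nb$to) if (!is.finite(dist[u])) {
      dist[u] <- dist[v] + 1
      queue <- c(queue, u)
    }
  }
  if (!is.finite(dist[to])) {
    comp_from <- names(dist)[is.finite(dist)]
    stop_degenerate(sprintf(
      "disconnected lineage: endpoint '%s' unreachable from '%s' after pruning (component of '%s': %s)",
      to, from, from, paste(sort(comp_from), collapse = ", ")))
  }
  # enumerate hop-minimal paths by walking the BFS layer DAG backwards
  paths <- list(to)
  for (step in seq_len(dist[to])) {
    paths <- do.call(c, lapply(paths, function(p) {
      v <- p[[1]]
      preds <- adj[[v]]$to[dist[adj[[v]]$to] == dist[v] - 1]
      lapply(preds, function(u) c(u, p))
    }))
  }
  if (length(paths) == 1) return(paths[[1]])
  wt <- function(p) {
    vapply(seq_len(length(p) - 1), function(i) {
      nb <- adj[[p[i]]]
      nb$w[match(p[i + 1], nb$to)]
    }, numeric(1))
  }
  bottleneck <- vapply(paths, function(p) min(wt(p)), numeric(1))
  best <- which(bottleneck >= max(bottleneck) - 1e-12)
  if (length(best) > 1) {
    keys <- vapply(paths[best], paste, character(1), collapse = "\r")
    best <- best[order(keys)][1]
  }
  paths[[best[1]]]
}

#' Extract a lineage path on the pruned cluster graph
#'
#' Removes edges with weight strictly below the pruning threshold (a weight
#' equal to the threshold is kept), then finds the hop-count shortest path
#' from root to endpoint; ties are broken by the largest minimum edge weight
#' along the path, then lexicographically. With a waypoint the path is the
#' concatenation of root -> waypoint and waypoint -> endpoint with repeated
#' clusters collapsed.
#'
#' @param cg A [cluster_connectivity()] result.
#' @param root,endpoint Cluster ids.
#' @param waypoint Optional cluster id the path must pass through.
#' @param labels Optional per-cell cluster labels; when given, the member
#'   cells of the path's clusters are attached.
#' @return An object of class `lineage_path`: `path` (ordered cluster ids),
#'   `waypoint`, and (when labels are given) `cells` with their clusters.
#' @export
prune_and_path <- function(cg, root, endpoint, waypoint = NULL,
                           labels = NULL) {
  nodes <- cg$clusters$cluster
  for (v in c(root, endpoint, waypoint))
    if (!v %in% nodes) stop_param(sprintf("unknown cluster '%s'", v))
  path <- if (is.null(waypoint)) {
    shortest_path_one(cg, root, endpoint)
  } else {
    p1 <- shortest_path_one(cg, root, waypoint)
    p2 <- shortest_path_one(cg, waypoint, endpoint)
    collapse_dups(c(p1, p2[-1]))
  }
  cells <- NULL
  if (!is.null(labels)) {
    labels <- as.character(labels)
    keep <- labels %in% path
    cells <- data.frame(cell = seq_along(labels)[keep],
                        cluster = labels[keep])
  }
  structure(list(path = path, root = root, endpoint = endpoint,
                 waypoint = waypoint, cells = cells),
            class = "lineage_path")
}

# Collapse loops: when a cluster reappears, cut the intermediate stretch.
collapse_dups <- function(p) {
  out <- character(0)
  for (v in p) {
    hit <- match(v, out)
    out <- if (is.na(hit)) c(out, v) else out[seq_len(hit)]
  }
  out
}

# Per-gene HVG ranking: dispersion of lognorm values standardized within 20
# gene-mean bins, deterministic tie-break by gene id. Returns gene ids,
# best first.
hvg_rank <- function(cm, n_bins = 20) {
  if (is.null(cm$layers$lognorm))
    stop_param("lognorm layer missing; call lognormalize() first")
  x <- cm$layers$lognorm
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    ix <- bins == b
    s <- stats::sd(disp[ix])
    z[ix] <- if (is.na(s) || s == 0) 0 else (disp[ix] - mean(disp[ix])) / s
  }
  cm$genes[order(-z, cm$genes)]
}

#' Highly variable genes: intersect within timepoint, union across
#'
#' Per replicate, the top `n_hvg` genes by a variance-stabilized dispersion
#' ranking of log-normalized values; within each timepoint the replicate
#' sets are intersected (a single replicate contributes its own set); the
#' final set is the union of the per-timepoint intersections.
#'
#' @param replicates Named list, one element per replicate: either a
#'   [count_matrix()] with a `"lognorm"` layer or a pre-ranked character
#'   vector of gene ids (best first).
#' @param timepoint Per-replicate timepoint labels (same length/order as
#'   `replicates`).
#' @param n_hvg Genes per replicate (default 2000).
#' @return An object of class `hvg_selection`: `per_replicate` (named list of
#'   sets), `per_timepoint` (list of intersections), `final` (union).
#' @export
select_hvg <- function(replicates, timepoint, n_hvg = 2000) {
  if (!length(replicates)) stop_param("need >= 1 replicate")
  if (length(timepoint) != length(replicates))
    stop_validation("timepoint labels must match replicates")
  per_rep <- lapply(replicates, function(r) {
    ranked <- if (inherits(r, "count_matrix")) hvg_rank(r) else as.character(r)
    if (n_hvg > length(ranked)) {
      mb_warn("n_hvg exceeds gene count; taking all genes")
      ranked
    } else ranked[seq_len(n_hvg)]
  })
  if (is.null(names(per_rep)))
    names(per_rep) <- paste0("rep", seq_along(per_rep))
  tps <- unique(as.character(timepoint))
  per_tp <- lapply(tps, function(tp) {
    sets <- per_rep[as.character(timepoint) == tp]
    Reduce(intersect, sets)
  })
  names(per_tp) <- tps
  final <- sort(unique(unlist(per_tp)))
  structure(list(per_replicate = per_rep, per_timepoint = per_tp,
                 final = final),
            class = "hvg_selection")
}

#' PC1-proxy pseudotime with an adjusted-R2 check
#'
#' PC1 of the standardized log-normalized expression over the HVG set, with
#' its sign oriented so the root cluster's mean score is minimal; pseudotime
#' is the min-max rescaled PC1 score. The adjusted R-squared of PC1 regressed
#' on cell-type indicators quantifies whether PC1 tracks annotated identity
#' progression.
#'
#' @param cm A [count_matrix()] with a `"lognorm"` layer (cells on the
#'   lineage).
#' @param hvg A [select_hvg()] result or a character vector of genes.
#' @param cell_type Per-cell annotation used for the adjusted-R2 check.
#' @param root_cells Logical or index vector marking the root cluster's
#'   cells.
#' @return List with `pseudotime` (named, in \[0, 1\]), `pc1` (oriented
#'   scores), `adj_r_squared`, `var_explained` (PC1 share).
#' @export
pc1_pseudotime <- function(cm, hvg, cell_type, root_cells) {
  if (is.null(cm$layers$lognorm))
    stop_param("lognorm layer missing; call lognormalize() first")
  genes <- if (inherits(hvg, "hvg_selection")) hvg$final else as.character(hvg)
  genes <- intersect(genes, cm$genes)
  n <- length(cm$entities)
  if (n < 3) stop_param("need >= 3 cells")
  x <- cm$layers$lognorm[, genes, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < 2) stop_degenerate("fewer than 2 HVGs with nonzero variance")
  if (length(cell_type) != n) stop_validation("cell_type must cover all cells")
  root <- seq_len(n) %in% seq_len(n)[root_cells]
  if (!any(root)) stop_param("no root cells marked")
  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  pc1 <- pca$x[, 1]
  if (mean(pc1[root]) > mean(pc1)) pc1 <- -pc1
  rng <- range(pc1)
  if (diff(rng) == 0) stop_degenerate("degenerate PCA: all cells identical on PC1")
  pt <- (pc1 - rng[1]) / diff(rng)
  names(pt) <- cm$entities
  fit <- stats::lm(pc1 ~ factor(cell_type))
  list(pseudotime = pt, pc1 = pc1,
       adj_r_squared = summary(fit)$adj.r.squared,
       var_explained = unname(pca$sdev[1]^2 / sum(pca$sdev^2)))
}

#' Binned pseudotime expression profiles with start-vs-end calls
#'
#' Cells below the 1st or above the 99th pseudotime percentile are trimmed;
#' the remaining pseudotime range is partitioned into `n_bins` equal-width
#' bins and per-bin mean expression is reported per gene. The start-vs-end
#' change call compares the first and last bins with a +1-corrected
#' two-sided permutation test on the difference of bin means; a gene is
#' called `up`/`down` when p < 0.001 and |logFC| > 2, where logFC is the
#' difference of mean log-normalized expression (last minus first bin) in
#' log2 units.
#'
#' @param pseudotime Per-cell pseudotime.
#' @param cm A [count_matrix()] with a `"lognorm"` layer (same cells).
#' @param genes Genes to profile.
#' @param trim Percentile pair, default `c(1, 99)`.
#' @param n_bins Number of equal-width bins (default 5).
#' @param n_perm Permutations for the start-vs-end test.
#' @param seed RNG seed.
#' @return data.frame with gene, one column per bin mean (`bin1..binK`),
#'   `logfc`, `p`, `call`.
#' @export
bin_profiles <- function(pseudotime, cm, genes = cm$genes, trim = c(1, 99),
                         n_bins = 5, n_perm = 1999, seed = 1L) {
  if (is.null(cm$layers$lognorm))
    stop_param("lognorm layer missing; call lognormalize() first")
  if (length(pseudotime) != length(cm$entities))
    stop_validation("pseudotime must cover all cells")
  qs <- stats::quantile(pseudotime, trim / 100)
  keep <- pseudotime >= qs[1] & pseudotime <= qs[2]
  if (sum(keep) < n_bins) stop_param("fewer cells than bins after trimming")
  pt <- pseudotime[keep]
  x <- cm$layers$lognorm[keep, , drop = FALSE]
  edges <- seq(min(pt), max(pt), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(pt, edges, rightmost.closed = TRUE), 1),
              n_bins)
  genes <- intersect(genes, cm$genes)
  empty <- setdiff(seq_len(n_bins), unique(bin))
  if (length(empty))
    mb_warn(sprintf("%d empty pseudotime bins reported as NA", length(empty)))
  out <- do.call(rbind, lapply(genes, function(g) {
    v <- x[, g]
    means <- vapply(seq_len(n_bins), function(b)
      if (any(bin == b)) mean(v[bin == b]) else NA_real_, numeric(1))
    first_b <- min(which(!is.na(means))); last_b <- max(which(!is.na(means)))
    a <- v[bin == first_b]; b2 <- v[bin == last_b]
    lfc <- (means[last_b] - means[first_b]) / log(2)
    set.seed(mb_seed(seed, paste0("binperm:", g)))
    p <- perm_p_mean_diff(a, b2, n_perm, max_exhaustive = 0)
    call <- if (p < 0.001 && abs(lfc) > 2) {
      if (lfc > 0) "up" else "down"
    } else "none"
    row <- as.data.frame(as.list(stats::setNames(means,
                                                 paste0("bin", seq_len(n_bins)))))
    cbind(data.frame(gene = g), row,
          data.frame(logfc = lfc, p = p, call = call))
  }))
  attr(out, "bin_edges") <- edges
  attr(out, "n_cells") <- sum(keep)
  out
}
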