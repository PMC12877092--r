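# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every quantity from first principles (double loops, exhaustive
# enumeration, closed forms) so they share no code path with the package.

# ---- fixtures ----

make_square_grid <- function(nr, nc, jitter = 0) {
  rc <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  spot_grid(sprintf("s_%d_%d", rc$row, rc$col), rc$row, rc$col,
            rc$col + stats::runif(nrow(rc), -jitter, jitter),
            rc$row + stats::runif(nrow(rc), -jitter, jitter))
}

make_line_grid <- function(n) {
  spot_grid(sprintf("L%02d", seq_len(n)), rep(0L, n), seq_len(n) - 1L,
            seq_len(n) - 1, rep(0, n))
}

make_labeling <- function(labels, types = sort(unique(setdiff(labels, "unassigned")))) {
  structure(list(labels = labels, tie_flag = rep(FALSE, length(labels)),
                 types = types),
            class = "spot_labeling")
}

make_profile <- function(freq_named, types, n_edges = 100) {
  K <- length(types)
  counts <- matrix(0, K, K, dimnames = list(types, types))
  for (nm in names(freq_named)) {
    ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
    counts[ab[1], ab[2]] <- freq_named[[nm]] * n_edges
    counts[ab[2], ab[1]] <- counts[ab[1], ab[2]]
  }
  structure(list(types = types, pair_counts = counts, freq = freq_named,
                 n_edges = n_edges, n_excluded = 0L),
            class = "pair_profile")
}

make_cluster_graph <- function(edges, prune_threshold = 0.05,
                               clusters = sort(unique(c(edges$from, edges$to)))) {
  structure(list(clusters = data.frame(cluster = clusters, size = 1L,
                                       degree = NA_real_),
                 edges = edges, prune_threshold = prune_threshold),
            class = "cluster_graph")
}

random_jittered_grid <- function(radius, jitter = 0.02, prefix = "j") {
  h <- hex_lattice(radius, prefix)
  spot_grid(h$barcode, h$array_row, h$array_col,
            h$x + stats::runif(nrow(h), -jitter, jitter),
            h$y + stats::runif(nrow(h), -jitter, jitter))
}

# count_matrix with an explicitly injected lognorm layer (for exact-value
# activation/pseudotime tests independent of the normalization arithmetic)
cm_with_layer <- function(lognorm) {
  cm <- count_matrix(matrix(1L, nrow(lognorm), ncol(lognorm),
                            dimnames = dimnames(lognorm)))
  cm$layers$lognorm <- lognorm
  cm
}

# ---- oracles ----

# all-pairs distance-threshold adjacency, as index pairs i < j
oracle_adjacency <- function(grid, tol = 1.05) {
  xy <- cbind(grid$x, grid$y)
  n <- nrow(xy)
  dmin <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (dij > 0 && dij < dmin) dmin <- dij
  }
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (dij <= tol * dmin) out <- rbind(out, c(i, j))
  }
  out
}

# neighbor-pair label counts as a named vector "A|B" (sorted labels)
oracle_pair_counts <- function(grid, labels, tol = 1.05) {
  adj <- oracle_adjacency(grid, tol)
  cnt <- list()
  if (!is.null(adj)) for (e in seq_len(nrow(adj))) {
    li <- labels[adj[e, 1]]; lj <- labels[adj[e, 2]]
    if (li == "unassigned" || lj == "unassigned") next
    key <- paste(sort(c(li, lj)), collapse = "|")
    cnt[[key]] <- (if (is.null(cnt[[key]])) 0 else cnt[[key]]) + 1
  }
  unlist(cnt)
}

# vectorized variant for large batches (independent route: string keys over
# which() hits on the distance matrix)
oracle_pair_counts_fast <- function(grid, labels, tol = 1.05) {
  d <- as.matrix(stats::dist(cbind(grid$x, grid$y)))
  pos <- d[upper.tri(d)]
  pitch <- min(pos[pos > 0])
  hit <- which(upper.tri(d) & d > 0 & d <= tol * pitch, arr.ind = TRUE)
  li <- labels[hit[, 1]]; lj <- labels[hit[, 2]]
  keep <- li != "unassigned" & lj != "unassigned"
  if (!any(keep)) return(NULL)
  key <- apply(cbind(li[keep], lj[keep]), 1,
               function(p) paste(sort(p), collapse = "|"))
  tab <- table(key)
  stats::setNames(as.numeric(tab), names(tab))
}

profile_as_keys <- function(profile) {
  pc <- profile$pair_counts
  ut <- which(upper.tri(pc, diag = TRUE) & pc > 0, arr.ind = TRUE)
  if (!nrow(ut)) return(NULL)
  keys <- apply(ut, 1, function(ij)
    paste(sort(c(rownames(pc)[ij[1]], colnames(pc)[ij[2]])), collapse = "|"))
  stats::setNames(as.numeric(pc[ut]), keys)
}

# direct double-sum Moran's I
oracle_moran_i <- function(adj, values) {
  n <- length(values)
  z <- values - mean(values)
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(adj))) {
    W[adj[e, 1], adj[e, 2]] <- 1
    W[adj[e, 2], adj[e, 1]] <- 1
  }
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# all permutations of 1..n (recursive, independent of the package's version)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))))
}

# exhaustive two-sided permutation p for |mean diff|, +1 on both sides,
# enumerating all C(n, na) group splits
oracle_perm_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  splits <- utils::combn(length(pooled), na)
  t_obs <- abs(mean(a) - mean(b))
  cnt <- 0
  for (k in seq_len(ncol(splits))) {
    ix <- splits[, k]
    if (abs(mean(pooled[ix]) - mean(pooled[-ix])) >= t_obs - 1e-12)
      cnt <- cnt + 1
  }
  (1 + cnt) / (1 + ncol(splits))
}

# exact two-sided rank-sum p by enumeration of all group splits
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (length(pooled) + 1) / 2
  splits <- utils::combn(length(pooled), na)
  w_all <- apply(splits, 2, function(ix) sum(r[ix]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# normal-approximation rank-sum z with tie correction, two-sided
oracle_ranksum_normal <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  2 * stats::pnorm(-abs(w - mu) / sqrt(sig2))
}

# best hop-minimal path via igraph enumeration + the documented tie-breaks
oracle_best_path <- function(cg, from, to) {
  keep <- cg$edges$weight >= cg$prune_threshold
  e <- cg$edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE, vertices = cg$clusters$cluster)
  if (from == to) return(from)
  sp <- suppressWarnings(igraph::all_simple_paths(g, from, to))
  if (!length(sp)) return(NULL)
  paths <- lapply(sp, function(p) names(p))
  len <- lengths(paths)
  paths <- paths[len == min(len)]
  wmin <- vapply(paths, function(p) {
    min(vapply(seq_len(length(p) - 1), function(i) {
      eid <- igraph::get_edge_ids(g, c(p[i], p[i + 1]))
      igraph::E(g)$weight[eid]
    }, numeric(1)))
  }, numeric(1))
  paths <- paths[wmin >= max(wmin) - 1e-12]
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths[[order(keys)[1]]]
}

random_test_graph <- function(n_nodes, p_edge = 0.35) {
  ids <- sprintf("k%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2))
  on <- stats::runif(nrow(pairs)) < p_edge
  make_cluster_graph(data.frame(from = ids[pairs[on, 1]],
                                to = ids[pairs[on, 2]],
                                weight = round(stats::runif(sum(on)), 3)),
                     clusters = ids)
}

# brute-force union kNN edges
oracle_knn <- function(embedding, k) {
  n <- nrow(embedding)
  edges <- NULL
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(embedding) - embedding[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# orthogonal-projection path ordering oracle
oracle_polyline_order <- function(grid, polyline, radius) {
  p <- cbind(grid$x, grid$y)
  n <- nrow(p)
  arc0 <- c(0, cumsum(sqrt(rowSums(diff(polyline)^2))))
  best_d <- rep(Inf, n); best_arc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    for (s in seq_len(nrow(polyline) - 1)) {
      a <- polyline[s, ]; b <- polyline[s + 1, ]
      v <- b - a; L2 <- sum(v^2)
      tt <- if (L2 > 0) min(1, max(0, sum((p[i, ] - a) * v) / L2)) else 0
      proj <- a + tt * v
      d <- sqrt(sum((p[i, ] - proj)^2))
      if (d < best_d[i]) { best_d[i] <- d
        best_arc[i] <- arc0[s] + tt * sqrt(L2) }
    }
  }
  keep <- best_d <= radius
  ord <- order(best_arc[keep], best_d[keep], grid$spots[keep])
  grid$spots[keep][ord]
}

hex_grid_for_tests <- function(radius) {
  h <- hex_lattice(radius, "hx")
  spot_grid(h$barcode, h$array_row, h$array_col, h$x, h$y)
}
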