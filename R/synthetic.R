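# Synthetic Visium-like tissue/organoid samples and single-cell datasets with
# known ground truth. The generator encodes the structural assumptions the
# downstream stages rely on: a hexagonal spot lattice, a progenitor-to-mature
# maturation axis tilting the cell-type mixture, timepoint-dependent
# composition, negative-binomial counts tied to type signatures, and organoids
# whose composition interpolates two tissue timepoints with a known weight.

#' Configuration for the synthetic data generator
#'
#' Defaults describe the study conditions the package is designed around:
#' fetal midbrain analogs at 7, 11 and 17 post-conceptional weeks (PCW) with
#' a ventricular-zone-like progenitor domain grading into mature types, and
#' organoid analogs at differentiation days 40/70/120 whose niche composition
#' interpolates between two tissue timepoints.
#'
#' @param seed Integer master seed; every stochastic draw derives from it.
#' @param n_types Number of cell types K (ordered from most progenitor-like
#'   to most mature).
#' @param grid_radius Hex rings of the tissue lattice (spots = 1 + 3r(r+1)).
#' @param organoid_radius Hex rings of the disc-shaped organoid lattice.
#' @param dirichlet_alpha Per-type positive Dirichlet concentrations for the
#'   spot mixtures (length `n_types` or scalar).
#' @param gradient_strength Nonnegative; how strongly the mixture tilts from
#'   progenitor types at the immature edge/core to mature types opposite.
#' @param timepoint_shift Nonnegative; how strongly the sample timepoint
#'   shifts the overall composition from progenitor-rich (early) to
#'   mature-rich (late).
#' @param n_genes Number of genes.
#' @param nb_mean Optional per-gene base means; drawn lognormal if `NULL`.
#' @param nb_dispersion Negative-binomial dispersion theta
#'   (variance = mu + mu^2/theta).
#' @param abundance_noise_shape Gamma shape of the multiplicative noise
#'   applied to the true mixture to emulate deconvolution uncertainty
#'   (larger = cleaner).
#' @param module_spec List of `list(id =, n_genes =, effect =)` gene modules
#'   for the single-cell generator; `effect` is the log-fold change of the
#'   module genes across the full pseudotime range.
#' @param mix_alpha Default organoid interpolation weight in \[0, 1\].
#' @param timepoints List of [sample_meta()] describing the samples the study
#'   design contains; the tissue entries define the PCW range used to tilt
#'   composition by age.
#' @param n_cells Cells in the single-cell generator.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_types = 4L,
                             grid_radius = 8L,
                             organoid_radius = 7L,
                             dirichlet_alpha = 2,
                             gradient_strength = 3,
                             timepoint_shift = 1.2,
                             n_genes = 150L,
                             nb_mean = NULL,
                             nb_dispersion = 2,
                             abundance_noise_shape = 50,
                             module_spec = list(
                               list(id = "m1", n_genes = 10L, effect = 1.0),
                               list(id = "m2", n_genes = 10L, effect = 0.5),
                               list(id = "m3", n_genes = 10L, effect = 0.0)),
                             mix_alpha = 0.5,
                             timepoints = default_timepoints(),
                             n_cells = 1000L) {
  if (length(dirichlet_alpha) == 1)
    dirichlet_alpha <- rep(dirichlet_alpha, n_types)
  if (length(dirichlet_alpha) != n_types)
    stop_param("dirichlet_alpha must have length 1 or n_types")
  if (any(dirichlet_alpha <= 0)) stop_param("dirichlet_alpha must be > 0")
  if (nb_dispersion <= 0) stop_param("nb_dispersion must be > 0")
  if (mix_alpha < 0 || mix_alpha > 1) stop_param("mix_alpha must be in [0, 1]")
  if (gradient_strength < 0) stop_param("gradient_strength must be >= 0")
  if (n_types < 2) stop_param("need at least 2 cell types")
  structure(list(seed = as.integer(seed), n_types = as.integer(n_types),
                 grid_radius = as.integer(grid_radius),
                 organoid_radius = as.integer(organoid_radius),
                 dirichlet_alpha = dirichlet_alpha,
                 gradient_strength = gradient_strength,
                 timepoint_shift = timepoint_shift,
                 n_genes = as.integer(n_genes), nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion,
                 abundance_noise_shape = abundance_noise_shape,
                 module_spec = module_spec, mix_alpha = mix_alpha,
                 timepoints = timepoints, n_cells = as.integer(n_cells)),
            class = "synthetic_config")
}

default_timepoints <- function() {
  list(sample_meta("tissue_7pcw", "tissue", 7),
       sample_meta("tissue_11pcw", "tissue", 11),
       sample_meta("tissue_17pcw", "tissue", 17),
       sample_meta("organoid_d40", "organoid", 40),
       sample_meta("organoid_d70", "organoid", 70),
       sample_meta("organoid_d120", "organoid", 120))
}

# Deterministic sub-seed below 2^31 from the master seed and a string key, so
# each generated object is reproducible independently of call order.
mb_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 1e6) * 10007) %% 2147483647)
}

#' Hexagonal lattice in Visium array coordinates
#'
#' Axial hex coordinates within `radius` rings of the origin, converted to
#' the Visium array convention (array_row = r, array_col = 2q + r, so the six
#' neighbors differ by (0, +/-2) and (+/-1, +/-1)) and to physical positions
#' with unit center-to-center pitch.
#'
#' @param radius Number of rings (>= 1); yields 1 + 3r(r+1) spots.
#' @param prefix Barcode prefix.
#' @return A data.frame with q, r, array_row, array_col, x, y, barcode.
#' @export
hex_lattice <- function(radius, prefix = "spot") {
  if (radius < 1) stop_param("radius must be >= 1")
  qr <- expand.grid(q = -radius:radius, r = -radius:radius)
  qr <- qr[(abs(qr$q) + abs(qr$r) + abs(qr$q + qr$r)) / 2 <= radius, ]
  qr <- qr[order(qr$r, qr$q), ]
  data.frame(q = qr$q, r = qr$r,
             array_row = qr$r, array_col = 2L * qr$q + qr$r,
             x = qr$q + qr$r / 2, y = qr$r * sqrt(3) / 2,
             barcode = sprintf("%s_%03d", prefix, seq_len(nrow(qr))))
}

hex_grid <- function(radius, prefix, meta = NULL) {
  h <- hex_lattice(radius, prefix)
  spot_grid(h$barcode, h$array_row, h$array_col, h$x, h$y, meta = meta)
}

# Per-type "maturity" positions, evenly spaced in [0, 1] from the most
# progenitor-like type to the most mature.
type_maturity <- function(K) seq(0, 1, length.out = K)

type_names <- function(K) {
  base <- c("ProgFP", "RglLate", "NbDA", "DA", "Astro", "Oligo")
  if (K <= length(base)) base[seq_len(K)] else sprintf("type%02d", seq_len(K))
}

# Normalized timepoint in [-1, 1] over the configured tissue PCW range.
timepoint_norm <- function(cfg, pcw) {
  tps <- vapply(Filter(function(m) m$kind == "tissue", cfg$timepoints),
                `[[`, numeric(1), "timepoint_value")
  if (length(tps) < 2 || diff(range(tps)) == 0) return(0)
  (pcw - mean(range(tps))) / (diff(range(tps)) / 2)
}

# Dirichlet concentration at maturation coordinate m for a sample at
# normalized timepoint tnorm: progenitor types enriched at low m / early t,
# mature types at high m / late t.
tilted_alpha <- function(cfg, m, tnorm) {
  u <- 2 * type_maturity(cfg$n_types) - 1
  outer(2 * m - 1, u, function(mm, uu)
    exp(cfg$gradient_strength * mm * uu)) *
    matrix(exp(cfg$timepoint_shift * tnorm * u), length(m), cfg$n_types,
           byrow = TRUE) *
    matrix(cfg$dirichlet_alpha, length(m), cfg$n_types, byrow = TRUE)
}

rdirichlet_rows <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow(alpha))
  g / rowSums(g)
}

# Per-gene base means, type signatures and maturation slopes, deterministic
# given cfg$seed so every sample of one study shares a single gene model.
gene_model <- function(cfg) {
  set.seed(mb_seed(cfg$seed, "gene_model"))
  G <- cfg$n_genes; K <- cfg$n_types
  base <- cfg$nb_mean
  if (is.null(base)) base <- stats::rlnorm(G, meanlog = log(2), sdlog = 0.6)
  if (length(base) != G) stop_param("nb_mean must have length n_genes")
  if (any(base <= 0)) stop_param("nb_mean must be positive")
  n_marker <- floor(0.6 * G)
  marker_type <- rep_len(seq_len(K), n_marker)
  n_mat <- floor(0.2 * G)
  fold <- matrix(1, K, G)
  for (g in seq_len(n_marker)) fold[marker_type[g], g] <- 8
  mat_slope <- numeric(G)
  mat_idx <- n_marker + seq_len(n_mat)
  mat_slope[mat_idx] <- sample(c(-1.5, 1.5), n_mat, replace = TRUE)
  genes <- sprintf("gene%03d", seq_len(G))
  list(genes = genes, base = base, fold = fold, mat_slope = mat_slope,
       marker_type = marker_type, maturation_genes = genes[mat_idx])
}

nb_counts <- function(mixture, maturation, gm, cfg, libsize = 2000) {
  mu <- (mixture %*% (gm$fold * matrix(gm$base, cfg$n_types, cfg$n_genes,
                                       byrow = TRUE))) *
    exp(outer(maturation - 0.5, gm$mat_slope))
  mu <- mu * libsize / mean(rowSums(mu))
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                nrow(mu))
  cnt
}

make_abundance <- function(mixture, spots, types) {
  noise <- matrix(stats::rgamma(length(mixture), shape = 50, rate = 50),
                  nrow(mixture))
  ab <- mixture * noise
  dimnames(ab) <- list(spots, types)
  abundance_matrix(ab)
}

ground_truth <- function(mixture, maturation, meta, tnorm,
                         mix_alpha = NA_real_, implied_timepoint = NA_real_,
                         pseudotime = NULL) {
  structure(list(mixture = mixture, maturation = maturation, meta = meta,
                 tnorm = tnorm, mix_alpha = mix_alpha,
                 implied_timepoint = implied_timepoint,
                 pseudotime = pseudotime),
            class = "ground_truth")
}

#' Generate a synthetic tissue section
#'
#' Hexagonal lattice of Visium-like spots whose cell-type mixture follows a
#' maturation gradient along the tissue's y axis (ventricular-zone-like
#' progenitor edge at low y, mature types opposite) and whose overall
#' composition shifts with the sample's gestational age. Counts are
#' negative-binomial around mixture-weighted type signatures; the returned
#' abundance matrix is the true mixture under multiplicative gamma noise,
#' emulating a deconvolution output.
#'
#' @param cfg A [synthetic_config()].
#' @param meta A [sample_meta()] with `kind = "tissue"`.
#' @return A list with `grid` ([spot_grid()]), `abundance`
#'   ([abundance_matrix()]), `counts` ([count_matrix()]) and `truth`
#'   (per-spot true mixture and maturation coordinate).
#' @export
generate_tissue_sample <- function(cfg, meta) {
  if (!inherits(meta, "sample_meta") || meta$kind != "tissue")
    stop_param("meta must be a tissue sample_meta")
  if (cfg$grid_radius < 1) stop_param("grid_radius must be >= 1")
  set.seed(mb_seed(cfg$seed, paste0("tissue:", meta$sample_id, ":",
                                    meta$replicate)))
  gm <- gene_model(cfg)  # re-seeds; per-sample seed restored below
  set.seed(mb_seed(cfg$seed, paste0("tissue-draw:", meta$sample_id, ":",
                                    meta$replicate)))
  grid <- hex_grid(cfg$grid_radius, meta$sample_id, meta)
  m <- (grid$y - min(grid$y)) / max(diff(range(grid$y)), .Machine$double.eps)
  tnorm <- timepoint_norm(cfg, meta$timepoint_value)
  mixture <- rdirichlet_rows(tilted_alpha(cfg, m, tnorm))
  colnames(mixture) <- type_names(cfg$n_types)
  rownames(mixture) <- grid$spots
  ab <- make_abundance(mixture, grid$spots, colnames(mixture))
  cnt <- nb_counts(mixture, m, gm, cfg)
  cm <- count_matrix(cnt, entities = grid$spots, genes = gm$genes)
  list(grid = grid, abundance = ab, counts = cm,
       truth = ground_truth(mixture, m, meta, tnorm))
}

#' Generate a synthetic organoid interpolating two tissue timepoints
#'
#' Disc-shaped lattice with a progenitor core grading into a mature
#' periphery. At each spot with maturation coordinate m, the mixture is
#' `(1 - alpha) * z_A(m) + alpha * z_B(m)` where `z_X(m)` is a Dirichlet draw
#' under tissue X's age-tilted concentration at the matched coordinate, so
#' the expected mixture field interpolates the two tissues with weight
#' `mix_alpha` and the implied timepoint is
#' `(1 - alpha) * t_A + alpha * t_B`.
#'
#' @param cfg A [synthetic_config()].
#' @param tissue_a,tissue_b `truth` entries from [generate_tissue_sample()]
#'   at distinct timepoints.
#' @param mix_alpha Interpolation weight in \[0, 1\].
#' @param meta A [sample_meta()] with `kind = "organoid"`.
#' @return As [generate_tissue_sample()]; `truth` also carries `mix_alpha`
#'   and the implied timepoint.
#' @export
generate_organoid_sample <- function(cfg, tissue_a, tissue_b,
                                     mix_alpha = cfg$mix_alpha, meta) {
  if (!inherits(tissue_a, "ground_truth") || !inherits(tissue_b, "ground_truth"))
    stop_param("tissue_a/tissue_b must be ground_truth from generate_tissue_sample")
  if (!is.numeric(mix_alpha) || length(mix_alpha) != 1 ||
      is.na(mix_alpha) || mix_alpha < 0 || mix_alpha > 1)
    stop_param("mix_alpha must be in [0, 1]")
  if (!inherits(meta, "sample_meta") || meta$kind != "organoid")
    stop_param("meta must be an organoid sample_meta")
  gm <- gene_model(cfg)
  set.seed(mb_seed(cfg$seed, paste0("organoid:", meta$sample_id, ":",
                                    meta$replicate, ":", mix_alpha)))
  grid <- hex_grid(cfg$organoid_radius, meta$sample_id, meta)
  rad <- sqrt(grid$x^2 + grid$y^2)
  # radial grading core -> periphery, with the coordinate distribution
  # quantile-matched to the tissue's so the two lattices weight maturation
  # stages comparably (a raw radial coordinate over-represents the periphery)
  n_sp <- length(rad)
  m <- as.numeric(stats::quantile(
    tissue_a$maturation,
    probs = (rank(rad, ties.method = "average") - 0.5) / n_sp, type = 7))
  # The organoid is composed of two contiguous angular sectors: a fraction
  # mix_alpha of the disc follows tissue B's age-tilted composition at the
  # matched maturation coordinate, the rest tissue A's. Contiguity keeps
  # neighboring spots mostly within one regime, so the neighbor-pair
  # statistics interpolate linearly in mix_alpha (pair frequencies are
  # quadratic in label proportions, so interpolating each spot's mixture
  # pointwise would bias the pair profile toward the younger tissue); the
  # sector orientation is random, so each spot's expected mixture over that
  # orientation is (1 - alpha) * A + alpha * B at its coordinate.
  theta <- (atan2(grid$y, grid$x) + stats::runif(1, 0, 2 * pi)) %% (2 * pi)
  in_b <- theta < 2 * pi * mix_alpha
  ca <- tilted_alpha(cfg, m, tissue_a$tnorm)
  cb <- tilted_alpha(cfg, m, tissue_b$tnorm)
  conc <- ca
  conc[in_b, ] <- cb[in_b, ]
  mixture <- rdirichlet_rows(conc)
  colnames(mixture) <- type_names(cfg$n_types)
  rownames(mixture) <- grid$spots
  ab <- make_abundance(mixture, grid$spots, colnames(mixture))
  cnt <- nb_counts(mixture, m, gm, cfg)
  cm <- count_matrix(cnt, entities = grid$spots, genes = gm$genes)
  t_a <- tissue_a$meta$timepoint_value
  t_b <- tissue_b$meta$timepoint_value
  list(grid = grid, abundance = ab, counts = cm,
       truth = ground_truth(mixture, m, meta, NA_real_, mix_alpha,
                            (1 - mix_alpha) * t_a + mix_alpha * t_b))
}

#' Generate a synthetic single-cell dataset with a lineage and gene modules
#'
#' Cells sit on a latent pseudotime in \[0, 1\]; cell-type labels progress
#' root -> intermediate -> terminal along it, cluster labels cut it into five
#' segments, and module genes change log-linearly with pseudotime at the
#' effect sizes given in `cfg$module_spec`. Replicate and timepoint labels
#' are assigned so the per-replicate HVG scheme and group comparisons are
#' exercisable: later cells are more likely to carry the later timepoint.
#'
#' @param cfg A [synthetic_config()].
#' @param n_timepoints Number of collection timepoints (>= 2 for the HVG
#'   intersect/union scheme).
#' @return A list with `counts` ([count_matrix()]), `cells` (a data.frame of
#'   per-cell metadata: donor, model, timepoint, replicate, cell_type,
#'   cluster), `modules` (named list of module gene ids) and `truth`
#'   (true pseudotime and module effects).
#' @export
generate_single_cell_dataset <- function(cfg, n_timepoints = 2L) {
  if (!length(cfg$module_spec)) stop_param("module_spec must be non-empty")
  if (n_timepoints < 2)
    stop_param("need >= 2 timepoints for the HVG intersect/union scheme")
  set.seed(mb_seed(cfg$seed, "single_cell"))
  n <- cfg$n_cells; G <- cfg$n_genes
  t <- stats::runif(n)
  genes <- sprintf("gene%03d", seq_len(G))
  base <- stats::rlnorm(G, meanlog = log(2), sdlog = 0.5)
  slope <- numeric(G)
  # stage markers: three blocks peaking early / mid / late, driving PC1
  n_marker <- floor(0.3 * G)
  stage <- rep_len(1:3, n_marker)
  # module genes: taken after the markers, with the configured effects
  idx <- n_marker
  modules <- list(); mod_effect <- numeric(0)
  for (ms in cfg$module_spec) {
    gi <- idx + seq_len(ms$n_genes)
    if (max(gi) > G) stop_param("n_genes too small for module_spec")
    modules[[ms$id]] <- genes[gi]
    slope[gi] <- ms$effect
    mod_effect[ms$id] <- ms$effect
    idx <- max(gi)
  }
  # extra trend genes so pseudotime is identifiable from expression
  n_trend <- min(G - idx, 40L)
  trend_idx <- idx + seq_len(n_trend)
  if (n_trend > 0)
    slope[trend_idx] <- sample(c(-1.5, 1.5), n_trend, TRUE)
  logmu <- matrix(log(base), n, G, byrow = TRUE) +
    outer(t - 0.5, slope)
  peak <- c(0.1, 0.5, 0.9)[stage]
  logmu[, seq_len(n_marker)] <- logmu[, seq_len(n_marker)] +
    2 * exp(-((outer(t, peak, "-"))^2) / (2 * 0.15^2))
  cnt <- matrix(stats::rnbinom(n * G, mu = exp(logmu),
                               size = cfg$nb_dispersion), n)
  cells <- sprintf("cell%04d", seq_len(n))
  cm <- count_matrix(cnt, entities = cells, genes = genes)
  cell_type <- cut(t, c(-Inf, 1 / 3, 2 / 3, Inf),
                   labels = c("progenitor", "intermediate", "terminal"))
  cluster <- paste0("c", as.integer(cut(t, seq(0, 1, 0.2),
                                        include.lowest = TRUE)))
  tp_levels <- paste0("t", seq_len(n_timepoints))
  centers <- seq(0.2, 0.8, length.out = n_timepoints)
  tp <- vapply(t, function(ti) {
    sample(tp_levels, 1, prob = stats::dnorm(ti, centers, 0.25))
  }, character(1))
  meta <- data.frame(cell = cells,
                     donor = "donor1", model = "synthetic",
                     timepoint = tp,
                     replicate = sample(c("r1", "r2"), n, TRUE),
                     cell_type = as.character(cell_type),
                     cluster = cluster,
                     stringsAsFactors = FALSE)
  list(counts = cm, cells = meta, modules = modules,
       truth = list(pseudotime = t, module_effect = mod_effect,
                    trend_genes = genes[trend_idx],
                    gene_slope = stats::setNames(slope, genes),
                    root_cluster = "c1", terminal_cluster = "c5"))
}

#' Generate a per-spot test field on a grid
#'
#' Fixture fields for spatial statistics: `constant` (all 1), `checkerboard`
#' (alternating +/-1 by lattice parity), `smooth_gradient` (linear in
#' physical x) or `iid_noise` (independent standard normals).
#'
#' @param grid A [spot_grid()].
#' @param pattern One of `"constant"`, `"checkerboard"`, `"smooth_gradient"`,
#'   `"iid_noise"`.
#' @param seed Seed used by `iid_noise`.
#' @return Numeric vector over the grid's spots.
#' @export
generate_field <- function(grid, pattern = c("constant", "checkerboard",
                                             "smooth_gradient", "iid_noise"),
                           seed = 1L) {
  if (!length(grid$spots)) stop_param("empty grid")
  pattern <- tryCatch(match.arg(pattern),
                      error = function(e) stop_param("unknown field pattern"))
  switch(pattern,
    constant = rep(1, length(grid$spots)),
    checkerboard = {
      rc <- grid$array_row + grid$array_col
      parity <- if (all(rc %% 2 == 0)) {
        # Visium convention: col parity == row parity; use axial q + r
        q <- (grid$array_col - grid$array_row) / 2
        (q + grid$array_row) %% 2
      } else rc %% 2
      ifelse(parity == 0, 1, -1)
    },
    smooth_gradient = as.numeric(scale(grid$x, scale = FALSE)),
    iid_noise = { set.seed(seed); stats::rnorm(length(grid$spots)) })
}

#' Write a generated sample in the formats the readers accept
#'
#' Emits the spot-position CSV, the MTX triplet with barcode/feature lists,
#' and the abundance table, so synthetic and real data follow one code path.
#'
#' @param sample A list from [generate_tissue_sample()] or
#'   [generate_organoid_sample()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spot_positions(sample$grid, file.path(dir, "tissue_positions.csv"))
  write_mtx_counts(sample$counts, file.path(dir, "matrix.mtx"),
                   file.path(dir, "barcodes.tsv"),
                   file.path(dir, "features.tsv"))
  ab <- data.frame(barcode = sample$abundance$spots, sample$abundance$values,
                   check.names = FALSE)
  utils::write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
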