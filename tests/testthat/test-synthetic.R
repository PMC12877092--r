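# The synthetic-data generator: lattice geometry, mixture structure,
# determinism, and the statistical features downstream stages assume.

test_that("hex lattices have the ring count and Visium neighbor offsets", {
  for (r in 1:4)
    expect_equal(nrow(hex_lattice(r)), 1 + 3 * r * (r + 1))
  h <- hex_lattice(1)
  grid <- build_adjacency(spot_grid(h$barcode, h$array_row, h$array_col,
                                    h$x, h$y))
  deg <- tabulate(c(grid$adjacency), nbins = 7)
  center <- which(h$q == 0 & h$r == 0)
  expect_equal(deg[center], 6)
  # Visium convention: array col parity equals row parity
  expect_true(all((h$array_col - h$array_row) %% 2 == 0))
  expect_error(hex_lattice(0), class = "mbstage_parameter_error")
})

test_that("tissue samples are deterministic given the seed", {
  cfg <- synthetic_config(seed = 42, grid_radius = 3L)
  meta <- sample_meta("t11", "tissue", 11)
  s1 <- generate_tissue_sample(cfg, meta)
  s2 <- generate_tissue_sample(cfg, meta)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$abundance$values, s2$abundance$values)
  expect_identical(s1$truth$mixture, s2$truth$mixture)
})

test_that("mixtures are simplex points and counts are valid", {
  cfg <- synthetic_config(seed = 7, grid_radius = 4L)
  s <- generate_tissue_sample(cfg, sample_meta("t", "tissue", 11))
  expect_true(all(abs(rowSums(s$truth$mixture) - 1) < 1e-9))
  expect_true(all(s$counts$counts >= 0))
  expect_true(all(s$counts$counts == round(s$counts$counts)))
  expect_true(all(s$abundance$values >= 0))
})

test_that("zero gradient recovers the analytic Dirichlet mean", {
  cfg <- synthetic_config(seed = 3, grid_radius = 12L, gradient_strength = 0,
                          timepoint_shift = 0,
                          dirichlet_alpha = c(1, 2, 3, 4))
  s <- generate_tissue_sample(cfg, sample_meta("t", "tissue", 11))
  n <- nrow(s$truth$mixture)
  expect_gt(n, 450)
  expected <- c(1, 2, 3, 4) / 10
  # Dirichlet component sd ~ sqrt(p(1-p)/(a0+1)); 3 standard errors
  se <- sqrt(expected * (1 - expected) / 11) / sqrt(n)
  expect_true(all(abs(colMeans(s$truth$mixture) - expected) < 3.5 * se))
})

test_that("mature-type abundance tracks the maturation coordinate", {
  for (s in 1:5) {
    cfg <- synthetic_config(seed = s, grid_radius = 12L)
    smp <- generate_tissue_sample(cfg, sample_meta("t", "tissue", 11))
    mature <- smp$truth$mixture[, ncol(smp$truth$mixture)]
    rho <- cor(mature, smp$truth$maturation, method = "spearman")
    expect_gt(rho, 0.5)
  }
})

test_that("organoid boundaries reproduce the parent tissues", {
  cfg <- synthetic_config(seed = 5, grid_radius = 5L, organoid_radius = 5L)
  a <- generate_tissue_sample(cfg, sample_meta("a", "tissue", 11))
  b <- generate_tissue_sample(cfg, sample_meta("b", "tissue", 17))
  o0 <- generate_organoid_sample(cfg, a$truth, b$truth, 0,
                                 sample_meta("o0", "organoid", 40))
  o1 <- generate_organoid_sample(cfg, a$truth, b$truth, 1,
                                 sample_meta("o1", "organoid", 40))
  # at the boundaries the mean mixture matches the corresponding tissue's
  expect_lt(max(abs(colMeans(o0$truth$mixture) - colMeans(a$truth$mixture))),
            0.06)
  expect_lt(max(abs(colMeans(o1$truth$mixture) - colMeans(b$truth$mixture))),
            0.06)
  # implied timepoint is the linear interpolation
  oh <- generate_organoid_sample(cfg, a$truth, b$truth, 0.5,
                                 sample_meta("oh", "organoid", 40))
  expect_equal(oh$truth$implied_timepoint, 14)
  expect_equal(o0$truth$implied_timepoint, 11)
  expect_equal(o1$truth$implied_timepoint, 17)
  expect_error(generate_organoid_sample(cfg, a$truth, b$truth, 1.2,
                                        sample_meta("x", "organoid", 40)),
               class = "mbstage_parameter_error")
})

test_that("single-cell datasets carry lineage and module structure", {
  cfg <- synthetic_config(seed = 2, n_cells = 1000L)
  sc <- generate_single_cell_dataset(cfg)
  sc2 <- generate_single_cell_dataset(cfg)
  expect_identical(sc$counts$counts, sc2$counts$counts)
  expect_identical(sc$cells, sc2$cells)
  expect_setequal(unique(sc$cells$cluster), paste0("c", 1:5))
  # cell type progresses along true pseudotime
  t <- sc$truth$pseudotime
  expect_lt(max(t[sc$cells$cell_type == "progenitor"]), 1 / 3 + 1e-9)
  expect_gt(min(t[sc$cells$cell_type == "terminal"]), 2 / 3 - 1e-9)
  # monotone module: mean activation increases across pseudotime quintiles
  cm <- lognormalize(sc$counts)
  ms <- activation_score(cm, sc$modules)
  q <- cut(t, quantile(t, seq(0, 1, 0.2)), include.lowest = TRUE)
  trend <- tapply(ms$scores[, "m1"], q, mean)
  expect_true(all(diff(trend) > 0))
  # null module: activation essentially unrelated to pseudotime
  expect_lt(abs(cor(ms$scores[, "m3"], t)), 0.2)
  expect_error(generate_single_cell_dataset(cfg, n_timepoints = 1),
               class = "mbstage_parameter_error")
})

test_that("field patterns follow their definitions", {
  g <- make_square_grid(2, 2)
  expect_equal(generate_field(g, "checkerboard"), c(1, -1, -1, 1))
  expect_equal(var(generate_field(g, "constant")), 0)
  expect_identical(generate_field(g, "iid_noise", seed = 9),
                   generate_field(g, "iid_noise", seed = 9))
  expect_error(generate_field(g, "swirl"), class = "mbstage_parameter_error")
  # checkerboard alternates on the hex lattice too (no constant parity trap)
  hx <- hex_grid_for_tests(2)
  f <- generate_field(hx, "checkerboard")
  expect_setequal(unique(f), c(-1, 1))
})

test_that("generated samples round-trip through the io readers", {
  cfg <- synthetic_config(seed = 8, grid_radius = 2L)
  s <- generate_tissue_sample(cfg, sample_meta("t", "tissue", 11))
  dir <- withr::local_tempdir()
  write_sample(s, dir)
  grid <- suppressMessages(
    read_spot_positions(file.path(dir, "tissue_positions.csv")))
  expect_identical(grid$spots, s$grid$spots)
  cm <- read_mtx_counts(file.path(dir, "matrix.mtx"),
                        file.path(dir, "barcodes.tsv"),
                        file.path(dir, "features.tsv"))
  expect_equal(unname(cm$counts), unname(s$counts$counts * 1.0))
  ab <- read_id_table(file.path(dir, "abundance.tsv"))
  expect_equal(as.matrix(ab), s$abundance$values, tolerance = 1e-6,
               ignore_attr = TRUE)
})
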