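# Readers/writers for the standard formats the pipeline touches, the
# scale-factor log-normalization, and the shared containers.

#' Construct a count matrix
#'
#' The package's basic expression container: an entity-by-gene matrix of
#' nonnegative integer counts (entities are cell or spot barcodes) plus
#' optional derived layers of identical shape (e.g. `"lognorm"`).
#'
#' @param counts Numeric matrix, entities in rows, genes in columns. Row and
#'   column names are taken as entity/gene ids unless `entities`/`genes` are
#'   given.
#' @param entities,genes Character vectors of unique ids; default to the
#'   dimnames of `counts`.
#' @param layers Named list of matrices with the same shape as `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, entities = rownames(counts),
                         genes = colnames(counts), layers = list()) {
  counts <- as.matrix(counts)
  if (is.null(entities) || is.null(genes))
    stop_validation("count_matrix needs entity and gene ids")
  entities <- as.character(entities)
  genes <- as.character(genes)
  if (length(entities) != nrow(counts) || length(genes) != ncol(counts))
    stop_validation("id lengths do not match count matrix dimensions")
  if (anyDuplicated(entities)) stop_validation("duplicate entity ids")
  if (anyDuplicated(genes)) stop_validation("duplicate gene ids")
  if (any(counts < 0)) stop_validation("negative counts")
  if (any(counts != round(counts))) stop_validation("non-integer counts")
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), dim(counts)))
      stop_validation(sprintf("layer '%s' shape differs from counts", nm))
  }
  dimnames(counts) <- list(entities, genes)
  structure(list(counts = counts, entities = entities, genes = genes,
                 layers = layers),
            class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d entities x %d genes; layers: %s\n",
              length(x$entities), length(x$genes),
              if (length(x$layers)) paste(names(x$layers), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Sample metadata
#'
#' @param sample_id Sample identifier.
#' @param kind `"tissue"` or `"organoid"`; determines the unit of
#'   `timepoint_value` (post-conceptional weeks for tissue, differentiation
#'   day for organoids).
#' @param timepoint_value Positive number on the scale implied by `kind`.
#' @param replicate Replicate label.
#' @return An object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, kind = c("tissue", "organoid"),
                        timepoint_value, replicate = "r1") {
  kind <- match.arg(kind)
  if (!is.numeric(timepoint_value) || length(timepoint_value) != 1 ||
      !is.finite(timepoint_value) || timepoint_value <= 0)
    stop_param("timepoint_value must be a single positive number")
  structure(list(sample_id = as.character(sample_id), kind = kind,
                 timepoint_value = timepoint_value,
                 replicate = as.character(replicate)),
            class = "sample_meta")
}

#' Spot lattice of one sample
#'
#' Holds spot ids, Visium array coordinates, physical coordinates and (after
#' [build_adjacency()]) the neighbor structure.
#'
#' @param spots Character vector of unique spot barcodes.
#' @param array_row,array_col Integer lattice coordinates (Visium array
#'   convention: column parity matches row parity, neighbors differ by
#'   (0, +/-2) or (+/-1, +/-1)).
#' @param x,y Physical center coordinates (arbitrary but common length unit).
#' @param meta Optional [sample_meta()].
#' @param adjacency Optional two-column integer matrix of spot-index pairs
#'   (i < j), usually filled in by [build_adjacency()].
#' @return An object of class `spot_grid`.
#' @export
spot_grid <- function(spots, array_row, array_col, x, y, meta = NULL,
                      adjacency = NULL) {
  spots <- as.character(spots)
  if (anyDuplicated(spots)) stop_validation("duplicate spot barcodes")
  n <- length(spots)
  if (any(lengths(list(array_row, array_col, x, y)) != n))
    stop_validation("coordinate lengths do not match number of spots")
  if (any(array_row != round(array_row)) || any(array_col != round(array_col)))
    stop_format("array coordinates must be integers")
  if (!is.null(adjacency)) adjacency <- validate_adjacency(adjacency, n)
  structure(list(spots = spots,
                 array_row = as.integer(array_row),
                 array_col = as.integer(array_col),
                 x = as.numeric(x), y = as.numeric(y),
                 meta = meta, adjacency = adjacency),
            class = "spot_grid")
}

validate_adjacency <- function(adjacency, n) {
  adjacency <- matrix(as.integer(adjacency), ncol = 2)
  if (nrow(adjacency)) {
    if (any(adjacency < 1) || any(adjacency > n))
      stop_validation("adjacency indices out of range")
    if (any(adjacency[, 1] == adjacency[, 2]))
      stop_validation("self-adjacency not allowed")
    adjacency <- t(apply(adjacency, 1, sort))
    adjacency <- unique(adjacency)
  }
  adjacency
}

#' @exportS3Method base::print
print.spot_grid <- function(x, ...) {
  cat(sprintf("spot_grid: %d spots; adjacency: %s; sample: %s\n",
              length(x$spots),
              if (is.null(x$adjacency)) "not built"
              else sprintf("%d edges", nrow(x$adjacency)),
              if (is.null(x$meta)) "unlabeled" else x$meta$sample_id))
  invisible(x)
}

#' Read Visium-style spot positions
#'
#' Parses the six-column `tissue_positions` dialect (barcode, in_tissue,
#' array_row, array_col, pxl_row, pxl_col). A header row is auto-detected by
#' attempting an integer parse of the second field, so both headered and
#' headerless generations of the format are accepted.
#'
#' @param path Path to the CSV file.
#' @param include_out_of_tissue Keep rows with `in_tissue = 0`? Default
#'   `FALSE`, the platform's usual filter.
#' @param meta Optional [sample_meta()] attached to the result.
#' @return A [spot_grid()] without adjacency; physical x/y are taken from the
#'   pixel columns (x = pxl_col, y = pxl_row). Spot order follows the file.
#'   The numbers of spots read/kept/filtered are reported via `message()`.
#' @export
read_spot_positions <- function(path, include_out_of_tissue = FALSE,
                                meta = NULL) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_format("empty spot-positions file")
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  if (length(first) != 6)
    stop_format("spot-positions rows must have 6 comma-separated fields")
  has_header <- is.na(suppressWarnings(as.integer(first[[2]])))
  tab <- utils::read.csv(text = lines, header = has_header,
                         colClasses = "character")
  if (ncol(tab) != 6)
    stop_format("spot-positions rows must have 6 comma-separated fields")
  names(tab) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row", "pxl_col")
  num <- lapply(tab[-1], function(col) suppressWarnings(as.numeric(col)))
  if (any(vapply(num, anyNA, logical(1))))
    stop_format("non-numeric field in spot-positions file")
  if (!all(num$in_tissue %in% c(0, 1)))
    stop_format("in_tissue flag must be 0 or 1")
  if (any(num$array_row != round(num$array_row)) ||
      any(num$array_col != round(num$array_col)))
    stop_format("array coordinates must be integers")
  if (anyDuplicated(tab$barcode)) stop_validation("duplicated spot barcode")
  keep <- if (include_out_of_tissue) rep(TRUE, nrow(tab)) else num$in_tissue == 1
  message(sprintf("read %d spots: kept %d, filtered %d (in_tissue)",
                  nrow(tab), sum(keep), sum(!keep)))
  spot_grid(spots = tab$barcode[keep],
            array_row = num$array_row[keep], array_col = num$array_col[keep],
            x = num$pxl_col[keep], y = num$pxl_row[keep], meta = meta)
}

#' Write spot positions in the `tissue_positions` dialect
#'
#' @param grid A [spot_grid()].
#' @param path Output CSV path.
#' @param header Write a header row? Default `FALSE` (headerless generation).
#' @export
write_spot_positions <- function(grid, path, header = FALSE) {
  tab <- data.frame(barcode = grid$spots, in_tissue = 1L,
                    array_row = grid$array_row, array_col = grid$array_col,
                    pxl_row = grid$y, pxl_col = grid$x)
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' Read a MatrixMarket count triplet with barcode and feature lists
#'
#' Reads the coordinate-format MTX file plus one-id-per-line barcode and
#' feature files. In this package's on-disk layout entities (barcodes) are the
#' MTX rows and features the columns, matching [write_mtx_counts()].
#'
#' @param matrix_path,barcodes_path,features_path File paths.
#' @return A [count_matrix()] with entities = barcodes, genes = features;
#'   entries absent from the triplet list are zero.
#' @export
read_mtx_counts <- function(matrix_path, barcodes_path, features_path) {
  for (p in c(matrix_path, barcodes_path, features_path))
    if (!file.exists(p)) stop_format(sprintf("file not found: %s", p))
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop_format(paste("bad MTX:", conditionMessage(e))))
  barcodes <- readLines(barcodes_path, warn = FALSE)
  features <- readLines(features_path, warn = FALSE)
  barcodes <- barcodes[nzchar(barcodes)]
  features <- features[nzchar(features)]
  if (length(barcodes) != nrow(m))
    stop_format(sprintf("barcode list (%d) does not match declared rows (%d)",
                        length(barcodes), nrow(m)))
  if (length(features) != ncol(m))
    stop_format(sprintf("feature list (%d) does not match declared columns (%d)",
                        length(features), ncol(m)))
  dense <- as.matrix(m)
  if (any(dense < 0)) stop_validation("negative values in count MTX")
  if (any(dense != round(dense)))
    stop_validation("fractional values in count MTX")
  count_matrix(dense, entities = barcodes, genes = features)
}

#' Write a count matrix as MTX + barcode/feature lists
#'
#' @param cm A [count_matrix()].
#' @param matrix_path,barcodes_path,features_path Output paths.
#' @export
write_mtx_counts <- function(cm, matrix_path, barcodes_path, features_path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(cm$counts, sparse = TRUE),
                              "generalMatrix"), matrix_path)
  writeLines(cm$entities, barcodes_path)
  writeLines(cm$genes, features_path)
  invisible(matrix_path)
}

#' Scale-factor log-normalization
#'
#' Per entity, counts are divided by the entity's total, multiplied by
#' `scale_factor` and log1p-transformed:
#' `lognorm = log(1 + count / total * scale_factor)`. Entities with zero total
#' get an all-zero row and a warning (they are retained; dropping cells is a
#' separate QC decision).
#'
#' @param cm A [count_matrix()].
#' @param scale_factor Positive scale factor; default 10,000.
#' @return The input with a `"lognorm"` layer added.
#' @export
lognormalize <- function(cm, scale_factor = 1e4) {
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      !is.finite(scale_factor) || scale_factor <= 0)
    stop_param("scale_factor must be a single positive number")
  totals <- rowSums(cm$counts)
  zero <- totals == 0
  if (all(zero)) stop_param("no entity has a positive total count")
  if (any(zero))
    mb_warn(sprintf("%d entities with zero total count kept as all-zero rows",
                    sum(zero)))
  denom <- ifelse(zero, 1, totals)
  ln <- log1p(cm$counts / denom * scale_factor)
  ln[zero, ] <- 0
  cm$layers[["lognorm"]] <- ln
  cm
}

#' Read a delimited table with a header and an id column
#'
#' Shared reader for abundance matrices and per-cell metadata tables.
#'
#' @param path Path to a tab- or comma-delimited file with a header row; the
#'   first column is taken as the row id.
#' @return A data.frame with ids as row names.
#' @export
read_id_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(tab)) stop_format("empty table")
  if (anyDuplicated(tab[[1]])) stop_validation("duplicate row ids")
  rownames(tab) <- as.character(tab[[1]])
  tab[-1]
}

#' Read a pipeline configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
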