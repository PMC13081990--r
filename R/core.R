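# Shared domain containers and file I/O.
#
# Conventions used by every module:
#   * image arrays are indexed (z, y, x), 1-based, pixel centers at integer
#     coordinates;
#   * physical voxel size is carried in nanometres as (z, y, x);
#   * spot z is stored in slice units, never nm; physical distances are
#     computed on demand from voxel_size_nm.

CHANNELS <- c("DAPI", "CH_647", "CH_CY3B")

DEFAULT_VOXEL_NM <- c(z = 1000, y = 103, x = 103)

#' Construct an image stack
#'
#' A single (round, channel) 3D intensity volume plus voxel-size metadata.
#' This is the unit every image operation consumes and returns.
#'
#' @param data numeric 3D array indexed `(z, y, x)`, all values `>= 0`.
#' @param voxel_size_nm numeric length-3 vector, voxel edge lengths in
#'   nanometres ordered `(z, y, x)`. Defaults to `c(1000, 103, 103)`, the
#'   acquisition geometry the rest of the package assumes.
#' @param round_id integer hybridization round (>= 0).
#' @param channel_id one of `"DAPI"`, `"CH_647"`, `"CH_CY3B"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size_nm = DEFAULT_VOXEL_NM,
                        round_id = 0L, channel_id = "DAPI") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array indexed (z, y, x)")
  if (anyNA(data) || any(data < 0))
    stop("image intensities must be finite and non-negative")
  voxel_size_nm <- as.numeric(voxel_size_nm)
  if (length(voxel_size_nm) != 3L || any(voxel_size_nm <= 0))
    stop("'voxel_size_nm' must be three positive values (z, y, x)")
  channel_id <- match.arg(channel_id, CHANNELS)
  structure(
    list(data = data,
         voxel_size_nm = stats::setNames(voxel_size_nm, c("z", "y", "x")),
         round_id = as.integer(round_id),
         channel_id = channel_id),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> round %d, channel %s, %d x %d x %d (z,y,x), voxel (%g, %g, %g) nm\n",
              x$round_id, x$channel_id, d[1], d[2], d[3],
              x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3]))
  invisible(x)
}

#' Read an image stack from a multi-page TIFF
#'
#' Each TIFF page is one z-plane; pages must share a common 2D shape.
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @param voxel_size_nm voxel size to attach; TIFF carries no calibrated
#'   voxel metadata here, so the default `(1000, 103, 103)` nm is used
#'   unless overridden.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, round_id = 0L, channel_id = "DAPI",
                       voxel_size_nm = DEFAULT_VOXEL_NM) {
  planes <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                     error = function(e) stop("unreadable stack: ", path,
                                              " (", conditionMessage(e), ")"))
  if (is.matrix(planes)) planes <- list(planes)
  shp <- lapply(planes, dim)
  if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L)
    stop("unreadable stack: inconsistent plane shapes in ", path)
  d2 <- dim(planes[[1]])
  data <- array(0, c(length(planes), d2[1], d2[2]))
  for (z in seq_along(planes)) data[z, , ] <- planes[[z]]
  if (any(data < 0)) stop("unreadable stack: negative intensities in ", path)
  image_stack(data, voxel_size_nm, round_id, channel_id)
}

#' Write an image stack to a multi-page TIFF
#'
#' Stored as 32-bit float, one page per z-plane. The TIFF writer defines
#' storage only for intensities in `[0, 1]`; rescale before writing.
#'
#' @param stack an `image_stack`.
#' @param path output path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (max(stack$data) > 1)
    stop("write_stack stores 32-bit float TIFF; intensities must lie in [0, 1]")
  planes <- lapply(seq_len(dim(stack$data)[1]),
                   function(z) stack$data[z, , ])
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  invisible(path)
}

SPOT_COLUMNS <- c("spot_id", "gene", "round_id", "channel_id",
                  "z", "y", "x", "intensity")

#' Construct / validate a spot table
#'
#' Detected transcript records: one row per spot with gene, round, channel,
#' `(z, y, x)` coordinates (z in slice units, y/x in pixels, 1-based) and
#' intensity.
#'
#' @param df data.frame with columns
#'   `spot_id, gene, round_id, channel_id, z, y, x, intensity`.
#' @return The validated data.frame (class `spot_table` prepended).
#' @export
spot_table <- function(df = NULL) {
  if (is.null(df))
    df <- data.frame(spot_id = integer(), gene = character(),
                     round_id = integer(), channel_id = character(),
                     z = numeric(), y = numeric(), x = numeric(),
                     intensity = numeric())
  missing <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing))
    stop("spot table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[SPOT_COLUMNS]
  if (anyDuplicated(df$spot_id)) stop("spot_ids must be unique within a table")
  if (nrow(df) && any(df$intensity < 0)) stop("spot intensities must be >= 0")
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Write / read a spot table CSV
#'
#' CSV with header `spot_id,gene,round_id,channel_id,z,y,x,intensity`;
#' `read_spot_table(write_spot_table(x))` is the identity up to
#' floating-point text round-trip.
#'
#' @param spots a `spot_table`.
#' @param path CSV path.
#' @export
write_spot_table <- function(spots, path) {
  spots <- spot_table(as.data.frame(spots))
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed spot CSV ", path, ": ",
                                          conditionMessage(e)))
  missing <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing))
    stop("malformed spot CSV ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(!stats::complete.cases(df[c("z", "y", "x", "intensity")]))
  if (length(bad))
    stop("malformed spot CSV ", path, ": non-numeric record at data line ",
         bad[1])
  spot_table(df)
}

#' Validate a nuclear label mask
#'
#' A 3D integer array the shape of the DAPI stack; 0 = background, k > 0 =
#' nucleus k. Labels are mutually exclusive by construction (one value per
#' voxel).
#'
#' @param labels 3D array of non-negative integers.
#' @return The array with class `label_mask` attribute set.
#' @export
label_mask <- function(labels) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array indexed (z, y, x)")
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  class(labels) <- c("label_mask", class(labels))
  labels
}

#' Construct a cell-by-gene soft-count matrix
#'
#' @param values numeric matrix, cells (rows) by genes (columns), entries
#'   >= 0 (soft counts may be fractional).
#' @param cell_meta data.frame with one row per cell: `label` (nucleus id),
#'   `worm_id`, `neuron_class` (or `"unassigned"`), `sex`.
#' @param gene_names character vector naming the columns.
#' @return An object of class `cell_gene_matrix`.
#' @export
cell_gene_matrix <- function(values, cell_meta, gene_names) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(cell_meta))
    stop("cell_meta must have one row per matrix row")
  if (ncol(values) != length(gene_names))
    stop("gene_names must match matrix columns")
  if (length(values) && any(values < 0)) stop("soft counts must be >= 0")
  for (col in c("label", "worm_id", "neuron_class", "sex"))
    if (is.null(cell_meta[[col]]))
      stop("cell_meta is missing column ", col)
  colnames(values) <- gene_names
  structure(list(values = values,
                 cell_meta = as.data.frame(cell_meta),
                 gene_names = as.character(gene_names)),
            class = "cell_gene_matrix")
}

#' @export
print.cell_gene_matrix <- function(x, ...) {
  cat(sprintf("<cell_gene_matrix> %d cells x %d genes, total soft counts %.2f\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Write a cell-by-gene matrix
#'
#' Emits a wide CSV (cells as rows; metadata columns first, then one column
#' per gene) and optionally a MatrixMarket triplet plus row/column index
#' files for interoperability.
#'
#' @param m a `cell_gene_matrix`.
#' @param path CSV output path.
#' @param mtx logical; also write `<path>.mtx`, `<path>.cells.txt`,
#'   `<path>.genes.txt`.
#' @export
write_matrix <- function(m, path, mtx = FALSE) {
  stopifnot(inherits(m, "cell_gene_matrix"))
  wide <- cbind(m$cell_meta[c("label", "worm_id", "neuron_class", "sex")],
                as.data.frame(m$values, check.names = FALSE))
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  if (mtx) {
    sm <- methods::as(Matrix::Matrix(m$values, sparse = TRUE), "generalMatrix")
    Matrix::writeMM(sm, paste0(path, ".mtx"))
    writeLines(as.character(m$cell_meta$label), paste0(path, ".cells.txt"))
    writeLines(m$gene_names, paste0(path, ".genes.txt"))
  }
  invisible(path)
}

#' Read back a cell-by-gene matrix CSV written by [write_matrix()]
#'
#' @param path CSV path.
#' @return A `cell_gene_matrix`.
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("label", "worm_id", "neuron_class", "sex")
  genes <- setdiff(names(df), meta_cols)
  cell_gene_matrix(as.matrix(df[genes]), df[meta_cols], genes)
}

#' Read a neuron annotation table
#'
#' CSV with columns `neuron_name,x,y,z,worm_id,sex`; coordinates are 1-based
#' pixels (x, y) and slice units (z) in the registered reference frame.
#'
#' @param path CSV path.
#' @return data.frame with the above columns.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_name", "x", "y", "z", "worm_id", "sex")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation CSV missing column(s): ", paste(missing, collapse = ", "))
  if (any(!nzchar(df$neuron_name))) stop("neuron_name must be nonempty")
  df[need]
}

#' Read a reference expression profile
#'
#' Long-format CSV (`class,gene,value`) or wide format (first column the
#' class, remaining columns genes). Values must be >= 0 and (class, gene)
#' pairs unique.
#'
#' @param path CSV path.
#' @param source_tag free-text provenance tag stored on the result.
#' @return data.frame `class, gene, value` with attribute `source`.
#' @export
read_reference_profile <- function(path, source_tag = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("class", "gene", "value") %in% names(df))) {
    out <- df[c("class", "gene", "value")]
  } else {
    genes <- names(df)[-1]
    out <- data.frame(
      class = rep(df[[1]], times = length(genes)),
      gene = rep(genes, each = nrow(df)),
      value = as.numeric(unlist(df[genes], use.names = FALSE)))
  }
  if (any(out$value < 0)) stop("reference values must be >= 0")
  if (anyDuplicated(out[c("class", "gene")]))
    stop("duplicate (class, gene) entries in reference profile")
  attr(out, "source") <- source_tag
  out
}
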