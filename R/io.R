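#' Write a grayscale field to disk
#'
#' Values go to a plain CSV (no header) and a JSON sidecar
#' (`<path>.json`) carries the pixel pitch and semantics tag.
#'
#' @param field a [grayscale_field()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "grayscale_field"))
  utils::write.table(field$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(pixel_pitch = field$pixel_pitch,
         semantics_tag = field$semantics_tag,
         n_rows = nrow(field$values), n_cols = ncol(field$values)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a grayscale field written by [write_field()]
#'
#' @param path CSV file path (expects the `<path>.json` sidecar).
#' @return a [grayscale_field()].
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(v) <- NULL
  grayscale_field(v, meta$pixel_pitch, meta$semantics_tag)
}

#' Export a field (or scaffold mask) as a normalized PNG preview
#'
#' @param values numeric or logical matrix.
#' @param path PNG file path.
#' @return `path`, invisibly; requires the `png` package.
#' @export
write_preview_png <- function(values, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  v <- as.matrix(values) * 1.0
  rng <- range(v)
  if (diff(rng) > 0) v <- (v - rng[1]) / diff(rng)
  png::writePNG(v, path)
  invisible(path)
}

#' Write an elasticity matrix as JSON
#'
#' Keys c11 ... c33 (and the redundant c21 diagnostic), units MPa.
#'
#' @param cm an [elasticity_matrix()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_elasticity <- function(cm, path) {
  stopifnot(inherits(cm, "elasticity_matrix"))
  jsonlite::write_json(
    list(c11 = cm$c11, c12 = cm$c12, c13 = cm$c13, c22 = cm$c22,
         c23 = cm$c23, c33 = cm$c33, c21 = cm$c21, units = "MPa"),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an elasticity matrix written by [write_elasticity()]
#'
#' @param path JSON file path.
#' @return an [elasticity_matrix()].
#' @export
read_elasticity <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  elasticity_matrix(x$c11, x$c12, x$c13, x$c22, x$c23, x$c33,
                    c21 = if (is.null(x$c21)) x$c12 else x$c21)
}

#' Write a scaffold design as JSON
#'
#' Serializes the 36 thickness values (cell-major, walls left/top/bottom/
#' right fastest) together with the layout metadata.
#'
#' @param design a [scaffold_design()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "scaffold_design"))
  jsonlite::write_json(
    list(thickness = design_vector(design), cell_size = design$cell_size,
         levels = design$levels, n_cells = c(3, 3),
         wall_order = c("left", "top", "bottom", "right"), units = "mm"),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a scaffold design written by [write_design()]
#'
#' @param path JSON file path.
#' @return a [scaffold_design()].
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaffold_design(x$thickness, cell_size = x$cell_size, levels = x$levels)
}
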