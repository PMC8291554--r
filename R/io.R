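#' Read and write cell-record tables
#'
#' Cell tables are plain CSV with the columns produced by
#' \code{\link{detect_cells}} (id, x_um, y_um, z_um, volume_um3,
#' eccentricity, intensity, channel, n_sections, valid).
#'
#' @param records cell record data.frame.
#' @param path CSV path.
#' @return \code{read_cells} returns the data.frame.
#' @export
write_cells <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write long activation tables
#'
#' Columns: animal_id, group, region, count.
#'
#' @param table activation data.frame.
#' @param path CSV path.
#' @export
write_activation <- function(table, path) {
  utils::write.csv(check_table(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activation
#' @export
read_activation <- function(path) {
  check_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an image column as multi-page TIFF plus geometry sidecar
#'
#' Frames are written as 16-bit pages of \code{<prefix>.tif} and the
#' geometry as \code{<prefix>.json}. Requires the \pkg{tiff} package.
#'
#' @param col an \code{image_column}.
#' @param prefix output path prefix.
#' @export
write_column <- function(col, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is needed for TIFF IO")
  fr <- col$frames
  pages <- lapply(seq_len(dim(fr)[1]),
                  function(f) pmin(pmax(fr[f, , ] / 65535, 0), 1))
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 16L)
  write_geometry(col$geometry, paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_column
#' @param prefix path prefix written by \code{write_column}.
#' @param column_id id assigned to the column.
#' @export
read_column <- function(prefix, column_id = 1L) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is needed for TIFF IO")
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  g <- read_geometry(paste0(prefix, ".json"))
  fr <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (f in seq_along(pages)) fr[f, , ] <- pages[[f]] * 65535
  structure(list(frames = fr, geometry = g, column_id = column_id,
                 nominal_origin_um = g$column_origin_um, truncated = FALSE),
            class = "image_column")
}
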