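#' Read and write TIFF stacks, images and masks
#'
#' Stacks are multi-page TIFF, one page per slice; masks are written as 8-bit
#' 0/255. Pixel size and Z spacing are not carried by plain TIFF, so they are
#' supplied on read.
#'
#' @param stack,image,mask objects to write.
#' @param path TIFF file path.
#' @param pixel_size,z_spacing,z_origin geometry to attach on read, um.
#' @return Readers return the corresponding container; writers return `path`
#'   invisibly.
#' @name tiff_io
NULL

need_tiff <- function() {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("TIFF input/output needs the 'tiff' package")
  }
}

#' @rdname tiff_io
#' @export
write_stack <- function(stack, path) {
  need_tiff()
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$voxels, 1)
  pages <- lapply(seq_len(dim(stack$voxels)[3]),
                  function(k) stack$voxels[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_stack <- function(path, pixel_size, z_spacing = 1, z_origin = 0) {
  need_tiff()
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vox <- array(unlist(pages),
               dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  image_stack(vox, pixel_size, z_spacing, z_origin)
}

#' @rdname tiff_io
#' @export
write_image <- function(image, path) {
  need_tiff()
  stopifnot(inherits(image, "image2d"))
  tiff::writeTIFF(image$pixels / max(image$pixels, 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_image <- function(path, pixel_size) {
  need_tiff()
  image2d(tiff::readTIFF(path), pixel_size)
}

#' @rdname tiff_io
#' @export
write_mask <- function(mask, path) {
  need_tiff()
  stopifnot(inherits(mask, "binary_mask"))
  tiff::writeTIFF(mask$pixels * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_mask <- function(path, pixel_size) {
  need_tiff()
  binary_mask(tiff::readTIFF(path) > 0.5, pixel_size)
}

#' Write / read groove intervals as CSV
#'
#' The extent travels in a header comment line so the interval table round
#' trips losslessly.
#'
#' @param grooves groove interval tibble.
#' @param path CSV path.
#' @return `read_grooves()` returns the interval tibble with its extent.
#' @export
write_grooves <- function(grooves, path) {
  writeLines(paste0("# extent_um=", attr(grooves, "extent")), path)
  readr::write_csv(grooves, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_grooves
#' @export
read_grooves <- function(path) {
  first <- readLines(path, n = 1)
  extent <- as.numeric(sub("# extent_um=", "", first, fixed = TRUE))
  out <- readr::read_csv(path, skip = 1, show_col_types = FALSE)
  attr(out, "extent") <- extent
  out
}
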