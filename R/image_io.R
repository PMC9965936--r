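#' Read a grayscale image from disk
#'
#' Reads an 8- or 16-bit PNG or TIFF file and returns an integer-valued
#' intensity matrix in `[0, 255]`. Color images are converted to grayscale
#' with the fixed ITU-R BT.601 luminance weights
#' `0.299 R + 0.587 G + 0.114 B`; an alpha channel, if present, is ignored.
#' Inputs with more than 8 bits per sample are rescaled by the linear map
#' `round(v / v_full * 255)` where `v_full` is the format's full-scale value,
#' so the maximum representable input value maps to 255.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An integer matrix (rows = image rows) with values in `[0, 255]`.
#' @seealso [write_gray_image()], [read_image_folder()]
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format '", ext, "' (PNG and TIFF are supported)",
           call. = FALSE)
    ),
    error = function(e) stop("cannot read image file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    arr <- if (nc >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]  # gray + alpha
    }
  }
  # readers return [0, 1]; full-scale input maps to 255
  img <- round(arr * 255)
  storage.mode(img) <- "double"
  assert_gray_image(img)
  img
}

#' Write a grayscale image to disk
#'
#' Writes an integer intensity matrix in `[0, 255]` as an 8-bit grayscale
#' PNG or TIFF, chosen by the file extension. PNG is the canonical format
#' used by the dataset layout; the write/read round trip preserves every
#' pixel exactly.
#'
#' @param img Integer matrix with values in `[0, 255]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  assert_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  v <- img / 255
  switch(ext,
    png  = png::writePNG(v, path),
    tif  = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}
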