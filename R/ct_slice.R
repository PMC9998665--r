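#' Construct a CT slice object
#'
#' A `ct_slice` holds one 2D grayscale slice on the canonical 8-bit scale
#' (integers in \[0, 255\]), its anatomical view, and optional in-plane pixel
#' spacing. All downstream stages (segmentation, rim extraction, measurement)
#' consume this object.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\].
#' @param view `"axial"` (both eyes visible, anterior at the top) or
#'   `"sagittal"` (one eye, anterior at the left).
#' @param pixel_spacing_mm Optional numeric of length 1 (isotropic) or 2
#'   (`c(row, col)`), mm per pixel; both components must be positive.
#' @param source_id Provenance string carried through to results.
#' @param window Optional `c(center, width)` in HU recorded if the slice was
#'   windowed from HU data (see [window_hu()]).
#' @return An object of class `ct_slice`.
#' @export
#' @examples
#' sl <- ct_slice(matrix(80, 32, 32), view = "axial", pixel_spacing_mm = 0.5)
#' dim(sl$pixels)
ct_slice <- function(pixels, view = c("axial", "sagittal"),
                     pixel_spacing_mm = NULL, source_id = "<memory>",
                     window = NULL) {
  view <- match.arg(view)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    abort("`pixels` must lie in [0, 255] on the canonical 8-bit scale")
  if (!is.null(pixel_spacing_mm)) {
    pixel_spacing_mm <- rep(as.numeric(pixel_spacing_mm), length.out = 2)
    if (any(!is.finite(pixel_spacing_mm)) || any(pixel_spacing_mm <= 0))
      abort("`pixel_spacing_mm` components must be positive")
    names(pixel_spacing_mm) <- c("row", "col")
  }
  structure(
    list(pixels = pixels, view = view, pixel_spacing_mm = pixel_spacing_mm,
         source_id = source_id, window = window),
    class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  sp <- if (is.null(x$pixel_spacing_mm)) "unknown spacing"
        else paste0(paste(signif(x$pixel_spacing_mm, 4), collapse = "x"), " mm/px")
  cat(sprintf("<ct_slice> %s, %d x %d px, %s (%s)\n",
              x$view, nrow(x$pixels), ncol(x$pixels), sp, x$source_id))
  invisible(x)
}

#' Window HU (or stored DICOM) values to the canonical 8-bit scale
#'
#' Applies the DICOM rescale transform `hu = stored * slope + intercept`,
#' then a linear intensity window and maps the result to \[0, 255\]
#' (round half away from zero, clipped). The default window is the standard
#' soft-tissue window, center 40 HU / width 400 HU, under which bone renders
#' near saturation and well above the bone threshold of 200 used by
#' [extract_rim_mask()].
#'
#' Windowing is monotone: increasing HU never decreases the canonical value.
#'
#' @param stored Numeric matrix (or vector) of stored pixel values.
#' @param slope,intercept DICOM rescale slope and intercept (defaults 1, 0).
#' @param center,width Window center and width in HU (defaults 40, 400).
#' @return Canonical 8-bit values, same shape as `stored`.
#' @export
#' @examples
#' window_hu(1064, intercept = -1024)  # 40 HU, window center -> 128
window_hu <- function(stored, slope = 1, intercept = 0,
                      center = 40, width = 400) {
  if (width <= 0) abort("window `width` must be positive")
  hu <- stored * slope + intercept
  v <- (hu - (center - width / 2)) / width * 255
  out <- round_half_away(pmin(pmax(v, 0), 255))
  out
}

#' Read an 8-bit grayscale PNG as a CT slice
#'
#' The PNG is taken as already windowed to the canonical 8-bit scale; pixel
#' spacing must be supplied by the caller (PNG carries none). Color images
#' with identical channels are collapsed to grayscale; true color input is
#' rejected.
#'
#' @param path PNG file path.
#' @inheritParams ct_slice
#' @return A [ct_slice()].
#' @export
read_ct_png <- function(path, view = c("axial", "sagittal"),
                        pixel_spacing_mm = NULL) {
  view <- match.arg(view)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    rgb <- img[, , seq_len(min(ch, 3)), drop = FALSE]
    if (max(abs(sweep(rgb, c(1, 2), rgb[, , 1]))) > 1e-9)
      abort(sprintf("`%s` is a color image; expected 8-bit grayscale", path))
    img <- rgb[, , 1]
  }
  ct_slice(round_half_away(img * 255), view = view,
           pixel_spacing_mm = pixel_spacing_mm, source_id = path)
}

#' Write a CT slice or a binary mask as an 8-bit PNG
#'
#' Masks are written as 0/255; slices as their canonical intensities.
#' The round trip through [read_ct_png()] / [read_mask_png()] is lossless.
#'
#' @param x A `ct_slice`, numeric matrix in \[0,255\], or logical mask matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_png8 <- function(x, path) {
  if (inherits(x, "ct_slice")) x <- x$pixels
  if (is.logical(x)) x <- x * 255
  png::writePNG(x / 255, path)
  invisible(path)
}

#' @rdname write_png8
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img >= 0.5
}
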