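#' Rim-extraction parameters
#'
#' Controls the three-stage bony-rim extraction of [extract_rim_mask()]:
#' strict intensity thresholding (bone is the only tissue rendered above 200
#' in a soft-tissue window), morphological opening (removes thin watermark
#' strokes), and removal of small connected components (residual noise).
#'
#' @param bone_threshold Grayscale threshold in \[0, 255\]; pixels strictly
#'   greater are kept. Default 200.
#' @param opening_radius Radius of the square structuring element,
#'   `(2r+1) x (2r+1)`; radius 0 disables opening. Default 1 (3x3), the
#'   smallest element that removes width-1 strokes.
#' @param min_component_area Minimum 8-connected component area in pixels
#'   (inclusive) to keep. Default 100.
#' @return An object of class `rim_config`.
#' @export
rim_config <- function(bone_threshold = 200, opening_radius = 1,
                       min_component_area = 100) {
  if (bone_threshold < 0 || bone_threshold > 255)
    abort("`bone_threshold` must lie in [0, 255]")
  if (opening_radius < 0) abort("`opening_radius` must be >= 0")
  if (min_component_area < 0) abort("`min_component_area` must be >= 0")
  structure(list(bone_threshold = bone_threshold,
                 opening_radius = as.integer(opening_radius),
                 min_component_area = min_component_area),
            class = "rim_config")
}

#' Threshold bright bone in a CT slice
#'
#' Keeps pixels with intensity strictly greater than the bone threshold.
#' A pixel of exactly 200 is excluded at the default threshold.
#'
#' @param slice A [ct_slice()].
#' @param config A [rim_config()].
#' @return Logical mask matrix.
#' @export
threshold_bone <- function(slice, config = rim_config()) {
  stopifnot(inherits(slice, "ct_slice"))
  slice$pixels > config$bone_threshold
}

#' Binary morphological opening with a square structuring element
#'
#' Erosion then dilation with a `(2*radius+1)`-square element; pixels outside
#' the image are background. Radius 0 is the identity. Opening is
#' anti-extensive (`open(M)` is a subset of `M`) and idempotent.
#'
#' @param mask Logical mask matrix.
#' @param radius Structuring-element radius in pixels.
#' @return Logical mask matrix of the same shape.
#' @export
morphological_open <- function(mask, radius = 1) {
  mask <- stopifnot_mask(mask)
  if (radius < 0) abort("`radius` must be >= 0")
  if (radius == 0 || !any(mask)) return(mask)
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "box")
  out <- EBImage::opening(mask * 1, kern)
  matrix(as.logical(out > 0.5), nrow(mask), ncol(mask))
}

# 8-connected component labels; 0 = background
label_components <- function(mask) {
  mask <- stopifnot_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  n <- length(idx)
  if (n == 0L) return(lab)
  map <- integer(h * w)
  map[idx] <- seq_len(n)
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + off[1]; cc <- c + off[2]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    nb <- (cc - 1L) * h + rr
    ok[ok] <- mask[nb[ok]]
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(map[idx[ok]], map[nb[ok]])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Remove small connected components from a binary mask
#'
#' Keeps exactly the 8-connected components whose pixel area is at least
#' `min_area` (inclusive); the output is always a subset of the input.
#'
#' @param mask Logical mask matrix.
#' @param min_area Minimum component area in pixels.
#' @return Logical mask matrix.
#' @export
remove_small_components <- function(mask, min_area = 100) {
  mask <- stopifnot_mask(mask)
  if (min_area < 0) abort("`min_area` must be >= 0")
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Extract the bony orbital rim mask from a CT slice
#'
#' Composes, in order: strict bone thresholding, morphological opening, and
#' small-component removal. On an axial slice the result contains the two
#' lateral orbital rims; on a sagittal slice the superior and inferior rims.
#'
#' @inheritParams threshold_bone
#' @return Logical rim mask.
#' @export
#' @seealso [axial_rim_apexes()], [sagittal_rim_apexes()]
extract_rim_mask <- function(slice, config = rim_config()) {
  m <- threshold_bone(slice, config)
  m <- morphological_open(m, config$opening_radius)
  m <- remove_small_components(m, config$min_component_area)
  if (!any(m)) abort("no bone found above threshold")
  m
}

# extremal set pixel in a (rows, cols) window of a mask.
# primary = "row" or "col": minimized first; ties broken on the other
# coordinate, also minimized. Returns c(row, col) or NULL if empty.
extremal_pixel <- function(mask, rows, cols, primary) {
  sub <- mask[rows, cols, drop = FALSE]
  if (!any(sub)) return(NULL)
  idx <- which(sub, arr.ind = TRUE)
  idx[, 1] <- rows[idx[, 1]]
  idx[, 2] <- cols[idx[, 2]]
  ord <- if (primary == "row") order(idx[, 1], idx[, 2])
         else order(idx[, 2], idx[, 1])
  unname(idx[ord[1], ])
}

new_rim_apexes <- function(view, apex_a, apex_b, regions) {
  structure(list(view = view, apex_a = apex_a, apex_b = apex_b,
                 region_a = regions[1], region_b = regions[2]),
            class = "rim_apexes")
}

#' @export
print.rim_apexes <- function(x, ...) {
  cat(sprintf("<rim_apexes> %s: %s (%d, %d), %s (%d, %d)\n", x$view,
              x$region_a, x$apex_a[1], x$apex_a[2],
              x$region_b, x$apex_b[1], x$apex_b[2]))
  invisible(x)
}

#' Locate the most protruding rim points
#'
#' On axial slices the lateral orbital rims sit in the leftmost and rightmost
#' thirds of the image and their most protruding (most anterior) point is the
#' rim pixel closest to the top: per third, the set pixel with the smallest
#' row, ties broken by smallest column. On sagittal slices the superior and
#' inferior rims sit in the upper and lower halves and protrude toward the
#' left: per half, the set pixel with the smallest column, ties broken by
#' smallest row.
#'
#' Coordinates are 1-based `(row, col)` with the origin at the top-left
#' pixel. With width `W`, the left third is columns `1..floor(W/3)` and the
#' right third is columns `ceiling(2W/3)+1..W` (middle discarded); with
#' height `H` the halves split after row `floor(H/2)`.
#'
#' @param rim_mask Logical rim mask from [extract_rim_mask()].
#' @return A `rim_apexes` object with `apex_a` and `apex_b` as
#'   `c(row, col)`.
#' @export
axial_rim_apexes <- function(rim_mask) {
  rim_mask <- stopifnot_mask(rim_mask)
  w <- ncol(rim_mask)
  left <- seq_len(floor(w / 3))
  right <- seq.int(ceiling(2 * w / 3) + 1, w)
  a <- extremal_pixel(rim_mask, seq_len(nrow(rim_mask)), left, "row")
  if (is.null(a)) abort("left_third has no rim pixels")
  b <- extremal_pixel(rim_mask, seq_len(nrow(rim_mask)), right, "row")
  if (is.null(b)) abort("right_third has no rim pixels")
  new_rim_apexes("axial", a, b, c("left_third", "right_third"))
}

#' @rdname axial_rim_apexes
#' @export
sagittal_rim_apexes <- function(rim_mask) {
  rim_mask <- stopifnot_mask(rim_mask)
  h <- nrow(rim_mask)
  upper <- seq_len(floor(h / 2))
  lower <- seq.int(floor(h / 2) + 1, h)
  a <- extremal_pixel(rim_mask, upper, seq_len(ncol(rim_mask)), "col")
  if (is.null(a)) abort("upper_half has no rim pixels")
  b <- extremal_pixel(rim_mask, lower, seq_len(ncol(rim_mask)), "col")
  if (is.null(b)) abort("lower_half has no rim pixels")
  new_rim_apexes("sagittal", a, b, c("upper_half", "lower_half"))
}
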