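#' Build a landmark set
#'
#' A landmark set names the pixel coordinates that define one exophthalmos
#' measurement: the two most protruding orbital-rim points and the corneal
#' apex (one per eye: two on an axial slice, one on a sagittal slice).
#' It is stored as a tibble with columns `landmark`, `row`, `col` and a
#' `view` attribute; coordinates are 1-based `(row, col)`.
#'
#' @param view `"axial"` or `"sagittal"`.
#' @param rim_apex_a,rim_apex_b `c(row, col)` rim apex coordinates; must
#'   differ.
#' @param corneal_apexes Named list of `c(row, col)`: `left_eye` and
#'   `right_eye` for axial, `eye` for sagittal.
#' @return A tibble of class `landmark_set`.
#' @export
landmark_set <- function(view = c("axial", "sagittal"), rim_apex_a,
                         rim_apex_b, corneal_apexes) {
  view <- match.arg(view)
  if (length(rim_apex_a) != 2 || length(rim_apex_b) != 2)
    abort("rim apexes must be (row, col) pairs")
  if (all(rim_apex_a == rim_apex_b))
    abort("rim_apex_a and rim_apex_b must differ")
  want <- if (view == "axial") c("left_eye", "right_eye") else "eye"
  if (!setequal(names(corneal_apexes), want))
    abort(sprintf("%s view needs corneal apexes named: %s",
                  view, paste(want, collapse = ", ")))
  corneal_apexes <- corneal_apexes[want]
  out <- tibble(
    landmark = c("rim_apex_a", "rim_apex_b", paste0("cornea_", want)),
    row = c(rim_apex_a[1], rim_apex_b[1],
            vapply(corneal_apexes, `[`, 0, 1)),
    col = c(rim_apex_a[2], rim_apex_b[2],
            vapply(corneal_apexes, `[`, 0, 2)))
  structure(out, view = view, class = c("landmark_set", class(out)))
}

landmark_xy <- function(landmarks, name) {
  i <- match(name, landmarks$landmark)
  if (is.na(i)) abort(sprintf("landmark `%s` is missing", name))
  c(landmarks$row[i], landmarks$col[i])
}

corneal_names <- function(landmarks) {
  grep("^cornea_", landmarks$landmark, value = TRUE)
}

#' Line through two pixel landmarks
#'
#' Returns the implicit line `a*col + b*row + c = 0` through two `(row, col)`
#' points, normalized so `a^2 + b^2 = 1` with the sign convention `a >= 0`
#' (and `b > 0` when `a = 0`). Both input points satisfy the line equation to
#' machine precision.
#'
#' @param p1,p2 Distinct `c(row, col)` points.
#' @return Named numeric `c(a, b, c)` of class `rim_line`.
#' @export
line_through <- function(p1, p2) {
  if (all(p1 == p2)) abort("cannot build a line through coincident points")
  a <- p2[1] - p1[1]          # delta row
  b <- -(p2[2] - p1[2])       # -delta col
  nrm <- sqrt(a^2 + b^2)
  a <- a / nrm; b <- b / nrm
  if (a < 0 || (a == 0 && b < 0)) { a <- -a; b <- -b }
  cc <- -(a * p1[2] + b * p1[1])
  structure(c(a = unname(a), b = unname(b), c = unname(cc)),
            class = "rim_line")
}

#' Perpendicular distance from a point to a rim line
#'
#' `|a*col + b*row + c|` for a normalized line from [line_through()]; the
#' exact Euclidean point-to-line distance in pixels.
#'
#' @param p `c(row, col)` point.
#' @param line A `rim_line`.
#' @return Nonnegative distance in pixels.
#' @export
point_line_distance <- function(p, line) {
  stopifnot(inherits(line, "rim_line"))
  abs(line["a"] * p[2] + line["b"] * p[1] + line["c"])[[1]]
}

#' Locate the corneal apex on a sagittal eye mask
#'
#' The anterior corneal surface faces the left of a sagittal slice, so the
#' apex is the mask pixel with the smallest column (ties broken by smallest
#' row).
#'
#' @param eye_mask Logical eye mask.
#' @return `c(row, col)`.
#' @export
corneal_apex_sagittal <- function(eye_mask) {
  eye_mask <- stopifnot_mask(eye_mask)
  p <- extremal_pixel(eye_mask, seq_len(nrow(eye_mask)),
                      seq_len(ncol(eye_mask)), "col")
  if (is.null(p)) abort("no eye found")
  p
}

#' Locate both corneal apexes on an axial eye mask
#'
#' The two eyes are taken as the two largest 8-connected components of the
#' mask (a warning is raised if spurious extra components are discarded) and
#' labeled `left_eye` / `right_eye` by centroid column. The anterior
#' direction is the top of an axial slice, so each apex is the component's
#' pixel with the smallest row (ties broken by smallest column).
#'
#' @param eye_mask Logical eye mask containing two eye components.
#' @return Named list `left_eye`, `right_eye` of `c(row, col)`.
#' @export
corneal_apex_axial <- function(eye_mask) {
  eye_mask <- stopifnot_mask(eye_mask)
  if (!any(eye_mask)) abort("no eye found")
  lab <- label_components(eye_mask)
  sizes <- tabulate(lab[lab > 0L])
  k <- length(sizes)
  if (k < 2) abort(sprintf("expected two eyes, found %d", k))
  if (k > 2)
    warn(sprintf("expected two eyes, found %d components; keeping the 2 largest", k))
  keep <- order(sizes, decreasing = TRUE)[1:2]
  apexes <- lapply(keep, function(l) {
    m <- lab == l
    extremal_pixel(m, seq_len(nrow(m)), seq_len(ncol(m)), "row")
  })
  cent <- vapply(keep, function(l) mean(which(lab == l, arr.ind = TRUE)[, 2]), 0)
  apexes <- apexes[order(cent)]
  names(apexes) <- c("left_eye", "right_eye")
  apexes
}

#' Per-eye distance from landmark geometry alone
#'
#' Computes the exact continuous point-to-line distance from each corneal
#' apex in a landmark set to the line through the two rim apexes. This is
#' the closed form that defines a phantom's ground-truth distance and the
#' quantity [measure_slice()] recovers from rasters.
#'
#' @param landmarks A [landmark_set()] (or tibble with columns `landmark`,
#'   `row`, `col` containing `rim_apex_a`, `rim_apex_b` and `cornea_*` rows).
#' @return Named numeric vector of distances in pixels, one per eye.
#' @export
true_distance <- function(landmarks) {
  if (!all(c("rim_apex_a", "rim_apex_b") %in% landmarks$landmark))
    abort("landmark set must contain rim_apex_a and rim_apex_b")
  eyes <- corneal_names(landmarks)
  if (length(eyes) < 1) abort("landmark set contains no corneal apex")
  line <- line_through(landmark_xy(landmarks, "rim_apex_a"),
                       landmark_xy(landmarks, "rim_apex_b"))
  d <- vapply(eyes, function(nm) point_line_distance(landmark_xy(landmarks, nm), line), 0)
  names(d) <- sub("^cornea_", "", eyes)
  d
}

#' Measure exophthalmos on one CT slice
#'
#' Runs the full geometric stage: extracts the bony rim
#' ([extract_rim_mask()]), localizes the rim apexes per view, finds the
#' corneal apex(es) on the supplied eye mask, builds the line through the rim
#' apexes, and reports the perpendicular distance from each corneal apex to
#' that line — the exophthalmometric value — in pixels and millimetres.
#'
#' @param slice A [ct_slice()].
#' @param eye_mask Logical eye mask (from [segment_eyes()] or ground truth).
#' @param rim_cfg A [rim_config()].
#' @return An object of class `exo_measurement`; see [tidy.exo_measurement()]
#'   for the per-eye tibble.
#' @details Millimetre output requires isotropic in-plane spacing: an
#'   anisotropic `pixel_spacing_mm` is an error (a perpendicular distance has
#'   no per-axis mm decomposition), and a missing spacing yields `NA` mm with
#'   a warning.
#' @export
measure_slice <- function(slice, eye_mask, rim_cfg = rim_config()) {
  stopifnot(inherits(slice, "ct_slice"))
  eye_mask <- stopifnot_mask(eye_mask)
  same_shape(slice$pixels, eye_mask, c("slice", "eye_mask"))
  rim <- extract_rim_mask(slice, rim_cfg)
  if (slice$view == "axial") {
    apex <- axial_rim_apexes(rim)
    corneas <- corneal_apex_axial(eye_mask)
  } else {
    apex <- sagittal_rim_apexes(rim)
    corneas <- list(eye = corneal_apex_sagittal(eye_mask))
  }
  lms <- landmark_set(slice$view, apex$apex_a, apex$apex_b, corneas)
  d_px <- true_distance(lms)
  sp <- slice$pixel_spacing_mm
  if (is.null(sp)) {
    warn("pixel spacing unknown; reporting distances in px only")
    d_mm <- rep(NA_real_, length(d_px))
  } else {
    if (abs(sp[1] - sp[2]) > 1e-9 * max(sp))
      abort("anisotropic pixel spacing: mm distances are undefined")
    d_mm <- d_px * sp[1]
  }
  structure(
    list(view = slice$view,
         line = line_through(apex$apex_a, apex$apex_b),
         landmarks = lms,
         distances = tibble(eye = names(d_px), distance_px = unname(d_px),
                            distance_mm = unname(d_mm)),
         pixel_spacing_mm = sp, rim_mask = rim, eye_mask = eye_mask,
         slice = slice, rim_config = rim_cfg),
    class = "exo_measurement")
}

#' @export
print.exo_measurement <- function(x, ...) {
  cat(sprintf("<exo_measurement> %s view (%s)\n", x$view, x$slice$source_id))
  print(x$distances)
  invisible(x)
}

#' Tidy an exophthalmos measurement
#'
#' @param x An `exo_measurement` from [measure_slice()].
#' @param ... Unused.
#' @return One row per eye: `source_id`, `view`, `eye`, `distance_px`,
#'   `distance_mm`.
#' @export
tidy.exo_measurement <- function(x, ...) {
  dplyr::bind_cols(tibble(source_id = x$slice$source_id, view = x$view),
                   x$distances)
}

#' @rdname tidy.exo_measurement
#' @export
glance.exo_measurement <- function(x, ...) {
  tibble(view = x$view, n_eyes = nrow(x$distances),
         mean_distance_px = mean(x$distances$distance_px),
         line_a = x$line["a"], line_b = x$line["b"], line_c = x$line["c"],
         pixel_spacing_mm = if (is.null(x$pixel_spacing_mm)) NA_real_
                            else x$pixel_spacing_mm[[1]])
}
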