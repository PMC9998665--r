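#' Specify a synthetic orbital CT phantom
#'
#' A phantom emulates a soft-tissue-window orbital CT slice: a mid-intensity
#' head region, eye globes as filled ellipses at a mid grayscale level, bony
#' orbital rim arcs as the only structures brighter than 200, optional thin
#' watermark strokes at bone intensity, and additive Gaussian noise. All
#' geometry is continuous and known, so the true eye mask, rim-apex
#' coordinates and exophthalmos distance are available in closed form.
#'
#' Bone arcs are slender elliptical rings described by center, semi-axes
#' `c(row, col)`, radial thickness and an angular half-extent around the
#' protrusion direction (`"up"` for axial lateral rims, `"left"` for
#' sagittal superior/inferior rims). The arc's most protruding point — the
#' true rim apex — is `center - c(radii[1], 0)` for `"up"` arcs and
#' `center - c(0, radii[2])` for `"left"` arcs.
#'
#' @param view `"axial"` (two globes, lateral rim arcs in the outer thirds)
#'   or `"sagittal"` (one globe, rim arcs in the upper and lower halves).
#' @param image_height,image_width Raster size in pixels.
#' @param background_level,tissue_level,globe_level Grayscale levels, all
#'   at most 200 (bone must be the only structure above the rim threshold).
#' @param bone_level Bone grayscale level, in 201..255.
#' @param globe_centers List of `c(row, col)` globe centers (2 for axial,
#'   1 for sagittal).
#' @param globe_radii List of `c(row, col)` globe semi-axes, same length.
#' @param bone_arcs List of arcs, each
#'   `list(center = c(row, col), radii = c(row, col), thickness, orient,
#'   half_angle_deg)`.
#' @param watermark_strokes `list(n, width)`: number of thin line artifacts
#'   at bone intensity and their stroke width (at most 2 px).
#' @param noise_sd Additive Gaussian noise SD in grayscale units (clipped to
#'   \[0, 255\], never wrapped).
#' @param pixel_spacing_mm Isotropic in-plane spacing, mm per pixel.
#' @param seed Integer seed controlling strokes and noise.
#' @return An object of class `phantom_spec`.
#' @export
#' @seealso [random_phantom_spec()], [render_phantom()]
phantom_spec <- function(view = c("axial", "sagittal"),
                         image_height = 256, image_width = 256,
                         background_level = 20, tissue_level = 90,
                         globe_level = 150, bone_level = 230,
                         globe_centers, globe_radii, bone_arcs,
                         watermark_strokes = list(n = 0, width = 1),
                         noise_sd = 5, pixel_spacing_mm = 0.5, seed = 1) {
  view <- match.arg(view)
  if (bone_level <= 200 || bone_level > 255)
    abort("invariant violated: bone_level must lie in 201..255")
  for (nm in c("background_level", "tissue_level", "globe_level")) {
    v <- get(nm)
    if (v < 0 || v > 200)
      abort(sprintf("invariant violated: %s must lie in [0, 200]", nm))
  }
  n_globes <- if (view == "axial") 2L else 1L
  if (length(globe_centers) != n_globes || length(globe_radii) != n_globes)
    abort(sprintf("invariant violated: %s view needs %d globe(s)", view, n_globes))
  if (length(bone_arcs) != 2L)
    abort("invariant violated: exactly 2 bone arcs are required")
  if (watermark_strokes$width > 2)
    abort("invariant violated: watermark stroke width must be <= 2 px")
  if (noise_sd < 0) abort("invariant violated: noise_sd must be >= 0")
  spec <- structure(
    list(view = view, image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         background_level = background_level, tissue_level = tissue_level,
         globe_level = globe_level, bone_level = bone_level,
         globe_centers = globe_centers, globe_radii = globe_radii,
         bone_arcs = bone_arcs, watermark_strokes = watermark_strokes,
         noise_sd = noise_sd, pixel_spacing_mm = pixel_spacing_mm,
         seed = as.integer(seed)),
    class = "phantom_spec")
  spec$rim_apex_true <- lapply(bone_arcs, arc_apex)
  validate_apex_regions(spec)
  spec
}

arc_apex <- function(arc) {
  if (arc$orient == "up") c(arc$center[1] - arc$radii[1], arc$center[2])
  else c(arc$center[1], arc$center[2] - arc$radii[2])
}

validate_apex_regions <- function(spec) {
  h <- spec$image_height; w <- spec$image_width
  ap <- spec$rim_apex_true
  if (spec$view == "axial") {
    cols <- sort(vapply(ap, `[`, 0, 2))
    if (!(cols[1] > 1 && cols[1] < w / 3))
      abort("invariant violated: one axial rim apex must lie strictly inside the left third")
    if (!(cols[2] > 2 * w / 3 && cols[2] < w))
      abort("invariant violated: one axial rim apex must lie strictly inside the right third")
  } else {
    rows <- sort(vapply(ap, `[`, 0, 1))
    if (!(rows[1] < h / 2 && rows[2] > h / 2))
      abort("invariant violated: sagittal rim apexes must lie in the upper and lower halves")
  }
  invisible(spec)
}

# coverage of an ellipse at pixel centers (1-based integer grid)
ellipse_mask <- function(h, w, center, radii, tol = 1e-9) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - center[1]) / radii[1])^2 + ((cc - center[2]) / radii[2])^2 <= 1 + tol
}

arc_mask <- function(h, w, arc, tol = 1e-9) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- arc$center[1] - rr   # positive toward the top of the image
  dx <- cc - arc$center[2]
  rho_out <- (dy / arc$radii[1])^2 + (dx / arc$radii[2])^2
  ri <- arc$radii - arc$thickness
  # thickness >= the minor semi-axis means a solid lobe (no inner hole)
  rho_in <- if (any(ri < 0.75)) Inf else (dy / ri[1])^2 + (dx / ri[2])^2
  ang <- atan2(dy, dx)
  a0 <- if (arc$orient == "up") pi / 2 else pi
  dang <- atan2(sin(ang - a0), cos(ang - a0))
  m <- rho_out <= 1 + tol & rho_in > 1 + tol &
    abs(dang) <= arc$half_angle_deg * pi / 180 + tol
  # 3x3 cap just inward of the apex keeps the digital apex at the
  # continuous apex row/col under morphological opening
  ap <- round(arc_apex(arc))
  cap_r <- if (arc$orient == "up") ap[1] + 0:2 else ap[1] + -1:1
  cap_c <- if (arc$orient == "up") ap[2] + -1:1 else ap[2] + 0:2
  cap_r <- cap_r[cap_r >= 1 & cap_r <= h]
  cap_c <- cap_c[cap_c >= 1 & cap_c <= w]
  m[cap_r, cap_c] <- TRUE
  m
}

chebyshev_dilate <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  out <- EBImage::dilate(mask * 1, EBImage::makeBrush(2 * radius + 1, "box"))
  matrix(as.logical(out > 0.5), nrow(mask), ncol(mask))
}

# seeded thin line artifacts crossing the image; pixels within 2 px
# (Chebyshev) of bone are left untouched so opening separates cleanly
watermark_mask <- function(h, w, n, width, keepout) {
  mask <- matrix(FALSE, h, w)
  if (n <= 0) return(mask)
  for (i in seq_len(n)) {
    theta <- runif(1, 0, pi)
    d <- c(sin(theta), cos(theta))
    mid <- c(runif(1, 0.2 * h, 0.8 * h), runif(1, 0.2 * w, 0.8 * w))
    t <- seq(-1.5 * max(h, w), 1.5 * max(h, w), by = 0.25)
    pr <- round(mid[1] + t * d[1]); pc <- round(mid[2] + t * d[2])
    for (k in seq_len(width) - 1L) {
      rr <- pr + round(k * d[2]); cc <- pc - round(k * d[1])
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      mask[cbind(rr[ok], cc[ok])] <- TRUE
    }
  }
  mask & !keepout
}

#' Render a phantom specification to a slice with ground truth
#'
#' Rasterizes the continuous geometry at pixel centers (globes as filled
#' ellipses, bone arcs as slender rings regularized by a 3x3 morphological
#' opening so the rendered bone is stable under the rim pipeline's own
#' opening), draws watermark strokes at bone intensity, then adds seeded
#' Gaussian noise clipped to \[0, 255\]. Ground-truth masks are taken before
#' noise; landmarks and the true distance come from the continuous geometry,
#' not from the raster.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_sample`: fields `slice`
#'   ([ct_slice()]), `eye_mask_true`, `bone_mask_true`, `watermark_mask`,
#'   `landmarks_true` ([landmark_set()]), `distance_true_px`,
#'   `distance_true_mm`, `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_height; w <- spec$image_width
  eye <- matrix(FALSE, h, w)
  for (i in seq_along(spec$globe_centers))
    eye <- eye | ellipse_mask(h, w, spec$globe_centers[[i]], spec$globe_radii[[i]])
  bone <- matrix(FALSE, h, w)
  for (arc in spec$bone_arcs) bone <- bone | arc_mask(h, w, arc)
  bone <- morphological_open(bone, 1)
  if (any(eye & bone))
    abort("invariant violated: globes overlap bone arcs")

  head <- ellipse_mask(h, w, c((h + 1) / 2, (w + 1) / 2),
                       c(0.48 * h, 0.48 * w))
  img <- matrix(spec$background_level, h, w)
  img[head] <- spec$tissue_level
  img[eye] <- spec$globe_level
  img[bone] <- spec$bone_level

  wm <- with_seed(spec$seed, {
    m <- watermark_mask(h, w, spec$watermark_strokes$n,
                        spec$watermark_strokes$width,
                        keepout = chebyshev_dilate(bone, 2))
    img[m] <- spec$bone_level
    if (spec$noise_sd > 0) {
      img <- img + rnorm(h * w, 0, spec$noise_sd)
      img <- round_half_away(pmin(pmax(img, 0), 255))
    }
    m
  })

  corneas <- phantom_corneal_apexes(spec)
  lms <- landmark_set(spec$view, spec$rim_apex_true[[1]],
                      spec$rim_apex_true[[2]], corneas)
  d_px <- true_distance(lms)
  slice <- ct_slice(img, view = spec$view,
                    pixel_spacing_mm = spec$pixel_spacing_mm,
                    source_id = sprintf("phantom-%s-seed%d", spec$view, spec$seed))
  structure(
    list(slice = slice, eye_mask_true = eye, bone_mask_true = bone,
         watermark_mask = wm, landmarks_true = lms,
         distance_true_px = d_px,
         distance_true_mm = d_px * spec$pixel_spacing_mm,
         spec = spec),
    class = "phantom_sample")
}

# continuous corneal apexes: anterior extreme of each globe
phantom_corneal_apexes <- function(spec) {
  if (spec$view == "axial") {
    ap <- lapply(seq_along(spec$globe_centers), function(i)
      c(spec$globe_centers[[i]][1] - spec$globe_radii[[i]][1],
        spec$globe_centers[[i]][2]))
    ord <- order(vapply(spec$globe_centers, `[`, 0, 2))
    stats::setNames(ap[ord], c("left_eye", "right_eye"))
  } else {
    list(eye = c(spec$globe_centers[[1]][1],
                 spec$globe_centers[[1]][2] - spec$globe_radii[[1]][2]))
  }
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s %dx%d, true distance(s) px: %s\n",
              x$spec$view, x$spec$image_height, x$spec$image_width,
              paste(sprintf("%s=%.2f", names(x$distance_true_px),
                            x$distance_true_px), collapse = ", ")))
  invisible(x)
}

#' Draw a randomized phantom specification
#'
#' Jitters a canonical orbital layout with seeded integer offsets: globe
#' centers and radii, rim-arc apex positions and arc depths all move a few
#' pixels per draw, keeping every spec invariant satisfied (apexes inside
#' their thirds/halves, globes clear of bone). All geometry lands on integer
#' coordinates so the rasterized landmark is the continuous landmark and the
#' discretization error of the full pipeline stays within about a pixel.
#'
#' The canonical layout at `size = 256`, spacing 0.5 mm/px, places the
#' corneal apex about 30 px anterior of the rim line (about 15 mm, the
#' clinical range); geometry scales proportionally with `size`.
#'
#' @param view `"axial"` or `"sagittal"`.
#' @param seed Integer seed (drives both the jitter and the rendered noise).
#' @param size Image side in pixels (square raster).
#' @param noise_sd,watermarks,stroke_width Artifact settings forwarded to
#'   [phantom_spec()].
#' @param pixel_spacing_mm Isotropic spacing, mm per pixel.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(view = c("axial", "sagittal"), seed = 1,
                                size = 256, noise_sd = 5, watermarks = 0,
                                stroke_width = 1, pixel_spacing_mm = 0.5) {
  view <- match.arg(view)
  s <- size / 256
  px <- function(x) as.integer(round(x * s))
  with_seed(seed, {
    j <- function(k) {
      k <- max(1L, as.integer(round(k * s)))
      sample(-k:k, 1)
    }
    if (view == "axial") {
      ar1 <- px(28) + j(2); ar2 <- px(28) + j(2)
      ac <- max(px(5), 2L); th <- max(px(6), 3L)
      a1 <- c(px(122) + j(3), px(44) + j(3))   # left lateral rim apex
      a2 <- c(px(122) + j(3), px(212) + j(3))  # right lateral rim apex
      gr1 <- c(px(26) + j(2), px(24) + j(1))
      gr2 <- c(px(26) + j(2), px(24) + j(1))
      # corneal protrusion: ~18 mm +/- ~2.9 mm at 0.5 mm/px, the
      # clinical axial exophthalmometry range
      d <- px(36) + j(10)
      # globes sit medial to the arcs with >= 2 px horizontal clearance
      g1 <- c(min(a1[1], a2[1]) - d + gr1[1],
              a1[2] + ac + 2L + gr1[2] + sample(0:1, 1))
      g2 <- c(min(a1[1], a2[1]) - d + gr2[1],
              a2[2] - ac - 2L - gr2[2] - sample(0:1, 1))
      arcs <- list(
        list(center = c(a1[1] + ar1, a1[2]), radii = c(ar1, ac),
             thickness = th, orient = "up", half_angle_deg = 60),
        list(center = c(a2[1] + ar2, a2[2]), radii = c(ar2, ac),
             thickness = th, orient = "up", half_angle_deg = 60))
      phantom_spec(view, size, size,
                   globe_centers = list(g1, g2),
                   globe_radii = list(gr1, gr2),
                   bone_arcs = arcs,
                   watermark_strokes = list(n = watermarks, width = stroke_width),
                   noise_sd = noise_sd, pixel_spacing_mm = pixel_spacing_mm,
                   seed = seed)
    } else {
      grad <- c(px(26) + j(2), px(24) + j(1))
      ac1 <- px(28) + j(2); ac2 <- px(28) + j(2)
      ar <- max(px(5), 2L); th <- max(px(6), 3L)
      a1 <- c(px(58) + j(3), px(70) + j(3))    # superior rim apex
      a2 <- c(px(190) + j(3), px(72) + j(3))   # inferior rim apex
      # corneal protrusion anterior of the rim line: ~8 mm +/- ~2.8 mm
      # at 0.5 mm/px, the clinical sagittal range
      d <- px(16) + j(9)
      g <- c(px(118) + j(3), min(a1[2], a2[2]) - d + grad[2])
      arcs <- list(
        list(center = c(a1[1], a1[2] + ac1), radii = c(ar, ac1),
             thickness = th, orient = "left", half_angle_deg = 60),
        list(center = c(a2[1], a2[2] + ac2), radii = c(ar, ac2),
             thickness = th, orient = "left", half_angle_deg = 60))
      phantom_spec(view, size, size,
                   globe_centers = list(g), globe_radii = list(grad),
                   bone_arcs = arcs,
                   watermark_strokes = list(n = watermarks, width = stroke_width),
                   noise_sd = noise_sd, pixel_spacing_mm = pixel_spacing_mm,
                   seed = seed)
    }
  })
}

#' Generate a seeded phantom corpus
#'
#' @inheritParams random_phantom_spec
#' @param n Number of phantoms.
#' @param ... Passed on to [random_phantom_spec()].
#' @return List of [render_phantom()] samples.
#' @export
phantom_corpus <- function(n, view = c("axial", "sagittal"), seed = 1, ...) {
  view <- match.arg(view)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seeds, function(s) render_phantom(random_phantom_spec(view, seed = s, ...)))
}

#' Write a phantom sample as paired files
#'
#' Writes `<stem>.png` (8-bit slice), `<stem>_eyemask.png` (0/255 mask) and
#' `<stem>_truth.json` (landmarks, true distances, spacing, seed).
#'
#' @param sample A [render_phantom()] sample.
#' @param dir Output directory (created if needed).
#' @param stem File stem.
#' @return The truth-file path, invisibly.
#' @export
write_phantom <- function(sample, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_png8(sample$slice, file.path(dir, paste0(stem, ".png")))
  write_png8(sample$eye_mask_true, file.path(dir, paste0(stem, "_eyemask.png")))
  truth <- list(
    schema_version = 1L, view = sample$spec$view, seed = sample$spec$seed,
    pixel_spacing_mm = sample$spec$pixel_spacing_mm,
    landmarks = as.data.frame(sample$landmarks_true),
    distance_true_px = as.list(sample$distance_true_px),
    distance_true_mm = as.list(sample$distance_true_mm))
  path <- file.path(dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
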