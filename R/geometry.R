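#' Display model: pixel / degree conversion
#'
#' The conversion anchor is the study display's own printed equivalence of
#' 240 px = 7.04 deg (deg_per_px = 7.04 / 240), which is internally
#' consistent with all other printed values (75 px -> 2.2 deg, 136 px ->
#' 3.99 deg, 800 px -> 23.5 deg). A tangent-based conversion from physical
#' screen size and viewing distance is available via `method = "tangent"`;
#' it differs slightly from the linear anchor (the source display's stated
#' geometry gives 7.21 deg for 240 px), so the linear anchor is the default.
#'
#' @param deg_per_px linear conversion factor.
#' @param screen_px optional c(width, height) in pixels.
#' @param screen_cm optional c(width, height) in cm.
#' @param viewing_distance_cm optional viewing distance in cm.
#' @return object of class `display_model`.
#' @export
display_model <- function(deg_per_px = 7.04 / 240,
                          screen_px = c(1152, 870),
                          screen_cm = c(40.7, 30.5),
                          viewing_distance_cm = 67) {
  stopifnot(deg_per_px > 0)
  structure(list(deg_per_px = deg_per_px, screen_px = screen_px,
                 screen_cm = screen_cm,
                 viewing_distance_cm = viewing_distance_cm),
            class = "display_model")
}

#' Convert pixels to degrees of visual angle (and back)
#'
#' @param px pixel count (vectorized).
#' @param display a [display_model()].
#' @param method `"linear"` (default; the display's printed equivalence) or
#'   `"tangent"` (small-angle-free conversion from physical geometry).
#' @return degrees (or pixels for the inverse).
#' @export
px_to_deg <- function(px, display = display_model(), method = c("linear", "tangent")) {
  method <- match.arg(method)
  if (method == "linear") return(px * display$deg_per_px)
  cm_per_px <- display$screen_cm[1] / display$screen_px[1]
  2 * atan((px * cm_per_px) / (2 * display$viewing_distance_cm)) * 180 / pi
}

#' @rdname px_to_deg
#' @param deg degrees of visual angle.
#' @export
deg_to_px <- function(deg, display = display_model(), method = c("linear", "tangent")) {
  method <- match.arg(method)
  if (method == "linear") return(deg / display$deg_per_px)
  cm_per_px <- display$screen_cm[1] / display$screen_px[1]
  2 * display$viewing_distance_cm * tan(deg * pi / 360) / cm_per_px
}

#' Object displacement induced by cropping an image
#'
#' For an image with the object initially centered, cropping `n_px` from one
#' side moves the image center by `n_px / 2` away from that side while the
#' object stays put, so the signed object-minus-center offset along the
#' cropped axis is `n_px / 2` toward the cropped side. Sign convention:
#' positive = toward the top (for vertical crops) or toward the right (for
#' horizontal crops), matching screen-centered coordinates.
#'
#' @param width_px,height_px image size before cropping.
#' @param side one of `"top"`, `"bottom"`, `"left"`, `"right"`.
#' @param n_px number of pixel rows/columns removed.
#' @return signed offset in px between object center and post-crop image
#'   center along the cropped axis.
#' @export
crop_displacement <- function(width_px, height_px, side = c("top", "bottom", "left", "right"),
                              n_px) {
  side <- match.arg(side)
  dim_px <- if (side %in% c("top", "bottom")) height_px else width_px
  if (n_px >= dim_px) stop_named("bad_crop", "crop of %d px exceeds dimension %d px", n_px, dim_px)
  # cropping the top pulls the image center down, leaving the object above it
  sgn <- switch(side, top = 1, bottom = -1, left = -1, right = 1)
  sgn * n_px / 2
}

#' Euclidean eccentricity
#'
#' @param dx_deg,dy_deg horizontal / vertical offsets (deg).
#' @return Euclidean norm in degrees.
#' @export
eccentricity <- function(dx_deg, dy_deg) sqrt(dx_deg^2 + dy_deg^2)

#' Enumerate a full factorial trial design
#'
#' Builds the complete crossing of the supplied factors with one row per
#' cell, optionally shuffled reproducibly. Every level of every factor
#' appears equally often, and the per-image repetition count equals the
#' product of the non-image factor level counts.
#'
#' @param factors named list of level vectors; a factor named `image`
#'   identifies the image factor.
#' @param shuffle_seed if non-NULL, rows are permuted deterministically.
#' @return data.frame with one column per factor plus `trial_id`.
#' @export
enumerate_design <- function(factors, shuffle_seed = NULL) {
  stopifnot(length(factors) >= 1, all(lengths(factors) >= 1))
  grid <- expand.grid(factors, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(shuffle_seed)) {
    grid <- with_seed(shuffle_seed, grid[sample.int(nrow(grid)), , drop = FALSE])
  }
  grid$trial_id <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  grid
}

#' Preset factorial designs
#'
#' `"exp1"`: one block of 200 trials = 25 images x saccade direction (left /
#' right) x vertical displacement (up / down) x mirroring, i.e. eight
#' presentations per image; the same crossing is recorded once per condition
#' block (look at image center / object / cue). `"exp2"`: 512 trials =
#' 16 image backgrounds x object (present / absent) x image-monitor contrast
#' (low / high) x image shift (left / right) x fixation-cross position
#' (top / bottom) x mirroring.
#'
#' @param preset `"exp1"` or `"exp2"`.
#' @param shuffle_seed optional deterministic shuffle.
#' @return design data.frame (one condition block for exp1).
#' @export
design_preset <- function(preset = c("exp1", "exp2"), shuffle_seed = NULL) {
  preset <- match.arg(preset)
  factors <- if (preset == "exp1") {
    list(image = sprintf("img%02d", 1:25),
         direction = c("left", "right"),
         displacement = c("up", "down"),
         mirrored = c(FALSE, TRUE))
  } else {
    list(image = sprintf("bg%02d", 1:16),
         object_present = c(TRUE, FALSE),
         contrast = c("low", "high"),
         shift = c("left", "right"),
         fixation = c("top", "bottom"),
         mirrored = c(FALSE, TRUE))
  }
  enumerate_design(factors, shuffle_seed = shuffle_seed)
}
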