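#' Synthetic thorax phantom specification
#'
#' Describes a synthetic chest CT exam: an elliptical soft-tissue body
#' containing two air-filled lungs, short high-attenuation rib arcs along the
#' chest wall, and crescent-shaped pleural plaques hugging the inner chest
#' wall (the outer rim of a lung). The phantom reproduces the property the
#' segmentation task hinges on: plaques attenuate more than lung and fat,
#' calcified plaques reach several hundred HU, and ribs — often in contact
#' with plaques — are brighter still.
#'
#' Soft plaque must stay below 100 HU and calcified plaque at or above it,
#' so the calcification threshold separates the two tissue classes by
#' construction (noise is truncated at 3 standard deviations to keep this
#' exact).
#'
#' @param image_size Pixels per side of each square axial slice.
#' @param pixel_spacing In-plane pixel size in mm.
#' @param slice_spacing Axial slice thickness/increment in mm.
#' @param n_slices Number of axial slices.
#' @param body_hu,lung_hu,rib_hu,plaque_soft_hu,plaque_calc_hu Mean tissue HU.
#' @param noise_sd Additive Gaussian noise SD in HU (truncated at 3 SD).
#' @param plaque_params Data frame from [plaque_params()]; zero rows gives a
#'   plaque-free control exam.
#' @param seed Integer seed making the exam fully deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512L, pixel_spacing = 0.7,
                         slice_spacing = 1.0, n_slices = 300L,
                         body_hu = 40, lung_hu = -800, rib_hu = 700,
                         plaque_soft_hu = 60, plaque_calc_hu = 400,
                         noise_sd = 10, plaque_params = plaque_params(),
                         seed = 1L) {
  geom <- c(image_size = image_size, pixel_spacing = pixel_spacing,
            slice_spacing = slice_spacing, n_slices = n_slices)
  for (f in names(geom))
    if (!is.finite(geom[[f]]) || geom[[f]] <= 0)
      stop("phantom_spec: `", f, "` must be strictly positive")
  if (!(plaque_soft_hu < 100 && plaque_calc_hu >= 100))
    stop("phantom_spec: need `plaque_soft_hu` < 100 <= `plaque_calc_hu` so the ",
         "calcification threshold separates the tissue classes")
  if (!(lung_hu < body_hu && body_hu < rib_hu))
    stop("phantom_spec: need `lung_hu` < `body_hu` < `rib_hu`")
  if (noise_sd < 0) stop("phantom_spec: `noise_sd` must be >= 0")
  pp <- validate_plaque_params(plaque_params, n_slices)
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing,
                 slice_spacing = slice_spacing, n_slices = as.integer(n_slices),
                 body_hu = body_hu, lung_hu = lung_hu, rib_hu = rib_hu,
                 plaque_soft_hu = plaque_soft_hu,
                 plaque_calc_hu = plaque_calc_hu, noise_sd = noise_sd,
                 plaque_params = pp, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Plaque parameter table for the phantom
#'
#' Each row places one crescent-shaped plaque on the rim of one lung.
#'
#' @param side `"left"` or `"right"` lung.
#' @param center_deg Angular position of the crescent centre on the lung rim
#'   (degrees, mathematical convention).
#' @param arc_deg Angular extent of the crescent in degrees.
#' @param thickness_mm Radial thickness of the crescent in mm.
#' @param slice_start First axial slice (1-based) the plaque appears on.
#' @param axial_slices Number of consecutive slices the plaque spans.
#' @param calcified Logical; calcified plaques take `plaque_calc_hu`.
#' @return A data frame with one row per plaque.
#' @export
plaque_params <- function(side = character(), center_deg = numeric(),
                          arc_deg = numeric(), thickness_mm = numeric(),
                          slice_start = integer(), axial_slices = integer(),
                          calcified = logical()) {
  data.frame(side = as.character(side), center_deg = as.numeric(center_deg),
             arc_deg = as.numeric(arc_deg),
             thickness_mm = as.numeric(thickness_mm),
             slice_start = as.integer(slice_start),
             axial_slices = as.integer(axial_slices),
             calcified = as.logical(calcified))
}

validate_plaque_params <- function(pp, n_slices) {
  need <- c("side", "center_deg", "arc_deg", "thickness_mm", "slice_start",
            "axial_slices", "calcified")
  if (!is.data.frame(pp) || !all(need %in% names(pp)))
    stop("phantom_spec: `plaque_params` must have columns ",
         paste(need, collapse = ", "))
  if (nrow(pp) == 0L) return(pp)
  if (!all(pp$side %in% c("left", "right")))
    stop("phantom_spec: plaque `side` must be 'left' or 'right'")
  for (f in c("arc_deg", "thickness_mm", "axial_slices"))
    if (any(!is.finite(pp[[f]]) | pp[[f]] <= 0))
      stop("phantom_spec: plaque `", f, "` must be strictly positive")
  if (any(pp$slice_start < 1L | pp$slice_start + pp$axial_slices - 1L > n_slices))
    stop("phantom_spec: plaque axial range [`slice_start`, `slice_start` + ",
         "`axial_slices` - 1] must lie within 1..n_slices")
  pp
}

# thorax geometry in pixel units, relative to image size S
phantom_geometry <- function(S) {
  list(body = list(cx = 0.50 * S, cy = 0.50 * S, a = 0.45 * S, b = 0.32 * S),
       left = list(cx = 0.30 * S, cy = 0.50 * S, a = 0.15 * S, b = 0.24 * S),
       right = list(cx = 0.70 * S, cy = 0.50 * S, a = 0.15 * S, b = 0.24 * S),
       rib_band = c(1.10, 1.22),
       rib_centers_deg = c(15, 75, 135, 195, 255, 315),
       rib_halfwidth_deg = 9)
}

# normalized elliptical radius and polar angle of every pixel w.r.t. an ellipse
ellipse_fields <- function(S, e) {
  x <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  y <- matrix(rep(seq_len(S), times = S), S, S)  # row index
  dx <- x - e$cx
  dy <- y - e$cy
  rho <- sqrt((dx / e$a)^2 + (dy / e$b)^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  list(rho = rho, theta = theta)
}

# TRUE where the angle lies within [center - half, center + half] mod 360
in_arc <- function(theta, center, half) {
  d <- abs((theta - center + 180) %% 360 - 180)
  d <= half
}

# crescent pixel set of one plaque: a radial band on the lung rim limited to
# an angular arc; thickness in mm is converted to a rho-band via the local
# rim radius (in pixels) at each pixel's angle
plaque_pixels <- function(fields, lung, thickness_px) {
  th <- fields$theta * pi / 180
  r_local <- 1 / sqrt((cos(th) / lung$a)^2 + (sin(th) / lung$b)^2)
  band <- thickness_px / r_local
  fields$rho <= 1 & fields$rho >= 1 - band
}

#' Generate one synthetic CT exam with exact ground truth
#'
#' Rasterizes the thorax described by a [phantom_spec()] into a [ct_volume]
#' plus exact plaque and calcified-plaque masks. The same spec (same seed)
#' always produces bit-identical output. Ground-truth volumes are obtained by
#' counting rasterized mask voxels times voxel volume.
#'
#' @param spec A [phantom_spec].
#' @param exam_id,participant_id,round Identifiers stamped on the outputs.
#' @return List with elements `volume` ([ct_volume]), `pp_mask` and
#'   `calc_mask` ([binary_mask], 3-D), and ground-truth volumes in mL
#'   `gt_pp_volume_ml`, `gt_calc_volume_ml`.
#' @export
generate_exam <- function(spec, exam_id = "exam", participant_id = "p",
                          round = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$image_size
  geom <- phantom_geometry(S)
  fb <- ellipse_fields(S, geom$body)
  fl <- ellipse_fields(S, geom$left)
  fr <- ellipse_fields(S, geom$right)

  base <- matrix(-1000, S, S)
  base[fb$rho <= 1] <- spec$body_hu
  in_lung <- fl$rho <= 1 | fr$rho <= 1
  base[in_lung] <- spec$lung_hu
  rib <- matrix(FALSE, S, S)
  for (f in list(fl, fr)) {
    band <- f$rho >= geom$rib_band[1] & f$rho <= geom$rib_band[2]
    ang <- Reduce(`|`, lapply(geom$rib_centers_deg, function(cd)
      in_arc(f$theta, cd, geom$rib_halfwidth_deg)))
    rib <- rib | (band & ang)
  }
  rib <- rib & fb$rho <= 1 & !in_lung
  base[rib] <- spec$rib_hu

  pp <- spec$plaque_params
  t_px <- pp$thickness_mm / spec$pixel_spacing
  plq <- vector("list", nrow(pp))
  if (nrow(pp) > 0L) {
    for (k in seq_len(nrow(pp))) {
      f <- if (pp$side[k] == "left") fl else fr
      lung <- geom[[pp$side[k]]]
      px <- plaque_pixels(f, lung, t_px[k]) &
        in_arc(f$theta, pp$center_deg[k], pp$arc_deg[k] / 2)
      plq[[k]] <- px
    }
  }

  vox <- array(base, dim = c(S, S, spec$n_slices))
  ppm <- array(0L, dim = c(S, S, spec$n_slices))
  ccm <- array(0L, dim = c(S, S, spec$n_slices))
  if (nrow(pp) > 0L) {
    ord <- order(pp$calcified) # soft first so calcified HU wins on overlap
    for (k in ord) {
      sl <- pp$slice_start[k]:(pp$slice_start[k] + pp$axial_slices[k] - 1L)
      hu <- if (pp$calcified[k]) spec$plaque_calc_hu else spec$plaque_soft_hu
      for (s in sl) {
        plane <- vox[, , s]
        plane[plq[[k]]] <- hu
        vox[, , s] <- plane
        mp <- ppm[, , s]; mp[plq[[k]]] <- 1L; ppm[, , s] <- mp
        if (pp$calcified[k]) {
          mc <- ccm[, , s]; mc[plq[[k]]] <- 1L; ccm[, , s] <- mc
        }
      }
    }
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed_(spec$seed, stats::rnorm(length(vox), 0, spec$noise_sd))
    noise <- pmin(pmax(noise, -3 * spec$noise_sd), 3 * spec$noise_sd)
    vox <- vox + array(noise, dim = dim(vox))
  }

  vol <- ct_volume(vox, spacing = c(spec$pixel_spacing, spec$pixel_spacing,
                                    spec$slice_spacing),
                   exam_id = exam_id, participant_id = participant_id,
                   round = round)
  vvox <- spec$pixel_spacing^2 * spec$slice_spacing / 1000 # mL per voxel
  list(volume = vol,
       pp_mask = binary_mask(ppm),
       calc_mask = binary_mask(ccm),
       gt_pp_volume_ml = sum(ppm) * vvox,
       gt_calc_volume_ml = sum(ccm) * vvox)
}

#' Longitudinal phantom pair (screening rounds 2 and 3)
#'
#' Produces two exams of the same synthetic participant in which every plaque
#' of the later round is grown by `growth_factor` in rasterized volume. Arc
#' extent is scaled by `sqrt(growth_factor)`; thickness is scaled such that
#' the annular-sector area also grows by `sqrt(growth_factor)` — the area of
#' a rim band of normalized depth `d` is proportional to `d * (2 - d)`, so a
#' plain thickness scaling would systematically undershoot for thick
#' plaques.
#'
#' @param spec A [phantom_spec] describing the round-2 exam.
#' @param growth_factor Target round-3 / round-2 ground-truth volume ratio,
#'   must be >= 1. `1` reproduces identical plaque geometry.
#' @param participant_id Shared participant identifier.
#' @return List with elements `round2` and `round3`, each as returned by
#'   [generate_exam()].
#' @export
generate_longitudinal_pair <- function(spec, growth_factor,
                                       participant_id = "p") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.finite(growth_factor) || growth_factor < 1)
    stop("`growth_factor` must be >= 1")
  r2 <- generate_exam(spec, exam_id = paste0(participant_id, "_r2"),
                      participant_id = participant_id, round = 2L)
  spec3 <- spec
  s <- sqrt(growth_factor)
  if (nrow(spec$plaque_params) > 0L) {
    geom <- phantom_geometry(spec$image_size)
    r_eff <- sqrt(geom$left$a * geom$left$b) # mean rim radius in pixels
    d <- pmin(spec$plaque_params$thickness_mm / spec$pixel_spacing / r_eff,
              0.95)
    a2 <- pmin(s * d * (2 - d), 0.999) # target area factor on the rim band
    d_new <- 1 - sqrt(1 - a2)
    spec3$plaque_params$thickness_mm <-
      spec$plaque_params$thickness_mm * d_new / d
    spec3$plaque_params$arc_deg <- pmin(spec$plaque_params$arc_deg * s, 175)
  }
  spec3$seed <- spec$seed + 1L # fresh noise realization at the later round
  r3 <- generate_exam(spec3, exam_id = paste0(participant_id, "_r3"),
                      participant_id = participant_id, round = 3L)
  list(round2 = r2, round3 = r3)
}

#' Draw a random desk-scale phantom specification
#'
#' Samples a plaque configuration (count, position, arc, thickness, axial
#' extent, calcification) for a small synthetic exam, reproducibly from a
#' seed. Axial extents are aligned to multiples of `align_slices` native
#' slices so that, at the default 5-mm MIP slab thickness on 1-mm slices,
#' slab-geometry volumes of the ground truth equal native volumes exactly.
#'
#' @param seed Integer seed.
#' @param image_size,n_slices,pixel_spacing,slice_spacing Grid geometry
#'   (defaults give a 64 x 64 x 40 exam with ~5.5 mm pixels).
#' @param n_plaques Number of plaques; `NULL` draws 2-4.
#' @param calc_prob Probability that a plaque is calcified.
#' @param align_slices Axial alignment unit in slices (1 disables alignment).
#' @param ... Passed on to [phantom_spec()] (e.g. tissue HU overrides).
#' @return A [phantom_spec].
#' @export
sample_phantom_spec <- function(seed, image_size = 64L, n_slices = 40L,
                                pixel_spacing = 5.5, slice_spacing = 1.0,
                                n_plaques = NULL, calc_prob = 0.5,
                                align_slices = 5L, ...) {
  with_seed_(seed, {
    if (is.null(n_plaques)) n_plaques <- sample(2:4, 1)
    al <- max(1L, as.integer(align_slices))
    n_units <- n_slices %/% al
    pp <- if (n_plaques == 0L) plaque_params() else {
      ext_units <- pmin(sample(2:4, n_plaques, replace = TRUE), n_units)
      start_units <- vapply(ext_units, function(e)
        sample.int(n_units - e + 1L, 1L), integer(1))
      plaque_params(
        side = sample(c("left", "right"), n_plaques, replace = TRUE),
        center_deg = stats::runif(n_plaques, 0, 360),
        arc_deg = stats::runif(n_plaques, 40, 110),
        thickness_mm = stats::runif(n_plaques, 9, 20),
        slice_start = (start_units - 1L) * al + 1L,
        axial_slices = ext_units * al,
        calcified = stats::runif(n_plaques) < calc_prob)
    }
    phantom_spec(image_size = image_size, pixel_spacing = pixel_spacing,
                 slice_spacing = slice_spacing, n_slices = n_slices,
                 plaque_params = pp, seed = sample.int(2^30, 1), ...)
  })
}

#' Write a phantom exam to disk
#'
#' Persists the CT volume and both ground-truth masks as NIfTI files and
#' returns the manifest row (exam id, participant, round, seed, ground-truth
#' volumes in mL, file paths).
#'
#' @param exam As returned by [generate_exam()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest row.
#' @return One-row data frame (invisibly writes three `.nii.gz` files).
#' @export
write_phantom_exam <- function(exam, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vol <- exam$volume
  p_vol <- file.path(dir, paste0(vol$exam_id, "_ct.nii.gz"))
  p_pp <- file.path(dir, paste0(vol$exam_id, "_pp.nii.gz"))
  p_cc <- file.path(dir, paste0(vol$exam_id, "_calc.nii.gz"))
  write_volume(vol, p_vol)
  write_mask(exam$pp_mask, vol$spacing, p_pp)
  write_mask(exam$calc_mask, vol$spacing, p_cc)
  data.frame(exam_id = vol$exam_id, participant_id = vol$participant_id,
             round = vol$round, seed = seed,
             gt_pp_volume_ml = exam$gt_pp_volume_ml,
             gt_calc_volume_ml = exam$gt_calc_volume_ml,
             ct_path = p_vol, pp_path = p_pp, calc_path = p_cc,
             stringsAsFactors = FALSE)
}
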