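#' Multiparametric volume container
#'
#' Holds one subject's co-registered multiparametric MR volumes: a
#' T2-weighted image, a diffusion-weighted b~0 image and a high-b
#' diffusion-weighted image, all on the same voxel grid, plus the voxel
#' spacing in millimetres.
#'
#' @param t2w,dwi_b0,dwi_high_b numeric 3D arrays of identical shape.
#' @param spacing numeric length-3, voxel spacing in mm (x, y, z).
#' @param subject_id character scalar identifier.
#' @return An object of class `mp_volume` with elements `sequences` (named
#'   list of the three arrays), `spacing` and `subject_id`.
#' @export
mp_volume <- function(t2w, dwi_b0, dwi_high_b, spacing, subject_id = "subject") {
  dims <- dim(t2w)
  if (length(dims) != 3L) stopf("sequences must be 3D arrays")
  if (!identical(dims, dim(dwi_b0)) || !identical(dims, dim(dwi_high_b))) {
    stopf("all three sequences must share the same shape")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stopf("spacing must be three strictly positive numbers (mm)")
  }
  structure(
    list(
      sequences = list(t2w = t2w, dwi_b0 = dwi_b0, dwi_high_b = dwi_high_b),
      spacing = spacing,
      subject_id = as.character(subject_id)
    ),
    class = "mp_volume"
  )
}

#' @export
print.mp_volume <- function(x, ...) {
  d <- dim(x$sequences$t2w)
  cat(sprintf(
    "<mp_volume> %s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    x$subject_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' Binary tumour label map
#'
#' @param mask 3D array coercible to 0/1.
#' @return Object of class `label_map` wrapping an integer 0/1 array.
#' @export
label_map <- function(mask) {
  if (length(dim(mask)) != 3L) stopf("mask must be a 3D array")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1))) stopf("mask values must be 0 or 1")
  m <- array(as.integer(mask), dim = dim(mask))
  structure(list(mask = m), class = "label_map")
}

#' Phantom configuration
#'
#' Describes one synthetic multiparametric phantom: a noisy background near
#' the standardized intensity scale (mean ~0, SD ~`noise_sd`), a spherical
#' tumour that is strongly hyperintense on the high-b DWI and intermediate
#' on T2w, and optional distractor spheres that mimic the non-tumour
#' structures (nodes, glands, artefacts) that share the tumour's DWI
#' hyperintensity. Intensities are generated directly near the standardized
#' scale so the mu + 2*sigma = 2.00 background threshold used downstream is
#' meaningful by construction.
#'
#' @param grid_shape integer length-3, voxels per axis; all >= 8.
#' @param spacing numeric length-3, mm per voxel (default the anisotropic
#'   2 x 2 x 5 mm typical of axial rectal DWI protocols).
#' @param tumour_radius tumour radius in mm (0 gives an empty label map).
#' @param tumour_centre tumour centre in mm (default: grid centre). Voxel
#'   `i` (1-based) sits at `(i - 1) * spacing` mm.
#' @param tumour_intensity named additive offsets (t2w, dwi_b0, dwi_high_b)
#'   applied inside the tumour.
#' @param distractors list of distractors, each a list with elements
#'   `centre` (mm), `radius` (mm) and `offsets` (named per-sequence additive
#'   intensity offsets).
#' @param noise_sd SD of the additive Gaussian background noise.
#' @param artefact_mode one of "none", "fat_suppression_band" (a bright
#'   in-plane band on the high-b DWI, emulating a failed fat suppression)
#'   or "ghosting" (a faint shifted replica added to the high-b DWI).
#' @param misalignment amplitude (mm) of a smooth sinusoidal displacement
#'   applied to the T2w channel only, to exercise the registration stage;
#'   0 (default) generates all channels aligned.
#' @param shape_perturbation relative amplitude of a smooth seeded radial
#'   perturbation of the tumour/distractor surface (0 = exact spheres, for
#'   which the analytic volume oracle holds).
#' @param seed integer; identical config + seed gives bit-identical output.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 16),
                           spacing = c(2, 2, 5),
                           tumour_radius = 9,
                           tumour_centre = NULL,
                           tumour_intensity = c(t2w = 1.5, dwi_b0 = 0.5,
                                                dwi_high_b = 4),
                           distractors = list(),
                           noise_sd = 1,
                           artefact_mode = c("none", "fat_suppression_band",
                                             "ghosting"),
                           misalignment = 0,
                           shape_perturbation = 0,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stopf("grid_shape must be three integers, all >= 8")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stopf("spacing must be three strictly positive numbers")
  }
  if (tumour_radius < 0) stopf("tumour_radius must be >= 0")
  if (is.null(tumour_centre)) tumour_centre <- (grid_shape - 1) / 2 * spacing
  artefact_mode <- match.arg(artefact_mode)
  structure(
    list(
      grid_shape = grid_shape, spacing = spacing,
      tumour_radius = tumour_radius, tumour_centre = as.numeric(tumour_centre),
      tumour_intensity = tumour_intensity, distractors = distractors,
      noise_sd = noise_sd, artefact_mode = artefact_mode,
      misalignment = misalignment, shape_perturbation = shape_perturbation,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

# Smoothly perturbed sphere mask on the voxel grid. Returns a logical array:
# TRUE where the voxel centre lies inside the (possibly perturbed) sphere.
sphere_mask <- function(grid_shape, spacing, centre, radius, perturbation = 0) {
  if (radius <= 0) return(array(FALSE, dim = grid_shape))
  cx <- (seq_len(grid_shape[1]) - 1) * spacing[1] - centre[1]
  cy <- (seq_len(grid_shape[2]) - 1) * spacing[2] - centre[2]
  cz <- (seq_len(grid_shape[3]) - 1) * spacing[3] - centre[3]
  dx2 <- array(rep(cx^2, times = grid_shape[2] * grid_shape[3]), grid_shape)
  dy2 <- array(rep(rep(cy^2, each = grid_shape[1]), times = grid_shape[3]),
               grid_shape)
  dz2 <- array(rep(cz^2, each = grid_shape[1] * grid_shape[2]), grid_shape)
  d2 <- dx2 + dy2 + dz2
  if (perturbation > 0) {
    # Smooth radial modulation: a few random plane waves of the direction
    # vector; keeps the surface smooth and the volume near-analytic.
    k <- matrix(rnorm(9), 3, 3)
    ph <- runif(3, 0, 2 * pi)
    d <- sqrt(pmax(d2, .Machine$double.eps))
    ux <- sqrt(dx2) / d
    uy <- sqrt(dy2) / d
    uz <- sqrt(dz2) / d
    mod <- 0
    for (j in 1:3) {
      mod <- mod + cos(2 * (k[1, j] * ux + k[2, j] * uy + k[3, j] * uz) + ph[j])
    }
    r_eff <- radius * (1 + perturbation * mod / 3)
    return(array(d2 <= r_eff^2, dim = grid_shape))
  }
  array(d2 <= radius^2, dim = grid_shape)
}

#' Generate a synthetic multiparametric phantom
#'
#' Deterministically (given `config$seed`) generates one subject: three
#' aligned sequence volumes and the ground-truth tumour label map. Tumour
#' voxels are hyperintense on the high-b DWI (mean at least two background
#' SDs above the background mean after standardization) and intermediate on
#' T2w; every distractor is hyperintense on the high-b DWI too.
#'
#' @param config a [phantom_config()].
#' @param subject_id identifier stored in the returned volume.
#' @return A list with elements `volume` ([mp_volume]), `labels`
#'   ([label_map]), `distractors` (list of logical arrays, the true
#'   distractor masks, kept as test oracles) and `config`.
#' @export
generate_phantom <- function(config, subject_id = "sub-001") {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape
  sp <- config$spacing
  extent <- (gs - 1) * sp
  if (config$tumour_radius > 0) {
    lo <- config$tumour_centre - config$tumour_radius
    hi <- config$tumour_centre + config$tumour_radius
    if (any(lo < 0) || any(hi > extent)) {
      stopf("tumour (centre %s mm, radius %.3g mm) extends outside the grid",
            paste(round(config$tumour_centre, 1), collapse = ","),
            config$tumour_radius)
    }
  }
  with_seed(config$seed, {
    tmask <- sphere_mask(gs, sp, config$tumour_centre, config$tumour_radius,
                         config$shape_perturbation)
    dmasks <- lapply(config$distractors, function(d) {
      m <- sphere_mask(gs, sp, d$centre, d$radius, config$shape_perturbation)
      if (any(m & tmask)) stopf("distractor overlaps the tumour")
      m
    })
    nvox <- prod(gs)
    seqs <- list(
      t2w = array(rnorm(nvox, 0, config$noise_sd), gs),
      dwi_b0 = array(rnorm(nvox, 0, config$noise_sd), gs),
      dwi_high_b = array(rnorm(nvox, 0, config$noise_sd), gs)
    )
    ti <- config$tumour_intensity
    for (s in names(seqs)) seqs[[s]][tmask] <- seqs[[s]][tmask] + ti[[s]]
    for (i in seq_along(dmasks)) {
      off <- config$distractors[[i]]$offsets
      for (s in names(seqs)) {
        seqs[[s]][dmasks[[i]]] <- seqs[[s]][dmasks[[i]]] + off[[s]]
      }
    }
    if (config$artefact_mode == "fat_suppression_band") {
      # bright in-plane band on the high-b DWI (failed fat suppression)
      y0 <- max(1L, round(gs[2] * 0.08))
      y1 <- max(y0, round(gs[2] * 0.2))
      seqs$dwi_high_b[, y0:y1, ] <- seqs$dwi_high_b[, y0:y1, ] + 3.5
    } else if (config$artefact_mode == "ghosting") {
      shift <- gs[1] %/% 2
      idx <- c((shift + 1):gs[1], 1:shift)
      seqs$dwi_high_b <- seqs$dwi_high_b + 0.35 * seqs$dwi_high_b[idx, , ]
    }
    if (config$misalignment > 0) {
      seqs$t2w <- displace_volume(seqs$t2w, sp, config$misalignment)
    }
    vol <- mp_volume(seqs$t2w, seqs$dwi_b0, seqs$dwi_high_b, sp, subject_id)
    list(
      volume = vol,
      labels = label_map(array(as.integer(tmask), gs)),
      distractors = dmasks,
      config = config
    )
  })
}

# Smooth sinusoidal in-plane displacement of amplitude `amp` mm, resampled
# with trilinear interpolation; used to misalign the T2w channel.
displace_volume <- function(arr, spacing, amp) {
  gs <- dim(arr)
  g <- expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]), z = seq_len(gs[3]))
  lx <- gs[1] * spacing[1]
  ly <- gs[2] * spacing[2]
  ux <- amp * sin(2 * pi * (g$y - 1) * spacing[2] / ly)
  uy <- amp * cos(2 * pi * (g$x - 1) * spacing[1] / lx)
  pts <- cbind(g$x + ux / spacing[1], g$y + uy / spacing[2], g$z)
  array(cpp_trilinear(arr, pts), gs)
}

#' Generate a cohort of phantom subjects
#'
#' Applies seeded per-subject jitter to tumour size, position and intensity
#' (and to any configured distractors) around `base_config`, yielding a
#' reproducible cohort with unique subject identifiers. Identifiers carry a
#' subject number so that parity-based discovery/validation assignment is
#' possible downstream.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base_config a [phantom_config()] used as the jitter centre.
#' @param seed integer master seed for the cohort stream.
#' @return Object of class `phantom_cohort`: a list of per-subject phantom
#'   lists (see [generate_phantom()]), with the seed kept as an attribute.
#' @export
generate_cohort <- function(n_subjects, base_config, seed = 1L) {
  stopifnot(inherits(base_config, "phantom_config"))
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  seeds <- derive_seeds(seed, n_subjects + 1L)
  extent <- (base_config$grid_shape - 1) * base_config$spacing
  cohort <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- with_seed(seeds[i], {
      c2 <- base_config
      c2$tumour_radius <- base_config$tumour_radius * runif(1, 0.8, 1.2)
      jit <- c(runif(2, -4, 4), runif(1, -2.5, 2.5))
      cen <- base_config$tumour_centre + jit
      c2$tumour_centre <- pmin(pmax(cen, c2$tumour_radius),
                               extent - c2$tumour_radius)
      c2$tumour_intensity <- base_config$tumour_intensity * runif(1, 0.9, 1.1)
      c2$distractors <- lapply(base_config$distractors, function(d) {
        d$radius <- d$radius * runif(1, 0.9, 1.1)
        dc <- d$centre + c(runif(2, -3, 3), runif(1, -2, 2))
        d$centre <- pmin(pmax(dc, d$radius), extent - d$radius)
        d
      })
      c2$seed <- seeds[i]
      c2
    })
    cohort[[i]] <- generate_phantom(cfg, subject_id = sprintf("sub-%03d", i))
  }
  structure(cohort, class = "phantom_cohort", seed = seed)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects (seed %s)\n", length(x),
              attr(x, "seed")))
  invisible(x)
}
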