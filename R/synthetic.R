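# Synthetic multi-modal phantoms: reproducible 4-channel volumes with a
# nested three-subregion "tumour" (ET within TC within WT), modality-specific
# contrast and additive noise, emitting the same case/NIfTI layout the I/O
# module consumes.  This is the test bed for every other module: it emulates
# the structure of BraTS-style data, not MR physics.

#' Default modality-by-subregion contrast offsets
#'
#' Rows are modalities (T1, T1-contrast, T2, T2-FLAIR), columns the nested
#' subregions (WT, TC, ET). A voxel accumulates the offsets of every
#' subregion that contains it, on top of the background level, mimicking the
#' canonical appearance: edema bright on T2/FLAIR, enhancing rim bright on
#' T1-contrast, core dark on T1.
#' @export
default_modality_contrast <- function() {
  m <- rbind(
    t1 = c(-15, -10, 5),
    t1ce = c(-10, 0, 45),
    t2 = c(30, 10, -5),
    flair = c(35, 5, 0)
  )
  colnames(m) <- region_order()
  m
}

#' Phantom specification
#'
#' @param grid_shape Volume extent `(z, y, x)` in voxels.
#' @param centre Tumour centre in voxel units; defaults to the grid centre.
#' @param radii Subregion radii `(r_WT, r_TC, r_ET)` in voxels,
#'   non-increasing. Zero radii give an empty subregion.
#' @param modality_contrast 4x3 offset matrix, see
#'   [default_modality_contrast()].
#' @param background Baseline tissue intensity.
#' @param noise_sigma Additive noise scale (standard deviation for Gaussian
#'   noise; also the amplitude used for salt-and-pepper corruption).
#' @param noise_type `"gaussian"` (default) or `"salt-pepper"` (a fraction
#'   `sp_fraction` of voxels forced to extreme values, emulating heavier
#'   acquisition artefacts).
#' @param sp_fraction Fraction of corrupted voxels for salt-and-pepper noise.
#' @param axis_ratios Per-axis scale of the ellipsoid (1,1,1 = sphere).
#' @param spacing mm per (z, y, x) voxel.
#' @param seed RNG seed; identical specs generate identical cases.
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L), centre = NULL,
                         radii = c(14, 9, 5),
                         modality_contrast = default_modality_contrast(),
                         background = 100, noise_sigma = 4,
                         noise_type = c("gaussian", "salt-pepper"),
                         sp_fraction = 0.01, axis_ratios = c(1, 1, 1),
                         spacing = c(1, 1, 1), seed = 1L) {
  noise_type <- match.arg(noise_type)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 1L)) stop("grid_shape must be positive")
  if (is.null(centre)) centre <- (grid_shape + 1) / 2
  if (length(radii) != 3L || any(diff(radii) > 0)) {
    stop("radii must be three non-increasing values (r_WT >= r_TC >= r_ET), got ",
         paste(radii, collapse = ", "))
  }
  stopifnot(all(dim(modality_contrast) == c(4L, 3L)), noise_sigma >= 0,
            length(axis_ratios) == 3L, all(axis_ratios > 0))
  structure(list(grid_shape = grid_shape, centre = centre, radii = radii,
                 modality_contrast = modality_contrast, background = background,
                 noise_sigma = noise_sigma, noise_type = noise_type,
                 sp_fraction = sp_fraction, axis_ratios = axis_ratios,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom case
#'
#' Builds the exact (noise-free) nested subregion geometry as the mask, and
#' the 4-modality intensity volume as background + accumulated subregion
#' contrasts + noise. The mask channels are always exactly nested by
#' construction.
#'
#' @param spec A [phantom_spec()].
#' @param case_id Identifier for the resulting [case_record()].
#' @return A [case_record()] with volume and mask.
#' @export
generate_phantom <- function(spec, case_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  co <- spatial_coords(g)
  d2 <- (((co$i - spec$centre[1]) / spec$axis_ratios[1])^2 +
           ((co$j - spec$centre[2]) / spec$axis_ratios[2])^2 +
           ((co$k - spec$centre[3]) / spec$axis_ratios[3])^2)
  n <- prod(g)
  mask <- array(0, c(3L, g))
  region <- matrix(0, n, 3L)
  for (r in 1:3) {
    if (spec$radii[r] > 0) region[, r] <- as.numeric(d2 <= spec$radii[r]^2)
    mask[r, , , ] <- array(region[, r], g)
  }
  inten <- array(0, c(4L, g))
  noise <- with_local_seed(spec$seed, {
    if (spec$noise_sigma == 0) {
      matrix(0, n, 4L)
    } else if (spec$noise_type == "gaussian") {
      matrix(stats::rnorm(4L * n, 0, spec$noise_sigma), n, 4L)
    } else {
      nz <- matrix(0, n, 4L)
      for (m in 1:4) {
        hit <- stats::runif(n) < spec$sp_fraction
        sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
        nz[hit, m] <- (sign * 10 * spec$noise_sigma)[hit]
      }
      nz
    }
  })
  for (m in 1:4) {
    v <- spec$background + region %*% spec$modality_contrast[m, ] + noise[, m]
    inten[m, , , ] <- array(v, g)
  }
  case_record(case_id,
              multimodal_volume(inten, spacing = spec$spacing),
              subregion_mask(mask, check = FALSE))
}

#' Jitter ranges for cohort generation
#'
#' Each entry is a `c(lo, hi)` range sampled uniformly per case;
#' `radius_scale` and `contrast_scale` multiply the base values,
#' `centre_shift` is an additive voxel offset drawn independently per axis,
#' `noise_sigma` replaces the base noise scale (`NULL` keeps it fixed).
#'
#' @param radius_scale,centre_shift,contrast_scale,noise_sigma Ranges.
#' @export
cohort_jitter <- function(radius_scale = c(0.8, 1.2), centre_shift = c(-2, 2),
                          contrast_scale = c(0.9, 1.1), noise_sigma = NULL) {
  j <- list(radius_scale = radius_scale, centre_shift = centre_shift,
            contrast_scale = contrast_scale, noise_sigma = noise_sigma)
  for (nm in names(j)) {
    r <- j[[nm]]
    if (!is.null(r) && (length(r) != 2L || r[2] < r[1])) {
      stop("empty or malformed jitter range for ", nm, ": ",
           paste(r, collapse = ", "))
    }
  }
  j
}

#' Generate a cohort of phantoms
#'
#' Case parameters are drawn from the jitter ranges in a fixed order
#' (radius scale, three centre shifts, noise sigma if ranged, contrast
#' scale, then the per-case noise seed), all from one generator seeded with
#' `seed` -- the same `(n, seed)` always reproduces the identical cohort.
#'
#' @param n Number of cases (>= 1).
#' @param base_spec A [phantom_spec()] giving the nominal case.
#' @param jitter A [cohort_jitter()].
#' @param seed Cohort seed.
#' @return List of [case_record()]s with ids `case_001`, ...
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            jitter = cohort_jitter(), seed = 1L) {
  stopifnot(n >= 1L)
  specs <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- base_spec
      rs <- stats::runif(1, jitter$radius_scale[1], jitter$radius_scale[2])
      s$radii <- base_spec$radii * rs
      s$centre <- base_spec$centre +
        stats::runif(3, jitter$centre_shift[1], jitter$centre_shift[2])
      if (!is.null(jitter$noise_sigma)) {
        s$noise_sigma <- stats::runif(1, jitter$noise_sigma[1],
                                      jitter$noise_sigma[2])
      }
      cs <- stats::runif(1, jitter$contrast_scale[1], jitter$contrast_scale[2])
      s$modality_contrast <- base_spec$modality_contrast * cs
      s$seed <- sample.int(.Machine$integer.max - 1L, 1L)
      s
    })
  })
  lapply(seq_len(n), function(i) {
    generate_phantom(specs[[i]], case_id = sprintf("case_%03d", i))
  })
}

#' Write a cohort to NIfTI files plus a manifest
#'
#' @param cases List of [case_record()]s.
#' @param dir Output directory.
#' @param datatype NIfTI storage type for intensities.
#' @return The manifest tibble (also written to `dir/manifest.csv`).
#' @export
write_cohort <- function(cases, dir, datatype = "float64") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(cs) {
    p <- write_case(cs, dir, datatype = datatype)
    tibble::tibble(case_id = cs$case_id,
                   t1 = basename(p$t1), t1ce = basename(p$t1ce),
                   t2 = basename(p$t2), flair = basename(p$flair),
                   label = if (is.null(p$label)) "" else basename(p$label))
  })
  mf <- dplyr::bind_rows(rows)
  write_manifest(mf, file.path(dir, "manifest.csv"))
  mf
}
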