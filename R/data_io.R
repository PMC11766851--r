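# BraTS-style case handling: domain types, NIfTI case loading, label-code
# mapping to the nested subregion channels, and geometric/intensity
# preprocessing.
#
# Axis convention: volumes are stored channel-first as (modality, z, y, x)
# with 1-based R indexing; NIfTI files are (x, y, z) on disk and are
# transposed on the way in/out.  Spacing vectors follow the (z, y, x) array
# order everywhere except inside nifti.R.

#' Modalities of a multi-modal case, in canonical order
#' @export
modality_order <- function() c("t1", "t1ce", "t2", "flair")

#' Subregion channels, in canonical order
#' @export
region_order <- function() c("WT", "TC", "ET")

#' BraTS label code table
#'
#' Maps integer label codes to the three nested, overlapping evaluation
#' subregions: whole tumour = necrotic core + edema + enhancing (1, 2, 4),
#' tumour core = necrotic core + enhancing (1, 4), enhancing tumour = 4.
#' The codes follow the BraTS convention; the table is replaceable wherever
#' it is consumed.
#' @export
brats_label_codes <- function() {
  list(WT = c(1, 2, 4), TC = c(1, 4), ET = 4)
}

#' Multi-modal volume container
#'
#' @param intensities 4D array `(modality, z, y, x)` with exactly 4 channels.
#' @param spacing mm per (z, y, x) axis.
#' @param affine 4x4 voxel-to-world map in NIfTI (x, y, z) convention.
#' @param modalities Channel names.
#' @return A validated `multimodal_volume`.
#' @export
multimodal_volume <- function(intensities, spacing = c(1, 1, 1), affine = NULL,
                              modalities = modality_order()) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 4L)
  if (dim(intensities)[1] != 4L) {
    stop("a multimodal_volume has exactly 4 modality channels, got ",
         dim(intensities)[1])
  }
  if (!all(is.finite(intensities))) stop("intensities must all be finite")
  if (is.null(affine)) affine <- diag(c(rev(spacing), 1))
  structure(list(intensities = intensities, spacing = spacing, affine = affine,
                 modalities = modalities),
            class = "multimodal_volume")
}

#' Subregion mask container
#'
#' Three binary channels (WT, TC, ET) on one grid. The subregions are
#' nested by definition (ET within TC within WT); a violated nesting is
#' *reported* through the `nesting_violations` attribute and a warning, never
#' silently repaired.
#'
#' @param channels 4D array `(region, z, y, x)` with values in \{0, 1\}.
#' @param regions Channel names.
#' @param check Validate nesting (default `TRUE`).
#' @export
subregion_mask <- function(channels, regions = region_order(), check = TRUE) {
  stopifnot(is.array(channels), length(dim(channels)) == 4L,
            dim(channels)[1] == 3L)
  if (!all(channels %in% c(0, 1))) stop("mask channels must be binary (0/1)")
  violations <- 0L
  if (check) {
    violations <- sum(channels[3, , , ] > channels[2, , , ]) +
      sum(channels[2, , , ] > channels[1, , , ])
    if (violations > 0L) {
      warning("subregion nesting ET ⊆ TC ⊆ WT violated at ",
              violations, " voxel comparisons (reported, not repaired)",
              call. = FALSE)
    }
  }
  structure(list(channels = channels, regions = regions),
            class = "subregion_mask", nesting_violations = violations)
}

#' One segmentation case
#'
#' @param case_id Identifier string.
#' @param volume A [multimodal_volume()].
#' @param mask A [subregion_mask()] or `NULL` (inference-only case).
#' @export
case_record <- function(case_id, volume, mask = NULL) {
  stopifnot(is.character(case_id), inherits(volume, "multimodal_volume"))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "subregion_mask"))
    if (!all(dim(mask$channels)[2:4] == dim(volume$intensities)[2:4])) {
      stop("volume and mask grids differ: ",
           paste(dim(volume$intensities)[2:4], collapse = "x"), " vs ",
           paste(dim(mask$channels)[2:4], collapse = "x"))
    }
  }
  structure(list(case_id = case_id, volume = volume, mask = mask),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  d <- dim(x$volume$intensities)
  cat("case", x$case_id, ":", paste(d, collapse = "x"),
      if (is.null(x$mask)) "(no mask)" else "(with mask)", "\n")
  invisible(x)
}

xyz_to_zyx <- function(a) aperm(a, c(3L, 2L, 1L))
zyx_to_xyz <- function(a) aperm(a, c(3L, 2L, 1L))

#' Convert an integer label volume to nested subregion channels
#'
#' @param labels 3D integer array `(z, y, x)` of label codes.
#' @param code_table Named list mapping each region to the codes it unions;
#'   default [brats_label_codes()].
#' @return A [subregion_mask()]; nesting holds by construction for nested
#'   code tables.
#' @export
labels_to_subregions <- function(labels, code_table = brats_label_codes()) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  known <- sort(unique(c(0, unlist(code_table))))
  present <- unique(as.vector(labels))
  bad <- setdiff(present, known)
  if (length(bad) > 0L) {
    counts <- vapply(bad, function(b) sum(labels == b), numeric(1))
    stop("unknown label codes: ",
         paste(sprintf("%g (n=%g)", bad, counts), collapse = ", "),
         "; known codes: ", paste(known, collapse = ", "))
  }
  d <- dim(labels)
  ch <- array(0, c(3L, d))
  for (r in seq_along(region_order())) {
    ch[r, , , ] <- as.numeric(labels %in% code_table[[region_order()[r]]])
  }
  subregion_mask(ch)
}

#' Convert subregion channels back to integer label codes
#'
#' Inverse of [labels_to_subregions()] for nested masks: enhancing voxels get
#' the ET code, remaining core voxels the necrotic-core code, remaining
#' whole-tumour voxels the edema code.
#'
#' @param mask A [subregion_mask()].
#' @return 3D integer array of codes \{0, 1, 2, 4\}.
#' @export
subregions_to_labels <- function(mask) {
  ch <- mask$channels
  lab <- array(0L, dim(ch)[2:4])
  lab[ch[1, , , ] > 0] <- 2L
  lab[ch[2, , , ] > 0] <- 1L
  lab[ch[3, , , ] > 0] <- 4L
  lab
}

#' Load a BraTS-style case from NIfTI files
#'
#' @param modality_paths Character vector of 4 NIfTI paths in
#'   [modality_order()] (T1, T1-contrast, T2, T2-FLAIR).
#' @param label_path Optional NIfTI path of the integer label volume.
#' @param case_id Case identifier; defaults to the common prefix of the file
#'   names.
#' @param code_table Label code table for [labels_to_subregions()].
#' @return A [case_record()].
#' @export
load_case <- function(modality_paths, label_path = NULL, case_id = NULL,
                      code_table = brats_label_codes()) {
  stopifnot(length(modality_paths) == 4L)
  missing <- modality_paths[!file.exists(modality_paths)]
  if (!is.null(label_path) && !file.exists(label_path)) {
    missing <- c(missing, label_path)
  }
  if (length(missing) > 0L) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  vols <- lapply(modality_paths, read_nifti)
  shapes <- lapply(vols, function(v) dim(v$data))
  if (any(vapply(shapes, length, integer(1)) != 3L)) {
    stop("all modality volumes must be 3D; got dims: ",
         paste(vapply(shapes, function(s) paste(s, collapse = "x"),
                      character(1)), collapse = ", "))
  }
  if (length(unique(vapply(shapes, paste, character(1), collapse = "x"))) != 1L) {
    stop("modality grids do not match: ",
         paste(sprintf("%s: %s", basename(modality_paths),
                       vapply(shapes, paste, character(1), collapse = "x")),
               collapse = "; "))
  }
  d_xyz <- shapes[[1]]
  inten <- array(0, c(4L, rev(d_xyz)))
  for (m in 1:4) inten[m, , , ] <- xyz_to_zyx(vols[[m]]$data)
  vol <- multimodal_volume(inten, spacing = rev(vols[[1]]$spacing),
                           affine = vols[[1]]$affine)
  mask <- NULL
  if (!is.null(label_path)) {
    lab <- read_nifti(label_path)
    if (length(dim(lab$data)) != 3L || !all(dim(lab$data) == d_xyz)) {
      stop("label grid ", paste(dim(lab$data), collapse = "x"),
           " does not match the modality grid ", paste(d_xyz, collapse = "x"))
    }
    mask <- labels_to_subregions(xyz_to_zyx(lab$data), code_table)
  }
  if (is.null(case_id)) {
    case_id <- sub("[_.-]?(t1|t1ce|t2|flair)?\\.nii(\\.gz)?$", "",
                   basename(modality_paths[1]))
  }
  case_record(case_id, vol, mask)
}

#' Write a case to NIfTI files
#'
#' One file per modality (`<id>_<modality>.nii.gz`) plus, when a mask is
#' present, an integer label volume (`<id>_seg.nii.gz`).
#'
#' @param case A [case_record()].
#' @param dir Output directory (created if needed).
#' @param datatype Storage type for the modalities (labels are uint8).
#' @return Named list of written paths.
#' @export
write_case <- function(case, dir, datatype = "float64") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- case$volume
  sp_xyz <- rev(v$spacing)
  paths <- list()
  for (m in seq_along(v$modalities)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", case$case_id, v$modalities[m]))
    write_nifti(zyx_to_xyz(v$intensities[m, , , ]), p, spacing = sp_xyz,
                affine = v$affine, datatype = datatype)
    paths[[v$modalities[m]]] <- p
  }
  if (!is.null(case$mask)) {
    p <- file.path(dir, sprintf("%s_seg.nii.gz", case$case_id))
    write_nifti(zyx_to_xyz(subregions_to_labels(case$mask)), p,
                spacing = sp_xyz, affine = v$affine, datatype = "uint8")
    paths$label <- p
  }
  paths
}

#' Write model predictions to NIfTI
#'
#' The probability grid is written as one 4D volume (x, y, z, region); if a
#' threshold is given, a second file with the binarised mask converted back
#' to BraTS integer codes is written alongside.
#'
#' @param prob Probability array `(3, z, y, x)`.
#' @param path Output path for the probability map (`.nii`/`.nii.gz`).
#' @param spacing mm per (z, y, x) axis.
#' @param affine Optional 4x4 voxel-to-world map.
#' @param threshold If non-`NULL`, also write `<path minus extension>_seg`
#'   with the thresholded integer labels.
#' @return Named list of written paths.
#' @export
write_prediction <- function(prob, path, spacing = c(1, 1, 1), affine = NULL,
                             threshold = NULL) {
  stopifnot(is.array(prob), length(dim(prob)) == 4L, dim(prob)[1] == 3L)
  d <- dim(prob)[2:4]
  arr <- array(0, c(rev(d), 3L))
  for (r in 1:3) arr[, , , r] <- zyx_to_xyz(prob[r, , , ])
  write_nifti(arr, path, spacing = rev(spacing), affine = affine,
              datatype = "float32")
  out <- list(prob = path)
  if (!is.null(threshold)) {
    mask <- predict_mask(prob, threshold)
    seg <- sub("(\\.nii(\\.gz)?)$", "_seg\\1", path)
    write_nifti(zyx_to_xyz(subregions_to_labels(mask)), seg,
                spacing = rev(spacing), affine = affine, datatype = "uint8")
    out$mask <- seg
  }
  out
}

#' Case manifests
#'
#' A manifest is a CSV with columns `case_id`, one path column per modality
#' (`t1`, `t1ce`, `t2`, `flair`) and an optional `label` column. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return `read_manifest()`: a tibble; `load_manifest_cases()`: a list of
#'   [case_record()]s.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", modality_order())
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest Tibble/data.frame of cases.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @param code_table Label code table.
#' @export
load_manifest_cases <- function(path, code_table = brats_label_codes()) {
  mf <- read_manifest(path)
  base <- dirname(path)
  resolve <- function(p) ifelse(is.na(p) | p == "", NA_character_,
                                ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                       file.path(base, p)))
  lapply(seq_len(nrow(mf)), function(i) {
    lab <- if ("label" %in% names(mf)) resolve(mf$label[i]) else NA_character_
    load_case(vapply(modality_order(), function(m) resolve(mf[[m]][i]),
                     character(1)),
              label_path = if (is.na(lab)) NULL else lab,
              case_id = mf$case_id[i], code_table = code_table)
  })
}

## ---- preprocessing ----------------------------------------------------------

znorm_nonzero <- function(x) {
  fg <- x != 0
  if (!any(fg)) return(x)
  mu <- mean(x[fg])
  sd <- stats::sd(x[fg])
  if (!is.finite(sd) || sd == 0) {
    warning("modality has zero foreground variance; normalised to all zeros",
            call. = FALSE)
    return(array(0, dim(x)))
  }
  x[fg] <- (x[fg] - mu) / sd
  x
}

croppad_zyx <- function(a, target) {
  # a: (C, z, y, x); centre crop/pad each spatial axis to `target`
  sp <- dim(a)[2:4]
  if (all(sp == target)) return(a)
  idx <- croppad_index(sp, as.integer(target))
  mat_to_fm(gather0(fm_to_mat(a), idx), as.integer(target))
}

#' Preprocess a case to the network input geometry
#'
#' Per-modality z-score normalisation over nonzero (foreground) voxels --
#' zero voxels stay zero, constant modalities normalise to all zeros with a
#' warning -- followed by a centre crop/zero-pad to `target_shape`. No
#' resampling is performed, so label topology is preserved exactly; the mask
#' undergoes the same crop/pad (nearest-neighbour semantics are trivial for
#' pure cropping/padding).
#'
#' @param case A [case_record()] (or [multimodal_volume()]).
#' @param target_shape Target `(z, y, x)` extent, default `c(96, 128, 128)`.
#' @return The preprocessed object, same class as the input.
#' @export
preprocess_case <- function(case, target_shape = c(96L, 128L, 128L)) {
  stopifnot(all(target_shape >= 1L))
  if (inherits(case, "multimodal_volume")) {
    return(preprocess_case(case_record("volume", case), target_shape)$volume)
  }
  v <- case$volume
  a <- v$intensities
  for (m in seq_len(dim(a)[1])) a[m, , , ] <- znorm_nonzero(a[m, , , ])
  sp <- dim(a)[2:4]
  a <- croppad_zyx(a, target_shape)
  affine <- v$affine
  off_xyz <- rev((sp - as.integer(target_shape)) %/% 2L)
  if (any(off_xyz != 0L)) {
    affine[1:3, 4] <- (affine %*% c(off_xyz, 1))[1:3]
  }
  vol <- multimodal_volume(a, spacing = v$spacing, affine = affine,
                           modalities = v$modalities)
  mask <- NULL
  if (!is.null(case$mask)) {
    mch <- croppad_zyx(case$mask$channels, target_shape)
    mask <- subregion_mask(mch, case$mask$regions, check = FALSE)
    attr(mask, "nesting_violations") <- attr(case$mask, "nesting_violations")
  }
  case_record(case$case_id, vol, mask)
}
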