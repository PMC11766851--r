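# Volumetric evaluation metrics and the training loss.
#
# DSC(G,P) = 2|G∩P| / (|G|+|P|);  IoU(G,P) = |G∩P| / |G∪P|;
# HD(G,P)  = max_{g in G} min_{p in P} d(g,p)  (directed form; the symmetric
# form, used for reporting, takes the max of both directions, and the 95th
# percentile variant replaces the max by a percentile).  Distances are
# Euclidean in millimetres using the voxel spacing.

as_binary_grid <- function(x) {
  if (inherits(x, "subregion_mask")) stop("pass one region channel, not a subregion_mask")
  stopifnot(is.array(x) || is.vector(x))
  if (!all(x %in% c(0, 1, FALSE, TRUE))) stop("mask must be binary")
  x
}

check_same_grid <- function(G, P) {
  if (!isTRUE(all.equal(dim(G) %||% length(G), dim(P) %||% length(P)))) {
    stop("grids differ: ", paste(dim(G), collapse = "x"), " vs ",
         paste(dim(P), collapse = "x"))
  }
}

#' Dice similarity coefficient
#'
#' `2|G∩P| / (|G| + |P|)`, in \[0, 1\]. Two empty masks score 1 by
#' convention (a correctly predicted absent region).
#'
#' @param G,P Binary arrays on one grid (ground truth, prediction).
#' @export
dsc <- function(G, P) {
  G <- as_binary_grid(G); P <- as_binary_grid(P)
  check_same_grid(G, P)
  sg <- sum(G); sp <- sum(P)
  if (sg + sp == 0) return(1)
  2 * sum(G * P) / (sg + sp)
}

#' Jaccard index (intersection over union)
#'
#' `|G∩P| / |G∪P|`, in \[0, 1\]; both-empty scores 1. Satisfies
#' `IoU = DSC / (2 - DSC)`.
#'
#' @param G,P Binary arrays on one grid.
#' @export
iou <- function(G, P) {
  G <- as_binary_grid(G); P <- as_binary_grid(P)
  check_same_grid(G, P)
  un <- sum(pmax(G, P))
  if (un == 0) return(1)
  sum(G * P) / un
}

# coordinates (voxels, 1-based) of the nonzero entries of a 3D binary array,
# scaled to mm
mask_coords_mm <- function(x, spacing) {
  w <- which(x > 0)
  d <- dim(x)
  cbind(((w - 1) %% d[1] + 1) * spacing[1],
        (((w - 1) %/% d[1]) %% d[2] + 1) * spacing[2],
        ((w - 1) %/% (d[1] * d[2]) + 1) * spacing[3])
}

# boundary voxels of a binary 3D array (voxels with a 6-neighbour outside)
mask_boundary <- function(x) {
  d <- dim(x)
  inner <- array(TRUE, d)
  shift_and <- function(ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    keep <- do.call(`[`, c(list(x), src))
    # voxels at the volume edge count as boundary (treat outside as 0)
    edge <- idx[[ax]] + by < 1L | idx[[ax]] + by > d[ax]
    edgearr <- array(FALSE, d)
    if (ax == 1L) edgearr[edge[seq_len(d[1])], , ] <- TRUE
    if (ax == 2L) edgearr[, edge[seq_len(d[2])], ] <- TRUE
    if (ax == 3L) edgearr[, , edge[seq_len(d[3])]] <- TRUE
    keep > 0 & !edgearr
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) inner <- inner & shift_and(ax, by)
  x > 0 & !inner
}

# directed min-distances (mm) from every voxel of G to the set P
directed_min_dists <- function(G, P, spacing) {
  inP <- G > 0 & P > 0
  dists <- rep(0, sum(G > 0))
  outside <- which(!(inP[G > 0]))
  if (length(outside) == 0L) return(dists)
  gc <- mask_coords_mm(G & !inP, spacing)
  pb <- mask_coords_mm(mask_boundary(P), spacing)
  step <- max(1L, floor(2e7 / nrow(pb)))
  mins <- numeric(nrow(gc))
  for (s in seq(1L, nrow(gc), by = step)) {
    e <- min(s + step - 1L, nrow(gc))
    blk <- gc[s:e, , drop = FALSE]
    d2 <- outer(blk[, 1], pb[, 1], "-")^2 +
      outer(blk[, 2], pb[, 2], "-")^2 +
      outer(blk[, 3], pb[, 3], "-")^2
    mins[s:e] <- sqrt(apply(d2, 1L, min))
  }
  dists[outside] <- mins
  dists
}

#' Hausdorff distance between binary masks
#'
#' Directed mode implements `max_g min_p d(g, p)`; symmetric mode (the
#' reporting default) takes the larger of the two directions. `percentile =
#' 95` replaces the maximum with the 95th percentile of the directed
#' min-distances (HD95). Distances are in mm via `spacing`.
#'
#' If either mask is empty the distance is undefined: the configured
#' `empty_value` (default: the grid diagonal in mm) is returned with a
#' warning and an `"empty"` attribute, so such cases are flagged, never
#' silently dropped.
#'
#' @param G,P Binary 3D arrays on one grid.
#' @param spacing mm per (z, y, x) axis.
#' @param mode `"symmetric"` or `"directed"` (G to P).
#' @param percentile 100 (max) or 95.
#' @param empty_value Penalty returned when a mask is empty.
#' @export
hausdorff_distance <- function(G, P, spacing = c(1, 1, 1),
                               mode = c("symmetric", "directed"),
                               percentile = 100, empty_value = NULL) {
  mode <- match.arg(mode)
  G <- as_binary_grid(G); P <- as_binary_grid(P)
  check_same_grid(G, P)
  stopifnot(percentile > 0, percentile <= 100)
  if (sum(G) == 0 || sum(P) == 0) {
    if (is.null(empty_value)) {
      empty_value <- sqrt(sum((dim(G) * spacing)^2))
    }
    warning("empty mask in Hausdorff computation; returning penalty ",
            signif(empty_value, 4), call. = FALSE)
    return(structure(empty_value, empty = TRUE))
  }
  agg <- function(d) {
    if (percentile == 100) max(d) else as.numeric(stats::quantile(d, percentile / 100))
  }
  h_gp <- agg(directed_min_dists(G, P, spacing))
  if (mode == "directed") return(h_gp)
  max(h_gp, agg(directed_min_dists(P, G, spacing)))
}

#' Soft Dice loss
#'
#' Mean over region channels of `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) +
#' eps)`: the Dice similarity subtracted from one, smoothed by `eps` so empty
#' regions are well-defined, and differentiable in the probabilities.
#'
#' @param prob Probability array `(3, z, y, x)` (or `N x 3` matrix), values
#'   in \[0, 1\].
#' @param target A [subregion_mask()] or binary array of matching shape.
#' @param eps Smoothing constant.
#' @return Scalar loss in \[0, 1\).
#' @export
dice_loss <- function(prob, target, eps = 1e-5) {
  if (inherits(target, "subregion_mask")) target <- target$channels
  p <- if (is.matrix(prob)) prob else fm_to_mat(prob)
  t <- if (is.matrix(target)) target else fm_to_mat(target)
  if (!all(dim(p) == dim(t))) {
    stop("probability and target shapes differ: ",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(t), collapse = "x"))
  }
  if (min(p) < 0 || max(p) > 1) stop("probabilities must lie in [0, 1]")
  vof(nn_dice_loss(p, t, eps))
}

#' Threshold probabilities into a subregion mask
#'
#' Per-channel thresholding; subregion nesting is *not* enforced -- a
#' violated nesting in the thresholded prediction is recorded in the mask's
#' `nesting_violations` attribute as a quality flag.
#'
#' @param prob Probability array `(3, z, y, x)` in \[0, 1\].
#' @param threshold Threshold in (0, 1).
#' @return A [subregion_mask()].
#' @export
predict_mask <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1), got ", threshold)
  }
  stopifnot(is.array(prob), length(dim(prob)) == 4L, dim(prob)[1] == 3L)
  if (min(prob) < 0 || max(prob) > 1) stop("probabilities must lie in [0, 1]")
  ch <- (prob >= threshold) * 1
  suppressWarnings(subregion_mask(ch, check = TRUE))
}

#' Per-case, per-region metrics
#'
#' @param truth,pred [subregion_mask()]s on one grid.
#' @param case_id Identifier for the output rows.
#' @param spacing mm per (z, y, x) axis for the Hausdorff distance.
#' @param hd_mode,hd_percentile Hausdorff variant, see
#'   [hausdorff_distance()].
#' @return Tibble with columns case_id, region, dsc, iou, hausdorff.
#' @export
evaluate_case <- function(truth, pred, case_id = "case",
                          spacing = c(1, 1, 1), hd_mode = "symmetric",
                          hd_percentile = 100) {
  stopifnot(inherits(truth, "subregion_mask"), inherits(pred, "subregion_mask"))
  rows <- lapply(1:3, function(r) {
    G <- truth$channels[r, , , ]
    P <- pred$channels[r, , , ]
    hd <- suppressWarnings(
      hausdorff_distance(G, P, spacing, mode = hd_mode,
                         percentile = hd_percentile))
    tibble::tibble(case_id = case_id, region = region_order()[r],
                   dsc = dsc(G, P), iou = iou(G, P),
                   hausdorff = as.numeric(hd),
                   hd_flagged = isTRUE(attr(hd, "empty")))
  })
  dplyr::bind_rows(rows)
}

#' Aggregate per-case metrics into a report
#'
#' Per-region mean and sample standard deviation (n-1) over cases, plus a
#' `Mean` row whose point value is the average of the three per-region means
#' (its spread is the standard deviation over cases of the per-case
#' region-mean).
#'
#' @param per_case Tibble from [evaluate_case()] rows (>= 1 case).
#' @return A `metric_report`: list with `per_case` and `summary` tibbles.
#' @export
aggregate_metrics <- function(per_case) {
  if (is.null(per_case) || nrow(per_case) == 0L) {
    stop("no cases to aggregate")
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  by_region <- per_case |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(dplyr::across(c("dsc", "iou", "hausdorff"),
                                   list(mean = mean, sd = sd0)),
                     .groups = "drop")
  case_means <- per_case |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(dplyr::across(c("dsc", "iou", "hausdorff"), mean),
                     .groups = "drop")
  mean_row <- tibble::tibble(
    region = "Mean",
    dsc_mean = mean(by_region$dsc_mean), dsc_sd = sd0(case_means$dsc),
    iou_mean = mean(by_region$iou_mean), iou_sd = sd0(case_means$iou),
    hausdorff_mean = mean(by_region$hausdorff_mean),
    hausdorff_sd = sd0(case_means$hausdorff)
  )
  ord <- c("Mean", "TC", "WT", "ET")
  summary <- dplyr::bind_rows(mean_row, by_region)
  summary <- summary[order(match(summary$region, ord)), ]
  structure(list(per_case = per_case, summary = summary),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  n <- length(unique(x$per_case$case_id))
  cat("Segmentation metrics over", n, "case(s) (mean ± sd)\n")
  s <- x$summary
  fmt <- function(m, sd) sprintf("%.3f ± %.3f", m, sd)
  out <- data.frame(Region = s$region,
                    DSC = fmt(s$dsc_mean, s$dsc_sd),
                    Jaccard = fmt(s$iou_mean, s$iou_sd),
                    Hausdorff = fmt(s$hausdorff_mean, s$hausdorff_sd))
  print(out, row.names = FALSE)
  ns <- attr(x, "n_skipped")
  if (!is.null(ns) && ns > 0L) cat("(", ns, "case(s) without mask skipped )\n")
  if (any(x$per_case$hd_flagged)) {
    cat("(", sum(x$per_case$hd_flagged),
        "empty-mask Hausdorff value(s) replaced by the penalty distance )\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.metric_report <- function(x, ...) x$per_case

#' @export
glance.metric_report <- function(x, ...) {
  s <- x$summary[x$summary$region == "Mean", ]
  tibble::tibble(n_cases = length(unique(x$per_case$case_id)),
                 mean_dsc = s$dsc_mean, mean_iou = s$iou_mean,
                 mean_hausdorff = s$hausdorff_mean)
}
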