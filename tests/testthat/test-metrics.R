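# Overlap metrics, Hausdorff distances, Dice loss, aggregation.

test_that("DSC follows its set-arithmetic definition on enumerated masks", {
  G <- array(0, c(4, 4, 2)); P <- array(0, c(4, 4, 2))
  G[1:4, 1, 1] <- 1                   # |G| = 4
  P[2:4, 1, 1] <- 1; P[1:3, 2, 1] <- 1  # |P| = 6, |G ∩ P| = 3
  expect_equal(dsc(G, P), 2 * 3 / (4 + 6))
  expect_equal(dsc(G, G), 1)
  D <- array(0, dim(G)); D[1, 4, 2] <- 1
  expect_equal(dsc(G, D), 0)          # disjoint non-empty
  expect_equal(dsc(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1)
  expect_error(dsc(G, array(0, c(3, 3, 3))), "grids differ")
})

test_that("IoU follows its definition and the DSC identity", {
  G <- array(0, c(4, 4, 2)); P <- array(0, c(4, 4, 2))
  G[1:4, 1, 1] <- 1
  P[2:4, 1, 1] <- 1; P[1:3, 2, 1] <- 1  # |G ∩ P| = 3, |G ∪ P| = 7
  expect_equal(iou(G, P), 3 / 7)
  expect_equal(iou(G, G), 1)
  for (s in 1:20) {
    mp <- random_mask_pair(s)
    d <- dsc(mp$G, mp$P)
    expect_equal(iou(mp$G, mp$P), d / (2 - d), tolerance = 1e-12)
  }
})

test_that("DSC and IoU agree exactly with brute-force oracles on 100 random mask pairs", {
  for (s in 1:100) {
    mp <- random_mask_pair(s)
    expect_equal(dsc(mp$G, mp$P), oracle_dsc(mp$G, mp$P), tolerance = 1e-13)
    expect_equal(iou(mp$G, mp$P), oracle_iou(mp$G, mp$P), tolerance = 1e-13)
    # symmetry of the overlap metrics
    expect_equal(dsc(mp$P, mp$G), dsc(mp$G, mp$P))
    expect_equal(iou(mp$P, mp$G), iou(mp$G, mp$P))
  }
})

test_that("Hausdorff distance reproduces hand-checked geometry", {
  G <- array(0, c(4, 5, 2)); G[1, 1, 1] <- 1
  P <- array(0, c(4, 5, 2)); P[4, 5, 1] <- 1
  expect_equal(hausdorff_distance(G, P), 5)  # 3-4-5 triangle, unit spacing
  expect_equal(hausdorff_distance(G, G), 0)
  # spacing turns voxel offsets into mm
  expect_equal(hausdorff_distance(G, P, spacing = c(2, 1, 1)),
               sqrt(36 + 16))
})

test_that("directed Hausdorff matches the all-pairs oracle and can be asymmetric", {
  for (s in 1:10) {
    mp <- random_mask_pair(s + 200, d = c(6L, 6L, 4L), p = 0.08)
    if (sum(mp$G) == 0 || sum(mp$P) == 0) next
    sp <- c(1, 1.5, 2)
    expect_equal(hausdorff_distance(mp$G, mp$P, sp, mode = "directed"),
                 oracle_directed_hd(mp$G, mp$P, sp), tolerance = 1e-10)
    expect_equal(hausdorff_distance(mp$G, mp$P, sp, mode = "symmetric"),
                 max(oracle_directed_hd(mp$G, mp$P, sp),
                     oracle_directed_hd(mp$P, mp$G, sp)), tolerance = 1e-10)
    expect_equal(hausdorff_distance(mp$G, mp$P, sp, percentile = 95,
                                    mode = "directed"),
                 oracle_directed_hd(mp$G, mp$P, sp, percentile = 95),
                 tolerance = 1e-10)
  }
  # a constructed pair where the two directions differ
  G <- array(0, c(8, 1, 1)); G[1, 1, 1] <- 1
  P <- array(0, c(8, 1, 1)); P[c(1, 8), 1, 1] <- 1
  expect_equal(hausdorff_distance(G, P, mode = "directed"), 0)
  expect_equal(hausdorff_distance(P, G, mode = "directed"), 7)
  expect_equal(hausdorff_distance(G, P, mode = "symmetric"), 7)
})

test_that("empty masks yield the flagged penalty distance, never a silent drop", {
  G <- array(0, c(4, 4, 4)); P <- array(0, c(4, 4, 4)); P[2, 2, 2] <- 1
  expect_warning(h <- hausdorff_distance(G, P), "empty mask")
  expect_equal(as.numeric(h), sqrt(3 * 16))  # grid diagonal default
  expect_true(attr(h, "empty"))
  expect_warning(h2 <- hausdorff_distance(G, P, empty_value = 99))
  expect_equal(as.numeric(h2), 99)
})

test_that("dice_loss matches hand-evaluated soft Dice on a worked grid", {
  # 2x2x1 grid, one channel pair worked by hand:
  # p = (0.8, 0.2, 0.6, 0.4), t = (1, 0, 1, 0)
  # num = 2*(0.8 + 0.6) + eps = 2.8 + eps; den = 2.0 + 2 + eps = 4 + eps
  p <- array(0, c(3, 2, 2, 1)); t <- array(0, c(3, 2, 2, 1))
  p[1, , , ] <- c(0.8, 0.2, 0.6, 0.4); t[1, , , ] <- c(1, 0, 1, 0)
  p[2, , , ] <- c(0.1, 0.9, 0.5, 0.5); t[2, , , ] <- c(0, 1, 1, 0)
  p[3, , , ] <- c(0.3, 0.3, 0.3, 0.3); t[3, , , ] <- c(0, 0, 0, 1)
  eps <- 1e-5
  want <- mean(c(1 - (2.8 + eps) / (4 + eps),
                 1 - (2 * 1.4 + eps) / (2 + 2 + eps),
                 1 - (2 * 0.3 + eps) / (1.2 + 1 + eps)))
  expect_equal(dice_loss(p, t), want, tolerance = 1e-12)
  # perfect and inverted predictions
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-4)
  expect_equal(dice_loss(1 - t, t), 1, tolerance = 1e-4)
  expect_error(dice_loss(array(0.5, c(3, 2, 2, 2)), t), "shapes differ")
  expect_error(dice_loss(p * 3, t), "\\[0, 1\\]")
})

test_that("aggregate_metrics reproduces the mean +/- sd table semantics", {
  rows <- dplyr::bind_rows(
    tibble::tibble(case_id = "a", region = c("WT", "TC", "ET"),
                   dsc = c(0.8, 0.6, 0.4), iou = c(0.7, 0.5, 0.3),
                   hausdorff = c(1, 2, 3), hd_flagged = FALSE),
    tibble::tibble(case_id = "b", region = c("WT", "TC", "ET"),
                   dsc = c(0.6, 0.8, 0.6), iou = c(0.5, 0.6, 0.5),
                   hausdorff = c(3, 2, 1), hd_flagged = FALSE))
  rep <- aggregate_metrics(rows)
  s <- rep$summary
  expect_identical(s$region, c("Mean", "TC", "WT", "ET"))
  expect_equal(s$dsc_mean[s$region == "WT"], 0.7)
  expect_equal(s$dsc_sd[s$region == "WT"], sd(c(0.8, 0.6)))
  # Mean row = average of the three per-region means
  expect_equal(s$dsc_mean[s$region == "Mean"],
               mean(s$dsc_mean[s$region != "Mean"]))
  expect_equal(s$hausdorff_mean[s$region == "Mean"],
               mean(s$hausdorff_mean[s$region != "Mean"]))
  # one case -> zero spread
  one <- aggregate_metrics(rows[rows$case_id == "a", ])
  expect_true(all(one$summary$dsc_sd == 0))
  expect_error(aggregate_metrics(rows[0, ]), "no cases")
  # random tables: Mean row equals the recomputed average (property)
  set.seed(9)
  rnd <- tibble::tibble(
    case_id = rep(sprintf("c%d", 1:6), each = 3),
    region = rep(c("WT", "TC", "ET"), 6),
    dsc = runif(18), iou = runif(18), hausdorff = runif(18, 0, 20),
    hd_flagged = FALSE)
  rr <- aggregate_metrics(rnd)$summary
  expect_equal(rr$iou_mean[rr$region == "Mean"],
               mean(rr$iou_mean[rr$region != "Mean"]), tolerance = 1e-12)
})

test_that("tidy, glance and autoplot views of a report work", {
  cases <- tiny_cohort(2)
  idmodel <- local({
    masks <- lapply(cases, function(cs) cs$mask$channels)
    i <- 0
    function(vol) { i <<- i + 1; masks[[i]] * 1 }
  })
  rep <- evaluate_model(idmodel, cases, preprocess = FALSE)
  expect_equal(nrow(tidy(rep)), 6L)
  g <- glance(rep)
  expect_equal(g$mean_dsc, 1)
  expect_equal(g$mean_hausdorff, 0)
  pl <- ggplot2::autoplot(rep)
  expect_s3_class(pl, "ggplot")
})
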