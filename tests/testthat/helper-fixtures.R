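# Shared fixtures, built in code and cached for the whole run.

.fix <- new.env()

tiny_spec <- function(noise_sigma = 2, seed = 7) {
  phantom_spec(grid_shape = c(16L, 16L, 16L), radii = c(6, 4, 2),
               noise_sigma = noise_sigma, seed = seed)
}

tiny_cohort <- function(n = 4) {
  key <- paste0("cohort", n)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- generate_cohort(n, tiny_spec(), seed = 11)
  }
  .fix[[key]]
}

tiny_model <- function() {
  if (is.null(.fix$tiny_model)) {
    .fix$tiny_model <- catseg_model(catseg_tiny_config(), seed = 1)
  }
  .fix$tiny_model
}

default_model <- function() {
  if (is.null(.fix$default_model)) {
    .fix$default_model <- catseg_model(catseg_config(), seed = 1)
  }
  .fix$default_model
}

# a short deterministic training run shared by several tests
short_run <- function() {
  if (is.null(.fix$short_run)) {
    m <- catseg_model(catseg_tiny_config(), seed = 1)
    .fix$short_run <- train_model(m, tiny_cohort(4),
                                  tiny_train_config(epochs = 6L,
                                                    eval_every = 6L,
                                                    seed = 42L))
  }
  .fix$short_run
}

random_fm <- function(C, sp, seed = 1) {
  set.seed(seed)
  array(rnorm(C * prod(sp)), c(C, sp))
}

# naive reference: per-voxel set arithmetic on coordinate lists
oracle_dsc <- function(G, P) {
  g <- which(G > 0); p <- which(P > 0)
  if (length(g) + length(p) == 0) return(1)
  2 * length(intersect(g, p)) / (length(g) + length(p))
}

oracle_iou <- function(G, P) {
  g <- which(G > 0); p <- which(P > 0)
  if (length(union(g, p)) == 0) return(1)
  length(intersect(g, p)) / length(union(g, p))
}

# all-pairs directed Hausdorff (double loop, mm)
oracle_directed_hd <- function(G, P, spacing = c(1, 1, 1), percentile = 100) {
  cg <- which(G > 0, arr.ind = TRUE)
  cp <- which(P > 0, arr.ind = TRUE)
  mins <- numeric(nrow(cg))
  for (i in seq_len(nrow(cg))) {
    best <- Inf
    for (j in seq_len(nrow(cp))) {
      d <- sqrt(sum(((cg[i, ] - cp[j, ]) * spacing)^2))
      if (d < best) best <- d
    }
    mins[i] <- best
  }
  if (percentile == 100) max(mins) else as.numeric(quantile(mins, percentile / 100))
}

random_mask_pair <- function(seed, d = c(8L, 8L, 8L), p = 0.12) {
  set.seed(seed)
  list(G = array(rbinom(prod(d), 1, p), d),
       P = array(rbinom(prod(d), 1, p), d))
}

# finite-difference gradient of a scalar-valued function at x
fd_grad <- function(f, x, h = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
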