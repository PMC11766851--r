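# Shifted-window transformer encoder: patch embedding, stages, the feature
# ladder, and attention behaviour.

test_that("patch partition + embedding halves each axis, widens to embed_dim, and is linear", {
  m <- tiny_model()
  x <- random_fm(4, c(16, 16, 16), seed = 1)
  t1 <- patch_partition_embed(m, x, normalise = FALSE)
  expect_equal(dim(t1), c(8L, 8L, 8L, 8L))
  # zero input -> pure bias pattern, constant over tokens
  t0 <- patch_partition_embed(m, array(0, c(4, 16, 16, 16)), normalise = FALSE)
  expect_equal(max(abs(sweep(catseg:::fm_to_mat(t0), 2,
                             m$params[["embed.b"]]))), 0)
  # doubling the input doubles (output - bias)
  t2 <- patch_partition_embed(m, 2 * x, normalise = FALSE)
  expect_equal(catseg:::fm_to_mat(t2) - catseg:::fm_to_mat(t0),
               2 * (catseg:::fm_to_mat(t1) - catseg:::fm_to_mat(t0)),
               tolerance = 1e-12)
})

test_that("stages trace the halving ladder and the full encoder emits six levels", {
  m <- tiny_model()
  emb <- m$config$embed_dim
  x <- random_fm(4, c(16, 16, 16), seed = 2)
  lv <- suppressWarnings(encode_volume(m, x))
  expect_named(lv, paste0("level", 0:5))
  expect_equal(lapply(lv, dim),
               list(level0 = c(emb, 16L, 16L, 16L),
                    level1 = c(emb, 8L, 8L, 8L),
                    level2 = c(2L * emb, 4L, 4L, 4L),
                    level3 = c(4L * emb, 2L, 2L, 2L),
                    level4 = c(8L * emb, 1L, 1L, 1L),
                    level5 = c(16L * emb, 1L, 1L, 1L)))
  # stage-by-stage channel doubling from a level-1 map
  t <- lv$level1
  for (s in 2:4) {
    t <- swin_stage(m, t, s)
    expect_equal(dim(t)[1], emb * 2^(s - 1L))
  }
  # inference is deterministic
  lv2 <- suppressWarnings(encode_volume(m, x))
  expect_identical(lv$level5, lv2$level5)
})

test_that("channel widths follow the published ladder at full embedding width", {
  cfg <- catseg_config()
  expect_identical(cfg$channels, c(48L, 48L, 96L, 192L, 384L, 768L))
})

test_that("patch merging conserves tokens 8:1 with padding accounted", {
  for (sp in list(c(8L, 8L, 8L), c(7L, 6L, 5L), c(1L, 3L, 9L))) {
    bi <- catseg:::block2_index(sp)
    expect_equal(prod(bi$out_spatial), prod((sp + 1L) %/% 2L))
    # every input token lands in exactly one output block slot
    used <- bi$idx[bi$idx > 0L]
    expect_equal(sort(used), seq_len(prod(sp)))
  }
})

test_that("attention weights in every window sum to one over keys", {
  m <- tiny_model()
  x <- random_fm(4, c(16, 16, 16), seed = 3)
  diag_env <- catseg:::.diag
  diag_env$capture <- TRUE
  diag_env$attention <- list()
  invisible(suppressWarnings(encode_volume(m, x)))
  diag_env$capture <- FALSE
  expect_gt(length(diag_env$attention), 0)
  for (S in diag_env$attention) {
    expect_equal(rowSums(S), rep(1, nrow(S)), tolerance = 1e-10)
    expect_true(all(S >= 0))
  }
  diag_env$attention <- list()
})

test_that("non-shifted window attention is equivariant to whole-window cyclic translation", {
  m <- tiny_model()
  cfg <- m$config
  sp <- c(8L, 8L, 8L)   # divisible by the 4^3 window: exact partition, no pads
  set.seed(4)
  x <- matrix(rnorm(prod(sp) * cfg$embed_dim), prod(sp), cfg$embed_dim)
  P <- function(nm) m$params[[nm]]
  fwd <- function(xm) catseg:::swin_block_fwd(xm, sp, cfg$embed_dim,
                                              cfg$num_heads[1], P, "s1.b1.",
                                              cfg, shifted = FALSE)
  roll_idx <- local({
    co <- catseg:::spatial_coords(sp)
    catseg:::coord_to_row(((co$i - 1L + 4L) %% 8L) + 1L,
                          ((co$j - 1L + 4L) %% 8L) + 1L,
                          ((co$k - 1L + 4L) %% 8L) + 1L, sp)
  })
  y <- fwd(x)
  y_rolled <- fwd(x[roll_idx, ])
  expect_equal(y_rolled, y[roll_idx, ], tolerance = 1e-10)
})

test_that("with zeroed residual branches a stage reduces to its patch merge", {
  m <- tiny_model()
  cfg <- m$config
  m2 <- m
  for (d in 1:2) {
    pre <- sprintf("s2.b%d.", d)
    for (nm in c("proj.W", "proj.b", "mlp2.W", "mlp2.b")) {
      m2$params[[paste0(pre, nm)]][] <- 0
    }
  }
  x <- random_fm(cfg$embed_dim, c(8, 8, 8), seed = 5)
  got <- swin_stage(m2, x, 2L)
  # independent merge oracle: 2x2x2 concat + layer norm + linear
  xm <- catseg:::fm_to_mat(x)
  bi <- catseg:::block2_index(c(8L, 8L, 8L))
  cat8 <- do.call(cbind, lapply(1:8, function(o) xm[bi$idx[, o], , drop = FALSE]))
  mu <- rowMeans(cat8)
  sdv <- sqrt(rowMeans((cat8 - mu)^2) + 1e-5)
  ln <- ((cat8 - mu) / sdv) * rep(m$params[["merge2.ln.g"]], each = nrow(cat8)) +
    rep(m$params[["merge2.ln.b"]], each = nrow(cat8))
  want <- ln %*% m$params[["merge2.W"]]
  expect_equal(catseg:::fm_to_mat(got), want, tolerance = 1e-10)
})

test_that("window padding and masking handle grids smaller than the window without error", {
  m <- tiny_model()
  x <- random_fm(m$config$embed_dim * 4, c(2, 2, 2), seed = 6)
  out <- swin_stage(m, x, 4L)   # merges to 1^3, window 4 clipped to 1
  expect_equal(dim(out), c(m$config$embed_dim * 8L, 1L, 1L, 1L))
  expect_true(all(is.finite(out)))
})
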