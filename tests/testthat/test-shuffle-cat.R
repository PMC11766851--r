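# Channel shuffle, global average pooling, channel attention, CAT blocks.

test_that("channel_shuffle equals the reshape-transpose oracle for all (C, G) with C <= 16", {
  oracle_perm <- function(C, G) {
    # fill a (C/G x G) matrix group by group, transpose, flatten
    as.vector(t(matrix(seq_len(C), nrow = C %/% G, ncol = G)))
  }
  for (C in 1:16) {
    for (G in seq_len(C)) {
      if (C %% G != 0L) next
      x <- array(0, c(C, 2, 2, 1))
      for (ch in seq_len(C)) x[ch, , , ] <- ch  # labelled channels
      got <- channel_shuffle(x, G)
      want_first <- oracle_perm(C, G)
      expect_equal(got[, 1, 1, 1], as.numeric(want_first),
                   label = sprintf("C=%d G=%d", C, G))
    }
  }
  # worked example: C = 4, G = 2, channels (a,b,c,d) -> (a,c,b,d)
  x <- array(0, c(4, 2, 2, 2))
  for (ch in 1:4) x[ch, , , ] <- c(10, 20, 30, 40)[ch]
  expect_equal(channel_shuffle(x, 2)[, 1, 1, 1], c(10, 30, 20, 40))
})

test_that("channel_shuffle is an involution under swapped factors and G = 1 is the identity", {
  set.seed(1)
  x <- random_fm(12, c(3, 4, 2), seed = 1)
  expect_identical(channel_shuffle(x, 1L), x)
  for (G in c(2L, 3L, 4L, 6L)) {
    expect_equal(channel_shuffle(channel_shuffle(x, G), 12L %/% G), x,
                 label = paste("G =", G))
  }
  expect_error(channel_shuffle(x, 5L), "divide")
})

test_that("channel_shuffle preserves the multiset of channel contents exactly", {
  set.seed(2)
  x <- random_fm(8, c(4, 3, 2), seed = 2)
  y <- channel_shuffle(x, 4L)
  fp <- function(a) sort(apply(a, 1, function(ch) paste(signif(ch, 12), collapse = ",")))
  expect_identical(fp(array(y, c(8, 24))), fp(array(x, c(8, 24))))
})

test_that("global_avg_pool is the per-channel spatial mean, linear, and constant-preserving", {
  # 2x2x1 worked example: values (1, 2, 3, 6) -> mean 3
  x <- array(0, c(2, 2, 2, 1))
  x[1, , , ] <- c(1, 2, 3, 6)
  x[2, , , ] <- 5  # constant channel -> its own value
  m <- global_avg_pool(x)
  expect_equal(m, c(3, 5))
  # linearity: GAP(a*x + b*y) = a*GAP(x) + b*GAP(y)
  set.seed(3)
  a <- random_fm(6, c(3, 2, 4), seed = 3)
  b <- random_fm(6, c(3, 2, 4), seed = 4)
  expect_equal(global_avg_pool(2.5 * a - 1.2 * b),
               2.5 * global_avg_pool(a) - 1.2 * global_avg_pool(b),
               tolerance = 1e-12)
})

test_that("channel_attention equals the composed GAP -> FC -> FC -> sigmoid -> scale oracle", {
  set.seed(5)
  C <- 8L; r <- 4L
  x <- random_fm(C, c(4, 4, 4), seed = 5)
  W1 <- matrix(rnorm(C * C / r), C, C / r); b1 <- rnorm(C / r)
  W2 <- matrix(rnorm(C * C / r), C / r, C); b2 <- rnorm(C)
  got <- channel_attention(x, W1, b1, W2, b2)
  # independent oracle assembled from base-R primitives
  m <- apply(x, 1, mean)
  h <- as.vector(t(W1) %*% m + b1)
  h <- ifelse(h >= 0, h, 0.01 * h)
  g <- 1 / (1 + exp(-(as.vector(t(W2) %*% h + b2))))
  want <- x
  for (ch in seq_len(C)) want[ch, , , ] <- x[ch, , , ] * g[ch]
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(g > 0 & g < 1))
})

test_that("zero-weight attention gives uniform 0.5 gates and disabling it gives the identity", {
  set.seed(6)
  C <- 8L
  x <- random_fm(C, c(3, 3, 3), seed = 6)
  z2 <- matrix(0, 2, C)
  got <- channel_attention(x, matrix(0, C, 2), rep(0, 2), z2, rep(0, C))
  expect_equal(got, x / 2, tolerance = 1e-12)
  expect_identical(channel_attention(x, matrix(0, C, 2), rep(0, 2), z2,
                                     rep(0, C), enabled = FALSE), x)
})

test_that("attention gates ignore spatial order and respond monotonically to channel means", {
  set.seed(7)
  C <- 4L
  x <- random_fm(C, c(2, 3, 2), seed = 7)
  W1 <- matrix(abs(rnorm(C * 1)), C, 1); b1 <- 0.1
  W2 <- matrix(abs(rnorm(C)), 1, C); b2 <- rep(0, C)
  gates_of <- function(a) {
    y <- channel_attention(a, W1, b1, W2, b2)
    (catseg:::fm_to_mat(y) / catseg:::fm_to_mat(a))[1, ]
  }
  # spatial permutation invariance
  xp <- x[, , , c(2, 1)]
  xp <- xp[, c(2, 1), , ]
  expect_equal(gates_of(xp), gates_of(x), tolerance = 1e-10)
  # nonnegative weights: raising one channel's mean never lowers its gate
  g0 <- gates_of(x)
  x2 <- x; x2[2, , , ] <- x2[2, , , ] + 1
  g1 <- gates_of(x2)
  expect_gte(g1[2], g0[2])
})

test_that("CAT blocks preserve spatial extent and follow the width ladder", {
  m <- tiny_model()
  ch <- m$config$channels
  for (lv in c(0L, 2L, 5L)) {
    sp <- c(6L, 5L, 4L)
    x <- random_fm(ch[lv + 1L], sp, seed = 10 + lv)
    y <- cat_block(m, x, lv)
    expect_equal(dim(y), c(ch[lv + 1L], sp))
    expect_true(all(is.finite(y)))
  }
  expect_error(cat_block(m, random_fm(3, c(4, 4, 4)), 0L), "expects")
})

test_that("a degenerate CAT block (no attention, unit norm) is LeakyReLU(conv(x))", {
  cfg <- catseg_tiny_config(attention_enabled = FALSE)
  m <- catseg_model(cfg, seed = 2)
  # force inference batch-norm to the identity: running mean 0, var 1 - eps
  st <- m$buffers[["cat1.bn."]]
  st$mean <- rep(0, cfg$channels[2])
  st$var <- rep(1 - cfg$bn_eps, cfg$channels[2])
  sp <- c(5L, 4L, 3L)
  x <- random_fm(cfg$channels[2], sp, seed = 20)
  got <- cat_block(m, x, 1L)
  conv <- catseg:::vof(catseg:::nn_conv3d(catseg:::fm_to_mat(x),
                                          m$params[["cat1.conv.W"]],
                                          m$params[["cat1.conv.b"]], sp))
  want <- ifelse(conv >= 0, conv, cfg$leaky_slope * conv)
  expect_equal(catseg:::fm_to_mat(got), want, tolerance = 1e-10)
})

test_that("the four ablation variants are constructible from single config switches", {
  variants <- list(
    full = catseg_tiny_config(),
    no_attention = catseg_tiny_config(attention_enabled = FALSE),
    no_shuffle = catseg_tiny_config(shuffle_enabled = FALSE),
    neither = catseg_tiny_config(shuffle_enabled = FALSE,
                                 attention_enabled = FALSE)
  )
  expect_true(variants$full$shuffle_enabled && variants$full$attention_enabled)
  expect_false(variants$no_attention$attention_enabled)
  expect_false(variants$no_shuffle$shuffle_enabled)
  expect_false(variants$neither$shuffle_enabled ||
                 variants$neither$attention_enabled)
  # each builds a working model
  for (v in variants) {
    mod <- catseg_model(v, seed = 3)
    p <- suppressWarnings(predict(mod, random_fm(4, c(8, 8, 8), seed = 1)))
    expect_equal(dim(p), c(3L, 8L, 8L, 8L))
  }
})
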