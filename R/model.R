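# Model assembly: parameter initialisation and the full forward pass.
#
# Parameters live in one flat named list of numeric arrays; the same forward
# code runs on plain arrays (inference) or on tape-wrapped leaves (training).

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

tnorm <- function(n, sd = 0.02) pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)

fm_to_mat <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(2L, 3L, 4L, 1L)), prod(d[2:4]), d[1])
}

mat_to_fm <- function(m, sp) {
  aperm(array(m, c(sp, ncol(m))), c(4L, 1L, 2L, 3L))
}

#' Build a channel-attention shifted-window segmentation model
#'
#' Instantiates all network parameters for a given [catseg_config()]:
#' the patch-embedding and four-stage shifted-window transformer encoder, a
#' full-resolution linear projection of the raw modalities (level 0), six CAT
#' encoding blocks over the channel ladder, five channel-shuffle permutations
#' (parameter-free), five residual decoder blocks and the 1x1x1 sigmoid head.
#'
#' @param config A [catseg_config()].
#' @param seed Integer seed for weight initialisation (transformer linears:
#'   truncated normal sd 0.02; convolutions: He-scaled normal).
#' @return A `catseg_model`: list with `config`, flat `params` list, and
#'   `buffers` (batch-norm running statistics, updated in place while
#'   training).
#' @export
catseg_model <- function(config = catseg_config(), seed = 1L) {
  cfg <- config
  ch <- cfg$channels
  params <- list()
  buffers <- new.env(parent = emptyenv())
  lin <- function(i, o, bias = TRUE, sd = 0.02) {
    out <- list(W = matrix(tnorm(i * o, sd), i, o))
    if (bias) out$b <- rep(0, o)
    out
  }
  conv <- function(cin, cout, k = 27L) {
    sd <- sqrt(2 / (k * cin))
    list(W = array(stats::rnorm(k * cin * cout, 0, sd), c(k, cin, cout)),
         b = rep(0, cout))
  }
  add <- function(prefix, lst) {
    for (nm in names(lst)) params[[paste0(prefix, nm)]] <<- lst[[nm]]
  }
  bn_init <- function(prefix, c) {
    params[[paste0(prefix, "g")]] <<- rep(1, c)
    params[[paste0(prefix, "b")]] <<- rep(0, c)
    st <- new.env(parent = emptyenv())
    st$mean <- rep(0, c); st$var <- rep(1, c)
    buffers[[prefix]] <- st
  }
  with_local_seed(seed, {
    # level-0 projection of the raw modalities
    add("proj0.", lin(cfg$in_channels, ch[1]))
    # patch partition + linear embedding (+ LN, Swin convention)
    add("embed.", lin(8L * cfg$in_channels, ch[2]))
    params[["embed.ln.g"]] <- rep(1, ch[2]); params[["embed.ln.b"]] <- rep(0, ch[2])
    nrel <- n_relpos(cfg$window_size)
    for (s in 1:4) {
      cs <- ch[s + 1L]
      if (s > 1L) {
        cp <- ch[s]
        params[[sprintf("merge%d.ln.g", s)]] <- rep(1, 8L * cp)
        params[[sprintf("merge%d.ln.b", s)]] <- rep(0, 8L * cp)
        add(sprintf("merge%d.", s), lin(8L * cp, cs, bias = FALSE))
      }
      for (d in seq_len(cfg$depths[s])) {
        pre <- sprintf("s%d.b%d.", s, d)
        params[[paste0(pre, "ln1.g")]] <- rep(1, cs)
        params[[paste0(pre, "ln1.b")]] <- rep(0, cs)
        params[[paste0(pre, "qkv.W")]] <- matrix(tnorm(cs * 3L * cs), cs, 3L * cs)
        params[[paste0(pre, "qkv.bq")]] <- rep(0, cs)
        params[[paste0(pre, "qkv.bv")]] <- rep(0, cs)
        add(paste0(pre, "proj."), lin(cs, cs))
        params[[paste0(pre, "tab")]] <-
          matrix(tnorm(nrel * cfg$num_heads[s]), nrel, cfg$num_heads[s])
        params[[paste0(pre, "ln2.g")]] <- rep(1, cs)
        params[[paste0(pre, "ln2.b")]] <- rep(0, cs)
        hid <- as.integer(round(cfg$mlp_ratio * cs))
        add(paste0(pre, "mlp1."), lin(cs, hid))
        add(paste0(pre, "mlp2."), lin(hid, cs))
      }
    }
    # final patch merge to level 5
    params[["merge5.ln.g"]] <- rep(1, 8L * ch[5]); params[["merge5.ln.b"]] <- rep(0, 8L * ch[5])
    add("merge5.", lin(8L * ch[5], ch[6], bias = FALSE))
    # six CAT encoding blocks
    for (i in 0:5) {
      ci <- ch[i + 1L]
      pre <- sprintf("cat%d.", i)
      add(paste0(pre, "conv."), conv(ci, ci))
      bn_init(paste0(pre, "bn."), ci)
      if (cfg$attention_enabled) {
        cr <- ci %/% cfg$attention_reduction
        add(paste0(pre, "att1."), lin(ci, cr, sd = sqrt(2 / ci)))
        add(paste0(pre, "att2."), lin(cr, ci, sd = sqrt(2 / cr)))
      }
    }
    # five residual decoder blocks (level L -> L-1)
    for (L in 5:1) {
      cin <- ch[L + 1L]; cout <- ch[L]
      pre <- sprintf("dec%d.", L)
      if (cfg$upsample_mode == "transpose-conv") {
        sd <- sqrt(2 / (8 * cin))
        params[[paste0(pre, "up.W")]] <- array(stats::rnorm(8L * cin * cout, 0, sd),
                                               c(8L, cin, cout))
        params[[paste0(pre, "up.b")]] <- rep(0, cout)
      } else {
        add(paste0(pre, "up."), lin(cin, cout, sd = sqrt(2 / cin)))
      }
      add(paste0(pre, "sc."), lin(2L * cout, cout, sd = sqrt(2 / (2 * cout))))
      add(paste0(pre, "conv1."), conv(2L * cout, cout))
      bn_init(paste0(pre, "bn1."), cout)
      add(paste0(pre, "conv2."), conv(cout, cout))
      bn_init(paste0(pre, "bn2."), cout)
    }
    add("head.", lin(ch[1], cfg$out_channels))
  })
  structure(list(config = cfg, params = params, buffers = buffers),
            class = "catseg_model")
}

#' @export
print.catseg_model <- function(x, ...) {
  cat("catseg segmentation model\n")
  print(x$config)
  cat("  parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Total number of trainable parameters
#' @param model A `catseg_model`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Closed-form parameter count of the channel-attention modules
#'
#' Each CAT block with width C carries two fully connected layers
#' (C -> C/r -> C) with biases: 2*C^2/r + C/r + C parameters. Used to verify
#' ablation variants differ by exactly this count.
#'
#' @param config A [catseg_config()].
#' @return Total attention-module parameter count over the six CAT blocks.
#' @export
attention_parameter_count <- function(config) {
  C <- config$channels
  r <- config$attention_reduction
  sum(2 * C^2 / r + C / r + C)
}

## ---- forward pieces ---------------------------------------------------------

shuffle_permutation <- function(C, G) {
  if (C %% G != 0L) stop("groups (", G, ") must divide the channel count (", C, ")")
  as.vector(matrix(seq_len(C), nrow = G, byrow = TRUE))
}

swin_block_fwd <- function(x, sp, C, heads, P, pre, cfg, shifted) {
  ws <- pmin(cfg$window_size, sp)
  sh <- if (shifted) ifelse(ws < sp, ws %/% 2L, 0L) else c(0L, 0L, 0L)
  wi <- window_index(sp, ws, as.integer(sh))
  bidx <- relpos_index(ws, cfg$window_size)
  h <- nn_layernorm(x, P(paste0(pre, "ln1.g")), P(paste0(pre, "ln1.b")))
  qkv <- nn_qkv_bias(nn_linear(h, P(paste0(pre, "qkv.W"))),
                     P(paste0(pre, "qkv.bq")), P(paste0(pre, "qkv.bv")))
  qw <- nn_gather_rows(qkv, wi$idx)
  aw <- nn_window_attention(qw, P(paste0(pre, "tab")), heads, wi$T, wi$nW,
                            bidx, wi$maskadd)
  a <- nn_gather_rows(aw, wi$inv)
  a <- nn_linear(a, P(paste0(pre, "proj.W")), P(paste0(pre, "proj.b")))
  x <- ag_add(x, a)
  h2 <- nn_layernorm(x, P(paste0(pre, "ln2.g")), P(paste0(pre, "ln2.b")))
  m <- nn_linear(nn_gelu(nn_linear(h2, P(paste0(pre, "mlp1.W")),
                                   P(paste0(pre, "mlp1.b")))),
                 P(paste0(pre, "mlp2.W")), P(paste0(pre, "mlp2.b")))
  ag_add(x, m)
}

merge_fwd <- function(x, sp, P, pre) {
  bi <- block2_index(sp)
  m <- nn_gather_cbind(x, bi$idx)
  m <- nn_layernorm(m, P(paste0(pre, "ln.g")), P(paste0(pre, "ln.b")))
  list(x = nn_linear(m, P(paste0(pre, "W"))), sp = bi$out_spatial)
}

stage_fwd <- function(x, sp, stage, P, cfg) {
  if (stage > 1L) {
    mg <- merge_fwd(x, sp, P, sprintf("merge%d.", stage))
    x <- mg$x; sp <- mg$sp
  }
  C <- cfg$channels[stage + 1L]
  for (d in seq_len(cfg$depths[stage])) {
    x <- swin_block_fwd(x, sp, C, cfg$num_heads[stage], P,
                        sprintf("s%d.b%d.", stage, d), cfg,
                        shifted = (d %% 2L == 0L))
  }
  list(x = x, sp = sp)
}

encode_fwd <- function(P, cfg, xmat, sp) {
  levels <- vector("list", 6L)
  levels[[1]] <- list(x = nn_linear(xmat, P("proj0.W"), P("proj0.b")), sp = sp)
  bi <- block2_index(sp)
  t <- nn_gather_cbind(xmat, bi$idx)
  t <- nn_linear(t, P("embed.W"), P("embed.b"))
  t <- nn_layernorm(t, P("embed.ln.g"), P("embed.ln.b"))
  cur <- list(x = t, sp = bi$out_spatial)
  for (s in 1:4) {
    cur <- stage_fwd(cur$x, cur$sp, s, P, cfg)
    levels[[s + 1L]] <- cur
  }
  levels[[6]] <- merge_fwd(cur$x, cur$sp, P, "merge5.")
  levels
}

channel_attention_fwd <- function(x, W1, b1, W2, b2, slope = 0.01) {
  m <- nn_col_mean(x)
  h <- nn_leaky_relu(nn_linear(m, W1, b1), slope)
  g <- nn_sigmoid(nn_linear(h, W2, b2))
  nn_col_scale(x, g)
}

cat_block_fwd <- function(x, sp, i, P, buffers, cfg, training) {
  pre <- sprintf("cat%d.", i)
  x <- nn_conv3d(x, P(paste0(pre, "conv.W")), P(paste0(pre, "conv.b")), sp)
  x <- nn_batchnorm(x, P(paste0(pre, "bn.g")), P(paste0(pre, "bn.b")),
                    buffers[[paste0(pre, "bn.")]], training,
                    cfg$bn_momentum, cfg$bn_eps)
  if (cfg$attention_enabled) {
    x <- channel_attention_fwd(x, P(paste0(pre, "att1.W")), P(paste0(pre, "att1.b")),
                               P(paste0(pre, "att2.W")), P(paste0(pre, "att2.b")),
                               cfg$leaky_slope)
  }
  nn_leaky_relu(x, cfg$leaky_slope)
}

decoder_block_fwd <- function(deep, sp_deep, skip, sp_skip, L, P, buffers, cfg,
                              training) {
  pre <- sprintf("dec%d.", L)
  if (cfg$upsample_mode == "transpose-conv") {
    u <- nn_tconv2(deep, P(paste0(pre, "up.W")), P(paste0(pre, "up.b")), sp_deep)
  } else {
    u <- nn_upsample2_trilinear(deep, sp_deep)
    u <- nn_linear(u, P(paste0(pre, "up.W")), P(paste0(pre, "up.b")))
  }
  sp_u <- 2L * sp_deep
  if (any(sp_u != sp_skip)) {
    u <- nn_gather_rows(u, croppad_index(sp_u, sp_skip))
  }
  m <- nn_cbind(u, skip)
  r <- nn_conv3d(m, P(paste0(pre, "conv1.W")), P(paste0(pre, "conv1.b")), sp_skip)
  r <- nn_batchnorm(r, P(paste0(pre, "bn1.g")), P(paste0(pre, "bn1.b")),
                    buffers[[paste0(pre, "bn1.")]], training,
                    cfg$bn_momentum, cfg$bn_eps)
  r <- nn_leaky_relu(r, cfg$leaky_slope)
  r <- nn_conv3d(r, P(paste0(pre, "conv2.W")), P(paste0(pre, "conv2.b")), sp_skip)
  r <- nn_batchnorm(r, P(paste0(pre, "bn2.g")), P(paste0(pre, "bn2.b")),
                    buffers[[paste0(pre, "bn2.")]], training,
                    cfg$bn_momentum, cfg$bn_eps)
  sc <- nn_linear(m, P(paste0(pre, "sc.W")), P(paste0(pre, "sc.b")))
  nn_leaky_relu(ag_add(r, sc), cfg$leaky_slope)
}

# Full forward pass on an (N x in_channels) voxel matrix.
# Returns list(prob = N x out_channels, spatial).
model_fwd <- function(params, buffers, cfg, xmat, sp, training = FALSE) {
  P <- function(nm) {
    v <- params[[nm]]
    if (is.null(v)) stop("missing parameter: ", nm)
    v
  }
  enc <- encode_fwd(P, cfg, xmat, sp)
  z <- vector("list", 6L)
  for (i in 0:5) {
    x <- enc[[i + 1L]]$x
    if (i >= 1L && cfg$shuffle_enabled && cfg$shuffle_groups > 1L) {
      x <- nn_col_permute(x, shuffle_permutation(cfg$channels[i + 1L],
                                                 cfg$shuffle_groups))
    }
    z[[i + 1L]] <- list(x = cat_block_fwd(x, enc[[i + 1L]]$sp, i, P, buffers,
                                          cfg, training),
                        sp = enc[[i + 1L]]$sp)
  }
  d <- z[[6]]
  for (L in 5:1) {
    skip <- z[[L]]
    d <- list(x = decoder_block_fwd(d$x, d$sp, skip$x, skip$sp, L, P, buffers,
                                    cfg, training),
              sp = skip$sp)
  }
  logits <- nn_linear(d$x, P("head.W"), P("head.b"))
  list(prob = nn_sigmoid(logits), sp = d$sp)
}

check_input_extent <- function(cfg, sp) {
  if (any(sp %% 32L != 0L)) {
    warning("input extent ", paste(sp, collapse = "x"),
            " is not divisible by 32; feature grids are padded internally ",
            "and the output is cropped back", call. = FALSE)
  }
}

as_volume_array <- function(volume) {
  if (inherits(volume, "case_record")) volume <- volume$volume
  if (inherits(volume, "multimodal_volume")) volume <- volume$intensities
  stopifnot(is.array(volume), length(dim(volume)) == 4L)
  volume
}

#' Segment a multi-modal volume
#'
#' Runs the full network in inference mode on a 4-channel volume and returns
#' per-voxel probabilities for the three nested subregions (WT, TC, ET), or a
#' thresholded [subregion_mask()].
#'
#' @param object A `catseg_model`.
#' @param volume 4D array `(modality, z, y, x)`, a `multimodal_volume`, or a
#'   `case_record`.
#' @param type `"prob"` for the probability array `(3, z, y, x)`, `"mask"`
#'   for a binarised `subregion_mask`.
#' @param threshold Binarisation threshold when `type = "mask"`.
#' @param ... Unused.
#' @export
predict.catseg_model <- function(object, volume, type = c("prob", "mask"),
                                 threshold = 0.5, ...) {
  type <- match.arg(type)
  a <- as_volume_array(volume)
  cfg <- object$config
  stopifnot(dim(a)[1] == cfg$in_channels)
  sp <- dim(a)[2:4]
  check_input_extent(cfg, sp)
  out <- model_fwd(object$params, object$buffers, cfg, fm_to_mat(a), sp,
                   training = FALSE)
  prob <- mat_to_fm(out$prob, out$sp)
  if (type == "prob") prob else predict_mask(prob, threshold)
}

#' Encoder feature ladder
#'
#' Returns the six encoder feature maps: level 0 is the raw input projected
#' to the embedding width at full resolution; levels 1-5 come from the
#' shifted-window transformer (patch embedding, four stages, final patch
#' merge), halving each spatial extent per level with channel widths
#' `embed_dim * c(1, 1, 2, 4, 8, 16)`.
#'
#' @param model A `catseg_model`.
#' @param volume 4D array `(modality, z, y, x)` (or case/volume object).
#' @return List of six 4D arrays `(C, z, y, x)`, names `level0`..`level5`.
#' @export
encode_volume <- function(model, volume) {
  a <- as_volume_array(volume)
  cfg <- model$config
  sp <- dim(a)[2:4]
  check_input_extent(cfg, sp)
  P <- function(nm) model$params[[nm]]
  enc <- encode_fwd(P, cfg, fm_to_mat(a), sp)
  out <- lapply(enc, function(e) mat_to_fm(e$x, e$sp))
  names(out) <- paste0("level", 0:5)
  out
}

#' Patch partition and linear embedding
#'
#' Splits the volume into non-overlapping 2x2x2 patches and linearly embeds
#' them, producing the level-1 token grid at half resolution per axis with
#' `embed_dim` channels (a linear map of the input, up to layer
#' normalisation which is applied afterwards inside [encode_volume()]).
#'
#' @param model A `catseg_model`.
#' @param volume 4D input array `(modality, z, y, x)`.
#' @param normalise Apply the embedding layer normalisation (default `TRUE`;
#'   set `FALSE` to expose the purely linear map).
#' @return 4D array `(embed_dim, z/2, y/2, x/2)`.
#' @export
patch_partition_embed <- function(model, volume, normalise = TRUE) {
  a <- as_volume_array(volume)
  sp <- dim(a)[2:4]
  P <- function(nm) model$params[[nm]]
  bi <- block2_index(sp)
  t <- nn_gather_cbind(fm_to_mat(a), bi$idx)
  t <- nn_linear(t, P("embed.W"), P("embed.b"))
  if (normalise) t <- nn_layernorm(t, P("embed.ln.g"), P("embed.ln.b"))
  mat_to_fm(t, bi$out_spatial)
}

#' Apply one transformer stage
#'
#' Stage 1 applies the stage's shifted-window transformer blocks only; stages
#' 2-4 first merge 2x2x2 patch neighbourhoods (halving each extent, doubling
#' channels) and then apply the blocks.
#'
#' @param model A `catseg_model`.
#' @param tokens 4D token array `(C, z, y, x)` at the stage's input level.
#' @param stage Stage number in 1..4.
#' @return 4D token array at the stage's output level.
#' @export
swin_stage <- function(model, tokens, stage) {
  stopifnot(is.array(tokens), length(dim(tokens)) == 4L,
            stage %in% 1:4)
  cfg <- model$config
  expected_in <- cfg$channels[stage + if (stage == 1L) 1L else 0L]
  if (dim(tokens)[1] != expected_in) {
    stop("stage ", stage, " expects ", expected_in, " input channels, got ",
         dim(tokens)[1])
  }
  P <- function(nm) model$params[[nm]]
  out <- stage_fwd(fm_to_mat(tokens), dim(tokens)[2:4], stage, P, cfg)
  mat_to_fm(out$x, out$sp)
}

#' Apply one CAT encoding block
#'
#' 3x3x3 convolution (stride 1, padding 1), 3D batch normalisation, channel
#' attention, LeakyReLU. Spatial extent is preserved exactly; the channel
#' count equals the block's ladder width.
#'
#' @param model A `catseg_model`.
#' @param x 4D feature array `(C, z, y, x)` at the block's level.
#' @param level Block level 0..5.
#' @param training Use batch statistics (and update running statistics)
#'   instead of running statistics.
#' @return 4D feature array, same spatial extent.
#' @export
cat_block <- function(model, x, level, training = FALSE) {
  stopifnot(is.array(x), length(dim(x)) == 4L, level %in% 0:5)
  cfg <- model$config
  if (dim(x)[1] != cfg$channels[level + 1L]) {
    stop("CAT block ", level, " expects ", cfg$channels[level + 1L],
         " channels, got ", dim(x)[1])
  }
  P <- function(nm) model$params[[nm]]
  out <- cat_block_fwd(fm_to_mat(x), dim(x)[2:4], level, P, model$buffers,
                       cfg, training)
  mat_to_fm(vof(out), dim(x)[2:4])
}

#' Apply one residual decoder block
#'
#' Upsamples the deeper map by 2 per axis (transposed convolution by
#' default), concatenates the skip feature map, and applies a residual
#' convolutional unit (two 3x3x3 conv + batch-norm layers with a projected
#' shortcut), returning a map at the skip's resolution and width.
#'
#' @param model A `catseg_model`.
#' @param deep 4D array at level `level` (the deeper map).
#' @param skip 4D array at level `level - 1` (the CAT-block output).
#' @param level Decoder level 1..5.
#' @param training Batch-norm mode as in [cat_block()].
#' @export
residual_decoder_block <- function(model, deep, skip, level, training = FALSE) {
  stopifnot(level %in% 1:5)
  cfg <- model$config
  P <- function(nm) model$params[[nm]]
  out <- decoder_block_fwd(fm_to_mat(deep), dim(deep)[2:4],
                           fm_to_mat(skip), dim(skip)[2:4],
                           level, P, model$buffers, cfg, training)
  mat_to_fm(vof(out), dim(skip)[2:4])
}

#' Segmentation head
#'
#' 1x1x1 convolution from the level-0 feature width to the three subregion
#' channels followed by a sigmoid, yielding independent per-voxel
#' probabilities (the subregions are nested and overlap, so a softmax would
#' be wrong here).
#'
#' @param model A `catseg_model`.
#' @param features 4D array `(embed_dim, z, y, x)` at input resolution.
#' @return 4D probability array `(3, z, y, x)` with values in (0, 1).
#' @export
segmentation_head <- function(model, features) {
  P <- function(nm) model$params[[nm]]
  out <- nn_sigmoid(nn_linear(fm_to_mat(features), P("head.W"), P("head.b")))
  mat_to_fm(out, dim(features)[2:4])
}
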