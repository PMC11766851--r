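#' Model configuration
#'
#' Hyperparameters of the channel-attention shifted-window segmentation
#' network. The defaults reproduce the published architecture: a four-stage
#' shifted-window transformer encoder (patch size 2, embedding width 48, two
#' blocks per stage) whose feature ladder runs 48, 48, 96, 192, 384, 768
#' channels from full resolution down to 1/32; parameter-free channel
#' shuffling with 4 groups on the five transformer-derived maps; six CAT
#' encoding blocks (3x3x3 convolution, batch normalisation, channel
#' attention, LeakyReLU); five residual decoder blocks; and a 1x1x1 sigmoid
#' head over the three nested tumour subregions (WT, TC, ET).
#'
#' @param embed_dim Transformer embedding width at the first stage. The
#'   channel ladder over levels 0..5 is `embed_dim * c(1, 1, 2, 4, 8, 16)`.
#' @param depths Transformer blocks per stage (4 stages).
#' @param num_heads Attention heads per stage; must divide the stage widths.
#' @param window_size 3D attention window (z, y, x tokens); clipped per level
#'   to the token grid, with cyclic shift + masking in alternate blocks.
#' @param patch_size Patch partition factor (2 halves each axis).
#' @param input_shape Expected volume extent `c(z, y, x)` after
#'   preprocessing.
#' @param in_channels Number of input modalities (T1, T1c, T2, FLAIR).
#' @param out_channels Output subregion channels (WT, TC, ET).
#' @param shuffle_groups Channel-shuffle group count G (4 by default; 2
#'   supported). Must divide every shuffled feature width.
#' @param shuffle_enabled Ablation switch for channel shuffling.
#' @param attention_reduction Bottleneck ratio r of the channel-attention
#'   module (C -> C/r -> C).
#' @param attention_enabled Ablation switch for channel attention.
#' @param upsample_mode `"transpose-conv"` (default) or `"trilinear+conv"`.
#' @param mlp_ratio Transformer MLP expansion factor.
#' @param leaky_slope Negative slope of every LeakyReLU.
#' @param bn_momentum,bn_eps Batch-normalisation running-stat momentum and
#'   variance floor.
#' @return A `catseg_config` list, validated.
#' @export
catseg_config <- function(embed_dim = 48L,
                          depths = c(2L, 2L, 2L, 2L),
                          num_heads = c(3L, 6L, 12L, 24L),
                          window_size = c(7L, 7L, 7L),
                          patch_size = 2L,
                          input_shape = c(96L, 128L, 128L),
                          in_channels = 4L,
                          out_channels = 3L,
                          shuffle_groups = 4L,
                          shuffle_enabled = TRUE,
                          attention_reduction = 4L,
                          attention_enabled = TRUE,
                          upsample_mode = c("transpose-conv", "trilinear+conv"),
                          mlp_ratio = 4,
                          leaky_slope = 0.01,
                          bn_momentum = 0.1,
                          bn_eps = 1e-5) {
  upsample_mode <- match.arg(upsample_mode)
  cfg <- list(
    embed_dim = as.integer(embed_dim), depths = as.integer(depths),
    num_heads = as.integer(num_heads), window_size = as.integer(window_size),
    patch_size = as.integer(patch_size), input_shape = as.integer(input_shape),
    in_channels = as.integer(in_channels), out_channels = as.integer(out_channels),
    shuffle_groups = as.integer(shuffle_groups),
    shuffle_enabled = isTRUE(shuffle_enabled),
    attention_reduction = as.integer(attention_reduction),
    attention_enabled = isTRUE(attention_enabled),
    upsample_mode = upsample_mode, mlp_ratio = as.numeric(mlp_ratio),
    leaky_slope = leaky_slope, bn_momentum = bn_momentum, bn_eps = bn_eps
  )
  cfg$channels <- cfg$embed_dim * c(1L, 1L, 2L, 4L, 8L, 16L)
  stopifnot(length(cfg$depths) == 4L, all(cfg$depths >= 1L),
            length(cfg$num_heads) == 4L, length(cfg$window_size) == 3L,
            cfg$patch_size == 2L, cfg$shuffle_groups >= 1L,
            cfg$attention_reduction >= 1L)
  stage_c <- cfg$channels[2:5]
  if (any(stage_c %% cfg$num_heads != 0L)) {
    stop("num_heads must divide the stage channel widths (",
         paste(stage_c, collapse = ", "), ")")
  }
  if (cfg$shuffle_enabled && any(cfg$channels[2:6] %% cfg$shuffle_groups != 0L)) {
    stop("shuffle_groups = ", cfg$shuffle_groups,
         " does not divide every shuffled channel width (",
         paste(cfg$channels[2:6], collapse = ", "), ")")
  }
  if (any(cfg$channels %% cfg$attention_reduction != 0L)) {
    stop("attention_reduction must divide every CAT block width")
  }
  class(cfg) <- "catseg_config"
  cfg
}

#' Desk-scale configuration for CPU experiments
#'
#' A reduced geometry (embedding width 8, 16^3 volumes, 4x4x4 windows, 2
#' heads per stage) that keeps the complete six-level architecture but trains
#' in minutes on one CPU. Used throughout the test-suite and examples.
#'
#' @param ... Overrides forwarded to [catseg_config()].
#' @export
catseg_tiny_config <- function(...) {
  catseg_config(embed_dim = 8L, num_heads = c(2L, 2L, 2L, 2L),
                window_size = c(4L, 4L, 4L), input_shape = c(16L, 16L, 16L),
                ...)
}

#' @export
print.catseg_config <- function(x, ...) {
  cat("catseg model configuration\n")
  cat("  input:", paste(x$input_shape, collapse = "x"), "voxels,",
      x$in_channels, "modalities ->", x$out_channels, "subregions\n")
  cat("  channel ladder (levels 0-5):", paste(x$channels, collapse = ", "), "\n")
  cat("  stages: depths", paste(x$depths, collapse = "/"),
      "heads", paste(x$num_heads, collapse = "/"),
      "window", paste(x$window_size, collapse = "x"), "\n")
  cat("  channel shuffle:", if (x$shuffle_enabled) paste0("G = ", x$shuffle_groups) else "disabled",
      "| channel attention:",
      if (x$attention_enabled) paste0("r = ", x$attention_reduction) else "disabled", "\n")
  invisible(x)
}

#' Read / write configurations as JSON
#'
#' @param path File path.
#' @param config A `catseg_config` (for writing).
#' @return `read_config()` returns a `catseg_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[setdiff(names(raw), "channels")]
  do.call(catseg_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
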