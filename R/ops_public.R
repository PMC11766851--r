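# Standalone, array-level forms of the novel block primitives.  These run
# the same internal code paths the model uses (on plain matrices, no tape).

#' Channel shuffle
#'
#' Parameter-free permutation of the channel axis: channels are reshaped
#' into `groups` groups, the group and within-group axes are transposed, and
#' the result is flattened back, so information can flow across channel
#' groups. Spatial content is untouched. Applying the shuffle with `groups`
#' and then with `C/groups` restores the original order.
#'
#' @param x 4D feature array `(C, z, y, x)` (or an `N x C` matrix).
#' @param groups Number of groups G; must divide C.
#' @return Shuffled array of identical shape.
#' @export
channel_shuffle <- function(x, groups) {
  if (is.matrix(x)) {
    return(vof(nn_col_permute(x, shuffle_permutation(ncol(x), groups))))
  }
  stopifnot(is.array(x), length(dim(x)) == 4L)
  perm <- shuffle_permutation(dim(x)[1], groups)
  x[perm, , , , drop = FALSE]
}

#' Global average pooling
#'
#' Per-channel arithmetic mean over all spatial positions:
#' `m_k = mean of channel k over the z*y*x grid` (the 2D textbook form
#' extended to volumes).
#'
#' @param x 4D feature array `(C, z, y, x)`.
#' @return Numeric vector of length C.
#' @export
global_avg_pool <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 4L)
  as.vector(vof(nn_col_mean(fm_to_mat(x))))
}

#' Channel attention (squeeze-and-excitation style)
#'
#' Gates each channel by `g = sigmoid(FC2(LeakyReLU(FC1(m))))` where `m` is
#' the global average pool of the input, FC1 maps C to C/r and FC2 back to
#' C. Output channel k is `g_k * x_k`; gates lie strictly inside (0, 1).
#' With `enabled = FALSE` the input is returned unchanged (ablation).
#'
#' @param x 4D feature array `(C, z, y, x)`.
#' @param W1,b1 First fully connected layer (C x C/r, length C/r).
#' @param W2,b2 Second fully connected layer (C/r x C, length C).
#' @param slope LeakyReLU negative slope between the two layers.
#' @param enabled Ablation switch.
#' @return Gated array of identical shape.
#' @export
channel_attention <- function(x, W1, b1, W2, b2, slope = 0.01, enabled = TRUE) {
  stopifnot(is.array(x), length(dim(x)) == 4L)
  if (!enabled) return(x)
  m <- fm_to_mat(x)
  out <- channel_attention_fwd(m, W1, b1, W2, b2, slope)
  mat_to_fm(vof(out), dim(x)[2:4])
}
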