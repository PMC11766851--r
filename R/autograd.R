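# Reverse-mode automatic differentiation on plain R matrices/arrays.
#
# Design: operations accept either plain numeric arrays or `ag` nodes
# (environments carrying a value).  When no input is a node, or no tape is
# active, every op degrades to a plain numeric computation -- inference and
# the public functional API share the exact code path used in training.
# During training a tape records each op together with a vector-Jacobian
# closure; ag_backward() replays the tape in reverse creation order.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- NULL
.ag$n <- 0L

is_ag <- function(x) inherits(x, "ag")

#' @keywords internal
vof <- function(x) if (is_ag(x)) x$v else x

ag_leaf <- function(value) {
  node <- new.env(parent = emptyenv())
  node$v <- value
  node$g <- NULL
  node$leaf <- TRUE
  class(node) <- "ag"
  node
}

# Record one op on the active tape. `inputs` is the full argument list (mixed
# plain/node); `vjp` maps the upstream gradient to a list of gradients aligned
# with `inputs` (entries for plain inputs are ignored and may be NULL).
ag_record <- function(value, inputs, vjp) {
  if (!.ag$recording) return(value)
  if (!any(vapply(inputs, is_ag, logical(1)))) return(value)
  node <- new.env(parent = emptyenv())
  node$v <- value
  node$g <- NULL
  node$leaf <- FALSE
  node$inputs <- inputs
  node$vjp <- vjp
  class(node) <- "ag"
  .ag$n <- .ag$n + 1L
  if (.ag$n > length(.ag$tape)) {
    .ag$tape <- c(.ag$tape, vector("list", max(1024L, length(.ag$tape))))
  }
  .ag$tape[[.ag$n]] <- node
  node
}

ag_tape_start <- function() {
  .ag$recording <- TRUE
  .ag$tape <- vector("list", 2048L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$recording <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

# Accumulate gradients into every node reachable from `loss` (a scalar node).
# Leaf nodes keep their gradient in $g; intermediate gradients are freed as
# soon as they have been propagated.
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$v) == 1L)
  loss$g <- 1
  if (.ag$n == 0L) return(invisible(NULL))
  for (i in seq(.ag$n, 1L)) {
    node <- .ag$tape[[i]]
    if (is.null(node$g) || node$leaf) next
    grads <- node$vjp(node$g)
    ins <- node$inputs
    for (j in seq_along(ins)) {
      inj <- ins[[j]]
      if (!is_ag(inj)) next
      gj <- grads[[j]]
      if (is.null(gj)) next
      inj$g <- if (is.null(inj$g)) gj else inj$g + gj
    }
    node$g <- NULL
    node$inputs <- NULL
    node$vjp <- NULL
  }
  invisible(NULL)
}

# Wrap a flat named list of parameter arrays as tape leaves.
ag_wrap_params <- function(params) lapply(params, ag_leaf)

# Collect gradients (zero where a parameter was unused).
ag_collect_grads <- function(leaves) {
  lapply(leaves, function(p) {
    if (is.null(p$g)) array(0, dim = dim(p$v) %||% length(p$v)) else p$g
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- elementwise / structural primitives -----------------------------------

ag_add <- function(a, b) {
  out <- vof(a) + vof(b)
  ag_record(out, list(a, b), function(g) list(g, g))
}

ag_ewmul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ag_record(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, s) {
  # s: plain scalar
  ag_record(vof(a) * s, list(a), function(g) list(g * s))
}

ag_matmul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ag_record(av %*% bv, list(a, b),
            function(g) list(g %*% t(bv), crossprod(av, g)))
}

# x: (N x K), W: (K x M), b: length-M vector or NULL
nn_linear <- function(x, W, b = NULL) {
  xv <- vof(x); Wv <- vof(W)
  out <- xv %*% Wv
  if (!is.null(b)) out <- out + rep(vof(b), each = nrow(out))
  ag_record(out, list(x, W, b), function(g) {
    list(g %*% t(Wv), crossprod(xv, g), if (is.null(b)) NULL else colSums(g))
  })
}

nn_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-vof(x)))
  ag_record(s, list(x), function(g) list(g * s * (1 - s)))
}

nn_leaky_relu <- function(x, slope = 0.01) {
  xv <- vof(x)
  out <- ifelse(xv >= 0, xv, slope * xv)
  ag_record(out, list(x), function(g) list(g * ifelse(xv >= 0, 1, slope)))
}

nn_gelu <- function(x) {
  xv <- vof(x)
  ph <- stats::pnorm(xv)
  ag_record(xv * ph, list(x),
            function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

# row-wise softmax of a matrix
nn_softmax_rows <- function(x) {
  xv <- vof(x)
  m <- xv - apply(xv, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ag_record(s, list(x), function(g) list(s * (g - rowSums(g * s))))
}

# concatenate along columns (channels)
nn_cbind <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ca <- ncol(av)
  ag_record(cbind(av, bv), list(a, b), function(g) {
    list(g[, seq_len(ca), drop = FALSE], g[, -seq_len(ca), drop = FALSE])
  })
}

# permute columns: out[, j] = x[, perm[j]]
nn_col_permute <- function(x, perm) {
  xv <- vof(x)
  inv <- order(perm)
  ag_record(xv[, perm, drop = FALSE], list(x),
            function(g) list(g[, inv, drop = FALSE]))
}

# scale column k of x by s[k]; s is a length-C vector (or 1 x C matrix)
nn_col_scale <- function(x, s) {
  xv <- vof(x); sv <- as.vector(vof(s))
  smat <- rep(sv, each = nrow(xv))
  ag_record(xv * smat, list(x, s), function(g) {
    gs <- colSums(g * xv)
    if (is.matrix(vof(s))) gs <- matrix(gs, 1L)
    list(g * smat, gs)
  })
}

# column means (global average pooling over voxels); returns 1 x C matrix
nn_col_mean <- function(x) {
  xv <- vof(x)
  n <- nrow(xv)
  ag_record(matrix(colMeans(xv), 1L), list(x),
            function(g) list(matrix(rep(as.vector(g) / n, each = n), n)))
}

## ---- gather / scatter -------------------------------------------------------

# rows of x by idx; idx == 0 yields a zero row
gather0 <- function(x, idx) {
  z <- idx == 0L
  if (!any(z)) return(x[idx, , drop = FALSE])
  i2 <- idx
  i2[z] <- 1L
  out <- x[i2, , drop = FALSE]
  out[z, ] <- 0
  out
}

# transpose of gather0: accumulate rows of g into an (n x C) matrix at idx
scatter_add <- function(g, idx, n) {
  keep <- idx > 0L
  out <- matrix(0, n, ncol(g))
  if (!any(keep)) return(out)
  tgt <- idx[keep]
  if (anyDuplicated(tgt) == 0L) {
    out[tgt, ] <- g[keep, , drop = FALSE]
    return(out)
  }
  rs <- rowsum(g[keep, , drop = FALSE], group = tgt, reorder = FALSE)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

nn_gather_rows <- function(x, idx) {
  xv <- vof(x)
  n <- nrow(xv)
  ag_record(gather0(xv, idx), list(x),
            function(g) list(scatter_add(g, idx, n)))
}

# out = cbind(x[idx[,1],], x[idx[,2],], ...): used by patch partition/merging
nn_gather_cbind <- function(x, idxmat) {
  xv <- vof(x)
  n <- nrow(xv); c0 <- ncol(xv); k <- ncol(idxmat)
  out <- matrix(0, nrow(idxmat), c0 * k)
  for (o in seq_len(k)) {
    out[, ((o - 1L) * c0 + 1L):(o * c0)] <- gather0(xv, idxmat[, o])
  }
  ag_record(out, list(x), function(g) {
    gx <- matrix(0, n, c0)
    for (o in seq_len(k)) {
      gx <- gx + scatter_add(g[, ((o - 1L) * c0 + 1L):(o * c0), drop = FALSE],
                             idxmat[, o], n)
    }
    list(gx)
  })
}
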