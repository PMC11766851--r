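# Volumetric network layers on the autodiff core.
#
# Feature maps travel internally as (N x C) matrices where N = prod(spatial)
# voxels in column-major (z fastest) order and spatial = c(d_z, d_y, d_x).
# All spatial bookkeeping (convolution neighbourhoods, patch partitions,
# window partitions, up/down-sampling) reduces to precomputed integer index
# tables, cached per geometry.

.idxcache <- new.env(parent = emptyenv())
.diag <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.idxcache[[key]])) .idxcache[[key]] <- build()
  .idxcache[[key]]
}

# 1-based voxel coordinates for a column-major (z fastest) spatial grid
spatial_coords <- function(sp) {
  key <- paste0("coords:", paste(sp, collapse = "x"))
  cache_get(key, function() {
    v <- 0:(prod(sp) - 1L)
    list(i = v %% sp[1] + 1L,
         j = (v %/% sp[1]) %% sp[2] + 1L,
         k = v %/% (sp[1] * sp[2]) + 1L)
  })
}

coord_to_row <- function(i, j, k, sp) i + (j - 1L) * sp[1] + (k - 1L) * sp[1] * sp[2]

# Index vectors (one per kernel offset) mapping output voxel -> input voxel,
# 0 where the offset leaves the grid (zero padding).
conv_index <- function(sp, kernel) {
  key <- paste0("conv", kernel, ":", paste(sp, collapse = "x"))
  cache_get(key, function() {
    r <- (kernel - 1L) %/% 2L
    co <- spatial_coords(sp)
    offs <- expand.grid(a = -r:r, b = -r:r, c = -r:r)
    lapply(seq_len(nrow(offs)), function(o) {
      si <- co$i + offs$a[o]; sj <- co$j + offs$b[o]; sk <- co$k + offs$c[o]
      ok <- si >= 1L & si <= sp[1] & sj >= 1L & sj <= sp[2] & sk >= 1L & sk <= sp[3]
      idx <- integer(length(si))
      idx[ok] <- coord_to_row(si[ok], sj[ok], sk[ok], sp)
      idx
    })
  })
}

# 2x2x2 block gather: output grid ceil(sp/2); column o of the index matrix
# holds, for each output voxel, the input voxel at block offset o (0 if the
# right-padded position falls outside the input).
block2_index <- function(sp) {
  key <- paste0("block2:", paste(sp, collapse = "x"))
  cache_get(key, function() {
    spo <- (sp + 1L) %/% 2L
    co <- spatial_coords(spo)
    offs <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
    idx <- matrix(0L, prod(spo), 8L)
    for (o in 1:8) {
      si <- 2L * co$i - 1L + offs$a[o]
      sj <- 2L * co$j - 1L + offs$b[o]
      sk <- 2L * co$k - 1L + offs$c[o]
      ok <- si <= sp[1] & sj <= sp[2] & sk <= sp[3]
      idx[ok, o] <- coord_to_row(si[ok], sj[ok], sk[ok], sp)
    }
    list(idx = idx, out_spatial = spo)
  })
}

# Transposed-conv (kernel 2, stride 2) scatter: for block offset o, input
# voxel n writes to output row up_index[[o]][n] on the doubled grid.
up2_index <- function(sp) {
  key <- paste0("up2:", paste(sp, collapse = "x"))
  cache_get(key, function() {
    spo <- 2L * sp
    co <- spatial_coords(sp)
    offs <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
    lapply(1:8, function(o) {
      coord_to_row(2L * co$i - 1L + offs$a[o],
                   2L * co$j - 1L + offs$b[o],
                   2L * co$k - 1L + offs$c[o], spo)
    })
  })
}

# Centre crop or zero-pad (both right/left balanced) to a target grid.
# Returns idx of length prod(target): source row in sp, or 0 for padding.
croppad_index <- function(sp, target) {
  key <- paste0("cp:", paste(sp, collapse = "x"), ">", paste(target, collapse = "x"))
  cache_get(key, function() {
    co <- spatial_coords(target)
    off <- (sp - target) %/% 2L  # may be negative (padding)
    si <- co$i + off[1]; sj <- co$j + off[2]; sk <- co$k + off[3]
    ok <- si >= 1L & si <= sp[1] & sj >= 1L & sj <= sp[2] & sk >= 1L & sk <= sp[3]
    idx <- integer(length(si))
    idx[ok] <- coord_to_row(si[ok], sj[ok], sk[ok], sp)
    idx
  })
}

## ---- convolutions -----------------------------------------------------------

# 3D convolution, stride 1, "same" zero padding. W: (K, Cin, Cout) with
# K = kernel^3 offsets in the conv_index order; b: length-Cout or NULL.
nn_conv3d <- function(x, W, b, spatial, kernel = 3L) {
  xv <- vof(x); Wv <- vof(W)
  tbl <- conv_index(spatial, kernel)
  K <- length(tbl)
  n <- nrow(xv); cin <- ncol(xv); cout <- dim(Wv)[3]
  out <- if (is.null(b)) matrix(0, n, cout) else matrix(rep(vof(b), each = n), n, cout)
  for (o in seq_len(K)) {
    out <- out + gather0(xv, tbl[[o]]) %*% matrix(Wv[o, , ], cin, cout)
  }
  ag_record(out, list(x, W, b), function(g) {
    gx <- matrix(0, n, cin)
    gW <- array(0, dim = dim(Wv))
    for (o in seq_len(K)) {
      xo <- gather0(xv, tbl[[o]])
      gW[o, , ] <- crossprod(xo, g)
      # scatter through offset o equals a gather through the opposite offset
      # (stride-1 same-padding shifts are inverse index maps)
      gx <- gx + gather0(g, tbl[[K + 1L - o]]) %*% t(matrix(Wv[o, , ], cin, cout))
    }
    list(gx, gW, if (is.null(b)) NULL else colSums(g))
  })
}

# Transposed 3D convolution, kernel 2, stride 2 (doubles each extent).
# W: (8, Cin, Cout); output blocks do not overlap.
nn_tconv2 <- function(x, W, b, spatial) {
  xv <- vof(x); Wv <- vof(W)
  tbl <- up2_index(spatial)
  n <- nrow(xv); cin <- ncol(xv); cout <- dim(Wv)[3]
  no <- 8L * n
  out <- if (is.null(b)) matrix(0, no, cout) else matrix(rep(vof(b), each = no), no, cout)
  for (o in 1:8) {
    out[tbl[[o]], ] <- out[tbl[[o]], ] + xv %*% matrix(Wv[o, , ], cin, cout)
  }
  ag_record(out, list(x, W, b), function(g) {
    gx <- matrix(0, n, cin)
    gW <- array(0, dim = dim(Wv))
    for (o in 1:8) {
      go <- g[tbl[[o]], , drop = FALSE]
      gW[o, , ] <- crossprod(xv, go)
      gx <- gx + go %*% t(matrix(Wv[o, , ], cin, cout))
    }
    list(gx, gW, if (is.null(b)) NULL else colSums(g))
  })
}

## ---- normalisation ----------------------------------------------------------

nn_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- vof(x)
  gm <- as.vector(vof(gamma)); bt <- as.vector(vof(beta))
  n <- nrow(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  out <- xhat * rep(gm, each = n) + rep(bt, each = n)
  ag_record(out, list(x, gamma, beta), function(g) {
    gg <- g * rep(gm, each = n)
    gx <- inv * (gg - rowMeans(gg) - xhat * rowMeans(gg * xhat))
    list(gx, colSums(g * xhat), colSums(g))
  })
}

# Batch normalisation over voxels (the "batch" of a 3D volume of batch size
# one is its voxel population).  `state` is an environment holding running
# mean/var, updated in place during training (unbiased running variance).
nn_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  xv <- vof(x)
  gm <- as.vector(vof(gamma)); bt <- as.vector(vof(beta))
  n <- nrow(xv)
  if (training) {
    mu <- colMeans(xv)
    xc <- xv - rep(mu, each = n)
    va <- colMeans(xc * xc)
    if (n > 1L) {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * va * n / (n - 1L)
    }
    inv <- 1 / sqrt(va + eps)
    xhat <- xc * rep(inv, each = n)
    out <- xhat * rep(gm, each = n) + rep(bt, each = n)
    ag_record(out, list(x, gamma, beta), function(g) {
      gg <- g * rep(gm, each = n)
      cm_gg <- colMeans(gg)
      cm_ggx <- colMeans(gg * xhat)
      gx <- rep(inv, each = n) *
        (gg - rep(cm_gg, each = n) - xhat * rep(cm_ggx, each = n))
      list(gx, colSums(g * xhat), colSums(g))
    })
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- (xv - rep(state$mean, each = n)) * rep(inv, each = n)
    out <- xhat * rep(gm, each = n) + rep(bt, each = n)
    ag_record(out, list(x, gamma, beta), function(g) {
      list(g * rep(gm * inv, each = n), colSums(g * xhat), colSums(g))
    })
  }
}

## ---- shifted-window attention ----------------------------------------------

# Relative-position index (T x T) for a window of dims ws = c(w1, w2, w3),
# indexing into the bias table of the (possibly larger) configured window
# `full`: table rows enumerate (2f1-1) x (2f2-1) x (2f3-1) relative offsets,
# so a window clipped to a small token grid addresses a subset of the table.
relpos_index <- function(ws, full = ws) {
  key <- paste0("relpos:", paste(ws, collapse = "x"), "|", paste(full, collapse = "x"))
  cache_get(key, function() {
    co <- spatial_coords(ws)
    d1 <- outer(co$i, co$i, "-") + full[1] - 1L
    d2 <- outer(co$j, co$j, "-") + full[2] - 1L
    d3 <- outer(co$k, co$k, "-") + full[3] - 1L
    matrix(as.integer(d1 * (2L * full[2] - 1L) * (2L * full[3] - 1L) +
                        d2 * (2L * full[3] - 1L) + d3 + 1L),
           prod(ws), prod(ws))
  })
}

n_relpos <- function(ws) prod(2L * ws - 1L)

# Window partition of a (d1,d2,d3) token grid with window ws and cyclic shift
# `sh` (vector, 0 = no shift).  Grid is right-padded to window multiples; pad
# slots map to source row 0 and are masked out of attention entirely.
# Returns: idx (length nW*T, source rows in window order), inv (length N,
# position of each original token in window order), maskadd (T x T x nW
# additive mask or NULL), nW, T.
window_index <- function(sp, ws, sh) {
  key <- paste0("win:", paste(sp, collapse = "x"), ":", paste(ws, collapse = "x"),
                ":", paste(sh, collapse = "x"))
  cache_get(key, function() {
    P <- ((sp + ws - 1L) %/% ws) * ws
    nWd <- P %/% ws
    nW <- prod(nWd)
    T <- prod(ws)
    wl <- spatial_coords(ws)      # slot-local coords, z fastest
    wo <- spatial_coords(nWd)     # window origins / ws
    idx <- integer(nW * T)
    rid <- integer(nW * T)        # region id of the source (unrolled) position
    axis_region <- function(p, P1, w1, s1) {
      if (s1 == 0L) return(rep.int(0L, length(p)))
      ifelse(p <= P1 - w1, 0L, ifelse(p <= P1 - s1, 1L, 2L))
    }
    for (w in seq_len(nW)) {
      qi <- (wo$i[w] - 1L) * ws[1] + wl$i
      qj <- (wo$j[w] - 1L) * ws[2] + wl$j
      qk <- (wo$k[w] - 1L) * ws[3] + wl$k
      # undo the cyclic shift: source position in the unrolled padded grid
      pi <- (qi - 1L + sh[1]) %% P[1] + 1L
      pj <- (qj - 1L + sh[2]) %% P[2] + 1L
      pk <- (qk - 1L + sh[3]) %% P[3] + 1L
      ok <- pi <= sp[1] & pj <= sp[2] & pk <= sp[3]
      rows <- ((w - 1L) * T + 1L):(w * T)
      idx[rows][ok] <- coord_to_row(pi[ok], pj[ok], pk[ok], sp)
      r <- axis_region(pi, P[1], ws[1], sh[1]) * 9L +
        axis_region(pj, P[2], ws[2], sh[2]) * 3L +
        axis_region(pk, P[3], ws[3], sh[3])
      r[!ok] <- -1L
      rid[rows] <- r
    }
    inv <- integer(prod(sp))
    inv[idx[idx > 0L]] <- which(idx > 0L)
    # additive attention mask per window
    need_mask <- any(sh > 0L) || any(idx == 0L)
    maskadd <- NULL
    if (need_mask) {
      maskadd <- array(0, dim = c(T, T, nW))
      for (w in seq_len(nW)) {
        rows <- ((w - 1L) * T + 1L):(w * T)
        r <- rid[rows]
        bad <- outer(r, r, "!=") | r < 0L | rep(r < 0L, each = T)
        if (any(bad)) maskadd[, , w][bad] <- -1e9
      }
      if (all(maskadd == 0)) maskadd <- NULL
    }
    list(idx = idx, inv = inv, maskadd = maskadd, nW = nW, T = T)
  })
}

# Multi-head self-attention within windows.  qkv: (nW*T x 3C) in window
# order; bias_table: (n_relpos x heads); returns (nW*T x C).
nn_window_attention <- function(qkv, bias_table, heads, T, nW, bias_idx, maskadd) {
  qv <- vof(qkv); tv <- vof(bias_table)
  C <- ncol(qv) %/% 3L
  dh <- C %/% heads
  scale <- 1 / sqrt(dh)
  out <- matrix(0, nrow(qv), C)
  keepS <- .ag$recording || isTRUE(.diag$capture)
  Ss <- if (keepS) vector("list", nW * heads) else NULL
  for (w in seq_len(nW)) {
    rows <- ((w - 1L) * T + 1L):(w * T)
    mk <- if (is.null(maskadd)) NULL else maskadd[, , w]
    for (h in seq_len(heads)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      q <- qv[rows, hc, drop = FALSE]
      k <- qv[rows, C + hc, drop = FALSE]
      v <- qv[rows, 2L * C + hc, drop = FALSE]
      A <- tcrossprod(q, k) * scale + matrix(tv[bias_idx, h], T, T)
      if (!is.null(mk)) A <- A + mk
      A <- A - apply(A, 1L, max)
      E <- exp(A)
      S <- E / rowSums(E)
      if (keepS) Ss[[(w - 1L) * heads + h]] <- S
      out[rows, hc] <- S %*% v
    }
  }
  if (isTRUE(.diag$capture)) .diag$attention <- c(.diag$attention, Ss)
  ag_record(out, list(qkv, bias_table), function(g) {
    gqkv <- matrix(0, nrow(qv), 3L * C)
    gtab <- matrix(0, nrow(tv), ncol(tv))
    for (h in seq_len(heads)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      dAacc <- matrix(0, T, T)
      for (w in seq_len(nW)) {
        rows <- ((w - 1L) * T + 1L):(w * T)
        q <- qv[rows, hc, drop = FALSE]
        k <- qv[rows, C + hc, drop = FALSE]
        v <- qv[rows, 2L * C + hc, drop = FALSE]
        S <- Ss[[(w - 1L) * heads + h]]
        go <- g[rows, hc, drop = FALSE]
        gS <- tcrossprod(go, v)
        dA <- S * (gS - rowSums(gS * S))
        gqkv[rows, hc] <- gqkv[rows, hc] + (dA %*% k) * scale
        gqkv[rows, C + hc] <- gqkv[rows, C + hc] + crossprod(dA, q) * scale
        gqkv[rows, 2L * C + hc] <- gqkv[rows, 2L * C + hc] + crossprod(S, go)
        dAacc <- dAacc + dA
      }
      rs <- rowsum(as.vector(dAacc), group = as.vector(bias_idx))
      gtab[as.integer(rownames(rs)), h] <- gtab[as.integer(rownames(rs)), h] + rs[, 1]
    }
    list(gqkv, gtab)
  })
}

# Add q and v biases to a packed qkv matrix (the key bias is omitted: a
# constant shift of every key cancels in the softmax, so its gradient is
# identically zero and it would be a dead parameter).
nn_qkv_bias <- function(qkv, bq, bv) {
  x <- vof(qkv)
  C <- ncol(x) %/% 3L
  n <- nrow(x)
  out <- x
  out[, 1:C] <- out[, 1:C] + rep(as.vector(vof(bq)), each = n)
  out[, (2L * C + 1L):(3L * C)] <- out[, (2L * C + 1L):(3L * C)] +
    rep(as.vector(vof(bv)), each = n)
  ag_record(out, list(qkv, bq, bv), function(g) {
    list(g, colSums(g[, 1:C, drop = FALSE]),
         colSums(g[, (2L * C + 1L):(3L * C), drop = FALSE]))
  })
}

## ---- interpolation ----------------------------------------------------------

# Factor-2 trilinear upsampling (half-pixel centres, borders clamped).
# Precomputes, for each output voxel, its 8 source rows and weights.
upsample2_index <- function(sp) {
  key <- paste0("up2lin:", paste(sp, collapse = "x"))
  cache_get(key, function() {
    spo <- 2L * sp
    co <- spatial_coords(spo)
    axis <- function(q, d) {
      src <- (q - 0.5) / 2 - 0.5 + 1  # 1-based source coordinate
      f <- floor(src)
      t <- src - f
      lo <- pmin(pmax(f, 1), d)
      hi <- pmin(pmax(f + 1, 1), d)
      list(lo = as.integer(lo), hi = as.integer(hi), t = t)
    }
    a1 <- axis(co$i, sp[1]); a2 <- axis(co$j, sp[2]); a3 <- axis(co$k, sp[3])
    m <- prod(spo)
    idx <- matrix(0L, m, 8L)
    wts <- matrix(0, m, 8L)
    o <- 0L
    for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
      o <- o + 1L
      i <- if (c1 == 0L) a1$lo else a1$hi
      j <- if (c2 == 0L) a2$lo else a2$hi
      k <- if (c3 == 0L) a3$lo else a3$hi
      w <- (if (c1 == 0L) 1 - a1$t else a1$t) *
        (if (c2 == 0L) 1 - a2$t else a2$t) *
        (if (c3 == 0L) 1 - a3$t else a3$t)
      idx[, o] <- coord_to_row(i, j, k, sp)
      wts[, o] <- w
    }
    list(idx = idx, w = wts, out_spatial = spo)
  })
}

nn_upsample2_trilinear <- function(x, spatial) {
  xv <- vof(x)
  tb <- upsample2_index(spatial)
  n <- nrow(xv)
  out <- matrix(0, nrow(tb$idx), ncol(xv))
  for (o in 1:8) out <- out + gather0(xv, tb$idx[, o]) * tb$w[, o]
  ag_record(out, list(x), function(g) {
    gx <- matrix(0, n, ncol(xv))
    for (o in 1:8) gx <- gx + scatter_add(g * tb$w[, o], tb$idx[, o], n)
    list(gx)
  })
}

## ---- loss -------------------------------------------------------------------

# Soft multi-label Dice loss: mean over channels of 1 - (2*sum(p*t)+eps) /
# (sum(p)+sum(t)+eps).  Differentiable in p.
nn_dice_loss <- function(p, t, eps = 1e-5) {
  pv <- vof(p); tv <- vof(t)
  num <- 2 * colSums(pv * tv) + eps
  den <- colSums(pv) + colSums(tv) + eps
  loss <- mean(1 - num / den)
  C <- ncol(pv)
  ag_record(loss, list(p, t), function(g) {
    gp <- matrix(0, nrow(pv), C)
    for (cc in seq_len(C)) {
      gp[, cc] <- -(2 * tv[, cc] * den[cc] - num[cc]) / (den[cc]^2) / C
    }
    list(as.numeric(g) * gp, NULL)
  })
}
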