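# ECoG decoders: three interchangeable backbones mapping an ECoG tensor
# (T x H x W z-scored high-gamma envelopes) to the 18 speech parameters per
# frame, each in a causal and a non-causal variant.
#
#   resnet3d: per-electrode temporal convolution stem, four residual blocks
#     of spatial 3x3 + strided temporal convolution (T -> T/16, grid -> 1x1),
#     then transposed temporal convolutions back to T.
#   swin3d: 2x2x2 patch tokens, shifted-window 3D multi-head attention in
#     three stages (2, 2, 6 layers) with patch merging, then temporal
#     upsampling.
#   lstm: three LSTM layers (bidirectional when non-causal) and a linear
#     projection; the temporal dimension is never resampled.
#
# All backbones share the prediction head, plus a full-resolution causal
# skip path so the strictly-causal variants retain current-frame
# information through their temporal bottlenecks: in causal mode every
# upsampling stage is delayed by one latent step, so outputs depend only on
# strictly-past latents, and the probe-verified causality contract is exact
# (bitwise) rather than approximate.

#' Decoder configuration
#' @param backbone `"resnet3d"`, `"swin3d"` or `"lstm"`.
#' @param causal Logical; causal variants use only past and present frames.
#' @param C Base channel/embedding width.
#' @param c0 Stem / skip-path channels.
#' @param Dh Prediction-head hidden width.
#' @param n_heads Attention heads (swin3d).
#' @param window Temporal x spatial attention window (swin3d), default
#'   `c(16, 2, 2)`.
#' @param stages Swin stage depths, default `c(2, 2, 6)`.
#' @param profile Voice profile for the head's frequency ranges.
#' @export
decoder_config <- function(backbone = c("resnet3d", "swin3d", "lstm"),
                           causal = TRUE, C = 32L, c0 = 32L, Dh = 32L,
                           n_heads = 4L, window = c(16L, 2L, 2L),
                           stages = c(2L, 2L, 6L), profile = "female") {
  backbone <- match.arg(backbone)
  list(backbone = backbone, causal = causal, C = as.integer(C),
       c0 = as.integer(c0), Dh = as.integer(Dh), n_heads = as.integer(n_heads),
       window = as.integer(window), stages = as.integer(stages),
       profile = profile)
}

# ---- shared helpers -----------------------------------------------------

# pad a T x E matrix to T_target frames; causal pads left (replicating the
# first frame: synthetic past only), non-causal pads both edges
pad_frames <- function(x, T_target, causal) {
  T <- nrow(x)
  pad <- T_target - T
  if (pad == 0L) return(list(x = x, left = 0L))
  if (causal) {
    list(x = rbind(x[rep(1L, pad), , drop = FALSE], x), left = pad)
  } else {
    pl <- pad %/% 2L
    pr <- pad - pl
    list(x = rbind(x[rep(1L, pl), , drop = FALSE], x,
                   x[rep(T, pr), , drop = FALSE]), left = pl)
  }
}

round_up <- function(n, m) as.integer(ceiling(n / m) * m)

# stack a list of T x E matrices into (B*Tp) x E with padding bookkeeping
stack_inputs <- function(xs, mult, causal) {
  T <- nrow(xs[[1L]])
  Tp <- round_up(T, mult)
  pads <- lapply(xs, pad_frames, T_target = Tp, causal = causal)
  list(x = do.call(rbind, lapply(pads, `[[`, "x")), T = T, Tp = Tp,
       left = pads[[1L]]$left)
}

# gather the unpadded output rows (b, left + 1 .. left + T)
crop_rows <- function(tape, node, B, Tp, T, left) {
  idx <- rep((seq_len(B) - 1L) * Tp, each = T) + rep(left + seq_len(T), B)
  tp_gather_rows(tape, node, idx)
}

# electrode-major reshape: (B*T) x E -> (B*T*E) x 1 with p inner
to_electrode_rows <- function(x) matrix(as.vector(t(x)), ncol = 1L)

# 2x2 spatial mean-pool on rows (bt, p), p column-major on H x W
spatial_pool <- function(tape, x, n_bt, H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  hh <- rep(seq_len(H2), times = W2)
  ww <- rep(seq_len(W2), each = H2)
  g <- NULL
  for (dw in 0:1) for (dh in 0:1) {
    p <- (2L * hh - 1L + dh) + (2L * ww - 1L + dw - 1L) * H
    idx <- rep((seq_len(n_bt) - 1L) * H * W, each = H2 * W2) + rep(p, n_bt)
    gi <- tp_gather_rows(tape, x, idx)
    g <- if (is.null(g)) gi else tp_add(tape, g, gi)
  }
  tp_scale(tape, g, 0.25)
}

# ---- 3D ResNet backbone -------------------------------------------------

resnet_init <- function(cfg, E) {
  c0 <- cfg$c0; C <- cfg$C
  p <- list(stem = he_init(5L * 2L, c0), stem_b = numeric(c0),
            skip_w = he_init(8L * E, c0), skip_b = numeric(c0))
  cin <- c0
  for (l in 1:4) {
    p[[paste0("sw", l)]] <- he_init(9L * cin, C)
    p[[paste0("sb", l)]] <- numeric(C)
    p[[paste0("tw", l)]] <- he_init(3L * C, C)
    p[[paste0("tb", l)]] <- numeric(C)
    p[[paste0("pr", l)]] <- he_init(1L * cin, C)
    cin <- C
  }
  for (l in 1:4) {
    p[[paste0("ut", l)]] <- he_init(2L * C, C)
    p[[paste0("ub", l)]] <- numeric(C)
  }
  c(p, list(head = head_init(C + c0, cfg$Dh, cfg$profile)))
}

resnet_forward <- function(tape, nodes, cfg, xin, B, Tp, H, W, causal) {
  E <- H * W
  xe <- to_electrode_rows(xin$x)
  maskcol <- rep(1, nrow(xe))      # validity channel (masked electrodes 0)
  if (!is.null(xin$maskvec)) maskcol <- rep(xin$maskvec, times = B * Tp)
  x0 <- tp_const(tape, cbind(xe, maskcol))
  stem <- tp_relu(tape, tp_conv1d(tape, x0, nodes$stem, nodes$stem_b,
                                  B, Tp, 5L, causal, P = E))
  skip <- tp_conv1d(tape, tp_const(tape, xin$x), nodes$skip_w,
                    nodes$skip_b, B, Tp, 8L, causal)
  cur <- stem; Tc <- Tp; Hc <- H; Wc <- W
  for (l in 1:4) {
    Ec <- Hc * Wc
    h <- if (Ec > 1L)
      tp_conv_taps(tape, cur, nodes[[paste0("sw", l)]], nodes[[paste0("sb", l)]],
                   conv_spatial_indices(B * Tc, Hc, Wc))
    else tp_conv_taps(tape, cur, tp_gather_rows(tape, nodes[[paste0("sw", l)]],
                                                seq_len(ncol(cur$value)) + 4L * ncol(cur$value)),
                      nodes[[paste0("sb", l)]], list(seq_len(nrow(cur$value))))
    h <- tp_relu(tape, h)
    h <- tp_conv1d(tape, h, nodes[[paste0("tw", l)]], nodes[[paste0("tb", l)]],
                   B, Tc, 3L, causal, P = Ec, stride = 2L)
    sk <- tp_conv1d(tape, cur, nodes[[paste0("pr", l)]], NULL,
                    B, Tc, 1L, causal, P = Ec, stride = 2L)
    cur <- tp_relu(tape, tp_add(tape, h, sk))
    Tc <- Tc %/% 2L
    if (Hc > 1L) {
      cur <- spatial_pool(tape, cur, B * Tc, Hc, Wc)
      Hc <- Hc %/% 2L; Wc <- Wc %/% 2L
    }
  }
  for (l in 1:4) {
    cur <- tp_relu(tape, tp_tconv1d(tape, cur, nodes[[paste0("ut", l)]],
                                    nodes[[paste0("ub", l)]], B, Tc, 2L, causal))
    Tc <- Tc * 2L
  }
  tp_cbind(tape, list(cur, skip))
}

# ---- LSTM backbone ------------------------------------------------------

lstm_init <- function(cfg, E) {
  C <- cfg$C
  dirs <- if (cfg$causal) 1L else 2L
  p <- list()
  cin <- E
  for (l in 1:3) {
    for (d in seq_len(dirs)) {
      key <- paste0("l", l, "d", d)
      p[[paste0(key, "_wx")]] <- he_init(cin, 4L * C)
      p[[paste0(key, "_wh")]] <- he_init(C, 4L * C) * 0.5
      p[[paste0(key, "_b")]] <- c(numeric(C), rep(1, C), numeric(2L * C))
    }
    cin <- C * dirs
  }
  p$wo <- he_init(cin, C)
  p$bo <- numeric(C)
  p$skip_w <- he_init(8L * E, cfg$c0)
  p$skip_b <- numeric(cfg$c0)
  c(p, list(head = head_init(C + cfg$c0, cfg$Dh, cfg$profile)))
}

# run one LSTM direction over a (B*T) x Cin node; returns (B*T) x C node
lstm_run <- function(tape, x, wx, wh, b, B, T, C, reverse = FALSE) {
  tp_lstm(tape, x, wx, wh, b, B, T, reverse = reverse)
}

lstm_forward <- function(tape, nodes, cfg, xin, B, Tp, H, W, causal) {
  C <- cfg$C
  cur <- tp_const(tape, xin$x)
  dirs <- if (causal) 1L else 2L
  for (l in 1:3) {
    outs <- list()
    for (d in seq_len(dirs)) {
      key <- paste0("l", l, "d", d)
      outs[[d]] <- lstm_run(tape, cur, nodes[[paste0(key, "_wx")]],
                            nodes[[paste0(key, "_wh")]],
                            nodes[[paste0(key, "_b")]],
                            B, Tp, C, reverse = d == 2L)
    }
    cur <- if (dirs == 1L) outs[[1L]] else tp_cbind(tape, outs)
  }
  feat <- tp_relu(tape, tp_add_bias(tape, tp_matmul(tape, cur, nodes$wo), nodes$bo))
  # short temporal-context skip from the raw electrode vectors, kept
  # linear (no activation) so the head's linear readout can represent an
  # exact linear unmixing of the electrode signals; the recurrent trunk
  # supplies nonlinearity and longer-range structure
  skip <- tp_conv1d(tape, tp_const(tape, xin$x), nodes$skip_w,
                    nodes$skip_b, B, Tp, 8L, causal)
  tp_cbind(tape, list(feat, skip))
}

# ---- 3D Swin backbone ---------------------------------------------------

#' Partition an ECoG tensor into 2x2x2 patch tokens
#'
#' Each non-overlapping 2x2x2 spatiotemporal patch becomes one token whose
#' raw feature is its 8 samples; a linear layer embeds these during
#' decoding.
#' @param values T x H x W array (T, H, W even).
#' @return List with `tokens` ((T/2 * H/2 * W/2) x 8 matrix, token rows
#'   ordered temporal-major then rows then cols) and `dims` (token grid).
#' @export
swin_patch_partition <- function(values) {
  d <- dim(values)
  T2 <- d[1L] %/% 2L; H2 <- d[2L] %/% 2L; W2 <- d[3L] %/% 2L
  tok <- matrix(0, T2 * H2 * W2, 8L)
  col <- 0L
  for (dw in 0:1) for (dh in 0:1) for (dt in 0:1) {
    col <- col + 1L
    sub <- values[seq_len(T2) * 2L - 1L + dt,
                  seq_len(H2) * 2L - 1L + dh,
                  seq_len(W2) * 2L - 1L + dw, drop = FALSE]
    tok[, col] <- as.vector(aperm(sub, c(3L, 2L, 1L)))  # w fastest, t slowest
  }
  list(tokens = tok, dims = c(T2, H2, W2))
}

# token row index on a (Tt, Ht, Wt) grid, t-major then h then w
tok_row <- function(t, h, w, dims) {
  (t - 1L) * dims[2L] * dims[3L] + (h - 1L) * dims[3L] + w
}

#' Window partition of a 3D token grid (with optional shift)
#'
#' Returns the token-index groups over which self-attention operates.  The
#' shifted layout offsets window boundaries by half a window, so a shifted
#' window spans tokens from adjacent unshifted windows (edge windows are
#' smaller; there is no cyclic wrap-around).
#' @param dims Token grid `c(Tt, Ht, Wt)`.
#' @param window Window size `c(P, M, M)`.
#' @param shift Logical: offset boundaries by half a window.
#' @return List of integer vectors of token row indices.
#' @export
swin_windows <- function(dims, window = c(16L, 2L, 2L), shift = FALSE) {
  cuts <- function(n, w, s) {
    if (s && w %/% 2L < n) edges <- unique(c(0L, seq(w %/% 2L, n, by = w), n))
    else edges <- unique(c(seq(0L, n, by = w), n))
    mapply(function(a, b) seq(a + 1L, b), edges[-length(edges)], edges[-1L],
           SIMPLIFY = FALSE)
  }
  gt <- cuts(dims[1L], window[1L], shift)
  gh <- cuts(dims[2L], window[2L], shift)
  gw <- cuts(dims[3L], window[3L], shift)
  out <- list()
  for (a in gt) for (b in gh) for (cc in gw) {
    grid <- expand.grid(w = cc, h = b, t = a)
    out[[length(out) + 1L]] <- tok_row(grid$t, grid$h, grid$w, dims)
  }
  out
}

# causal attention mask (additive) for one window's token temporal indices
causal_mask <- function(tvec) {
  M <- outer(tvec, tvec, function(q, k) ifelse(k <= q, 0, -Inf))
  M
}

swin_init <- function(cfg, E) {
  C <- cfg$C
  p <- list(embed = he_init(8L, C), embed_b = numeric(C))
  Cs <- C
  for (s in seq_along(cfg$stages)) {
    for (l in seq_len(cfg$stages[s])) {
      key <- paste0("s", s, "l", l)
      p[[paste0(key, "_ln1g")]] <- rep(1, Cs)
      p[[paste0(key, "_ln1b")]] <- numeric(Cs)
      p[[paste0(key, "_qkv")]] <- he_init(Cs, 3L * Cs)
      p[[paste0(key, "_qkvb")]] <- numeric(3L * Cs)
      p[[paste0(key, "_wo")]] <- he_init(Cs, Cs)
      p[[paste0(key, "_wob")]] <- numeric(Cs)
      p[[paste0(key, "_ln2g")]] <- rep(1, Cs)
      p[[paste0(key, "_ln2b")]] <- numeric(Cs)
      p[[paste0(key, "_f1")]] <- he_init(Cs, 2L * Cs)
      p[[paste0(key, "_f1b")]] <- numeric(2L * Cs)
      p[[paste0(key, "_f2")]] <- he_init(2L * Cs, Cs)
      p[[paste0(key, "_f2b")]] <- numeric(Cs)
    }
    if (s < length(cfg$stages)) {
      p[[paste0("merge", s)]] <- he_init(8L * Cs, 2L * Cs)
      p[[paste0("merge", s, "_b")]] <- numeric(2L * Cs)
      Cs <- 2L * Cs
    }
  }
  for (l in 1:3) {
    p[[paste0("ut", l)]] <- he_init(2L * Cs, Cs)
    p[[paste0("ub", l)]] <- numeric(Cs)
  }
  p$skip_w <- he_init(8L * E, cfg$c0)
  p$skip_b <- numeric(cfg$c0)
  c(p, list(head = head_init(Cs + cfg$c0, cfg$Dh, cfg$profile)))
}

# one windowed multi-head self-attention + FFN block on tokens of one trial
swin_block <- function(tape, nodes, key, x, dims, shift, causal, n_heads,
                       window) {
  Cs <- ncol(x$value)
  dh <- Cs %/% n_heads
  xn <- tp_layernorm_rows(tape, x, nodes[[paste0(key, "_ln1g")]],
                          nodes[[paste0(key, "_ln1b")]])
  qkv <- tp_add_bias(tape, tp_matmul(tape, xn, nodes[[paste0(key, "_qkv")]]),
                     nodes[[paste0(key, "_qkvb")]])
  wins <- swin_windows(dims, window, shift)
  t_of <- (seq_len(prod(dims)) - 1L) %/% (dims[2L] * dims[3L]) + 1L
  parts <- vector("list", length(wins))
  for (wi in seq_along(wins)) {
    rows <- wins[[wi]]
    qkv_w <- tp_gather_rows(tape, qkv, rows)
    mask <- if (causal) causal_mask(t_of[rows]) else NULL
    heads <- vector("list", n_heads)
    for (hh in seq_len(n_heads)) {
      q <- tp_cols(tape, qkv_w, (hh - 1L) * dh + seq_len(dh))
      k <- tp_cols(tape, qkv_w, Cs + (hh - 1L) * dh + seq_len(dh))
      v <- tp_cols(tape, qkv_w, 2L * Cs + (hh - 1L) * dh + seq_len(dh))
      sc <- tp_scale(tape, tp_matmul(tape, q, tp_t(tape, k)), 1 / sqrt(dh))
      if (!is.null(mask)) sc <- tp_add(tape, sc, mask)
      heads[[hh]] <- tp_matmul(tape, tp_softmax_rows(tape, sc), v)
    }
    parts[[wi]] <- tp_cbind(tape, heads)
  }
  att <- tp_rbind(tape, parts)
  inv <- integer(prod(dims))
  inv[unlist(wins)] <- seq_len(prod(dims))
  att <- tp_gather_rows(tape, att, inv)
  att <- tp_add_bias(tape, tp_matmul(tape, att, nodes[[paste0(key, "_wo")]]),
                     nodes[[paste0(key, "_wob")]])
  x <- tp_add(tape, x, att)
  xn2 <- tp_layernorm_rows(tape, x, nodes[[paste0(key, "_ln2g")]],
                           nodes[[paste0(key, "_ln2b")]])
  h <- tp_relu(tape, tp_add_bias(tape, tp_matmul(tape, xn2, nodes[[paste0(key, "_f1")]]),
                                 nodes[[paste0(key, "_f1b")]]))
  h <- tp_add_bias(tape, tp_matmul(tape, h, nodes[[paste0(key, "_f2")]]),
                   nodes[[paste0(key, "_f2b")]])
  tp_add(tape, x, h)
}

# merge 2x2x2 adjacent tokens -> half the tokens per axis, double channels
swin_merge <- function(tape, nodes, s, x, dims) {
  T2 <- max(dims[1L] %/% 2L, 1L); H2 <- max(dims[2L] %/% 2L, 1L)
  W2 <- max(dims[3L] %/% 2L, 1L)
  grid <- expand.grid(w = seq_len(W2), h = seq_len(H2), t = seq_len(T2))
  parts <- list()
  for (dt in 0:1) for (dh in 0:1) for (dw in 0:1) {
    tt <- pmin(2L * grid$t - 1L + dt, dims[1L])
    hh2 <- pmin(2L * grid$h - 1L + dh, dims[2L])
    ww2 <- pmin(2L * grid$w - 1L + dw, dims[3L])
    parts[[length(parts) + 1L]] <- tp_gather_rows(tape, x, tok_row(tt, hh2, ww2, dims))
  }
  merged <- tp_cbind(tape, parts)
  out <- tp_add_bias(tape, tp_matmul(tape, merged, nodes[[paste0("merge", s)]]),
                     nodes[[paste0("merge", s, "_b")]])
  list(x = out, dims = c(T2, H2, W2))
}

swin_forward <- function(tape, nodes, cfg, xin, B, Tp, H, W, causal) {
  E <- H * W
  feats <- vector("list", B)
  for (b in seq_len(B)) {
    xb <- xin$x[((b - 1L) * Tp + 1L):(b * Tp), , drop = FALSE]
    pp <- swin_patch_partition(array(xb, c(Tp, H, W)))
    x <- tp_add_bias(tape, tp_matmul(tape, tp_const(tape, pp$tokens),
                                     nodes$embed), nodes$embed_b)
    dims <- pp$dims
    for (s in seq_along(cfg$stages)) {
      for (l in seq_len(cfg$stages[s])) {
        x <- swin_block(tape, nodes, paste0("s", s, "l", l), x, dims,
                        shift = (l %% 2L == 0L), causal = causal,
                        n_heads = cfg$n_heads, window = cfg$window)
      }
      if (s < length(cfg$stages)) {
        m <- swin_merge(tape, nodes, s, x, dims)
        x <- m$x; dims <- m$dims
      }
    }
    feats[[b]] <- x    # dims[1] tokens x Cs (spatial collapsed to 1x1)
  }
  cur <- tp_rbind(tape, feats)    # rows (b, token_t)
  Tc <- dim(feats[[1L]]$value)[1L]
  for (l in 1:3) {
    cur <- tp_relu(tape, tp_tconv1d(tape, cur, nodes[[paste0("ut", l)]],
                                    nodes[[paste0("ub", l)]], B, Tc, 2L, causal))
    Tc <- Tc * 2L
  }
  # causal full-resolution skip from the raw electrode vectors
  skip <- tp_relu(tape, tp_conv1d(tape, tp_const(tape, xin$x), nodes$skip_w,
                                  nodes$skip_b, B, Tp, 8L, causal))
  tp_cbind(tape, list(cur, skip))
}

# ---- decode API ---------------------------------------------------------

backbone_mult <- function(backbone) {
  switch(backbone, resnet3d = 16L, swin3d = 16L, lstm = 1L)
}

skip_kernel <- function(backbone) 8L

# map constrained parameter values to the head's raw (pre-activation) scale
raw_targets <- function(pm, profile) {
  rg <- head_ranges(profile)
  raw <- matrix(0, nrow(pm), 18L)
  for (j in seq_along(HEAD_SIG_COLS)) {
    col <- HEAD_SIG_COLS[j]
    u <- pmin(pmax((pm[, col] - rg$lo[j]) / (rg$hi[j] - rg$lo[j]), 0.02), 0.98)
    raw[, col] <- stats::qlogis(u)
  }
  for (col in HEAD_SOFT_COLS) {
    raw[, col] <- log(expm1(pmax(pm[, col], 1e-3)))
  }
  raw
}

# Closed-form warm start: fit a ridge regression from the skip path's
# causal context features onto the raw parameter targets and install it in
# the skip convolution + linear readout.  Training then starts from an
# analytically sensible decode and Adam refines all parts jointly.
ridge_warmstart <- function(params, config, xs, guid, E) {
  if (length(params$skip_b) < 19L) return(params)  # needs >= 18 skip channels
  k <- skip_kernel(config$backbone)
  n_use <- min(length(xs), 300L)
  Xs <- list(); Ys <- list()
  for (i in seq_len(n_use)) {
    m <- xs[[i]]
    T <- nrow(m)
    ctx <- lapply(0:(k - 1L), function(l) {
      src <- if (config$causal) seq_len(T) - l else seq_len(T) - l + k %/% 2L
      out <- m[pmin(pmax(src, 1L), T), , drop = FALSE]
      out[src < 1L | src > T, ] <- 0       # match the conv's zero padding
      out
    })
    keep <- k:T        # onset frames lack full context; exclude from fit
    Xs[[i]] <- do.call(cbind, ctx)[keep, , drop = FALSE]
    Ys[[i]] <- raw_targets(guid[[i]], config$profile)[keep, , drop = FALSE]
  }
  X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
  xm <- colMeans(X); ym <- colMeans(Y)
  W <- tryCatch(solve(crossprod(sweep(X, 2L, xm)) + diag(ncol(X)),
                      crossprod(sweep(X, 2L, xm), sweep(Y, 2L, ym))),
                error = function(e) NULL)
  if (is.null(W)) return(params)
  # context order in tp_conv1d: tap j reads offset -(k-j) (causal), so tap
  # k is lag 0, tap k-1 is lag 1, ...; our ctx blocks are lag 0..k-1
  perm <- integer(0)
  for (j in seq_len(k)) {
    lag <- k - j
    perm <- c(perm, lag * E + seq_len(E))
  }
  params$skip_w[perm, seq_len(18L)] <- W
  params$skip_w[, 19:ncol(params$skip_w)] <- params$skip_w[, 19:ncol(params$skip_w)] * 0.3
  params$skip_b[seq_len(18L)] <- ym - as.numeric(xm %*% W)
  D <- nrow(params$head$wlin)
  c0 <- length(params$skip_b)
  # start as the pure ridge decode: only the identity block reads out;
  # every other path into the raw outputs revives through its gradients
  params$head$wlin[] <- 0
  params$head$wlin[D - c0 + seq_len(18L), ] <- diag(18L)
  params$head$w2[] <- 0
  params$head$b2[] <- 0
  params
}

decoder_init <- function(cfg, E) {
  switch(cfg$backbone,
         resnet3d = resnet_init(cfg, E),
         swin3d = swin_init(cfg, E),
         lstm = lstm_init(cfg, E))
}

decoder_forward <- function(tape, nodes, cfg, xin, B, H, W) {
  fwd <- switch(cfg$backbone, resnet3d = resnet_forward,
                swin3d = swin_forward, lstm = lstm_forward)
  feat <- fwd(tape, nodes, cfg, xin, B, xin$Tp, H, W, cfg$causal)
  pred_p <- head_forward(tape, nodes$head, feat, B, xin$Tp, cfg$causal)
  crop_rows(tape, pred_p, B, xin$Tp, xin$T, xin$left)
}

#' Decode speech parameters from an ECoG tensor
#' @param x An `ecog_tensor`.
#' @param model A trained `nv_decoder` (or list with `params`, `config`).
#' @return `speech_params` (one set of 18 parameters per input frame).
#' @export
decode <- function(x, model) {
  cfg <- model$config
  vals <- ecog_matrix(x)
  vals[, !as.vector(x$valid_mask)] <- 0   # occluded/rejected electrodes
  d <- dim(x$values)
  tape <- nv_tape()
  nodes <- rapply(model$params, function(v) tp_const(tape, v),
                  how = "replace", classes = c("numeric", "matrix", "array"))
  nodes$head$profile <- cfg$profile
  xin <- stack_inputs(list(vals), backbone_mult(cfg$backbone), cfg$causal)
  xin$maskvec <- as.numeric(as.vector(x$valid_mask))
  pred <- decoder_forward(tape, nodes, cfg, xin, 1L, d[2L], d[3L])
  speech_params_from_matrix(pred$value)
}

#' Probe whether a decoder is causal at frame t
#'
#' Randomly perturbs all frames strictly after `t` and checks that the
#' decoded parameters at frames `1..t` are bitwise unchanged.  Vacuously
#' true at `t = T` (no future frames exist).
#' @param decode_fn Function `ecog_tensor -> speech_params`-like matrix.
#' @param x `ecog_tensor` input.
#' @param t Probe frame (`1 <= t <= T`).
#' @param seed Seed for the perturbation.
#' @return TRUE iff outputs at frames `<= t` are invariant.
#' @export
causality_probe <- function(decode_fn, x, t, seed = 0L) {
  T <- ecog_frames(x)
  stopifnot(t >= 1L, t <= T)
  base <- as.matrix(decode_fn(x))
  if (t == T) return(TRUE)
  pert <- x
  pert$values[(t + 1L):T, , ] <- with_seed(seed, {
    pert$values[(t + 1L):T, , ] + stats::rnorm(length(pert$values[(t + 1L):T, , ]), 0, 3)
  })
  out <- as.matrix(decode_fn(pert))
  identical(base[seq_len(t), ], out[seq_len(t), ])
}

#' Train an ECoG decoder on paired (ECoG, spectrogram, guidance) trials
#'
#' Minimizes `L_MSS + lambda1 L_STOI + lambda2 L_supervision +
#' lambda3 L_reference` with Adam (lr 1e-3).  Guidance parameters come from
#' the dataset's ground truth or, when `guidance_model` is a trained
#' auto-encoder, from encoding each trial's spectrogram.
#' @param data An `nv_dataset` (its train split is used) or a list of
#'   trials with `ecog`, `spec` and `params`.
#' @param config [decoder_config()].
#' @param seed Integer seed (training is deterministic given it).
#' @param steps,batch,lr Optimization settings.
#' @param speaker `speaker_params` used by the differentiable synthesizer
#'   during training (defaults to the dataset's generating speaker).
#' @param guidance_model Optional `nv_autoencoder` supplying guidance.
#' @param weights Loss weights.
#' @param verbose Print progress.
#' @return An `nv_decoder`.
#' @export
train_decoder <- function(data, config = decoder_config(), seed = 0L,
                          steps = 250L, batch = 8L, lr = 1e-3,
                          warmup = 0.5, speaker = NULL, guidance_model = NULL,
                          weights = loss_weights(), verbose = FALSE) {
  trials <- if (inherits(data, "nv_dataset")) data$trials[data$train] else data
  if (is.null(speaker) && inherits(data, "nv_dataset")) speaker <- data$speaker
  if (is.null(speaker)) stop("train_decoder: speaker parameters required")
  K <- speaker$K
  T <- ecog_frames(trials[[1L]]$ecog)
  H <- dim(trials[[1L]]$ecog$values)[2L]
  W <- dim(trials[[1L]]$ecog$values)[3L]
  xs <- lapply(trials, function(tr) ecog_matrix(tr$ecog))
  specs <- lapply(trials, function(tr) unclass(as.matrix(tr$spec)))
  guid <- lapply(trials, function(tr) {
    if (!is.null(guidance_model)) as.matrix(encode(tr$spec, guidance_model))
    else as.matrix(tr$params)
  })
  sup <- lapply(trials, trial_supervision)
  nc <- param_norm_consts(config$profile)
  band_ind <- octave_band_matrix(K)
  fb_t <- t(mel_filterbank(80L, K))
  mult <- backbone_mult(config$backbone)
  with_seed(seed, {
    params <- decoder_init(config, H * W)
    params <- ridge_warmstart(params, config, xs, guid, H * W)
    flat <- params_flatten(params)
    flat <- flat[!vapply(flat, is.character, TRUE)]
    opt <- adam_init(flat, lr = lr)
    curve <- numeric(steps)
    avg <- NULL; n_avg <- 0L      # Polyak tail average damps optimizer jitter
    n_warm <- min(steps, round(warmup * steps))
    for (step in seq_len(steps)) {
      idx <- sample.int(length(trials), min(batch, length(trials)),
                        replace = length(trials) < batch)
      B <- length(idx)
      xin <- stack_inputs(xs[idx], mult, config$causal)
      S_stack <- do.call(rbind, specs[idx])
      G_stack <- do.call(rbind, guid[idx])
      f0_ref <- unlist(lapply(sup[idx], function(s) s$f0))
      fm_ref <- do.call(rbind, lapply(sup[idx], function(s) s$formants))
      tape <- nv_tape()
      nodes <- leafify_state(tape, flat)
      dn <- unflatten_nodes(nodes)
      dn$head$profile <- config$profile
      pred <- decoder_forward(tape, dn, config, xin, B, H, W)
      pn <- pred_to_pn(tape, pred)
      # warm-up phase: parameter-matching terms only; the spectral terms
      # (and the synthesizer pass they need) join after n_warm steps
      if (step > n_warm) {
        noise <- do.call(rbind, lapply(seq_len(B), function(b)
          noise_excitation(T, K, seed = (seed + step * 131L + b) %% 2^30)))
        syn <- synth_forward(tape, pn, speaker_nodes_const(tape, speaker),
                             T, K, noise, B = B)
        L <- tp_mss(tape, syn$S, S_stack, fb_t)
        for (b in seq_len(B)) {
          rows <- ((b - 1L) * T + 1L):(b * T)
          st <- tp_stoi(tape, tp_gather_rows(tape, syn$S, rows),
                        S_stack[rows, , drop = FALSE], band_ind)
          L <- tp_add(tape, L, tp_scale(tape, st, -weights$lambda1))
        }
      } else L <- NULL
      # supervision in natural units (Hz) for pitch/formant tracking; the
      # reference term on the normalized parameter scale, where the printed
      # per-parameter weights are commensurate across all 18 channels
      Ls <- tp_scale(
        tape, tp_supervision(tape, pred, f0_ref, fm_ref, weights$beta),
        weights$lambda2)
      L <- if (is.null(L)) Ls else tp_add(tape, L, Ls)
      # percent units on the normalized scale keep the reference term
      # commensurate with the Hz-scale supervision term
      pred_n <- tp_scale(tape, tp_normalize_params(tape, pred, nc), 100)
      L <- tp_add(tape, L, tp_scale(
        tape, tp_reference(tape, pred_n, 100 * normalize_params_num(G_stack, nc),
                           weights$ref), weights$lambda3))
      if (!is.finite(L$value)) stop("train_decoder: loss diverged (NaN/Inf) at step ", step)
      tp_backward(tape, L)
      opt$lr <- if (step > n_warm) lr / 10 else lr   # gentle spectral fine-tune
      res <- adam_step(opt, flat, collect_grads(nodes))
      flat <- res$params; opt <- res$opt
      if (step > 0.75 * steps) {
        n_avg <- n_avg + 1L
        avg <- if (is.null(avg)) flat
        else mapply(function(a, b) a + (b - a) / n_avg, avg, flat,
                    SIMPLIFY = FALSE)
      }
      curve[step] <- L$value
      if (verbose && step %% 25L == 0L)
        message(sprintf("step %d loss %.2f", step, L$value))
    }
    final <- unflatten_nodes(if (is.null(avg)) flat else avg)
    final$head$profile <- config$profile
    structure(list(params = final, config = config, curve = curve,
                   speaker = speaker, seed = seed, trained = TRUE),
              class = "nv_decoder")
  })
}

#' @export
print.nv_decoder <- function(x, ...) {
  cat(sprintf("nv_decoder: %s (%s), C = %d, %d training steps\n",
              x$config$backbone, if (x$config$causal) "causal" else "non-causal",
              x$config$C, length(x$curve)))
  if (length(x$curve))
    cat(sprintf("  final loss %.3f (start %.3f)\n",
                utils::tail(x$curve, 1L), x$curve[1L]))
  invisible(x)
}

#' @export
predict.nv_decoder <- function(object, x, ...) decode(x, object)

#' Convenience wrappers for the three backbones
#'
#' `resnet_decode`, `swin_decode` and `lstm_decode` run the corresponding
#' backbone on an ECoG tensor given a decoder state (trained or freshly
#' initialized with [decoder_state()]).
#' @param x `ecog_tensor`.
#' @param model `nv_decoder` state whose backbone matches.
#' @return `speech_params`.
#' @export
resnet_decode <- function(x, model) {
  stopifnot(model$config$backbone == "resnet3d"); decode(x, model)
}

#' @rdname resnet_decode
#' @export
swin_decode <- function(x, model) {
  stopifnot(model$config$backbone == "swin3d"); decode(x, model)
}

#' @rdname resnet_decode
#' @export
lstm_decode <- function(x, model) {
  stopifnot(model$config$backbone == "lstm"); decode(x, model)
}

#' Create an untrained decoder state (random weights)
#' @param config [decoder_config()].
#' @param grid Electrode grid `c(H, W)`.
#' @param seed Seed for the initialization.
#' @return `nv_decoder` with `trained = FALSE`.
#' @export
decoder_state <- function(config = decoder_config(), grid = c(8L, 8L),
                          seed = 0L) {
  params <- with_seed(seed, decoder_init(config, prod(grid)))
  structure(list(params = params, config = config, curve = numeric(0),
                 seed = seed, trained = FALSE),
            class = "nv_decoder")
}
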