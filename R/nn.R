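# Minimal volumetric neural-network core: explicit layers with hand-written
# forward/backward passes. Tensors are (D,H,W,C,B) arrays; convolutions are
# lowered to BLAS matrix multiplies via the im2col kernels in src/. Layers
# are environments (mutable caches and parameters); a model is an environment
# holding an ordered layer list, a frozen-group set and a spec.

.nf <- new.env(parent = emptyenv())
.nf$id <- 0L

new_layer <- function(type, group, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$group <- group
  l$id <- (.nf$id <- .nf$id + 1L)
  l$params <- list()
  l$grads <- list()
  l$state <- list()
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = l)
  l
}

he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

layer_conv3d <- function(in_ch, out_ch, k, stride = 1, pad = 0, group = "misc") {
  l <- new_layer("conv3d", group, in_ch = in_ch, out_ch = out_ch,
                 k = k, stride = stride, pad = pad)
  l$params$W <- array(he_init(k^3 * in_ch * out_ch, k^3 * in_ch),
                      c(k, k, k, in_ch, out_ch))
  l$params$b <- numeric(out_ch)
  l
}

layer_bn <- function(ch, group = "misc", momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn", group, ch = ch, momentum = momentum, eps = eps)
  l$params$gamma <- rep(1, ch)
  l$params$beta <- numeric(ch)
  l$state$rm <- numeric(ch)
  l$state$rv <- rep(1, ch)
  l
}

layer_relu <- function(group = "misc") new_layer("relu", group)

layer_maxpool <- function(k = 3, stride = 2, pad = 1, group = "misc")
  new_layer("maxpool", group, k = k, stride = stride, pad = pad)

layer_gap <- function(group = "misc") new_layer("gap", group)

layer_flatten <- function(group = "misc") new_layer("flatten", group)

layer_reshape <- function(target_dims, group = "misc")
  new_layer("reshape", group, target_dims = target_dims)

layer_upsample <- function(factor = 2, group = "misc")
  new_layer("upsample", group, factor = factor)

layer_dense <- function(in_w, out_w, group = "misc", init_sd = NULL) {
  l <- new_layer("dense", group, in_w = in_w, out_w = out_w)
  sdv <- init_sd %||% sqrt(2 / in_w)
  l$params$W <- matrix(rnorm(in_w * out_w, 0, sdv), in_w, out_w)
  l$params$b <- numeric(out_w)
  l
}

layer_se <- function(ch, reduction = 16, group = "se") {
  h <- max(1L, as.integer(round(ch / reduction)))
  l <- new_layer("se", group, ch = ch, hidden = h)
  l$params$W1 <- matrix(he_init(ch * h, ch), ch, h)
  l$params$b1 <- numeric(h)
  l$params$W2 <- matrix(rnorm(h * ch, 0, sqrt(1 / h)), h, ch)
  l$params$b2 <- numeric(ch)
  l
}

layer_daft <- function(ch, tab_width, hidden = 8, group = "daft") {
  l <- new_layer("daft", group, ch = ch, tab_width = tab_width, hidden = hidden)
  l$params$W1 <- matrix(he_init((ch + tab_width) * hidden, ch + tab_width),
                        ch + tab_width, hidden)
  l$params$b1 <- numeric(hidden)
  # zero-initialized output layer: alpha = 1, beta = 0 at initialization,
  # so the block starts as the identity
  l$params$W2 <- matrix(0, hidden, 2 * ch)
  l$params$b2 <- numeric(2 * ch)
  l
}

# Basic residual block: conv-bn-relu-conv-bn (+ projection skip) -> relu.
layer_resblock <- function(in_ch, out_ch, stride = 1, group = "misc") {
  l <- new_layer("resblock", group, in_ch = in_ch, out_ch = out_ch,
                 stride = stride)
  l$sub <- list(
    conv1 = layer_conv3d(in_ch, out_ch, 3, stride, 1, group),
    bn1 = layer_bn(out_ch, group),
    conv2 = layer_conv3d(out_ch, out_ch, 3, 1, 1, group),
    bn2 = layer_bn(out_ch, group))
  if (stride != 1 || in_ch != out_ch) {
    l$sub$down_conv <- layer_conv3d(in_ch, out_ch, 1, stride, 0, group)
    l$sub$down_bn <- layer_bn(out_ch, group)
  }
  l
}

# ---- forward / backward dispatch ------------------------------------------

gap_fwd <- function(x) {
  d <- dim(x)
  s <- d[1] * d[2] * d[3]
  arr <- aperm(x, c(1, 2, 3, 5, 4))
  dim(arr) <- c(s, d[5], d[4])
  colMeans(arr, dims = 1)                       # B x C
}

gap_bwd <- function(dout, d) {
  s <- d[1] * d[2] * d[3]
  arr <- array(rep(as.vector(dout), each = s) / s, c(s, d[5], d[4]))
  dim(arr) <- c(d[1], d[2], d[3], d[5], d[4])
  aperm(arr, c(1, 2, 3, 5, 4))
}

# per-(batch,channel) scaling of a feature map; w is B x C
scale_map <- function(x, w) {
  d <- dim(x)
  s <- d[1] * d[2] * d[3]
  m <- chan_mat(x)                              # (S*B) x C, spatial fastest
  wm <- w[rep(seq_len(d[5]), each = s), , drop = FALSE]
  chan_unmat(m * wm, d)
}

# sum over spatial voxels of x*y per (batch, channel): returns B x C
spatial_dot <- function(x, y) {
  d <- dim(x)
  s <- d[1] * d[2] * d[3]
  m <- chan_mat(x) * chan_mat(y)
  dim(m) <- c(s, d[5], d[4])
  colSums(m, dims = 1)
}

layer_fwd <- function(l, x, training = FALSE, tab = NULL) {
  switch(l$type,
    conv3d = {
      d <- dim(x)
      xp <- pad5d(x, l$pad)
      dp <- dim(xp)
      o <- nf_conv3d_fwd(as.vector(xp), as.integer(dp),
                         as.vector(l$params$W), l$params$b, l$k, l$stride)
      no <- (dp[1:3] - l$k) %/% l$stride + 1
      l$cache <- list(xp = xp, dp = dp, d = d, no = no)
      array(o, c(no, l$out_ch, d[5]))
    },
    bn = {
      d <- dim(x)
      m <- chan_mat(x)
      n <- nrow(m)
      if (training) {
        mu <- colMeans(m)
        xc <- m - rep(mu, each = n)
        va <- colMeans(xc^2)
        invstd <- 1 / sqrt(va + l$eps)
        xhat <- xc * rep(invstd, each = n)
        l$state$rm <- (1 - l$momentum) * l$state$rm + l$momentum * mu
        l$state$rv <- (1 - l$momentum) * l$state$rv + l$momentum * va
        l$cache <- list(xhat = xhat, invstd = invstd, d = d, training = TRUE)
      } else {
        invstd <- 1 / sqrt(l$state$rv + l$eps)
        xhat <- (m - rep(l$state$rm, each = n)) * rep(invstd, each = n)
        l$cache <- list(invstd = invstd, d = d, training = FALSE)
      }
      y <- xhat * rep(l$params$gamma, each = n) + rep(l$params$beta, each = n)
      chan_unmat(y, d)
    },
    relu = {
      l$cache <- list(mask = x > 0)
      x * (x > 0)
    },
    maxpool = {
      d <- dim(x)
      xp <- pad5d(x, l$pad)
      dp <- dim(xp)
      r <- nf_maxpool_fwd(as.vector(xp), as.integer(dp), l$k, l$stride)
      no <- (dp[1:3] - l$k) %/% l$stride + 1
      l$cache <- list(argmax = r$argmax, dp = dp, d = d, no = no)
      array(r$out, c(no, d[4], d[5]))
    },
    gap = {
      l$cache <- list(d = dim(x))
      gap_fwd(x)
    },
    flatten = {
      d <- dim(x)
      l$cache <- list(d = d)
      t(matrix(x, ncol = d[5]))
    },
    reshape = {
      b <- nrow(x)
      l$cache <- list()
      array(t(x), c(l$target_dims, b))
    },
    upsample = {
      d <- dim(x)
      f <- l$factor
      l$cache <- list(d = d)
      x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f),
        rep(seq_len(d[3]), each = f), , , drop = FALSE]
    },
    dense = {
      l$cache <- list(x = x)
      x %*% l$params$W + rep(l$params$b, each = nrow(x))
    },
    se = {
      s <- gap_fwd(x)
      h1 <- s %*% l$params$W1 + rep(l$params$b1, each = nrow(s))
      h1 <- h1 * (h1 > 0)
      w <- sigmoid(h1 %*% l$params$W2 + rep(l$params$b2, each = nrow(s)))
      l$cache <- list(x = x, s = s, h1 = h1, w = w, d = dim(x))
      scale_map(x, w)
    },
    daft = {
      if (is.null(tab)) stop("DAFT layer needs a tabular conditioning input")
      if (ncol(tab) != l$tab_width) stop("tabular width mismatch for DAFT")
      s <- gap_fwd(x)
      z <- cbind(s, tab)
      h1 <- z %*% l$params$W1 + rep(l$params$b1, each = nrow(z))
      h1 <- h1 * (h1 > 0)
      ab <- h1 %*% l$params$W2 + rep(l$params$b2, each = nrow(z))
      alpha <- 1 + ab[, seq_len(l$ch), drop = FALSE]
      beta <- ab[, l$ch + seq_len(l$ch), drop = FALSE]
      l$cache <- list(x = x, z = z, h1 = h1, alpha = alpha, d = dim(x))
      d <- dim(x)
      s2 <- d[1] * d[2] * d[3]
      bm <- beta[rep(seq_len(d[5]), each = s2), , drop = FALSE]
      chan_unmat(chan_mat(scale_map(x, alpha)) + bm, d)
    },
    resblock = {
      sub <- l$sub
      o1 <- layer_fwd(sub$conv1, x, training)
      o1 <- layer_fwd(sub$bn1, o1, training)
      l$cache_r1 <- o1 > 0
      o1 <- o1 * l$cache_r1
      o2 <- layer_fwd(sub$conv2, o1, training)
      o2 <- layer_fwd(sub$bn2, o2, training)
      sk <- if (!is.null(sub$down_conv))
        layer_fwd(sub$down_bn, layer_fwd(sub$down_conv, x, training), training)
      else x
      y <- o2 + sk
      l$cache_r2 <- y > 0
      y * l$cache_r2
    },
    stop("unknown layer type: ", l$type))
}

layer_bwd <- function(l, dout) {
  switch(l$type,
    conv3d = {
      ca <- l$cache
      dv <- as.vector(dout)
      l$grads$W <- array(nf_conv3d_dw(as.vector(ca$xp), as.integer(ca$dp),
                                      dv, l$out_ch, l$k, l$stride),
                         dim(l$params$W))
      db <- dout
      dim(db) <- c(prod(ca$no), l$out_ch, ca$d[5])
      l$grads$b <- colSums(colSums(aperm(db, c(1, 3, 2))))
      if (isTRUE(l$is_input)) return(NULL)   # nothing upstream consumes dx
      dxp <- array(nf_conv3d_dx(as.vector(l$params$W), as.integer(ca$dp),
                                dv, l$out_ch, l$k, l$stride), ca$dp)
      unpad5d(dxp, l$pad, ca$d)
    },
    bn = {
      ca <- l$cache
      dm <- chan_mat(dout)
      n <- nrow(dm)
      if (ca$training) {
        dxhat <- dm * rep(l$params$gamma, each = n)
        mean_dxhat <- colMeans(dxhat)
        mean_dxx <- colMeans(dxhat * ca$xhat)
        dx <- (dxhat - rep(mean_dxhat, each = n) -
               ca$xhat * rep(mean_dxx, each = n)) * rep(ca$invstd, each = n)
        l$grads$gamma <- colSums(dm * ca$xhat)
        l$grads$beta <- colSums(dm)
        chan_unmat(dx, ca$d)
      } else {
        l$grads$gamma <- numeric(l$ch)   # eval-mode step never trains
        l$grads$beta <- numeric(l$ch)
        chan_unmat(dm * rep(l$params$gamma * ca$invstd, each = n), ca$d)
      }
    },
    relu = dout * l$cache$mask,
    maxpool = {
      ca <- l$cache
      dxp <- nf_maxpool_bwd(as.vector(dout), ca$argmax, prod(ca$dp))
      unpad5d(array(dxp, ca$dp), l$pad, ca$d)
    },
    gap = gap_bwd(dout, l$cache$d),
    flatten = array(t(dout), l$cache$d),
    reshape = {
      b <- dim(dout)[length(dim(dout))]
      t(matrix(dout, ncol = b))
    },
    upsample = {
      d <- l$cache$d
      f <- l$factor
      arr <- dout
      dim(arr) <- c(f, d[1], f, d[2], f, d[3], d[4] * d[5])
      arr <- aperm(arr, c(1, 3, 5, 2, 4, 6, 7))
      dim(arr) <- c(f^3, d[1] * d[2] * d[3] * d[4] * d[5])
      array(colSums(arr), d)
    },
    dense = {
      l$grads$W <- crossprod(l$cache$x, dout)
      l$grads$b <- colSums(dout)
      dout %*% t(l$params$W)
    },
    se = {
      ca <- l$cache
      d <- ca$d
      dx_direct <- scale_map(dout, ca$w)
      dw <- spatial_dot(dout, ca$x)
      dz2 <- dw * ca$w * (1 - ca$w)
      l$grads$W2 <- crossprod(ca$h1, dz2)
      l$grads$b2 <- colSums(dz2)
      dh1 <- (dz2 %*% t(l$params$W2)) * (ca$h1 > 0)
      l$grads$W1 <- crossprod(ca$s, dh1)
      l$grads$b1 <- colSums(dh1)
      ds <- dh1 %*% t(l$params$W1)
      dx_direct + gap_bwd(ds, d)
    },
    daft = {
      ca <- l$cache
      d <- ca$d
      dx_direct <- scale_map(dout, ca$alpha)
      dalpha <- spatial_dot(dout, ca$x)
      dbeta <- spatial_dot(dout, array(1, d))
      dab <- cbind(dalpha, dbeta)
      l$grads$W2 <- crossprod(ca$h1, dab)
      l$grads$b2 <- colSums(dab)
      dh1 <- (dab %*% t(l$params$W2)) * (ca$h1 > 0)
      l$grads$W1 <- crossprod(ca$z, dh1)
      l$grads$b1 <- colSums(dh1)
      dz <- dh1 %*% t(l$params$W1)
      l$dtab <- dz[, l$ch + seq_len(l$tab_width), drop = FALSE]
      dx_direct + gap_bwd(dz[, seq_len(l$ch), drop = FALSE], d)
    },
    resblock = {
      sub <- l$sub
      dy <- dout * l$cache_r2
      d2 <- layer_bwd(sub$bn2, dy)
      d2 <- layer_bwd(sub$conv2, d2)
      d2 <- d2 * l$cache_r1
      d2 <- layer_bwd(sub$bn1, d2)
      dx1 <- layer_bwd(sub$conv1, d2)
      dx2 <- if (!is.null(sub$down_conv))
        layer_bwd(sub$down_conv, layer_bwd(sub$down_bn, dy))
      else dy
      dx1 + dx2
    },
    stop("unknown layer type: ", l$type))
}

# ---- model container -------------------------------------------------------

nf_model <- function(layers, spec = NULL, kind = "generic") {
  m <- new.env(parent = emptyenv())
  m$layers <- layers
  m$spec <- spec
  m$kind <- kind
  m$frozen <- character()
  class(m) <- "nf_model"
  m
}

#' Run a model forward
#'
#' @param model An `nf_model`.
#' @param x Input tensor (D,H,W,C,B array or B x F matrix for tabular heads).
#' @param tab Optional tabular conditioning matrix (DAFT models).
#' @param training Batch-norm mode; frozen groups always run in eval mode.
#' @param capture Optional layer index whose output to attach as
#'   attribute "captured".
#' @return Model output (logit matrix for classifiers).
#' @export
model_forward <- function(model, x, tab = NULL, training = FALSE,
                          capture = NULL) {
  cap <- NULL
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    tr <- training && !(l$group %in% model$frozen)
    x <- layer_fwd(l, x, training = tr, tab = tab)
    if (!is.null(capture) && i == capture) cap <- x
  }
  if (!is.null(cap)) attr(x, "captured") <- cap
  x
}

#' Backpropagate through a model
#'
#' Layer caches from the most recent [model_forward()] call are consumed.
#'
#' @param model An `nf_model`.
#' @param dout Gradient of the loss in the model output.
#' @param stop_at Stop after back-propagating into the output of layer
#'   `stop_at` (0 = all the way to the input).
#' @return Gradient with respect to that activation.
#' @export
model_backward <- function(model, dout, stop_at = 0) {
  for (i in rev(seq_along(model$layers))) {
    if (i <= stop_at) break
    dout <- layer_bwd(model$layers[[i]], dout)
  }
  dout
}

# Flat list of parameter-holding layers (recursing into composites).
walk_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (!is.null(l$sub)) out <- c(out, walk_layers(l$sub))
    if (length(l$params)) out <- c(out, list(l))
  }
  out
}

#' Count model parameters
#'
#' @param model An `nf_model`.
#' @param groups Optional character vector restricting to parameter groups.
#' @param trainable_only Exclude frozen groups.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, groups = NULL, trainable_only = FALSE) {
  ls <- walk_layers(model$layers)
  known <- unique(vapply(ls, function(l) l$group, ""))
  if (!is.null(groups)) {
    bad <- setdiff(groups, known)
    if (length(bad)) stop("unknown parameter group(s): ", paste(bad, collapse = ", "))
  }
  tot <- 0L
  for (l in ls) {
    if (!is.null(groups) && !(l$group %in% groups)) next
    if (trainable_only && l$group %in% model$frozen) next
    tot <- tot + sum(vapply(l$params, length, 0L))
  }
  as.integer(tot)
}

#' Freeze parameter groups
#'
#' Frozen groups are skipped by the optimizer and their batch-norm layers run
#' in inference mode, so a training step leaves them bit-identical.
#'
#' @param model An `nf_model`.
#' @param groups Character vector of group names.
#' @return The model, invisibly (modified in place).
#' @export
freeze_groups <- function(model, groups) {
  known <- unique(vapply(walk_layers(model$layers), function(l) l$group, ""))
  bad <- setdiff(groups, known)
  if (length(bad)) stop("unknown parameter group(s): ", paste(bad, collapse = ", "))
  model$frozen <- union(model$frozen, groups)
  invisible(model)
}

#' Extract / restore all learnable state
#'
#' State covers parameters and batch-norm running statistics, keyed by layer
#' id, so checkpoints round-trip bit-exactly.
#'
#' @param model An `nf_model`.
#' @return Named list (for `get_state`).
#' @export
get_state <- function(model) {
  ls <- walk_layers(model$layers)
  st <- lapply(ls, function(l) list(params = l$params, state = l$state,
                                    group = l$group))
  names(st) <- sprintf("p%03d", seq_along(ls))   # stable walk order
  st
}

#' @rdname get_state
#' @param state A state list from [get_state()].
#' @export
set_state <- function(model, state) {
  ls <- walk_layers(model$layers)
  if (length(ls) != length(state))
    stop("state does not match model topology")
  for (i in seq_along(ls)) {
    s <- state[[i]]
    if (!identical(s$group, ls[[i]]$group) ||
        !identical(names(s$params), names(ls[[i]]$params)))
      stop("state does not match model topology")
    ls[[i]]$params <- s$params
    ls[[i]]$state <- s$state
  }
  invisible(model)
}

#' Fingerprint of a parameter group
#'
#' @param model An `nf_model`.
#' @param group Group name.
#' @return MD5 string over the group's parameters.
#' @export
group_hash <- function(model, group) {
  ls <- walk_layers(model$layers)
  ps <- lapply(ls[vapply(ls, function(l) l$group == group, TRUE)],
               function(l) l$params)
  nf_hash(ps)
}

# ---- optimizer -------------------------------------------------------------

adam_new <- function(beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  o <- new.env(parent = emptyenv())
  o$beta1 <- beta1; o$beta2 <- beta2; o$eps <- eps
  o$t <- 0L
  o$m <- list(); o$v <- list()
  o
}

adam_step <- function(opt, model, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (l in walk_layers(model$layers)) {
    if (l$group %in% model$frozen) next
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      key <- paste0("l", l$id, ".", nm)
      m <- opt$m[[key]] %||% (g * 0)
      v <- opt$v[[key]] %||% (g * 0)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      opt$m[[key]] <- m
      opt$v[[key]] <- v
      mhat <- m / (1 - b1^opt$t)
      vhat <- v / (1 - b2^opt$t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  invisible(model)
}

# Plain (momentum-free) SGD step; the classic optimizer for which the
# regime learning rates 0.1 / 0.001 are standard.
sgd_step <- function(model, lr) {
  for (l in walk_layers(model$layers)) {
    if (l$group %in% model$frozen) next
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      l$params[[nm]] <- l$params[[nm]] - lr * g
    }
  }
  invisible(model)
}

# ---- losses ----------------------------------------------------------------

# Weighted binary cross-entropy on logits; returns loss and d(loss)/d(logit).
bce_loss <- function(logits, y, pos_weight = 1) {
  p <- sigmoid(logits)
  w <- ifelse(y == 1, pos_weight, 1)
  eps <- 1e-12
  loss <- -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / sum(w)
  dlogit <- w * (p - y) / sum(w)
  list(loss = loss, dlogit = dlogit)
}

mse_loss <- function(pred, target) {
  n <- length(pred)
  list(loss = sum((pred - target)^2) / n, dpred = 2 * (pred - target) / n)
}
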