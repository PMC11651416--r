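# Parameter store, layer primitives, and SGD with momentum.
#
# Parameters live in an environment keyed "<layer>.W" / "<layer>.b";
# gradients accumulate in a mirror environment. Feature maps are arrays
# (H, W, C). Convolutions run through the compiled im2col kernels; weight
# matrices are (Cout x k*k*Cin) with (ki, kj, cin) packed fastest-first.

new_param_env <- function() new.env(parent = emptyenv())

param_count <- function(par) {
  sum(vapply(ls(par), function(nm) length(par[[nm]]), numeric(1)))
}

init_conv <- function(par, name, cin, cout, k, bias = 0) {
  fan_in <- cin * k * k
  par[[paste0(name, ".W")]] <- matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)),
                                      cout, fan_in)
  par[[paste0(name, ".b")]] <- rep(bias, cout)
  invisible(par)
}

init_fc <- function(par, name, nin, nout, bias = 0) {
  par[[paste0(name, ".W")]] <- matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
  par[[paste0(name, ".b")]] <- rep(bias, nout)
  invisible(par)
}

acc_grad <- function(gr, name, g) {
  if (is.null(gr[[name]])) gr[[name]] <- g else gr[[name]] <- gr[[name]] + g
  invisible(gr)
}

conv_fwd <- function(par, name, x, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  cpp_conv2d_forward(x, par[[paste0(name, ".W")]], par[[paste0(name, ".b")]],
                     as.integer(k), as.integer(stride), as.integer(pad))
}

conv_bwd <- function(par, gr, name, x, dy, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  r <- cpp_conv2d_backward(x, par[[paste0(name, ".W")]], dy,
                           as.integer(k), as.integer(stride), as.integer(pad))
  acc_grad(gr, paste0(name, ".W"), r$dW)
  acc_grad(gr, paste0(name, ".b"), as.numeric(r$db))
  r$dx
}

fc_fwd <- function(par, name, x) {
  # x: (nin x batch) matrix
  par[[paste0(name, ".W")]] %*% x + par[[paste0(name, ".b")]]
}

fc_bwd <- function(par, gr, name, x, dy) {
  acc_grad(gr, paste0(name, ".W"), dy %*% t(x))
  acc_grad(gr, paste0(name, ".b"), rowSums(dy))
  t(par[[paste0(name, ".W")]]) %*% dy
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(pre, dy) {
  dy[pre <= 0] <- 0
  dy
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

# backward of upsample2: sum each 2x2 block
downsum2 <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1, d[1], by = 2); i2 <- seq(2, d[1], by = 2)
  j1 <- seq(1, d[2], by = 2); j2 <- seq(2, d[2], by = 2)
  dy[i1, j1, , drop = FALSE] + dy[i1, j2, , drop = FALSE] +
    dy[i2, j1, , drop = FALSE] + dy[i2, j2, , drop = FALSE]
}

# stride-2 subsampling (parameter-free extra pyramid level) and its backward
subsample2 <- function(x) {
  d <- dim(x)
  x[seq(1, d[1], by = 2), seq(1, d[2], by = 2), , drop = FALSE]
}

subsample2_bwd <- function(dy, H, W) {
  d <- dim(dy)
  dx <- array(0, dim = c(H, W, d[3]))
  dx[seq(1, H, by = 2), seq(1, W, by = 2), ] <- dy
  dx
}

# per-channel instance normalization (per-sample spatial statistics):
# stabilizes from-scratch small-batch training where batch statistics are
# unavailable. Learnable per-channel gain/shift.
init_in <- function(par, name, C) {
  par[[paste0(name, ".g")]] <- rep(1, C)
  par[[paste0(name, ".b")]] <- rep(0, C)
  invisible(par)
}

in_fwd <- function(par, name, x) {
  d <- dim(x); C <- d[3]
  xm <- matrix(x, ncol = C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  s <- sqrt(colMeans(xc^2) + 1e-5)
  xhat <- sweep(xc, 2, s, "/")
  y <- sweep(sweep(xhat, 2, par[[paste0(name, ".g")]], "*"), 2,
             par[[paste0(name, ".b")]], "+")
  list(y = array(y, dim = d), xhat = xhat, s = s)
}

in_bwd <- function(par, gr, name, cache, dy) {
  d <- dim(dy); C <- d[3]
  dym <- matrix(dy, ncol = C)
  xhat <- cache$xhat
  acc_grad(gr, paste0(name, ".g"), colSums(dym * xhat))
  acc_grad(gr, paste0(name, ".b"), colSums(dym))
  dxh <- sweep(dym, 2, par[[paste0(name, ".g")]], "*")
  dx <- sweep(dxh, 2, colMeans(dxh)) - sweep(xhat, 2, colMeans(dxh * xhat), "*")
  array(sweep(dx, 2, cache$s, "/"), dim = d)
}

zeros_like_env <- function() new.env(parent = emptyenv())

#' @noRd
sgd_step <- function(par, gr, vel, lr, momentum = 0.9, weight_decay = 1e-4,
                     clip_norm = 10) {
  nms <- ls(gr)
  # global gradient-norm clipping for stability
  total <- 0
  for (nm in nms) total <- total + sum(gr[[nm]]^2)
  total <- sqrt(total)
  scale <- if (is.finite(total) && total > clip_norm) clip_norm / total else 1
  for (nm in nms) {
    g <- gr[[nm]] * scale
    if (weight_decay > 0 && endsWith(nm, ".W")) g <- g + weight_decay * par[[nm]]
    v <- vel[[nm]]
    if (is.null(v)) v <- 0 * g
    v <- momentum * v - lr * g
    vel[[nm]] <- v
    par[[nm]] <- par[[nm]] + v
  }
  invisible(total)
}

# greedy hard-NMS over a box matrix, returning kept row indices (score order)
nms_indices <- function(boxes, scores, thr, max_keep = nrow(boxes)) {
  n <- nrow(boxes)
  if (n == 0) return(integer(0))
  M <- cpp_iou_matrix(boxes, boxes)
  ord <- order(-scores, seq_len(n))
  alive <- rep(TRUE, n)
  keep <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    if (length(keep) >= max_keep) break
    alive[M[i, ] > thr] <- FALSE
    alive[i] <- FALSE
  }
  keep
}
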