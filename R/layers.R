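# Minimal reverse-mode layer toolkit for the 3D detector.
#
# A "module" is an environment with fwd(x), bwd(dy) and a param_list()
# returning references to its parameter/gradient slots. Feature tensors are
# R arrays dim c(Z, Y, X, C); the (nvox x C) matrix view used by the C++
# convolution kernels is the same memory (z varies fastest), so reshaping
# is free. Gradients accumulate until zero_grads() is called, which lets a
# batch be processed patch by patch.

as_fmap <- function(x) { if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L); x }

mat_view <- function(x) { d <- dim(x); dim(x) <- c(prod(d[1:3]), d[4]); x }

arr_view <- function(m, sdim) { dim(m) <- c(sdim, ncol(m)); m }

mod_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                     groups = 1L, bias_init = 0, need_dx = TRUE) {
  if (cin %% groups != 0 || cout %% groups != 0)
    stop("channel counts (", cin, ", ", cout, ") not divisible by groups = ", groups)
  self <- new.env(parent = emptyenv())
  fan_in <- k^3 * cin / groups
  self$w <- matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  self$b <- rep(bias_init, cout)
  self$gw <- self$w * 0; self$gb <- self$b * 0
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad); self$groups <- as.integer(groups)
  self$need_dx <- isTRUE(need_dx)
  pointwise <- k == 1L && stride == 1L && groups == 1L
  if (pointwise) {
    # 1x1x1 stride-1: plain matrix product, no im2col needed
    self$fwd <- function(x) {
      x <- as_fmap(x)
      self$in_dim <- dim(x)[1:3]
      self$x_mat <- mat_view(x)
      y <- self$x_mat %*% self$w
      arr_view(y + rep(self$b, each = nrow(y)), self$in_dim)
    }
    self$bwd <- function(dy) {
      dy <- mat_view(as_fmap(dy))
      self$gw <- self$gw + crossprod(self$x_mat, dy)
      self$gb <- self$gb + colSums(dy)
      if (!self$need_dx) return(NULL)
      arr_view(tcrossprod(dy, self$w), self$in_dim)
    }
  } else {
    self$fwd <- function(x) {
      x <- as_fmap(x)
      self$in_dim <- dim(x)[1:3]
      out <- conv3d_fwd_cpp(mat_view(x), self$in_dim, self$w, self$b,
                            self$k, self$stride, self$pad, self$groups,
                            return_col = TRUE)
      self$col <- out$col
      self$out_dim <- out$odims
      arr_view(out$y, out$odims)
    }
    self$bwd <- function(dy) {
      dy <- mat_view(as_fmap(dy))
      g <- conv3d_bwd_cpp(self$col, self$in_dim, self$w, dy,
                          self$k, self$stride, self$pad, self$groups,
                          need_dx = self$need_dx)
      self$gw <- self$gw + g$dW
      self$gb <- self$gb + g$db
      if (!self$need_dx) return(NULL)
      arr_view(g$dx, self$in_dim)
    }
  }
  self$param_list <- function()
    list(list(env = self, value = "w", grad = "gw", conv_weight = TRUE),
         list(env = self, value = "b", grad = "gb", conv_weight = FALSE))
  self
}

# Instance normalisation (per channel over the spatial grid); batch-size
# independent, which suits the single-patch batches used at desk scale.
mod_inorm <- function(C, eps = 1e-5) {
  self <- new.env(parent = emptyenv())
  self$gamma <- rep(1, C); self$beta <- rep(0, C)
  self$ggamma <- rep(0, C); self$gbeta <- rep(0, C)
  self$eps <- eps
  # rep(v, each = n) column-broadcasting avoids sweep()'s aperm copies
  self$fwd <- function(x) {
    x <- as_fmap(x)
    sdim <- dim(x)[1:3]
    xm <- mat_view(x)
    n <- nrow(xm)
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + self$eps)
    xhat <- xc * rep(istd, each = n)
    self$xhat <- xhat; self$istd <- istd; self$sdim <- sdim
    arr_view(xhat * rep(self$gamma, each = n) + rep(self$beta, each = n), sdim)
  }
  self$bwd <- function(dy) {
    dym <- mat_view(as_fmap(dy))
    n <- nrow(dym)
    self$ggamma <- self$ggamma + colSums(dym * self$xhat)
    self$gbeta <- self$gbeta + colSums(dym)
    dxhat <- dym * rep(self$gamma, each = n)
    s1 <- colMeans(dxhat)
    s2 <- colMeans(dxhat * self$xhat)
    dx <- dxhat - rep(s1, each = n) - self$xhat * rep(s2, each = n)
    arr_view(dx * rep(self$istd, each = n), self$sdim)
  }
  self$param_list <- function()
    list(list(env = self, value = "gamma", grad = "ggamma", conv_weight = FALSE),
         list(env = self, value = "beta", grad = "gbeta", conv_weight = FALSE))
  self
}

mod_relu <- function() {
  self <- new.env(parent = emptyenv())
  self$fwd <- function(x) { self$mask <- x > 0; x * self$mask }
  self$bwd <- function(dy) dy * self$mask
  self$param_list <- function() list()
  self
}

mod_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !is.environment(mods[[1]]))
    mods <- mods[[1]]
  self <- new.env(parent = emptyenv())
  self$mods <- mods
  self$fwd <- function(x) { for (m in self$mods) x <- m$fwd(x); x }
  self$bwd <- function(dy) { for (m in rev(self$mods)) dy <- m$bwd(dy); dy }
  self$param_list <- function()
    do.call(c, lapply(self$mods, function(m) m$param_list()))
  self
}

# y = relu(body(x) + x); identity skip (channel counts must match).
mod_residual <- function(body) {
  self <- new.env(parent = emptyenv())
  self$body <- body
  self$fwd <- function(x) {
    s <- self$body$fwd(x) + x
    self$mask <- s > 0
    s * self$mask
  }
  self$bwd <- function(dy) {
    ds <- dy * self$mask
    self$body$bwd(ds) + ds
  }
  self$param_list <- function() self$body$param_list()
  self
}

# Cross-stage-partial wrapper: channels split 50/50; the first half passes
# through `body` (a residual unit on C/2 channels), the second half bypasses
# it; halves are re-concatenated and fused by a 1x1x1 transition.
mod_csp <- function(C, body, transition) {
  if (C %% 2L != 0L) stop("CSP block needs an even channel count, got ", C)
  self <- new.env(parent = emptyenv())
  self$C <- as.integer(C); self$body <- body; self$transition <- transition
  self$fwd <- function(x) {
    h <- self$C %/% 2L
    x1 <- x[, , , seq_len(h), drop = FALSE]
    x2 <- x[, , , h + seq_len(self$C - h), drop = FALSE]
    y1 <- self$body$fwd(x1)
    cat4 <- array(c(y1, x2), dim = c(dim(x)[1:3], self$C))
    self$transition$fwd(cat4)
  }
  self$bwd <- function(dy) {
    h <- self$C %/% 2L
    dcat <- self$transition$bwd(dy)
    dy1 <- dcat[, , , seq_len(h), drop = FALSE]
    dx2 <- dcat[, , , h + seq_len(self$C - h), drop = FALSE]
    dx1 <- self$body$bwd(dy1)
    array(c(dx1, dx2), dim = dim(dcat))
  }
  self$param_list <- function()
    c(self$body$param_list(), self$transition$param_list())
  self
}

# Nearest-neighbour 2x upsampling (FPN top-down path).
mod_upsample2 <- function() {
  self <- new.env(parent = emptyenv())
  self$fwd <- function(x) {
    x <- as_fmap(x)
    d <- dim(x)
    self$in_dim <- d
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
      rep(seq_len(d[3]), each = 2), , drop = FALSE]
  }
  self$bwd <- function(dy) {
    d <- self$in_dim
    dx <- array(0, dim = d)
    for (oz in 1:2) for (oy in 1:2) for (ox in 1:2)
      dx <- dx + dy[seq(oz, 2 * d[1], by = 2), seq(oy, 2 * d[2], by = 2),
                    seq(ox, 2 * d[3], by = 2), , drop = FALSE]
    dx
  }
  self$param_list <- function() list()
  self
}

collect_params <- function(mods) do.call(c, lapply(mods, function(m) m$param_list()))

zero_grads <- function(params) {
  for (p in params) assign(p$grad, get(p$value, envir = p$env) * 0, envir = p$env)
  invisible(NULL)
}

#' Number of trainable parameters of a model
#' @param model a model built by [build_model()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(get(p$value, envir = p$env)), 0))
}
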