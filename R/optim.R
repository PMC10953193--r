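# Ranger optimiser: RAdam with gradient centralization on convolution
# weights, wrapped in Lookahead slow/fast weight averaging. A plain Adam
# mode is kept as a fallback switch.

optim_new <- function(params, lr = 1e-3, optimizer = "ranger",
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      lookahead_k = 6L, lookahead_alpha = 0.5,
                      grad_centralization = TRUE) {
  state <- lapply(params, function(p) {
    v <- get(p$value, envir = p$env)
    list(m = v * 0, v = v * 0, slow = v)
  })
  list(params = params, state = state, lr = lr, optimizer = optimizer,
       beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       lookahead_k = lookahead_k, lookahead_alpha = lookahead_alpha,
       grad_centralization = grad_centralization)
}

optim_step <- function(opt, grad_scale = 1) {
  opt$t <- opt$t + 1L
  t <- opt$t
  b1 <- opt$beta1; b2 <- opt$beta2
  rho_inf <- 2 / (1 - b2) - 1
  rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- get(p$grad, envir = p$env) * grad_scale
    if (opt$grad_centralization && isTRUE(p$conv_weight) && is.matrix(g) &&
        nrow(g) > 1L) {
      # centre the gradient of each output filter (one column per filter)
      g <- sweep(g, 2, colMeans(g))
    }
    st <- opt$state[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g * g
    mhat <- st$m / (1 - b1^t)
    if (opt$optimizer == "ranger" && rho_t <= 4) {
      upd <- opt$lr * mhat                       # RAdam un-adapted warmup step
    } else {
      vhat <- sqrt(st$v / (1 - b2^t))
      r <- if (opt$optimizer == "ranger")
        sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
               ((rho_inf - 4) * (rho_inf - 2) * rho_t))
      else 1
      upd <- opt$lr * r * mhat / (vhat + opt$eps)
    }
    w <- get(p$value, envir = p$env) - upd
    if (opt$optimizer == "ranger" && t %% opt$lookahead_k == 0L) {
      st$slow <- st$slow + opt$lookahead_alpha * (w - st$slow)
      w <- st$slow
    }
    assign(p$value, w, envir = p$env)
    opt$state[[i]] <- st
  }
  opt
}
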