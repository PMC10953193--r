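test_that("head outputs have the contracted shapes and channel count", {
  m <- build_model(tiny_model_config(), seed = 1)
  out <- forward(m, array(runif(64^3), dim = c(64, 64, 64)))
  expect_identical(lapply(out, dim),
                   list(c(32L, 32L, 32L, 15L), c(16L, 16L, 16L, 15L),
                        c(8L, 8L, 8L, 15L)))
  out2 <- forward(m, array(runif(16 * 24 * 32), dim = c(16, 24, 32)))
  expect_identical(dim(out2[[1]]), c(8L, 12L, 16L, 15L))
  expect_identical(dim(out2[[3]]), c(2L, 3L, 4L, 15L))
  expect_error(forward(m, array(0, dim = c(30, 32, 32))), "divisible by 8")
  expect_error(model_config("nonesuch"), "should be one of")
})

test_that("forward is pure, deterministic and finite on degenerate input", {
  m <- build_model(tiny_model_config(), seed = 2)
  zeros <- array(0, dim = c(16, 16, 16))
  o1 <- forward(m, zeros)
  expect_true(all(vapply(o1, function(a) all(is.finite(a)), TRUE)))
  x <- array(runif(16^3), dim = c(16, 16, 16))
  a <- forward(m, x)
  invisible(forward(m, array(runif(16^3), dim = c(16, 16, 16))))
  b <- forward(m, x)
  expect_identical(a, b)                     # no state leaks between calls
})

test_that("backbone variants are interchangeable and CSP cuts parameters", {
  for (variant in c("resnet", "resnext", "csp_resnext")) {
    for (fpn in c(TRUE, FALSE)) {
      m <- build_model(model_config(variant, use_fpn = fpn, base_channels = 4,
                                    cardinality = 4), seed = 3)
      out <- forward(m, array(runif(16^3), dim = c(16, 16, 16)))
      expect_identical(dim(out[[1]]), c(8L, 8L, 8L, 15L))
    }
  }
  n_csp <- n_parameters(build_model(model_config("csp_resnext", TRUE, 8), seed = 1))
  n_next <- n_parameters(build_model(model_config("resnext", TRUE, 8), seed = 1))
  expect_lt(n_csp, n_next)
  # parameter counts are monotone in width for each variant
  for (variant in c("resnet", "resnext", "csp_resnext")) {
    n4 <- n_parameters(build_model(model_config(variant, TRUE, 4), seed = 1))
    n8 <- n_parameters(build_model(model_config(variant, TRUE, 8), seed = 1))
    expect_lt(n4, n8)
  }
})

test_that("the CSP block wires split, residual path, concat and transition", {
  set.seed(4)
  blk <- csp_resnext_block(8L, cardinality = 4L, seed = 5)
  x <- array(rnorm(6 * 6 * 6 * 8), dim = c(6, 6, 6, 8))
  y <- blk$fwd(x)
  expect_identical(dim(y), dim(x))           # spatial shape preserved
  expect_error(csp_resnext_block(7L), "even")

  # zero residual path: block output equals transition(identity, passthrough)
  zero_blk <- csp_resnext_block(8L, cardinality = 4L, seed = 5)
  for (p in zero_blk$body$param_list())
    assign(p$value, get(p$value, envir = p$env) * 0, envir = p$env)
  y0 <- zero_blk$fwd(x)
  # body(x1) = relu(0 + x1) since the residual body collapses to zero
  ref <- zero_blk$transition$fwd(array(c(pmax(x[, , , 1:4], 0), x[, , , 5:8]),
                                       dim = dim(x)))
  expect_equal(y0, ref, tolerance = 1e-12)

  # grouped convolution parameter count matches the closed form
  g <- 4L; cin <- 8L; cout <- 8L; k <- 3L
  conv <- lungrpn:::mod_conv(cin, cout, k, groups = g)
  expect_identical(length(conv$w), as.integer(k^3 * (cin / g) * cout))
})

test_that("every parameter is reachable by gradients from the loss", {
  for (fpn in c(TRUE, FALSE)) {
    m <- build_model(tiny_model_config(fpn = fpn), seed = 6)
    lungrpn:::zero_grads(m$params)
    set.seed(7)
    anchors <- enumerate_anchors(lapply(c(2L, 4L, 8L), function(s) rep(16L, 3) %/% s))
    gts <- data.frame(z = c(5, 11), y = c(5, 10), x = c(6, 12),
                      diameter = c(6, 12))
    asg <- assign_nearest(anchors, gts)
    for (i in 1:3) {
      out <- forward(m, array(runif(16^3), dim = c(16, 16, 16)))
      ls <- detection_loss(out, asg, with_grad = TRUE)
      lungrpn:::backward(m, ls$grad)
    }
    nonzero <- vapply(m$params, function(p)
      any(get(p$grad, envir = p$env) != 0), TRUE)
    expect_true(all(nonzero))
  }
})

test_that("model gradients match finite differences", {
  m <- build_model(tiny_model_config(), seed = 8)
  px <- array(runif(8^3), dim = c(8, 8, 8))
  anchors <- enumerate_anchors(lapply(c(2L, 4L, 8L), function(s) rep(8L, 3) %/% s))
  asg <- assign_nearest(anchors, data.frame(z = 4.2, y = 3.9, x = 4.4,
                                            diameter = 6))
  lossfn <- function() detection_loss(forward(m, px), asg)$total
  lungrpn:::zero_grads(m$params)
  ls <- detection_loss(forward(m, px), asg, with_grad = TRUE)
  lungrpn:::backward(m, ls$grad)
  set.seed(9)
  for (rep in 1:10) {
    pi <- sample(length(m$params), 1)
    pr <- m$params[[pi]]
    w <- get(pr$value, envir = pr$env)
    j <- sample(length(w), 1)
    g <- get(pr$grad, envir = pr$env)[j]
    h <- 1e-5; w0 <- w[j]
    w[j] <- w0 + h; assign(pr$value, w, envir = pr$env); f1 <- lossfn()
    w[j] <- w0 - h; assign(pr$value, w, envir = pr$env); f2 <- lossfn()
    w[j] <- w0; assign(pr$value, w, envir = pr$env)
    fd <- (f1 - f2) / (2 * h)
    expect_lt(abs(fd - g) / max(1e-6, abs(fd) + abs(g)), 1e-4)
  }
})

test_that("checkpoints restore bit-identical inference", {
  m <- build_model(tiny_model_config(), seed = 10)
  # perturb weights away from the build seed so restoration is non-trivial
  for (p in m$params) {
    w <- get(p$value, envir = p$env)
    assign(p$value, w + rnorm(length(w), sd = 0.01), envir = p$env)
  }
  x <- array(runif(16^3), dim = c(16, 16, 16))
  before <- forward(m, x)
  path <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(m, path)
  restored <- load_checkpoint(path)
  expect_identical(forward(restored, x), before)
})
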