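test_that("gradient step obeys its fixed points and the dense recursion", {
  model <- make_gaussian_model(6, 0.5, 3)
  xstar <- rand_image(6, 1)
  y <- forward(model, xstar)
  # zero gradient at the noiseless truth; mu = 0 is the identity
  expect_equal(pgd_step(model, xstar, y, mu = 0.3), xstar, tolerance = 1e-12)
  x0 <- rand_image(6, 2)
  expect_equal(pgd_step(model, x0, y, mu = 0), x0)

  # 50 iterations with identity projector match the explicit dense recursion
  A <- model_dense(model)
  mu <- 1 / svd(A, nu = 0, nv = 0)$d[1]^2
  net <- build_unrolled_net("pgd", 50, dncnn_config(L = 0, width = 2), 6, mu = mu)
  tr <- run_unrolled(net, model, y, identity_projector = TRUE)
  xk <- rep(0, 36)
  yv <- as.vector(y)
  for (k in 1:50) {
    xk <- xk + mu * t(A) %*% (yv - A %*% xk)
    expect_lt(max(abs(as.vector(t(tr$trace[[k]][, , 1])) - xk)), 1e-8)
  }
})

test_that("iterates of gradient descent approach the least-squares solution monotonically", {
  model <- make_gaussian_model(6, 0.5, 7)
  xstar <- rand_image(6, 9)
  y <- forward(model, xstar)
  A <- model_dense(model)
  # minimum-norm least-squares solution (iterates start at 0, stay in row space)
  xls <- t(A) %*% solve(A %*% t(A), as.vector(y))
  mu <- 1 / svd(A, nu = 0, nv = 0)$d[1]^2
  net <- build_unrolled_net("pgd", 40, dncnn_config(L = 0, width = 2), 6, mu = mu)
  tr <- run_unrolled(net, model, y, identity_projector = TRUE)
  dist <- vapply(tr$trace, function(x) sqrt(sum((as.vector(t(x[, , 1])) - xls)^2)), 0)
  expect_true(all(diff(dist) <= 1e-12))
  expect_true(all(diff(per_step_psnr(lapply(tr$trace, function(x) x[, , 1]),
                                     demun:::vec_to_img(xls, 6))) >= -1e-9))
})

test_that("memory coefficients validate their triangular structure", {
  expect_s3_class(pgd_coefficients(4, 0.5), "memory_coefficients")
  expect_error(memory_coefficients(c(1, 1), list(1)), class = "demun_config_error")
  expect_error(memory_coefficients(c(1, 1), list(1, c(1, 2, 3))),
               class = "demun_state_error")
  cf <- pgd_coefficients(6, 0.3)
  expect_equal(sum(lengths(cf$beta)), 6 * 7 / 2)
  expect_equal(cf$beta[[4]], c(0, 0, 0, 0.3))
})

test_that("the memory step generalizes gradient descent exactly", {
  set.seed(31)
  for (inst in 1:20) {
    model <- make_gaussian_model(6, 0.5, 100 + inst)
    y <- forward(model, matrix(runif(36), 6))
    mu <- runif(1, 0.05, 0.3)
    np <- build_unrolled_net("pgd", 6, dncnn_config(L = 0, width = 2), 6, mu = mu)
    nd <- build_unrolled_net("demun", 6, dncnn_config(L = 0, width = 2), 6, mu = mu)
    tp <- run_unrolled(np, model, y, identity_projector = TRUE)
    td <- run_unrolled(nd, model, y, identity_projector = TRUE)
    worst <- max(vapply(1:6, function(s) max(abs(tp$trace[[s]] - td$trace[[s]])), 0))
    expect_lt(worst, 1e-9)
  }
})

test_that("the first memory step is beta_00 A'y and both evaluation paths agree", {
  model <- make_gaussian_model(5, 0.4, 2)
  y <- forward(model, rand_image(5, 3))
  cf <- memory_coefficients(runif(1, 0.2, 2), list(0.7))
  x0 <- array(0, c(5, 5, 1))
  g0 <- adjoint(model, y)
  xt <- demun_step(model, x0, list(g0), cf, step = 1)
  expect_equal(xt, 0.7 * g0, tolerance = 1e-12)

  # channel-stacked 1x1-convolution path equals term-by-term summation
  set.seed(12)
  model <- make_gaussian_model(6, 0.5, 5)
  cf6 <- memory_coefficients(rnorm(6), lapply(1:6, rnorm))
  x <- array(rnorm(36 * 3), c(6, 6, 3))
  gs <- lapply(1:6, function(j) array(rnorm(36 * 3), c(6, 6, 3)))
  direct <- demun_step(model, x, gs, cf6, step = 6)
  conv <- demun_step(model, x, gs, cf6, step = 6, as_conv1x1 = TRUE)
  expect_lt(max(abs(direct - conv)), 1e-9)

  expect_error(demun_step(model, x, gs[1:3], cf6, step = 6),
               class = "demun_state_error")
})

test_that("nesterov reduces to gradient descent without momentum and matches the textbook recursion", {
  model <- make_gaussian_model(6, 0.5, 13)
  xstar <- rand_image(6, 6)
  y <- forward(model, xstar)
  x <- rand_image(6, 7)
  expect_equal(nesterov_step(model, x, y, mu = 0.1, gamma = 0),
               pgd_step(model, x, y, mu = 0.1), tolerance = 1e-14)

  # independent reference recursion with explicit matrices
  A <- model_dense(model)
  mu <- 1 / svd(A, nu = 0, nv = 0)$d[1]^2
  T <- 12
  net <- build_unrolled_net("nesterov", T, dncnn_config(L = 0, width = 2), 6, mu = mu)
  tr <- run_unrolled(net, model, y, identity_projector = TRUE)
  tt <- 1; xk <- rep(0, 36); xprev <- xk
  yv <- as.vector(y)
  for (k in 1:T) {
    tn <- (1 + sqrt(1 + 4 * tt^2)) / 2
    gam <- if (k == 1) 0 else (tt - 1) / tn
    tt <- tn
    z <- xk + gam * (xk - xprev)
    xnew <- z + mu * t(A) %*% (yv - A %*% z)
    xprev <- xk; xk <- as.vector(xnew)
    expect_lt(max(abs(as.vector(t(tr$trace[[k]][, , 1])) - xk)), 1e-10)
  }
})

test_that("memory coefficients can replay a nesterov trace exactly", {
  model <- make_gaussian_model(6, 0.5, 17)
  y <- forward(model, rand_image(6, 8))
  mu <- stable_step_size(model)
  T <- 6
  net <- build_unrolled_net("nesterov", T, dncnn_config(L = 0, width = 2), 6, mu = mu)
  ref <- run_unrolled(net, model, y, keep_pre = TRUE, identity_projector = TRUE)
  fit <- match_memory_coefficients(model, as.vector(y),
                                   lapply(ref$pre, function(p) p[, , 1]))
  expect_lt(max(fit$residuals), 1e-8)
  # replaying the fitted coefficients reproduces the trace
  nd <- build_unrolled_net("demun", T, dncnn_config(L = 0, width = 2), 6)
  nd$scheme_params$alpha <- fit$coeffs$alpha
  nd$scheme_params$beta <- fit$coeffs$beta
  td <- run_unrolled(nd, model, y, identity_projector = TRUE)
  worst <- max(vapply(1:T, function(s) max(abs(td$trace[[s]] - ref$trace[[s]])), 0))
  expect_lt(worst, 1e-8)
})

test_that("amp reduces to a unit gradient step without the Onsager term", {
  model <- make_gaussian_model(6, 0.5, 19)
  y <- as.vector(forward(model, rand_image(6, 4)))
  x <- runif(36)
  st <- amp_step(model, x, y, z_prev = NULL, divergence = 0)
  ref <- pgd_step(model, demun:::vec_to_img(x, 6), matrix(y, ncol = 1), mu = 1)
  expect_equal(demun:::vec_to_img(st$xt, 6), ref, tolerance = 1e-12)
  expect_warning(amp_step(make_dct_model(6, 0.5, seed = 1), x, y), "Gaussian")
})

test_that("amp with a soft-threshold denoiser recovers a sparse signal", {
  set.seed(7)
  model <- make_gaussian_model(16, 0.5, seed = 21)       # n = 256, m = 128
  x0 <- numeric(256); x0[sample(256, 10)] <- rnorm(10)   # k = 10
  y <- as.vector(forward(model, x0))
  rec <- amp_recover(model, y, soft_threshold_denoiser(2.5), iters = 30,
                     probes = 1, seed = 3)
  nmse_db <- 10 * log10(sum((rec$x - x0)^2) / sum(x0^2))
  expect_lt(nmse_db, -30)
  # noise track decreases
  expect_lt(rec$tau[30], rec$tau[1])
})

test_that("the divergence probe is exact for linear denoisers", {
  set.seed(5)
  v <- rnorm(256)
  for (cc in c(0.3, 0.7, 1.5)) {
    est <- mc_divergence(function(u) cc * u, v, m = 128, probes = 10, seed = 2)
    expect_equal(est, cc * 256 / 128, tolerance = 0.02 * cc * 2)
  }
  # single probe stays within 2% as well (Rademacher probes are exact here)
  est1 <- mc_divergence(function(u) 0.5 * u, v, m = 128, probes = 1, seed = 4)
  expect_equal(est1, 1, tolerance = 0.02)
})

test_that("run_unrolled composes forced cases and is deterministic", {
  model <- make_gaussian_model(6, 0.5, 23)
  y <- forward(model, rand_image(6, 5))
  pc <- dncnn_config(L = 1, width = 3, residual = TRUE)
  net <- build_unrolled_net("demun", 1, pc, 6, mu = 0.4, seed = 2)
  net <- zero_output_projector(net)
  tr <- run_unrolled(net, model, y)
  expect_equal(tr$trace[[1]][, , 1], 0.4 * adjoint(model, y)[, , 1],
               tolerance = 1e-12)

  # determinism: identical nets and inputs give bit-identical traces
  net2 <- build_unrolled_net("demun", 3, pc, 6, mu = 0.4, seed = 2)
  t1 <- run_unrolled(net2, model, y)
  t2 <- run_unrolled(net2, model, y)
  expect_identical(t1$trace, t2$trace)

  # noiseless fixed point: at x = x* with an identity projection every
  # scheme's gradient step returns x*
  xstar <- rand_image(6, 30)
  ystar <- forward(model, xstar)
  expect_equal(pgd_step(model, xstar, ystar, 0.3), xstar, tolerance = 1e-12)
  expect_equal(nesterov_step(model, xstar, ystar, 0.3, 0.5, xstar), xstar,
               tolerance = 1e-12)
  g <- adjoint(model, ystar - forward(model, xstar))
  expect_equal(demun_step(model, xstar, list(g), pgd_coefficients(1, 0.3), 1),
               xstar, tolerance = 1e-12)

  expect_error(build_unrolled_net("demun", 0, pc, 6), class = "demun_config_error")
})
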