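test_that("gaussian operator has the stated shape, distribution and determinism", {
  m <- make_gaussian_model(side = 50, sampling_rate = 0.1, seed = 1)
  expect_equal(dim(model_dense(m)), c(250L, 2500L))

  # entry variance 1/m within a 4-standard-error band (pooled over seeds)
  side <- 8; rate <- 0.5
  ent <- unlist(lapply(1:50, function(s) model_dense(make_gaussian_model(side, rate, s))))
  mm <- round(rate * side^2)
  se <- (1 / mm) * sqrt(2 / (length(ent) - 1))
  expect_lt(abs(var(ent) - 1 / mm), 4 * se)

  # same seed -> identical matrix; different seed -> different
  expect_identical(model_dense(make_gaussian_model(8, 0.5, 7)),
                   model_dense(make_gaussian_model(8, 0.5, 7)))
  expect_false(identical(model_dense(make_gaussian_model(8, 0.5, 7)),
                         model_dense(make_gaussian_model(8, 0.5, 8))))

  # column energy: E||A e_j||^2 = 1 (Monte-Carlo over seeds)
  cn <- vapply(1:200, function(s) {
    mean(colSums(model_dense(make_gaussian_model(4, 1.0, s))^2))
  }, 0)
  expect_lt(abs(mean(cn) - 1), 0.02)

  expect_error(make_gaussian_model(8, 0), class = "demun_config_error")
  expect_error(make_gaussian_model(8, 1.2), class = "demun_config_error")
})

test_that("dct operator rows are orthonormal and match the dense oracle", {
  # full transform: A A' = A' A = I
  full <- model_dense(make_dct_model(4, 1.0, seed = 1))
  expect_lt(max(abs(full %*% t(full) - diag(16))), 1e-10)
  expect_lt(max(abs(t(full) %*% full - diag(16))), 1e-10)

  # any rate / pattern: A A' = I
  for (rate in c(0.1, 0.25, 0.5, 0.75, 1.0)) {
    for (pat in c("uniform-random-rows", "low-frequency-first")) {
      md <- make_dct_model(8, rate, pattern = pat, seed = 3)
      A <- model_dense(md)
      expect_lt(max(abs(A %*% t(A) - diag(md$m))), 1e-10)
    }
  }

  # matrix-free forward/adjoint equal dense products
  md <- make_dct_model(8, 0.5, "uniform-random-rows", seed = 5)
  A <- model_dense(md)
  x <- rand_image(8, 11)
  r <- rnorm(md$m)
  xv <- as.vector(t(x))                                # row-major vec
  expect_lt(max(abs(forward(md, x) - A %*% xv)), 1e-8)
  adj <- adjoint(md, r)[, , 1]
  expect_lt(max(abs(as.vector(t(adj)) - t(A) %*% r)), 1e-8)
  ata <- adjoint(md, forward(md, x))[, , 1]
  expect_lt(max(abs(as.vector(t(ata)) - t(A) %*% (A %*% xv))), 1e-8)

  # low-frequency-first starts at the DC row
  lf <- make_dct_model(8, 0.25, "low-frequency-first", seed = 1)
  expect_equal(lf$rows[1], 1L)
})

test_that("forward/adjoint satisfy the adjoint identity and shape contracts", {
  for (maker in list(function(s) make_gaussian_model(6, 0.3, s),
                     function(s) make_dct_model(6, 0.3, seed = s))) {
    set.seed(99)
    for (i in 1:100) {
      mk <- maker(i %% 7 + 1)
      x <- matrix(rnorm(36), 6)
      r <- rnorm(mk$m)
      expect_lt(abs(sum(forward(mk, x) * r) - sum(x * adjoint(mk, r)[, , 1])), 1e-8)
    }
  }
  mg <- make_gaussian_model(6, 0.3, 1)
  expect_equal(as.vector(forward(mg, matrix(0, 6, 6))), rep(0, mg$m))
  expect_error(adjoint(mg, rnorm(mg$m + 1)), class = "demun_shape_error")
  expect_error(forward(mg, matrix(0, 5, 5)), class = "demun_shape_error")
})

test_that("additive noise is seeded, exact at sigma 0, and correctly scaled", {
  y <- rnorm(100)
  expect_identical(add_noise(y, noise_spec(0, seed = 1)), y)
  yn1 <- add_noise(y, noise_spec(0.05, seed = 3))
  yn2 <- add_noise(y, noise_spec(0.05, seed = 3))
  expect_identical(yn1, yn2)

  # chi-square band on the sample sd at m = 1e4
  big <- numeric(1e4)
  w <- add_noise(big, noise_spec(0.05, seed = 9)) - big
  expect_gt(sd(w), 0.0485)
  expect_lt(sd(w), 0.0515)

  # the study's noise grid is accepted
  for (s in c(0.01, 0.025, 0.05, 0.10)) expect_s3_class(noise_spec(s), "noise_spec")
  expect_error(noise_spec(-0.1), class = "demun_config_error")
})

test_that("input SNR follows its definition and the 6 dB scaling law", {
  mg <- make_gaussian_model(8, 0.25, seed = 2)
  imgs <- rand_batch(8, 10, 21)

  # direct two-line recomputation
  sig <- 0.05
  y <- forward(mg, imgs)
  expect_equal(input_snr_db(mg, imgs, noise_spec(sig)),
               10 * log10(mean(colSums(y^2)) / (mg$m * sig^2)))

  # doubling sigma costs exactly 20 log10(2) dB
  expect_equal(input_snr_db(mg, imgs, noise_spec(0.05)) -
                 input_snr_db(mg, imgs, noise_spec(0.10)),
               20 * log10(2), tolerance = 1e-12)

  # a signal with ||Ax||^2 = m sigma^2 sits at 0 dB
  x <- rand_image(8, 5)
  e <- sqrt(sum(forward(mg, x)^2) / (mg$m * sig^2))
  expect_equal(input_snr_db(mg, x / e, noise_spec(sig)), 0, tolerance = 1e-10)

  expect_error(input_snr_db(mg, imgs, noise_spec(0)), class = "demun_undefined_snr")
})

test_that("operator norm and stable step size are exact for the DCT kind", {
  md <- make_dct_model(8, 0.5, seed = 1)
  expect_equal(operator_norm_sq(md), 1)
  mg <- make_gaussian_model(8, 0.5, seed = 1)
  smax2 <- svd(model_dense(mg), nu = 0, nv = 0)$d[1]^2
  expect_equal(operator_norm_sq(mg), smax2, tolerance = 1e-6)
  expect_equal(stable_step_size(mg), 1 / smax2, tolerance = 1e-6)
})
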