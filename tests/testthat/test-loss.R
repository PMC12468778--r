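test_that("last-layer loss is the pixel-sum squared error of the final step", {
  tr <- rand_trace(4, 3, 1)
  xstar <- tr[[4]]
  expect_equal(last_layer_loss(tr, xstar), 0)
  expect_equal(last_layer_loss(lapply(tr, function(x) xstar + 1), xstar), 9)
  # 2-line oracle on a random pair
  set.seed(2)
  a <- matrix(rnorm(9), 3); b <- matrix(rnorm(9), 3)
  expect_equal(last_layer_loss(list(a), b), sum((a - b)^2))
  expect_error(last_layer_loss(list(matrix(0, 2, 2)), matrix(0, 3, 3)),
               class = "demun_shape_error")
})

test_that("weighted intermediate loss interpolates between equal weights and last-layer", {
  # hand-evaluated: T=3, omega=0.5, per-step errors (4, 2, 1)
  side <- 2
  xstar <- matrix(0, side, side)
  mk <- function(err) matrix(sqrt(err / side^2), side, side)
  tr <- list(mk(4), mk(2), mk(1))
  expect_equal(weighted_intermediate_loss(tr, xstar, omega = 0.5), 3.0)

  # omega = 1: plain sum of per-step losses
  tr2 <- rand_trace(5, 4, 3)
  xs <- matrix(0.3, 4, 4)
  expect_equal(weighted_intermediate_loss(tr2, xs, 1),
               sum(vapply(tr2, function(x) sum((x - xs)^2), 0)))

  # omega -> 0 approaches the last-layer loss, bounded by omega * sum of
  # intermediate errors
  om <- 1e-6
  gap <- weighted_intermediate_loss(tr2, xs, om) - last_layer_loss(tr2, xs)
  bound <- om * sum(vapply(tr2[-5], function(x) sum((x - xs)^2), 0))
  expect_gte(gap, 0)
  expect_lte(gap, bound * (1 + 1e-12))

  expect_error(weighted_intermediate_loss(tr2, xs, 0), class = "demun_config_error")
  expect_error(weighted_intermediate_loss(tr2, xs, 1.5), class = "demun_config_error")
})

test_that("skip-layer loss supervises every skip-th step counting back from T", {
  expect_equal(skip_loss_steps(15, 3), c(3L, 6L, 9L, 12L, 15L))
  expect_equal(skip_loss_steps(6, 6), 6L)
  expect_error(skip_loss_steps(15, 4), class = "demun_config_error")

  tr <- rand_trace(15, 3, 7)
  xs <- matrix(0, 3, 3)
  manual <- sum(vapply(c(3, 6, 9, 12, 15), function(i) sum((tr[[i]] - xs)^2), 0))
  expect_equal(skip_layer_loss(tr, xs, 3), manual)
})

test_that("loss-family identities hold on random traces", {
  set.seed(42)
  for (rep in 1:100) {
    T <- sample(2:8, 1)
    tr <- rand_trace(T, 3, rep)
    xs <- matrix(rnorm(9), 3)
    # l_{s,1} == l_{i,1}
    expect_equal(skip_layer_loss(tr, xs, 1),
                 weighted_intermediate_loss(tr, xs, 1), tolerance = 1e-12)
    # l_{s,T} == l_ll
    expect_equal(skip_layer_loss(tr, xs, T), last_layer_loss(tr, xs),
                 tolerance = 1e-12)
    # l_{i,w} - l_ll = sum_{i<T} w^(T-i) ||x_i - x*||^2 exactly
    om <- runif(1, 0.05, 1)
    gap <- weighted_intermediate_loss(tr, xs, om) - last_layer_loss(tr, xs)
    direct <- sum(vapply(seq_len(T - 1),
                         function(i) om^(T - i) * sum((tr[[i]] - xs)^2), 0))
    expect_equal(gap, direct, tolerance = 1e-10)
  }
})

test_that("the intermediate loss is non-decreasing in omega for a fixed trace", {
  tr <- rand_trace(6, 4, 9)
  xs <- matrix(0, 4, 4)
  vals <- vapply(c(0.01, 0.1, 0.25, 0.5, 0.75, 0.95, 1),
                 function(om) weighted_intermediate_loss(tr, xs, om), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("loss specs validate and the preset grid matches the ablation study", {
  expect_error(loss_spec("weighted_intermediate", omega = 0), class = "demun_config_error")
  expect_error(loss_spec("skip_L", skip = 4, T = 15), class = "demun_config_error")
  grid <- loss_preset_grid(T = 30)
  omegas <- vapply(grid[grepl("^li_", names(grid))], function(s) s$omega, 0)
  expect_setequal(unname(omegas), c(1, 0.95, 0.85, 0.75, 0.5, 0.25, 0.1, 0.01))
  expect_equal(grid$ls_5$skip, 5L)
  expect_equal(grid$lll$family, "last_layer")

  # loss_weights agrees with the direct evaluations
  tr <- rand_trace(6, 3, 4)
  xs <- matrix(0, 3, 3)
  for (spec in list(loss_spec("last_layer"),
                    loss_spec("weighted_intermediate", omega = 0.7),
                    loss_spec("skip_L", skip = 2, T = 6))) {
    w <- demun:::loss_weights(spec, 6)
    expect_equal(sum(w * vapply(tr, function(x) sum((x - xs)^2), 0)),
                 trace_loss(spec, tr, xs), tolerance = 1e-12)
  }
})
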