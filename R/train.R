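# End-to-end training of unrolled networks.
#
# Measurement/image pairs are generated on the fly from the training images
# and the experiment's fixed operator instance; if sigma > 0, every batch
# draws fresh noise. The configured loss supervises the trace with per-step
# weights w_i (see loss_weights); per-image losses are pixel sums, reduced by
# the batch mean. Optimization is Adam over all projector weights plus the
# scheme's scalar parameters.

# Collect trainable parameters of a network into one nested list.
net_params <- function(net) {
  list(proj = lapply(net$projectors, function(p) p$params),
       scheme = net$scheme_params)
}

net_set_params <- function(net, params) {
  for (i in seq_along(net$projectors)) {
    net$projectors[[i]]$params <- params$proj[[i]]
  }
  net$scheme_params <- params$scheme
  net
}

# Compute loss value and full gradient for one batch (used by the trainer and
# by the finite-difference gradient tests).
net_loss_and_grads <- function(net, model, xstar, y, weights, training = TRUE) {
  N <- dim(xstar)[3L]
  fw <- unrolled_fwd(net, model, y, training = training, keep_cache = TRUE)
  loss <- 0
  dTrace <- vector("list", net$T)
  for (s in seq_len(net$T)) {
    diff <- fw$trace[[s]] - xstar
    loss <- loss + weights[s] * sum(diff^2) / N
    dTrace[[s]] <- 2 * weights[s] * diff / N
  }
  bw <- unrolled_bwd(net, model, fw, dTrace)
  list(loss = loss, grads = list(proj = bw$proj_grads, scheme = bw$scheme_grads),
       net = fw$net)
}

#' Train an unrolled network
#'
#' @param net an `unrolled_net` (see [build_unrolled_net()]).
#' @param model the fixed `measurement_model` for this experiment.
#' @param train_set an `image_set` at the network's resolution.
#' @param spec a `loss_spec`.
#' @param epochs number of passes over the training set.
#' @param batch_size images per gradient step.
#' @param lr Adam learning rate.
#' @param sigma measurement-noise standard deviation during training (fresh
#'   draws every batch when > 0).
#' @param seed integer seed governing shuffling and noise draws.
#' @param verbose print one line per epoch.
#' @return List with `net` (trained network) and `log` (data.frame of
#'   per-epoch mean batch loss).
#' @export
train_unrolled <- function(net, model, train_set, spec, epochs = 15L,
                           batch_size = 16L, lr = 1e-3, sigma = 0,
                           seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "unrolled_net"), inherits(model, "measurement_model"),
            inherits(train_set, "image_set"), inherits(spec, "loss_spec"))
  if (train_set$side != net$side) {
    stop_shape("training images", net$side, train_set$side)
  }
  weights <- loss_weights(spec, net$T)
  params <- net_params(net)
  opt <- adam_init(params)
  nimg <- train_set$count
  losses <- numeric(epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    order_ep <- with_seed(seed + 1000L * ep, sample.int(nimg))
    batch_losses <- c()
    for (b0 in seq(1L, nimg, by = batch_size)) {
      idx <- order_ep[b0:min(b0 + batch_size - 1L, nimg)]
      xstar <- train_set$images[, , idx, drop = FALSE]
      y <- forward(model, xstar)
      if (sigma > 0) {
        step <- step + 1L
        y <- add_noise(y, noise_spec(sigma, seed = seed + 100000L + step))
      }
      lg <- net_loss_and_grads(net, model, xstar, y, weights, training = TRUE)
      if (!is.finite(lg$loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; last finite epoch losses: ",
             paste(signif(losses[seq_len(ep - 1)], 4), collapse = ", "))
      }
      net <- lg$net                     # BN running statistics advance
      upd <- adam_step(params, lg$grads, opt, lr = lr)
      params <- upd$params
      opt <- upd$state
      net <- net_set_params(net, params)
      batch_losses <- c(batch_losses, lg$loss)
    }
    losses[ep] <- mean(batch_losses)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f", ep, losses[ep]))
    }
  }
  list(net = net, log = data.frame(epoch = seq_len(epochs), loss = losses))
}

#' Evaluate a network on a test set
#'
#' Measurements are built with the same operator instance used in training
#' (one fixed seeded noise draw per evaluation when `sigma > 0`); the
#' projectors run in inference mode (BN running statistics).
#'
#' @param net a trained `unrolled_net`.
#' @param model the experiment's `measurement_model`.
#' @param test_set an `image_set`.
#' @param sigma test-time noise standard deviation.
#' @param seed integer seed for the test noise draw.
#' @param config label stored in the records (config fingerprint).
#' @return List with `records` (data.frame: per-image `psnr`, `ssim`),
#'   `per_step_psnr` (T-vector averaged over images) and `trace` of the last
#'   batch.
#' @export
evaluate_unrolled <- function(net, model, test_set, sigma = 0, seed = 1L,
                              config = "default") {
  stopifnot(inherits(net, "unrolled_net"), inherits(test_set, "image_set"))
  if (test_set$side != net$side) stop_shape("test images", net$side, test_set$side)
  xstar <- test_set$images
  y <- forward(model, xstar)
  if (sigma > 0) y <- add_noise(y, noise_spec(sigma, seed = seed))
  tr <- run_unrolled(net, model, y)
  N <- test_set$count
  ps <- vapply(seq_len(N), function(t) psnr(tr$trace[[net$T]][, , t], xstar[, , t]), 0)
  ss <- if (test_set$side >= 11) {
    vapply(seq_len(N), function(t) ssim(tr$trace[[net$T]][, , t], xstar[, , t]), 0)
  } else {
    rep(NA_real_, N)
  }
  step_psnr <- vapply(seq_len(net$T), function(s) {
    mean(vapply(seq_len(N), function(t) psnr(tr$trace[[s]][, , t], xstar[, , t]), 0))
  }, 0)
  list(records = data.frame(image = seq_len(N), psnr = ps, ssim = ss,
                            config = config, stringsAsFactors = FALSE),
       per_step_psnr = step_psnr,
       trace = tr)
}

#' PSNR of the adjoint (back-projection) baseline
#'
#' The learning-free estimate `x = A' y`, the input every unrolled scheme
#' starts from after one unit gradient step at zero.
#'
#' @param model a `measurement_model`.
#' @param test_set an `image_set`.
#' @param sigma optional noise level; `seed` its draw.
#' @param seed integer seed.
#' @return Mean PSNR (dB) over the set.
#' @export
adjoint_baseline_psnr <- function(model, test_set, sigma = 0, seed = 1L) {
  y <- forward(model, test_set$images)
  if (sigma > 0) y <- add_noise(y, noise_spec(sigma, seed = seed))
  bp <- adjoint(model, y)
  mean(vapply(seq_len(test_set$count),
              function(t) psnr(bp[, , t], test_set$images[, , t]), 0))
}
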