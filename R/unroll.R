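# Iteration engines producing reconstruction traces.
#
# All schemes share the template: from the current estimate form a
# pre-projection state x~ (a gradient-type step), then apply the projector.
# Steps are 1-indexed here: step s maps x_{s-1} to x_s, with x_0 = 0, and the
# gradient at iterate j is g_j = A'(y - A x_j) (stored as g[[j + 1]]).
#
# The deep-memory update generalizes them all:
#     x~_{s-1} = alpha_s x_{s-1} + sum_{j=1..s} beta_s[j] g_{j-1},
# with every alpha and beta trainable. Fixing alpha = 1, beta_s = (0,...,0,mu)
# recovers plain gradient descent with step size mu.

#' Memory coefficients for the deep-memory scheme
#'
#' @param alpha numeric vector of length `T`: weight on the current iterate at
#'   each step.
#' @param beta list of length `T`; `beta[[s]]` has length `s` and weighs the
#'   stored gradients `g_0 ... g_{s-1}` at step `s`.
#' @return A `memory_coefficients` object.
#' @export
memory_coefficients <- function(alpha, beta) {
  T <- length(alpha)
  if (length(beta) != T) stop_config("beta must have one entry per step")
  for (s in seq_len(T)) {
    if (length(beta[[s]]) != s) {
      stop(errorCondition(
        sprintf("beta[[%d]] must have length %d (one weight per stored gradient)", s, s),
        class = c("demun_state_error", "error")))
    }
  }
  structure(list(alpha = as.numeric(alpha), beta = lapply(beta, as.numeric), T = T),
            class = "memory_coefficients")
}

#' The fixed-coefficient view recovering projected gradient descent
#'
#' `alpha_s = 1`, `beta_s = (0, ..., 0, mu)`: only the current gradient is
#' used, with step size `mu`.
#'
#' @param T number of steps.
#' @param mu step size.
#' @return A `memory_coefficients` object.
#' @export
pgd_coefficients <- function(T, mu = 1) {
  memory_coefficients(rep(1, T),
                      lapply(seq_len(T), function(s) c(rep(0, s - 1), mu)))
}

#' Nesterov momentum schedule
#'
#' The canonical accelerated schedule `gamma_s = (t_{s-1} - 1) / t_s` with
#' `t_0 = 1`, `t_s = (1 + sqrt(1 + 4 t_{s-1}^2)) / 2`; the first step has no
#' momentum.
#'
#' @param T number of steps.
#' @return Numeric vector `gamma_1 ... gamma_T` (first entry 0).
#' @export
nesterov_gamma_schedule <- function(T) {
  tt <- 1
  gam <- numeric(T)
  for (s in seq_len(T)) {
    tn <- (1 + sqrt(1 + 4 * tt^2)) / 2
    gam[s] <- if (s == 1) 0 else (tt - 1) / tn
    tt <- tn
  }
  gam
}

#' One gradient-descent step
#'
#' `x~ = x + mu A'(y - A x)`.
#'
#' @param model a `measurement_model`.
#' @param x current estimate (matrix or batch).
#' @param y measurements (`m x N`).
#' @param mu step size.
#' @return Pre-projection state, same shape as `x`.
#' @export
pgd_step <- function(model, x, y, mu) {
  arr <- as_image_batch(x, model$side)
  out <- arr + mu * adjoint(model, y - forward(model, arr))
  if (is.matrix(x)) out[, , 1L] else out
}

#' One deep-memory step
#'
#' `x~ = alpha_s x + sum_j beta_s[j] g_{j-1}` over the full gradient history.
#' Equivalently (and bit-comparably, see `as_conv1x1`), a one-by-one
#' convolution over the channel stack `[x, g_0, ..., g_{s-1}]`.
#'
#' @param model a `measurement_model`.
#' @param x current estimate `x_{s-1}` (matrix or batch).
#' @param grads list of gradient images `g_0 ... g_{s-1}` (same shape as `x`).
#' @param coeffs a `memory_coefficients` object.
#' @param step step index `s` in `1..T`.
#' @param as_conv1x1 evaluate via an explicit 1x1 convolution over the channel
#'   stack instead of the term-by-term sum (identical result; used to check
#'   the convolutional view).
#' @return Pre-projection state.
#' @export
demun_step <- function(model, x, grads, coeffs, step, as_conv1x1 = FALSE) {
  stopifnot(inherits(coeffs, "memory_coefficients"))
  if (length(grads) != step) {
    stop(errorCondition(
      sprintf("gradient history has %d entries, step %d needs %d",
              length(grads), step, step),
      class = c("demun_state_error", "error")))
  }
  single <- is.matrix(x)
  arr <- as_image_batch(x, model$side)
  w <- c(coeffs$alpha[step], coeffs$beta[[step]])
  if (as_conv1x1) {
    # stack channels (side, side, N, C) and contract with the 1x1 kernel w
    stack <- c(list(arr), lapply(grads, as_image_batch, side = model$side))
    d <- dim(arr)
    flat <- vapply(stack, as.vector, numeric(prod(d)))   # (side*side*N) x C
    out <- array(flat %*% w, dim = d)
  } else {
    out <- coeffs$alpha[step] * arr
    for (j in seq_len(step)) {
      out <- out + coeffs$beta[[step]][j] * as_image_batch(grads[[j]], model$side)
    }
  }
  if (single) out[, , 1L] else out
}

#' One Nesterov-accelerated step
#'
#' `z = x + gamma (x - x_prev)` followed by a gradient step at `z`.
#'
#' @param model a `measurement_model`.
#' @param x current estimate; `x_prev` the previous one (used by momentum).
#' @param y measurements.
#' @param mu step size.
#' @param gamma momentum weight for this step.
#' @param x_prev previous estimate (defaults to `x`, i.e. no momentum).
#' @return Pre-projection state.
#' @export
nesterov_step <- function(model, x, y, mu, gamma, x_prev = x) {
  single <- is.matrix(x)
  xa <- as_image_batch(x, model$side)
  pa <- as_image_batch(x_prev, model$side)
  z <- xa + gamma * (xa - pa)
  out <- z + mu * adjoint(model, y - forward(model, z))
  if (single) out[, , 1L] else out
}

# ---- approximate message passing -------------------------------------------

#' Hutchinson divergence estimate of a denoiser
#'
#' Estimates `(1/m) sum_i d eta_i / d v_i` with Rademacher probes:
#' `mean_p <eps_p, (eta(v + delta eps_p) - eta(v)) / delta> / m`. For a linear
#' denoiser `eta(v) = c v` the estimate equals `c n / m` exactly, any probe
#' count.
#'
#' @param denoiser function of a numeric vector returning a vector.
#' @param v evaluation point.
#' @param m normalizer (number of measurements).
#' @param probes number of Rademacher probes.
#' @param delta probe step (default scaled to the signal).
#' @param seed integer seed for the probes.
#' @return Scalar divergence estimate (normalized by `m`).
#' @export
mc_divergence <- function(denoiser, v, m, probes = 1L, delta = NULL, seed = 1L) {
  n <- length(v)
  if (is.null(delta)) delta <- max(abs(v)) / 1000 + 1e-12
  base <- denoiser(v)
  with_seed(seed, {
    est <- vapply(seq_len(probes), function(p) {
      eps <- sample(c(-1, 1), n, replace = TRUE)
      sum(eps * (denoiser(v + delta * eps) - base)) / delta
    }, 0)
    mean(est) / m
  })
}

#' Soft-threshold denoiser factory
#'
#' Returns `eta(v, tau) = sign(v) max(|v| - lambda tau, 0)`, the proximal
#' operator of the l1 norm with data-adaptive threshold `lambda tau`, where
#' `tau` is the working noise estimate supplied by the AMP driver.
#'
#' @param lambda threshold multiplier.
#' @return Function `(v, tau) -> vector`.
#' @export
soft_threshold_denoiser <- function(lambda = 2.5) {
  function(v, tau) sign(v) * pmax(abs(v) - lambda * tau, 0)
}

#' One approximate-message-passing step
#'
#' `x~ = x + A' z` with the Onsager-corrected residual
#' `z = y - A x + z_prev * div`, where `div` is the (1/m-normalized)
#' divergence of the previous denoiser application. Forcing `div = 0` gives a
#' plain gradient step with unit step size.
#'
#' @param model a `measurement_model` (Gaussian kind expected; a warning is
#'   issued otherwise since the Onsager correction assumes it).
#' @param x current estimate as a length-n vector.
#' @param y measurement vector.
#' @param z_prev previous residual (length m), or `NULL` on the first step.
#' @param divergence the stored divergence of the previous denoiser (scalar).
#' @return List with `xt` (pre-denoising state, length n) and `z` (updated
#'   residual).
#' @export
amp_step <- function(model, x, y, z_prev = NULL, divergence = 0) {
  if (model$kind != "gaussian") {
    warning("AMP's Onsager correction assumes a Gaussian measurement ensemble")
  }
  xa <- as_image_batch(x, model$side)
  z <- y - as.vector(forward(model, xa))
  if (!is.null(z_prev)) z <- z + z_prev * divergence
  list(xt = as.vector(x) + img_to_vec(adjoint(model, z)[, , 1L]), z = z)
}

#' Sparse recovery with approximate message passing
#'
#' Runs the standard denoising-AMP recursion with a vector denoiser
#' `eta(v, tau)` and Monte-Carlo Onsager correction, tracking the working
#' noise level `tau = ||z|| / sqrt(m)`.
#'
#' @param model a Gaussian `measurement_model`.
#' @param y measurement vector.
#' @param denoiser function `(v, tau) -> vector` (see
#'   [soft_threshold_denoiser()]).
#' @param iters number of iterations.
#' @param probes Rademacher probes for the divergence estimate.
#' @param seed integer seed for the probes.
#' @return List with `x` (final estimate, length n), `trace` (per-iteration
#'   estimates) and `tau` (per-iteration noise estimates).
#' @export
amp_recover <- function(model, y, denoiser, iters = 30L, probes = 1L, seed = 1L) {
  n <- model$n; m <- model$m
  x <- numeric(n)
  z <- NULL; div <- 0
  trace <- vector("list", iters)
  taus <- numeric(iters)
  for (t in seq_len(iters)) {
    st <- amp_step(model, x, y, z, div)
    z <- st$z
    tau <- sqrt(sum(z^2) / m)
    taus[t] <- tau
    eta_t <- function(v) denoiser(v, tau)
    x <- eta_t(st$xt)
    div <- mc_divergence(eta_t, st$xt, m, probes = probes,
                         seed = seed + t)
    trace[[t]] <- x
  }
  list(x = x, trace = trace, tau = taus)
}

#' Memory coefficients reproducing another scheme's trace
#'
#' Given the identity-projector trace of a reference scheme (e.g. Nesterov),
#' solves, step by step, the small least-squares system expressing the
#' reference pre-projection state in the deep-memory basis
#' `[x_{s-1}, g_0, ..., g_{s-1}]`. When the reference iterates are (as for
#' gradient-type methods) polynomials in `A'A` applied to `A'y`, the residual
#' is zero and the returned coefficients replay the trace exactly.
#'
#' @param model a `measurement_model`.
#' @param y measurement vector (single instance).
#' @param ref_pre list of reference pre-projection states `x~_0 ... x~_{T-1}`
#'   (images), with identity projector so `x_s = x~_{s-1}`.
#' @return List with `coeffs` (a `memory_coefficients`) and `residuals`
#'   (per-step least-squares residual norms).
#' @export
match_memory_coefficients <- function(model, y, ref_pre) {
  T <- length(ref_pre)
  side <- model$side
  y <- matrix(y, ncol = 1L)
  x <- array(0, dim = c(side, side, 1L))
  gs <- list()
  alpha <- numeric(T)
  beta <- vector("list", T)
  resid <- numeric(T)
  for (s in seq_len(T)) {
    gs[[s]] <- adjoint(model, y - forward(model, x))
    basis <- cbind(as.vector(x), vapply(gs, as.vector, numeric(side^2)))
    target <- as.vector(as_image_batch(ref_pre[[s]], side))
    # pivoted least squares; rank-deficient columns (e.g. x_0 = 0) get
    # coefficient 0
    sol <- qr.coef(qr(basis), target)
    sol[is.na(sol)] <- 0
    alpha[s] <- sol[1L]
    beta[[s]] <- sol[-1L]
    resid[s] <- sqrt(sum((basis %*% sol - target)^2))
    x <- as_image_batch(ref_pre[[s]], side)   # identity projector
  }
  list(coeffs = memory_coefficients(alpha, beta), residuals = resid)
}

# ---- full unrolled network --------------------------------------------------

#' Assemble an unrolled reconstruction network
#'
#' @param scheme one of `"demun"`, `"pgd"`, `"nesterov"`, `"amp"`.
#' @param T number of unrolled steps (>= 1).
#' @param projector_config a `dncnn_config` shared by all steps.
#' @param side image side length the network reconstructs.
#' @param share_weights use one projector for all steps instead of per-step
#'   weights (ablation switch; default `FALSE`).
#' @param mu initial/fixed step size for the pgd / nesterov schemes (a single
#'   trainable scalar shared across steps).
#' @param seed integer seed for weight initialization.
#' @return An `unrolled_net`. Deep-memory coefficients start at the
#'   gradient-descent view (`alpha = 1`, `beta_ss = 1`), so the untrained
#'   network computes plain projected gradient descent with unit step.
#' @export
build_unrolled_net <- function(scheme = c("demun", "pgd", "nesterov", "amp"),
                               T, projector_config, side,
                               share_weights = FALSE, mu = 1, seed = 1L) {
  scheme <- match.arg(scheme)
  check_scalar(T, "T")
  if (T < 1) stop_config("T must be >= 1")
  T <- as.integer(T)
  nproj <- if (share_weights) 1L else T
  projectors <- lapply(seq_len(nproj), function(s) {
    build_dncnn(projector_config, seed = seed + s - 1L)
  })
  scheme_params <- switch(scheme,
    demun = {
      cf <- pgd_coefficients(T, mu)
      list(alpha = cf$alpha, beta = cf$beta)
    },
    pgd = list(mu = mu),
    nesterov = list(mu = mu),
    amp = list())
  structure(list(scheme = scheme, T = T, side = as.integer(side),
                 share_weights = isTRUE(share_weights),
                 projector_config = projector_config,
                 projectors = projectors, scheme_params = scheme_params,
                 gamma = if (scheme == "nesterov") nesterov_gamma_schedule(T) else NULL,
                 seed = as.integer(seed)),
            class = "unrolled_net")
}

#' @export
print.unrolled_net <- function(x, ...) {
  cat(sprintf("<unrolled_net: %s, T=%d, side=%d, residual=%s, %s projector weights>\n",
              x$scheme, x$T, x$side, x$projector_config$residual,
              if (x$share_weights) "shared" else "per-step"))
  invisible(x)
}

proj_at <- function(net, s) {
  net$projectors[[if (net$share_weights) 1L else s]]
}

# Forward pass through the whole unrolled network on a batch.
# Returns trace (x_1..x_T), pre-projection states, gradient history and the
# per-step caches needed by the backward pass.
unrolled_fwd <- function(net, model, y, training = FALSE, keep_cache = FALSE,
                         identity_projector = FALSE) {
  T <- net$T
  N <- ncol(y)
  side <- net$side
  x <- array(0, dim = c(side, side, N))
  xs <- vector("list", T + 1L); xs[[1L]] <- x
  xts <- vector("list", T)
  gs <- vector("list", T)              # gs[[s]] = A'(y - A x_{s-1})
  caches <- vector("list", T)
  resid_flag <- net$projector_config$residual
  z <- NULL; div <- 0                  # amp state
  amp_resid <- vector("list", T)
  for (s in seq_len(T)) {
    r <- y - forward(model, x)
    if (net$scheme %in% c("demun", "pgd")) gs[[s]] <- adjoint(model, r)
    xt <- switch(net$scheme,
      demun = {
        w <- net$scheme_params
        acc <- w$alpha[s] * x
        for (j in seq_len(s)) acc <- acc + w$beta[[s]][j] * gs[[j]]
        acc
      },
      pgd = x + net$scheme_params$mu * gs[[s]],
      nesterov = {
        xp <- if (s == 1L) x else xs[[s - 1L]]
        zst <- x + net$gamma[s] * (x - xp)
        gz <- adjoint(model, y - forward(model, zst))
        caches[[s]]$nesterov_gz <- gz
        xt <- zst + net$scheme_params$mu * gz
        xt
      },
      amp = {
        zs <- matrix(r, nrow = model$m) + if (is.null(z)) 0 else z * div
        z <- zs
        amp_resid[[s]] <- zs
        x + adjoint(model, zs)
      })
    xts[[s]] <- xt
    if (identity_projector) {
      xn <- xt
    } else {
      pj <- proj_at(net, s)
      fw <- dncnn_fwd(pj, xt, training = training, keep_cache = keep_cache)
      if (training && pj$config$batchnorm) {
        idx <- if (net$share_weights) 1L else s
        net$projectors[[idx]]$state <- fw$state
      }
      caches[[s]]$proj <- fw$cache
      xn <- if (resid_flag) xt + fw$out else fw$out
    }
    if (net$scheme == "amp" && !identity_projector) {
      # divergence of the projection step for the next Onsager term
      # (stop-gradient: treated as a constant during training)
      div <- amp_proj_divergence(net, model, s, xt, resid_flag, training)
    }
    xs[[s + 1L]] <- xn
    x <- xn
  }
  list(trace = xs[-1L], pre = xts, grads = gs, caches = caches,
       xs = xs, net = net, amp_resid = amp_resid)
}

# Divergence (1/m-normalized) of the projection step via one Rademacher probe
# through the projector, seeded off the step index for determinism.
amp_proj_divergence <- function(net, model, s, xt, resid_flag, training) {
  pj <- proj_at(net, s)
  d <- dim(xt)
  delta <- max(abs(xt)) / 1000 + 1e-12
  eps <- with_seed(net$seed + 7919L * s,
                   array(sample(c(-1, 1), prod(d), replace = TRUE), dim = d))
  f0 <- dncnn_fwd(pj, xt, training = training)$out
  f1 <- dncnn_fwd(pj, xt + delta * eps, training = training)$out
  if (resid_flag) { f0 <- xt + f0; f1 <- xt + delta * eps + f1 }
  # per-image divergence averaged over the batch
  mean(colSums(matrix(eps * (f1 - f0) / delta, ncol = d[3L]))) / model$m
}

#' Run an unrolled network (inference)
#'
#' @param net an `unrolled_net`.
#' @param model the `measurement_model` the network was (or will be) trained
#'   against.
#' @param y measurements, `m x N` matrix or length-m vector.
#' @param keep_pre also return the pre-projection states.
#' @param identity_projector skip the projectors entirely (the bare iterative
#'   scheme); useful for oracle comparisons.
#' @return A `reconstruction_trace`: list with `trace` (list of
#'   `side x side x N` arrays, `x_1 ... x_T`) and optionally `pre`.
#' @export
run_unrolled <- function(net, model, y, keep_pre = FALSE,
                         identity_projector = FALSE) {
  stopifnot(inherits(net, "unrolled_net"), inherits(model, "measurement_model"))
  y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  if (nrow(y) != model$m) stop_shape("measurements", model$m, nrow(y))
  fw <- unrolled_fwd(net, model, y, training = FALSE, keep_cache = FALSE,
                     identity_projector = identity_projector)
  structure(list(trace = fw$trace, pre = if (keep_pre) fw$pre else NULL,
                 T = net$T, scheme = net$scheme),
            class = "reconstruction_trace")
}

# Backward pass for the trainable schemes (demun, pgd, nesterov, amp with
# stop-gradient Onsager). dTrace is a list of gradients w.r.t. x_1..x_T
# (zeros allowed). Returns gradients for every projector and for the scheme
# parameters.
unrolled_bwd <- function(net, model, fw, dTrace) {
  T <- net$T
  side <- net$side
  resid_flag <- net$projector_config$residual
  dX <- lapply(fw$xs, function(x) x * 0)
  for (s in seq_len(T)) dX[[s + 1L]] <- dTrace[[s]]
  dG <- vector("list", T)
  proj_grads <- vector("list", if (net$share_weights) 1L else T)
  sp <- net$scheme_params
  dmu <- 0
  dalpha <- if (net$scheme == "demun") numeric(T) else NULL
  dbeta <- if (net$scheme == "demun") lapply(seq_len(T), numeric) else NULL

  AtA <- function(v) adjoint(model, forward(model, v))

  for (s in rev(seq_len(T))) {
    dxn <- dX[[s + 1L]]
    # through the projection step
    pj <- proj_at(net, s)
    bw <- dncnn_bwd(pj, fw$caches[[s]]$proj, dxn)
    idx <- if (net$share_weights) 1L else s
    proj_grads[[idx]] <- if (is.null(proj_grads[[idx]])) bw$grads else {
      nl_map2(`+`, proj_grads[[idx]], bw$grads)
    }
    dxt <- bw$dInput
    if (resid_flag) dxt <- dxt + dxn
    # through the gradient-type step
    if (net$scheme == "demun") {
      dalpha[s] <- sum(dxt * fw$xs[[s]])
      for (j in seq_len(s)) {
        dbeta[[s]][j] <- sum(dxt * fw$grads[[j]])
        dG[[j]] <- if (is.null(dG[[j]])) sp$beta[[s]][j] * dxt else {
          dG[[j]] + sp$beta[[s]][j] * dxt
        }
      }
      dX[[s]] <- dX[[s]] + sp$alpha[s] * dxt
    } else if (net$scheme == "pgd") {
      dmu <- dmu + sum(dxt * fw$grads[[s]])
      dX[[s]] <- dX[[s]] + dxt
      dG[[s]] <- if (is.null(dG[[s]])) sp$mu * dxt else dG[[s]] + sp$mu * dxt
    } else if (net$scheme == "nesterov") {
      dmu <- dmu + sum(dxt * fw$caches[[s]]$nesterov_gz)
      dz <- dxt - sp$mu * AtA(dxt)
      gam <- net$gamma[s]
      dX[[s]] <- dX[[s]] + (1 + gam) * dz
      if (s >= 2L) dX[[s - 1L]] <- dX[[s - 1L]] - gam * dz
    } else if (net$scheme == "amp") {
      # x~ = x + A'(y - A x) + A'(z_prev * div); last term constant
      dX[[s]] <- dX[[s]] + dxt - AtA(dxt)
    }
    # close the gradient-history path g_s = A'(y - A x_{s-1})
    if (net$scheme %in% c("demun", "pgd") && !is.null(dG[[s]])) {
      dX[[s]] <- dX[[s]] - AtA(dG[[s]])
    }
  }
  list(proj_grads = proj_grads,
       scheme_grads = switch(net$scheme,
         demun = list(alpha = dalpha, beta = dbeta),
         pgd = list(mu = dmu),
         nesterov = list(mu = dmu),
         amp = list()))
}
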