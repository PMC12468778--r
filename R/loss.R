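# Training-loss family over a reconstruction trace x_1 ... x_T.
#
# Per-image loss is the pixel-sum of squared error (norms taken literally);
# batch reduction (mean over images) happens in the trainer, not here.
# A trace is a list of T images (side x side matrices or side x side x N
# batches with a common N; batches are summed like extra pixels).

sq_err <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_shape("trace element", dim(b), dim(a))
  sum((a - b)^2)
}

#' Loss specification
#'
#' @param family `"last_layer"`, `"weighted_intermediate"` or `"skip_L"`.
#' @param omega weight base in (0, 1] for `weighted_intermediate`; step `i`
#'   (of `T`) is weighted `omega^(T - i)`, so `omega = 1` supervises every
#'   step equally and `omega -> 0` approaches the last-layer loss.
#' @param skip skip factor for `skip_L`; must divide `T`.
#' @param T number of unrolled steps.
#' @return A `loss_spec` object.
#' @export
loss_spec <- function(family = c("weighted_intermediate", "last_layer", "skip_L"),
                      omega = 1, skip = 1L, T = NULL) {
  family <- match.arg(family)
  if (family == "weighted_intermediate" && (omega <= 0 || omega > 1)) {
    stop_config("omega must be in (0, 1], got ", omega)
  }
  if (family == "skip_L") {
    if (is.null(T)) stop_config("skip_L requires T")
    if (T %% skip != 0) stop_config("skip factor ", skip, " must divide T = ", T)
  }
  structure(list(family = family, omega = omega, skip = as.integer(skip), T = T),
            class = "loss_spec")
}

#' Last-layer loss
#'
#' Squared Euclidean distance between the final estimate and the truth,
#' summed over pixels.
#'
#' @param trace list of per-step estimates `x_1 ... x_T`.
#' @param xstar ground-truth image (same shape as the trace elements).
#' @return Scalar loss.
#' @export
last_layer_loss <- function(trace, xstar) {
  T <- length(trace)
  if (T < 1) stop_config("trace must have length >= 1")
  sq_err(trace[[T]], xstar)
}

#' Weighted intermediate loss
#'
#' `sum_i omega^(T - i) ||x_i - x*||^2`: every unrolled step is supervised,
#' with geometrically decaying emphasis on earlier steps.
#'
#' @inheritParams last_layer_loss
#' @param omega weight base in (0, 1].
#' @return Scalar loss.
#' @export
weighted_intermediate_loss <- function(trace, xstar, omega = 1) {
  if (omega <= 0 || omega > 1) stop_config("omega must be in (0, 1], got ", omega)
  T <- length(trace)
  w <- omega^(T - seq_len(T))
  sum(vapply(seq_len(T), function(i) w[i] * sq_err(trace[[i]], xstar), 0))
}

#' Steps supervised by the skip-L loss
#'
#' Every `skip`-th step counting back from `T`: `{skip, 2 skip, ..., T}`.
#' For `T = 15, skip = 3` these are steps 3, 6, 9, 12 and 15.
#'
#' @param T number of steps.
#' @param skip skip factor (must divide `T`).
#' @return Increasing integer vector of supervised step indices.
#' @export
skip_loss_steps <- function(T, skip) {
  if (T %% skip != 0) stop_config("skip factor ", skip, " must divide T = ", T)
  sort(T - (0:(T / skip - 1)) * skip)
}

#' Skip-L intermediate loss
#'
#' Sum of squared errors at every `skip`-th step counting back from the last:
#' `skip = 1` reproduces the unweighted intermediate loss, `skip = T` the
#' last-layer loss.
#'
#' @inheritParams last_layer_loss
#' @param skip skip factor (must divide `T`).
#' @return Scalar loss.
#' @export
skip_layer_loss <- function(trace, xstar, skip) {
  steps <- skip_loss_steps(length(trace), skip)
  sum(vapply(steps, function(i) sq_err(trace[[i]], xstar), 0))
}

#' Evaluate a loss specification on a trace
#'
#' @param spec a `loss_spec`.
#' @inheritParams last_layer_loss
#' @return Scalar loss.
#' @export
trace_loss <- function(spec, trace, xstar) {
  stopifnot(inherits(spec, "loss_spec"))
  switch(spec$family,
    last_layer            = last_layer_loss(trace, xstar),
    weighted_intermediate = weighted_intermediate_loss(trace, xstar, spec$omega),
    skip_L                = skip_layer_loss(trace, xstar, spec$skip))
}

# Per-step weights w_i so that loss = sum_i w_i ||x_i - x*||^2; the trainer
# backpropagates 2 w_i (x_i - x*).
loss_weights <- function(spec, T) {
  stopifnot(inherits(spec, "loss_spec"))
  switch(spec$family,
    last_layer            = c(rep(0, T - 1), 1),
    weighted_intermediate = spec$omega^(T - seq_len(T)),
    skip_L                = as.numeric(seq_len(T) %in% skip_loss_steps(T, spec$skip)))
}

#' The ablation grid of loss presets
#'
#' The named grid used by the sensitivity study: the unweighted intermediate
#' loss, geometrically weighted variants with
#' `omega in {0.95, 0.85, 0.75, 0.5, 0.25, 0.1, 0.01}`, the skip-5 loss, and
#' the last-layer loss.
#'
#' @param T number of unrolled steps (needed by the skip-5 member).
#' @return Named list of `loss_spec` objects.
#' @export
loss_preset_grid <- function(T = 30L) {
  specs <- list(li_1 = loss_spec("weighted_intermediate", omega = 1))
  for (om in c(0.95, 0.85, 0.75, 0.5, 0.25, 0.1, 0.01)) {
    specs[[sprintf("li_%g", om)]] <- loss_spec("weighted_intermediate", omega = om)
  }
  specs$ls_5 <- loss_spec("skip_L", skip = 5L, T = T)
  specs$lll <- loss_spec("last_layer")
  specs
}
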