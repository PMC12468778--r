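# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no stored data.

rand_image <- function(side, seed) {
  set.seed(seed)
  matrix(runif(side * side), side, side)
}

rand_batch <- function(side, n, seed) {
  set.seed(seed)
  array(runif(side * side * n), dim = c(side, side, n))
}

# A trace of T random images, for loss/metric identities.
rand_trace <- function(T, side, seed) {
  set.seed(seed)
  lapply(seq_len(T), function(i) matrix(rnorm(side * side), side, side))
}

# Tiny experiment config that trains in seconds (used by harness tests).
tiny_config <- function(...) {
  defaults <- list(side = 12L, sampling_rate = 0.3, T = 2L, L = 1L,
                   width = 4L, epochs = 2L, n_train = 30L, n_test = 10L,
                   batch_size = 10L)
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}

# Set every weight of a projector's output conv to zero, making P(x) == 0.
zero_output_projector <- function(net) {
  for (i in seq_along(net$projectors)) {
    net$projectors[[i]]$params$output$W[] <- 0
    if (net$projector_config$final_bias) {
      net$projectors[[i]]$params$output$b <- 0
    }
  }
  net
}
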