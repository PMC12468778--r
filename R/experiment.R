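# Experiment harness: one config = one operator instance + one network +
# one loss, trained and evaluated end to end; the ablation runner crosses
# config axes and writes one summary row per cell, keyed by a config hash so
# completed cells are skipped on re-runs.

#' Build an experiment configuration
#'
#' Defaults describe the toy tier (one-CPU scale); the full-scale settings of
#' the study (side 50, T = 30, L = 5, width 64, 2500 test images) are valid
#' values of the same fields.
#'
#' @param kind measurement kind, `"gaussian"` or `"dct"`.
#' @param side image side length.
#' @param sampling_rate m/n in (0, 1]; the study grid is 0.1-0.4.
#' @param scheme unrolling scheme (`"demun"`, `"pgd"`, `"nesterov"`, `"amp"`).
#' @param T unrolled steps.
#' @param L projector depth; `width` its channels.
#' @param residual residual projection steps.
#' @param loss_family,omega,skip loss selection (see [loss_spec()]).
#' @param sigma measurement-noise sd (train and test).
#' @param pattern DCT undersampling pattern.
#' @param epochs,batch_size,lr optimizer settings.
#' @param n_train,n_test synthetic set sizes; `data_kind` their generator.
#' @param seed_weights,seed_data,seed_noise,seed_operator independent seeds.
#' @return An `experiment_config` (named list, serializable to YAML).
#' @export
experiment_config <- function(kind = "gaussian", side = 16L, sampling_rate = 0.25,
                              scheme = "demun", T = 4L, L = 3L, width = 16L,
                              residual = TRUE, loss_family = "weighted_intermediate",
                              omega = 1, skip = 1L, sigma = 0,
                              pattern = "uniform-random-rows",
                              epochs = 15L, batch_size = 16L, lr = 1e-3,
                              n_train = 200L, n_test = 40L, data_kind = "cartoons",
                              seed_weights = 1L, seed_data = 1L,
                              seed_noise = 1L, seed_operator = 1L) {
  cfg <- list(kind = kind, side = as.integer(side), sampling_rate = sampling_rate,
              scheme = scheme, T = as.integer(T), L = as.integer(L),
              width = as.integer(width), residual = isTRUE(residual),
              loss_family = loss_family, omega = omega, skip = as.integer(skip),
              sigma = sigma, pattern = pattern, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), lr = lr,
              n_train = as.integer(n_train), n_test = as.integer(n_test),
              data_kind = data_kind, seed_weights = as.integer(seed_weights),
              seed_data = as.integer(seed_data), seed_noise = as.integer(seed_noise),
              seed_operator = as.integer(seed_operator))
  class(cfg) <- c("experiment_config", "list")
  cfg
}

#' Stable hash of an experiment configuration
#'
#' @param config an `experiment_config`.
#' @return Character hash stamping all outputs of the cell.
#' @export
config_hash <- function(config) {
  flat <- unclass(config)[order(names(unclass(config)))]
  rlang::hash(flat)
}

#' Read / write experiment configurations as YAML
#'
#' @param path YAML file path.
#' @param config an `experiment_config`.
#' @return `read_config` returns an `experiment_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(experiment_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

cfg_loss_spec <- function(config) {
  loss_spec(config$loss_family, omega = config$omega, skip = config$skip,
            T = config$T)
}

cfg_model <- function(config) {
  if (config$kind == "gaussian") {
    make_gaussian_model(config$side, config$sampling_rate, seed = config$seed_operator)
  } else {
    make_dct_model(config$side, config$sampling_rate, pattern = config$pattern,
                   seed = config$seed_operator)
  }
}

#' Run one experiment cell
#'
#' Generates the data, builds the operator and network from the config's
#' seeds, trains, evaluates, and returns the per-image records plus a one-row
#' summary stamped with the config hash. Re-running the same config
#' reproduces the summary to float tolerance.
#'
#' @param config an `experiment_config`.
#' @param verbose print per-epoch training loss.
#' @return List with `summary` (one-row data.frame), `records`,
#'   `per_step_psnr`, `log`, `net`, `model` and `hash`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  h <- config_hash(config)
  dat <- generate_images(config$data_kind, config$n_train + config$n_test,
                         config$side, seed = config$seed_data)
  spl <- split_images(dat, config$n_train / (config$n_train + config$n_test),
                      seed = config$seed_data)
  model <- cfg_model(config)
  pc <- dncnn_config(L = config$L, width = config$width,
                     residual = config$residual)
  net <- build_unrolled_net(config$scheme, config$T, pc, config$side,
                            mu = stable_step_size(model),
                            seed = config$seed_weights)
  fit <- train_unrolled(net, model, spl$train, cfg_loss_spec(config),
                        epochs = config$epochs, batch_size = config$batch_size,
                        lr = config$lr, sigma = config$sigma,
                        seed = config$seed_noise, verbose = verbose)
  ev <- evaluate_unrolled(fit$net, model, spl$test, sigma = config$sigma,
                          seed = config$seed_noise + 1L, config = h)
  summary <- data.frame(
    hash = h, kind = config$kind, sampling_rate = config$sampling_rate,
    scheme = config$scheme, T = config$T, L = config$L,
    residual = config$residual, loss_family = config$loss_family,
    omega = config$omega, skip = config$skip, sigma = config$sigma,
    psnr_mean = mean(ev$records$psnr), psnr_sd = stats::sd(ev$records$psnr),
    ssim_mean = mean(ev$records$ssim), ssim_sd = stats::sd(ev$records$ssim),
    n_images = nrow(ev$records), stringsAsFactors = FALSE)
  list(summary = summary, records = ev$records, per_step_psnr = ev$per_step_psnr,
       log = fit$log, net = fit$net, model = model, hash = h)
}

#' Run an ablation grid
#'
#' Crosses the supplied axes over a base configuration and runs each cell.
#' Each cell writes `<hash>.csv` (its summary row) into `out_dir`; cells
#' whose file already exists are skipped, making interrupted grids resumable.
#' A failing cell is logged and marked, not fatal.
#'
#' @param base an `experiment_config` supplying fixed fields.
#' @param axes named list of vectors: config fields to cross.
#' @param out_dir directory for per-cell summaries (created if needed).
#' @param verbose print progress.
#' @return data.frame binding every cell's summary row (failed cells carry
#'   `NA` metrics and an `error` message column).
#' @export
ablate <- function(base, axes, out_dir = tempfile("ablation"), verbose = FALSE) {
  stopifnot(inherits(base, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(axes, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    for (ax in names(axes)) cfg[[ax]] <- grid[i, ax]
    h <- config_hash(cfg)
    cell_file <- file.path(out_dir, paste0(h, ".csv"))
    if (file.exists(cell_file)) {
      rows[[i]] <- utils::read.csv(cell_file, stringsAsFactors = FALSE)
      if (verbose) message("cell ", i, "/", nrow(grid), " cached (", h, ")")
      next
    }
    res <- tryCatch(run_experiment(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      warning("ablation cell failed (", h, "): ", conditionMessage(res))
      row <- data.frame(hash = h, error = conditionMessage(res),
                        stringsAsFactors = FALSE)
      for (ax in names(axes)) row[[ax]] <- grid[i, ax]
    } else {
      row <- res$summary
      row$error <- ""
    }
    utils::write.csv(row, cell_file, row.names = FALSE)
    rows[[i]] <- row
    if (verbose) message("cell ", i, "/", nrow(grid), " done (", h, ")")
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (mcol in miss) r[[mcol]] <- NA
    r[, sort(names(r))]
  }))
  rownames(out) <- NULL
  out
}

#' Named ablation presets
#'
#' `scheme-by-loss` crosses the four unrolling schemes with the last-layer and
#' unweighted intermediate losses (the loss-vs-scheme grid); `loss-grid`
#' enumerates the loss-sensitivity presets of [loss_preset_grid()].
#'
#' @param name preset name.
#' @param base base `experiment_config`.
#' @return List with `base` and `axes`, ready for [ablate()].
#' @export
ablation_preset <- function(name = c("scheme-by-loss", "loss-grid"), base = experiment_config()) {
  name <- match.arg(name)
  if (name == "scheme-by-loss") {
    base$residual <- FALSE
    list(base = base,
         axes = list(scheme = c("demun", "pgd", "nesterov", "amp"),
                     loss_family = c("last_layer", "weighted_intermediate")))
  } else {
    list(base = base,
         axes = list(omega = c(1, 0.95, 0.85, 0.75, 0.5, 0.25, 0.1, 0.01)))
  }
}

#' Save / load a trained network checkpoint
#'
#' Weights, memory coefficients and BN statistics are stored as an RDS file
#' next to a JSON manifest of the generating configuration.
#'
#' @param net an `unrolled_net`.
#' @param path checkpoint path (`.rds`).
#' @param config optional `experiment_config` recorded in the manifest.
#' @return `path` invisibly; `load_checkpoint` returns the `unrolled_net`.
#' @export
save_checkpoint <- function(net, path, config = NULL) {
  saveRDS(net, path)
  manifest <- list(scheme = net$scheme, T = net$T, side = net$side,
                   config = if (is.null(config)) NULL else unclass(config),
                   hash = if (is.null(config)) NULL else config_hash(config))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "unrolled_net"))
  net
}
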