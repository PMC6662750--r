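#' Lagged-input multilayer perceptron for phase prediction
#'
#' The network maps 30-minute-binned light and skin-temperature histories to
#' the reference rhythm value at each bin. Light enters with lags 0-24 h in
#' 30-minute steps (49 columns); each temperature variable with lags 0-5 h
#' (11 columns), so a single-sensor model has 60 inputs plus a bias and
#' (60+1)x5 + (5+1) = 311 trainable weights; the 6-variable model has 115
#' inputs and 586 weights. Training is full-batch resilient backpropagation
#' repeated from `restarts` random initializations; the restart with the
#' lowest final training MSE is kept.
#'
#' @name neural_net
NULL

#' Number of trainable weights for a 5-hidden-neuron network
#'
#' (n_inputs + 1) x hidden + (hidden + 1).
#'
#' @param n_inputs number of input columns (excluding bias)
#' @param hidden hidden-layer size
#' @return integer weight count
#' @export
count_weights <- function(n_inputs, hidden = 5) {
  stopifnot(n_inputs >= 1)
  (n_inputs + 1) * hidden + (hidden + 1)
}

#' Build the lagged design matrix for one participant
#'
#' One row per 30-minute bin with a complete lag history: rows lacking the
#' full `light_lag_hours` of prior light history are excluded, not padded.
#' The target is the reference waveform value interpolated at the bin center.
#'
#' @param binned a `binned_matrix` with a `light` column and one or more
#'   columns starting with `temp`
#' @param reference a `reference_waveform` covering the binned span
#' @param in_lab optional (start, end) intervals, minutes, marking in-lab rows
#' @param participant_id identifier carried through to predictions
#' @param config a [run_config()]
#' @return object of class `lagged_design`: list(X, y, time, in_lab,
#'   participant_id, columns)
#' @export
build_lagged_design <- function(binned, reference, in_lab = NULL,
                                participant_id = "p1",
                                config = run_config()) {
  stopifnot(inherits(binned, "binned_matrix"), "light" %in% names(binned))
  bm <- config$bin_minutes
  n_llag <- as.integer(config$light_lag_hours * 60 / bm)   # 48
  n_tlag <- as.integer(config$temp_lag_hours * 60 / bm)    # 10
  temp_vars <- grep("^temp", names(binned), value = TRUE)
  if (length(temp_vars) == 0) stop("binned matrix has no temperature columns")
  nb <- nrow(binned)
  rows <- seq_len(nb)[seq_len(nb) > n_llag]
  if (length(rows) == 0) stop("no bins with a complete 24-h lag history")
  lag_block <- function(v, lags, prefix) {
    m <- vapply(lags, function(k) v[rows - k], numeric(length(rows)))
    colnames(m) <- sprintf("%s_lag%02d", prefix, lags)
    m
  }
  X <- lag_block(binned$light, 0:n_llag, "light")
  for (tv in temp_vars)
    X <- cbind(X, lag_block(binned[[tv]], 0:n_tlag, tv))
  times <- binned$time[rows]
  y <- stats::approx(reference$t, reference$values, xout = times,
                     rule = 2)$y
  lab <- rep(FALSE, length(rows))
  if (!is.null(in_lab) && NROW(in_lab) > 0) {
    iv <- as.matrix(in_lab[, 1:2, drop = FALSE])
    for (i in seq_len(nrow(iv)))
      lab <- lab | (times >= iv[i, 1] & times < iv[i, 2])
  }
  if (anyNA(X) || anyNA(y)) stop("lagged design contains missing entries")
  structure(list(X = X, y = y, time = times, in_lab = lab,
                 participant_id = participant_id, columns = colnames(X)),
            class = "lagged_design")
}

#' Column scaling parameters from a set of training designs
#'
#' Per-column mean and SD pooled over the training participants (the n-1
#' group in leave-one-out cross-validation); applied identically to the
#' held-out participant. Zero-variance columns are dropped with a warning.
#'
#' @param designs list of `lagged_design`
#' @return object of class `scaling_params`
#' @export
scaling_params <- function(designs) {
  X <- do.call(rbind, lapply(designs, function(d) d$X))
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  keep <- is.finite(s) & s > 0
  if (!all(keep))
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  structure(list(mean = m, sd = s, keep = keep), class = "scaling_params")
}

apply_scaling <- function(design, sp) {
  X <- sweep(sweep(design$X, 2, sp$mean, "-"), 2, sp$sd, "/")
  X[, sp$keep, drop = FALSE]
}

#' Train the network with resilient backpropagation and random restarts
#'
#' Full-batch iRprop- minimizing MSE, repeated `config$restarts` times from
#' independent uniform(-0.5, 0.5) weight initializations drawn from seeded
#' substreams; the restart with the lowest final training MSE is selected
#' (ties by lowest restart index). Restarts with non-finite loss are
#' discarded with a warning.
#'
#' @param designs list of `lagged_design` (training participants)
#' @param config a [run_config()]
#' @param seed integer seed for the restart substreams
#' @param scaling optional pre-computed `scaling_params` (defaults to scaling
#'   fitted on `designs`)
#' @return object of class `circa_mlp`: the selected weights, scaling,
#'   per-restart errors and the selected restart index
#' @export
train_rprop <- function(designs, config = run_config(), seed = 1L,
                        scaling = NULL) {
  if (inherits(designs, "lagged_design")) designs <- list(designs)
  sp <- scaling %||% scaling_params(designs)
  X <- do.call(rbind, lapply(designs, function(d) apply_scaling(d, sp)))
  y <- unlist(lapply(designs, function(d) d$y))
  stopifnot(all(y >= -0.2), all(y <= 1.2))  # targets on the [0,1] scale
  I <- ncol(X); H <- config$hidden_neurons
  best <- NULL; errs <- rep(NA_real_, config$restarts); best_r <- NA_integer_
  for (r in seq_len(config$restarts)) {
    set.seed(derive_seed(seed, "rprop_init", r))
    W1 <- matrix(stats::runif((I + 1) * H, -0.5, 0.5), I + 1, H)
    w2 <- stats::runif(H + 1, -0.5, 0.5)
    fit <- rprop_fit(X, y, W1, w2, config$epochs, config$step_tol,
                     1.2, 0.5, 0.07, 50)
    if (!is.finite(fit$mse)) {
      warning("restart ", r, " diverged (non-finite loss); discarded")
      next
    }
    errs[r] <- fit$mse
    if (is.null(best) || fit$mse < best$mse) { best <- fit; best_r <- r }
  }
  if (is.null(best)) stop("all restarts diverged: training failed")
  structure(list(W1 = best$W1, w2 = as.numeric(best$w2),
                 training_error = best$mse, initial_error = best$mse0,
                 epochs_run = best$epochs,
                 restart_errors = errs, restart_index = best_r,
                 scaling = sp, columns = designs[[1]]$columns,
                 hidden = H, seed = as.integer(seed)),
            class = "circa_mlp")
}

#' @export
print.circa_mlp <- function(x, ...) {
  cat(sprintf(
    "<circa_mlp: %d inputs, %d hidden, %d weights; train MSE %.4g (restart %d/%d)>\n",
    sum(x$scaling$keep), x$hidden, count_weights(sum(x$scaling$keep), x$hidden),
    x$training_error, x$restart_index, length(x$restart_errors)))
  invisible(x)
}

#' Predict the target rhythm for a design
#'
#' Applies the training-set scaling and the forward pass; one predicted value
#' per row, timestamped at the bin centers.
#'
#' @param object a `circa_mlp`
#' @param design a `lagged_design` with the same columns as training
#' @param ... unused
#' @return data.frame with columns `time` and `value`
#' @export
predict.circa_mlp <- function(object, design, ...) {
  if (!identical(design$columns, object$columns))
    stop("design columns do not match the training design")
  X <- apply_scaling(design, object$scaling)
  data.frame(time = design$time,
             value = as.numeric(mlp_forward(X, object$W1, object$w2)))
}

#' Save / load a trained network as JSON
#'
#' Weights and scaling constants are serialized as 17-significant-digit
#' strings so that a save/load round trip reproduces predictions bit-exactly
#' (plain JSON numbers lose the last bits).
#'
#' @param model a `circa_mlp`
#' @param path JSON file path
#' @return `path` (save) or the restored `circa_mlp` (load)
#' @export
save_model <- function(model, path) {
  enc <- function(x) sprintf("%.17g", x)
  obj <- list(W1 = apply(model$W1, 2, enc), w2 = enc(model$w2),
              scaling_mean = enc(model$scaling$mean),
              scaling_sd = enc(model$scaling$sd),
              scaling_keep = model$scaling$keep,
              columns = model$columns, hidden = model$hidden,
              training_error = enc(model$training_error),
              restart_index = model$restart_index, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(s) as.numeric(s)
  sp <- structure(list(mean = stats::setNames(dec(obj$scaling_mean),
                                              obj$columns),
                       sd = stats::setNames(dec(obj$scaling_sd),
                                            obj$columns),
                       keep = obj$scaling_keep), class = "scaling_params")
  structure(list(W1 = apply(obj$W1, 2, dec), w2 = dec(obj$w2),
                 training_error = dec(obj$training_error),
                 restart_errors = NULL, restart_index = obj$restart_index,
                 scaling = sp, columns = obj$columns, hidden = obj$hidden,
                 seed = obj$seed),
            class = "circa_mlp")
}

#' Leave-one-out cross-validated predictions
#'
#' For each participant the network is trained on all the others (training
#' targets keep in-lab rows) and predictions are emitted only for the
#' held-out participant's out-of-lab rows, simulating real-world data
#' collection. Participants with no out-of-lab rows are skipped with a
#' warning.
#'
#' @param designs named list of `lagged_design`, length >= 3
#' @param config a [run_config()]
#' @param seed integer seed
#' @param keep_models also return the per-fold models
#' @return named list of per-participant prediction data.frames (attribute
#'   `models` when `keep_models`)
#' @export
loocv <- function(designs, config = run_config(), seed = 1L,
                  keep_models = FALSE) {
  stopifnot(length(designs) >= 3)
  ids <- vapply(designs, function(d) d$participant_id, character(1))
  names(designs) <- ids
  preds <- list(); models <- list()
  for (i in seq_along(designs)) {
    held <- designs[[i]]
    if (!any(!held$in_lab)) {
      warning("participant ", ids[i], " has no out-of-lab rows; skipped")
      next
    }
    train <- designs[-i]
    model <- train_rprop(train, config, seed = derive_seed(seed, "fold", i))
    p <- predict(model, held)
    p <- p[!held$in_lab, , drop = FALSE]
    preds[[ids[i]]] <- p
    if (keep_models) models[[ids[i]]] <- model
  }
  if (keep_models) attr(preds, "models") <- models
  preds
}

#' Train the final network on the full cohort
#'
#' A single model trained on all participants, for application to
#' independent datasets (e.g., a diurnal-trained model applied to night-shift
#' recordings).
#'
#' @inheritParams loocv
#' @return a `circa_mlp`
#' @export
train_final <- function(designs, config = run_config(), seed = 1L) {
  train_rprop(designs, config, seed = derive_seed(seed, "final"))
}
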