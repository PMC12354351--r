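# Automated training: data feeding, multi-task loss, the session loop with
# held-out evaluation and checkpointing, and the repeated-runs harness.

#' Training hyperparameters
#'
#' @param batch_size minibatch size (>= 1).
#' @param epochs number of passes over the training split.
#' @param learning_rate Adam step size (> 0).
#' @param optimizer only `"adam"` is provided.
#' @param eval_every_n_steps evaluate on the held-out split every this many
#'   steps; `NULL` (default) evaluates at the end of every epoch.
#' @param checkpoint_dir directory for checkpoints (`NULL` = no files).
#' @param seed seed controlling shuffling (parameter initialization is owned
#'   by the model's own config seed).
#' @param early_stop_patience stop after this many evaluations without
#'   improvement in held-out Hits@10; `Inf` disables.
#' @param verbose print progress lines.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 128L, epochs = 10L, learning_rate = 1e-3,
                         optimizer = "adam", eval_every_n_steps = NULL,
                         checkpoint_dir = NULL, seed = 7L,
                         early_stop_patience = Inf, verbose = FALSE) {
  stopifnot(batch_size >= 1L, learning_rate > 0, epochs >= 1L,
            identical(optimizer, "adam"))
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 eval_every_n_steps = eval_every_n_steps,
                 checkpoint_dir = checkpoint_dir, seed = as.integer(seed),
                 early_stop_patience = early_stop_patience, verbose = verbose),
            class = "train_config")
}

#' Batches of record indices for one epoch
#'
#' Every record appears in exactly one batch; the final partial batch is
#' emitted. The shuffle order is a deterministic function of the seed.
#'
#' @param dataset a `tcm_corpus`/list of records, or an integer record count.
#' @param batch_size records per batch.
#' @param shuffle permute the order before batching.
#' @param seed shuffle seed.
#' @return list of integer index vectors.
#' @export
batch_feeder <- function(dataset, batch_size, shuffle = TRUE, seed = 1L) {
  n <- if (is.numeric(dataset) && length(dataset) == 1L) as.integer(dataset)
       else length(dataset)
  stopifnot(n >= 1L, batch_size >= 1L)
  if (batch_size > n)
    warning("batch_size (", batch_size, ") exceeds dataset size (", n,
            "); emitting a single batch")
  idx <- if (shuffle) with_seed(seed, sample.int(n)) else seq_len(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Multi-task multi-label loss
#'
#' Sum over the five category tasks of the (optionally weighted) mean
#' sigmoid cross-entropy between a task's score vector (logits) and its
#' multi-hot label matrix. Returns the scalar total and the per-task terms.
#'
#' @param score_vectors list of 5 logit matrices (B x task width).
#' @param label_sets list of 5 multi-hot 0/1 matrices of matching shape.
#' @param task_weights numeric length 5.
#' @return list with `total` and `per_task`.
#' @export
multi_task_loss <- function(score_vectors, label_sets, task_weights = rep(1, 5)) {
  stopifnot(length(score_vectors) == 5L, length(label_sets) == 5L)
  per_task <- numeric(5)
  for (t in 1:5) {
    z <- score_vectors[[t]]; y <- label_sets[[t]]
    if (!identical(dim(z), dim(y)))
      stop("task ", t, ": score matrix ", paste(dim(z), collapse = "x"),
           " does not match label matrix ", paste(dim(y), collapse = "x"),
           " (label outside the task's vocabulary?)")
    if (any(y != 0 & y != 1)) stop("task ", t, ": labels must be 0/1")
    if (ncol(z) == 0L) next
    per_task[t] <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / length(z)
  }
  list(total = sum(per_task * task_weights), per_task = per_task)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(v) v * 0),
       v = lapply(params, function(v) v * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- checkpoints ------------------------------------------------------------

CHECKPOINT_VERSION <- "1.0"

#' Save / load a model checkpoint
#'
#' Checkpoints carry a format version, the model kind, its configuration,
#' vocabularies, partition, prior matrix and all parameters; loading
#' verifies the version and reproduces evaluation metrics bit-for-bit.
#'
#' @param model a `tcm_model`.
#' @param path file path (`.rds`).
#' @return `path` invisibly (save); the restored `tcm_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(version = CHECKPOINT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("checkpoint version mismatch: file has ", obj$version %||% "<none>",
         ", this package reads ", CHECKPOINT_VERSION)
  obj$model
}

# ---- training loop ----------------------------------------------------------

#' Train a model
#'
#' Minibatch Adam over the training split with periodic held-out
#' evaluation. The best-Hits@10 parameters are retained (and checkpointed
#' when a directory is configured); training aborts with a diagnostic if
#' the loss becomes non-finite. The whole run is deterministic given the
#' model's initialization seed and the training seed.
#'
#' @param model a `tcm_model` (untrained).
#' @param split a `tcm_split` from [split_dataset()], or a list with
#'   `train`/`test` corpora.
#' @param config a `train_config`.
#' @return list with `model` (best parameters restored), `log` (a
#'   `train_log`: per-step losses and evaluation snapshots) and
#'   `best_hits10`.
#' @export
train_model <- function(model, split, config = train_config()) {
  train <- split$train; test <- split$test
  stopifnot(length(train) >= 1L, length(test) >= 1L)
  state <- adam_init(model$params)
  steps <- 0L
  loss_log <- list()
  eval_log <- list()
  best <- list(hits10 = -Inf, params = model$params, step = 0L)
  evals_since_best <- 0L
  stop_early <- FALSE

  eval_now <- function() {
    rep <- evaluate_ranking(model, test)
    eval_log[[length(eval_log) + 1L]] <<- data.frame(
      step = steps, auc = rep$auc, hits_at_10 = rep$hits_at_10,
      mean_rank = rep$mean_rank, mrr = rep$mrr, hits_avg = rep$hits_avg)
    if (rep$hits_at_10 > best$hits10) {
      best <<- list(hits10 = rep$hits_at_10, params = model$params, step = steps)
      evals_since_best <<- 0L
      if (!is.null(config$checkpoint_dir))
        save_checkpoint(model, file.path(config$checkpoint_dir, "best.rds"))
    } else {
      evals_since_best <<- evals_since_best + 1L
      if (evals_since_best >= config$early_stop_patience) stop_early <<- TRUE
    }
    if (config$verbose)
      message(sprintf("step %d: held-out Hits@10 %.4f (best %.4f)",
                      steps, rep$hits_at_10, best$hits10))
  }

  for (epoch in seq_len(config$epochs)) {
    batches <- suppressWarnings(
      batch_feeder(train, config$batch_size, shuffle = TRUE,
                   seed = config$seed * 1000L + epoch))
    for (bidx in batches) {
      batch <- prepare_batch(train[bidx], model)
      got <- loss_and_gradients(model, batch)
      if (!is.finite(got$loss))
        stop("training diverged at step ", steps + 1L, " (epoch ", epoch,
             "): loss = ", got$loss, "; lower the learning rate")
      upd <- adam_step(model$params, got$grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      steps <- steps + 1L
      loss_log[[steps]] <- c(step = steps, epoch = epoch, loss = got$loss)
      if (!is.null(config$eval_every_n_steps) &&
          steps %% config$eval_every_n_steps == 0L) eval_now()
      if (stop_early) break
    }
    if (is.null(config$eval_every_n_steps) && !stop_early) eval_now()
    if (stop_early) {
      if (config$verbose) message("early stop at epoch ", epoch)
      break
    }
  }
  if (length(eval_log) == 0L) eval_now()
  model$params <- best$params
  log <- structure(list(
    losses = as.data.frame(do.call(rbind, loss_log)),
    evals = do.call(rbind, eval_log),
    best_step = best$step
  ), class = "train_log")
  list(model = model, log = log, best_hits10 = best$hits10)
}

#' @export
print.train_log <- function(x, ...) {
  n <- nrow(x$losses)
  cat("<train_log> ", n, " steps; loss ", sprintf("%.4f", x$losses$loss[1L]),
      " -> ", sprintf("%.4f", x$losses$loss[n]),
      "; best held-out Hits@10 at step ", x$best_step, "\n", sep = "")
  invisible(x)
}

#' Repeated-runs harness
#'
#' Trains a model several times with different initialization/shuffle seeds
#' and reports each evaluation metric as mean and standard deviation over
#' the runs, the protocol used to damp indicator fluctuation.
#'
#' @param make_model function(seed) returning a fresh untrained `tcm_model`.
#' @param split a `tcm_split`.
#' @param config a `train_config` (its seed is offset per run).
#' @param n_runs number of repetitions (default 5).
#' @return list with `reports` (per-run `metric_report`s) and `summary`
#'   (data.frame: metric, mean, sd).
#' @export
train_repeated <- function(make_model, split, config = train_config(),
                           n_runs = 5L) {
  reports <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + 100L * r
    fit <- train_model(make_model(config$seed + r), split, cfg)
    reports[[r]] <- evaluate_ranking(fit$model, split$test)
  }
  metrics <- c("auc", "hits_at_10", "mean_rank", "mrr", "hits_avg")
  vals <- sapply(metrics, function(m) vapply(reports, `[[`, numeric(1), m))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = n_runs,
                                       dimnames = list(NULL, metrics))
  list(reports = reports,
       summary = data.frame(metric = metrics,
                            mean = colMeans(vals),
                            sd = apply(vals, 2L, stats::sd),
                            row.names = NULL))
}
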