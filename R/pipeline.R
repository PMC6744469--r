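#' Experiment configuration
#'
#' A config fully determines every byte of an experiment run: cohort sizes and
#' composition, recording length, preprocessing, network architecture,
#' optimizer settings and all seeds. The defaults are a desk-scale analogue
#' of a clinical study: 600 training, 50 validation and 100 test patients
#' with two-hour nights, the training pool thinned to every 12th overlapping
#' window.
#'
#' @param n_train,n_val,n_test Cohort split sizes.
#' @param severity_mix Severity proportions passed to [sample_cohort()].
#' @param recording_duration_s Night length per patient, seconds.
#' @param target_fs,window_s,overlap,invalid_threshold Preprocessing
#'   parameters (see [epoch_signal()]).
#' @param train_thin Keep every `train_thin`-th valid epoch when pooling
#'   training epochs (see [pool_training_epochs()]).
#' @param val_thin Thinning for the validation pool; denser than the training
#'   pool by default so that the early-stopping criterion tracks a
#'   low-variance validation MSE.
#' @param split `"ahi_sorted"` (sort by target AHI, every k-th patient to the
#'   test set, validation drawn at random from the remainder) or `"random"`.
#' @param layer_sizes Network architecture.
#' @param training A [training_config()].
#' @param seed Master seed; all stage seeds are derived from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_train = 600L, n_val = 50L, n_test = 100L,
                              severity_mix = c(0.486, 0.254, 0.129, 0.131),
                              recording_duration_s = 7200,
                              target_fs = 0.5, window_s = 600,
                              overlap = 0.98, invalid_threshold = 0.1,
                              train_thin = 12L, val_thin = 4L,
                              split = c("ahi_sorted", "random"),
                              layer_sizes = c(300, 60, 15, 5, 1),
                              training = training_config(),
                              seed = 1L) {
  split <- match.arg(split)
  stopifnot(n_train >= 1, n_val >= 1, n_test >= 1)
  structure(
    list(n_train = as.integer(n_train), n_val = as.integer(n_val),
         n_test = as.integer(n_test), severity_mix = severity_mix,
         recording_duration_s = recording_duration_s,
         target_fs = target_fs, window_s = window_s, overlap = overlap,
         invalid_threshold = invalid_threshold,
         train_thin = as.integer(train_thin),
         val_thin = as.integer(val_thin), split = split,
         layer_sizes = as.integer(layer_sizes), training = training,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML or JSON
#'
#' Top-level keys match the arguments of [experiment_config()]; optimizer
#' settings sit under a `training:` block matching [training_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tr <- do.call(training_config, raw$training %||% list())
  raw$training <- NULL
  do.call(experiment_config, c(raw, list(training = tr)))
}

# Derive stage seeds (< 2^31) from the master seed.
stage_seeds <- function(seed) {
  withr::with_seed(as.integer(seed), {
    s <- sample.int(.Machine$integer.max - 1L, 4L)
    list(cohort = s[1], split = s[2], ahi_init = s[3], odi_init = s[4])
  })
}

#' Assign cohort members to training, validation and test sets
#'
#' The default strategy mirrors a stratified clinical split: patients are
#' sorted by target AHI and every k-th patient is assigned to the test set,
#' guaranteeing test coverage of the full severity range; the validation set
#' is then drawn at random from the remainder. The `"random"` strategy
#' shuffles everything.
#'
#' @param profiles Cohort tibble from [sample_cohort()].
#' @param n_val,n_test Validation and test set sizes.
#' @param strategy `"ahi_sorted"` or `"random"`.
#' @param seed Seed for the random draws.
#' @return The cohort tibble with an added `set` column
#'   (`train` / `validation` / `test`).
#' @export
split_cohort <- function(profiles, n_val, n_test,
                         strategy = c("ahi_sorted", "random"), seed = 1L) {
  strategy <- match.arg(strategy)
  n <- nrow(profiles)
  if (n_val + n_test >= n) abort("Cohort too small for the requested split.")
  withr::with_seed(as.integer(seed), {
    if (strategy == "ahi_sorted") {
      ord <- order(profiles$target_ahi)
      k <- max(2L, floor(n / n_test))
      test_idx <- ord[seq(k, n, by = k)]
      if (length(test_idx) > n_test) test_idx <- test_idx[seq_len(n_test)]
      while (length(test_idx) < n_test) {  # top up from unused, rare
        pool <- setdiff(ord, test_idx)
        test_idx <- c(test_idx, sample(pool, 1L))
      }
    } else {
      test_idx <- sample.int(n, n_test)
    }
    rest <- setdiff(seq_len(n), test_idx)
    val_idx <- sample(rest, n_val)
  })
  set <- rep("train", n)
  set[test_idx] <- "test"
  set[val_idx] <- "validation"
  profiles$set <- factor(set, levels = c("train", "validation", "test"))
  profiles
}

# Simulate + preprocess one cohort subset into a pooled training matrix.
build_pool <- function(profiles, config, thin) {
  sets <- purrr::pmap(list(seq_len(nrow(profiles))), function(i) {
    p <- profiles[i, ]
    night <- simulate_record(p)
    prepare_record(night$record, night$events,
                   target_fs = config$target_fs, window_s = config$window_s,
                   overlap = config$overlap,
                   invalid_threshold = config$invalid_threshold)
  })
  pool_training_epochs(sets, record_ids = profiles$patient_id, thin = thin)
}

#' Run the full simulate / train / evaluate experiment
#'
#' Samples a synthetic cohort, splits it, pools overlapping training epochs,
#' trains two networks with identical machinery but different targets — one
#' for AHI, one for ODI — estimates full-night indices for every test
#' patient, and assembles the complete evaluation battery for both indices.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return An `osa_experiment`: `cohort` (with set assignment), `models`,
#'   `histories`, `estimates` (per-patient tibble), `evaluation` (list with
#'   `ahi` and `odi` [evaluate_estimates()] reports), `timings`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- stage_seeds(config$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- list()

  t0 <- tic()
  n_total <- config$n_train + config$n_val + config$n_test
  cohort <- sample_cohort(n_total, config$severity_mix, seed = seeds$cohort,
                          recording_duration_s = config$recording_duration_s)
  cohort <- split_cohort(cohort, config$n_val, config$n_test,
                         strategy = config$split, seed = seeds$split)
  timings$cohort <- tic() - t0
  say("Cohort: %d patients (%d train / %d val / %d test)", n_total,
      config$n_train, config$n_val, config$n_test)

  t0 <- tic()
  train_pool <- build_pool(cohort[cohort$set == "train", ], config,
                           thin = config$train_thin)
  val_pool <- build_pool(cohort[cohort$set == "validation", ], config,
                         thin = config$val_thin)
  timings$preprocess <- tic() - t0
  say("Pooled %d training and %d validation epochs",
      nrow(train_pool$inputs), nrow(val_pool$inputs))

  fit_one <- function(target, init_seed) {
    t0 <- tic()
    model <- init_model(config$layer_sizes, seed = init_seed)
    norms <- fit_normalization(train_pool$inputs, train_pool[[target]])
    model$input_norm <- norms$input_norm
    model$target_norm <- norms$target_norm
    fit <- scg_train(model, train_pool$inputs, train_pool[[target]],
                     val_pool$inputs, val_pool[[target]],
                     config = config$training)
    say("%s network: %d iterations (%s), best validation MSE %.4g at %d [%.0f s]",
        toupper(sub("target_", "", target)),
        nrow(fit$history$iterations), fit$history$stop_reason,
        fit$history$best_val_mse, fit$history$best_iteration, tic() - t0)
    fit
  }
  t0 <- tic()
  fit_ahi <- fit_one("target_ahi", seeds$ahi_init)
  fit_odi <- fit_one("target_odi", seeds$odi_init)
  timings$train <- tic() - t0

  t0 <- tic()
  test_cohort <- cohort[cohort$set == "test", ]
  est <- purrr::map_dfr(seq_len(nrow(test_cohort)), function(i) {
    p <- test_cohort[i, ]
    night <- simulate_record(p)
    es <- prepare_record(night$record,
                         target_fs = config$target_fs,
                         window_s = config$window_s,
                         overlap = config$overlap,
                         invalid_threshold = config$invalid_threshold)
    X <- es$epochs[es$valid_mask, , drop = FALSE]
    tibble::tibble(
      patient_id = p$patient_id,
      ref_ahi = night$reference$ahi,
      est_ahi = mean(predict(fit_ahi$model, X)),
      ref_odi = night$reference$odi,
      est_odi = mean(predict(fit_odi$model, X))
    )
  })
  timings$estimate <- tic() - t0

  evaluation <- list(
    ahi = evaluate_estimates(
      dplyr::transmute(est, patient_id = .data$patient_id,
                       reference = .data$ref_ahi, estimate = .data$est_ahi),
      index = "ahi"),
    odi = evaluate_estimates(
      dplyr::transmute(est, patient_id = .data$patient_id,
                       reference = .data$ref_odi, estimate = .data$est_odi),
      index = "odi")
  )
  structure(
    list(cohort = cohort,
         models = list(ahi = fit_ahi$model, odi = fit_odi$model),
         histories = list(ahi = fit_ahi$history, odi = fit_odi$history),
         estimates = est,
         evaluation = evaluation,
         timings = timings,
         config = config),
    class = "osa_experiment"
  )
}

#' @export
print.osa_experiment <- function(x, ...) {
  cat(sprintf("<osa_experiment> %d patients, seed %d\n",
              nrow(x$cohort), x$config$seed))
  for (idx in c("ahi", "odi")) {
    ev <- x$evaluation[[idx]]
    cat(sprintf(
      "  %s: median abs error %.2f ev/h, accuracy %.1f%%, ICC %.3f\n",
      toupper(idx), ev$errors$median_abs_error, 100 * ev$accuracy, ev$icc$icc
    ))
  }
  invisible(x)
}

# --- file-based workflow (the CLI surface) ---------------------------------

#' File-based pipeline stages
#'
#' Thin wrappers that run the pipeline against a directory layout, for use
#' from the command line (`inst/cli/oxinet.R`) or scripts. `cmd_simulate()`
#' writes one record CSV and one annotation CSV per patient plus a cohort
#' manifest; `cmd_train()` reads them back, trains both networks and saves
#' the serialized models and histories; `cmd_evaluate()` writes evaluation
#' reports and per-patient estimates. Identical configs produce identical
#' bytes.
#'
#' @param config An [experiment_config()].
#' @param dir Working directory for the run's files.
#' @param verbose Print progress.
#' @return The directory, invisibly.
#' @export
cmd_simulate <- function(config, dir, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) abort(sprintf("Directory not writable: %s", dir))
  seeds <- stage_seeds(config$seed)
  n_total <- config$n_train + config$n_val + config$n_test
  cohort <- sample_cohort(n_total, config$severity_mix, seed = seeds$cohort,
                          recording_duration_s = config$recording_duration_s)
  cohort <- split_cohort(cohort, config$n_val, config$n_test,
                         strategy = config$split, seed = seeds$split)
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    night <- simulate_record(p)
    write_spo2_csv(night$record, file.path(dir, paste0(p$patient_id, "_spo2.csv")))
    write_events_csv(night$events, file.path(dir, paste0(p$patient_id, "_events.csv")))
  }
  write_manifest_json(cohort, file.path(dir, "manifest.json"),
                      extra = list(seed = config$seed))
  if (verbose) message(sprintf("Wrote %d patients to %s", nrow(cohort), dir))
  invisible(dir)
}

load_cohort_set <- function(dir, set) {
  manifest <- read_manifest_json(file.path(dir, "manifest.json"))
  cohort <- manifest$profiles[manifest$profiles$set == set, ]
  if (!nrow(cohort)) abort(sprintf("No '%s' patients in %s", set, dir))
  cohort
}

#' @rdname cmd_simulate
#' @export
cmd_train <- function(config, dir, verbose = TRUE) {
  if (!file.exists(file.path(dir, "manifest.json"))) {
    abort(sprintf("No cohort manifest in %s; run the simulate stage first.", dir))
  }
  seeds <- stage_seeds(config$seed)
  read_set_pool <- function(set, thin) {
    cohort <- load_cohort_set(dir, set)
    sets <- purrr::map(seq_len(nrow(cohort)), function(i) {
      p <- cohort[i, ]
      rec <- read_spo2_csv(file.path(dir, paste0(p$patient_id, "_spo2.csv")))
      ev <- read_events_csv(file.path(dir, paste0(p$patient_id, "_events.csv")))
      prepare_record(rec, ev, target_fs = config$target_fs,
                     window_s = config$window_s, overlap = config$overlap,
                     invalid_threshold = config$invalid_threshold)
    })
    pool_training_epochs(sets, record_ids = cohort$patient_id, thin = thin)
  }
  train_pool <- read_set_pool("train", config$train_thin)
  val_pool <- read_set_pool("validation", config$val_thin)
  for (target in c("ahi", "odi")) {
    init_seed <- if (target == "ahi") seeds$ahi_init else seeds$odi_init
    model <- init_model(config$layer_sizes, seed = init_seed)
    norms <- fit_normalization(train_pool$inputs,
                               train_pool[[paste0("target_", target)]])
    model$input_norm <- norms$input_norm
    model$target_norm <- norms$target_norm
    fit <- scg_train(model, train_pool$inputs,
                     train_pool[[paste0("target_", target)]],
                     val_pool$inputs, val_pool[[paste0("target_", target)]],
                     config = config$training)
    save_model(fit$model, file.path(dir, paste0("model_", target, ".json")))
    jsonlite::write_json(
      list(best_iteration = fit$history$best_iteration,
           best_val_mse = fit$history$best_val_mse,
           stop_reason = fit$history$stop_reason,
           iterations = fit$history$iterations),
      file.path(dir, paste0("history_", target, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    if (verbose) {
      message(sprintf("%s network: stopped by %s, best iteration %d",
                      toupper(target), fit$history$stop_reason,
                      fit$history$best_iteration))
    }
  }
  invisible(dir)
}

#' @rdname cmd_simulate
#' @export
cmd_evaluate <- function(config, dir, verbose = TRUE) {
  for (f in c("model_ahi.json", "model_odi.json", "manifest.json")) {
    if (!file.exists(file.path(dir, f))) {
      abort(sprintf("Missing %s in %s; run earlier stages first.", f, dir))
    }
  }
  models <- list(ahi = load_model(file.path(dir, "model_ahi.json")),
                 odi = load_model(file.path(dir, "model_odi.json")))
  cohort <- load_cohort_set(dir, "test")
  est <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    rec <- read_spo2_csv(file.path(dir, paste0(p$patient_id, "_spo2.csv")))
    ev <- read_events_csv(file.path(dir, paste0(p$patient_id, "_events.csv")))
    ref <- annotation_indices(ev, rec$duration_s)
    es <- prepare_record(rec, target_fs = config$target_fs,
                         window_s = config$window_s, overlap = config$overlap,
                         invalid_threshold = config$invalid_threshold)
    X <- es$epochs[es$valid_mask, , drop = FALSE]
    tibble::tibble(patient_id = p$patient_id,
                   ref_ahi = ref$ahi, est_ahi = mean(predict(models$ahi, X)),
                   ref_odi = ref$odi, est_odi = mean(predict(models$odi, X)))
  })
  readr::write_csv(est, file.path(dir, "estimates.csv"))
  for (idx in c("ahi", "odi")) {
    ev <- evaluate_estimates(
      tibble::tibble(patient_id = est$patient_id,
                     reference = est[[paste0("ref_", idx)]],
                     estimate = est[[paste0("est_", idx)]]),
      index = idx
    )
    write_report(ev, file.path(dir, paste0("report_", idx)))
    if (verbose) print(ev)
  }
  invisible(dir)
}
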