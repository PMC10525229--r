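# End-to-end experiment orchestration: simulate -> condition -> slice ->
# spectrogram -> texture features -> GA selection -> six classifiers.
#
# A single global seed fans out deterministically to per-stage seeds, so a
# rerun with the same configuration reproduces every artifact bit-for-bit.

# Stage seeds derived from the global seed by a fixed affine scheme; the
# modulus keeps derived seeds inside the 32-bit integer range.
.stage_seed <- function(global_seed, stage) {
  offsets <- c(synth = 1L, filter = 2L, spectrogram = 3L, features = 4L,
               select = 5L, classify = 6L)
  as.integer((as.numeric(global_seed) + offsets[[stage]] * 100003) %% 2147483647)
}

#' Experiment configuration
#'
#' Bundles the per-stage configurations of the full pipeline. The defaults
#' are the desk-scale benchmark: 6 recordings of 20 s, 5 events per class
#' per recording, high class separability and a low noise floor, with a
#' compact GA search (population 30, 25 generations) sized for interactive
#' runs.
#'
#' @param synth a [synth_config()].
#' @param filter a [filter_config()] or `NULL` to skip conditioning.
#' @param spectrogram a [spectrogram_config()].
#' @param ng gray levels for quantization.
#' @param texture a [texture_config()].
#' @param ga a [ga_config()] or `NULL` to skip selection (all features kept).
#' @param models character vector of classifier kinds to train.
#' @param train_fraction fraction of events used for training.
#' @param seed global integer seed; all stage seeds derive from it.
#' @param out_dir directory for artifacts, or `NULL` to keep everything in
#'   memory.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(synth = synth_config(),
                              filter = NULL,
                              spectrogram = spectrogram_config(log_floor = 0.02),
                              ng = 32,
                              texture = texture_config(),
                              ga = ga_config(genome_length = 32,
                                             population_size = 30,
                                             generations = 25),
                              models = .jm_kinds,
                              train_fraction = 2 / 3,
                              seed = 1L,
                              out_dir = NULL) {
  bad <- setdiff(models, .jm_kinds)
  if (length(bad)) stop("unknown classifier kind(s): ", paste(bad, collapse = ", "))
  structure(list(synth = synth, filter = filter, spectrogram = spectrogram,
                 ng = ng, texture = texture, ga = ga, models = models,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full jaw-movement classification experiment
#'
#' Executes every stage in order: synthesizes labeled recordings, optionally applies
#' the adaptive low-pass conditioning, slices labeled event segments,
#' converts each to a quantized time-frequency image, extracts the
#' 32-feature texture vector, optionally runs the GA feature selection, then
#' trains and evaluates the configured classifiers on a stratified
#' two-thirds/one-third split. When `cfg$out_dir` is set, every intermediate
#' artifact (WAV, label CSV, feature CSV, selection JSON, report JSON) is
#' written along with a manifest of content hashes.
#'
#' @param cfg an [experiment_config()].
#' @return an object of class `jm_experiment`: `features` (feature table),
#'   `selection` (`jm_selection` or `NULL`), `reports` (named list of
#'   `jm_report`), `split`, `manifest` (data.frame of file hashes, empty if
#'   nothing was written) and `seeds`.
#' @export
run_experiment <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  seeds <- vapply(c("synth", "filter", "spectrogram", "features", "select",
                    "classify"),
                  function(s) .stage_seed(cfg$seed, s), integer(1))
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  # 1. simulate
  segments <- list()
  for (r in seq_len(cfg$synth$n_recordings)) {
    rec <- tryCatch(
      generate_recording(cfg$synth, seed = seeds[["synth"]] + r),
      error = function(e) stop("stage synth, recording ", r, ": ",
                               conditionMessage(e), call. = FALSE))
    sig <- rec$signal
    if (!is.null(out)) {
      wav <- file.path(out, sprintf("recording_%02d.wav", r))
      lab <- file.path(out, sprintf("recording_%02d_labels.csv", r))
      write_wav(sig, wav); emit(wav)
      write_labels(rec$labels, lab); emit(lab)
    }
    # 2. condition
    if (!is.null(cfg$filter)) {
      sig <- tryCatch(adaptive_lowpass(sig, cfg$filter),
                      error = function(e) stop("stage filter, recording ", r,
                                               ": ", conditionMessage(e),
                                               call. = FALSE))
    }
    # 3. slice
    segments <- c(segments, slice_events(sig, rec$labels))
  }

  # 4. spectrogram + texture features
  features <- tryCatch(
    extract_feature_table(segments, cfg$spectrogram, cfg$ng, cfg$texture),
    error = function(e) stop("stage features: ", conditionMessage(e),
                             call. = FALSE))
  if (!is.null(out)) {
    fcsv <- file.path(out, "features.csv")
    write_feature_table(features, fcsv); emit(fcsv)
  }

  # 5. split, then GA selection on the training rows only, so the feature
  # subset never sees the held-out test events
  split <- split_train_test(features, cfg$train_fraction,
                            seed = seeds[["classify"]])
  selection <- NULL
  if (!is.null(cfg$ga)) {
    ga_cfg <- cfg$ga
    ga_cfg$seed <- seeds[["select"]]
    ga_cfg$genome_length <- ncol(features) - 1L
    selection <- tryCatch(ga_run(split$train, ga_cfg),
                          error = function(e) stop("stage select: ",
                                                   conditionMessage(e),
                                                   call. = FALSE))
    keep <- c(selection$selected_names, "class")
    split$train <- split$train[, keep, drop = FALSE]
    split$test <- split$test[, keep, drop = FALSE]
    if (!is.null(out)) {
      sjson <- file.path(out, "selection.json")
      jsonlite::write_json(list(mask = as.integer(selection$best_mask),
                                selected = selection$selected_names,
                                best_fitness = selection$best_fitness,
                                trajectory = selection$fitness_trajectory),
                           sjson, auto_unbox = TRUE, digits = NA)
      emit(sjson)
    }
  }

  # 6. train and evaluate the classifier suite
  reports <- list()
  for (kind in cfg$models) {
    mcfg <- model_config(kind, seed = seeds[["classify"]])
    model <- tryCatch(train_classifier(kind, split$train, mcfg),
                      error = function(e) stop("stage classify (", kind, "): ",
                                               conditionMessage(e),
                                               call. = FALSE))
    reports[[kind]] <- evaluate(model, split$test)
  }
  if (!is.null(out)) {
    rjson <- file.path(out, "reports.json")
    jsonlite::write_json(report_bundle_json(reports), rjson,
                         auto_unbox = TRUE, digits = NA)
    emit(rjson)
  }

  manifest <- if (length(written)) {
    data.frame(file = basename(written),
               md5 = unname(tools::md5sum(written)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(file = character(0), md5 = character(0))
  }
  if (!is.null(out)) {
    utils::write.csv(manifest, file.path(out, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  structure(list(features = features, selection = selection, reports = reports,
                 split = split, manifest = manifest, seeds = seeds),
            class = "jm_experiment")
}

# Plain-list rendering of a set of reports, stable field order, for JSON.
report_bundle_json <- function(reports) {
  lapply(reports, function(rep) {
    pc <- rep$per_class
    list(totals = as.list(rep$totals),
         per_class = lapply(seq_len(nrow(pc)), function(i) {
           list(class = pc$class[i], precision = pc$precision[i],
                recall = pc$recall[i], f1 = pc$f1[i], flag = pc$flag[i])
         }),
         confusion = apply(rep$confusion, 1, as.list))
  })
}

#' @export
print.jm_experiment <- function(x, ...) {
  cat("<jm_experiment>\n")
  cat(sprintf("  events: %d, features kept: %d\n", nrow(x$features),
              if (is.null(x$selection)) ncol(x$features) - 1L
              else sum(x$selection$best_mask)))
  for (kind in names(x$reports)) {
    t <- x$reports[[kind]]$totals
    cat(sprintf("  %-14s precision %6.2f  recall %6.2f  F1 %6.2f\n",
                kind, t["precision"], t["recall"], t["f1"]))
  }
  invisible(x)
}
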