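#' Truncated two-decimal macro mean accuracy
#'
#' The unweighted mean of per-class accuracies, truncated (toward
#' zero, not rounded) to two decimals — the convention used by
#' mean-recognition-accuracy rows in activity-recognition report
#' tables.
#'
#' @param per_class Numeric vector of per-class accuracies in percent.
#' @return Scalar percentage with exactly two decimals of precision.
#' @export
#' @examples
#' macro_accuracy(c(98.81, 98.47, 91.23, 92.07, 93.18, 98.47))  # 95.37
macro_accuracy <- function(per_class) {
  trunc(mean(per_class) * 100) / 100
}

#' Split labelled frames into train and test sets
#'
#' `stratified_windows` samples a fixed fraction of frames per class;
#' `leave_subjects_out` holds out whole subjects (no frame of a held-out
#' subject appears in training). Deterministic given `seed`.
#'
#' @param frames List of labelled [har_frame()]s.
#' @param protocol `"stratified_windows"` or `"leave_subjects_out"`.
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `test` frame lists.
#' @export
split_frames <- function(frames,
                         protocol = c("stratified_windows",
                                      "leave_subjects_out"),
                         fraction = 0.7, seed = 1L) {
  protocol <- match.arg(protocol)
  labels <- vapply(frames, `[[`, "", "label")
  if (anyNA(labels)) stop("all frames must be labelled")
  idx_train <- withr::with_seed(as.integer(seed), {
    if (protocol == "stratified_windows") {
      unlist(lapply(split(seq_along(frames), labels), function(i)
        sample(i, max(1L, round(fraction * length(i))))))
    } else {
      subjects <- vapply(frames, `[[`, "", "subject")
      uniq <- unique(subjects)
      n_train <- max(1L, round(fraction * length(uniq)))
      keep <- sample(uniq, n_train)
      which(subjects %in% keep)
    }
  })
  train <- frames[sort(idx_train)]
  test <- frames[setdiff(seq_along(frames), idx_train)]
  if (protocol == "stratified_windows") {
    miss <- setdiff(unique(labels),
                    vapply(test, `[[`, "", "label"))
    if (length(miss))
      stop("class absent from test split: ", paste(miss, collapse = ", "))
  }
  list(train = train, test = test)
}

#' Evaluation report: confusion matrix and accuracies
#'
#' Builds the standard report from true and predicted labels: a K x K
#' confusion matrix (rows = true class), per-class accuracy (the
#' diagonal over the row sum, i.e. recall, in percent) and the macro
#' mean truncated to two decimals.
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param classifier Tag recorded in the report (`"proposed"`,
#'   `"lsvm"`, `"rf"`, ...).
#' @param overlap_ratio Overlap used to produce the frames (recorded).
#' @return Object of class `har_report` with fields `confusion`,
#'   `per_class`, `macro_mean`, `classifier`, `overlap_ratio`.
#' @export
har_report <- function(truth, predicted, classifier = "proposed",
                       overlap_ratio = NA_real_) {
  if (length(truth) == 0) stop("empty test set")
  classes <- levels(factor(truth))
  truth <- factor(truth, levels = classes)
  predicted <- factor(predicted, levels = union(classes,
                                                unique(predicted)))
  confusion <- table(truth = truth, predicted = predicted)
  per_class <- 100 * diag(confusion[classes, classes, drop = FALSE]) /
    rowSums(confusion)
  structure(list(confusion = unclass(confusion),
                 per_class = per_class,
                 macro_mean = macro_accuracy(per_class),
                 classifier = classifier,
                 overlap_ratio = overlap_ratio),
            class = "har_report")
}

#' @export
print.har_report <- function(x, ...) {
  cat(sprintf("<har_report> %s%s\n", x$classifier,
              if (!is.na(x$overlap_ratio))
                sprintf(" @ %.0f%% overlap", 100 * x$overlap_ratio)
              else ""))
  tab <- data.frame(activity = names(x$per_class),
                    accuracy = sprintf("%.2f", x$per_class))
  print(tab, row.names = FALSE)
  cat(sprintf("Mean recognition accuracy: %.2f\n", x$macro_mean))
  invisible(x)
}

#' Run the full pipeline on labelled streams and evaluate
#'
#' Preprocesses each stream (median filter, moving average, per-stream
#' min-max normalisation), frames at the configured window/overlap,
#' extracts the multi-fused feature bank, splits train/test, evolves
#' the GA feature weights on the training partition, trains the
#' template classifier and the two baselines, and reports all three on
#' the test partition.
#'
#' @param streams List of labelled [har_stream()]s.
#' @param config A [har_config()].
#' @param seed Integer seed for the split and the GA.
#' @param protocol Split protocol (see [split_frames()]).
#' @param baselines Logical; also fit and report the LSVM and
#'   random-forest baselines (default `TRUE`).
#' @param evolve_weights Logical; run the GA (default `TRUE`; `FALSE`
#'   uses unit weights, useful for quick checks).
#' @return List of class `har_run`: `reports` (named list of
#'   `har_report`s), `model`, `evolution`, `table` (the full feature
#'   table), `split`.
#' @export
har_run_pipeline <- function(streams, config = har_config(), seed = 1L,
                             protocol = "stratified_windows",
                             baselines = TRUE, evolve_weights = TRUE) {
  frames <- unlist(lapply(streams, function(s)
    frame_stream(preprocess_stream(s, config),
                 config$window_seconds, config$overlap_ratio)),
    recursive = FALSE)
  if (length(frames) == 0) stop("no frames produced; streams too short?")
  table <- har_feature_table(frames, config)
  labels <- table$label
  idx_train <- withr::with_seed(as.integer(seed), {
    if (protocol == "stratified_windows") {
      sort(unlist(lapply(split(seq_along(frames), labels), function(i)
        sample(i, max(1L, round(config$split_fraction * length(i)))))))
    } else {
      subjects <- vapply(frames, `[[`, "", "subject")
      uniq <- unique(subjects)
      keep <- sample(uniq, max(1L, round(config$split_fraction *
                                           length(uniq))))
      which(subjects %in% keep)
    }
  })
  train_tab <- table[idx_train, , drop = FALSE]
  test_tab <- table[-idx_train, , drop = FALSE]
  feat_cols <- setdiff(names(table), "label")
  evolution <- NULL
  weights <- rep(1, length(feat_cols))
  if (evolve_weights) {
    evolution <- evolve(train_tab[feat_cols], train_tab$label, config,
                        seed = seed)
    weights <- evolution$best
  }
  model <- har_train(train_tab, weights = weights, config = config)
  reports <- list(proposed = har_report(
    test_tab$label, har_predict(model, test_tab),
    "proposed", config$overlap_ratio))
  if (baselines) {
    for (kind in c("lsvm", "rf")) {
      b <- train_baseline(kind, train_tab, seed = seed)
      reports[[kind]] <- har_report(
        test_tab$label, predict_baseline(b, test_tab), kind,
        config$overlap_ratio)
    }
  }
  structure(list(reports = reports, model = model, evolution = evolution,
                 table = table, idx_train = idx_train),
            class = "har_run")
}

#' @export
print.har_run <- function(x, ...) {
  for (r in x$reports) print(r)
  invisible(x)
}

#' Sweep sliding-window overlap ratios
#'
#' Reruns the full pipeline per overlap ratio with the same seed and
#' tabulates per-class accuracy (proposed classifier) by ratio plus
#' the truncated macro means.
#'
#' @param streams Labelled [har_stream()]s.
#' @param ratios Overlap ratios to sweep (default `c(0.1, 0.3, 0.6)`).
#' @param config Base [har_config()] (its `overlap_ratio` is replaced
#'   per run).
#' @param seed Integer seed shared by all runs.
#' @param ... Passed on to [har_run_pipeline()].
#' @return List of class `har_sweep`: `table` (data frame of per-class
#'   accuracies, one column per ratio), `macro_means` (named vector),
#'   `runs` (the individual `har_run`s).
#' @export
sweep_overlaps <- function(streams, ratios = c(0.1, 0.3, 0.6),
                           config = har_config(), seed = 1L, ...) {
  runs <- lapply(ratios, function(r) {
    cfg <- config
    cfg$overlap_ratio <- r
    har_run_pipeline(streams, cfg, seed = seed, ...)
  })
  per_class <- lapply(runs, function(run) run$reports$proposed$per_class)
  classes <- names(per_class[[1]])
  tab <- data.frame(activity = classes,
                    vapply(per_class, function(p) p[classes],
                           numeric(length(classes))))
  names(tab)[-1] <- sprintf("slide_%d", round(100 * ratios))
  macro <- vapply(per_class, macro_accuracy, 0)
  names(macro) <- names(tab)[-1]
  structure(list(table = tab, macro_means = macro, runs = runs,
                 ratios = ratios),
            class = "har_sweep")
}

#' @export
print.har_sweep <- function(x, ...) {
  cat("<har_sweep> per-class accuracy (%) by overlap ratio\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) sprintf("%.2f", v))
  print(tab, row.names = FALSE)
  cat("Mean recognition accuracy:",
      paste(sprintf("%s=%.2f", names(x$macro_means), x$macro_means),
            collapse = "  "), "\n")
  invisible(x)
}

#' Per-trial feature-weight report
#'
#' Tabulates the best chromosome of one or more GA runs ("trials"),
#' either per gene or grouped by feature kind (the 13 classic rows:
#' zero crossing rate, fundamental frequency, signal magnitude area,
#' signal energy, mean, median, mode, standard deviation, variance,
#' phase angle, correlation, min, max), where a grouped cell is the
#' mean weight of that kind's genes.
#'
#' @param evolutions List of [evolve()] results (or single result).
#' @param grouped Logical; group genes by feature kind (default
#'   `TRUE`).
#' @param n_imf IMFs per axis in the registry (default 3).
#' @return Data frame, rows = features (or kinds), columns = trials.
#' @export
weight_report <- function(evolutions, grouped = TRUE, n_imf = 3) {
  if (inherits(evolutions, "har_evolution"))
    evolutions <- list(evolutions)
  reg <- har_feature_registry(n_imf)
  cols <- lapply(evolutions, function(ev) {
    w <- ev$best
    if (length(w) != nrow(reg))
      stop("chromosome length does not match the feature registry")
    names(w) <- reg$name
    w
  })
  if (!grouped) {
    out <- data.frame(feature = reg$name,
                      vapply(cols, identity, numeric(nrow(reg))))
  } else {
    kinds <- c("zcr", "f0", "sma", "energy", "mean", "median", "mode",
               "std", "var", "phase", "corr", "min", "max")
    kind_labels <- c("Zero Crossing Rate", "Fundamental Frequency",
                     "Signal Magnitude Area", "Signal Energy", "Mean",
                     "Median", "Mode", "Standard Deviation", "Variance",
                     "Phase Angle", "Correlation", "Min", "Max")
    out <- data.frame(feature = kind_labels,
                      vapply(cols, function(w)
                        vapply(kinds, function(k)
                          mean(w[reg$kind == k]), 0),
                        numeric(length(kinds))))
  }
  names(out)[-1] <- paste0("trial_", seq_along(cols))
  rownames(out) <- NULL
  out
}
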