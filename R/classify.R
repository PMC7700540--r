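#' Build per-class templates
#'
#' The template for a class is the elementwise mean of the (retained,
#' reweighted) training vectors of that class — the stored pattern each
#' test vector is matched against.
#'
#' @param features Matrix or data frame of retained, reweighted feature
#'   columns.
#' @param labels Class labels (>= 1 sample per class).
#' @return Matrix, one row per class (row names are class labels in
#'   first-appearance order of `factor` levels).
#' @export
build_templates <- function(features, labels) {
  m <- as.matrix(features)
  labels <- factor(labels)
  if (any(table(labels) < 1)) stop("every class needs at least 1 sample")
  out <- matrix(0, nlevels(labels), ncol(m),
                dimnames = list(levels(labels), colnames(m)))
  for (cl in levels(labels))
    out[cl, ] <- colMeans(m[labels == cl, , drop = FALSE])
  out
}

## cosine similarity; negative Euclidean distance when either vector is
## all-zero (cosine undefined)
similarity_score <- function(v, template, metric = "cosine") {
  if (metric == "euclidean") return(-sqrt(sum((v - template)^2)))
  nv <- sqrt(sum(v^2)); nt <- sqrt(sum(template^2))
  if (nv == 0 || nt == 0) return(-sqrt(sum((v - template)^2)))
  sum(v * template) / (nv * nt)
}

#' Match a test vector against class templates
#'
#' Scores the vector against every template (cosine similarity by
#' default; negative Euclidean distance when either vector is all-zero
#' or `metric = "euclidean"`) and predicts the argmax; exact ties go to
#' the earliest class in training-label order.
#'
#' @param vector Numeric test vector (already reweighted and restricted
#'   to retained features).
#' @param templates Template matrix from [build_templates()].
#' @param metric `"cosine"` or `"euclidean"`.
#' @return List with `label` and named `scores`.
#' @export
match_template <- function(vector, templates, metric = "cosine") {
  if (length(vector) != ncol(templates))
    stop("vector length (", length(vector),
         ") does not match template width (", ncol(templates), ")")
  scores <- apply(templates, 1, similarity_score, v = as.numeric(vector),
                  metric = metric)
  list(label = rownames(templates)[which.max(scores)], scores = scores)
}

#' Train the weighted template-matching classifier
#'
#' Full training path of the proposed classifier: min-max normalise the
#' feature columns (training extremes are stored and reapplied at
#' prediction), reweight by the evolved chromosome, restrict to the
#' contributive features ([select_features()]), and build per-class
#' mean templates.
#'
#' @param features Data frame of feature columns plus a `label` column,
#'   or a matrix/data frame of features with `labels` given separately.
#' @param labels Class labels (ignored when `features` has a `label`
#'   column).
#' @param weights Evolved per-feature weight vector (one gene per
#'   feature column); `NULL` means unit weights.
#' @param config A [har_config()] (similarity metric snapshot).
#' @return Object of class `har_model`.
#' @export
har_train <- function(features, labels = NULL, weights = NULL,
                      config = har_config()) {
  fl <- split_feature_frame(features, labels)
  m <- fl$m; labels <- fl$labels
  if (is.null(weights)) weights <- rep(1, ncol(m))
  if (length(weights) != ncol(m))
    stop("one weight per feature column required")
  extremes <- rbind(min = apply(m, 2, min), max = apply(m, 2, max))
  mn <- normalize_columns(m, extremes)
  retained <- select_features(weights, colnames(m))
  mw <- reweight(mn, weights)[, retained, drop = FALSE]
  structure(list(templates = build_templates(mw, labels),
                 weights = stats::setNames(weights, colnames(m)),
                 retained = retained,
                 extremes = extremes,
                 classes = levels(factor(labels)),
                 similarity = config$similarity,
                 config = config),
            class = "har_model")
}

#' @export
print.har_model <- function(x, ...) {
  cat(sprintf("<har_model> %d class(es), %d/%d features retained, %s matching\n",
              nrow(x$templates), length(x$retained), length(x$weights),
              x$similarity))
  invisible(x)
}

#' Predict activity labels with a trained template model
#'
#' Applies the stored normalisation extremes (clamping to `[0, 1]`),
#' the chromosome weights and the retained-feature restriction, then
#' matches each row against the class templates.
#'
#' @param model A [har_train()] model.
#' @param features Data frame/matrix of feature columns (a `label`
#'   column, if present, is ignored).
#' @return Character vector of predicted labels with attribute
#'   `"scores"` (matrix of per-class similarities).
#' @export
har_predict <- function(model, features) {
  stopifnot(inherits(model, "har_model"))
  fl <- split_feature_frame(features, labels = NA, require_labels = FALSE)
  m <- fl$m
  if (!all(names(model$weights) %in% colnames(m)))
    stop("prediction features lack columns: ",
         paste(setdiff(names(model$weights), colnames(m)), collapse = ", "))
  m <- m[, names(model$weights), drop = FALSE]
  mn <- normalize_columns(m, model$extremes, clamp = TRUE)
  mw <- reweight(mn, model$weights)[, model$retained, drop = FALSE]
  res <- apply(mw, 1, match_template, templates = model$templates,
               metric = model$similarity)
  labels <- vapply(res, `[[`, "", "label")
  scores <- t(vapply(res, `[[`, numeric(nrow(model$templates)), "scores"))
  attr(labels, "scores") <- scores
  labels
}

#' Train and apply the baseline classifiers
#'
#' The two classifier configurations used inside the GA fitness,
#' exposed for comparison columns: a linear SVM (cost 1) and a random
#' forest (100 trees).
#'
#' @param kind `"lsvm"` or `"rf"`.
#' @param features Feature data frame (with `label` column) or matrix.
#' @param labels Class labels (if not in `features`).
#' @param seed Integer seed (controls the forest).
#' @return Object of class `har_baseline`.
#' @export
train_baseline <- function(kind = c("lsvm", "rf"), features,
                           labels = NULL, seed = 1L) {
  kind <- match.arg(kind)
  fl <- split_feature_frame(features, labels)
  m <- fl$m; labels <- factor(fl$labels)
  if (nlevels(labels) < 2) stop("baselines need at least 2 classes")
  varying <- apply(m, 2, function(v) stats::sd(v) > 0)
  fit <- if (kind == "lsvm")
    e1071::svm(m, labels, kernel = "linear", cost = 1, scale = varying)
  else withr::with_seed(as.integer(seed),
    randomForest::randomForest(m, labels, ntree = 100))
  structure(list(kind = kind, fit = fit, features = colnames(m)),
            class = "har_baseline")
}

#' @rdname train_baseline
#' @param model A `har_baseline` model.
#' @export
predict_baseline <- function(model, features) {
  stopifnot(inherits(model, "har_baseline"))
  fl <- split_feature_frame(features, labels = NA, require_labels = FALSE)
  m <- fl$m[, model$features, drop = FALSE]
  as.character(predict(model$fit, m))
}

## --- helpers -------------------------------------------------------

## Accepts either (data.frame with label column) or (matrix, labels)
split_feature_frame <- function(features, labels = NULL,
                                require_labels = TRUE) {
  if (is.data.frame(features) && "label" %in% names(features)) {
    labels <- features$label
    features <- features[setdiff(names(features), "label")]
  }
  m <- as.matrix(features)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("f", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  if (require_labels && (is.null(labels) || all(is.na(labels))))
    stop("labels are required")
  list(m = m, labels = labels)
}

## Column-wise min-max with stored extremes; constant columns -> 0.
normalize_columns <- function(m, extremes, clamp = TRUE) {
  out <- m
  for (j in seq_len(ncol(m))) {
    lo <- extremes[1, j]; hi <- extremes[2, j]
    if (hi == lo) out[, j] <- 0
    else {
      v <- (m[, j] - lo) / (hi - lo)
      out[, j] <- if (clamp) pmin(pmax(v, 0), 1) else v
    }
  }
  out
}

#' Serialise / restore a trained model as JSON
#'
#' @param model A [har_model()][har_train()] object.
#' @param path JSON file path.
#' @return `read_har_model()` returns the restored `har_model`.
#' @export
write_har_model <- function(model, path) {
  stopifnot(inherits(model, "har_model"))
  x <- list(template_classes = rownames(model$templates),
            template_features = colnames(model$templates),
            templates = apply(model$templates, 1, as.numeric,
                              simplify = FALSE),
            feature_names = names(model$weights),
            weights = as.numeric(model$weights),
            retained = model$retained,
            extremes_min = as.numeric(model$extremes[1, ]),
            extremes_max = as.numeric(model$extremes[2, ]),
            classes = model$classes,
            similarity = model$similarity)
  jsonlite::write_json(x, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_har_model
#' @export
read_har_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  templates <- if (is.list(x$templates)) do.call(rbind, x$templates)
               else as.matrix(x$templates)
  dimnames(templates) <- list(x$template_classes, x$template_features)
  extremes <- rbind(min = x$extremes_min, max = x$extremes_max)
  colnames(extremes) <- x$feature_names
  structure(list(templates = templates,
                 weights = stats::setNames(x$weights, x$feature_names),
                 retained = x$retained,
                 extremes = extremes,
                 classes = x$classes,
                 similarity = x$similarity,
                 config = har_config()),
            class = "har_model")
}
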