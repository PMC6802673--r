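#' Leave-one-out cross-validation accuracy
#'
#' Each record is held out in turn, the scale-then-classify pipeline is
#' refit on the remaining n-1 records, and the held-out record is
#' predicted. The score is the pooled fraction of correct held-out
#' predictions (per-fold balanced accuracy is degenerate for
#' single-record folds).
#'
#' @param dataset An \code{encoded_dataset} with at least 3 records.
#' @param classifier An \code{fb_classifier}.
#' @return List of class \code{"fb_eval"}: \code{dataset_id},
#'   \code{output}, \code{blocks}, \code{classifier}, \code{cv},
#'   \code{score}, \code{predictions} (one per record),
#'   \code{n_features}, \code{n_records}.
#' @export
loocv_accuracy <- function(dataset, classifier) {
  stopifnot(inherits(dataset, "encoded_dataset"))
  n <- nrow(dataset$x)
  if (n < 3L) stop("LOOCV needs at least 3 records", call. = FALSE)
  preds <- integer(n)
  for (i in seq_len(n)) {
    preds[i] <- fit_predict_pipeline(dataset$x[-i, , drop = FALSE],
                                     dataset$y[-i],
                                     dataset$x[i, , drop = FALSE],
                                     classifier)
  }
  new_eval(dataset, classifier, cv = "LOOCV",
           score = mean(preds == dataset$y), predictions = preds)
}

# engineered-feature values for records `rows`, with every group
# statistic (cell means, category counts) estimated from records `ref`
# only; a group unseen in `ref` falls back to the reference grand mean
# (MA) or probability 0
strict_block_matrix <- function(records, ref, rows, blocks) {
  key_of <- function(idx, axes) {
    do.call(paste, c(records[idx, axes, drop = FALSE], sep = "\r"))
  }
  ma_cols <- function(axes, label) {
    refk <- key_of(ref, axes); rk <- key_of(rows, axes)
    m <- vapply(fb_proteins(), function(p) {
      means <- tapply(records[[p]][ref], refk, mean)
      est <- unname(means[rk])
      est[is.na(est)] <- mean(records[[p]][ref])
      est - records[[p]][rows]
    }, numeric(length(rows)))
    m <- matrix(m, nrow = length(rows),
                dimnames = list(NULL, ma_colname(fb_proteins(), label)))
    m
  }
  prob_cols <- function(axes_list, names) {
    m <- vapply(axes_list, function(axes) {
      refk <- key_of(ref, axes); rk <- key_of(rows, axes)
      counts <- table(refk)
      p <- unname(counts[rk]) / length(ref)
      ifelse(is.na(p), 0, p)
    }, numeric(length(rows)))
    matrix(m, nrow = length(rows), dimnames = list(NULL, names))
  }
  parts <- lapply(blocks, function(b) switch(b,
    Metab  = build_metab(records[rows, , drop = FALSE]),
    MAmix  = ma_cols(fb_axes(), "experim"),
    MAi    = do.call(cbind, lapply(fb_axes(), function(a)
               ma_cols(a, axis_label(a)))),
    OneHot = build_one_hot(records[rows, , drop = FALSE]),
    ProbMix = prob_cols(list(fb_axes()), "Prob_Mix"),
    ProbECs = prob_cols(as.list(fb_axes()),
                        c("Prob_Animal", "Prob_Treat", "Prob_Period")),
    stop("unknown feature block: ", b, call. = FALSE)))
  do.call(cbind, parts)
}

#' Leakage-free (strict) LOOCV for engineered features
#'
#' The default pipeline computes group-mean-centered and probability
#' features on the full table before cross-validation, as the original
#' study scripts do; the held-out record then contributes to its own
#' group's statistics, a mild form of information leakage. This strict
#' variant recomputes every engineered feature inside each training
#' fold: the held-out record's centered features use group means (and
#' category counts) estimated from the training records only.
#'
#' @param records Canonical study table.
#' @param spec Dataset spec (output + blocks).
#' @param classifier An \code{fb_classifier}.
#' @return An \code{fb_eval}, \code{cv = "LOOCV-strict"}.
#' @export
loocv_accuracy_strict <- function(records, spec, classifier) {
  records <- validate_study_table(records)
  y <- binarize_output(records, spec$output)
  keep <- which(!is.na(y))
  if (length(keep) < 3L) stop("LOOCV needs at least 3 records", call. = FALSE)
  preds <- integer(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    tr <- setdiff(keep, i)
    xtr <- strict_block_matrix(records, tr, tr, spec$blocks)
    xte <- strict_block_matrix(records, tr, i, spec$blocks)
    preds[j] <- fit_predict_pipeline(xtr, y[tr], xte, classifier)
  }
  ds <- list(spec = spec, x = strict_block_matrix(records, keep, keep,
                                                  spec$blocks),
             y = y[keep])
  class(ds) <- "encoded_dataset"
  new_eval(ds, classifier, cv = "LOOCV-strict",
           score = mean(preds == y[keep]), predictions = preds)
}

new_eval <- function(dataset, classifier, cv, score, predictions = NULL) {
  structure(list(
    dataset_id = dataset$spec$id, output = dataset$spec$output,
    blocks = paste(dataset$spec$blocks, collapse = "+"),
    classifier = classifier$family, cv = cv, score = score,
    predictions = predictions,
    n_features = ncol(dataset$x), n_records = nrow(dataset$x)
  ), class = "fb_eval")
}

#' @export
print.fb_eval <- function(x, ...) {
  cat(sprintf("<eval %s | %s | %s: score %.3f (%d records, %d features)>\n",
              x$dataset_id, x$classifier, x$cv, x$score, x$n_records,
              x$n_features))
  invisible(x)
}

balanced_accuracy <- function(truth, pred) {
  # undefined per-class rates (no positives / no negatives in truth)
  # count as 0, so a fold missing a class is penalised, not skipped
  sens <- if (any(truth == 1)) mean(pred[truth == 1] == 1) else 0
  spec <- if (any(truth == 0)) mean(pred[truth == 0] == 0) else 0
  (sens + spec) / 2
}

# stratified fold assignment: within each class, shuffled records are
# dealt round-robin to folds
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold balanced accuracy
#'
#' Class-stratified folds with a stated shuffle seed; the score is the
#' mean over folds of the balanced accuracy (sensitivity + specificity)/2
#' of the held-out predictions. A held-out fold missing a class scores
#' the missing class's rate as 0 and logs a warning.
#'
#' @param dataset An \code{encoded_dataset}.
#' @param classifier An \code{fb_classifier}.
#' @param k Number of folds (2, 3, 5 or 10 in the default grid).
#' @param seed Shuffle seed for fold assignment.
#' @return An \code{fb_eval} with \code{cv = "<k>-fold"}.
#' @export
kfold_score <- function(dataset, classifier, k = 5L, seed = 42L) {
  stopifnot(inherits(dataset, "encoded_dataset"), k >= 2L,
            k <= nrow(dataset$x))
  fold <- stratified_folds(dataset$y, k, seed)
  scores <- numeric(k)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    truth <- dataset$y[te]
    if (length(unique(truth)) < 2L) {
      warning(sprintf("fold %d lacks one class; its rate counts as 0", f),
              call. = FALSE)
    }
    pred <- fit_predict_pipeline(dataset$x[-te, , drop = FALSE],
                                 dataset$y[-te],
                                 dataset$x[te, , drop = FALSE], classifier)
    scores[f] <- balanced_accuracy(truth, pred)
  }
  new_eval(dataset, classifier, cv = sprintf("%d-fold", k),
           score = mean(scores))
}

#' Evaluate a grid of datasets x classifiers
#'
#' Runs every (dataset spec, classifier) cell under LOOCV (default) or a
#' k-fold scheme and collects a tidy results table. A failing cell is
#' recorded with an \code{NA} score and the error message rather than
#' aborting the grid.
#'
#' @param records Canonical study table.
#' @param specs Dataset specs from [enumerate_datasets()].
#' @param classifiers Named list of \code{fb_classifier}s; default the
#'   seven-family panel.
#' @param cv \code{"loocv"} or \code{"kfold"}.
#' @param k,seed Fold count and shuffle seed when \code{cv = "kfold"}.
#' @param verbose Print one line per dataset.
#' @return \code{data.frame} with columns \code{dataset_id},
#'   \code{output}, \code{blocks}, \code{classifier}, \code{cv},
#'   \code{score}, \code{n_features}, \code{n_records}, \code{error}.
#' @export
grid_evaluate <- function(records, specs = enumerate_datasets(),
                          classifiers = default_classifiers(),
                          cv = c("loocv", "kfold"), k = 5L, seed = 42L,
                          verbose = FALSE) {
  cv <- match.arg(cv)
  records <- validate_study_table(records)
  blocks <- build_feature_blocks(records)
  rows <- vector("list", length(specs) * length(classifiers))
  ri <- 0L
  for (spec in specs) {
    ds <- assemble_dataset(records, spec, blocks = blocks)
    if (verbose) message("evaluating ", spec$id)
    for (clf in classifiers) {
      ri <- ri + 1L
      res <- tryCatch({
        ev <- if (cv == "loocv") loocv_accuracy(ds, clf)
              else kfold_score(ds, clf, k = k, seed = seed)
        data.frame(dataset_id = ev$dataset_id, output = ev$output,
                   blocks = ev$blocks, classifier = ev$classifier,
                   cv = ev$cv, score = ev$score, n_features = ev$n_features,
                   n_records = ev$n_records, error = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(dataset_id = spec$id, output = spec$output,
                   blocks = paste(spec$blocks, collapse = "+"),
                   classifier = clf$family, cv = cv, score = NA_real_,
                   n_features = NA_integer_, n_records = NA_integer_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[ri]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Select the best model for one output
#'
#' Argmax by score among the grid rows for that output; ties are broken
#' by fewer input features, then by the fixed classifier-family order of
#' [fb_classifier_families()].
#'
#' @param results Grid results from [grid_evaluate()].
#' @param output_name One of the six bone outputs.
#' @return The winning row of \code{results} (a one-row data frame).
#' @export
select_best <- function(results, output_name) {
  output_name <- match.arg(output_name, fb_bones())
  sub <- results[results$output == output_name & !is.na(results$score), ,
                 drop = FALSE]
  if (!nrow(sub)) stop("no results for output ", output_name, call. = FALSE)
  fam_rank <- match(sub$classifier, fb_classifier_families())
  ord <- order(-sub$score, sub$n_features, fam_rank)
  sub[ord[1], , drop = FALSE]
}
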