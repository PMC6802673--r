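drop_column_dataset <- function(dataset, col) {
  keep <- setdiff(dataset$columns, col)
  if (!length(keep)) stop("cannot remove the only feature", call. = FALSE)
  out <- dataset
  out$x <- dataset$x[, keep, drop = FALSE]
  out$columns <- keep
  out
}

keep_column_dataset <- function(dataset, col) {
  out <- dataset
  out$x <- dataset$x[, col, drop = FALSE]
  out$columns <- col
  out
}

#' Removal-based feature importance
#'
#' For the chosen model (dataset spec + classifier family), removes each
#' input feature in turn, recomputes the LOOCV accuracy without it, and
#' reports the difference to the pool (all-features) accuracy. A negative
#' delta means the model suffers without the feature (the feature is
#' important); a positive delta means the feature behaves as noise and
#' removing it improves the model.
#'
#' @param records Canonical study table, or a pre-assembled
#'   \code{encoded_dataset} (in which case \code{spec} is ignored).
#' @param spec Dataset spec of the model under analysis (>= 2 features).
#' @param classifier \code{fb_classifier} of the model under analysis.
#' @return \code{data.frame} with \code{output}, \code{feature},
#'   \code{new_score}, \code{delta} (= new - pool), plus the pool score as
#'   attribute \code{"pool_score"}; rows ordered by ascending delta (most
#'   important first).
#' @export
importance_by_removal <- function(records, spec = NULL, classifier) {
  ds <- if (inherits(records, "encoded_dataset")) records
        else assemble_dataset(records, spec)
  spec <- ds$spec
  if (ncol(ds$x) < 2L) stop("removal importance needs >= 2 features", call. = FALSE)
  pool <- loocv_accuracy(ds, classifier)
  rows <- lapply(ds$columns, function(col) {
    ev <- loocv_accuracy(drop_column_dataset(ds, col), classifier)
    data.frame(output = spec$output, feature = col,
               new_score = ev$score, delta = ev$score - pool$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delta, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pool_score") <- pool$score
  out
}

#' Single-feature models
#'
#' Refits the chosen model using each input feature alone (same
#' classifier family, same LOOCV scheme) and reports each single-feature
#' accuracy and its difference to the pool accuracy.
#'
#' @inheritParams importance_by_removal
#' @return \code{data.frame} with \code{output}, \code{feature},
#'   \code{score}, \code{delta}; pool score as attribute
#'   \code{"pool_score"}; rows ordered by ascending score.
#' @export
one_feature_models <- function(records, spec = NULL, classifier) {
  ds <- if (inherits(records, "encoded_dataset")) records
        else assemble_dataset(records, spec)
  spec <- ds$spec
  pool <- loocv_accuracy(ds, classifier)
  rows <- lapply(ds$columns, function(col) {
    ev <- loocv_accuracy(keep_column_dataset(ds, col), classifier)
    data.frame(output = spec$output, feature = col,
               score = ev$score, delta = ev$score - pool$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$score, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pool_score") <- pool$score
  out
}

#' Refine a best model by dropping its most harmful feature
#'
#' If any single removal strictly improves the pool LOOCV accuracy, the
#' refined model is the pool model without the removal giving the largest
#' improvement; otherwise the pool model is returned unchanged.
#'
#' @param pool_score Pool (all-features) LOOCV accuracy.
#' @param ablation Result of [importance_by_removal()].
#' @return List with \code{dropped} (feature name or \code{NA}),
#'   \code{score} (refined accuracy), \code{improved} (logical).
#' @export
refine_best <- function(pool_score, ablation) {
  best <- ablation[which.max(ablation$new_score), , drop = FALSE]
  if (nrow(best) && best$new_score > pool_score) {
    list(dropped = best$feature, score = best$new_score, improved = TRUE)
  } else {
    list(dropped = NA_character_, score = pool_score, improved = FALSE)
  }
}
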