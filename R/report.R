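#' Run the full modelling pipeline and collect a report bundle
#'
#' Executes every stage on an integrated study table: descriptive group
#' summaries, feature encoding, dataset enumeration, the LOOCV grid over
#' all classifier families, best-model selection per bone output,
#' removal-based feature importance and single-feature models for each
#' best model, model refinement, and the one-hot versus
#' group-mean-centered encoding comparison. Record counts are logged at
#' each stage. Optionally writes every table as CSV.
#'
#' @param records Integrated canonical study table (e.g. from
#'   [integrate_tables()], [read_study_table()] or
#'   [generate_synthetic_study()]).
#' @param out_dir Directory for CSV outputs; \code{NULL} to skip writing.
#' @param combinations Block combinations for the dataset enumeration.
#' @param classifiers Classifier panel; default the seven pinned families.
#' @param seed Root seed for the stochastic classifier families.
#' @param verbose Log per-dataset progress.
#' @return A list of class \code{"fb_report"}: \code{summaries},
#'   \code{manifest}, \code{grid}, \code{best}, \code{importance},
#'   \code{one_feature}, \code{refined}, \code{encoding_comparison}.
#' @export
run_all <- function(records, out_dir = NULL,
                    combinations = default_block_combinations(),
                    classifiers = NULL, seed = 42L, verbose = FALSE) {
  records <- validate_study_table(records)
  if (is.null(classifiers)) classifiers <- default_classifiers(seed)
  message("pipeline input: ", nrow(records), " records")

  summaries <- summarize_groups(records)
  specs <- enumerate_datasets(combinations)
  manifest <- dataset_manifest(specs)
  message("enumerated ", length(specs), " datasets x ",
          length(classifiers), " classifiers")

  grid <- grid_evaluate(records, specs, classifiers, verbose = verbose)
  message("grid evaluated: ", nrow(grid), " models")

  best_rows <- lapply(fb_bones(), function(out) select_best(grid, out))
  best <- do.call(rbind, best_rows)

  importance <- list(); one_feature <- list(); refined_rows <- list()
  for (i in seq_len(nrow(best))) {
    out <- best$output[i]
    spec <- list(id = best$dataset_id[i], output = out,
                 blocks = strsplit(best$blocks[i], "+", fixed = TRUE)[[1]])
    clf <- classifiers[[best$classifier[i]]]
    imp <- importance_by_removal(records, spec, clf)
    onef <- one_feature_models(records, spec, clf)
    ref <- refine_best(attr(imp, "pool_score"), imp)
    importance[[out]] <- imp
    one_feature[[out]] <- onef
    refined_rows[[out]] <- data.frame(
      output = out, classifier = best$classifier[i], blocks = best$blocks[i],
      pool_score = attr(imp, "pool_score"), dropped = ref$dropped,
      refined_score = ref$score, stringsAsFactors = FALSE)
  }
  refined <- do.call(rbind, refined_rows)
  rownames(refined) <- NULL

  comparison <- compare_encodings(grid)

  bundle <- structure(list(
    summaries = summaries, manifest = manifest, grid = grid, best = best,
    importance = importance, one_feature = one_feature, refined = refined,
    encoding_comparison = comparison), class = "fb_report")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' One-hot versus group-mean-centered encoding comparison
#'
#' For each bone output, the best LOOCV score among the one-hot arms
#' (block lists containing \code{OneHot}) versus the best among the
#' centered-feature arms (all others).
#'
#' @param grid Results table from [grid_evaluate()].
#' @return \code{data.frame} with \code{output}, \code{onehot_score},
#'   \code{ma_score}, \code{ma_minus_onehot}.
#' @export
compare_encodings <- function(grid) {
  grid <- grid[!is.na(grid$score), , drop = FALSE]
  is_onehot <- grepl("OneHot", grid$blocks, fixed = TRUE)
  rows <- lapply(intersect(fb_bones(), unique(grid$output)), function(out) {
    sub <- grid[grid$output == out, , drop = FALSE]
    oh <- sub$score[is_onehot[grid$output == out]]
    ma <- sub$score[!is_onehot[grid$output == out]]
    data.frame(output = out,
               onehot_score = if (length(oh)) max(oh) else NA_real_,
               ma_score = if (length(ma)) max(ma) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ma_minus_onehot <- out$ma_score - out$onehot_score
  out
}

#' Write a report bundle as CSV files
#'
#' Files written (fixed names, fixed column orders):
#' \code{group_summaries.csv}, \code{dataset_manifest.csv},
#' \code{grid_loocv.csv}, \code{best_models.csv},
#' \code{feature_importance.csv}, \code{one_feature_models.csv},
#' \code{refined_models.csv}, \code{encoding_comparison.csv}.
#'
#' @param bundle An \code{fb_report} from [run_all()].
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "fb_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(bundle$summaries, "group_summaries.csv")
  w(bundle$manifest, "dataset_manifest.csv")
  w(bundle$grid, "grid_loocv.csv")
  w(bundle$best, "best_models.csv")
  w(do.call(rbind, bundle$importance), "feature_importance.csv")
  w(do.call(rbind, bundle$one_feature), "one_feature_models.csv")
  w(bundle$refined, "refined_models.csv")
  w(bundle$encoding_comparison, "encoding_comparison.csv")
  invisible(out_dir)
}

#' @export
print.fb_report <- function(x, ...) {
  cat("<fetalbone report bundle>\n")
  cat("  grid:", nrow(x$grid), "models\n")
  cat("  best models:\n")
  b <- x$best
  for (i in seq_len(nrow(b))) {
    cat(sprintf("    %-3s %-10s %-22s score %.3f\n", b$output[i],
                b$classifier[i], b$blocks[i], b$score[i]))
  }
  invisible(x)
}
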