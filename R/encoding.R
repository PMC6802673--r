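#' Robust scaling
#'
#' Centers by the median and scales by the interquartile range
#' (Q3 - Q1, linear-interpolation quantiles, i.e. `stats::quantile`
#' type 7). A zero IQR maps the whole vector to zeros rather than
#' dividing by zero; this also makes constant columns inert downstream.
#'
#' @param values Non-empty finite numeric vector.
#' @return Numeric vector of the same length.
#' @export
robust_scale <- function(values) {
  if (!length(values)) stop("cannot robust-scale an empty vector", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  med <- stats::median(values)
  iqr <- unname(diff(stats::quantile(values, c(0.25, 0.75), type = 7)))
  if (iqr == 0) return(rep(0, length(values)))
  (values - med) / iqr
}

#' Binarize a bone output into low/high classes
#'
#' Robust-scales the output separately within each animal type (fetal and
#' maternal bone values live on very different scales; a joint scaling
#' would make the classes encode animal type rather than low/high), then
#' thresholds at 0, the image of the median. Values at or below the
#' median get class 0, values above get class 1.
#'
#' @param records Canonical study table.
#' @param output_name One of the six bone outputs.
#' @return Integer vector of 0/1 classes aligned to \code{records}; rows
#'   with a missing output get \code{NA}.
#' @export
binarize_output <- function(records, output_name) {
  output_name <- match.arg(output_name, fb_bones())
  y <- rep(NA_integer_, nrow(records))
  for (a in fb_levels()$animal) {
    idx <- which(records$animal == a & !is.na(records[[output_name]]))
    if (!length(idx)) next
    vals <- records[[output_name]][idx]
    if (length(unique(vals)) == 1L) {
      stop(sprintf("output '%s' is constant within animal type '%s'; classes undefined",
                   output_name, a), call. = FALSE)
    }
    y[idx] <- as.integer(robust_scale(vals) > 0)
  }
  y
}

#' Experiment-centered (moving-average) feature
#'
#' For each record, the mean of a biomarker over all records sharing the
#' record's condition values on the given axes, minus the record's own
#' value (group mean - value; the record is included in its own group
#' mean). Grouping by all three axes is the mixed ("experim") centering.
#'
#' @param records Canonical study table.
#' @param protein_name One of the six biomarkers.
#' @param condition_set Non-empty subset of \code{c("animal","treat","period")}.
#' @return Numeric vector aligned to \code{records}.
#' @export
moving_average <- function(records, protein_name, condition_set = fb_axes()) {
  protein_name <- match.arg(protein_name, fb_proteins())
  condition_set <- match.arg(condition_set, fb_axes(), several.ok = TRUE)
  x <- records[[protein_name]]
  if (anyNA(x)) stop("protein '", protein_name, "' has missing values", call. = FALSE)
  g <- interaction(records[condition_set], drop = TRUE)
  stats::ave(x, g) - x
}

ma_colname <- function(protein, axis_label) paste0("MA-", protein, "-", axis_label)

# single-axis labels as used in engineered column names
axis_label <- function(axis) c(animal = "Animal", treat = "Treat", period = "Period")[axis]

#' Engineered feature blocks
#'
#' Builders for the six named feature blocks:
#' \describe{
#'   \item{Metab}{the six raw biomarker concentrations;}
#'   \item{MAmix}{six group-mean-centered biomarkers within the joint
#'     (animal x treat x period) grouping, columns `MA-<protein>-experim`;}
#'   \item{MAi}{eighteen centered biomarkers, one per single condition
#'     axis, columns `MA-<protein>-Animal/-Treat/-Period`;}
#'   \item{OneHot}{six redundant binary condition indicators
#'     (`Animal_Fetus`, `Animal_Mon`, `Treat_Con`, `Treat_Res`,
#'     `Period_Late`, `Period_Mid`);}
#'   \item{ProbECs}{per-axis empirical category probabilities
#'     (`Prob_Animal`, `Prob_Treat`, `Prob_Period`);}
#'   \item{ProbMix}{the empirical probability of the record's full
#'     condition cell (`Prob_Mix`).}
#' }
#'
#' @param records Canonical study table with all six proteins present.
#' @return A numeric matrix with rows aligned to \code{records}.
#' @name feature_blocks
NULL

#' @rdname feature_blocks
#' @export
build_metab <- function(records) {
  m <- as.matrix(records[fb_proteins()])
  if (anyNA(m)) stop("proteins incomplete; integrate/filter first", call. = FALSE)
  dimnames(m) <- list(NULL, fb_proteins())
  m
}

#' @rdname feature_blocks
#' @export
build_ma_mixed <- function(records) {
  cols <- lapply(fb_proteins(), function(p) moving_average(records, p, fb_axes()))
  m <- do.call(cbind, cols)
  colnames(m) <- ma_colname(fb_proteins(), "experim")
  m
}

#' @rdname feature_blocks
#' @export
build_ma_single <- function(records) {
  cols <- list()
  for (axis in fb_axes()) {
    for (p in fb_proteins()) {
      cols[[ma_colname(p, axis_label(axis))]] <-
        moving_average(records, p, axis)
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}

#' @rdname feature_blocks
#' @export
build_one_hot <- function(records) {
  m <- cbind(
    Animal_Fetus = as.integer(records$animal == "fetus"),
    Animal_Mon   = as.integer(records$animal == "mother"),
    Treat_Con    = as.integer(records$treat == "control"),
    Treat_Res    = as.integer(records$treat == "restricted"),
    Period_Late  = as.integer(records$period == "late"),
    Period_Mid   = as.integer(records$period == "middle")
  )
  m
}

#' @rdname feature_blocks
#' @export
build_probabilities <- function(records) {
  n <- nrow(records)
  if (!n) stop("empty table", call. = FALSE)
  prob_axis <- function(axis) {
    tab <- table(records[[axis]])
    as.numeric(tab[records[[axis]]]) / n
  }
  prob_ecs <- cbind(Prob_Animal = prob_axis("animal"),
                    Prob_Treat = prob_axis("treat"),
                    Prob_Period = prob_axis("period"))
  cell <- interaction(records[fb_axes()], drop = TRUE)
  prob_mix <- cbind(Prob_Mix = as.numeric(table(cell)[cell]) / n)
  list(ProbECs = prob_ecs, ProbMix = prob_mix)
}

#' Build all feature blocks for a study table
#'
#' @param records Canonical study table with complete proteins.
#' @return Named list of matrices: \code{Metab}, \code{MAmix}, \code{MAi},
#'   \code{OneHot}, \code{ProbMix}, \code{ProbECs}.
#' @export
build_feature_blocks <- function(records) {
  records <- validate_study_table(records)
  probs <- build_probabilities(records)
  list(
    Metab  = build_metab(records),
    MAmix  = build_ma_mixed(records),
    MAi    = build_ma_single(records),
    OneHot = build_one_hot(records),
    ProbMix = probs$ProbMix,
    ProbECs = probs$ProbECs
  )
}

fb_block_names <- function() c("Metab", "MAmix", "MAi", "OneHot", "ProbMix", "ProbECs")
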