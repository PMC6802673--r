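#' Default feature-block combinations
#'
#' The twelve block combinations enumerated by default, covering: every
#' non-empty subset of \{Metab, MAmix, MAi\} (7); the three of those of
#' size at most two containing Metab or MAmix, augmented with the two
#' condition-probability blocks (3); and the two one-hot comparison arms,
#' \{OneHot, Metab\} and \{OneHot\} (2). Together with the six bone
#' outputs this yields the default grid of 72 datasets. The list is a
#' documented convention, overridable in [enumerate_datasets()].
#'
#' @return A named list of character vectors of block names.
#' @export
default_block_combinations <- function() {
  combos <- list(
    c("Metab"),
    c("MAmix"),
    c("MAi"),
    c("MAmix", "Metab"),
    c("MAi", "Metab"),
    c("MAi", "MAmix"),
    c("MAi", "MAmix", "Metab"),
    c("Metab", "ProbMix", "ProbECs"),
    c("MAmix", "ProbMix", "ProbECs"),
    c("MAmix", "Metab", "ProbMix", "ProbECs"),
    c("OneHot", "Metab"),
    c("OneHot")
  )
  stats::setNames(combos, vapply(combos, paste, "", collapse = "+"))
}

#' Enumerate modelling dataset specifications
#'
#' Crosses the block combinations with the six binary bone outputs. The
#' default scheme yields 12 x 6 = 72 dataset specifications.
#'
#' @param combinations Named list of character vectors of block names;
#'   defaults to [default_block_combinations()].
#' @param outputs Bone outputs to model; default all six.
#' @return A list of dataset specs, each a list with \code{id},
#'   \code{output}, \code{blocks}.
#' @export
enumerate_datasets <- function(combinations = default_block_combinations(),
                               outputs = fb_bones()) {
  outputs <- match.arg(outputs, fb_bones(), several.ok = TRUE)
  if (!length(combinations)) stop("no block combinations given", call. = FALSE)
  for (combo in combinations) {
    if (!length(combo) || anyDuplicated(combo)) {
      stop("each combination must be a non-empty duplicate-free block list",
           call. = FALSE)
    }
    unknown <- setdiff(combo, fb_block_names())
    if (length(unknown)) {
      stop("unknown feature block(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(names(combinations))) {
    names(combinations) <- vapply(combinations, paste, "", collapse = "+")
  }
  specs <- list()
  for (out in outputs) {
    for (cname in names(combinations)) {
      specs[[length(specs) + 1L]] <- list(
        id = paste0(out, ":", cname),
        output = out,
        blocks = combinations[[cname]]
      )
    }
  }
  specs
}

#' Assemble an encoded dataset from a specification
#'
#' Horizontally concatenates the spec's feature blocks in spec order and
#' binarizes the spec's bone output. Records missing that output are
#' dropped from both the matrix and the labels; engineered features are
#' computed on the full table first (matching the study scripts), so a
#' record's centered features reflect all records in its condition cell.
#'
#' @param records Canonical study table with complete proteins.
#' @param spec A dataset spec from [enumerate_datasets()].
#' @param blocks Optional precomputed [build_feature_blocks()] result for
#'   \code{records} (avoids recomputation across many specs).
#' @return A list of class \code{"encoded_dataset"}: \code{spec},
#'   \code{x} (numeric matrix), \code{y} (integer 0/1), \code{columns}.
#' @export
assemble_dataset <- function(records, spec, blocks = NULL) {
  if (is.null(blocks)) blocks <- build_feature_blocks(records)
  x <- do.call(cbind, blocks[spec$blocks])
  y <- binarize_output(records, spec$output)
  keep <- !is.na(y)
  if (!any(keep)) {
    stop("no records retain output '", spec$output, "'", call. = FALSE)
  }
  out <- list(spec = spec, x = x[keep, , drop = FALSE],
              y = y[keep], columns = colnames(x))
  class(out) <- "encoded_dataset"
  out
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf("<encoded_dataset %s: %d records x %d features, %d/%d high class>\n",
              x$spec$id, nrow(x$x), ncol(x$x), sum(x$y), length(x$y)))
  invisible(x)
}

#' List the default dataset enumeration as a data frame
#'
#' @param specs Output of [enumerate_datasets()].
#' @return \code{data.frame} with \code{id}, \code{output}, \code{blocks}.
#' @export
dataset_manifest <- function(specs = enumerate_datasets()) {
  data.frame(
    id = vapply(specs, `[[`, "", "id"),
    output = vapply(specs, `[[`, "", "output"),
    blocks = vapply(specs, function(s) paste(s$blocks, collapse = "+"), ""),
    stringsAsFactors = FALSE
  )
}
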