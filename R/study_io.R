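#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

#' Canonical variable names
#'
#' The six serum bone-turnover biomarkers and the six bone phenotype
#' measurements handled by the pipeline, in their fixed canonical order.
#' PTH is parathyroid hormone (ng/mL); BALP bone alkaline phosphatase
#' (mU/mL); BGLAP osteocalcin (ng/mL); TRAP tartrate-resistant acid
#' phosphatase (U/L); INTP N-terminal telopeptides of type I collagen
#' (ng/mL); CTX-I C-terminal telopeptides of type I collagen (ng/mL).
#' Bone outputs are femur/humerus weight (g), length (mm), diameter (mm).
#'
#' @name fb_variables
#' @return Character vectors of canonical names.
NULL

#' @rdname fb_variables
#' @export
fb_proteins <- function() c("PTH", "BALP", "BGLAP", "INTP", "TRAP", "CTX-I")

#' @rdname fb_variables
#' @export
fb_bones <- function() c("Fw", "Fl", "Fd", "Hw", "Hl", "Hd")

#' @rdname fb_variables
#' @export
fb_axes <- function() c("animal", "treat", "period")

# canonical levels per experimental-condition axis; first level is the
# reference used in one-hot column ordering
fb_levels <- function() {
  list(
    animal = c("fetus", "mother"),
    treat  = c("control", "restricted"),
    period = c("middle", "late")
  )
}

# accepted spellings -> canonical label, per axis (case-insensitive)
fb_label_map <- function() {
  list(
    animal = c(fetus = "fetus", foetus = "fetus", f = "fetus",
               mother = "mother", mon = "mother", maternal = "mother",
               m = "mother"),
    treat  = c(control = "control", con = "control", c = "control",
               restricted = "restricted", res = "restricted",
               restriction = "restricted", r = "restricted"),
    period = c(middle = "middle", mid = "middle", m = "middle",
               late = "late", l = "late")
  )
}

canonicalize_level <- function(x, axis) {
  map <- fb_label_map()[[axis]]
  out <- unname(map[tolower(trimws(as.character(x)))])
  if (anyNA(out) && !anyNA(x)) {
    bad <- unique(x[is.na(out)])
    stop(sprintf("unrecognised '%s' label(s): %s", axis,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Default schema mapping file columns to canonical roles
#'
#' A schema is a named character vector: names are canonical roles
#' (\code{serum_id}, \code{animal_id}, the three condition axes, the six
#' proteins and six bone outputs), values are the column names used in the
#' CSV being read. The default assumes the supplementary-file style header
#' (\code{SerNum}, \code{Animal}, \code{Treat}, \code{Period}, protein and
#' bone names as in [fb_proteins()] / [fb_bones()]).
#'
#' @param ... Named overrides, e.g. \code{serum_id = "SampleID"}.
#' @return Named character vector.
#' @export
default_schema <- function(...) {
  schema <- c(
    serum_id = "SerNum", animal_id = "AnimalID",
    animal = "Animal", treat = "Treat", period = "Period",
    stats::setNames(fb_proteins(), fb_proteins()),
    stats::setNames(fb_bones(), fb_bones())
  )
  dots <- c(...)
  if (length(dots)) schema[names(dots)] <- dots
  schema
}

#' Read a study table from CSV
#'
#' Reads a flat table of study records (one row per animal/serum sample),
#' maps columns to canonical roles through \code{schema}, normalises the
#' three experimental-condition labels and validates the result. Bone or
#' protein columns missing from the file are permitted (the corresponding
#' cells are absent); this is how separate bone-only and serum-only tables
#' are read before [integrate_tables()].
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping canonical roles to column
#'   names; see [default_schema()]. Roles absent from the file are dropped
#'   silently except \code{serum_id} and the three condition axes, which are
#'   required.
#' @return A \code{data.frame} with canonical columns: \code{serum_id},
#'   optionally \code{animal_id}, \code{animal}, \code{treat},
#'   \code{period}, then whichever of the six proteins and six bone outputs
#'   the file carries. Missing cells are \code{NA}, never zero.
#' @export
read_study_table <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  # canonical role names in the file take over when the schema's column
  # is absent, so tables written by write_study_table() read back as-is
  for (role in names(schema)) {
    if (!(schema[[role]] %in% names(raw)) && role %in% names(raw)) {
      schema[[role]] <- role
    }
  }
  required <- c("serum_id", fb_axes())
  miss <- setdiff(schema[required], names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  present <- schema[schema %in% names(raw)]
  out <- raw[, unname(present), drop = FALSE]
  names(out) <- names(present)
  if (nrow(out) == 0L) return(validate_study_table(out))

  for (axis in fb_axes()) out[[axis]] <- canonicalize_level(out[[axis]], axis)
  out$serum_id <- as.character(out$serum_id)
  for (v in intersect(c(fb_proteins(), fb_bones()), names(out))) {
    val <- out[[v]]
    if (!is.numeric(val)) {
      num <- suppressWarnings(as.numeric(ifelse(trimws(val) == "", NA, val)))
      bad <- which(!is.na(val) & trimws(val) != "" & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                     v, bad[1], val[bad[1]]), call. = FALSE)
      }
      val <- num
    }
    out[[v]] <- val
  }
  validate_study_table(out)
}

#' Validate a canonical study table
#'
#' Checks the invariants every study table must satisfy: unique
#' \code{serum_id}, canonical two-level condition labels, and finite,
#' non-negative protein concentrations (where present).
#'
#' @param records A canonical study \code{data.frame}.
#' @return The validated table, invisibly classed \code{"study_table"}.
#' @export
validate_study_table <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("serum_id", fb_axes())
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("table lacks canonical column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$serum_id)) {
    dup <- records$serum_id[duplicated(records$serum_id)][1]
    stop("duplicate serum_id: ", dup, call. = FALSE)
  }
  for (axis in fb_axes()) {
    ok <- records[[axis]] %in% fb_levels()[[axis]]
    if (nrow(records) && !all(ok)) {
      stop(sprintf("non-canonical '%s' value: %s", axis,
                   records[[axis]][!ok][1]), call. = FALSE)
    }
  }
  for (p in intersect(fb_proteins(), names(records))) {
    v <- records[[p]]
    if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
      stop("protein '", p, "' has a negative or non-finite value",
           call. = FALSE)
    }
  }
  class(records) <- unique(c("study_table", class(records)))
  invisible(records)
}

#' Integrate bone-phenotype and serum-biomarker tables
#'
#' Inner join on the key (\code{serum_id}, \code{animal}, \code{treat},
#' \code{period}). Only records with all six protein concentrations and at
#' least one bone measurement survive; the number of rows dropped at each
#' step is reported as a message. A key matching more than one row in
#' either table is an integrity error.
#'
#' @param bone_table Study table carrying the bone outputs.
#' @param serum_table Study table carrying the protein concentrations.
#' @return Integrated canonical study table.
#' @export
integrate_tables <- function(bone_table, serum_table) {
  bone_table <- validate_study_table(bone_table)
  serum_table <- validate_study_table(serum_table)
  key <- c("serum_id", fb_axes())
  bk <- do.call(paste, c(bone_table[key], sep = "\r"))
  sk <- do.call(paste, c(serum_table[key], sep = "\r"))
  if (anyDuplicated(bk) || anyDuplicated(sk)) {
    stop("join key (serum_id + conditions) is not unique; ",
         "a one-to-many match would result", call. = FALSE)
  }
  keep_b <- setdiff(names(bone_table), c(fb_proteins()))
  keep_s <- c(key, intersect(fb_proteins(), names(serum_table)))
  merged <- merge(bone_table[keep_b], serum_table[keep_s], by = key)
  if (nrow(merged) == 0L) {
    warning("bone and serum tables share no (serum_id, conditions) keys",
            call. = FALSE)
    return(validate_study_table(merged))
  }
  n0 <- nrow(merged)
  prot_ok <- rowSums(is.na(as.matrix(merged[fb_proteins()]))) == 0
  bone_cols <- intersect(fb_bones(), names(merged))
  bone_ok <- if (length(bone_cols)) {
    rowSums(!is.na(as.matrix(merged[bone_cols]))) > 0
  } else rep(FALSE, n0)
  merged <- merged[prot_ok & bone_ok, , drop = FALSE]
  rownames(merged) <- NULL
  message(sprintf(
    "integrated %d records (bone %d x serum %d; %d matched keys, %d dropped for incomplete proteins/bones)",
    nrow(merged), nrow(bone_table), nrow(serum_table), n0, n0 - nrow(merged)))
  # canonical row order: keys sorted, so input order never matters
  merged <- merged[order(merged$serum_id, merged$animal, merged$treat,
                         merged$period), , drop = FALSE]
  rownames(merged) <- NULL
  validate_study_table(merged)
}

#' Descriptive group summaries (mean and standard error)
#'
#' Per-group mean and standard error of the mean (SEm = sd/sqrt(n), sample
#' standard deviation with the n-1 denominator) for the requested
#' variables, grouped by a subset of the three condition axes. Groups of
#' size one report \code{NA} for the SEm. This is the ingestion-validation
#' report: with the study table it reproduces the descriptive rows of the
#' published group-mean tables.
#'
#' @param records Canonical study table.
#' @param group_by Character vector of condition axes (subset of
#'   \code{animal}, \code{treat}, \code{period}).
#' @param variables Variable names to summarise (proteins and/or bones).
#' @return A \code{data.frame} with the grouping columns, \code{variable},
#'   \code{mean}, \code{sem}, \code{n}, rows ordered by group then
#'   variable.
#' @export
summarize_groups <- function(records, group_by = fb_axes(),
                             variables = intersect(c(fb_proteins(), fb_bones()),
                                                   names(records))) {
  records <- validate_study_table(records)
  group_by <- match.arg(group_by, fb_axes(), several.ok = TRUE)
  unknown <- setdiff(variables, names(records))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  gkey <- interaction(records[group_by], drop = TRUE, lex.order = TRUE,
                      sep = "/")
  rows <- list()
  for (g in levels(gkey)) {
    sub <- records[gkey == g, , drop = FALSE]
    for (v in variables) {
      x <- sub[[v]]
      x <- x[!is.na(x)]
      if (!length(x)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, mean = mean(x),
        sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  keyvals <- do.call(rbind, strsplit(out$group, "/", fixed = TRUE))
  colnames(keyvals) <- group_by
  cbind(as.data.frame(keyvals, stringsAsFactors = FALSE),
        out[c("variable", "mean", "sem", "n")])
}

#' Load the goat study table, if installed
#'
#' The package reproduces a published goat fetal-bone study whose
#' 56-record integrated table is distributed as that article's first
#' supplementary file, not with this package. Placing a CSV copy at
#' \code{inst/extdata/goat_study.csv} before installation (canonical or
#' supplementary-style headers, see [default_schema()]) makes it
#' available here; the headline-reproduction tests and reports use this
#' loader.
#'
#' @param path Optional explicit path to the CSV; default looks in the
#'   installed package's \code{extdata}.
#' @return Validated canonical study table.
#' @export
load_goat_study <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "goat_study.csv", package = "fetalbone")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("the goat study table is not installed; place the study's ",
         "supplementary 56-record CSV at inst/extdata/goat_study.csv ",
         "and reinstall", call. = FALSE)
  }
  read_study_table(path)
}

#' Write a canonical study table to CSV
#'
#' Fixed, documented column order: \code{serum_id}, \code{animal_id} (if
#' present), the three condition axes, the six proteins, the six bone
#' outputs (those present).
#'
#' @param records Canonical study table.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_study_table <- function(records, path) {
  records <- validate_study_table(records)
  ord <- intersect(c("serum_id", "animal_id", fb_axes(), fb_proteins(),
                     fb_bones()), names(records))
  utils::write.csv(records[ord], path, row.names = FALSE)
  invisible(path)
}
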