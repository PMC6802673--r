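# small in-code fixtures shared across tests

# a minimal valid study table: one record per factorial cell (or n per
# cell), proteins filled deterministically, bones optional
make_cell_table <- function(n_per_cell = 1L, bones = TRUE) {
  cells <- expand.grid(animal = c("fetus", "mother"),
                       treat = c("control", "restricted"),
                       period = c("middle", "late"),
                       stringsAsFactors = FALSE)
  rec <- cells[rep(seq_len(8), each = n_per_cell), ]
  n <- nrow(rec)
  rec <- data.frame(serum_id = sprintf("S%02d", seq_len(n)), rec,
                    stringsAsFactors = FALSE)
  for (k in seq_along(fb_proteins())) {
    rec[[fb_proteins()[k]]] <- seq_len(n) * k + k   # distinct, positive
  }
  if (bones) for (k in seq_along(fb_bones())) {
    rec[[fb_bones()[k]]] <- rev(seq_len(n)) + 10 * k
  }
  validate_study_table(rec)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a classifier object that always predicts the training majority class
# (ties -> class 0); used to exercise the CV harness independently of
# any library classifier
majority_classifier <- function() {
  structure(list(family = "majority", params = list(), seed = NA_integer_,
                 fit_predict = function(xtr, ytr, xte) {
                   cls <- as.integer(mean(ytr) > 0.5)
                   rep(cls, nrow(xte))
                 }),
            class = "fb_classifier")
}

# a classifier predicting a fixed label for everything
constant_classifier <- function(label) {
  structure(list(family = "const", params = list(label = label),
                 seed = NA_integer_,
                 fit_predict = function(xtr, ytr, xte) rep(label, nrow(xte))),
            class = "fb_classifier")
}
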