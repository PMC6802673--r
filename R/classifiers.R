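# Classifier registry. Each classifier is a small S3 object holding the
# family label, the pinned hyperparameters and a fit_predict closure
# (train matrix, 0/1 train labels, test matrix) -> 0/1 predictions.
# Hyperparameters are pinned explicitly rather than inherited from library
# defaults, so results are reproducible across library versions.

new_classifier <- function(family, params, fit_predict, seed = NA_integer_) {
  structure(list(family = family, params = params, seed = seed,
                 fit_predict = fit_predict),
            class = "fb_classifier")
}

#' @export
print.fb_classifier <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<classifier %s (%s)>\n", x$family, ps))
  invisible(x)
}

#' Construct one of the seven pinned classifier families
#'
#' Families and pinned hyperparameters:
#' \describe{
#'   \item{KNN}{nearest neighbour, k = 5, uniform vote (`class::knn`);}
#'   \item{SVM linear}{linear max-margin, cost C = 1 (`e1071::svm`);}
#'   \item{SVM}{RBF-kernel max-margin, C = 1, gamma =
#'     1 / (n_features x overall feature variance) (`e1071::svm`);}
#'   \item{LR}{L2-penalised logistic regression, C = 1, i.e. ridge logistic
#'     with lambda = 1/(n C) (`glmnet`);}
#'   \item{DT}{decision tree, Gini impurity, unrestricted depth
#'     (`rpart`);}
#'   \item{RF}{random forest, 100 trees (`randomForest`), seeded;}
#'   \item{XGB}{gradient-boosted trees, 100 rounds, learning rate 0.1,
#'     max depth 3 (`xgboost`), seeded.}
#' }
#'
#' @param family One of \code{"KNN"}, \code{"SVM linear"}, \code{"SVM"},
#'   \code{"LR"}, \code{"DT"}, \code{"RF"}, \code{"XGB"}.
#' @param seed Seed for the stochastic families (RF, XGB).
#' @return An \code{fb_classifier} object.
#' @export
make_classifier <- function(family = fb_classifier_families(), seed = 42L) {
  family <- match.arg(family)
  switch(family,
    "KNN" = new_classifier("KNN", list(k = 5, vote = "uniform"),
      function(xtr, ytr, xte) {
        k <- min(5L, nrow(xtr))
        as.integer(as.character(
          class::knn(xtr, xte, cl = factor(ytr, levels = 0:1), k = k)))
      }),
    "SVM linear" = new_classifier("SVM linear", list(C = 1),
      function(xtr, ytr, xte) {
        fit <- e1071::svm(xtr, factor(ytr, levels = 0:1), kernel = "linear",
                          cost = 1, scale = FALSE)
        as.integer(as.character(predict(fit, xte)))
      }),
    "SVM" = new_classifier("SVM", list(C = 1, gamma = "1/(p*var)"),
      function(xtr, ytr, xte) {
        v <- mean((xtr - mean(xtr))^2)   # population variance of all entries
        gam <- if (v > 0) 1 / (ncol(xtr) * v) else 1 / ncol(xtr)
        fit <- e1071::svm(xtr, factor(ytr, levels = 0:1), kernel = "radial",
                          cost = 1, gamma = gam, scale = FALSE)
        as.integer(as.character(predict(fit, xte)))
      }),
    "LR" = new_classifier("LR", list(penalty = "l2", C = 1),
      function(xtr, ytr, xte) {
        if (ncol(xtr) == 1L) {           # glmnet needs >= 2 columns
          xtr <- cbind(xtr, 0); xte <- cbind(xte, 0)
        }
        fit <- glmnet::glmnet(xtr, factor(ytr, levels = 0:1),
                              family = "binomial", alpha = 0,
                              lambda = 1 / nrow(xtr), standardize = FALSE)
        as.integer(predict(fit, xte, type = "response")[, 1] > 0.5)
      }),
    "DT" = new_classifier("DT", list(criterion = "gini", max_depth = Inf),
      function(xtr, ytr, xte) {
        df <- as.data.frame(xtr); names(df) <- paste0("V", seq_len(ncol(xtr)))
        df$.y <- factor(ytr, levels = 0:1)
        fit <- rpart::rpart(.y ~ ., df, method = "class",
                            parms = list(split = "gini"),
                            control = rpart::rpart.control(
                              minsplit = 2, minbucket = 1, cp = 0,
                              maxdepth = 30, xval = 0))
        nd <- as.data.frame(xte); names(nd) <- paste0("V", seq_len(ncol(xte)))
        as.integer(as.character(predict(fit, nd, type = "class")))
      }),
    "RF" = new_classifier("RF", list(n_trees = 100), seed = seed,
      fit_predict = function(xtr, ytr, xte) {
        set.seed(seed)
        fit <- randomForest::randomForest(xtr, factor(ytr, levels = 0:1),
                                          ntree = 100)
        as.integer(as.character(predict(fit, xte)))
      }),
    "XGB" = new_classifier("XGB",
      list(n_rounds = 100, learning_rate = 0.1, max_depth = 3), seed = seed,
      fit_predict = function(xtr, ytr, xte) {
        set.seed(seed)
        dtr <- xgboost::xgb.DMatrix(unname(xtr), label = ytr, nthread = 1)
        fit <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 3,
                        eta = 0.1, nthread = 1, seed = seed),
          data = dtr, nrounds = 100, verbose = 0)
        p <- predict(fit, xgboost::xgb.DMatrix(unname(xte), nthread = 1))
        as.integer(p > 0.5)
      })
  )
}

#' @rdname make_classifier
#' @export
fb_classifier_families <- function() {
  c("KNN", "SVM linear", "SVM", "LR", "DT", "RF", "XGB")
}

#' The default seven-classifier panel
#'
#' @param seed Seed passed to the stochastic families.
#' @return Named list of \code{fb_classifier} objects in the fixed family
#'   order used for tie-breaking in [select_best()].
#' @export
default_classifiers <- function(seed = 42L) {
  fams <- fb_classifier_families()
  stats::setNames(lapply(fams, make_classifier, seed = seed), fams)
}

# robust scaler fit on training rows only; constant columns map to zero
fit_robust_scaler <- function(x) {
  med <- apply(x, 2, stats::median)
  q <- apply(x, 2, stats::quantile, probs = c(0.25, 0.75), type = 7)
  list(median = med, iqr = q[2, ] - q[1, ])
}

apply_robust_scaler <- function(scaler, x) {
  out <- sweep(x, 2, scaler$median, "-")
  scale_by <- ifelse(scaler$iqr == 0, 0, 1 / scaler$iqr)
  sweep(out, 2, scale_by, "*")
}

#' Scale-then-classify pipeline
#'
#' The evaluation pipeline: a robust scaler (median/IQR) is fit on the
#' training rows only and applied to both training and test rows, then
#' the classifier is fit on the scaled training data and applied to the
#' scaled test rows. A single-class training set short-circuits to
#' predicting that class, with a warning.
#'
#' @param train_x,train_y Training feature matrix and 0/1 labels.
#' @param test_x Test feature matrix (same columns).
#' @param classifier An \code{fb_classifier}.
#' @return Integer 0/1 predictions, one per test row.
#' @export
fit_predict_pipeline <- function(train_x, train_y, test_x, classifier) {
  stopifnot(inherits(classifier, "fb_classifier"),
            nrow(train_x) == length(train_y))
  if (length(unique(train_y)) == 1L) {
    warning("single-class training set; predicting the majority class",
            call. = FALSE)
    return(rep(as.integer(train_y[1]), nrow(test_x)))
  }
  scaler <- fit_robust_scaler(train_x)
  classifier$fit_predict(apply_robust_scaler(scaler, train_x),
                         as.integer(train_y),
                         apply_robust_scaler(scaler, test_x))
}
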