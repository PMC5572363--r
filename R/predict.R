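#' Assemble the IF-prediction dataset from experiment records
#'
#' Keeps only the proportion-level (Phase II) maps: predictor `x` is the
#' proportion of co-segregating markers in percent, response `y` is the
#' map inflation factor in percent, one row per map. Phase I sequential
#' records are excluded with a message stating the count.
#'
#' @param records record data frame from [phase2_sampled()] (possibly
#'   row-bound with [phase1_sequential()] output).
#' @return data frame x, y, lg.
#' @export
make_if_dataset <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("no experiment records supplied")
  dropped <- sum(records$mode != "phaseII_sampled")
  if (dropped > 0)
    message("excluding ", dropped, " non-proportion-level record(s)")
  rec <- records[records$mode == "phaseII_sampled", , drop = FALSE]
  if (nrow(rec) == 0) stop("no proportion-level records to model")
  data.frame(x = rec$proportion_pct, y = rec$IF, lg = rec$lg,
             stringsAsFactors = FALSE)
}

# One fit/predict closure per model tag. GLM is the Gaussian
# identity-link model and is numerically identical to LR; both are kept
# so the panel mirrors the conventional model list.
if_model_fits <- list(
  LR = function(tr, te) predict(lm(y ~ x, tr), te),
  GLM = function(tr, te) predict(glm(y ~ x, data = tr, family = gaussian()),
                                 te),
  POLY2 = function(tr, te) predict(lm(y ~ poly(x, 2, raw = TRUE), tr), te),
  POLY3 = function(tr, te) predict(lm(y ~ poly(x, 3, raw = TRUE), tr), te),
  KNN = function(tr, te) {
    mu <- mean(tr$x); s <- sd(tr$x)
    if (s == 0) s <- 1
    fit <- caret::knnreg(data.frame(x = (tr$x - mu) / s), tr$y, k = 5)
    predict(fit, data.frame(x = (te$x - mu) / s))
  },
  SVM = function(tr, te) {
    if (sd(tr$y) == 0) return(rep(tr$y[1], nrow(te)))  # nothing to scale
    as.numeric(predict(e1071::svm(y ~ x, data = tr, kernel = "radial"),
                       te))
  },
  CART = function(tr, te) {
    fit <- rpart::rpart(y ~ x, data = tr, method = "anova")
    cp <- fit$cptable[which.min(fit$cptable[, "xerror"]), "CP"]
    predict(rpart::prune(fit, cp = cp), te)
  },
  RF = function(tr, te) {
    if (sd(tr$y) == 0) return(rep(tr$y[1], nrow(te)))
    predict(randomForest::randomForest(y ~ x, data = tr, ntree = 500), te)
  }
)

score_predictions <- function(obs, pred) {
  rmse <- sqrt(mean((obs - pred)^2))
  acc <- if (sd(obs) == 0 || sd(pred) == 0) NA_real_ else cor(obs, pred)
  c(RMSE = rmse, accuracy = acc)
}

#' Fit the regression panel predicting IF from co-segregation proportion
#'
#' Fits linear regression (LR), the Gaussian identity-link generalized
#' linear model (GLM), quadratic and cubic polynomial regressions
#' (POLY2/POLY3), k-nearest-neighbour regression (KNN, k = 5 on the
#' standardized predictor), radial-basis support-vector regression
#' (SVM), a cost-complexity-pruned regression tree (CART) and a
#' 500-tree random forest (RF), under one of two partition designs:
#' an 80/20 holdout split, or 10-fold cross-validation with 5
#' replicates where per-fold scores are averaged over the 50
#' fold-evaluations. All models share the same seeded partition, and
#' goodness of fit is scored as the root mean square error (RMSE) and
#' the Pearson correlation between predicted and observed values in the
#' test data.
#'
#' @param dataset data frame from [make_if_dataset()] (columns x, y).
#' @param design `"holdout_80_20"` or `"cv10x5"`.
#' @param seed partition seed.
#' @param models subset of model tags to fit.
#' @return data frame: model, design, RMSE, accuracy.
#' @export
fit_if_models <- function(dataset, design = c("holdout_80_20", "cv10x5"),
                          seed = 1L, models = names(if_model_fits)) {
  design <- match.arg(design)
  stopifnot(all(models %in% names(if_model_fits)), nrow(dataset) >= 50)
  n <- nrow(dataset)
  if (design == "holdout_80_20") {
    test_sets <- with_seed(derive_seed(seed, "holdout"), {
      list(sort(sample.int(n, round(0.2 * n))))
    })
  } else {
    test_sets <- with_seed(derive_seed(seed, "cv"), {
      sets <- list()
      for (repl in 1:5) {
        fold <- sample(rep_len(1:10, n))
        for (f in 1:10) sets[[length(sets) + 1]] <- which(fold == f)
      }
      sets
    })
  }
  out <- lapply(models, function(mod) {
    scores <- vapply(test_sets, function(test) {
      tr <- dataset[-test, , drop = FALSE]
      te <- dataset[test, , drop = FALSE]
      pred <- with_seed(derive_seed(seed, mod, length(test)),
                        if_model_fits[[mod]](tr, te))
      score_predictions(te$y, pred)
    }, c(RMSE = 0, accuracy = 0))
    data.frame(model = mod, design = design,
               RMSE = mean(scores["RMSE", ]),
               accuracy = mean(scores["accuracy", ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
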