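#' Default hyperparameter grids for the five classifier families
#'
#' Grids are ordered from simpler to more complex configurations, so
#' cross-validation ties resolve to the simpler model. Logistic regression
#' has no tunable hyperparameters (empty grid). All grids can be overridden
#' by passing a modified copy to the training functions.
#'
#' @return Named list of data.frames, one per method.
#' @export
default_grids <- function() {
  rf <- expand.grid(max_depth = c(3, 5, 0), num_trees = c(100, 300, 500),
                    mtry_rule = c("sqrt", "all"), stringsAsFactors = FALSE)
  svm <- rbind(
    expand.grid(kernel = "linear", cost = c(0.1, 1, 10), gamma_mult = NA_real_,
                stringsAsFactors = FALSE),
    expand.grid(kernel = "radial", cost = c(0.1, 1, 10), gamma_mult = c(0.5, 1, 2),
                stringsAsFactors = FALSE))
  gbm <- expand.grid(eta = c(0.01, 0.1), max_depth = c(3, 5),
                     nrounds = c(100, 300), stringsAsFactors = FALSE)
  nn <- expand.grid(size = c(8, 16), decay = c(0.1, 0.01),
                    stringsAsFactors = FALSE)
  list(random_forest = rf,
       logistic_regression = data.frame(),
       svm = svm,
       gbm = gbm,
       neural_net = nn)
}

tr_methods <- function() {
  c("random_forest", "logistic_regression", "svm", "gbm", "neural_net")
}

#' Fit one classifier
#'
#' Fits the requested model family on the supplied rows (all of them; the
#' caller decides whether that is a training split or the full dataset) using
#' only the named features, and returns an object whose
#' [predict_prob()] method yields the probability of the `target` class.
#' SVM probabilities come from e1071's cross-validated sigmoid calibration;
#' the neural net is a single-hidden-layer perceptron with weight-decay
#' regularization on standardized inputs.
#'
#' @param train data.frame with `label` plus feature columns.
#' @param method one of `random_forest`, `logistic_regression`, `svm`,
#'   `gbm`, `neural_net`.
#' @param params one-row data.frame (or list) of hyperparameters for the
#'   method; see [default_grids()] for the fields.
#' @param features character vector of feature columns to use (default: all).
#' @param seed integer seed; fits are deterministic (single-threaded).
#' @return Object of class `tr_model`.
#' @export
fit_model <- function(train, method, params = NULL,
                      features = feature_columns(train), seed = 1L) {
  method <- match.arg(method, tr_methods())
  if (length(unique(train$label)) < 2) {
    stop_invalid("training data must contain both classes")
  }
  x <- as.matrix(train[, features, drop = FALSE])
  y <- factor(train$label, levels = c("non_target", "target"))
  params <- as.list(params)
  fit <- with_seed(seed, switch(method,
    random_forest = {
      p <- length(features)
      mtry <- if (identical(params$mtry_rule, "all")) p else max(1, floor(sqrt(p)))
      md <- params$max_depth %||% 0
      ranger::ranger(x = as.data.frame(x), y = y, probability = TRUE,
                     num.trees = params$num_trees %||% 300,
                     max.depth = md, mtry = mtry,
                     seed = seed, num.threads = 1)
    },
    logistic_regression = {
      df <- data.frame(.y = as.integer(y == "target"), as.data.frame(x))
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    svm = {
      kernel <- params$kernel %||% "radial"
      base_gamma <- 1 / (ncol(x) * max(mean(apply(x, 2, var)), 1e-12))
      gamma <- base_gamma * (if (is.null(params$gamma_mult) ||
                                 is.na(params$gamma_mult)) 1 else params$gamma_mult)
      e1071::svm(x = x, y = y, kernel = kernel, cost = params$cost %||% 1,
                 gamma = gamma, probability = TRUE, scale = TRUE)
    },
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y == "target"),
                                     nthread = 1)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       eta = params$eta %||% 0.1,
                                       max_depth = params$max_depth %||% 3,
                                       nthread = 1, seed = seed),
                         data = dtrain, nrounds = params$nrounds %||% 100,
                         verbose = 0)
    },
    neural_net = {
      center <- colMeans(x); scale <- apply(x, 2, sd); scale[scale == 0] <- 1
      xs <- sweep(sweep(x, 2, center), 2, scale, "/")
      fit <- nnet::nnet(xs, as.integer(y == "target"),
                        size = params$size %||% 8,
                        decay = params$decay %||% 0.1,
                        maxit = 500, trace = FALSE, MaxNWts = 5000)
      list(net = fit, center = center, scale = scale)
    }))
  structure(list(method = method, params = params, fit = fit,
                 features = features, seed = as.integer(seed)),
            class = "tr_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict target probabilities from a fitted classifier
#'
#' @param model a `tr_model` from [fit_model()].
#' @param newdata data.frame containing at least the model's feature columns.
#' @return Numeric vector of probabilities of the `target` class, in \[0, 1\].
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "tr_model"))
  missing <- setdiff(model$features, names(newdata))
  if (length(missing)) {
    stop_invalid("newdata lacks feature(s): ", paste(missing, collapse = ", "))
  }
  x <- as.matrix(newdata[, model$features, drop = FALSE])
  p <- switch(model$method,
    random_forest = predict(model$fit, data = as.data.frame(x),
                            num.threads = 1)$predictions[, "target"],
    logistic_regression = unname(predict(model$fit,
                                         newdata = as.data.frame(x),
                                         type = "response")),
    svm = {
      pr <- predict(model$fit, newdata = x, probability = TRUE)
      attr(pr, "probabilities")[, "target"]
    },
    gbm = predict(model$fit, newdata = xgboost::xgb.DMatrix(x, nthread = 1)),
    neural_net = {
      xs <- sweep(sweep(x, 2, model$fit$center), 2, model$fit$scale, "/")
      as.vector(predict(model$fit$net, xs))
    })
  pmin(pmax(as.numeric(p), 0), 1)
}

# stratified fold assignment: each class spread evenly over folds
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (idx in split(seq_along(labels), labels)) {
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Tune hyperparameters by stratified cross-validated AUROC
#'
#' Evaluates each grid row by stratified k-fold cross-validation on the
#' training rows, scoring with AUROC, and returns the best row. Ties resolve
#' to the earliest grid row; grids from [default_grids()] are ordered
#' simpler-first, so ties favor the simpler model.
#'
#' @param train training rows (balanced; at least `2 * cv_folds`).
#' @param method classifier family.
#' @param grid data.frame of candidate hyperparameters; an empty or one-row
#'   grid is returned as-is without cross-validation.
#' @param features feature columns to use.
#' @param cv_folds number of folds (default 5).
#' @param seed integer seed (fold assignment and fits).
#' @return List with `params` (one-row data.frame or NULL), `cv_auroc`
#'   (vector over grid rows, NA when no CV was run).
#' @export
tune_model <- function(train, method, grid = default_grids()[[method]],
                       features = feature_columns(train), cv_folds = 5L,
                       seed = 1L) {
  method <- match.arg(method, tr_methods())
  if (nrow(train) < 2 * cv_folds) {
    stop_invalid("need at least ", 2 * cv_folds, " rows for ", cv_folds,
                 "-fold tuning, have ", nrow(train))
  }
  if (is.null(grid) || nrow(grid) <= 1) {
    params <- if (is.null(grid) || nrow(grid) == 0) NULL else grid[1, , drop = FALSE]
    return(list(params = params, cv_auroc = NA_real_))
  }
  folds <- stratified_folds(train$label, cv_folds, derive_seed(seed, "tune"))
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    aurocs <- vapply(seq_len(cv_folds), function(f) {
      fit <- fit_model(train[folds != f, , drop = FALSE], method,
                       params = grid[g, , drop = FALSE], features = features,
                       seed = derive_seed(seed, "tune", g * 100 + f))
      held <- train[folds == f, , drop = FALSE]
      auroc(predict_prob(fit, held), held$label == "target")
    }, 0)
    mean(aurocs)
  }, 0)
  best <- which.max(scores) # first maximum: simpler grid rows come first
  list(params = grid[best, , drop = FALSE], cv_auroc = scores)
}

#' Tune and fit every method on every negative-set training split
#'
#' For each classifier family and each of the ten datasets, tunes on the
#' training split by cross-validated AUROC and fits the chosen configuration
#' on that split, yielding `length(methods) * length(datasets)` models.
#'
#' @param datasets list of labeled datasets from [build_datasets()].
#' @param features feature columns to use (e.g. the selected features, or the
#'   three primary features).
#' @param methods classifier families to include (default: all five).
#' @param grids named list of grids (default [default_grids()]).
#' @param cv_folds folds for tuning.
#' @param seed master seed.
#' @return Nested list `models[[method]][[set]]` of `tr_model` objects, each
#'   carrying the tuned parameters.
#' @export
train_all <- function(datasets, features, methods = tr_methods(),
                      grids = default_grids(), cv_folds = 5L, seed = 1L) {
  out <- lapply(methods, function(m) {
    lapply(seq_along(datasets), function(i) {
      train <- datasets[[i]][datasets[[i]]$split == "train", , drop = FALSE]
      tuned <- tune_model(train, m, grid = grids[[m]], features = features,
                          cv_folds = cv_folds,
                          seed = derive_seed(seed, "tune", i))
      fit <- fit_model(train, m, params = tuned$params, features = features,
                       seed = derive_seed(seed, "fit", i))
      fit$cv_auroc <- tuned$cv_auroc
      fit$negative_set <- i
      fit
    })
  })
  names(out) <- methods
  out
}
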