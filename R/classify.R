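# Nested cross-validation: participant-wise 60/40 outer holdout repeated ten
# times, 10-fold grid-search tuning inside each outer training set (skipped
# for naive Bayes), ReliefF selection and any SMOTE fitted on the outer
# training set only, and metrics on the untouched outer test set.

#' Evaluation configuration for nested cross-validation
#'
#' @param algorithms Subset of \code{c("svm", "knn", "nb", "rf")}.
#' @param n_repeats Outer repeats. Default 10.
#' @param train_fraction Fraction of participants in the outer training set.
#'   Default 0.6.
#' @param inner_folds Inner cross-validation folds for grid search. Default
#'   10.
#' @param grids Named list of hyperparameter grids (data.frames), rows
#'   ordered simple-to-complex so accuracy ties resolve toward the simpler
#'   model. Defaults: SVM radial with cost in \{0.1, 1, 10, 100\} and gamma
#'   in \{0.001, 0.01, 0.1, 1\}; kNN with k in \{3, 5, ..., 15\}; RF with 500
#'   trees and mtry in \{sqrt(p), p/3, p/2\}. Naive Bayes is never tuned.
#' @param k_override Optional ReliefF k override (e.g. 15 for the fNIRS
#'   stream).
#' @param manual_cutoff Optional fixed number of selected features.
#' @param smote_threshold Class-ratio above which the training minority class
#'   is SMOTE-balanced. Default 1.1.
#' @param seed Master seed for splits, folds and SMOTE.
#' @return List of class \code{"eval_config"}.
#' @export
eval_config <- function(algorithms = c("svm", "knn", "nb", "rf"),
                        n_repeats = 10, train_fraction = 0.6,
                        inner_folds = 10, grids = default_grids(),
                        k_override = NULL, manual_cutoff = NULL,
                        smote_threshold = 1.1, seed = 1L) {
  algorithms <- match.arg(algorithms, c("svm", "knn", "nb", "rf"),
                          several.ok = TRUE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (inner_folds < 2) stop("inner_folds must be at least 2")
  structure(list(algorithms = algorithms, n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction,
                 inner_folds = as.integer(inner_folds), grids = grids,
                 k_override = k_override, manual_cutoff = manual_cutoff,
                 smote_threshold = smote_threshold, seed = as.integer(seed)),
            class = "eval_config")
}

#' @rdname eval_config
#' @export
default_grids <- function() {
  list(svm = expand.grid(gamma = c(0.001, 0.01, 0.1, 1),
                         cost = c(0.1, 1, 10, 100))[
                           order(rep(c(0.1, 1, 10, 100), each = 4)), ],
       knn = data.frame(k = c(3, 5, 7, 9, 11, 13, 15)),
       rf = data.frame(mtry_rule = c("sqrt", "third", "half"),
                       stringsAsFactors = FALSE))
}

#' Participant-wise outer split
#'
#' Splits at the participant level so that every window of a participant
#' falls on exactly one side.
#'
#' @param groups Participant id per row.
#' @param train_fraction Fraction of participants assigned to training.
#' @param seed Seed for the random participant selection.
#' @return List with \code{train} and \code{test} participant ids.
#' @export
outer_split <- function(groups, train_fraction = 0.6, seed = 1L) {
  if (is.null(groups) || !length(groups)) stop("group vector missing")
  ids <- unique(groups)
  if (length(ids) < 5) stop("need at least 5 participants to split")
  n_train <- round(train_fraction * length(ids))
  n_train <- min(max(n_train, 1L), length(ids) - 1L)
  train <- with_seed(seed, sample(ids, n_train))
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

rf_mtry <- function(rule, p) {
  v <- switch(rule, sqrt = sqrt(p), third = p / 3, half = p / 2,
              stop("unknown mtry rule: ", rule))
  max(1L, min(p, round(v)))
}

fit_and_predict <- function(algo, params, x_train, y_train, x_test,
                            positive) {
  lev <- levels(y_train)
  if (algo == "svm") {
    fit <- e1071::svm(x_train, y_train, kernel = "radial",
                      cost = params$cost, gamma = params$gamma)
    pred <- stats::predict(fit, x_test, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    dv_pos <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1]][1]
    score <- if (identical(dv_pos, positive)) dv else -dv
  } else if (algo == "knn") {
    pred <- class::knn(x_train, x_test, y_train, k = params$k, prob = TRUE)
    p_win <- attr(pred, "prob")
    score <- ifelse(pred == positive, p_win, 1 - p_win)
  } else if (algo == "nb") {
    fit <- e1071::naiveBayes(x_train, y_train)
    raw <- stats::predict(fit, x_test, type = "raw")
    score <- raw[, positive]
    pred <- factor(lev[max.col(raw[, lev, drop = FALSE])], levels = lev)
  } else if (algo == "rf") {
    fit <- randomForest::randomForest(x_train, y_train, ntree = 500,
                                      mtry = rf_mtry(params$mtry_rule,
                                                     ncol(x_train)))
    pred <- stats::predict(fit, x_test)
    score <- stats::predict(fit, x_test, type = "prob")[, positive]
  } else stop("unknown algorithm: ", algo)
  list(pred = factor(pred, levels = lev), score = as.numeric(score))
}

inner_grid_search <- function(algo, grid, x, y, folds, seed, positive) {
  fold_id <- with_seed(seed, sample(rep(seq_len(folds),
                                        length.out = length(y))))
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2 || !any(!tr)) next
      res <- fit_and_predict(algo, grid[g, , drop = FALSE],
                             x[tr, , drop = FALSE], y[tr],
                             x[!tr, , drop = FALSE], positive)
      correct <- correct + sum(res$pred == y[!tr])
    }
    acc[g] <- correct / length(y)
  }
  which.max(acc)  # first maximum = simplest model wins ties
}

#' Nested cross-validation report
#'
#' For each of \code{n_repeats} outer repeats: participants are split
#' 60/40; ReliefF feature selection, z-score standardisation and (when the
#' training class ratio exceeds \code{smote_threshold}) SMOTE balancing are
#' fitted on the outer training rows only; each algorithm is tuned by
#' \code{inner_folds}-fold grid search on the training rows (naive Bayes is
#' not tuned), refitted on the full training set, and scored on the untouched
#' test rows. A leakage guard hashes the test rows before selection/tuning
#' and verifies them untouched afterwards. A repeat whose training rows
#' collapse to a single class is resampled with a shifted, logged seed.
#'
#' @param dataset A [build_task_dataset()] result.
#' @param config An [eval_config()].
#' @return Object of class \code{"cv_report"}: \code{per_repeat} (long
#'   data.frame of metrics), \code{aggregate} (mean and sd per algorithm and
#'   metric), \code{chance} (corrected chance threshold per repeat from the
#'   realised test size, and their mean), \code{selection} and \code{tuning}
#'   logs, and \code{seeds}.
#' @export
nested_cv <- function(dataset, config = eval_config()) {
  stopifnot(inherits(dataset, "labelled_dataset"),
            inherits(config, "eval_config"))
  x <- dataset$x; y <- dataset$y; groups <- dataset$groups
  positive <- levels(y)[2]
  per <- NULL
  sel_log <- list()
  tune_log <- list()
  seeds <- integer(config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$seed + r
    repeat {
      sp <- outer_split(groups, config$train_fraction, seed_r)
      tr <- groups %in% sp$train
      if (length(unique(y[tr])) == 2 && length(unique(y[!tr])) == 2) break
      seed_r <- seed_r + 1000L  # degenerate split: resample, log the shift
    }
    seeds[r] <- seed_r
    x_test_guard <- x[!tr, , drop = FALSE]
    sel <- select_features(x[tr, , drop = FALSE], y[tr],
                           k_override = config$k_override,
                           manual_cutoff = config$manual_cutoff)
    cols <- sel$selected
    mu <- colMeans(x[tr, cols, drop = FALSE])
    sdv <- apply(x[tr, cols, drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    std <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
    xtr <- std(x[tr, cols, drop = FALSE]); ytr <- y[tr]
    xte <- std(x[!tr, cols, drop = FALSE]); yte <- y[!tr]
    cnt <- table(ytr)
    if (max(cnt) / min(cnt) > config$smote_threshold) {
      minority <- names(cnt)[which.min(cnt)]
      aug <- smote(xtr[ytr == minority, , drop = FALSE],
                   target_count = max(cnt), seed = seed_r + 500L)
      xtr <- rbind(xtr[ytr != minority, , drop = FALSE], aug)
      ytr <- factor(c(as.character(ytr[ytr != minority]),
                      rep(minority, nrow(aug))), levels = levels(y))
    }
    sel_log[[r]] <- list(k = sel$k, cutoff = sel$cutoff, features = cols)
    tune_log[[r]] <- list()
    for (algo in config$algorithms) {
      if (algo == "nb") {
        params <- data.frame(row.names = 1)  # tuning skipped by design
        tuned <- "untuned"
      } else {
        grid <- config$grids[[algo]]
        best <- inner_grid_search(algo, grid, xtr, ytr, config$inner_folds,
                                  seed_r + 77L, positive)
        params <- grid[best, , drop = FALSE]
        tuned <- paste(names(params), unlist(params), sep = "=",
                       collapse = ", ")
      }
      res <- fit_and_predict(algo, params, xtr, ytr, xte, positive)
      m <- binary_metrics(yte, res$pred, res$score, positive)
      per <- rbind(per, data.frame(repeat_ = r, algorithm = algo,
                                   n_test = length(yte), t(m)))
      tune_log[[r]][[algo]] <- tuned
    }
    if (!identical(x_test_guard, x[!tr, , drop = FALSE]))
      stop("leakage guard tripped: test rows were modified")
  }
  agg <- do.call(rbind, lapply(split(per, per$algorithm), function(d) {
    data.frame(algorithm = d$algorithm[1],
               t(colMeans(d[, c("accuracy", "f1", "tpr", "tnr", "auc")],
                          na.rm = TRUE)),
               t(stats::setNames(apply(d[, c("accuracy", "f1", "tpr", "tnr",
                                             "auc")], 2, stats::sd,
                                       na.rm = TRUE),
                                 c("accuracy_sd", "f1_sd", "tpr_sd",
                                   "tnr_sd", "auc_sd"))))
  }))
  rownames(agg) <- NULL
  n_test <- unique(per[, c("repeat_", "n_test")])$n_test
  structure(list(task = dataset$task, stream = dataset$stream,
                 per_repeat = per, aggregate = agg,
                 chance = list(per_repeat = chance_threshold(n_test),
                               mean = mean(chance_threshold(n_test)),
                               n_test = n_test),
                 selection = sel_log, tuning = tune_log, seeds = seeds,
                 config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat("Nested CV:", x$task, "task,", x$stream, "features -",
      length(x$seeds), "repeats\n")
  cat("Corrected chance threshold (mean over realised test sizes):",
      round(x$chance$mean, 4), "\n\n")
  a <- x$aggregate
  tab <- data.frame(algorithm = toupper(a$algorithm))
  for (m in c("accuracy", "f1", "tpr", "tnr", "auc"))
    tab[[m]] <- sprintf("%0.3f (%0.2f)", a[[m]], a[[paste0(m, "_sd")]])
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  above <- object$aggregate$accuracy > object$chance$mean
  cat("Task:", object$task, "/", object$stream, "\n")
  for (i in seq_len(nrow(object$aggregate)))
    cat(sprintf("  %-4s accuracy %0.3f %s corrected chance %0.4f\n",
                toupper(object$aggregate$algorithm[i]),
                object$aggregate$accuracy[i],
                if (above[i]) ">" else "<=", object$chance$mean))
  invisible(object)
}
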