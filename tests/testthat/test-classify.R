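test_that("binary metrics match hand-computed confusion quantities", {
  y <- factor(rep(c("neg", "pos"), c(6, 4)), levels = c("neg", "pos"))
  expect_equal(binary_metrics(y, y, scores = as.numeric(y == "pos")),
               c(accuracy = 1, f1 = 1, tpr = 1, tnr = 1, auc = 1))

  # TP = 3, FN = 1, TN = 5, FP = 1
  pred <- factor(c("neg", "neg", "neg", "neg", "neg", "pos",
                   "pos", "pos", "pos", "neg"), levels = c("neg", "pos"))
  m <- binary_metrics(y, pred)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["f1"]), 0.75)
  expect_equal(unname(m["tpr"]), 0.75)
  expect_equal(unname(m["tnr"]), 0.8333, tolerance = 1e-4)

  expect_warning(m1 <- binary_metrics(factor(rep("pos", 3),
                                             levels = c("neg", "pos")),
                                      factor(rep("pos", 3),
                                             levels = c("neg", "pos"))),
                 "single-class")
  expect_true(is.na(m1["tpr"]))
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:10) {
    y <- factor(sample(c("neg", "pos"), 40, replace = TRUE),
                levels = c("neg", "pos"))
    if (length(unique(y)) < 2) next
    sc <- rnorm(40) + (y == "pos") * runif(1, 0, 2)
    m <- binary_metrics(y, y, scores = sc)
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, levels = c("neg", "pos"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(unname(m["auc"]), ref, tolerance = 1e-10)
  }
})

test_that("the corrected chance level matches the exact binomial computation", {
  expect_equal(chance_threshold(400), 0.54)
  expect_equal(chance_threshold(160), 0.5625)
  expect_lt(abs(chance_threshold(1e6) - 0.5), 0.001)
  set.seed(42)
  for (n in c(1:20, sample(21:10000, 60))) {
    expect_equal(chance_threshold(n), exact_chance_oracle(n),
                 info = paste("n =", n))
  }
  # decreases toward 1/2 with growing test sets (up to quantile granularity)
  ladder <- chance_threshold(c(50, 200, 1000, 5000, 1e5))
  expect_true(all(diff(ladder) < 0))
  expect_true(all(ladder >= 0.5))
  expect_true(all(chance_threshold(seq(50, 5000, by = 50)) >= 0.5))
  expect_error(chance_threshold(400, alpha = 1.2), "alpha")
  expect_error(chance_threshold(0), "at least 1")
})

test_that("outer splits are participant-wise and reproducible", {
  groups <- rep(sprintf("p%02d", 1:20), each = 46)
  sp <- outer_split(groups, 0.6, seed = 9)
  expect_equal(length(sp$train), 12L)
  expect_equal(length(sp$test), 8L)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, outer_split(groups, 0.6, seed = 9))
  expect_error(outer_split(rep("p1", 10), 0.6, 1), "at least 5")
  expect_error(outer_split(NULL, 0.6, 1), "group vector")
})

make_cv_dataset <- function(n_participants = 8, windows = 12, p_noise = 3,
                            effect = 2, seed = 50) {
  set.seed(seed)
  rows <- n_participants * 2 * windows
  y <- factor(rep(rep(c("Easy", "Hard"), each = windows), n_participants),
              levels = c("Easy", "Hard"))
  x <- cbind(sig1 = (y == "Hard") * effect + rnorm(rows),
             sig2 = (y == "Hard") * effect / 2 + rnorm(rows),
             matrix(rnorm(rows * p_noise), rows,
                    dimnames = list(NULL, paste0("n", 1:p_noise))))
  structure(list(x = x, y = y,
                 groups = rep(sprintf("p%02d", 1:n_participants),
                              each = 2 * windows),
                 task = "demand", stream = "fnirs",
                 balance = table(y)),
            class = "labelled_dataset")
}

test_that("nested CV separates a strong effect and reports coherent metrics", {
  ds <- make_cv_dataset()
  cfg <- eval_config(algorithms = c("svm", "nb"), n_repeats = 4,
                     inner_folds = 4, seed = 3,
                     grids = list(svm = expand.grid(gamma = c(0.01, 0.1),
                                                    cost = c(1, 10))))
  r <- nested_cv(ds, cfg)
  expect_s3_class(r, "cv_report")
  metrics <- r$per_repeat[, c("accuracy", "f1", "tpr", "tnr", "auc")]
  expect_true(all(metrics >= 0 & metrics <= 1, na.rm = TRUE))
  expect_gt(r$aggregate$accuracy[r$aggregate$algorithm == "svm"],
            r$chance$mean)
  # balanced classes: accuracy lies between tpr and tnr
  for (i in seq_len(nrow(r$per_repeat))) {
    row <- r$per_repeat[i, ]
    expect_gte(row$accuracy, min(row$tpr, row$tnr) - 1e-9)
    expect_lte(row$accuracy, max(row$tpr, row$tnr) + 1e-9)
  }
  # aggregates recompute exactly from the per-repeat table
  for (alg in c("svm", "nb")) {
    d <- r$per_repeat[r$per_repeat$algorithm == alg, ]
    expect_equal(r$aggregate$accuracy[r$aggregate$algorithm == alg],
                 mean(d$accuracy))
    expect_equal(r$aggregate$accuracy_sd[r$aggregate$algorithm == alg],
                 sd(d$accuracy))
  }
  # naive Bayes is never tuned
  expect_true(all(vapply(r$tuning, function(t) t$nb == "untuned",
                         logical(1))))
  # train/test participants disjoint in every repeat (leakage guard ran)
  expect_equal(nrow(r$per_repeat), 4L * 2L)

  r2 <- nested_cv(ds, cfg)
  expect_identical(r$per_repeat, r2$per_repeat)  # same seed, same report
})

test_that("nested CV applies SMOTE to imbalanced training data", {
  ds <- make_cv_dataset(n_participants = 6, windows = 10, effect = 1)
  drop_rows <- which(ds$y == "Hard" & ds$groups %in%
                       sprintf("p%02d", 1:3))[1:20]
  ds$x <- ds$x[-drop_rows, ]
  ds$y <- ds$y[-drop_rows]
  ds$groups <- ds$groups[-drop_rows]
  cfg <- eval_config(algorithms = "nb", n_repeats = 2, seed = 5)
  expect_no_error(r <- nested_cv(ds, cfg))
  expect_equal(nrow(r$per_repeat), 2L)
})

test_that("kNN and random forest run through the same tuning path", {
  ds <- make_cv_dataset(n_participants = 6, windows = 8)
  cfg <- eval_config(algorithms = c("knn", "rf"), n_repeats = 2,
                     inner_folds = 3, seed = 11,
                     grids = list(knn = data.frame(k = c(3, 5)),
                                  rf = data.frame(mtry_rule = c("sqrt",
                                                                "half"))))
  r <- nested_cv(ds, cfg)
  expect_setequal(unique(r$per_repeat$algorithm), c("knn", "rf"))
  expect_true(all(r$per_repeat$accuracy >= 0 & r$per_repeat$accuracy <= 1))
  expect_match(r$tuning[[1]]$knn, "^k=")
  expect_match(r$tuning[[1]]$rf, "^mtry_rule=")
})

test_that("run_study assembles per-task, per-stream reports deterministically", {
  cfg <- sim_config(n_participants = 5, seed = 77)
  co <- simulate_cohort(cfg, conditions = c("easy", "hard"))
  study <- run_study(co, eval_config(algorithms = "nb", n_repeats = 2,
                                     seed = 9), tasks = "demand")
  expect_s3_class(study, "study_report")
  expect_named(study$reports, c("demand_fnirs", "demand_hr"))
  expect_equal(study$chance_printed$demand, 0.54)
  expect_equal(study$chance_printed$pain, 0.5625)
  agg <- study$reports$demand_fnirs$aggregate
  expect_equal(agg$algorithm, "nb")
  expect_true(all(agg[, c("accuracy", "f1", "tpr", "tnr", "auc")] >= 0 &
                    agg[, c("accuracy", "f1", "tpr", "tnr", "auc")] <= 1))
  # fNIRS stream records the explicit k override, HR stream the k rule
  expect_equal(study$reports$demand_fnirs$selection[[1]]$k, 15L)
  expect_equal(study$reports$demand_hr$selection[[1]]$k, 3L)

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  report_json(study, f1)
  report_json(study, f2)
  expect_identical(readLines(f1), readLines(f2))
})
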