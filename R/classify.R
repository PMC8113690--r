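# RBF-SVM diagnosis (MCS vs UWS) and prognosis (positive vs negative
# outcome) protocol: label construction, stratified 70/30 split, grid search
# in 5-fold cross-validation, and report metrics.

feature_set_columns <- function(name) {
  switch(name,
         hi = c("coh_41", "coh_41pm2"),
         lo = c("coh_2", "coh_4"),
         speech = c("coh_delta", "coh_theta"),
         combo = c("coh_2", "coh_4", "coh_delta", "coh_theta"),
         stop("unknown feature set '", name, "'", call. = FALSE))
}

#' Classification labels for a task
#'
#' Diagnosis labels patients MCS versus UWS; prognosis labels the outcome
#' positive versus negative, where a positive outcome is any advance in the
#' ordered consciousness categories UWS < MCS- < MCS+ < EMCS between
#' baseline and follow-up, and stasis or regress is negative.
#'
#' @param participants Participant tibble (patients only; healthy controls
#'   are rejected).
#' @param task `"diagnosis"` or `"prognosis"`.
#' @return Factor of labels, positive class last
#'   (`MCS` for diagnosis, `positive` for prognosis).
#' @export
make_labels <- function(participants, task = c("diagnosis", "prognosis")) {
  task <- match.arg(task)
  if (any(participants$group == "HC"))
    stop("healthy controls cannot enter a patient-only task", call. = FALSE)
  if (task == "diagnosis") {
    factor(participants$group, levels = c("UWS", "MCS"))
  } else {
    lev <- doc_levels()
    pos <- match(participants$followup_category, lev) >
      match(participants$baseline_category, lev)
    factor(ifelse(pos, "positive", "negative"),
           levels = c("negative", "positive"))
  }
}

#' Stratified train/test split
#'
#' Randomly assigns approximately `train_frac` of each class to the
#' training set; the per-class training count is `floor(frac * n + 0.5)`
#' (ties rounded toward training). Both classes must appear in both sets.
#'
#' @param data Data frame with a `label` factor column.
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed; the split is reproducible from it.
#' @return List with `train` and `test` tibbles.
#' @export
split_train_test <- function(data, train_frac = 0.7, seed = 1) {
  stopifnot("label" %in% names(data))
  tab <- table(data$label)
  if (length(tab) < 2 || any(tab < 2))
    stop("both classes need at least 2 members", call. = FALSE)
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      i <- which(data$label == cl)
      n_tr <- floor(train_frac * length(i) + 0.5)
      n_tr <- min(max(n_tr, 1), length(i) - 1)  # both sets non-empty per class
      sample(i, n_tr)
    }))
  })
  list(train = data[sort(idx_train), , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE])
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    i <- sample(which(labels == cl))
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

#' Fit an RBF-kernel SVM with grid search
#'
#' Standardizes the features with training-set statistics only, then
#' selects the (cost, gamma) pair maximizing mean accuracy in stratified
#' k-fold cross-validation over a log-2 grid; ties are broken toward the
#' smaller cost, then the smaller gamma. The final model is refit on the
#' whole training set at the selected parameters.
#'
#' @param train Training tibble with a `label` column and feature columns.
#' @param feature_cols Feature column names.
#' @param cost_grid,gamma_grid Candidate values.
#' @param k Number of cross-validation folds (default 5; reduced when a
#'   class is smaller than k so every fold keeps both classes).
#' @param seed Integer seed for fold assignment.
#' @return An `rhythm_svm` object.
#' @export
fit_svm_gridsearch <- function(train, feature_cols,
                               cost_grid = 2^seq(-5, 15, by = 1),
                               gamma_grid = 2^seq(-15, 3, by = 1),
                               k = 5, seed = 1) {
  stopifnot(length(cost_grid) > 0, length(gamma_grid) > 0)
  labels <- droplevels(factor(train$label))
  if (nlevels(labels) < 2)
    stop("training set must contain both classes", call. = FALSE)
  X <- as.matrix(train[, feature_cols, drop = FALSE])
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_)

  if (min(table(labels)) < 2)
    stop("each class needs at least 2 training members for cross-validation",
         call. = FALSE)
  k_eff <- min(k, min(table(labels)))
  grid <- expand.grid(gamma = sort(gamma_grid), cost = sort(cost_grid))
  grid <- grid[order(grid$cost, grid$gamma), ]

  acc <- withr::with_seed(seed, {
    fold <- stratified_folds(labels, k_eff)
    vapply(seq_len(nrow(grid)), function(g) {
      correct <- 0L
      for (f in seq_len(k_eff)) {
        tr <- fold != f
        fit <- e1071::svm(Xs[tr, , drop = FALSE], labels[tr],
                          kernel = "radial", cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = FALSE)
        pred <- stats::predict(fit, Xs[!tr, , drop = FALSE])
        correct <- correct + sum(pred == labels[!tr])
      }
      correct / length(labels)
    }, numeric(1))
  })
  best <- which.max(acc)  # grid ordered by cost then gamma: ties -> smallest
  fit <- e1071::svm(Xs, labels, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], scale = FALSE,
                    probability = FALSE)
  structure(list(fit = fit, cost = grid$cost[best], gamma = grid$gamma[best],
                 cv_accuracy = acc[best], center = center, scale = scale_,
                 feature_cols = feature_cols, levels = levels(labels)),
            class = "rhythm_svm")
}

#' @export
print.rhythm_svm <- function(x, ...) {
  cat(sprintf("<rhythm_svm: RBF, cost = %g, gamma = %g, CV accuracy = %.3f, features: %s>\n",
              x$cost, x$gamma, x$cv_accuracy,
              paste(x$feature_cols, collapse = ", ")))
  invisible(x)
}

decision_scores <- function(model, Xs) {
  pr <- stats::predict(model$fit, Xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # orient so larger score = second (positive) class
  cn <- colnames(dv)[1]
  first <- strsplit(cn, "/")[[1]][1]
  s <- as.numeric(dv[, 1])
  if (first == model$levels[2]) s else -s
}

#' Evaluate a fitted classifier on a test set
#'
#' Computes the 2x2 confusion matrix from hard predictions (positive class
#' = second factor level), sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' accuracy, AUC from the continuous SVM decision scores, and a Pearson
#' chi-square test (without continuity correction; the Yates-corrected
#' statistic is attached) on the confusion table.
#'
#' @param model An `rhythm_svm`.
#' @param test Test tibble with `label` and the model's feature columns.
#' @return A `classifier_report` (list): `confusion`, `sensitivity`,
#'   `specificity`, `accuracy`, `auc`, `chi2`, `chi2_p`, `best_cost`,
#'   `best_gamma`.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "rhythm_svm"), nrow(test) > 0)
  Xs <- scale(as.matrix(test[, model$feature_cols, drop = FALSE]),
              center = model$center, scale = model$scale)
  truth <- factor(test$label, levels = model$levels)
  pred <- factor(stats::predict(model$fit, Xs), levels = model$levels)
  neg <- model$levels[1]; pos <- model$levels[2]
  conf <- table(truth = truth, predicted = pred)
  tp <- conf[pos, pos]; fn <- conf[pos, neg]
  tn <- conf[neg, neg]; fp <- conf[neg, pos]
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / sum(conf)

  auc <- NA_real_
  if (nlevels(droplevels(truth)) == 2) {
    sc <- decision_scores(model, Xs)
    roc <- pROC::roc(response = truth, predictor = sc,
                     levels = model$levels, direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
  } else {
    warning("single-class test set: AUC undefined")
  }
  chi <- tryCatch(
    suppressWarnings(stats::chisq.test(conf, correct = FALSE)),
    error = function(e) NULL)
  chi_yates <- tryCatch(
    suppressWarnings(stats::chisq.test(conf, correct = TRUE)),
    error = function(e) NULL)
  structure(list(confusion = conf,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 auc = auc,
                 chi2 = if (is.null(chi)) NA_real_ else unname(chi$statistic),
                 chi2_p = if (is.null(chi)) NA_real_ else chi$p.value,
                 chi2_yates = if (is.null(chi_yates)) NA_real_ else
                   unname(chi_yates$statistic),
                 best_cost = model$cost, best_gamma = model$gamma),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  print(x$confusion)
  cat(sprintf("sensitivity %.3f, specificity %.3f, accuracy %.3f, AUC %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$auc))
  cat(sprintf("chi-square %.3f (p = %.4g); cost %g, gamma %g\n",
              x$chi2, x$chi2_p, x$best_cost, x$best_gamma))
  invisible(x)
}

#' @rdname tidy_rhythmtrack
#' @export
tidy.classifier_report <- function(x, ...) {
  tibble::tibble(metric = c("sensitivity", "specificity", "accuracy", "auc",
                            "chi2", "chi2_p"),
                 value = c(x$sensitivity, x$specificity, x$accuracy, x$auc,
                           x$chi2, x$chi2_p))
}

#' @rdname tidy_rhythmtrack
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy, auc = x$auc, chi2 = x$chi2,
                 chi2_p = x$chi2_p, best_cost = x$best_cost,
                 best_gamma = x$best_gamma)
}

#' Repeated split-fit-evaluate classification protocol
#'
#' A single random 70/30 split makes test metrics strongly seed-dependent
#' with ~30 patients, so the protocol repeats split, grid-search fit, and
#' evaluation over `n_repeats` derived seeds and summarizes the per-seed
#' metrics by their median. With `n_repeats = 1` it reproduces a single
#' split exactly.
#'
#' Participants with incomplete speech data are excluded from the `speech`
#' and `combo` feature sets.
#'
#' @param features Cohort feature tibble (one row per participant, with
#'   metadata and `coh_*` columns, e.g. `simulate_cohort()$features`).
#' @param feature_set `"hi"`, `"lo"`, `"speech"`, or `"combo"`.
#' @param task `"diagnosis"` or `"prognosis"`.
#' @param n_repeats Number of repeated splits.
#' @param seed Master seed; repeat i uses a seed derived from it.
#' @param permute_labels Randomly permute the labels anew in every repeat
#'   (chance baseline destroying any feature-label association).
#' @param train_frac Training fraction.
#' @param ... Passed to [fit_svm_gridsearch()] (grids, folds).
#' @return A `protocol_result`: `per_seed` tibble of metrics and `summary`
#'   one-row tibble of medians.
#' @export
run_protocol <- function(features, feature_set = "hi",
                         task = c("diagnosis", "prognosis"),
                         n_repeats = 25, seed = 1, permute_labels = FALSE,
                         train_frac = 0.7, ...) {
  task <- match.arg(task)
  cols <- feature_set_columns(feature_set)
  dat <- dplyr::filter(features, .data$group != "HC")
  if (feature_set %in% c("speech", "combo"))
    dat <- dplyr::filter(dat, .data$speech_complete)
  dat$label <- make_labels(dat, task)
  per_seed <- purrr::map(seq_len(n_repeats), function(i) {
    s <- derive_seed(seed, 10L + i)
    if (permute_labels)
      dat$label <- withr::with_seed(derive_seed(s, 77), sample(dat$label))
    sp <- split_train_test(dat, train_frac = train_frac, seed = s)
    model <- fit_svm_gridsearch(sp$train, cols, seed = s, ...)
    rep_ <- evaluate_classifier(model, sp$test)
    dplyr::mutate(glance(rep_), split_seed = s, repeat_id = i,
                  n_train = nrow(sp$train), n_test = nrow(sp$test),
                  .before = 1)
  }) |> dplyr::bind_rows()
  summary <- per_seed |>
    dplyr::summarise(dplyr::across(
      c("sensitivity", "specificity", "accuracy", "auc"),
      ~ stats::median(.x, na.rm = TRUE), .names = "median_{.col}"))
  structure(list(per_seed = per_seed, summary = summary,
                 feature_set = feature_set, task = task,
                 n_repeats = n_repeats, seed = seed),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result: %s features, %s task, %d repeats>\n",
              x$feature_set, x$task, x$n_repeats))
  print(x$summary)
  invisible(x)
}

#' @rdname tidy_rhythmtrack
#' @export
tidy.protocol_result <- function(x, ...) x$per_seed

#' @rdname tidy_rhythmtrack
#' @export
glance.protocol_result <- function(x, ...) {
  dplyr::mutate(x$summary, feature_set = x$feature_set, task = x$task,
                n_repeats = x$n_repeats, .before = 1)
}
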