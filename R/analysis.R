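SUBSET_NAMES <- c("male_vs_female", "baseline_vs_female", "baseline_vs_male")

#' Classifier specification
#'
#' Settings for the polynomial-kernel support vector machine: degree-3
#' polynomial kernel, numerical tolerance 0.001, and an 8:2 train/test split.
#' `max_iterations` is carried as declared configuration; the libsvm backend
#' iterates to tolerance convergence and exposes no hard cap.
#'
#' @param degree polynomial kernel degree.
#' @param cost soft-margin regularization constant C.
#' @param coef0 kernel offset (inhomogeneous polynomial).
#' @param max_iterations declared iteration limit.
#' @param tolerance termination tolerance of the optimizer.
#' @param train_fraction fraction of rows used for training.
#' @param standardize standardize features with training-set statistics.
#' @param seed split seed.
#' @return a `classifier_spec` object.
#' @export
classifier_spec <- function(degree = 3, cost = 1, coef0 = 1,
                            max_iterations = 100, tolerance = 0.001,
                            train_fraction = 0.8, standardize = TRUE,
                            seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  if (max_iterations < 1) stopf("max_iterations must be >= 1")
  structure(list(degree = degree, cost = cost, coef0 = coef0,
                 max_iterations = max_iterations, tolerance = tolerance,
                 train_fraction = train_fraction, standardize = standardize,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Wilcoxon signed-rank feature elimination
#'
#' For each feature column, tests the paired differences between two
#' row-aligned feature-table slices with the two-sided Wilcoxon signed-rank
#' test (exact null distribution for n <= 25 non-zero pairs, normal
#' approximation with continuity correction above). Features whose p-value is
#' >= `alpha` are eliminated; features with p < `alpha` are retained. A
#' feature with all-zero differences is eliminated with p = 1.
#'
#' @param features_a,features_b data frames with the 8 feature columns,
#'   paired row-for-row (same subject/window ordering).
#' @param alpha significance level for retention.
#' @param feature_names feature columns to test.
#' @return data frame with columns `feature`, `p_value`, `retained`.
#' @export
wilcoxon_filter <- function(features_a, features_b, alpha = 0.05,
                            feature_names = FEATURE_NAMES) {
  if (nrow(features_a) != nrow(features_b))
    stopf("slices must be paired: %d vs %d rows", nrow(features_a), nrow(features_b))
  if (nrow(features_a) < 5)
    stopf("need at least 5 pairs per feature, got %d", nrow(features_a))
  res <- lapply(feature_names, function(f) {
    d <- features_a[[f]] - features_b[[f]]
    nz <- d[d != 0]
    p <- if (length(nz) == 0) 1 else
      suppressWarnings(stats::wilcox.test(nz, exact = length(nz) <= 25,
                                          correct = TRUE)$p.value)
    data.frame(feature = f, p_value = p, retained = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble a binary classification subset from the feature table
#'
#' Restricts the feature table to one channel/band cell and builds the two
#' classes of the requested subset under the given intervention:
#' `male_vs_female` contrasts the two groups' intervention windows (positive
#' class male); `baseline_vs_male` / `baseline_vs_female` contrast a group's
#' intervention windows (positive class) against the same group's baseline
#' windows (negative class).
#'
#' @param features feature table from [extract_features()].
#' @param subset one of `"male_vs_female"`, `"baseline_vs_female"`,
#'   `"baseline_vs_male"`.
#' @param intervention condition label, e.g. `"MI-1"`.
#' @param channel,band the cell to classify.
#' @param feature_names feature columns to keep (e.g. the Wilcoxon-retained set).
#' @return list with `x` (numeric matrix), `y` (factor, levels neg/pos with
#'   positive second), and `meta` (key columns of the kept rows).
#' @export
assemble_subset <- function(features, subset, intervention, channel, band,
                            feature_names = FEATURE_NAMES) {
  subset <- match.arg(subset, SUBSET_NAMES)
  if (!channel %in% features$channel)
    stopf("channel '%s' absent from the feature table", channel)
  if (!band %in% features$band)
    stopf("band '%s' absent from the feature table", band)
  cell <- features[features$channel == channel & features$band == band, ]
  pick <- function(grp, cond) cell[cell$group == grp & cell$condition == cond, ]
  if (subset == "male_vs_female") {
    pos <- pick("male", intervention); neg <- pick("female", intervention)
    labels <- c("female", "male")
  } else {
    grp <- sub("baseline_vs_", "", subset)
    pos <- pick(grp, intervention); neg <- pick(grp, "baseline")
    labels <- c("baseline", grp)
  }
  if (nrow(pos) == 0) stopf("empty positive class (%s / %s)", subset, intervention)
  if (nrow(neg) == 0) stopf("empty negative class (%s / %s)", subset, intervention)
  ord <- function(d) d[order(d$subject_id, d$window), ]
  pos <- ord(pos); neg <- ord(neg)
  both <- rbind(neg, pos)
  x <- as.matrix(both[, feature_names, drop = FALSE])
  y <- factor(rep(labels, c(nrow(neg), nrow(pos))), levels = labels)
  list(x = x, y = y,
       meta = both[, c("subject_id", "group", "condition", "channel", "band", "window")])
}

#' Stratified train/test split indices
#'
#' Per class, `floor(train_fraction * n)` rows go to training; the rest to
#' test. Deterministic given the seed.
#'
#' @param y factor of class labels.
#' @param train_fraction training fraction.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_stratified <- function(y, train_fraction = 0.8, seed = 1L) {
  set.seed(seed)
  train <- integer(0)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    n_tr <- floor(train_fraction * length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Fit the polynomial SVM on a stratified split and score the held-out part
#'
#' Features are standardized with training-set statistics (unless disabled),
#' the SVM is fitted on the training partition, and the confusion counts and
#' sensitivity/specificity/accuracy are computed on the held-out partition.
#' The second factor level of `y` is the positive class.
#'
#' @param x numeric feature matrix.
#' @param y factor with two levels (positive class second).
#' @param spec a [classifier_spec()].
#' @return list with `counts` (TP/FP/TN/FN), `metrics`
#'   (sensitivity/specificity/accuracy, in percent), `n_train`, `n_test`.
#' @export
fit_and_score <- function(x, y, spec = classifier_spec()) {
  if (nlevels(y) != 2 || length(unique(y)) != 2)
    stopf("both classes must be present")
  if (nrow(x) < 5) stopf("need at least 5 rows, got %d", nrow(x))
  idx <- split_stratified(y, spec$train_fraction, spec$seed)
  if (length(unique(y[idx$train])) < 2 || length(unique(y[idx$test])) < 2)
    stopf("a class is absent from a partition after the split; adjust the seed or use stratification-friendly class sizes")
  xtr <- x[idx$train, , drop = FALSE]
  xte <- x[idx$test, , drop = FALSE]
  if (spec$standardize) {
    mu <- colMeans(xtr)
    sd_ <- apply(xtr, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sd_, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sd_, "/")
  }
  fit <- e1071::svm(xtr, y[idx$train], kernel = "polynomial",
                    degree = spec$degree, coef0 = spec$coef0, cost = spec$cost,
                    tolerance = spec$tolerance, scale = FALSE)
  pred <- stats::predict(fit, xte)
  counts <- confusion_counts(y[idx$test], pred, positive = levels(y)[2])
  list(counts = counts, metrics = performance_metrics(counts),
       n_train = length(idx$train), n_test = length(idx$test))
}

#' Confusion counts for binary predictions
#'
#' @param truth,pred factors over the same two levels.
#' @param positive label of the positive class.
#' @return list with integers `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  list(TP = sum(truth == positive & pred == positive),
       FP = sum(truth != positive & pred == positive),
       TN = sum(truth != positive & pred != positive),
       FN = sum(truth == positive & pred != positive))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sen = TP/(TP+FN) x 100, Spec = TN/(TN+FP) x 100,
#' Acc = (TP+TN)/(TP+FN+TN+FP) x 100. A metric with an empty denominator is
#' reported as `NA` (undefined), not 0.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN`.
#' @return list with `sensitivity`, `specificity`, `accuracy`, in percent.
#' @export
performance_metrics <- function(counts) {
  with(counts, {
    total <- TP + FP + TN + FN
    list(
      sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
      specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
      accuracy = if (total > 0) 100 * (TP + TN) / total else NA_real_
    )
  })
}

#' Sweep the classifier over every subset, intervention, channel and band
#'
#' For each cell: pair the two classes, run the Wilcoxon feature elimination,
#' assemble the subset on the retained features, fit the polynomial SVM on a
#' stratified 8:2 split, and record the held-out metrics. Cells that fail a
#' precondition (too few rows, unpairable classes, no retained features) are
#' recorded as skipped with a reason rather than failing the sweep.
#'
#' @param features feature table covering the cells to sweep.
#' @param subsets subset names to include.
#' @param interventions intervention labels to include.
#' @param spec a [classifier_spec()]; each cell's split seed is derived from
#'   `spec$seed` and the cell key.
#' @param alpha Wilcoxon retention level.
#' @param filter apply the Wilcoxon elimination (`TRUE`) or use all 8
#'   features (`FALSE`).
#' @param channels,bands cells to sweep (defaults: all present in `features`).
#' @param min_rows minimum rows per class for a cell to be attempted.
#' @return data frame with one row per cell: subset, intervention, channel,
#'   band, accuracy, sensitivity, specificity, n_train, n_test, n_features,
#'   skip_reason (`NA` when the cell ran).
#' @export
channel_band_sweep <- function(features, subsets = SUBSET_NAMES,
                               interventions = c("MI-1", "MI-2", "MI-3", "MI-4"),
                               spec = classifier_spec(), alpha = 0.05,
                               filter = TRUE,
                               channels = unique(features$channel),
                               bands = unique(features$band),
                               min_rows = 5) {
  grid <- expand.grid(subset = subsets, intervention = interventions,
                      channel = channels, band = bands,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- data.frame(g, accuracy = NA_real_, sensitivity = NA_real_,
                      specificity = NA_real_, n_train = NA_integer_,
                      n_test = NA_integer_, n_features = NA_integer_,
                      skip_reason = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      asm_all <- assemble_subset(features, g$subset, g$intervention,
                                 g$channel, g$band)
      npos <- sum(asm_all$y == levels(asm_all$y)[2])
      nneg <- sum(asm_all$y == levels(asm_all$y)[1])
      if (min(npos, nneg) < min_rows)
        stopf("fewer than %d rows in a class (%d vs %d)", min_rows, nneg, npos)
      keep <- FEATURE_NAMES
      if (filter) {
        if (npos != nneg) stopf("classes not pairable (%d vs %d rows)", nneg, npos)
        a <- as.data.frame(asm_all$x[asm_all$y == levels(asm_all$y)[2], , drop = FALSE])
        b <- as.data.frame(asm_all$x[asm_all$y == levels(asm_all$y)[1], , drop = FALSE])
        wil <- wilcoxon_filter(a, b, alpha)
        keep <- wil$feature[wil$retained]
        if (length(keep) == 0) stopf("no features retained at alpha = %g", alpha)
      }
      cell_spec <- spec
      cell_spec$seed <- derive_seed(spec$seed, g$subset, g$intervention,
                                    g$channel, g$band)
      asm <- assemble_subset(features, g$subset, g$intervention, g$channel,
                             g$band, feature_names = keep)
      fs <- fit_and_score(asm$x, asm$y, cell_spec)
      list(fs = fs, nfeat = length(keep))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$skip_reason <- conditionMessage(res)
    } else {
      out$accuracy <- res$fs$metrics$accuracy
      out$sensitivity <- res$fs$metrics$sensitivity
      out$specificity <- res$fs$metrics$specificity
      out$n_train <- res$fs$n_train
      out$n_test <- res$fs$n_test
      out$n_features <- res$nfeat
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
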