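fake_slice <- function(n, shift = 0, seed = 1) {
  set.seed(seed)
  as.data.frame(matrix(rnorm(n * 8), n,
                       dimnames = list(NULL, c("activity", "mobility",
                                               "complexity", "mean", "std",
                                               "variance", "skew", "kurtosis")))) |>
    transform(activity = activity + shift)
}

test_that("identical slices eliminate every feature", {
  a <- fake_slice(12)
  res <- wilcoxon_filter(a, a)
  expect_true(all(!res$retained))
  expect_true(all(res$p_value == 1))
})

test_that("a strong shift in one feature is retained, others eliminated", {
  a <- fake_slice(20, seed = 2)
  b <- a
  b$activity <- b$activity + 10   # +10 sigma shift
  res <- wilcoxon_filter(a, b)
  expect_true(res$retained[res$feature == "activity"])
  expect_lt(res$p_value[res$feature == "activity"], 0.05)
})

test_that("five all-positive differences give exact p = 0.0625 and elimination", {
  a <- fake_slice(5, seed = 3)
  b <- a
  b$activity <- b$activity - abs(rnorm(5)) - 0.1   # a - b all positive
  res <- wilcoxon_filter(a, b)
  expect_equal(res$p_value[res$feature == "activity"], 0.0625)
  expect_false(res$retained[res$feature == "activity"])
})

test_that("signed-rank p-values match full sign-pattern enumeration", {
  set.seed(4)
  for (i in 1:5) {
    d <- rnorm(10)
    a <- fake_slice(10, seed = 100 + i)
    b <- a
    b$activity <- a$activity - d
    res <- wilcoxon_filter(a, b)
    expect_equal(res$p_value[res$feature == "activity"], signed_rank_p_enum(d),
                 tolerance = 1e-12)
  }
})

test_that("unpaired or tiny slices are rejected", {
  expect_error(wilcoxon_filter(fake_slice(10), fake_slice(9)), "paired")
  expect_error(wilcoxon_filter(fake_slice(4), fake_slice(4)), "at least 5")
})

toy_features <- function(n_subj = 9) {
  grid <- expand.grid(subject_id = sprintf("s%02d", seq_len(2 * n_subj)),
                      condition = c("baseline", "MI-1", "MI-2"),
                      channel = c("C3", "C4"), band = c("delta", "beta"),
                      window = 0:3, stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("s", "", grid$subject_id)) <= n_subj,
                       "male", "female")
  set.seed(5)
  for (f in c("activity", "mobility", "complexity", "mean", "std",
              "variance", "skew", "kurtosis"))
    grid[[f]] <- rnorm(nrow(grid))
  grid$degenerate <- FALSE
  grid
}

test_that("subset assembly produces the expected class sizes and polarity", {
  tab <- toy_features()
  asm <- assemble_subset(tab, "male_vs_female", "MI-2", "C3", "delta")
  expect_equal(as.vector(table(asm$y)), c(36, 36))
  expect_equal(levels(asm$y), c("female", "male"))
  asm2 <- assemble_subset(tab, "baseline_vs_male", "MI-1", "C4", "beta")
  expect_equal(levels(asm2$y), c("baseline", "male"))
  expect_equal(sum(asm2$y == "male"), 36)
  expect_true(all(asm2$meta$condition[asm2$y == "baseline"] == "baseline"))
  expect_error(assemble_subset(tab, "male_vs_female", "MI-1", "P3", "delta"),
               "channel")
})

test_that("performance metrics follow the Sen/Spec/Acc formulas", {
  m <- performance_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(unlist(m), c(sensitivity = 100, specificity = 100, accuracy = 100))
  m <- performance_metrics(list(TP = 3, FN = 1, TN = 2, FP = 2))
  expect_equal(unlist(m), c(sensitivity = 75, specificity = 50, accuracy = 62.5))
  m <- performance_metrics(list(TP = 0, FN = 0, TN = 4, FP = 0))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 100)
  expect_equal(m$accuracy, 100)
})

test_that("metrics agree with a brute-force recount on enumerated tables", {
  for (tp in 0:5) for (fp in 0:5) for (tn in 0:5) for (fn in 0:5) {
    if (tp + fp + tn + fn == 0) next
    truth <- factor(rep(c("pos", "neg"), c(tp + fn, tn + fp)),
                    levels = c("neg", "pos"))
    pred <- factor(c(rep("pos", tp), rep("neg", fn),
                     rep("neg", tn), rep("pos", fp)), levels = c("neg", "pos"))
    counts <- confusion_counts(truth, pred, positive = "pos")
    expect_equal(unlist(counts), c(TP = tp, FP = fp, TN = tn, FN = fn))
    m <- performance_metrics(counts)
    if (tp + fn > 0) expect_equal(m$sensitivity, 100 * mean(pred[truth == "pos"] == "pos"))
    if (tn + fp > 0) expect_equal(m$specificity, 100 * mean(pred[truth == "neg"] == "neg"))
    expect_equal(m$accuracy, 100 * mean(pred == truth))
  }
})

test_that("accuracy is invariant to swapping class polarity", {
  counts <- list(TP = 7, FP = 2, TN = 5, FN = 3)
  swapped <- list(TP = counts$TN, FP = counts$FN, TN = counts$TP, FN = counts$FP)
  m1 <- performance_metrics(counts)
  m2 <- performance_metrics(swapped)
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$sensitivity, m2$specificity)
})

test_that("the stratified split is disjoint, exhaustive and seeded", {
  y <- factor(rep(c("a", "b"), c(1280, 1280)))
  sp <- split_stratified(y, 0.8, seed = 42)
  expect_length(sp$train, 2048)
  expect_length(sp$test, 512)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_identical(sp, split_stratified(y, 0.8, seed = 42))
  expect_false(identical(sp$train, split_stratified(y, 0.8, seed = 43)$train))
  # per-class floor rounding
  y2 <- factor(rep(c("a", "b"), c(36, 36)))
  sp2 <- split_stratified(y2, 0.8, seed = 1)
  expect_equal(as.vector(table(y2[sp2$train])), c(28, 28))
})

test_that("a linearly separable problem is classified perfectly", {
  set.seed(6)
  x <- cbind(feature = c(rnorm(40), rnorm(40, mean = 8)))
  y <- factor(rep(c("a", "b"), each = 40))
  res <- fit_and_score(x, y, classifier_spec(seed = 0))
  expect_equal(res$metrics$accuracy, 100)
  expect_equal(res$counts$TP + res$counts$TN, res$n_test)
  expect_equal(res$n_train + res$n_test, 80)
})

test_that("degenerate classification inputs are rejected", {
  x <- matrix(rnorm(8), 4)
  expect_error(fit_and_score(x, factor(rep("a", 4), levels = c("a", "b"))),
               "class")
  x2 <- matrix(rnorm(12), 6)
  y2 <- factor(c("a", "a", "a", "a", "a", "b"))
  expect_error(fit_and_score(x2, y2), "split|partition|class")
})

test_that("the sweep covers the grid and skips infeasible cells with reasons", {
  tab <- toy_features(n_subj = 9)
  sw <- channel_band_sweep(tab, subsets = c("male_vs_female", "baseline_vs_male"),
                           interventions = c("MI-1", "MI-2"),
                           channels = c("C3", "C4"), bands = c("delta", "beta"))
  expect_equal(nrow(sw), 2 * 2 * 2 * 2)
  # pure-noise features: most cells should be skipped by the Wilcoxon filter
  expect_true(any(!is.na(sw$skip_reason)))
  ran <- sw[is.na(sw$skip_reason), ]
  if (nrow(ran) > 0) {
    expect_true(all(ran$accuracy >= 0 & ran$accuracy <= 100))
    expect_true(all(ran$n_train + ran$n_test == 72))
  }
  # identical seed reproduces the sweep exactly
  sw2 <- channel_band_sweep(tab, subsets = c("male_vs_female", "baseline_vs_male"),
                            interventions = c("MI-1", "MI-2"),
                            channels = c("C3", "C4"), bands = c("delta", "beta"))
  expect_identical(sw, sw2)
})

test_that("an injected activity contrast is found by the sweep", {
  tab <- toy_features(n_subj = 9)
  sel <- tab$band == "delta" & tab$group == "male" & tab$condition != "baseline"
  tab$activity[sel] <- tab$activity[sel] + 12
  sw <- channel_band_sweep(tab, subsets = "male_vs_female",
                           interventions = "MI-1",
                           channels = c("C3", "C4"), bands = c("delta", "beta"))
  delta_acc <- sw$accuracy[sw$band == "delta"]
  expect_true(all(delta_acc == 100))
})
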