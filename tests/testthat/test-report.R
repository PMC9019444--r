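test_that("STA deviation summarizes ranges and paired-difference SD per group", {
  rec <- data.frame(subject_id = sprintf("s%d", 1:5),
                    group = c("male", "male", "male", "female", "female"),
                    sta1 = c(50, 55, 60, 50, 60),
                    sta2 = c(40, 45, 50, 40, 44))
  s <- sta_deviation(rec)
  expect_equal(s$sd_diff[s$group == "male"], 0)        # constant differences
  expect_equal(s$sd_diff[s$group == "female"], sd(c(10, 16)))
  expect_equal(s$sd_diff[s$group == "female"], 4.2426, tolerance = 1e-4)
  expect_equal(s$sta1_min[s$group == "male"], 50)
  expect_equal(s$sta2_max[s$group == "female"], 44)
})

test_that("a group with fewer than 2 records is omitted with a warning", {
  rec <- data.frame(subject_id = c("a", "b", "c"),
                    group = c("male", "male", "female"),
                    sta1 = c(50, 52, 41), sta2 = c(40, 40, 39))
  expect_warning(s <- sta_deviation(rec), "female")
  expect_equal(s$group, "male")
})

test_that("STA deviation recovers the generator SDs and male > female ordering", {
  cfg <- simulation_config(n_per_group = 500, seed = 31)
  s <- sta_deviation(simulate_sta(cfg))
  m <- s[s$group == "male", ]; f <- s[s$group == "female", ]
  expect_lt(abs(m$sd_diff - 7.12) / 7.12, 0.1)
  expect_lt(abs(f$sd_diff - 6.38) / 6.38, 0.1)
  expect_gt(m$sd_diff, f$sd_diff)
})

fake_sweep <- function(acc) {
  n <- length(acc)
  data.frame(subset = "male_vs_female", intervention = "MI-1",
             channel = rep(c("C3", "C4", "P3", "T3"), length.out = n),
             band = rep(c("delta", "beta"), length.out = n),
             accuracy = acc, sensitivity = acc, specificity = acc,
             n_train = 56L, n_test = 16L, n_features = 3L,
             skip_reason = NA_character_, stringsAsFactors = FALSE)
}

test_that("report filtering keeps exactly the at-or-above-threshold cells", {
  rep_all50 <- make_report(fake_sweep(rep(50, 8)))
  expect_equal(nrow(rep_all50$filtered), 0)
  expect_equal(nrow(rep_all50$full), 8)

  one_hit <- make_report(fake_sweep(c(rep(50, 7), 100)))
  expect_equal(nrow(one_hit$filtered), 1)
  expect_equal(one_hit$filtered$accuracy, 100)

  acc <- c(50, 69.994, 69.996, 70, 85, 100, 40, 72.22)
  rep_mix <- make_report(fake_sweep(acc))
  # >= 70 after rounding to 2 decimals: 69.996 rounds to 70.00 and stays
  n_kept <- sum(round(acc, 2) >= 70)
  expect_equal(sum(lengths(strsplit(rep_mix$filtered$channel, ", "))), n_kept)
})

test_that("channels with identical metrics collapse into one display row", {
  sw <- fake_sweep(rep(100, 4))
  sw$band <- "gamma"
  rep_ <- make_report(sw)
  expect_equal(nrow(rep_$filtered), 1)
  expect_equal(rep_$filtered$channel, "C3, C4, P3, T3")
})

test_that("the pipeline runs end to end, deterministically, and writes artifacts", {
  cfg <- pipeline_config(
    simulation = simulation_config(n_per_group = 3, segment_duration = 60,
                                   conditions = c("baseline", "MI-1")),
    window_s = 30, interventions = "MI-1", subsets = "male_vs_female",
    seed = 99
  )
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  res1 <- run_pipeline(cfg, dir1, verbose = FALSE)
  res2 <- run_pipeline(cfg, dir2, verbose = FALSE)
  expect_identical(res1$sweep, res2$sweep)
  expect_identical(res1$features, res2$features)
  # row count: subjects x conditions x channels x bands x windows
  expect_equal(nrow(res1$features), 6 * 2 * 14 * 5 * 2)
  expect_true(file.exists(file.path(dir1, "features.tsv")))
  expect_true(file.exists(file.path(dir1, "report_full.tsv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  # filtered report is exactly the >= threshold subset of the full table
  full <- res1$report$full
  kept <- sum(!is.na(full$accuracy) & round(full$accuracy, 2) >= 70)
  expect_equal(sum(lengths(strsplit(res1$report$filtered$channel, ", "))), kept)
})

test_that("scalp regions partition the 14-channel montage", {
  regions <- stresswave:::EEG_REGIONS
  expect_setequal(unlist(regions), stresswave:::EEG_CHANNELS)
  expect_equal(sum(lengths(regions)), 14)
})
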