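test_that("the walking rule applies three strict inequalities", {
  th_w <- walking_thresholds("walker")
  th_c <- walking_thresholds("wheelchair")
  expect_true(walking_indicator(fake_features(9, 3, 1), th_w))
  # boundary equality fails: the inequalities are strict
  expect_false(walking_indicator(fake_features(8, 3, 1), th_w))
  expect_false(walking_indicator(fake_features(9, 4, 1), th_w))
  expect_false(walking_indicator(fake_features(9, 3, 0.7), th_w))
  # the variance threshold is the only one that differs by locomotion type
  expect_false(walking_indicator(fake_features(9, 3, 0.5), th_w))
  expect_true(walking_indicator(fake_features(9, 3, 0.5), th_c))
})

test_that("features from the wrong sensor or side are rejected", {
  th <- walking_thresholds("walker")
  expect_error(walking_indicator(fake_features(9, 3, 1, role = "Aff"), th),
               "non-affected")
  expect_error(walking_indicator(fake_features(9, 3, 1,
                                               placement = "upper_arm"), th),
               "non-affected")
  expect_error(walking_thresholds("walker", theta1 = -1), "positive")
})

test_that("raising theta1/theta3 or lowering theta2 never adds walking windows", {
  set.seed(17)
  f <- fake_features(runif(300, 6, 11), runif(300, 2, 6), runif(300, 0, 2))
  base <- walking_indicator(f, walking_thresholds("walker"))
  for (i in 1:20) {
    t1 <- 8 + runif(1, 0, 2); t2 <- 4 - runif(1, 0, 2)
    t3 <- 0.7 + runif(1, 0, 1)
    tighter <- walking_indicator(f, walking_thresholds("walker", theta1 = t1,
                                                       theta2 = t2,
                                                       theta3 = t3))
    expect_true(all(base | !tighter))  # tighter set is a subset
  }
})

test_that("flagged windows merge into maximal segments and back", {
  s1 <- windows_to_segments(c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(nrow(s1), 1)
  expect_equal(s1$duration_s, 3)
  expect_equal(s1$start_s, 1); expect_equal(s1$end_s, 4)

  s2 <- windows_to_segments(c(TRUE, FALSE, TRUE))
  expect_equal(nrow(s2), 2)
  expect_equal(s2$duration_s, c(1, 1))

  expect_equal(nrow(windows_to_segments(c(FALSE, FALSE))), 0)

  # round trip: the union of segments reproduces the flag set exactly
  set.seed(4)
  for (k in 1:10) {
    fl <- runif(60) < 0.4
    seg <- windows_to_segments(fl)
    back <- rep(FALSE, 60)
    for (i in seq_len(nrow(seg))) back[seg$start_window[i]:seg$end_window[i]] <- TRUE
    expect_identical(back, fl)
  }
})

test_that("truth table scores window-level agreement and closes to 100%", {
  ann <- data.frame(start_s = c(0, 10), end_s = c(10, 20),
                    label = c("walk", "sit"))
  perfect <- detection_truth_table(c(rep(TRUE, 10), rep(FALSE, 10)), ann)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)

  none <- detection_truth_table(rep(FALSE, 20), ann)
  expect_equal(none$tp, 0); expect_equal(none$fn, 50)
  expect_equal(none$tn, 50); expect_equal(none$fp, 0)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 100)

  # closure invariant under random predictions and labels
  set.seed(8)
  for (k in 1:10) {
    tt <- detection_truth_table(runif(20) < 0.5, ann)
    expect_equal(tt$tp + tt$tn + tt$fp + tt$fn, 100, tolerance = 0.01)
  }

  # no walking annotated anywhere: specificity defined, sensitivity is NaN
  allsit <- detection_truth_table(rep(FALSE, 20),
                                  data.frame(start_s = 0, end_s = 20,
                                             label = "sit"))
  expect_true(is.nan(allsit$sensitivity))
  expect_error(detection_truth_table(rep(TRUE, 5),
                                     data.frame(start_s = 100, end_s = 110,
                                                label = "walk")),
               "cover")
})

test_that("detector on a synthetic day reaches 90% window sensitivity and specificity", {
  p <- gait_profile()
  day <- simulate_recording_day(p, short_day_script(seed = 23))
  al <- assign_sides(align_streams(day$streams), p$affected_side)
  roles <- sapply(al, function(x) paste(x$placement, x$role))
  f <- window_features(al[[which(roles == "thigh NonAff")]])
  fl <- walking_indicator(f, walking_thresholds("walker"))
  tt <- detection_truth_table(fl, day$annotations)
  expect_gte(tt$sensitivity, 90)
  expect_gte(tt$specificity, 90)
})

test_that("the physiotherapy mask removes only overlapping segments", {
  seg <- windows_to_segments(c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 10)))
  ann <- data.frame(start_s = 14, end_s = 26, label = "physiotherapy_walk")
  kept <- apply_exclusions(seg, ann)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start_s, 0)
  # nothing excluded without matching labels or annotations
  expect_equal(nrow(apply_exclusions(seg, NULL)), 2)
  expect_equal(nrow(apply_exclusions(seg, data.frame(start_s = 0, end_s = 30,
                                                     label = "walk"))), 2)
})
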