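test_that("per-chamber control distance averages the right pairs", {
  d <- matrix(c(0, 0.2, 0.4,
                0.2, 0, 0.6,
                0.4, 0.6, 0), 3, 3,
              dimnames = list(c("c1", "c2", "t1"), c("c1", "c2", "t1")))
  meta <- tibble::tibble(sample_id = c("c1", "c2", "t1"),
                         chamber_id = c("C1", "C2", "T1"),
                         treatment = c("control", "control", "trt"))
  got <- per_chamber_control_distance(d, meta)
  expect_equal(got$value[got$chamber_id == "C1"], 0.2)
  expect_equal(got$value[got$chamber_id == "C2"], 0.2)
  expect_equal(got$value[got$chamber_id == "T1"], 0.5)

  # a duplicate of the treated sample gets the identical value
  d2 <- rbind(cbind(d, t2 = c(0.4, 0.6, 0)), t2 = c(0.4, 0.6, 0, 0))
  colnames(d2) <- rownames(d2) <- c("c1", "c2", "t1", "t2")
  meta2 <- dplyr::bind_rows(meta, tibble::tibble(
    sample_id = "t2", chamber_id = "T2", treatment = "trt"))
  got2 <- per_chamber_control_distance(d2, meta2)
  expect_equal(got2$value[got2$chamber_id == "T2"], 0.5)

  # all-identical chambers score zero everywhere
  z <- matrix(0, 3, 3, dimnames = dimnames(d))
  expect_true(all(per_chamber_control_distance(z, meta)$value == 0))

  expect_error(per_chamber_control_distance(
    d, dplyr::mutate(meta, treatment = c("control", "x", "y"))),
    ">= 2 control")
})

test_that("control normalization gives an exactly flat control mean", {
  s <- tibble::tibble(
    chamber_id = c("C1", "C2", "C3", "T1"),
    treatment = c("control", "control", "control", "trt"),
    time_h = 10,
    value = c(0.1, 0.2, 0.3, 0.5))
  n <- normalize_to_control(s)
  expect_equal(n$value[1:3], c(0.5, 1.0, 1.5))
  expect_equal(n$value[4], 2.5)
  # flatness on random multi-time series, to machine precision
  s2 <- flat_series(seed = 2)
  n2 <- normalize_to_control(s2)
  ctrl_means <- n2 |>
    dplyr::filter(treatment == "control") |>
    dplyr::group_by(time_h) |>
    dplyr::summarise(m = mean(value))
  expect_true(all(abs(ctrl_means$m - 1) < 1e-12))
  # scale invariance: rescaling a time point changes nothing
  s3 <- dplyr::mutate(s2, value = value * ifelse(time_h == 96, 50, 1))
  expect_equal(normalize_to_control(s3)$value, n2$value, tolerance = 1e-12)
  # zero control mean names the offending time point
  s4 <- dplyr::mutate(s2, value = ifelse(
    time_h == 48 & treatment == "control", 0, value))
  expect_error(normalize_to_control(s4), "48")
})

test_that("baseline normalization anchors every group mean at 24 h", {
  s <- normalize_to_control(flat_series(seed = 5))
  b <- normalize_to_baseline(s)
  means <- b |>
    dplyr::filter(time_h == 24) |>
    dplyr::group_by(treatment) |>
    dplyr::summarise(m = mean(value))
  expect_true(all(abs(means$m - 1) < 1e-12))
  # the control group (already mean-1 everywhere) is unchanged
  expect_equal(b$value[b$treatment == "control"],
               s$value[s$treatment == "control"], tolerance = 1e-12)
  expect_error(normalize_to_baseline(s, baseline_time = 33), "baseline")
})

test_that("trapezoid AUC matches closed forms and is additive", {
  expect_equal(trapezoid_auc(c(72, 120, 216), c(1, 1, 1), c(72, 216)), 144)
  y <- 1 + (c(72, 144, 216) - 72) / 144   # linear 1 -> 2
  expect_equal(trapezoid_auc(c(72, 144, 216), y, c(72, 216)), 216)
  expect_equal(trapezoid_auc(c(72, 216), c(1, 3), c(72, 216)), 288)
  expect_error(trapezoid_auc(c(72, 120), c(1, 1), c(72, 216)), "boundary")
  # additivity across the shared 216-h anchor
  set.seed(11)
  t <- mbra_schedule()
  v <- exp(rnorm(length(t), 0, 0.4))
  expect_equal(trapezoid_auc(t, v, c(72, 216)) +
                 trapezoid_auc(t, v, c(216, 274)),
               trapezoid_auc(t, v, c(72, 274)), tolerance = 1e-12)
})

test_that("above/below AUC splits at baseline crossings exactly", {
  expect_equal(phase_auc_above_below(c(72, 216), c(1, 1), c(72, 216)),
               c(auc_above = 0, auc_below = 0))
  expect_equal(phase_auc_above_below(c(72, 216), c(0.5, 1.5), c(72, 216)),
               c(auc_above = 18, auc_below = 18))
  expect_equal(phase_auc_above_below(c(72, 140, 216), c(2, 2, 2),
                                     c(72, 216)),
               c(auc_above = 144, auc_below = 0))
  # decomposition identity on random trajectories
  set.seed(12)
  t <- mbra_schedule()
  for (i in 1:10) {
    v <- exp(rnorm(length(t), 0, 0.5))
    ab <- phase_auc_above_below(t, v, c(72, 216))
    expect_equal(ab[["auc_above"]] - ab[["auc_below"]],
                 trapezoid_auc(t, v - 1, c(72, 216)), tolerance = 1e-12)
    expect_gte(ab[["auc_above"]], 0)
    expect_gte(ab[["auc_below"]], 0)
  }
})

test_that("score_readout composes normalizations and phase AUCs", {
  s <- flat_series(seed = 21)
  auc <- score_readout(s, readout = "density")
  expect_setequal(unique(auc$phase), c("treatment", "post"))
  expect_equal(nrow(auc), 6 * 2)
  # control chambers of a null series center on the flat-curve AUC
  ctrl <- auc |>
    dplyr::filter(treatment == "control", phase == "treatment")
  expect_equal(mean(ctrl$auc), 144, tolerance = 144 * 0.15)
  # strictly-positive trajectories satisfy auc = above - below + duration
  expect_equal(auc$auc, auc$auc_above - auc$auc_below +
                 ifelse(auc$phase == "treatment", 144, 58),
               tolerance = 1e-10)
})
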