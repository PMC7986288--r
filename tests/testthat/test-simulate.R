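# small, fast configs for generator property tests
small_cfg <- function(treatments = list(), seed = 1, ...) {
  simulation_config(treatments = treatments, n_features = 60,
                    depth = 1500, n_transcript_families = 30,
                    seed = seed, ...)
}

test_that("generation is deterministic and validates the chamber budget", {
  cfg <- small_cfg(list(effect_spec("x", density_fold = 2)), seed = 42)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(ft_counts(e1$feature_table), ft_counts(e2$feature_table))
  expect_identical(e1$cq, e2$cq)
  expect_identical(e1$plate_readings, e2$plate_readings)
  expect_identical(ape::write.tree(e1$tree), ape::write.tree(e2$tree))
  expect_error(simulation_config(
    treatments = lapply(paste0("t", 1:8), effect_spec)),
    "Chamber budget")
  expect_error(effect_spec("x", shift_fold = -1), "> 0")
  expect_error(effect_spec("x", shift_fraction = 1.4), "\\[0, 1\\]")
})

test_that("experiment structure matches the configured design", {
  cfg <- small_cfg(list(effect_spec("a"), effect_spec("b")), seed = 5)
  ex <- generate_experiment(cfg)
  expect_equal(nrow(ex$metadata), (3 + 2 * 3) * 17)
  expect_equal(length(unique(ex$metadata$chamber_id)), 9)
  expect_equal(sort(unique(ex$metadata$treatment)), c("a", "b", "control"))
  expect_equal(sort(unique(ex$metadata$time_h)), mbra_schedule())
  expect_equal(dim(ft_counts(ex$feature_table)), c(9 * 17, 60))
  expect_equal(unname(rowSums(ft_counts(ex$feature_table))),
               rep(1500, 9 * 17))
  # transcripts exist exactly for the 120-h samples
  expect_equal(sort(ft_samples(ex$transcripts)),
               sort(ex$metadata$sample_id[ex$metadata$time_h == 120]))
  # the tree covers the features
  expect_setequal(ex$tree$tip.label, ex$feature_table$feature_id)
})

test_that("a zero-effect treatment yields an all-null answer key", {
  ex <- generate_experiment(small_cfg(list(effect_spec("inert")), seed = 8))
  expect_true(all(as.character(ex$answer_key$class) == "none"))
  expect_false(any(ex$answer_key$sig_treatment))
})

test_that("controls lose alpha diversity within 48 h then stay stable", {
  set.seed(77)
  drops <- replicate(8, {
    ex <- generate_experiment(small_cfg(seed = sample.int(1e6, 1)))
    m <- ft_counts(ex$feature_table)
    obs <- tibble::tibble(
      sample_id = rownames(m),
      observed = apply(m, 1, observed_features)) |>
      dplyr::inner_join(ex$metadata, by = "sample_id") |>
      dplyr::group_by(time_h) |>
      dplyr::summarise(m = mean(observed))
    c(start = obs$m[obs$time_h == 0],
      settled = obs$m[obs$time_h == 48],
      late = mean(obs$m[obs$time_h >= 72]))
  })
  avg <- rowMeans(drops)
  expect_gt(avg[["start"]], avg[["settled"]] * 1.1)    # clear initial drop
  expect_lt(abs(avg[["settled"]] - avg[["late"]]),      # then stationary
            0.05 * avg[["settled"]])
})

test_that("a persistent density doubling appears in post-phase loads", {
  set.seed(123)
  ratios <- replicate(50, {
    ex <- generate_experiment(small_cfg(
      list(effect_spec("dens", density_fold = 2, reversible = FALSE)),
      seed = sample.int(1e6, 1)))
    curve <- fit_qpcr_standard_curve(ex$qpcr_standards)
    load <- tibble::tibble(sample_id = ex$cq$sample_id,
                           value = quantify_density(ex$cq$cq, curve)) |>
      dplyr::inner_join(ex$metadata, by = "sample_id") |>
      dplyr::filter(phase == "post") |>
      dplyr::group_by(treatment) |>
      dplyr::summarise(m = mean(value))
    load$m[load$treatment == "dens"] / load$m[load$treatment == "control"]
  })
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("a reversible composition effect recovers after exposure", {
  set.seed(321)
  recov <- replicate(12, {
    ex <- generate_experiment(small_cfg(
      list(effect_spec("dys", shift_fraction = 0.3, shift_fold = 4,
                       dropout_fraction = 0.2, reversible = TRUE)),
      seed = sample.int(1e6, 1)))
    s <- readout_series(ex, "jaccard") |>
      normalize_to_control() |>
      normalize_to_baseline()
    trt <- s[s$treatment == "dys", ]
    c(during = mean(trt$value[trt$time_h > 96 & trt$time_h <= 216]),
      after = mean(trt$value[trt$time_h >= 264]))
  })
  avg <- rowMeans(recov)
  expect_gt(avg[["during"]], 1.05)                # elevated under exposure
  expect_lt(avg[["after"]] - 1, (avg[["during"]] - 1) / 2)  # recovering
})

test_that("the answer key reflects each effect dial and reversibility", {
  key <- derive_answer_key(list(
    effect_spec("a", density_fold = 2, reversible = FALSE),
    effect_spec("b", shift_fraction = 0.2, shift_fold = 3,
                reversible = TRUE),
    effect_spec("c", dropout_fraction = 0.1, reversible = TRUE)))
  expect_equal(
    as.character(key$class[key$treatment == "a" & key$readout == "density"]),
    "non_reversible")
  expect_equal(
    as.character(key$class[key$treatment == "b" &
                             key$readout == "weighted_unifrac"]),
    "reversible")
  expect_equal(
    as.character(key$class[key$treatment == "b" & key$readout == "jaccard"]),
    "none")
  expect_equal(
    as.character(key$class[key$treatment == "c" & key$readout == "jaccard"]),
    "reversible")
  expect_false(any(key$sig_post[key$readout == "transcriptome"]))
})

test_that("simulated plates sit on the curve when noise-free", {
  curve <- reporter_standard_curve(10^(1:5), 0.1 + 0.3 * (0:4))
  p <- simulate_plate_readings(1e4, curve, dilutions = c(10, 100, 1000),
                               noise_sd = 0)
  expect_equal(p$od620, approx(curve$log10_conc, curve$od,
                               xout = log10(1e4 / c(10, 100, 1000)),
                               rule = 2)$y)
  # response increases with concentration in the linear range
  p2 <- simulate_plate_readings(2e4, curve, dilutions = c(10, 100, 1000),
                                noise_sd = 0)
  expect_true(all(p2$od620 >= p$od620))
  expect_error(simulate_plate_readings(-1, curve), "positive")
})

test_that("clade sampling returns coherent sets of the requested size", {
  set.seed(9)
  ex <- generate_experiment(small_cfg(seed = 1))
  tree <- ex$tree
  for (n in c(0, 5, 18, 60)) {
    s <- mbrascreen:::clade_sample(tree, n)
    expect_length(s, n)
    expect_true(all(s %in% seq_len(60)))
    expect_false(anyDuplicated(s) > 0)
  }
  excl <- 1:30
  s <- mbrascreen:::clade_sample(tree, 10, exclude = excl)
  expect_false(any(s %in% excl))
})
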