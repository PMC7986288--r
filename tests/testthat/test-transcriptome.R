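test_that("the q28/80% read filter is exact and inclusive at the boundary", {
  reads <- generate_quality_reads(4, 10, c(1, 0.8, 0.7, 0), seed = 2)
  kept <- quality_filter(reads)
  expect_equal(kept$id, reads$id[1:2])   # 100% and exactly 80% pass
  # order preserved, filter idempotent
  expect_equal(quality_filter(kept), kept)
  # a 100-base all-Q30 read is kept
  allq30 <- tibble::tibble(id = "r", sequence = strrep("A", 100),
                           quality = strrep(intToUtf8(30 + 33), 100))
  expect_equal(nrow(quality_filter(allq30)), 1)
  # empty reads are dropped with a warning
  withq <- dplyr::bind_rows(allq30, tibble::tibble(
    id = "empty", sequence = "", quality = ""))
  expect_warning(out <- quality_filter(withq), "empty")
  expect_equal(out$id, "r")
})

test_that("generated reads carry the requested qualifying-base counts", {
  reads <- generate_quality_reads(3, 100, c(1, 0.5, 0.333), seed = 7)
  n_pass <- vapply(phred_scores(reads$quality),
                   function(q) sum(q >= 28), integer(1))
  expect_equal(n_pass, c(100L, 50L, 33L))
  r2 <- generate_quality_reads(1, 10, 0.8, seed = 1)
  expect_equal(sum(phred_scores(r2$quality)[[1]] >= 28), 8L)
  expect_equal(nrow(generate_quality_reads(0, 50, 1)), 0)
  expect_error(generate_quality_reads(2, 0, 1), "read_length")
  # deterministic given seed
  expect_identical(generate_quality_reads(5, 40, 0.6, seed = 33),
                   generate_quality_reads(5, 40, 0.6, seed = 33))
})

test_that("transcript distance to control reuses bray-curtis means", {
  m <- matrix(c(0.6, 0.4,
                0.6, 0.4,
                0.1, 0.9), nrow = 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "t1"), c("g1", "g2")))
  meta <- tibble::tibble(sample_id = c("c1", "c2", "t1"),
                         chamber_id = c("C1", "C2", "T1"),
                         treatment = c("control", "control", "trt"))
  got <- transcript_distance_to_control(feature_table(m), meta)
  expect_equal(got$value[got$chamber_id == "C1"], 0)
  # hand: bray((0.1,0.9),(0.6,0.4)) = 1 - 2*(0.1+0.4)/2 = 0.5
  expect_equal(got$value[got$chamber_id == "T1"], 0.5)
  # treated identical to controls scores zero
  m2 <- m
  m2["t1", ] <- m2["c1", ]
  expect_true(all(transcript_distance_to_control(
    feature_table(m2), meta)$value == 0))
})

test_that("volcano thresholds are inclusive on log2fc, strict on q", {
  cls <- classify_volcano(c(4, 3.999, 5, -4, -5, 0),
                          c(0.05, 0.05, 0.10, 0.099, 0.2, 0.001))
  expect_equal(as.character(cls), c("up", "ns", "ns", "down", "ns", "ns"))
})

test_that("volcano computes fold changes, Welch p and BH q per family", {
  set.seed(14)
  n_fam <- 40
  base <- rep(1 / n_fam, n_fam)
  mk <- function(mult, n = 3, noise = 0.01) {
    m <- t(replicate(n, base * mult * exp(rnorm(n_fam, 0, noise))))
    m <- m / rowSums(m)
    dimnames(m) <- list(paste0("s", seq_len(n), "_", sample(1e6, 1)),
                        paste0("g", seq_len(n_fam)))
    feature_table(m)
  }
  up_mult <- rep(1, n_fam); up_mult[1] <- 40; up_mult[2] <- 1 / 40
  treated <- mk(up_mult)
  ctrl <- mk(rep(1, n_fam))
  v <- volcano(treated, ctrl)
  expect_s3_class(v, "mbra_volcano")
  expect_equal(as.character(v$class[v$family_id == "g1"]), "up")
  expect_equal(as.character(v$class[v$family_id == "g2"]), "down")
  expect_true(all(v$q >= v$p - 1e-15))
  expect_equal(v$q, p.adjust(v$p, "BH"))
  # identical groups: fold change zero, nothing significant
  v0 <- volcano(ctrl, ctrl)
  expect_true(all(abs(v0$log2fc) < 1e-12))
  expect_true(all(as.character(v0$class) == "ns"))
  expect_error(volcano(mk(rep(1, n_fam), n = 1), ctrl), "2 replicates")
})

test_that("planted 16-fold families are recovered with high sensitivity", {
  set.seed(60)
  hits <- replicate(20, {
    n_fam <- 60
    base <- exp(rnorm(n_fam, 0, 1))
    # a floor of genuinely rare families keeps the pseudocount small, and
    # planting on mid-abundance families keeps renormalization from
    # compressing the realized fold change
    base[1:3] <- base[1:3] * 1e-4
    planted <- order(base)[6:11]  # low mass, but far above the floor
    mult <- rep(1, n_fam)
    mult[planted] <- rep(c(20, 1 / 20), 3)
    mk <- function(m) {
      x <- t(replicate(3, base * m * exp(rnorm(n_fam, 0, 0.1))))
      x <- x / rowSums(x)
      dimnames(x) <- list(paste0("s", 1:3, sample(1e6, 1)),
                          paste0("g", seq_len(n_fam)))
      feature_table(x)
    }
    v <- volcano(mk(mult), mk(rep(1, n_fam)))
    found <- v$class[match(paste0("g", planted), v$family_id)]
    mean(found != "ns")
  })
  expect_gte(mean(hits), 0.9)
})
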