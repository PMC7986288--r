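#' Specify a synthetic treatment effect
#'
#' Declares what a simulated compound does to the community while it is in
#' the feed medium (the 72-216 h exposure window). All folds are
#' multiplicative and apply only during exposure; after exposure ends a
#' reversible effect relaxes back to baseline exponentially while a
#' persistent one stays in force.
#'
#' @param treatment Treatment label.
#' @param density_fold Fold change of total bacterial load.
#' @param shift_fraction Fraction of features whose relative abundance is
#'   perturbed.
#' @param shift_fold Fold change applied to the shifted features. An
#'   abundance fold change moves abundance-weighted composition metrics
#'   (weighted UniFrac, Bray-Curtis) but barely touches presence/absence
#'   metrics.
#' @param dropout_fraction Fraction of features suppressed to near-zero
#'   abundance during exposure (a presence-level effect: the ground truth
#'   for Jaccard and unweighted UniFrac, and for observed richness).
#' @param evenness_delta Target reduction in Pielou evenness of the
#'   expected community (0 = no effect).
#' @param lps_fold,flic_fold Fold change of bioactive LPS / flagellin.
#' @param transcript_shift_fraction,transcript_fold Fraction of transcript
#'   families perturbed and their fold change.
#' @param reversible Does the effect relax to baseline after exposure?
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(treatment,
                        density_fold = 1,
                        shift_fraction = 0, shift_fold = 1,
                        dropout_fraction = 0,
                        evenness_delta = 0,
                        lps_fold = 1, flic_fold = 1,
                        transcript_shift_fraction = 0, transcript_fold = 1,
                        reversible = TRUE) {
  folds <- c(density_fold, shift_fold, lps_fold, flic_fold, transcript_fold)
  if (any(folds <= 0)) abort("All fold changes must be > 0.")
  fracs <- c(shift_fraction, dropout_fraction, transcript_shift_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("Fractions must lie in [0, 1].")
  if (evenness_delta < 0 || evenness_delta >= 1) {
    abort("`evenness_delta` must lie in [0, 1).")
  }
  structure(list(treatment = treatment, density_fold = density_fold,
                 shift_fraction = shift_fraction, shift_fold = shift_fold,
                 dropout_fraction = dropout_fraction,
                 evenness_delta = evenness_delta,
                 lps_fold = lps_fold, flic_fold = flic_fold,
                 transcript_shift_fraction = transcript_shift_fraction,
                 transcript_fold = transcript_fold,
                 reversible = isTRUE(reversible)),
            class = "effect_spec")
}

#' Configure a synthetic MBRA experiment
#'
#' Default values reproduce the screen's design: 24 chambers at most per
#' experiment, 3 untreated control chambers, triplicate treatment chambers,
#' the standard 17-point sampling schedule with exposure from 72 to 216 h,
#' and an initial community contraction (a subset of inoculum features
#' washing out geometrically over the first 48 h) after which controls are
#' stationary.
#'
#' @param treatments List of [effect_spec()] objects.
#' @param n_controls Number of untreated chambers (default 3).
#' @param replicates Chambers per treatment (default 3).
#' @param times Sampling times in hours (default [mbra_schedule()]).
#' @param treatment_window Exposure window in hours (default 72-216).
#' @param n_features Number of community features (default 200).
#' @param depth Sequencing depth per sample (default 15000).
#' @param theta Dirichlet-multinomial precision; smaller = more
#'   overdispersed counts (default 200).
#' @param feature_noise_sd Per-feature per-sample log-normal noise sdlog.
#' @param chamber_feature_sd sdlog of persistent per-chamber, per-feature
#'   log-normal offsets (founder effects: each chamber settles into its own
#'   stable community that differs reproducibly from its neighbours).
#' @param load_noise_sd Per-time log-normal noise sdlog of bacterial load.
#' @param chamber_load_sd sdlog of the persistent per-chamber load offset.
#' @param assay_noise_sd Per-time log-normal noise sdlog of bioassay
#'   analyte levels.
#' @param chamber_assay_sd sdlog of persistent per-chamber analyte offsets.
#' @param plate_noise_sd Gaussian OD noise on simulated plate readings.
#' @param stabilization List describing the initial community contraction:
#'   `fraction` of inoculum features that wash out of every chamber,
#'   `chamber_fraction` that are additionally absent from each individual
#'   chamber from inoculation onwards (a chamber-specific founder set —
#'   ecological drift that gives every chamber a persistent
#'   presence/absence identity, already in place at the 24-h baseline),
#'   their residual `survival` fraction, and the `duration` in hours of the
#'   shared contraction.
#' @param baseline_sdlog sdlog of the log-normal baseline feature
#'   abundances.
#' @param recovery_halflife Half-life (hours) of post-exposure relaxation
#'   of reversible effects. Default 8 h: the chambers run at an 8-h
#'   retention time, so compound washout — the physical driver of
#'   relaxation — proceeds with this half-life.
#' @param n_transcript_families Gene families in the transcript table.
#' @param transcript_noise_sd Log-normal replicate noise of transcript
#'   abundances.
#' @param experiment_id Experiment label.
#' @param seed Integer seed; the whole experiment is deterministic given
#'   the config and seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(treatments = list(),
                              n_controls = 3, replicates = 3,
                              times = mbra_schedule(),
                              treatment_window = c(72, 216),
                              n_features = 200, depth = 15000,
                              theta = 200,
                              feature_noise_sd = 0.2,
                              chamber_feature_sd = 0.2,
                              load_noise_sd = 0.1,
                              chamber_load_sd = 0.15,
                              assay_noise_sd = 0.15,
                              chamber_assay_sd = 0.2,
                              plate_noise_sd = 0.01,
                              stabilization = list(fraction = 0.25,
                                                   chamber_fraction = 0.1,
                                                   survival = 0.02,
                                                   duration = 48),
                              baseline_sdlog = 1.5,
                              recovery_halflife = 8,
                              n_transcript_families = 300,
                              transcript_noise_sd = 0.3,
                              experiment_id = "E1",
                              seed = 1) {
  if (length(treatments) > 0 &&
      !all(vapply(treatments, inherits, logical(1), "effect_spec"))) {
    abort("`treatments` must be a list of effect_spec objects.")
  }
  n_chambers <- n_controls + replicates * length(treatments)
  if (n_chambers > 24) {
    abort(paste0("Chamber budget exceeded: ", n_chambers,
                 " chambers requested, the array has 24."))
  }
  if (n_controls < 2) abort("Need >= 2 control chambers.")
  if (replicates < 2 && length(treatments) > 0) {
    abort("Need >= 2 replicates per treatment for any statistical use.")
  }
  structure(as.list(environment()), class = "simulation_config")
}

# effect response at time t: 0 before exposure, 1 during, exponential
# relaxation (half-life h) after iff reversible
effect_response <- function(time_h, window, reversible, halflife) {
  ifelse(time_h <= window[1], 0,
         ifelse(time_h <= window[2], 1,
                if (reversible) 2^(-(time_h - window[2]) / halflife) else 1))
}

# exponent a such that pielou_evenness(p^a) drops by `delta`
evenness_exponent <- function(p, delta) {
  if (delta == 0) return(1)
  p <- p / sum(p)
  target <- max(pielou_evenness(p) - delta, 1e-3)
  f <- function(a) pielou_evenness(p^a) - target
  if (f(60) > 0) abort("`evenness_delta` unreachable for this community.")
  uniroot(f, c(1, 60), tol = 1e-10)$root
}

#' Generate a complete synthetic MBRA experiment
#'
#' Simulates one experiment of the screen: a log-normal baseline community
#' per experiment; an initial contraction in which a fixed subset of
#' features washes out geometrically over the first 48 h (controls are
#' stationary thereafter); per-chamber, per-time compositions perturbed by
#' each treatment's [effect_spec()] during the exposure window, relaxing
#' exponentially after exposure iff reversible; counts drawn by
#' Dirichlet-multinomial at the configured depth; total bacterial load
#' reported as a qPCR Cq table (with standard rows); bioactive LPS and
#' flagellin as reporter plate readings over a dilution series; transcript
#' relative abundances at the mid-exposure 120-h time point; a random
#' coalescent feature tree for the phylogenetic metrics; and a
#' machine-readable answer key derived from the effect specs.
#'
#' All randomness is governed by `config$seed`: the same config gives
#' byte-identical output.
#'
#' @param config A [simulation_config()].
#' @return Object of class `mbra_experiment`: list with `feature_table`,
#'   `metadata`, `cq`, `qpcr_standards`, `plate_readings`,
#'   `reporter_standards`, `transcripts`, `tree`, `answer_key`, `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nf <- config$n_features
  feature_ids <- sprintf("OTU%04d", seq_len(nf))
  tree <- ape::rcoal(nf, tip.label = feature_ids)

  # donor baseline community and the washout set of the initial contraction
  base <- stats::rlnorm(nf, meanlog = 0, sdlog = config$baseline_sdlog)
  names(base) <- feature_ids
  lineage <- simulate_lineages(nf)
  washout <- sample(nf, round(config$stabilization$fraction * nf))

  chambers <- chamber_plan(config)
  eff_by_trt <- setNames(config$treatments,
                         vapply(config$treatments, `[[`, "", "treatment"))
  # per-treatment target sets and evenness exponents, fixed for the run
  # treatment responses are phylogenetically coherent: both the abundance
  # shift and the dropout hit whole clades (blooms and extirpations of
  # related taxa), drawn disjointly per treatment
  shift_sets <- lapply(eff_by_trt, function(e)
    clade_sample(tree, round(e$shift_fraction * nf), weights = base))
  dropout_sets <- lapply(seq_along(eff_by_trt), function(i)
    clade_sample(tree,
                 round(eff_by_trt[[i]]$dropout_fraction * nf),
                 exclude = shift_sets[[i]]))
  names(dropout_sets) <- names(eff_by_trt)
  stab_comp <- base
  stab_comp[washout] <- stab_comp[washout] * config$stabilization$survival
  even_exp <- lapply(eff_by_trt, function(e)
    evenness_exponent(stab_comp, e$evenness_delta))
  transcript_ids <- sprintf("FAM%04d", seq_len(config$n_transcript_families))
  tr_base <- stats::rlnorm(config$n_transcript_families, 0, 1.5)
  tr_sets <- lapply(eff_by_trt, function(e)
    sample(config$n_transcript_families,
           round(e$transcript_shift_fraction *
                   config$n_transcript_families)))

  qpcr_std <- tibble(sample_id = sprintf("STD%+d", -3:3),
                     log10_quantity = -3:3,
                     cq = 30 - 3.321928 * (-3:3))
  rep_std <- list(
    LPS = reporter_standard_curve(10^(1:5), 0.1 + 0.3 * (0:4), "LPS"),
    FliC = reporter_standard_curve(10^(0:4), 0.1 + 0.3 * (0:4), "FliC"))
  analyte_base <- c(LPS = 1e4, FliC = 1e3)
  dilutions <- c(10, 100, 1000)

  nt <- length(config$times)
  ns <- nrow(chambers) * nt
  sample_ids <- character(ns)
  count_mat <- matrix(0L, ns, nf)
  cq_vec <- numeric(ns)
  conc_mat <- matrix(0, ns, length(analyte_base),
                     dimnames = list(NULL, names(analyte_base)))
  tr_rows <- list()
  si <- 0L
  for (ci in seq_len(nrow(chambers))) {
    ch <- chambers[ci, ]
    eff <- eff_by_trt[[ch$treatment]]
    # persistent chamber effects: each chamber is its own stable community
    chamber_feat <- exp(rnorm(nf, 0, config$chamber_feature_sd))
    ch_frac <- config$stabilization$chamber_fraction %||% 0
    chamber_washout <- sample(setdiff(seq_len(nf), washout),
                              round(ch_frac * nf))
    chamber_load <- exp(rnorm(1, 0, config$chamber_load_sd))
    chamber_assay <- setNames(
      exp(rnorm(length(analyte_base), 0, config$chamber_assay_sd)),
      names(analyte_base))
    for (t in config$times) {
      si <- si + 1L
      sid <- sprintf("%s_%s_T%03d", config$experiment_id, ch$chamber_id, t)
      sample_ids[si] <- sid
      r <- if (is.null(eff)) 0 else
        effect_response(t, config$treatment_window, eff$reversible,
                        config$recovery_halflife)
      w <- base
      stab <- config$stabilization
      decay <- stab$survival^(min(t, stab$duration) / stab$duration)
      w[washout] <- w[washout] * decay
      # founder absences are in force from inoculation: chamber identity is
      # established before the 24-h baseline snapshot
      w[chamber_washout] <- w[chamber_washout] * stab$survival
      if (!is.null(eff) && r > 0) {
        set <- shift_sets[[ch$treatment]]
        if (length(set) > 0) w[set] <- w[set] * eff$shift_fold^r
        drop_set <- dropout_sets[[ch$treatment]]
        if (length(drop_set) > 0) w[drop_set] <- w[drop_set] * 1e-3^r
        a <- 1 + (even_exp[[ch$treatment]] - 1) * r
        if (a != 1) w <- (w / sum(w))^a
      }
      w <- w * chamber_feat * exp(rnorm(nf, 0, config$feature_noise_sd))
      pi <- w / sum(w)
      g <- rgamma(nf, shape = config$theta * pi)
      p <- if (sum(g) > 0) g / sum(g) else pi
      count_mat[si, ] <- as.integer(rmultinom(1, config$depth, p))

      load <- chamber_load * exp(rnorm(1, 0, config$load_noise_sd)) *
        (if (is.null(eff)) 1 else eff$density_fold^r)
      cq_vec[si] <- 30 - 3.321928 * log10(load)

      for (an in names(analyte_base)) {
        fold <- if (is.null(eff)) 1 else
          switch(an, LPS = eff$lps_fold, FliC = eff$flic_fold)^r
        conc_mat[si, an] <- analyte_base[[an]] * fold *
          chamber_assay[[an]] * exp(rnorm(1, 0, config$assay_noise_sd))
      }

      if (t == 120) {
        v <- tr_base
        if (!is.null(eff)) {
          set <- tr_sets[[ch$treatment]]
          if (length(set) > 0) v[set] <- v[set] * eff$transcript_fold^r
        }
        v <- v * exp(rnorm(config$n_transcript_families, 0,
                           config$transcript_noise_sd))
        tr_rows[[sid]] <- v / sum(v)
      }

    }
  }

  dimnames(count_mat) <- list(sample_ids, feature_ids)
  rownames(conc_mat) <- sample_ids
  metadata <- tibble(
    sample_id = sample_ids,
    chamber_id = rep(chambers$chamber_id, each = nt),
    treatment = rep(chambers$treatment, each = nt),
    replicate = rep(chambers$replicate, each = nt),
    experiment_id = config$experiment_id,
    time_h = rep(config$times, nrow(chambers)),
    phase = assign_phase(rep(config$times, nrow(chambers)),
                         config$treatment_window))
  # plate readings: curve response to conc/dilution, plus OD noise, drawn
  # after the per-sample loop so the per-sample RNG stream stays compact
  plate <- purrr::map_dfr(names(analyte_base), function(an) {
    curve <- rep_std[[an]]
    grid <- tidyr::expand_grid(sample_id = sample_ids,
                               dilution_factor = dilutions)
    od <- approx(curve$log10_conc, curve$od,
                 xout = log10(conc_mat[grid$sample_id, an] /
                                grid$dilution_factor),
                 rule = 2, ties = "ordered")$y
    dplyr::mutate(grid, analyte = an, .after = "sample_id") |>
      dplyr::mutate(od620 = od + rnorm(length(od), 0,
                                       config$plate_noise_sd))
  })
  tr_mat <- do.call(rbind, tr_rows)
  dimnames(tr_mat) <- list(names(tr_rows), transcript_ids)

  structure(list(
    feature_table = feature_table(count_mat, lineage = lineage),
    metadata = metadata,
    cq = tibble(sample_id = sample_ids, cq = cq_vec,
                log10_quantity = NA_real_),
    qpcr_standards = qpcr_std,
    plate_readings = plate,
    reporter_standards = rep_std,
    transcripts = feature_table(tr_mat),
    tree = tree,
    answer_key = derive_answer_key(config$treatments),
    config = config), class = "mbra_experiment")
}

#' Standard validation panel of synthetic treatments
#'
#' A seven-condition panel spanning the effect space the screen is designed
#' to detect, used throughout the package's validation suites: a reversible
#' and a persistent community disruption (clade-level abundance shift plus
#' feature dropout), a persistent density increase, a reversible LPS
#' induction, a persistent flagellin induction, a transcriptome shift, and
#' a null treatment. Every composition cell of the dysbiosis conditions is
#' truthfully flagged in the answer key because the shift and dropout dials
#' are applied together.
#'
#' @return List of seven [effect_spec()] objects.
#' @export
standard_panel <- function() {
  list(
    effect_spec("dysbiosis_rev", shift_fraction = 0.3, shift_fold = 4,
                dropout_fraction = 0.2, reversible = TRUE),
    effect_spec("dysbiosis_per", shift_fraction = 0.3, shift_fold = 4,
                dropout_fraction = 0.2, reversible = FALSE),
    effect_spec("density_up", density_fold = 2, reversible = FALSE),
    effect_spec("lps_up", lps_fold = 3, reversible = TRUE),
    effect_spec("flic_up", flic_fold = 4, reversible = FALSE),
    effect_spec("transcript_shift", transcript_shift_fraction = 0.2,
                transcript_fold = 8, reversible = TRUE),
    effect_spec("null_compound"))
}

# sample ~n tips as a phylogenetically coherent set: preferably one clade
# of about the target size, else a union of large clades, topping up with
# random leftover tips; `exclude` tips are never picked. With `weights`
# (baseline abundances), among suitably sized clades the one whose share of
# total abundance best matches its share of features is chosen, so that
# perturbing a fixed fraction of features moves a commensurate fraction of
# community mass.
clade_sample <- function(tree, n_target, exclude = integer(0),
                         weights = NULL) {
  ntip <- length(tree$tip.label)
  if (n_target <= 0) return(integer(0))
  pool <- setdiff(seq_len(ntip), exclude)
  if (n_target >= length(pool)) return(sort(pool))
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]
    below[[parent]] <- c(below[[parent]], below[[po$edge[e, 2]]])
  }
  clades <- lapply((ntip + 1):(ntip + tree$Nnode), function(node)
    setdiff(below[[node]], exclude))
  sizes <- lengths(clades)
  # single clades close to the target (70-100% of it) are preferred
  snug <- which(sizes <= n_target & sizes >= 0.7 * n_target)
  if (length(snug) > 0) {
    picked <- if (is.null(weights)) {
      clades[[sample(snug, 1)]]
    } else {
      target_mass <- n_target / ntip
      mass <- vapply(clades[snug], function(tips)
        sum(weights[tips]) / sum(weights), numeric(1))
      clades[[snug[which.min(abs(mass - target_mass))]]]
    }
  } else {
    picked <- integer(0)
    for (k in sample(seq_along(clades))) {
      tips <- clades[[k]]
      if (length(tips) > 0 && length(tips) <= n_target - length(picked) &&
          !any(tips %in% picked)) {
        picked <- c(picked, tips)
      }
      if (length(picked) >= n_target) break
    }
  }
  if (length(picked) < n_target) {
    picked <- c(picked, sample(setdiff(pool, picked),
                               n_target - length(picked)))
  }
  sort(picked)
}

chamber_plan <- function(config) {
  rows <- list()
  idx <- 0
  for (i in seq_len(config$n_controls)) {
    idx <- idx + 1
    rows[[idx]] <- tibble(chamber_id = sprintf("C%02d", idx),
                          treatment = "control", replicate = i)
  }
  for (e in config$treatments) {
    for (i in seq_len(config$replicates)) {
      idx <- idx + 1
      rows[[idx]] <- tibble(chamber_id = sprintf("C%02d", idx),
                            treatment = e$treatment, replicate = i)
    }
  }
  dplyr::bind_rows(rows)
}

simulate_lineages <- function(nf) {
  orders <- c("Bacteroidales", "Clostridiales", "Lactobacillales",
              "Enterobacteriales", "Verrucomicrobiales", "Bifidobacteriales")
  genera <- list(c("Bacteroides", "Prevotella"),
                 c("Faecalibacterium", "Blautia", "Roseburia"),
                 c("Streptococcus", "Lactobacillus"),
                 c("Escherichia"), c("Akkermansia"), c("Bifidobacterium"))
  o <- sample(seq_along(orders), nf, replace = TRUE,
              prob = c(0.3, 0.4, 0.1, 0.05, 0.05, 0.1))
  vapply(o, function(i) {
    g <- sample(genera[[i]], 1)
    paste("Bacteria", "PhylumX", "ClassX", orders[i], "FamilyX", g,
          sep = ";")
  }, character(1))
}

#' Ground-truth answer key for a set of effect specs
#'
#' Derives, deterministically from the [effect_spec()]s alone, which
#' treatment x readout x phase cells carry a real effect and the implied
#' reversibility class. Each effect dial maps to the readouts it moves:
#' `density_fold` to the density readout; the abundance shift
#' (`shift_fraction`/`shift_fold`) to weighted UniFrac, which weights
#' branches by abundance; `dropout_fraction` (a presence-level effect) to
#' Jaccard, unweighted UniFrac and observed richness; `evenness_delta` to
#' evenness and (by suppressing rare taxa below detection) observed
#' richness; `lps_fold`/`flic_fold` to the bioassays;
#' and the transcript shift to the single-time-point transcriptome
#' distance (treatment phase only).
#'
#' @param treatments List of [effect_spec()]s.
#' @return Tibble: `treatment`, `readout`, `sig_treatment`, `sig_post`,
#'   `class`.
#' @export
derive_answer_key <- function(treatments) {
  purrr::map_dfr(treatments, function(e) {
    shift <- e$shift_fraction > 0 && e$shift_fold != 1
    dropout <- e$dropout_fraction > 0
    hit <- c(
      density = e$density_fold != 1,
      jaccard = dropout,
      unweighted_unifrac = dropout,
      weighted_unifrac = shift,
      observed = dropout || e$evenness_delta > 0,
      evenness = e$evenness_delta > 0,
      lps = e$lps_fold != 1,
      flic = e$flic_fold != 1,
      transcriptome = e$transcript_shift_fraction > 0 &&
        e$transcript_fold != 1)
    post <- hit & !e$reversible
    post["transcriptome"] <- FALSE     # measured in-exposure only
    tibble(treatment = e$treatment, readout = names(hit),
           sig_treatment = unname(hit), sig_post = unname(post),
           class = classify_reversibility(unname(hit), unname(post)))
  })
}

#' Simulate reporter plate readings for a known concentration
#'
#' OD at each dilution is the standard curve's (monotone piecewise-linear,
#' constant beyond its range) response to `concentration / dilution`, plus
#' Gaussian noise. With zero noise, quantification through
#' [quantify_bioactive()] recovers the true concentration exactly.
#'
#' @param concentration True analyte concentration (positive).
#' @param curve A `reporter_curve` from [reporter_standard_curve()].
#' @param dilutions Strictly increasing positive dilution factors.
#' @param noise_sd Gaussian OD noise standard deviation.
#' @param seed Optional integer seed for just this call.
#' @return Tibble: `dilution_factor`, `od620`.
#' @export
simulate_plate_readings <- function(concentration, curve,
                                    dilutions = c(10, 100, 1000),
                                    noise_sd = 0, seed = NULL) {
  if (concentration <= 0) abort("`concentration` must be positive.")
  if (any(diff(dilutions) <= 0) || any(dilutions <= 0)) {
    abort("`dilutions` must be positive and strictly increasing.")
  }
  if (!is.null(seed)) set.seed(seed)
  od <- approx(curve$log10_conc, curve$od,
               xout = log10(concentration / dilutions), rule = 2,
               ties = "ordered")$y
  tibble(dilution_factor = dilutions,
         od620 = od + rnorm(length(dilutions), 0, noise_sd))
}

#' Generate reads with a controlled fraction of high-quality bases
#'
#' Read `i` gets exactly `round(fraction[i] * read_length)` bases with
#' Phred quality >= `min_q` and the rest strictly below, at positions drawn
#' deterministically from the seed. Built as ground truth for exercising
#' the read quality filter.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length (>= 1).
#' @param fraction_high_quality Per-read fraction(s) in \[0, 1\], recycled
#'   to `n_reads`.
#' @param min_q Quality threshold the fractions refer to (default 28).
#' @param seed Optional integer seed for just this call.
#' @return Tibble of reads: `id`, `sequence`, `quality` (Phred+33).
#' @export
generate_quality_reads <- function(n_reads, read_length,
                                   fraction_high_quality, min_q = 28,
                                   seed = NULL) {
  if (n_reads == 0) {
    return(tibble(id = character(), sequence = character(),
                  quality = character()))
  }
  if (read_length < 1) abort("`read_length` must be >= 1.")
  frac <- rep_len(fraction_high_quality, n_reads)
  if (any(frac < 0 | frac > 1)) abort("Fractions must lie in [0, 1].")
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(n_reads), function(i) {
    k <- round(frac[i] * read_length)
    q <- sample(2:(min_q - 1), read_length, replace = TRUE)
    if (k > 0) {
      pos <- sample(read_length, k)
      q[pos] <- sample(min_q:40, k, replace = TRUE)
    }
    tibble(id = sprintf("read_%04d", i),
           sequence = paste(sample(c("A", "C", "G", "T"), read_length,
                                   replace = TRUE), collapse = ""),
           quality = intToUtf8(q + 33L))
  })
}
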