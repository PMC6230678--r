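#' Simulation configuration for a synthetic EoE cohort
#'
#' Describes the cohort the generator emulates: the three clinical groups at
#' the study sizes (18 controls, 13 EoE without food impaction, 14 EoE with
#' food impaction), an overdispersed count model for the digital mRNA panel,
#' a multiplicative per-lane technical scale (what control-based
#' normalization removes by construction), and planted group effects.
#'
#' @param n_control,n_eoe_nofi,n_eoe_fi Group sizes (each >= 2; defaults
#'   18/13/14).
#' @param panel A [probe_annotation()]; default [default_panel()].
#' @param baseline_mean Global multiplier (>0) on per-gene baseline means.
#' @param dispersion Negative-binomial size parameter (>0); smaller means
#'   more overdispersion. Default 15 (count CV of roughly 26% at high
#'   abundance, typical of targeted panels, and consistent with planted
#'   fold effects of 0.3-0.5 reaching adjusted significance at the study's
#'   group sizes).
#' @param eoe_effect Named fold map applied to both EoE groups vs Control.
#' @param fi_effect Named fold map applied to `EoE_FI` vs `EoE_no_FI`.
#' @param lane_scale_sd SD of the log-normal per-lane technical scale factor
#'   (on the natural-log scale). Default 0.15.
#' @param background_mean Poisson mean of negative-control counts, added to
#'   every probe's expected count as nonspecific background. Default 5.
#' @param pos_counts_per_fM Expected positive-control counts per fM of spike
#'   concentration (before lane scaling). Default 60.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_control = 18, n_eoe_nofi = 13, n_eoe_fi = 14,
                       panel = default_panel(), baseline_mean = 1,
                       dispersion = 15, eoe_effect = default_eoe_effect(),
                       fi_effect = default_fi_effect(), lane_scale_sd = 0.15,
                       background_mean = 5, pos_counts_per_fM = 60,
                       seed = 1L) {
  cfg <- list(n_control = as.integer(n_control),
              n_eoe_nofi = as.integer(n_eoe_nofi),
              n_eoe_fi = as.integer(n_eoe_fi),
              panel = panel, baseline_mean = baseline_mean,
              dispersion = dispersion, eoe_effect = eoe_effect,
              fi_effect = fi_effect, lane_scale_sd = lane_scale_sd,
              background_mean = background_mean,
              pos_counts_per_fM = pos_counts_per_fM, seed = as.integer(seed))
  if (any(c(cfg$n_control, cfg$n_eoe_nofi, cfg$n_eoe_fi) < 2))
    stop("configuration error: all group sizes must be >= 2")
  if (cfg$dispersion <= 0 || cfg$baseline_mean <= 0 ||
      cfg$lane_scale_sd < 0 || cfg$background_mean <= 0)
    stop("configuration error: scale parameters must be positive")
  for (eff in list(cfg$eoe_effect, cfg$fi_effect)) {
    if (length(eff)) {
      if (is.null(names(eff)) || any(!nzchar(names(eff))))
        stop("configuration error: effect maps must be named gene -> fold")
      if (any(eff <= 0))
        stop("configuration error: all fold factors must be > 0")
      unknown <- setdiff(names(eff), probes_of_class(panel, "Endogenous"))
      if (length(unknown))
        stop("configuration error: effect genes not in panel: ",
             paste(unknown, collapse = ", "))
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_groups <- function(config) {
  factor(rep(GROUP_LEVELS,
             times = c(config$n_control, config$n_eoe_nofi, config$n_eoe_fi)),
         levels = GROUP_LEVELS)
}

sim_sample_ids <- function(config) {
  sprintf("S%03d", seq_len(config$n_control + config$n_eoe_nofi + config$n_eoe_fi))
}

#' Simulate a raw count set with known ground truth
#'
#' Endogenous and housekeeping counts are negative-binomial with mean
#' `baseline_mean * gene_baseline * group_fold * lane_scale + background_mean`
#' and size `dispersion`; per-gene baselines are drawn log-uniformly over
#' \[50, 5000\] once per panel from the seed, so genes have heterogeneous
#' abundance. Positive-control counts are Poisson with mean proportional to
#' spike concentration times the lane scale; negative controls are
#' Poisson(`background_mean`). Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [raw_count_set()]) and `truth`
#'   (group labels, per-gene true fold map per contrast, per-lane true scale
#'   factors, per-gene baseline means).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ann <- config$panel
  endo <- probes_of_class(ann, "Endogenous")
  hk <- probes_of_class(ann, "Housekeeping")
  pos <- probes_of_class(ann, "Positive")
  neg <- probes_of_class(ann, "Negative")
  groups <- sim_groups(config)
  ids <- sim_sample_ids(config)
  n <- length(ids)

  baseline <- exp(stats::runif(length(endo), log(50), log(5000)))
  names(baseline) <- endo
  hk_baseline <- exp(stats::runif(length(hk), log(200), log(2000)))
  names(hk_baseline) <- hk
  lane_scale <- exp(stats::rnorm(n, 0, config$lane_scale_sd))
  names(lane_scale) <- ids

  fold <- matrix(1, length(endo), nlevels(groups),
                 dimnames = list(endo, levels(groups)))
  if (length(config$eoe_effect)) {
    g <- names(config$eoe_effect)
    fold[g, "EoE_no_FI"] <- fold[g, "EoE_no_FI"] * config$eoe_effect
    fold[g, "EoE_FI"] <- fold[g, "EoE_FI"] * config$eoe_effect
  }
  if (length(config$fi_effect)) {
    g <- names(config$fi_effect)
    fold[g, "EoE_FI"] <- fold[g, "EoE_FI"] * config$fi_effect
  }

  counts <- matrix(0L, nrow(ann), n, dimnames = list(ann$probe, ids))
  for (j in seq_len(n)) {
    mu_endo <- config$baseline_mean * baseline * fold[, as.character(groups[j])] *
      lane_scale[j] + config$background_mean
    counts[endo, j] <- stats::rnbinom(length(endo), mu = mu_endo,
                                      size = config$dispersion)
    mu_hk <- hk_baseline * lane_scale[j] + config$background_mean
    counts[hk, j] <- stats::rnbinom(length(hk), mu = mu_hk,
                                    size = config$dispersion)
    conc <- ann$concentration[match(pos, ann$probe)]
    counts[pos, j] <- stats::rpois(length(pos),
                                   config$pos_counts_per_fM * conc * lane_scale[j])
    counts[neg, j] <- stats::rpois(length(neg), config$background_mean)
  }

  truth <- list(
    group = stats::setNames(as.character(groups), ids),
    fold = list(eoe_vs_control = config$eoe_effect,
                fi_vs_nofi = config$fi_effect),
    lane_scale = lane_scale,
    gene_baseline = baseline
  )
  list(counts = raw_count_set(counts, ann,
                              lane_attributes = lapply(ids, function(i)
                                list(ID = i))),
       truth = truth)
}

#' Default symptom and comorbidity prevalences
#'
#' Per-group prevalences of the binary clinical fields, set to the observed
#' cohort fractions (e.g. dysphagia 14/14 in `EoE_FI`, 9/13 in `EoE_no_FI`,
#' 5/18 in controls). RAST/skin-prick testing is emulated as assessed in only
#' 5 of 18 controls (the reduced denominator seen in real chart review);
#' untested samples are missing, not negative.
#'
#' @return A named list `group -> named vector symptom -> probability`.
#' @export
default_prevalences <- function() {
  tbl <- rbind(
    dysphagia           = c(14 / 14, 9 / 13, 5 / 18),
    food_impaction      = c(1, 0, 0),
    chest_pain          = c(3 / 14, 0, 2 / 18),
    epigastric_pain     = c(4 / 14, 6 / 13, 9 / 18),
    reflux              = c(4 / 14, 6 / 13, 11 / 18),
    feeding_difficulties = c(0, 0, 0),
    vomiting            = c(2 / 14, 4 / 13, 2 / 18),
    pallor              = c(3 / 14, 1 / 13, 1 / 18),
    edema               = c(1 / 14, 0, 0),
    loss_of_vascularity = c(7 / 14, 2 / 13, 0),
    furrowing           = c(11 / 14, 9 / 13, 3 / 18),
    exudate             = c(6 / 14, 5 / 13, 0),
    eczema              = c(5 / 14, 3 / 13, 1 / 18),
    asthma              = c(8 / 14, 5 / 13, 1 / 18),
    rhinoconjunctivitis = c(7 / 14, 9 / 13, 4 / 18),
    food_allergy        = c(4 / 14, 3 / 13, 0),
    rast_positive       = c(11 / 14, 8 / 13, 0)
  )
  colnames(tbl) <- c("EoE_FI", "EoE_no_FI", "Control")
  lapply(as.data.frame(tbl), function(col) stats::setNames(col, rownames(tbl)))
}

#' Simulate a clinical metadata table
#'
#' One row per simulated sample, in the same order and with the same group
#' labels as [simulate_counts()] under the same config. Binary fields are
#' drawn independently per stated prevalence ("yes"/"no", with `NA` for
#' not-assessed); numeric fields (age, serum IgE, eosinophil counts) are
#' drawn from group-typical distributions (controls have zero esophageal
#' eosinophilia; EoE groups have comparable eosinophil counts — by design,
#' since tissue eosinophilia does not separate the FI subgroup).
#'
#' @param config A [sim_config()].
#' @param prevalences `group -> symptom -> probability in [0,1]` (default
#'   [default_prevalences()]). Unknown group keys are an error.
#' @return A validated `clinical_table` data.frame.
#' @export
simulate_metadata <- function(config, prevalences = default_prevalences()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  unknown <- setdiff(names(prevalences), GROUP_LEVELS)
  if (length(unknown))
    stop("configuration error: unknown group key(s): ",
         paste(unknown, collapse = ", "))
  for (g in names(prevalences)) {
    p <- prevalences[[g]]
    if (any(p < 0 | p > 1))
      stop("configuration error: prevalences must be in [0,1]")
  }
  # separate stream from the count draws, still reproducible from one config
  set.seed(config$seed + 1L)
  groups <- as.character(sim_groups(config))
  ids <- sim_sample_ids(config)
  n <- length(ids)

  symptoms <- unique(unlist(lapply(prevalences, names)))
  meta <- data.frame(sample_id = ids, group = groups,
                     stringsAsFactors = FALSE)
  for (s in symptoms) {
    p <- vapply(groups, function(g) {
      pv <- prevalences[[g]]
      if (is.null(pv) || !s %in% names(pv)) NA_real_ else unname(pv[s])
    }, numeric(1))
    draw <- ifelse(is.na(p), NA,
                   ifelse(stats::runif(n) < p, "yes", "no"))
    meta[[s]] <- draw
  }
  # controls mostly untested for food-antigen sensitization
  if ("rast_positive" %in% names(meta)) {
    ctrl <- which(groups == "Control")
    if (length(ctrl) > 5) {
      untested <- sample(ctrl, length(ctrl) - 5L)
      meta$rast_positive[untested] <- NA
    }
  }

  age_rng <- list(EoE_FI = c(10.7, 17.6), EoE_no_FI = c(9.1, 15.7),
                  Control = c(10.6, 18.0))
  ige_med <- c(EoE_FI = 214, EoE_no_FI = 100.5, Control = 98)
  ige_sdlog <- c(EoE_FI = 0.6, EoE_no_FI = 1.1, Control = 0.35)
  meta$age_years <- round(vapply(groups, function(g)
    stats::runif(1, age_rng[[g]][1], age_rng[[g]][2]), numeric(1)), 2)
  meta$serum_ige <- round(vapply(groups, function(g)
    stats::rlnorm(1, log(ige_med[g]), ige_sdlog[g]), numeric(1)), 1)
  eos <- function(med) round(med * stats::rlnorm(1, 0, 0.5))
  meta$eos_proximal <- vapply(groups, function(g)
    if (g == "Control") 0 else eos(25), numeric(1))
  meta$eos_distal <- vapply(groups, function(g)
    if (g == "Control") 0 else eos(if (g == "EoE_FI") 50 else 70), numeric(1))
  meta$eos_max <- pmax(meta$eos_proximal, meta$eos_distal)
  rownames(meta) <- NULL
  validate_clinical_table(meta)
  meta
}
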