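# Synthetic cohort generator: ground truth, probe-level expression matrices
# and qPCR Ct tables with the statistical structure the downstream screen and
# caller assume, so every stage runs without external downloads.

CORE_TARGETS <- c("sweyjawbu", "alk5p", "alk3p", "hprt1", "esd")
## Targets whose template is produced by the fusion-bearing cells only, so
## their abundance mixes with tumor-cell fraction.  ALK 5' and the reference
## genes are expressed by all cells and ignore the fraction.
FUSION_TARGETS <- c("sweyjawbu", "alk3p")

#' Catalogue of ALK fusion-variant identifiers
#'
#' Twenty-seven hybrid subtypes across the eight fusion partners seen in
#' NSCLC (EML4, KIF5B, STRN, KLC1, TFG, CUX1, TPR, HIP1).  EML4-ALK, by far
#' the most common, contributes twenty breakpoint variants; the remaining
#' partners one each.  Identifiers are synthetic labels, not junction
#' sequences.
#'
#' @return character vector of 27 variant ids.
#' @export
alk_variant_catalogue <- function() {
  c(sprintf("EML4-ALK_v%02d", 1:20),
    "KIF5B-ALK", "STRN-ALK", "KLC1-ALK", "TFG-ALK",
    "CUX1-ALK", "TPR-ALK", "HIP1-ALK")
}

#' Default fusion-subtype primer panel
#'
#' Seventeen primer pairs covering the 27 catalogue variants: ten EML4 pairs,
#' each amplifying a junction shared by two adjacent EML4 breakpoint
#' variants, plus one pair per other partner.  Expected melt temperatures
#' are spread over 78-91 degrees C so pairs are distinguishable by melt
#' analysis.
#'
#' @return an `alk_panel` data frame with columns `pair_id`, `variants`
#'   (semicolon-separated variant ids) and `expected_tm`.
#' @export
default_panel <- function() {
  cat <- alk_variant_catalogue()
  eml4 <- cat[1:20]
  pairs <- data.frame(
    pair_id = c(sprintf("EML4_P%02d", 1:10),
                c("KIF5B_P1", "STRN_P1", "KLC1_P1", "TFG_P1",
                  "CUX1_P1", "TPR_P1", "HIP1_P1")),
    variants = c(vapply(1:10, function(k)
      paste(eml4[c(2 * k - 1, 2 * k)], collapse = ";"), character(1)),
      cat[21:27]),
    expected_tm = 78 + 0.8 * (0:16),
    stringsAsFactors = FALSE
  )
  validate_panel(pairs)
}

validate_panel <- function(pairs, variant_catalogue = NULL) {
  need <- c("pair_id", "variants", "expected_tm")
  if (!all(need %in% names(pairs)))
    stop_validation("panel must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(pairs$pair_id))
    stop_validation("duplicate pair_id in panel")
  tm <- pairs$expected_tm
  if (!is.numeric(tm) || any(!is.finite(tm)) || any(tm <= 70 | tm >= 95))
    stop_validation("expected_tm must lie strictly inside (70, 95) degrees C")
  covered <- unique(unlist(strsplit(pairs$variants, ";", fixed = TRUE)))
  if (any(!nzchar(covered)))
    stop_validation("empty variant id in panel")
  if (!is.null(variant_catalogue)) {
    missing <- setdiff(variant_catalogue, covered)
    if (length(missing))
      stop_validation("panel covers no primer pair for variant(s): %s",
                      paste(missing, collapse = ", "))
  }
  class(pairs) <- c("alk_panel", "data.frame")
  pairs
}

panel_variants <- function(panel) {
  strsplit(panel$variants, ";", fixed = TRUE)
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic cohort.  The generative model is
#' log2-additive Gaussian for probe intensities and a mixture-abundance Ct
#' model for qPCR: for target t in sample i with tumor-cell fraction f,
#' abundance is `a = f * pos_t + (1 - f) * neg_t` when the target's template
#' is fusion-derived (marker, ALK 3', subtype amplicons) and `a = neg_t`
#' otherwise; then `Ct = ct_intercept - log(a) / log(efficiency) + noise`,
#' censored above `max_ct`.
#'
#' @param group_sizes named counts for the subgroups `alk`, `egfr`, `kras`,
#'   `tn` (triple negative), `normal`.  The default is a scaled-down cohort
#'   (16 ALK-positive / 40 negative) for fast iteration; the
#'   `"e_geod_31210"` preset uses the E-GEOD-31210 246-array composition
#'   (11 / 127 / 20 / 68 tumors plus 20 adjacent-normal profiles).
#' @param n_probesets number of probe sets on the simulated array (>= 2; the
#'   first two slots hold the marker and the ALK 3' probe-set analogues).
#' @param probes_per_set probes per probe set.
#' @param marker_effect_log2 log2 mean shift of the marker probe set
#'   (242964_at analogue) in ALK-positive samples; default log2(37.4).
#' @param alk_effect_log2 log2 shift of the ALK probe set (208212_s_at
#'   analogue); default log2(29.8).
#' @param baseline_mean,baseline_sd distribution of per-probe-set baseline
#'   log2 intensity.
#' @param probe_offset_sd SD of per-probe additive affinity offsets (these
#'   are what median polish must remove).
#' @param noise_sd_log2 per-observation Gaussian noise SD on the log2 scale.
#' @param ct_intercept cycles at unit abundance, shared across targets.
#' @param ct_noise_sd Gaussian Ct noise, cycles.
#' @param amplification_efficiency per-cycle amplification factor in (1, 2].
#' @param tumor_fraction_range interval in \[0, 1\] from which tumor-cell
#'   fractions are drawn uniformly.
#' @param max_ct censoring limit in cycles (the assay runs 40 cycles).
#' @param tm_jitter_sd SD of melt-temperature jitter, degrees C.
#' @param abundance named list of `c(pos =, neg =)` template abundances per
#'   core target plus `amplicon` for panel targets.
#' @param variant_catalogue fusion-variant ids assigned to positives.
#' @param seed master seed; every operation derives its own sub-stream.
#' @param preset `"small"` (default) or `"e_geod_31210"`.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(group_sizes = NULL,
                       n_probesets = 500L,
                       probes_per_set = 4L,
                       marker_effect_log2 = log2(37.4),
                       alk_effect_log2 = log2(29.8),
                       baseline_mean = 8,
                       baseline_sd = 2,
                       probe_offset_sd = 1,
                       noise_sd_log2 = 0.8,
                       ct_intercept = 38,
                       ct_noise_sd = 0.5,
                       amplification_efficiency = 2,
                       tumor_fraction_range = c(0.2, 0.9),
                       max_ct = 40,
                       tm_jitter_sd = 0.1,
                       abundance = NULL,
                       variant_catalogue = alk_variant_catalogue(),
                       seed = 1L,
                       preset = c("small", "e_geod_31210")) {
  preset <- match.arg(preset)
  if (is.null(group_sizes)) {
    group_sizes <- switch(preset,
      small = c(alk = 16L, egfr = 12L, kras = 8L, tn = 12L, normal = 8L),
      e_geod_31210 = c(alk = 11L, egfr = 127L, kras = 20L, tn = 68L,
                       normal = 20L))
  }
  if (is.null(abundance)) {
    abundance <- list(
      sweyjawbu = c(pos = 200, neg = 1),
      alk3p     = c(pos = 150, neg = 2),
      alk5p     = c(pos = 2,   neg = 2),
      hprt1     = c(pos = 50,  neg = 50),
      esd       = c(pos = 50,  neg = 50),
      amplicon  = c(pos = 2000, neg = 0))
  }
  cfg <- list(group_sizes = group_sizes, n_probesets = as.integer(n_probesets),
              probes_per_set = as.integer(probes_per_set),
              marker_effect_log2 = marker_effect_log2,
              alk_effect_log2 = alk_effect_log2,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              probe_offset_sd = probe_offset_sd,
              noise_sd_log2 = noise_sd_log2,
              ct_intercept = ct_intercept, ct_noise_sd = ct_noise_sd,
              amplification_efficiency = amplification_efficiency,
              tumor_fraction_range = tumor_fraction_range,
              max_ct = max_ct, tm_jitter_sd = tm_jitter_sd,
              abundance = abundance,
              variant_catalogue = variant_catalogue,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  gs <- cfg$group_sizes
  need <- c("alk", "egfr", "kras", "tn", "normal")
  if (!all(need %in% names(gs)))
    stop_validation("group_sizes must name groups %s", paste(need, collapse = ", "))
  if (any(gs < 0) || any(gs != round(gs)))
    stop_validation("group sizes must be nonnegative counts")
  if (cfg$noise_sd_log2 < 0 || cfg$ct_noise_sd < 0 || cfg$tm_jitter_sd < 0)
    stop_validation("noise standard deviations must be >= 0")
  eff <- cfg$amplification_efficiency
  if (!is.finite(eff) || eff <= 1 || eff > 2)
    stop_validation("amplification_efficiency must lie in (1, 2]")
  tfr <- cfg$tumor_fraction_range
  if (length(tfr) != 2L || any(tfr < 0) || any(tfr > 1) || tfr[1] > tfr[2])
    stop_validation("tumor_fraction_range must be an interval within [0, 1]")
  if (cfg$max_ct <= 0)
    stop_validation("max_ct must be positive")
  for (ab in cfg$abundance)
    if (any(!is.finite(ab)) || any(ab < 0))
      stop_validation("abundance parameters must be finite and nonnegative")
  class(cfg) <- "sim_config"
  cfg
}

#' Assign ground-truth status, variant and tumor fraction to a cohort
#'
#' Builds one `TruthRecord` per sample: the ALK group is rearrangement
#' positive with a fusion variant drawn uniformly from the catalogue; all
#' tumor samples get a tumor-cell fraction drawn uniformly from the
#' configured range (adjacent-normal profiles get fraction 0).
#'
#' @param config a [sim_config()].
#' @return data frame with columns `sample_id`, `group_label`, `true_status`,
#'   `variant_id` (NA for negatives) and `tumor_fraction`.
#' @export
assign_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gs <- config$group_sizes
  if (gs[["alk"]] > 0 && length(config$variant_catalogue) == 0L)
    stop_validation("variant_catalogue is empty but ALK-positive samples were requested")
  n <- sum(gs)
  group <- rep(names(gs), times = gs)
  truth <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group_label = group,
    true_status = ifelse(group == "alk", "positive", "negative"),
    stringsAsFactors = FALSE)
  with_seed(sub_seed(config$seed, 1L), {
    truth$variant_id <- NA_character_
    npos <- sum(truth$true_status == "positive")
    if (npos > 0)
      truth$variant_id[truth$true_status == "positive"] <-
        sample(config$variant_catalogue, npos, replace = TRUE)
    tfr <- config$tumor_fraction_range
    truth$tumor_fraction <- ifelse(
      truth$group_label == "normal", 0,
      stats::runif(n, tfr[1], tfr[2]))
  })
  truth
}

#' Simulate a probe-level expression matrix
#'
#' Log2 intensities are baseline (per probe set, right-skewed with the
#' configured mean and SD) + probe affinity offset + group effect + Gaussian
#' noise.  The first two probe sets are the marker
#' (`242964_at`) and ALK (`208212_s_at`) analogues, elevated by their
#' configured log2 effects in ALK-positive samples; all other probe sets are
#' exchangeable across groups.  Probe offsets make median-polish
#' summarization nontrivial.
#'
#' @param config a [sim_config()].
#' @param truth output of [assign_truth()].
#' @return a `probe_matrix`: list with `values` (probes x samples),
#'   `probeset` (named map probe -> probe set) and `labels` (named map
#'   sample -> group).
#' @export
simulate_probe_matrix <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) == 0L) stop_validation("truth must be nonempty")
  if (config$n_probesets < 2L)
    stop_validation("n_probesets must be >= 2 to place the marker probe sets")
  ps_ids <- c("242964_at", "208212_s_at",
              if (config$n_probesets > 2L)
                sprintf("ps_%04d", seq_len(config$n_probesets - 2L)))
  k <- config$probes_per_set
  probe_ids <- paste0(rep(ps_ids, each = k), "_p", rep(seq_len(k), times = length(ps_ids)))
  probeset <- stats::setNames(rep(ps_ids, each = k), probe_ids)
  n <- nrow(truth)
  pos <- truth$true_status == "positive"
  with_seed(sub_seed(config$seed, 2L), {
    ## right-skewed baseline (shifted exponential with the configured mean
    ## and SD): log2 array intensities have a long high tail, and that tail
    ## is what keeps quantile normalization from clipping probe sets that
    ## are strongly elevated in a minority of samples
    baseline <- config$baseline_mean - config$baseline_sd +
      stats::rexp(length(ps_ids)) * config$baseline_sd
    offsets <- stats::rnorm(length(probe_ids), 0, config$probe_offset_sd)
    effect <- matrix(0, nrow = length(ps_ids), ncol = n)
    effect[1, pos] <- config$marker_effect_log2
    effect[2, pos] <- config$alk_effect_log2
    values <- baseline[rep(seq_along(ps_ids), each = k)] + offsets +
      effect[rep(seq_along(ps_ids), each = k), , drop = FALSE] +
      matrix(stats::rnorm(length(probe_ids) * n, 0, config$noise_sd_log2),
             nrow = length(probe_ids))
  })
  dimnames(values) <- list(probe_ids, truth$sample_id)
  probe_matrix(values, probeset, stats::setNames(truth$group_label, truth$sample_id))
}

#' Construct a probe-level matrix object
#'
#' @param values numeric matrix of log2 intensities, probes x samples, with
#'   dimnames.
#' @param probeset named character map from probe id to probe-set id.
#' @param labels named character map from sample id to subgroup tag.
#' @export
probe_matrix <- function(values, probeset, labels) {
  if (!is.matrix(values) || any(!is.finite(values)))
    stop_validation("probe matrix values must be a finite numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("probe matrix needs probe and sample dimnames")
  if (!setequal(rownames(values), names(probeset)))
    stop_validation("every probe must map to exactly one probe set")
  if (!setequal(colnames(values), names(labels)))
    stop_validation("every sample must carry a group label")
  structure(list(values = values,
                 probeset = probeset[rownames(values)],
                 labels = labels[colnames(values)]),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes / %d probe sets x %d samples\n",
              nrow(x$values), length(unique(x$probeset)), ncol(x$values)))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$labels)),
                               table(x$labels)), collapse = " "), "\n")
  invisible(x)
}

#' Cycle threshold from template abundance
#'
#' `Ct = intercept - log(a) / log(efficiency)`; zero abundance never
#' amplifies (infinite Ct).
#'
#' @param abundance template abundance (arbitrary units, >= 0).
#' @param intercept cycles at unit abundance.
#' @param efficiency per-cycle amplification factor in (1, 2].
#' @export
ct_value <- function(abundance, intercept, efficiency = 2) {
  ifelse(abundance > 0, intercept - log(abundance) / log(efficiency), Inf)
}

#' Simulate a long-format qPCR Ct table
#'
#' Emits one row per sample x target for the marker, ALK 5'/3', the HPRT1 and
#' ESD reference genes, and every panel primer pair.  Fusion-derived targets
#' (marker, ALK 3', the amplicon of the pair covering the sample's variant)
#' mix positive-cell and background abundance by tumor fraction; Ct values
#' beyond `max_ct` (or from zero template) are censored and written as NA.
#' Melt temperatures are emitted only for amplified panel targets.
#'
#' @param config a [sim_config()].
#' @param truth output of [assign_truth()].
#' @param panel an `alk_panel`; must cover every variant present in `truth`.
#' @return a `ct_table` data frame (`sample_id`, `target_id`, `ct`, `tm`)
#'   with attribute `max_ct`.
#' @export
simulate_ct_table <- function(config, truth, panel = default_panel()) {
  stopifnot(inherits(config, "sim_config"))
  panel <- validate_panel(panel)
  used <- unique(stats::na.omit(truth$variant_id))
  covered <- unique(unlist(panel_variants(panel)))
  if (length(setdiff(used, covered)))
    stop_validation("panel does not cover variant(s): %s",
                    paste(setdiff(used, covered), collapse = ", "))
  targets <- c(CORE_TARGETS, panel$pair_id)
  pv <- panel_variants(panel)
  n <- nrow(truth)
  rows <- vector("list", n)
  with_seed(sub_seed(config$seed, 3L), {
    for (i in seq_len(n)) {
      pos <- truth$true_status[i] == "positive"
      f <- truth$tumor_fraction[i]
      ab <- vapply(targets, function(tg) {
        if (tg %in% CORE_TARGETS) {
          p <- config$abundance[[tg]]
          fe <- if (pos && tg %in% FUSION_TARGETS) f else 0
        } else {
          p <- config$abundance$amplicon
          covers <- pos && !is.na(truth$variant_id[i]) &&
            truth$variant_id[i] %in% pv[[match(tg, panel$pair_id)]]
          fe <- if (covers) f else 0
        }
        fe * p[["pos"]] + (1 - fe) * p[["neg"]]
      }, numeric(1))
      ct <- ct_value(ab, config$ct_intercept, config$amplification_efficiency) +
        stats::rnorm(length(ab), 0, config$ct_noise_sd)
      ct[!is.finite(ct) | ct > config$max_ct] <- NA_real_
      tm <- rep(NA_real_, length(ab))
      amp_panel <- !is.na(ct) & targets %in% panel$pair_id
      if (any(amp_panel)) {
        exp_tm <- panel$expected_tm[match(targets[amp_panel], panel$pair_id)]
        tm[amp_panel] <- exp_tm + stats::rnorm(sum(amp_panel), 0, config$tm_jitter_sd)
      }
      rows[[i]] <- data.frame(sample_id = truth$sample_id[i], target_id = targets,
                              ct = ct, tm = tm, stringsAsFactors = FALSE)
    }
  })
  ct_table(do.call(rbind, rows), max_ct = config$max_ct)
}

#' Construct a Ct table object
#'
#' @param df data frame with columns `sample_id`, `target_id`, `ct`
#'   (NA = censored / no amplification), `tm`.
#' @param max_ct censoring limit in cycles.
#' @export
ct_table <- function(df, max_ct = 40) {
  need <- c("sample_id", "target_id", "ct", "tm")
  if (!all(need %in% names(df)))
    stop_validation("ct table must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df[c("sample_id", "target_id")]))
    stop_validation("duplicate (sample_id, target_id) entry in ct table")
  ok <- is.na(df$ct) | (df$ct > 0 & df$ct <= max_ct)
  if (!all(ok))
    stop_validation("ct values must lie in (0, max_ct] or be censored (NA)")
  rownames(df) <- NULL
  structure(df, class = c("ct_table", "data.frame"), max_ct = max_ct)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [assign_truth()], [simulate_probe_matrix()]
#' and [simulate_ct_table()] under the single configured seed.
#'
#' @param config a [sim_config()].
#' @param panel fusion-subtype panel definition.
#' @return list with elements `truth`, `probes`, `ct`, `panel`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), panel = default_panel()) {
  truth <- assign_truth(config)
  list(truth = truth,
       probes = simulate_probe_matrix(config, truth),
       ct = simulate_ct_table(config, truth, panel),
       panel = panel,
       config = config)
}
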