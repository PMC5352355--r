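# End-to-end orchestration and the subcommand CLI.

#' Run the full screening-and-calling pipeline on a synthetic cohort
#'
#' Simulates a cohort, runs the microarray screen (quantile normalization,
#' median-polish summarization, SAM, fold change), trains the three-level
#' caller on the cohort's labelled Ct table, calls every sample with subtype
#' evidence, simulates the FISH and IHC reference assays, and evaluates
#' concordance against FISH.  With `out_dir` set, every stage's table is
#' written in its standard format.
#'
#' @param config a [sim_config()].
#' @param panel an `alk_panel`.
#' @param n_perm SAM permutations.
#' @param fdr FDR threshold used when reporting significant probe sets.
#' @param ct_detect,tm_tol subtype detection thresholds.
#' @param out_dir optional output directory.
#' @return list with `truth`, `probes`, `expr`, `de` (a `sam_fit`), `fit`
#'   (an `alk_caller`), `calls`, `fish`, `ihc`, `conc`.
#' @export
run_pipeline <- function(config = sim_config(), panel = default_panel(),
                         n_perm = 1000L, fdr = 0.05,
                         ct_detect = 35, tm_tol = 0.5, out_dir = NULL) {
  cohort <- simulate_cohort(config, panel)
  norm <- cohort$probes
  norm$values <- quantile_normalize(norm$values)
  expr <- median_polish_summarize(norm)
  de <- sam(expr, positive_label = "alk", n_perm = n_perm,
            seed = sub_seed(config$seed, 10L))
  status <- stats::setNames(cohort$truth$true_status, cohort$truth$sample_id)
  fit <- alk_caller(cohort$ct, status, max_ct = config$max_ct)
  calls <- predict(fit, ct = cohort$ct, panel = panel,
                   ct_detect = ct_detect, tm_tol = tm_tol)
  fish <- simulate_fish(cohort$truth, seed = sub_seed(config$seed, 4L))
  ihc <- simulate_ihc(cohort$truth, seed = sub_seed(config$seed, 5L))
  conc <- concordance(calls, fish)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_truth(cohort$truth, file.path(out_dir, "truth.csv"))
    write_probe_matrix(cohort$probes, file.path(out_dir, "probes.tsv"))
    write_ct_table(cohort$ct, file.path(out_dir, "ct.csv"))
    write_panel(panel, file.path(out_dir, "panel.tsv"))
    write_de_results(de, file.path(out_dir, "de.tsv"))
    write_calls(calls, file.path(out_dir, "calls.json"))
    utils::write.csv(fish, file.path(out_dir, "fish.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(ihc, file.path(out_dir, "ihc.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(unclass(conc), file.path(out_dir, "concordance.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  list(truth = cohort$truth, probes = cohort$probes, ct = cohort$ct,
       expr = expr, de = de, fit = fit, calls = calls, fish = fish,
       ihc = ihc, conc = conc, fdr = fdr)
}

#' Write SAM differential-expression results as TSV
#'
#' @param de a `sam_fit`.
#' @param path file path.
#' @export
write_de_results <- function(de, path) {
  utils::write.table(
    de$results[c("probeset_id", "d_stat", "fold_change_linear", "q_value", "rank")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cli_opts <- function(args) {
  opts <- list(); pos <- character(0); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args) || startsWith(args[i + 1L], "--"))
        stop_validation("flag %s needs a value", a)
      opts[[substring(a, 3L)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

cli_log <- function(stage, config_path, seed, ...) {
  digest <- if (!is.null(config_path) && file.exists(config_path))
    unname(tools::md5sum(config_path)) else "defaults"
  message(sprintf("alkscreen %s | %s | seed=%s | config=%s%s",
                  as.character(utils::packageVersion("alkscreen")), stage,
                  seed, digest,
                  paste0(vapply(list(...), function(kv)
                    sprintf(" | %s", kv), character(1)), collapse = "")))
}

#' Subcommand command-line interface
#'
#' Drives the pipeline from file to file.  Subcommands:
#' \describe{
#'   \item{simulate}{`--out DIR [--config cfg.yaml] [--seed S]` — write
#'     truth/probes/ct/panel for a synthetic cohort.}
#'   \item{discover}{`--probes m.tsv --labels truth.csv --out de.tsv
#'     [--n-perm N] [--fdr F] [--seed S] [--probe-fasta p.fa --transcripts
#'     t.fa --hits hits.tsv]` — screen for markers; optionally match probe
#'     sequences to transcripts.}
#'   \item{call}{`--ct ct.csv --truth truth.csv --out calls.json
#'     [--panel panel.tsv] [--ct-detect C] [--tm-tol T]` — train cutoffs on
#'     the labelled table and call every sample (also writes a flat CSV
#'     next to the JSON).}
#'   \item{evaluate}{`--calls calls.json --truth truth.csv --out conc.json
#'     [--fish fish.csv] [--seed S]` — concordance against FISH (simulated
#'     from truth unless a FISH table is supplied).}
#'   \item{report}{`--calls calls.json --out report.txt` — human-readable
#'     summary.}
#' }
#' Every run logs the package version, the config digest and the seed.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, 0 on success (invisibly).
#' @export
alkscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop_validation("usage: alkscreen <simulate|discover|call|evaluate|report> [flags]")
    sub <- args[1L]
    parsed <- cli_opts(args[-1L])
    o <- parsed$opts
    need <- function(flag) {
      if (is.null(o[[flag]])) stop_validation("%s: --%s is required", sub, flag)
      o[[flag]]
    }
    switch(sub,
      simulate = {
        seed <- as.integer(o$seed %||% 1L)
        cfg <- read_run_config(o$config)
        if (!is.null(o$seed)) cfg$sim$seed <- seed
        out <- need("out")
        cohort <- simulate_cohort(cfg$sim)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_truth(cohort$truth, file.path(out, "truth.csv"))
        write_probe_matrix(cohort$probes, file.path(out, "probes.tsv"))
        write_ct_table(cohort$ct, file.path(out, "ct.csv"))
        write_panel(cohort$panel, file.path(out, "panel.tsv"))
        cli_log("simulate", o$config, cfg$sim$seed,
                sprintf("samples=%d", nrow(cohort$truth)),
                sprintf("probes=%d", nrow(cohort$probes$values)))
      },
      discover = {
        seed <- as.integer(o$seed %||% 1L)
        pm <- read_probe_matrix(need("probes"), read_truth(need("labels")))
        pm$values <- quantile_normalize(pm$values)
        expr <- median_polish_summarize(pm)
        de <- sam(expr, positive_label = "alk",
                  n_perm = as.integer(o[["n-perm"]] %||% 1000L), seed = seed)
        write_de_results(de, need("out"))
        nsig <- sum(de$results$q_value < as.numeric(o$fdr %||% 0.05))
        if (!is.null(o[["probe-fasta"]])) {
          probes <- read_fasta(o[["probe-fasta"]])
          tx <- read_fasta(need("transcripts"))
          hits <- match_probes(stats::setNames(as.character(probes), names(probes)),
                               tx, max_mismatch = as.integer(o[["max-mismatch"]] %||% 1L))
          write_probe_hits(hits, need("hits"))
        }
        cli_log("discover", NULL, seed,
                sprintf("probesets=%d", nrow(de$results)),
                sprintf("q<fdr=%d", nsig))
      },
      call = {
        max_ct <- as.numeric(o[["max-ct"]] %||% 40)
        ct <- read_ct_table(need("ct"), max_ct = max_ct)
        truth <- read_truth(need("truth"))
        fit <- alk_caller(ct, stats::setNames(truth$true_status, truth$sample_id),
                          max_ct = max_ct)
        panel <- if (!is.null(o$panel)) read_panel(o$panel)
        calls <- predict(fit, ct = ct, panel = panel,
                         ct_detect = as.numeric(o[["ct-detect"]] %||% 35),
                         tm_tol = as.numeric(o[["tm-tol"]] %||% 0.5))
        out <- need("out")
        write_calls(calls, out)
        utils::write.csv(as.data.frame(calls),
                         sub("\\.json$", ".csv", out),
                         row.names = FALSE, quote = FALSE)
        cli_log("call", NULL, "-", sprintf("samples=%d", nrow(calls)),
                sprintf("positive=%d", sum(calls$status == "positive")))
      },
      evaluate = {
        seed <- as.integer(o$seed %||% 1L)
        calls <- read_calls(need("calls"))
        truth <- read_truth(need("truth"))
        fish <- if (!is.null(o$fish))
          utils::read.csv(o$fish, stringsAsFactors = FALSE)
        else simulate_fish(truth, seed = seed)
        conc <- concordance(calls, fish)
        jsonlite::write_json(unclass(conc), need("out"), auto_unbox = TRUE,
                             digits = 10, pretty = TRUE)
        cli_log("evaluate", NULL, seed,
                sprintf("samples=%d", nrow(calls)),
                sprintf("discordant=%d", length(conc$discordant_ids)))
      },
      report = {
        calls <- read_calls(need("calls"))
        out <- need("out")
        lines <- c(
          sprintf("alkscreen call report (%d samples)", nrow(calls)),
          sprintf("positive: %d | negative: %d | indeterminate: %d",
                  sum(calls$status == "positive"),
                  sum(calls$status == "negative"),
                  sum(calls$status == "indeterminate")),
          sprintf("cutoffs: marker %.3f | imbalance %.3f | combined %.3f (cycles)",
                  attr(calls, "cutoffs")[["marker"]],
                  attr(calls, "cutoffs")[["imbalance"]],
                  attr(calls, "cutoffs")[["combined"]]),
          if (any(calls$discordant))
            sprintf("subtype+/score- discordant: %s",
                    paste(calls$sample_id[calls$discordant], collapse = ", "))
          else "no subtype/score discordance")
        writeLines(lines, out)
        cli_log("report", NULL, "-", sprintf("samples=%d", nrow(calls)))
      },
      stop_validation("unknown subcommand '%s'", sub))
    0L
  }, alkscreen_validation_error = function(e) {
    message("alkscreen: ", conditionMessage(e))
    1L
  }, error = function(e) {
    message("alkscreen: internal error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
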