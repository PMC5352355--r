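# Readers and writers for the pipeline's plain-text formats: probe matrices
# (TSV), long-format Ct tables (CSV, censored Ct written as the token NA),
# truth records (CSV), panel definitions (TSV), call reports (JSON), probe
# hits (BED-like TSV) and run configuration (YAML).

read_table_checked <- function(path, sep, required) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_validation("%s: missing column(s): %s", path,
                    paste(missing, collapse = ", "))
  df
}

## Convert a character column to numeric with a line-numbered message on
## failure; the literal token NA denotes a censored / absent value.
numeric_column <- function(df, col, path) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !is.na(raw) & raw != "NA" & raw != "")
  if (length(bad))
    stop_validation("%s:%d: column '%s': non-numeric value '%s'",
                    path, bad[1] + 1L, col, raw[bad[1]])
  val[raw == ""] <- NA_real_
  val
}

#' Write / read a probe-level matrix as TSV
#'
#' Rows are probes; the first two columns are `probe_id` and `probeset_id`,
#' the remaining columns one per sample.  Group labels travel in the truth
#' CSV, so `read_probe_matrix()` takes them separately (a named vector or a
#' truth data frame).
#'
#' @param pm a [probe_matrix()].
#' @param path file path.
#' @export
write_probe_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "probe_matrix"))
  df <- data.frame(probe_id = rownames(pm$values),
                   probeset_id = unname(pm$probeset[rownames(pm$values)]),
                   pm$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_matrix
#' @param labels named character map sample -> group, or a truth data frame
#'   with `sample_id` and `group_label`.
#' @export
read_probe_matrix <- function(path, labels) {
  df <- read_table_checked(path, "\t", c("probe_id", "probeset_id"))
  if (anyDuplicated(df$probe_id))
    stop_validation("%s: duplicate probe_id '%s'", path,
                    df$probe_id[anyDuplicated(df$probe_id)])
  samples <- setdiff(names(df), c("probe_id", "probeset_id"))
  if (length(samples) == 0L) stop_validation("%s: no sample columns", path)
  values <- vapply(samples, function(cn) numeric_column(df, cn, path),
                   numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(df$probe_id, samples))
  if (any(is.na(values))) stop_validation("%s: missing intensity values", path)
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$group_label, labels$sample_id)
  probe_matrix(values, stats::setNames(df$probeset_id, df$probe_id), labels)
}

#' Write / read a long-format Ct table as CSV
#'
#' Columns `sample_id`, `target_id`, `ct`, `tm`; a censored (no
#' amplification) Ct is written as the literal token `NA`, never a number.
#'
#' @param ct a [ct_table()].
#' @param path file path.
#' @export
write_ct_table <- function(ct, path) {
  stopifnot(inherits(ct, "ct_table"))
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @param max_ct censoring limit recorded on the object.
#' @export
read_ct_table <- function(path, max_ct = 40) {
  df <- read_table_checked(path, ",", c("sample_id", "target_id", "ct", "tm"))
  ct_table(data.frame(sample_id = df$sample_id, target_id = df$target_id,
                      ct = numeric_column(df, "ct", path),
                      tm = numeric_column(df, "tm", path),
                      stringsAsFactors = FALSE),
           max_ct = max_ct)
}

#' Write / read ground-truth records as CSV
#' @param truth data frame from [assign_truth()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read_table_checked(path, ",",
                           c("sample_id", "group_label", "true_status",
                             "variant_id", "tumor_fraction"))
  df$tumor_fraction <- numeric_column(df, "tumor_fraction", path)
  df$variant_id[df$variant_id == "NA" | df$variant_id == ""] <- NA_character_
  bad <- which(!df$true_status %in% c("positive", "negative"))
  if (length(bad))
    stop_validation("%s:%d: column 'true_status': invalid value '%s'",
                    path, bad[1] + 1L, df$true_status[bad[1]])
  if (any(df$tumor_fraction < 0 | df$tumor_fraction > 1, na.rm = TRUE))
    stop_validation("%s: tumor_fraction outside [0, 1]", path)
  df
}

#' Write / read a fusion-subtype panel definition as TSV
#'
#' Columns `pair_id`, `variants` (semicolon-separated variant ids) and
#' `expected_tm` (degrees C, inside (70, 95)).
#'
#' @param panel an `alk_panel`.
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param variant_catalogue optional variant universe; every catalogue
#'   variant must be covered by at least one pair.
#' @export
read_panel <- function(path, variant_catalogue = NULL) {
  df <- read_table_checked(path, "\t", c("pair_id", "variants", "expected_tm"))
  df$expected_tm <- numeric_column(df, "expected_tm", path)
  validate_panel(df, variant_catalogue)
}

#' Write / read ALK call reports as JSON
#'
#' One object per sample carrying every metric and flag, plus the cutoffs
#' used, under a top-level `cutoffs` / `calls` pair.
#'
#' @param calls an `alk_calls` data frame from [predict.alk_caller()].
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  obj <- list(cutoffs = as.list(attr(calls, "cutoffs")),
              calls = as.data.frame(calls))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calls <- obj$calls
  for (col in c("dct_marker", "dct_imbalance", "combined"))
    calls[[col]] <- as.numeric(calls[[col]])
  if (is.null(calls$variant_id)) calls$variant_id <- NA_character_
  structure(calls, class = c("alk_calls", "data.frame"),
            cutoffs = unlist(obj$cutoffs))
}

#' Write probe hits as a BED-like TSV
#'
#' Columns: transcript, 0-based start, half-open end, probe id, mismatch
#' count, strand.
#'
#' @param hits data frame from [match_probes()].
#' @param path file path.
#' @export
write_probe_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript or probe sequences from FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  Biostrings::readDNAStringSet(path)
}

#' Read a YAML run configuration
#'
#' Recognized blocks: `sim` (arguments of [sim_config()]), `sam` (`n_perm`,
#' `fdr`), `caller` (`ct_detect`, `tm_tol`, `max_ct`) and a top-level
#' `seed`.  Anything omitted falls back to the package defaults, which are
#' the screening constants: 1000 permutations, FDR threshold 0.05, a 40-cycle
#' Ct ceiling, subtype detection at Ct 35 within 0.5 degrees C of the
#' expected melt temperature.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return validated list with elements `sim`, `sam`, `caller`, `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  simargs <- raw$sim %||% list()
  simargs$seed <- simargs$seed %||% seed
  if (!is.null(simargs$group_sizes))
    simargs$group_sizes <- unlist(simargs$group_sizes)
  if (!is.null(simargs$abundance))
    simargs$abundance <- lapply(simargs$abundance, unlist)
  cfg <- list(
    sim = do.call(sim_config, simargs),
    sam = list(n_perm = raw$sam$n_perm %||% 1000L,
               fdr = raw$sam$fdr %||% 0.05),
    caller = list(ct_detect = raw$caller$ct_detect %||% 35,
                  tm_tol = raw$caller$tm_tol %||% 0.5,
                  max_ct = raw$caller$max_ct %||% 40),
    seed = as.integer(seed))
  if (cfg$sam$n_perm < 1 || cfg$sam$fdr <= 0 || cfg$sam$fdr >= 1)
    stop_validation("sam block: need n_perm >= 1 and fdr in (0, 1)")
  if (cfg$caller$ct_detect <= 0 || cfg$caller$ct_detect > cfg$caller$max_ct)
    stop_validation("caller block: need 0 < ct_detect <= max_ct")
  cfg
}
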