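## qPCR well tables, DNA-sample QC and replicate handling.
##
## Wells are plain data frames with one row per amplification reaction:
##   sample_id, primer_id, ct (numeric; NA = non-detect), ct_raw (as parsed,
##   including over-cutoff values kept for audit), nondetect (logical),
##   tm_peaks (list column of numeric melting-peak temperatures, degC),
##   replicate (integer), row (source row for error reporting).
##
## Ct values above the non-detect cutoff are treated as absence of template
## (primer cross-reactivity background), but the raw value is always retained.

#' Quality-control configuration for qPCR data
#'
#' Bundles the DNA-quality and amplification thresholds used throughout the
#' pipeline. Defaults are the study's working thresholds: samples need an
#' A260/A230 ratio above 0.6 and at least 30 ng/ul of DNA; Ct values above 35
#' cycles are treated as non-detects (the level at which the AluYb8 primers
#' show no cross-reactivity with zebrafish DNA); melting peaks within
#' `tm_tolerance` of `amplicon_tm` identify genuine amplicon, anything else
#' alone is a primer dimer.
#'
#' @param min_a260_230 minimum acceptable A260/A230 ratio (exclusive bound).
#' @param min_concentration minimum DNA concentration in ng/ul (inclusive).
#' @param ct_nondetect_cutoff Ct value (cycles) above which a reaction is
#'   scored as a non-detect.
#' @param amplicon_tm expected melting temperature of the specific amplicon
#'   (degC); `NA` disables melting-curve screening.
#' @param tm_tolerance half-width of the accepted melting-peak window (degC).
#' @return an object of class `qc_config` (a named list).
#' @examples
#' qc_config()
#' qc_config(amplicon_tm = 84)
#' @export
qc_config <- function(min_a260_230 = 0.6, min_concentration = 30,
                      ct_nondetect_cutoff = 35, amplicon_tm = NA_real_,
                      tm_tolerance = 1.5) {
  stopifnot(min_a260_230 > 0, min_concentration > 0, ct_nondetect_cutoff > 0,
            tm_tolerance > 0, tm_tolerance < 10)
  structure(list(min_a260_230 = min_a260_230,
                 min_concentration = min_concentration,
                 ct_nondetect_cutoff = ct_nondetect_cutoff,
                 amplicon_tm = amplicon_tm,
                 tm_tolerance = tm_tolerance),
            class = "qc_config")
}

# canonical primer tokens: ACHE_N (mutant-specific), ACHE_S (wild-type
# specific), ALU_YB8 (human Alu repeat); anything else passes through
# upper-cased so target/reference gene names survive.
normalize_primer_id <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", as.character(x)))
  out <- toupper(as.character(x))
  out[key %in% c("ACHEN", "N")] <- "ACHE_N"
  out[key %in% c("ACHES", "S")] <- "ACHE_S"
  out[key %in% c("ALUYB8", "ALU", "ALUYB")] <- "ALU_YB8"
  out
}

# sentinels a thermocycler export may use for "no Cq called"
.nondetect_tokens <- c("", "undetermined", "undet", "na", "nd", "non_detect",
                       "nondetect", "no ct", "-")

parse_ct <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  sentinel <- is.na(x) | tolower(x) %in% .nondetect_tokens
  num <- suppressWarnings(as.numeric(x[!sentinel]))
  bad <- which(!sentinel)[is.na(num)]
  if (length(bad)) {
    stop(sprintf("unparseable Ct value '%s' at row %d", x[bad[1]], bad[1]),
         call. = FALSE)
  }
  out[!sentinel] <- num
  out
}

parse_tm_peaks <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
    as.numeric(strsplit(trimws(s), ";", fixed = TRUE)[[1]])
  })
}

# apply the non-detect convention to parsed Ct values
apply_nondetect <- function(ct_raw, cutoff) {
  if (any(ct_raw < 0, na.rm = TRUE)) {
    stop("negative Ct values are not valid", call. = FALSE)
  }
  nondetect <- is.na(ct_raw) | ct_raw > cutoff
  list(ct = ifelse(nondetect, NA_real_, ct_raw), nondetect = nondetect)
}

#' Read a qPCR well table from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row. Mandatory columns
#' (renameable through `schema`) are `sample_id`, `primer_id` and `ct`;
#' optional columns are `tm_peaks` (semicolon-joined melting-peak
#' temperatures) and `replicate`. Empty or "Undetermined" Ct fields, and Ct
#' values above `cfg$ct_nondetect_cutoff`, become non-detects; the raw parsed
#' value is kept in `ct_raw` for audit.
#'
#' @param path path to the CSV file.
#' @param cfg a [qc_config()].
#' @param schema optional named list mapping canonical column names
#'   (`sample_id`, `primer_id`, `ct`, `tm_peaks`, `replicate`) to the file's
#'   column names.
#' @return a wells data frame (see package details) with one row per well.
#' @export
read_well_table <- function(path, cfg = qc_config(), schema = NULL) {
  sch <- list(sample_id = "sample_id", primer_id = "primer_id", ct = "ct",
              tm_peaks = "tm_peaks", replicate = "replicate")
  sch[names(schema)] <- schema
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  for (col in c("sample_id", "primer_id", "ct")) {
    if (!sch[[col]] %in% names(raw)) {
      stop(sprintf("missing mandatory column '%s'", sch[[col]]), call. = FALSE)
    }
  }
  ct_raw <- parse_ct(raw[[sch$ct]])
  nd <- apply_nondetect(ct_raw, cfg$ct_nondetect_cutoff)
  tm <- if (sch$tm_peaks %in% names(raw)) parse_tm_peaks(raw[[sch$tm_peaks]])
        else rep(list(numeric(0)), nrow(raw))
  sample_id <- as.character(raw[[sch$sample_id]])
  primer_id <- normalize_primer_id(raw[[sch$primer_id]])
  repl <- if (sch$replicate %in% names(raw)) {
    as.integer(raw[[sch$replicate]])
  } else {
    # number replicates within each (sample, primer) group in file order
    as.integer(stats::ave(seq_len(nrow(raw)),
                          paste(sample_id, primer_id, sep = "\r"),
                          FUN = seq_along))
  }
  out <- data.frame(row = seq_len(nrow(raw)),
                    sample_id = sample_id,
                    primer_id = primer_id,
                    ct = nd$ct, ct_raw = ct_raw, nondetect = nd$nondetect,
                    replicate = repl,
                    stringsAsFactors = FALSE)
  out$tm_peaks <- tm
  out
}

#' Write a qPCR well table to CSV
#'
#' Inverse of [read_well_table()]: numeric Ct values (including retained
#' over-cutoff raw values) are written as numbers, true non-detects as
#' `Undetermined`, and melting peaks as a semicolon-joined list.
#'
#' @param wells a wells data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(wells, path) {
  ct_out <- ifelse(!is.na(wells$ct_raw), format(wells$ct_raw, trim = TRUE),
                   "Undetermined")
  tm_out <- vapply(wells$tm_peaks, function(p) paste(p, collapse = ";"), "")
  df <- data.frame(sample_id = wells$sample_id, primer_id = wells$primer_id,
                   ct = ct_out, tm_peaks = tm_out,
                   replicate = wells$replicate, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DNA sample table from CSV
#'
#' Columns: `sample_id`, `concentration_ng_ul`, `a260_280`, `a260_230`, and
#' optionally `cell_line` and `experiment_set`.
#'
#' @param path path to the CSV file.
#' @return a data frame of DNA samples.
#' @export
read_sample_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("sample_id", "concentration_ng_ul", "a260_280", "a260_230")) {
    if (!col %in% names(raw)) {
      stop(sprintf("missing mandatory column '%s'", col), call. = FALSE)
    }
  }
  raw
}

#' DNA-quality filter for extracted samples
#'
#' A sample fails when its A260/A230 ratio is at or below
#' `cfg$min_a260_230` or its concentration is below `cfg$min_concentration`.
#' The A260/A280 ratio is recorded and reported but is not part of the hard
#' filter. Every violated criterion is listed; a missing measurement fails
#' with criterion `"missing_measurement"`.
#'
#' @param samples data frame with at least `concentration_ng_ul` and
#'   `a260_230` columns (one row per DNA sample).
#' @param cfg a [qc_config()].
#' @return `samples` with added logical `pass` and list column `violations`.
#' @examples
#' s <- data.frame(sample_id = c("a", "b", "c"),
#'                 concentration_ng_ul = c(45, 45, 29),
#'                 a260_230 = c(1.1, 0.5, 1.1))
#' qc_filter_sample(s)$pass
#' @export
qc_filter_sample <- function(samples, cfg = qc_config()) {
  stopifnot(is.data.frame(samples),
            all(c("concentration_ng_ul", "a260_230") %in% names(samples)))
  conc <- samples$concentration_ng_ul
  a23 <- samples$a260_230
  violations <- lapply(seq_len(nrow(samples)), function(i) {
    v <- character(0)
    if (is.na(conc[i]) || is.na(a23[i])) v <- c(v, "missing_measurement")
    if (!is.na(a23[i]) && a23[i] <= cfg$min_a260_230) v <- c(v, "a260_230")
    if (!is.na(conc[i]) && conc[i] < cfg$min_concentration) {
      v <- c(v, "concentration")
    }
    v
  })
  samples$pass <- lengths(violations) == 0L
  samples$violations <- violations
  samples
}

#' Classify individual qPCR wells as usable, dimer-only or non-detect
#'
#' Wells with a non-detect Ct are `nondetect`. When melting-curve screening
#' is enabled (`cfg$amplicon_tm` set), wells whose melting peaks all fall
#' outside `amplicon_tm` +/- `tm_tolerance` contain only primer dimer and are
#' `dimer_only`; a dimer peak co-occurring with an in-window amplicon peak is
#' allowed (two peaks in the melting curve are expected for these primers).
#' Wells with no melting data are kept usable with a `melt_data_absent` note
#' and a warning, never silently excluded.
#'
#' @param wells a wells data frame.
#' @param cfg a [qc_config()].
#' @return `wells` with added `verdict` (one of `"usable"`, `"dimer_only"`,
#'   `"nondetect"`) and `qc_note` columns.
#' @export
qc_filter_well <- function(wells, cfg = qc_config()) {
  stopifnot(is.data.frame(wells))
  n <- nrow(wells)
  verdict <- rep("usable", n)
  note <- rep("", n)
  verdict[is.na(wells$ct)] <- "nondetect"
  if (!is.na(cfg$amplicon_tm)) {
    numeric_idx <- which(!is.na(wells$ct))
    for (i in numeric_idx) {
      peaks <- wells$tm_peaks[[i]]
      if (!length(peaks)) {
        note[i] <- "melt_data_absent"
      } else if (!any(abs(peaks - cfg$amplicon_tm) <= cfg$tm_tolerance)) {
        verdict[i] <- "dimer_only"
      }
    }
    n_absent <- sum(note == "melt_data_absent")
    if (n_absent > 0) {
      warning(sprintf("%d well(s) have no melting data; kept as usable",
                      n_absent), call. = FALSE)
    }
  }
  wells$verdict <- verdict
  wells$qc_note <- note
  wells
}

#' Collapse technical qPCR replicates to per-(sample, primer) means
#'
#' Reactions are run in duplicate; this averages the numeric Ct values of
#' each (sample, primer) group. A group mixing a numeric Ct with a
#' non-detect keeps the numeric value and is flagged `discordant` (the
#' appropriate handling is left to the analyst; nothing is dropped silently).
#'
#' @param wells a wells data frame (typically the `usable` and `nondetect`
#'   rows after [qc_filter_well()]; `dimer_only` wells should be excluded
#'   first).
#' @return data frame with `sample_id`, `primer_id`, `ct_mean`, `ct_sd`
#'   (NA when fewer than two numeric replicates), `n` (numeric replicates)
#'   and logical `discordant`.
#' @export
collapse_replicates <- function(wells) {
  stopifnot(is.data.frame(wells))
  if (!nrow(wells)) {
    return(data.frame(sample_id = character(0), primer_id = character(0),
                      ct_mean = numeric(0), ct_sd = numeric(0),
                      n = integer(0), discordant = logical(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(wells$sample_id, wells$primer_id, sep = "\r")
  f <- factor(key, levels = unique(key))
  num <- !is.na(wells$ct)
  ct0 <- ifelse(num, wells$ct, 0)
  n_total <- as.vector(rowsum(rep(1L, length(f)), f, reorder = FALSE))
  n <- as.vector(rowsum(as.integer(num), f, reorder = FALSE))
  s1 <- as.vector(rowsum(ct0, f, reorder = FALSE))
  s2 <- as.vector(rowsum(ct0^2, f, reorder = FALSE))
  ct_mean <- ifelse(n > 0, s1 / n, NA_real_)
  ct_var <- ifelse(n >= 2, pmax(s2 - n * ct_mean^2, 0) / (n - 1), NA_real_)
  first <- match(levels(f), key)
  out <- data.frame(sample_id = wells$sample_id[first],
                    primer_id = wells$primer_id[first],
                    ct_mean = ct_mean, ct_sd = sqrt(ct_var), n = n,
                    discordant = n >= 1 & n < n_total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$sample_id, out$primer_id), , drop = FALSE]
}

#' Write a QC report as JSON lines
#'
#' One JSON object per record. For well tables the verdict and note from
#' [qc_filter_well()] are reported; for sample tables the pass flag and the
#' violated criteria from [qc_filter_sample()].
#'
#' @param x a QC-annotated data frame (`verdict` or `pass` column present).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(x, path) {
  stopifnot(is.data.frame(x))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    rec <- if ("verdict" %in% names(x)) {
      list(sample_id = x$sample_id[i], primer_id = x$primer_id[i],
           replicate = x$replicate[i], verdict = x$verdict[i],
           note = x$qc_note[i])
    } else {
      list(sample_id = x$sample_id[i], pass = x$pass[i],
           violations = x$violations[[i]])
    }
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
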