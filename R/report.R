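#' Percentage with half-away-from-zero rounding
#'
#' `100 * numerator / denominator` rounded to `decimals` places with halves
#' rounded away from zero (so 25.63 -> 26 and 87.15 -> 87.2), the
#' convention behind conventional report percentages, unlike R's
#' banker's rounding in [round()].
#'
#' @param numerator Non-negative count.
#' @param denominator Positive count.
#' @param decimals Number of decimal places (default 0).
#' @return The rounded percentage.
#' @examples
#' percent(645, 2478, 0)
#' percent(264, 303, 1)
#' @export
percent <- function(numerator, denominator, decimals = 0L) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0)) stop("numerator must be non-negative")
  round_half_away(100 * numerator / denominator, decimals)
}

# round half away from zero at d decimals
round_half_away <- function(x, d = 0L) {
  f <- 10^d
  # nudge by one ulp so values meant to be exact halves are not lost to
  # binary representation (e.g. 84.158... * 10 = 841.5800000000001 is fine,
  # but 0.5 stored as 0.49999... would round down)
  sign(x) * floor(abs(x) * f + 0.5 + .Machine$double.eps * abs(x) * f) / f
}

#' Verify the sum identities of a partition or summary
#'
#' Checks, without raising, the accounting identities a run must satisfy:
#' a Venn partition's four categories must sum to the focal proteome size,
#' and an ancestry summary's pattern counts plus the multi-copy and
#' unresolved buckets must sum to the number of dual-homolog orthogroups.
#' Each identity is reported with its own pass/fail status.
#'
#' @param x A `venn_partition` or `ancestry_summary` (or a bare named
#'   count vector).
#' @param total The expected total the counts must sum to.
#' @return List with `pass` (all identities hold) and `messages`
#'   (one status line per identity).
#' @examples
#' consistency_check(c(n_unique = 2867, n_only_A = 656, n_only_P = 1329,
#'                     n_both = 2478), total = 7330)
#' @export
consistency_check <- function(x, total = NULL) {
  msgs <- character()
  ok <- TRUE
  check <- function(name, got, want) {
    good <- got == want
    msgs <<- c(msgs, sprintf("%s: %d %s %d [%s]", name, got,
                             if (good) "==" else "!=", want,
                             if (good) "pass" else "FAIL"))
    ok <<- ok && good
  }
  if (inherits(x, "venn_partition")) {
    if (is.null(total)) total <- attr(x, "total")
    check("venn total = focal proteome size", sum(x), total)
  } else if (inherits(x, "ancestry_summary")) {
    if (is.null(total)) total <- x$n_groups
    check("pattern counts + multi-copy + unresolved = orthogroups",
          sum(x$counts), total)
  } else {
    if (is.null(total)) stop("'total' required for a bare count vector")
    check("count sum = total", sum(x), total)
  }
  list(pass = ok, messages = msgs)
}

#' Read a flat key = value configuration file
#'
#' Minimal TOML-style flat configuration: one `key = value` pair per line,
#' `#` comments, quoted or bare strings, numbers and true/false. Values
#' containing commas are split into vectors.
#'
#' @param path Configuration file path.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- vapply(parts, function(p) {
      p <- gsub('^"|"$', "", p)
      p
    }, "")
    num <- suppressWarnings(as.numeric(parsed))
    out[[key]] <- if (!any(is.na(num))) num
                  else if (all(tolower(parsed) %in% c("true", "false")))
                    tolower(parsed) == "true"
                  else unname(parsed)
  }
  out
}

#' Run the full gene-origin attribution pipeline
#'
#' Executes the stages in order — similarity search, reciprocal best hits,
#' orthogroup construction, Venn partition, triplet classification and
#' evidence tally, and (optionally) a toolkit screen — and writes the
#' result tables plus a run manifest to `outdir`. The run is deterministic
#' for fixed inputs: rerunning on identical inputs reproduces identical
#' output bytes.
#'
#' @param focal,ref_host,ref_symbiont Paths to the three proteome FASTA
#'   files (focal species, host-lineage reference, symbiont-lineage
#'   reference).
#' @param outdir Output directory (created if missing).
#' @param scoring A [scoring_scheme].
#' @param toolkit Optional [toolkit_definition] to screen against the focal
#'   proteome.
#' @param correct Use Poisson-corrected distances in classification?
#' @param tolerance Tie tolerance for [classify_triplet].
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters only when the inputs were simulated).
#' @return Invisibly, a list with the [triplet_origin] fit, the toolkit
#'   calls (or `NULL`) and the output paths.
#' @export
run_pipeline <- function(focal, ref_host, ref_symbiont, outdir,
                         scoring = scoring_scheme(), toolkit = NULL,
                         correct = FALSE, tolerance = 1e-12, seed = NULL) {
  for (f in c(focal, ref_host, ref_symbiont))
    if (!file.exists(f)) stop("input FASTA not found: ", f)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  N <- read_fasta(focal, "N")
  A <- read_fasta(ref_host, "A")
  P <- read_fasta(ref_symbiont, "P")
  fit <- triplet_origin(N, A, P, scoring = scoring, correct = correct,
                        tolerance = tolerance)

  utils::write.table(fit$orthogroups,
                     file.path(outdir, "orthogroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$summary$per_gene,
                     file.path(outdir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("NA", "NP", "AP"))
    utils::write.table(fit$rbh[[nm]],
                       file.path(outdir, sprintf("rbh_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- NULL
  if (!is.null(toolkit)) {
    calls <- screen_toolkit(toolkit, N, scoring)
    utils::write.table(calls, file.path(outdir, "toolkit_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  tally <- symbiont_evidence_tally(fit$summary)
  summary_json <- list(
    counts = as.list(fit$summary$counts),
    percentages = as.list(pattern_percentages(fit$summary)),
    venn = as.list(unclass(fit$venn)[seq_along(fit$venn)]),
    host_count = tally$host_count,
    symbiont_count = tally$symbiont_count,
    verdict = tally$verdict)
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- c(
    sprintf("tripletOrigin %s",
            as.character(utils::packageVersion("tripletOrigin"))),
    sprintf("focal: %s", basename(focal)),
    sprintf("ref_host: %s", basename(ref_host)),
    sprintf("ref_symbiont: %s", basename(ref_symbiont)),
    sprintf("seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("gap_open: %d", scoring$gap_open),
    sprintf("gap_extend: %d", scoring$gap_extend),
    sprintf("evalue_threshold: %g", scoring$evalue_threshold),
    sprintf("min_coverage: %g", scoring$min_coverage),
    sprintf("correct: %s", correct),
    sprintf("tolerance: %g", tolerance))
  writeLines(manifest, file.path(outdir, "manifest.txt"))

  invisible(list(fit = fit, toolkit_calls = calls, outdir = outdir))
}

# percentages of the dual-homolog total, printed-report convention
pattern_percentages <- function(summary) {
  tot <- summary$n_groups
  if (tot == 0) return(stats::setNames(numeric(0), character(0)))
  vapply(summary$counts, function(k) percent(k, tot, 0L), numeric(1))
}
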