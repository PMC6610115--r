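#' Scoring scheme for protein similarity search
#'
#' Bundles the substitution matrix, affine gap penalties, Karlin-Altschul
#' E-value constants and hit filters used by every search stage. The affine
#' convention is: a gap of length k costs `gap_open + (k - 1) * gap_extend`.
#'
#' Defaults are the ubiquitous protein-search settings: BLOSUM62,
#' gap open 11 / extend 1, lambda = 0.267 and K = 0.041 (gapped BLOSUM62
#' constants), an E-value acceptance threshold of 1e-5, and a minimum
#' subject coverage of 0.7 standing in for a "full length" hit filter.
#' `X` scores 0 against every residue (neutral handling of unknowns) and is
#' excluded from identity and distance counts.
#'
#' @param substitution_matrix Square integer scoring matrix with row/column
#'   names covering the 20 canonical letters plus `X`. Default: BLOSUM62
#'   with the `X` row/column zeroed.
#' @param gap_open Cost of opening a gap (charged for the first gapped
#'   position); positive integer.
#' @param gap_extend Cost of each further gapped position; positive integer,
#'   `gap_open >= gap_extend >= 1`.
#' @param evalue_lambda,evalue_K Karlin-Altschul constants (positive reals).
#' @param evalue_threshold Hits with E-value at or above this are discarded.
#' @param min_coverage Minimum fraction of the subject (reference) length
#'   that the local alignment must cover for a hit to pass.
#' @return An object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' sc$gap_open
#' @export
scoring_scheme <- function(substitution_matrix = NULL,
                           gap_open = 11L, gap_extend = 1L,
                           evalue_lambda = 0.267, evalue_K = 0.041,
                           evalue_threshold = 1e-5, min_coverage = 0.7) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62x()
  m <- substitution_matrix
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("substitution matrix must be square with matching dimnames")
  if (!all(AA_ALPHABET21 %in% rownames(m)))
    stop("substitution matrix must cover the 20 amino acids plus 'X'")
  m <- m[AA_ALPHABET21, AA_ALPHABET21]
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open >= gap_extend && gap_extend >= 1))
    stop("require gap_open >= gap_extend >= 1")
  if (evalue_lambda <= 0 || evalue_K <= 0)
    stop("E-value constants must be positive")
  if (evalue_threshold <= 0) stop("evalue_threshold must be positive")
  if (min_coverage < 0 || min_coverage > 1)
    stop("min_coverage must lie in [0, 1]")
  structure(list(substitution_matrix = m,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 evalue_lambda = evalue_lambda, evalue_K = evalue_K,
                 evalue_threshold = evalue_threshold,
                 min_coverage = min_coverage),
            class = "scoring_scheme")
}

# BLOSUM62 restricted to the package alphabet, X neutralised to 0.
blosum62x <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET21, AA_ALPHABET21]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring scheme: gap open", x$gap_open, "/ extend", x$gap_extend,
      sprintf("; E-value lambda=%.3f K=%.3f threshold=%g; min coverage %.2f\n",
              x$evalue_lambda, x$evalue_K, x$evalue_threshold,
              x$min_coverage))
  invisible(x)
}

check_sequence <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L) stop(what, " must be one string")
  s <- toupper(s)
  if (grepl(sprintf("[^%s]", paste(AA_ALPHABET21, collapse = "")), s))
    stop("illegal character in ", what)
  s
}

# Biostrings charges gapOpening + k*gapExtension for a k-gap; the package
# convention gap_open + (k-1)*gap_extend is recovered by shifting the
# opening cost down by one extension.
biostrings_gap <- function(scoring)
  list(opening = scoring$gap_open - scoring$gap_extend,
       extension = scoring$gap_extend)

align_result <- function(pa, a, b, type) {
  pat <- as.character(Biostrings::alignedPattern(pa))
  sub <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(sub, "")[[1]]
  both <- pc != "-" & sc != "-"
  informative <- both & pc != "X" & sc != "X"
  ident <- if (any(informative))
    sum(pc[informative] == sc[informative]) / sum(informative) else NA_real_
  cov <- if (nchar(b) > 0) sum(sc != "-") / nchar(b) else NA_real_
  structure(list(score = Biostrings::score(pa),
                 aligned_a = pat, aligned_b = sub,
                 identity_fraction = ident, coverage = cov,
                 type = type),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment, score %g, identity %s, coverage %s\n",
              x$type, x$score,
              format(x$identity_fraction, digits = 3),
              format(x$coverage, digits = 3)))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch global alignment of two protein sequences under the
#' scheme's substitution matrix and affine gap costs (a k-length gap costs
#' `gap_open + (k - 1) * gap_extend`). The traceback is deterministic, so
#' repeated calls give byte-identical alignments.
#'
#' @param a,b Protein sequences (strings over the 20 canonical letters
#'   plus `X`).
#' @param scoring A [scoring_scheme].
#' @return An `alignment_result`: list with `score`, the two gapped strings
#'   (`aligned_a`, `aligned_b`, equal length), `identity_fraction`
#'   (matches / aligned non-gap, non-`X` columns) and `coverage` (aligned
#'   `b` positions / length of `b`).
#' @examples
#' global_align("ACDE", "ACDE", scoring_scheme())$score
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  a <- check_sequence(a, "'a'"); b <- check_sequence(b, "'b'")
  g <- biostrings_gap(scoring)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    # forced all-gap alignment: one gap of length max(|a|, |b|)
    k <- max(nchar(a), nchar(b))
    score <- if (k == 0L) 0
             else -(scoring$gap_open + (k - 1L) * scoring$gap_extend)
    return(structure(list(
      score = score,
      aligned_a = if (nchar(a)) a else strrep("-", k),
      aligned_b = if (nchar(b)) b else strrep("-", k),
      identity_fraction = NA_real_,
      coverage = if (nchar(b)) 0 else NA_real_,
      type = "global"), class = "alignment_result"))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scoring$substitution_matrix,
    gapOpening = g$opening, gapExtension = g$extension, type = "global")
  align_result(pa, a, b, "global")
}

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman local alignment under the same affine convention as
#' [global_align]. The score is never negative; when no residue pair scores
#' positively the optimal local alignment is empty with score 0.
#'
#' @inheritParams global_align
#' @return An `alignment_result` (see [global_align]); for the empty
#'   alignment the gapped strings are `""` and identity/coverage are `NA`.
#' @export
local_align <- function(a, b, scoring = scoring_scheme()) {
  a <- check_sequence(a, "'a'"); b <- check_sequence(b, "'b'")
  g <- biostrings_gap(scoring)
  if (nchar(a) == 0L || nchar(b) == 0L)
    return(structure(list(score = 0, aligned_a = "", aligned_b = "",
                          identity_fraction = NA_real_, coverage = NA_real_,
                          type = "local"),
                     class = "alignment_result"))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scoring$substitution_matrix,
    gapOpening = g$opening, gapExtension = g$extension, type = "local")
  if (Biostrings::score(pa) <= 0)
    return(structure(list(score = 0, aligned_a = "", aligned_b = "",
                          identity_fraction = NA_real_, coverage = NA_real_,
                          type = "local"),
                     class = "alignment_result"))
  align_result(pa, a, b, "local")
}

# vectorised local scores of one query against many subjects
local_scores <- function(query, subjects, scoring) {
  if (length(subjects) == 0L) return(numeric())
  g <- biostrings_gap(scoring)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    substitutionMatrix = scoring$substitution_matrix,
    gapOpening = g$opening, gapExtension = g$extension,
    type = "local", scoreOnly = TRUE)
  pmax(s, 0)
}

#' Karlin-Altschul E-value approximation
#'
#' Expected number of chance local alignments scoring at least `score` in a
#' search of a query of length `query_len` against a database of total
#' length `subject_total_len`: `E = K * m * n * exp(-lambda * S)`.
#'
#' @param score Local alignment raw score.
#' @param query_len,subject_total_len Positive lengths (residues).
#' @param scoring A [scoring_scheme] supplying `evalue_lambda`/`evalue_K`.
#' @return The E-value (non-negative real).
#' @examples
#' estimate_evalue(40, 100, 100, scoring_scheme())
#' @export
estimate_evalue <- function(score, query_len, subject_total_len,
                            scoring = scoring_scheme()) {
  if (any(query_len <= 0) || any(subject_total_len <= 0))
    stop("sequence lengths must be positive")
  scoring$evalue_K * query_len * subject_total_len *
    exp(-scoring$evalue_lambda * score)
}

#' Pairwise distance from a global alignment
#'
#' The p-distance is the fraction of mismatching columns among aligned
#' non-gap, non-`X` columns of the optimal global alignment. With
#' `correct = TRUE` the Poisson-type correction for the 20-state uniform
#' substitution model is applied, `d = -(19/20) * log(1 - 20 p / 19)`,
#' converting the observed fraction into expected substitutions per site.
#' At or beyond the model's saturation point (`p >= 0.95`) the corrected
#' distance is the sentinel `Inf`.
#'
#' @inheritParams global_align
#' @param correct Apply the 20-state Poisson correction?
#' @return A single non-negative distance (`NaN` when the alignment has no
#'   informative columns).
#' @export
alignment_distance <- function(a, b, scoring = scoring_scheme(),
                               correct = FALSE) {
  al <- global_align(a, b, scoring)
  pc <- strsplit(al$aligned_a, "")[[1]]
  sc <- strsplit(al$aligned_b, "")[[1]]
  informative <- pc != "-" & sc != "-" & pc != "X" & sc != "X"
  if (!any(informative)) return(NaN)
  p <- sum(pc[informative] != sc[informative]) / sum(informative)
  if (!correct) return(p)
  correct_p_distance(p)
}

# Poisson-type correction for the 20-state uniform model; Inf past
# saturation (p >= 19/20 up to numerical slack, conservatively p >= 0.95).
correct_p_distance <- function(p) {
  ifelse(p >= 0.95, Inf, -(19 / 20) * log(1 - 20 * p / 19))
}
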