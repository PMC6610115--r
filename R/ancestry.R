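PATTERN_LEVELS <- c("PATTERN_I", "PATTERN_II", "PATTERN_III",
                    "MULTI_COPY", "UNRESOLVED")

#' Pairwise distances within a single-copy triplet
#'
#' Computes the three pairwise distances among the focal (`N`),
#' host-reference (`A`) and symbiont-reference (`P`) members of a
#' single-copy orthogroup from optimal global alignments. The p-distance is
#' mismatches over aligned non-gap, non-`X` columns; with
#' `correct = TRUE` the 20-state Poisson correction is applied (saturated
#' pairs, p >= 0.95, get the sentinel `Inf`).
#'
#' @param seq_N,seq_A,seq_P The three member sequences.
#' @param scoring A [scoring_scheme].
#' @param correct Apply the Poisson-type correction?
#' @return Named numeric vector `c(d_NA, d_NP, d_AP)` with attribute
#'   `corrected`.
#' @examples
#' triplet_distances("ACDE", "ACDE", "ACDF")
#' @export
triplet_distances <- function(seq_N, seq_A, seq_P,
                              scoring = scoring_scheme(), correct = FALSE) {
  d <- c(d_NA = alignment_distance(seq_N, seq_A, scoring, correct),
         d_NP = alignment_distance(seq_N, seq_P, scoring, correct),
         d_AP = alignment_distance(seq_A, seq_P, scoring, correct))
  attr(d, "corrected") <- correct
  d
}

#' Classify a triplet into an origin pattern by its nearest pair
#'
#' The smallest of the three pairwise distances names the sister pair and
#' thereby the origin pattern of the focal gene:
#' * `PATTERN_I` — focal gene nearest the host-lineage reference
#'   (`d_NA` minimal): host nuclear origin.
#' * `PATTERN_II` — focal gene nearest the symbiont-lineage reference
#'   (`d_NP` minimal): symbiont origin.
#' * `PATTERN_III` — the two references are each other's nearest
#'   (`d_AP` minimal), the focal gene an outgroup: also far from the host
#'   lineage, counted as symbiont origin.
#'
#' When the two smallest distances differ by less than `tolerance` the
#' triplet is `UNRESOLVED`.
#'
#' @param distances Numeric vector `c(d_NA, d_NP, d_AP)` (order is
#'   positional; names are ignored).
#' @param tolerance Minimal margin between the two smallest distances for a
#'   resolved call (default `1e-12`: exact ties only).
#' @return One of `"PATTERN_I"`, `"PATTERN_II"`, `"PATTERN_III"`,
#'   `"UNRESOLVED"`.
#' @examples
#' classify_triplet(c(0.1, 0.3, 0.3))
#' @export
classify_triplet <- function(distances, tolerance = 1e-12) {
  stopifnot(length(distances) == 3L, all(!is.na(distances)),
            all(distances >= 0 | is.infinite(distances)))
  d <- as.numeric(distances)
  o <- order(d)
  if (is.infinite(d[o[1]])) return("UNRESOLVED")  # all pairs saturated
  margin <- d[o[2]] - d[o[1]]
  if (is.nan(margin) || margin < tolerance) return("UNRESOLVED")
  c("PATTERN_I", "PATTERN_II", "PATTERN_III")[o[1]]
}

#' Classify every orthogroup of a dataset
#'
#' Single-copy triplets are classified by [classify_triplet] from alignment
#' distances; multi-copy groups are tallied under `MULTI_COPY` without
#' classification (multi-copy families cannot be resolved by a single
#' nearest-pair decision); groups lacking a member in one or more species
#' (partial or species-unique) are outside the three-species comparison and
#' are not counted.
#'
#' @param orthogroups An `orthogroups` table from [build_orthogroups] (or
#'   any data frame with `group_id`, `species`, `member_id`, `single_copy`,
#'   `multi_copy`).
#' @param proteomes Named list of the three [proteome]s (`N`, `A`, `P`).
#' @param scoring A [scoring_scheme].
#' @param correct Use Poisson-corrected distances?
#' @param tolerance Tie tolerance passed to [classify_triplet].
#' @return An object of class `ancestry_summary`: list with `counts`
#'   (named vector over `PATTERN_I`, `PATTERN_II`, `PATTERN_III`,
#'   `MULTI_COPY`, `UNRESOLVED`), `per_gene` (data frame: `group_id`,
#'   `focal_id`, `d_NA`, `d_NP`, `d_AP`, `label`) and `n_groups` (number of
#'   classified + multi-copy groups).
#' @export
classify_dataset <- function(orthogroups, proteomes,
                             scoring = scoring_scheme(),
                             correct = FALSE, tolerance = 1e-12) {
  look <- proteome_lookup(proteomes[c("N", "A", "P")])
  counts <- stats::setNames(integer(length(PATTERN_LEVELS)), PATTERN_LEVELS)
  rows <- list()
  if (nrow(orthogroups)) {
    missing <- setdiff(orthogroups$member_id, names(look$sequences))
    if (length(missing))
      stop("orthogroup member(s) without sequence: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    sp <- split(orthogroups, orthogroups$group_id)
    for (grp in sp) {
      if (grp$multi_copy[1]) {
        counts["MULTI_COPY"] <- counts["MULTI_COPY"] + 1L
        next
      }
      if (!grp$single_copy[1]) next  # partial / species-unique group
      ids <- stats::setNames(grp$member_id, grp$species)
      d <- triplet_distances(look$sequences[[ids[["N"]]]],
                             look$sequences[[ids[["A"]]]],
                             look$sequences[[ids[["P"]]]],
                             scoring, correct)
      lab <- classify_triplet(d, tolerance)
      counts[lab] <- counts[lab] + 1L
      rows[[length(rows) + 1L]] <-
        data.frame(group_id = grp$group_id[1], focal_id = ids[["N"]],
                   d_NA = d[["d_NA"]], d_NP = d[["d_NP"]],
                   d_AP = d[["d_AP"]], label = lab)
    }
  }
  per_gene <- do.call(rbind, rows)
  if (is.null(per_gene))
    per_gene <- data.frame(group_id = character(), focal_id = character(),
                           d_NA = numeric(), d_NP = numeric(),
                           d_AP = numeric(), label = character())
  structure(list(counts = counts, per_gene = per_gene,
                 n_groups = sum(counts)),
            class = "ancestry_summary")
}

#' @export
print.ancestry_summary <- function(x, ...) {
  cat("ancestry summary over", x$n_groups, "orthogroups\n")
  print(x$counts)
  tally <- symbiont_evidence_tally(x)
  cat(sprintf("host evidence %d vs symbiont evidence %d: %s\n",
              tally$host_count, tally$symbiont_count, tally$verdict))
  invisible(x)
}

#' Venn partition of a focal proteome against two references
#'
#' Assigns each focal gene to exactly one of four categories by the
#' presence of at least one passing hit against the host-lineage reference
#' (`A`) and the symbiont-lineage reference (`P`): unique (neither),
#' only `A`, only `P`, or both. Category sizes always sum to the focal
#' proteome size.
#'
#' @param focal_proteome The focal [proteome].
#' @param hits_vs_A,hits_vs_P Hit tables (data frames with a `query`
#'   column, e.g. from [best_hits]) against the two references.
#' @return An object of class `venn_partition`: named integer vector
#'   `c(n_unique, n_only_A, n_only_P, n_both)` with attribute `total`.
#' @export
venn_partition <- function(focal_proteome, hits_vs_A, hits_vs_P) {
  stopifnot(inherits(focal_proteome, "proteome"))
  in_A <- focal_proteome$ids %in% hits_vs_A$query
  in_P <- focal_proteome$ids %in% hits_vs_P$query
  out <- c(n_unique = sum(!in_A & !in_P),
           n_only_A = sum(in_A & !in_P),
           n_only_P = sum(!in_A & in_P),
           n_both = sum(in_A & in_P))
  structure(out, total = length(focal_proteome), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("homolog Venn partition of", attr(x, "total"), "focal genes\n")
  print(unclass(x)[seq_along(x)])
  invisible(x)
}

#' Tally host vs symbiont evidence
#'
#' Host evidence is the `PATTERN_I` count (focal gene nearest the
#' host-lineage reference); symbiont evidence is `PATTERN_II + PATTERN_III`
#' (focal gene far from the host-lineage reference). `MULTI_COPY` and
#' `UNRESOLVED` groups carry no evidence either way. The verdict is
#' `"symbiont-dominant"` when symbiont evidence strictly exceeds host
#' evidence, `"host-dominant"` when strictly smaller, else
#' `"indeterminate"`.
#'
#' @param summary An `ancestry_summary` from [classify_dataset], or a named
#'   count vector over the pattern labels.
#' @return List with `host_count`, `symbiont_count`, `verdict`.
#' @examples
#' symbiont_evidence_tally(c(PATTERN_I = 645, PATTERN_II = 635,
#'                           PATTERN_III = 722))
#' @export
symbiont_evidence_tally <- function(summary) {
  counts <- if (inherits(summary, "ancestry_summary")) summary$counts
            else summary
  get <- function(k) if (k %in% names(counts)) as.integer(counts[[k]]) else 0L
  host <- get("PATTERN_I")
  symb <- get("PATTERN_II") + get("PATTERN_III")
  verdict <- if (symb > host) "symbiont-dominant"
             else if (symb < host) "host-dominant"
             else "indeterminate"
  list(host_count = host, symbiont_count = symb, verdict = verdict)
}
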