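#' Fit a gene-origin attribution to three proteomes
#'
#' The front door of the package. Given the focal proteome and the two
#' lineage references (host-lineage and symbiont-lineage), it runs the full
#' inference: all-vs-all local-alignment search, best hits per direction,
#' reciprocal best hits per species pair, orthogroups as connected
#' components of the RBH union graph, a Venn partition of the focal genes
#' by homolog presence, nearest-pair classification of every single-copy
#' triplet into origin patterns, and the host-vs-symbiont evidence tally.
#'
#' Pattern I (focal gene nearest the host-lineage reference) is host-origin
#' evidence; Patterns II and III (focal gene far from the host-lineage
#' reference) are symbiont-origin evidence. Multi-copy orthogroups are
#' counted but never classified.
#'
#' @param focal,ref_host,ref_symbiont [proteome]s of the focal species and
#'   the two references.
#' @param scoring A [scoring_scheme].
#' @param correct Use Poisson-corrected distances in classification?
#' @param tolerance Tie tolerance for [classify_triplet].
#' @return An object of class `triplet_origin`: list with elements
#'   `proteomes`, `rbh` (the three RBH tables), `orthogroups`, `venn`
#'   (a `venn_partition`), `summary` (an `ancestry_summary`), `tally`
#'   (host/symbiont counts and verdict), `scoring` and `call`. Methods:
#'   [print.triplet_origin()], [summary.triplet_origin()],
#'   [coef.triplet_origin()], [plot.triplet_origin()],
#'   [simulate.triplet_origin()].
#' @examples
#' \donttest{
#' d <- simulate_dataset(sim_config(n_families = 12, sequence_length = 80))
#' fit <- triplet_origin(d$proteomes$N, d$proteomes$A, d$proteomes$P)
#' coef(fit)
#' }
#' @export
triplet_origin <- function(focal, ref_host, ref_symbiont,
                           scoring = scoring_scheme(), correct = FALSE,
                           tolerance = 1e-12) {
  stopifnot(inherits(focal, "proteome"), inherits(ref_host, "proteome"),
            inherits(ref_symbiont, "proteome"))
  proteomes <- list(N = focal, A = ref_host, P = ref_symbiont)

  sm_NA <- score_matrix(focal, ref_host, scoring)
  sm_NP <- score_matrix(focal, ref_symbiont, scoring)
  sm_AP <- score_matrix(ref_host, ref_symbiont, scoring)

  hits_vs_A <- best_hits_from_scores(sm_NA, focal, ref_host, scoring)
  hits_vs_P <- best_hits_from_scores(sm_NP, focal, ref_symbiont, scoring)

  rbh <- list(
    "NA" = rbh_from_scores(sm_NA, focal, ref_host, scoring),
    "NP" = rbh_from_scores(sm_NP, focal, ref_symbiont, scoring),
    "AP" = rbh_from_scores(sm_AP, ref_host, ref_symbiont, scoring))
  within <- lapply(proteomes, within_species_rbh, scoring = scoring)

  og <- build_orthogroups(rbh[["NA"]], rbh[["NP"]], rbh[["AP"]], proteomes,
                          rbh_within = within)
  venn <- venn_partition(focal, hits_vs_A, hits_vs_P)
  summ <- classify_dataset(og, proteomes, scoring, correct, tolerance)
  tally <- symbiont_evidence_tally(summ)

  structure(list(proteomes = proteomes, rbh = rbh, orthogroups = og,
                 venn = venn, summary = summ, tally = tally,
                 hits = list(vs_A = hits_vs_A, vs_P = hits_vs_P),
                 scoring = scoring, correct = correct,
                 tolerance = tolerance, call = match.call()),
            class = "triplet_origin")
}

# RBH from a precomputed score matrix (local scores are symmetric)
rbh_from_scores <- function(sm, P, Q, scoring) {
  fwd <- best_hits_from_scores(sm, P, Q, scoring)
  rev <- best_hits_from_scores(t(sm), Q, P, scoring)
  if (nrow(fwd) == 0L || nrow(rev) == 0L)
    return(data.frame(id_P = character(), id_Q = character()))
  back <- stats::setNames(rev$subject, rev$query)
  keep <- !is.na(back[fwd$subject]) & back[fwd$subject] == fwd$query
  out <- data.frame(id_P = fwd$query[keep], id_Q = fwd$subject[keep])
  out[order(out$id_P), , drop = FALSE]
}

#' @export
print.triplet_origin <- function(x, ...) {
  cat("Gene-origin attribution (triplet nearest-pair classification)\n\n")
  cat(sprintf("Proteomes: focal %d, host-ref %d, symbiont-ref %d genes\n",
              length(x$proteomes$N), length(x$proteomes$A),
              length(x$proteomes$P)))
  cat(sprintf("Venn: %d unique | %d host-only | %d symbiont-only | %d both\n",
              x$venn[["n_unique"]], x$venn[["n_only_A"]],
              x$venn[["n_only_P"]], x$venn[["n_both"]]))
  cat("Pattern counts: ")
  cat(paste(names(x$summary$counts), x$summary$counts, sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("Evidence: host %d vs symbiont %d -> %s\n",
              x$tally$host_count, x$tally$symbiont_count, x$tally$verdict))
  invisible(x)
}

#' Summarise a gene-origin attribution fit
#'
#' @param object A `triplet_origin` fit.
#' @param ... Unused.
#' @return A `summary.triplet_origin` list with pattern counts and
#'   percentages (of the dual-homolog orthogroup total), the Venn
#'   partition, the evidence tally and the consistency-check report.
#' @method summary triplet_origin
#' @export
summary.triplet_origin <- function(object, ...) {
  structure(list(counts = object$summary$counts,
                 percentages = pattern_percentages(object$summary),
                 n_groups = object$summary$n_groups,
                 venn = object$venn, tally = object$tally,
                 checks = list(
                   venn = consistency_check(object$venn),
                   summary = consistency_check(object$summary))),
            class = "summary.triplet_origin")
}

#' @export
print.summary.triplet_origin <- function(x, ...) {
  cat("Pattern classification of", x$n_groups, "dual-homolog orthogroups\n")
  tab <- data.frame(count = as.integer(x$counts),
                    percent = as.numeric(x$percentages),
                    row.names = names(x$counts))
  print(tab)
  cat("\n")
  print(x$venn)
  cat(sprintf("\nEvidence: host %d vs symbiont %d -> %s\n",
              x$tally$host_count, x$tally$symbiont_count, x$tally$verdict))
  for (m in c(x$checks$venn$messages, x$checks$summary$messages))
    cat(" ", m, "\n")
  invisible(x)
}

#' Estimated origin-pattern proportions
#'
#' @param object A `triplet_origin` fit.
#' @param ... Unused.
#' @return Named vector of Pattern I/II/III proportions among resolved
#'   single-copy triplets.
#' @method coef triplet_origin
#' @export
coef.triplet_origin <- function(object, ...) {
  k <- object$summary$counts[c("PATTERN_I", "PATTERN_II", "PATTERN_III")]
  if (sum(k) == 0) return(stats::setNames(rep(NaN, 3L), names(k)))
  k / sum(k)
}

#' Plot a gene-origin attribution fit
#'
#' Two base-graphics panels: the homolog Venn category sizes and the
#' pattern counts, host-origin evidence in a distinct colour.
#'
#' @param x A `triplet_origin` fit.
#' @param ... Passed to [graphics::barplot()].
#' @method plot triplet_origin
#' @export
plot.triplet_origin <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(unclass(x$venn)[seq_along(x$venn)],
                    main = "Homolog Venn partition", las = 2,
                    ylab = "focal genes", col = "grey70", ...)
  cols <- c(PATTERN_I = "#d95f02", PATTERN_II = "#1b9e77",
            PATTERN_III = "#1b9e77", MULTI_COPY = "grey70",
            UNRESOLVED = "grey90")
  graphics::barplot(x$summary$counts, main = "Origin patterns", las = 2,
                    ylab = "orthogroups", col = cols[names(x$summary$counts)],
                    ...)
  invisible(x)
}

#' Simulate datasets from a fitted origin-pattern mixture
#'
#' Parametric resampling: draws synthetic three-species datasets whose
#' topology proportions equal the fit's estimated Pattern I/II/III
#' proportions, with as many single-copy families as the fit classified.
#'
#' @param object A `triplet_origin` fit.
#' @param nsim Number of datasets.
#' @param seed Master seed for the first dataset; dataset `i` uses
#'   `seed + i - 1`.
#' @param sequence_length Simulated protein length.
#' @param ... Unused.
#' @return A list of `nsim` results of [simulate_dataset].
#' @importFrom stats simulate
#' @export
simulate.triplet_origin <- function(object, nsim = 1, seed = 1L,
                                    sequence_length = 300L, ...) {
  p <- coef(object)
  if (any(is.nan(p))) stop("fit has no resolved triplets to resample from")
  n <- sum(object$summary$counts[c("PATTERN_I", "PATTERN_II",
                                   "PATTERN_III")])
  lapply(seq_len(nsim), function(i)
    simulate_dataset(sim_config(
      n_families = n, topology_proportions = unname(p),
      sequence_length = sequence_length,
      master_seed = as.integer(seed) + i - 1L)))
}
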