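#' Best passing hit per query between two proteomes
#'
#' Full dynamic-programming local alignment of every query against every
#' subject (no heuristic seeding), keeping for each query the
#' maximal-scoring subject whose Karlin-Altschul E-value falls below the
#' scheme's threshold and whose alignment covers at least `min_coverage`
#' of the subject. The E-value search space is query length times the
#' total subject proteome length. Score ties break deterministically by
#' lexicographic subject id. Queries with no passing hit are absent from
#' the result.
#'
#' @param query_proteome,subject_proteome [proteome]s.
#' @param scoring A [scoring_scheme].
#' @return Data frame with one row per query holding a passing hit:
#'   `query`, `subject`, `score`, `evalue`, `identity`, `coverage`.
#' @export
best_hits <- function(query_proteome, subject_proteome,
                      scoring = scoring_scheme()) {
  sm <- score_matrix(query_proteome, subject_proteome, scoring)
  best_hits_from_scores(sm, query_proteome, subject_proteome, scoring)
}

# all-vs-all local score matrix (queries in rows, subjects in columns)
score_matrix <- function(query_proteome, subject_proteome, scoring) {
  q <- query_proteome$sequences
  s <- subject_proteome$sequences
  out <- matrix(0, nrow = length(q), ncol = length(s),
                dimnames = list(names(q), names(s)))
  if (length(q) == 0L || length(s) == 0L) return(out)
  subjects <- Biostrings::AAStringSet(unname(s))
  g <- biostrings_gap(scoring)
  for (i in seq_along(q)) {
    sc <- Biostrings::pairwiseAlignment(
      subjects, Biostrings::AAString(q[[i]]),
      substitutionMatrix = scoring$substitution_matrix,
      gapOpening = g$opening, gapExtension = g$extension,
      type = "local", scoreOnly = TRUE)
    out[i, ] <- pmax(sc, 0)
  }
  out
}

best_hits_from_scores <- function(sm, query_proteome, subject_proteome,
                                  scoring) {
  n_total <- sum(nchar(subject_proteome$sequences))
  rows <- vector("list", nrow(sm))
  subj_order <- order(colnames(sm))  # lexicographic tie-break
  for (i in seq_len(nrow(sm))) {
    if (ncol(sm) == 0L) next
    sc <- sm[i, subj_order]
    j <- which.max(sc)  # first max in lexicographic subject order
    qid <- rownames(sm)[i]
    sid <- names(sc)[j]
    qlen <- nchar(query_proteome$sequences[[qid]])
    if (qlen == 0L) next
    ev <- estimate_evalue(sc[[j]], qlen, n_total, scoring)
    if (ev >= scoring$evalue_threshold) next
    al <- local_align(query_proteome$sequences[[qid]],
                      subject_proteome$sequences[[sid]], scoring)
    if (is.na(al$coverage) || al$coverage < scoring$min_coverage) next
    rows[[i]] <- data.frame(query = qid, subject = sid, score = sc[[j]],
                            evalue = ev, identity = al$identity_fraction,
                            coverage = al$coverage)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query = character(), subject = character(),
                      score = numeric(), evalue = numeric(),
                      identity = numeric(), coverage = numeric())
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two proteomes
#'
#' A pair `(p, q)` is reported when `q` is `p`'s best passing hit in the
#' second proteome and `p` is `q`'s best passing hit in the first — the
#' standard orthology proxy. Local alignment scores are symmetric, so one
#' score matrix serves both directions.
#'
#' @param P,Q [proteome]s.
#' @param scoring A [scoring_scheme].
#' @return Data frame with columns `id_P`, `id_Q`, one row per reciprocal
#'   pair, ordered by `id_P`.
#' @export
reciprocal_best_hits <- function(P, Q, scoring = scoring_scheme()) {
  sm <- score_matrix(P, Q, scoring)
  fwd <- best_hits_from_scores(sm, P, Q, scoring)
  rev <- best_hits_from_scores(t(sm), Q, P, scoring)
  if (nrow(fwd) == 0L || nrow(rev) == 0L)
    return(data.frame(id_P = character(), id_Q = character()))
  back <- stats::setNames(rev$subject, rev$query)
  keep <- !is.na(back[fwd$subject]) & back[fwd$subject] == fwd$query
  out <- data.frame(id_P = fwd$query[keep], id_Q = fwd$subject[keep])
  out[order(out$id_P), , drop = FALSE]
}

#' Within-species reciprocal best hits (in-paralog edges)
#'
#' Reciprocal best hits of a proteome against itself, self-hits excluded,
#' under the same E-value and coverage filters as the cross-species search.
#' Cross-species reciprocal best hits alone cannot place a within-species
#' duplicate into its family's orthogroup (the duplicate is never any
#' other species' single best hit); linking mutual within-species best
#' hits, as orthology clustering tools do for in-paralogs, routes
#' multi-copy families into the multi-copy bucket.
#'
#' @param P A [proteome].
#' @param scoring A [scoring_scheme].
#' @return Data frame with columns `id_P`, `id_Q` (unordered mutual pairs,
#'   each reported once).
#' @export
within_species_rbh <- function(P, scoring = scoring_scheme()) {
  sm <- score_matrix(P, P, scoring)
  diag(sm) <- -Inf
  fwd <- best_hits_from_scores(sm, P, P, scoring)
  if (nrow(fwd) == 0L) return(data.frame(id_P = character(),
                                         id_Q = character()))
  back <- stats::setNames(fwd$subject, fwd$query)
  keep <- !is.na(back[fwd$subject]) & back[fwd$subject] == fwd$query &
    fwd$query < fwd$subject  # report each mutual pair once
  out <- data.frame(id_P = fwd$query[keep], id_Q = fwd$subject[keep])
  out[order(out$id_P), , drop = FALSE]
}

#' Build orthogroups from three reciprocal-best-hit edge sets
#'
#' Orthogroups are the connected components of the graph whose vertices are
#' all genes of the three proteomes and whose edges are the union of the
#' three pairwise RBH sets. A component with exactly one member in each of
#' the three species is a single-copy triplet; a component with more than
#' one member in any species is flagged multi-copy and is excluded from
#' triplet classification. Genes in no RBH pair form singleton groups.
#'
#' @param rbh_NA,rbh_NP,rbh_AP RBH data frames (two id columns each) from
#'   [reciprocal_best_hits] for the focal/host, focal/symbiont and
#'   host/symbiont proteome pairs.
#' @param proteomes Named list of the three [proteome]s (`N`, `A`, `P`).
#' @param rbh_within Optional list of within-species edge tables from
#'   [within_species_rbh], appended to the edge union so duplicates join
#'   their family's component.
#' @return An object of class `orthogroups`: data frame with columns
#'   `group_id`, `species`, `member_id`, `single_copy`, `multi_copy`
#'   (one row per gene).
#' @export
build_orthogroups <- function(rbh_NA, rbh_NP, rbh_AP, proteomes,
                              rbh_within = NULL) {
  stopifnot(all(c("N", "A", "P") %in% names(proteomes)))
  look <- proteome_lookup(proteomes[c("N", "A", "P")])
  vertices <- names(look$sequences)
  edge_sets <- c(list(rbh_NA, rbh_NP, rbh_AP), rbh_within)
  edges <- do.call(rbind, lapply(edge_sets, function(e)
    stats::setNames(e, c("from", "to"))))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = vertices))
  comp <- igraph::components(g)
  member <- comp$membership[vertices]
  # stable group ids in order of first appearance
  first <- !duplicated(member)
  relabel <- stats::setNames(seq_len(sum(first)), member[first])
  gid <- sprintf("OG%05d", relabel[as.character(member)])
  df <- data.frame(group_id = gid, species = unname(look$species[vertices]),
                   member_id = vertices, row.names = NULL)
  per <- table(df$group_id, factor(df$species, levels = c("N", "A", "P")))
  multi <- rownames(per)[apply(per > 1, 1, any)]
  single <- rownames(per)[apply(per == 1, 1, all)]
  df$multi_copy <- df$group_id %in% multi
  df$single_copy <- df$group_id %in% single
  class(df) <- c("orthogroups", class(df))
  df
}

#' @export
print.orthogroups <- function(x, ...) {
  n_groups <- length(unique(x$group_id))
  n_single <- length(unique(x$group_id[x$single_copy]))
  n_multi <- length(unique(x$group_id[x$multi_copy]))
  cat(sprintf("orthogroups: %d groups over %d genes (%d single-copy triplets, %d multi-copy)\n",
              n_groups, nrow(x), n_single, n_multi))
  invisible(x)
}

#' Fraction of queries with a homolog in a reference proteome
#'
#' Percentage of query genes with at least one passing hit (E-value and
#' coverage filters of the scheme) in the reference proteome.
#'
#' @param query_proteome,reference_proteome [proteome]s; the query proteome
#'   must be non-empty.
#' @param scoring A [scoring_scheme].
#' @return Percentage in `[0, 100]`.
#' @export
homolog_fraction <- function(query_proteome, reference_proteome,
                             scoring = scoring_scheme()) {
  if (length(query_proteome) == 0L)
    stop("query proteome is empty")
  hits <- best_hits(query_proteome, reference_proteome, scoring)
  100 * nrow(hits) / length(query_proteome)
}
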