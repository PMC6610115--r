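#' Curated gene-toolkit definition
#'
#' A toolkit is a curated set of marker genes (e.g. the meiosis-specific
#' detection toolkit, flagellum component genes, or plastid translocon
#' components) screened for presence or absence in a proteome. Each gene
#' carries one or more true reference sequences and optionally decoy
#' paralogs: related but non-orthologous genes (a Rad21-like mitotic
#' cohesin beside a meiotic Rec8) that a plain similarity search would
#' confuse with the target. A candidate hit is only accepted when its
#' nearest neighbour among references and decoys is a true reference.
#'
#' @param name Toolkit name.
#' @param genes Data frame with columns `gene` (unique names) and
#'   `category` (grouping tag for category count tables).
#' @param references [proteome] of reference sequences.
#' @param reference_gene Named character vector mapping reference sequence
#'   ids to gene names.
#' @param decoys Optional [proteome] of decoy sequences.
#' @param decoy_gene Named character vector mapping decoy ids to the gene
#'   they are a decoy for.
#' @return An object of class `toolkit_definition`.
#' @export
toolkit_definition <- function(name, genes, references, reference_gene,
                               decoys = NULL, decoy_gene = NULL) {
  stopifnot(is.data.frame(genes), all(c("gene", "category") %in% names(genes)),
            inherits(references, "proteome"))
  if (anyDuplicated(genes$gene))
    stop("gene names must be unique within a toolkit")
  if (!all(references$ids %in% names(reference_gene)))
    stop("every reference sequence must map to a gene")
  if (!all(reference_gene %in% genes$gene))
    stop("reference maps to unknown gene")
  if (is.null(decoys)) {
    decoys <- proteome("decoy", character(), character())
    decoy_gene <- character()
  }
  if (length(intersect(references$ids, decoys$ids)))
    stop("reference and decoy sets must be disjoint")
  genes_without_ref <- setdiff(genes$gene, reference_gene)
  if (length(genes_without_ref))
    stop("toolkit gene(s) without reference sequence: ",
         paste(genes_without_ref, collapse = ", "))
  structure(list(name = name, genes = genes, references = references,
                 reference_gene = reference_gene, decoys = decoys,
                 decoy_gene = decoy_gene),
            class = "toolkit_definition")
}

#' @export
print.toolkit_definition <- function(x, ...) {
  cat(sprintf("toolkit '%s': %d genes, %d reference and %d decoy sequences\n",
              x$name, nrow(x$genes), length(x$references), length(x$decoys)))
  invisible(x)
}

#' Read a toolkit definition from FASTA + TSV
#'
#' The TSV needs columns `seq_id`, `gene`, `category`, `is_decoy`
#' (TRUE/FALSE); the FASTA holds all reference and decoy sequences under
#' those ids.
#'
#' @param fasta_path FASTA of reference and decoy sequences.
#' @param tsv_path Tab-separated metadata.
#' @param name Toolkit name (default: TSV file stem).
#' @return A [toolkit_definition].
#' @export
read_toolkit <- function(fasta_path, tsv_path, name = NULL) {
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(tsv_path))
  meta <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("seq_id", "gene", "category", "is_decoy")
  if (!all(need %in% names(meta)))
    stop("toolkit TSV must have columns: ", paste(need, collapse = ", "))
  meta$is_decoy <- as.logical(meta$is_decoy)
  seqs <- read_fasta(fasta_path, species = paste0(name, "_toolkit"))
  missing <- setdiff(meta$seq_id, seqs$ids)
  if (length(missing))
    stop("toolkit TSV references absent sequence(s): ",
         paste(missing, collapse = ", "))
  refs <- meta[!meta$is_decoy, ]
  decs <- meta[meta$is_decoy, ]
  genes <- unique(refs[c("gene", "category")])
  toolkit_definition(
    name = name, genes = genes,
    references = proteome(paste0(name, "_ref"), refs$seq_id,
                          seqs$sequences[refs$seq_id]),
    reference_gene = stats::setNames(refs$gene, refs$seq_id),
    decoys = if (nrow(decs))
      proteome(paste0(name, "_decoy"), decs$seq_id,
               seqs$sequences[decs$seq_id]) else NULL,
    decoy_gene = if (nrow(decs))
      stats::setNames(decs$gene, decs$seq_id) else NULL)
}

#' Screen one toolkit gene against a proteome
#'
#' The candidate is the best passing hit (E-value below threshold, local
#' alignment covering at least `min_coverage` of the reference) of any of
#' the gene's reference sequences in the proteome. The gene is called
#' present only when the candidate's nearest sequence among the gene's
#' references and decoys — by Poisson-corrected global-alignment distance —
#' is a true reference; when the nearest is a decoy the gene is absent and
#' the decoy is named. A two-class nearest-neighbour decision stands in for
#' full gene-tree placement of the candidate.
#'
#' @param toolkit A [toolkit_definition].
#' @param gene Gene name within the toolkit.
#' @param target The [proteome] to screen.
#' @param scoring A [scoring_scheme].
#' @return A `presence_call`: list with `gene`, `present`, `candidate_id`
#'   (best hit id or `NA`), `nearest_label` (`"reference"`, `"decoy"` or
#'   `NA`), `nearest_id`, `evalue`.
#' @export
screen_gene <- function(toolkit, gene, target, scoring = scoring_scheme()) {
  stopifnot(inherits(toolkit, "toolkit_definition"))
  if (!gene %in% toolkit$genes$gene) stop("unknown toolkit gene: ", gene)
  absent <- structure(list(gene = gene, present = FALSE,
                           candidate_id = NA_character_,
                           nearest_label = NA_character_,
                           nearest_id = NA_character_, evalue = NA_real_),
                      class = "presence_call")
  if (length(target) == 0L) {
    warning("screening '", gene, "' against an empty proteome")
    return(absent)
  }
  ref_ids <- names(toolkit$reference_gene)[toolkit$reference_gene == gene]
  refs <- toolkit$references$sequences[ref_ids]
  # best passing candidate over all references of the gene
  best <- NULL
  n_total <- sum(nchar(target$sequences))
  for (rid in ref_ids) {
    sc <- local_scores(refs[[rid]], target$sequences, scoring)
    ord <- order(names(target$sequences))
    sc <- sc[ord]
    cand_ids <- names(target$sequences)[ord]
    j <- which.max(sc)
    ev <- estimate_evalue(sc[j], nchar(refs[[rid]]), n_total, scoring)
    if (ev >= scoring$evalue_threshold) next
    al <- local_align(refs[[rid]], target$sequences[[cand_ids[j]]], scoring)
    cov <- sum(strsplit(al$aligned_a, "")[[1]] != "-") / nchar(refs[[rid]])
    if (cov < scoring$min_coverage) next
    if (is.null(best) || sc[j] > best$score)
      best <- list(id = cand_ids[j], score = sc[j], evalue = ev)
  }
  if (is.null(best)) return(absent)
  # nearest-neighbour disambiguation among references and decoys
  dec_ids <- names(toolkit$decoy_gene)[toolkit$decoy_gene == gene]
  pool <- c(refs, toolkit$decoys$sequences[dec_ids])
  labels <- c(rep("reference", length(ref_ids)), rep("decoy", length(dec_ids)))
  cand_seq <- target$sequences[[best$id]]
  d <- vapply(pool, function(s)
    alignment_distance(cand_seq, s, scoring, correct = TRUE), numeric(1))
  k <- which.min(d)  # deterministic: first minimum in pool order
  structure(list(gene = gene, present = labels[k] == "reference",
                 candidate_id = best$id, nearest_label = labels[k],
                 nearest_id = names(pool)[k], evalue = best$evalue),
            class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat(sprintf("%s: %s", x$gene, if (x$present) "present" else "absent"))
  if (!is.na(x$candidate_id))
    cat(sprintf(" (candidate %s, nearest %s %s, E=%.3g)",
                x$candidate_id, x$nearest_label, x$nearest_id, x$evalue))
  cat("\n")
  invisible(x)
}

#' Screen a whole toolkit against a proteome
#'
#' One [screen_gene] call per toolkit gene, in toolkit order.
#'
#' @inheritParams screen_gene
#' @return A `toolkit_calls` data frame: `gene`, `category`, `present`,
#'   `candidate_id`, `nearest_label`, `nearest_id`, `evalue`.
#' @export
screen_toolkit <- function(toolkit, target, scoring = scoring_scheme()) {
  calls <- lapply(toolkit$genes$gene, function(g)
    screen_gene(toolkit, g, target, scoring))
  out <- data.frame(
    gene = vapply(calls, `[[`, "", "gene"),
    category = toolkit$genes$category,
    present = vapply(calls, `[[`, NA, "present"),
    candidate_id = vapply(calls, `[[`, "", "candidate_id"),
    nearest_label = vapply(calls, `[[`, "", "nearest_label"),
    nearest_id = vapply(calls, `[[`, "", "nearest_id"),
    evalue = vapply(calls, `[[`, 0.0, "evalue"))
  class(out) <- c("toolkit_calls", class(out))
  out
}

#' Presence/absence matrix in X/- convention
#'
#' Formats one or more toolkit screening results as the conventional
#' presence matrix: `X` for found, `-` for not found, species in rows and
#' genes in columns.
#'
#' @param calls_list Named list of `toolkit_calls` (names = species tags).
#' @return Character matrix of `"X"`/`"-"`.
#' @export
presence_matrix <- function(calls_list) {
  stopifnot(length(calls_list) >= 1L)
  genes <- calls_list[[1]]$gene
  m <- t(vapply(calls_list, function(cc) {
    stopifnot(identical(cc$gene, genes))
    ifelse(cc$present, "X", "-")
  }, character(length(genes))))
  colnames(m) <- genes
  m
}

#' Decide sexual reproduction from meiosis-toolkit calls
#'
#' A species is called capable of sexual reproduction when at least
#' `threshold` meiosis-specific toolkit genes are present (boundary
#' inclusive), else asexual. The default threshold of 6 present genes is
#' the standard rule for meiosis-toolkit screens of microalgal genomes.
#'
#' @param calls A `toolkit_calls` data frame (or logical vector of
#'   presence flags).
#' @param threshold Minimal number of present genes for a sexual verdict.
#' @return `"sexual"` or `"asexual"`.
#' @examples
#' decide_sexual_reproduction(c(rep(TRUE, 5), rep(FALSE, 3)))
#' @export
decide_sexual_reproduction <- function(calls, threshold = 6L) {
  if (threshold < 0) stop("'threshold' must be non-negative")
  present <- if (is.data.frame(calls)) calls$present else as.logical(calls)
  if (sum(present) >= threshold) "sexual" else "asexual"
}

#' Column total of a category count table
#'
#' Sums the per-category gene counts of one species in a category count
#' table (e.g. the eight flagellum-associated gene categories).
#'
#' @param count_table Data frame with a `category` column and one numeric
#'   column per species.
#' @param species Species column name.
#' @return Integer total.
#' @export
category_totals <- function(count_table, species) {
  stopifnot(is.data.frame(count_table))
  if (nrow(count_table) == 0L) return(0L)
  if (!species %in% names(count_table))
    stop("unknown species tag: ", species)
  v <- count_table[[species]]
  if (any(v < 0)) stop("category counts must be non-negative")
  as.integer(sum(v))
}

#' Ratio of two gene-category totals
#'
#' E.g. the ratio of flagellum-associated gene totals between motile and
#' nonmotile protists.
#'
#' @param total_a,total_b Totals; `total_b` must be positive.
#' @return `total_a / total_b`.
#' @examples
#' motility_ratio(104, 55)
#' @export
motility_ratio <- function(total_a, total_b) {
  if (total_b <= 0) stop("denominator total must be positive")
  total_a / total_b
}
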