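#' Draw a random root protein sequence
#'
#' Residues are i.i.d. uniform over the 20 canonical amino-acid letters.
#' Fixing `seed` makes the draw reproducible; `seed = NULL` uses the current
#' RNG state.
#'
#' @param length Non-negative sequence length (residues).
#' @param seed Optional integer seed.
#' @return A single string of `length` residues.
#' @examples
#' sample_root_sequence(10, seed = 1)
#' @export
sample_root_sequence <- function(length, seed = NULL) {
  if (length < 0) stop("'length' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (length == 0) return("")
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

#' Evolve a protein sequence along a branch
#'
#' 20-state Jukes-Cantor-type substitution process: substitution events
#' arrive independently at each site as a Poisson process with rate 1 per
#' unit branch length (so the expected number of substitutions per site
#' equals `branch_length`), and each event replaces the current residue by
#' one drawn uniformly from the other 19 letters. `X` residues are inert.
#' Sequence length is preserved; there are no indels.
#'
#' @param sequence Input protein sequence.
#' @param branch_length Expected substitutions per site (>= 0).
#' @param seed Optional integer seed.
#' @return The evolved sequence (same length).
#' @examples
#' evolve_sequence("ACDEACDE", 0.5, seed = 1)
#' @export
evolve_sequence <- function(sequence, branch_length, seed = NULL) {
  if (branch_length < 0) stop("'branch_length' must be non-negative")
  sequence <- check_sequence(sequence)
  if (!is.null(seed)) set.seed(seed)
  if (nchar(sequence) == 0L || branch_length == 0) return(sequence)
  res <- strsplit(sequence, "")[[1]]
  mutable <- res != "X"
  n_events <- stats::rpois(length(res), branch_length)
  n_events[!mutable] <- 0L
  while (any(n_events > 0L)) {
    i <- which(n_events > 0L)
    for (j in i) {
      others <- AA20[AA20 != res[j]]
      res[j] <- others[sample.int(19L, 1L)]
    }
    n_events[i] <- n_events[i] - 1L
  }
  paste(res, collapse = "")
}

#' Expected p-distance under the 20-state uniform model
#'
#' Closed form for the probability that two homologous sites differ after a
#' total path length `t` (sum of the branch lengths separating the two
#' sequences): `(19/20) * (1 - exp(-20 t / 19))`. Saturates at 19/20 as
#' `t` grows.
#'
#' @param total_path_length Total expected substitutions per site along the
#'   path joining the two sequences (>= 0).
#' @return Expected fraction of differing sites, in `[0, 19/20)`.
#' @examples
#' expected_p_distance(0.2)
#' @export
expected_p_distance <- function(total_path_length) {
  if (any(total_path_length < 0)) stop("path length must be non-negative")
  (19 / 20) * (1 - exp(-20 * total_path_length / 19))
}

#' Simulation configuration
#'
#' Parameters of the synthetic three-species dataset: a focal species `N`,
#' a host-lineage reference `A` and a symbiont-lineage reference `P`.
#' Shared gene families evolve along one of the three rooted triplet
#' topologies, named by the sister pair: `"NA"` (focal sister to the host
#' reference, the host-origin pattern), `"NP"` (focal sister to the
#' symbiont reference) and `"AP"` (the two references sister, focal
#' outgroup). Sister taxa diverge from each other only after the internal
#' branch, so at default branch lengths the sister pair is separated by
#' `2 * terminal_branch` while either sister and the outgroup are separated
#' by `2 * terminal_branch + 2 * internal_branch`.
#'
#' Family counts per topology are allocated deterministically from
#' `topology_proportions` by largest remainder, so the realised counts are
#' exact, not multinomial draws.
#'
#' @param n_families Number of shared single-copy families.
#' @param topology_proportions Named or unnamed numeric vector of three
#'   non-negative fractions (order `NA`, `NP`, `AP`) summing to 1
#'   (tolerance 1e-9).
#' @param n_unique Genes with no homolog elsewhere, per species; a single
#'   count recycled to the three species or a vector of three (order N, A,
#'   P).
#' @param n_multicopy Shared families carrying a within-focal-species
#'   duplicate.
#' @param duplication_distance Branch length separating the focal duplicate
#'   from its template. The default 0.5 is a clearly diverged but still
#'   readily detectable paralog; push it towards saturation to stress the
#'   search stage.
#' @param terminal_branch,internal_branch Branch lengths (expected
#'   substitutions per site) of the triplet topologies.
#' @param sequence_length Protein length (residues) of every simulated gene.
#' @param master_seed Integer master seed; per-family seeds are derived from
#'   it by a counter scheme (see [simulate_dataset]).
#' @param toolkit_spec Optional toolkit plan: a data frame with columns
#'   `gene`, `present` (logical) and `decoy_distance` (see
#'   [simulate_toolkit]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 100L,
                       topology_proportions = c("NA" = 0.26, "NP" = 0.26,
                                                "AP" = 0.48),
                       n_unique = 0L, n_multicopy = 0L,
                       duplication_distance = 0.5,
                       terminal_branch = 0.3, internal_branch = 0.3,
                       sequence_length = 300L, master_seed = 20190703L,
                       toolkit_spec = NULL) {
  p <- as.numeric(topology_proportions)
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("topology_proportions must be 3 non-negative fractions summing to 1")
  n_unique <- rep_len(as.integer(n_unique), 3L)
  if (n_families < 0 || any(n_unique < 0) || n_multicopy < 0)
    stop("counts must be non-negative")
  if (terminal_branch < 0 || internal_branch < 0 || duplication_distance < 0)
    stop("branch lengths must be non-negative")
  if (sequence_length < 1) stop("sequence_length must be positive")
  master_seed <- as.integer(master_seed)
  if (is.na(master_seed)) stop("master_seed must be an integer")
  if (!is.null(toolkit_spec)) {
    stopifnot(is.data.frame(toolkit_spec),
              all(c("gene", "present", "decoy_distance") %in%
                    names(toolkit_spec)))
  }
  structure(list(n_families = as.integer(n_families),
                 topology_proportions = stats::setNames(p, c("NA", "NP", "AP")),
                 n_unique = stats::setNames(n_unique, c("N", "A", "P")),
                 n_multicopy = as.integer(n_multicopy),
                 duplication_distance = duplication_distance,
                 terminal_branch = terminal_branch,
                 internal_branch = internal_branch,
                 sequence_length = as.integer(sequence_length),
                 master_seed = master_seed,
                 toolkit_spec = toolkit_spec),
            class = "sim_config")
}

# Deterministic largest-remainder apportionment of n into round(n * p).
largest_remainder <- function(n, p) {
  quota <- n * p
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    # ties broken by category order, deterministically
    ord <- order(-(quota - base), seq_along(p))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# counter scheme: unit k (family, unique gene, duplicate or toolkit gene)
# uses seed (master_seed + k) mod (2^31 - 1)
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) + counter) %% 2147483647)
}

#' Simulate a three-species proteome dataset with known gene histories
#'
#' For each shared family a root sequence is drawn and evolved along the
#' family's triplet topology: the outgroup lineage branches at the root
#' (terminal + internal branch), the two sister lineages share the internal
#' branch before splitting into their terminal branches. Unique genes are
#' fresh random sequences with no homolog; multi-copy families are `AP`-like
#' shared families whose focal gene gains a within-species duplicate at
#' `duplication_distance`. Every record id appears in exactly one truth
#' entry. Per-family seeds are derived from the master seed by a counter,
#' so a fixed configuration reproduces byte-identical proteomes while
#' changing only `master_seed` changes sequences but no label counts.
#'
#' @param config A [sim_config].
#' @return A list with `proteomes` (named list of three [proteome]s:
#'   `N`, `A`, `P`), `truth` (data frame: `family_id`, `label` in
#'   `{NA, NP, AP, UNIQUE, MULTI}`, `species`, `member_id`, one row per
#'   record) and `config`.
#' @examples
#' d <- simulate_dataset(sim_config(n_families = 5, sequence_length = 60))
#' table(unique(d$truth[c("family_id", "label")])$label)
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  counts <- largest_remainder(config$n_families, config$topology_proportions)
  labels <- rep(c("NA", "NP", "AP"), counts)
  L <- config$sequence_length
  tb <- config$terminal_branch
  ib <- config$internal_branch
  counter <- 0L
  rows <- list()
  seqs <- list(N = character(), A = character(), P = character())

  evolve_triplet <- function(label) {
    root <- sample_root_sequence(L)
    # outgroup hangs off the root; sisters share the internal branch
    anc_sisters <- evolve_sequence(root, ib)
    out <- evolve_sequence(root, tb + ib)
    s1 <- evolve_sequence(anc_sisters, tb)
    s2 <- evolve_sequence(anc_sisters, tb)
    switch(label,
           "NA" = list(N = s1, A = s2, P = out),
           "NP" = list(N = s1, P = s2, A = out),
           "AP" = list(A = s1, P = s2, N = out))
  }

  for (i in seq_along(labels)) {
    counter <- counter + 1L
    set.seed(derive_seed(config$master_seed, counter))
    fam <- sprintf("fam%04d", i)
    trip <- evolve_triplet(labels[i])
    for (sp in c("N", "A", "P")) {
      id <- sprintf("%s_%s", fam, sp)
      seqs[[sp]][id] <- trip[[sp]]
      rows[[length(rows) + 1L]] <-
        data.frame(family_id = fam, label = labels[i], species = sp,
                   member_id = id)
    }
  }

  # multi-copy families: AP-like shared family plus a focal duplicate
  for (j in seq_len(config$n_multicopy)) {
    counter <- counter + 1L
    set.seed(derive_seed(config$master_seed, counter))
    fam <- sprintf("multi%03d", j)
    trip <- evolve_triplet("AP")
    dup <- evolve_sequence(trip$N, config$duplication_distance)
    members <- list(N = c(trip$N, dup), A = trip$A, P = trip$P)
    for (sp in c("N", "A", "P")) {
      for (k in seq_along(members[[sp]])) {
        id <- sprintf("%s_%s%s", fam, sp, if (k > 1) paste0(".", k) else "")
        seqs[[sp]][id] <- members[[sp]][k]
        rows[[length(rows) + 1L]] <-
          data.frame(family_id = fam, label = "MULTI", species = sp,
                     member_id = id)
      }
    }
  }

  # unique genes: unrelated random sequences
  for (sp in c("N", "A", "P")) {
    for (j in seq_len(config$n_unique[[sp]])) {
      counter <- counter + 1L
      set.seed(derive_seed(config$master_seed, counter))
      fam <- sprintf("uniq_%s%03d", sp, j)
      id <- paste0(fam, "_g")
      seqs[[sp]][id] <- sample_root_sequence(L)
      rows[[length(rows) + 1L]] <-
        data.frame(family_id = fam, label = "UNIQUE", species = sp,
                   member_id = id)
    }
  }

  truth <- do.call(rbind, rows)
  proteomes <- lapply(stats::setNames(c("N", "A", "P"), c("N", "A", "P")),
                      function(sp)
                        proteome(sp, names(seqs[[sp]]), unname(seqs[[sp]])))
  list(proteomes = proteomes, truth = truth, config = config)
}

#' Simulate a toolkit definition plus a proteome to screen
#'
#' Builds, for each planned gene, a reference sequence and (when
#' `decoy_distance` is a positive finite number) a decoy paralog diverged
#' from it by `decoy_distance`. The screened proteome carries a moderately
#' diverged copy (`carrier_distance`) of the reference when the gene is
#' planted present. When it is planted absent: with a decoy, the proteome
#' carries a decoy-derived copy instead — the situation where a related
#' but non-orthologous gene (a Rad21-like cohesin next to a missing Rec8)
#' would fool a plain similarity search; without a decoy, the gene has no
#' homolog in the proteome at all.
#'
#' @param plan Data frame with columns `gene`, `present` (logical),
#'   `decoy_distance` (numeric; `NA` or 0 means no decoy) and optionally
#'   `category`.
#' @param sequence_length Residues per simulated gene.
#' @param carrier_distance Branch length between the planted proteome copy
#'   and its template (default 0.1).
#' @param master_seed Integer seed.
#' @param species Species tag of the screened proteome.
#' @return A list with `toolkit` (a [toolkit_definition]) and `proteome`
#'   (the [proteome] to screen), plus `plan`.
#' @export
simulate_toolkit <- function(plan, sequence_length = 300L,
                             carrier_distance = 0.1,
                             master_seed = 20190703L, species = "N") {
  stopifnot(is.data.frame(plan),
            all(c("gene", "present", "decoy_distance") %in% names(plan)))
  if (is.null(plan$category)) plan$category <- "default"
  refs <- character(); decoys <- character()
  decoy_gene <- character(); carried <- character()
  for (i in seq_len(nrow(plan))) {
    set.seed(derive_seed(master_seed, 100000L + i))
    ref <- sample_root_sequence(sequence_length)
    refs[paste0(plan$gene[i], "_ref")] <- ref
    has_decoy <- is.finite(plan$decoy_distance[i]) &&
      plan$decoy_distance[i] > 0
    dec <- NULL
    if (has_decoy) {
      dec <- evolve_sequence(ref, plan$decoy_distance[i])
      decoys[paste0(plan$gene[i], "_decoy")] <- dec
      decoy_gene[paste0(plan$gene[i], "_decoy")] <- plan$gene[i]
    }
    if (plan$present[i]) {
      carried[paste0("cand_", plan$gene[i])] <-
        evolve_sequence(ref, carrier_distance)
    } else if (has_decoy) {
      carried[paste0("cand_", plan$gene[i])] <-
        evolve_sequence(dec, carrier_distance)
    }  # absent without decoy: no homolog planted
  }
  genes <- data.frame(gene = plan$gene, category = plan$category)
  tk <- toolkit_definition(
    name = "simulated",
    genes = genes,
    references = proteome("toolkit_ref", names(refs), unname(refs)),
    reference_gene = stats::setNames(plan$gene, names(refs)),
    decoys = if (length(decoys))
      proteome("toolkit_decoy", names(decoys), unname(decoys)) else NULL,
    decoy_gene = if (length(decoys)) decoy_gene else NULL)
  list(toolkit = tk,
       proteome = proteome(species, names(carried), unname(carried)),
       plan = plan)
}

#' Orthogroups from a simulation truth table
#'
#' Converts the generator's ground-truth family memberships into an
#' orthogroups table of the same shape [build_orthogroups] produces, with
#' one group per simulated family. This bypasses the similarity-search
#' stage entirely: use it to study the triplet classifier in isolation
#' from search error, or to scale classifier experiments past the point
#' where all-vs-all search is worth its cost.
#'
#' @param truth Truth data frame from [simulate_dataset].
#' @return An `orthogroups` data frame (`group_id`, `species`,
#'   `member_id`, `single_copy`, `multi_copy`).
#' @export
truth_orthogroups <- function(truth) {
  stopifnot(all(c("family_id", "label", "species", "member_id") %in%
                  names(truth)))
  df <- data.frame(group_id = truth$family_id, species = truth$species,
                   member_id = truth$member_id)
  per <- table(df$group_id, factor(df$species, levels = c("N", "A", "P")))
  multi <- rownames(per)[apply(per > 1, 1, any)]
  single <- rownames(per)[apply(per == 1, 1, all)]
  df$multi_copy <- df$group_id %in% multi
  df$single_copy <- df$group_id %in% single
  class(df) <- c("orthogroups", class(df))
  df
}
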