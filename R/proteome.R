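# Canonical amino-acid alphabet; 'X' is tolerated as an unknown residue.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET21 <- c(AA20, "X")

#' Construct a proteome
#'
#' A proteome is the complete set of identified protein sequences of one
#' species, tagged with a short species label. Sequences are plain upper-case
#' strings over the 20 canonical amino-acid letters plus `X` (unknown
#' residue). Record ids must be unique within a proteome.
#'
#' @param species Single species tag (non-empty string).
#' @param ids Character vector of record ids; non-empty tokens without
#'   whitespace, unique within the proteome.
#' @param sequences Character vector of amino-acid sequences, same length as
#'   `ids`.
#' @param descriptions Optional character vector of header descriptions
#'   (retained but unused by the pipeline).
#' @return An object of class `proteome`: a list with elements `species`,
#'   `ids`, `sequences` (named by id) and `descriptions`.
#' @examples
#' p <- proteome("noc", c("g1", "g2"), c("ACDE", "MKV"))
#' length(p)
#' @export
proteome <- function(species, ids, sequences, descriptions = NULL) {
  if (!is.character(species) || length(species) != 1L || !nzchar(species))
    stop("'species' must be a single non-empty string")
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("'ids' and 'sequences' must have the same length")
  if (any(!nzchar(ids)) || any(grepl("\\s", ids)))
    stop("record ids must be non-empty and contain no whitespace")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET21, collapse = "")), sequences)
  if (any(bad))
    stop("illegal character(s) in sequence of record(s): ",
         paste(ids[bad], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  names(sequences) <- ids
  structure(list(species = species, ids = ids, sequences = sequences,
                 descriptions = descriptions),
            class = "proteome")
}

#' @export
length.proteome <- function(x) length(x$ids)

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("proteome '%s': %d records", x$species, length(x)), "\n")
  if (length(x)) {
    show <- utils::head(x$ids, 5L)
    cat("  ids:", paste(show, collapse = ", "),
        if (length(x) > 5L) "..." else "", "\n")
  }
  invisible(x)
}

#' Read a proteome from a FASTA file
#'
#' The record id is the first whitespace-delimited token of each header; the
#' remainder of the header is kept as a description. Sequences are
#' upper-cased. Trailing `*` (stop codon artifact) is stripped; an internal
#' `*`, or any character outside the 20 canonical letters plus `X`, is an
#' error naming the offending record. The species tag is supplied by the
#' caller, never parsed from headers, because header conventions vary across
#' proteome releases.
#'
#' @param path Path to a FASTA file.
#' @param species Species tag to attach to every record.
#' @return A [proteome].
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 some protein", "ACDE"), f)
#' read_fasta(f, "noc")
#' @export
read_fasta <- function(path, species) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(proteome(species, character(), character()))
  }
  headers <- names(set)
  if (any(!nzchar(trimws(headers))))
    stop("malformed FASTA header (empty) in ", path)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)  # tolerate trailing stop
  if (any(grepl("*", seqs, fixed = TRUE))) {
    bad <- ids[grepl("*", seqs, fixed = TRUE)]
    stop("internal stop codon '*' in record(s): ", paste(bad, collapse = ", "))
  }
  proteome(species, ids, seqs, desc)
}

#' Write a proteome to a FASTA file
#'
#' Output is 60-column wrapped and byte-deterministic for a fixed proteome:
#' writing the same proteome twice yields identical files.
#'
#' @param x A [proteome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "proteome"))
  headers <- ifelse(nzchar(x$descriptions),
                    paste(x$ids, x$descriptions), x$ids)
  set <- Biostrings::BStringSet(unname(x$sequences))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# internal: fetch sequences by id across a list of proteomes
proteome_lookup <- function(proteomes) {
  seqs <- unlist(unname(lapply(proteomes, function(p) p$sequences)))
  species <- unlist(unname(lapply(proteomes, function(p)
    stats::setNames(rep(p$species, length(p)), p$ids))))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("record id(s) shared across proteomes: ",
         paste(unique(dup), collapse = ", "))
  list(sequences = seqs, species = species)
}
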