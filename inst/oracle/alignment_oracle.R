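# Independent exhaustive-alignment oracle and small data generators.
#
# The oracle scores alignments by recursion over the space of all monotone
# alignment paths (match / insert / delete columns), with the affine gap
# convention of the package: a k-length gap costs gap_open + (k-1) *
# gap_extend. Memoisation collapses shared suffixes, so the recursion is
# exhaustive over alignments while staying fast at the tiny lengths it is
# used for. It shares no code with the alignment engine under test.

oracle_global <- function(a, b, scoring) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  m <- scoring$substitution_matrix
  op <- scoring$gap_open; ex <- scoring$gap_extend
  memo <- array(NA_real_, dim = c(la + 1L, lb + 1L, 3L))
  # state: 1 = last column was match/start, 2 = in gap of a, 3 = in gap of b
  rec <- function(i, j, s) {
    if (i > la && j > lb) return(0)
    if (!is.na(memo[i, j, s])) return(memo[i, j, s])
    best <- -Inf
    if (i <= la && j <= lb)
      best <- max(best, m[av[i], bv[j]] + rec(i + 1L, j + 1L, 1L))
    if (j <= lb)
      best <- max(best, -(if (s == 2L) ex else op) + rec(i, j + 1L, 2L))
    if (i <= la)
      best <- max(best, -(if (s == 3L) ex else op) + rec(i + 1L, j, 3L))
    memo[i, j, s] <<- best
    best
  }
  rec(1L, 1L, 1L)
}

oracle_local <- function(a, b, scoring) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  m <- scoring$substitution_matrix
  op <- scoring$gap_open; ex <- scoring$gap_extend
  memo <- array(NA_real_, dim = c(la + 1L, lb + 1L, 3L))
  # best score of any alignment extension starting at (i, j); may stop
  # anywhere (the 0 branch), so every local alignment is enumerated
  rec <- function(i, j, s) {
    if (!is.na(memo[i, j, s])) return(memo[i, j, s])
    best <- 0
    if (i <= la && j <= lb)
      best <- max(best, m[av[i], bv[j]] + rec(i + 1L, j + 1L, 1L))
    if (j <= lb)
      best <- max(best, -(if (s == 2L) ex else op) + rec(i, j + 1L, 2L))
    if (i <= la)
      best <- max(best, -(if (s == 3L) ex else op) + rec(i + 1L, j, 3L))
    memo[i, j, s] <<- best
    best
  }
  best <- 0
  for (i in seq_len(la + 1L))
    for (j in seq_len(lb + 1L))
      best <- max(best, rec(i, j, 1L))
  best
}

# random sequences over an arbitrary alphabet
random_seqs <- function(n, min_len, max_len, alphabet = c("A", "C", "D")) {
  vapply(seq_len(n), function(i) {
    L <- sample(min_len:max_len, 1L)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, "")
}

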