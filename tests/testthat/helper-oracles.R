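# Independent alignment oracles used to check the package's aligners.
# Affine convention throughout: a gap of length L costs gap_open + L * gap_ext.

oracle_subst <- function(x, y, sc) {
  if (x %in% c("A", "C", "G", "T") && x == y) sc$match else sc$mismatch
}

# exhaustive affine Needleman-Wunsch score (three-state DP, score only)
oracle_nw_score <- function(a, b, sc = scoring_params()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  go <- -(sc$gap_open + sc$gap_ext); ge <- -sc$gap_ext
  M <- matrix(-Inf, n + 1, m + 1); E <- M; F <- M
  M[1, 1] <- 0
  for (j in seq_len(m)) E[1, j + 1] <- -(sc$gap_open + sc$gap_ext * j)
  for (i in seq_len(n)) F[i + 1, 1] <- -(sc$gap_open + sc$gap_ext * i)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- oracle_subst(av[i], bv[j], sc)
    M[i + 1, j + 1] <- max(M[i, j], E[i, j], F[i, j]) + s
    E[i + 1, j + 1] <- max(M[i + 1, j] + go, E[i + 1, j] + ge, F[i + 1, j] + go)
    F[i + 1, j + 1] <- max(M[i, j + 1] + go, F[i, j + 1] + ge, E[i, j + 1] + go)
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

# exhaustive affine Smith-Waterman: best local score and its coordinates
oracle_sw <- function(a, b, sc = scoring_params()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  go <- -(sc$gap_open + sc$gap_ext); ge <- -sc$gap_ext
  M <- matrix(0, n + 1, m + 1); E <- matrix(-Inf, n + 1, m + 1); F <- E
  best <- 0; bi <- NA; bj <- NA
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- oracle_subst(av[i], bv[j], sc)
    M[i + 1, j + 1] <- max(0, M[i, j] + s, E[i, j] + s, F[i, j] + s)
    E[i + 1, j + 1] <- max(M[i + 1, j] + go, E[i + 1, j] + ge, F[i + 1, j] + go)
    F[i + 1, j + 1] <- max(M[i, j + 1] + go, F[i, j + 1] + ge, E[i, j + 1] + go)
    if (M[i + 1, j + 1] > best) { best <- M[i + 1, j + 1]; bi <- i; bj <- j }
  }
  list(score = best, a_end = bi, b_end = bj)
}

# score an alignment returned as two gapped strings, affine convention
rescore_alignment <- function(al, sc = scoring_params()) {
  a <- strsplit(al$aligned_a, "")[[1]]; b <- strsplit(al$aligned_b, "")[[1]]
  s <- 0; in_ga <- FALSE; in_gb <- FALSE
  for (i in seq_along(a)) {
    if (a[i] == "-") {
      s <- s - if (in_ga) sc$gap_ext else sc$gap_open + sc$gap_ext
      in_ga <- TRUE; in_gb <- FALSE
    } else if (b[i] == "-") {
      s <- s - if (in_gb) sc$gap_ext else sc$gap_open + sc$gap_ext
      in_gb <- TRUE; in_ga <- FALSE
    } else {
      s <- s + oracle_subst(a[i], b[i], sc)
      in_ga <- FALSE; in_gb <- FALSE
    }
  }
  s
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

# fraction of differing positions between equal-length strings
hamming_frac <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# small shared simulation for mapper tests: one reference chromosome with a
# known implanted element
make_tiny_case <- function(seed = 11, chrom_len = 60000L, elem_len = 1500L,
                           tir_len = 30L) {
  set.seed(seed)
  lib <- make_synthetic_library(n_families = 1, lengths = elem_len,
                                tir_lengths = tir_len, seed = seed + 1)
  ref <- setNames(random_dna(chrom_len), "chr1")
  list(lib = lib, ref = ref)
}
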