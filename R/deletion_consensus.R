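#' Global (Needleman-Wunsch) alignment of two sequences
#'
#' Affine-gap global alignment (gap of length L costs
#' `gap_open + L * gap_ext`), exposed from the package's compiled core.
#'
#' @param a,b Sequences (character scalars).
#' @param scoring [scoring_params()].
#' @return List with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length) and `score`.
#' @export
nw_align <- function(a, b, scoring = scoring_params()) {
  r <- nw_align_cpp(clean_dna(a), clean_dna(b), scoring$match,
                    scoring$mismatch, scoring$gap_open, scoring$gap_ext)
  r
}

#' Left-normalize a deletion interval
#'
#' A deletion of repeated sequence has several equivalent representations
#' (the same phenomenon behind the slightly different KP breakpoints
#' reported across studies). This shifts the interval leftwards while the
#' base before the gap equals the last deleted base, yielding a canonical
#' representation for comparisons.
#'
#' @param canonical Canonical element sequence.
#' @param interval Integer vector `c(start, end)` (1-based closed).
#' @return Normalized `c(start, end)`.
#' @export
normalize_deletion <- function(canonical, interval) {
  s <- interval[1]; e <- interval[2]
  v <- strsplit(canonical, "")[[1]]
  while (s > 1L && v[s - 1L] == v[e]) {
    s <- s - 1L; e <- e - 1L
  }
  c(s, e)
}

# internal deletions (canonical-coordinate gap runs >= min_gap, strictly
# inside the element) and match blocks from a canonical-vs-copy global
# alignment
alignment_gaps <- function(canonical, copy, scoring, min_gap = 20L) {
  al <- nw_align(canonical, copy, scoring)
  ca <- strsplit(al$aligned_a, "")[[1]]
  cb <- strsplit(al$aligned_b, "")[[1]]
  can_pos <- cumsum(ca != "-")           # canonical coordinate per column
  gap_in_copy <- cb == "-" & ca != "-"
  r <- rle(gap_in_copy)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dels <- list()
  L <- nchar(canonical)
  for (k in which(r$values)) {
    cs <- can_pos[starts[k]]; ce <- can_pos[ends[k]]
    if (ce - cs + 1L < min_gap) next
    if (cs <= 1L || ce >= L) next       # terminal truncation, not a deletion
    nd <- normalize_deletion(canonical, c(cs, ce))
    dels[[length(dels) + 1L]] <- nd
  }
  dels <- if (length(dels)) {
    do.call(rbind, lapply(dels, function(d) data.frame(start = d[1], end = d[2])))
  } else data.frame(start = integer(0), end = integer(0))
  # aligned blocks: maximal canonical intervals where the copy is present
  present <- cb != "-" & ca != "-"
  rb <- rle(present)
  be <- cumsum(rb$lengths); bs <- be - rb$lengths + 1L
  blocks <- do.call(rbind, lapply(which(rb$values), function(k) {
    data.frame(canonical_start = can_pos[bs[k]], canonical_end = can_pos[be[k]])
  })) %||% data.frame(canonical_start = integer(0), canonical_end = integer(0))
  list(deletions = dels, blocks = blocks, alignment = al)
}

#' Extract element copies from contigs
#'
#' Locates all copies of a canonical element in a contig set by chaining
#' collinear local alignments (an internally deleted copy produces two
#' chained blocks separated by a canonical-coordinate gap), extracts the
#' copy sequence, and refines block and deletion coordinates with a global
#' alignment of the copy against the canonical. Gaps in the canonical
#' coordinate chain of at least `min_gap` nt are recorded as internal
#' deletions (left-normalized); copies shorter than `min_complete` are
#' flagged incomplete and conventionally excluded from consensus building.
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param canonical Canonical element sequence (character scalar).
#' @param element_name Element family label carried on each copy.
#' @param scoring [scoring_params()].
#' @param min_gap Minimum internal deletion length (nt).
#' @param min_complete Completeness threshold (nt; default 800).
#' @param block_min_score Minimum local-alignment score for a block.
#' @param max_join_gap Maximum contig-coordinate gap when chaining blocks.
#' @return List of `element_copy` objects: `element_name`, `contig_id`,
#'   `contig_start`, `contig_end`, `strand`, `copy_sequence`, `blocks`,
#'   `deletions`, `complete`, `canonical_length`.
#' @export
extract_element_copies <- function(contigs, canonical, element_name = "element",
                                   scoring = scoring_params(), min_gap = 20L,
                                   min_complete = 800L, block_min_score = 300,
                                   max_join_gap = 1000L) {
  contigs <- as_genome(contigs)
  canonical <- clean_dna(canonical)
  hits <- align_query(canonical, contigs, scoring, min_score = block_min_score)
  copies <- list()
  if (!nrow(hits)) return(copies)
  # recover canonical coordinates of each block (minus-strand hits report
  # coordinates of the reverse-complemented query)
  qlen <- nchar(canonical)
  # re-derive query coords by re-aligning each hit region; cheaper: align_query
  # does not return them, so compute from a windowed alignment
  hits$q_start <- NA_integer_; hits$q_end <- NA_integer_
  for (i in seq_len(nrow(hits))) {
    q <- if (hits$strand[i] == "+") canonical else revcomp(canonical)
    sub <- substr(contigs[[hits$contig_id[i]]], hits$start[i], hits$end[i])
    pa <- sw_local(q, sub, scoring)
    h <- pa_hit(pa, qlen)
    if (hits$strand[i] == "+") {
      hits$q_start[i] <- h$q_start; hits$q_end[i] <- h$q_end
    } else {
      hits$q_start[i] <- qlen - h$q_end + 1L
      hits$q_end[i] <- qlen - h$q_start + 1L
    }
  }
  grp <- split(seq_len(nrow(hits)), paste(hits$contig_id, hits$strand))
  for (idx in grp) {
    h <- hits[idx, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    # chain blocks left to right along the contig; a chain breaks when
    # blocks are far apart on the contig or canonical order regresses
    chain_id <- integer(nrow(h))
    cur <- 1L
    chain_id[1] <- cur
    for (i in seq_len(nrow(h))[-1]) {
      fwd <- if (h$strand[i] == "+") h$q_start[i] >= h$q_start[i - 1L] - 30L
             else h$q_start[i] <= h$q_start[i - 1L] + 30L
      near <- h$start[i] - h$end[i - 1L] <= max_join_gap
      if (!(fwd && near)) cur <- cur + 1L
      chain_id[i] <- cur
    }
    for (ci in unique(chain_id)) {
      b <- h[chain_id == ci, , drop = FALSE]
      cs <- min(b$start); ce <- max(b$end)
      copy_seq <- substr(contigs[[b$contig_id[1]]], cs, ce)
      if (b$strand[1] == "-") copy_seq <- revcomp(copy_seq)
      ref <- alignment_gaps(canonical, copy_seq, scoring, min_gap)
      copies[[length(copies) + 1L]] <- structure(list(
        element_name = element_name,
        contig_id = b$contig_id[1],
        contig_start = cs, contig_end = ce, strand = b$strand[1],
        copy_sequence = copy_seq,
        blocks = ref$blocks,
        deletions = ref$deletions,
        complete = nchar(copy_seq) >= min_complete,
        canonical_length = qlen), class = "element_copy")
    }
  }
  copies
}

#' Report the largest internal deletion of an element copy
#'
#' @param copy An `element_copy`.
#' @return List with `interval` (the largest internal deletion as
#'   `c(start, end)` in canonical coordinates, or `NULL`) and
#'   `remaining_length` (canonical length minus the summed deletion
#'   lengths).
#' @export
detect_internal_deletion <- function(copy) {
  d <- copy$deletions
  if (!nrow(d)) {
    return(list(interval = NULL, remaining_length = copy$canonical_length))
  }
  lens <- d$end - d$start + 1L
  list(interval = c(d$start[which.max(lens)], d$end[which.max(lens)]),
       remaining_length = copy$canonical_length - sum(lens))
}

msa_sequences <- function(copies) {
  if (is.character(copies)) {
    seqs <- copies
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    return(seqs)
  }
  keep <- vapply(copies, function(cp) isTRUE(cp$complete), logical(1))
  seqs <- vapply(copies[keep], function(cp) cp$copy_sequence, character(1))
  names(seqs) <- vapply(copies[keep], function(cp)
    paste0(cp$contig_id, ":", cp$contig_start, "-", cp$contig_end), character(1))
  seqs
}

pdist_aligned <- function(al) {
  a <- strsplit(al$aligned_a, "")[[1]]
  b <- strsplit(al$aligned_b, "")[[1]]
  mean(a != b)
}

#' Progressive multiple alignment of element copies
#'
#' Aligns the closest pair first (full pairwise distances from global
#' alignments), then adds the remaining sequences nearest-first, each
#' aligned against the growing profile (count-weighted mean column
#' scores). For two sequences this reduces exactly to the global pairwise
#' alignment.
#'
#' @param copies Character vector of sequences, or a list of
#'   `element_copy` objects (incomplete copies are excluded).
#' @param scoring [scoring_params()].
#' @return Object of class `msa`: named character vector of equal-length
#'   gapped rows; degapping any row recovers its input sequence.
#' @export
build_msa <- function(copies, scoring = scoring_params()) {
  seqs <- msa_sequences(copies)
  n <- length(seqs)
  if (n < 2L) stop("insufficient copies: need >= 2 usable sequences")
  seqs <- vapply(seqs, clean_dna, character(1))
  if (n == 2L) {
    al <- nw_align(seqs[[1]], seqs[[2]], scoring)
    out <- c(al$aligned_a, al$aligned_b)
    names(out) <- names(seqs)
    return(structure(out, class = "msa"))
  }
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- pdist_aligned(nw_align(seqs[[i]], seqs[[j]], scoring))
  }
  start <- which(D == min(D[upper.tri(D)]), arr.ind = TRUE)[1, ]
  order_in <- as.integer(start)
  remaining <- setdiff(seq_len(n), order_in)
  while (length(remaining)) {
    mean_d <- vapply(remaining, function(r) mean(D[r, order_in]), numeric(1))
    nxt <- remaining[which.min(mean_d)]
    order_in <- c(order_in, nxt)
    remaining <- setdiff(remaining, nxt)
  }

  al <- nw_align(seqs[[order_in[1]]], seqs[[order_in[2]]], scoring)
  rows <- c(al$aligned_a, al$aligned_b)
  for (k in order_in[-(1:2)]) {
    prof <- msa_profile(rows)
    pr <- profile_align_cpp(prof, seqs[[k]], scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_ext)
    ops <- strsplit(pr$ops, "")[[1]]
    rows <- apply_profile_ops(rows, seqs[[k]], ops)
  }
  names(rows) <- names(seqs)[order_in]
  structure(rows[match(names(seqs), names(rows))], class = "msa")
}

msa_profile <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  prof <- matrix(0L, 5L, ncol(m),
                 dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (b in c("A", "C", "G", "T", "-")) prof[b, ] <- colSums(m == b)
  prof
}

apply_profile_ops <- function(rows, seq, ops) {
  sv <- strsplit(seq, "")[[1]]
  old <- strsplit(rows, "")
  width <- length(ops)
  new_rows <- matrix("-", length(rows) + 1L, width)
  ci <- 0L; si <- 0L
  for (w in seq_along(ops)) {
    op <- ops[w]
    if (op == "M") {
      ci <- ci + 1L; si <- si + 1L
      for (r in seq_along(old)) new_rows[r, w] <- old[[r]][ci]
      new_rows[length(rows) + 1L, w] <- sv[si]
    } else if (op == "D") {
      ci <- ci + 1L
      for (r in seq_along(old)) new_rows[r, w] <- old[[r]][ci]
    } else {                        # 'I': new column, only the new sequence
      si <- si + 1L
      new_rows[length(rows) + 1L, w] <- sv[si]
    }
  }
  out <- apply(new_rows, 1L, paste, collapse = "")
  names(out) <- c(names(rows), "")
  out
}

#' Plurality consensus from a multiple alignment
#'
#' Per column, the most frequent residue is emitted when its fraction of
#' all rows reaches `plurality_fraction`, otherwise `N`; columns where
#' gaps hold the majority are dropped. When a canonical sequence is
#' supplied, the consensus is globally aligned back to it and the largest
#' internal gap reported as the consensus deletion interval
#' (left-normalized).
#'
#' @param msa An [build_msa()] result (or any character vector of
#'   equal-length gapped rows).
#' @param plurality_fraction Minimum residue fraction (of all rows,
#'   gaps included) for a base call.
#' @param canonical Optional canonical sequence for deletion inference.
#' @param scoring [scoring_params()].
#' @param min_gap Minimum deletion length (nt).
#' @param element_name Label for the result.
#' @return `consensus_result` list: `element_name`, `consensus_sequence`,
#'   `length_bp`, `deletion_interval` (or `NULL`), `n_copies_used`.
#' @export
consensus_from_msa <- function(msa, plurality_fraction = 0.5,
                               canonical = NULL, scoring = scoring_params(),
                               min_gap = 20L, element_name = "element") {
  rows <- as.character(msa)
  stopifnot(length(rows) >= 2L, length(unique(nchar(rows))) == 1L)
  m <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(m)
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- sum(col == "-")
    if (gaps > n / 2) return("")            # majority-gap column dropped
    tab <- table(col[col != "-"])
    best <- names(tab)[which.max(tab)]      # ties: first alphabetically
    if (tab[[best]] / n >= plurality_fraction) best else "N"
  }, character(1))
  consensus <- paste(cons, collapse = "")
  deletion <- NULL
  if (!is.null(canonical)) {
    gaps <- alignment_gaps(clean_dna(canonical), consensus, scoring, min_gap)
    if (nrow(gaps$deletions)) {
      lens <- gaps$deletions$end - gaps$deletions$start + 1L
      k <- which.max(lens)
      deletion <- c(gaps$deletions$start[k], gaps$deletions$end[k])
    }
  }
  structure(list(element_name = element_name,
                 consensus_sequence = consensus,
                 length_bp = nchar(consensus),
                 deletion_interval = deletion,
                 n_copies_used = n),
            class = "consensus_result")
}

#' Kimura two-parameter distance from an alignment
#'
#' With p the transition fraction and q the transversion fraction over the
#' ungapped columns of a pairwise alignment, the K2P distance is
#' `-1/2 * ln((1 - 2p - q) * sqrt(1 - 2q))`. Saturated alignments (the
#' logarithm argument is non-positive) return `NA` with attribute
#' `saturated = TRUE`.
#'
#' @param aligned_a,aligned_b Gapped aligned strings of equal length.
#' @return K2P distance (numeric scalar, or saturated `NA`).
#' @seealso [kimura_from_pq()] for the closed form.
#' @export
kimura_distance <- function(aligned_a, aligned_b) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("alignment has no ungapped A/C/G/T column")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  purine <- c("A", "G")
  transition <- a != b & ((a %in% purine) == (b %in% purine))
  transversion <- a != b & !transition
  kimura_from_pq(sum(transition) / n, sum(transversion) / n)
}

#' Kimura two-parameter distance from substitution fractions
#'
#' @param p Transition fraction.
#' @param q Transversion fraction.
#' @return `-1/2 * ln((1 - 2p - q) * sqrt(1 - 2q))`; saturated inputs
#'   return `NA` with attribute `saturated = TRUE`.
#' @export
kimura_from_pq <- function(p, q) {
  arg <- (1 - 2 * p - q) * sqrt(1 - 2 * q)
  if (is.nan(arg) || arg <= 0) {
    return(structure(NA_real_, saturated = TRUE))
  }
  -0.5 * log(arg)
}

#' Kimura divergence landscape
#'
#' Bins each copy's length (bp) by its K2P distance to its family
#' consensus; total bp across bins equals the total length of the copies
#' used, so the landscape conserves sequence mass.
#'
#' @param copies List of `element_copy` objects (or a named list of
#'   character vectors keyed by element).
#' @param consensi Named list mapping element name to consensus sequence
#'   (character) or `consensus_result`.
#' @param bin_width Distance bin width.
#' @param scoring [scoring_params()].
#' @return `data.frame`: `element_class`, `bin_start`, `bin_end`,
#'   `bp_covered`, aggregated over copies.
#' @export
divergence_landscape <- function(copies, consensi, bin_width = 0.05,
                                 scoring = scoring_params()) {
  rows <- list()
  for (cp in copies) {
    if (is.character(cp)) {
      el <- names(cp) %||% "element"; seq <- unname(cp)
    } else {
      el <- cp$element_name; seq <- cp$copy_sequence
    }
    cons <- consensi[[el]]
    if (is.null(cons)) {
      warning("no consensus for element ", el, "; copy skipped")
      next
    }
    if (inherits(cons, "consensus_result")) cons <- cons$consensus_sequence
    al <- nw_align(seq, cons, scoring)
    d <- kimura_distance(al$aligned_a, al$aligned_b)
    if (is.na(d)) {
      warning("saturated distance for a copy of ", el, "; copy skipped")
      next
    }
    bin <- floor(d / bin_width)
    rows[[length(rows) + 1L]] <- data.frame(
      element_class = el, bin_start = bin * bin_width,
      bin_end = (bin + 1) * bin_width, bp_covered = nchar(seq),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(element_class = character(0), bin_start = numeric(0),
                      bin_end = numeric(0), bp_covered = numeric(0)))
  }
  agg <- stats::aggregate(bp_covered ~ element_class + bin_start + bin_end,
                          do.call(rbind, rows), sum)
  agg[order(agg$element_class, agg$bin_start), ]
}
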