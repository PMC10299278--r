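#' Alignment scoring parameters
#'
#' Defaults (match +2, mismatch -3, gap open 5, gap extend 2, both as
#' positive costs; a gap of length L costs `gap_open + L * gap_ext`) are
#' tolerant of a few percent assembly noise while rejecting random matches
#' of TIR-sized queries.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_ext Gap costs (positive).
#' @return List of class `scoring_params`.
#' @export
scoring_params <- function(match = 2, mismatch = -3, gap_open = 5, gap_ext = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_ext > 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "scoring_params")
}

# substitution matrix over the DNA alphabet: exact A/C/G/T matches score
# `match`, everything else (including IUPAC ambiguity codes and N) scores
# `mismatch`; the masking character '+' is unalignable
subst_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
               "V", "H", "D", "B", "N", "-", "+", ".")
  m <- matrix(scoring$mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (b in c("A", "C", "G", "T")) m[b, b] <- scoring$match
  m["+", ] <- -1000
  m[, "+"] <- -1000
  m
}

pa_hit <- function(pa, qlen) {
  pr <- Biostrings::pattern(pa)
  sr <- Biostrings::subject(pa)
  q_start <- Biostrings::start(pr)
  q_end <- Biostrings::end(pr)
  list(score = Biostrings::score(pa),
       q_start = q_start, q_end = q_end,
       s_start = Biostrings::start(sr), s_end = Biostrings::end(sr),
       pident = Biostrings::pid(pa),
       qcov = (q_end - q_start + 1) / qlen)
}

sw_local <- function(query, subject, scoring) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = subst_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  pa
}

align_global_local <- function(pattern, subject, scoring) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = subst_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
}

# all local alignments of query in subject above min_score, found by
# iterated Smith-Waterman with masking of previous hits
sw_all_hits <- function(query, subject, scoring, min_score, max_hits = 20L) {
  hits <- list()
  qlen <- nchar(query)
  subj <- subject
  for (i in seq_len(max_hits)) {
    pa <- sw_local(query, subj, scoring)
    h <- pa_hit(pa, qlen)
    if (h$score < min_score || h$s_end < h$s_start) break
    hits[[length(hits) + 1L]] <- h
    substr(subj, h$s_start, h$s_end) <-
      strrep("+", h$s_end - h$s_start + 1L)
  }
  hits
}

# precomputed seed set (PDict + seed offsets) for one query orientation
seed_pdict <- function(query, k = 21L, n_seeds = 12L) {
  qlen <- nchar(query)
  k <- min(k, qlen)
  starts <- unique(pmax(1L, as.integer(round(
    seq(1L, qlen - k + 1L, length.out = min(n_seeds, qlen - k + 1L))))))
  pats <- substring(query, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", pats)
  if (!any(ok)) return(NULL)
  list(pdict = Biostrings::PDict(Biostrings::DNAStringSet(pats[ok])),
       starts = starts[ok], qlen = qlen)
}

as_dna <- function(x) {
  if (methods::is(x, "DNAString")) x else Biostrings::DNAString(x)
}

# exact k-mer seeding: returns candidate subject windows (start, end) where
# the query plausibly aligns; `subject` may be a character or a
# (pre-converted) DNAString, `seeds` a precomputed seed_pdict()
seed_windows <- function(query, subject, k = 21L, n_seeds = 12L,
                         margin = 60L, cluster_gap = NULL, seeds = NULL) {
  qlen <- nchar(query)
  seeds <- seeds %||% seed_pdict(query, k, n_seeds)
  if (is.null(seeds)) return(NULL)
  subject_ds <- as_dna(subject)
  slen <- length(subject_ds)
  m <- Biostrings::matchPDict(seeds$pdict, subject_ds)
  qs <- rep(seeds$starts, lengths(m))
  ss <- unlist(lapply(m, Biostrings::start), use.names = FALSE)
  if (!length(ss)) return(NULL)
  diag <- ss - qs
  o <- order(diag)
  diag <- diag[o]; qs <- qs[o]; ss <- ss[o]
  gap <- cluster_gap %||% max(50L, as.integer(0.3 * qlen))
  cl <- cumsum(c(1L, diff(diag) > gap))
  do.call(rbind, lapply(split(seq_along(cl), cl), function(idx) {
    d0 <- min(diag[idx]); d1 <- max(diag[idx])
    data.frame(start = max(1L, d0 + 1L - margin),
               end = min(slen, d1 + qlen + margin),
               n_seeds = length(idx))
  }))
}

# hits of query in one subject strand via seeding + windowed Smith-Waterman
seeded_hits <- function(query, subject, scoring, min_score, max_hits = 20L,
                        seed_k = 21L, subject_ds = NULL, seeds = NULL) {
  win <- seed_windows(query, subject_ds %||% subject, k = seed_k,
                      seeds = seeds)
  if (is.null(win)) return(list())
  hits <- list()
  for (w in seq_len(nrow(win))) {
    sub <- substr(subject, win$start[w], win$end[w])
    for (h in sw_all_hits(query, sub, scoring, min_score, max_hits)) {
      h$s_start <- h$s_start + win$start[w] - 1L
      h$s_end <- h$s_end + win$start[w] - 1L
      hits[[length(hits) + 1L]] <- h
    }
  }
  # windows can abut; drop duplicate intervals
  if (length(hits) > 1) {
    key <- vapply(hits, function(h) paste(h$s_start, h$s_end), character(1))
    hits <- hits[!duplicated(key)]
  }
  hits
}

#' Align a query against assembly contigs
#'
#' Finds all significant local alignments of `query` in a set of contigs,
#' on both strands. Small problems are solved by exhaustive Smith-Waterman
#' (iterated with masking so every hit above `min_score` is reported);
#' larger contigs are screened with exact k-mer seeds and the
#' Smith-Waterman restricted to candidate windows. Results are sorted by
#' score (ties broken by contig id, coordinate, then strand) so output
#' order is deterministic.
#'
#' @param query Query sequence (character scalar).
#' @param contigs Named character vector or `DNAStringSet` of contigs.
#' @param scoring [scoring_params()].
#' @param min_score Minimum raw alignment score to report; defaults to half
#'   the maximum attainable score of the query.
#' @param method `"auto"` (exhaustive when `|query| * |contig| <= 1e6`,
#'   seeded otherwise), `"exhaustive"`, or `"seed"`.
#' @param max_hits_per_contig Per contig/strand cap on reported hits.
#' @return `data.frame` of class `contig_hits`: `contig_id`, `start`,
#'   `end` (1-based closed contig interval), `strand`, `score`, `pident`,
#'   `qcov`, `query_len`.
#' @export
align_query <- function(query, contigs, scoring = scoring_params(),
                        min_score = NULL, method = c("auto", "exhaustive", "seed"),
                        max_hits_per_contig = 20L) {
  method <- match.arg(method)
  if (methods::is(contigs, "XStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  query <- clean_dna(query)
  qlen <- nchar(query)
  min_score <- min_score %||% ceiling(0.5 * scoring$match * qlen)

  q_by_strand <- c("+" = query, "-" = revcomp(query))
  seeds_by_strand <- lapply(q_by_strand, seed_pdict)
  rows <- list()
  for (cid in names(contigs)) {
    subj <- contigs[[cid]]
    use_exhaustive <- switch(method,
      exhaustive = TRUE, seed = FALSE,
      auto = qlen * nchar(subj) <= 1e6)
    subj_ds <- if (!use_exhaustive) Biostrings::DNAString(subj) else NULL
    for (strand in c("+", "-")) {
      q <- q_by_strand[[strand]]
      hits <- if (use_exhaustive) {
        sw_all_hits(q, subj, scoring, min_score, max_hits_per_contig)
      } else {
        seeded_hits(q, subj, scoring, min_score, max_hits_per_contig,
                    subject_ds = subj_ds, seeds = seeds_by_strand[[strand]])
      }
      for (h in hits) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = cid, start = h$s_start, end = h$s_end,
          strand = strand, score = h$score, pident = h$pident,
          qcov = h$qcov, query_len = qlen, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(contig_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), score = numeric(0), pident = numeric(0),
               qcov = numeric(0), query_len = integer(0))
  }
  out <- out[order(-out$score, out$contig_id, out$start, out$strand), ]
  rownames(out) <- NULL
  class(out) <- c("contig_hits", "data.frame")
  out
}

#' Filter alignment hits on identity and query coverage
#'
#' @param hits A `contig_hits` data.frame from [align_query()].
#' @param min_identity Minimum percent identity (0-100).
#' @param min_coverage Minimum aligned fraction of the query (0-1).
#' @return The surviving hits; count is monotonically non-increasing in
#'   both thresholds.
#' @export
filter_hits <- function(hits, min_identity = 85, min_coverage = 0.8) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 1)
  out <- hits[hits$pident >= min_identity & hits$qcov >= min_coverage, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a junction query spanning a genome-transposon junction
#'
#' Given a TIR-query hit in a contig, extracts the genomic flank on the
#' element-external side of the matched TIR plus the matched span itself.
#' The result always reads flank-then-TIR: hits whose external flank lies
#' downstream in contig coordinates are reverse-complemented. Flanks are
#' truncated at contig ends, with the truncated length recorded.
#'
#' @param contigs Named character vector of contigs.
#' @param hit One hit row: a list/one-row data.frame with `contig_id`,
#'   `start`, `end`, `strand`, `element_name`, `end_label`.
#' @param flank_len_bp Requested flank length (default 3000; 6000 is used
#'   when re-resolving ambiguous placements).
#' @return A `junction_query` list: `contig_id`, `sequence`,
#'   `flank_len_bp`, `actual_flank_bp`, `orientation`, `element_name`,
#'   `end_label`, `side` (`"left"` for the junction upstream of the element
#'   5' end, `"right"` downstream of its 3' end), `span` (matched TIR span
#'   length) and the source `hit`. A hit with zero available flank is
#'   rejected (`rejected = TRUE`, `reason = "no flank"`).
#' @export
extract_junction_query <- function(contigs, hit, flank_len_bp = 3000) {
  if (methods::is(contigs, "XStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  hit <- as.list(hit)
  subj <- contigs[[hit$contig_id]]
  if (is.null(subj)) stop("hit refers to unknown contig: ", hit$contig_id)
  clen <- nchar(subj)
  stopifnot(hit$start >= 1, hit$end <= clen)
  # The element-external flank lies upstream in contig coordinates for
  # (five_prime, +) and (three_prime, -) hits, downstream otherwise.
  # Upstream flanks ("left" junctions) yield the insertion coordinate
  # directly; downstream flanks ("right" junctions) are reverse-complemented
  # so the JQ still reads flank -> matched span, and their coordinate is
  # later corrected by the target-site-duplication length.
  flank_left <- (hit$end_label == "five_prime") == (hit$strand == "+")
  if (flank_left) {
    fs <- max(1L, hit$start - as.integer(flank_len_bp))
    actual <- hit$start - fs
    seq <- substr(subj, fs, hit$end)
  } else {
    fe <- min(clen, hit$end + as.integer(flank_len_bp))
    actual <- fe - hit$end
    seq <- revcomp(substr(subj, hit$start, fe))
  }
  if (actual <= 0L) {
    return(structure(list(rejected = TRUE, reason = "no flank",
                          contig_id = hit$contig_id, hit = hit),
                     class = "junction_query"))
  }
  structure(list(
    rejected = FALSE,
    contig_id = hit$contig_id,
    sequence = seq,
    flank_len_bp = as.integer(flank_len_bp),
    actual_flank_bp = as.integer(actual),
    truncated = actual < flank_len_bp,
    orientation = hit$strand,
    element_name = hit$element_name,
    end_label = hit$end_label,
    side = if (flank_left) "left" else "right",
    span = hit$end - hit$start + 1L,
    hit = hit), class = "junction_query")
}

#' Run junction discovery (WF1) over a transposon library
#'
#' Extracts both TIR queries of every non-excluded element, aligns them
#' against the contigs, filters hits on identity and coverage, and extracts
#' one junction query per surviving hit.
#'
#' @param lib A [te_library()].
#' @param contigs Named character vector or `DNAStringSet` of contigs.
#' @param scoring [scoring_params()].
#' @param internal_ext_bp Internal extension of the TIR queries.
#' @param flank_len_bp Junction-query flank length.
#' @param min_identity,min_coverage Hit significance thresholds.
#' @return List with `hits` (all significant hits, annotated with element
#'   and end), `jqs` (list of `junction_query` objects) and `rejected`
#'   (junction queries rejected for lack of flank).
#' @export
discover_junctions <- function(lib, contigs, scoring = scoring_params(),
                               internal_ext_bp = 100, flank_len_bp = 3000,
                               min_identity = 85, min_coverage = 0.8) {
  if (methods::is(contigs, "XStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  elements <- setdiff(lib$records$name, lib$exclude)
  all_hits <- list()
  for (el in elements) {
    queries <- extract_tir_queries(lib, el, internal_ext_bp)
    for (qi in seq_len(nrow(queries))) {
      h <- align_query(queries$sequence[qi], contigs, scoring)
      h <- filter_hits(h, min_identity, min_coverage)
      if (nrow(h)) {
        h$element_name <- el
        h$end_label <- queries$end_label[qi]
        all_hits[[length(all_hits) + 1L]] <- h
      }
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    data.frame(contig_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), score = numeric(0), pident = numeric(0),
               qcov = numeric(0), query_len = integer(0),
               element_name = character(0), end_label = character(0))
  jqs <- list(); rejected <- list()
  for (i in seq_len(nrow(hits))) {
    jq <- extract_junction_query(contigs, hits[i, ], flank_len_bp)
    if (isTRUE(jq$rejected)) rejected[[length(rejected) + 1L]] <- jq
    else jqs[[length(jqs) + 1L]] <- jq
  }
  list(hits = hits, jqs = jqs, rejected = rejected)
}
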