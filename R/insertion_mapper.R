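as_genome <- function(x) {
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

#' Map a junction query onto the reference genome
#'
#' Seeds the junction query's genomic flank against both strands of every
#' chromosome with exact k-mers, evaluates each candidate locus by forcing
#' a full (global-in-pattern) alignment of the flank, and interprets the
#' best locus in one of two ways: either the whole JQ continues
#' contiguously in the reference (the element is present there too:
#' "completely blue"), or the flank ends at a breakpoint and the TIR-side
#' remainder matches the canonical element instead ("blue-red", a
#' sample-specific insertion). All candidate loci scoring within `delta`
#' of the best are retained as secondary placements for the ambiguity call.
#'
#' For "left" junctions the breakpoint is the reference base to which the
#' last flank base aligns; for "right" junctions (flank mapped on the minus
#' strand) it is the base immediately before the first aligned flank
#' position, which underestimates the insertion coordinate by the
#' target-site-duplication length and is corrected once the TSD is known.
#'
#' @param jq A `junction_query`.
#' @param reference Named character vector (or `DNAStringSet`) of
#'   chromosomes.
#' @param canonical_te Canonical sequence of the junction query's element.
#' @param scoring [scoring_params()].
#' @param delta Relative score margin within which a secondary locus makes
#'   the placement ambiguous.
#' @param min_identity Minimum flank percent identity for a placement.
#' @param cont_identity Identity above which the TIR-side remainder is
#'   considered to continue in the genome (conserved insertion).
#' @param te_identity Identity above which the remainder is considered to
#'   match the canonical element (specific insertion).
#' @param seed_k,max_windows Seeding granularity and candidate cap.
#' @param reference_index Optional list of pre-built `DNAString` objects,
#'   one per chromosome, to avoid re-converting the reference when mapping
#'   many junction queries.
#' @return A `placement` list; `placed = FALSE` with a `reason` when no
#'   candidate locus survives.
#' @export
map_junction <- function(jq, reference, canonical_te,
                         scoring = scoring_params(), delta = 0.95,
                         min_identity = 85, cont_identity = 90,
                         te_identity = 80, seed_k = 31L, max_windows = 8L,
                         reference_index = NULL) {
  stopifnot(inherits(jq, "junction_query"), !isTRUE(jq$rejected))
  reference <- as_genome(reference)
  reference_index <- reference_index %||% lapply(reference, as_dna)
  af <- jq$actual_flank_bp
  flank <- substr(jq$sequence, 1L, af)
  tirpart <- substring(jq$sequence, af + 1L)

  cand <- list()
  for (strand in c("+", "-")) {
    fl <- if (strand == "+") flank else revcomp(flank)
    seeds <- seed_pdict(fl, k = min(seed_k, af), n_seeds = 30L)
    for (ch in names(reference)) {
      win <- seed_windows(fl, reference_index[[ch]], margin = 300L,
                          cluster_gap = 2000L, seeds = seeds)
      if (is.null(win)) next
      for (w in seq_len(nrow(win))) {
        cand[[length(cand) + 1L]] <- data.frame(
          chromosome = ch, strand = strand,
          wstart = win$start[w], wend = win$end[w], n_seeds = win$n_seeds[w],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) {
    return(structure(list(jq = jq, placed = FALSE, reason = "no seed match",
                          secondary = empty_secondary()),
                     class = "placement"))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$n_seeds), , drop = FALSE]
  # only loci with a seed count comparable to the best can possibly score
  # within the ambiguity margin; skip the rest before the costly alignment
  cand <- cand[cand$n_seeds >= 0.5 * cand$n_seeds[1], , drop = FALSE]
  cand <- utils::head(cand, max_windows)

  cand$score <- NA_real_
  cand$g_start <- NA_integer_; cand$g_end <- NA_integer_
  cand$identity <- NA_real_
  for (i in seq_len(nrow(cand))) {
    fl <- if (cand$strand[i] == "+") flank else revcomp(flank)
    sub <- substr(reference[[cand$chromosome[i]]], cand$wstart[i], cand$wend[i])
    pa <- align_global_local(fl, sub, scoring)
    h <- pa_hit(pa, af)
    cand$score[i] <- h$score
    cand$identity[i] <- h$pident
    if (cand$strand[i] == "+") {
      cand$g_start[i] <- cand$wstart[i] + h$s_start - 1L
      cand$g_end[i] <- cand$wstart[i] + h$s_end - 1L
    } else {
      # minus-strand placement of the reverse-complemented flank: the
      # flank's last base maps to the lowest reference coordinate
      cand$g_start[i] <- cand$wstart[i] + h$s_start - 1L
      cand$g_end[i] <- cand$wstart[i] + h$s_end - 1L
    }
  }
  # collapse candidates that landed on the same locus
  key <- paste(cand$chromosome, round(cand$g_start / 1000))
  cand <- cand[order(-cand$score), , drop = FALSE]
  cand <- cand[!duplicated(key[order(-cand$score)]), , drop = FALSE]

  best <- cand[1, ]
  if (is.na(best$score) || best$identity < min_identity) {
    return(structure(list(jq = jq, placed = FALSE,
                          reason = "no placement above identity threshold",
                          secondary = empty_secondary()),
                     class = "placement"))
  }
  sec <- cand[-1, , drop = FALSE]
  sec <- sec[!is.na(sec$score) & sec$score >= delta * best$score, , drop = FALSE]
  secondary <- sec[, c("chromosome", "strand", "g_start", "g_end", "score")]

  breakpoint <- if (best$strand == "+") best$g_end else best$g_start - 1L

  # does the TIR-side remainder continue contiguously in the genome?
  chrom_seq <- reference[[best$chromosome]]
  lt <- nchar(tirpart) + 20L
  gs <- if (best$strand == "+") {
    substr(chrom_seq, best$g_end + 1L, min(nchar(chrom_seq), best$g_end + lt))
  } else {
    revcomp(substr(chrom_seq, max(1L, best$g_start - lt), best$g_start - 1L))
  }
  contiguous <- FALSE
  cont_id <- NA_real_
  if (nchar(gs) >= nchar(tirpart)) {
    h <- pa_hit(align_global_local(tirpart, gs, scoring), nchar(tirpart))
    cont_id <- h$pident
    contiguous <- h$pident >= cont_identity
  }

  # does the remainder match the canonical element?
  te_segment <- NULL
  if (!contiguous && !is.null(canonical_te)) {
    canonical_te <- as.character(canonical_te)
    L <- nchar(canonical_te)
    h_f <- pa_hit(align_global_local(tirpart, canonical_te, scoring),
                  nchar(tirpart))
    h_r <- pa_hit(align_global_local(tirpart, revcomp(canonical_te), scoring),
                  nchar(tirpart))
    h <- if (h_f$score >= h_r$score) h_f else h_r
    if (h$pident >= te_identity) {
      if (h_f$score >= h_r$score) {
        te_segment <- list(start = h$s_start, end = h$s_end,
                           identity = h$pident, te_strand = "+")
      } else {
        te_segment <- list(start = L - h$s_end + 1L, end = L - h$s_start + 1L,
                           identity = h$pident, te_strand = "-")
      }
    }
  }

  structure(list(jq = jq, placed = TRUE,
                 chromosome = best$chromosome, strand = best$strand,
                 genome_start = best$g_start, genome_end = best$g_end,
                 genome_identity = best$identity, score = best$score,
                 breakpoint = as.integer(breakpoint),
                 contiguous = contiguous, continuation_identity = cont_id,
                 te_segment = te_segment,
                 secondary = secondary),
            class = "placement")
}

empty_secondary <- function() {
  data.frame(chromosome = character(0), strand = character(0),
             g_start = integer(0), g_end = integer(0), score = numeric(0))
}

# reference coordinate of the base preceding a conserved element whose JQ
# covered its 3'-side junction: scan back from the breakpoint for the
# element's leading TIR
conserved_left_boundary <- function(placement, lib, reference) {
  el <- placement$jq$element_name
  rec <- lib_record(lib, el)
  tir5 <- substr(rec$sequence, 1L, rec$tir_length_bp)
  chrom_seq <- as_genome(reference)[[placement$chromosome]]
  lo <- max(1L, placement$breakpoint - rec$length_bp - 100L)
  win <- substr(chrom_seq, lo, placement$breakpoint)
  m <- Biostrings::matchPattern(tir5, Biostrings::DNAString(win),
                                max.mismatch = 3L)
  if (!length(m)) return(placement$breakpoint)
  lo + Biostrings::start(m)[1] - 2L
}

#' Classify a placed junction query as an insertion call
#'
#' Applies the status partition: `specific` (split flank/TE placement with
#' no same-family reference TE annotation near the breakpoint),
#' `conserved_annotated` / `conserved_unannotated` (JQ contiguous in the
#' reference, with/without an overlapping same-family annotation record),
#' `ambiguous` (a secondary placement within the score margin on a
#' different locus), or `unresolvable` (unplaced, too little flank, or no
#' interpretable TIR side) with a chromosome hint when every candidate
#' placement agrees on one chromosome.
#'
#' @param placement A [map_junction()] result.
#' @param ref_te_gff `GRanges` of reference TE annotation records with a
#'   `Name` column holding the element family.
#' @param lib The [te_library()] (used to locate the element boundary for
#'   conserved calls seen from their 3' junction).
#' @param reference The reference genome (same object mapped against).
#' @param min_flank Minimum flank length (bp) for a resolvable call.
#' @param ambig_dist Minimum distance (bp) between placements for them to
#'   count as distinct loci.
#' @param family_window Breakpoint tolerance (bp) against annotation
#'   records when deciding conserved vs specific.
#' @return One-row `data.frame` (a mapped-insertion record).
#' @export
classify_insertion <- function(placement, ref_te_gff, lib = NULL,
                               reference = NULL, min_flank = 500L,
                               ambig_dist = 10000L, family_window = 100L) {
  jq <- placement$jq
  row <- data.frame(
    element_name = jq$element_name, chromosome = NA_character_,
    insertion_coord = NA_integer_, status = NA_character_,
    arm_hint = NA_character_, tsd = NA_character_,
    supporting_contigs = jq$contig_id, side = jq$side,
    end_label = jq$end_label, breakpoint = NA_integer_,
    strand = NA_character_, score = NA_real_, n_secondary = 0L,
    hit_start = jq$hit$start, hit_end = jq$hit$end,
    reason = NA_character_, stringsAsFactors = FALSE)

  hint <- function() {
    chroms <- unique(c(if (isTRUE(placement$placed)) placement$chromosome,
                       placement$secondary$chromosome))
    if (length(chroms) == 1L) chroms else NA_character_
  }

  if (!isTRUE(placement$placed)) {
    row$status <- "unresolvable"
    row$reason <- placement$reason %||% "unplaced"
    row$arm_hint <- hint()
    return(row)
  }
  row$chromosome <- placement$chromosome
  row$breakpoint <- placement$breakpoint
  row$strand <- placement$strand
  row$score <- placement$score
  row$insertion_coord <- placement$breakpoint

  if (jq$actual_flank_bp < min_flank) {
    row$status <- "unresolvable"
    row$reason <- "flank below minimum"
    row$arm_hint <- hint()
    return(row)
  }

  sec <- placement$secondary
  distinct <- sec$chromosome != placement$chromosome |
    abs(sec$g_start - placement$genome_start) > ambig_dist
  row$n_secondary <- sum(distinct)
  if (any(distinct)) {
    row$status <- "ambiguous"
    row$arm_hint <- hint()
    return(row)
  }

  same_family_near <- function(pt) {
    if (is.null(ref_te_gff) || !length(ref_te_gff)) return(FALSE)
    ann <- ref_te_gff[!is.na(ref_te_gff$Name) &
                        ref_te_gff$Name == jq$element_name]
    if (!length(ann)) return(FALSE)
    any(as.character(GenomicRanges::seqnames(ann)) == placement$chromosome &
          GenomicRanges::start(ann) - family_window <= pt &
          GenomicRanges::end(ann) + family_window >= pt)
  }

  if (isTRUE(placement$contiguous)) {
    coord <- if (jq$side == "left") placement$breakpoint
             else if (!is.null(lib) && !is.null(reference)) {
               conserved_left_boundary(placement, lib, reference)
             } else placement$breakpoint
    row$insertion_coord <- coord
    probe <- coord + 1L
    row$status <- if (same_family_near(probe)) "conserved_annotated"
                  else "conserved_unannotated"
    return(row)
  }
  if (!is.null(placement$te_segment)) {
    if (same_family_near(placement$breakpoint)) {
      row$status <- "conserved_annotated"
    } else {
      row$status <- "specific"
    }
    return(row)
  }
  row$status <- "unresolvable"
  row$reason <- "TIR side matches neither genome nor element"
  row$arm_hint <- hint()
  row
}

#' Detect a target site duplication from element flanks
#'
#' Compares the sequence immediately 5' of an element copy (in its contig)
#' with the sequence immediately 3' of it, and returns the longest k in
#' `k_range` for which the terminal k-mers are identical. If the reference
#' and insertion coordinate are supplied, candidate k-mers that also equal
#' the reference k-mer ending at the insertion coordinate are preferred.
#'
#' @param element_flanks List with `left` (sequence ending at the element
#'   start) and `right` (sequence starting after the element end).
#' @param k_range Closed integer range of duplication lengths to test.
#' @param expected_k Biologically expected length (8 for P-element-like
#'   TSDs); used only to break preference ties.
#' @param reference,chromosome,insertion_coord Optional reference context.
#' @return List with `tsd` (string or `NULL`), `k`, and `reason` when no
#'   duplication was found.
#' @export
detect_tsd <- function(element_flanks, k_range = c(4L, 12L), expected_k = 8L,
                       reference = NULL, chromosome = NULL,
                       insertion_coord = NULL) {
  left <- element_flanks$left
  right <- element_flanks$right
  if (is.null(left) || is.null(right) || !nzchar(left) || !nzchar(right)) {
    return(list(tsd = NULL, k = NA_integer_, reason = "flanks unavailable"))
  }
  ks <- seq(min(k_range[2], nchar(left), nchar(right)), k_range[1])
  hit <- integer(0)
  for (k in ks) {
    if (substr(left, nchar(left) - k + 1L, nchar(left)) ==
        substr(right, 1L, k)) hit <- c(hit, k)
  }
  if (!length(hit)) {
    return(list(tsd = NULL, k = NA_integer_,
                reason = "no terminal duplication in k range"))
  }
  pick <- max(hit)
  if (!is.null(reference) && !is.null(chromosome) && !is.null(insertion_coord)) {
    reference <- as_genome(reference)
    agree <- vapply(hit, function(k) {
      refk <- substr(reference[[chromosome]],
                     insertion_coord - k + 1L, insertion_coord)
      refk == substr(right, 1L, k)
    }, logical(1))
    if (any(agree)) pick <- max(hit[agree])
  }
  list(tsd = substr(right, 1L, pick), k = pick, reason = NULL)
}

#' Pair element-end hits within contigs and detect their TSDs
#'
#' Pairs five-prime and three-prime TIR hits of the same element on the
#' same contig and strand into element-copy spans, then compares the
#' contig sequence immediately outside the span on both sides to call the
#' target site duplication.
#'
#' @param hits Annotated hit table from [discover_junctions()].
#' @param contigs Named character vector of contigs.
#' @param lib The [te_library()] (bounds the plausible span length).
#' @param k_range,expected_k Passed to [detect_tsd()].
#' @return `data.frame` with one row per paired element copy: `contig_id`,
#'   `element_name`, `strand`, `span_start`, `span_end`, `tsd`, `tsd_k`.
#' @export
pair_element_spans <- function(hits, contigs, lib, k_range = c(4L, 12L),
                               expected_k = 8L) {
  contigs <- as_genome(contigs)
  out <- list()
  if (!nrow(hits)) return(empty_spans())
  grp <- split(seq_len(nrow(hits)),
               paste(hits$contig_id, hits$element_name, hits$strand))
  for (idx in grp) {
    h <- hits[idx, ]
    rec <- lib_record(lib, h$element_name[1])
    max_span <- rec$length_bp + 200L
    five <- h[h$end_label == "five_prime", , drop = FALSE]
    three <- h[h$end_label == "three_prime", , drop = FALSE]
    if (!nrow(five) || !nrow(three)) next
    used <- logical(nrow(three))
    for (i in seq_len(nrow(five))) {
      if (h$strand[1] == "+") {
        ok <- !used & three$start > five$start[i] &
          three$end - five$start[i] + 1L <= max_span
        if (!any(ok)) next
        j <- which(ok)[which.min(three$start[ok])]
        span <- c(five$start[i], three$end[j])
      } else {
        ok <- !used & three$start < five$start[i] &
          five$end[i] - three$start + 1L <= max_span
        if (!any(ok)) next
        j <- which(ok)[which.max(three$start[ok])]
        span <- c(three$start[j], five$end[i])
      }
      used[j] <- TRUE
      subj <- contigs[[h$contig_id[1]]]
      kmax <- max(k_range)
      left <- substr(subj, max(1L, span[1] - kmax - 2L), span[1] - 1L)
      right <- substr(subj, span[2] + 1L,
                      min(nchar(subj), span[2] + kmax + 2L))
      td <- detect_tsd(list(left = left, right = right), k_range, expected_k)
      out[[length(out) + 1L]] <- data.frame(
        contig_id = h$contig_id[1], element_name = h$element_name[1],
        strand = h$strand[1], span_start = span[1], span_end = span[2],
        tsd = td$tsd %||% NA_character_, tsd_k = td$k,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_spans())
  do.call(rbind, out)
}

empty_spans <- function() {
  data.frame(contig_id = character(0), element_name = character(0),
             strand = character(0), span_start = integer(0),
             span_end = integer(0), tsd = character(0), tsd_k = integer(0))
}

# attach TSDs from paired element spans to insertion calls, and correct
# right-junction specific coordinates by the TSD length
finalize_coords <- function(calls, spans) {
  if (!nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    m <- spans$contig_id == calls$supporting_contigs[i] &
      spans$element_name == calls$element_name[i] &
      spans$span_start - 2L <= calls$hit_start[i] &
      spans$span_end + 2L >= calls$hit_end[i]
    if (any(m) && !is.na(spans$tsd[which(m)[1]])) {
      calls$tsd[i] <- spans$tsd[which(m)[1]]
    }
  }
  fix <- calls$side == "right" & calls$status == "specific" & !is.na(calls$tsd)
  calls$insertion_coord[fix] <- calls$breakpoint[fix] + nchar(calls$tsd[fix])
  calls
}

status_priority <- c(specific = 1, conserved_annotated = 2,
                     conserved_unannotated = 3, ambiguous = 4,
                     unresolvable = 5)

#' Merge redundant insertion calls
#'
#' Calls with the same element and chromosome whose coordinates differ by
#' at most `coord_tolerance` (the two junctions of one copy, or the same
#' junction seen in overlapping contigs) are merged into a single call
#' carrying all supporting contigs. Coordinates from "left" junctions are
#' exact and take precedence within a merged group.
#'
#' @param insertions Insertion-call `data.frame`.
#' @param coord_tolerance Maximum coordinate difference (bp) for merging.
#' @return Merged call table; row count is non-increasing.
#' @export
merge_redundant <- function(insertions, coord_tolerance = 20L) {
  if (!nrow(insertions)) return(insertions)
  placed <- !is.na(insertions$insertion_coord)
  keep <- insertions[!placed, , drop = FALSE]
  x <- insertions[placed, , drop = FALSE]
  out <- list()
  for (key in unique(paste(x$element_name, x$chromosome))) {
    g <- x[paste(x$element_name, x$chromosome) == key, , drop = FALSE]
    g <- g[order(g$insertion_coord), , drop = FALSE]
    cl <- cumsum(c(1L, diff(g$insertion_coord) > coord_tolerance))
    for (ci in unique(cl)) {
      m <- g[cl == ci, , drop = FALSE]
      row <- m[which.min(status_priority[m$status]), , drop = FALSE]
      lefts <- m$side == "left" & m$status %in%
        c("specific", "conserved_annotated", "conserved_unannotated")
      row$insertion_coord <- if (any(lefts)) {
        as.integer(stats::median(m$insertion_coord[lefts]))
      } else max(m$insertion_coord)
      row$supporting_contigs <- paste(unique(unlist(
        strsplit(m$supporting_contigs, ","))), collapse = ",")
      tsds <- m$tsd[!is.na(m$tsd)]
      row$tsd <- if (length(tsds)) tsds[1] else NA_character_
      row$n_support <- nrow(m)
      out[[length(out) + 1L]] <- row
    }
  }
  merged <- do.call(rbind, out)
  if (nrow(keep)) {
    keep$n_support <- 1L
    merged <- rbind(merged, keep)
  }
  merged <- merged[order(merged$chromosome, merged$insertion_coord), ]
  rownames(merged) <- NULL
  merged
}

#' Flag insertional hotspots
#'
#' An insertion site is a hotspot when at least `min_count` annotated
#' transposon records fall within `window_bp` of its coordinate.
#'
#' @param insertions Insertion-call `data.frame` (needs `chromosome`,
#'   `insertion_coord`).
#' @param annotation_gff `GRanges` of annotated transposon insertions.
#' @param window_bp Half-window around the coordinate (bp).
#' @param min_count Minimum annotated records for a hotspot.
#' @return Logical vector, one flag per insertion (NA coordinate gives
#'   `FALSE`).
#' @export
flag_hotspot <- function(insertions, annotation_gff, window_bp = 50L,
                         min_count = 3L) {
  flags <- rep(FALSE, nrow(insertions))
  ok <- !is.na(insertions$insertion_coord) & !is.na(insertions$chromosome)
  if (!any(ok) || is.null(annotation_gff) || !length(annotation_gff)) {
    return(flags)
  }
  q <- GenomicRanges::GRanges(
    insertions$chromosome[ok],
    IRanges::IRanges(pmax(1L, insertions$insertion_coord[ok] - window_bp),
                     insertions$insertion_coord[ok] + window_bp))
  n <- GenomicRanges::countOverlaps(q, annotation_gff, ignore.strand = TRUE)
  flags[ok] <- n >= min_count
  flags
}

#' Re-map an ambiguous junction query with an extended flank
#'
#' Re-extracts the junction query with a longer flank (default 6000 bp)
#' from its source contig and re-maps it. If the longer flank resolves the
#' placement to a unique locus the new placement is returned; otherwise
#' the original is returned with a reason.
#'
#' @param jq The original `junction_query`.
#' @param contigs Named character vector of contigs.
#' @param reference,canonical_te,scoring As in [map_junction()].
#' @param flank_len_bp Extended flank length.
#' @param ... Further arguments to [map_junction()].
#' @return A `placement`; its `resolved_by_extension` field records the
#'   outcome.
#' @export
resolve_ambiguous <- function(jq, contigs, reference, canonical_te,
                              scoring = scoring_params(),
                              flank_len_bp = 6000, ...) {
  original <- map_junction(jq, reference, canonical_te, scoring, ...)
  jq2 <- extract_junction_query(contigs, jq$hit, flank_len_bp)
  # a contig must offer a meaningfully longer flank (at least 1.5x) for the
  # re-mapping to stand a chance of separating repeat copies
  if (isTRUE(jq2$rejected) ||
      jq2$actual_flank_bp < 1.5 * jq$actual_flank_bp) {
    original$resolved_by_extension <- FALSE
    original$extension_reason <- "no extension possible"
    return(original)
  }
  extended <- map_junction(jq2, reference, canonical_te, scoring, ...)
  if (isTRUE(extended$placed) && nrow(extended$secondary) == 0L) {
    extended$resolved_by_extension <- TRUE
    return(extended)
  }
  original$resolved_by_extension <- FALSE
  original$extension_reason <- "still ambiguous at extended flank"
  original
}
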