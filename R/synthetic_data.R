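#' Random nucleotide sequence
#'
#' @param n Length in bases.
#' @return A character scalar of `n` uniformly drawn A/C/G/T.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic transposon library
#'
#' Builds `n_families` artificial class-II element families with perfect
#' terminal inverted repeats (a random TIR at the 5' end, its reverse
#' complement at the 3' end) around random internal sequence. Family sizes
#' default to a spread of realistic DNA-transposon lengths.
#'
#' @param n_families Number of families.
#' @param lengths,tir_lengths Integer vectors (recycled) of element and TIR
#'   lengths.
#' @param seed Random seed (mandatory: the library is part of the simulated
#'   truth).
#' @return A [te_library()] whose element names are `synTE1`, `synTE2`, ...
#' @export
make_synthetic_library <- function(n_families = 5,
                                   lengths = c(2907L, 1728L, 2121L, 1666L, 1435L),
                                   tir_lengths = c(31L, 26L, 26L, 26L, 33L),
                                   seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  lengths <- rep_len(as.integer(lengths), n_families)
  tir_lengths <- rep_len(as.integer(tir_lengths), n_families)
  seqs <- character(n_families)
  for (i in seq_len(n_families)) {
    tir <- random_dna(tir_lengths[i])
    internal <- random_dna(lengths[i] - 2L * tir_lengths[i])
    seqs[i] <- paste0(tir, internal, revcomp(tir))
  }
  names(seqs) <- paste0("synTE", seq_len(n_families))
  te_library(seqs,
             data.frame(name = names(seqs), length_bp = lengths,
                        tir_length_bp = tir_lengths,
                        ref_copy_number = 0L),
             exclude = character(0))
}

#' Simulation parameters
#'
#' Defines the study conditions the simulator emulates: a multi-chromosome
#' reference, implanted element copies that are conserved (present in the
#' reference) or sample-specific, 8-nt target site duplications, a fraction
#' of copies carrying a fixed internal deletion (KP-style), and contigs
#' fragmented from the sample genome with tunable noise and optional
#' contig-end truncation of elements.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gene_count,mean_gene_length Synthetic gene annotation shape.
#' @param het_fraction Fraction of each chromosome (from its start, a
#'   pericentromere stand-in) marked heterochromatic.
#' @param het_chromosomes Chromosomes treated as wholly heterochromatic
#'   (the Y-chromosome analogue); must be listed in `chrom_lengths` to
#'   take effect.
#' @param n_conserved,n_specific Implant counts by truth status.
#' @param unannotated_fraction Fraction of conserved implants deliberately
#'   omitted from the reference TE annotation (emulating annotation gaps).
#' @param deletion_fraction Fraction of implants carrying the internal
#'   deletion, among families long enough to host it.
#' @param deletion_interval Closed canonical-coordinate interval removed in
#'   deletion carriers (default the KP-style 806-2561).
#' @param tsd_len Target site duplication length (bp).
#' @param contig_length,contig_overlap Contig tiling of the sample genome.
#' @param substitution_rate,indel_rate Per-base contig noise rates in [0,1].
#' @param truncation_prob Per-specific-implant probability that a contig
#'   boundary is forced inside the element, leaving a remnant shorter than
#'   `truncation_remnant`.
#' @param truncation_remnant Length (bp) of the element remnant left by a
#'   forced truncation; below the 800-bp completeness threshold.
#' @param min_spacing Minimum distance between implants (bp).
#' @param edge_margin Implants are kept at least this far from chromosome
#'   ends so full flanks exist.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(chrom_lengths = c(chr2L = 400000L, chr2R = 400000L,
                                         chr3L = 400000L, chr3R = 400000L,
                                         chrX = 400000L),
                       gene_count = 300L, mean_gene_length = 2000L,
                       het_fraction = 0.2, het_chromosomes = "chrY",
                       n_conserved = 10L, n_specific = 20L,
                       unannotated_fraction = 0.3,
                       deletion_fraction = 0.2,
                       deletion_interval = c(806L, 2561L),
                       tsd_len = 8L,
                       contig_length = 50000L, contig_overlap = 8000L,
                       substitution_rate = 0, indel_rate = 0,
                       truncation_prob = 0, truncation_remnant = 400L,
                       min_spacing = 12000L, edge_margin = 10000L) {
  p <- list(chrom_lengths = chrom_lengths, gene_count = as.integer(gene_count),
            mean_gene_length = as.integer(mean_gene_length),
            het_fraction = het_fraction, het_chromosomes = het_chromosomes,
            n_conserved = as.integer(n_conserved),
            n_specific = as.integer(n_specific),
            unannotated_fraction = unannotated_fraction,
            deletion_fraction = deletion_fraction,
            deletion_interval = as.integer(deletion_interval),
            tsd_len = as.integer(tsd_len),
            contig_length = as.integer(contig_length),
            contig_overlap = as.integer(contig_overlap),
            substitution_rate = substitution_rate, indel_rate = indel_rate,
            truncation_prob = truncation_prob,
            truncation_remnant = as.integer(truncation_remnant),
            min_spacing = as.integer(min_spacing),
            edge_margin = as.integer(edge_margin))
  rates <- c(het_fraction = het_fraction,
             unannotated_fraction = unannotated_fraction,
             deletion_fraction = deletion_fraction,
             substitution_rate = substitution_rate, indel_rate = indel_rate,
             truncation_prob = truncation_prob)
  bad <- rates < 0 | rates > 1
  if (any(bad)) stop("rate(s) outside [0,1]: ",
                     paste(names(rates)[bad], collapse = ", "))
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (p$contig_overlap >= p$contig_length)
    stop("contig_overlap must be smaller than contig_length")
  structure(p, class = "sim_params")
}

# draw implant positions on chromosomes, respecting spacing and margins
draw_positions <- function(chrom_lengths, n, min_spacing, edge_margin,
                           taken = data.frame(chromosome = character(0),
                                              pos = integer(0)),
                           max_retries = 1000L) {
  out <- data.frame(chromosome = character(0), pos = integer(0))
  probs <- chrom_lengths / sum(chrom_lengths)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      chrom <- sample(names(chrom_lengths), 1L, prob = probs)
      lo <- edge_margin
      hi <- chrom_lengths[[chrom]] - edge_margin
      if (hi <= lo) next
      pos <- as.integer(floor(runif(1, lo, hi)))
      near <- c(taken$pos[taken$chromosome == chrom],
                out$pos[out$chromosome == chrom])
      if (!length(near) || min(abs(near - pos)) >= min_spacing) {
        out <- rbind(out, data.frame(chromosome = chrom, pos = pos))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place implant ", i,
                  " after ", max_retries, " retries; reduce min_spacing or counts")
  }
  out
}

# assign families and deletion-carrier status to n implants
assign_families <- function(lib, n, deletion_fraction, deletion_interval,
                            internal_ext_bp = 100L) {
  fams <- lib$records$name
  fam <- fams[((seq_len(n) - 1L) %% length(fams)) + 1L]  # every family used
  fam <- sample(fam)                                     # in random order
  eligible <- vapply(fam, function(f) {
    r <- lib$records[lib$records$name == f, ]
    deletion_interval[1] > r$tir_length_bp + internal_ext_bp &&
      deletion_interval[2] < r$length_bp - (r$tir_length_bp + internal_ext_bp)
  }, logical(1))
  carrier <- eligible & (runif(n) < deletion_fraction)
  data.frame(element_name = fam, carrier = carrier, stringsAsFactors = FALSE)
}

implant_seq <- function(lib, element, carrier, deletion_interval) {
  s <- lib$sequences[[element]]
  if (carrier) {
    s <- paste0(substr(s, 1L, deletion_interval[1] - 1L),
                substr(s, deletion_interval[2] + 1L, nchar(s)))
  }
  s
}

# splice implants (sorted data.frame: pos, seq) into one chromosome string;
# returns list(sequence, offsets) where offsets[i] is the final coordinate of
# the last base before implant i's inserted material
splice_implants <- function(base, pos, ins) {
  o <- order(pos)
  pos <- pos[o]; ins <- ins[o]
  pieces <- character(0)
  coords <- integer(length(pos))
  prev <- 0L; shift <- 0L
  for (i in seq_along(pos)) {
    pieces <- c(pieces, substr(base, prev + 1L, pos[i]), ins[i])
    coords[i] <- pos[i] + shift
    shift <- shift + nchar(ins[i])
    prev <- pos[i]
  }
  pieces <- c(pieces, substr(base, prev + 1L, nchar(base)))
  list(sequence = paste(pieces, collapse = ""), coords = coords, order = o)
}

#' Generate a synthetic reference genome with conserved implants
#'
#' Builds random chromosomes, implants the conserved element copies (each
#' flanked by a duplicated target-site k-mer), tiles a synthetic gene
#' annotation, and defines a heterochromatin interval set. A configurable
#' fraction of conserved implants is deliberately left out of the TE
#' annotation to emulate annotation gaps in real references.
#'
#' @param lib A [te_library()].
#' @param params A [sim_params()] object.
#' @param seed Random seed; fixing it fixes every output byte-for-byte.
#' @return Object of class `reference_bundle`: `reference` (named character
#'   vector), `genes`, `te_annotation`, `heterochromatin` (GRanges),
#'   `truth_conserved` (data.frame), plus the library and parameters.
#' @export
generate_reference <- function(lib, params, seed) {
  stopifnot(inherits(params, "sim_params"), !missing(seed))
  set.seed(seed)
  chroms <- params$chrom_lengths
  base <- setNames(vapply(chroms, random_dna, character(1)), names(chroms))

  total_implant_len <- params$n_conserved * max(lib$records$length_bp)
  if (any(chroms < 2 * params$edge_margin) ||
      total_implant_len > sum(chroms) / 2) {
    stop("implants exceed chromosome capacity for these parameters")
  }

  fam <- assign_families(lib, params$n_conserved, params$deletion_fraction,
                         params$deletion_interval)
  pos <- draw_positions(chroms, params$n_conserved, params$min_spacing,
                        params$edge_margin)
  truth <- cbind(fam, pos)
  truth$tsd_sequence <- vapply(seq_len(nrow(truth)), function(i) {
    substr(base[[truth$chromosome[i]]],
           truth$pos[i] - params$tsd_len + 1L, truth$pos[i])
  }, character(1))
  truth$insert_seq <- vapply(seq_len(nrow(truth)), function(i) {
    implant_seq(lib, truth$element_name[i], truth$carrier[i],
                params$deletion_interval)
  }, character(1))

  reference <- base
  truth$insertion_coord <- rep(NA_integer_, nrow(truth))
  for (ch in names(chroms)) {
    idx <- which(truth$chromosome == ch)
    if (!length(idx)) next
    sp <- splice_implants(base[[ch]], truth$pos[idx],
                          paste0(truth$insert_seq[idx], truth$tsd_sequence[idx]))
    reference[[ch]] <- sp$sequence
    truth$insertion_coord[idx[sp$order]] <- sp$coords
  }
  truth$element_start <- truth$insertion_coord + 1L
  truth$element_end <- truth$insertion_coord + nchar(truth$insert_seq)
  truth$annotated <- rep(TRUE, nrow(truth))
  n_un <- floor(params$unannotated_fraction * nrow(truth))
  if (n_un > 0) truth$annotated[sample(nrow(truth), n_un)] <- FALSE

  n_ann <- sum(truth$annotated)
  te_annotation <- GenomicRanges::GRanges(
    seqnames = truth$chromosome[truth$annotated],
    ranges = IRanges::IRanges(truth$element_start[truth$annotated],
                              truth$element_end[truth$annotated]),
    strand = rep("+", n_ann),
    type = rep("transposable_element", n_ann),
    ID = sprintf("TE%04d", which(truth$annotated)),
    Name = truth$element_name[truth$annotated])

  genes <- simulate_genes(names(chroms), chroms, params)
  het <- simulate_heterochromatin(names(chroms), chroms, params)

  truth$status_truth <- rep("conserved", nrow(truth))
  truth$deletion_start <- ifelse(truth$carrier, params$deletion_interval[1], NA_integer_)
  truth$deletion_end <- ifelse(truth$carrier, params$deletion_interval[2], NA_integer_)
  truth$full_length_flag <- !truth$carrier

  structure(list(reference = reference, genes = genes,
                 te_annotation = te_annotation, heterochromatin = het,
                 truth_conserved = truth, library = lib, params = params),
            class = "reference_bundle")
}

simulate_genes <- function(chrom_names, chroms, params) {
  n_per <- pmax(1L, round(params$gene_count * chroms / sum(chroms)))
  gr_list <- lapply(seq_along(chrom_names), function(i) {
    n <- n_per[i]
    step <- floor(chroms[i] / (n + 1))
    starts <- as.integer(step * seq_len(n) -
                           round(runif(n, 0, step / 4)))
    widths <- pmax(300L, as.integer(round(
      params$mean_gene_length * (0.5 + runif(n)))))
    ends <- pmin(starts + widths - 1L, chroms[i])
    GenomicRanges::GRanges(chrom_names[i], IRanges::IRanges(starts, ends),
                           strand = sample(c("+", "-"), n, replace = TRUE))
  })
  gr <- suppressWarnings(do.call(c, gr_list))
  gr$type <- "gene"
  gr$ID <- sprintf("gene%04d", seq_along(gr))
  gr$Name <- gr$ID
  gr
}

simulate_heterochromatin <- function(chrom_names, chroms, params) {
  if (params$het_fraction == 0) {
    return(GenomicRanges::GRanges())
  }
  widths <- as.integer(round(params$het_fraction * chroms))
  keep <- widths >= 1L
  GenomicRanges::GRanges(chrom_names[keep],
                         IRanges::IRanges(1L, widths[keep]))
}

#' Implant sample-specific insertions into the reference
#'
#' Each specific implant inserts a canonical (optionally internally deleted)
#' element sequence at a uniformly drawn position, flanked by a duplicated
#' `tsd_len`-mer of the sequence immediately 5' of the insertion point.
#' Truth coordinates are recorded in reference coordinates, with the
#' insertion coordinate being the last reference base before the inserted
#' material.
#'
#' @param ref_bundle A [generate_reference()] result.
#' @param seed Random seed.
#' @return Object of class `sample_bundle`: `sample_genome` (named character
#'   vector), `truth` (full truth table, conserved + specific rows), and the
#'   originating `reference_bundle`.
#' @export
implant_insertions <- function(ref_bundle, seed) {
  stopifnot(inherits(ref_bundle, "reference_bundle"), !missing(seed))
  set.seed(seed)
  params <- ref_bundle$params
  lib <- ref_bundle$library
  reference <- ref_bundle$reference
  chroms <- setNames(nchar(reference), names(reference))

  fam <- assign_families(lib, params$n_specific, params$deletion_fraction,
                         params$deletion_interval)
  taken <- data.frame(chromosome = ref_bundle$truth_conserved$chromosome,
                      pos = ref_bundle$truth_conserved$insertion_coord)
  pos <- draw_positions(chroms, params$n_specific, params$min_spacing,
                        params$edge_margin, taken = taken)
  truth <- cbind(fam, pos)
  truth$insertion_coord <- truth$pos
  truth$tsd_sequence <- vapply(seq_len(nrow(truth)), function(i) {
    substr(reference[[truth$chromosome[i]]],
           truth$pos[i] - params$tsd_len + 1L, truth$pos[i])
  }, character(1))
  truth$insert_seq <- vapply(seq_len(nrow(truth)), function(i) {
    implant_seq(lib, truth$element_name[i], truth$carrier[i],
                params$deletion_interval)
  }, character(1))

  sample_genome <- reference
  truth$sample_coord <- rep(NA_integer_, nrow(truth))
  for (ch in names(reference)) {
    idx <- which(truth$chromosome == ch)
    if (!length(idx)) next
    sp <- splice_implants(reference[[ch]], truth$pos[idx],
                          paste0(truth$insert_seq[idx], truth$tsd_sequence[idx]))
    sample_genome[[ch]] <- sp$sequence
    truth$sample_coord[idx[sp$order]] <- sp$coords
  }

  truth$status_truth <- rep("specific", nrow(truth))
  truth$deletion_start <- ifelse(truth$carrier, params$deletion_interval[1], NA_integer_)
  truth$deletion_end <- ifelse(truth$carrier, params$deletion_interval[2], NA_integer_)
  truth$full_length_flag <- !truth$carrier
  truth$annotated <- rep(NA, nrow(truth))

  cons <- ref_bundle$truth_conserved
  cons$sample_coord <- cons$insertion_coord
  # shift conserved sample coordinates by specific implants placed upstream
  for (i in seq_len(nrow(cons))) {
    up <- truth$chromosome == cons$chromosome[i] &
      truth$insertion_coord < cons$insertion_coord[i]
    cons$sample_coord[i] <- cons$insertion_coord[i] +
      sum(nchar(truth$insert_seq[up])) + sum(up) * params$tsd_len
  }
  cols <- c("element_name", "chromosome", "insertion_coord", "sample_coord",
            "status_truth", "tsd_sequence", "deletion_start", "deletion_end",
            "full_length_flag", "annotated", "insert_seq", "carrier")
  truth_all <- rbind(cons[, cols], truth[, cols])
  rownames(truth_all) <- NULL

  structure(list(sample_genome = sample_genome, truth = truth_all,
                 reference_bundle = ref_bundle, params = params),
            class = "sample_bundle")
}

# apply substitution / 1-nt indel noise to one sequence
mutate_sequence <- function(s, sub_rate, indel_rate) {
  if (sub_rate == 0 && indel_rate == 0) return(s)
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit)) {
      v[hit] <- vapply(v[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
  }
  if (indel_rate > 0) {
    hit <- which(runif(n) < indel_rate)
    if (length(hit)) {
      ins <- runif(length(hit)) < 0.5
      out <- vector("list", n)
      out[seq_len(n)] <- as.list(v)
      for (k in seq_along(hit)) {
        i <- hit[k]
        if (ins[k]) out[[i]] <- c(sample(c("A", "C", "G", "T"), 1L), v[i])
        else out[[i]] <- character(0)
      }
      v <- unlist(out)
    }
  }
  paste(v, collapse = "")
}

#' Fragment a sample genome into noisy contigs
#'
#' Tiles each chromosome with overlapping windows, optionally forces a
#' contig boundary inside randomly chosen specific implants (leaving an
#' element remnant shorter than the completeness threshold), and applies
#' substitution and 1-nt indel noise at the configured rates.
#'
#' @param sample_bundle An [implant_insertions()] result.
#' @param seed Random seed.
#' @return Object of class `contig_set`: a named character vector of contig
#'   sequences with an `origin` attribute (`data.frame` of contig_id,
#'   chromosome, sample_start, sample_end) and a `truncated_implants`
#'   attribute listing truth rows whose element was deliberately cut.
#' @export
fragment_to_contigs <- function(sample_bundle, seed) {
  stopifnot(inherits(sample_bundle, "sample_bundle"), !missing(seed))
  set.seed(seed)
  params <- sample_bundle$params
  genome <- sample_bundle$sample_genome
  truth <- sample_bundle$truth

  windows <- list()
  for (ch in names(genome)) {
    len <- nchar(genome[[ch]])
    step <- params$contig_length - params$contig_overlap
    starts <- seq(1L, max(1L, len - params$contig_overlap), by = step)
    ends <- pmin(starts + params$contig_length - 1L, len)
    keep <- !duplicated(ends)
    windows[[ch]] <- data.frame(chromosome = ch, start = as.integer(starts[keep]),
                                end = as.integer(ends[keep]))
  }
  win <- do.call(rbind, windows)

  # forced truncation: cut every window containing the whole element so only
  # a sub-threshold remnant of the element remains in the left piece
  truncated <- integer(0)
  spec <- which(truth$status_truth == "specific")
  for (i in spec) {
    if (runif(1) >= params$truncation_prob) next
    es <- truth$sample_coord[i] + 1L
    ee <- truth$sample_coord[i] + nchar(truth$insert_seq[i])
    ch <- truth$chromosome[i]
    hitw <- which(win$chromosome == ch & win$start <= es & win$end >= ee)
    if (!length(hitw)) next
    cut <- es + params$truncation_remnant - 1L
    new_rows <- do.call(rbind, lapply(hitw, function(w) {
      data.frame(chromosome = ch,
                 start = c(win$start[w], cut + 1L),
                 end = c(cut, win$end[w]))
    }))
    win <- rbind(win[-hitw, ], new_rows)
    truncated <- c(truncated, i)
  }
  win <- win[order(win$chromosome, win$start), ]
  rownames(win) <- NULL

  seqs <- vapply(seq_len(nrow(win)), function(k) {
    s <- substr(genome[[win$chromosome[k]]], win$start[k], win$end[k])
    mutate_sequence(s, params$substitution_rate, params$indel_rate)
  }, character(1))
  names(seqs) <- sprintf("tig%05d", seq_len(nrow(win)))
  win$contig_id <- names(seqs)

  structure(seqs,
            origin = win[, c("contig_id", "chromosome", "start", "end")],
            truncated_implants = truncated,
            class = "contig_set")
}

#' Write a simulation to disk as standard formats
#'
#' Writes reference and sample FASTA, contig FASTA, gene and TE GFF3,
#' heterochromatin BED and the truth table TSV.
#'
#' @param sample_bundle An [implant_insertions()] result.
#' @param contigs A [fragment_to_contigs()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sample_bundle, contigs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rb <- sample_bundle$reference_bundle
  paths <- c(reference = file.path(dir, "reference.fa"),
             sample = file.path(dir, "sample.fa"),
             contigs = file.path(dir, "contigs.fa"),
             genes = file.path(dir, "genes.gff3"),
             te = file.path(dir, "te_annotation.gff3"),
             het = file.path(dir, "heterochromatin.bed"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(rb$reference), paths["reference"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sample_bundle$sample_genome),
                              paths["sample"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(as.character(contigs), names(contigs))),
    paths["contigs"])
  rtracklayer::export(rb$genes, paths["genes"], format = "gff3")
  rtracklayer::export(rb$te_annotation, paths["te"], format = "gff3")
  rtracklayer::export(rb$heterochromatin, paths["het"], format = "bed")
  tt <- sample_bundle$truth
  tt$insert_seq <- NULL   # keep the table small; sequences live in FASTA
  write_tsv(tt, paths["truth"])
  invisible(paths)
}

#' Compare insertion calls against a simulation truth table
#'
#' A truth implant counts as recovered when a call of the same element on
#' the same chromosome lies within `coord_tol` of the true insertion
#' coordinate and (optionally) carries the expected status class.
#'
#' @param calls Mapped insertion calls (`data.frame` from the mapping
#'   stage, one row per merged call).
#' @param truth Truth table from [implant_insertions()].
#' @param coord_tol Allowed absolute coordinate error (bp).
#' @param check_status Require the call status to match the truth status
#'   (`specific` vs any `conserved_*`).
#' @return List with `recall`, `n_recovered`, `coord_errors` (per recovered
#'   implant), `tsd_exact_rate` (over recovered specific implants with a
#'   truth TSD), and the per-implant `detail` data.frame.
#' @export
evaluate_calls <- function(calls, truth, coord_tol = 0, check_status = TRUE) {
  detail <- truth[, c("element_name", "chromosome", "insertion_coord",
                      "status_truth", "tsd_sequence")]
  detail$recovered <- FALSE
  detail$coord_error <- NA_integer_
  detail$tsd_called <- NA_character_
  for (i in seq_len(nrow(detail))) {
    cand <- calls$element_name == detail$element_name[i] &
      calls$chromosome == detail$chromosome[i] &
      abs(calls$insertion_coord - detail$insertion_coord[i]) <= coord_tol
    if (check_status) {
      want <- if (detail$status_truth[i] == "specific") "specific"
              else c("conserved_annotated", "conserved_unannotated")
      cand <- cand & calls$status %in% want
    }
    if (any(cand)) {
      j <- which(cand)[which.min(abs(calls$insertion_coord[cand] -
                                       detail$insertion_coord[i]))]
      detail$recovered[i] <- TRUE
      detail$coord_error[i] <- abs(calls$insertion_coord[j] -
                                     detail$insertion_coord[i])
      detail$tsd_called[i] <- calls$tsd[j]
    }
  }
  spec <- detail$status_truth == "specific" & detail$recovered
  tsd_rate <- if (any(spec)) {
    mean(!is.na(detail$tsd_called[spec]) &
           detail$tsd_called[spec] == detail$tsd_sequence[spec])
  } else NA_real_
  list(recall = mean(detail$recovered),
       n_recovered = sum(detail$recovered),
       coord_errors = detail$coord_error[detail$recovered],
       tsd_exact_rate = tsd_rate,
       detail = detail)
}
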