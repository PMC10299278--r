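small_params <- function(...) {
  sim_params(chrom_lengths = c(chr1 = 80000L, chr2 = 80000L),
             n_conserved = 3L, n_specific = 5L, min_spacing = 6000L,
             edge_margin = 5000L, gene_count = 40L, ...)
}

test_that("parameter validation rejects out-of-range rates", {
  expect_error(small_params(substitution_rate = 1.2), "rate")
  expect_error(small_params(truncation_prob = -0.1), "rate")
  expect_error(sim_params(chrom_lengths = c(100000L)), "named")
})

test_that("the same seed reproduces every artifact byte-for-byte", {
  lib <- make_synthetic_library(seed = 1)
  run <- function() {
    rb <- generate_reference(lib, small_params(substitution_rate = 0.005),
                             seed = 5)
    sb <- implant_insertions(rb, seed = 6)
    ct <- fragment_to_contigs(sb, seed = 7)
    list(rb = rb, sb = sb, ct = ct)
  }
  a <- run(); b <- run()
  expect_identical(a$rb$reference, b$rb$reference)
  expect_identical(a$sb$sample_genome, b$sb$sample_genome)
  expect_identical(as.character(a$ct), as.character(b$ct))
  expect_identical(a$sb$truth, b$sb$truth)
})

test_that("conserved implants are annotated minus the configured fraction", {
  lib <- make_synthetic_library(seed = 1)
  p <- sim_params(chrom_lengths = c(chr1 = 200000L, chr2 = 200000L),
                  n_conserved = 10L, n_specific = 0L,
                  unannotated_fraction = 0.3, min_spacing = 6000L,
                  edge_margin = 5000L)
  rb <- generate_reference(lib, p, seed = 9)
  expect_equal(nrow(rb$truth_conserved), 10L)
  expect_equal(length(rb$te_annotation), 7L)   # 3 of 10 deliberately omitted
})

test_that("zero heterochromatin fraction gives an empty interval set", {
  lib <- make_synthetic_library(seed = 1)
  rb <- generate_reference(lib, small_params(het_fraction = 0), seed = 2)
  expect_equal(length(rb$heterochromatin), 0L)
})

test_that("implants carry TSDs and are recoverable at their coordinates", {
  lib <- make_synthetic_library(seed = 1)
  rb <- generate_reference(lib, small_params(deletion_fraction = 1), seed = 3)
  sb <- implant_insertions(rb, seed = 4)
  tt <- sb$truth
  expect_equal(nrow(tt), 8L)
  for (i in seq_len(nrow(tt))) {
    g <- sb$sample_genome[[tt$chromosome[i]]]
    ins <- tt$insert_seq[i]
    k <- nchar(tt$tsd_sequence[i])
    expect_identical(substr(g, tt$sample_coord[i] + 1,
                            tt$sample_coord[i] + nchar(ins)), ins)
    expect_identical(substr(g, tt$sample_coord[i] - k + 1, tt$sample_coord[i]),
                     tt$tsd_sequence[i])
    expect_identical(substr(g, tt$sample_coord[i] + nchar(ins) + 1,
                            tt$sample_coord[i] + nchar(ins) + k),
                     tt$tsd_sequence[i])
  }
  # internally deleted implants have the expected reduced length
  carriers <- tt[tt$carrier, ]
  if (nrow(carriers)) {
    lens <- nchar(carriers$insert_seq)
    full <- lib$records$length_bp[match(carriers$element_name,
                                        lib$records$name)]
    expect_equal(lens, full - (2561 - 806 + 1))
  }
})

test_that("a 2907-nt canonical with the 806-2561 deletion implants 1151 nt", {
  lib <- make_synthetic_library(seed = 1)  # synTE1 has length 2907
  p <- sim_params(chrom_lengths = c(chr1 = 100000L), n_conserved = 0L,
                  n_specific = 1L, deletion_fraction = 1,
                  min_spacing = 5000L, edge_margin = 5000L)
  set.seed(2)
  found <- FALSE
  for (seed in 1:20) {   # families are drawn; find a synTE1 carrier draw
    rb <- generate_reference(lib, p, seed = seed)
    sb <- implant_insertions(rb, seed = seed + 100)
    tt <- sb$truth
    if (tt$element_name[1] == "synTE1" && tt$carrier[1]) {
      expect_equal(nchar(tt$insert_seq[1]), 2907L - 1756L)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("noise-free full-coverage contigs reconstruct the sample genome", {
  lib <- make_synthetic_library(seed = 1)
  p <- small_params(contig_length = 20000L, contig_overlap = 0L)
  rb <- generate_reference(lib, p, seed = 3)
  sb <- implant_insertions(rb, seed = 4)
  ct <- fragment_to_contigs(sb, seed = 5)
  origin <- attr(ct, "origin")
  for (ch in names(sb$sample_genome)) {
    pieces <- unclass(ct)[origin$contig_id[origin$chromosome == ch]]
    expect_identical(paste(pieces, collapse = ""), sb$sample_genome[[ch]])
  }
})

test_that("substitution noise matches its binomial expectation", {
  set.seed(77)
  s <- random_dna(10000)
  m <- tirmap:::mutate_sequence(s, 0.01, 0)
  mm <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.01)
  expect_gte(mm, bounds[1])
  expect_lte(mm, bounds[2])
})

test_that("forced truncation leaves a sub-threshold element remnant", {
  lib <- make_synthetic_library(seed = 1)
  p <- small_params(truncation_prob = 1)
  rb <- generate_reference(lib, p, seed = 3)
  sb <- implant_insertions(rb, seed = 4)
  ct <- fragment_to_contigs(sb, seed = 5)
  cut <- attr(ct, "truncated_implants")
  expect_gt(length(cut), 0)
  origin <- attr(ct, "origin")
  for (i in cut) {
    es <- sb$truth$sample_coord[i] + 1L
    ch <- sb$truth$chromosome[i]
    # the contig ending inside the element keeps < 800 nt of it
    left <- origin[origin$chromosome == ch & origin$start <= es &
                     origin$end >= es & origin$end < es +
                     nchar(sb$truth$insert_seq[i]) - 1L, ]
    expect_gt(nrow(left), 0)
    expect_lt(max(left$end) - es + 1L, 800L)
  }
})

test_that("simulations write standard formats and a truth TSV", {
  lib <- make_synthetic_library(seed = 1)
  rb <- generate_reference(lib, small_params(), seed = 3)
  sb <- implant_insertions(rb, seed = 4)
  ct <- fragment_to_contigs(sb, seed = 5)
  dir <- tempfile()
  paths <- write_simulation(sb, ct, dir)
  expect_true(all(file.exists(paths)))
  tt <- read.delim(paths["truth"])
  expect_equal(nrow(tt), nrow(sb$truth))
  ref <- Biostrings::readDNAStringSet(paths["reference"])
  expect_identical(as.character(ref), rb$reference)
})
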