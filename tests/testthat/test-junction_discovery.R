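test_that("an exact substring is found at its position with full identity", {
  set.seed(42)
  q <- random_dna(131)
  contig <- paste0(random_dna(100), q, random_dna(400))
  hits <- align_query(q, c(tig1 = contig))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 101L)
  expect_equal(hits$end, 231L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$pident, 100)
  expect_equal(hits$qcov, 1)
})

test_that("align_query equals the exhaustive Smith-Waterman oracle", {
  set.seed(43)
  for (rep in 1:12) {
    qlen <- sample(10:50, 1)
    clen <- sample(40:200, 1)
    q <- random_dna(qlen)
    contig <- random_dna(clen)
    # implant a mutated copy half the time so scores are non-trivial
    if (rep %% 2 == 0) {
      pos <- sample(clen - qlen, 1)
      substr(contig, pos, pos + qlen - 1) <- tirmap:::mutate_sequence(q, 0.05, 0)
    }
    ora_f <- oracle_sw(q, contig)
    ora_r <- oracle_sw(revcomp(q), contig)
    best_oracle <- max(ora_f$score, ora_r$score)
    hits <- align_query(q, c(tig = contig), min_score = 1,
                        method = "exhaustive")
    if (best_oracle < 1) {
      expect_true(nrow(hits) == 0 || hits$score[1] == best_oracle)
    } else {
      expect_equal(hits$score[1], best_oracle)
    }
  }
})

test_that("single-substitution query recovers oracle score and coordinates", {
  set.seed(44)
  q <- random_dna(20)
  contig <- paste0(random_dna(20), q, random_dna(20))
  substr(contig, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                    substr(contig, 30, 30))[1]
  ora <- oracle_sw(q, contig)
  hits <- align_query(q, c(tig = contig), min_score = 5, method = "exhaustive")
  expect_equal(hits$score[1], ora$score)
  expect_equal(hits$end[1], ora$b_end)
})

test_that("reverse-strand matches mirror the forward search", {
  set.seed(45)
  q <- random_dna(60)
  contig <- paste0(random_dna(150), revcomp(q), random_dna(150))
  hits <- align_query(q, c(tig = contig))
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 151L)
  expect_equal(hits$end, 210L)
  fwd <- align_query(revcomp(q), c(tig = contig))
  fwd <- fwd[fwd$strand == "+", ]
  expect_equal(fwd$start, hits$start)
  expect_equal(fwd$end, hits$end)
})

test_that("seeded and exhaustive search agree on implanted queries", {
  set.seed(46)
  q <- random_dna(131)
  contig <- paste0(random_dna(5000), tirmap:::mutate_sequence(q, 0.01, 0),
                   random_dna(5000))
  h1 <- align_query(q, c(tig = contig), method = "exhaustive")
  h2 <- align_query(q, c(tig = contig), method = "seed")
  expect_equal(h2$score[1], h1$score[1])
  expect_equal(h2$start[1], h1$start[1])
  expect_equal(h2$end[1], h1$end[1])
})

test_that("filter_hits applies thresholds monotonically", {
  hits <- data.frame(contig_id = "t", start = 1:3, end = 11:13, strand = "+",
                     score = c(30, 20, 10), pident = c(95, 85, 70),
                     qcov = c(1, 1, 1), query_len = 10)
  expect_equal(nrow(filter_hits(hits, 0, 0)), 3L)
  expect_equal(nrow(filter_hits(hits, 90, 0.8)), 1L)
  f1 <- nrow(filter_hits(hits, 80, 0.5))
  f2 <- nrow(filter_hits(hits, 90, 0.5))
  f3 <- nrow(filter_hits(hits, 90, 0.9))
  expect_true(f2 <= f1 && f3 <= f2)
})

test_that("junction query extraction follows the index arithmetic", {
  set.seed(47)
  contig <- random_dna(20000)
  hit <- list(contig_id = "tig", start = 5001L, end = 5131L, strand = "+",
              element_name = "el", end_label = "five_prime")
  jq <- extract_junction_query(c(tig = contig), hit, flank_len_bp = 3000)
  expect_equal(jq$actual_flank_bp, 3000L)
  expect_identical(jq$sequence, substr(contig, 2001, 5131))
  expect_equal(nchar(jq$sequence), jq$actual_flank_bp + jq$span)
  expect_equal(jq$side, "left")

  # flank truncated at the contig start
  hit2 <- list(contig_id = "tig", start = 150L, end = 280L, strand = "+",
               element_name = "el", end_label = "five_prime")
  jq2 <- extract_junction_query(c(tig = contig), hit2, flank_len_bp = 3000)
  expect_equal(jq2$actual_flank_bp, 149L)
  expect_true(jq2$truncated)

  # three-prime hits read flank -> TIR after reverse complement
  hit3 <- list(contig_id = "tig", start = 5001L, end = 5131L, strand = "+",
               element_name = "el", end_label = "three_prime")
  jq3 <- extract_junction_query(c(tig = contig), hit3, flank_len_bp = 3000)
  expect_equal(jq3$side, "right")
  expect_identical(jq3$sequence, revcomp(substr(contig, 5001, 8131)))

  # zero available flank is rejected with a reason
  hit4 <- list(contig_id = "tig", start = 1L, end = 131L, strand = "+",
               element_name = "el", end_label = "five_prime")
  jq4 <- extract_junction_query(c(tig = contig), hit4)
  expect_true(jq4$rejected)
  expect_equal(jq4$reason, "no flank")

  # re-extraction at 6000 doubles the flank when the contig allows
  jq6 <- extract_junction_query(c(tig = contig), hit, flank_len_bp = 6000)
  expect_equal(jq6$actual_flank_bp, 5000L)  # bounded by the contig start
  hit5 <- list(contig_id = "tig", start = 7001L, end = 7131L, strand = "+",
               element_name = "el", end_label = "five_prime")
  expect_equal(extract_junction_query(c(tig = contig), hit5,
                                      flank_len_bp = 6000)$actual_flank_bp,
               6000L)
})

test_that("every intact implanted element end yields a hit at its position", {
  lib <- make_synthetic_library(n_families = 2, lengths = c(1500, 1200),
                                tir_lengths = c(30, 25), seed = 55)
  p <- sim_params(chrom_lengths = c(chr1 = 120000L), n_conserved = 0L,
                  n_specific = 3L, min_spacing = 10000L, edge_margin = 8000L,
                  contig_length = 120000L, contig_overlap = 0L)
  rb <- generate_reference(lib, p, seed = 56)
  sb <- implant_insertions(rb, seed = 57)
  ct <- fragment_to_contigs(sb, seed = 58)
  disc <- discover_junctions(lib, ct)
  tt <- sb$truth
  for (i in seq_len(nrow(tt))) {
    el_start <- tt$sample_coord[i] + 1L
    el_end <- tt$sample_coord[i] + nchar(tt$insert_seq[i])
    h <- disc$hits[disc$hits$element_name == tt$element_name[i], ]
    expect_true(any(h$end_label == "five_prime" & h$start == el_start))
    expect_true(any(h$end_label == "three_prime" & h$end == el_end))
  }
})
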