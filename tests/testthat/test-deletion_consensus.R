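test_that("global aligner agrees with the Needleman-Wunsch oracle", {
  set.seed(61)
  for (rep in 1:15) {
    a <- random_dna(sample(5:60, 1))
    b <- random_dna(sample(5:60, 1))
    al <- nw_align(a, b)
    expect_equal(al$score, oracle_nw_score(a, b))
    # the reported alignment really has the reported score
    expect_equal(rescore_alignment(al), al$score)
    expect_identical(degap(al$aligned_a), a)
    expect_identical(degap(al$aligned_b), b)
  }
})

test_that("copies with internal deletions are extracted and called exactly", {
  set.seed(62)
  lib <- make_synthetic_library(n_families = 1, lengths = 2907,
                                tir_lengths = 31, seed = 63)
  canonical <- lib$sequences[["synTE1"]]
  del <- normalize_deletion(canonical, c(806L, 2561L))
  kp <- paste0(substr(canonical, 1, del[1] - 1),
               substring(canonical, del[2] + 1))
  contigs <- c(full = paste0(random_dna(2000), canonical, random_dna(2000)),
               kp = paste0(random_dna(2000), kp, random_dna(2000)),
               remnant = paste0(random_dna(2000), substr(canonical, 1, 500)))
  copies <- extract_element_copies(contigs, canonical, "synTE1")
  by_tig <- split(copies, vapply(copies, `[[`, character(1), "contig_id"))

  full <- by_tig$full[[1]]
  expect_equal(nrow(full$deletions), 0L)
  expect_true(full$complete)
  expect_equal(detect_internal_deletion(full)$remaining_length, 2907L)

  kp_copy <- by_tig$kp[[1]]
  d <- detect_internal_deletion(kp_copy)
  expect_equal(d$interval, del)
  expect_equal(d$remaining_length, 2907L - 1756L)

  remnant <- by_tig$remnant[[1]]
  expect_false(remnant$complete)
})

test_that("deletion arithmetic matches the canonical KP variants", {
  # remaining length is canonical length minus the deleted span
  expect_equal(2907L - (2560L - 808L + 1L), 1154L)
  set.seed(64)
  lib <- make_synthetic_library(n_families = 1, lengths = 2907,
                                tir_lengths = 31, seed = 65)
  canonical <- lib$sequences[["synTE1"]]
  for (del in list(c(808L, 2560L), c(806L, 2561L))) {
    copy_seq <- paste0(substr(canonical, 1, del[1] - 1),
                       substring(canonical, del[2] + 1))
    contigs <- c(t1 = paste0(random_dna(1500), copy_seq, random_dna(1500)))
    cp <- extract_element_copies(contigs, canonical, "synTE1")[[1]]
    dd <- detect_internal_deletion(cp)
    expect_equal(dd$remaining_length, 2907L - (del[2] - del[1] + 1L))
    expect_equal(dd$interval, normalize_deletion(canonical, del))
  }
})

test_that("progressive alignment handles identical and indel cases", {
  expect_error(build_msa("ACGT"), "insufficient copies")
  msa_id <- build_msa(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                        c = "ACGTACGTAC"))
  expect_false(any(grepl("-", msa_id, fixed = TRUE)))

  # a 2-nt insertion produces exactly one 2-column gap block, same as NW
  set.seed(66)
  s <- random_dna(60)
  s2 <- paste0(substr(s, 1, 30), "GT", substring(s, 31))
  msa2 <- build_msa(c(a = s, b = s2))
  expect_equal(nchar(msa2[["a"]]), 62L)
  gaps <- gregexpr("-+", msa2[["a"]])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 2L)
  al <- nw_align(s, s2)
  expect_equal(rescore_alignment(list(aligned_a = msa2[["a"]],
                                      aligned_b = msa2[["b"]])), al$score)

  # degapping recovers every input, in any input order
  set.seed(67)
  seqs <- setNames(vapply(1:5, function(i)
    tirmap:::mutate_sequence(s, 0.05, 0.01), character(1)), letters[1:5])
  msa5 <- build_msa(seqs)
  expect_equal(length(unique(nchar(msa5))), 1L)
  for (nm in names(seqs)) expect_identical(degap(msa5[[nm]]), seqs[[nm]])
})

test_that("plurality consensus follows the counting rule", {
  # 11 rows: column 1 has 6 A / 5 G -> A; column 2 has 5 A / 5 G / 1 gap -> N
  rows <- c(rep("AA", 5), "AG", rep("GG", 4), "G-")
  cons <- consensus_from_msa(rows)
  expect_equal(cons$consensus_sequence, "AN")
  # majority-gap columns are dropped
  rows2 <- c("A-C", "A-C", "AGC", "A-C", "A-C")
  expect_equal(consensus_from_msa(rows2)$consensus_sequence, "AC")
  # identical inputs reproduce themselves (idempotence)
  set.seed(68)
  s <- random_dna(40)
  expect_equal(consensus_from_msa(rep(s, 7))$consensus_sequence, s)
})

test_that("KP-like consensus recovers breakpoints and sequence", {
  set.seed(69)
  lib <- make_synthetic_library(n_families = 1, lengths = 2907,
                                tir_lengths = 31, seed = 70)
  canonical <- lib$sequences[["synTE1"]]
  del <- normalize_deletion(canonical, c(806L, 2561L))
  kp <- paste0(substr(canonical, 1, del[1] - 1), substring(canonical, del[2] + 1))
  copies <- setNames(vapply(1:11, function(i)
    tirmap:::mutate_sequence(kp, 0.01, 0), character(1)),
    paste0("copy", 1:11))
  msa <- build_msa(copies)
  cons <- consensus_from_msa(msa, canonical = canonical,
                             element_name = "synTE1")
  expect_equal(cons$deletion_interval, del)
  expect_equal(cons$n_copies_used, 11L)
  expect_lte(hamming_frac(cons$consensus_sequence, kp), 0.01)
})

test_that("K2P distance matches the closed form and flags saturation", {
  expect_equal(kimura_distance("ACGTACGT", "ACGTACGT"), 0)
  expect_equal(kimura_from_pq(0.1, 0.05), 0.17018, tolerance = 1e-4)
  expect_equal(kimura_from_pq(0.1, 0), -0.5 * log(0.8))
  sat <- kimura_from_pq(0.45, 0.45)
  expect_true(is.na(sat))
  expect_true(attr(sat, "saturated"))
  # grid agreement with the closed form
  for (p in seq(0, 0.3, by = 0.05)) for (q in seq(0, 0.2, by = 0.05)) {
    expect_equal(kimura_from_pq(p, q),
                 -0.5 * log((1 - 2 * p - q) * sqrt(1 - 2 * q)),
                 tolerance = 1e-12)
  }
  # gap columns are excluded
  expect_equal(kimura_distance("AC-GT", "AC-GT"), 0)
})

test_that("K2P distance agrees with an independent phylogenetic implementation", {
  set.seed(71)
  a <- random_dna(2000)
  b <- tirmap:::mutate_sequence(a, 0.08, 0)
  d_pkg <- kimura_distance(a, b)
  m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
  d_ape <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
  expect_equal(d_pkg, d_ape, tolerance = 1e-9)
})

test_that("divergence landscape conserves total aligned bp", {
  set.seed(72)
  cons <- random_dna(500)
  mk_copy <- function(rate, el = "fam1") {
    structure(list(element_name = el,
                   copy_sequence = tirmap:::mutate_sequence(cons, rate, 0)),
              class = "element_copy")
  }
  copies <- c(lapply(rep(0.01, 3), mk_copy), lapply(rep(0.12, 2), mk_copy))
  land <- divergence_landscape(copies, list(fam1 = cons), bin_width = 0.05)
  expect_equal(sum(land$bp_covered),
               sum(vapply(copies, function(cp) nchar(cp$copy_sequence),
                          numeric(1))))
  expect_equal(sort(unique(land$bin_start)), c(0, 0.1))
  # identical copies all land in the first bin
  same <- lapply(1:3, function(i) mk_copy(0))
  land0 <- divergence_landscape(same, list(fam1 = cons), bin_width = 0.05)
  expect_equal(land0$bin_start, 0)
  expect_equal(land0$bp_covered, 1500)
  # no copies -> empty landscape; no consensus -> skipped with warning
  expect_equal(nrow(divergence_landscape(list(), list(fam1 = cons))), 0L)
  expect_warning(divergence_landscape(list(mk_copy(0, "unknown")),
                                      list(fam1 = cons)), "no consensus")
})
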