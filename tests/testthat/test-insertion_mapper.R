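# build a one-chromosome sample with one implant and return the pieces
implant_case <- function(seed = 11, ref_len = 60000L, coord = 30000L,
                         tsd_len = 8L) {
  set.seed(seed)
  lib <- make_synthetic_library(n_families = 1, lengths = 1500,
                                tir_lengths = 30, seed = seed + 1)
  ref <- setNames(random_dna(ref_len), "chr1")
  el <- lib$sequences[["synTE1"]]
  tsd <- substr(ref[["chr1"]], coord - tsd_len + 1L, coord)
  sample_chr <- paste0(substr(ref[["chr1"]], 1, coord), el, tsd,
                       substring(ref[["chr1"]], coord + 1))
  list(lib = lib, ref = ref, coord = coord, tsd = tsd,
       sample = setNames(sample_chr, "chr1"), element = el)
}

test_that("a specific implant maps as a split placement at the exact coordinate", {
  cs <- implant_case()
  contig <- c(tig1 = substr(cs$sample[["chr1"]], cs$coord - 5000,
                            cs$coord + nchar(cs$element) + 5000))
  res <- map_sample(cs$lib, contig, cs$ref, NULL)
  ins <- res$insertions
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$status, "specific")
  expect_equal(ins$insertion_coord, cs$coord)
  expect_equal(ins$tsd, cs$tsd)
  expect_equal(ins$n_support, 2L)   # both junctions merged into one call
})

test_that("a JQ that is an exact reference substring places contiguously", {
  cs <- implant_case(seed = 21)
  # the element is present in the reference itself: conserved insertion
  ref2 <- cs$sample
  contig <- c(tig1 = substr(ref2[["chr1"]], cs$coord - 5000,
                            cs$coord + nchar(cs$element) + 5000))
  res <- map_sample(cs$lib, contig, ref2, NULL)
  ins <- res$insertions
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$status, "conserved_unannotated")
  expect_equal(ins$insertion_coord, cs$coord)

  # with a same-family annotation record the call becomes annotated
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    cs$coord + 1L, cs$coord + nchar(cs$element)), Name = "synTE1")
  res2 <- map_sample(cs$lib, contig, ref2, ann)
  expect_equal(res2$insertions$status, "conserved_annotated")
})

test_that("a flank matching two identical repeats is ambiguous and resolves at 6000", {
  set.seed(31)
  lib <- make_synthetic_library(n_families = 1, lengths = 1500,
                                tir_lengths = 30, seed = 32)
  rep_seq <- random_dna(4000)
  ref_chr <- paste0(random_dna(10000), rep_seq, random_dna(20000),
                    rep_seq, random_dna(10000))
  ref <- setNames(ref_chr, "chr1")
  coord <- 14000L   # end of the first repeat copy
  el <- lib$sequences[["synTE1"]]
  tsd <- substr(ref_chr, coord - 7L, coord)
  sample_chr <- paste0(substr(ref_chr, 1, coord), el, tsd,
                       substring(ref_chr, coord + 1))
  contig <- c(tig1 = substr(sample_chr, coord - 6900, coord + 2000))
  disc <- discover_junctions(lib, contig)
  left <- Filter(function(j) j$side == "left", disc$jqs)
  expect_gte(length(left), 1L)
  jq <- left[[1]]
  pl <- map_junction(jq, ref, el)
  expect_gte(nrow(pl$secondary), 1L)
  call <- classify_insertion(pl, NULL)
  expect_equal(call$status, "ambiguous")

  pl6 <- resolve_ambiguous(jq, contig, ref, el)
  expect_true(pl6$resolved_by_extension)
  call6 <- classify_insertion(pl6, NULL)
  expect_equal(call6$status, "specific")
  expect_equal(call6$insertion_coord, coord)

  # a contig too short for extension reports why it stayed put
  short_contig <- c(tig1 = substr(sample_chr, coord - 3100, coord + 2000))
  disc2 <- discover_junctions(lib, short_contig)
  left2 <- Filter(function(j) j$side == "left", disc2$jqs)[[1]]
  pls <- resolve_ambiguous(left2, short_contig, ref, el)
  expect_false(pls$resolved_by_extension)
  expect_equal(pls$extension_reason, "no extension possible")
})

test_that("short flanks are unresolvable with a chromosome hint", {
  cs <- implant_case(seed = 41)
  contig <- c(tig1 = substr(cs$sample[["chr1"]], cs$coord - 5000,
                            cs$coord + nchar(cs$element) + 5000))
  disc <- discover_junctions(cs$lib, contig)
  jq <- disc$jqs[[1]]
  pl <- map_junction(jq, cs$ref, cs$element)
  call <- classify_insertion(pl, NULL, min_flank = 5000L)
  expect_equal(call$status, "unresolvable")
  expect_equal(call$arm_hint, "chr1")
})

test_that("TSD detection returns the longest duplicated terminal k-mer", {
  set.seed(51)
  left <- paste0(random_dna(20), "ATCGGTAC")
  right <- paste0("ATCGGTAC", random_dna(20))
  td <- detect_tsd(list(left = left, right = right))
  expect_equal(td$tsd, "ATCGGTAC")
  expect_equal(td$k, 8L)

  # a 10-mer duplication is reported in full, not as its 8-mer suffix
  dup <- "GATTACAGGT"
  td10 <- detect_tsd(list(left = paste0("CCCCCCCCCC", dup),
                          right = paste0(dup, "CCCCCCCCCC")))
  expect_equal(td10$k, 10L)
  expect_equal(td10$tsd, dup)

  # flanks sharing no terminal k-mer
  none <- detect_tsd(list(left = "ACGTACGTACGT", right = "TTGGCCAATTGG"))
  expect_null(none$tsd)
  expect_match(none$reason, "no terminal duplication")

  # unavailable flanks (single-TIR detections)
  miss <- detect_tsd(list(left = NULL, right = "ACGT"))
  expect_null(miss$tsd)
  expect_equal(miss$reason, "flanks unavailable")
})

test_that("merging respects the coordinate tolerance boundary", {
  row <- function(coord, contig) {
    data.frame(element_name = "el", chromosome = "chr1",
               insertion_coord = coord, status = "specific",
               arm_hint = NA, tsd = NA_character_,
               supporting_contigs = contig, side = "left",
               end_label = "five_prime", breakpoint = coord, strand = "+",
               score = 100, n_secondary = 0L, hit_start = 1L, hit_end = 10L,
               reason = NA, stringsAsFactors = FALSE)
  }
  two <- rbind(row(1000L, "a"), row(1020L, "b"))
  m <- merge_redundant(two, coord_tolerance = 20L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$supporting_contigs, "a,b")
  apart <- rbind(row(1000L, "a"), row(1021L, "b"))
  expect_equal(nrow(merge_redundant(apart, coord_tolerance = 20L)), 2L)
  # different families never merge
  other <- rbind(row(1000L, "a"),
                 transform(row(1000L, "b"), element_name = "el2"))
  expect_equal(nrow(merge_redundant(other, coord_tolerance = 20L)), 2L)
})

test_that("hotspot flagging applies the count and window definition", {
  ins <- data.frame(element_name = "el", chromosome = "chr1",
                    insertion_coord = 5000L)
  ann_at <- function(coords) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(coords, coords + 10L))
  }
  expect_true(flag_hotspot(ins, ann_at(c(4980, 5000, 5040)),
                           window_bp = 50, min_count = 3))
  expect_false(flag_hotspot(ins, ann_at(c(4980, 5000)),
                            window_bp = 50, min_count = 3))
  # three records just beyond the window do not qualify
  expect_false(flag_hotspot(ins, ann_at(c(5062, 5065, 5070)),
                            window_bp = 50, min_count = 3))
  expect_true(flag_hotspot(ins, ann_at(c(5050, 5050, 5050)),
                           window_bp = 50, min_count = 3))
})
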