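#' Default element exclude list
#'
#' Families conventionally excluded from TIR-anchored discovery in
#' *D. melanogaster* because curated TIR metadata is unavailable or the
#' family is too abundant/mis-annotated to map reliably (1360).
#'
#' @return Character vector of element names.
#' @export
te_default_exclude <- function() {
  c("1360", "looper1", "FB", "hopper2", "INE-1", "Tc1-2")
}

# "29-31" style ranged TIR lengths are stored as their maximum: a longer
# anchor only extends the query further into genuinely element-internal
# sequence
parse_tir_length <- function(x) {
  x <- gsub("–", "-", as.character(x))   # en-dash tolerated
  vapply(x, function(v) {
    parts <- suppressWarnings(as.integer(strsplit(v, "-", fixed = TRUE)[[1]]))
    if (anyNA(parts)) stop("unparseable TIR length: ", v)
    max(parts)
  }, integer(1), USE.NAMES = FALSE)
}

#' Construct a transposon library
#'
#' A library couples canonical element sequences with per-element metadata
#' (element length, terminal-inverted-repeat length, annotated reference
#' copy number). Records violating the library invariants are collected in
#' `$invalid` with a reason, not silently dropped.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   canonical element sequences.
#' @param metadata `data.frame` with columns `name`, `length_bp`,
#'   `tir_length_bp` (ranged entries such as `"29-31"` are stored as their
#'   maximum), `ref_copy_number`.
#' @param exclude Element names representable in the metadata but excluded
#'   from downstream discovery (see [te_default_exclude()]).
#' @return An object of class `te_library` with components `records`
#'   (validated metadata), `sequences` (named character vector), `invalid`
#'   (rejected records with reasons) and `exclude`.
#' @export
te_library <- function(sequences, metadata, exclude = te_default_exclude()) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) && length(sequences) > 0) {
    stop("sequences must be named by element")
  }
  sequences <- vapply(sequences, clean_dna, character(1))
  need <- c("name", "length_bp", "tir_length_bp", "ref_copy_number")
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols)) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  metadata$name <- as.character(metadata$name)
  metadata$length_bp <- as.integer(metadata$length_bp)
  metadata$tir_length_bp <- parse_tir_length(metadata$tir_length_bp)
  metadata$ref_copy_number <- as.integer(metadata$ref_copy_number)

  if (anyDuplicated(metadata$name)) {
    stop("duplicate element name(s) in metadata: ",
         paste(unique(metadata$name[duplicated(metadata$name)]), collapse = ", "))
  }
  no_meta <- setdiff(names(sequences), metadata$name)
  if (length(no_meta)) {
    stop("missing metadata row for element(s): ", paste(no_meta, collapse = ", "))
  }
  no_seq <- setdiff(metadata$name, names(sequences))
  if (length(no_seq)) {
    stop("missing sequence for element(s): ", paste(no_seq, collapse = ", "))
  }
  metadata <- metadata[match(names(sequences), metadata$name), , drop = FALSE]

  # hard errors: declared length must equal the sequence length
  seq_len <- nchar(sequences)[metadata$name]
  bad_len <- metadata$length_bp != unname(seq_len)
  if (any(bad_len)) {
    stop("sequence/metadata length mismatch for: ",
         paste(sprintf("%s (metadata %d, sequence %d)",
                       metadata$name[bad_len], metadata$length_bp[bad_len],
                       seq_len[bad_len]), collapse = "; "))
  }

  # soft invariant: 0 < tir_length < length/2; offenders reported, kept out
  reason <- rep(NA_character_, nrow(metadata))
  bad_tir <- metadata$tir_length_bp <= 0 |
    metadata$tir_length_bp >= metadata$length_bp / 2
  reason[bad_tir] <- "TIR length outside (0, length/2)"
  bad_cn <- !is.na(metadata$ref_copy_number) & metadata$ref_copy_number < 0
  reason[bad_cn & is.na(reason)] <- "negative reference copy number"

  ok <- is.na(reason)
  invalid <- cbind(metadata[!ok, , drop = FALSE],
                   reason = reason[!ok])
  if (nrow(invalid)) {
    warning("dropping ", nrow(invalid), " invalid record(s): ",
            paste(invalid$name, collapse = ", "))
  }
  if (length(sequences) == 0L) warning("empty transposon library")

  structure(list(records = metadata[ok, , drop = FALSE],
                 sequences = sequences[metadata$name[ok]],
                 invalid = invalid,
                 exclude = exclude),
            class = "te_library")
}

#' @export
print.te_library <- function(x, ...) {
  cat("te_library with", nrow(x$records), "element(s)\n")
  if (nrow(x$records)) print(x$records, row.names = FALSE)
  if (nrow(x$invalid)) cat(nrow(x$invalid), "invalid record(s) rejected\n")
  invisible(x)
}

#' @export
length.te_library <- function(x) nrow(x$records)

#' Load a transposon library from FASTA + metadata TSV
#'
#' @param fasta_path FASTA of canonical element sequences; identifiers must
#'   match metadata rows one-to-one.
#' @param metadata_table_path TSV with columns `name`, `length_bp`,
#'   `tir_length_bp`, `ref_copy_number`.
#' @inheritParams te_library
#' @return A [te_library()] object.
#' @export
load_te_library <- function(fasta_path, metadata_table_path,
                            exclude = te_default_exclude()) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- read_tsv(metadata_table_path)
  if (length(seqs) == 0L && nrow(meta) == 0L) {
    return(te_library(character(0),
                      data.frame(name = character(0), length_bp = integer(0),
                                 tir_length_bp = integer(0),
                                 ref_copy_number = integer(0)),
                      exclude = exclude))
  }
  te_library(seqs, meta, exclude = exclude)
}

#' Write a transposon library to FASTA + metadata TSV
#'
#' Round-trips with [load_te_library()].
#'
#' @param lib A `te_library`.
#' @param fasta_path,metadata_table_path Output paths.
#' @return Invisibly, the library.
#' @export
write_te_library <- function(lib, fasta_path, metadata_table_path) {
  stopifnot(inherits(lib, "te_library"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(lib$sequences), fasta_path)
  write_tsv(lib$records, metadata_table_path)
  invisible(lib)
}

lib_record <- function(lib, element) {
  i <- match(element, lib$records$name)
  if (is.na(i)) stop("unknown element: ", element)
  c(as.list(lib$records[i, ]), list(sequence = unname(lib$sequences[[element]])))
}

#' Extract the two TIR-anchored discovery queries of an element
#'
#' The five-prime query is the first `tir_length + internal_ext_bp` bases of
#' the canonical sequence and the three-prime query the last such bases,
#' both reported in the canonical element's own orientation. The internal
#' extension (default 100 bp) makes the two element ends distinguishable.
#'
#' @param lib A `te_library`.
#' @param element Element name.
#' @param internal_ext_bp Internal extension beyond the TIR, in bp.
#' @return `data.frame` with one row per end: `element_name`, `end_label`
#'   (`"five_prime"`/`"three_prime"`), `sequence`, `tir_length_bp`,
#'   `internal_ext_bp`.
#' @export
extract_tir_queries <- function(lib, element, internal_ext_bp = 100) {
  rec <- lib_record(lib, element)
  qlen <- rec$tir_length_bp + internal_ext_bp
  if (rec$length_bp <= qlen) {
    stop(sprintf(
      "element %s (%d bp) too short for TIR+%d bp queries; reduce internal_ext_bp",
      element, rec$length_bp, internal_ext_bp))
  }
  data.frame(
    element_name = element,
    end_label = c("five_prime", "three_prime"),
    sequence = c(substr(rec$sequence, 1L, qlen),
                 substr(rec$sequence, rec$length_bp - qlen + 1L, rec$length_bp)),
    tir_length_bp = rec$tir_length_bp,
    internal_ext_bp = internal_ext_bp,
    stringsAsFactors = FALSE)
}

#' Sanity-check an element's terminal inverted repeats
#'
#' Reports whether the reverse complement of the three-prime TIR matches the
#' five-prime TIR within `max_mismatches` (Hamming). Report-only; never an
#' error.
#'
#' @param lib A `te_library`.
#' @param element Element name.
#' @param max_mismatches Allowed mismatches.
#' @return List with `pass`, `mismatches`, `tir5`, `tir3_rc`.
#' @export
validate_tirs <- function(lib, element, max_mismatches = 2) {
  rec <- lib_record(lib, element)
  t <- rec$tir_length_bp
  tir5 <- substr(rec$sequence, 1L, t)
  tir3 <- substr(rec$sequence, rec$length_bp - t + 1L, rec$length_bp)
  tir3_rc <- revcomp(tir3)
  mm <- hamming(tir5, tir3_rc)
  list(pass = mm <= max_mismatches, mismatches = mm,
       tir5 = tir5, tir3_rc = tir3_rc)
}
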