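insertions_granges <- function(insertions) {
  ok <- !is.na(insertions$insertion_coord) & !is.na(insertions$chromosome)
  GenomicRanges::GRanges(
    insertions$chromosome[ok],
    IRanges::IRanges(insertions$insertion_coord[ok],
                     insertions$insertion_coord[ok]),
    idx = which(ok))
}

#' Assign hit and close genes to insertion calls
#'
#' A gene is "hit" when its span contains the insertion coordinate and
#' "close" when it lies within `window_bp` of it (the flank window:
#' closeness is defined by presence of the gene sequence in the extracted
#' flanking sequence). The two sets are disjoint by construction.
#'
#' @param insertions Insertion-call `data.frame` (`chromosome`,
#'   `insertion_coord`).
#' @param gene_gff `GRanges` of genes carrying a `Name` (or `ID`) column.
#' @param window_bp Closeness window (default 3000, matching the junction
#'   query flank length).
#' @return `data.frame` with one row per insertion: `hit_genes`,
#'   `close_genes` (comma-separated symbols), `close_distances`.
#' @export
assign_genes <- function(insertions, gene_gff, window_bp = 3000L) {
  gene_name <- gene_gff$Name %||% gene_gff$ID
  if (is.null(gene_name)) gene_name <- paste0("gene", seq_along(gene_gff))
  chroms <- unique(insertions$chromosome[!is.na(insertions$chromosome)])
  unknown <- setdiff(chroms, GenomeInfoDb::seqlevels(gene_gff))
  if (length(unknown)) {
    stop("unknown chromosome(s) in insertion calls: ",
         paste(unknown, collapse = ", "))
  }
  out <- data.frame(hit_genes = rep(NA_character_, nrow(insertions)),
                    close_genes = NA_character_,
                    close_distances = NA_character_,
                    stringsAsFactors = FALSE)
  q <- insertions_granges(insertions)
  if (!length(q)) return(out)
  hit <- GenomicRanges::findOverlaps(q, gene_gff, ignore.strand = TRUE)
  # "close" means the gene lies within the flank window: its edge at most
  # window_bp bases away counting the gene's first base (gap + 1)
  near <- GenomicRanges::findOverlaps(q, gene_gff, maxgap = window_bp - 1L,
                                      ignore.strand = TRUE)
  for (i in seq_along(q)) {
    row <- q$idx[i]
    hg <- unique(gene_name[S4Vectors::subjectHits(hit)[
      S4Vectors::queryHits(hit) == i]])
    ng <- S4Vectors::subjectHits(near)[S4Vectors::queryHits(near) == i]
    cg <- setdiff(unique(gene_name[ng]), hg)
    if (length(hg)) out$hit_genes[row] <- paste(hg, collapse = ",")
    if (length(cg)) {
      dists <- vapply(cg, function(g) {
        j <- ng[gene_name[ng] == g]
        min(GenomicRanges::distance(q[i], gene_gff[j],
                                    ignore.strand = TRUE)) + 1L
      }, numeric(1))
      out$close_genes[row] <- paste(cg, collapse = ",")
      out$close_distances[row] <- paste(dists, collapse = ",")
    }
  }
  out
}

#' Heterochromatin membership of insertion calls
#'
#' @param insertions Insertion-call `data.frame`.
#' @param het_bed `GRanges` of heterochromatic intervals.
#' @param het_chromosomes Chromosomes treated as wholly heterochromatic
#'   (the Y chromosome by convention).
#' @return Logical vector, one flag per insertion.
#' @export
classify_heterochromatin <- function(insertions, het_bed,
                                     het_chromosomes = c("Y", "chrY")) {
  flags <- insertions$chromosome %in% het_chromosomes
  flags[is.na(flags)] <- FALSE
  q <- insertions_granges(insertions)
  if (length(q) && !is.null(het_bed) && length(het_bed)) {
    ov <- GenomicRanges::countOverlaps(q, het_bed, ignore.strand = TRUE) > 0
    flags[q$idx] <- flags[q$idx] | ov
  }
  flags
}

#' Insertion density per gene class
#'
#' Computes insertions-per-gene densities for heterochromatic and
#' non-heterochromatic genes, either from explicit incidence counts or
#' from gene assignments plus per-gene heterochromatin flags. The
#' numerator counts insertion-to-gene incidences (an insertion hitting two
#' overlapping genes contributes once to each), matching the convention of
#' published per-gene density figures.
#'
#' @param het_insertions,het_genes,nonhet_insertions,nonhet_genes Explicit
#'   incidence and gene counts.
#' @param assignments Optional [assign_genes()] result (used with
#'   `gene_het_flags` instead of explicit counts).
#' @param gene_het_flags Named logical vector: is each gene
#'   heterochromatic?
#' @return `density_report` list with counts, full-precision densities,
#'   2-decimal display densities, and their ratio. A class with zero genes
#'   yields `NA` density.
#' @export
density_stats <- function(het_insertions = NULL, het_genes = NULL,
                          nonhet_insertions = NULL, nonhet_genes = NULL,
                          assignments = NULL, gene_het_flags = NULL) {
  if (!is.null(assignments)) {
    stopifnot(!is.null(gene_het_flags))
    genes_per_row <- lapply(seq_len(nrow(assignments)), function(i) {
      unique(stats::na.omit(unlist(strsplit(
        c(assignments$hit_genes[i], assignments$close_genes[i]), ","))))
    })
    all_genes <- unique(unlist(genes_per_row))
    het_set <- all_genes[gene_het_flags[all_genes] %in% TRUE]
    nonhet_set <- setdiff(all_genes, het_set)
    incid <- unlist(genes_per_row)
    het_insertions <- sum(incid %in% het_set)
    nonhet_insertions <- sum(incid %in% nonhet_set)
    het_genes <- length(het_set)
    nonhet_genes <- length(nonhet_set)
  }
  dens <- function(n, g) if (g > 0) n / g else NA_real_
  het_density <- dens(het_insertions, het_genes)
  nonhet_density <- dens(nonhet_insertions, nonhet_genes)
  # display values truncate at the second decimal (the convention implied by
  # published per-gene densities such as 137/149 -> 0.91); full precision is
  # retained in het_density / nonhet_density
  show2 <- function(x) if (is.na(x)) NA_real_ else trunc(x * 100) / 100
  structure(list(
    het_gene_count = het_genes, het_insertion_count = het_insertions,
    nonhet_gene_count = nonhet_genes, nonhet_insertion_count = nonhet_insertions,
    het_density = het_density, nonhet_density = nonhet_density,
    het_density_2dp = show2(het_density),
    nonhet_density_2dp = show2(nonhet_density),
    ratio = het_density / nonhet_density), class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("heterochromatic genes: %d, hit by %d insertions (%.2f/gene)\n",
              x$het_gene_count, x$het_insertion_count, x$het_density_2dp))
  cat(sprintf("other genes:           %d, hit by %d insertions (%.2f/gene)\n",
              x$nonhet_gene_count, x$nonhet_insertion_count,
              x$nonhet_density_2dp))
  cat(sprintf("density ratio: %.2f\n", x$ratio))
  invisible(x)
}

#' Per-chromosome insertion frequency
#'
#' @param x Character vector of chromosomes, a `data.frame` with a
#'   `chromosome` column, or a named numeric vector of precomputed counts.
#' @return `data.frame` with `chromosome`, `count` and `percent`
#'   (1 decimal place), sorted by decreasing count. Percentages recomputed
#'   from the counts always reproduce the displayed values.
#' @export
chromosome_frequency <- function(x) {
  counts <- if (is.data.frame(x)) table(x$chromosome)
            else if (!is.null(names(x)) && is.numeric(x)) x
            else table(x)
  counts <- counts[counts > 0]
  if (!length(counts)) {
    return(data.frame(chromosome = character(0), count = integer(0),
                      percent = numeric(0)))
  }
  df <- data.frame(chromosome = names(counts),
                   count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df$percent <- round(100 * df$count / sum(df$count), 1)
  df <- df[order(-df$count, df$chromosome), ]
  rownames(df) <- NULL
  df
}

#' Fraction of insertions in heterochromatin, as a percentage
#'
#' @param n_het Insertions in heterochromatic regions.
#' @param n_total All insertions in the considered set.
#' @param digits Rounding for display (default 1 decimal place).
#' @return Percentage.
#' @export
heterochromatic_fraction <- function(n_het, n_total, digits = 1) {
  round(100 * n_het / n_total, digits)
}

iupac_regex_chars <- c(A = "A", C = "C", G = "G", T = "T",
                       R = "AG", Y = "CT", S = "CG", W = "AT",
                       K = "GT", M = "AC", B = "CGT", D = "AGT",
                       H = "ACT", V = "ACG", N = "ACGT")

#' Best placement of an IUPAC motif in a site
#'
#' Scans both strands of a site for the placement of an IUPAC-degenerate
#' motif with the fewest mismatches (an A/C/G/T base matches a degenerate
#' motif position when it belongs to that position's base set).
#'
#' @param site_sequence Site to scan (A/C/G/T).
#' @param motif_iupac Motif in the IUPAC alphabet (e.g. `"GGCCAGAC"` or
#'   `"ATRGTCCGGACWAT"`).
#' @param max_mismatches Threshold for the match flag.
#' @return List: `match` (best placement within threshold?),
#'   `mismatches`, `start`, `strand`, `site_window`.
#' @export
motif_score <- function(site_sequence, motif_iupac, max_mismatches = 0L) {
  site_sequence <- clean_dna(site_sequence)
  motif_iupac <- toupper(motif_iupac)
  if (!all(strsplit(motif_iupac, "")[[1]] %in% names(iupac_regex_chars))) {
    stop("motif contains non-IUPAC characters")
  }
  m <- nchar(motif_iupac)
  if (m > nchar(site_sequence)) stop("motif longer than site")
  best <- list(mismatches = Inf, start = NA_integer_, strand = NA_character_,
               site_window = NA_character_)
  pat <- Biostrings::DNAString(motif_iupac)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") site_sequence else revcomp(site_sequence)
    subj <- Biostrings::DNAString(s)
    starts <- seq_len(nchar(s) - m + 1L)
    mm <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                      with.indels = FALSE, fixed = "subject")
    i <- which.min(mm)
    if (mm[i] < best$mismatches) {
      st <- if (strand == "+") starts[i] else nchar(s) - (starts[i] + m - 1L) + 1L
      best <- list(mismatches = as.integer(mm[i]), start = st, strand = strand,
                   site_window = substr(s, starts[i], starts[i] + m - 1L))
    }
  }
  best$match <- best$mismatches <= max_mismatches
  best[c("match", "mismatches", "start", "strand", "site_window")]
}

#' Export gene lists for external enrichment analysis
#'
#' Writes (a) the deduplicated genes tagged by sample-specific insertions
#' only and (b) all hit/close genes, one symbol per line, in the plain
#' format accepted by web enrichment tools.
#'
#' @param insertions Insertion-call `data.frame` with `status`.
#' @param assignments Matching [assign_genes()] result.
#' @param dir Output directory.
#' @return Invisibly, a list with the two gene vectors and file paths.
#' @export
export_gene_lists <- function(insertions, assignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes_of <- function(rows) {
    g <- unlist(strsplit(as.character(stats::na.omit(
      c(assignments$hit_genes[rows], assignments$close_genes[rows]))), ","))
    sort(unique(as.character(g %||% character(0))))
  }
  specific <- genes_of(which(insertions$status == "specific"))
  all_genes <- genes_of(seq_len(nrow(insertions)))
  p1 <- file.path(dir, "genes_specific_insertions.txt")
  p2 <- file.path(dir, "genes_all_insertions.txt")
  writeLines(specific, p1)
  writeLines(all_genes, p2)
  invisible(list(specific = specific, all = all_genes, paths = c(p1, p2)))
}
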