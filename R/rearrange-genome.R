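#' Encode two annotated genomes as signed block permutations
#'
#' Gene-order-resolution analog of nucleotide-level collinear-block
#' detection: genes present in both records (normalized names, each present
#' once per genome) are taken in `a`'s coordinate order; maximal runs that
#' are contiguous and co-oriented in both genomes are merged into blocks.
#' Blocks are numbered 1..n along `a` (all +), and `b`'s permutation gives
#' its block order with signs relative to `a`.  Genes absent from either
#' genome are ignored.
#'
#' @param a,b [genome_record()]s sharing at least two gene names.
#' @param frame frame label for the resulting permutations.
#' @return List of two [signed_permutation()]s (`a` first).
#' @export
encode_lcb_permutations <- function(a, b, frame = NULL) {
  gene_tab <- function(rec) {
    f <- rec$features
    g <- f[f$kind == "gene" & f$part == 1L, , drop = FALSE]
    g$norm <- normalize_gene_name(ifelse(is.na(g$name), g$id, g$name))
    g <- g[!g$norm %in% g$norm[duplicated(g$norm)], , drop = FALSE]
    g[order(g$start), , drop = FALSE]
  }
  ga <- gene_tab(a); gb <- gene_tab(b)
  shared <- intersect(ga$norm, gb$norm)
  if (length(shared) < 2L) stop("records share fewer than 2 usable genes")
  ga <- ga[ga$norm %in% shared, , drop = FALSE]
  gb <- gb[gb$norm %in% shared, , drop = FALSE]
  idx_a <- stats::setNames(seq_len(nrow(ga)), ga$norm)
  sgn_a <- stats::setNames(ifelse(ga$strand == "+", 1L, -1L), ga$norm)
  ## b as a signed sequence of a-indices
  seq_b <- idx_a[gb$norm] *
    ifelse(gb$strand == "+", 1L, -1L) * sgn_a[gb$norm]
  ## maximal runs: successive values incrementing by exactly 1 are contiguous
  ## and co-oriented in both genomes (ascending positive, or descending
  ## negative magnitudes)
  brk <- c(TRUE, diff(seq_b) != 1L)
  run_id <- cumsum(brk)
  runs <- split(seq_b, run_id)
  lo <- vapply(runs, function(r) min(abs(r)), numeric(1))
  sign_run <- vapply(runs, function(r) sign(r[1]), numeric(1))
  ## number blocks by their order along a
  block_no <- rank(lo)
  b_perm <- as.integer(block_no * sign_run)
  if (is.null(frame)) frame <- paste0(a$id, "~", b$id)
  list(signed_permutation(seq_len(length(runs)), taxon = a$id, frame = frame),
       signed_permutation(b_perm, taxon = b$id, frame = frame))
}

#' Invert a genomic segment in place
#'
#' Reverse-complements the sequence of `interval` (0-based half-open) and
#' re-coordinates the contained features, flipping their strands.  Errors if
#' an interval endpoint bisects a feature.
#'
#' @param record a [genome_record()].
#' @param interval integer pair `c(start, end)`.
#' @return The modified [genome_record()].
#' @export
apply_inversion <- function(record, interval) {
  s <- interval[1]; e <- interval[2]
  len <- nchar(record$sequence)
  if (s < 0 || e > len || s >= e) stop("invalid interval")
  f <- record$features
  bisect <- (f$start < s & f$end > s) | (f$start < e & f$end > e)
  if (any(bisect)) {
    stop("interval endpoint bisects feature(s): ",
         paste(unique(f$id[bisect]), collapse = ", "))
  }
  ## wrapped features half in/half out also count as bisected
  ins <- f$start >= s & f$end <= e
  half <- tapply(ins, f$id, function(z) length(unique(z)) > 1L)
  if (any(half)) {
    stop("interval splits wrapped feature(s): ",
         paste(names(half)[half], collapse = ", "))
  }
  seg <- substr(record$sequence, s + 1L, e)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  sequence <- paste0(substr(record$sequence, 1L, s), rc,
                     substr(record$sequence, e + 1L, len))
  new_start <- ifelse(ins, s + (e - f$end), f$start)
  new_end <- ifelse(ins, s + (e - f$start), f$end)
  f$start <- as.integer(new_start); f$end <- as.integer(new_end)
  f$strand <- ifelse(ins, ifelse(f$strand == "+", "-", "+"), f$strand)
  genome_record(record$id, sequence, f, record$topology)
}

#' Bundled rearrangement distance table for 15 lycophyte plastomes
#'
#' The published pairwise breakpoint/inversion distance table over 14
#' Selaginellaceae plastomes plus two outgroups, entered from the printed
#' lower-triangle (BP/IV cells).  Used to reproduce the reported correlation
#' between the two distances (r = 0.977 over the 105 pairs).
#'
#' @return Data frame: `taxon_a`, `taxon_b`, `bp`, `iv` (105 rows).
#' @export
lycophyte_distance_table <- function() {
  path <- system.file("extdata", "table2_rearrangement_distances.tsv",
                      package = "plastidyn", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
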