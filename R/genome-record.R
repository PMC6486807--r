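#' Annotated genome records
#'
#' A `genome_record` is the unit of structural analysis: a single circular or
#' linear DNA sequence together with gene, repeat-copy and region features.
#' Coordinates are 0-based half-open internally (GFF3 on disk is 1-based
#' inclusive).  On a circular record a feature may wrap the origin; it is then
#' stored as two sub-interval rows sharing one feature id, with `wrap = TRUE`.
#'
#' @param id genome identifier (FASTA/GFF3 seqid).
#' @param sequence DNA string over A, C, G, T, N (case-insensitive).
#' @param features data frame as produced by [genome_features()]; may be empty.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, features = genome_features(),
                          topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("sequence may contain only A, C, G, T, N")
  }
  rec <- structure(list(id = id, topology = topology, sequence = sequence,
                        features = features),
                   class = "genome_record")
  validate_genome_record(rec)
  rec
}

#' Construct or normalize a genome feature table
#'
#' @param id feature identifiers (unique per feature; wrap parts share an id).
#' @param kind one of `"gene"`, `"repeat_copy"`, `"region"`.
#' @param name gene name or region name (e.g. LSC, SSC, DR_A, IR_B).
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param wrap logical: part of an origin-wrapping feature.
#' @param part sub-interval index (1 for ordinary features).
#' @param pair_id repeat pair identifier for `repeat_copy` features.
#' @param status gene status: intact, pseudo, intron_lost.
#' @return A data frame with one row per feature part.
#' @export
genome_features <- function(id = character(), kind = character(),
                            name = character(), start = integer(),
                            end = integer(), strand = character(),
                            wrap = logical(), part = integer(),
                            pair_id = character(), status = character()) {
  n <- length(id)
  rep_or <- function(x, default) {
    if (length(x) == 0L && n > 0L) rep(default, n) else x
  }
  data.frame(id = as.character(id), kind = as.character(kind),
             name = rep_or(name, NA_character_),
             start = as.integer(start), end = as.integer(end),
             strand = rep_or(strand, "+"),
             wrap = rep_or(wrap, FALSE),
             part = rep_or(as.integer(part), 1L),
             pair_id = rep_or(pair_id, NA_character_),
             status = rep_or(status, "intact"),
             stringsAsFactors = FALSE)
}

#' @rdname genome_record
#' @param x object to validate.
#' @export
validate_genome_record <- function(x) {
  f <- x$features
  len <- nchar(x$sequence)
  if (nrow(f) == 0L) return(invisible(x))
  if (any(f$start >= f$end)) stop("feature parts must satisfy start < end")
  if (any(f$start < 0L) || any(f$end > len)) {
    stop("feature interval outside [0, ", len, ")")
  }
  if (!all(f$strand %in% c("+", "-"))) stop("unknown strand value")
  if (!all(f$kind %in% c("gene", "repeat_copy", "region"))) {
    stop("unknown feature kind")
  }
  if (anyDuplicated(paste(f$id, f$part))) stop("feature ids not unique")
  wrap_ids <- unique(f$id[f$wrap])
  if (any(table(f$id[f$id %in% wrap_ids]) != 2L)) {
    stop("a wrapping feature must have exactly two parts")
  }
  if (length(wrap_ids) > 0L && x$topology != "circular") {
    stop("wrapping features require a circular record")
  }
  invisible(x)
}

#' @export
print.genome_record <- function(x, ...) {
  cat("genome_record", x$id, paste0("(", x$topology, ")"),
      nchar(x$sequence), "bp,", length(unique(x$features$id)), "features\n")
  invisible(x)
}

#' Feature length in bp (summing wrap parts)
#' @param record a `genome_record`.
#' @param feature_id feature identifier.
#' @export
feature_length <- function(record, feature_id) {
  f <- record$features[record$features$id == feature_id, , drop = FALSE]
  if (nrow(f) == 0L) stop("no feature with id ", feature_id)
  sum(f$end - f$start)
}

## lower-case, strip copy suffixes like "_1", "-2"
normalize_gene_name <- function(x) {
  sub("[_-][0-9]+$", "", tolower(x))
}

## ---- FASTA + GFF3 I/O -----------------------------------------------------

#' Read an annotated genome from FASTA + GFF3
#'
#' The FASTA must contain exactly one record whose id matches the GFF3 seqid.
#' GFF3 coordinates (1-based inclusive) are converted to 0-based half-open.
#' A `region` feature carrying `Is_circular=true` sets circular topology.
#' Two feature lines sharing one `ID` are read as the two parts of an
#' origin-wrapping feature.
#'
#' @param seq_path FASTA file with one record.
#' @param ann_path GFF3 annotation file.
#' @return A [genome_record()].
#' @export
read_genome <- function(seq_path, ann_path) {
  seqs <- Biostrings::readDNAStringSet(seq_path)
  if (length(seqs) != 1L) {
    stop("FASTA must contain exactly one record, found ", length(seqs))
  }
  id <- sub("\\s.*$", "", names(seqs)[1])
  sequence <- as.character(seqs[[1]])
  gff <- ape::read.gff(ann_path, GFF3 = TRUE)
  if (nrow(gff) > 0 && !all(gff$seqid == id)) {
    stop("GFF3 seqid does not match FASTA id ", id)
  }
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_,
           character(1))
  }
  topology <- "linear"
  is_region_line <- gff$type == "region"
  circ <- attr_get(gff$attributes, "Is_circular")
  if (any(is_region_line & !is.na(circ) & tolower(circ) == "true")) {
    topology <- "circular"
  }
  keep <- gff$type %in% c("gene", "repeat_region", "region")
  ## drop the whole-sequence topology line itself
  whole <- gff$type == "region" & gff$start == 1 & gff$end == nchar(sequence) &
    !is.na(circ)
  keep <- keep & !whole
  gff <- gff[keep, , drop = FALSE]
  if (nrow(gff) > 0 && any(!as.character(gff$strand) %in% c("+", "-"))) {
    stop("unknown strand in GFF3")
  }
  kind <- c(gene = "gene", repeat_region = "repeat_copy",
            region = "region")[as.character(gff$type)]
  ids <- attr_get(gff$attributes, "ID")
  ids[is.na(ids)] <- paste0("f", seq_len(nrow(gff)))[is.na(ids)]
  wrap <- ids %in% ids[duplicated(ids)]
  part <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  feats <- genome_features(
    id = ids, kind = kind,
    name = attr_get(gff$attributes, "Name"),
    start = gff$start - 1L, end = gff$end,
    strand = as.character(gff$strand),
    wrap = wrap, part = part,
    pair_id = attr_get(gff$attributes, "pair_id"),
    status = ifelse(is.na(attr_get(gff$attributes, "status")), "intact",
                    attr_get(gff$attributes, "status")))
  genome_record(id, sequence, feats, topology)
}

#' Write an annotated genome to FASTA + GFF3
#'
#' Inverse of [read_genome()]: coordinates are converted back to 1-based
#' inclusive and a `region` line with `Is_circular=true` records circular
#' topology.
#'
#' @param record a [genome_record()].
#' @param seq_path output FASTA path.
#' @param ann_path output GFF3 path.
#' @export
write_genome <- function(record, seq_path, ann_path) {
  s <- Biostrings::DNAStringSet(record$sequence)
  names(s) <- record$id
  Biostrings::writeXStringSet(s, seq_path, width = 70L)
  len <- nchar(record$sequence)
  lines <- c("##gff-version 3",
             paste("##sequence-region", record$id, 1L, len))
  circ <- if (record$topology == "circular") ";Is_circular=true" else ""
  lines <- c(lines, paste(record$id, "plastidyn", "region", 1L, len, ".", "+",
                          ".", paste0("ID=", record$id, circ), sep = "\t"))
  f <- record$features
  if (nrow(f) > 0L) {
    type <- c(gene = "gene", repeat_copy = "repeat_region",
              region = "region")[f$kind]
    attrs <- paste0("ID=", f$id)
    attrs <- ifelse(is.na(f$name), attrs, paste0(attrs, ";Name=", f$name))
    attrs <- ifelse(is.na(f$pair_id), attrs,
                    paste0(attrs, ";pair_id=", f$pair_id))
    attrs <- ifelse(f$status == "intact", attrs,
                    paste0(attrs, ";status=", f$status))
    lines <- c(lines, paste(record$id, "plastidyn", type, f$start + 1L, f$end,
                            ".", f$strand, ".", attrs, sep = "\t"))
  }
  writeLines(lines, ann_path)
  invisible(record)
}

## ---- summaries ------------------------------------------------------------

#' GC content of a genome
#'
#' Fraction (G + C) / (A + C + G + T); N bases are excluded from the
#' denominator.
#'
#' @param record a [genome_record()] or a plain DNA string.
#' @return GC fraction in \[0, 1\].
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(record) {
  s <- if (inherits(record, "genome_record")) record$sequence else
    toupper(record)
  if (nchar(s) == 0L) stop("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                        c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0L) stop("sequence contains no unambiguous bases")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

.gene_class <- function(name) {
  ifelse(startsWith(name, "trn"), "trna",
         ifelse(startsWith(name, "rrn"), "rrna", "protein"))
}

#' Summary statistics of an annotated genome
#'
#' Counts of distinct genes by class (protein-coding, tRNA, rRNA), duplicated
#' genes (present in both repeat copies are counted once as "different" and
#' reported separately), GC content, and the size of the large repeat region
#' (one copy).  Genes with `status = "pseudo"` are excluded from the distinct
#' gene counts.
#'
#' @param record a [genome_record()].
#' @return One-row data frame with columns `id`, `size_bp`, `n_genes`,
#'   `n_protein`, `n_trna`, `n_rrna`, `n_protein_dup`, `n_trna_dup`,
#'   `n_rrna_dup`, `gc`, `repeat_region_bp`.
#' @export
genome_summary <- function(record) {
  f <- record$features
  genes <- f[f$kind == "gene" & f$part == 1L, , drop = FALSE]
  genes <- genes[genes$status != "pseudo", , drop = FALSE]
  nm <- normalize_gene_name(ifelse(is.na(genes$name), genes$id, genes$name))
  cls <- .gene_class(nm)
  n_copies <- table(nm)
  distinct <- if (is.null(names(n_copies))) character(0) else names(n_copies)
  d_cls <- .gene_class(distinct)
  dup <- distinct[n_copies[distinct] > 1L]
  dup_cls <- .gene_class(dup)
  reps <- f[f$kind == "repeat_copy", , drop = FALSE]
  repeat_bp <- if (nrow(reps) == 0L) 0L else {
    max(vapply(split(reps$end - reps$start, reps$id), sum, numeric(1)))
  }
  data.frame(
    id = record$id,
    size_bp = nchar(record$sequence),
    n_genes = length(distinct),
    n_protein = sum(d_cls == "protein"),
    n_trna = sum(d_cls == "trna"),
    n_rrna = sum(d_cls == "rrna"),
    n_protein_dup = sum(dup_cls == "protein"),
    n_trna_dup = sum(dup_cls == "trna"),
    n_rrna_dup = sum(dup_cls == "rrna"),
    gc = gc_content(record),
    repeat_region_bp = as.integer(repeat_bp),
    stringsAsFactors = FALSE
  )
}

#' Write genome summaries as TSV
#' @param records list of [genome_record()]s.
#' @param path output TSV.
#' @export
write_genome_summaries <- function(records, path) {
  df <- do.call(rbind, lapply(records, genome_summary))
  out <- data.frame(id = df$id, size_bp = df$size_bp, n_genes = df$n_genes,
                    n_protein = df$n_protein, n_trna = df$n_trna,
                    n_rrna = df$n_rrna, gc = df$gc,
                    repeat_region_bp = df$repeat_region_bp)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Gene presence/status matrix across genomes
#'
#' One row per genome, one column per gene of `gene_universe` (names are
#' normalized case-insensitively, copy suffixes stripped).  The cell state is
#' read from the gene's `status` field, defaulting to `"intact"`; genes without
#' a feature are `"absent"`.
#'
#' @param records list of [genome_record()]s.
#' @param gene_universe character vector of gene names (defines the columns).
#' @return Character matrix with values in
#'   intact, pseudo, intron_lost, absent.
#' @export
gene_presence_matrix <- function(records, gene_universe) {
  cols <- normalize_gene_name(gene_universe)
  m <- matrix("absent", length(records), length(cols),
              dimnames = list(vapply(records, function(r) r$id, character(1)),
                              cols))
  ok_status <- c("intact", "pseudo", "intron_lost")
  for (i in seq_along(records)) {
    f <- records[[i]]$features
    genes <- f[f$kind == "gene" & f$part == 1L, , drop = FALSE]
    if (nrow(genes) == 0L) next
    nm <- normalize_gene_name(ifelse(is.na(genes$name), genes$id, genes$name))
    if (any(!genes$status %in% ok_status)) {
      stop("unknown gene status: ",
           paste(setdiff(genes$status, ok_status), collapse = ", "))
    }
    for (j in seq_along(nm)) {
      if (nm[j] %in% cols) m[i, nm[j]] <- genes$status[j]
    }
  }
  m
}
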