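test_that("FASTA + GFF3 reading applies the coordinate conventions", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gff <- file.path(dir, "g.gff3")
  set.seed(42)
  seq <- rand_dna(10000)
  starts <- seq(1, 10000, 80)
  writeLines(c(">chr1", substring(seq, starts, pmin(starts + 79, 10000))), fa)
  genes <- sprintf(
    "chr1\tsrc\tgene\t%d\t%d\t.\t%s\t.\tID=g%d;Name=gene%d",
    c(1, 501, 1001, 2001, 5001), c(300, 800, 1600, 2500, 5400),
    c("+", "-", "+", "+", "-"), 1:5, 1:5)
  writeLines(c("##gff-version 3", "##sequence-region chr1 1 10000",
               "chr1\tsrc\tregion\t1\t10000\t.\t+\t.\tID=chr1;Is_circular=true",
               genes), gff)
  rec <- read_genome(fa, gff)
  expect_s3_class(rec, "genome_record")
  expect_equal(rec$topology, "circular")
  expect_equal(sum(rec$features$kind == "gene"), 5L)
  g1 <- rec$features[rec$features$name == "gene1", ]
  expect_equal(c(g1$start, g1$end), c(0L, 300L))  # 1..300 -> [0, 300)
  expect_equal(rec$sequence, seq)
})

test_that("malformed inputs are rejected", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "two.fa")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa)
  gff <- file.path(dir, "x.gff3")
  writeLines(c("##gff-version 3"), gff)
  expect_error(read_genome(fa, gff), "exactly one record")

  expect_error(genome_record("x", "ACGTACGT", genome_features(
    id = "f1", kind = "gene", name = "g", start = 2L, end = 12L,
    strand = "+")), "outside")
  expect_error(genome_record("x", "ACGTACGT", genome_features(
    id = "f1", kind = "gene", name = "g", start = 1L, end = 4L,
    strand = "?")), "strand")
  expect_error(genome_record("x", "ACGTNNRR"), "only A, C, G, T, N")
})

test_that("write/read round-trips coordinates, strands, wrap and topology", {
  feats <- genome_features(
    id = c("w1", "w1", "g2", "r1"),
    kind = c("gene", "gene", "gene", "repeat_copy"),
    name = c("psbA", "psbA", "rbcL", "DR_A"),
    start = c(9900L, 0L, 500L, 3000L), end = c(10000L, 120L, 900L, 4200L),
    strand = c("+", "+", "-", "+"),
    wrap = c(TRUE, TRUE, FALSE, FALSE), part = c(1L, 2L, 1L, 1L),
    pair_id = c(NA, NA, NA, "big"))
  rec <- genome_record("chr", rand_dna(10000, seed = 3), feats, "circular")
  dir <- withr::local_tempdir()
  write_genome(rec, file.path(dir, "g.fa"), file.path(dir, "g.gff3"))
  rec2 <- read_genome(file.path(dir, "g.fa"), file.path(dir, "g.gff3"))
  expect_identical(rec2$sequence, rec$sequence)
  expect_identical(rec2$topology, rec$topology)
  f1 <- rec$features[order(rec$features$id, rec$features$part), ]
  f2 <- rec2$features[order(rec2$features$id, rec2$features$part), ]
  expect_equal(f2$start, f1$start)
  expect_equal(f2$end, f1$end)
  expect_equal(f2$strand, f1$strand)
  expect_equal(f2$wrap, f1$wrap)
  expect_equal(f2$pair_id, f1$pair_id)
})

test_that("gc_content follows its definition and symmetries", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("GCNNNN"), 1.0)    # N excluded from denominator
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("NNNN"), "unambiguous")
  s <- rand_dna(2000, seed = 1, gc = 0.6)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(gc_content(s), gc_content(rc))
})

test_that("simulated architectures hit the GC target at length >= 100 kb", {
  rec <- simulate_architecture(lsc_bp = 45000L, ssc_bp = 45000L,
                               big_repeat_bp = 5000L,
                               big_orientation = "direct",
                               gc_target = 0.529, seed = 7L)
  expect_gte(nchar(rec$sequence), 100000L)
  expect_lt(abs(gc_content(rec) - 0.529), 0.01)
})

test_that("genome_summary counts distinct and duplicated genes", {
  ## 61 protein + 8 tRNA + 4 rRNA distinct; one protein and one tRNA and all
  ## four rRNAs duplicated (second copies in the other repeat region)
  prot <- paste0("pcg", 1:61)
  trna <- paste0("trn", letters[1:8])
  rrna <- paste0("rrn", c(16, 23, 5, 4.5))
  nm <- c(prot, trna, rrna, "pcg1", "trna", rrna)   # duplicates
  starts <- seq(0L, by = 100L, length.out = length(nm))
  rec <- mk_gene_record("tam", paste0("f", seq_along(nm)), "+", starts)
  rec$features$name <- nm
  s <- genome_summary(rec)
  expect_equal(s$n_genes, 73L)
  expect_equal(s$n_protein, 61L)
  expect_equal(s$n_trna, 8L)
  expect_equal(s$n_rrna, 4L)
  expect_equal(s$n_rrna_dup, 4L)
  expect_equal(s$n_protein_dup, 1L)
  expect_equal(s$size_bp, nchar(rec$sequence))

  empty <- genome_record("e", rand_dna(100, seed = 2))
  s0 <- genome_summary(empty)
  expect_equal(s0$n_genes + s0$n_protein + s0$n_trna + s0$n_rrna, 0L)
})

test_that("gene presence matrix reads status and marks absences", {
  r1 <- mk_gene_record("sp1", c("ndhA", "ndhB", "rbcL"), "+",
                       c(0L, 100L, 200L))
  r2 <- mk_gene_record("sp2", c("ndhA", "rbcL"), "+", c(0L, 200L),
                       status = c("pseudo", "intact"))
  m <- gene_presence_matrix(list(r1, r2), c("ndhA", "ndhB", "rbcL"))
  expect_equal(m["sp2", "ndhb"], "absent")
  expect_equal(m["sp2", "ndha"], "pseudo")
  expect_equal(m["sp1", "ndha"], "intact")

  r3 <- r2
  r3$features$status[1] <- "garbled"
  expect_error(gene_presence_matrix(list(r3), "ndhA"), "unknown gene status")
})

test_that("planted gene losses are recovered in the family matrix", {
  genes <- c(paste0("ndh", LETTERS[1:5]), "rbcL", "psbA")
  set.seed(9)
  lost <- matrix(stats::runif(14 * 5) < 0.3, 14, 5)   # ndh losses only
  recs <- lapply(1:14, function(i) {
    keep <- c(genes[1:5][!lost[i, ]], "rbcL", "psbA")
    mk_gene_record(paste0("sp", i), keep, "+",
                   seq(0L, by = 100L, length.out = length(keep)))
  })
  m <- gene_presence_matrix(recs, genes)
  absent_per_gene <- colSums(m[, normalize_gene_name(genes[1:5])] == "absent")
  expect_equal(unname(absent_per_gene), unname(colSums(lost)))
})
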