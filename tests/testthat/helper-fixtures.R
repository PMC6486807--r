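# Shared builders for small in-code fixtures.

# genome with point genes at given starts (50 bp each)
mk_gene_record <- function(id, genes, strands, starts, len = NULL,
                           status = "intact", topology = "linear") {
  if (is.null(len)) len <- max(starts) + 100L
  feats <- genome_features(id = genes, kind = "gene", name = genes,
                           start = as.integer(starts),
                           end = as.integer(starts) + 50L,
                           strand = strands, status = status)
  genome_record(id, paste(rep("A", len), collapse = ""), feats, topology)
}

# random DNA string
rand_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# compact architecture for fast recombination/repeat tests
small_architecture <- function(big_orientation = "direct",
                               small = TRUE, seed = 11L) {
  simulate_architecture(
    lsc_bp = 8000L, ssc_bp = 9000L, big_repeat_bp = 1500L,
    big_orientation = big_orientation,
    small_repeat_bp = if (small) 400L else NULL,
    small_orientation = "inverted",
    gc_target = 0.53, seed = seed, id = paste0("arch_", big_orientation))
}

random_signed_perm <- function(n) {
  sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
}
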