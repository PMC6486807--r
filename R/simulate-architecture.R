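#' Simulate a quadripartite plastome architecture
#'
#' Generates a circular genome with two single-copy regions (LSC, SSC)
#' separated by a pair of identical large repeats (direct, or inverted with
#' the second copy reverse-complemented), optionally with a second small
#' repeat pair placed one copy per single-copy region (the psbK-trnQ analog
#' seen in some Selaginella plastomes).  The background sequence is i.i.d.
#' with P(G) = P(C) = gc_target / 2, which is sufficient for repeat-detection
#' and GC-content testing; repeat copies are exact.
#'
#' @param lsc_bp,ssc_bp single-copy region lengths (the small repeat copy, if
#'   any, is embedded inside and counted in these lengths).
#' @param big_repeat_bp length of the large repeat (one copy).
#' @param big_orientation `"direct"` or `"inverted"`.
#' @param small_repeat_bp optional small repeat length (`NULL` for none).
#' @param small_orientation orientation of the small pair in the master form.
#' @param gc_target target GC fraction.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param id genome identifier.
#' @return A [genome_record()] with region and repeat_copy features; repeat
#'   copies share a `pair_id`.
#' @export
simulate_architecture <- function(lsc_bp, ssc_bp, big_repeat_bp,
                                  big_orientation = c("direct", "inverted"),
                                  small_repeat_bp = NULL,
                                  small_orientation = c("inverted", "direct"),
                                  gc_target = 0.529, seed = 1L,
                                  id = "synthetic_plastome") {
  big_orientation <- match.arg(big_orientation)
  small_orientation <- match.arg(small_orientation)
  if (lsc_bp <= 0 || ssc_bp <= 0 || big_repeat_bp <= 0) {
    stop("region and repeat lengths must be positive")
  }
  if (!is.null(small_repeat_bp) &&
      (small_repeat_bp >= lsc_bp || small_repeat_bp >= ssc_bp)) {
    stop("small repeat does not fit inside the single-copy regions")
  }
  set.seed(seed)
  rand_seq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc_target) / 2, gc_target / 2,
                          gc_target / 2, (1 - gc_target) / 2)),
          collapse = "")
  }
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  lsc <- rand_seq(lsc_bp)
  ssc <- rand_seq(ssc_bp)
  big_a <- rand_seq(big_repeat_bp)
  big_b <- if (big_orientation == "direct") big_a else revcomp(big_a)

  feats <- genome_features()
  small_rows <- NULL
  if (!is.null(small_repeat_bp)) {
    r <- small_repeat_bp
    sa <- (lsc_bp - r) %/% 2L              # inside LSC
    sb <- (ssc_bp - r) %/% 2L              # inside SSC (local coordinate)
    unit <- substr(lsc, sa + 1L, sa + r)
    copy_b <- if (small_orientation == "direct") unit else revcomp(unit)
    substr(ssc, sb + 1L, sb + r) <- copy_b
    sb_abs <- lsc_bp + big_repeat_bp + sb
    small_rows <- genome_features(
      id = c("small_rep_A", "small_rep_B"), kind = "repeat_copy",
      name = c("psbK_trnQ_A", "psbK_trnQ_B"),
      start = c(sa, sb_abs), end = c(sa + r, sb_abs + r),
      strand = c("+", if (small_orientation == "direct") "+" else "-"),
      pair_id = "small_repeat")
  }

  sequence <- paste0(lsc, big_a, ssc, big_b)
  ## block chance extension at planted-pair boundaries so detection recovers
  ## the planted coordinates exactly
  chars <- strsplit(sequence, "")[[1]]
  L_tot <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  at <- function(p) chars[(p %% L_tot) + 1L]
  set_diff <- function(p, forbidden) {
    p <- (p %% L_tot) + 1L
    if (chars[p] %in% forbidden) {
      chars[p] <<- sample(setdiff(c("A", "C", "G", "T"), forbidden), 1L)
    }
  }
  block_pair <- function(a, b, r, orientation) {
    if (orientation == "direct") {
      set_diff(b - 1L, at(a - 1L))
      set_diff(b + r, at(a + r))
    } else {
      set_diff(b + r, comp[[at(a - 1L)]])
      set_diff(b - 1L, comp[[at(a + r)]])
    }
  }
  block_pair(lsc_bp, lsc_bp + big_repeat_bp + ssc_bp, big_repeat_bp,
             big_orientation)
  if (!is.null(small_repeat_bp)) {
    sa0 <- (lsc_bp - small_repeat_bp) %/% 2L
    sb0 <- lsc_bp + big_repeat_bp + (ssc_bp - small_repeat_bp) %/% 2L
    block_pair(sa0, sb0, small_repeat_bp, small_orientation)
  }
  sequence <- paste(chars, collapse = "")
  l1 <- lsc_bp; l2 <- lsc_bp + big_repeat_bp
  l3 <- l2 + ssc_bp; l4 <- l3 + big_repeat_bp
  big_label <- if (big_orientation == "direct") c("DR_A", "DR_B") else
    c("IR_A", "IR_B")
  feats <- rbind(
    genome_features(id = c("LSC", "SSC"), kind = "region",
                    name = c("LSC", "SSC"),
                    start = c(0L, l2), end = c(l1, l3), strand = "+"),
    genome_features(id = c("big_rep_A", "big_rep_B"), kind = "repeat_copy",
                    name = big_label,
                    start = c(l1, l3), end = c(l2, l4),
                    strand = c("+", if (big_orientation == "direct") "+"
                               else "-"),
                    pair_id = "big_repeat"),
    small_rows)
  genome_record(id, sequence, feats, topology = "circular")
}

#' Reference architectures for the recombination model
#'
#' Three deterministic fixtures covering the canonical repeat layouts:
#' `DR_only` (large direct pair, no small pair), `IRDR_uncinata` (large
#' inverted pair plus a small inverted pair, one copy per single-copy region)
#' and `DRIR_bisulcata` (large direct pair plus a small inverted pair).  The
#' small pair is inverted in the master form: that is the only geometry under
#' which flip events at the large and small pairs generate the documented
#' two-isomer chain.
#'
#' @return Named list of three [genome_record()]s.
#' @export
fixture_figure5 <- function() {
  list(
    DR_only = simulate_architecture(
      lsc_bp = 45800L, ssc_bp = 47700L, big_repeat_bp = 13900L,
      big_orientation = "direct", gc_target = 0.532, seed = 101L,
      id = "DR_only"),
    IRDR_uncinata = simulate_architecture(
      lsc_bp = 77800L, ssc_bp = 40800L, big_repeat_bp = 12800L,
      big_orientation = "inverted", small_repeat_bp = 2700L,
      small_orientation = "inverted", gc_target = 0.549, seed = 102L,
      id = "IRDR_uncinata"),
    DRIR_bisulcata = simulate_architecture(
      lsc_bp = 55600L, ssc_bp = 59700L, big_repeat_bp = 12600L,
      big_orientation = "direct", small_repeat_bp = 1800L,
      small_orientation = "inverted", gc_target = 0.528, seed = 103L,
      id = "DRIR_bisulcata")
  )
}

#' Simulate a Yule (pure-birth) tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return A rooted binary `phylo` tree with branch lengths.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  set.seed(seed)
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

#' Simulate a two-state character under the symmetric Mk model
#'
#' Evolves a binary character (states `IR`/`DR`, encoded 0/1) down a tree by
#' the 2-state symmetric Markov process: the probability of a state change
#' along a branch of length b is (1 - exp(-2 * rate * b)) / 2.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param rate symmetric transition rate per unit branch length.
#' @param root_state state at the root, `"DR"` or `"IR"`.
#' @param seed integer seed.
#' @return List with `tip_states` (named character over tips) and
#'   `node_states` (internal nodes, indexed as in the `phylo` object).
#' @export
simulate_binary_character <- function(tree, rate, root_state = "DR",
                                      seed = 1L) {
  if (rate < 0) stop("rate must be >= 0")
  stopifnot(root_state %in% c("DR", "IR"))
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- character(ntip + nnode)
  root <- ntip + 1L
  states[root] <- root_state
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    b <- tr$edge.length[e]
    p_change <- (1 - exp(-2 * rate * b)) / 2
    flip <- stats::runif(1) < p_change
    other <- c(DR = "IR", IR = "DR")
    states[child] <- if (flip) other[[states[parent]]] else states[parent]
  }
  tips <- states[seq_len(ntip)]
  names(tips) <- tree$tip.label
  list(tip_states = tips, node_states = states[root:(ntip + nnode)])
}

#' Simulate Brownian-motion tip values on a tree
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param seed integer seed.
#' @param rate Brownian rate (variance per unit branch length).
#' @param root_value value at the root.
#' @return Named numeric vector of tip values.
#' @export
simulate_brownian <- function(tree, seed = 1L, rate = 1, root_value = 0) {
  set.seed(seed)
  ntip <- length(tree$tip.label)
  vals <- numeric(ntip + tree$Nnode)
  vals[ntip + 1L] <- root_value
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    vals[tr$edge[e, 2]] <- vals[tr$edge[e, 1]] +
      stats::rnorm(1, 0, sqrt(rate * tr$edge.length[e]))
  }
  stats::setNames(vals[seq_len(ntip)], tree$tip.label)
}
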