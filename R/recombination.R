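#' Molecule forms: segment-level circular genome configurations
#'
#' The recombination model works at segment resolution: a circular molecule is
#' an ordered list of oriented segment tokens, delimited by repeat-copy
#' boundaries.  The two copies of a repeat pair carry the same token (they are
#' identical sequence); single-copy arcs get their own tokens.  Two forms are
#' the same molecule iff their token lists agree up to rotation and
#' whole-molecule reflection (reversal with all orientations flipped), which
#' is what [canonical_key()] captures.
#'
#' @param tokens character vector of segment identifiers in circular order.
#' @param orient integer vector of +1/-1 orientations.
#' @param kind `"full_length"` or `"subgenomic"`.
#' @return An object of class `molecule_form`.
#' @export
molecule_form <- function(tokens, orient = rep(1L, length(tokens)),
                          kind = c("full_length", "subgenomic")) {
  kind <- match.arg(kind)
  if (length(tokens) != length(orient)) stop("tokens/orient length mismatch")
  if (!all(orient %in% c(-1L, 1L))) stop("orient must be +1/-1")
  structure(list(tokens = as.character(tokens), orient = as.integer(orient),
                 kind = kind),
            class = "molecule_form")
}

#' @export
print.molecule_form <- function(x, ...) {
  cat(x$kind, "molecule:",
      paste(paste0(ifelse(x$orient > 0, "", "-"), x$tokens), collapse = " "),
      "\n")
  invisible(x)
}

#' Canonical key of a circular oriented segment list
#'
#' Lexicographically minimal token string over all rotations of the form and
#' of its reflection; invariant under rotation and reflection, so it
#' deduplicates molecule forms.
#'
#' @param form a [molecule_form()].
#' @return A single string.
#' @export
canonical_key <- function(form) {
  tok <- form$tokens; ori <- form$orient
  n <- length(tok)
  render <- function(tk, o) {
    paste(paste0(tk, ifelse(o > 0, ":+", ":-")), collapse = "|")
  }
  best <- NULL
  rtok <- rev(tok); rori <- -rev(ori)
  for (r in seq_len(n)) {
    idx <- c(seq(r, n), if (r > 1) seq_len(r - 1))
    for (cand in list(render(tok[idx], ori[idx]),
                      render(rtok[idx], rori[idx]))) {
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}

.pair_positions <- function(form, pair_id) {
  pos <- which(form$tokens == pair_id)
  if (length(pos) != 2L) {
    stop("pair ", pair_id, " does not occur exactly twice on this form")
  }
  pos
}

#' Relative orientation of a repeat pair on a molecule form
#'
#' `"direct"` if the two copies are co-oriented on the circle, `"inverted"`
#' otherwise; invariant under rotation and reflection.
#'
#' @param form a [molecule_form()].
#' @param pair_id repeat pair token.
#' @export
pair_orientation <- function(form, pair_id) {
  pos <- .pair_positions(form, pair_id)
  if (form$orient[pos[1]] == form$orient[pos[2]]) "direct" else "inverted"
}

#' Flip event: recombination between inverted repeat copies
#'
#' Reverses (with orientations negated) the arc strictly between the two
#' copies of an inverted pair.  The two possible arcs give
#' reflection-equivalent circles, so the canonical result is unique; this
#' implementation uses the arc following the first occurrence.
#'
#' @inheritParams pair_orientation
#' @return The recombinant full-length [molecule_form()] (one child).
#' @export
flip <- function(form, pair_id) {
  pos <- .pair_positions(form, pair_id)
  if (pair_orientation(form, pair_id) != "inverted") {
    stop("pair ", pair_id, " is not inverted on this form; flip needs an IR")
  }
  i <- pos[1]; j <- pos[2]
  tok <- form$tokens; ori <- form$orient
  if (j - i > 1L) {
    seg <- seq(i + 1L, j - 1L)
    tok[seg] <- rev(tok[seg])
    ori[seg] <- -rev(ori[seg])
  }
  molecule_form(tok, ori, kind = form$kind)
}

#' Split event: recombination between direct repeat copies
#'
#' Excises two circular subgenomic molecules, each retaining one full repeat
#' copy and one of the two arcs; the segment multiset (repeat copies counted
#' once each) is conserved.
#'
#' @inheritParams pair_orientation
#' @return List of two subgenomic [molecule_form()]s.
#' @export
split_at <- function(form, pair_id) {
  pos <- .pair_positions(form, pair_id)
  if (pair_orientation(form, pair_id) != "direct") {
    stop("pair ", pair_id, " is not direct on this form; split needs a DR")
  }
  i <- pos[1]; j <- pos[2]
  n <- length(form$tokens)
  arc1 <- if (j - i > 1L) seq(i + 1L, j - 1L) else integer(0)
  arc2 <- c(if (j < n) seq(j + 1L, n), if (i > 1L) seq_len(i - 1L))
  child1 <- molecule_form(form$tokens[c(i, arc1)], form$orient[c(i, arc1)],
                          kind = "subgenomic")
  child2 <- molecule_form(form$tokens[c(j, arc2)], form$orient[c(j, arc2)],
                          kind = "subgenomic")
  list(child1, child2)
}

.form_pairs <- function(form) {
  tab <- table(form$tokens)
  names(tab)[tab == 2L]
}

#' Convert an annotated genome to its segment-level molecule form
#'
#' Repeat-copy features delimit the segments: each copy becomes its pair
#' token (orientation from strand), each arc between consecutive copies
#' becomes a single-copy segment token.  Arc tokens are named after the region
#' feature containing the arc start when available.
#'
#' @param record a [genome_record()] with `repeat_copy` features.
#' @return A [molecule_form()] with a `segments` attribute (data frame of
#'   token lengths and roles).
#' @export
as_molecule_form <- function(record) {
  f <- record$features
  reps <- f[f$kind == "repeat_copy" & f$part == 1L, , drop = FALSE]
  if (nrow(reps) == 0L) stop("record has no repeat_copy features")
  reps <- reps[order(reps$start), , drop = FALSE]
  regions <- f[f$kind == "region", , drop = FALSE]
  len <- nchar(record$sequence)
  tokens <- character(0); orient <- integer(0)
  seg_tok <- character(0); seg_len <- numeric(0); seg_rep <- logical(0)
  arc_name <- function(s, e) {
    hit <- regions$name[regions$start <= s & regions$end >= e]
    if (length(hit) >= 1L) hit[1] else NA_character_
  }
  used <- character(0)
  k <- nrow(reps)
  for (r in seq_len(k)) {
    tokens <- c(tokens, reps$pair_id[r])
    orient <- c(orient, if (reps$strand[r] == "+") 1L else -1L)
    if (!reps$pair_id[r] %in% seg_tok) {
      seg_tok <- c(seg_tok, reps$pair_id[r])
      seg_len <- c(seg_len, reps$end[r] - reps$start[r])
      seg_rep <- c(seg_rep, TRUE)
    }
    arc_s <- reps$end[r]
    arc_e <- if (r < k) reps$start[r + 1L] else reps$start[1L] + len
    if (arc_e > arc_s) {
      nm <- arc_name(arc_s, min(arc_e, len))
      tokname <- if (!is.na(nm) && !nm %in% used) nm else
        paste0("seg", length(seg_tok) + 1L)
      used <- c(used, tokname)
      tokens <- c(tokens, tokname)
      orient <- c(orient, 1L)
      seg_tok <- c(seg_tok, tokname)
      seg_len <- c(seg_len, arc_e - arc_s)
      seg_rep <- c(seg_rep, FALSE)
    }
  }
  out <- molecule_form(tokens, orient, kind = "full_length")
  attr(out, "segments") <- data.frame(token = seg_tok, length = seg_len,
                                      is_repeat = seg_rep,
                                      stringsAsFactors = FALSE)
  out
}

#' Enumerate all molecule forms reachable by repeat-mediated recombination
#'
#' Breadth-first closure from the master chromosome: flips at inverted pairs
#' produce further full-length isomers; splits at direct pairs produce
#' terminal subgenomic molecules.  Forms are deduplicated by
#' [canonical_key()].
#'
#' @param master a [genome_record()] with repeat_copy features, or a
#'   [molecule_form()].
#' @param max_forms guard against runaway inputs.
#' @return An object of class `state_graph`: list with `forms` (named list of
#'   molecule forms keyed canonically), `events` (data frame: type, pair_id,
#'   parent, child1, child2), `master_key`, and `segments` (token metadata
#'   when available).
#' @export
enumerate_forms <- function(master, max_forms = 10000L) {
  form0 <- if (inherits(master, "molecule_form")) master else
    as_molecule_form(master)
  segments <- attr(form0, "segments")
  key0 <- canonical_key(form0)
  forms <- stats::setNames(list(form0), key0)
  events <- data.frame(type = character(), pair_id = character(),
                       parent = character(), child1 = character(),
                       child2 = character(), stringsAsFactors = FALSE)
  queue <- key0
  while (length(queue) > 0L) {
    key <- queue[[1L]]; queue <- queue[-1L]
    form <- forms[[key]]
    for (p in .form_pairs(form)) {
      if (pair_orientation(form, p) == "inverted") {
        child <- flip(form, p)
        ck <- canonical_key(child)
        if (!ck %in% names(forms)) {
          forms[[ck]] <- child
          queue <- c(queue, ck)
        }
        ev <- data.frame(type = "flip", pair_id = p, parent = key,
                         child1 = ck, child2 = NA_character_,
                         stringsAsFactors = FALSE)
        events <- rbind(events, ev)
      } else {
        children <- split_at(form, p)
        cks <- vapply(children, canonical_key, character(1))
        for (ci in 1:2) {
          if (!cks[ci] %in% names(forms)) forms[[cks[ci]]] <- children[[ci]]
        }
        events <- rbind(events, data.frame(
          type = "split", pair_id = p, parent = key,
          child1 = cks[1], child2 = cks[2], stringsAsFactors = FALSE))
      }
      if (length(forms) > max_forms) {
        stop("more than ", max_forms, " molecule forms; runaway input?")
      }
    }
  }
  events <- events[!duplicated(events), , drop = FALSE]
  structure(list(forms = forms, events = events, master_key = key0,
                 segments = segments),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  kinds <- vapply(x$forms, function(f) f$kind, character(1))
  cat("recombination state graph:", sum(kinds == "full_length"),
      "full-length form(s),", sum(kinds == "subgenomic"),
      "distinct subgenomic molecule(s),", nrow(x$events), "event(s)\n")
  invisible(x)
}

#' Full-length and subgenomic form counts of a state graph
#' @param graph a `state_graph`.
#' @return Named list: `full_length`, `subgenomic` (distinct canonical forms),
#'   `split_children` (subgenomic children over split events, with
#'   multiplicity).
#' @export
form_counts <- function(graph) {
  kinds <- vapply(graph$forms, function(f) f$kind, character(1))
  splits <- graph$events[graph$events$type == "split", , drop = FALSE]
  list(full_length = sum(kinds == "full_length"),
       subgenomic = sum(kinds == "subgenomic"),
       split_children = 2L * nrow(splits))
}

#' Classify the master structure as DR or IR
#'
#' DR iff the two copies of the largest repeat pair are co-oriented.
#'
#' @param record a [genome_record()] with repeat annotation (or detectable
#'   large pair, see [large_repeat_pair()]).
#' @return `"DR"` or `"IR"`.
#' @export
classify_master_structure <- function(record) {
  pair <- large_repeat_pair(record)
  if (pair$orientation == "direct") "DR" else "IR"
}

.big_pair_token <- function(graph) {
  if (!is.null(graph$segments)) {
    reps <- graph$segments[graph$segments$is_repeat, , drop = FALSE]
    reps$token[which.max(reps$length)]
  } else {
    ## widest-spread pair as a fallback: first pair on the master form
    .form_pairs(graph$forms[[graph$master_key]])[1]
  }
}

#' Classify the dynamic structure of a plastome population
#'
#' `IRDR_coexisting` iff the reachable full-length forms include at least one
#' with the large pair direct and one with it inverted; otherwise `DR_only`
#' or `IR_only` according to the master.
#'
#' @param graph a `state_graph` from [enumerate_forms()].
#' @return One of `"DR_only"`, `"IR_only"`, `"IRDR_coexisting"`.
#' @export
classify_dynamic <- function(graph) {
  big <- .big_pair_token(graph)
  full <- Filter(function(f) f$kind == "full_length", graph$forms)
  ors <- vapply(full, function(f) pair_orientation(f, big), character(1))
  if (any(ors == "direct") && any(ors == "inverted")) return("IRDR_coexisting")
  if (pair_orientation(graph$forms[[graph$master_key]], big) == "direct") {
    "DR_only"
  } else {
    "IR_only"
  }
}

#' Equilibrium stoichiometry over full-length isomers
#'
#' Under highly efficient reciprocal recombination the full-length isomers are
#' assumed equimolar; returns the uniform distribution over them.
#'
#' @param graph a `state_graph`.
#' @return Named numeric vector (canonical keys) summing to 1.
#' @export
stoichiometry <- function(graph) {
  full <- names(Filter(function(f) f$kind == "full_length", graph$forms))
  if (length(full) == 0L) stop("state graph has no full-length forms")
  stats::setNames(rep(1 / length(full), length(full)), full)
}

#' Random segment-level architecture (for property testing)
#'
#' Builds a random full-length molecule form with `n_pairs` repeat pairs of
#' random orientation interleaved with single-copy segments of random
#' orientation.
#'
#' @param n_single number of single-copy segments.
#' @param n_pairs number of repeat pairs (each placed twice).
#' @param seed integer seed.
#' @return A [molecule_form()].
#' @export
random_molecule_form <- function(n_single = 4L, n_pairs = 2L, seed = 1L) {
  set.seed(seed)
  tokens <- c(paste0("seg", seq_len(n_single)),
              rep(paste0("rep", seq_len(n_pairs)), each = 2L))
  ord <- sample(length(tokens))
  molecule_form(tokens[ord], sample(c(-1L, 1L), length(tokens), TRUE))
}
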