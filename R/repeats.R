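#' Detect maximal exact repeat pairs in a genome
#'
#' Finds all maximal exact repeated pairs longer than `min_len`, in both
#' orientations (direct, and inverted = second copy matching the reverse
#' complement), respecting circular wrap.  Detection is seed-and-extend on
#' shared (min_len + 1)-mers grouped by diagonal, which reconstructs every
#' maximal repeat exactly (a maximal repeat of length L contains L - k + 1
#' consecutive seeds on one diagonal).  Matching is exact (identity 1.0).
#' Tandem arrays (overlapping copies) are collapsed to one entry with the
#' unit length and copy count; degenerate self-overlapping inverted
#' (palindromic) hits are excluded.
#'
#' @param record a [genome_record()] or plain DNA string (treated linear).
#' @param min_len report pairs strictly longer than this (default 15 bp).
#' @return Data frame with columns `pair_id`, `start_a`, `end_a`, `strand_a`,
#'   `start_b`, `end_b`, `strand_b`, `length`, `orientation`, `copies`
#'   (2 for dispersed pairs, the copy count for tandem arrays; for arrays
#'   `length` is the unit length).  Coordinates are 0-based half-open on the
#'   input genome.
#' @export
find_repeats <- function(record, min_len = 15L) {
  if (min_len < 4L) stop("min_len below seed width (4)")
  s <- if (inherits(record, "genome_record")) record$sequence else
    toupper(record)
  circular <- inherits(record, "genome_record") &&
    record$topology == "circular"
  L <- nchar(s)
  if (L < 2L * min_len) stop("sequence shorter than 2 * min_len")
  k <- min_len + 1L
  S2 <- if (circular) paste0(s, s) else s
  n2 <- nchar(S2)
  starts <- seq_len(n2 - k + 1L)
  kmers <- substring(S2, starts, starts + k - 1L)

  pair_rows <- function(idx_by_kmer) {
    ## all unordered seed pairs (i < j) within each k-mer group
    res_i <- vector("list", length(idx_by_kmer))
    res_j <- vector("list", length(idx_by_kmer))
    for (g in seq_along(idx_by_kmer)) {
      v <- idx_by_kmer[[g]]
      m <- length(v)
      if (m < 2L) next
      if (m > 2000L) stop("low-complexity seed explosion; raise min_len")
      cmb <- utils::combn(v, 2L)
      res_i[[g]] <- cmb[1L, ]
      res_j[[g]] <- cmb[2L, ]
    }
    list(i = unlist(res_i), j = unlist(res_j))
  }

  merge_runs <- function(i, j) {
    ## merge consecutive seeds on each diagonal (j - i) into maximal runs
    if (length(i) == 0L) {
      return(data.frame(i = integer(), j = integer(), len = integer()))
    }
    d <- j - i
    ord <- order(d, i)
    d <- d[ord]; i <- i[ord]; j <- j[ord]
    new_run <- c(TRUE, d[-1L] != d[-length(d)] | i[-1L] != i[-length(i)] + 1L)
    run_id <- cumsum(new_run)
    i0 <- i[new_run]
    j0 <- j[new_run]
    len <- tabulate(run_id) + k - 1L
    data.frame(i = i0, j = j0, len = len)
  }

  out <- list()
  add_row <- function(a, b, len, orientation, copies = 2L) {
    out[[length(out) + 1L]] <<- data.frame(
      start_a = a, end_a = a + len, strand_a = "+",
      start_b = b, end_b = b + len,
      strand_b = if (orientation == "inverted") "-" else "+",
      length = len, orientation = orientation, copies = copies,
      stringsAsFactors = FALSE)
  }

  ## ---- direct orientation -------------------------------------------------
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  grp <- split(starts[dup], kmers[dup])
  pr <- pair_rows(grp)
  runs <- merge_runs(pr$i, pr$j)
  seen <- character(0)
  tandem_foot <- list()
  if (nrow(runs) > 0L) runs <- runs[order(-runs$len), , drop = FALSE]
  for (r in seq_len(nrow(runs))) {
    i0 <- runs$i[r]; j0 <- runs$j[r]; len <- runs$len[r]
    d0 <- j0 - i0
    if (circular && d0 %% L == 0L) next          # trivial self-identity
    if (len > L) len <- L
    a <- (i0 - 1L) %% L
    b <- (j0 - 1L) %% L
    if (d0 < len) {
      ## overlapping copies: tandem array with unit d0
      foot_a <- a
      foot_len <- min(d0 + len, L)
      key <- paste0("T", foot_a)
      dup <- any(vapply(tandem_foot, function(f) {
        foot_a >= f[1] && foot_a + foot_len <= f[1] + f[2]
      }, logical(1)))
      if (!dup) {
        tandem_foot[[length(tandem_foot) + 1L]] <- c(foot_a, foot_len)
        add_row(a, (a + d0) %% L, d0, "direct", copies = len %/% d0 + 1L)
      }
      next
    }
    canon <- paste0("D", min(a, b), "_", max(a, b), "_", len)
    if (canon %in% seen) next
    seen <- c(seen, canon)
    add_row(min(a, b), max(a, b), len, "direct")
  }

  ## ---- inverted orientation ----------------------------------------------
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(S2)))
  rkmers <- substring(rc2, starts, starts + k - 1L)
  ## position p in rc2 corresponds to forward start (n2 - p - k + 2) in S2
  shared_f <- kmers %in% rkmers
  shared_r <- rkmers %in% kmers
  both <- c(kmers[shared_f], rkmers[shared_r])
  both_idx <- c(which(shared_f), length(starts) + which(shared_r))
  grp2 <- lapply(split(seq_along(both), both), function(ix) both_idx[ix])
  ii <- list(); jj <- list()
  for (g in grp2) {
    fwd <- g[g <= length(starts)]
    rev <- g[g > length(starts)] - length(starts)
    if (length(fwd) == 0L || length(rev) == 0L) next
    if (length(fwd) * length(rev) > 4e6) {
      stop("low-complexity seed explosion; raise min_len")
    }
    e <- expand.grid(i = fwd, p = rev)
    ii[[length(ii) + 1L]] <- e$i
    jj[[length(jj) + 1L]] <- n2 - e$p - k + 2L
  }
  i <- unlist(ii); j <- unlist(jj)
  if (length(i) > 0L) {
    ## inverted runs share the anti-diagonal i + j; consecutive seeds have
    ## ascending i; reuse merge_runs on (i, c - i) via transformed coords
    cdiag <- i + j
    ord <- order(cdiag, i)
    cdiag <- cdiag[ord]; i <- i[ord]; j <- j[ord]
    new_run <- c(TRUE, cdiag[-1L] != cdiag[-length(cdiag)] |
                   i[-1L] != i[-length(i)] + 1L)
    run_id <- cumsum(new_run)
    i0 <- i[new_run]
    nseed <- tabulate(run_id)
    len <- nseed + k - 1L
    b0 <- j[cumsum(tabulate(run_id))]            # j of last seed = copy B start
    for (r in seq_along(i0)) {
      ln_r <- len[r]
      if (ln_r > L) next
      a <- (i0[r] - 1L) %% L
      b <- (b0[r] - 1L) %% L
      if (a == b) next                           # palindrome at one locus
      ## exclude circularly overlapping copies (degenerate palindromic locus)
      gap1 <- (b - a) %% L
      gap2 <- (a - b) %% L
      if (gap1 < ln_r || gap2 < ln_r) next
      lo <- min(a, b); hi <- max(a, b)
      canon <- paste0("I", lo, "_", hi, "_", ln_r)
      if (canon %in% seen) next
      seen <- c(seen, canon)
      add_row(lo, hi, ln_r, "inverted")
    }
  }

  if (length(out) == 0L) {
    res <- data.frame(start_a = integer(), end_a = integer(),
                      strand_a = character(), start_b = integer(),
                      end_b = integer(), strand_b = character(),
                      length = integer(), orientation = character(),
                      copies = integer(), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[res$length > min_len | res$copies > 2L, , drop = FALSE]
    ## drop dispersed pairs fully inside a collapsed tandem footprint
    if (length(tandem_foot) > 0L && nrow(res) > 0L) {
      inside <- function(a, e) {
        any(vapply(tandem_foot, function(f) {
          a >= f[1] && e <= f[1] + f[2]
        }, logical(1)))
      }
      drop <- vapply(seq_len(nrow(res)), function(r) {
        res$copies[r] == 2L &&
          inside(res$start_a[r], res$end_a[r]) &&
          inside(res$start_b[r], res$end_b[r])
      }, logical(1))
      res <- res[!drop, , drop = FALSE]
    }
    ## drop non-maximal sub-pairs: same-diagonal truncated representations of
    ## a longer pair (can arise from runs clipped at the doubled-sequence edge)
    if (nrow(res) > 1L) {
      res <- res[order(-res$length), , drop = FALSE]
      modL <- function(x) ((x %% L) + L) %% L
      drop <- rep(FALSE, nrow(res))
      for (r in 2:nrow(res)) {
        for (q in seq_len(r - 1L)) {
          if (drop[q] || res$orientation[r] != res$orientation[q]) next
          if (res$length[q] <= res$length[r]) next
          da <- modL(res$start_a[r] - res$start_a[q])
          if (res$orientation[r] == "direct") {
            db <- modL(res$start_b[r] - res$start_b[q])
            if (da == db && da <= res$length[q] - res$length[r]) {
              drop[r] <- TRUE; break
            }
          } else {
            db <- modL(res$end_b[q] - res$end_b[r])
            if (da == db && da <= res$length[q] - res$length[r]) {
              drop[r] <- TRUE; break
            }
          }
        }
      }
      res <- res[!drop, , drop = FALSE]
    }
    res <- res[order(-res$length), , drop = FALSE]
  }
  if (nrow(res) > 0L) res$pair_id <- paste0("rp", seq_len(nrow(res)))
  else res$pair_id <- character(0)
  rownames(res) <- NULL
  res[, c("pair_id", "start_a", "end_a", "strand_a", "start_b", "end_b",
          "strand_b", "length", "orientation", "copies")]
}

#' Summarize repeat pairs by size class and orientation
#'
#' Counts detected pairs per (size bin, orientation).  Large repeat-region
#' pairs (>= `exclude_bp`, i.e. the DR/IR copies themselves) are excluded
#' from the dispersed-repeat count, mirroring the practice of removing one
#' DR/IR copy before counting repeats.
#'
#' @param pairs data frame from [find_repeats()].
#' @param breaks ascending size-class breakpoints; default bins
#'   (15, 30\], (30, 50\], (50, Inf).
#' @param exclude_bp drop pairs at least this long (default 1000, the large
#'   repeat region); use `Inf` to keep everything.
#' @return Data frame `bin` x `orientation` with counts; total equals the
#'   number of retained pairs.
#' @export
repeat_summary <- function(pairs, breaks = c(15, 30, 50, Inf),
                           exclude_bp = 1000) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("size bins must be ordered and disjoint (strictly ascending breaks)")
  }
  keep <- pairs[pairs$length < exclude_bp, , drop = FALSE]
  bins <- cut(keep$length, breaks = breaks, right = TRUE)
  tab <- table(bin = bins, orientation = factor(keep$orientation,
                                                levels = c("direct",
                                                           "inverted")))
  as.data.frame(tab, stringsAsFactors = FALSE)
}

#' The large repeat pair (DR/IR region) of a plastome
#'
#' Returns the longest repeat pair, from `repeat_copy` annotation when
#' present, otherwise by exact detection; errors when no pair of at least
#' 1 kb exists (no quadripartite structure).
#'
#' @param record a [genome_record()].
#' @return One-row data frame in the [find_repeats()] schema.
#' @export
large_repeat_pair <- function(record) {
  f <- record$features
  reps <- f[f$kind == "repeat_copy" & f$part == 1L, , drop = FALSE]
  if (nrow(reps) >= 2L && any(!is.na(reps$pair_id))) {
    lens <- vapply(split(reps$end - reps$start, reps$pair_id), max, numeric(1))
    big <- names(lens)[which.max(lens)]
    cp <- reps[reps$pair_id == big, , drop = FALSE]
    cp <- cp[order(cp$start), , drop = FALSE]
    if (nrow(cp) == 2L && max(cp$end - cp$start) >= 1000L) {
      return(data.frame(
        pair_id = big,
        start_a = cp$start[1], end_a = cp$end[1], strand_a = cp$strand[1],
        start_b = cp$start[2], end_b = cp$end[2], strand_b = cp$strand[2],
        length = cp$end[1] - cp$start[1],
        orientation = if (cp$strand[1] == cp$strand[2]) "direct" else
          "inverted",
        copies = 2L, stringsAsFactors = FALSE))
    }
  }
  det <- find_repeats(record, min_len = 999L)
  det <- det[det$length >= 1000L & det$copies == 2L, , drop = FALSE]
  if (nrow(det) == 0L) {
    stop("no repeat pair >= 1 kb: record has no quadripartite structure")
  }
  det[which.max(det$length), , drop = FALSE]
}

#' Write repeat pairs as TSV
#' @param pairs data frame from [find_repeats()].
#' @param path output file.
#' @export
write_repeats <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
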