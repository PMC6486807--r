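#' Signed permutations of collinear blocks
#'
#' A signed permutation represents the order and strand of locally collinear
#' blocks (LCBs) along one genome, in a block frame shared with other genomes.
#' Blocks are nonzero signed integers with pairwise-distinct magnitudes; the
#' sign encodes strand orientation relative to the frame.
#'
#' @param blocks integer vector of nonzero signed values with distinct
#'   magnitudes.
#' @param taxon taxon label.
#' @param frame name of the shared block frame.
#' @return An object of class `signed_permutation`.
#' @examples
#' signed_permutation(c(1, -2, 3), taxon = "sp1")
#' @export
signed_permutation <- function(blocks, taxon = "", frame = "") {
  blocks <- as.integer(blocks)
  if (length(blocks) < 1L) stop("a signed permutation needs at least one block")
  if (any(blocks == 0L)) stop("blocks must be nonzero signed integers")
  if (anyDuplicated(abs(blocks))) stop("block magnitudes must be distinct")
  structure(list(blocks = blocks, taxon = taxon, frame = frame),
            class = "signed_permutation")
}

#' @export
print.signed_permutation <- function(x, ...) {
  cat("signed permutation", if (nzchar(x$taxon)) paste0("[", x$taxon, "]"),
      if (nzchar(x$frame)) paste0("frame=", x$frame), "\n")
  cat(" ", paste(ifelse(x$blocks > 0, paste0("+", x$blocks), x$blocks),
                 collapse = " "), "\n")
  invisible(x)
}

#' @export
length.signed_permutation <- function(x) length(x$blocks)

.perm_blocks <- function(p) {
  if (inherits(p, "signed_permutation")) p$blocks else as.integer(p)
}

.check_same_frame <- function(p, q) {
  pb <- .perm_blocks(p); qb <- .perm_blocks(q)
  if (inherits(p, "signed_permutation") && inherits(q, "signed_permutation") &&
      nzchar(p$frame) && nzchar(q$frame) && !identical(p$frame, q$frame)) {
    stop("permutations come from different block frames: ",
         p$frame, " vs ", q$frame)
  }
  if (!setequal(abs(pb), abs(qb))) {
    stop("permutations do not share the same block magnitude set")
  }
  list(p = pb, q = qb)
}

## Express p in the coordinate frame where q is the identity: the composition
## q^-1 . p, relabelled to magnitudes 1..n.  Reversal distances are
## left-invariant, so d(p, q) = d(q^-1 p, identity).
.compose_relative <- function(p, q) {
  pq <- .check_same_frame(p, q)
  pb <- pq$p; qb <- pq$q
  n <- length(pb)
  pos <- integer(n); sgn <- integer(n)
  pos[abs(qb)] <- seq_len(n)
  sgn[abs(qb)] <- sign(qb)
  as.integer(pos[abs(pb)] * sign(pb) * sgn[abs(pb)])
}

## Apply reversal of positions i..j (1-based, inclusive) to a signed vector.
.reverse_segment <- function(v, i, j) {
  v[i:j] <- -rev(v[i:j])
  v
}

#' Breakpoint distance between two signed permutations
#'
#' Number of signed adjacencies of `p` (with linear caps 0 and n+1) that are
#' not adjacencies of `q`, orientation respected: the adjacency (x, y) is
#' conserved iff `q` contains (x, y) or its reading on the opposite strand
#' (-y, -x).
#'
#' @param p,q `signed_permutation` objects (or plain signed integer vectors)
#'   over the same block magnitude set.
#' @return A non-negative integer; 0 iff the permutations are equal.
#' @examples
#' breakpoint_distance(c(1, -2, 3), c(1, 2, 3))  # 2
#' @export
breakpoint_distance <- function(p, q) {
  r <- .compose_relative(p, q)
  n <- length(r)
  capped <- c(0L, r, n + 1L)
  sum(diff(capped) != 1L)
}

## ---- Hannenhalli-Pevzner inversion distance -------------------------------

## Breakpoint-graph analysis of a signed permutation relative to the identity.
## Returns cycle count and hurdle/fortress corrections.
.hp_analyze <- function(r) {
  n <- length(r)
  ## unsigned doubling: +x -> (2x-1, 2x); -x -> (2x, 2x-1); caps 0, 2n+1
  dbl <- integer(2L * n)
  for (k in seq_len(n)) {
    x <- r[k]
    dbl[c(2L * k - 1L, 2L * k)] <-
      if (x > 0) c(2L * x - 1L, 2L * x) else c(-2L * x, -2L * x - 1L)
  }
  u <- c(0L, dbl, 2L * n + 1L)           # positions 0..2n+1 (index - 1)
  m <- n + 1L                             # number of black / gray edges
  posof <- integer(2L * n + 2L)           # value -> 0-based position
  posof[u + 1L] <- seq_along(u) - 1L

  ## black edges join positions (2i, 2i+1), i = 0..n
  ## gray edges join values (2k, 2k+1),   k = 0..n
  ## Each vertex has exactly one black and one gray edge; follow cycles.
  cyc_of_gray <- integer(m)               # gray edge k+1 -> cycle id
  visited <- rep(FALSE, 2L * n + 2L)      # by position (0-based + 1)
  n_cycles <- 0L
  for (start in seq(0L, 2L * n, by = 2L)) {
    if (visited[start + 1L]) next
    n_cycles <- n_cycles + 1L
    p <- start
    repeat {
      visited[p + 1L] <- TRUE
      pp <- if (p %% 2L == 0L) p + 1L else p - 1L   # cross the black edge
      visited[pp + 1L] <- TRUE
      v <- u[pp + 1L]
      k <- v %/% 2L                                  # gray edge of value v
      cyc_of_gray[k + 1L] <- n_cycles
      w <- if (v %% 2L == 0L) v + 1L else v - 1L
      p <- posof[w + 1L]                             # cross the gray edge
      if (p == start) break
    }
  }

  ## gray edge geometry: endpoints of gray edge k are values 2k, 2k+1
  gi <- pmin(posof[seq(0L, 2L * n, by = 2L) + 1L],
             posof[seq(1L, 2L * n + 1L, by = 2L) + 1L])
  gj <- pmax(posof[seq(0L, 2L * n, by = 2L) + 1L],
             posof[seq(1L, 2L * n + 1L, by = 2L) + 1L])
  oriented_edge <- (gj - gi) %% 2L == 0L  # spans an odd number of elements
  ## a cycle with a single gray edge is an adjacency; never part of a component
  trivial_cycle <- tabulate(cyc_of_gray, n_cycles) == 1L

  list(n = n, c = n_cycles, gi = gi, gj = gj,
       cyc_of_gray = cyc_of_gray, oriented_edge = oriented_edge,
       trivial_cycle = trivial_cycle)
}

## Union-find over cycles through interleaving gray edges; returns the
## unoriented components and their position footprints.
.hp_components <- function(an) {
  m <- length(an$gi)
  parent <- seq_len(an$c)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  if (m > 1L) {
    for (a in seq_len(m - 1L)) {
      for (b in seq((a + 1L), m)) {
        ## strict interleaving on the line
        if ((an$gi[a] < an$gi[b] && an$gi[b] < an$gj[a] && an$gj[a] < an$gj[b]) ||
            (an$gi[b] < an$gi[a] && an$gi[a] < an$gj[b] && an$gj[b] < an$gj[a])) {
          union(an$cyc_of_gray[a], an$cyc_of_gray[b])
        }
      }
    }
  }
  comp_of_cycle <- vapply(seq_len(an$c), find, integer(1))
  keep <- !an$trivial_cycle               # drop adjacency cycles
  comp_ids <- unique(comp_of_cycle[keep])
  comps <- lapply(comp_ids, function(id) {
    cycles <- which(comp_of_cycle == id & keep)
    edges <- which(an$cyc_of_gray %in% cycles)
    list(edges = edges,
         oriented = any(an$oriented_edge[edges]),
         span = c(min(an$gi[edges]), max(an$gj[edges])))
  })
  comps
}

## Hurdle count from the circular run-length reading of unoriented components.
## A hurdle is an unoriented component whose positions are consecutive on the
## circle of positions restricted to unoriented components.
.hp_hurdles <- function(comps) {
  unor <- Filter(function(cp) !cp$oriented, comps)
  nu <- length(unor)
  if (nu == 0L) return(list(h = 0L, f = 0L))
  ## label every gray-edge endpoint position with its component
  lab <- unlist(lapply(seq_len(nu), function(i) {
    rep(i, length(unor[[i]]$positions))
  }))
  pos <- unlist(lapply(unor, function(cp) cp$positions))
  ord <- order(pos)
  seq_lab <- lab[ord]
  hurdles_of <- function(seq_lab, ids) {
    if (length(ids) == 0L) return(integer(0))
    s <- seq_lab[seq_lab %in% ids]
    if (length(s) == 0L) return(integer(0))
    r <- rle(s)$values
    ## circular merge
    if (length(r) > 1L && r[1L] == r[length(r)]) r <- r[-length(r)]
    tab <- table(r)
    as.integer(names(tab)[tab == 1L])
  }
  ids <- seq_len(nu)
  hs <- hurdles_of(seq_lab, ids)
  h <- length(hs)
  f <- 0L
  if (h > 0L) {
    super <- vapply(hs, function(hid) {
      before <- setdiff(hurdles_of(seq_lab, ids), hid)
      after <- hurdles_of(seq_lab, setdiff(ids, hid))
      length(setdiff(after, before)) > 0L
    }, logical(1))
    if (h %% 2L == 1L && all(super)) f <- 1L
  }
  list(h = h, f = f)
}

#' Minimum inversion (reversal) distance between signed permutations
#'
#' Exact Hannenhalli-Pevzner distance
#' \eqn{d = (n + 1) - c + h + f} computed on the breakpoint graph of the
#' composed permutation \eqn{q^{-1} p} (cycles \eqn{c}, hurdles \eqn{h},
#' fortress indicator \eqn{f}), with linear caps.
#'
#' @inheritParams breakpoint_distance
#' @return Minimum number of signed reversals transforming `p` into `q`.
#' @examples
#' inversion_distance(c(-1), c(1))          # 1
#' inversion_distance(c(2, 1), c(1, 2))     # 3: the minimal hurdle
#' @export
inversion_distance <- function(p, q) {
  r <- .compose_relative(p, q)
  n <- length(r)
  an <- .hp_analyze(r)
  comps <- .hp_components(an)
  ## attach endpoint positions for the hurdle reading
  comps <- lapply(comps, function(cp) {
    cp$positions <- sort(c(an$gi[cp$edges], an$gj[cp$edges]))
    cp
  })
  hf <- .hp_hurdles(comps)
  as.integer(n + 1L - an$c + hf$h + hf$f)
}

## ---- exhaustive BFS oracle -------------------------------------------------

.bfs_cache <- new.env(parent = emptyenv())

## Lehmer-code ranking of rows of an unsigned permutation matrix (values 1..n).
.rank_perm_rows <- function(M) {
  n <- ncol(M)
  fact <- cumprod(c(1, seq_len(max(n - 1L, 1L))))  # 0!..(n-1)!
  r <- numeric(nrow(M))
  for (i in seq_len(n - 1L)) {
    smaller <- rep(0L, nrow(M))
    for (j in seq(i + 1L, n)) smaller <- smaller + (M[, j] < M[, i])
    r <- r + smaller * fact[n - i + 1L]
  }
  r
}

.encode_rows <- function(M) {
  ## signed matrix -> integer code: lehmer(|M|) * 2^n + sign bits
  n <- ncol(M)
  bits <- numeric(nrow(M))
  for (j in seq_len(n)) bits <- bits * 2 + (M[, j] < 0)
  .rank_perm_rows(abs(M)) * 2^n + bits
}

## Full single-source BFS over all signed permutations of size n from the
## identity, by reversal moves.  Returns an integer distance vector indexed by
## .encode_rows code + 1.
.reversal_distance_table <- function(n) {
  key <- as.character(n)
  if (!is.null(.bfs_cache[[key]])) return(.bfs_cache[[key]])
  if (n > 7L) stop("BFS oracle supports n <= 7 (state space too large beyond)")
  n_states <- factorial(n) * 2^n
  dist <- rep(-1L, n_states)
  frontier <- matrix(seq_len(n), nrow = 1L)
  dist[.encode_rows(frontier) + 1] <- 0L
  d <- 0L
  ivs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ivs <- ivs[ivs[, 1] <= ivs[, 2], , drop = FALSE]
  while (nrow(frontier) > 0L) {
    nxt <- vector("list", nrow(ivs))
    for (e in seq_len(nrow(ivs))) {
      i <- ivs[e, 1]; j <- ivs[e, 2]
      G <- frontier
      G[, i:j] <- -G[, j:i, drop = FALSE]
      nxt[[e]] <- G
    }
    cand <- do.call(rbind, nxt)
    codes <- .encode_rows(cand) + 1
    keep <- dist[codes] < 0L
    cand <- cand[keep, , drop = FALSE]
    codes <- codes[keep]
    if (length(codes) == 0L) break
    first <- !duplicated(codes)
    cand <- cand[first, , drop = FALSE]
    codes <- codes[first]
    d <- d + 1L
    dist[codes] <- d
    frontier <- cand
  }
  .bfs_cache[[key]] <- dist
  dist
}

#' Exact inversion distance by breadth-first search (test oracle)
#'
#' Independent oracle for [inversion_distance()]: exhaustive BFS over reversal
#' moves on the full signed-permutation state space (feasible for n <= 7;
#' the distance table from the identity is cached per size).
#'
#' @inheritParams breakpoint_distance
#' @param limit error if the true distance exceeds this bound.
#' @return Exact minimum number of reversals.
#' @export
inversion_distance_bfs <- function(p, q, limit = 30L) {
  r <- .compose_relative(p, q)
  n <- length(r)
  dist <- .reversal_distance_table(n)
  d <- dist[.encode_rows(matrix(r, nrow = 1L)) + 1]
  if (is.na(d) || d < 0L) stop("state not reached by BFS (internal error)")
  if (d > limit) stop("BFS oracle limit exceeded (distance ", d, " > ", limit, ")")
  as.integer(d)
}

#' Parsimonious reversal scenario between two permutations
#'
#' Returns an ordered list of reversals (position ranges in `p`'s coordinate
#' after previous steps) of length exactly `inversion_distance(p, q)` whose
#' sequential application transforms `p` into `q`.  Among reversals that
#' decrease the distance, the lexicographically lowest-index one is chosen,
#' making the scenario deterministic.
#'
#' @inheritParams breakpoint_distance
#' @return A list of integer pairs `c(i, j)` (1-based inclusive positions).
#' @export
sorting_scenario <- function(p, q) {
  r <- .compose_relative(p, q)
  n <- length(r)
  id <- seq_len(n)
  steps <- list()
  d <- inversion_distance(r, id)
  while (d > 0L) {
    found <- FALSE
    for (i in seq_len(n)) {
      for (j in i:n) {
        cand <- .reverse_segment(r, i, j)
        if (inversion_distance(cand, id) == d - 1L) {
          steps[[length(steps) + 1L]] <- c(i, j)
          r <- cand
          d <- d - 1L
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("no distance-decreasing reversal found (internal error)")
  }
  steps
}

#' Pairwise rearrangement distance matrices
#'
#' Computes breakpoint (BP) and inversion (IV) distances over all pairs of
#' permutations sharing one block frame.
#'
#' @param perms list of [signed_permutation()] objects with distinct taxon
#'   names.
#' @return An object of class `distance_table`: list with `taxa`, integer
#'   matrices `bp` and `iv` (symmetric, zero diagonal).
#' @export
pairwise_distance_matrix <- function(perms) {
  taxa <- vapply(perms, function(p) p$taxon, character(1))
  if (anyDuplicated(taxa)) stop("duplicate taxon names in permutation list")
  k <- length(perms)
  bp <- matrix(0L, k, k, dimnames = list(taxa, taxa))
  iv <- matrix(0L, k, k, dimnames = list(taxa, taxa))
  if (k > 1L) {
    for (a in seq_len(k - 1L)) {
      for (b in seq(a + 1L, k)) {
        bp[a, b] <- bp[b, a] <- breakpoint_distance(perms[[a]], perms[[b]])
        iv[a, b] <- iv[b, a] <- inversion_distance(perms[[a]], perms[[b]])
      }
    }
  }
  structure(list(taxa = taxa, bp = bp, iv = iv), class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("pairwise rearrangement distances over", length(x$taxa), "taxa (BP/IV)\n")
  m <- matrix("", length(x$taxa), length(x$taxa),
              dimnames = list(x$taxa, x$taxa))
  m[lower.tri(m)] <- paste0(x$bp[lower.tri(m)], "/", x$iv[lower.tri(m)])
  diag(m) <- "-"
  print(m[, seq_len(ncol(m) - 1L), drop = FALSE], quote = FALSE)
  invisible(x)
}

#' Export a distance table as lower-triangle BP/IV TSV
#'
#' @param x a `distance_table`.
#' @param path output file.
#' @export
write_distance_table <- function(x, path) {
  k <- length(x$taxa)
  lines <- c(paste(c("taxon", x$taxa), collapse = "\t"))
  for (a in seq_len(k)) {
    cells <- if (a > 1L) {
      vapply(seq_len(a - 1L), function(b) paste0(x$bp[a, b], "/", x$iv[a, b]),
             character(1))
    } else character(0)
    lines <- c(lines, paste(c(x$taxa[a], cells, "-"), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write signed permutation TSV
#'
#' The interchange format is one line per taxon,
#' `taxon<TAB>comma-separated signed integers`, preceded by a `#frame=` header.
#'
#' @param perms list of `signed_permutation`s.
#' @param path file path.
#' @return `read_permutations` returns a list of `signed_permutation`s.
#' @export
write_permutations <- function(perms, path) {
  frame <- unique(vapply(perms, function(p) p$frame, character(1)))
  frame <- frame[nzchar(frame)]
  lines <- paste0("#frame=", if (length(frame)) frame[1] else "")
  for (p in perms) {
    lines <- c(lines, paste0(p$taxon, "\t", paste(p$blocks, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_permutations
#' @export
read_permutations <- function(path) {
  lines <- readLines(path)
  frame <- sub("^#frame=", "", lines[startsWith(lines, "#frame=")][1])
  if (is.na(frame)) frame <- ""
  lines <- lines[!startsWith(lines, "#")]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    signed_permutation(as.integer(strsplit(parts[2], ",")[[1]]),
                       taxon = parts[1], frame = frame)
  })
}

#' Apply k random reversals to a signed permutation
#'
#' Simulates an inversion history: `k` uniformly chosen index ranges applied
#' sequentially, reproducible under `seed`.
#'
#' @param start a `signed_permutation` (or signed integer vector).
#' @param k number of reversal events (>= 0).
#' @param seed integer seed.
#' @return List with `start_perm`, `events` (list of position ranges),
#'   `end_perm`, `seed`; class `inversion_history`.
#' @export
simulate_inversion_history <- function(start, k, seed = 1L) {
  if (k < 0) stop("k must be >= 0")
  set.seed(seed)
  v <- .perm_blocks(start)
  n <- length(v)
  taxon <- if (inherits(start, "signed_permutation")) start$taxon else ""
  frame <- if (inherits(start, "signed_permutation")) start$frame else ""
  events <- vector("list", k)
  for (e in seq_len(k)) {
    ij <- sort(sample.int(n, 2L, replace = TRUE))
    events[[e]] <- ij
    v <- .reverse_segment(v, ij[1], ij[2])
  }
  structure(list(
    start_perm = signed_permutation(.perm_blocks(start), taxon, frame),
    events = events,
    end_perm = signed_permutation(v, paste0(taxon, "_derived"), frame),
    seed = seed
  ), class = "inversion_history")
}
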