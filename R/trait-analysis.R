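#' Two-state Mk ancestral-state reconstruction
#'
#' Fits the symmetric 2-state Mk model ("unordered and equally weighted") to
#' a binary DR/IR character on a rooted tree: the single transition rate is
#' ML-optimized, the likelihood is computed by Felsenstein pruning with
#' change probability (1 - exp(-2 rate b)) / 2 per branch of length b, the
#' root prior is flat (0.5, 0.5) as forced by the symmetric model, and
#' marginal ancestral-state probabilities are obtained by combining the
#' downward partial likelihoods with the likelihood of the rest of the tree
#' (the standard re-rooting construction).
#'
#' @param tree a rooted binary `phylo` tree with branch lengths.
#' @param states named character vector tip -> `"DR"`/`"IR"` (every tip).
#' @return Object of class `mk_fit`: list with `rate`, `logL`,
#'   `node_marginals` (matrix, rows = internal nodes in `phylo` numbering,
#'   columns `p_IR`, `p_DR`), and `boundary` (TRUE when the all-same-state
#'   rate-0 boundary was returned).
#' @export
mk_fit <- function(tree, states) {
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(states))) {
    stop("every tip needs a state")
  }
  if (!all(states[tree$tip.label] %in% c("DR", "IR"))) {
    stop("states must be DR or IR")
  }
  x <- states[tree$tip.label]
  ## state order: 1 = IR, 2 = DR
  tipvec <- ifelse(x == "DR", 2L, 1L)
  nnode <- tree$Nnode
  edge <- tree$edge; blen <- tree$edge.length
  root <- ntip + 1L

  down <- function(rate) {
    ## post-order partial likelihoods L[node, state]
    Lk <- matrix(0, ntip + nnode, 2)
    Lk[cbind(seq_len(ntip), tipvec)] <- 1
    po <- ape::reorder.phylo(tree, "postorder")
    pe <- po$edge; pb <- po$edge.length
    Lk[(ntip + 1L):(ntip + nnode), ] <- 1
    for (e in seq_len(nrow(pe))) {
      par <- pe[e, 1]; ch <- pe[e, 2]
      pc <- (1 - exp(-2 * rate * pb[e])) / 2
      P <- matrix(c(1 - pc, pc, pc, 1 - pc), 2, 2)
      Lk[par, ] <- Lk[par, ] * as.vector(P %*% Lk[ch, ])
    }
    Lk
  }
  loglik <- function(rate) {
    Lk <- down(rate)
    log(sum(0.5 * Lk[root, ]))
  }

  boundary <- FALSE
  if (length(unique(tipvec)) == 1L) {
    rate_hat <- 0
    boundary <- TRUE
  } else {
    opt <- stats::optimize(function(lr) loglik(exp(lr)),
                           interval = log(c(1e-8, 1e3)),
                           maximum = TRUE, tol = 1e-12)
    rate_hat <- exp(opt$maximum)
  }
  ll <- loglik(rate_hat)

  ## marginals: for each node, partial-from-above ("up") combined with down
  Lk <- down(rate_hat)
  up <- matrix(1, ntip + nnode, 2)
  co <- ape::reorder.phylo(tree, "cladewise")   # preorder edges
  ce <- co$edge; cb <- co$edge.length
  children <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in seq_len(nrow(ce))) {
    par <- ce[e, 1]; ch <- ce[e, 2]
    pc <- (1 - exp(-2 * rate_hat * cb[e])) / 2
    P <- matrix(c(1 - pc, pc, pc, 1 - pc), 2, 2)
    ## contribution of siblings of ch below par
    sib_part <- up[par, ]
    eidx <- which(edge[, 1] == par & edge[, 2] != ch)
    for (se in eidx) {
      psib <- (1 - exp(-2 * rate_hat * blen[se])) / 2
      Ps <- matrix(c(1 - psib, psib, psib, 1 - psib), 2, 2)
      sib_part <- sib_part * as.vector(Ps %*% Lk[edge[se, 2], ])
    }
    up[ch, ] <- as.vector(t(P) %*% sib_part)
  }
  marg <- matrix(0, nnode, 2,
                 dimnames = list(NULL, c("p_IR", "p_DR")))
  prior <- c(0.5, 0.5)
  for (nd in (ntip + 1L):(ntip + nnode)) {
    w <- Lk[nd, ] * up[nd, ] * prior
    marg[nd - ntip, ] <- w / sum(w)
  }
  structure(list(rate = rate_hat, logL = ll, node_marginals = marg,
                 boundary = boundary, tree = tree,
                 states = x),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("2-state Mk fit: rate =", signif(x$rate, 4), " logL =",
      signif(x$logL, 6), if (x$boundary) "(boundary: all tips identical)",
      "\n")
  invisible(x)
}

## clade key: sorted tip labels of the descendants of a node
.clade_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  vapply((ntip + 1L):(ntip + tree$Nnode), function(nd) {
    paste(sort(desc[[nd]]), collapse = "|")
  }, character(1))
}

#' Summarize ancestral-state reconstruction over a tree sample
#'
#' Fits the Mk model per tree (one rate each) and matches clades across trees
#' by their tip bipartitions.  For each clade seen in any tree it reports the
#' fraction of trees containing it, the mean marginal state probabilities,
#' and the fraction of trees in which a change is reconstructed on the
#' clade's stem branch (parent and child most-probable marginal states
#' differ).
#'
#' @param trees list of `phylo` trees sharing one tip set (or a `multiPhylo`).
#' @param states named character vector tip -> `"DR"`/`"IR"`.
#' @return Data frame: clade, n_trees, presence, mean_p_DR, mean_p_IR,
#'   change_fraction.
#' @export
summarize_asr_over_trees <- function(trees, states) {
  trees <- unclass(trees)
  tipset <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), tipset)) stop("tip set mismatch")
  }
  acc <- new.env(parent = emptyenv())
  for (tr in trees) {
    fit <- mk_fit(tr, states)
    keys <- .clade_keys(tr)
    ntip <- length(tr$tip.label)
    best <- apply(fit$node_marginals, 1, which.max)  # 1 = IR, 2 = DR
    parent_of <- integer(ntip + tr$Nnode)
    parent_of[tr$edge[, 2]] <- tr$edge[, 1]
    for (ni in seq_along(keys)) {
      nd <- ntip + ni
      pa <- parent_of[nd]
      changed <- if (pa == 0L) 0 else
        as.numeric(best[ni] != best[pa - ntip])
      rec <- acc[[keys[ni]]]
      if (is.null(rec)) rec <- c(n = 0, p_ir = 0, p_dr = 0, chg = 0)
      rec <- rec + c(1, fit$node_marginals[ni, "p_IR"],
                     fit$node_marginals[ni, "p_DR"], changed)
      acc[[keys[ni]]] <- rec
    }
  }
  keys <- ls(acc)
  res <- do.call(rbind, lapply(keys, function(k) {
    rec <- acc[[k]]
    data.frame(clade = k, n_trees = rec[["n"]],
               presence = rec[["n"]] / length(trees),
               mean_p_DR = rec[["p_dr"]] / rec[["n"]],
               mean_p_IR = rec[["p_ir"]] / rec[["n"]],
               change_fraction = rec[["chg"]] / rec[["n"]],
               stringsAsFactors = FALSE)
  }))
  res[order(-res$presence, -nchar(res$clade)), ]
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y numeric vectors of equal length (>= 3), nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's algorithm: at each internal node of a rooted binary tree the
#' contrast (x1 - x2) / sqrt(v1 + v2) is computed from the two daughter
#' values, the ancestral value is the variance-weighted average, and the
#' parent branch is lengthened by v1 v2 / (v1 + v2).  Polytomies and
#' zero-length cherries are rejected.
#'
#' @param tree rooted binary `phylo` with positive branch lengths.
#' @param values named numeric vector tip -> value.
#' @return Data frame with one row per internal node: `node`, `contrast`
#'   (standardized), `raw`, `variance`.
#' @export
pic_contrasts <- function(tree, values) {
  ntip <- length(tree$tip.label)
  if (!ape::is.rooted(tree) || !ape::is.binary.phylo(tree)) {
    stop("tree must be rooted and binary (no polytomies)")
  }
  if (!all(tree$tip.label %in% names(values))) stop("all tips need values")
  po <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  val <- numeric(nn); vlen <- numeric(nn)
  val[seq_len(ntip)] <- values[tree$tip.label]
  ## branch length (possibly lengthened) above each node
  eb <- numeric(nn)
  eb[po$edge[, 2]] <- po$edge.length
  node_id <- c(); contrast <- c(); raw <- c(); variance <- c()
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (nd in unique(po$edge[, 1])) {
    ch <- kids[[as.character(nd)]]
    v1 <- eb[ch[1]]; v2 <- eb[ch[2]]
    if (v1 + v2 <= 0) stop("zero-length cherry at node ", nd)
    rawc <- val[ch[1]] - val[ch[2]]
    contrast <- c(contrast, rawc / sqrt(v1 + v2))
    raw <- c(raw, rawc)
    variance <- c(variance, v1 + v2)
    node_id <- c(node_id, nd)
    val[nd] <- (val[ch[1]] / v1 + val[ch[2]] / v2) / (1 / v1 + 1 / v2)
    eb[nd] <- eb[nd] + v1 * v2 / (v1 + v2)
  }
  data.frame(node = node_id, contrast = contrast, raw = raw,
             variance = variance)
}

#' Correlation of two traits through phylogenetically independent contrasts
#'
#' Correlation of the two contrast sets constrained through the origin,
#' r = sum(cx cy) / sqrt(sum(cx^2) sum(cy^2)), with a two-sided t test on
#' n_contrasts - 1 degrees of freedom.
#'
#' @param tree rooted binary `phylo` with positive branch lengths.
#' @param x,y named numeric vectors tip -> value.
#' @return List with `r`, `p`, `n` (number of contrasts).
#' @export
pic_correlation <- function(tree, x, y) {
  cx <- pic_contrasts(tree, x)$contrast
  cy <- pic_contrasts(tree, y)$contrast
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  df <- length(cx) - 1L
  p <- if (abs(r) >= 1 - 1e-15) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tstat), df)
  }
  list(r = r, p = p, n = length(cx))
}
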