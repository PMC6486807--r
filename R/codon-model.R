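## Codon-level machinery shared by the simulator and the ML estimator.
## Genetic code: translation table 11 (plastid/bacterial); its 61 sense
## codons and stop set (TAA, TAG, TGA) coincide with the standard code.

.codon_env <- new.env(parent = emptyenv())

.codon_universe <- function() {
  if (!is.null(.codon_env$u)) return(.codon_env$u)
  nt <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  code <- Biostrings::getGeneticCode("11")
  aa <- code[codons]
  sense <- codons[aa != "*"]
  aa <- aa[match(sense, codons)]
  n <- length(sense)                     # 61
  cmat <- do.call(rbind, strsplit(sense, ""))
  ndiff <- matrix(0L, n, n)
  is_ts <- matrix(FALSE, n, n)           # transition at the differing site
  is_syn <- matrix(FALSE, n, n)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n)) {
    di <- sweep(cmat, 2, cmat[i, ], FUN = "!=")
    nd <- rowSums(di)
    ndiff[i, ] <- nd
    one <- which(nd == 1L)
    for (j in one) {
      p <- which(di[j, ])
      is_ts[i, j] <- transitions[[cmat[i, p]]] == cmat[j, p]
      is_syn[i, j] <- aa[i] == aa[j]
    }
  }
  u <- list(codons = sense, aa = aa, n = n, ndiff = ndiff,
            is_ts = is_ts, is_syn = is_syn,
            stops = codons[code[codons] == "*"])
  .codon_env$u <- u
  u
}

#' GY94-type codon rate matrix
#'
#' 61x61 instantaneous rate matrix over the sense codons of translation
#' table 11: single-nucleotide changes at rate proportional to the target
#' codon frequency, multiplied by `kappa` for transitions and by `omega` for
#' nonsynonymous changes; scaled so the expected rate is one substitution per
#' codon per unit time.
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param freqs equilibrium codon frequencies over the 61 sense codons
#'   (nonnegative, summing to 1).
#' @return List with `Q` (scaled rate matrix), `freqs`, and the flux
#'   proportion `rho_syn` that is synonymous.
#' @export
gy94_rate_matrix <- function(kappa, omega, freqs) {
  u <- .codon_universe()
  if (length(freqs) != u$n) stop("freqs must cover the 61 sense codons")
  if (abs(sum(freqs) - 1) > 1e-9) stop("codon frequencies must sum to 1")
  if (any(freqs < 0)) stop("codon frequencies must be nonnegative")
  Q <- matrix(0, u$n, u$n, dimnames = list(u$codons, u$codons))
  single <- u$ndiff == 1L
  rate <- matrix(0, u$n, u$n)
  rate[single] <- 1
  rate[single & u$is_ts] <- kappa
  rate[single & !u$is_syn] <- rate[single & !u$is_syn] * omega
  Q <- rate * matrix(freqs, u$n, u$n, byrow = TRUE)
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(freqs * diag(Q))
  if (mean_rate <= 0) stop("degenerate rate matrix")
  Q <- Q / mean_rate
  flux <- freqs * Q
  rho_syn <- sum(flux[single & u$is_syn])
  list(Q = Q, freqs = freqs, rho_syn = rho_syn)
}

## transition probabilities exp(Qt) via symmetrization (Q reversible wrt pi)
.codon_P <- function(Q, freqs, t) {
  pi_s <- pmax(freqs, 1e-12)
  D <- sqrt(pi_s)
  S <- (D %o% (1 / D)) * Q
  S <- (S + t(S)) / 2
  E <- eigen(S, symmetric = TRUE)
  P <- (1 / D %o% D) * (E$vectors %*% (t(E$vectors) * exp(E$values * t)))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' F3x4 codon frequencies
#'
#' Codon frequencies as products of position-specific nucleotide frequencies
#' computed from the supplied in-frame sequences, renormalized over the 61
#' sense codons.
#'
#' @param seqs character vector of in-frame DNA sequences.
#' @return Numeric vector of length 61 (named by codon), summing to 1.
#' @export
codon_freqs_f3x4 <- function(seqs) {
  u <- .codon_universe()
  pos_counts <- matrix(0, 3, 4, dimnames = list(NULL, c("T", "C", "A", "G")))
  for (s in seqs) {
    s <- toupper(s)
    chars <- strsplit(s, "")[[1]]
    keep <- chars %in% c("T", "C", "A", "G")
    pos <- ((seq_along(chars) - 1L) %% 3L) + 1L
    tab <- table(factor(pos[keep], 1:3), factor(chars[keep],
                                                c("T", "C", "A", "G")))
    pos_counts <- pos_counts + as.matrix(tab)
  }
  pf <- pos_counts / rowSums(pos_counts)
  cmat <- do.call(rbind, strsplit(u$codons, ""))
  f <- pf[1, cmat[, 1]] * pf[2, cmat[, 2]] * pf[3, cmat[, 3]]
  f <- f / sum(f)
  stats::setNames(f, u$codons)
}

#' Simulate a diverged pair of in-frame coding sequences
#'
#' Draws an ancestral sequence from the supplied codon frequencies and evolves
#' one descendant for `t` expected substitutions per codon under the GY94-type
#' model ([gy94_rate_matrix()]); the returned pair are the ancestor and the
#' descendant.  No internal stop codons can arise (the state space is the 61
#' sense codons).
#'
#' @param t expected substitutions per codon (>= 0).
#' @param kappa,omega model parameters.
#' @param n_codons number of codons.
#' @param freqs codon frequencies (default uniform over the 61 sense codons).
#' @param seed integer seed.
#' @return Named character vector of two sequences (`ancestor`, `descendant`).
#' @export
simulate_codon_pair <- function(t, kappa, omega, n_codons,
                                freqs = NULL, seed = 1L) {
  if (t < 0) stop("t must be >= 0")
  u <- .codon_universe()
  if (is.null(freqs)) freqs <- rep(1 / u$n, u$n)
  if (length(freqs) != u$n) stop("freqs must cover the 61 sense codons")
  if (abs(sum(freqs) - 1) > 1e-9) stop("codon frequencies must sum to 1")
  set.seed(seed)
  anc <- sample.int(u$n, n_codons, replace = TRUE, prob = freqs)
  if (t == 0) {
    s <- paste(u$codons[anc], collapse = "")
    return(c(ancestor = s, descendant = s))
  }
  M <- gy94_rate_matrix(kappa, omega, freqs)
  P <- .codon_P(M$Q, freqs, t)
  dec <- vapply(anc, function(i) {
    sample.int(u$n, 1L, prob = P[i, ])
  }, integer(1))
  c(ancestor = paste(u$codons[anc], collapse = ""),
    descendant = paste(u$codons[dec], collapse = ""))
}

#' In-frame codon alignment container
#'
#' @param gene gene name.
#' @param seqs named character vector (taxon -> in-frame sequence); equal
#'   lengths, multiples of 3, no internal stop codons; gaps only as whole
#'   `---` codons.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(gene, seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by taxon")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  if (lens[1] %% 3L != 0L) stop("alignment length must be a multiple of 3")
  u <- .codon_universe()
  for (tx in names(seqs)) {
    cods <- substring(toupper(seqs[[tx]]), seq(1, lens[1], 3), seq(3, lens[1], 3))
    if (any(cods[-length(cods)] %in% u$stops)) {
      stop("internal stop codon in ", tx)
    }
  }
  structure(list(gene = gene, seqs = toupper(seqs),
                 n_codons = unname(lens[1]) %/% 3L),
            class = "codon_alignment")
}

#' Read one gene's codon alignment from FASTA
#' @param path FASTA file; taxon ids in headers.
#' @param gene gene name (default: file base name).
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, gene = NULL) {
  s <- Biostrings::readDNAStringSet(path)
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  codon_alignment(gene, stats::setNames(as.character(s),
                                        sub("\\s.*$", "", names(s))))
}

## codon index vectors for a taxon pair, with pairwise deletion of codons
## containing gaps/ambiguity in either sequence
.pair_codons <- function(aln, pair) {
  u <- .codon_universe()
  if (!all(pair %in% names(aln$seqs))) {
    stop("pair taxa not in alignment: ",
         paste(setdiff(pair, names(aln$seqs)), collapse = ", "))
  }
  idx <- lapply(pair, function(tx) {
    s <- aln$seqs[[tx]]
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    match(cods, u$codons)
  })
  keep <- !is.na(idx[[1]]) & !is.na(idx[[2]])
  list(a = idx[[1]][keep], b = idx[[2]][keep])
}

.rate_row <- function(aln, pair, dN, dS, omega, kappa, t, logL, method,
                      flag = "") {
  data.frame(gene = aln$gene, pair = paste(pair, collapse = ":"),
             dN = dN, dS = dS, omega = omega, kappa = kappa, t = t,
             logL = logL, method = method, flag = flag,
             stringsAsFactors = FALSE)
}

#' Maximum-likelihood pairwise dN/dS under the GY94 codon model
#'
#' Estimates (t, kappa, omega) for one taxon pair by maximizing the pairwise
#' codon likelihood under [gy94_rate_matrix()] with F3x4 frequencies computed
#' from the two sequences.  dS and dN partition the branch length t over the
#' synonymous/nonsynonymous site proportions of the fitted model: with
#' rho_S the fitted synonymous flux proportion and p_S the synonymous flux
#' proportion under omega = 1 (the synonymous site fraction),
#' dS = t * rho_S / (3 p_S) and dN = t * rho_N / (3 (1 - p_S)), so that
#' dN/dS = omega.
#'
#' @param aln a [codon_alignment()].
#' @param pair character vector of two taxon names.
#' @param n_restarts extra random restarts of the optimizer.
#' @return One-row data frame: gene, pair, dN, dS, omega, kappa, t, logL,
#'   method, flag (`"dS_saturated"` when dS > 5).
#' @export
ml_pairwise_rates <- function(aln, pair, n_restarts = 2L) {
  pc <- .pair_codons(aln, pair)
  if (length(pc$a) < 30L) stop("fewer than 30 shared ungapped codons")
  u <- .codon_universe()
  if (all(pc$a == pc$b)) {
    return(.rate_row(aln, pair, 0, 0, NA_real_, NA_real_, 0, NA_real_,
                     "ML_F3x4"))
  }
  counts <- matrix(0, u$n, u$n)
  tab <- table(pc$a, pc$b)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.vector(tab)
  pi_f <- codon_freqs_f3x4(c(u$codons[pc$a], u$codons[pc$b]))
  pi_f <- pmax(pi_f, 1e-10); pi_f <- pi_f / sum(pi_f)
  nz <- which(counts > 0, arr.ind = TRUE)
  nzc <- counts[nz]
  negll <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2]); omega <- exp(par[3])
    M <- gy94_rate_matrix(kappa, omega, pi_f)
    P <- .codon_P(M$Q, pi_f, t)
    lik <- pi_f[nz[, 1]] * P[nz]
    -sum(nzc * log(pmax(lik, 1e-300)))
  }
  p_diff <- mean(pc$a != pc$b)
  start0 <- c(log(max(-log(1 - min(p_diff, 0.95)), 0.01)), log(2), log(0.5))
  lower <- log(c(1e-6, 0.01, 1e-4)); upper <- log(c(50, 100, 20))
  best <- NULL
  starts <- list(start0)
  if (n_restarts > 0L) {
    set.seed(sum(nzc) + length(pc$a))  # deterministic restarts
    for (r in seq_len(n_restarts)) {
      starts[[r + 1L]] <- pmin(pmax(start0 + stats::rnorm(3, 0, 1), lower),
                               upper)
    }
  }
  for (st in starts) {
    fit <- try(stats::optim(st, negll, method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(factr = 1e4, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("codon ML optimization failed to converge")
  t_hat <- exp(best$par[1]); kappa_hat <- exp(best$par[2])
  omega_hat <- exp(best$par[3])
  M_hat <- gy94_rate_matrix(kappa_hat, omega_hat, pi_f)
  M_neu <- gy94_rate_matrix(kappa_hat, 1, pi_f)
  p_syn_sites <- M_neu$rho_syn            # synonymous site fraction
  rho_s <- M_hat$rho_syn
  dS <- t_hat * rho_s / (3 * p_syn_sites)
  dN <- t_hat * (1 - rho_s) / (3 * (1 - p_syn_sites))
  .rate_row(aln, pair, dN, dS, omega_hat, kappa_hat, t_hat, -best$value,
            "ML_F3x4", flag = if (dS > 5) "dS_saturated" else "")
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counting estimator used as an independent check on the ML route:
#' synonymous/nonsynonymous site counts per codon (averaged over the two
#' sequences), multi-step codon differences resolved by equal weighting of
#' all substitution paths avoiding stop codons, and Jukes-Cantor correction
#' of the proportions.
#'
#' @inheritParams ml_pairwise_rates
#' @return One-row data frame in the [ml_pairwise_rates()] schema
#'   (method `"NG86"`); saturated proportions (p >= 3/4) give `NA` with flag
#'   `"saturated"`.
#' @export
ng86_rates <- function(aln, pair) {
  pc <- .pair_codons(aln, pair)
  u <- .codon_universe()
  ## synonymous site count of one codon: fraction of single-nt changes that
  ## are synonymous, times 3 (changes to stop codons excluded from sense
  ## targets but count as nonsynonymous opportunities, per the original
  ## method's treatment of the 3 sites per codon)
  syn_sites <- vapply(seq_len(u$n), function(i) {
    nb <- which(u$ndiff[i, ] == 1L)
    ## number of sense single-nt neighbors is <= 9; each of 9 possible
    ## changes is synonymous iff it leads to a sense codon with the same aa
    3 * sum(u$is_syn[i, nb]) / 9
  }, numeric(1))
  S <- sum((syn_sites[pc$a] + syn_sites[pc$b]) / 2)
  N <- 3 * length(pc$a) - S
  sd_tot <- 0; nd_tot <- 0
  diffs <- which(pc$a != pc$b)
  for (s in diffs) {
    i <- pc$a[s]; j <- pc$b[s]
    ci <- strsplit(u$codons[i], "")[[1]]
    cj <- strsplit(u$codons[j], "")[[1]]
    posd <- which(ci != cj)
    perms <- if (length(posd) == 1L) list(posd) else
      if (length(posd) == 2L) list(posd, rev(posd)) else
        lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1)), function(o) posd[o])
    path_sd <- c(); path_nd <- c()
    for (ord in perms) {
      cur <- ci; sdp <- 0; ndp <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- cj[p]
        from <- match(paste(cur, collapse = ""), u$codons)
        to <- match(paste(nxt, collapse = ""), u$codons)
        if (is.na(to) || is.na(from)) { ok <- FALSE; break }
        if (u$is_syn[from, to]) sdp <- sdp + 1 else ndp <- ndp + 1
        cur <- nxt
      }
      if (ok) { path_sd <- c(path_sd, sdp); path_nd <- c(path_nd, ndp) }
    }
    if (length(path_sd) == 0L) {
      ## all paths pass through stops; split evenly
      path_sd <- length(posd) / 2; path_nd <- length(posd) / 2
    }
    sd_tot <- sd_tot + mean(path_sd)
    nd_tot <- nd_tot + mean(path_nd)
  }
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  pS <- sd_tot / S; pN <- nd_tot / N
  dS <- jc(pS); dN <- jc(pN)
  flag <- if (is.na(dS) || is.na(dN)) "saturated" else ""
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  .rate_row(aln, pair, dN, dS, omega, NA_real_, NA_real_, NA_real_,
            "NG86", flag)
}
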