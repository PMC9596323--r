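# Genome-wide summaries from a biallelic genotype matrix: LD pruning,
# heterozygosity, standardized multilocus heterozygosity (stMLH), and
# KING-robust pairwise kinship.

#' Prune SNPs in strong linkage disequilibrium
#'
#' Sliding site-count windows (`window_sites` wide, advanced by
#' `step_sites`). Within each window, for every still-retained pair with
#' genotype-count correlation `r^2 >= r2_max`, one member is removed
#' uniformly at random. After the scan, no surviving within-window pair
#' reaches the threshold. r-squared is the squared Pearson correlation of
#' 0/1/2 codes over pairwise-complete individuals; monomorphic sites have
#' undefined correlation and are treated as r-squared 0.
#'
#' @param g a [GenotypeMatrix-class].
#' @param window_sites,step_sites,r2_max window width, step (both in
#'   sites) and the pruning threshold.
#' @param seed integer seed for the random member choice.
#' @return sorted integer vector of retained site indices.
#' @export
ldPrune <- function(g, window_sites = 50L, step_sites = 5L, r2_max = 0.5,
                    seed = NULL) {
  calls <- genotypes(g)
  m <- ncol(calls)
  stopifnot(m >= 2)
  withSeed(seed, {
    keep <- rep(TRUE, m)
    starts <- seq(1L, max(1L, m - 1L), by = step_sites)
    for (s in starts) {
      win <- s:min(s + window_sites - 1L, m)
      idx <- win[keep[win]]
      if (length(idx) < 2L) next
      r2 <- suppressWarnings(cor(calls[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      for (a in seq_len(length(idx) - 1L)) {
        if (!keep[idx[a]]) next
        for (b in (a + 1L):length(idx)) {
          if (!keep[idx[b]]) next
          if (r2[a, b] >= r2_max) {
            drop <- if (runif(1) < 0.5) idx[a] else idx[b]
            keep[drop] <- FALSE
            if (drop == idx[a]) break
          }
        }
      }
    }
    which(keep)
  })
}

#' Per-individual proportion of heterozygous calls
#'
#' @param g a [GenotypeMatrix-class].
#' @return named numeric vector: fraction of non-missing calls equal to
#'   1 per individual.
#' @export
heterozygosity <- function(g) {
  calls <- genotypes(g)
  rowSums(calls == 1L, na.rm = TRUE) / rowSums(!is.na(calls))
}

#' Standardized multilocus heterozygosity (stMLH)
#'
#' An individual's heterozygous-call proportion divided by the mean,
#' over the loci at which that individual was typed, of the cohort
#' heterozygosity of those loci (fraction of non-missing individuals
#' heterozygous at the locus). Under complete typing the cohort mean of
#' stMLH is exactly 1.
#'
#' @param g a [GenotypeMatrix-class]; every individual needs at least
#'   one non-missing call.
#' @return named numeric vector of stMLH values.
#' @export
stMLH <- function(g) {
  calls <- genotypes(g)
  typed <- !is.na(calls)
  if (any(rowSums(typed) == 0))
    stop("individual with zero typed loci")
  locus_het <- colSums(calls == 1L, na.rm = TRUE) / colSums(typed)
  prop_het <- rowSums(calls == 1L, na.rm = TRUE) / rowSums(typed)
  denom <- (typed %*% locus_het) / rowSums(typed)
  setNames(as.vector(prop_het / denom), rownames(calls))
}

#' KING-robust pairwise kinship
#'
#' The between-family robust kinship estimator: for a dyad (i, j),
#' `phi = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa(i) + N_Aa(j))`, where
#' `N_Aa,Aa` counts sites at which both are heterozygous, `N_AA,aa`
#' counts opposite homozygotes, and the denominators count heterozygous
#' sites of each member over sites typed in both. Duplicate genotypes
#' give exactly 0.5 when no opposite homozygotes exist; unrelated pairs
#' center on 0 (and can go negative); parent-offspring pairs center on
#' 0.25.
#'
#' @param g a [GenotypeMatrix-class]; a warning is issued below 100
#'   polymorphic sites.
#' @return a [KinshipMatrix-class] (diagonal 0.5; dyads with no shared
#'   typed sites are `NA`).
#' @export
kingKinship <- function(g) {
  calls <- genotypes(g)
  poly <- apply(calls, 2, function(x) length(unique(x[!is.na(x)])) > 1L)
  if (sum(poly) < 100L)
    warning("fewer than 100 polymorphic sites; kinship estimates unstable")
  N <- (!is.na(calls)) * 1
  H <- (calls == 1L & !is.na(calls)) * 1
  A0 <- (calls == 0L & !is.na(calls)) * 1
  A2 <- (calls == 2L & !is.na(calls)) * 1
  hh <- tcrossprod(H)
  opp <- tcrossprod(A0, A2); opp <- opp + t(opp)
  hn <- tcrossprod(H, N)          # het in i over sites typed in both
  denom <- hn + t(hn)
  shared <- tcrossprod(N)
  phi <- (hh - 2 * opp) / denom
  phi[shared == 0] <- NA_real_
  phi[denom == 0 & shared > 0] <- NA_real_
  diag(phi) <- 0.5
  dimnames(phi) <- list(rownames(calls), rownames(calls))
  KinshipMatrix(phi)
}

#' KING-robust kinship for selected dyads
#'
#' Same estimator as [kingKinship()] but evaluated only for the listed
#' pairs, avoiding the full matrix for large simulated cohorts.
#'
#' @param g a [GenotypeMatrix-class].
#' @param i,j parallel vectors of row indices or ids defining dyads.
#' @return numeric vector of kinship estimates.
#' @export
kingKinshipPairs <- function(g, i, j) {
  calls <- genotypes(g)
  if (is.character(i)) i <- match(i, rownames(calls))
  if (is.character(j)) j <- match(j, rownames(calls))
  gi <- calls[i, , drop = FALSE]
  gj <- calls[j, , drop = FALSE]
  both <- !is.na(gi) & !is.na(gj)
  hi <- gi == 1L & both
  hj <- gj == 1L & both
  hh <- rowSums(hi & hj)
  opp <- rowSums(((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L)) & both)
  denom <- rowSums(hi) + rowSums(hj)
  out <- (hh - 2 * opp) / denom
  out[rowSums(both) == 0] <- NA_real_
  unname(out)
}

#' Transform kinship to coefficients of relatedness
#'
#' `r = 2 * phi` for positive kinship; non-positive kinship (pairs less
#' related than the typical pair) maps to `r = 0`, so a kinship range of
#' (-0.21, 0.24) maps to relatedness (0, 0.48).
#'
#' @param phi numeric vector/matrix of kinship values, or a
#'   [KinshipMatrix-class].
#' @return object of the same shape with relatedness values.
#' @export
kinshipToRelatedness <- function(phi) {
  if (is(phi, "KinshipMatrix")) phi <- kinship(phi)
  ifelse(!is.na(phi) & phi > 0, 2 * phi, ifelse(is.na(phi), NA_real_, 0))
}

#' Audit an LD-pruned site set
#'
#' Recomputes r-squared for every retained pair inside every window and
#' returns the maximum found; used to verify that pruning left no
#' violating pair.
#'
#' @inheritParams ldPrune
#' @param retained integer site indices returned by [ldPrune()].
#' @return maximum within-window r-squared among retained pairs.
#' @export
ldPruneAudit <- function(g, retained, window_sites = 50L, step_sites = 5L) {
  calls <- genotypes(g)
  m <- ncol(calls)
  worst <- 0
  for (s in seq(1L, max(1L, m - 1L), by = step_sites)) {
    win <- s:min(s + window_sites - 1L, m)
    idx <- intersect(win, retained)
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(cor(calls[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 0
    worst <- max(worst, max(r2))
  }
  worst
}
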