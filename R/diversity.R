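# Per-individual MHC heterozygosity indices and dyadic complementarity,
# the seven heterozygosity and four complementarity measures used for
# the genome-wide-versus-MHC comparison.

.classOfLocus <- function(locus) unname(MHC_CLASS[locus])

.meanPairDiff <- function(seqs) {
  # mean count of differing aligned residues over unordered pairs
  seqs <- unique(seqs)
  if (length(seqs) < 2L) return(NA_real_)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences in a grouping must share one aligned length")
  pairs <- combn(length(seqs), 2L)
  mean(apply(pairs, 2L, function(p) {
    a <- strsplit(seqs[[p[1]]], "")[[1]]
    b <- strsplit(seqs[[p[2]]], "")[[1]]
    sum(a != b)
  }))
}

#' Per-individual MHC heterozygosity indices
#'
#' The seven indices: distinct allele counts per class (class I = A+B,
#' class II = DQA+DRB), mean pairwise amino-acid differences between an
#' individual's alleles (class I combined; DQA and DRB separately, as
#' their segments derive from different receptor domains), and distinct
#' supertype counts per class. Individuals with fewer than two alleles
#' in a grouping get `NA` for that amino-acid index.
#'
#' @param calls allele-call data.frame (`individual`, `locus`,
#'   `allele`, `sequence`), e.g. from [callMhcGenotypes()] or a truth
#'   table joined to sequences.
#' @param supertype_sets named list of supertype maps (named integer
#'   vectors allele -> supertype, `NA` allowed) with elements `classI`,
#'   `DQA`, `DRB`, e.g. built from [assignSupertypes()] results.
#' @param proteins optional named character vector allele -> protein;
#'   computed by translation when absent.
#' @return data.frame, one row per individual: `n_alleles_classI`,
#'   `n_alleles_classII`, `mean_aa_diff_classI`, `mean_aa_diff_DQA`,
#'   `mean_aa_diff_DRB`, `n_supertypes_classI`, `n_supertypes_classII`.
#' @export
heterozygosityIndices <- function(calls, supertype_sets, proteins = NULL) {
  stopifnot(all(c("individual", "locus", "allele") %in% names(calls)))
  if (is.null(proteins)) {
    stopifnot("sequence" %in% names(calls))
    uq <- !duplicated(calls$allele)
    proteins <- character(0)
    for (loc in unique(calls$locus)) {
      sel <- uq & calls$locus == loc
      if (!any(sel)) next
      tr <- translateAlleles(setNames(calls$sequence[sel], calls$allele[sel]),
                             frame = MHC_FRAME[[loc]])
      proteins <- c(proteins, setNames(tr$protein, tr$allele))
    }
  }
  st_of <- function(alleles, which_set) {
    st <- supertype_sets[[which_set]][alleles]
    unique(st[!is.na(st)])
  }
  inds <- unique(calls$individual)
  out <- do.call(rbind, lapply(inds, function(ind) {
    cc <- calls[calls$individual == ind, , drop = FALSE]
    aI <- unique(cc$allele[.classOfLocus(cc$locus) == "I"])
    aII <- unique(cc$allele[.classOfLocus(cc$locus) == "II"])
    aDQA <- unique(cc$allele[cc$locus == "DQA"])
    aDRB <- unique(cc$allele[cc$locus == "DRB"])
    data.frame(
      individual = ind,
      n_alleles_classI = length(aI),
      n_alleles_classII = length(aII),
      mean_aa_diff_classI = .meanPairDiff(proteins[aI]),
      mean_aa_diff_DQA = .meanPairDiff(proteins[aDQA]),
      mean_aa_diff_DRB = .meanPairDiff(proteins[aDRB]),
      n_supertypes_classI = length(st_of(aI, "classI")),
      # DQA and DRB are clustered separately, so their supertype
      # universes are disjoint and class II counts add
      n_supertypes_classII = length(st_of(aDQA, "DQA")) +
        length(st_of(aDRB, "DRB")),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dyadic MHC complementarity
#'
#' For every unordered dyad: numbers of shared and total unique alleles
#' and supertypes per class (class I supertypes live in the combined
#' A+B universe; class II pools DQA and DRB supertypes, kept distinct
#' between loci).
#'
#' @inheritParams heterozygosityIndices
#' @return data.frame, one row per dyad: `id1`, `id2`,
#'   `shared_alleles_classI/II`, `total_alleles_classI/II`,
#'   `shared_supertypes_classI/II`, `total_supertypes_classI/II`.
#' @export
dyadComplementarity <- function(calls, supertype_sets) {
  inds <- unique(calls$individual)
  stopifnot(length(inds) >= 2L)
  sets <- lapply(inds, function(ind) {
    cc <- calls[calls$individual == ind, , drop = FALSE]
    aI <- unique(cc$allele[.classOfLocus(cc$locus) == "I"])
    aDQA <- unique(cc$allele[cc$locus == "DQA"])
    aDRB <- unique(cc$allele[cc$locus == "DRB"])
    stI <- supertype_sets$classI[aI]
    stQ <- supertype_sets$DQA[aDQA]
    stR <- supertype_sets$DRB[aDRB]
    tag <- function(prefix, v) {
      v <- v[!is.na(v)]
      if (!length(v)) character(0) else paste0(prefix, v)
    }
    list(aI = aI, aII = unique(c(aDQA, aDRB)),
         stI = unique(stI[!is.na(stI)]),
         stII = unique(c(tag("Q", stQ), tag("R", stR))))
  })
  names(sets) <- inds
  pairs <- combn(length(inds), 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    x <- sets[[pairs[1, k]]]; y <- sets[[pairs[2, k]]]
    sh <- function(a, b) length(intersect(a, b))
    tu <- function(a, b) length(union(a, b))
    data.frame(id1 = inds[pairs[1, k]], id2 = inds[pairs[2, k]],
               shared_alleles_classI = sh(x$aI, y$aI),
               total_alleles_classI = tu(x$aI, y$aI),
               shared_alleles_classII = sh(x$aII, y$aII),
               total_alleles_classII = tu(x$aII, y$aII),
               shared_supertypes_classI = sh(x$stI, y$stI),
               total_supertypes_classI = tu(x$stI, y$stI),
               shared_supertypes_classII = sh(x$stII, y$stII),
               total_supertypes_classII = tu(x$stII, y$stII),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
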