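#' GenotypeMatrix: biallelic SNP genotypes for a cohort
#'
#' Holds an individuals-by-sites matrix of alternate-allele counts
#' (0, 1, 2, or `NA` for missing) together with site metadata.
#'
#' @slot calls integer matrix, individuals in rows (rownames are ids),
#'   sites in columns; entries in `{0,1,2,NA}`.
#' @slot sites data.frame with one row per site; at least columns
#'   `chrom` and `pos`.
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", sites = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  g <- object@calls
  if (is.null(rownames(g))) msg <- c(msg, "calls must have individual ids as rownames")
  bad <- !(g %in% c(0L, 1L, 2L, NA))
  if (any(bad)) msg <- c(msg, "genotype calls must be 0, 1, 2 or NA")
  if (nrow(object@sites) != ncol(g))
    msg <- c(msg, "sites must have one row per genotype column")
  if (!all(c("chrom", "pos") %in% names(object@sites)))
    msg <- c(msg, "sites needs 'chrom' and 'pos' columns")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls numeric/integer matrix of 0/1/2 alternate-allele counts
#'   (`NA` = missing) with individual ids as rownames.
#' @param sites optional data.frame of site records (`chrom`, `pos`);
#'   synthesised as a single synthetic chromosome when omitted.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 2, 1), 2, 2,
#'   dimnames = list(c("i1", "i2"), NULL)))
#' nSites(g)
#' @export
GenotypeMatrix <- function(calls, sites = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(sites))
    sites <- data.frame(chrom = "chrSim", pos = seq_len(ncol(calls)))
  new("GenotypeMatrix", calls = calls, sites = sites)
}

#' KinshipMatrix: symmetric pairwise kinship estimates
#'
#' @slot phi symmetric numeric matrix of kinship coefficients; the
#'   KING-robust estimator can produce negative values for pairs less
#'   related than the typical pair.
#' @export
setClass("KinshipMatrix", representation(phi = "matrix"))

setValidity("KinshipMatrix", function(object) {
  p <- object@phi
  if (nrow(p) != ncol(p)) return("kinship matrix must be square")
  if (!isTRUE(all.equal(p, t(p), tolerance = 1e-8, check.attributes = FALSE)))
    return("kinship matrix must be symmetric")
  TRUE
})

#' Construct a KinshipMatrix
#' @param phi square symmetric numeric matrix of kinship coefficients.
#' @return A [KinshipMatrix-class] object.
#' @export
KinshipMatrix <- function(phi) {
  phi <- as.matrix(phi)
  if (is.null(rownames(phi))) {
    rownames(phi) <- colnames(phi) <- paste0("ind", seq_len(nrow(phi)))
  }
  new("KinshipMatrix", phi = phi)
}

#' AmpliconPool: collapsed amplicon reads for one individual at one locus
#'
#' Unique sequences with their copy numbers, after collapsing identical
#' reads. This is the unit the artifact filters operate on.
#'
#' @slot individual character id.
#' @slot locus one of `"A"`, `"B"`, `"DQA"`, `"DRB"`.
#' @slot sequences character vector of distinct DNA sequences.
#' @slot copies integer vector of read counts, parallel to `sequences`.
#' @export
setClass("AmpliconPool",
  representation(individual = "character", locus = "character",
                 sequences = "character", copies = "integer"))

setValidity("AmpliconPool", function(object) {
  msg <- character()
  if (!object@locus %in% MHC_LOCI)
    msg <- c(msg, "locus must be one of A, B, DQA, DRB")
  if (length(object@sequences) != length(object@copies))
    msg <- c(msg, "sequences and copies must be parallel")
  if (anyDuplicated(object@sequences))
    msg <- c(msg, "sequences must be unique (reads are collapsed)")
  if (length(object@copies) && any(object@copies < 1L))
    msg <- c(msg, "copies must be >= 1")
  if (length(object@sequences) && any(!nzchar(object@sequences)))
    msg <- c(msg, "sequences must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct an AmpliconPool
#' @param individual individual id.
#' @param locus MHC locus label (`A`, `B`, `DQA`, `DRB`).
#' @param sequences character vector of distinct sequences.
#' @param copies integer copy numbers parallel to `sequences`.
#' @return An [AmpliconPool-class] object.
#' @export
AmpliconPool <- function(individual, locus, sequences, copies) {
  new("AmpliconPool", individual = as.character(individual),
      locus = as.character(locus), sequences = as.character(sequences),
      copies = as.integer(copies))
}

#' SupertypeAssignment: allele-to-supertype mapping with its dendrogram
#'
#' @slot assignment data.frame with columns `allele` and `supertype`
#'   (integer label, `NA` for unassigned singletons).
#' @slot tree the average-linkage clustering record (hclust-compatible).
#' @slot pss integer vector of 1-based alignment columns used.
#' @slot metadata list of notes about how the assignment was produced.
#' @export
setClass("SupertypeAssignment",
  representation(assignment = "data.frame", tree = "ANY",
                 pss = "integer", metadata = "list"))

setValidity("SupertypeAssignment", function(object) {
  a <- object@assignment
  if (!all(c("allele", "supertype") %in% names(a)))
    return("assignment needs 'allele' and 'supertype' columns")
  TRUE
})

#' FitResult: a fitted model from the statistical layer
#'
#' @slot coefficients data.frame with columns `term`, `estimate`, `se`,
#'   `z`, `p`.
#' @slot vcov variance-covariance matrix of the coefficient estimates
#'   (robust sandwich for the bounded-influence fits).
#' @slot varcomp named numeric; `genetic` and `residual` variance
#'   components for mixed models, empty otherwise.
#' @slot logLik numeric log-likelihood (or robust objective proxy).
#' @slot converged logical.
#' @slot method character label of the fitting routine.
#' @export
setClass("FitResult",
  representation(coefficients = "data.frame", vcov = "matrix",
                 varcomp = "numeric", logLik = "numeric",
                 converged = "logical", method = "character"))

setValidity("FitResult", function(object) {
  cf <- object@coefficients
  need <- c("term", "estimate", "se", "z", "p")
  if (!all(need %in% names(cf)))
    return("coefficients needs term/estimate/se/z/p columns")
  ok <- is.finite(cf$p)
  if (any(cf$p[ok] < 0 | cf$p[ok] > 1)) return("p-values must lie in [0,1]")
  TRUE
})
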