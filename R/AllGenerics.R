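#' Accessors for mhcdiv classes
#'
#' @param x an mhcdiv object.
#' @name accessors
NULL

#' @rdname accessors
#' @return `genotypes()` returns the integer calls matrix.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @return `siteInfo()` returns the site metadata data.frame.
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname accessors
#' @return `individuals()` returns the individual ids.
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname accessors
#' @return `nSites()` returns the number of sites.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @return `kinship()` returns the symmetric kinship matrix.
#' @export
setGeneric("kinship", function(x) standardGeneric("kinship"))

#' @rdname accessors
#' @return `supertypes()` returns a named integer vector of supertype
#'   labels (`NA` = unassigned).
#' @export
setGeneric("supertypes", function(x) standardGeneric("supertypes"))

#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("siteInfo", "GenotypeMatrix", function(x) x@sites)

#' @rdname accessors
#' @export
setMethod("individuals", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname accessors
#' @export
setMethod("nSites", "GenotypeMatrix", function(x) ncol(x@calls))

#' @rdname accessors
#' @export
setMethod("kinship", "KinshipMatrix", function(x) x@phi)

#' @rdname accessors
#' @export
setMethod("individuals", "KinshipMatrix", function(x) rownames(x@phi))

#' @rdname accessors
#' @export
setMethod("supertypes", "SupertypeAssignment", function(x)
  setNames(x@assignment$supertype, x@assignment$allele))

#' @describeIn accessors coefficient table of a fit.
#' @param object a [FitResult-class].
#' @param ... unused.
#' @export
setMethod("coef", "FitResult", function(object, ...) {
  setNames(object@coefficients$estimate, object@coefficients$term)
})

#' @describeIn accessors coefficient covariance matrix of a fit.
#' @export
setMethod("vcov", "FitResult", function(object, ...) object@vcov)

#' Coefficient table of a fit
#' @param x a [FitResult-class].
#' @return data.frame with term, estimate, se, z, p.
#' @export
fitTable <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@coefficients
}

#' Variance components of a mixed-model fit
#' @param x a [FitResult-class].
#' @return named numeric vector (`genetic`, `residual`) or empty.
#' @export
varComp <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@varcomp
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "individuals x",
      ncol(object@calls), "sites;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(object@calls))))
})

setMethod("show", "KinshipMatrix", function(object) {
  p <- object@phi[upper.tri(object@phi)]
  cat("KinshipMatrix:", nrow(object@phi), "individuals;",
      sprintf("dyadic phi in [%.3f, %.3f]\n",
              suppressWarnings(min(p, na.rm = TRUE)),
              suppressWarnings(max(p, na.rm = TRUE))))
})

setMethod("show", "AmpliconPool", function(object) {
  cat(sprintf("AmpliconPool %s/%s: %d unique sequences, %d reads\n",
              object@individual, object@locus, length(object@sequences),
              sum(object@copies)))
})

setMethod("show", "SupertypeAssignment", function(object) {
  st <- object@assignment$supertype
  cat("SupertypeAssignment:", nrow(object@assignment), "alleles,",
      length(unique(st[!is.na(st)])), "supertypes,",
      sum(is.na(st)), "unassigned;",
      length(object@pss), "sites used\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@method, ")",
      if (!object@converged) " [NOT CONVERGED]", "\n", sep = "")
  print(object@coefficients, digits = 4, row.names = FALSE)
  if (length(object@varcomp))
    cat("variance components:",
        paste(names(object@varcomp),
              sprintf("%.4g", object@varcomp), collapse = ", "), "\n")
})
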