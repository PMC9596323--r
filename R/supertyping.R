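# MHC supertyping: translation, positively-selected-site screening,
# z-descriptor matrices, deterministic average-linkage clustering and a
# minimum-size branch cut.

#' Translate nucleotide alleles to protein
#'
#' Standard-code translation after discarding `frame` leading bases;
#' a trailing partial codon is dropped. Alleles with an internal stop
#' codon are flagged (they are excluded from alignments downstream,
#' with a warning).
#'
#' @param dna named character vector (or `DNAStringSet`) of allele
#'   sequences.
#' @param frame reading-frame offset, 0, 1 or 2.
#' @return data.frame: `allele`, `protein`, `internal_stop`.
#' @export
translateAlleles <- function(dna, frame = 0L) {
  stopifnot(frame %in% 0:2)
  if (is(dna, "DNAStringSet")) dna <- setNames(as.character(dna), names(dna))
  if (is.null(names(dna))) names(dna) <- paste0("allele", seq_along(dna))
  if (any(nchar(dna) - frame < 3L)) stop("sequences too short to translate")
  trimmed <- substr(dna, frame + 1L, nchar(dna))
  trimmed <- substr(trimmed, 1L, (nchar(trimmed) %/% 3L) * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(trimmed)))
  data.frame(allele = names(dna), protein = unname(aa),
             internal_stop = grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)),
             stringsAsFactors = FALSE)
}

# ---- dN/dS counting machinery (Nei-Gojobori style, per codon) --------

.codonSynFrac <- local({
  cache <- new.env()
  function(codon) {
    if (!is.null(cache[[codon]])) return(cache[[codon]])
    gc <- Biostrings::GENETIC_CODE
    aa <- gc[[codon]]
    s <- 0
    nt <- c("A", "C", "G", "T")
    for (p in 1:3) {
      for (b in setdiff(nt, substr(codon, p, p))) {
        mut <- codon
        substr(mut, p, p) <- b
        if (gc[[mut]] == aa) s <- s + 1 / 3
      }
    }
    cache[[codon]] <- s   # synonymous sites (0..3)
    s
  }
})

# syn / nonsyn difference counts between two codons, averaged over all
# minimal mutational pathways that avoid stop codons where possible
.codonPairDiff <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  acc <- c(syn = 0, nonsyn = 0); npath <- 0L
  for (ord in perms(pos)) {
    cur <- c1; d <- c(syn = 0, nonsyn = 0); ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*" && gc[[c1]] != "*" && gc[[c2]] != "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) d["syn"] <- d["syn"] + 1 else
        d["nonsyn"] <- d["nonsyn"] + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + d; npath <- npath + 1L }
  }
  if (npath == 0L) {  # all paths hit stops; count ignoring stop rule
    for (ord in perms(pos)) {
      cur <- c1; d <- c(syn = 0, nonsyn = 0)
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == gc[[cur]]) d["syn"] <- d["syn"] + 1 else
          d["nonsyn"] <- d["nonsyn"] + 1
        cur <- nxt
      }
      acc <- acc + d; npath <- npath + 1L
    }
  }
  acc / npath
}

#' Screen codon columns for positive selection (counting test)
#'
#' A deliberately simple per-column screen for sites under positive
#' selection: across all unordered allele pairs, synonymous and
#' nonsynonymous differences at each codon column are counted
#' (Nei-Gojobori pathway averaging), and the column's nonsynonymous
#' excess is assessed with a one-sided binomial test against the
#' column's mutational opportunity (its mean fraction of nonsynonymous
#' sites). Columns significant after Benjamini-Hochberg correction at
#' `fdr` are reported. This is a screening convenience; externally
#' derived site lists (e.g. from codon-model Bayes empirical Bayes
#' analyses) can be supplied to downstream steps instead and take
#' precedence when available.
#'
#' @param dna character vector of equal-length, in-frame nucleotide
#'   alleles (at least 3).
#' @param frame reading-frame offset applied before codon splitting.
#' @param fdr false discovery rate for the BH cutoff.
#' @return list of class `PSSResult`: `positions` (sorted 1-based codon
#'   columns), `p` (per-column adjusted p-values), `source =
#'   "builtin_counting"`.
#' @export
builtinPss <- function(dna, frame = 0L, fdr = 0.05) {
  stopifnot(length(dna) >= 3L)
  if (length(unique(nchar(dna))) != 1L) stop("alleles must share one length")
  body <- substr(dna, frame + 1L, nchar(dna))
  nc <- nchar(body[[1]]) %/% 3L
  codons <- matrix("", length(dna), nc)
  for (k in seq_len(nc))
    codons[, k] <- substr(body, (k - 1L) * 3L + 1L, k * 3L)
  pvals <- rep(NA_real_, nc)
  for (k in seq_len(nc)) {
    uq <- unique(codons[, k])
    if (length(uq) == 1L) next
    cnt <- table(factor(codons[, k], levels = uq))
    syn <- 0; nonsyn <- 0
    for (a in seq_along(uq)) {
      for (b in seq_len(a - 1L)) {
        d <- .codonPairDiff(uq[[a]], uq[[b]])
        npair <- cnt[[a]] * cnt[[b]]
        syn <- syn + d[["syn"]] * npair
        nonsyn <- nonsyn + d[["nonsyn"]] * npair
      }
    }
    tot <- syn + nonsyn
    if (tot == 0) next
    syn_sites <- mean(vapply(codons[, k], .codonSynFrac, numeric(1)))
    p_nonsyn <- (3 - syn_sites) / 3
    x <- round(nonsyn); n <- round(tot)
    pvals[k] <- pbinom(x - 1L, n, p_nonsyn, lower.tail = FALSE)
  }
  tested <- which(!is.na(pvals))
  adj <- rep(NA_real_, nc)
  adj[tested] <- p.adjust(pvals[tested], "BH")
  structure(list(positions = sort(tested[adj[tested] <= fdr]),
                 p = adj, source = "builtin_counting"),
            class = "PSSResult")
}

#' Wrap an externally supplied PSS list
#'
#' @param positions 1-based alignment (codon) columns from an external
#'   site-model analysis.
#' @param alignment_length optional length used to validate positions.
#' @return list of class `PSSResult` with `source = "external_list"`.
#' @export
externalPss <- function(positions, alignment_length = NULL) {
  positions <- sort(unique(as.integer(positions)))
  stopifnot(all(positions >= 1L))
  if (!is.null(alignment_length) && any(positions > alignment_length))
    stop("PSS positions exceed alignment length")
  structure(list(positions = positions, p = NULL, source = "external_list"),
            class = "PSSResult")
}

#' The five z-descriptor physiochemical scales
#'
#' Published five-dimensional descriptors per amino acid: z1
#' (hydrophobicity), z2 (steric bulk), z3 (polarity), z4 and z5
#' (electronic effects), shipped as a data file.
#'
#' @return 20 x 5 numeric matrix, rownames are one-letter residue codes.
#' @export
zDescriptorTable <- function() {
  f <- system.file("extdata", "zdescriptors.csv", package = "mhcdiv",
                   mustWork = TRUE)
  tab <- read.csv(f, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, c("z1", "z2", "z3", "z4", "z5")])
  rownames(m) <- tab$aa
  m
}

#' Build the allele-by-descriptor matrix over selected sites
#'
#' One row per allele; for each selected alignment column, the five
#' z-descriptors of the residue there, columns ordered site-major
#' (site1 z1..z5, site2 z1..z5, ...). Permuting the site order permutes
#' column blocks without changing any pairwise Euclidean distance.
#'
#' @param proteins named character vector of equal-length amino-acid
#'   sequences (one per allele).
#' @param pss a `PSSResult` or integer vector of 1-based columns
#'   (non-empty).
#' @param table descriptor matrix from [zDescriptorTable()].
#' @return numeric matrix, `length(proteins)` x `5 * length(pss)`.
#' @export
zMatrix <- function(proteins, pss, table = zDescriptorTable()) {
  if (inherits(pss, "PSSResult")) pss <- pss$positions
  pss <- as.integer(pss)
  if (!length(pss)) stop("PSS set is empty")
  if (length(unique(nchar(proteins))) != 1L)
    stop("protein sequences must share one length")
  if (any(pss < 1L | pss > nchar(proteins[[1]])))
    stop("PSS positions outside alignment")
  if (is.null(names(proteins))) names(proteins) <- paste0("allele", seq_along(proteins))
  out <- matrix(NA_real_, length(proteins), 5L * length(pss),
                dimnames = list(names(proteins),
                                paste0("site", rep(pss, each = 5L), "_z",
                                       rep(1:5, length(pss)))))
  for (s in seq_along(pss)) {
    res <- substr(proteins, pss[[s]], pss[[s]])
    bad <- !res %in% rownames(table)
    if (any(bad)) stop("residue(s) without descriptors at column ", pss[[s]],
                       ": ", paste(unique(res[bad]), collapse = ", "))
    out[, (s - 1L) * 5L + 1:5] <- table[res, , drop = FALSE]
  }
  out
}

#' Deterministic average-linkage agglomeration
#'
#' Average-linkage (UPGMA) hierarchical clustering on Euclidean
#' distances with an explicit tie rule: among candidate merges at equal
#' distance, the pair whose member labels sort lexicographically
#' smallest is merged, so the dendrogram is independent of input order.
#'
#' @param m numeric matrix (rows = items) or a `dist` object.
#' @return an object of class `hclust` (merge, height, order, labels).
#' @export
averageLinkage <- function(m) {
  d <- if (inherits(m, "dist")) as.matrix(m) else
    as.matrix(dist(m, method = "euclidean"))
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  stopifnot(n >= 2)
  active <- seq_len(n)
  size <- rep(1L, n)
  node <- -seq_len(n)                 # hclust convention: leaves negative
  key <- labels                        # lexicographic tie-break key
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  ord_children <- vector("list", n - 1L)
  D <- d
  diag(D) <- Inf
  leaves <- lapply(seq_len(n), identity)
  for (step in seq_len(n - 1L)) {
    idx <- which(active > 0L)
    sub <- D[idx, idx, drop = FALSE]
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ck <- apply(cand, 1, function(rc) {
      ks <- sort(c(key[idx[rc[1]]], key[idx[rc[2]]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(ck)[1], ]
    i <- idx[pick[[1]]]; j <- idx[pick[[2]]]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- h
    ord_children[[step]] <- c(leaves[[i]], leaves[[j]])
    # Lance-Williams average-linkage update into slot i
    ni <- size[i]; nj <- size[j]
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- newd; D[, i] <- newd
    D[i, i] <- Inf; D[j, ] <- Inf; D[, j] <- Inf
    size[i] <- ni + nj
    node[i] <- step
    key[i] <- min(key[i], key[j])
    leaves[[i]] <- ord_children[[step]]
    active[j] <- 0L
  }
  structure(list(merge = merge, height = height,
                 order = leaves[[which(active > 0L)]],
                 labels = labels, method = "average",
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a dendrogram into supertypes with a minimum cluster size
#'
#' Adaptive branch cut: the sorted merge heights are scanned for their
#' largest gap; when that gap exceeds `min_gap_frac` of the tree height
#' the dendrogram is cut inside it (never above `cut_frac` of the
#' maximum height), so well-separated branches become clusters whatever
#' their number. Without a material gap -- and for all-identical rows --
#' a single cluster is returned. Branches smaller than
#' `min_cluster_size` are left unassigned (`NA`) rather than forced
#' into a cluster. Labels are renumbered in order of first appearance.
#' A global cut resolves the coarsest separation scale; nested
#' structure at finer scales is not chased.
#'
#' @param hc an `hclust` object (e.g. from [averageLinkage()]).
#' @param min_cluster_size smallest branch reported as a supertype.
#' @param min_gap_frac smallest height gap (as a fraction of the tree
#'   height) treated as a real cluster separation; smaller values split
#'   more aggressively.
#' @param cut_frac ceiling on the cut height, as a fraction of the
#'   maximum merge height.
#' @return integer vector of supertype labels named by item, `NA` for
#'   unassigned singleton-like branches.
#' @export
cutSupertypeTree <- function(hc, min_cluster_size = 2L, min_gap_frac = 0.2,
                             cut_frac = 0.99) {
  stopifnot(inherits(hc, "hclust"), min_cluster_size >= 1L,
            min_gap_frac > 0, min_gap_frac < 1,
            cut_frac > 0, cut_frac <= 1)
  n <- length(hc$labels)
  hmax <- max(hc$height)
  hs <- sort(unique(hc$height))
  cl <- if (hmax == 0 || length(hs) < 2L) {
    rep(1L, n)
  } else {
    gaps <- diff(hs)
    best <- which.max(gaps)
    if (gaps[best] < min_gap_frac * hmax) {
      rep(1L, n)
    } else {
      h0 <- min((hs[best] + hs[best + 1L]) / 2, cut_frac * hmax)
      cutree(hc, h = h0)
    }
  }
  names(cl) <- hc$labels
  tab <- table(cl)
  small <- as.integer(names(tab)[tab < min_cluster_size])
  cl[cl %in% small] <- NA_integer_
  ok <- !is.na(cl)
  cl[ok] <- as.integer(factor(cl[ok], levels = unique(cl[ok])))
  cl
}

#' Assign MHC alleles to supertypes
#'
#' Full supertyping pass for one grouping (combined class I A+B, DQA,
#' or DRB): translate, pick sites (an external PSS list when given,
#' otherwise the builtin counting screen; if neither yields sites, all
#' variable columns are used and flagged), build the z-descriptor
#' matrix, cluster with deterministic average linkage and cut with the
#' minimum-size rule.
#'
#' @param dna named character vector of nucleotide alleles (equal
#'   length; the grouping's amplicons are equal length and gap-free, so
#'   alignment reduces to column stacking).
#' @param frame reading-frame offset.
#' @param pss optional external PSS (integer positions or
#'   [externalPss()] result).
#' @param min_cluster_size,min_gap_frac,cut_frac see
#'   [cutSupertypeTree()].
#' @param fdr FDR for the builtin screen.
#' @return a [SupertypeAssignment-class].
#' @export
assignSupertypes <- function(dna, frame = 0L, pss = NULL,
                             min_cluster_size = 2L, min_gap_frac = 0.2,
                             cut_frac = 0.99, fdr = 0.05) {
  if (is(dna, "DNAStringSet")) dna <- setNames(as.character(dna), names(dna))
  tr <- translateAlleles(dna, frame)
  if (any(tr$internal_stop)) {
    warning("excluding ", sum(tr$internal_stop),
            " allele(s) with internal stop codons")
    tr <- tr[!tr$internal_stop, , drop = FALSE]
  }
  if (nrow(tr) < 2L) stop("need at least 2 translatable alleles")
  proteins <- setNames(tr$protein, tr$allele)
  meta <- list(
    note = paste("PSS from the builtin pairwise counting screen are a",
                 "declared simplification of codon-model site inference;",
                 "supply an external site list for the faithful route."))
  if (!is.null(pss)) {
    pssr <- if (inherits(pss, "PSSResult")) pss else
      externalPss(pss, nchar(proteins[[1]]))
  } else {
    pssr <- builtinPss(dna[tr$allele], frame = frame, fdr = fdr)
  }
  positions <- pssr$positions
  if (!length(positions)) {
    cols <- seq_len(nchar(proteins[[1]]))
    varying <- cols[vapply(cols, function(k)
      length(unique(substr(proteins, k, k))) > 1L, logical(1))]
    if (!length(varying)) {
      assignment <- data.frame(allele = names(proteins), supertype = 1L)
      return(new("SupertypeAssignment", assignment = assignment, tree = NULL,
                 pss = integer(0),
                 metadata = c(meta, list(fallback = "monomorphic alignment"))))
    }
    positions <- varying
    meta$fallback <- "no significant PSS; all variable columns used"
  }
  zm <- zMatrix(proteins, positions)
  hc <- averageLinkage(zm)
  cl <- cutSupertypeTree(hc, min_cluster_size, min_gap_frac, cut_frac)
  new("SupertypeAssignment",
      assignment = data.frame(allele = names(cl), supertype = unname(cl),
                              stringsAsFactors = FALSE),
      tree = hc, pss = as.integer(positions),
      metadata = c(meta, list(pss_source = pssr$source,
                              min_gap_frac = min_gap_frac,
                              cut_frac = cut_frac,
                              min_cluster_size = min_cluster_size)))
}
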