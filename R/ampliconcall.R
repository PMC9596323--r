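# MHC allele calling from amplicon read pools: locus assignment and
# length filtering, rare k-mer artifact removal, read-fraction thresholds
# with cross-individual rescue, and known/new classification against a
# reference catalog.

#' Filter configuration for the amplicon allele caller
#'
#' Defaults follow the published filter chain: a 15 bp scanning window,
#' removal of sequences with 12 consecutive k-mers below 15% of the
#' median k-mer coverage, a 5% minimum read fraction per individual and
#' locus, and rescue of sequences above 1000 copies that exceed 5% of
#' reads in another individual.
#'
#' @param kmer_window scanning window width in bp.
#' @param consecutive_low number of consecutive low-coverage window
#'   positions that condemns a sequence.
#' @param coverage_frac low-coverage cutoff as a fraction of the median
#'   k-mer coverage of the pool.
#' @param min_read_frac minimum fraction of the individual's filtered
#'   reads at the locus (kept when `>=`, a literal "at minimum").
#' @param rescue_min_copies rescue requires strictly more copies than
#'   this.
#' @param rescue_other_frac rescue requires a read fraction strictly
#'   above this in at least one other individual.
#' @param target_length named integer amplicon length per locus.
#' @return list of class `FilterConfig`.
#' @export
filterConfig <- function(kmer_window = 15L, consecutive_low = 12L,
                         coverage_frac = 0.15, min_read_frac = 0.05,
                         rescue_min_copies = 1000L, rescue_other_frac = 0.05,
                         target_length = MHC_TARGET_LENGTH) {
  stopifnot(kmer_window >= 1, consecutive_low >= 1,
            coverage_frac > 0, coverage_frac < 1,
            min_read_frac > 0, min_read_frac < 1,
            rescue_other_frac > 0, rescue_other_frac < 1)
  structure(list(kmer_window = as.integer(kmer_window),
                 consecutive_low = as.integer(consecutive_low),
                 coverage_frac = coverage_frac,
                 min_read_frac = min_read_frac,
                 rescue_min_copies = as.integer(rescue_min_copies),
                 rescue_other_frac = rescue_other_frac,
                 target_length = target_length),
            class = "FilterConfig")
}

#' Collapse raw reads into an AmpliconPool
#'
#' @param reads character vector of reads (one entry per read).
#' @param individual,locus pool labels.
#' @return An [AmpliconPool-class] with identical reads collapsed.
#' @export
collapseReads <- function(reads, individual, locus) {
  if (!length(reads)) stop("no reads to collapse")
  tab <- table(reads)
  AmpliconPool(individual, locus, names(tab), as.integer(tab))
}

.dnaToInt <- local({
  conv <- integer(256)
  conv[utf8ToInt("A")] <- 0L; conv[utf8ToInt("C")] <- 1L
  conv[utf8ToInt("G")] <- 2L; conv[utf8ToInt("T")] <- 3L
  conv[utf8ToInt("a")] <- 0L; conv[utf8ToInt("c")] <- 1L
  conv[utf8ToInt("g")] <- 2L; conv[utf8ToInt("t")] <- 3L
  function(seqs) {
    # rows = sequences (equal length), entries in 0..3
    t(vapply(seqs, function(s) conv[utf8ToInt(s)],
             integer(nchar(seqs[[1]])), USE.NAMES = FALSE))
  }
})

# Hamming distances between equal-length reads and catalog sequences
.hammingToCatalog <- function(reads, refs) {
  rm <- .dnaToInt(reads)
  out <- matrix(0L, length(reads), length(refs))
  for (j in seq_along(refs)) {
    cj <- .dnaToInt(refs[j])[1, ]
    out[, j] <- as.integer(rowSums(rm != matrix(cj, nrow(rm), length(cj),
                                                byrow = TRUE)))
  }
  out
}

#' Assign reads to loci and filter for amplicon target length
#'
#' Each read is assigned to the locus of its highest-identity catalog
#' sequence (Hamming identity over equal-length sequences). Reads whose
#' length matches no locus target length are discarded, as are reads
#' equidistant from catalog sequences of different loci. Surviving reads
#' are collapsed per locus.
#'
#' @param reads character vector of merged reads for one individual.
#' @param catalog reference catalog data.frame (`name`, `locus`,
#'   `sequence`), e.g. from [readCatalogFasta()].
#' @param cfg a [filterConfig()].
#' @param individual id attached to the returned pools.
#' @return named list of [AmpliconPool-class], one per locus with
#'   surviving reads (empty loci are omitted, with a warning if nothing
#'   survives at all).
#' @export
assignAndLengthFilter <- function(reads, catalog, cfg = filterConfig(),
                                  individual = "ind") {
  stopifnot(nrow(catalog) > 0)
  pools <- list()
  lens <- nchar(reads)
  for (L in unique(nchar(catalog$sequence))) {
    sel <- lens == L
    if (!any(sel)) next
    refs <- catalog[nchar(catalog$sequence) == L, ]
    tab <- table(reads[sel])
    uq <- names(tab)
    hd <- .hammingToCatalog(uq, refs$sequence)
    best <- hd == apply(hd, 1, min)
    locus_of <- apply(best, 1, function(b) {
      loc <- unique(refs$locus[b])
      if (length(loc) == 1L) loc else NA_character_
    })
    for (loc in unique(stats::na.omit(locus_of))) {
      # target length check: read length must equal this locus's target
      if (L != cfg$target_length[[loc]]) next
      pick <- !is.na(locus_of) & locus_of == loc
      pools[[loc]] <- AmpliconPool(individual, loc, uq[pick],
                                   as.integer(tab[pick]))
    }
  }
  if (!length(pools)) warning("no reads survived locus/length assignment for ",
                              individual)
  pools
}

.kmerCodes <- function(M, w) {
  # M: integer matrix (rows = sequences, values 0..3); returns rows x
  # (L-w+1) matrix of base-4 k-mer codes (exact doubles for w <= 15)
  L <- ncol(M)
  np <- L - w + 1L
  K <- matrix(0, nrow(M), np)
  for (t in 0:(w - 1L))
    K <- K + M[, (1L + t):(np + t), drop = FALSE] * 4^t
  K
}

#' Rare k-mer artifact filter
#'
#' Computes, for every distinct k-mer of the pool, its coverage: the
#' copy-weighted number of window positions at which it occurs across the
#' pool's unique sequences. A unique sequence is removed when it contains
#' at least `consecutive_low` consecutive window positions whose k-mer
#' coverage falls below `coverage_frac` times the median coverage over
#' the pool's distinct k-mers. Chimeras and error-ridden reads carry runs
#' of rare junction k-mers and are the intended casualties; a pool with a
#' single unique sequence is always kept.
#'
#' @param pool an [AmpliconPool-class] (sequences of equal length at
#'   least `kmer_window` long).
#' @param cfg a [filterConfig()].
#' @return the filtered [AmpliconPool-class].
#' @export
kmerFilter <- function(pool, cfg = filterConfig()) {
  stopifnot(is(pool, "AmpliconPool"))
  n <- length(pool@sequences)
  if (n <= 1L) return(pool)
  if (any(nchar(pool@sequences) < cfg$kmer_window))
    stop("all sequences must be at least kmer_window long")
  if (length(unique(nchar(pool@sequences))) != 1L)
    stop("kmerFilter expects equal-length sequences (length-filter first)")
  K <- .kmerCodes(.dnaToInt(pool@sequences), cfg$kmer_window)
  np <- ncol(K)
  kv <- as.vector(K)
  u <- unique(kv)
  idx <- match(kv, u)
  cov_u <- as.vector(rowsum(rep(as.numeric(pool@copies), times = np),
                            idx, reorder = TRUE))
  thr <- cfg$coverage_frac * median(cov_u)
  covM <- matrix(cov_u[idx], n, np)
  low <- covM < thr
  run <- integer(n); worst <- integer(n)
  for (j in seq_len(np)) {
    run <- ifelse(low[, j], run + 1L, 0L)
    worst <- pmax(worst, run)
  }
  keep <- worst < cfg$consecutive_low
  AmpliconPool(pool@individual, pool@locus,
               pool@sequences[keep], pool@copies[keep])
}

#' Read-fraction threshold with cross-individual rescue
#'
#' Per individual, keeps sequences comprising at least `min_read_frac` of
#' that individual's filtered reads at the locus. Additionally rescues
#' sequences with strictly more than `rescue_min_copies` copies that
#' exceed `rescue_other_frac` of the read total in at least one *other*
#' individual. The two criteria are parallel; their union is retained.
#'
#' @param pools list of k-mer-filtered [AmpliconPool-class] objects for
#'   one locus, one per individual.
#' @param cfg a [filterConfig()].
#' @return data.frame of retained calls: `individual`, `locus`,
#'   `sequence`, `copies`, `fraction`, `status` (`"kept"`/`"rescued"`).
#' @export
thresholdAndRescue <- function(pools, cfg = filterConfig()) {
  stopifnot(length(pools) > 0)
  locus <- unique(vapply(pools, function(p) p@locus, character(1)))
  if (length(locus) != 1L) stop("pools must all be from one locus")
  df <- do.call(rbind, lapply(pools, function(p) {
    tot <- sum(p@copies)
    data.frame(individual = p@individual, locus = p@locus,
               sequence = p@sequences, copies = p@copies,
               fraction = p@copies / tot, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  kept <- df$fraction >= cfg$min_read_frac
  rescued <- rep(FALSE, nrow(df))
  cand <- which(!kept & df$copies > cfg$rescue_min_copies)
  for (i in cand) {
    other <- df$sequence == df$sequence[i] & df$individual != df$individual[i]
    rescued[i] <- any(df$fraction[other] > cfg$rescue_other_frac)
  }
  out <- df[kept | rescued, , drop = FALSE]
  out$status <- ifelse(kept[kept | rescued], "kept", "rescued")
  rownames(out) <- NULL
  out
}

#' Classify retained calls as previously described or new
#'
#' A call is `known` when its sequence matches a catalog sequence of the
#' same locus exactly (100% identity, 0 gaps); anything else is `new`.
#' New sequences receive deterministic provisional names
#' `{locus}-new-{i}`, indexed by lexicographic sequence order within the
#' locus across the whole cohort, so reruns and permuted individual
#' orders name them identically. Calls retained by the rescue rule keep
#' status `"rescued"`; `matched_name` is set only for `known` calls.
#'
#' @param calls data.frame from [thresholdAndRescue()] (possibly several
#'   loci bound together).
#' @param catalog reference catalog data.frame (`name`, `locus`,
#'   `sequence`).
#' @return the calls data.frame with `allele`, `status`
#'   (`known`/`new`/`rescued`) and `matched_name` columns.
#' @export
classifyAlleles <- function(calls, catalog) {
  if (!nrow(calls)) {
    calls$allele <- calls$matched_name <- character(0)
    return(calls)
  }
  key <- paste(calls$locus, calls$sequence)
  ckey <- paste(catalog$locus, catalog$sequence)
  hit <- match(key, ckey)
  calls$allele <- catalog$name[hit]
  calls$matched_name <- NA_character_
  provisional <- character(nrow(calls))
  for (loc in unique(calls$locus)) {
    new_here <- is.na(hit) & calls$locus == loc
    if (!any(new_here)) next
    uq <- sort(unique(calls$sequence[new_here]))
    provisional[new_here] <- sprintf("%s-new-%d",
                                     loc, match(calls$sequence[new_here], uq))
  }
  calls$allele[is.na(hit)] <- provisional[is.na(hit)]
  known <- !is.na(hit) & calls$status == "kept"
  calls$matched_name[known] <- catalog$name[hit[known]]
  calls$status[calls$status == "kept"] <- ifelse(is.na(hit[calls$status == "kept"]),
                                                 "new", "known")
  calls
}

#' Call MHC genotypes for a cohort
#'
#' Runs the full filter chain: locus assignment and length filtering
#' (skipped when collapsed, locus-labelled pools are supplied), rare
#' k-mer filtering per individual pool, the per-individual read-fraction
#' threshold with cross-individual rescue, and known/new classification.
#'
#' @param x either a named list of raw read vectors (one per
#'   individual), or a list of [AmpliconPool-class] objects (e.g. from
#'   [simulateCohortReads()] or [readAmpliconFastq()]).
#' @param catalog reference catalog data.frame (`name`, `locus`,
#'   `sequence`).
#' @param cfg a [filterConfig()].
#' @return data.frame of allele calls: `individual`, `locus`,
#'   `sequence`, `copies`, `fraction`, `status`, `allele`,
#'   `matched_name`.
#' @export
callMhcGenotypes <- function(x, catalog, cfg = filterConfig()) {
  pools <- if (length(x) && is(x[[1]], "AmpliconPool")) {
    lapply(x, function(p) {
      keep <- nchar(p@sequences) == cfg$target_length[[p@locus]]
      AmpliconPool(p@individual, p@locus, p@sequences[keep], p@copies[keep])
    })
  } else {
    unlist(lapply(names(x), function(ind)
      assignAndLengthFilter(x[[ind]], catalog, cfg, individual = ind)),
      use.names = FALSE)
  }
  pools <- lapply(pools, kmerFilter, cfg = cfg)
  loci <- vapply(pools, function(p) p@locus, character(1))
  calls <- do.call(rbind, lapply(unique(loci), function(loc)
    thresholdAndRescue(pools[loci == loc], cfg)))
  calls <- classifyAlleles(calls, catalog)
  rownames(calls) <- NULL
  calls[order(calls$individual, calls$locus, calls$allele), ]
}

#' Copy-number drop diagnostic
#'
#' Reports, per locus, the fold drop between the last sequence above a
#' copy threshold and the first below it (pooled over individuals) - the
#' diagnostic behind the rescue threshold choice. Not a filter.
#'
#' @param pools list of [AmpliconPool-class].
#' @param threshold copy-number threshold (default 1000).
#' @return data.frame: `locus`, `last_above`, `first_below`,
#'   `fold_drop` (`NA` when one side is empty).
#' @export
copyNumberDropStat <- function(pools, threshold = 1000) {
  loci <- vapply(pools, function(p) p@locus, character(1))
  do.call(rbind, lapply(unique(loci), function(loc) {
    copies <- sort(unlist(lapply(pools[loci == loc], function(p) p@copies)),
                   decreasing = TRUE)
    above <- copies[copies > threshold]
    below <- copies[copies <= threshold]
    la <- if (length(above)) min(above) else NA_real_
    fb <- if (length(below)) max(below) else NA_real_
    data.frame(locus = loc, last_above = la, first_below = fb,
               fold_drop = la / fb)
  }))
}
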