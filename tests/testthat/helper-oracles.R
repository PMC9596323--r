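# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by the most naive route
# available (loops, exhaustive enumeration) so they stay independent of
# the package's vectorised implementations.

# two-pass loop implementation of stMLH
stmlh_oracle <- function(calls) {
  n <- nrow(calls); m <- ncol(calls)
  locus_het <- numeric(m)
  for (j in seq_len(m)) {
    x <- calls[, j]
    locus_het[j] <- mean(x[!is.na(x)] == 1)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    typed <- which(!is.na(calls[i, ]))
    out[i] <- mean(calls[i, typed] == 1) / mean(locus_het[typed])
  }
  setNames(out, rownames(calls))
}

# naive UPGMA: clusters as index lists, inter-cluster distance recomputed
# from the original matrix as the mean over all cross pairs
brute_average_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(clusters)) for (b in seq_len(a - 1L)) {
      h <- mean(d[clusters[[a]], clusters[[b]]])
      if (h < bh - 1e-12) { bh <- h; best <- c(b, a) }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# naive UPGMA partition into k clusters (stop merging at k groups)
brute_average_cut <- function(d, k) {
  d <- as.matrix(d)
  clusters <- lapply(seq_len(nrow(d)), identity)
  while (length(clusters) > k) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(clusters)) for (b in seq_len(a - 1L)) {
      h <- mean(d[clusters[[a]], clusters[[b]]])
      if (h < bh - 1e-12) { bh <- h; best <- c(b, a) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(nrow(d))
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# adjusted Rand index between two labelings (NA treated as its own label)
ari <- function(a, b) {
  a <- as.integer(factor(a, exclude = NULL))
  b <- as.integer(factor(b, exclude = NULL))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# partitions equal up to label renaming (NA matched to NA)
same_partition <- function(a, b) {
  a <- unname(a); b <- unname(b)
  if (length(a) != length(b)) return(FALSE)
  if (!identical(is.na(a), is.na(b))) return(FALSE)
  ok <- !is.na(a)
  all(outer(a[ok], a[ok], "==") == outer(b[ok], b[ok], "=="))
}

# is a child's genotype possible given its parents' (per site)?
mendelian_ok <- function(gc, gs, gd) {
  can <- function(g) switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
  any(outer(can(gs), can(gd), "+") == gc)
}

# brute-force rare k-mer filter matching the documented definition
kmer_filter_oracle <- function(seqs, copies, window, consecutive_low,
                               coverage_frac) {
  np <- nchar(seqs) - window + 1L
  kmers <- lapply(seq_along(seqs), function(i)
    substring(seqs[i], 1:np[i], window:nchar(seqs[i])))
  cov <- new.env()
  for (i in seq_along(seqs)) for (k in kmers[[i]])
    cov[[k]] <- (if (is.null(cov[[k]])) 0 else cov[[k]]) + copies[i]
  all_cov <- unlist(mget(ls(cov), envir = cov))
  thr <- coverage_frac * median(all_cov)
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    low <- vapply(kmers[[i]], function(k) cov[[k]] < thr, logical(1))
    run <- rle(low)
    worst <- if (any(run$values)) max(run$lengths[run$values]) else 0L
    keep[i] <- worst < consecutive_low
  }
  keep
}

# random DNA of given length
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# a tiny two-locus catalog with short target lengths for filter tests
toy_catalog <- function() {
  data.frame(
    name = c("toy-A*01", "toy-A*02", "toy-B*01"),
    locus = c("A", "A", "B"),
    sequence = c("ACGTACGTACGTACGTACGTACGTACGTAC",
                 "ACGTACGTACGTACGTACGTACGTACGTCC",
                 "TTGCATGCATGCATGCATGCATGCATGCAT"),
    stringsAsFactors = FALSE)
}

toy_filter_cfg <- function(...) {
  filterConfig(target_length = c(A = 30L, B = 30L, DQA = 31L, DRB = 32L), ...)
}
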