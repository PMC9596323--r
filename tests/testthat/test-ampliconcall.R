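# Amplicon allele caller: locus assignment, rare k-mer filter,
# read-fraction threshold with rescue, known/new classification.

test_that("locus assignment keeps exact-length best matches and drops ties", {
  cfg <- toy_filter_cfg()
  base <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  catB <- base
  substr(catB, 1, 2) <- "TT"   # locus B reference differs at positions 1-2
  cat <- data.frame(name = c("toy-A*01", "toy-B*01"), locus = c("A", "B"),
                    sequence = c(base, catB), stringsAsFactors = FALSE)
  readA <- base                               # exact A match
  short <- substr(base, 1, 25)                # wrong length: discarded
  tie <- base
  substr(tie, 1, 1) <- "T"                    # Hamming 1 to each catalog entry
  pools <- assignAndLengthFilter(c(readA, readA, short, tie), cat, cfg, "i1")
  expect_named(pools, "A")
  expect_equal(pools$A@sequences, readA)
  expect_equal(pools$A@copies, 2L)
  expect_warning(assignAndLengthFilter(short, cat, cfg, "i2"), "no reads")
})

test_that("k-mer filter removes runs of rare k-mers per the hand oracle", {
  set.seed(20)
  # S1 abundant (non-repetitive, so its 16 k-mers are distinct); S2
  # shares only its first 15 bp -> 15 rare k-mers in a row. Coverage by
  # hand: 1 shared k-mer at 102, 15 S1-private at 100, 15 S2-private at
  # 2; median 100, threshold 15 -> S2 removed.
  s1 <- "ACGGTTACGATCCGTTAAGCCTGATCAGAT"
  s2 <- paste0(substr(s1, 1, 15), "GGATCCGGATTCGGA")
  pool <- AmpliconPool("i1", "A", c(s1, s2), c(100L, 2L))
  kept <- kmerFilter(pool, filterConfig())
  expect_equal(kept@sequences, s1)
  # hand-enumerated coverage: shared k-mer 102; 15 k-mers each private
  expect_equal(kmer_filter_oracle(c(s1, s2), c(100, 2), 15, 12, 0.15),
               c(TRUE, FALSE))

  # boundary: 11 consecutive low-coverage k-mers < 12 -> kept
  b1 <- rand_dna(25)
  b2 <- b1; substr(b2, 15, 15) <- if (substr(b1, 15, 15) == "A") "C" else "A"
  poolb <- AmpliconPool("i1", "A", c(b1, b2), c(100L, 2L))
  expect_equal(kmer_filter_oracle(c(b1, b2), c(100, 2), 15, 12, 0.15),
               c(TRUE, TRUE))
  expect_setequal(kmerFilter(poolb, filterConfig())@sequences, c(b1, b2))
  # at length 30 the same single mismatch yields 15 low k-mers -> removed
  c1 <- rand_dna(30)
  c2 <- c1; substr(c2, 15, 15) <- if (substr(c1, 15, 15) == "A") "C" else "A"
  poolc <- AmpliconPool("i1", "A", c(c1, c2), c(100L, 2L))
  expect_equal(kmerFilter(poolc, filterConfig())@sequences, c1)

  # all reads identical (single unique sequence) -> kept
  pool1 <- AmpliconPool("i1", "A", s1, 500L)
  expect_identical(kmerFilter(pool1)@sequences, s1)

  # agreement with the brute-force oracle on random pools
  set.seed(42)
  for (rep in 1:5) {
    base <- rand_dna(40)
    variants <- vapply(1:6, function(i) {
      v <- base
      for (p in sample(40, sample(0:8, 1)))
        substr(v, p, p) <- sample(c("A", "C", "G", "T"), 1)
      v
    }, character(1))
    variants <- unique(variants)
    copies <- sample(c(1, 2, 5, 50, 100), length(variants), replace = TRUE)
    pool <- AmpliconPool("i1", "A", variants, as.integer(copies))
    got <- kmerFilter(pool)@sequences
    want <- variants[kmer_filter_oracle(variants, copies, 15, 12, 0.15)]
    expect_setequal(got, want)
  }
})

test_that("read-fraction threshold honours its boundary and the rescue rule", {
  mk <- function(ind, seqs, copies) AmpliconPool(ind, "DRB", seqs, copies)
  sA <- rand_dna(32); sB <- rand_dna(32); sC <- rand_dna(32)
  # {60, 35, 5} of 100: C sits exactly at 5% and is kept ("at minimum 5%")
  calls <- thresholdAndRescue(list(mk("i1", c(sA, sB, sC), c(60L, 35L, 5L))),
                              toy_filter_cfg())
  expect_setequal(calls$sequence, c(sA, sB, sC))
  expect_true(all(calls$status == "kept"))
  # {60, 36, 4}: C dropped
  calls2 <- thresholdAndRescue(list(mk("i1", c(sA, sB, sC), c(60L, 36L, 4L))),
                               toy_filter_cfg())
  expect_setequal(calls2$sequence, c(sA, sB))

  # rescue: 1200 copies at 2% in the focal animal, 6% in another
  p_focal <- mk("i1", c(sA, sC), c(58800L, 1200L))       # C at 2%
  p_other <- mk("i2", c(sA, sC), c(9400L, 600L))         # C at 6%
  calls3 <- thresholdAndRescue(list(p_focal, p_other), toy_filter_cfg())
  crow <- calls3[calls3$individual == "i1" & calls3$sequence == sC, ]
  expect_equal(crow$status, "rescued")
  # without the second individual the same call disappears
  calls4 <- thresholdAndRescue(list(p_focal), toy_filter_cfg())
  expect_false(sC %in% calls4$sequence)
})

test_that("threshold is monotone and copy numbers are conserved", {
  set.seed(7)
  seqs <- vapply(1:8, function(i) rand_dna(30), character(1))
  pool <- AmpliconPool("i1", "A", seqs,
                       as.integer(c(500, 300, 90, 50, 30, 15, 10, 5)))
  keep_at <- function(frac) {
    cfg <- toy_filter_cfg(min_read_frac = frac)
    thresholdAndRescue(list(pool), cfg)$sequence
  }
  prev <- keep_at(0.20)
  for (f in c(0.10, 0.05, 0.02, 0.005)) {
    cur <- keep_at(f)
    expect_true(all(prev %in% cur))  # lowering the cutoff never drops a call
    prev <- cur
  }
  filtered <- kmerFilter(pool, toy_filter_cfg())
  retained <- thresholdAndRescue(list(filtered), toy_filter_cfg())
  expect_lte(sum(retained$copies), sum(filtered@copies))
  expect_lte(sum(filtered@copies), sum(pool@copies))
})

test_that("classification separates known from new with stable names", {
  cat <- toy_catalog()
  sNew <- cat$sequence[1]
  substr(sNew, 5, 5) <- if (substr(sNew, 5, 5) == "G") "T" else "G"
  calls <- data.frame(
    individual = c("i1", "i1", "i2"), locus = "A",
    sequence = c(cat$sequence[1], sNew, sNew),
    copies = c(100L, 50L, 60L), fraction = c(.6, .3, .9),
    status = "kept", stringsAsFactors = FALSE)
  out <- classifyAlleles(calls, cat)
  expect_equal(out$status, c("known", "new", "new"))
  expect_equal(out$allele[1], "toy-A*01")
  expect_equal(out$matched_name[1], "toy-A*01")
  # the same new sequence gets the same provisional name in both animals
  expect_equal(out$allele[2], out$allele[3])
  expect_match(out$allele[2], "^A-new-")
  expect_true(all(is.na(out$matched_name[2:3])))
  # provisional naming is invariant to individual order
  out_perm <- classifyAlleles(calls[c(3, 1, 2), ], cat)
  expect_setequal(paste(out$individual, out$allele),
                  paste(out_perm$individual, out_perm$allele))
})

test_that("end-to-end calling is invariant to read and individual order", {
  cat <- toy_catalog()
  cfg <- toy_filter_cfg()
  set.seed(21)
  mkreads <- function() {
    c(rep(cat$sequence[1], 400), rep(cat$sequence[2], 350),
      rep(cat$sequence[3], 500), rep(rand_dna(30), 3))
  }
  reads <- list(i1 = mkreads(), i2 = mkreads())
  calls <- callMhcGenotypes(reads, cat, cfg)
  calls_perm <- callMhcGenotypes(list(i2 = sample(reads$i2),
                                      i1 = sample(reads$i1)), cat, cfg)
  key <- function(x) {
    k <- paste(x$individual, x$locus, x$allele, x$copies)
    sort(k)
  }
  expect_identical(key(calls), key(calls_perm))
})
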