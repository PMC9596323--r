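# Supertyping: translation, PSS screening, z-descriptor matrices,
# deterministic average linkage, minimum-size branch cut.

test_that("translation honours frames, trailing bases and stop flags", {
  expect_equal(translateAlleles(c(a = "ATGGCT"))$protein, "MA")
  expect_equal(translateAlleles(c(a = "TATGGCT"), frame = 1)$protein, "MA")
  expect_equal(translateAlleles(c(a = "ATGGCTAC"))$protein, "MA")  # partial codon dropped
  tr <- translateAlleles(c(ok = "ATGGCTGCT", bad = "ATGTAAGCT"))
  expect_equal(tr$internal_stop, c(FALSE, TRUE))
  # terminal stop is not an internal stop
  expect_false(translateAlleles(c(x = "ATGTAA"))$internal_stop)
})

test_that("PSS counting screen flags nonsynonymous columns only", {
  # invariant alignment: nothing flagged
  al <- rep("ATGGCTAAA", 4)
  expect_length(builtinPss(al)$positions, 0)

  # purely synonymous variation (CTx all code Leu): nothing flagged
  syn <- c("ATGCTTAAA", "ATGCTCAAA", "ATGCTAAAA", "ATGCTGAAA")
  expect_length(builtinPss(syn)$positions, 0)

  # one nonsynonymous column among invariant ones: codon 2 from
  # {CTT=L, GTT=V, CCT=P, GCT=A}. Hand count: 6 pairs differ by
  # 1+1+2+2+1+1 = 8 single-base steps, all nonsynonymous on every
  # pathway; each codon has exactly 1 synonymous site (the 4-fold third
  # position), so the nonsynonymous opportunity is 2/3 and the
  # one-sided binomial p is (2/3)^8 ~ 0.039
  div <- c("ATGCTTGCTGCTGCT", "ATGGTTGCTGCTGCT",
           "ATGCCTGCTGCTGCT", "ATGGCTGCTGCTGCT")
  res <- builtinPss(div)
  expect_equal(res$positions, 2L)
  expect_equal(res$p[2], (2 / 3)^8, tolerance = 1e-9)
})

test_that("z-matrix is a faithful site-major descriptor lookup", {
  zt <- zDescriptorTable()
  expect_equal(dim(zt), c(20L, 5L))
  expect_setequal(rownames(zt), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])

  prot <- c(a1 = "MKL", a2 = "MRL")
  zm <- zMatrix(prot, 2)
  expect_equal(dim(zm), c(2L, 5L))
  expect_equal(unname(zm["a1", ]), unname(zt["K", ]))
  expect_equal(unname(zm["a2", ]), unname(zt["R", ]))

  # identical alleles -> identical rows, zero distance
  zm2 <- zMatrix(c(x = "MKL", y = "MKL"), c(1, 3))
  expect_equal(dist(zm2)[1], 0)

  # permuting the site order leaves pairwise distances unchanged
  prot3 <- c(a = "MKLW", b = "ARNC", c = "GHIP")
  d1 <- dist(zMatrix(prot3, c(1, 2, 4)))
  d2 <- dist(zMatrix(prot3, c(4, 1, 2)))
  expect_equal(as.vector(d1), as.vector(d2))
})

test_that("average linkage agrees with a brute-force UPGMA oracle", {
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    m <- matrix(rnorm(n * 3), n)
    rownames(m) <- letters[seq_len(n)]
    hc <- averageLinkage(m)
    expect_equal(sort(hc$height),
                 sort(brute_average_linkage(dist(m))), tolerance = 1e-9)
    for (k in 2:(n - 1)) {
      expect_true(same_partition(cutree(hc, k = k),
                                 brute_average_cut(dist(m), k)))
    }
  }
})

test_that("tie-breaking makes the dendrogram input-order invariant", {
  # four points with many equal distances (unit square corners)
  m <- rbind(p1 = c(0, 0), p2 = c(0, 1), p3 = c(1, 0), p4 = c(1, 1))
  h1 <- averageLinkage(m)
  h2 <- averageLinkage(m[c(3, 1, 4, 2), ])
  expect_equal(sort(h1$height), sort(h2$height))
  ct1 <- cutree(h1, k = 2)[rownames(m)]
  ct2 <- cutree(h2, k = 2)[rownames(m)]
  expect_true(same_partition(ct1, ct2))
})

test_that("minimum-size branch cut recovers planted structure", {
  set.seed(42)
  # two tight groups of 3, separated by >= 10x the within-group spread
  zm <- rbind(matrix(rnorm(9, 0, 0.1), 3), matrix(rnorm(9, 10, 0.1), 3))
  rownames(zm) <- paste0("al", 1:6)
  cl <- cutSupertypeTree(averageLinkage(zm), min_cluster_size = 2)
  expect_equal(length(unique(cl)), 2L)
  expect_true(all(!is.na(cl)))
  expect_equal(ari(cl, rep(1:2, each = 3)), 1)

  # all rows identical -> a single supertype
  zid <- matrix(1, 4, 5, dimnames = list(paste0("a", 1:4), NULL))
  expect_equal(unname(cutSupertypeTree(averageLinkage(zid), 2)),
               rep(1L, 4))

  # far outlier below the minimum size stays unassigned
  zo <- rbind(matrix(rnorm(25, 0, 0.1), 5), out = rep(50, 5))
  rownames(zo) <- c(paste0("a", 1:5), "out")
  clo <- cutSupertypeTree(averageLinkage(zo), min_cluster_size = 2)
  expect_true(is.na(clo["out"]))
  expect_true(all(clo[paste0("a", 1:5)] == 1L))
})

test_that("planted residue profiles are recovered through the full pass", {
  set.seed(43)
  # three groups of alleles built from distinct residue profiles at the
  # variable codons; grouping should be recovered exactly (ARI = 1)
  mk_codon <- c(K = "AAA", D = "GAT", W = "TGG", P = "CCA", G = "GGA",
                R = "CGT", F = "TTT")
  profiles <- list(c("K", "D", "W"), c("P", "G", "R"), c("F", "K", "P"))
  backbone <- "ATGGCTGCTGCTGCT"  # 5 codons; variable codons 2..4
  alleles <- character(0)
  truth <- integer(0)
  for (gidx in seq_along(profiles)) {
    for (v in 1:3) {
      s <- backbone
      for (ci in 1:3) {
        at <- 3 * ci + 1
        substr(s, at, at + 2) <- mk_codon[[profiles[[gidx]][ci]]]
      }
      # silent third-position wobble in codon 5 keeps alleles distinct
      substr(s, 15, 15) <- c("T", "C", "A")[v]
      alleles <- c(alleles, s); truth <- c(truth, gidx)
    }
  }
  names(alleles) <- paste0("al", seq_along(alleles))
  st <- assignSupertypes(alleles, min_cluster_size = 2)
  expect_equal(ari(supertypes(st)[names(alleles)], truth), 1)
  # label invariance under permuted input order
  perm <- sample(length(alleles))
  st2 <- assignSupertypes(alleles[perm], min_cluster_size = 2)
  expect_true(same_partition(supertypes(st)[names(alleles)],
                             supertypes(st2)[names(alleles)]))
})

test_that("external PSS lists take precedence and are validated", {
  pss <- externalPss(c(5, 2, 2))
  expect_equal(pss$positions, c(2L, 5L))
  expect_error(externalPss(10, alignment_length = 5), "exceed")
  dna <- c(a = "ATGAAAGCTGCTGCT", b = "ATGTGTGCTGCTGCT",
           c = "ATGGATGCTGCTGCT", d = "ATGCCAGCTGCTGCT")
  st <- assignSupertypes(dna, pss = c(2))
  expect_equal(st@pss, 2L)
  expect_equal(st@metadata$pss_source, "external_list")
})
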