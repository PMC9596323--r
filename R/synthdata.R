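# Synthetic cohorts: pedigrees, SNP genotypes, MHC haplotypes, amplicon
# read pools, dyadic count tables. Everything is deterministic under the
# seed argument (local RNG state, restored on exit).

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration for pedigree and SNP generation
#'
#' @param n_founders number of founder individuals (>= 2).
#' @param n_generations number of bred generations after the founders.
#' @param n_sites number of SNP sites.
#' @param maf_min,maf_max bounds of the uniform law the per-block minor
#'   allele frequencies are drawn from; set equal for a point mass.
#' @param ld_block_size sites per perfectly correlated LD block (1 =
#'   independent sites).
#' @param genotyping_error probability that a genotype call has one
#'   allele flipped (0/2 become 1; 1 becomes 0 or 2).
#' @param offspring_per_pair litter size per mated pair per generation.
#' @param mating `"monogamy"` (shuffled one-to-one pairing) or
#'   `"polygyny"` (each female mated to a random male).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(n_founders = 8L, n_generations = 2L, n_sites = 1000L,
                      maf_min = 0.05, maf_max = 0.5, ld_block_size = 1L,
                      genotyping_error = 0, offspring_per_pair = 2L,
                      mating = c("monogamy", "polygyny")) {
  mating <- match.arg(mating)
  stopifnot(n_founders >= 2, n_generations >= 0, n_sites >= 1,
            ld_block_size >= 1, offspring_per_pair >= 1,
            maf_min > 0, maf_max <= 0.5, maf_min <= maf_max,
            genotyping_error >= 0, genotyping_error <= 1)
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_sites = as.integer(n_sites),
                 maf_min = maf_min, maf_max = maf_max,
                 ld_block_size = as.integer(ld_block_size),
                 genotyping_error = genotyping_error,
                 offspring_per_pair = as.integer(offspring_per_pair),
                 mating = mating),
            class = "SimConfig")
}

#' Simulate a multi-generation pedigree
#'
#' Founders are unrelated; each later generation is produced by random
#' mating among opposite-sex, non-sibling members of the previous
#' generation. Parent rows always precede child rows.
#'
#' @param cfg a [simConfig()] list.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return data.frame with columns `id`, `sire`, `dam` (NA for founders),
#'   `sex` (`"M"`/`"F"`), `generation` (founders = 0).
#' @export
simulatePedigree <- function(cfg = simConfig(), seed = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(seed, {
    sex <- c("M", "F", sample(c("M", "F"), cfg$n_founders - 2L, replace = TRUE))
    sex <- sex[seq_len(cfg$n_founders)]
    ped <- data.frame(id = sprintf("G0_%03d", seq_len(cfg$n_founders)),
                      sire = NA_character_, dam = NA_character_,
                      sex = sex, generation = 0L,
                      stringsAsFactors = FALSE)
    for (g in seq_len(cfg$n_generations)) {
      prev <- ped[ped$generation == g - 1L, ]
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      if (!length(males) || !length(females))
        stop("generation ", g - 1L, " lacks one sex; cannot breed further")
      sibs <- function(a, b) {
        pa <- prev[prev$id == a, c("sire", "dam")]
        pb <- prev[prev$id == b, c("sire", "dam")]
        any(!is.na(unlist(pa)) & unlist(pa) %in% unlist(pb))
      }
      pairs <- list()
      if (cfg$mating == "monogamy") {
        m <- sample(males); f <- sample(females)
        used_f <- character()
        for (mm in m) {
          cand <- setdiff(f, used_f)
          cand <- cand[!vapply(cand, function(ff) sibs(mm, ff), logical(1))]
          if (!length(cand)) next
          ff <- cand[[1]]
          used_f <- c(used_f, ff)
          pairs[[length(pairs) + 1L]] <- c(mm, ff)
        }
      } else {
        for (ff in sample(females)) {
          cand <- males[!vapply(males, function(mm) sibs(mm, ff), logical(1))]
          if (!length(cand)) next
          pairs[[length(pairs) + 1L]] <- c(sample(cand, 1L), ff)
        }
      }
      if (!length(pairs))
        stop("no compatible pairs in generation ", g - 1L)
      kid <- 0L
      for (p in pairs) {
        for (k in seq_len(cfg$offspring_per_pair)) {
          kid <- kid + 1L
          ped <- rbind(ped, data.frame(
            id = sprintf("G%d_%03d", g, kid), sire = p[[1]], dam = p[[2]],
            sex = sample(c("M", "F"), 1L), generation = g,
            stringsAsFactors = FALSE))
        }
      }
      born <- ped$generation == g
      if (!any(ped$sex[born] == "M")) ped$sex[which(born)[1]] <- "M"
      if (sum(born) > 1L && !any(ped$sex[born] == "F"))
        ped$sex[which(born)[2]] <- "F"
    }
    rownames(ped) <- NULL
    validatePedigree(ped)
    ped
  })
}

#' Validate a pedigree table
#'
#' Checks that parents precede children, founders have no parents, and no
#' individual is its own ancestor.
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`, `generation`).
#' @return invisibly `TRUE`; stops on violation.
#' @export
validatePedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam", "generation") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids")
  idx <- match(ped$id, ped$id)
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p)
    if (any(!p[known] %in% ped$id)) stop("unknown parent id in ", col)
    if (any(match(p[known], ped$id) >= which(known)))
      stop("parent rows must precede child rows")
  }
  founder <- is.na(ped$sire) & is.na(ped$dam)
  if (any(xor(is.na(ped$sire), is.na(ped$dam))))
    stop("individuals must have both parents or neither")
  # topological order established above implies acyclicity
  invisible(TRUE)
}

#' Simulate biallelic SNP genotypes by gene dropping
#'
#' Founder haplotypes are drawn under Hardy-Weinberg equilibrium at
#' per-block allele frequencies from the configured MAF law; offspring
#' receive one allele from each parent per block (Mendelian
#' transmission). All sites within an LD block copy the same underlying
#' variant, giving within-block r-squared of 1 before error injection.
#' Genotyping error flips one allele of a call at the configured rate.
#'
#' @param ped pedigree from [simulatePedigree()].
#' @param cfg a [simConfig()] list.
#' @param seed integer seed.
#' @return A [GenotypeMatrix-class]; `siteInfo()` carries the block id
#'   and simulated MAF of each site.
#' @export
simulateSnpGenotypes <- function(ped, cfg = simConfig(), seed = NULL) {
  validatePedigree(ped)
  withSeed(seed, {
    n <- nrow(ped)
    n_blocks <- ceiling(cfg$n_sites / cfg$ld_block_size)
    maf <- if (cfg$maf_min == cfg$maf_max) rep(cfg$maf_min, n_blocks) else
      runif(n_blocks, cfg$maf_min, cfg$maf_max)
    H1 <- matrix(0L, n, n_blocks, dimnames = list(ped$id, NULL))
    H2 <- H1
    for (i in seq_len(n)) {
      if (is.na(ped$sire[i])) {
        H1[i, ] <- rbinom(n_blocks, 1L, maf)
        H2[i, ] <- rbinom(n_blocks, 1L, maf)
      } else {
        s <- match(ped$sire[i], ped$id); d <- match(ped$dam[i], ped$id)
        pick_s <- runif(n_blocks) < 0.5
        pick_d <- runif(n_blocks) < 0.5
        H1[i, ] <- ifelse(pick_s, H1[s, ], H2[s, ])
        H2[i, ] <- ifelse(pick_d, H1[d, ], H2[d, ])
      }
    }
    gb <- H1 + H2
    block_of <- rep(seq_len(n_blocks), each = cfg$ld_block_size)[seq_len(cfg$n_sites)]
    g <- gb[, block_of, drop = FALSE]
    if (cfg$genotyping_error > 0) {
      err <- matrix(runif(length(g)) < cfg$genotyping_error, nrow(g))
      up <- matrix(runif(length(g)) < 0.5, nrow(g))
      flip <- function(x, up) ifelse(x == 1L, ifelse(up, 2L, 0L), 1L)
      g[err] <- flip(g[err], up[err])
    }
    sites <- data.frame(chrom = "chrSim", pos = seq_len(cfg$n_sites),
                        block = block_of, maf = maf[block_of])
    GenotypeMatrix(g, sites)
  })
}

#' MHC simulation specification
#'
#' Defines per-locus allele pools, haplotype composition and the read
#' generation law. Defaults emulate the sequenced amplicons: 195 bp
#' class I (A, B) segments, a 188 bp DQ alpha-1 segment and a 252 bp DR
#' beta-1 segment, allele pool sizes in line with the tallies observed in
#' olive baboons (16 A / 32 B / 9 DQA / 27 DRB), and per-allele read
#' depth of about 4031 reads (SD 2313) as reported for class I amplicon
#' sequencing.
#'
#' @param n_alleles named integer pool size per locus.
#' @param alleles_per_haplotype named integer; distinct alleles carried
#'   per haplotype per locus (multi-gene loci carry several).
#' @param n_haplotypes haplotype pool size per locus.
#' @param n_variable_codons codon positions allowed to vary per locus
#'   (sets the polymorphism available for supertyping).
#' @param n_supertype_centers residue-profile centers per locus; alleles
#'   are built around these centers (plus silent wobble changes and
#'   occasional extra substitutions), so supertype clustering has real
#'   structure to recover.
#' @param known_frac fraction of each pool placed in the reference
#'   catalog (the rest surface as "new" alleles when called).
#' @param depth_mean,depth_sd,depth_min normal read-depth law per true
#'   allele (reads), truncated below at `depth_min`; `depth_sd = 0`
#'   gives constant depth.
#' @param error_rate per-base substitution error probability.
#' @param chimera_rate probability that a read is a single-breakpoint
#'   two-parent PCR chimera.
#' @return list of class `MhcSimSpec`.
#' @export
mhcSimSpec <- function(n_alleles = c(A = 16L, B = 32L, DQA = 9L, DRB = 27L),
                       alleles_per_haplotype = c(A = 2L, B = 4L, DQA = 1L, DRB = 3L),
                       n_haplotypes = 8L,
                       n_variable_codons = 14L,
                       n_supertype_centers = 3L,
                       known_frac = 0.55,
                       depth_mean = 4031, depth_sd = 2313, depth_min = 100,
                       error_rate = 0.001, chimera_rate = 0.02) {
  stopifnot(all(MHC_LOCI %in% names(n_alleles)),
            all(MHC_LOCI %in% names(alleles_per_haplotype)),
            depth_mean > 0, depth_min >= 1, depth_sd >= 0,
            error_rate >= 0, error_rate < 1,
            chimera_rate >= 0, chimera_rate < 1,
            known_frac > 0, known_frac <= 1)
  structure(list(n_alleles = n_alleles,
                 alleles_per_haplotype = alleles_per_haplotype,
                 n_haplotypes = as.integer(n_haplotypes),
                 n_variable_codons = as.integer(n_variable_codons),
                 n_supertype_centers = as.integer(n_supertype_centers),
                 known_frac = known_frac,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 depth_min = depth_min,
                 error_rate = error_rate, chimera_rate = chimera_rate),
            class = "MhcSimSpec")
}

SENSE_CODONS <- local({
  cod <- names(Biostrings::GENETIC_CODE)
  cod[Biostrings::GENETIC_CODE != "*"]
})

randCodingSeq <- function(n_codons, lead = 0L) {
  lead_nt <- if (lead > 0L) paste(sample(c("A", "C", "G", "T"), lead,
                                         replace = TRUE), collapse = "") else ""
  paste0(lead_nt, paste(sample(SENSE_CODONS, n_codons, replace = TRUE),
                        collapse = ""))
}

# substitute a nonsynonymous sense codon at 1-based codon position k
mutateCodon <- function(seq, k, lead) {
  at <- lead + (k - 1L) * 3L + 1L
  cur <- substr(seq, at, at + 2L)
  aa <- Biostrings::GENETIC_CODE[[cur]]
  alt <- SENSE_CODONS[Biostrings::GENETIC_CODE[SENSE_CODONS] != aa]
  paste0(substr(seq, 1L, at - 1L), sample(alt, 1L),
         substr(seq, at + 3L, nchar(seq)))
}

#' Simulate MHC allele pools and per-individual truth genotypes
#'
#' Builds, per locus, a pool of distinct same-length coding alleles:
#' a shared backbone, a handful of residue-profile centers that carry
#' nonsynonymous substitutions at the variable codons (the planted
#' supertype structure), silent third-position wobble at reserved
#' four-fold-degenerate codons to keep alleles distinct, and occasional
#' extra nonsynonymous changes for within-center spread. Haplotypes are
#' allele multisets dropped through the pedigree (one from each
#' parent), and the per-individual allele truth is recorded.
#'
#' @param ped pedigree data.frame.
#' @param spec an [mhcSimSpec()] list.
#' @param seed integer seed.
#' @return list with elements
#'   `alleles` (data.frame: locus, name, sequence, known),
#'   `truth` (data.frame: individual, locus, allele), and
#'   `haplotypes` (per-locus list of allele-name vectors).
#' @export
simulateMhcTruth <- function(ped, spec = mhcSimSpec(), seed = NULL) {
  validatePedigree(ped)
  withSeed(seed, {
    alleles <- NULL
    haps <- list()
    for (loc in MHC_LOCI) {
      len <- MHC_TARGET_LENGTH[[loc]]
      lead <- MHC_FRAME[[loc]]
      n_codons <- (len - lead) %/% 3L
      base <- randCodingSeq(n_codons, lead)
      # reserve the last three codons as four-fold-degenerate wobble
      # slots (Leu/Gly/Pro families): silent variation there keeps
      # alleles distinct without touching the residue profile
      wob <- (n_codons - 2L):n_codons
      fams <- c("CTT", "GGT", "CCT")
      for (w in seq_along(wob)) {
        at <- lead + (wob[w] - 1L) * 3L + 1L
        substr(base, at, at + 2L) <- fams[w]
      }
      varc <- sort(sample(n_codons - 3L,
                          min(spec$n_variable_codons, n_codons - 3L)))
      k_centers <- max(1L, spec$n_supertype_centers)
      centers <- vapply(seq_len(k_centers), function(ci) {
        s <- base
        for (k in varc) s <- mutateCodon(s, k, lead)
        s
      }, character(1))
      pool <- character(spec$n_alleles[[loc]])
      third <- c("T", "C", "A", "G")
      for (i in seq_len(spec$n_alleles[[loc]])) {
        s <- centers[[(i - 1L) %% k_centers + 1L]]
        w <- (i - 1L) %/% k_centers          # encode in silent wobble
        for (slot in seq_along(wob)) {
          at <- lead + (wob[slot] - 1L) * 3L + 3L
          substr(s, at, at) <- third[(w %% 4L) + 1L]
          w <- w %/% 4L
        }
        if (runif(1) < 0.25)                 # mild within-center spread
          s <- mutateCodon(s, sample(varc, 1L), lead)
        pool[i] <- s
      }
      pool <- unique(pool)
      nm <- sprintf("Paan-%s*syn%02d", loc, seq_along(pool))
      known <- seq_along(pool) <= max(1L, round(spec$known_frac * length(pool)))
      alleles <- rbind(alleles, data.frame(locus = loc, name = nm,
                                           sequence = pool, known = known,
                                           stringsAsFactors = FALSE))
      k <- spec$alleles_per_haplotype[[loc]]
      haps[[loc]] <- replicate(spec$n_haplotypes,
                               sample(nm, min(k, length(nm))),
                               simplify = FALSE)
    }
    # drop two haplotypes per founder through the pedigree, per locus
    truth <- NULL
    for (loc in MHC_LOCI) {
      hp <- haps[[loc]]
      h1 <- h2 <- vector("list", nrow(ped))
      names(h1) <- names(h2) <- ped$id
      for (i in seq_len(nrow(ped))) {
        if (is.na(ped$sire[i])) {
          h1[[i]] <- hp[[sample(length(hp), 1L)]]
          h2[[i]] <- hp[[sample(length(hp), 1L)]]
        } else {
          s <- match(ped$sire[i], ped$id); d <- match(ped$dam[i], ped$id)
          h1[[i]] <- if (runif(1) < 0.5) h1[[s]] else h2[[s]]
          h2[[i]] <- if (runif(1) < 0.5) h1[[d]] else h2[[d]]
        }
      }
      for (i in seq_len(nrow(ped))) {
        al <- sort(unique(c(h1[[i]], h2[[i]])))
        truth <- rbind(truth, data.frame(individual = ped$id[i], locus = loc,
                                         allele = al, stringsAsFactors = FALSE))
      }
    }
    list(alleles = alleles, truth = truth, haplotypes = haps)
  })
}

# conditional Binomial(L, e) | X >= 1 draws, vectorised
rcondBinomPos <- function(n, L, e) {
  if (n == 0L) return(integer(0))
  p0 <- dbinom(0, L, e)
  qbinom(runif(n, p0, 1), L, e)
}

#' Simulate an amplicon read pool for one individual at one locus
#'
#' Reads are copies of the true alleles with independent per-base
#' substitution errors, plus single-breakpoint two-parent chimeras at the
#' configured rate. The pool is returned collapsed (unique sequences with
#' copy numbers), the form the artifact filters consume.
#'
#' @param truth_seqs character vector of the individual's true allele
#'   sequences at this locus (equal length).
#' @param individual,locus labels for the pool.
#' @param spec an [mhcSimSpec()] list (depth / error / chimera law).
#' @param seed integer seed.
#' @return An [AmpliconPool-class].
#' @export
simulateAmpliconReads <- function(truth_seqs, individual, locus,
                                  spec = mhcSimSpec(), seed = NULL) {
  if (!length(truth_seqs)) stop("empty truth allele set")
  L <- unique(nchar(truth_seqs))
  if (length(L) != 1L) stop("truth alleles must share one length")
  withSeed(seed, {
    n_all <- length(truth_seqs)
    depth <- if (spec$depth_sd == 0) rep(round(spec$depth_mean), n_all) else
      pmax(round(rnorm(n_all, spec$depth_mean, spec$depth_sd)), spec$depth_min)
    seqs <- character(0); cnt <- numeric(0)
    err_parent <- integer(0); err_k <- integer(0)
    chim_a <- integer(0); chim_b <- integer(0); chim_bp <- integer(0)
    p_clean <- (1 - spec$error_rate)^L
    for (a in seq_len(n_all)) {
      n <- depth[[a]]
      n_chim <- rbinom(1L, n, spec$chimera_rate)
      n_norm <- n - n_chim
      n_err <- rbinom(1L, n_norm, 1 - p_clean)
      seqs <- c(seqs, truth_seqs[[a]]); cnt <- c(cnt, n_norm - n_err)
      err_parent <- c(err_parent, rep(a, n_err))
      if (n_chim > 0L) {
        chim_a <- c(chim_a, rep(a, n_chim))
        partner <- if (n_all > 1L)
          sample(setdiff(seq_len(n_all), a), n_chim, replace = TRUE)
        else rep(a, n_chim)
        chim_b <- c(chim_b, partner)
        chim_bp <- c(chim_bp, sample(L - 1L, n_chim, replace = TRUE))
      }
    }
    if (length(err_parent)) {
      err_k <- rcondBinomPos(length(err_parent), L, spec$error_rate)
      one <- err_k == 1L
      if (any(one)) {
        par <- truth_seqs[err_parent[one]]
        pos <- sample.int(L, sum(one), replace = TRUE)
        old <- substr(par, pos, pos)
        nb <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     character(1), USE.NAMES = FALSE)
        seqs <- c(seqs, paste0(substr(par, 1L, pos - 1L), nb,
                               substr(par, pos + 1L, L)))
        cnt <- c(cnt, rep(1, sum(one)))
      }
      for (i in which(!one)) {
        s <- strsplit(truth_seqs[[err_parent[[i]]]], "")[[1]]
        pos <- sample.int(L, err_k[[i]])
        for (p in pos) s[[p]] <- sample(setdiff(c("A", "C", "G", "T"), s[[p]]), 1L)
        seqs <- c(seqs, paste(s, collapse = "")); cnt <- c(cnt, 1)
      }
    }
    if (length(chim_a)) {
      seqs <- c(seqs, paste0(substr(truth_seqs[chim_a], 1L, chim_bp),
                             substr(truth_seqs[chim_b], chim_bp + 1L, L)))
      cnt <- c(cnt, rep(1, length(chim_a)))
    }
    keep <- cnt > 0
    tot <- rowsum(cnt[keep], seqs[keep])
    AmpliconPool(individual, locus, rownames(tot), as.integer(tot[, 1]))
  })
}

#' Simulate a cohort of amplicon pools from an MHC truth table
#'
#' @param truth truth data.frame from [simulateMhcTruth()].
#' @param alleles allele table from [simulateMhcTruth()].
#' @param spec an [mhcSimSpec()].
#' @param seed integer seed.
#' @return list of [AmpliconPool-class] objects, one per
#'   individual-locus cell, named `"{individual}.{locus}"`.
#' @export
simulateCohortReads <- function(truth, alleles, spec = mhcSimSpec(),
                                seed = NULL) {
  withSeed(seed, {
    pools <- list()
    seqs <- setNames(alleles$sequence, alleles$name)
    for (ind in unique(truth$individual)) {
      for (loc in unique(truth$locus[truth$individual == ind])) {
        al <- truth$allele[truth$individual == ind & truth$locus == loc]
        pools[[paste(ind, loc, sep = ".")]] <-
          simulateAmpliconReads(unname(seqs[al]), ind, loc, spec)
      }
    }
    pools
  })
}

#' Simulate dyadic shared-allele counts under a Poisson log-linear model
#'
#' For every unordered dyad, draws
#' `count ~ Poisson(exp(intercept + beta_kinship * phi + beta_total * total))`,
#' the generative counterpart of the dyadic complementarity regressions.
#' Used for parameter-recovery checks of the robust Poisson layer.
#'
#' @param K a [KinshipMatrix-class] or symmetric matrix of kinship phi.
#' @param beta_kinship,beta_total,intercept model coefficients.
#' @param totals optional numeric vector of per-dyad totals (recycled in
#'   dyad order); defaults to `4 + Poisson(8)` draws, roughly the scale
#'   of total unique alleles in a dyad.
#' @param seed integer seed.
#' @return data.frame: `id1`, `id2`, `kinship`, `total`, `count`.
#' @export
simulateDyadicCounts <- function(K, beta_kinship, beta_total = 0,
                                 intercept = 0, totals = NULL, seed = NULL) {
  phi <- if (is(K, "KinshipMatrix")) kinship(K) else as.matrix(K)
  ids <- rownames(phi)
  ut <- which(upper.tri(phi), arr.ind = TRUE)
  withSeed(seed, {
    n <- nrow(ut)
    tot <- if (is.null(totals)) 4 + rpois(n, 8) else rep_len(totals, n)
    k <- phi[ut]
    lambda <- exp(intercept + beta_kinship * k + beta_total * tot)
    data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
               kinship = k, total = tot,
               count = rpois(n, lambda), stringsAsFactors = FALSE)
  })
}
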