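# End-to-end orchestration: simulate -> call MHC genotypes ->
# genome-wide summaries -> supertype -> diversity -> association models,
# with a content-hashed manifest for reproducibility.

#' Pipeline configuration
#'
#' Bundles all stage configurations. Defaults produce a 22-individual
#' style cohort (8 founders, two bred generations of two offspring per
#' pair) with 10,000 SNP sites in 2-site LD blocks, the default MHC
#' simulation spec, and the default filter chain.
#'
#' @param sim a [simConfig()] for pedigree and SNPs.
#' @param mhc an [mhcSimSpec()].
#' @param filter a [filterConfig()].
#' @param prune list with `window_sites`, `step_sites`, `r2_max`.
#' @param supertype list with `min_cluster_size`, `cut_frac`, `fdr` and
#'   optional per-grouping external PSS lists.
#' @param write_fastq write per-individual FASTQ files (off by default;
#'   pools are passed in memory).
#' @param stages character vector of stages to run, in dependency
#'   order; a prefix of the full set.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sim = simConfig(n_founders = 8L, n_generations = 2L,
                                           n_sites = 10000L, ld_block_size = 2L),
                           mhc = mhcSimSpec(),
                           filter = filterConfig(),
                           prune = list(window_sites = 50L, step_sites = 5L,
                                        r2_max = 0.5),
                           supertype = list(min_cluster_size = 2L,
                                            min_gap_frac = 0.2,
                                            cut_frac = 0.99, fdr = 0.05,
                                            pss = NULL),
                           write_fastq = FALSE,
                           stages = c("simulate", "genotype-mhc", "genomewide",
                                      "supertype", "diversity", "stats")) {
  all_stages <- c("simulate", "genotype-mhc", "genomewide", "supertype",
                  "diversity", "stats")
  stopifnot(all(stages %in% all_stages),
            identical(stages, all_stages[seq_along(stages)]))
  structure(list(sim = sim, mhc = mhc, filter = filter, prune = prune,
                 supertype = supertype, write_fastq = write_fastq,
                 stages = stages),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; omitted keys
#' keep their defaults. Unknown keys are an error.
#'
#' @param file YAML path.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  known <- c("sim", "mhc", "filter", "prune", "supertype", "write_fastq",
             "stages")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- list()
  if (!is.null(raw$sim)) args$sim <- do.call(simConfig, raw$sim)
  if (!is.null(raw$mhc)) {
    for (k in c("n_alleles", "alleles_per_haplotype"))
      if (!is.null(raw$mhc[[k]])) raw$mhc[[k]] <- unlist(raw$mhc[[k]])
    args$mhc <- do.call(mhcSimSpec, raw$mhc)
  }
  if (!is.null(raw$filter)) {
    if (!is.null(raw$filter$target_length))
      raw$filter$target_length <- unlist(raw$filter$target_length)
    args$filter <- do.call(filterConfig, raw$filter)
  }
  for (k in c("prune", "supertype", "write_fastq", "stages"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(pipelineConfig, args)
}

.logStage <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in dependency order on a synthetic
#' cohort, writing each stage's outputs as CSV (plus VCF and optional
#' FASTQ) under `out_dir`, and finishes with `manifest.json` recording
#' the seed, parameters, declared methodological simplifications, and
#' an md5 hash of every output file. A rerun with the same seed is
#' byte-identical.
#'
#' @param out_dir output directory (created; must be empty or absent).
#' @param config a [pipelineConfig()].
#' @param seed integer master seed; every stochastic stage derives its
#'   own stream from it.
#' @return invisibly, a list with the in-memory stage products.
#' @export
runPipeline <- function(out_dir, config = pipelineConfig(), seed = 1L) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (dir.exists(out_dir) && length(dir(out_dir)))
    stop("out_dir exists and is not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(seed = seed)
  run_stage <- function(stage, expr) {
    .logStage(stage, "start")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% config$stages) run_stage("simulate", {
    res$ped <- simulatePedigree(config$sim, seed = seed)
    res$geno <- simulateSnpGenotypes(res$ped, config$sim, seed = seed + 1L)
    res$mhc <- simulateMhcTruth(res$ped, config$mhc, seed = seed + 2L)
    res$pools <- simulateCohortReads(res$mhc$truth, res$mhc$alleles,
                                     config$mhc, seed = seed + 3L)
    write.csv(res$ped, file.path(out_dir, "pedigree.csv"), row.names = FALSE)
    writeGenotypeVcf(res$geno, file.path(out_dir, "genotypes.vcf"))
    write.csv(res$mhc$truth, file.path(out_dir, "mhc_truth.csv"),
              row.names = FALSE)
    write.csv(res$mhc$alleles, file.path(out_dir, "mhc_alleles.csv"),
              row.names = FALSE)
    writeCatalogFasta(res$mhc$alleles[res$mhc$alleles$known, ],
                      file.path(out_dir, "catalog.fasta"))
    if (config$write_fastq) {
      fq <- file.path(out_dir, "fastq")
      dir.create(fq)
      for (p in res$pools) writeAmpliconFastq(p, fq)
    }
  })

  if ("genotype-mhc" %in% config$stages) run_stage("genotype-mhc", {
    catalog <- res$mhc$alleles[res$mhc$alleles$known,
                               c("name", "locus", "sequence")]
    res$calls <- callMhcGenotypes(res$pools, catalog, config$filter)
    write.csv(res$calls, file.path(out_dir, "mhc_calls.csv"),
              row.names = FALSE)
    new_alleles <- res$calls[res$calls$status != "known", ]
    new_alleles <- new_alleles[!duplicated(new_alleles$allele), ]
    if (nrow(new_alleles)) {
      x <- Biostrings::DNAStringSet(new_alleles$sequence)
      names(x) <- sprintf("%s locus=%s", new_alleles$allele, new_alleles$locus)
      Biostrings::writeXStringSet(x, file.path(out_dir, "new_alleles.fasta"))
    }
  })

  if ("genomewide" %in% config$stages) run_stage("genomewide", {
    retained <- ldPrune(res$geno, config$prune$window_sites,
                        config$prune$step_sites, config$prune$r2_max,
                        seed = seed + 4L)
    res$retained <- retained
    pruned <- GenotypeMatrix(genotypes(res$geno)[, retained, drop = FALSE],
                             siteInfo(res$geno)[retained, c("chrom", "pos")])
    res$K <- kingKinship(pruned)
    res$diversity_gw <- data.frame(
      individual = individuals(pruned),
      proportion_het = heterozygosity(pruned),
      stMLH = stMLH(pruned), row.names = NULL)
    write.csv(siteInfo(res$geno)[retained, c("chrom", "pos")],
              file.path(out_dir, "retained_sites.csv"), row.names = FALSE)
    write.csv(res$diversity_gw,
              file.path(out_dir, "genomewide_diversity.csv"),
              row.names = FALSE)
    write.csv(data.frame(id = individuals(res$K), kinship(res$K)),
              file.path(out_dir, "kinship.csv"), row.names = FALSE)
  })

  if ("supertype" %in% config$stages) run_stage("supertype", {
    uq <- res$calls[!duplicated(res$calls$allele), ]
    groupings <- list(
      classI = list(sel = uq$locus %in% c("A", "B"), frame = 0L),
      DQA = list(sel = uq$locus == "DQA", frame = MHC_FRAME[["DQA"]]),
      DRB = list(sel = uq$locus == "DRB", frame = MHC_FRAME[["DRB"]]))
    res$supertypes <- lapply(names(groupings), function(gr) {
      sel <- groupings[[gr]]$sel
      assignSupertypes(setNames(uq$sequence[sel], uq$allele[sel]),
                       frame = groupings[[gr]]$frame,
                       pss = config$supertype$pss[[gr]],
                       min_cluster_size = config$supertype$min_cluster_size,
                       min_gap_frac = config$supertype$min_gap_frac,
                       cut_frac = config$supertype$cut_frac,
                       fdr = config$supertype$fdr)
    })
    names(res$supertypes) <- names(groupings)
    st_df <- do.call(rbind, lapply(names(res$supertypes), function(gr)
      cbind(grouping = gr, res$supertypes[[gr]]@assignment)))
    write.csv(st_df, file.path(out_dir, "supertypes.csv"), row.names = FALSE)
    pss_df <- do.call(rbind, lapply(names(res$supertypes), function(gr)
      if (length(res$supertypes[[gr]]@pss))
        data.frame(grouping = gr, position = res$supertypes[[gr]]@pss)))
    write.csv(pss_df, file.path(out_dir, "pss.csv"), row.names = FALSE)
  })

  if ("diversity" %in% config$stages) run_stage("diversity", {
    st_sets <- lapply(res$supertypes, supertypes)
    res$indices <- heterozygosityIndices(res$calls, st_sets)
    res$indices$stMLH <- res$diversity_gw$stMLH[
      match(res$indices$individual, res$diversity_gw$individual)]
    res$dyads <- dyadComplementarity(res$calls, st_sets)
    phi <- kinship(res$K)
    res$dyads$kinship <- phi[cbind(res$dyads$id1, res$dyads$id2)]
    write.csv(res$indices, file.path(out_dir, "mhc_indices.csv"),
              row.names = FALSE)
    write.csv(res$dyads, file.path(out_dir, "dyad_complementarity.csv"),
              row.names = FALSE)
  })

  if ("stats" %in% config$stages) run_stage("stats", {
    res$models <- runAssociationModels(res$indices, res$K, res$dyads)
    write.csv(res$models, file.path(out_dir, "model_results.csv"),
              row.names = FALSE)
  })

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "mhcdiv",
    version = as.character(utils::packageVersion("mhcdiv")),
    seed = seed,
    stages = config$stages,
    parameters = list(sim = unclass(config$sim),
                      mhc = unclass(config$mhc),
                      filter = unclass(config$filter),
                      prune = config$prune,
                      supertype = config$supertype[c("min_cluster_size",
                                                     "min_gap_frac",
                                                     "cut_frac", "fdr")]),
    deviations = c(
      "PSS from builtin pairwise counting screen unless an external site list is supplied",
      "equal-length gap-free amplicons: multiple alignment reduces to column stacking"),
    files = lapply(setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .logStage("done", "outputs in ", out_dir)
  invisible(res)
}

#' Summarise a completed pipeline run
#'
#' Builds the bookkeeping tables a cohort report needs: per-locus
#' counts of previously described and newly identified alleles with a
#' column-summing total row, per-individual allele and supertype count
#' frequency distributions per class, and the association model table.
#'
#' @param run_dir directory written by [runPipeline()].
#' @return list of data.frames: `allele_counts`, `histograms`,
#'   `models`; also written as `report_*.csv` in `run_dir`.
#' @export
reportRun <- function(run_dir) {
  calls <- read.csv(file.path(run_dir, "mhc_calls.csv"),
                    stringsAsFactors = FALSE)
  uq <- calls[!duplicated(paste(calls$locus, calls$allele)), ]
  counts <- do.call(rbind, lapply(MHC_LOCI, function(loc) {
    here <- uq[uq$locus == loc, ]
    # rescued calls matching the catalog carry its name, so count by name
    known <- sum(!grepl("-new-", here$allele))
    data.frame(locus = loc, previously_described = known,
               newly_identified = nrow(here) - known, total = nrow(here))
  }))
  counts <- rbind(counts, data.frame(
    locus = "All", previously_described = sum(counts$previously_described),
    newly_identified = sum(counts$newly_identified),
    total = sum(counts$total)))
  idx_file <- file.path(run_dir, "mhc_indices.csv")
  hists <- NULL
  if (file.exists(idx_file)) {
    idx <- read.csv(idx_file, stringsAsFactors = FALSE)
    hvars <- c("n_alleles_classI", "n_alleles_classII",
               "n_supertypes_classI", "n_supertypes_classII")
    hists <- do.call(rbind, lapply(hvars, function(v) {
      tab <- table(idx[[v]])
      data.frame(index = v, value = as.integer(names(tab)),
                 n_individuals = as.integer(tab))
    }))
  }
  models_file <- file.path(run_dir, "model_results.csv")
  models <- if (file.exists(models_file))
    read.csv(models_file, stringsAsFactors = FALSE) else NULL
  write.csv(counts, file.path(run_dir, "report_allele_counts.csv"),
            row.names = FALSE)
  if (!is.null(hists))
    write.csv(hists, file.path(run_dir, "report_histograms.csv"),
              row.names = FALSE)
  list(allele_counts = counts, histograms = hists, models = models)
}
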