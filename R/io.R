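# File formats: catalog FASTA, amplicon FASTQ, genotype VCF/TSV.

#' Write a reference allele catalog as FASTA
#'
#' Headers are `>{name} locus={A|B|DQA|DRB}`.
#'
#' @param alleles data.frame with `name`, `locus`, `sequence` (e.g. the
#'   known subset of [simulateMhcTruth()]'s allele table).
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeCatalogFasta <- function(alleles, file) {
  x <- Biostrings::DNAStringSet(alleles$sequence)
  names(x) <- sprintf("%s locus=%s", alleles$name, alleles$locus)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read a reference allele catalog FASTA
#'
#' @param file FASTA with headers `>{name} locus={A|B|DQA|DRB}`.
#' @return data.frame: `name`, `locus`, `sequence`.
#' @export
readCatalogFasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  hdr <- names(x)
  name <- sub("\\s.*$", "", hdr)
  locus <- sub("^.*locus=(\\S+).*$", "\\1", hdr)
  if (any(!locus %in% MHC_LOCI))
    stop("catalog headers must carry locus={A|B|DQA|DRB}")
  data.frame(name = unname(name), locus = unname(locus),
             sequence = unname(as.character(x)), stringsAsFactors = FALSE)
}

#' Write an amplicon pool as gzipped FASTQ
#'
#' Reads are expanded from the collapsed pool; qualities are a constant
#' Q35 placeholder (quality trimming is out of scope). The file is
#' named `{individual}_{locus}.fastq.gz`.
#'
#' @param pool an [AmpliconPool-class].
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
writeAmpliconFastq <- function(pool, dir) {
  stopifnot(is(pool, "AmpliconPool"))
  file <- file.path(dir, sprintf("%s_%s.fastq.gz", pool@individual, pool@locus))
  seqs <- rep(pool@sequences, pool@copies)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s_%s_read%06d", pool@individual, pool@locus,
                      seq_along(seqs))
  quals <- Biostrings::BStringSet(strrep("D", nchar(seqs)))  # Phred+33 Q35
  Biostrings::writeXStringSet(x, file, format = "fastq", compress = TRUE,
                              qualities = quals)
  invisible(file)
}

#' Read an amplicon FASTQ into a collapsed pool
#'
#' @param file FASTQ(.gz) named `{individual}_{locus}.fastq(.gz)`;
#'   individual and locus are parsed from the name unless given.
#' @param individual,locus optional explicit labels.
#' @return An [AmpliconPool-class].
#' @export
readAmpliconFastq <- function(file, individual = NULL, locus = NULL) {
  base <- sub("\\.fastq(\\.gz)?$", "", basename(file))
  if (is.null(locus)) locus <- sub("^.*_", "", base)
  if (is.null(individual)) individual <- sub("_[^_]+$", "", base)
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  collapseReads(as.character(x), individual, locus)
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' GT-only records on synthetic coordinates (REF `A`, ALT `G`), enough
#' to round-trip genotypes through standard VCF tooling.
#'
#' @param g a [GenotypeMatrix-class].
#' @param file output path (plain text).
#' @return the path, invisibly.
#' @export
writeGenotypeVcf <- function(g, file) {
  calls <- genotypes(g)
  si <- siteInfo(g)
  gt <- matrix("./.", ncol(calls), nrow(calls))
  codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (i in seq_len(nrow(calls))) {
    x <- calls[i, ]
    gt[!is.na(x), i] <- codes[as.character(x[!is.na(x)])]
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(calls)), collapse = "\t")),
             con)
  body <- cbind(si$chrom, si$pos, sprintf("site%d", seq_len(ncol(calls))),
                "A", "G", ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(file)
}

#' Read genotypes from a VCF
#'
#' Parses diploid GT fields to 0/1/2 alternate-allele counts (missing
#' to `NA`).
#'
#' @param file VCF path.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeVcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("\\|", "/", gt)
  count <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & grepl("^[0-9]+/[0-9]+$", x)
    parts <- strsplit(x[ok], "/")
    out[ok] <- vapply(parts, function(p) sum(as.integer(p) > 0L), integer(1))
    out
  }
  m <- apply(gt, 2, count)
  calls <- t(m)
  colnames(calls) <- NULL
  sites <- data.frame(chrom = v@fix[, "CHROM"],
                      pos = as.integer(v@fix[, "POS"]))
  GenotypeMatrix(calls, sites)
}

#' Write / read a genotype matrix as TSV
#'
#' Plain individuals-by-sites table with ids in the first column.
#'
#' @param g a [GenotypeMatrix-class].
#' @param file path.
#' @return the path (write) or a [GenotypeMatrix-class] (read).
#' @export
writeGenotypeTsv <- function(g, file) {
  calls <- genotypes(g)
  df <- data.frame(id = rownames(calls), calls, check.names = FALSE)
  colnames(df)[-1] <- sprintf("site%d", seq_len(ncol(calls)))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeGenotypeTsv
#' @export
readGenotypeTsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df[[1]]
  GenotypeMatrix(calls)
}
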