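#' Read genotypes from a VCF file
#'
#' Consumes the GT field only. Biallelic SNP records are kept; multiallelic
#' or indel records are skipped with a warning. Phased (`|`) and unphased
#' (`/`) genotypes are treated identically; `./.` becomes `NA`.
#'
#' @param path path to a VCF 4.x file (plain or gzipped)
#' @param population optional named character vector (sample -> label) or a
#'   path to a two-column population map file; may also be attached later.
#'   When omitted, all samples get label `"unknown"`.
#' @return a [genotype_dataset()]
#' @export
read_vcf <- function(path, population = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # keep matrix shape even for a single record
  if (is.null(fix) || nrow(fix) == 0) stop("VCF contains no variant records")
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) stop("VCF contains no sample genotypes")
  samples <- colnames(gt)[-1]

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    warning(n_skip, " multiallelic/indel record(s) skipped")
  }
  if (!any(keep)) stop("VCF contains no biallelic SNP records")

  gtm <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # decode "0/1", "1|1", ... -> dosage; anything containing "." -> NA
  d <- suppressWarnings(as.integer(substr(gtm, 1, 1)) +
                          as.integer(substr(gtm, 3, 3)))
  G <- t(matrix(d, nrow = nrow(gtm)))  # samples x snps
  rownames(G) <- samples

  id <- fix[keep, "ID"]
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  id[is.na(id) | id == "."] <- paste0(chrom, ":", pos)[is.na(id) | id == "."]
  snps <- data.frame(chrom = chrom, pos = pos, snp_id = id,
                     ref = ref[keep], alt = alt[keep],
                     stringsAsFactors = FALSE)

  if (is.character(population) && length(population) == 1 &&
      file.exists(population)) {
    population <- read_pop_map(population)
  }
  if (is.null(population)) {
    population <- stats::setNames(rep("unknown", length(samples)), samples)
  }
  genotype_dataset(G, snps, population)
}

#' Write a genotype dataset to a VCF file
#'
#' Emits a minimal VCF 4.2 with the GT field only; missing genotypes are
#' written as `./.`. `read_vcf()` of the written file reproduces the
#' dataset (dosages, sample ids, SNP table).
#'
#' @param ds a [genotype_dataset()]
#' @param path output file path
#' @export
write_vcf <- function(ds, path) {
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  n <- length(ds$samples)
  m <- nrow(ds$snps)
  gt <- matrix("./.", nrow = m, ncol = n)
  idx <- !is.na(t(ds$G))
  gt[idx] <- gt_codes[as.character(t(ds$G))[idx]]
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples), collapse = "\t"))
  body <- paste(ds$snps$chrom, ds$snps$pos, ds$snps$snp_id,
                ds$snps$ref, ds$snps$alt, ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
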