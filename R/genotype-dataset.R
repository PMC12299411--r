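#' Construct a two-population genotype dataset
#'
#' The common currency of all scans in the package: an ordered set of samples
#' with population labels and a samples x SNPs matrix of alt-allele dosages.
#'
#' @param G integer matrix, samples in rows and SNPs in columns; entries must
#'   be 0, 1, 2 or `NA` (missing genotype).
#' @param snps data frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `snp_id`, `ref`, `alt`. Rows are reordered by
#'   `(chrom, pos)` together with the columns of `G`.
#' @param population named character vector mapping sample id to population
#'   label; names must cover `rownames(G)`. Downstream scans expect exactly
#'   two labels.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `samples`, `population`, `snps`, `G`.
#' @export
genotype_dataset <- function(G, snps, population) {
  if (!is.matrix(G)) G <- as.matrix(G)
  storage.mode(G) <- "integer"
  samples <- rownames(G)
  if (is.null(samples)) stop("G must have sample ids as rownames")
  req <- c("chrom", "pos", "snp_id", "ref", "alt")
  if (!all(req %in% names(snps))) {
    stop("snps must have columns: ", paste(req, collapse = ", "))
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (nrow(snps) != ncol(G)) stop("nrow(snps) must equal ncol(G)")
  if (any(snps$pos < 1)) stop("positions must be >= 1 (1-based VCF convention)")
  if (anyDuplicated(paste(snps$chrom, snps$pos))) {
    stop("duplicate (chrom, pos) in snps")
  }
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (!all(samples %in% names(population))) {
    stop("population labels missing for some samples")
  }
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  G <- G[, ord, drop = FALSE]
  colnames(G) <- snps$snp_id
  structure(
    list(samples = samples,
         population = population[samples],
         snps = snps,
         G = G),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  tab <- table(x$population)
  cat("genotype_dataset:", length(x$samples), "samples x",
      nrow(x$snps), "SNPs\n")
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  miss <- mean(is.na(x$G))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(length(x$samples), nrow(x$snps))

#' Population labels present in a dataset
#' @param ds a `genotype_dataset`
#' @return sorted character vector of unique labels
#' @export
pop_labels <- function(ds) sort(unique(unname(ds$population)))

#' Pooled alt-allele frequencies
#'
#' Computed over non-missing genotypes across all samples.
#'
#' @param ds a `genotype_dataset`
#' @return numeric vector, one frequency per SNP (NaN for all-missing SNPs)
#' @export
allele_freq <- function(ds) {
  colMeans(ds$G, na.rm = TRUE) / 2
}

# per-population allele frequency / het fraction / non-missing count,
# returned as lists keyed by population label
pop_site_stats <- function(ds) {
  labs <- pop_labels(ds)
  out <- lapply(labs, function(l) {
    Gp <- ds$G[ds$population == l, , drop = FALSE]
    n <- colSums(!is.na(Gp))
    list(n = n,
         p = colSums(Gp, na.rm = TRUE) / (2 * pmax(n, 1)),
         h = colSums(Gp == 1, na.rm = TRUE) / pmax(n, 1),
         alt = colSums(Gp, na.rm = TRUE))
  })
  names(out) <- labs
  out
}

#' Read a sample-to-population map
#'
#' Two whitespace- or tab-separated columns: sample id, population label.
#' No header.
#'
#' @param path file path
#' @return named character vector (names are sample ids)
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("sample", "population"))
  stats::setNames(df$population, df$sample)
}

#' Write a sample-to-population map
#' @param ds a `genotype_dataset`
#' @param path output file path
#' @export
write_pop_map <- function(ds, path) {
  utils::write.table(
    data.frame(sample = ds$samples, population = unname(ds$population)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
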