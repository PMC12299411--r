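#' Quality-control configuration
#'
#' @param sample_call_rate_min minimum fraction of non-missing genotypes a
#'   sample must have to be retained (samples strictly below are excluded);
#'   default 0.90.
#' @param maf_min minimum pooled minor allele frequency (SNPs strictly below
#'   are removed); default 0.05.
#' @return a `qc_config` list
#' @export
qc_config <- function(sample_call_rate_min = 0.90, maf_min = 0.05) {
  stopifnot(sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 maf_min = maf_min),
            class = "qc_config")
}

#' Merge two genotype datasets on shared SNPs
#'
#' Restricts to SNPs present in both inputs, matched on `(chrom, pos)`.
#' When a site's ref/alt alleles are swapped between the inputs, dosages in
#' the second dataset are flipped (`2 - g`). Sites whose allele pairs do not
#' match even after swapping are dropped (reported via a message).
#'
#' @param a,b `genotype_dataset` objects with disjoint sample ids, each
#'   carrying its own population labels
#' @return merged `genotype_dataset`
#' @export
merge_datasets <- function(a, b) {
  if (length(intersect(a$samples, b$samples)) > 0) {
    stop("sample id sets must be disjoint")
  }
  key_a <- paste(a$snps$chrom, a$snps$pos)
  key_b <- paste(b$snps$chrom, b$snps$pos)
  common <- intersect(key_a, key_b)
  if (length(common) == 0) stop("no SNPs in common between the datasets")
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  same <- a$snps$ref[ia] == b$snps$ref[ib] & a$snps$alt[ia] == b$snps$alt[ib]
  swap <- a$snps$ref[ia] == b$snps$alt[ib] & a$snps$alt[ia] == b$snps$ref[ib]
  drop_n <- sum(!(same | swap))
  if (drop_n > 0) {
    message(drop_n, " site(s) dropped: allele pairs do not match")
  }
  keep <- same | swap
  if (!any(keep)) stop("no SNPs in common between the datasets")
  ia <- ia[keep]; ib <- ib[keep]; swap <- swap[keep]
  Ga <- a$G[, ia, drop = FALSE]
  Gb <- b$G[, ib, drop = FALSE]
  if (any(swap)) {
    Gb[, swap] <- 2L - Gb[, swap, drop = FALSE]
  }
  G <- rbind(Ga, Gb)
  genotype_dataset(G, a$snps[ia, , drop = FALSE],
                   c(a$population, b$population))
}

#' Filter samples by genotype call rate
#'
#' Samples with a non-missing fraction strictly below
#' `cfg$sample_call_rate_min` are excluded.
#'
#' @param ds a `genotype_dataset`
#' @param cfg a [qc_config()]
#' @return filtered `genotype_dataset`
#' @export
filter_samples_by_call_rate <- function(ds, cfg = qc_config()) {
  cr <- rowMeans(!is.na(ds$G))
  keep <- cr >= cfg$sample_call_rate_min
  if (!any(keep)) stop("all samples removed by call-rate filter")
  genotype_dataset(ds$G[keep, , drop = FALSE], ds$snps,
                   ds$population[keep])
}

#' Filter SNPs by minor allele frequency
#'
#' MAF is computed on non-missing genotypes pooled over all samples; SNPs
#' with MAF strictly below `cfg$maf_min` are removed.
#'
#' @inheritParams filter_samples_by_call_rate
#' @return filtered `genotype_dataset`
#' @export
filter_snps_by_maf <- function(ds, cfg = qc_config()) {
  p <- allele_freq(ds)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing column: treat as monomorphic
  keep <- maf >= cfg$maf_min
  if (!any(keep)) stop("all SNPs removed by MAF filter")
  genotype_dataset(ds$G[, keep, drop = FALSE],
                   ds$snps[keep, , drop = FALSE], ds$population)
}

#' Impute missing genotypes
#'
#' A frequency-preserving stand-in for haplotype-based imputation. Mode
#' `"frequency_sample"` (default) draws each missing genotype from
#' Hardy-Weinberg proportions at the population-specific allele frequency;
#' it preserves the per-population allele frequencies that every downstream
#' statistic consumes. Mode `"major_allele"` fills with the most frequent
#' observed genotype at the SNP, pooled over populations.
#'
#' @param ds a `genotype_dataset`
#' @param mode `"frequency_sample"` or `"major_allele"`
#' @param seed integer seed making `"frequency_sample"` reproducible
#' @return `genotype_dataset` with no missing entries
#' @export
impute_missing <- function(ds, mode = c("frequency_sample", "major_allele"),
                           seed = 1L) {
  mode <- match.arg(mode)
  G <- ds$G
  if (!anyNA(G)) return(ds)
  if (mode == "major_allele") {
    for (j in which(colSums(is.na(G)) > 0)) {
      tab <- tabulate(G[, j] + 1L, nbins = 3L)
      G[is.na(G[, j]), j] <- which.max(tab) - 1L
    }
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    for (lab in unique(unname(ds$population))) {
      rows <- which(ds$population == lab)
      Gp <- G[rows, , drop = FALSE]
      nm <- is.na(Gp)
      if (!any(nm)) next
      p <- colSums(Gp, na.rm = TRUE) / (2 * pmax(colSums(!nm), 1))
      pj <- rep(p, each = length(rows))[nm]
      Gp[nm] <- stats::rbinom(sum(nm), 2L, pj)
      G[rows, ] <- Gp
    }
  }
  genotype_dataset(G, ds$snps, ds$population)
}

#' Run the full genotype quality-control pipeline
#'
#' Fixed order: merge (done upstream) -> sample call-rate filter ->
#' imputation -> MAF filter.
#'
#' @param ds merged `genotype_dataset`
#' @param cfg a [qc_config()]
#' @param impute_mode passed to [impute_missing()]
#' @param seed passed to [impute_missing()]
#' @return quality-controlled `genotype_dataset` with no missing entries
#' @export
qc_pipeline <- function(ds, cfg = qc_config(),
                        impute_mode = "frequency_sample", seed = 1L) {
  ds <- filter_samples_by_call_rate(ds, cfg)
  ds <- impute_missing(ds, impute_mode, seed)
  filter_snps_by_maf(ds, cfg)
}
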