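#' Per-site Weir-Cockerham F_ST for two populations
#'
#' The Weir & Cockerham (1984) theta estimator evaluated from per-population
#' diploid sample sizes, alt-allele frequencies and observed heterozygote
#' fractions. Vectorized over sites. Returns `NA` where the denominator
#' `a + b + c` is zero (e.g. both populations monomorphic for the same
#' allele). Negative estimates are retained.
#'
#' @param n1,n2 diploid sample counts (>= 1)
#' @param p1,p2 alt-allele frequencies in `[0, 1]`
#' @param h1,h2 observed heterozygote fractions in `[0, 1]`
#' @return numeric vector of theta estimates (with NA where undefined)
#' @export
wc_fst_site <- function(n1, p1, h1, n2, p2, h2) {
  if (any(n1 < 1) || any(n2 < 1)) stop("diploid counts must be >= 1")
  if (any(c(p1, p2, h1, h2) < 0) || any(c(p1, p2, h1, h2) > 1)) {
    stop("frequencies and heterozygote fractions must lie in [0, 1]")
  }
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  out <- a / denom
  out[denom == 0] <- NA_real_
  out
}

#' Z-score normalization with missing values
#'
#' Standardizes by the mean and standard deviation (denominator `n - 1`) of
#' the non-missing entries; missing entries stay missing.
#'
#' @param values numeric vector, possibly with `NA`
#' @return z-scores of the same length
#' @export
z_normalize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("zero standard deviation: z-scores undefined")
  (values - mean(values[ok])) / s
}

#' Per-site nucleotide diversity
#'
#' The average number of pairwise differences among all sampled alleles at
#' a biallelic site: `pi = 2 c (N - c) / (N (N - 1))` for `c` alt alleles
#' out of `N` total.
#'
#' @param alt_count alt-allele count(s), `0 <= alt_count <= allele_total`
#' @param allele_total total sampled alleles (>= 2)
#' @return numeric vector of diversity values
#' @export
site_pi <- function(alt_count, allele_total) {
  if (any(allele_total < 2)) stop("allele_total must be >= 2")
  if (any(alt_count < 0) || any(alt_count > allele_total)) {
    stop("alt_count must lie in [0, allele_total]")
  }
  2 * alt_count * (allele_total - alt_count) /
    (allele_total * (allele_total - 1))
}

#' Log2 ratio of nucleotide diversity
#'
#' `log2(pi1 / pi2)`; `NA` when either diversity is zero (such sites are
#' excluded from the ratio tail rather than pseudo-counted).
#'
#' @param pi1,pi2 nonnegative diversity values (pi1 is the numerator role)
#' @return numeric vector with NA where undefined
#' @export
log2_pi_ratio <- function(pi1, pi2) {
  out <- log2(pi1 / pi2)
  out[pi1 == 0 | pi2 == 0] <- NA_real_
  out
}

#' Joint top-tail selection of sweep loci
#'
#' Thresholds are the `1 - tail_fraction` quantiles (linear interpolation
#' between order statistics) of the non-missing `z_fst` values and of the
#' non-missing `|log2_ratio|` values. A locus is selected when its z(F_ST)
#' strictly exceeds the z threshold AND its absolute log2 pi-ratio strictly
#' exceeds the ratio threshold. Selected loci are assigned to the
#' lower-diversity population: the denominator-role population when
#' `log2_ratio > 0`, the numerator-role population when `< 0`.
#'
#' @param records data frame with columns `z_fst`, `log2_ratio` (as built
#'   by [sweep_scan()])
#' @param tail_fraction upper-tail mass defining both thresholds
#'   (default 0.05)
#' @param pop1,pop2 labels of the numerator-role and denominator-role
#'   populations
#' @return `records` with `selected` and `selected_pop` columns filled,
#'   plus attributes `z_threshold` and `ratio_threshold`
#' @export
select_loci <- function(records, tail_fraction = 0.05,
                        pop1 = "pop1", pop2 = "pop2") {
  ok <- !is.na(records$z_fst) & !is.na(records$log2_ratio)
  if (sum(ok) < 20) {
    stop("fewer than 20 records with both statistics: quantiles unstable")
  }
  zthr <- stats::quantile(records$z_fst[!is.na(records$z_fst)],
                          1 - tail_fraction, names = FALSE)
  rthr <- stats::quantile(abs(records$log2_ratio[!is.na(records$log2_ratio)]),
                          1 - tail_fraction, names = FALSE)
  sel <- !is.na(records$z_fst) & !is.na(records$log2_ratio) &
    records$z_fst > zthr & abs(records$log2_ratio) > rthr
  records$selected <- sel
  records$selected_pop <- NA_character_
  records$selected_pop[sel & records$log2_ratio > 0] <- pop2
  records$selected_pop[sel & records$log2_ratio < 0] <- pop1
  attr(records, "z_threshold") <- zthr
  attr(records, "ratio_threshold") <- rthr
  records
}

#' Selective-sweep scan combining z(F_ST) and the log2 pi-ratio
#'
#' Computes the per-site Weir-Cockerham F_ST between the two populations,
#' z-normalizes it genome-wide, computes per-population nucleotide
#' diversity and its log2 ratio, and flags loci in the joint top
#' `tail_fraction` tails, assigning each to the population with eroded
#' diversity.
#'
#' @param ds a `genotype_dataset` with exactly two population labels
#' @param numerator population label used as the pi-ratio numerator;
#'   defaults to the alphabetically-first label
#' @param tail_fraction upper-tail mass for both selection thresholds
#'   (default 0.05)
#' @return object of class `sweep_scan`: list with `records` (chrom, pos,
#'   snp_id, fst, z_fst, pi_pop1, pi_pop2, log2_ratio, selected,
#'   selected_pop), `numerator`, `denominator`, `tail_fraction`,
#'   `z_threshold`, `ratio_threshold`
#' @export
sweep_scan <- function(ds, numerator = NULL, tail_fraction = 0.05) {
  labs <- pop_labels(ds)
  if (length(labs) != 2) stop("sweep_scan needs exactly two populations")
  if (is.null(numerator)) numerator <- labs[1]
  if (!numerator %in% labs) stop("numerator must be one of: ",
                                 paste(labs, collapse = ", "))
  denominator <- setdiff(labs, numerator)

  st <- pop_site_stats(ds)
  s1 <- st[[numerator]]
  s2 <- st[[denominator]]
  fst <- wc_fst_site(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  z_fst <- z_normalize(fst)
  pi1 <- site_pi(s1$alt, 2 * s1$n)
  pi2 <- site_pi(s2$alt, 2 * s2$n)
  ratio <- log2_pi_ratio(pi1, pi2)

  records <- data.frame(
    chrom = ds$snps$chrom, pos = ds$snps$pos, snp_id = ds$snps$snp_id,
    fst = fst, z_fst = z_fst, pi_pop1 = pi1, pi_pop2 = pi2,
    log2_ratio = ratio, stringsAsFactors = FALSE)
  records <- select_loci(records, tail_fraction,
                         pop1 = numerator, pop2 = denominator)

  structure(list(records = records, numerator = numerator,
                 denominator = denominator, tail_fraction = tail_fraction,
                 z_threshold = attr(records, "z_threshold"),
                 ratio_threshold = attr(records, "ratio_threshold")),
            class = "sweep_scan")
}

#' Aggregate sweep-selection counts
#'
#' @param records a `sweep_scan` object or its `records` data frame
#' @return list with `n_sites`, `n_selected` and `per_population` counts
#' @export
sweep_summary <- function(records) {
  if (inherits(records, "sweep_scan")) records <- records$records
  per_pop <- table(records$selected_pop[records$selected])
  list(n_sites = nrow(records),
       n_selected = sum(records$selected),
       per_population = stats::setNames(as.integer(per_pop),
                                        names(per_pop)))
}

#' @export
print.sweep_scan <- function(x, ...) {
  s <- sweep_summary(x)
  cat(sprintf("sweep_scan: %d sites, tail fraction %.2f\n",
              s$n_sites, x$tail_fraction))
  cat(sprintf("  pi-ratio orientation: log2(pi[%s] / pi[%s])\n",
              x$numerator, x$denominator))
  cat(sprintf("  thresholds: z(F_ST) > %.3f, |log2 ratio| > %.3f\n",
              x$z_threshold, x$ratio_threshold))
  cat(sprintf("  selected: %d (%s)\n", s$n_selected,
              paste(sprintf("%s: %d", names(s$per_population),
                            s$per_population), collapse = ", ")))
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) sweep_summary(object)

#' @export
as.data.frame.sweep_scan <- function(x, ...) x$records

#' Export sweep results as TSV and a JSON summary
#'
#' @param scan a [sweep_scan()] object
#' @param path base path; writes `<path>.tsv` and `<path>_summary.json`
#' @return invisibly, the paths written
#' @export
export_sweep <- function(scan, path) {
  tsv <- paste0(path, ".tsv")
  utils::write.table(scan$records, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- sweep_summary(scan)
  js <- paste0(path, "_summary.json")
  jsonlite::write_json(
    list(n_sites = s$n_sites, n_selected = s$n_selected,
         per_population = as.list(s$per_population),
         numerator = scan$numerator),
    js, auto_unbox = TRUE)
  invisible(c(tsv, js))
}
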