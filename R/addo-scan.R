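#' Bonferroni genome-wide significance threshold
#'
#' @param n_snps total number of SNPs tested (>= 1)
#' @param alpha family-wise error rate (default 0.05)
#' @return `alpha / n_snps`
#' @export
bonferroni_threshold <- function(n_snps, alpha = 0.05) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  alpha / n_snps
}

#' Orthogonalize a dominance column against its additive column
#'
#' Returns the least-squares residual of `d` on `x`,
#' `d - x (x'd / x'x)`, computed through a rank-revealing QR factorization.
#' When `x` is the zero vector, `d` is returned unchanged.
#'
#' @param x additive coding column
#' @param d dominance coding column of the same length
#' @return numeric vector orthogonal to `x` (within 1e-10)
#' @export
orthogonalize_dominance <- function(x, d) {
  stopifnot(length(x) == length(d))
  sxx <- sum(x * x)
  if (sxx == 0) return(d)
  qr_x <- qr(matrix(x, ncol = 1))
  d - qr.fitted(qr_x, d)
}

#' Additive/dominance nested-model association scan
#'
#' For each SNP, three nested least-squares models of the surrogate
#' phenotype are compared: M0 (intercept only), MA (intercept + centered
#' additive dosage) and MAD (intercept + additive + dominance residualized
#' on the additive column). `p_add` is the F-test of MA against M0 with
#' (1, n-2) degrees of freedom; `p_dom` the F-test of MAD against MA with
#' (1, n-3). In `"gls"` mode the response and all design columns are first
#' whitened by the inverse Cholesky factor of
#' `V = sigma2_a K_a + sigma2_d K_d + sigma2_e I`, so the F-tests account
#' for the fitted covariance structure; `"ols"` mode regresses on the raw
#' columns.
#'
#' @param y phenotype vector (typically [surrogate_phenotype()])
#' @param ds a `genotype_dataset` with no missing genotypes
#' @param vc a [reml_fit()] result; required in `"gls"` mode
#' @param K kinship matrices (see [kinship_matrices()]); required in
#'   `"gls"` mode
#' @param mode `"gls"` (default) or `"ols"`
#' @param alpha family-wise error rate for the Bonferroni threshold
#' @return object of class `addo_scan`: list with `records` (data frame of
#'   per-SNP chrom, pos, snp_id, beta_add, beta_dom, p_add, p_dom, sig_add,
#'   sig_dom), `threshold`, `mode`, `n`, `m`
#' @export
addo_scan <- function(y, ds, vc = NULL, K = NULL,
                      mode = c("gls", "ols"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (anyNA(ds$G)) stop("missing genotypes: run qc_pipeline() first")
  n <- length(y)
  if (n != length(ds$samples)) stop("length(y) must match the sample count")
  m <- nrow(ds$snps)

  X <- additive_design(ds)
  D <- dominance_design(ds)
  ones <- rep(1, n)

  if (mode == "gls") {
    if (is.null(vc) || is.null(K)) {
      stop("gls mode requires variance components (vc) and kinships (K)")
    }
    V <- vc$sigma2_a * K$K_a + vc$sigma2_d * K$K_d + vc$sigma2_e * diag(n)
    L <- t(chol(V))  # V = L L'
    y <- forwardsolve(L, y)
    X <- forwardsolve(L, X)
    D <- forwardsolve(L, D)
    ones <- forwardsolve(L, rep(1, n))
  }

  # residualize everything on the (possibly whitened) intercept
  proj1 <- function(M) M - tcrossprod(ones, crossprod(M, ones)) / sum(ones^2)
  yt <- as.vector(proj1(matrix(y, ncol = 1)))
  Xt <- proj1(X)
  Dt <- proj1(D)

  rss0 <- sum(yt^2)
  sxx <- colSums(Xt^2)
  sxy <- as.vector(crossprod(Xt, yt))
  poly_x <- sxx > 1e-12 * n
  beta_add <- ifelse(poly_x, sxy / sxx, NA_real_)
  rss_a <- rss0 - ifelse(poly_x, sxy^2 / sxx, 0)
  rss_a <- pmax(rss_a, 0)

  # dominance column orthogonalized against the additive column
  sxd <- colSums(Xt * Dt)
  Dp <- Dt - sweep(Xt, 2, ifelse(poly_x, sxd / sxx, 0), `*`)
  sdd <- colSums(Dp^2)
  sdy <- as.vector(crossprod(Dp, yt))
  poly_d <- sdd > 1e-10 * pmax(colSums(Dt^2), 1e-300)
  beta_dom <- ifelse(poly_d, sdy / sdd, NA_real_)
  rss_ad <- rss_a - ifelse(poly_d, sdy^2 / sdd, 0)
  rss_ad <- pmax(rss_ad, 0)

  f_add <- (rss0 - rss_a) / (rss_a / (n - 2))
  p_add <- stats::pf(f_add, 1, n - 2, lower.tail = FALSE)
  p_add[!poly_x] <- NA_real_
  f_dom <- (rss_a - rss_ad) / (rss_ad / (n - 3))
  p_dom <- stats::pf(f_dom, 1, n - 3, lower.tail = FALSE)
  p_dom[!poly_d | !poly_x] <- NA_real_

  thr <- bonferroni_threshold(m, alpha)
  records <- data.frame(
    chrom = ds$snps$chrom, pos = ds$snps$pos, snp_id = ds$snps$snp_id,
    beta_add = beta_add, beta_dom = beta_dom,
    p_add = p_add, p_dom = p_dom,
    sig_add = !is.na(p_add) & p_add <= thr,
    sig_dom = !is.na(p_dom) & p_dom <= thr,
    stringsAsFactors = FALSE)

  structure(list(records = records, threshold = thr, mode = mode,
                 n = n, m = m, vc = vc, alpha = alpha),
            class = "addo_scan")
}

#' @export
print.addo_scan <- function(x, ...) {
  cat(sprintf("addo_scan (%s mode): %d samples, %d SNPs\n",
              x$mode, x$n, x$m))
  cat(sprintf("  Bonferroni threshold: %.3g\n", x$threshold))
  cat(sprintf("  significant: %d additive, %d dominance\n",
              sum(x$records$sig_add), sum(x$records$sig_dom)))
  invisible(x)
}

#' @export
summary.addo_scan <- function(object, ...) {
  r <- object$records
  out <- list(n = object$n, m = object$m, mode = object$mode,
              threshold = object$threshold,
              n_sig_add = sum(r$sig_add), n_sig_dom = sum(r$sig_dom),
              n_sig_both = sum(r$sig_add & r$sig_dom),
              n_dom_only = sum(r$sig_dom & !r$sig_add))
  if (!is.null(object$vc) && !object$vc$degenerate) {
    out$share_add <- object$vc$share_add
    out$share_dom <- object$vc$share_dom
  }
  class(out) <- "summary.addo_scan"
  out
}

#' @export
print.summary.addo_scan <- function(x, ...) {
  cat(sprintf("Nested additive/dominance scan (%s): %d SNPs, n = %d\n",
              x$mode, x$m, x$n))
  cat(sprintf("  threshold %.3g; %d additive and %d dominance loci (%d shared, %d dominance-only)\n",
              x$threshold, x$n_sig_add, x$n_sig_dom, x$n_sig_both,
              x$n_dom_only))
  if (!is.null(x$share_add)) {
    cat(sprintf("  variance shares: additive %.2f%%, dominance %.2f%%\n",
                x$share_add, x$share_dom))
  }
  invisible(x)
}

#' @export
as.data.frame.addo_scan <- function(x, ...) x$records

#' Significant SNP sets at a significance level
#'
#' Inclusive comparison (`p <= alpha`).
#'
#' @param records the `records` data frame of an [addo_scan()], or the scan
#'   object itself
#' @param alpha significance level (default: the scan's Bonferroni
#'   threshold)
#' @return list with character vectors `set_add`, `set_dom` of SNP ids
#' @export
significance_sets <- function(records, alpha = NULL) {
  if (inherits(records, "addo_scan")) {
    if (is.null(alpha)) alpha <- records$threshold
    records <- records$records
  }
  if (is.null(alpha)) stop("alpha required when passing a raw data frame")
  list(set_add = records$snp_id[!is.na(records$p_add) &
                                  records$p_add <= alpha],
       set_dom = records$snp_id[!is.na(records$p_dom) &
                                  records$p_dom <= alpha])
}

#' Export scan results as Manhattan and Q-Q tables
#'
#' The Manhattan table is the per-SNP record list sorted by (chrom, pos).
#' The Q-Q tables give, for each effect, observed -log10 p-values against
#' the expected quantiles `-log10((i - 0.5) / m)` for rank i.
#'
#' @param scan an [addo_scan()] object
#' @param path optional base path; writes `<path>_manhattan.tsv`,
#'   `<path>_qq_add.tsv`, `<path>_qq_dom.tsv` when given
#' @return invisibly, list of the three data frames
#' @export
export_scan <- function(scan, path = NULL) {
  r <- scan$records[order(scan$records$chrom, scan$records$pos), ]
  qq <- function(p) {
    p <- sort(p[!is.na(p)])
    mm <- length(p)
    data.frame(expected = -log10((seq_len(mm) - 0.5) / mm),
               observed = -log10(p))
  }
  out <- list(manhattan = r, qq_add = qq(r$p_add), qq_dom = qq(r$p_dom))
  if (!is.null(path)) {
    utils::write.table(out$manhattan, paste0(path, "_manhattan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$qq_add, paste0(path, "_qq_add.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$qq_dom, paste0(path, "_qq_dom.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
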