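#' Centered additive design matrix
#'
#' Column j is `g_j - 2 p_j`, with `p_j` the pooled alt-allele frequency, so
#' every column has mean zero. Monomorphic SNPs give zero columns (allowed;
#' reported in the `"monomorphic"` attribute).
#'
#' @param ds a `genotype_dataset` with no missing genotypes
#' @return n x m numeric matrix with attributes `p` (allele frequencies) and
#'   `monomorphic` (logical per-SNP flag)
#' @export
additive_design <- function(ds) {
  if (anyNA(ds$G)) stop("missing genotypes: impute before building designs")
  p <- colMeans(ds$G) / 2
  Z <- sweep(ds$G + 0, 2, 2 * p)
  attr(Z, "p") <- p
  attr(Z, "monomorphic") <- p == 0 | p == 1
  Z
}

#' Centered dominance design matrix
#'
#' Column j is `h_j - 2 p_j q_j`, the heterozygote indicator centered at its
#' Hardy-Weinberg expectation. The column mean is zero exactly when genotype
#' proportions are at HWE.
#'
#' @inheritParams additive_design
#' @return n x m numeric matrix with attributes `p` and `monomorphic`
#' @export
dominance_design <- function(ds) {
  if (anyNA(ds$G)) stop("missing genotypes: impute before building designs")
  p <- colMeans(ds$G) / 2
  H <- (ds$G == 1) + 0
  W <- sweep(H, 2, 2 * p * (1 - p))
  attr(W, "p") <- p
  attr(W, "monomorphic") <- p == 0 | p == 1
  W
}

#' Additive genomic relationship matrix
#'
#' VanRaden method-1 scaling: `K_a = Z Z' / (2 sum_j p_j q_j)`.
#'
#' @param Z_a matrix from [additive_design()] (carries the frequency vector)
#' @return n x n symmetric matrix of class `matrix`
#' @export
additive_grm <- function(Z_a) {
  p <- attr(Z_a, "p")
  if (is.null(p)) stop("Z_a must come from additive_design()")
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all SNPs monomorphic: additive GRM undefined")
  K <- tcrossprod(Z_a) / denom
  dimnames(K) <- list(rownames(Z_a), rownames(Z_a))
  K
}

#' Dominance genomic relationship matrix
#'
#' `K_d = W W' / sum_j 2 p_j q_j (1 - 2 p_j q_j)`, the HWE variance of the
#' centered heterozygosity coding.
#'
#' @param W_d matrix from [dominance_design()]
#' @return n x n symmetric matrix
#' @export
dominance_grm <- function(W_d) {
  p <- attr(W_d, "p")
  if (is.null(p)) stop("W_d must come from dominance_design()")
  twopq <- 2 * p * (1 - p)
  denom <- sum(twopq * (1 - twopq))
  if (denom == 0) stop("all SNPs monomorphic: dominance GRM undefined")
  K <- tcrossprod(W_d) / denom
  dimnames(K) <- list(rownames(W_d), rownames(W_d))
  K
}

#' Additive and dominance kinships from a dataset
#'
#' Convenience wrapper building both relationship matrices.
#'
#' @param ds a `genotype_dataset` with no missing genotypes
#' @return list with elements `K_a`, `K_d`
#' @export
kinship_matrices <- function(ds) {
  list(K_a = additive_grm(additive_design(ds)),
       K_d = dominance_grm(dominance_design(ds)))
}

#' Export a relationship matrix as square text
#' @param K square matrix with sample-id dimnames
#' @param path output file path
#' @export
write_grm <- function(K, path) {
  utils::write.table(format(K, digits = 10), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
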