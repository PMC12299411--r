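#' Principal component analysis of an additive GRM
#'
#' Eigendecomposition of the additive relationship matrix. Component scores
#' are eigenvectors scaled by the square root of their eigenvalues, and the
#' variance explained by each component is its eigenvalue divided by the
#' trace of the matrix. The sign of PC1 is fixed so that the mean score of
#' the alphabetically-first population label is negative, making downstream
#' effect signs reproducible.
#'
#' @param K_a symmetric additive GRM
#' @param k number of components to retain (default 10, capped at n)
#' @param population optional named vector of population labels used for the
#'   PC1 sign convention (and attached to the result)
#' @return object of class `grm_pca`: list with `eigenvalues` (all n,
#'   descending), `var_explained` (fractions of the trace for the retained
#'   k), `scores` (n x k), `pc1`, `population`
#' @export
grm_pca <- function(K_a, k = 10, population = NULL) {
  n <- nrow(K_a)
  if (k > n) stop("k must not exceed the number of samples")
  e <- eigen(K_a, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  tr <- sum(diag(K_a))
  k <- min(k, n)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k)
  rownames(scores) <- rownames(K_a)
  colnames(scores) <- paste0("PC", seq_len(k))
  if (!is.null(population)) {
    ids <- rownames(K_a)
    pop <- if (!is.null(ids) && !is.null(names(population)))
      population[ids] else population
    first <- sort(unique(unname(pop)))[1]
    if (mean(scores[pop == first, 1]) > 0) scores[, 1] <- -scores[, 1]
  }
  structure(
    list(eigenvalues = lam,
         var_explained = lam[seq_len(k)] / tr,
         scores = scores,
         pc1 = scores[, 1],
         population = population),
    class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  cat("grm_pca:", length(x$pc1), "samples,",
      ncol(x$scores), "components retained\n")
  ve <- x$var_explained[seq_len(min(3, length(x$var_explained)))]
  cat("  var explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve),
            collapse = ", "), "\n")
  invisible(x)
}

#' Standardized PC1 surrogate phenotype
#'
#' PC1 centered to mean zero and scaled to unit variance, ready for use as
#' the response of the association scan. Standardizing makes the estimated
#' variance-component shares scale-free.
#'
#' @param pca a [grm_pca()] result
#' @return numeric vector named by sample id
#' @export
surrogate_phenotype <- function(pca) {
  y <- pca$pc1
  stats::setNames(as.vector(scale(y)), names(y))
}

#' Export PCA scores as TSV
#'
#' Writes sample, population and the retained component scores, with the
#' variance explained recorded in a header comment.
#'
#' @param pca a [grm_pca()] result
#' @param path output file path
#' @export
write_pca <- function(pca, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# var_explained: ",
                    paste(sprintf("%.6f", pca$var_explained),
                          collapse = " ")), con)
  df <- data.frame(sample = rownames(pca$scores),
                   population = if (is.null(pca$population)) NA_character_
                                else unname(pca$population[rownames(pca$scores)]),
                   pca$scores, check.names = FALSE)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}
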