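#' Multifactor ANOVA of a litter trait on genotype and environment
#'
#' Fits a fixed-effects linear model of the response on the listed factors
#' (all treated as categorical) and reports Type II sums of squares, which
#' are order-invariant for main-effects models. Repeated litters per sow
#' enter as independent records; the resulting sow-level pseudo-replication
#' is a documented caveat of this design.
#'
#' @param tbl data frame of phenotype records; must contain `response` and
#'   every factor in `factors`
#' @param response name of the response column (e.g. `"TNB"` or `"NBA"`)
#' @param factors character vector of factor column names, genotype first
#'   by convention
#' @return object of class `pheno_anova`: the per-factor table (factor, df,
#'   sum_sq, F, p) plus `residual_df`, `residual_ss`, `model`
#' @export
anova_fit <- function(tbl, response, factors) {
  stopifnot(response %in% names(tbl), all(factors %in% names(tbl)))
  if (anyNA(tbl[[response]])) stop("missing responses not allowed")
  if ("genotype" %in% factors &&
      length(unique(tbl$genotype)) < 2) {
    stop("need at least 2 genotype levels")
  }
  dat <- tbl
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  fml <- stats::reformulate(factors, response = response)
  fit <- stats::lm(fml, data = dat)

  al <- stats::alias(fit)
  if (!is.null(al$Complete)) {
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(al$Complete), collapse = ", "))
  }

  if (stats::var(dat[[response]]) == 0) {
    tab <- data.frame(factor = factors, df = NA_integer_,
                      sum_sq = 0, F = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    warning("constant response: model sum of squares is zero")
    return(structure(list(table = tab, residual_df = stats::df.residual(fit),
                          residual_ss = 0, model = fit,
                          constant_response = TRUE),
                     class = "pheno_anova"))
  }

  a2 <- car::Anova(fit, type = 2)
  rn <- rownames(a2)
  resid_row <- rn == "Residuals"
  tab <- data.frame(factor = rn[!resid_row],
                    df = a2$Df[!resid_row],
                    sum_sq = a2$`Sum Sq`[!resid_row],
                    F = a2$`F value`[!resid_row],
                    p = a2$`Pr(>F)`[!resid_row],
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 residual_df = a2$Df[resid_row],
                 residual_ss = a2$`Sum Sq`[resid_row],
                 model = fit, constant_response = FALSE),
            class = "pheno_anova")
}

#' @export
print.pheno_anova <- function(x, ...) {
  cat("Multifactor ANOVA (Type II sums of squares)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Residuals: df = %d, SS = %.4g\n",
              x$residual_df, x$residual_ss))
  invisible(x)
}

# insertion-absorption compact letter display from a pairwise significance
# matrix: groups sharing no letter differ significantly, groups sharing a
# letter do not
cld_from_pairs <- function(groups, sig_pair) {
  cols <- list(groups)  # start: one letter covering every group
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!sig_pair[i, j]) next
    gi <- groups[i]; gj <- groups[j]
    for (ci in seq_along(cols)) {
      if (gi %in% cols[[ci]] && gj %in% cols[[ci]]) {
        # insertion: split the offending letter column
        cols[[length(cols) + 1]] <- setdiff(cols[[ci]], gi)
        cols[[ci]] <- setdiff(cols[[ci]], gj)
      }
    }
    # absorption: drop empty columns, duplicates and proper subsets
    cols <- cols[lengths(cols) > 0]
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a == b || !keep[a] || !keep[b]) next
        if (all(cols[[a]] %in% cols[[b]]) &&
            (length(cols[[a]]) < length(cols[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    cols <- cols[keep]
  }
  letters_out <- stats::setNames(vector("list", k), groups)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) {
      letters_out[[g]] <- c(letters_out[[g]], letters[ci])
    }
  }
  lapply(letters_out, function(l) sort(unique(l)))
}

#' Genotype group means with a compact letter display
#'
#' All pairwise genotype comparisons by Welch (unequal-variance) t-tests at
#' level `alpha`; the compact letter display assigns letters so that two
#' genotype groups share a letter if and only if they were not declared
#' significantly different. Groups of size 1 are excluded with a warning.
#'
#' @param tbl phenotype data frame with a `genotype` column
#' @param response response column name
#' @param alpha pairwise significance level (default 0.05)
#' @return object of class `group_letters`: data frame with `genotype`,
#'   `mean`, `n`, `letters`, plus the pairwise p-value matrix in
#'   `attr(, "p_matrix")`
#' @export
group_letters <- function(tbl, response, alpha = 0.05) {
  stopifnot("genotype" %in% names(tbl), response %in% names(tbl))
  split_y <- split(tbl[[response]], tbl$genotype)
  sizes <- lengths(split_y)
  if (any(sizes < 2)) {
    warning("excluding genotype group(s) of size 1: ",
            paste(names(split_y)[sizes < 2], collapse = ", "))
    split_y <- split_y[sizes >= 2]
  }
  groups <- names(split_y)
  k <- length(groups)
  if (k < 2) stop("need at least 2 genotype groups of size >= 2")

  pm <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    p <- tryCatch(stats::t.test(split_y[[i]], split_y[[j]])$p.value,
                  error = function(e) 1)
    if (is.na(p)) p <- 1  # e.g. both groups essentially constant and equal
    pm[i, j] <- pm[j, i] <- p
  }
  sig <- !is.na(pm) & pm < alpha
  cld <- cld_from_pairs(groups, sig)

  out <- data.frame(genotype = groups,
                    mean = vapply(split_y, mean, 0),
                    n = as.integer(lengths(split_y)),
                    letters = vapply(cld, paste, "", collapse = ""),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "p_matrix") <- pm
  attr(out, "alpha") <- alpha
  class(out) <- c("group_letters", "data.frame")
  out
}

#' @export
print.group_letters <- function(x, ...) {
  cat("Genotype group means (letters: groups sharing none differ, p <",
      attr(x, "alpha"), ")\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
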