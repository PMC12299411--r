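# Restricted maximum likelihood for the two-kinship mixed model
#   y = 1*b + u_a + u_d + e,   u_a ~ N(0, K_a s2_a),  u_d ~ N(0, K_d s2_d),
#   e ~ N(0, I s2_e)
# fitted by average-information REML with EM fallback steps and variances
# bounded below at (effectively) zero.

reml_loglik <- function(y, X, V) {
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(list(ll = -Inf))
  Vinv <- chol2inv(cV)
  XtVinv <- crossprod(X, Vinv)
  XtVinvX <- XtVinv %*% X
  cX <- chol(XtVinvX)
  P <- Vinv - t(XtVinv) %*% chol2inv(cX) %*% XtVinv
  Py <- P %*% y
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                  sum(y * Py))
  list(ll = as.numeric(ll), P = P, Py = Py)
}

#' REML variance components under additive + dominance kinships
#'
#' Estimates `(sigma2_a, sigma2_d, sigma2_e)` maximizing the restricted
#' likelihood of `y ~ N(1 b, sigma2_a K_a + sigma2_d K_d + sigma2_e I)` by
#' average-information iterations (with EM fallback when an AI step is not
#' accepted). Variances are bounded below at zero. Convergence is declared
#' when successive restricted log-likelihoods differ by less than `tol`.
#'
#' When `K_a`, `K_d` and the identity are (numerically) linearly dependent —
#' e.g. both kinships equal to the identity — the variance decomposition is
#' unidentifiable; the fit is returned with `degenerate = TRUE` rather than
#' reporting arbitrary values.
#'
#' @param y numeric phenotype vector (e.g. the standardized PC1 surrogate)
#' @param K list with elements `K_a` and `K_d` (see [kinship_matrices()])
#' @param tol convergence tolerance on the restricted log-likelihood
#'   (default 1e-6)
#' @param max_iter maximum iterations (default 200); non-convergence is an
#'   error carrying the last iterate in its `condition$last` field
#' @return object of class `reml_fit`: list with `sigma2_a`, `sigma2_d`,
#'   `sigma2_e`, `share_add`, `share_dom` (percent of genetic variance),
#'   `loglik`, `iterations`, `converged`, `degenerate`
#' @export
reml_fit <- function(y, K, tol = 1e-6, max_iter = 200) {
  K_a <- K$K_a; K_d <- K$K_d
  n <- length(y)
  stopifnot(nrow(K_a) == n, nrow(K_d) == n)
  X <- matrix(1, n, 1)

  # identifiability: Gram matrix of vec(K_a), vec(K_d), vec(I)
  Ks <- list(K_a, K_d, diag(n))
  Gm <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    Gm[i, j] <- Gm[j, i] <- sum(Ks[[i]] * Ks[[j]])
  }
  if (rcond(Gm) < 1e-10) {
    warning("kinship matrices are linearly dependent: ",
            "variance decomposition is unidentifiable")
    return(structure(list(sigma2_a = NA_real_, sigma2_d = NA_real_,
                          sigma2_e = stats::var(y), share_add = NA_real_,
                          share_dom = NA_real_, loglik = NA_real_,
                          iterations = 0L, converged = FALSE,
                          degenerate = TRUE),
                     class = "reml_fit"))
  }

  vy <- stats::var(y)
  lb <- 1e-8 * vy
  theta <- rep(vy / 3, 3)
  cur <- reml_loglik(y, X, theta[1] * K_a + theta[2] * K_d +
                       theta[3] * diag(n))
  if (!is.finite(cur$ll)) stop("initial variance matrix not positive definite")

  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    P <- cur$P; Py <- cur$Py
    KPy <- list(K_a %*% Py, K_d %*% Py, Py)
    grad <- numeric(3)
    trPK <- c(sum(P * K_a), sum(P * K_d), sum(diag(P)))
    for (i in 1:3) grad[i] <- -0.5 * (trPK[i] - sum(Py * KPy[[i]]))
    AI <- matrix(0, 3, 3)
    PKPy <- lapply(KPy, function(v) P %*% v)
    for (i in 1:3) for (j in i:3) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    }

    # active set: components held at the floor with a negative gradient are
    # constrained out of the AI system (a joint step through the boundary is
    # not an ascent direction)
    free <- theta > 2 * lb | grad > 0
    if (!any(free)) free <- rep(TRUE, 3)
    step <- numeric(3)
    sol <- tryCatch(solve(AI[free, free, drop = FALSE], grad[free]),
                    error = function(e) NULL)
    if (!is.null(sol)) step[free] <- sol
    accepted <- FALSE
    if (!is.null(sol)) {
      for (h in 0:15) {
        cand <- pmax(theta + step / 2^h, lb)
        new <- reml_loglik(y, X, cand[1] * K_a + cand[2] * K_d +
                             cand[3] * diag(n))
        if (is.finite(new$ll) && new$ll >= cur$ll - 1e-10) {
          accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) {
      # EM-REML step: monotone but slow; used when AI is unusable
      cand <- pmax(theta + theta^2 *
                     (vapply(1:3, function(i) sum(Py * KPy[[i]]),
                             0) - trPK) / n, lb)
      new <- reml_loglik(y, X, cand[1] * K_a + cand[2] * K_d +
                           cand[3] * diag(n))
      if (!is.finite(new$ll)) break
    }
    delta <- abs(new$ll - cur$ll)
    theta <- cand
    cur <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  if (!converged) {
    cond <- simpleError(sprintf(
      "REML did not converge in %d iterations", max_iter))
    cond$last <- list(sigma2 = theta, loglik = cur$ll)
    stop(cond)
  }

  theta[theta <= 2 * lb] <- 0
  sg <- theta[1] + theta[2]
  structure(list(sigma2_a = theta[1], sigma2_d = theta[2],
                 sigma2_e = theta[3],
                 share_add = if (sg > 0) 100 * theta[1] / sg else NA_real_,
                 share_dom = if (sg > 0) 100 * theta[2] / sg else NA_real_,
                 loglik = cur$ll, iterations = it, converged = TRUE,
                 degenerate = FALSE),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("reml_fit (additive + dominance kinships)\n")
  if (x$degenerate) {
    cat("  DEGENERATE: kinships unidentifiable; no decomposition reported\n")
    return(invisible(x))
  }
  cat(sprintf("  sigma2_a = %.4g, sigma2_d = %.4g, sigma2_e = %.4g\n",
              x$sigma2_a, x$sigma2_d, x$sigma2_e))
  if (!is.na(x$share_add)) {
    cat(sprintf("  genetic-variance shares: additive %.2f%%, dominance %.2f%%\n",
                x$share_add, x$share_dom))
  }
  cat(sprintf("  logLik = %.4f after %d iteration(s)\n", x$loglik,
              x$iterations))
  invisible(x)
}

#' Percent shares of genetic variance
#'
#' @param vc a [reml_fit()] result, or any list with `sigma2_a`, `sigma2_d`
#' @return named numeric vector `c(share_add, share_dom)` summing to 100
#' @export
variance_shares <- function(vc) {
  sg <- vc$sigma2_a + vc$sigma2_d
  if (is.na(sg) || sg <= 0) stop("both genetic variances are zero")
  c(share_add = 100 * vc$sigma2_a / sg,
    share_dom = 100 * vc$sigma2_d / sg)
}
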