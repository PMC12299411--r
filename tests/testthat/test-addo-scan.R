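test_that("Bonferroni threshold divides alpha by the SNP count", {
  expect_equal(bonferroni_threshold(50), 1e-3)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("dominance orthogonalization removes the additive component", {
  x <- c(-1, 0, 1)
  d <- c(-0.5, 0.5, -0.5)
  expect_equal(orthogonalize_dominance(x, d), d)  # x'd = 0 already
  expect_equal(orthogonalize_dominance(x, x), rep(0, 3))
  set.seed(1)
  x2 <- stats::rnorm(50)
  d2 <- stats::rnorm(50)
  dp <- orthogonalize_dominance(x2, d2)
  expect_lt(abs(sum(dp * x2)), 1e-10)
  expect_equal(orthogonalize_dominance(x2, dp), dp)  # idempotent
  expect_equal(orthogonalize_dominance(rep(0, 5), 1:5), 1:5)
})

test_that("ols scan p-values match brute-force nested lm fits", {
  set.seed(55)
  ds <- bn_dataset(41, n1 = 15, n2 = 15, m = 20, fst = 0.2)
  y <- stats::rnorm(30) + as.numeric(ds$population == "pop2")
  sc <- addo_scan(y, ds, mode = "ols")
  X <- additive_design(ds)
  D <- dominance_design(ds)
  for (j in seq_len(20)) {
    x <- X[, j]
    if (sum(x^2) < 1e-12) next
    dp <- orthogonalize_dominance(x, stats::resid(stats::lm(D[, j] ~ x)))
    m0 <- stats::lm(y ~ 1)
    ma <- stats::lm(y ~ x)
    # square-of-t identity for the additive test
    tstat <- summary(ma)$coefficients["x", "t value"]
    fa <- stats::anova(m0, ma)
    expect_equal(sc$records$p_add[j], fa$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(fa$F[2], tstat^2, tolerance = 1e-10)
    if (sum(dp^2) > 1e-10) {
      mad <- stats::lm(y ~ x + dp)
      fd <- stats::anova(ma, mad)
      expect_equal(sc$records$p_dom[j], fd$`Pr(>F)`[2], tolerance = 1e-8)
      # nested-model residual sums of squares are monotone
      expect_lte(stats::deviance(mad), stats::deviance(ma) + 1e-12)
      expect_lte(stats::deviance(ma), stats::deviance(m0) + 1e-12)
    }
  }
})

test_that("gls mode with zero genetic variance reproduces ols", {
  ds <- bn_dataset(42, n1 = 40, n2 = 40, m = 100)
  y <- pc1_of(ds)
  K <- kinship_matrices(ds)
  vc0 <- structure(list(sigma2_a = 0, sigma2_d = 0, sigma2_e = 1,
                        degenerate = FALSE), class = "reml_fit")
  sc_gls <- addo_scan(y, ds, vc = vc0, K = K, mode = "gls")
  sc_ols <- addo_scan(y, ds, mode = "ols")
  expect_equal(sc_gls$records$p_add, sc_ols$records$p_add, tolerance = 1e-8)
  expect_equal(sc_gls$records$p_dom, sc_ols$records$p_dom, tolerance = 1e-8)
})

test_that("gls mode whitens by the fitted covariance", {
  ds <- bn_dataset(43, n1 = 50, n2 = 50, m = 150)
  y <- pc1_of(ds)
  K <- kinship_matrices(ds)
  vc <- reml_fit(y, K)
  sc <- addo_scan(y, ds, vc = vc, K = K, mode = "gls")
  expect_equal(nrow(sc$records), 150)
  expect_true(all(sc$records$p_add >= 0 & sc$records$p_add <= 1,
                  na.rm = TRUE))
})

test_that("planted frequency-divergent locus is detected below Bonferroni", {
  planted <- data.frame(index = 1001, p1 = 0.05, p2 = 0.95)
  ds <- bn_dataset(44, n1 = 150, n2 = 150, m = 2001,
                   planted_additive = planted)
  y <- pc1_of(ds)
  sc <- addo_scan(y, ds, mode = "ols")
  j <- match("snp_01001", sc$records$snp_id)
  expect_lt(sc$records$p_add[j], 0.05 / 2001)
  expect_true(sc$records$sig_add[j])
})

test_that("dominance-signature locus: significant p_dom but unremarkable z(F_ST)", {
  planted <- data.frame(index = 1001, allele_freq = 0.5,
                        het_frac_pop1 = 1, het_frac_pop2 = 0)
  ds <- bn_dataset(45, n1 = 150, n2 = 150, m = 2001,
                   planted_dominance = planted)
  y <- pc1_of(ds)
  sc <- addo_scan(y, ds, mode = "ols")
  j <- match("snp_01001", sc$records$snp_id)
  expect_lt(sc$records$p_dom[j], 0.05 / 2001)

  sw <- sweep_scan(ds)
  z <- sw$records$z_fst
  j2 <- match("snp_01001", sw$records$snp_id)
  expect_lt(z[j2], stats::quantile(z[-j2], 0.95, na.rm = TRUE))
})

test_that("additive column is population-blind at a dominance-signature locus, the orthogonalized dominance column is not", {
  planted <- data.frame(index = 1, allele_freq = 0.5,
                        het_frac_pop1 = 1, het_frac_pop2 = 0)
  ds <- bn_dataset(46, n1 = 200, n2 = 200, m = 50,
                   planted_dominance = planted)
  X <- additive_design(ds)
  D <- dominance_design(ds)
  dp <- orthogonalize_dominance(X[, 1], D[, 1])
  in1 <- ds$population == "pop1"
  # additive coding: near-identical distribution across populations
  expect_lt(abs(mean(X[in1, 1]) - mean(X[!in1, 1])), 0.15)
  # dominance residual: means separated by ~1 (het excess vs het deficit)
  expect_gt(abs(mean(dp[in1]) - mean(dp[!in1])), 0.85)
})

test_that("permuted phenotype gives calibrated additive type-I error", {
  ds <- bn_dataset(47, n1 = 150, n2 = 150, m = 2000)
  y <- pc1_of(ds)
  set.seed(470)
  y_perm <- sample(y)
  sc <- addo_scan(y_perm, ds, mode = "ols")
  rate <- mean(sc$records$p_add < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("significance sets use an inclusive threshold", {
  rec <- data.frame(snp_id = c("a", "b", "c"),
                    p_add = c(1e-3, 1e-3 + 1e-9, 1),
                    p_dom = c(1, NA, 1e-4))
  s <- significance_sets(rec, alpha = 1e-3)
  expect_identical(s$set_add, "a")        # exactly equal -> included
  expect_identical(s$set_dom, "c")        # NA p-values never qualify
  s2 <- significance_sets(rec[0, ], alpha = 1e-3)
  expect_length(s2$set_add, 0)
  rec_all1 <- transform(rec, p_add = 1, p_dom = 1)
  s3 <- significance_sets(rec_all1, alpha = 1e-3)
  expect_length(s3$set_add, 0)
  expect_length(s3$set_dom, 0)
})

test_that("scan export produces sorted Manhattan rows and definitional Q-Q quantiles", {
  rec <- data.frame(chrom = c("2", "1", "1"), pos = c(5L, 300L, 100L),
                    snp_id = c("c", "b", "a"),
                    beta_add = 0, beta_dom = 0,
                    p_add = c(0.5, 0.01, 0.2), p_dom = c(0.9, 0.8, 0.7),
                    sig_add = FALSE, sig_dom = FALSE)
  scan <- structure(list(records = rec, threshold = 1e-3, mode = "ols",
                         n = 10, m = 3), class = "addo_scan")
  out <- export_scan(scan)
  expect_identical(out$manhattan$snp_id, c("a", "b", "c"))
  expect_equal(out$qq_add$expected,
               -log10((1:3 - 0.5) / 3))

  # uniform p-values hug the diagonal
  set.seed(48)
  ds <- bn_dataset(48, n1 = 20, n2 = 20, m = 500)
  scu <- addo_scan(sample(stats::rnorm(40)), ds, mode = "ols")
  qq <- export_scan(scu)$qq_add
  expect_lt(mean(abs(qq$observed - qq$expected)), 0.15)
})
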