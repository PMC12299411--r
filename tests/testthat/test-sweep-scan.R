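# independently coded Weir-Cockerham theta (dual-implementation oracle):
# literal a/b/c transcription with explicit loops over the two populations
wc_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

test_that("Weir-Cockerham theta: limits, oracle equality, symmetry", {
  # fixed difference between populations
  expect_equal(wc_fst_site(50, 1, 0, 50, 0, 0), 1)
  # both monomorphic for the same allele
  expect_true(is.na(wc_fst_site(50, 0, 0, 50, 0, 0)))
  # dual-implementation equality at HWE heterozygosity
  expect_equal(wc_fst_site(10, 0.8, 0.32, 10, 0.2, 0.32),
               wc_oracle(c(10, 10), c(0.8, 0.2), c(0.32, 0.32)),
               tolerance = 1e-12)
  # oracle equality across a random grid
  set.seed(61)
  for (i in 1:50) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    p1 <- stats::runif(1); p2 <- stats::runif(1)
    h1 <- stats::runif(1, 0, 2 * min(p1, 1 - p1))
    h2 <- stats::runif(1, 0, 2 * min(p2, 1 - p2))
    expect_equal(wc_fst_site(n1, p1, h1, n2, p2, h2),
                 wc_oracle(c(n1, n2), c(p1, p2), c(h1, h2)),
                 tolerance = 1e-12)
    # symmetric under swapping populations
    expect_equal(wc_fst_site(n1, p1, h1, n2, p2, h2),
                 wc_fst_site(n2, p2, h2, n1, p1, h1), tolerance = 1e-12)
  }
  expect_error(wc_fst_site(0, 0.5, 0.5, 10, 0.5, 0.5), ">= 1")
  expect_error(wc_fst_site(10, 1.5, 0, 10, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("theta increases with allele-frequency divergence at HWE", {
  grid <- seq(0.5, 0.95, by = 0.05)
  vals <- vapply(grid, function(p1) {
    p2 <- 1 - p1
    wc_fst_site(100, p1, 2 * p1 * (1 - p1), 100, p2, 2 * p2 * (1 - p2))
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("z-normalization standardizes the non-missing entries", {
  expect_equal(z_normalize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(62)
  v <- stats::rnorm(100, 5, 3)
  z <- z_normalize(v)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(stats::sd(z), 1)

  z2 <- z_normalize(c(0.1, NA, 0.3))
  expect_true(is.na(z2[2]))
  expect_equal(z2[c(1, 3)],
               (c(0.1, 0.3) - 0.2) / stats::sd(c(0.1, 0.3)))
  expect_error(z_normalize(c(1, 1, 1)), "zero standard deviation")
  expect_error(z_normalize(c(1, NA)), "at least 2")
})

test_that("site diversity equals the average pairwise allele difference", {
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(2, 4), 2 / 3)  # 4 differing pairs of 6
  expect_equal(site_pi(1, 2), 1)
  # brute-force enumeration over all C(N,2) allele pairs, N <= 10
  for (N in 2:10) for (c in 0:N) {
    alleles <- c(rep(1, c), rep(0, N - c))
    pairs <- utils::combn(N, 2)
    brute <- mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
    expect_equal(site_pi(c, N), brute)
  }
  expect_error(site_pi(0, 1), ">= 2")
  expect_error(site_pi(5, 4), "alt_count")
})

test_that("log2 diversity ratio guards against zero diversity", {
  expect_equal(log2_pi_ratio(0.3, 0.3), 0)
  expect_equal(log2_pi_ratio(0.4, 0.2), 1)
  expect_true(is.na(log2_pi_ratio(0.4, 0)))
  expect_true(is.na(log2_pi_ratio(0, 0.4)))
})

test_that("joint tail selection is a strict conjunction", {
  set.seed(63)
  rec <- data.frame(z_fst = stats::rnorm(100),
                    log2_ratio = stats::rnorm(100))
  # plant: one record above z threshold but with tiny |ratio|
  rec$z_fst[1] <- 10
  rec$log2_ratio[1] <- 0
  out <- select_loci(rec, 0.05)
  expect_false(out$selected[1])
  expect_true(all(is.na(out$selected_pop) == !out$selected))
  expect_error(select_loci(rec[1:10, ], 0.05), "fewer than 20")
})

test_that("neutral background selects at most the tail fraction of sites", {
  ds <- bn_dataset(64, n1 = 150, n2 = 150, m = 2000)
  sw <- sweep_scan(ds)
  expect_lte(mean(sw$records$selected), 0.05)
})

test_that("planted diversity-eroded loci are selected and assigned to the swept population", {
  planted <- data.frame(index = seq(101, 1001, by = 100),
                        p1 = 0.01, p2 = 0.5)
  ds <- bn_dataset(65, n1 = 150, n2 = 150, m = 2000,
                   planted_sweep = planted)
  sw <- sweep_scan(ds)  # numerator defaults to pop1 (alphabetically first)
  ids <- sprintf("snp_%05d", planted$index)
  hit <- sw$records[match(ids, sw$records$snp_id), ]
  expect_gte(sum(hit$selected & hit$selected_pop == "pop1"), 8)
  # eroded diversity in pop1 makes the ratio negative
  expect_true(all(hit$log2_ratio < 0, na.rm = TRUE))
})

test_that("dominance-signature loci stay out of the z(F_ST) tail", {
  misses <- 0
  for (s in 1:5) {
    planted <- data.frame(index = 500, allele_freq = 0.5,
                          het_frac_pop1 = 1, het_frac_pop2 = 0)
    ds <- bn_dataset(650 + s, n1 = 150, n2 = 150, m = 1000,
                     planted_dominance = planted)
    sw <- sweep_scan(ds)
    j <- match("snp_00500", sw$records$snp_id)
    thr <- stats::quantile(sw$records$z_fst[-j], 0.95, na.rm = TRUE)
    if (abs(sw$records$z_fst[j]) < thr) misses <- misses + 1
  }
  expect_gte(misses, 4)
})

test_that("realized F_ST tracks the simulator's divergence parameter", {
  mean_fst <- function(FF, s) {
    ds <- bn_dataset(660 + s, n1 = 100, n2 = 100, m = 500, fst = FF)
    st <- popdivscan:::pop_site_stats(ds)
    mean(wc_fst_site(st[[1]]$n, st[[1]]$p, st[[1]]$h,
                     st[[2]]$n, st[[2]]$p, st[[2]]$h), na.rm = TRUE)
  }
  avg <- vapply(c(0.01, 0.1, 0.3), function(FF) {
    mean(vapply(1:3, function(s) mean_fst(FF, s), 0))
  }, 0)
  expect_true(all(diff(avg) > 0))
})

test_that("sweep export writes the per-site table and a JSON summary", {
  ds <- bn_dataset(67, n1 = 30, n2 = 30, m = 100)
  sw <- sweep_scan(ds)
  base <- tempfile()
  export_sweep(sw, base)
  tab <- utils::read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(tab), 100)
  js <- jsonlite::read_json(paste0(base, "_summary.json"))
  expect_equal(js$n_sites, 100)
  expect_equal(js$n_selected, sum(sw$records$selected))
})
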