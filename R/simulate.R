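#' Configuration of a synthetic two-population experiment
#'
#' Describes a Balding-Nichols two-population genotype simulation with
#' optional planted loci: additive-divergent loci (allele-frequency
#' contrast), dominance-signature loci (equal allele frequencies but
#' contrasting heterozygote fractions — the pattern invisible to
#' frequency-based statistics), and sweep loci (near-fixation in one
#' population, eroding its diversity). A phenotype model attaches
#' litter-size records with genotype, parity and residual effects.
#'
#' @param n_pop1,n_pop2 diploid sample counts (defaults 300 and 300)
#' @param m number of SNPs (default 2000)
#' @param fst_param Balding-Nichols divergence F in (0, 1) (default 0.05)
#' @param pop_labels two population labels; the first plays the pi-ratio
#'   numerator role by default downstream
#' @param planted_additive data frame (index, p1, p2) of loci whose
#'   per-population frequencies are set directly
#' @param planted_dominance data frame (index, allele_freq, het_frac_pop1,
#'   het_frac_pop2): both populations share `allele_freq`; heterozygote
#'   fractions are set per population with the remaining mass split equally
#'   between the homozygotes
#' @param planted_sweep data frame (index, p1, p2) with near-fixation in
#'   one population
#' @param missing_rate fraction of genotypes masked missing (default 0)
#' @param phenotype list: `locus` (SNP index), `a` additive effect, `d`
#'   dominance effect, `intercept`, `parity_effects` (one value per parity
#'   level), `residual_sd`, `loss_rate` (per-piglet probability that a TNB
#'   count does not survive to NBA), `n_sows`, `litters_range`
#' @param seed integer seed governing every random draw
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_pop1 = 300, n_pop2 = 300, m = 2000,
                       fst_param = 0.05,
                       pop_labels = c("pop1", "pop2"),
                       planted_additive = NULL,
                       planted_dominance = NULL,
                       planted_sweep = NULL,
                       missing_rate = 0,
                       phenotype = NULL,
                       seed = 1L) {
  stopifnot(fst_param > 0, fst_param < 1,
            missing_rate >= 0, missing_rate < 1,
            length(pop_labels) == 2, n_pop1 >= 1, n_pop2 >= 1, m >= 1)
  idx <- c(planted_additive$index, planted_dominance$index,
           planted_sweep$index)
  if (length(idx) > 0) {
    stopifnot(all(idx >= 1), all(idx <= m), !anyDuplicated(idx))
  }
  fr <- c(planted_additive$p1, planted_additive$p2,
          planted_dominance$allele_freq, planted_sweep$p1, planted_sweep$p2,
          planted_dominance$het_frac_pop1, planted_dominance$het_frac_pop2)
  if (length(fr) > 0) stopifnot(all(fr >= 0), all(fr <= 1))
  if (!is.null(phenotype)) {
    defaults <- list(a = 0, d = 0, intercept = 12,
                     parity_effects = c(0, 1, 1.2, 0.8),
                     residual_sd = 3, loss_rate = 0.08,
                     n_sows = 200, litters_range = c(2, 5))
    phenotype <- utils::modifyList(defaults, phenotype)
    stopifnot(!is.null(phenotype$locus), phenotype$locus >= 1,
              phenotype$locus <= m,
              phenotype$loss_rate >= 0, phenotype$loss_rate < 1)
  }
  structure(list(n_pop1 = n_pop1, n_pop2 = n_pop2, m = m,
                 fst_param = fst_param, pop_labels = pop_labels,
                 planted_additive = planted_additive,
                 planted_dominance = planted_dominance,
                 planted_sweep = planted_sweep,
                 missing_rate = missing_rate,
                 phenotype = phenotype, seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Simulate per-population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies `p_j ~ Uniform(0.05, 0.95)`; each population draws
#' `p_ij ~ Beta(p_j (1-F)/F, (1-p_j)(1-F)/F)` independently, so the
#' expected per-site F_ST is the configured `fst_param`. Planted loci
#' overwrite the background draws.
#'
#' @param cfg a [sim_config()]
#' @return list with vectors `p1`, `p2` (length m) and `ancestral`
#' @export
simulate_frequencies <- function(cfg) {
  with_seed(cfg$seed, {
    FF <- cfg$fst_param
    p_anc <- stats::runif(cfg$m, 0.05, 0.95)
    shape <- (1 - FF) / FF
    p1 <- stats::rbeta(cfg$m, p_anc * shape, (1 - p_anc) * shape)
    p2 <- stats::rbeta(cfg$m, p_anc * shape, (1 - p_anc) * shape)
    for (pl in list(cfg$planted_additive, cfg$planted_sweep)) {
      if (!is.null(pl)) {
        p1[pl$index] <- pl$p1
        p2[pl$index] <- pl$p2
      }
    }
    if (!is.null(cfg$planted_dominance)) {
      p1[cfg$planted_dominance$index] <- cfg$planted_dominance$allele_freq
      p2[cfg$planted_dominance$index] <- cfg$planted_dominance$allele_freq
    }
    list(p1 = p1, p2 = p2, ancestral = p_anc)
  })
}

#' Simulate a two-population genotype dataset
#'
#' Background genotypes are binomial(2, p) within each population (HWE).
#' Dominance-signature loci are drawn from explicit genotype-class
#' frequencies: the configured heterozygote fraction, with the remaining
#' mass split equally between the two homozygotes, so both populations keep
#' the same allele frequency. Missingness is applied uniformly at
#' `missing_rate`.
#'
#' @param freqs result of [simulate_frequencies()]
#' @param cfg the same [sim_config()]
#' @return a `genotype_dataset`
#' @export
simulate_genotypes <- function(freqs, cfg) {
  with_seed(cfg$seed + 1L, {
    n1 <- cfg$n_pop1; n2 <- cfg$n_pop2; m <- cfg$m
    G1 <- matrix(stats::rbinom(n1 * m, 2, rep(freqs$p1, each = n1)),
                 nrow = n1)
    G2 <- matrix(stats::rbinom(n2 * m, 2, rep(freqs$p2, each = n2)),
                 nrow = n2)
    if (!is.null(cfg$planted_dominance)) {
      pd <- cfg$planted_dominance
      for (r in seq_len(nrow(pd))) {
        j <- pd$index[r]
        for (side in 1:2) {
          h <- if (side == 1) pd$het_frac_pop1[r] else pd$het_frac_pop2[r]
          n <- if (side == 1) n1 else n2
          g <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                      prob = c((1 - h) / 2, h, (1 - h) / 2))
          if (side == 1) G1[, j] <- g else G2[, j] <- g
        }
      }
    }
    G <- rbind(G1, G2)
    if (cfg$missing_rate > 0) {
      mask <- stats::runif(length(G)) < cfg$missing_rate
      G[mask] <- NA_integer_
    }
    ids <- c(sprintf("%s_%04d", cfg$pop_labels[1], seq_len(n1)),
             sprintf("%s_%04d", cfg$pop_labels[2], seq_len(n2)))
    rownames(G) <- ids
    population <- stats::setNames(rep(cfg$pop_labels, c(n1, n2)), ids)
    snps <- data.frame(chrom = "1", pos = seq_len(m) * 1000L,
                       snp_id = sprintf("snp_%05d", seq_len(m)),
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
    genotype_dataset(G, snps, population)
  })
}

#' Simulate litter-size phenotype records
#'
#' Sows are sampled from the dataset; each contributes several litters.
#' The latent litter mean is
#' `intercept + a (g - 1) + d [g == 1] + parity effect`; TNB is the
#' rounded truncated-normal draw (minimum 0) around it, and NBA is TNB
#' minus a binomial loss.
#'
#' @param ds a `genotype_dataset` containing the phenotype locus
#' @param cfg a [sim_config()] with a `phenotype` entry
#' @return data frame with columns `sow_id`, `litter_id`, `genotype`
#'   (0/0, 0/1, 1/1), `TNB`, `NBA`, `parity`
#' @export
simulate_phenotypes <- function(ds, cfg) {
  ph <- cfg$phenotype
  if (is.null(ph)) stop("cfg has no phenotype model")
  with_seed(cfg$seed + 2L, {
    g_all <- ds$G[, ph$locus]
    if (anyNA(g_all)) g_all[is.na(g_all)] <- 1L
    n_sows <- min(ph$n_sows, length(ds$samples))
    sows <- sample(ds$samples, n_sows)
    g <- g_all[sows]
    n_lit <- sample(ph$litters_range[1]:ph$litters_range[2], n_sows,
                    replace = TRUE)
    sow_id <- rep(sows, n_lit)
    g_rep <- rep(g, n_lit)
    n_par <- length(ph$parity_effects)
    parity <- unlist(lapply(n_lit, function(k) {
      seq_len(k) - 1L
    })) %% n_par + 1L
    latent <- ph$intercept + ph$a * (g_rep - 1) + ph$d * (g_rep == 1) +
      ph$parity_effects[parity]
    tnb <- pmax(0L, as.integer(round(stats::rnorm(length(latent), latent,
                                                  ph$residual_sd))))
    nba <- tnb - stats::rbinom(length(tnb), tnb, ph$loss_rate)
    data.frame(sow_id = sow_id,
               litter_id = paste0(sow_id, "_L", unlist(lapply(n_lit, seq_len))),
               genotype = c("0/0", "0/1", "1/1")[g_rep + 1L],
               TNB = tnb, NBA = nba,
               parity = parity, stringsAsFactors = FALSE)
  })
}

#' Default planted-locus layout for the fixture suite
#'
#' 10 additive-divergent loci (p 0.05 vs 0.95), 5 dominance-signature loci
#' (allele frequency 0.5; one population all heterozygous, the other none),
#' and 10 sweep loci (p 0.01 vs 0.5: near-fixation erodes diversity in the
#' first population).
#'
#' @param m SNP count the indices must fit into
#' @return list of the three planted-locus data frames
#' @export
default_planted_loci <- function(m = 2000) {
  stopifnot(m >= 250)
  list(
    planted_additive = data.frame(index = seq(101, 1001, by = 100),
                                  p1 = 0.05, p2 = 0.95),
    planted_dominance = data.frame(index = seq(1051, 1251, by = 50),
                                   allele_freq = 0.5,
                                   het_frac_pop1 = 1, het_frac_pop2 = 0),
    planted_sweep = data.frame(index = seq(1301, 1751, by = 50),
                               p1 = 0.01, p2 = 0.5))
}

#' Write the canonical synthetic fixture suite
#'
#' Generates and writes: (i) a neutral background dataset (300+300 samples,
#' 2000 SNPs, F = 0.05); (ii) the same background with the
#' [default_planted_loci()] planted; (iii) two toy 5-sample VCFs sharing
#' sites for merge/IO tests; (iv) a phenotype CSV with a planted dominant
#' deleterious effect; plus a JSON manifest recording seeds and planted
#' indices. Regeneration with the same seed is byte-identical.
#'
#' @param out_dir output directory (created if needed)
#' @param seed base seed (default 1)
#' @return invisibly, the manifest list
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  cfg_neutral <- sim_config(seed = seed)
  ds_n <- simulate_genotypes(simulate_frequencies(cfg_neutral), cfg_neutral)
  write_vcf(ds_n, file.path(out_dir, "neutral.vcf"))
  write_pop_map(ds_n, file.path(out_dir, "neutral.popmap"))

  pl <- default_planted_loci(2000)
  cfg_pl <- sim_config(planted_additive = pl$planted_additive,
                       planted_dominance = pl$planted_dominance,
                       planted_sweep = pl$planted_sweep,
                       missing_rate = 0.02,
                       phenotype = list(locus = pl$planted_dominance$index[1],
                                        a = 0, d = -2),
                       seed = seed + 10L)
  freqs <- simulate_frequencies(cfg_pl)
  ds_p <- simulate_genotypes(freqs, cfg_pl)
  write_vcf(ds_p, file.path(out_dir, "planted.vcf"))
  write_pop_map(ds_p, file.path(out_dir, "planted.popmap"))

  ph <- simulate_phenotypes(impute_missing(ds_p, seed = seed + 20L), cfg_pl)
  utils::write.csv(ph, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)

  cfg_a <- sim_config(n_pop1 = 5, n_pop2 = 1, m = 30, fst_param = 0.1,
                      pop_labels = c("toyA", "drop"), seed = seed + 30L)
  toy_a <- simulate_genotypes(simulate_frequencies(cfg_a), cfg_a)
  toy_a <- genotype_dataset(toy_a$G[1:5, , drop = FALSE], toy_a$snps,
                            toy_a$population[1:5])
  cfg_b <- sim_config(n_pop1 = 5, n_pop2 = 1, m = 30, fst_param = 0.1,
                      pop_labels = c("toyB", "drop"), seed = seed + 31L)
  toy_b <- simulate_genotypes(simulate_frequencies(cfg_b), cfg_b)
  toy_b <- genotype_dataset(toy_b$G[1:5, , drop = FALSE], toy_b$snps,
                            toy_b$population[1:5])
  write_vcf(toy_a, file.path(out_dir, "toy_a.vcf"))
  write_vcf(toy_b, file.path(out_dir, "toy_b.vcf"))

  manifest <- list(
    seed = seed,
    neutral = list(file = "neutral.vcf", n = c(300, 300), m = 2000,
                   fst_param = 0.05, seed = seed),
    planted = list(file = "planted.vcf", n = c(300, 300), m = 2000,
                   fst_param = 0.05, missing_rate = 0.02,
                   seed = seed + 10L,
                   additive_indices = pl$planted_additive$index,
                   dominance_indices = pl$planted_dominance$index,
                   sweep_indices = pl$planted_sweep$index),
    phenotypes = list(file = "phenotypes.csv",
                      locus_index = pl$planted_dominance$index[1],
                      a = 0, d = -2),
    toys = list(files = c("toy_a.vcf", "toy_b.vcf"),
                seeds = c(seed + 30L, seed + 31L)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
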