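# shared fixture builders (all data generated in code)

# minimal dataset from an explicit dosage matrix
toy_ds <- function(G, pops = NULL, chrom = "1", pos = NULL) {
  n <- nrow(G); m <- ncol(G)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(G) <- ids
  if (is.null(pops)) pops <- rep(c("popA", "popB"), length.out = n)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  snps <- data.frame(chrom = chrom, pos = pos,
                     snp_id = sprintf("m%03d", seq_len(m)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_dataset(G, snps, stats::setNames(pops, ids))
}

# write VCF body lines (list of c(chrom,pos,id,ref,alt,gt1,gt2,...)) to a file
write_vcf_text <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r[1:5], ".", ".", ".", "GT", r[-(1:5)]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# Balding-Nichols background dataset, optionally with planted loci
bn_dataset <- function(seed, n1 = 150, n2 = 150, m = 2000, fst = 0.05,
                       planted_additive = NULL, planted_dominance = NULL,
                       planted_sweep = NULL, missing_rate = 0) {
  cfg <- sim_config(n_pop1 = n1, n_pop2 = n2, m = m, fst_param = fst,
                    planted_additive = planted_additive,
                    planted_dominance = planted_dominance,
                    planted_sweep = planted_sweep,
                    missing_rate = missing_rate, seed = seed)
  simulate_genotypes(simulate_frequencies(cfg), cfg)
}

# PC1 surrogate phenotype of a (no-missing) dataset
pc1_of <- function(ds) {
  K <- additive_grm(additive_design(ds))
  surrogate_phenotype(grm_pca(K, k = 2, population = ds$population))
}
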