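#' Three-way set comparison of scan hits
#'
#' Exact set algebra over SNP (or gene) identifier sets from the additive
#' scan, the dominance scan and the sweep scan. `n_add_and_sweep_only`
#' excludes the triple intersection; `n_unique_lmm_addo` is the number of
#' additive-or-dominance hits not found by the sweep scan.
#'
#' @param set_add,set_dom,set_sweep character vectors of identifiers drawn
#'   from the same universe
#' @return object of class `comparison_summary`: list of counts `n_add`,
#'   `n_dom`, `n_sweep`, `n_add_and_dom`, `n_add_and_sweep_only`,
#'   `n_all_three`, `n_union_lmm_addo`, `n_unique_lmm_addo`
#' @export
venn_counts <- function(set_add, set_dom, set_sweep) {
  A <- unique(set_add); D <- unique(set_dom); S <- unique(set_sweep)
  triple <- intersect(intersect(A, D), S)
  lmm <- union(A, D)
  structure(list(
    n_add = length(A),
    n_dom = length(D),
    n_sweep = length(S),
    n_add_and_dom = length(intersect(A, D)),
    n_add_and_sweep_only = length(setdiff(intersect(A, S), triple)),
    n_all_three = length(triple),
    n_union_lmm_addo = length(lmm),
    n_unique_lmm_addo = length(setdiff(lmm, S))),
    class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("comparison_summary (additive / dominance / sweep)\n")
  cat(sprintf("  sizes: add %d, dom %d, sweep %d\n",
              x$n_add, x$n_dom, x$n_sweep))
  cat(sprintf("  add&dom %d, add&sweep (excl. triple) %d, all three %d\n",
              x$n_add_and_dom, x$n_add_and_sweep_only, x$n_all_three))
  cat(sprintf("  add|dom union %d, of which %d not found by the sweep scan\n",
              x$n_union_lmm_addo, x$n_unique_lmm_addo))
  invisible(x)
}

#' Read a gene model from GFF3 or BED
#'
#' GFF3: features of type `gene` (or all features when none are typed
#' `gene`); the gene name comes from the `Name` attribute, falling back to
#' `gene_id`/`ID`. BED: name column. Coordinates are returned 1-based
#' inclusive.
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file
#' @return data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_name` (class `gene_model`)
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  name <- NULL
  for (f in c("Name", "gene_id", "ID", "name")) {
    if (f %in% names(md) && !all(is.na(md[[f]]))) {
      name <- as.character(md[[f]])
      break
    }
  }
  if (is.null(name)) name <- paste0("gene_", seq_along(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_name = name, stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  if (any(df$start > df$end)) stop("gene intervals with start > end")
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Annotate SNPs against a gene model
#'
#' A SNP inside a gene interval is `within` (distance 0). Otherwise the
#' nearest gene within `flank` bp is reported, with the relation `upstream`
#' or `downstream` decided by that gene's strand. SNPs with no gene within
#' the flank are `intergenic`. Ties are broken by smallest distance, then
#' alphabetical gene name. Each SNP annotates to at most one gene.
#'
#' @param snps data frame with `chrom`, `pos`, `snp_id` (e.g. the `snps`
#'   element of a `genotype_dataset`)
#' @param genes a [read_gene_model()] data frame
#' @param flank neighborhood in bp (default 5000)
#' @return data frame with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `gene`, `relation` (within/upstream/downstream/intergenic), `distance`
#' @export
annotate_snps <- function(snps, genes, flank = 5000) {
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)

  out <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                    pos = snps$pos, gene = NA_character_,
                    relation = "intergenic", distance = NA_real_,
                    stringsAsFactors = FALSE)

  # candidate gene hits within the flank window
  win <- GenomicRanges::resize(snp_gr, width = 2 * flank + 1, fix = "center")
  hits <- GenomicRanges::findOverlaps(win, gene_gr, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(snp_gr[qi], gene_gr[si], ignore.strand = TRUE)
  # distance() gives the gap size; a SNP adjacent to a gene has gap 0 but is
  # outside it, so report gap + 1 as the bp distance for non-overlapping hits
  inside <- d == 0 &
    snps$pos[qi] >= genes$start[si] & snps$pos[qi] <= genes$end[si]
  dist_bp <- ifelse(inside, 0, d + 1)
  cand <- data.frame(qi = qi, si = si, dist = dist_bp,
                     gene = genes$gene_name[si],
                     stringsAsFactors = FALSE)
  cand <- cand[cand$dist <= flank, , drop = FALSE]
  if (nrow(cand) == 0) return(out)
  cand <- cand[order(cand$qi, cand$dist, cand$gene), , drop = FALSE]
  best <- cand[!duplicated(cand$qi), , drop = FALSE]

  pos <- snps$pos[best$qi]
  g_start <- genes$start[best$si]
  g_end <- genes$end[best$si]
  g_strand <- genes$strand[best$si]
  rel <- character(nrow(best))
  rel[best$dist == 0] <- "within"
  before <- best$dist > 0 & pos < g_start  # SNP 5' of gene on + strand
  after <- best$dist > 0 & pos > g_end
  rel[before] <- ifelse(g_strand[before] == "+", "upstream", "downstream")
  rel[after] <- ifelse(g_strand[after] == "+", "downstream", "upstream")

  out$gene[best$qi] <- best$gene
  out$relation[best$qi] <- rel
  out$distance[best$qi] <- best$dist
  out$distance[out$relation == "intergenic"] <- NA_real_
  out
}

#' Gene-level three-way comparison
#'
#' Maps each SNP set to the genes its members annotate to (relation other
#' than intergenic) and applies the same set algebra as [venn_counts()].
#'
#' @param annotations an [annotate_snps()] data frame covering every SNP in
#'   the sets
#' @param set_add,set_dom,set_sweep character vectors of SNP ids
#' @return a gene-level `comparison_summary`, with the per-set gene vectors
#'   in its `"genes"` attribute
#' @export
genes_for_sets <- function(annotations, set_add, set_dom, set_sweep) {
  gene_of <- function(ids) {
    rows <- annotations$snp_id %in% ids &
      annotations$relation != "intergenic" & !is.na(annotations$gene)
    unique(annotations$gene[rows])
  }
  ga <- gene_of(set_add); gd <- gene_of(set_dom); gs <- gene_of(set_sweep)
  out <- venn_counts(ga, gd, gs)
  attr(out, "genes") <- list(add = ga, dom = gd, sweep = gs)
  out
}
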