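# Feature engineering: four per-SNP features plus five pairwise
# absolute-difference features. The pairwise vector is the model's sole input.

#' Names of the five pairwise features, in the fixed model order
#' @export
PAIR_FEATURE_NAMES <- c("chr_diff", "pos_diff", "pval_diff", "gene_diff",
                        "intergenic_diff")

#' Encode a chromosome token as an integer code
#'
#' Autosomes `1`..`22` map to themselves, `X` to 23, `Y` to 24, `MT` to 25,
#' and anything else (patch scaffolds, unplaced contigs, typos) to 26.
#' Tokens are normalized first, so `chr17` and `" x "` work.
#'
#' @param chrom Character vector of chromosome tokens.
#' @return Integer vector of codes in 1..26.
#' @export
#' @examples
#' encode_chromosome(c("7", "X", "GL000220.1"))
encode_chromosome <- function(chrom) {
  chrom <- normalize_chromosome(chrom)
  map <- c(stats::setNames(1:22, as.character(1:22)), X = 23L, Y = 24L, MT = 25L)
  out <- unname(map[chrom])
  out[is.na(out)] <- 26L
  as.integer(out)
}

#' Transform a p-value to the -log10 scale
#'
#' P-values of exactly 0 (and any value below the double-underflow guard
#' 1e-300, which parsed strings can hit) are clamped to 1e-300, so the
#' transformed value is bounded by 300.
#'
#' @param p Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Numeric vector, \eqn{-\log_{10}(\max(p, 10^{-300}))}.
#' @export
#' @examples
#' transform_pvalue(c(1, 0, 5e-8))
transform_pvalue <- function(p) {
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad) > 0) {
    stop_data("p-value out of [0, 1]: %g", p[bad[1]])
  }
  -log10(pmax(p, 1e-300))
}

#' Count mapped genes
#'
#' Length of the normalized gene list; duplicates are counted as present
#' (the field reports mapping multiplicity, not a gene set).
#'
#' @param genes A list of character vectors (one per SNP), or a single
#'   character vector treated as one SNP's gene list.
#' @return Integer vector of gene counts.
#' @export
count_genes <- function(genes) {
  if (is.list(genes)) lengths(genes) else length(genes)
}

#' Intergenic indicator
#'
#' 1 when the SNP has no mapped gene after normalization (blank, `-`, `NA`
#' and `NR` placeholders all count as "no gene data"), else 0.
#'
#' @inheritParams count_genes
#' @return Integer vector of 0/1 flags.
#' @export
intergenic_flag <- function(genes) {
  as.integer(count_genes(genes) == 0L)
}

#' Compute the per-SNP engineered features
#'
#' @param records A cleaned record tibble (see [clean_records()]).
#' @return A tibble with columns `rsid`, `gene_count`, `is_intergenic`,
#'   `log_pvalue`, `chr_encoded` and `position` (carried for pairwise use).
#' @export
snp_features <- function(records) {
  tibble::tibble(
    rsid = records$rsid,
    gene_count = count_genes(records$genes),
    is_intergenic = intergenic_flag(records$genes),
    log_pvalue = transform_pvalue(records$p_value),
    chr_encoded = encode_chromosome(records$chromosome),
    position = records$position
  )
}

#' Compute the five pairwise absolute-difference features
#'
#' `pos_diff` is the plain absolute coordinate difference for all pairs,
#' including cross-chromosome pairs: when `chr_diff != 0` the chromosomal
#' discrepancy itself signals positional dissimilarity and the tree ensemble
#' conditions on it, so no sentinel is substituted.
#'
#' @param ref,cand Per-SNP feature tibbles from [snp_features()]; rows are
#'   matched positionally (single-row inputs recycle).
#' @return A tibble with columns `chr_diff`, `pos_diff`, `pval_diff`,
#'   `gene_diff`, `intergenic_diff`, all non-negative.
#' @export
pair_features <- function(ref, cand) {
  tibble::tibble(
    chr_diff = abs(ref$chr_encoded - cand$chr_encoded),
    pos_diff = abs(ref$position - cand$position),
    pval_diff = abs(ref$log_pvalue - cand$log_pvalue),
    gene_diff = abs(ref$gene_count - cand$gene_count),
    intergenic_diff = abs(ref$is_intergenic - cand$is_intergenic)
  )
}
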