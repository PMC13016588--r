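# Shared fixture builders. Everything is generated in code; no stored data.

make_records <- function(rsid, chromosome, position, genes, p_value,
                         trait = NA_character_, label = "positive") {
  tibble::tibble(
    rsid = rsid, chromosome = as.character(chromosome), position = position,
    genes = if (is.list(genes)) genes else list(genes),
    p_value = p_value, trait = trait, label = label
  )
}

# Random per-SNP feature rows for property tests.
random_features <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    rsid = sprintf("rs%d", seq_len(n)),
    gene_count = sample(0:5, n, TRUE),
    is_intergenic = sample(0:1, n, TRUE),
    log_pvalue = stats::runif(n, 0, 300),
    chr_encoded = sample(1:26, n, TRUE),
    position = sample.int(2e8, n)
  ))
}

# A tiny separable record fixture: two clusters of positives/negatives on
# different chromosomes with disjoint p-value bands, so similar pairs have
# uniformly small differences and dissimilar pairs large ones.
separable_records <- function(n_pos = 20, n_neg = 40, seed = 11) {
  withr::with_seed(seed, {
    pos <- make_records(
      rsid = sprintf("rs1%04d", seq_len(n_pos)),
      chromosome = "2",
      position = 1e7 + sample.int(5e4, n_pos),
      genes = replicate(n_pos, c("GENEA"), simplify = FALSE),
      p_value = 10^(-stats::runif(n_pos, 8, 9)),
      label = "positive"
    )
    neg <- make_records(
      rsid = sprintf("rs2%04d", seq_len(n_neg)),
      chromosome = sample(c("9", "15", "X"), n_neg, TRUE),
      position = 1.5e8 + sample.int(5e7, n_neg),
      genes = replicate(n_neg, character(0), simplify = FALSE),
      p_value = 10^(-stats::runif(n_neg, 1, 3)),
      label = "negative"
    )
    list(positives = pos, negatives = neg)
  })
}

separable_pairset <- function(n_per_class = 60, seed = 11) {
  recs <- separable_records(seed = seed)
  build_training_pairs(recs$positives, recs$negatives,
                       n_per_class = n_per_class, seed = seed)
}

# A pair set in which only pos_diff carries class signal.
single_feature_pairset <- function(n = 100, seed = 3) {
  withr::with_seed(seed, {
    half <- n / 2
    feats <- tibble::tibble(
      chr_diff = sample(0:3, n, TRUE),
      pos_diff = c(stats::runif(half, 0, 1e4), stats::runif(half, 1e6, 1e8)),
      pval_diff = stats::runif(n, 0, 5),
      gene_diff = sample(0:2, n, TRUE),
      intergenic_diff = sample(0:1, n, TRUE)
    )
  })
  snpsim:::new_pair_set(feats, c(rep(1L, n / 2), rep(0L, n / 2)),
                        ref_ids = sprintf("ra%d", seq_len(n)),
                        cand_ids = sprintf("rb%d", seq_len(n)), seed = seed)
}

# Brute-force AUC: concordant score-pair counting, ties worth 0.5.
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

write_positive_fixture <- function(path, rows) {
  writeLines(c("riskAllele\tlocations\tmappedGenes\tpValue", rows), path)
  path
}

write_negative_fixture <- function(path, rows,
                                   header = "SNPS\tSTRONGEST SNP-RISK ALLELE\tCHR_ID\tCHR_POS\tMAPPED_GENE\tP-VALUE\tDISEASE/TRAIT") {
  writeLines(c(header, rows), path)
  path
}
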