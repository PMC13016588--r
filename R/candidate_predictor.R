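# Candidate prediction: score every background-pool SNP against every
# reference (disease-associated) SNP, keep the top k per reference, then
# apply the significance / recurrence enrichment filter with its reporting
# summaries (Manhattan, recurrence, gene-category and chromosome tables).

prediction_row_block <- function(ref, cand, scores) {
  tibble::tibble(
    ref_rsid = ref$rsid, ref_chr = ref$chromosome, ref_pos = ref$position,
    ref_genes = join_genes(ref$genes), ref_pvalue = ref$p_value,
    cand_rsid = cand$rsid, cand_chr = cand$chromosome, cand_pos = cand$position,
    cand_genes = join_genes(cand$genes), cand_pvalue = cand$p_value,
    similarity_score = scores
  )
}

score_pool <- function(model, ref_feat, pool_feat, batch_size) {
  n <- nrow(pool_feat)
  scores <- numeric(n)
  start <- 1L
  while (start <= n) {
    end <- min(start + batch_size - 1L, n)
    block <- pair_features(ref_feat[rep(1L, end - start + 1L), ],
                           pool_feat[start:end, ])
    scores[start:end] <- predict_similarity(model, block)
    start <- end + 1L
  }
  scores
}

#' Rank the candidate pool against one reference SNP
#'
#' Scores every pool member and returns the `k` highest-scoring candidates in
#' descending score order, ties broken by ascending rsid (so outputs are
#' bit-reproducible). If the pool is smaller than `k`, the whole pool is
#' returned sorted.
#'
#' @param model A trained `similarity_model`.
#' @param ref A single-row record tibble (the positive reference SNP).
#' @param pool A record tibble of candidate (negative) SNPs.
#' @param k Number of candidates to keep.
#' @param batch_size Pool rows scored per model call; results are independent
#'   of this value, it only bounds memory.
#' @return A prediction tibble (one row per selected candidate) with the
#'   fixed column layout of [write_predictions_tsv()].
#' @export
rank_candidates <- function(model, ref, pool, k = 10, batch_size = 50000) {
  if (nrow(pool) == 0) stop_data("candidate pool is empty")
  if (k < 1) stop_config("k must be >= 1")
  ref_feat <- snp_features(ref)
  pool_feat <- snp_features(pool)
  scores <- score_pool(model, ref_feat, pool_feat, batch_size)
  ord <- order(-scores, pool$rsid)
  take <- ord[seq_len(min(k, nrow(pool)))]
  prediction_row_block(ref[rep(1L, length(take)), ], pool[take, ], scores[take])
}

#' Predict top-k candidates for every reference SNP
#'
#' Concatenates [rank_candidates()] over all references: the result has
#' exactly `|references| * k` rows whenever the pool holds at least `k`
#' SNPs. The same candidate may appear under several references; that
#' multiplicity is the recurrence signal used by [filter_candidates()].
#'
#' @param model A trained `similarity_model`.
#' @param references Record tibble of positive SNPs.
#' @param pool Record tibble of candidate SNPs (disjoint from the references
#'   by construction: labels differ).
#' @param k Candidates per reference (default 10).
#' @param batch_size Pool rows scored per model call.
#' @param verbose Emit progress messages every 50 references.
#' @return The concatenated prediction tibble.
#' @export
predict_all <- function(model, references, pool, k = 10, batch_size = 50000,
                        verbose = FALSE) {
  if (nrow(references) == 0) stop_data("no reference SNPs supplied")
  if (nrow(pool) < k) stop_data("pool (%d) smaller than k (%d)", nrow(pool), k)
  ref_feat <- snp_features(references)
  pool_feat <- snp_features(pool)
  blocks <- vector("list", nrow(references))
  for (r in seq_len(nrow(references))) {
    scores <- score_pool(model, ref_feat[r, ], pool_feat, batch_size)
    ord <- order(-scores, pool$rsid)
    take <- ord[seq_len(k)]
    blocks[[r]] <- prediction_row_block(references[rep(r, k), ], pool[take, ],
                                        scores[take])
    if (verbose && r %% 50 == 0) {
      message(sprintf("scored %d / %d references", r, nrow(references)))
    }
  }
  dplyr::bind_rows(blocks)
}

#' Candidate recurrence counts
#'
#' How many times each candidate rsID occurs across the full prediction
#' table, i.e. for how many reference SNPs it entered the top-k list.
#' Counts sum to the table's row count.
#'
#' @param table A prediction tibble.
#' @return A named integer vector (rsid -> count), sorted decreasing.
#' @export
recurrence_counts <- function(table) {
  if (nrow(table) == 0) return(integer(0))
  counts <- table(table$cand_rsid)
  sort(stats::setNames(as.integer(counts), names(counts)), decreasing = TRUE)
}

#' Enrichment filter: genome-wide significance and/or recurrence
#'
#' A prediction row is retained iff the candidate's own catalog p-value
#' (its original-trait association; candidates carry no disease-specific
#' p-value) satisfies \eqn{-\log_{10}(p) \ge} `logp_threshold`, or the
#' candidate was predicted for at least `min_recurrence` references. The
#' defaults are the genome-wide significance constant 7.3
#' (\eqn{p \le 5\times10^{-8}}) and a recurrence of 6, below which predicted
#' multiplicities are common enough to be noise.
#'
#' @param table A prediction tibble.
#' @param logp_threshold Minimum \eqn{-\log_{10}(p)} (default 7.3).
#' @param min_recurrence Minimum prediction multiplicity (default 6).
#' @return A `filter_result` list: `retained` (rows passing, with
#'   `recurrence_count`, `passes_significance`, `passes_recurrence` columns),
#'   `recurrence` (the full counts map) and `thresholds`.
#' @export
filter_candidates <- function(table, logp_threshold = 7.3, min_recurrence = 6) {
  if (logp_threshold <= 0 || min_recurrence <= 0) {
    stop_config("filter thresholds must be positive")
  }
  rec <- recurrence_counts(table)
  logp <- transform_pvalue(table$cand_pvalue)
  passes_sig <- !is.na(logp) & logp >= logp_threshold
  rec_count <- as.integer(rec[table$cand_rsid])
  rec_count[is.na(rec_count)] <- 0L
  passes_rec <- rec_count >= min_recurrence
  retained <- table[passes_sig | passes_rec, , drop = FALSE]
  retained$recurrence_count <- rec_count[passes_sig | passes_rec]
  retained$passes_significance <- passes_sig[passes_sig | passes_rec]
  retained$passes_recurrence <- passes_rec[passes_sig | passes_rec]
  structure(list(retained = retained, recurrence = rec,
                 thresholds = c(logp_threshold = logp_threshold,
                                min_recurrence = min_recurrence)),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf(
    "<filter_result> %d rows retained (-log10(p) >= %g and/or recurrence >= %g)\n",
    nrow(x$retained), x$thresholds[["logp_threshold"]],
    x$thresholds[["min_recurrence"]]))
  invisible(x)
}

#' Gene membership across the three SNP categories
#'
#' For every gene symbol seen anywhere: `snp_org` if a positive (original,
#' experimentally confirmed) SNP maps to it, `snp_freq` if a retained
#' candidate passing the recurrence rule maps to it, `snp_signif` if a
#' retained candidate passing the significance rule maps to it. One gene can
#' hold all three flags; such genes are the strongest leads.
#'
#' @param positives Record tibble of positive SNPs.
#' @param filtered A `filter_result`.
#' @return A tibble (`gene`, `snp_org`, `snp_freq`, `snp_signif`).
#' @export
gene_categories <- function(positives, filtered) {
  org <- unique(unlist(positives$genes))
  ret <- filtered$retained
  freq <- unique(unlist(split_genes(ret$cand_genes[ret$passes_recurrence])))
  signif <- unique(unlist(split_genes(ret$cand_genes[ret$passes_significance])))
  genes <- sort(unique(c(org, freq, signif)))
  tibble::tibble(
    gene = genes,
    snp_org = genes %in% org,
    snp_freq = genes %in% freq,
    snp_signif = genes %in% signif
  )
}

#' Chromosome distribution of predicted candidates
#'
#' Counts unique candidate rsIDs per chromosome token. Candidates appearing
#' under several references are counted once.
#'
#' @param table A prediction tibble.
#' @return A tibble (`chromosome`, `n`) ordered by chromosome code.
#' @export
chromosome_distribution <- function(table) {
  uniq <- table[!duplicated(table$cand_rsid), , drop = FALSE]
  counts <- table(uniq$cand_chr)
  out <- tibble::tibble(chromosome = names(counts), n = as.integer(counts))
  out[order(encode_chromosome(out$chromosome), out$chromosome), ]
}

#' Manhattan-plot data for predicted candidates
#'
#' One row per unique candidate (set `unique_candidates = FALSE` to keep all
#' prediction rows) with its chromosome, position, \eqn{-\log_{10}(p)} and a
#' genome-wide-significance flag (`>=` convention, so a p-value of exactly
#' `threshold_p` is above the line).
#'
#' @param table A prediction tibble.
#' @param threshold_p Significance threshold p-value (default 5e-8).
#' @param unique_candidates Deduplicate candidates first (default TRUE).
#' @return A tibble (`cand_rsid`, `chromosome`, `position`, `log_pvalue`,
#'   `above_threshold`).
#' @export
manhattan_data <- function(table, threshold_p = 5e-8, unique_candidates = TRUE) {
  if (unique_candidates) table <- table[!duplicated(table$cand_rsid), , drop = FALSE]
  logp <- transform_pvalue(table$cand_pvalue)
  tibble::tibble(
    cand_rsid = table$cand_rsid,
    chromosome = table$cand_chr,
    position = table$cand_pos,
    log_pvalue = logp,
    above_threshold = logp >= transform_pvalue(threshold_p)
  )
}

#' Annotate predictions with reference/alternative alleles
#'
#' Left-joins a local allele table (3 columns: `rsid`, `ref_allele`,
#' `alt_allele`) on the candidate rsID. Unmatched candidates keep missing
#' alleles; duplicated rsIDs in the allele table use the first occurrence
#' with a warning.
#'
#' @param table A prediction tibble.
#' @param allele_table A data frame with columns `rsid`, `ref_allele`,
#'   `alt_allele`, or a path to such a TSV.
#' @return The input tibble with `ref_allele` / `alt_allele` columns and an
#'   `allele_report` attribute counting unmatched candidates.
#' @export
annotate_alleles <- function(table, allele_table) {
  if (is.character(allele_table)) {
    allele_table <- readr::read_tsv(allele_table,
                                    col_types = readr::cols(.default = readr::col_character()),
                                    progress = FALSE)
  }
  needed <- c("rsid", "ref_allele", "alt_allele")
  if (!all(needed %in% names(allele_table))) {
    stop_config("allele table must have columns: %s", paste(needed, collapse = ", "))
  }
  dup <- duplicated(allele_table$rsid)
  if (any(dup)) {
    warning(sprintf("allele table has %d duplicated rsid(s); first occurrence used",
                    sum(dup)))
    allele_table <- allele_table[!dup, , drop = FALSE]
  }
  idx <- match(table$cand_rsid, allele_table$rsid)
  out <- table
  out$ref_allele <- allele_table$ref_allele[idx]
  out$alt_allele <- allele_table$alt_allele[idx]
  attr(out, "allele_report") <- list(unmatched = sum(is.na(idx)))
  out
}
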