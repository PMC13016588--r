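# Synthetic catalogs and the simulated similarity-group validation study.
#
# The simulator serves two purposes: (1) TSV fixtures in both catalog
# dialects, with the quirks real exports carry (allele-suffixed rsids,
# "chromosome:position" tokens, blank/"-" gene fields, p-values spanning 1
# down to exact 0), so every pipeline stage is testable without a download;
# (2) the 500-SNP similarity-group dataset used to verify that the model can
# learn similarity structure at all: groups are realized as
# (chromosome, position-window, p-value-band) clusters, i.e. exactly the
# axes the engineered features see, so a competent model must separate them.

CHROMOSOME_TOKENS <- c(as.character(1:22), "X", "Y", "MT")

#' Configuration of the simulated similarity-group study
#'
#' @param n_snps Total SNPs (default 500).
#' @param n_groups Number of similarity groups (default 10; at most 25, one
#'   distinct chromosome per group).
#' @param within_group_span Width in bp of each group's position window
#'   (default 100,000 — the scale of a tightly linked locus).
#' @param intergenic_rate Fraction of groups carrying no mapped gene
#'   (default 0.2).
#' @param n_train_pairs,n_test_pairs Balanced pair counts for the study
#'   (defaults 400 / 200; must be even).
#' @param gene_pool Invented gene symbols to draw from (no real gene names,
#'   so fixtures never make accidental biological claims).
#' @param seed Integer master seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_snps = 500, n_groups = 10,
                              within_group_span = 1e5, intergenic_rate = 0.2,
                              n_train_pairs = 400, n_test_pairs = 200,
                              gene_pool = sprintf("GENE%04d", 1:200),
                              seed = 42) {
  if (n_groups > length(CHROMOSOME_TOKENS)) {
    stop_config("n_groups (%d) exceeds the %d distinct chromosome codes",
                n_groups, length(CHROMOSOME_TOKENS))
  }
  if (n_groups < 2 || n_snps < 2 * n_groups) {
    stop_config("need at least 2 groups with at least 2 SNPs each")
  }
  if (n_train_pairs %% 2 != 0 || n_test_pairs %% 2 != 0) {
    stop_config("pair counts must be even (balanced classes)")
  }
  structure(list(n_snps = as.integer(n_snps), n_groups = as.integer(n_groups),
                 within_group_span = within_group_span,
                 intergenic_rate = intergenic_rate,
                 n_train_pairs = as.integer(n_train_pairs),
                 n_test_pairs = as.integer(n_test_pairs),
                 gene_pool = gene_pool, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate SNPs in pre-defined similarity groups
#'
#' Each group lives on its own chromosome, inside its own `within_group_span`
#' position window and its own disjoint \eqn{-\log_{10}(p)} band, with a
#' group-constant gene count — so groups are well separated along every
#' engineered feature axis by construction. Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return A list: `records` (record tibble, `label = NA`), `groups`
#'   (integer group label per record) and `config`.
#' @export
generate_similarity_groups <- function(config = simulation_config()) {
  g <- config$n_groups
  sizes <- rep(config$n_snps %/% g, g)
  extra <- config$n_snps %% g
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  withr::with_seed(config$seed, {
    chroms <- CHROMOSOME_TOKENS[seq_len(g)]
    base_pos <- round(stats::runif(g, 5e6, 1.5e8))
    # disjoint -log10(p) bands of width 2 separated by gaps of 2
    band_lo <- 2 + 4 * (seq_len(g) - 1)
    n_intergenic <- round(config$intergenic_rate * g)
    gene_count <- rep(1:5, length.out = g)
    if (n_intergenic > 0) gene_count[seq_len(n_intergenic)] <- 0L
    gene_count <- sample(gene_count)  # decouple gene count from p band

    group <- rep(seq_len(g), sizes)
    n <- length(group)
    position <- base_pos[group] +
      round(stats::runif(n, 0, config$within_group_span))
    logp <- stats::runif(n, band_lo[group], band_lo[group] + 2)
    genes <- lapply(seq_len(n), function(i) {
      k <- gene_count[group[i]]
      if (k == 0) character(0) else sample(config$gene_pool, k)
    })
    records <- tibble::tibble(
      rsid = sprintf("rs%07d", 9000000 + seq_len(n)),
      chromosome = chroms[group],
      position = position,
      genes = genes,
      p_value = 10^(-logp),
      trait = NA_character_,
      label = NA_character_
    )
  })
  list(records = records, groups = group, config = config)
}

#' Sample balanced within-/cross-group pair sets
#'
#' Similar pairs (label 1) draw both members from one group; dissimilar pairs
#' (label 0) straddle two groups. Train and test sets are balanced and
#' pair-disjoint (individual SNPs may appear in both, mirroring the main
#' protocol's plain pair-level split).
#'
#' @param snps Record tibble from [generate_similarity_groups()].
#' @param labels Integer group label per record.
#' @param n_train,n_test Even pair counts.
#' @param seed Integer seed.
#' @return A list of two `pair_set`s: `train` and `test`.
#' @export
sample_group_pairs <- function(snps, labels, n_train = 400, n_test = 200,
                               seed = 42) {
  if (length(unique(labels)) < 2) stop_data("need at least 2 groups")
  if (min(table(labels)) < 2) stop_data("every group needs at least 2 members")
  n_sim <- (n_train + n_test) / 2
  n_dis <- n_sim
  feats <- snp_features(snps)
  m <- nrow(snps)
  withr::with_seed(seed, {
    # enumerate all unordered pairs' group relation lazily via linear codes
    total <- choose(m, 2)
    within_codes <- integer(0)
    cross_codes <- integer(0)
    # enumerate within-group pairs exactly (small); sample cross-group pairs
    for (gl in unique(labels)) {
      idx <- which(labels == gl)
      cmb <- utils::combn(idx, 2)
      within_codes <- c(within_codes,
                        (cmb[2, ] - 1) * (cmb[2, ] - 2) / 2 + cmb[1, ])
    }
    if (n_sim > length(within_codes)) {
      stop_data("requested %d similar pairs but only %d within-group pairs exist",
                n_sim, length(within_codes))
    }
    n_cross_total <- total - length(within_codes)
    if (n_dis > n_cross_total) {
      stop_data("requested %d dissimilar pairs but only %.0f cross-group pairs exist",
                n_dis, n_cross_total)
    }
    sim_codes <- sample(within_codes, n_sim)
    # rejection-sample distinct cross-group codes
    got <- integer(0)
    while (length(got) < n_dis) {
      cand <- sample.int(total, min(4 * n_dis, total))
      cand <- setdiff(cand, c(within_codes, got))
      got <- c(got, cand[seq_len(min(length(cand), n_dis - length(got)))])
    }
    decode <- function(codes) {
      j <- ceiling((1 + sqrt(1 + 8 * codes)) / 2)
      i <- codes - (j - 1) * (j - 2) / 2
      over <- i < 1
      j[over] <- j[over] - 1
      i[over] <- codes[over] - (j[over] - 1) * (j[over] - 2) / 2
      cbind(i = as.integer(i), j = as.integer(j))
    }
    sim_ij <- decode(sim_codes)
    dis_ij <- decode(got)
    build <- function(ij, lab) {
      new_pair_set(pair_features(feats[ij[, 1], ], feats[ij[, 2], ]),
                   rep(lab, nrow(ij)),
                   ref_ids = snps$rsid[ij[, 1]], cand_ids = snps$rsid[ij[, 2]],
                   seed = seed)
    }
    sim_train <- seq_len(n_train / 2)
    dis_train <- seq_len(n_train / 2)
    combine <- function(sim_rows, dis_rows) {
      sim <- build(sim_ij[sim_rows, , drop = FALSE], 1L)
      dis <- build(dis_ij[dis_rows, , drop = FALSE], 0L)
      new_pair_set(dplyr::bind_rows(sim$pairs[PAIR_FEATURE_NAMES],
                                    dis$pairs[PAIR_FEATURE_NAMES]),
                   c(rep(1L, length(sim_rows)), rep(0L, length(dis_rows))),
                   ref_ids = c(sim$ref_ids, dis$ref_ids),
                   cand_ids = c(sim$cand_ids, dis$cand_ids),
                   seed = seed)
    }
    list(
      train = combine(sim_train, dis_train),
      test = combine(n_train / 2 + seq_len(n_test / 2),
                     n_train / 2 + seq_len(n_test / 2))
    )
  })
}

#' Run the simulated similarity-group validation study
#'
#' Generates the grouped SNPs, samples balanced train/test pairs, trains the
#' constrained forest and evaluates on the held-out pairs. With defaults
#' (500 SNPs, 10 groups, 400/200 pairs) the groups are separable by
#' construction and the held-out ROC-AUC is expected to be 1.0.
#'
#' @param config A [simulation_config()].
#' @param model_cfg A [model_config()]; its seed defaults to the simulation
#'   seed.
#' @return A list: `report` (the [evaluate_model()] result), `auc`,
#'   `n_train`, `n_test`, `sim` (the generated dataset) and `model`.
#' @export
simulated_validation <- function(config = simulation_config(),
                                 model_cfg = NULL) {
  if (is.null(model_cfg)) model_cfg <- model_config(seed = config$seed)
  sim <- generate_similarity_groups(config)
  pairs <- sample_group_pairs(sim$records, sim$groups,
                              n_train = config$n_train_pairs,
                              n_test = config$n_test_pairs,
                              seed = config$seed)
  model <- train_similarity_model(pairs$train, model_cfg)
  report <- evaluate_model(model, pairs$test)
  list(report = report, auc = report$roc_auc,
       n_train = nrow(pairs$train$pairs), n_test = nrow(pairs$test$pairs),
       sim = sim, model = model)
}

random_rsids <- function(n, offset) {
  sprintf("rs%d", offset + sample.int(9e6, n))
}

format_pvalue <- function(p) {
  out <- formatC(p, format = "g", digits = 6)
  out[p == 0] <- "0"
  out
}

#' Generate a synthetic catalog pair in both TSV dialects
#'
#' Writes a positive file (association-download dialect: `riskAllele`,
#' `locations`, `mappedGenes`, `pValue`) and a negative file (full-catalog
#' dialect: `SNPS`, `STRONGEST SNP-RISK ALLELE`, `CHR_ID`, `CHR_POS`,
#' `MAPPED_GENE`, `P-VALUE`, `DISEASE/TRAIT`) with realistic quirks:
#' allele-suffixed risk alleles, mixed `,`/`;` gene separators, `-`
#' placeholders for intergenic rows at `intergenic_rate`, and p-values
#' including exact 0 and 1 among the negatives.
#'
#' Positives are placed in clustered loci (significant p-values). When
#' `planted_structure` is on, a fraction of negatives is planted near
#' positive loci — same chromosome, nearby position, matching p-value band —
#' so an end-to-end run should recover them in the top-k lists; negatives
#' are also given a chromosome-18 excess, so the chromosome summary has a
#' detectable mode.
#'
#' @param n_positive,n_negative Record counts (defaults 189 / 5,000, the
#'   positive-set scale of the motivating case study and a pool large enough
#'   for non-trivial ranking).
#' @param dir Output directory (created if missing).
#' @param planted_structure Plant near-positive negatives and the
#'   chromosome-18 excess (default TRUE).
#' @param intergenic_rate Fraction of rows with no gene data (default 0.2).
#' @param significant_fraction Fraction of negatives with
#'   \eqn{-\log_{10}(p) \ge 7.3} (default 0.1).
#' @param seed Integer seed.
#' @return A list with `positive_path`, `negative_path`, `sidecar_path`
#'   (JSON with the generating config and ground truth) and `planted`
#'   (rsids of the planted near-positive negatives).
#' @export
generate_catalog <- function(n_positive = 189, n_negative = 5000,
                             dir = tempfile("snpsim_catalog_"),
                             planted_structure = TRUE, intergenic_rate = 0.2,
                             significant_fraction = 0.1, seed = 42) {
  if (n_positive < 2) stop_config("n_positive must be >= 2")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alleles <- c("A", "C", "G", "T", "?")
  withr::with_seed(seed, {
    # --- positives: clustered significant loci on autosomes
    n_loci <- max(2, min(20, n_positive %/% 5))
    locus_chr <- sample(as.character(1:22), n_loci, replace = TRUE)
    locus_pos <- round(stats::runif(n_loci, 1e6, 2e8))
    locus_of <- sample.int(n_loci, n_positive, replace = TRUE)
    pos_chr <- locus_chr[locus_of]
    pos_pos <- locus_pos[locus_of] + round(stats::runif(n_positive, 0, 5e4))
    pos_logp <- stats::runif(n_positive, 7.5, 40)
    pos_rsid <- random_rsids(n_positive, 1e7)
    pos_genes <- make_gene_fields(n_positive, intergenic_rate)

    positive <- data.frame(
      riskAllele = paste0(pos_rsid, "-", sample(alleles, n_positive, TRUE)),
      locations = paste0(pos_chr, ":", pos_pos),
      mappedGenes = pos_genes,
      pValue = format_pvalue(10^(-pos_logp)),
      check.names = FALSE
    )

    # --- negatives: background pool
    n_planted <- if (planted_structure) min(n_negative %/% 10, 5 * n_positive) else 0L
    n_bg <- n_negative - n_planted
    chr_weights <- stats::setNames(rep(1, 25), CHROMOSOME_TOKENS)
    if (planted_structure) chr_weights["18"] <- 6  # planted chromosome-18 excess
    neg_chr <- sample(CHROMOSOME_TOKENS, n_bg, TRUE, prob = chr_weights)
    neg_pos <- round(stats::runif(n_bg, 1, 2.4e8))
    sig <- stats::runif(n_bg) < significant_fraction
    neg_logp <- ifelse(sig, stats::runif(n_bg, 7.3, 30), stats::runif(n_bg, 0.3, 7.3))
    neg_p <- 10^(-neg_logp)
    # quirks: a handful of exact-0 and exact-1 p-values
    if (n_bg >= 10) {
      neg_p[1:2] <- 0
      neg_p[3:4] <- 1
    }
    neg_rsid <- random_rsids(n_bg, 2e7)
    neg_genes <- make_gene_fields(n_bg, intergenic_rate)

    planted_rsid <- character(0)
    if (n_planted > 0) {
      host <- sample.int(n_positive, n_planted, replace = TRUE)
      planted_rsid <- random_rsids(n_planted, 4e7)
      pl_chr <- pos_chr[host]
      pl_pos <- pos_pos[host] + round(stats::runif(n_planted, -2e4, 2e4))
      pl_pos <- pmax(pl_pos, 1)
      pl_logp <- pos_logp[host] + stats::runif(n_planted, -0.5, 0.5)
      neg_chr <- c(neg_chr, pl_chr)
      neg_pos <- c(neg_pos, pl_pos)
      neg_p <- c(neg_p, 10^(-pl_logp))
      neg_rsid <- c(neg_rsid, planted_rsid)
      neg_genes <- c(neg_genes, pos_genes[host])
    }
    shuffle <- sample.int(length(neg_rsid))
    traits <- sprintf("Trait %s", sample(LETTERS[1:12], length(neg_rsid), TRUE))
    negative <- data.frame(
      SNPS = neg_rsid[shuffle],
      `STRONGEST SNP-RISK ALLELE` = paste0(neg_rsid[shuffle], "-",
                                           sample(alleles, length(neg_rsid), TRUE)),
      CHR_ID = neg_chr[shuffle],
      CHR_POS = neg_pos[shuffle],
      MAPPED_GENE = neg_genes[shuffle],
      `P-VALUE` = format_pvalue(neg_p[shuffle]),
      `DISEASE/TRAIT` = traits,
      check.names = FALSE
    )
  })
  positive_path <- file.path(dir, "positive_catalog.tsv")
  negative_path <- file.path(dir, "negative_catalog.tsv")
  sidecar_path <- file.path(dir, "catalog_truth.json")
  readr::write_tsv(positive, positive_path, progress = FALSE)
  readr::write_tsv(negative, negative_path, progress = FALSE)
  jsonlite::write_json(
    list(n_positive = n_positive, n_negative = n_negative, seed = seed,
         planted_structure = planted_structure,
         intergenic_rate = intergenic_rate,
         significant_fraction = significant_fraction,
         planted_rsids = planted_rsid),
    sidecar_path, auto_unbox = TRUE, digits = NA
  )
  list(positive_path = positive_path, negative_path = negative_path,
       sidecar_path = sidecar_path, planted = planted_rsid)
}

# Gene fields with realistic separator quirks: ",", "; " mixes and the
# " - " intergenic placeholder.
make_gene_fields <- function(n, intergenic_rate) {
  pool <- sprintf("GENE%04d", 1:300)
  vapply(seq_len(n), function(i) {
    if (stats::runif(1) < intergenic_rate) {
      sample(c("-", "", "NA"), 1)
    } else {
      k <- sample(1:3, 1)
      sep <- sample(c(",", "; "), 1)
      paste(sample(pool, k), collapse = sep)
    }
  }, character(1))
}
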