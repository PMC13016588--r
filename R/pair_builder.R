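# Construction of labeled training pairs. Similar pairs (label 1) draw both
# members from the positive set; dissimilar pairs (label 0) pair a positive
# with a negative. Negative-negative pairs are undefined by the scheme.

new_pair_set <- function(features, labels, ref_ids, cand_ids, seed = NA_integer_) {
  pairs <- features
  pairs$pair_label <- as.integer(labels)
  structure(
    list(
      pairs = pairs,
      ref_ids = ref_ids,
      cand_ids = cand_ids,
      class_counts = c(similar = sum(labels == 1L), dissimilar = sum(labels == 0L)),
      seed = seed
    ),
    class = "pair_set"
  )
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d pairs (%d similar / %d dissimilar)\n",
              nrow(x$pairs), x$class_counts[["similar"]],
              x$class_counts[["dissimilar"]]))
  invisible(x)
}

#' Build a balanced labeled pair set
#'
#' Samples `n_per_class` distinct positive-positive pairs uniformly over the
#' \eqn{\binom{|P|}{2}} possibilities (all of them if fewer exist), labeled 1,
#' and `n_per_class` distinct positive-negative pairs, labeled 0. In every
#' pair the positive SNP is the `ref` member; positive-positive pairs are
#' ordered by rsid. Deterministic given `seed`.
#'
#' @param positives,negatives Cleaned record tibbles.
#' @param n_per_class Pairs per class. The default 848 (1,696 pairs total)
#'   yields a test-set support of about 339 pairs at a 20% hold-out split,
#'   the scale at which the reference protocol was evaluated.
#' @param seed Integer seed.
#' @return A `pair_set`: feature tibble with `pair_label`, parallel
#'   `ref_ids` / `cand_ids`, class counts and the seed.
#' @export
build_training_pairs <- function(positives, negatives, n_per_class = 848,
                                 seed = 42) {
  n_pos <- nrow(positives)
  n_neg <- nrow(negatives)
  if (n_pos < 2) stop_data("need at least 2 positive SNPs, got %d", n_pos)
  if (n_neg < 1) stop_data("need at least 1 negative SNP")
  if (n_per_class < 1) stop_config("n_per_class must be >= 1")
  n_cross <- n_pos * n_neg
  if (n_per_class > n_cross) {
    stop_data("n_per_class = %d exceeds the %d distinct dissimilar pairs",
              n_per_class, n_cross)
  }
  feats_p <- snp_features(positives)
  feats_n <- snp_features(negatives)

  withr::with_seed(seed, {
    # similar pairs: uniform without replacement over unordered positive pairs
    n_sim <- min(n_per_class, choose(n_pos, 2))
    ij <- sample_unordered_pairs(n_pos, n_sim)
    # order each pair by rsid so outputs are reproducible conventions
    swap <- positives$rsid[ij[, "i"]] > positives$rsid[ij[, "j"]]
    a <- ifelse(swap, ij[, "j"], ij[, "i"])
    b <- ifelse(swap, ij[, "i"], ij[, "j"])
    sim_feat <- pair_features(feats_p[a, ], feats_p[b, ])

    # dissimilar pairs: uniform without replacement over the cross product,
    # sampled as linear codes so it is never materialized
    codes <- sample.int(n_cross, n_per_class)
    pi <- (codes - 1L) %% n_pos + 1L
    ni <- (codes - 1L) %/% n_pos + 1L
    dis_feat <- pair_features(feats_p[pi, ], feats_n[ni, ])

    new_pair_set(
      features = dplyr::bind_rows(sim_feat, dis_feat),
      labels = c(rep(1L, n_sim), rep(0L, n_per_class)),
      ref_ids = c(positives$rsid[a], positives$rsid[pi]),
      cand_ids = c(positives$rsid[b], negatives$rsid[ni]),
      seed = seed
    )
  })
}

subset_pair_set <- function(ps, idx) {
  new_pair_set(
    features = ps$pairs[idx, setdiff(names(ps$pairs), "pair_label"), drop = FALSE],
    labels = ps$pairs$pair_label[idx],
    ref_ids = ps$ref_ids[idx],
    cand_ids = ps$cand_ids[idx],
    seed = ps$seed
  )
}

#' Stratified train/test split of a pair set
#'
#' Splits by `pair_label` so per-class proportions are preserved within one
#' pair; per-stratum test sizes are `round(test_fraction * n_class)`.
#' Deterministic given `seed`.
#'
#' @param pairset A `pair_set`.
#' @param test_fraction Fraction held out, in (0, 1). Default 0.2.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both `pair_set`s,
#'   forming a partition of the input.
#' @export
split_train_test <- function(pairset, test_fraction = 0.2, seed = 42) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_config("test_fraction must lie strictly between 0 and 1")
  }
  labels <- pairset$pairs$pair_label
  test_idx <- integer(0)
  withr::with_seed(seed, {
    for (cls in sort(unique(labels))) {
      cls_idx <- which(labels == cls)
      if (length(cls_idx) < 2) {
        stop_data("class %d has fewer than 2 pairs; cannot split", cls)
      }
      n_test <- max(1L, round(test_fraction * length(cls_idx)))
      test_idx <- c(test_idx, sample(cls_idx, n_test))
    }
  })
  list(
    train = subset_pair_set(pairset, setdiff(seq_along(labels), test_idx)),
    test = subset_pair_set(pairset, sort(test_idx))
  )
}
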