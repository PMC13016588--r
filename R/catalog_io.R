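# Reading and writing GWAS-Catalog-style TSV files.
#
# Two export dialects are supported: the "association download" dialect used
# for the positive (disease-associated) set, with columns riskAllele,
# locations, mappedGenes, pValue; and the "full catalog" dialect used for the
# negative/candidate pool, with columns SNPS (or STRONGEST SNP-RISK ALLELE),
# CHR_ID, CHR_POS, MAPPED_GENE, P-VALUE, DISEASE/TRAIT. Both are normalized
# into one record model: a tibble with columns rsid, chromosome, position,
# genes (list column of gene symbols), p_value, trait, label.

PREDICTION_COLUMNS <- c(
  "ref_rsid", "ref_chr", "ref_pos", "ref_genes", "ref_pvalue",
  "cand_rsid", "cand_chr", "cand_pos", "cand_genes", "cand_pvalue",
  "similarity_score"
)

#' Extract an rsID from a risk-allele token
#'
#' Catalog exports append the risk allele to the variant identifier
#' (`rs12345-A`); the identifier is everything before the first `-`.
#' The operation is idempotent: applying it to an already-clean rsID is a
#' no-op.
#'
#' @param token Character vector of risk-allele tokens.
#' @return Character vector of rsIDs.
#' @export
#' @examples
#' parse_risk_allele(c("rs12345-A", "rs12345", "  rs999-?"))
parse_risk_allele <- function(token) {
  out <- trimws(as.character(token))
  bad <- which(is.na(out) | !nzchar(out))
  if (length(bad) > 0) {
    stop_data("empty risk-allele token at row %d", bad[1])
  }
  sub("-.*$", "", out)
}

#' Parse a `chromosome:position` location token
#'
#' Splits on the first `:`; the chromosome part is normalized with
#' [normalize_chromosome()], the position parsed as a non-negative integer.
#' Tokens missing either part, or with a non-numeric position, yield `NA`
#' in both fields (they are counted later by [clean_records()]).
#'
#' @param token Character vector of location tokens.
#' @return A tibble with columns `chromosome` and `position`.
#' @export
#' @examples
#' parse_location(c("17:4500000", "X:123", ""))
parse_location <- function(token) {
  token <- as.character(token)
  has_colon <- !is.na(token) & grepl(":", token, fixed = TRUE)
  chrom <- rep(NA_character_, length(token))
  pos <- rep(NA_real_, length(token))
  if (any(has_colon)) {
    chrom_part <- sub(":.*$", "", token[has_colon])
    pos_part <- sub("^[^:]*:", "", token[has_colon])
    chrom_v <- normalize_chromosome(chrom_part)
    pos_v <- suppressWarnings(as.numeric(pos_part))
    ok <- nzchar(chrom_v) & !is.na(pos_v) & pos_v >= 0 & pos_v == floor(pos_v)
    chrom[has_colon][ok] <- chrom_v[ok]
    pos[has_colon][ok] <- pos_v[ok]
  }
  tibble::tibble(chromosome = chrom, position = pos)
}

# Case- and whitespace-insensitive header lookup; returns index or NA.
match_header <- function(wanted, headers) {
  norm <- function(x) gsub("\\s+", " ", tolower(trimws(x)))
  match(norm(wanted), norm(headers))
}

read_catalog_tsv <- function(path) {
  if (!file.exists(path)) stop_config("catalog file not found: %s", path)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

require_columns <- function(headers, required, path) {
  idx <- match_header(required, headers)
  if (anyNA(idx)) {
    stop_config("catalog %s is missing required column(s): %s",
                path, paste(required[is.na(idx)], collapse = ", "))
  }
  idx
}

parse_p_value <- function(x) {
  suppressWarnings(as.numeric(x))
}

# Multi-location rows carry several ";"-separated chromosome:position tokens;
# the first is used and the occurrence counted in the `multi_location`
# attribute of the returned tibble.
first_location <- function(tokens) {
  multi <- grepl(";", tokens, fixed = TRUE)
  list(token = sub(";.*$", "", tokens), n_multi = sum(multi, na.rm = TRUE))
}

#' Read a positive (disease-associated) catalog file
#'
#' Parses the association-download dialect: required columns `riskAllele`,
#' `locations` (`chromosome:position`), `mappedGenes` and `pValue`
#' (header match is case- and whitespace-insensitive). Every row becomes one
#' record with `label = "positive"`; rows with unparseable positions or
#' p-values survive here and are handled by [clean_records()].
#'
#' @param path Path to a tab-separated catalog export.
#' @return A tibble of SNP records (`rsid`, `chromosome`, `position`, `genes`
#'   list column, `p_value`, `trait`, `label`), with attribute
#'   `multi_location` counting rows whose location field held several
#'   `;`-separated locations (the first is used).
#' @export
read_positive_catalog <- function(path) {
  raw <- read_catalog_tsv(path)
  idx <- require_columns(names(raw), c("riskAllele", "locations", "mappedGenes", "pValue"), path)
  loc <- first_location(raw[[idx[2]]])
  parsed_loc <- parse_location(loc$token)
  out <- tibble::tibble(
    rsid = parse_risk_allele(raw[[idx[1]]]),
    chromosome = parsed_loc$chromosome,
    position = parsed_loc$position,
    genes = split_genes(raw[[idx[3]]]),
    p_value = parse_p_value(raw[[idx[4]]]),
    trait = NA_character_,
    label = "positive"
  )
  attr(out, "multi_location") <- loc$n_multi
  out
}

#' Read a negative/candidate catalog file
#'
#' Parses the full-catalog dialect: required columns `CHR_ID`, `CHR_POS`,
#' `MAPPED_GENE`, `P-VALUE`, plus at least one of `SNPS` /
#' `STRONGEST SNP-RISK ALLELE`. The identifier is taken from `SNPS` when
#' present and non-empty, else derived from the risk-allele column; the trait
#' comes from `DISEASE/TRAIT` when present. Every row gets
#' `label = "negative"`.
#'
#' @inheritParams read_positive_catalog
#' @return A tibble of SNP records, as [read_positive_catalog()].
#' @export
read_negative_catalog <- function(path) {
  raw <- read_catalog_tsv(path)
  idx <- require_columns(names(raw), c("CHR_ID", "CHR_POS", "MAPPED_GENE", "P-VALUE"), path)
  snps_idx <- match_header("SNPS", names(raw))
  risk_idx <- match_header("STRONGEST SNP-RISK ALLELE", names(raw))
  if (is.na(snps_idx) && is.na(risk_idx)) {
    stop_config("catalog %s needs a SNPS or STRONGEST SNP-RISK ALLELE column", path)
  }
  n <- nrow(raw)
  rsid <- if (!is.na(snps_idx)) trimws(raw[[snps_idx]]) else rep(NA_character_, n)
  need_fallback <- is.na(rsid) | !nzchar(rsid)
  if (any(need_fallback)) {
    if (is.na(risk_idx)) {
      stop_data("empty SNPS value at row %d and no risk-allele column",
                which(need_fallback)[1])
    }
    rsid[need_fallback] <- parse_risk_allele(raw[[risk_idx]][need_fallback])
  }
  trait_idx <- match_header("DISEASE/TRAIT", names(raw))
  pos <- suppressWarnings(as.numeric(raw[[idx[2]]]))
  pos[!is.na(pos) & (pos < 0 | pos != floor(pos))] <- NA_real_
  tibble::tibble(
    rsid = rsid,
    chromosome = normalize_chromosome(raw[[idx[1]]]),
    position = pos,
    genes = split_genes(raw[[idx[3]]]),
    p_value = parse_p_value(raw[[idx[4]]]),
    trait = if (!is.na(trait_idx)) as.character(raw[[trait_idx]]) else NA_character_,
    label = "negative"
  )
}

#' Drop or keep records with unparseable fields
#'
#' The modelling stages require a numeric position and a p-value in
#' \eqn{[0, 1]}. Under the default `"drop"` policy, records failing either
#' requirement are removed and counted per reason; `"keep-with-missing"`
#' passes everything through (for audits).
#'
#' @param records A record tibble from one of the catalog readers.
#' @param policy `"drop"` (default) or `"keep-with-missing"`.
#' @return A list with `records` (the kept tibble) and `report`, a named list
#'   counting `bad_position`, `bad_pvalue` and `n_removed`.
#' @export
clean_records <- function(records, policy = c("drop", "keep-with-missing")) {
  policy <- match.arg(policy)
  bad_pos <- is.na(records$position) | is.na(records$chromosome)
  bad_p <- is.na(records$p_value) | records$p_value < 0 | records$p_value > 1
  bad_p[is.na(bad_p)] <- TRUE
  report <- list(
    bad_position = sum(bad_pos),
    bad_pvalue = sum(bad_p),
    n_removed = if (policy == "drop") sum(bad_pos | bad_p) else 0L
  )
  kept <- if (policy == "drop") records[!(bad_pos | bad_p), ] else records
  list(records = kept, report = report)
}

#' Write a prediction table as TSV
#'
#' Fixed column order (`ref_rsid`, `ref_chr`, `ref_pos`, `ref_genes`,
#' `ref_pvalue`, then the same five `cand_*` columns, then
#' `similarity_score`); gene lists are `,`-joined strings. Any extra columns
#' (e.g. filter flags) are appended after the fixed block.
#'
#' @param predictions A prediction tibble from [predict_all()] or
#'   [filter_candidates()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  extra <- setdiff(names(predictions), PREDICTION_COLUMNS)
  ordered <- predictions[, c(PREDICTION_COLUMNS, extra), drop = FALSE]
  readr::write_tsv(ordered, path, progress = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions_tsv()]
#'
#' @param path Path to the predictions TSV.
#' @return The prediction tibble with numeric positions, p-values and scores.
#' @export
read_predictions_tsv <- function(path) {
  if (!file.exists(path)) stop_config("predictions file not found: %s", path)
  out <- readr::read_tsv(path, col_types = readr::cols(
    ref_rsid = readr::col_character(), ref_chr = readr::col_character(),
    ref_pos = readr::col_double(), ref_genes = readr::col_character(),
    ref_pvalue = readr::col_double(),
    cand_rsid = readr::col_character(), cand_chr = readr::col_character(),
    cand_pos = readr::col_double(), cand_genes = readr::col_character(),
    cand_pvalue = readr::col_double(),
    similarity_score = readr::col_double(), .default = readr::col_guess()
  ), progress = FALSE)
  missing <- setdiff(PREDICTION_COLUMNS, names(out))
  if (length(missing) > 0) {
    stop_config("predictions file %s is missing column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  out$ref_genes[is.na(out$ref_genes)] <- ""
  out$cand_genes[is.na(out$cand_genes)] <- ""
  out
}
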