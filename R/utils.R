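#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Condition helpers: configuration errors (bad columns, bad parameters) and
# data errors (contract violations at run time) carry distinct classes so a
# shell wrapper can map them to distinct exit codes.
stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("snpsim_config_error", "snpsim_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("snpsim_data_error", "snpsim_error")))
}

#' Normalize a chromosome token
#'
#' Uppercases, trims whitespace and removes a leading `chr` prefix so that
#' common export variants (`chr17`, ` x `) collapse onto the canonical tokens
#' `1`..`22`, `X`, `Y`, `MT` used by [encode_chromosome()].
#'
#' @param chrom Character vector of raw chromosome tokens.
#' @return Character vector of normalized tokens (`NA` stays `NA`).
#' @export
#' @examples
#' normalize_chromosome(c("chr17", " x ", "MT"))
normalize_chromosome <- function(chrom) {
  out <- toupper(trimws(as.character(chrom)))
  sub("^CHR", "", out)
}

# Gene-field tokenization: GWAS-Catalog exports mix "," and ";" separators and
# mark intergenic rows with " - " (or leave the field blank / "NA" / "NR").
# All of those normalize to an empty gene list.
split_genes <- function(x) {
  x <- as.character(x)
  lapply(x, function(field) {
    if (is.na(field)) return(character(0))
    toks <- trimws(strsplit(field, "[,;]")[[1]])
    toks[nzchar(toks) & !toks %in% c("-", "NA", "NR")]
  })
}

join_genes <- function(genes) {
  vapply(genes, function(g) paste(g, collapse = ","), character(1))
}

# Uniform sample of `n` distinct unordered index pairs from 1..m (i < j).
# Enumerates when the pair universe is small, otherwise samples linear codes.
sample_unordered_pairs <- function(m, n) {
  total <- choose(m, 2)
  if (n > total) stop_data("requested %d pairs but only %.0f exist", n, total)
  codes <- sample.int(total, n)
  # decode linear code k (1-based) into (i, j), i < j: k = (j-1)(j-2)/2 + i
  j <- ceiling((1 + sqrt(1 + 8 * codes)) / 2)
  i <- codes - (j - 1) * (j - 2) / 2
  # guard against sqrt rounding at exact triangular numbers
  over <- i < 1
  j[over] <- j[over] - 1
  i[over] <- codes[over] - (j[over] - 1) * (j[over] - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}
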