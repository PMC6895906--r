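#' Normalize a disease name
#'
#' Lower-cases, trims leading/trailing whitespace, and collapses internal runs
#' of whitespace to a single space, so that names from different sources
#' ("Alzheimer's Disease", " alzheimer's  disease ") key identically. An
#' optional synonym map (named character vector, `names(map)` are normalized
#' aliases, values the canonical names) is applied after normalization; this is
#' how user catalogs are matched to phenotype-network entries.
#'
#' @param x character vector of disease names.
#' @param synonyms optional named character vector mapping normalized aliases
#'   to canonical normalized names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_disease(c(" Parkinson's   Disease", "EPILEPSY"))
normalize_disease <- function(x, synonyms = NULL) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  if (!is.null(synonyms)) {
    stopifnot(is.character(synonyms), !is.null(names(synonyms)))
    hit <- match(x, names(synonyms))
    x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  x
}

# Round half away from zero (commercial rounding). base::round() rounds half
# to even, which would report 1607/837 differently from the conventional
# one-decimal ratio.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical unordered-pair representation: element-wise (min, max) on the
# lexicographic order, so (a, b) and (b, a) share one key.
canonical_pair <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  list(a = pmin(a, b), b = pmax(a, b))
}

pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p$a, p$b, sep = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic per-stream seed derived from a root seed and a stream name,
# kept inside 32-bit integer range. Lets each synthetic sub-generator be
# regenerated independently of the others.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
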