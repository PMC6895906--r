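# Small in-code fixtures shared across test files.

mutation_fixture <- function(n = 3, disease = "ataxia", gene = "SACS",
                             source = "curated") {
  data.frame(
    disease = disease, gene = gene, build = "hg19", chrom = "13",
    pos = as.numeric(seq_len(n)), ref = "A", alt = "G", source = source,
    pathogenicity = "pathogenic", stringsAsFactors = FALSE
  )
}

write_mutation_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gmt_fixture <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, paste0(nm, " description"), sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  path
}

# genes x samples study with r regions x k samples, constant baseline
flat_study <- function(n_genes = 4, regions = c("cortex", "putamen", "medulla"),
                       k = 2, value = 5) {
  samples <- paste0("s", seq_len(length(regions) * k))
  m <- matrix(value, n_genes, length(samples),
              dimnames = list(paste0("g", seq_len(n_genes)), samples))
  expression_study(m, stats::setNames(rep(regions, each = k), samples))
}
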