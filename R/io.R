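# Readers and writers for the plain-text study layout.

#' Read and write genotype matrices
#'
#' Genotypes travel as TSV with lines in rows and markers in columns,
#' first column `line`, calls coded `A` (cultivated parent), `B` (wild
#' parent) or `NA`.
#'
#' @param path file path
#' @param geno character genotype matrix
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  geno <- as.matrix(df[, -1, drop = FALSE])
  rownames(geno) <- df[[1]]
  mode(geno) <- "character"
  assert_genotype_matrix(geno)
  geno
}

#' @rdname genotype_io
#' @export
write_genotypes_tsv <- function(geno, path) {
  df <- data.frame(line = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker map TSV (`marker`, `chrom`, `pos_cM`)
#' @param path file path
#' @return data.frame sorted by chromosome and position
#' @export
read_map_tsv <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chrom", "pos_cM") %in% names(map)))
  map[order(map$chrom, map$pos_cM), , drop = FALSE]
}

#' Read a replicate-level phenotype TSV
#'
#' Expected columns: `line`, `env` (WW/WL), `rep`, `trait`, `value`.
#' @param path file path
#' @return long-format data.frame
#' @export
read_phenotypes_tsv <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line", "env", "rep", "trait", "value") %in% names(ph)))
  if (!all(ph$env %in% c("WW", "WL")))
    stop("environment codes must be WW or WL")
  ph
}

#' Read a marker physical-anchor TSV (`marker`, `chrom`, `bp`; 1-based)
#' @param path file path
#' @return data.frame with one bp per marker
#' @export
read_anchors_tsv <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chrom", "bp") %in% names(a)))
  if (any(a$bp < 1)) stop("bp positions are 1-based and must be >= 1")
  if (anyDuplicated(a$marker)) stop("anchor table has duplicated markers")
  a
}
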