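# Internal helpers shared across modules.

# Union-find with path halving; `n` elements, returns merge/find closures.
uf_new <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  components <- function() {
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
  }
  list(find = find, union = union, components = components)
}

# Connected components of an undirected edge list over n nodes.
# Returns an integer component label per node (1-based, by first appearance).
connected_components <- function(n, edges_i, edges_j) {
  uf <- uf_new(n)
  if (length(edges_i)) {
    for (k in seq_along(edges_i)) uf$union(edges_i[k], edges_j[k])
  }
  uf$components()
}

# Genotype matrices use character codes "A" (P1), "B" (P2), NA for missing.
# Numeric dosage: A -> -1 (cultivated parent), B -> +1 (wild parent).
geno_to_dosage <- function(geno) {
  stopifnot(is.matrix(geno))
  d <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  d[geno == "A"] <- -1
  d[geno == "B"] <- 1
  d
}

dosage_to_geno <- function(dos) {
  g <- matrix(NA_character_, nrow(dos), ncol(dos), dimnames = dimnames(dos))
  g[dos == -1] <- "A"
  g[dos == 1] <- "B"
  g
}

assert_genotype_matrix <- function(geno) {
  if (!is.matrix(geno) || !is.character(geno))
    stop("genotype matrix must be a character matrix with codes 'A'/'B'/NA")
  bad <- !(geno %in% c("A", "B")) & !is.na(geno)
  if (any(bad))
    stop("genotype calls outside {A, B, NA}: e.g. ",
         paste(utils::head(unique(geno[bad]), 3), collapse = ", "))
  if (nrow(geno) < 2L || ncol(geno) < 2L)
    stop("genotype matrix needs at least 2 lines and 2 markers")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
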