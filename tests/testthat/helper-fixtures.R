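# small fixtures shared across test files; everything built in code

mini_scheme <- function() {
  location_scheme(c("nucleus", "cytoplasm"),
                  c(nuclear = "nucleus", cytosol = "cytoplasm",
                    vesicles = "unmappable"))
}

# single-label table from a named character vector protein -> label
single_label_table <- function(labels, source = "src") {
  annotation_table(names(labels), unname(labels), source = source)
}

# write lines to a temp file, return path
tmp_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# random strictly-positive composition
random_simplex <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

# random row-stochastic matrix
random_stochastic <- function(k) {
  m <- matrix(stats::rgamma(k * k, shape = 1), k, k)
  m / rowSums(m)
}

# brute-force rooted clade set of a phylo tree (independent of the package's
# prop.part-based implementation): walk edges recursively
brute_clades <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  leaves_under <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    sort(unlist(lapply(kids[[as.character(node)]], leaves_under)))
  }
  internal <- unique(tree$edge[, 1])
  sort(vapply(internal, function(nd)
    paste(leaves_under(nd), collapse = "|"), ""))
}
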