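spec2 <- function(v, id, sch = mini_scheme()) location_spectrum(v, sch, id)

test_that("spectrum distance is the Euclidean norm of the difference", {
  sch <- seven_class_scheme()
  p <- location_spectrum(c(.5, .5, 0, 0, 0, 0, 0), sch, "a")
  q <- location_spectrum(c(.2, .8, 0, 0, 0, 0, 0), sch, "b")
  expect_equal(spectrum_distance(p, p), 0)
  expect_equal(spectrum_distance(p, q), sqrt(0.09 + 0.09), tolerance = 1e-12)
  i1 <- location_spectrum(c(1, 0, 0, 0, 0, 0, 0), sch, "i")
  i2 <- location_spectrum(c(0, 1, 0, 0, 0, 0, 0), sch, "j")
  expect_equal(spectrum_distance(i1, i2), sqrt(2))
  other <- location_spectrum(c(.5, .5), mini_scheme(), "x")
  expect_error(spectrum_distance(p, other), "different schemes")
})

test_that("pairwise distances are symmetric, zero-diagonal, consistent and metric", {
  set.seed(3)
  sch <- seven_class_scheme()
  sps <- lapply(1:6, function(i)
    location_spectrum(random_simplex(7), sch, paste0("org", i)))
  d <- pairwise_distances(sps)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(d[i, j], spectrum_distance(sps[[i]], sps[[j]]),
                 tolerance = 1e-12)
  # triangle inequality
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  expect_error(pairwise_distances(list(sps[[1]], sps[[1]])), "duplicate")
})

test_that("UPGMA reproduces hand-computed merges and heights", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma_tree(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))

  d3 <- matrix(c(0, 2, 6,
                 2, 0, 6,
                 6, 6, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma_tree(d3)
  expect_equal(brute_clades(t3), sort(c("A|B", "A|B|C")))
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 6)
  # heights: AB node at 1, root at 3 -> C branch length 3
  expect_equal(sort(unname(t3$edge.length)), c(1, 1, 2, 3))

  expect_error(upgma_tree(matrix(c(0, -1, -1, 0), 2,
                                 dimnames = list(c("A", "B"), c("A", "B")))),
               "negative")
})

test_that("UPGMA reconstructs any ultrametric distance matrix exactly", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    ref <- ape::rcoal(n, tip.label = sprintf("t%02d", 1:n))
    D <- ape::cophenetic.phylo(ref)
    ord <- sample(n)                       # label order must not matter
    D <- D[ord, ord]
    tr <- upgma_tree(D)
    cp <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(cp - D)), 1e-9)
    expect_equal(tree_topology_distance(tr, ref), 0)
    # ultrametricity of the output
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(diff(range(depths)), 1e-9)
  }
})

test_that("UPGMA agrees with average-linkage hclust on generic matrices", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    x <- matrix(stats::rnorm(n * 5), n)
    rownames(x) <- sprintf("s%02d", 1:n)
    D <- as.matrix(stats::dist(x))
    tr <- upgma_tree(D)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    oracle <- ape::as.phylo(hc)
    expect_equal(tree_topology_distance(tr, oracle), 0)
    expect_equal(sort(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]),
                 sort(ape::cophenetic.phylo(oracle)[rownames(D), colnames(D)]),
                 tolerance = 1e-9)
    oracle2 <- phangorn::upgma(stats::as.dist(D))
    expect_equal(tree_topology_distance(tr, oracle2), 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)],
                 ape::cophenetic.phylo(oracle2)[rownames(D), colnames(D)],
                 tolerance = 1e-9)
  }
})

test_that("UPGMA tie-breaking is deterministic under label permutation", {
  # all off-diagonal distances distinct: permuting labels must not change
  # the tree
  set.seed(8)
  n <- 7
  x <- matrix(stats::rnorm(n * 4), n)
  rownames(x) <- sprintf("L%d", 1:n)
  D <- as.matrix(stats::dist(x))
  t1 <- upgma_tree(D)
  for (i in 1:5) {
    ord <- sample(n)
    t2 <- upgma_tree(D[ord, ord])
    expect_equal(tree_topology_distance(t1, t2), 0)
  }
  # exact ties resolved lexicographically: equidistant triple merges A,B first
  dt <- matrix(1, 3, 3) - diag(3)
  dimnames(dt) <- list(c("C", "A", "B"), c("C", "A", "B"))
  tt <- upgma_tree(dt)
  expect_true("A|B" %in% brute_clades(tt))
})

test_that("newick output round-trips and malformed input reports a position", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  path <- tempfile(fileext = ".nwk")
  write_newick(upgma_tree(d2), path)
  txt <- readLines(path)
  expect_match(txt, ";$")
  expect_match(txt, "A:0.2")
  set.seed(4)
  tr <- ape::rcoal(10, tip.label = sprintf("x%02d", 1:10))
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(tree_topology_distance(back, tr), 0)
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-6)

  bad <- tempfile(fileext = ".nwk")
  writeLines("(A:0.2,B:0.2;", bad)
  expect_error(read_newick(bad), "position 13")
  writeLines("(A:0.2,B:0.2)", bad)
  expect_error(read_newick(bad), "missing terminating")
  writeLines("(A:0.2,B:0.2));", bad)
  expect_error(read_newick(bad), "unmatched")
})

test_that("topology distance is the symmetric clade-set difference", {
  t_ab <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  t_ac <- ape::read.tree(text = "((A:1,C:1):1,B:2);")
  expect_equal(tree_topology_distance(t_ab, t_ab), 0)
  expect_equal(tree_topology_distance(t_ab, t_ac), 2)
  cat4 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  bal4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  brute <- length(setdiff(brute_clades(cat4), brute_clades(bal4))) +
    length(setdiff(brute_clades(bal4), brute_clades(cat4)))
  expect_equal(tree_topology_distance(cat4, bal4), brute)
  expect_error(tree_topology_distance(t_ab,
                                      ape::read.tree(text = "((A:1,B:1):1,D:2);")),
               "leaf sets")
})

test_that("PCA projection centers, orders variance and preserves distances at full rank", {
  sch <- seven_class_scheme()
  # identical spectra -> all coordinates zero
  same <- lapply(1:4, function(i)
    location_spectrum(rep(1 / 7, 7), sch, paste0("o", i)))
  expect_equal(max(abs(pca_project(same, 2))), 0)

  # two distinct points (duplicated): PC1 symmetric about 0, separation = d
  p <- c(.4, .3, .1, .1, .05, .03, .02); q <- c(.1, .1, .4, .2, .1, .05, .05)
  four <- list(location_spectrum(p, sch, "a1"), location_spectrum(p, sch, "a2"),
               location_spectrum(q, sch, "b1"), location_spectrum(q, sch, "b2"))
  sc <- pca_project(four, 1)
  expect_equal(sum(sc[, 1]), 0, tolerance = 1e-12)
  d <- spectrum_distance(four[[1]], four[[3]])
  expect_equal(abs(sc["a1", 1] - sc["b1", 1]), d, tolerance = 1e-9)

  # full rank: projected pairwise distances equal spectrum distances
  set.seed(31)
  sps <- lapply(1:9, function(i)
    location_spectrum(random_simplex(7), sch, paste0("r", i)))
  full <- pca_project(sps, 7)
  expect_equal(as.matrix(stats::dist(full)), pairwise_distances(sps),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_project(sps, 9), "k must")
})

test_that("ortholog/in-paralog splitting follows the group roles", {
  g <- ortholog_groups(data.frame(
    group_id   = c("g1", "g1", "g2", "g2", "g2", "g2", "g3", "g3"),
    species_id = c("hs", "mm", "hs", "hs", "hs", "mm", "hs", "dm"),
    gene_id    = c("H1", "M1", "H2", "H2b", "H2c", "M2", "H3", "D3"),
    role       = c("seed_ortholog", "seed_ortholog",
                   "seed_ortholog", "inparalog", "inparalog",
                   "seed_ortholog", "seed_ortholog", "seed_ortholog")))
  out <- split_ortholog_paralog_sets(g, c("hs", "mm"))
  # g1: clean 1:1 orthologs; g2: hs side expanded -> H2 excluded, H2b/H2c in-paralogs
  expect_equal(out$hs$orthologs, "H1")
  expect_equal(out$hs$inparalogs, c("H2b", "H2c"))
  expect_equal(out$mm$orthologs, c("M1", "M2"))
  expect_equal(out$mm$inparalogs, character(0))

  # a gene in an in-paralog group vs a third species leaves the ortholog set
  g2 <- ortholog_groups(data.frame(
    group_id   = c("a", "a", "b", "b", "b"),
    species_id = c("hs", "mm", "hs", "hs", "dm"),
    gene_id    = c("H1", "M1", "H1", "H1b", "D1"),
    role       = c("seed_ortholog", "seed_ortholog",
                   "seed_ortholog", "inparalog", "seed_ortholog")))
  expect_error(ortholog_groups(data.frame(
    group_id = c("x", "x"), species_id = c("s", "s"),
    gene_id = c("G", "G"), role = c("seed_ortholog", "seed_ortholog"))),
    "duplicate gene")
  out2 <- split_ortholog_paralog_sets(g2, c("hs", "mm"))
  expect_equal(out2$hs$orthologs, character(0))   # H1 duplicated vs dm

  expect_error(split_ortholog_paralog_sets(g, c("hs", "zz")), "absent")
})
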