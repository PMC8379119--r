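#' Euclidean distance between two location spectra
#'
#' The straight-line (Pythagorean) distance
#' \deqn{d(p, q) = \sqrt{\sum_i (q_i - p_i)^2}}{d(p,q) = sqrt(sum (q_i - p_i)^2)}
#' between two composition vectors over the same scheme; the proxy used to
#' compare the location spectra of organisms (and of predictions vs
#' experiments).
#'
#' @param p,q `location_spectrum`s over the same scheme.
#' @return A non-negative number.
#' @export
spectrum_distance <- function(p, q) {
  stopifnot(inherits(p, "location_spectrum"),
            inherits(q, "location_spectrum"))
  if (!same_classes(p, q))
    stop("spectra use different schemes", call. = FALSE)
  sqrt(sum((unname(q$values) - unname(p$values))^2))
}

#' All pairwise spectrum distances
#'
#' @param spectra List of `location_spectrum`s with unique organism ids over a
#'   common scheme.
#' @return A symmetric numeric matrix with zero diagonal, labeled by organism
#'   id.
#' @export
pairwise_distances <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 2L)
  lapply(spectra, function(s) stopifnot(inherits(s, "location_spectrum")))
  ids <- vapply(spectra, function(s) s$organism_id, "")
  if (anyDuplicated(ids))
    stop("duplicate organism id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (s in spectra[-1L])
    if (!same_classes(spectra[[1L]], s))
      stop("spectra use different schemes", call. = FALSE)
  x <- do.call(rbind, lapply(spectra, as.numeric))
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(ids, ids)
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    stop("distance matrix needs unique labels", call. = FALSE)
  if (anyNA(d) || any(!is.finite(d)))
    stop("distance matrix contains NA/non-finite entries", call. = FALSE)
  if (any(d < 0))
    stop("distance matrix contains negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  d
}

#' UPGMA tree from a distance matrix
#'
#' Unweighted pair group method with arithmetic mean: repeatedly merge the
#' two closest clusters, placing the new node at height `d/2`; the distance
#' from the merged cluster `AB` to any other cluster `C` is the
#' size-weighted average `(|A| d(A,C) + |B| d(B,C)) / (|A| + |B|)`. The
#' result is a rooted, ultrametric `phylo` tree (all root-to-leaf path
#' lengths equal). Ties between equally close pairs are broken by the
#' lexicographic order of the smallest member label in each cluster, so the
#' output is deterministic across platforms.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal and
#'   unique row/column labels (e.g. from [pairwise_distances()]).
#' @return An [ape::as.phylo] `phylo` object (rooted, with branch lengths).
#' @export
upgma_tree <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 labels", call. = FALSE)
  labels <- rownames(d)
  # active cluster state
  cl <- lapply(seq_len(n), function(i)
    list(members = labels[i], size = 1L, height = 0, tip = i, node = NULL,
         children = NULL))
  key <- vapply(cl, function(c) min(c$members), "")   # tie-break key
  D <- d
  for (step in seq_len(n - 1L)) {
    m <- length(cl)
    if (m == 1L) break
    # find the closest pair; ties -> lexicographic (min label, then partner)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      cand_d <- D[i, j]
      cand_key <- sort(c(key[i], key[j]))
      if (is.null(best) || cand_d < best$d ||
          (cand_d == best$d &&
           (cand_key[1L] < best$key[1L] ||
            (cand_key[1L] == best$key[1L] && cand_key[2L] < best$key[2L])))) {
        best <- list(i = i, j = j, d = cand_d, key = cand_key)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    new <- list(members = c(cl[[i]]$members, cl[[j]]$members),
                size = cl[[i]]$size + cl[[j]]$size,
                height = h, tip = NA_integer_,
                children = list(cl[[i]], cl[[j]]))
    # weighted-average linkage update
    others <- setdiff(seq_len(m), c(i, j))
    newrow <- (cl[[i]]$size * D[i, others] + cl[[j]]$size * D[j, others]) /
      new$size
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, newrow), c(newrow, 0))
    cl <- c(cl[others], list(new))
    key <- c(key[others], min(new$members))
  }
  build_phylo(cl[[1L]], labels)
}

# convert the nested cluster produced by upgma_tree into an ape phylo
build_phylo <- function(root, labels) {
  n <- length(labels)
  edge <- matrix(0L, 2L * n - 2L, 2L)
  edge_len <- numeric(2L * n - 2L)
  next_node <- n + 1L
  e <- 0L
  rec <- function(cluster, parent_id, parent_height) {
    if (!is.na(cluster$tip)) {
      id <- cluster$tip
    } else {
      id <- next_node; next_node <<- next_node + 1L
    }
    if (!is.null(parent_id)) {
      e <<- e + 1L
      edge[e, ] <<- c(parent_id, id)
      edge_len[e] <<- parent_height - cluster$height
    }
    if (is.na(cluster$tip))
      for (ch in cluster$children) rec(ch, id, cluster$height)
    id
  }
  rec(root, NULL, NA_real_)
  tr <- list(edge = edge, edge.length = edge_len, tip.label = labels,
             Nnode = n - 1L)
  class(tr) <- "phylo"
  stats::reorder(tr)
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers around [ape::write.tree()] / [ape::read.tree()]. Writing
#' keeps at least 10 significant digits on branch lengths and terminates the
#' string with `;`. Reading first checks the text for structural errors
#' (unbalanced parentheses, missing terminal semicolon) and reports the
#' 1-based character offset of the first problem.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `write_newick` returns `path` invisibly; `read_newick` returns a
#'   `phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick(txt)
  ape::read.tree(text = txt)
}

# structural scan reporting the position of the first syntax problem
check_newick <- function(txt) {
  chars <- strsplit(txt, "")[[1L]]
  depth <- 0L
  done <- FALSE
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (done && !grepl("^\\s$", ch))
      stop("newick parse error at position ", pos,
           ": text after terminating ';'", call. = FALSE)
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error at position ", pos,
             ": unmatched ')'", call. = FALSE)
    } else if (ch == ";") {
      if (depth > 0L)
        stop("newick parse error at position ", pos, ": ", depth,
             " unclosed '(' before ';'", call. = FALSE)
      done <- TRUE
    }
  }
  if (!done)
    stop("newick parse error at position ", length(chars) + 1L,
         ": missing terminating ';'", call. = FALSE)
  invisible(TRUE)
}

#' Rooted topology distance between two trees
#'
#' The symmetric difference of the two trees' rooted clade sets, where a
#' clade is the set of leaf names under an internal node. Zero if and only
#' if the rooted topologies are identical; branch lengths are ignored. Both
#' trees must carry the same leaf set.
#'
#' @param a,b `phylo` trees on the same leaves.
#' @return A non-negative even integer.
#' @export
tree_topology_distance <- function(a, b) {
  stopifnot(inherits(a, "phylo"), inherits(b, "phylo"))
  if (!setequal(a$tip.label, b$tip.label) ||
      length(a$tip.label) != length(b$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
  ca <- rooted_clades(a)
  cb <- rooted_clades(b)
  sum(!(ca %in% cb)) + sum(!(cb %in% ca))
}

# canonical string per internal-node clade (including the root clade)
rooted_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  vapply(pp, function(ix)
    paste(sort(tree$tip.label[ix]), collapse = "\r"), "")
}

#' PCA projection of location spectra
#'
#' Principal component analysis of the organism x class spectrum matrix:
#' columns are mean-centered (covariance PCA, no scaling — the spectra
#' already share a scale) and the organisms are projected onto the top `k`
#' principal axes. Axis signs follow the convention that the loading of
#' largest absolute value on each axis is positive. With `k` equal to the
#' number of classes the projection is an isometry of the centered data, so
#' pairwise projected distances equal the spectrum distances.
#'
#' @param spectra List of >= 3 `location_spectrum`s (common scheme, unique
#'   ids).
#' @param k Number of components (`1 <= k < length(spectra)` and
#'   `k <=` number of classes).
#' @return A numeric matrix (organisms x `k`), rownames = organism ids,
#'   colnames `PC1..PCk`.
#' @export
pca_project <- function(spectra, k = 2) {
  stopifnot(is.list(spectra))
  if (length(spectra) < 3L)
    stop("need at least 3 spectra for a PCA view", call. = FALSE)
  ids <- vapply(spectra, function(s) s$organism_id, "")
  if (anyDuplicated(ids))
    stop("duplicate organism id(s)", call. = FALSE)
  x <- do.call(rbind, lapply(spectra, as.numeric))
  if (k < 1 || k >= length(spectra) || k > ncol(x))
    stop("k must satisfy 1 <= k < n_organisms and k <= n_classes",
         call. = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  pr <- stats::prcomp(xc, center = FALSE, scale. = FALSE)
  scores <- pr$x
  if (ncol(scores) < k)   # degenerate rank: pad with zero coordinates
    scores <- cbind(scores, matrix(0, nrow(scores), k - ncol(scores)))
  scores <- scores[, seq_len(k), drop = FALSE]
  rot <- pr$rotation
  for (j in seq_len(min(k, ncol(rot)))) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(ids, paste0("PC", seq_len(k)))
  scores
}

#' Read an ortholog-group table
#'
#' Normalized TSV with columns `group_id`, `species_id`, `gene_id`, `role`
#' (`seed_ortholog` or `inparalog`). Groups are pairwise (InParanoid style),
#' so a gene may belong to several groups against different partner species
#' but not appear twice within one group; each group must have at least one
#' seed ortholog per represented species.
#'
#' @param path File path.
#' @return A data frame of class `ortholog_groups`.
#' @export
read_ortholog_groups <- function(path) {
  if (!file.exists(path)) stop("ortholog table not found: ", path,
                               call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           quote = "", fileEncoding = "UTF-8")
  ortholog_groups(raw)
}

#' @rdname read_ortholog_groups
#' @param x Data frame with the four columns above.
#' @export
ortholog_groups <- function(x) {
  need <- c("group_id", "species_id", "gene_id", "role")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("ortholog table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x)[need]
  bad_role <- setdiff(unique(x$role), c("seed_ortholog", "inparalog"))
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  # groups are per species pair (InParanoid style): a gene may sit in several
  # groups against different partner species, but not twice in one group
  key <- paste(x$group_id, x$species_id, x$gene_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate gene row(s) within a group: ",
         paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 5L),
               collapse = ", "), call. = FALSE)
  for (g in split(x, x$group_id)) {
    seeds <- unique(g$species_id[g$role == "seed_ortholog"])
    missing_seed <- setdiff(unique(g$species_id), seeds)
    if (length(missing_seed))
      stop("group ", g$group_id[1L], " lacks a seed ortholog for species: ",
           paste(missing_seed, collapse = ", "), call. = FALSE)
  }
  class(x) <- c("ortholog_groups", "data.frame")
  x
}

#' Ortholog and in-paralog gene subsets for a species pair
#'
#' Splits the genes of two species into the two subsets used to contrast
#' sequence divergence against gene duplication:
#' * **orthologs** — seed-ortholog genes of groups spanning the pair, excluding
#'   any gene whose species side carries in-paralogs in any group of the
#'   table (duplicated lineages are removed from the ortholog subset);
#' * **in-paralogs** — the in-paralog-role genes of the pair's groups, without
#'   the seed ortholog (the most likely ancestor gene of the expansion).
#'
#' @param groups An `ortholog_groups` table.
#' @param species_pair Character vector of two species ids.
#' @return A named list (one element per species), each a list with character
#'   vectors `orthologs` and `inparalogs`.
#' @export
split_ortholog_paralog_sets <- function(groups, species_pair) {
  stopifnot(inherits(groups, "ortholog_groups"))
  species_pair <- as.character(species_pair)
  if (length(species_pair) != 2L || anyDuplicated(species_pair))
    stop("species_pair must name two distinct species", call. = FALSE)
  absent <- setdiff(species_pair, unique(groups$species_id))
  if (length(absent))
    stop("species absent from the table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  by_group <- split(groups, groups$group_id)
  spans <- vapply(by_group, function(g)
    all(species_pair %in% g$species_id), TRUE)
  pair_groups <- by_group[spans]
  out <- list()
  for (s in species_pair) {
    orth <- character(); inpar <- character()
    for (g in pair_groups) {
      side <- g[g$species_id == s, , drop = FALSE]
      seeds <- side$gene_id[side$role == "seed_ortholog"]
      inp <- side$gene_id[side$role == "inparalog"]
      inpar <- c(inpar, setdiff(inp, seeds))
      if (length(inp) == 0L) orth <- c(orth, seeds)
    }
    # a seed whose lineage expanded against ANY species is not a clean ortholog
    dup_somewhere <- unlist(lapply(by_group, function(g) {
      side <- g[g$species_id == s, , drop = FALSE]
      if (any(side$role == "inparalog")) side$gene_id else character()
    }), use.names = FALSE)
    out[[s]] <- list(orthologs = sort(setdiff(unique(orth), dup_somewhere)),
                     inparalogs = sort(unique(inpar)))
  }
  out
}
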