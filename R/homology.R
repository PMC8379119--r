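#' HSSP-curve distance (HVAL)
#'
#' Distance, in percentage-identity points, of an alignment from the
#' empirical HSSP curve that separates reliably similar protein pairs from
#' unreliable ones (positive above the curve). For alignment length `L` and
#' percentage pairwise sequence identity `PID`:
#' \deqn{HVAL(L, PID) = PID - \begin{cases}
#'   100 & L \le 11\\
#'   480 \cdot L^{-0.32 (1 + e^{-L/1000})} & 11 < L \le 450\\
#'   19.5 & L > 450
#' \end{cases}}{HVAL(L,PID) = PID - [100 if L<=11; 480*L^(-0.32*(1+exp(-L/1000))) if L<=450; 19.5 if L>450]}
#' For long alignments `HVAL = 0` corresponds to roughly 20% identity.
#' Vectorized over both arguments.
#'
#' @param aln_len Alignment length(s) `L` (integer >= 1; aligned residues,
#'   insertions/deletions not counted).
#' @param pid Percentage identity in `[0, 100]`.
#' @return Numeric HVAL value(s).
#' @examples
#' hval(10, 30)    # -70: first branch
#' hval(500, 40)   # 20.5: constant branch
#' @export
hval <- function(aln_len, pid) {
  if (any(aln_len < 1)) stop("aln_len must be >= 1", call. = FALSE)
  if (any(pid < 0 | pid > 100))
    stop("pid must lie in [0, 100]", call. = FALSE)
  pid - hssp_curve(aln_len)
}

#' @rdname hval
#' @details `hssp_curve()` returns the curve itself: the PID at which HVAL is
#'   zero for a given alignment length.
#' @export
hssp_curve <- function(aln_len) {
  ifelse(aln_len <= 11, 100,
         ifelse(aln_len <= 450,
                480 * aln_len^(-0.32 * (1 + exp(-aln_len / 1000))),
                19.5))
}

#' Read a BLAST-outfmt-6-style hit table
#'
#' Tab-separated with (at least) the columns `qseqid`, `sseqid`, `pident`,
#' `length`, `evalue`, named in a header line; extra columns are ignored.
#'
#' @param path File path.
#' @return A data frame with columns `query_id`, `target_id`, `pid`,
#'   `aln_len`, `evalue`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("qseqid", "sseqid", "pident", "length", "evalue")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("hit table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  alignment_hits(raw$qseqid, raw$sseqid, raw$pident, raw$length, raw$evalue)
}

#' @rdname read_hit_table
#' @param query_id,target_id Protein identifiers.
#' @param pid Percent identity in `[0, 100]`.
#' @param aln_len Alignment length (>= 1).
#' @param evalue Alignment e-value (>= 0).
#' @export
alignment_hits <- function(query_id, target_id, pid, aln_len, evalue = 0) {
  h <- data.frame(query_id = as.character(query_id),
                  target_id = as.character(target_id),
                  pid = as.numeric(pid), aln_len = as.integer(aln_len),
                  evalue = rep_len(as.numeric(evalue), length(query_id)),
                  stringsAsFactors = FALSE)
  if (nrow(h)) {
    if (any(h$pid < 0 | h$pid > 100))
      stop("pid must lie in [0, 100]", call. = FALSE)
    if (any(h$aln_len < 1)) stop("aln_len must be >= 1", call. = FALSE)
    if (any(h$evalue < 0)) stop("evalue must be >= 0", call. = FALSE)
  }
  h
}

#' Cluster proteins into sequence families at an HVAL threshold
#'
#' Greedy largest-degree-first (Hobohm-2-style) clustering on the graph of
#' protein pairs whose (symmetrized) HVAL exceeds `threshold`: repeatedly
#' select the unassigned protein with the most unassigned above-threshold
#' neighbours (ties broken by lexicographic id) as a family seed, assign it
#' together with all those neighbours to one family, and remove them.
#' Proteins without above-threshold partners end up as singleton families.
#' Every non-seed member thus has HVAL > `threshold` to its seed; pairs at
#' exactly the threshold are not clustered. Duplicate/reciprocal hits are
#' symmetrized by keeping the larger HVAL.
#'
#' @param hits Hit data frame (see [alignment_hits()]) over one protein set.
#' @param universe Character vector of all protein ids (so proteins without
#'   hits form singletons). Hits referencing ids outside the universe are an
#'   error.
#' @param threshold HVAL cutoff (default 4, the redundancy threshold at which
#'   family members reliably share their native location).
#' @return An object of class `family_assignment`: a list with `families`
#'   (list of `list(seed, members)`) and `threshold`.
#' @export
cluster_families <- function(hits, universe, threshold = 4) {
  universe <- unique(as.character(universe))
  outside <- setdiff(unique(c(hits$query_id, hits$target_id)), universe)
  if (length(outside))
    stop("hit(s) reference proteins outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  adj <- new.env(parent = emptyenv())
  if (nrow(hits)) {
    hv <- hval(hits$aln_len, hits$pid)
    keep <- hv > threshold & hits$query_id != hits$target_id
    q <- hits$query_id[keep]; t <- hits$target_id[keep]
    for (i in seq_along(q)) {
      assign(q[i], unique(c(mget(q[i], adj, ifnotfound = list(character()))[[1L]], t[i])), adj)
      assign(t[i], unique(c(mget(t[i], adj, ifnotfound = list(character()))[[1L]], q[i])), adj)
    }
  }
  unassigned <- sort(universe)
  families <- list()
  repeat {
    if (!length(unassigned)) break
    deg <- vapply(unassigned, function(p) {
      nb <- mget(p, adj, ifnotfound = list(character()))[[1L]]
      length(intersect(nb, unassigned))
    }, 0L)
    if (all(deg == 0L)) {
      families <- c(families, lapply(unassigned, function(p)
        list(seed = p, members = p)))
      break
    }
    seed <- unassigned[which.max(deg)]    # unassigned is sorted: ties -> lexicographic
    nb <- intersect(mget(seed, adj, ifnotfound = list(character()))[[1L]],
                    unassigned)
    members <- sort(unique(c(seed, nb)))
    families <- c(families, list(list(seed = seed, members = members)))
    unassigned <- setdiff(unassigned, members)
  }
  structure(list(families = families, threshold = threshold),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  sizes <- vapply(x$families, function(f) length(f$members), 0L)
  cat("Family assignment:", length(x$families), "families,",
      sum(sizes), "proteins (threshold HVAL >", x$threshold, ")\n")
  cat("  family sizes:", paste(utils::head(sort(sizes, decreasing = TRUE), 10L),
                               collapse = ", "),
      if (length(sizes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.family_assignment <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$families), function(i) {
    f <- x$families[[i]]
    data.frame(family_id = sprintf("F%04d", i),
               protein_id = f$members,
               is_seed = f$members == f$seed,
               stringsAsFactors = FALSE)
  }))
}

#' Homology-based transfer of location annotations
#'
#' For each query, hits with `evalue >= evalue_max` are discarded (the
#' default keeps only matches with e-value strictly below 1); the closest
#' remaining hit — minimal e-value, ties broken by higher percent identity,
#' then lexicographic target id — donates its full label set to the query.
#' Queries without a surviving hit are absent from the output.
#'
#' @param queries Character vector of query protein ids.
#' @param hits Hit data frame of queries against the reference set.
#' @param reference_annotations `annotation_table` covering every reference
#'   protein actually chosen as a best hit (a chosen target without
#'   annotation is an error).
#' @param evalue_max Strict upper bound on the e-value of usable hits.
#' @param source Source string recorded on the transferred records.
#' @return An `annotation_table` with one record per annotated query.
#' @export
transfer_annotations <- function(queries, hits, reference_annotations,
                                 evalue_max = 1, source = "HBI") {
  stopifnot(inherits(reference_annotations, "annotation_table"))
  queries <- unique(as.character(queries))
  h <- hits[hits$query_id %in% queries & hits$evalue < evalue_max, ,
            drop = FALSE]
  if (!nrow(h)) return(annotation_table(character(), list(), source))
  # deterministic best-hit selection per query
  h <- h[order(h$query_id, h$evalue, -h$pid, h$target_id), , drop = FALSE]
  best <- h[!duplicated(h$query_id), , drop = FALSE]
  ref_idx <- match(best$target_id, reference_annotations$protein_id)
  if (anyNA(ref_idx))
    stop("best-hit target(s) lack reference annotation: ",
         paste(utils::head(unique(best$target_id[is.na(ref_idx)]), 5L),
               collapse = ", "), call. = FALSE)
  annotation_table(best$query_id,
                   reference_annotations$labels[ref_idx],
                   source = source)
}

#' Annotation coverage of protein families
#'
#' Given a family assignment and the set of proteins with (experimental)
#' annotation, reports which fraction of families contains at least one
#' annotated member — i.e. how far within-family annotation transfer could
#' reach — and which fraction of proteins sits in such families.
#'
#' @param fams A `family_assignment`.
#' @param annotated Character vector of annotated protein ids.
#' @return A list: `n_families`, `n_covered_families`, `fraction_families`,
#'   `n_proteins`, `n_proteins_in_covered`, `fraction_proteins`.
#' @export
family_coverage <- function(fams, annotated) {
  stopifnot(inherits(fams, "family_assignment"))
  annotated <- as.character(annotated)
  covered <- vapply(fams$families, function(f)
    any(f$members %in% annotated), TRUE)
  sizes <- vapply(fams$families, function(f) length(f$members), 0L)
  n_fam <- length(fams$families)
  list(n_families = n_fam,
       n_covered_families = sum(covered),
       fraction_families = if (n_fam) sum(covered) / n_fam else NaN,
       n_proteins = sum(sizes),
       n_proteins_in_covered = sum(sizes[covered]),
       fraction_proteins = if (sum(sizes)) sum(sizes[covered]) / sum(sizes)
                           else NaN)
}
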