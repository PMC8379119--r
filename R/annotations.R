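#' Annotation tables
#'
#' An annotation table holds one record per `(protein_id, source)` pair: the
#' (possibly multi-label) set of location labels assigned to a protein by one
#' source (a database, a predictor, or homology transfer), plus an optional
#' reliability level. Internally it is a data frame with columns `protein_id`,
#' `source`, `reliability` and a list column `labels`.
#'
#' @param protein_id Character vector of non-empty protein identifiers.
#' @param labels List of non-empty character vectors (one label set per
#'   record), or a character vector for single-label records.
#' @param source Character vector (recycled) naming the annotation source.
#' @param reliability Optional character vector (recycled) of reliability
#'   levels; `NA` where unknown.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(protein_id, labels, source = "unknown",
                             reliability = NA_character_) {
  protein_id <- as.character(protein_id)
  n <- length(protein_id)
  if (!is.list(labels)) labels <- as.list(as.character(labels))
  if (length(labels) != n)
    stop("labels must have one entry per protein_id", call. = FALSE)
  labels <- lapply(labels, function(l) unique(trimws(as.character(l))))
  source <- rep_len(as.character(source), n)
  reliability <- rep_len(as.character(reliability), n)
  tab <- data.frame(protein_id = protein_id, source = source,
                    reliability = reliability, stringsAsFactors = FALSE)
  tab$labels <- labels
  class(tab) <- c("annotation_table", "data.frame")
  validate_annotation_table(tab)
}

validate_annotation_table <- function(tab) {
  if (nrow(tab)) {
    if (anyNA(tab$protein_id) || any(!nzchar(tab$protein_id)))
      stop("protein_id must be non-empty", call. = FALSE)
    empty <- lengths(tab$labels) == 0L |
      vapply(tab$labels, function(l) any(!nzchar(l)), TRUE)
    if (any(empty))
      stop("empty label set in row(s): ",
           paste(utils::head(which(empty), 5L), collapse = ", "),
           call. = FALSE)
    key <- paste(tab$protein_id, tab$source, sep = "\r")
    dup <- duplicated(key)
    if (any(dup))
      stop("duplicate (protein_id, source) pair(s): ",
           paste(utils::head(unique(sub("\r", ", ", key[dup])), 5L),
                 collapse = "; "), call. = FALSE)
  }
  tab
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("Annotation table:", nrow(x), "records,",
      length(unique(x$protein_id)), "proteins,",
      length(unique(x$source)), "source(s)\n")
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    lab <- vapply(show$labels, paste, "", collapse = ";")
    print(data.frame(protein_id = show$protein_id, source = show$source,
                     reliability = show$reliability, labels = lab))
    if (nrow(x) > 6L) cat("...\n")
  }
  invisible(x)
}

#' Read / write an annotation TSV
#'
#' Tab-separated, UTF-8, header required with columns `protein_id`, `source`,
#' `reliability`, `labels`; the `labels` field holds one or more location
#' labels separated by semicolons. Surrounding whitespace on labels is
#' stripped; empty label fields and duplicate `(protein_id, source)` pairs are
#' rejected.
#'
#' @param path File path.
#' @return `read_annotation_table` returns an `annotation_table` (empty data
#'   files give an empty table); `write_annotation_table` returns `path`
#'   invisibly.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           quote = "", check.names = TRUE,
                           fileEncoding = "UTF-8")
  need <- c("protein_id", "source", "reliability", "labels")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(raw))
    return(annotation_table(character(), list()))
  labels <- strsplit(raw$labels, ";", fixed = TRUE)
  labels <- lapply(labels, function(l) trimws(l[nzchar(trimws(l))]))
  bad <- lengths(labels) == 0L
  if (any(bad))
    stop("empty labels field in data row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  rel <- raw$reliability
  rel[!nzchar(rel)] <- NA_character_
  annotation_table(raw$protein_id, labels, raw$source, rel)
}

#' @rdname read_annotation_table
#' @param table An `annotation_table`.
#' @export
write_annotation_table <- function(table, path) {
  stopifnot(inherits(table, "annotation_table"))
  out <- data.frame(protein_id = table$protein_id, source = table$source,
                    reliability = ifelse(is.na(table$reliability), "",
                                         table$reliability),
                    labels = vapply(table$labels, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Project an annotation table onto a location scheme
#'
#' Maps every raw label through the scheme's synonym map (case-insensitive
#' after whitespace normalization). Labels mapping to `"unmappable"` are
#' dropped, and records whose entire label set becomes empty are removed:
#' proteins whose annotations cannot be expressed in the scheme are excluded
#' from downstream composition estimates rather than distorted. Raw labels
#' absent from the synonym map are a hard error — silent dropping would bias
#' the resulting spectra.
#'
#' Projection is idempotent: applying it twice with the same scheme changes
#' nothing.
#'
#' @param table An `annotation_table`.
#' @param scheme A `location_scheme`.
#' @return A projected `annotation_table` (possibly with fewer records).
#' @export
project_to_scheme <- function(table, scheme) {
  stopifnot(inherits(table, "annotation_table"),
            inherits(scheme, "location_scheme"))
  if (!nrow(table)) return(table)
  all_raw <- unique(normalize_label(unlist(table$labels)))
  unknown <- setdiff(all_raw, names(scheme$synonyms))
  if (length(unknown))
    stop("labels not covered by the scheme's synonym map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  mapped <- lapply(table$labels, function(l) {
    m <- unname(scheme$synonyms[normalize_label(l)])
    unique(m[m != "unmappable"])
  })
  keep <- lengths(mapped) > 0L
  out <- table[keep, , drop = FALSE]
  out$labels <- mapped[keep]
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Keep only single-label records
#'
#' Restricts an annotation table to records carrying exactly one location
#' label, the filtering applied before estimating spectra and building
#' confusion matrices (only proteins with a single annotation enter those
#' computations).
#'
#' @param table An `annotation_table`.
#' @return An `annotation_table` with only the single-label records.
#' @export
filter_single_label <- function(table) {
  stopifnot(inherits(table, "annotation_table"))
  out <- table[lengths(table$labels) == 1L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Restrict an annotation table to one source
#'
#' @param table An `annotation_table`.
#' @param source Source name to keep.
#' @return An `annotation_table`.
#' @export
filter_source <- function(table, source) {
  stopifnot(inherits(table, "annotation_table"))
  out <- table[table$source == source, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Merge reliability levels
#'
#' Replaces each record's reliability level according to `merge_map`. The
#' default map collapses the four Human-Protein-Atlas-style levels into two:
#' `Validated` and `Supportive` become `"reliable"`, `Uncertain` and
#' `Unreliable` become `"speculative"`.
#'
#' @param table An `annotation_table`.
#' @param merge_map Named character vector mapping each present level to its
#'   merged level. Every non-`NA` level present in the table must appear.
#' @return An `annotation_table` with merged reliability levels.
#' @export
merge_reliability_levels <- function(table,
                                     merge_map = c(Validated = "reliable",
                                                   Supportive = "reliable",
                                                   Uncertain = "speculative",
                                                   Unreliable = "speculative")) {
  stopifnot(inherits(table, "annotation_table"))
  present <- unique(table$reliability[!is.na(table$reliability)])
  unmapped <- setdiff(present, names(merge_map))
  if (length(unmapped))
    stop("reliability level(s) missing from merge_map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  out <- table
  idx <- !is.na(out$reliability)
  out$reliability[idx] <- unname(merge_map[out$reliability[idx]])
  out
}
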