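#' Location schemes
#'
#' A location scheme is an ordered set of subcellular location classes plus a
#' synonym map that projects raw annotation labels (which differ between
#' databases and predictors) onto those classes. Labels that have no sensible
#' class map to the sentinel `"unmappable"` and are dropped during projection.
#'
#' @param classes Character vector of unique, non-empty class names, in order.
#' @param synonyms Named character vector: names are raw label strings, values
#'   are class names or `"unmappable"`. Matching is case-insensitive after
#'   whitespace normalization; every class name is implicitly a synonym of
#'   itself.
#' @return An object of class `location_scheme` with elements `classes` and
#'   `synonyms` (the latter with normalized names).
#' @examples
#' sch <- location_scheme(c("nucleus", "cytoplasm"),
#'                        c("nucleoplasm" = "nucleus"))
#' @export
location_scheme <- function(classes, synonyms = character()) {
  classes <- as.character(classes)
  if (length(classes) < 1L || anyNA(classes) || any(!nzchar(classes)))
    stop("scheme classes must be non-empty strings", call. = FALSE)
  if (anyDuplicated(classes))
    stop("scheme classes must be unique", call. = FALSE)
  synonyms <- unlist(synonyms)
  if (length(synonyms)) {
    if (is.null(names(synonyms)) || any(!nzchar(names(synonyms))))
      stop("synonyms must be a named character vector", call. = FALSE)
    bad <- setdiff(unique(as.character(synonyms)), c(classes, "unmappable"))
    if (length(bad))
      stop("synonym targets not in scheme: ", paste(bad, collapse = ", "),
           call. = FALSE)
    names(synonyms) <- normalize_label(names(synonyms))
    if (anyDuplicated(names(synonyms)))
      stop("duplicate synonym keys after normalization", call. = FALSE)
  }
  # classes map to themselves unless explicitly overridden
  self <- structure(classes, names = normalize_label(classes))
  self <- self[!(names(self) %in% names(synonyms))]
  structure(list(classes = classes,
                 synonyms = c(as.character(synonyms), self) |>
                   stats::setNames(c(names(synonyms), names(self)))),
            class = "location_scheme")
}

# canonical key for case/whitespace-insensitive label matching
normalize_label <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' @export
print.location_scheme <- function(x, ...) {
  cat("Location scheme with", length(x$classes), "classes:\n ",
      paste(x$classes, collapse = ", "), "\n")
  cat(" ", length(x$synonyms), "synonym entries\n")
  invisible(x)
}

#' The canonical seven-class location scheme
#'
#' The common projection shared by the major whole-proteome location
#' predictors: secreted, nucleus, cytoplasm, plasma membrane, mitochondrion,
#' endoplasmic reticulum, Golgi apparatus (in this order). The bundled synonym
#' map covers frequent database spellings (e.g. "nucleoplasm", "ER membrane",
#' "extracellular"); it is a best-effort default and can be replaced or
#' extended via [read_scheme()] or [location_scheme()].
#'
#' @return A `location_scheme`.
#' @export
seven_class_scheme <- function() {
  path <- system.file("extdata", "seven_class_scheme.txt",
                      package = "locspectra", mustWork = TRUE)
  read_scheme(path)
}

#' Read / write a location-scheme configuration file
#'
#' Plain-text format: a line `classes: a, b, c` giving the ordered class list,
#' followed by one `synonym<TAB>class` line per synonym (class may be the
#' sentinel `unmappable`). Blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @return `read_scheme` returns a `location_scheme`; `write_scheme` returns
#'   `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cl <- grep("^classes:", lines)
  if (length(cl) != 1L)
    stop("scheme file needs exactly one 'classes:' line", call. = FALSE)
  classes <- trimws(strsplit(sub("^classes:", "", lines[cl]), ",")[[1L]])
  syn_lines <- lines[-cl]
  synonyms <- character()
  if (length(syn_lines)) {
    parts <- strsplit(syn_lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed synonym line(s): ",
           paste(syn_lines[lengths(parts) != 2L], collapse = "; "),
           call. = FALSE)
    synonyms <- stats::setNames(trimws(vapply(parts, `[`, "", 2L)),
                                trimws(vapply(parts, `[`, "", 1L)))
  }
  location_scheme(classes, synonyms)
}

#' @rdname read_scheme
#' @param scheme A `location_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "location_scheme"))
  syn <- scheme$synonyms
  # skip trivial self-entries when serializing
  keep <- !(names(syn) == normalize_label(syn))
  out <- c(paste0("classes: ", paste(scheme$classes, collapse = ", ")),
           paste0(names(syn)[keep], "\t", syn[keep]))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
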