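#' Location spectra
#'
#' A location spectrum is the composition vector of a proteome over the
#' classes of a location scheme: entry `x` is the fraction of proteins whose
#' (single) location is class `x`. The raw predicted spectrum is conventionally
#' written `P = (p_1, ..., p_n)` and its error-corrected counterpart
#' `C = (c_1, ..., c_n)`.
#'
#' @param values Numeric vector over the scheme classes; non-negative, summing
#'   to 1 (within 1e-9).
#' @param scheme A `location_scheme`.
#' @param organism_id Organism identifier string.
#' @param n_proteins Number of proteins the vector was computed from (`NA` for
#'   theoretical spectra).
#' @param corrected Logical: has the confusion-matrix correction been applied?
#' @return An object of class `location_spectrum` with fields `organism_id`,
#'   `classes`, `values` (named), `n_proteins`, `corrected`.
#' @export
location_spectrum <- function(values, scheme, organism_id = "organism",
                              n_proteins = NA_integer_, corrected = FALSE) {
  stopifnot(inherits(scheme, "location_scheme"))
  values <- as.numeric(values)
  k <- length(scheme$classes)
  if (length(values) != k)
    stop("spectrum length ", length(values), " != ", k, " scheme classes",
         call. = FALSE)
  if (any(values < 0))
    stop("spectrum values must be non-negative", call. = FALSE)
  if (abs(sum(values) - 1) > 1e-9)
    stop("spectrum values must sum to 1 (got ", format(sum(values)), ")",
         call. = FALSE)
  structure(list(organism_id = as.character(organism_id),
                 classes = scheme$classes,
                 values = stats::setNames(values, scheme$classes),
                 n_proteins = as.integer(n_proteins),
                 corrected = isTRUE(corrected)),
            class = "location_spectrum")
}

#' @export
print.location_spectrum <- function(x, digits = 4, ...) {
  cat(sprintf("Location spectrum for '%s' (%s%s)\n", x$organism_id,
              if (x$corrected) "corrected" else "uncorrected",
              if (is.na(x$n_proteins)) "" else
                sprintf(", n = %d proteins", x$n_proteins)))
  print(round(x$values, digits))
  invisible(x)
}

#' @export
as.double.location_spectrum <- function(x, ...) unname(x$values)

# schemes are compared by their ordered class list
same_classes <- function(a, b) identical(a$classes, b$classes)

#' Compute the location spectrum of a prediction set
#'
#' Counts single-label records per class and divides by the number of
#' records. All records must carry exactly one label from the scheme; apply
#' [project_to_scheme()] and [filter_single_label()] first.
#'
#' @param predictions A single-label `annotation_table`.
#' @param scheme A `location_scheme`.
#' @param organism_id Organism identifier stored in the result.
#' @return An uncorrected `location_spectrum` with `n_proteins = nrow(predictions)`.
#' @export
compute_spectrum <- function(predictions, scheme, organism_id = "organism") {
  stopifnot(inherits(predictions, "annotation_table"),
            inherits(scheme, "location_scheme"))
  if (!nrow(predictions))
    stop("cannot compute a spectrum from an empty table", call. = FALSE)
  if (any(lengths(predictions$labels) != 1L))
    stop("all records must be single-label; apply filter_single_label()",
         call. = FALSE)
  lab <- unlist(predictions$labels)
  bad <- setdiff(unique(lab), scheme$classes)
  if (length(bad))
    stop("labels outside the scheme: ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(lab, levels = scheme$classes))
  location_spectrum(as.numeric(counts) / nrow(predictions), scheme,
                    organism_id, n_proteins = nrow(predictions))
}

#' Build a confusion matrix from predictions and observations
#'
#' Element `(p, o)` counts the proteins predicted in class `p` and observed
#' (experimentally annotated) in class `o`; the diagonal holds the correct
#' predictions. Only proteins present in both tables are counted, both
#' single-label over the same scheme.
#'
#' @param pred,obs Single-label `annotation_table`s (predicted and observed).
#' @param scheme A `location_scheme`.
#' @return An integer matrix of class `confusion_matrix` (predicted rows x
#'   observed columns, dimnames = scheme classes).
#' @export
build_confusion <- function(pred, obs, scheme) {
  stopifnot(inherits(pred, "annotation_table"),
            inherits(obs, "annotation_table"),
            inherits(scheme, "location_scheme"))
  for (t in list(pred, obs))
    if (any(lengths(t$labels) != 1L))
      stop("confusion matrices require single-label tables", call. = FALSE)
  ids <- intersect(pred$protein_id, obs$protein_id)
  if (!length(ids))
    stop("no shared proteins between predictions and observations",
         call. = FALSE)
  p <- unlist(pred$labels[match(ids, pred$protein_id)])
  o <- unlist(obs$labels[match(ids, obs$protein_id)])
  bad <- setdiff(unique(c(p, o)), scheme$classes)
  if (length(bad))
    stop("labels outside the scheme: ", paste(bad, collapse = ", "),
         call. = FALSE)
  m <- table(factor(p, levels = scheme$classes),
             factor(o, levels = scheme$classes))
  m <- matrix(as.integer(m), nrow = length(scheme$classes),
              dimnames = list(predicted = scheme$classes,
                              observed = scheme$classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Row-normalize a confusion matrix
#'
#' Divides each row of `M` by its row sum, giving `M'` with
#' `M'(p, o) = M(p, o) / sum_i M(p, i)`: the conditional distribution of the
#' observed class given the predicted class. Rows whose class was never
#' predicted in the reference data have no defined ratio; they are set to the
#' corresponding identity row (predicted class taken at face value), with a
#' warning, as the least-informative consistent convention.
#'
#' @param m A `confusion_matrix`.
#' @return A row-stochastic matrix of class `normalized_confusion`.
#' @export
row_normalize <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  rs <- rowSums(m)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  nz <- rs > 0
  out[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  if (any(!nz)) {
    warning("class(es) never predicted in the reference set; using identity ",
            "row(s) for: ", paste(rownames(m)[!nz], collapse = ", "),
            call. = FALSE)
    out[!nz, ] <- diag(nrow(m))[!nz, , drop = FALSE]
  }
  structure(out, class = c("normalized_confusion", class(out)))
}

#' Correct a predicted spectrum with a normalized confusion matrix
#'
#' Applies the law-of-total-probability adjustment
#' \deqn{c_x = \sum_i M'(i, x) \, p_i}{c_x = sum_i M'(i,x) * p_i}
#' redistributing each predicted fraction `p_i` over the classes the
#' predictor actually tends to hit when it outputs class `i`. Because `M'` is
#' row-stochastic the corrected vector again sums to 1.
#'
#' @param p An uncorrected `location_spectrum`.
#' @param mprime A `normalized_confusion` over the same classes.
#' @return A `location_spectrum` with `corrected = TRUE`.
#' @export
correct_spectrum <- function(p, mprime) {
  stopifnot(inherits(p, "location_spectrum"),
            inherits(mprime, "normalized_confusion"))
  if (p$corrected)
    stop("spectrum is already corrected", call. = FALSE)
  if (!identical(p$classes, rownames(mprime)))
    stop("spectrum and confusion matrix use different schemes", call. = FALSE)
  cx <- as.numeric(p$values %*% mprime)   # c_x = sum_i M'(i,x) p_i
  out <- p
  out$values <- stats::setNames(cx, p$classes)
  out$corrected <- TRUE
  out
}

#' Read / write spectra as TSV
#'
#' Long format with columns `organism_id`, `class`, `value`, `n_proteins`,
#' `corrected`; one block of rows per organism, classes in scheme order.
#'
#' @param spectra A `location_spectrum` or list of them.
#' @param path File path.
#' @param scheme A `location_scheme` the file's classes must match.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` returns a
#'   list of `location_spectrum`.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "location_spectrum")) spectra <- list(spectra)
  rows <- do.call(rbind, lapply(spectra, function(s)
    data.frame(organism_id = s$organism_id, class = s$classes,
               value = unname(s$values), n_proteins = s$n_proteins,
               corrected = s$corrected, stringsAsFactors = FALSE)))
  utils::write.table(format(rows, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path, scheme) {
  stopifnot(inherits(scheme, "location_scheme"))
  raw <- utils::read.delim(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("organism_id", "class", "value", "n_proteins", "corrected")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("spectrum table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(split(raw, factor(raw$organism_id, levels = unique(raw$organism_id))),
         function(d) {
           v <- d$value[match(scheme$classes, d$class)]
           if (anyNA(v))
             stop("spectrum for ", d$organism_id[1L],
                  " does not cover all scheme classes", call. = FALSE)
           location_spectrum(v, scheme, d$organism_id[1L],
                             n_proteins = d$n_proteins[1L],
                             corrected = isTRUE(as.logical(d$corrected[1L])))
         })
}

#' Read / write a confusion matrix as TSV
#'
#' Square matrix with a class header row and first column (predicted rows,
#' observed columns). Counts by default; `ratios = TRUE` reads/writes the
#' row-normalized form.
#'
#' @param m A `confusion_matrix` or `normalized_confusion`.
#' @param path File path.
#' @param scheme A `location_scheme`.
#' @param ratios Logical: is the file row-normalized ratios rather than counts?
#' @return `write_confusion` returns `path` invisibly; `read_confusion`
#'   returns a `confusion_matrix` (or `normalized_confusion` if `ratios`).
#' @export
write_confusion <- function(m, path) {
  stopifnot(is.matrix(m))
  df <- data.frame(class = rownames(m), m, check.names = FALSE)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path, scheme, ratios = FALSE) {
  stopifnot(inherits(scheme, "location_scheme"))
  raw <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!identical(raw[[1L]], scheme$classes) ||
      !identical(names(raw)[-1L], scheme$classes))
    stop("confusion matrix classes do not match the scheme", call. = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  dimnames(m) <- list(predicted = scheme$classes, observed = scheme$classes)
  if (ratios) {
    if (any(m < 0 | m > 1))
      stop("ratio matrix entries must lie in [0, 1]", call. = FALSE)
    structure(m, class = c("normalized_confusion", class(m)))
  } else {
    storage.mode(m) <- "integer"
    structure(m, class = c("confusion_matrix", class(m)))
  }
}
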