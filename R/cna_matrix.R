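#' Construct a copy-number matrix with per-sample class labels
#'
#' The canonical container of the pipeline: a real-valued samples-by-probes
#' matrix of copy-number values (scale-agnostic: raw copy number or log ratio,
#' the downstream methods only assume ordinal structure) plus one class label
#' per sample. The positive class defaults to `"ACA"` (adenocarcinoma), the
#' negative class being everything else (in the motivating two-class design,
#' `"SCC"`, squamous cell carcinoma).
#'
#' @param values Numeric matrix, rows = samples, columns = probes. Row and
#'   column names are used as sample and probe identifiers and must be unique.
#' @param labels Character vector of per-sample class labels, one per row of
#'   `values` (recycled names are not allowed; order must match rows).
#' @param positive_class The label value treated as the positive class.
#'
#' @return An object of class `cna_matrix`: a list with elements `values`,
#'   `labels`, `positive_class`.
#' @examples
#' m <- matrix(rnorm(12, 2, 0.3), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("p", 1:4)))
#' cna_matrix(m, c("ACA", "ACA", "SCC"))
#' @export
cna_matrix <- function(values, labels, positive_class = "ACA") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample_%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("probe_%06d", seq_len(ncol(values)))
  labels <- as.character(labels)
  obj <- structure(
    list(values = values, labels = labels, positive_class = positive_class),
    class = "cna_matrix")
  validate_cna_matrix(obj)
  obj
}

#' Validate a cna_matrix object
#'
#' Checks the container invariants: unique sample and probe identifiers,
#' one label per sample, and no missing or non-finite values (missingness is
#' rejected, not imputed).
#'
#' @param x A `cna_matrix`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_cna_matrix <- function(x) {
  stopifnot(inherits(x, "cna_matrix"))
  v <- x$values
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(v)[duplicated(colnames(v))]
  if (length(dup))
    stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  if (length(x$labels) != nrow(v))
    stop("need one label per sample: ", nrow(v), " samples but ",
         length(x$labels), " labels")
  if (anyNA(x$labels) || any(x$labels == ""))
    stop("missing label for sample(s): ",
         paste(rownames(v)[is.na(x$labels) | x$labels == ""], collapse = ", "))
  bad <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing/non-finite value at sample '", rownames(v)[bad[1, 1]],
         "', probe '", colnames(v)[bad[1, 2]], "'")
  invisible(x)
}

#' @export
print.cna_matrix <- function(x, ...) {
  tab <- table(x$labels)
  cat("cna_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " probes\n", sep = "")
  cat("  classes: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      " (positive = ", x$positive_class, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.cna_matrix <- function(x) dim(x$values)

#' Sample identifiers of a cna_matrix
#' @param x A `cna_matrix`.
#' @return Character vector.
#' @export
sample_ids <- function(x) rownames(x$values)

#' Probe identifiers of a cna_matrix
#' @param x A `cna_matrix`.
#' @return Character vector.
#' @export
probe_ids <- function(x) colnames(x$values)

#' Logical vector marking positive-class samples
#' @param x A `cna_matrix`.
#' @return Logical vector, `TRUE` for samples of the positive class.
#' @export
is_positive <- function(x) x$labels == x$positive_class

# Both classes must be present for ranking/classification; shared guard.
check_two_classes <- function(x) {
  pos <- sum(is_positive(x))
  if (pos == 0L || pos == length(x$labels))
    stop("both classes must be present (positive class '",
         x$positive_class, "': ", pos, " of ", length(x$labels), " samples)")
  invisible(x)
}

#' Read a labelled copy-number matrix from a TSV file
#'
#' Reads a tab-separated matrix with a header row and row identifiers in the
#' first column. The canonical orientation is samples-as-rows; GEO
#' series-matrix style probes-as-rows input is accepted via
#' `orientation = "probes"` and transposed on load. Class labels come either
#' from an embedded line keyed `class` (a column named `class` when samples
#' are rows, a row with id `class` when probes are rows) or from a separate
#' two-column sample-to-label TSV given as `labels`.
#'
#' @param path Path to the matrix TSV.
#' @param orientation `"samples"` (rows are samples, canonical) or `"probes"`
#'   (rows are probes; the matrix is transposed).
#' @param labels Optional path to a two-column TSV (sample id, label) with no
#'   header. If `NULL`, an embedded `class` line is required.
#' @param positive_class Label treated as positive; default `"ACA"`.
#' @return A validated [cna_matrix].
#' @export
read_cna_matrix <- function(path, orientation = c("samples", "probes"),
                            labels = NULL, positive_class = "ACA") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("matrix file needs row ids plus data columns: ", path)
  row_ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  col_ids <- colnames(body)

  lab <- NULL
  if (orientation == "samples" && "class" %in% col_ids) {
    lab <- stats::setNames(body[["class"]], row_ids)
    body <- body[, col_ids != "class", drop = FALSE]
    col_ids <- colnames(body)
  } else if (orientation == "probes" && "class" %in% row_ids) {
    i <- which(row_ids == "class")[1L]
    lab <- stats::setNames(as.character(body[i, ]), col_ids)
    body <- body[-i, , drop = FALSE]
    row_ids <- row_ids[-i]
  }

  num <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow = nrow(body),
           dimnames = list(row_ids, col_ids)))
  bad <- which(is.na(num) | as.matrix(body) == "", arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric or blank cell at row '", row_ids[bad[1, 1]],
         "', column '", col_ids[bad[1, 2]], "' in ", path)

  if (orientation == "probes") num <- t(num)

  if (!is.null(labels)) {
    if (!file.exists(labels)) stop("labels file not found: ", labels)
    lt <- utils::read.delim(labels, header = FALSE, sep = "\t",
                            colClasses = "character")
    if (ncol(lt) < 2L) stop("labels file must have two columns: ", labels)
    lab <- stats::setNames(lt[[2L]], lt[[1L]])
  }
  if (is.null(lab))
    stop("no labels: supply a `class` line in the matrix or a labels file")
  missing <- setdiff(rownames(num), names(lab))
  if (length(missing))
    stop("missing label for sample(s): ", paste(missing, collapse = ", "))
  cna_matrix(num, unname(lab[rownames(num)]), positive_class = positive_class)
}

#' Write a cna_matrix to the canonical samples-as-rows TSV layout
#'
#' The class label is written as the first data column, keyed `class`, so the
#' file round-trips through [read_cna_matrix]. Values are formatted with 15
#' significant digits, which reproduces ordinary decimal inputs verbatim.
#'
#' @param x A `cna_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cna_matrix <- function(x, path) {
  validate_cna_matrix(x)
  vals <- format(x$values, digits = 15, trim = TRUE, scientific = FALSE)
  df <- data.frame(sample_id = rownames(x$values), class = x$labels,
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `set_id`, `description`, then one or more member gene ids. Duplicate
#' members within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A list of `gene_set` objects (lists with `set_id`, `description`,
#'   `members`); empty list for an empty file.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has ", length(f), " field(s); need >= 3")
    out[[i]] <- gene_set(f[1L], f[2L], f[-(1:2)])
  }
  out
}

#' Construct a gene set
#'
#' @param set_id Set identifier (KEGG id, GO id, cytoband, ...).
#' @param description Free-text description.
#' @param members Character vector of member gene ids; duplicates collapsed.
#' @return A `gene_set` object.
#' @export
gene_set <- function(set_id, description, members) {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (!length(members)) stop("gene set '", set_id, "' has no members")
  structure(list(set_id = set_id, description = description,
                 members = members), class = "gene_set")
}

#' Write a gene-set collection to a GMT file
#' @param sets List of `gene_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$set_id, s$description, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
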