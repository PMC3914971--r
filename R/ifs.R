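#' Incremental feature selection over a ranked probe list
#'
#' For each i in 1..`max_n`, evaluates the cosine nearest-neighbour classifier
#' by leave-one-out cross-validation on the top-i probes of the ranking and
#' records sensitivity, specificity, accuracy and MCC. Every row is a fresh
#' LOOCV on exactly the top-i prefix; the procedure is fully deterministic.
#'
#' @param x A [cna_matrix].
#' @param ranked A `ranked_probes` data frame (normally from [mrmr_rank]).
#' @param max_n Largest prefix size to evaluate; defaults to the full ranking,
#'   capped at 1000.
#' @return An `ifs_table`: data frame with columns `i`, `sn`, `sp`, `acc`,
#'   `mcc` and attributes `probe_ids` (the ranked ids used) and `method`.
#' @export
run_ifs <- function(x, ranked, max_n = min(nrow(ranked), 1000L)) {
  validate_cna_matrix(x)
  stopifnot(inherits(ranked, "ranked_probes"))
  if (!nrow(ranked)) stop("empty ranking")
  if (max_n < 1L || max_n > nrow(ranked))
    stop("max_n must be in 1..", nrow(ranked))
  ids <- ranked$probe_id[seq_len(max_n)]
  missing <- setdiff(ids, probe_ids(x))
  if (length(missing))
    stop("ranked probe(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  rows <- vector("list", max_n)
  for (i in seq_len(max_n)) {
    m <- classification_metrics(loocv_confusion(x, ids[seq_len(i)]))
    rows[[i]] <- data.frame(i = i, sn = m$sn, sp = m$sp,
                            acc = m$acc, mcc = m$mcc)
  }
  structure(do.call(rbind, rows),
            class = c("ifs_table", "data.frame"),
            probe_ids = ids, method = attr(ranked, "method"))
}

#' Select the optimal probe subset from an IFS table
#'
#' The optimum is the smallest prefix size achieving the maximum MCC
#' (parsimony on ties).
#'
#' @param table An `ifs_table` from [run_ifs].
#' @param ranked The `ranked_probes` the table was computed from (used to
#'   recover the probe prefix); may be omitted if the table carries its
#'   `probe_ids` attribute.
#' @return An `optimal_subset`: list with `size`, `probe_ids`, `metrics`
#'   (a `performance_metrics`).
#' @export
select_optimal <- function(table, ranked = NULL) {
  stopifnot(inherits(table, "ifs_table"))
  if (!nrow(table)) stop("empty IFS table")
  ids <- if (!is.null(ranked)) ranked$probe_id else attr(table, "probe_ids")
  i_opt <- which.max(table$mcc)           # first max = smallest subset
  size <- table$i[i_opt]
  if (is.null(ids) || length(ids) < size)
    stop("ranking does not cover the optimal prefix")
  structure(list(size = size,
                 probe_ids = ids[seq_len(size)],
                 metrics = structure(list(sn = table$sn[i_opt],
                                          sp = table$sp[i_opt],
                                          acc = table$acc[i_opt],
                                          mcc = table$mcc[i_opt]),
                                     class = "performance_metrics")),
            class = "optimal_subset")
}

#' @export
print.optimal_subset <- function(x, ...) {
  cat("optimal subset: ", x$size, " probes\n  ", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Write an IFS table to TSV
#'
#' One row per prefix size with the metrics at full precision (15 significant
#' digits) plus 4-decimal display columns, mirroring the usual presentation of
#' IFS runs.
#'
#' @param table An `ifs_table` (or data frame with columns i, sn, sp, acc,
#'   mcc); `i` must be contiguous from 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifs_table <- function(table, path) {
  if (!nrow(table)) stop("empty IFS table")
  need <- c("i", "sn", "sp", "acc", "mcc")
  if (!all(need %in% colnames(table)))
    stop("IFS table must have columns ", paste(need, collapse = ", "))
  if (!identical(as.integer(table$i), seq_len(nrow(table))))
    stop("IFS table subset sizes must be contiguous from 1")
  df <- data.frame(
    i = table$i,
    sn = format(table$sn, digits = 15, trim = TRUE),
    sp = format(table$sp, digits = 15, trim = TRUE),
    acc = format(table$acc, digits = 15, trim = TRUE),
    mcc = format(table$mcc, digits = 15, trim = TRUE),
    sn_4dp = sprintf("%.4f", table$sn), sp_4dp = sprintf("%.4f", table$sp),
    acc_4dp = sprintf("%.4f", table$acc), mcc_4dp = sprintf("%.4f", table$mcc))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an IFS table written by [write_ifs_table]
#' @param path Path to the TSV.
#' @return An `ifs_table` data frame (full-precision columns only).
#' @export
read_ifs_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("i", "sn", "sp", "acc", "mcc")
  if (!all(need %in% colnames(df)))
    stop("IFS table file must have columns ", paste(need, collapse = ", "),
         ": ", path)
  out <- data.frame(i = as.integer(df$i), sn = as.numeric(df$sn),
                    sp = as.numeric(df$sp), acc = as.numeric(df$acc),
                    mcc = as.numeric(df$mcc))
  structure(out, class = c("ifs_table", "data.frame"))
}

#' Export per-probe standardized values for heatmap display
#'
#' Restricts the matrix to the optimal probe subset, standardizes each probe
#' across samples (mean 0, sd 1), and orders samples as all positives followed
#' by all negatives — the layout used for subtype heatmaps. Zero-variance
#' probes are emitted as all-zero rows with a warning.
#'
#' @param x A [cna_matrix].
#' @param subset An `optimal_subset` (or character vector of probe ids).
#' @return A probes-by-samples numeric matrix with attribute `sample_class`
#'   giving the class of each column.
#' @export
export_heatmap_data <- function(x, subset) {
  validate_cna_matrix(x)
  ids <- if (inherits(subset, "optimal_subset")) subset$probe_ids else subset
  missing <- setdiff(ids, probe_ids(x))
  if (length(missing))
    stop("probe(s) absent from matrix: ", paste(missing, collapse = ", "))
  ord <- order(!is_positive(x))           # positives first, stable
  v <- x$values[ord, ids, drop = FALSE]
  ctr <- colMeans(v)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance probe(s) emitted as zeros: ",
            paste(ids[sds == 0], collapse = ", "))
    sds[sds == 0] <- 1
  }
  out <- (t(v) - ctr) / sds                # probes x samples
  attr(out, "sample_class") <- x$labels[ord]
  out
}
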