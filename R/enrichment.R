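#' Build the 2x2 over-representation contingency table
#'
#' Counts laid out as in classical gene-set enrichment reports:
#' `a` = genes from the query list with the annotation, `b` = list genes
#' without it, `c` = genome genes (excluding the list) with the annotation,
#' `d` = genome genes (excluding the list) without it. The gene set is
#' intersected with the universe before counting.
#'
#' @param gene_list Character vector of query genes; must be a subset of
#'   `universe`.
#' @param gene_set A [gene_set] or character vector of member genes.
#' @param universe Character vector: the background gene universe.
#' @return A `contingency_table` object: list with integer `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(gene_list, gene_set, universe) {
  members <- if (inherits(gene_set, "gene_set")) gene_set$members else gene_set
  gene_list <- unique(as.character(gene_list))
  universe <- unique(as.character(universe))
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(outside, collapse = ", "))
  members <- intersect(members, universe)
  a <- length(intersect(gene_list, members))
  b <- length(gene_list) - a
  c_ <- length(members) - a
  d <- length(universe) - length(gene_list) - c_
  structure(list(a = a, b = b, c = c_, d = d), class = "contingency_table")
}

#' One-sided Fisher exact (hypergeometric upper-tail) p-value
#'
#' The over-representation p-value: with population N = a+b+c+d, K = a+c
#' annotated genes and n = a+b draws (the list), returns
#' P(X >= a) for X hypergeometric. The tail is summed in log space for
#' numerical stability. Degenerate margins (empty list or empty annotation)
#' give p = 1 by convention.
#'
#' @param ct A `contingency_table` from [build_contingency], or a list/vector
#'   with elements a, b, c, d.
#' @return p-value in (0, 1].
#' @examples
#' fisher_upper_tail(build_contingency(letters[1:4], letters[3:6], letters))
#' @export
fisher_upper_tail <- function(ct) {
  a <- as.numeric(ct[["a"]]); b <- as.numeric(ct[["b"]])
  c_ <- as.numeric(ct[["c"]]); d <- as.numeric(ct[["d"]])
  if (min(a, b, c_, d) < 0) stop("negative contingency count")
  K <- a + c_          # annotated in universe
  n <- a + b           # list size
  N <- a + b + c_ + d
  if (n == 0 || K == 0) return(1)
  hi <- min(K, n)
  if (a == 0) return(1)
  lw <- stats::dhyper(a:hi, K, N - K, n, log = TRUE)
  m <- max(lw)
  min(1, exp(m + log(sum(exp(lw - m)))))
}

#' Over-representation analysis of a gene list against a collection
#'
#' For every set in the collection, builds the contingency table against the
#' universe and computes the one-sided hypergeometric upper-tail p-value.
#' Raw p-values are reported (no multiplicity correction), matching the
#' classical presentation of enrichment tables; an optional
#' Benjamini-Hochberg column can be requested.
#'
#' @param gene_list Character vector of query genes (subset of the universe).
#' @param collections List of [gene_set] objects.
#' @param universe Background gene universe. If `NULL`, defaults to the union
#'   of all collection members plus the query list, with a warning — supply
#'   the array or genome universe for honest inference.
#' @param p_adjust If `TRUE`, append a `p_bh` Benjamini-Hochberg column
#'   (off by default).
#' @return Data frame with one row per set: `set_id`, `description`, `a`,
#'   `b`, `c`, `d`, `p_value` (and optionally `p_bh`), sorted by ascending
#'   p-value then set id.
#' @export
enrich_gene_list <- function(gene_list, collections, universe = NULL,
                             p_adjust = FALSE) {
  if (!length(gene_list)) stop("empty gene list")
  if (!length(collections))
    return(data.frame(set_id = character(0), description = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  if (is.null(universe)) {
    universe <- unique(c(unlist(lapply(collections, `[[`, "members")),
                         gene_list))
    warning("no universe supplied; defaulting to the union of collection ",
            "members and the query list")
  }
  rows <- lapply(collections, function(s) {
    ct <- build_contingency(gene_list, s, universe)
    data.frame(set_id = s$set_id, description = s$description,
               a = ct$a, b = ct$b, c = ct$c, d = ct$d,
               p_value = fisher_upper_tail(ct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  if (p_adjust) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
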