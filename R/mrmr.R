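#' Discretize copy-number values into three states per probe
#'
#' Mutual information is estimated from discrete densities, so each probe is
#' reduced to loss / neutral / gain states relative to its own distribution:
#' value v maps to -1 if v < mean - alpha*sd, +1 if v > mean + alpha*sd, and 0
#' otherwise, using the sample standard deviation (n-1 denominator). A
#' zero-variance probe maps entirely to state 0. `alpha = 1` is the
#' convention of the original mRMR software.
#'
#' @param x A [cna_matrix].
#' @param alpha Positive threshold multiplier.
#' @return A `cna_discrete` object: list with `states` (integer matrix in
#'   \{-1, 0, 1\}, same shape and dimnames as the input values), `labels`,
#'   `positive_class`, `alpha`, and the per-probe `center`/`spread` used.
#' @examples
#' m <- cna_matrix(matrix(c(0, 0, 10, 2, 2, 2), 3, 2,
#'                 dimnames = list(NULL, c("a", "b"))), c("ACA", "ACA", "SCC"))
#' discretize_cna(m)$states
#' @export
discretize_cna <- function(x, alpha = 1) {
  validate_cna_matrix(x)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive number")
  v <- x$values
  center <- colMeans(v)
  spread <- apply(v, 2L, stats::sd)
  spread[is.na(spread)] <- 0
  states <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  ok <- spread > 0
  if (any(ok)) {
    lo <- sweep(v[, ok, drop = FALSE], 2L, center[ok] - alpha * spread[ok])
    hi <- sweep(v[, ok, drop = FALSE], 2L, center[ok] + alpha * spread[ok])
    s <- matrix(0L, nrow(v), sum(ok))
    s[lo < 0] <- -1L
    s[hi > 0] <- 1L
    states[, ok] <- s
  }
  structure(list(states = states, labels = x$labels,
                 positive_class = x$positive_class,
                 alpha = alpha, center = center, spread = spread),
            class = "cna_discrete")
}

#' Mutual information between two discrete vectors, in bits
#'
#' Plug-in estimate over the observed joint cells:
#' \deqn{I(x, y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x) p(y)}}
#' with empirical probabilities; cells with zero joint probability contribute
#' nothing. Symmetric, non-negative, and `mutual_information(x, x)` equals the
#' empirical entropy of `x`.
#'
#' @param x,y Vectors of equal length (any discrete values).
#' @return Non-negative mutual information in bits.
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0 bits
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (!length(x)) stop("empty vectors")
  joint <- table(x, y)
  mi_from_counts(joint)
}

# MI in bits from a joint count table/matrix; 0 log 0 := 0.
mi_from_counts <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

# --- vectorized MI internals -------------------------------------------------
# One-hot indicator matrices (n x p, numeric 0/1) for states -1, 0, +1.
state_indicators <- function(states) {
  lapply(c(-1L, 0L, 1L), function(s) (states == s) * 1)
}

# MI (bits) between a single discrete variable, given as an n x k one-hot
# indicator matrix `u`, and every probe column of the indicator list `ind`.
# Summation runs in a fixed (state within level) cell order so that exact
# count ties give exact score ties.
mi_vs_all <- function(u, ind, n) {
  pj <- lapply(ind, function(ib) crossprod(u, ib) / n)  # each k x p
  prow <- Reduce(`+`, pj)                               # k x p, marginal of u
  pcol <- lapply(pj, colSums)                           # state marginals
  mi <- numeric(ncol(ind[[1L]]))
  for (s in seq_along(ind)) {
    for (a in seq_len(nrow(pj[[s]]))) {
      pp <- pj[[s]][a, ]
      e <- prow[a, ] * pcol[[s]]
      nz <- pp > 0
      mi[nz] <- mi[nz] + pp[nz] * log2(pp[nz] / e[nz])
    }
  }
  mi
}

# Relevance I(probe; class) for all probes.
relevance_all <- function(dx) {
  ind <- state_indicators(dx$states)
  u <- cbind(dx$labels == dx$positive_class,
             dx$labels != dx$positive_class) * 1
  mi_vs_all(u, ind, nrow(dx$states))
}

check_two_classes_discrete <- function(dx) {
  pos <- sum(dx$labels == dx$positive_class)
  if (pos == 0L || pos == length(dx$labels))
    stop("both classes must be present (positive class '",
         dx$positive_class, "': ", pos, " of ", length(dx$labels),
         " samples)")
  invisible(dx)
}

ranked_probes <- function(probe_id, score, method) {
  structure(data.frame(rank = seq_along(probe_id), probe_id = probe_id,
                       score = score, stringsAsFactors = FALSE),
            class = c("ranked_probes", "data.frame"), method = method)
}

#' Rank probes by mutual-information relevance to the class (MaxRel)
#'
#' Probes are sorted by I(probe; class) in decreasing order; ties keep input
#' probe order (stable). The score column is the relevance in bits.
#'
#' @param dx A `cna_discrete` from [discretize_cna].
#' @param top_n Number of probes to keep; truncated to the probe count with a
#'   warning if larger. Default 1000.
#' @return A `ranked_probes` data frame with columns `rank`, `probe_id`,
#'   `score` and attribute `method = "maxrel"`.
#' @export
max_rel_rank <- function(dx, top_n = 1000L) {
  stopifnot(inherits(dx, "cna_discrete"))
  check_two_classes_discrete(dx)
  p <- ncol(dx$states)
  if (top_n < 1L) stop("top_n must be >= 1")
  if (top_n > p) {
    warning("top_n (", top_n, ") exceeds probe count (", p, "); truncating")
    top_n <- p
  }
  rel <- relevance_all(dx)
  ord <- order(-rel)[seq_len(top_n)]        # order() is stable: input order on ties
  ranked_probes(colnames(dx$states)[ord], rel[ord], "maxrel")
}

#' Rank probes by maximum relevance, minimum redundancy (mRMR)
#'
#' Greedy forward selection. Round 1 picks the probe with maximum relevance
#' D = I(probe; class). Round m+1 picks the unselected probe maximizing the
#' combined criterion: with `criterion = "difference"` (default, the MID form
#' of the original mRMR software) the score is D - R, where
#' R = (1/m) * sum of I(probe; s) over the m already-selected probes s; with
#' `criterion = "quotient"` (MIQ) the score is D / R (D when R = 0). Ties at
#' any round are broken by input probe order. Both relevance and redundancy
#' are computed on the discretized states.
#'
#' @param dx A `cna_discrete` from [discretize_cna].
#' @param top_n Number of rounds/probes to select (default 1000); truncated
#'   with a warning if it exceeds the probe count.
#' @param criterion `"difference"` (D - R) or `"quotient"` (D / R).
#' @return A `ranked_probes` data frame (`rank` = selection round h,
#'   `probe_id`, `score` = criterion value at selection) with attribute
#'   `method = "mrmr"`.
#' @export
mrmr_rank <- function(dx, top_n = 1000L,
                      criterion = c("difference", "quotient")) {
  stopifnot(inherits(dx, "cna_discrete"))
  criterion <- match.arg(criterion)
  check_two_classes_discrete(dx)
  p <- ncol(dx$states)
  if (top_n < 1L) stop("top_n must be >= 1")
  if (top_n > p) {
    warning("top_n (", top_n, ") exceeds probe count (", p, "); truncating")
    top_n <- p
  }
  n <- nrow(dx$states)
  ind <- state_indicators(dx$states)
  rel <- relevance_all(dx)

  sel <- integer(top_n)
  sel_score <- numeric(top_n)
  red_sum <- numeric(p)        # sum over selected probes of I(probe; selected)
  for (m in seq_len(top_n)) {
    if (m == 1L) {
      score <- rel
    } else if (criterion == "difference") {
      score <- rel - red_sum / (m - 1)
    } else {
      r <- red_sum / (m - 1)
      score <- ifelse(r > 0, rel / r, rel)
    }
    score[sel[seq_len(m - 1L)]] <- -Inf
    s <- which.max(score)      # first maximum = input-order tie break
    sel[m] <- s
    sel_score[m] <- score[s]
    if (m < top_n) {
      u <- cbind(ind[[1L]][, s], ind[[2L]][, s], ind[[3L]][, s])
      red_sum <- red_sum + mi_vs_all(u, ind, n)
    }
  }
  ranked_probes(colnames(dx$states)[sel], sel_score, "mrmr")
}

#' Write a probe ranking to TSV (rank, probe_id, score)
#' @param ranked A `ranked_probes` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_probes"))
  df <- ranked
  df$score <- format(df$score, digits = 15, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe ranking written by [write_ranking]
#' @param path Path to the ranking TSV.
#' @param method Ranking method recorded in the attribute.
#' @return A `ranked_probes` data frame.
#' @export
read_ranking <- function(path, method = "mrmr") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("rank", "probe_id", "score") %in% colnames(df)))
    stop("ranking file must have columns rank, probe_id, score: ", path)
  ranked_probes(df$probe_id, as.numeric(df$score), method)
}
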