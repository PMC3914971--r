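#' Specification of a synthetic two-class copy-number cohort
#'
#' Describes a cohort with a small planted set of class-informative probes,
#' blocks of redundant (jittered near-copy) partner probes, and a large
#' background of uninformative probes around a diploid baseline. The defaults
#' mirror the motivating study's cohort: 208 positive (ACA) and 93 negative
#' (SCC) samples.
#'
#' Planted probes carry a mean copy-number shift between classes of
#' `effect_size * noise_sd`, with alternating sign across planted probes
#' (copy-number gains and losses both occur in real subtype contrasts, and a
#' purely one-sided shift would leave the two class-mean vectors collinear —
#' invisible to the scale-invariant cosine nearness used downstream). Each
#' positive-class sample carries each planted alteration with probability
#' `penetrance` (tumour heterogeneity); the per-carrier shift is scaled by
#' `1/penetrance` so the class-mean shift contract holds exactly.
#'
#' @param n_pos,n_neg Positive / negative class sample counts (each >= 2).
#' @param p_total Total probe count.
#' @param n_informative Number of planted parent probes.
#' @param informative Integer indices of the planted parents; default places
#'   them at `1, 2+block_size, ...` so each parent is directly followed by its
#'   `block_size` redundant partners.
#' @param effect_size Class-mean shift of each planted probe, in units of
#'   `noise_sd` (>= 0).
#' @param penetrance Probability, in (0, 1], that a positive-class sample
#'   carries a given planted alteration.
#' @param block_size Number of redundant near-copy partners per parent (>= 0).
#' @param noise_sd Standard deviation of the probe-level Gaussian noise (> 0).
#' @param jitter_sd Standard deviation of the independent jitter added to each
#'   redundant partner; the default keeps the parent-partner Pearson
#'   correlation above 0.9 by construction.
#' @param baseline Baseline copy-number value (2 = diploid).
#' @param seed Integer seed; all draws flow from one generator stream.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_pos = 208L, n_neg = 93L, p_total = 2000L,
                           n_informative = 10L, informative = NULL,
                           effect_size = 2, penetrance = 0.8,
                           block_size = 2L, noise_sd = 0.3, jitter_sd = 0.2,
                           baseline = 2, seed = 1L) {
  if (is.null(informative))
    informative <- seq(1L, by = block_size + 1L, length.out = n_informative)
  informative <- as.integer(informative)
  n_informative <- length(informative)
  spec <- structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         p_total = as.integer(p_total), informative = informative,
         effect_size = effect_size, penetrance = penetrance,
         block_size = as.integer(block_size), noise_sd = noise_sd,
         jitter_sd = jitter_sd, baseline = baseline, seed = as.integer(seed)),
    class = "synthetic_spec")
  if (spec$n_pos < 2L || spec$n_neg < 2L)
    stop("need at least 2 samples per class")
  if (spec$effect_size < 0) stop("effect_size must be >= 0")
  if (spec$noise_sd <= 0) stop("noise_sd must be > 0")
  if (spec$jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (spec$penetrance <= 0 || spec$penetrance > 1)
    stop("penetrance must be in (0, 1]")
  if (spec$p_total < n_informative * (1L + spec$block_size))
    stop("p_total must be >= n_informative * (1 + block_size)")
  occupied <- planted_indices(spec)
  if (any(duplicated(unlist(occupied))))
    stop("informative probes and their partner blocks overlap")
  if (max(unlist(occupied)) > spec$p_total)
    stop("planted probes fall outside 1..p_total")
  spec
}

# Parent index -> integer vector c(parent, partners...)
planted_indices <- function(spec) {
  lapply(spec$informative, function(j) j + 0:spec$block_size)
}

synthetic_probe_ids <- function(p_total) {
  sprintf("probe_%06d", seq_len(p_total))
}

#' Generate a synthetic two-class copy-number cohort with known ground truth
#'
#' Draws the cohort described by a [synthetic_spec]: background probes are
#' class-independent Gaussian noise around `baseline`; each planted parent
#' probe is shifted in (a `penetrance` fraction of) positive-class samples;
#' each redundant partner equals its parent plus small independent jitter.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec].
#' @return A list with elements `matrix` (a [cna_matrix], labels `"ACA"` for
#'   positives and `"SCC"` for negatives) and `truth` (a `synthetic_truth`
#'   object: `informative` parent probe ids, `partners` named list of partner
#'   ids per parent, `signs` of the planted shifts, and the `spec`).
#' @examples
#' out <- generate_cna(synthetic_spec(n_pos = 20, n_neg = 10, p_total = 100,
#'                                    n_informative = 5, seed = 7))
#' dim(out$matrix)
#' out$truth$informative
#' @export
generate_cna <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  p <- spec$p_total
  pid <- synthetic_probe_ids(p)
  sid <- sprintf("sample_%03d", seq_len(n))
  labels <- c(rep("ACA", spec$n_pos), rep("SCC", spec$n_neg))

  values <- matrix(stats::rnorm(n * p, spec$baseline, spec$noise_sd), n, p,
                   dimnames = list(sid, pid))
  k <- length(spec$informative)
  signs <- rep(c(1, -1), length.out = k)
  delta <- spec$effect_size * spec$noise_sd / spec$penetrance
  partners <- stats::setNames(vector("list", k), pid[spec$informative])
  for (i in seq_len(k)) {
    j <- spec$informative[i]
    carrier <- stats::rbinom(spec$n_pos, 1L, spec$penetrance)
    values[seq_len(spec$n_pos), j] <-
      values[seq_len(spec$n_pos), j] + carrier * signs[i] * delta
    if (spec$block_size > 0L) {
      idx <- j + seq_len(spec$block_size)
      for (b in idx)
        values[, b] <- values[, j] + stats::rnorm(n, 0, spec$jitter_sd)
      partners[[i]] <- pid[idx]
    } else {
      partners[[i]] <- character(0)
    }
  }
  truth <- structure(
    list(informative = pid[spec$informative], partners = partners,
         signs = signs, spec = spec),
    class = "synthetic_truth")
  list(matrix = cna_matrix(values, labels, positive_class = "ACA"),
       truth = truth)
}

#' Generate synthetic gene-set collections with one planted enriched set
#'
#' Builds a 1:1 synthetic probe-to-gene universe (`g_<probe_id>`), one
#' "planted" set containing the genes of the informative parent probes padded
#' with random genes up to `set_size`, and `n_null_sets` random sets drawn
#' from the universe. Supports testing over-representation analysis end to
#' end: the planted set should rank first when the informative genes are
#' tested against the collection.
#'
#' @param truth A `synthetic_truth` from [generate_cna].
#' @param n_null_sets Number of random null sets (>= 0).
#' @param set_size Members per set (>= 1, <= universe size).
#' @param seed Integer seed.
#' @return A list with `sets` (list of [gene_set]; the planted set has id
#'   `"planted"`) and `universe` (character vector of all gene ids).
#' @export
generate_genesets <- function(truth, n_null_sets = 50L, set_size = 20L,
                              seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (set_size < 1L) stop("set_size must be >= 1")
  universe <- paste0("g_", synthetic_probe_ids(truth$spec$p_total))
  if (set_size > length(universe))
    stop("set_size (", set_size, ") exceeds universe size (",
         length(universe), ")")
  set.seed(seed)
  planted_genes <- paste0("g_", truth$informative)
  pad <- setdiff(universe, planted_genes)
  extra <- max(0L, set_size - length(planted_genes))
  planted <- gene_set("planted", "planted informative-gene set",
                      c(planted_genes, sample(pad, extra)))
  sets <- list(planted)
  for (i in seq_len(n_null_sets)) {
    sets[[i + 1L]] <- gene_set(sprintf("null_%03d", i), "random null set",
                               sample(universe, set_size))
  }
  list(sets = sets, universe = universe)
}

#' Generate BED-style probe positions and gene models for a synthetic cohort
#'
#' Places every probe on one chromosome at 10 kb spacing and defines one gene
#' per probe (`g_<probe_id>`) spanning 200 bp around it, so that with the
#' default 2 kb extension each probe maps to exactly its own gene. This is
#' plumbing for exercising the probe-to-gene mapping stage on synthetic runs;
#' it makes no attempt to emulate real gene architecture.
#'
#' @param truth A `synthetic_truth` from [generate_cna].
#' @return A list with `probes` (data frame: probe_id, chrom, pos; 0-based)
#'   and `genes` (data frame: gene_id, chrom, start, end; 0-based half-open).
#' @export
generate_annotation <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  pid <- synthetic_probe_ids(truth$spec$p_total)
  pos <- 5000L + (seq_along(pid) - 1L) * 10000L
  list(
    probes = data.frame(probe_id = pid, chrom = "chr1", pos = pos,
                        stringsAsFactors = FALSE),
    genes = data.frame(gene_id = paste0("g_", pid), chrom = "chr1",
                       start = pos - 100L, end = pos + 100L,
                       stringsAsFactors = FALSE))
}
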