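#' Read probe positions from a BED3+1 file
#'
#' Expected columns (tab-separated, no header): chrom, start, end, probe_id,
#' with 0-based half-open coordinates as in BED; the probe position is the
#' start coordinate (probes are points, end is conventionally start + 1).
#'
#' @param path Path to the BED file.
#' @return Data frame with columns `probe_id`, `chrom`, `pos` (0-based).
#' @export
read_probe_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("probe BED needs 4 columns (chrom, start, end, id)")
  out <- data.frame(probe_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    pos = as.integer(df[[2L]]), stringsAsFactors = FALSE)
  if (any(out$pos < 0)) stop("negative probe position in ", path)
  dup <- out$probe_id[duplicated(out$probe_id)]
  if (length(dup))
    stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  out
}

#' Read gene models from a BED3+1 file
#'
#' Expected columns (tab-separated, no header): chrom, start, end, gene_id,
#' 0-based half-open with start < end.
#'
#' @param path Path to the BED file.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("gene BED needs 4 columns (chrom, start, end, id)")
  out <- data.frame(gene_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0)) stop("negative gene start in ", path)
  if (any(out$start >= out$end))
    stop("gene with start >= end: ",
         paste(out$gene_id[out$start >= out$end], collapse = ", "))
  out
}

#' Map probes to genes with symmetric upstream/downstream extension
#'
#' Probe p maps to gene g iff the chromosomes match and
#' `start(g) - extension <= pos(p) < end(g) + extension`
#' (0-based half-open arithmetic; the extended start is clipped at 0). The
#' default 2 kb extension captures probes just up- or downstream of a gene
#' body. Strand is ignored — the extension is applied symmetrically on both
#' sides. A probe may map to several genes and vice versa.
#'
#' @param probes Data frame from [read_probe_bed] (columns probe_id, chrom,
#'   pos).
#' @param genes Data frame from [read_gene_bed] (columns gene_id, chrom,
#'   start, end).
#' @param extension Non-negative extension in bp (default 2000).
#' @return Data frame with columns `probe_id`, `gene_id`, one row per
#'   overlapping pair, ordered by probe then gene input order.
#' @export
map_probes_to_genes <- function(probes, genes, extension = 2000L) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% colnames(probes)),
            all(c("gene_id", "chrom", "start", "end") %in% colnames(genes)))
  if (extension < 0) stop("extension must be >= 0")
  if (!nrow(probes) || !nrow(genes))
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  # 1-based inclusive ranges for GRanges; half-open [start-ext, end+ext)
  # becomes [start-ext+1, end+ext] with the left edge clipped at position 0.
  pg <- GenomicRanges::GRanges(
    seqnames = probes$chrom,
    ranges = IRanges::IRanges(start = probes$pos + 1L,
                              width = 1L))
  gg <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(genes$start - extension, 0L) + 1L,
                              end = genes$end + extension))
  hits <- GenomicRanges::findOverlaps(pg, gg)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ord <- order(qi, si)
  data.frame(probe_id = probes$probe_id[qi[ord]],
             gene_id = genes$gene_id[si[ord]], stringsAsFactors = FALSE)
}

#' Genes corresponding to an optimal probe subset
#'
#' Union of the genes mapped to by the subset's probes, deduplicated and
#' sorted. Unmapped probes contribute nothing.
#'
#' @param subset An `optimal_subset` (or character vector of probe ids).
#' @param map A probe-to-gene map from [map_probes_to_genes].
#' @return Sorted character vector of unique gene ids.
#' @export
genes_of_subset <- function(subset, map) {
  ids <- if (inherits(subset, "optimal_subset")) subset$probe_ids else subset
  sort(unique(map$gene_id[map$probe_id %in% ids]))
}

#' Write a probe-to-gene map to TSV
#' @param map Data frame from [map_probes_to_genes].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_gene_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
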