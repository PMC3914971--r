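#' Read a pipeline configuration from a YAML file
#'
#' The configuration mirrors the stages of [run_pipeline]; see that help page
#' for the recognized blocks and defaults.
#'
#' @param path Path to a YAML config file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end subtype-classification pipeline
#'
#' Orchestrates simulate (or load) -> discretize -> MaxRel + mRMR ranking ->
#' incremental feature selection -> optimal subset -> probe-to-gene mapping ->
#' over-representation analysis, writing every intermediate artifact to the
#' output directory together with a machine-readable JSON manifest. The run
#' is deterministic: an identical configuration (including seed) produces an
#' identical manifest.
#'
#' Recognized configuration entries (all optional unless noted):
#' \describe{
#'   \item{output_dir}{required; created if absent}
#'   \item{seed}{integer, default 1; seeds the synthetic stages}
#'   \item{simulate}{list of [synthetic_spec] arguments; mutually exclusive
#'     with `input`}
#'   \item{input}{list: `matrix` (TSV path, required), `orientation`
#'     (`"samples"`/`"probes"`), `labels` (optional path),
#'     `probes_bed`/`genes_bed` (optional BED paths for mapping),
#'     `gmt` (optional gene-set file), `universe` (optional gene list file)}
#'   \item{mrmr}{list: `alpha` (default 1), `top_n` (default 1000),
#'     `criterion` (default `"difference"`)}
#'   \item{ifs}{list: `max_n` (default = top_n)}
#'   \item{map}{list: `extension` (default 2000)}
#'   \item{enrich}{list: `n_null_sets`, `set_size` (synthetic runs only)}
#' }
#'
#' @param config A named list, or path to a YAML file.
#' @return The manifest, invisibly: list with `files`, `optimal`
#'   (size + metrics), `top_enrichment`, `input_md5`, `parameters`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config must set output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  files <- list()
  log <- function(...) message("[pipeline] ", ...)

  # --- stage: cohort -------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    spec <- do.call(synthetic_spec,
                    c(config$simulate, list(seed = seed)))
    log("simulate: ", spec$n_pos, "+", spec$n_neg, " samples x ",
        spec$p_total, " probes, seed ", seed)
    sim <- generate_cna(spec)
    mat <- sim$matrix
    truth <- sim$truth
    files$matrix <- file.path(out_dir, "matrix.tsv")
    write_cna_matrix(mat, files$matrix)
    files$truth <- file.path(out_dir, "truth.tsv")
    utils::write.table(
      data.frame(parent = truth$informative, sign = truth$signs,
                 partners = vapply(truth$partners, paste, "",
                                   collapse = ",")),
      files$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (!is.null(config$input)) {
    if (is.null(config$input$matrix)) stop("input stage: matrix path missing")
    if (!file.exists(config$input$matrix))
      stop("cohort stage failed: input matrix not found: ",
           config$input$matrix)
    mat <- read_cna_matrix(config$input$matrix,
                           orientation = config$input$orientation %||%
                             "samples",
                           labels = config$input$labels)
    files$matrix <- config$input$matrix
    log("loaded ", nrow(mat$values), " samples x ", ncol(mat$values),
        " probes from ", config$input$matrix)
  } else stop("config must contain either `simulate` or `input`")

  # --- stage: ranking ------------------------------------------------------
  alpha <- config$mrmr$alpha %||% 1
  top_n <- as.integer(config$mrmr$top_n %||% 1000L)
  top_n <- min(top_n, ncol(mat$values))
  criterion <- config$mrmr$criterion %||% "difference"
  log("rank: alpha=", alpha, ", top_n=", top_n, ", criterion=", criterion)
  dx <- discretize_cna(mat, alpha = alpha)
  maxrel <- max_rel_rank(dx, top_n = top_n)
  mrmr <- mrmr_rank(dx, top_n = top_n, criterion = criterion)
  files$maxrel <- file.path(out_dir, "maxrel.tsv")
  files$mrmr <- file.path(out_dir, "mrmr.tsv")
  write_ranking(maxrel, files$maxrel)
  write_ranking(mrmr, files$mrmr)

  # --- stage: IFS ----------------------------------------------------------
  max_n <- as.integer(config$ifs$max_n %||% top_n)
  max_n <- min(max_n, nrow(mrmr))
  log("ifs: evaluating prefixes 1..", max_n)
  tab <- run_ifs(mat, mrmr, max_n = max_n)
  opt <- select_optimal(tab, mrmr)
  log("ifs optimum: ", opt$size, " probes, MCC=",
      sprintf("%.4f", opt$metrics$mcc))
  files$ifs_table <- file.path(out_dir, "ifs_table.tsv")
  write_ifs_table(tab, files$ifs_table)
  files$optimal_probes <- file.path(out_dir, "optimal_probes.txt")
  writeLines(opt$probe_ids, files$optimal_probes)
  files$heatmap <- file.path(out_dir, "heatmap_data.tsv")
  hm <- export_heatmap_data(mat, opt)
  utils::write.table(
    data.frame(probe_id = rownames(hm),
               format(hm, digits = 15, trim = TRUE), check.names = FALSE),
    files$heatmap, sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: probe -> gene map -------------------------------------------
  extension <- as.integer(config$map$extension %||% 2000L)
  annot <- NULL
  if (!is.null(truth)) {
    annot <- generate_annotation(truth)
  } else if (!is.null(config$input$probes_bed) &&
             !is.null(config$input$genes_bed)) {
    annot <- list(probes = read_probe_bed(config$input$probes_bed),
                  genes = read_gene_bed(config$input$genes_bed))
  }
  gene_list <- NULL
  if (!is.null(annot)) {
    log("map: extension=", extension, " bp")
    pg <- map_probes_to_genes(annot$probes, annot$genes,
                              extension = extension)
    files$probe_gene_map <- file.path(out_dir, "probe_gene_map.tsv")
    write_probe_gene_map(pg, files$probe_gene_map)
    gene_list <- genes_of_subset(opt, pg)
    files$optimal_genes <- file.path(out_dir, "optimal_genes.txt")
    writeLines(gene_list, files$optimal_genes)
  }

  # --- stage: enrichment ---------------------------------------------------
  top_enrich <- NULL
  if (!is.null(gene_list) && length(gene_list)) {
    if (!is.null(truth)) {
      gs <- generate_genesets(truth,
                              n_null_sets =
                                as.integer(config$enrich$n_null_sets %||%
                                             50L),
                              set_size =
                                as.integer(config$enrich$set_size %||% 20L),
                              seed = seed)
      sets <- gs$sets
      universe <- gs$universe
      files$gmt <- file.path(out_dir, "genesets.gmt")
      write_gmt(sets, files$gmt)
    } else {
      sets <- if (!is.null(config$input$gmt))
        read_gmt(config$input$gmt) else NULL
      universe <- if (!is.null(config$input$universe))
        readLines(config$input$universe) else NULL
    }
    if (!is.null(sets)) {
      log("enrich: ", length(sets), " sets, list of ", length(gene_list),
          " genes")
      er <- enrich_gene_list(gene_list, sets, universe)
      files$enrichment <- file.path(out_dir, "enrichment.tsv")
      ef <- er
      ef$p_value <- format(ef$p_value, digits = 15, trim = TRUE)
      utils::write.table(ef, files$enrichment, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      top_enrich <- utils::head(er, 5L)
    }
  }

  manifest <- list(
    files = lapply(files, normalizePath),
    parameters = list(seed = seed, alpha = alpha, top_n = top_n,
                      criterion = criterion, max_n = max_n,
                      extension = extension),
    input_md5 = as.list(tools::md5sum(unlist(files["matrix"]))),
    optimal = list(size = opt$size,
                   metrics = unclass(opt$metrics)),
    top_enrichment = top_enrich)
  files$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  log("manifest: ", files$manifest)
  invisible(manifest)
}
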