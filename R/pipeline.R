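# End-to-end pipeline: normalize -> filter -> (group) -> network ->
# evaluate -> report, driven by a key-value config (list or YAML file).
# Every artifact carries a commented provenance header (parameters, seed,
# package version); identical config + seed gives identical outputs.

default_config <- function() {
  list(method = "COO", k = 100,
       min_fpkm = 0.5, min_fraction = 0.5, min_libraries = 6,
       n_folds = 3, seed = 1,
       term_min_size = 20, term_max_size = 1000,
       annotation_format = "tsv", annotation_name = "annotations",
       genome_gene_total = NULL)
}

provenance_header <- function(cfg) {
  c(paste0("aggcoex ", as.character(utils::packageVersion("aggcoex"))),
    paste0("method: ", cfg$method, "  k: ", cfg$k),
    paste0("min_fpkm: ", cfg$min_fpkm, "  min_fraction: ",
           cfg$min_fraction, "  min_libraries: ", cfg$min_libraries),
    paste0("n_folds: ", cfg$n_folds, "  seed: ", cfg$seed))
}

write_tsv_artifact <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full coexpression pipeline
#'
#' Reads the count matrix, gene lengths, sample table and annotation
#' collection(s) named in the config, builds the requested network,
#' summarizes its topology, evaluates it by neighbor-voting AUROC, and
#' writes five TSV artifacts (`fpkm.tsv`, `network.tsv`, `topology.tsv`,
#' `term_auroc.tsv`, `dataset_auroc.tsv`) under `out_dir`, each with a
#' commented provenance header. Input files are never modified.
#'
#' @param config a named list or the path of a YAML file with keys
#'   `counts`, `lengths`, `samples`, `annotations` (path, or list of
#'   `path`/`format`/`name` entries), `out_dir`, and optional parameter
#'   overrides (`method`, `k`, `min_fpkm`, `min_fraction`,
#'   `min_libraries`, `n_folds`, `seed`, `term_min_size`,
#'   `term_max_size`, `genome_gene_total`).
#' @param ... individual key overrides; these win over the config file.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file does not exist: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(), config)
  cfg <- utils::modifyList(cfg, list(...))
  for (key in c("counts", "lengths", "samples", "annotations",
                "out_dir")) {
    if (is.null(cfg[[key]])) stop("config misses '", key, "'",
                                  call. = FALSE)
  }
  ann_spec <- cfg$annotations
  if (is.character(ann_spec)) {
    ann_spec <- list(list(path = ann_spec, format = cfg$annotation_format,
                          name = cfg$annotation_name))
  } else if (!is.null(ann_spec$path)) {
    ann_spec <- list(ann_spec)
  }
  paths <- c(cfg$counts, cfg$lengths, cfg$samples,
             vapply(ann_spec, `[[`, "", "path"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path does not exist: ", missing[[1L]], call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(cfg)

  message("[read] ingesting counts, lengths, samples, annotations")
  cm <- read_count_matrix(cfg$counts, cfg$lengths)
  st <- read_sample_table(cfg$samples)
  anns <- lapply(ann_spec, function(a)
    read_annotations(a$path,
                     format = if (is.null(a$format)) "tsv" else a$format,
                     dataset_name = if (is.null(a$name)) "annotations"
                                    else a$name))

  message("[normalize] FPKM normalization")
  fm <- fpkm_normalize(cm)
  out <- list(fpkm = file.path(cfg$out_dir, "fpkm.tsv"))
  write_expression(fm, out$fpkm, header = hdr)

  message("[network] building ", cfg$method, cfg$k)
  net <- gcn(cm, st, method = cfg$method, k = cfg$k,
             min_fpkm = cfg$min_fpkm, min_fraction = cfg$min_fraction,
             min_libraries = cfg$min_libraries)
  out$network <- file.path(cfg$out_dir, "network.tsv")
  write_network(net, out$network)

  message("[topology] degree statistics")
  ts <- degree_stats(net, genome_gene_total = cfg$genome_gene_total)
  out$topology <- file.path(cfg$out_dir, "topology.tsv")
  write_tsv_artifact(as.data.frame(unclass(ts)), out$topology, hdr)

  message("[evaluate] neighbor-voting AUROC")
  rows <- do.call(rbind, lapply(anns, function(a) {
    af <- filter_terms(a, net, cfg$term_min_size, cfg$term_max_size)
    neighbor_voting_auroc(net, af, n_folds = cfg$n_folds,
                          seed = cfg$seed)
  }))
  out$term_auroc <- file.path(cfg$out_dir, "term_auroc.tsv")
  write_tsv_artifact(rows, out$term_auroc, hdr)

  dm <- dataset_mean_auroc(rows)
  report <- rbind(dm$dataset_means,
                  data.frame(dataset_name = "Average",
                             mean_auroc = dm$average))
  out$dataset_auroc <- file.path(cfg$out_dir, "dataset_auroc.tsv")
  write_tsv_artifact(report, out$dataset_auroc, hdr)

  message("[done] ", length(out), " artifacts in ", cfg$out_dir)
  invisible(out)
}
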