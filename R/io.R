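# Tabular input/output: count matrices, sample tables, annotation
# collections (GMT or gene<TAB>term pairs) and network edge lists.
# All TSV readers skip '#'-prefixed comment lines; gene identifiers are
# opaque strings and are never reordered on read.

read_tsv_table <- function(path, header = TRUE) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  utils::read.delim(path, header = header, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Construct a count matrix
#'
#' A `count_matrix` holds non-negative integer fragment counts (genes in
#' rows, samples in columns) together with a per-gene transcript length in
#' base pairs, the two ingredients of FPKM normalization.
#'
#' @param counts numeric matrix of non-negative integers with unique row
#'   (gene) and column (sample) names.
#' @param gene_lengths named numeric vector of positive lengths in bp; must
#'   cover every gene in `counts`.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `gene_lengths` (aligned to the row order of `counts`).
#' @export
count_matrix <- function(counts, gene_lengths) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("counts must have gene row names and sample column names",
         call. = FALSE)
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) {
    stop("duplicated gene id: ", dup_g[[1L]], call. = FALSE)
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop("duplicated sample id: ", dup_s[[1L]], call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  missing_len <- setdiff(gene_ids, names(gene_lengths))
  if (length(missing_len)) {
    stop("no length for gene: ", missing_len[[1L]], call. = FALSE)
  }
  len <- as.numeric(gene_lengths[gene_ids])
  if (anyNA(len) || any(len <= 0) || any(len != round(len))) {
    stop("gene lengths must be positive integers (bp)", call. = FALSE)
  }
  names(len) <- gene_ids
  structure(list(counts = counts, gene_lengths = len),
            class = "count_matrix")
}

#' Read a count matrix and gene-length table from TSV
#'
#' @param counts_path TSV with a header row of sample ids and gene ids in
#'   the first column.
#' @param lengths_path TSV mapping gene id to transcript length in bp
#'   (two columns, with or without a header).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, lengths_path) {
  tab <- read_tsv_table(counts_path)
  if (ncol(tab) < 2L) stop("count matrix needs >= 1 sample column",
                           call. = FALSE)
  gene_ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop("non-numeric count value in ", counts_path,
                     call. = FALSE)
  rownames(m) <- gene_ids

  lt <- read_length_table(lengths_path)
  count_matrix(m, lt)
}

read_length_table <- function(path) {
  raw <- read_tsv_table(path, header = FALSE)
  if (ncol(raw) < 2L) stop("length table needs two columns", call. = FALSE)
  # tolerate a header row (second field non-numeric)
  if (is.na(suppressWarnings(as.numeric(raw[1L, 2L])))) {
    raw <- raw[-1L, , drop = FALSE]
  }
  len <- suppressWarnings(as.numeric(raw[[2L]]))
  if (anyNA(len)) stop("non-numeric gene length in ", path, call. = FALSE)
  stats::setNames(len, as.character(raw[[1L]]))
}

#' Read a sample table
#'
#' Expects columns `sample_id` and `group_id` (the study/bioproject used as
#' the aggregation unit) and an optional `organ` column. Extra columns are
#' preserved untouched; row order is preserved.
#'
#' @param path TSV file path.
#' @return A `data.frame` of class `sample_table`.
#' @export
read_sample_table <- function(path) {
  tab <- read_tsv_table(path)
  sample_table(tab)
}

#' @rdname read_sample_table
#' @param x data.frame with at least `sample_id` and `group_id` columns.
#' @export
sample_table <- function(x) {
  need <- c("sample_id", "group_id")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("sample table missing column: ", miss[[1L]], call. = FALSE)
  }
  x$sample_id <- as.character(x$sample_id)
  x$group_id <- as.character(x$group_id)
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup)) stop("duplicated sample id: ", dup[[1L]], call. = FALSE)
  if (any(is.na(x$group_id) | x$group_id == "")) {
    stop("empty group_id for sample: ",
         x$sample_id[which(is.na(x$group_id) | x$group_id == "")[1L]],
         call. = FALSE)
  }
  if (!"organ" %in% names(x)) x$organ <- NA_character_
  class(x) <- c("sample_table", "data.frame")
  x
}

#' Construct an annotation collection
#'
#' @param dataset_name label of the annotation dataset (e.g. `"GObp"`).
#' @param terms named list mapping term id to a character vector of gene
#'   ids; duplicates within a term are removed, empty terms are dropped
#'   with a warning.
#' @param labels optional named character vector of term descriptions.
#' @return An object of class `annotation_collection`.
#' @export
annotation_collection <- function(dataset_name, terms, labels = NULL) {
  stopifnot(is.list(terms))
  if (is.null(names(terms)) || anyNA(names(terms)) ||
      any(names(terms) == "")) {
    stop("every term needs an id", call. = FALSE)
  }
  terms <- lapply(terms, function(g) unique(as.character(g)))
  empty <- lengths(terms) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " term(s) with zero genes",
            call. = FALSE)
    terms <- terms[!empty]
  }
  if (!length(terms)) stop("annotation collection has no terms",
                           call. = FALSE)
  structure(list(dataset_name = as.character(dataset_name),
                 terms = terms, labels = labels),
            class = "annotation_collection")
}

#' Read a functional annotation collection
#'
#' Supports the standard GMT gene-set format (term, description, genes...)
#' and a two-column `gene<TAB>term` TSV. Duplicate (gene, term) pairs are
#' deduplicated silently; terms left with zero genes are dropped with a
#' warning.
#'
#' @param path file path.
#' @param format `"gmt"` or `"tsv"`.
#' @param dataset_name label carried through evaluation/enrichment tables.
#' @return An [annotation_collection()].
#' @export
read_annotations <- function(path, format = c("gmt", "tsv"),
                             dataset_name = "annotations") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty annotation file: ", path, call. = FALSE)
  if (format == "gmt") {
    terms <- fgsea::gmtPathways(path)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L)) {
      stop("tsv annotations need gene<TAB>term rows", call. = FALSE)
    }
    gene <- vapply(parts, `[[`, "", 1L)
    term <- vapply(parts, `[[`, "", 2L)
    # allow an optional header row
    if (identical(tolower(gene[[1L]]), "gene") &&
        identical(tolower(term[[1L]]), "term")) {
      gene <- gene[-1L]
      term <- term[-1L]
    }
    terms <- split(gene, factor(term, levels = unique(term)))
  }
  annotation_collection(dataset_name, terms)
}

#' @export
print.annotation_collection <- function(x, ...) {
  sizes <- lengths(x$terms)
  cat("Annotation collection '", x$dataset_name, "': ", length(x$terms),
      " terms, set sizes ", min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

canonical_edges <- function(gene_a, gene_b, score) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (any(gene_a == gene_b)) {
    stop("self-loop edge on gene: ", gene_a[gene_a == gene_b][1L],
         call. = FALSE)
  }
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]
  gene_a[swap] <- gene_b[swap]
  gene_b[swap] <- tmp
  df <- data.frame(gene_a = gene_a, gene_b = gene_b, score = score,
                   stringsAsFactors = FALSE)
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

score_semantics <- function(method) {
  if (identical(method, "COO")) "cooccurrence_frequency" else "hrr_rank"
}

#' Write / read a network edge list
#'
#' Edge lists are TSV files with a commented provenance header recording the
#' method tag (HRR or COO), the sparsity `k`, the number of aggregated
#' groups and the score semantics. Each undirected edge is written once
#' with the lexicographically smaller gene first, so files diff
#' deterministically.
#'
#' @param network a `gcn` object.
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a `gcn` object (nodes are the sorted union of edge endpoints).
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "gcn"))
  header <- c(
    "# aggcoex network edge list",
    paste0("# method: ", network$method),
    paste0("# k: ", network$k),
    paste0("# n_groups: ", if (is.na(network$n_groups)) "NA"
           else network$n_groups),
    paste0("# score: ", score_semantics(network$method)),
    paste0("# n_nodes: ", length(network$nodes))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("gene_a\tgene_b\tscore", con)
  edges <- canonical_edges(network$edges$gene_a, network$edges$gene_b,
                           network$edges$score)
  writeLines(paste(edges$gene_a, edges$gene_b,
                   format(edges$score, trim = TRUE, scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  get_field <- function(name) {
    hit <- grep(paste0("^# ", name, ": "), hdr, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^# ", name, ": "), "", hit[[1L]])
  }
  method <- get_field("method")
  if (!method %in% c("HRR", "COO")) {
    stop("network file lacks a valid '# method:' header", call. = FALSE)
  }
  k <- as.integer(get_field("k"))
  n_groups <- suppressWarnings(as.integer(get_field("n_groups")))
  tab <- read_tsv_table(path)
  if (!all(c("gene_a", "gene_b", "score") %in% names(tab))) {
    stop("network file needs gene_a, gene_b, score columns", call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(tab$score))
  if (anyNA(score)) stop("non-numeric score in ", path, call. = FALSE)
  edges <- canonical_edges(tab$gene_a, tab$gene_b, score)
  new_gcn(edges, nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
          method = method, k = k, n_groups = n_groups)
}

#' Write an expression matrix as TSV
#'
#' @param x a matrix (genes x samples) or an object with `$values`.
#' @param path file path.
#' @param header character vector of provenance lines (written '#'-prefixed).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, header = character()) {
  v <- if (is.list(x) && !is.null(x$values)) x$values else x
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene_id", colnames(v)), collapse = "\t"), con)
  utils::write.table(data.frame(gene_id = rownames(v), v,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
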