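# FPKM normalization, low-expression filtering and study grouping.
#
# FPKM(g, s) = counts(g, s) * 1e9 / (length_bp(g) * total_counts(s)),
# with per-sample totals taken over all genes of the ingested matrix.
# Normalization happens once, on the full matrix; grouping and per-group
# filtering operate on slices of that single FPKM matrix.

new_fpkm_matrix <- function(values, provenance = list(filters = character())) {
  structure(list(values = values, provenance = provenance),
            class = "fpkm_matrix")
}

expr_values <- function(x) {
  if (inherits(x, "fpkm_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected an fpkm_matrix or a matrix", call. = FALSE)
}

#' FPKM-normalize a count matrix
#'
#' Converts fragment counts to fragments per kilobase of transcript per
#' million mapped fragments. Per-sample totals are the column sums over all
#' genes in `cm`; a cell is zero exactly where its count is zero.
#'
#' @param cm a [count_matrix()].
#' @return An `fpkm_matrix` (list with a genes x samples `values` matrix
#'   and a `provenance` record of applied filters).
#' @export
fpkm_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- colSums(cm$counts)
  if (any(totals == 0)) {
    stop("sample with zero total counts: ",
         colnames(cm$counts)[which(totals == 0)[1L]], call. = FALSE)
  }
  v <- sweep(cm$counts, 1L, cm$gene_lengths, "/")
  v <- sweep(v, 2L, totals, "/") * 1e9
  new_fpkm_matrix(v)
}

#' Filter low-expression and constant genes
#'
#' A gene is removed when the number of samples in which its FPKM falls
#' below `min_fpkm` is at least `min_fraction` of the samples (the boundary
#' is inclusive: a gene must clear `min_fpkm` in a strict majority of
#' libraries at the 0.5/0.5 defaults). Genes with identical expression in
#' every sample are additionally removed (their Pearson correlation is
#' undefined); their count is reported via `message()`. Surviving genes
#' keep their input order, so the operation is idempotent.
#'
#' @param fm an `fpkm_matrix`.
#' @param min_fpkm expression floor in FPKM units (default 0.5).
#' @param min_fraction fraction of libraries allowed below the floor
#'   before removal (default 0.5).
#' @return A filtered `fpkm_matrix`.
#' @export
filter_low_expression <- function(fm, min_fpkm = 0.5, min_fraction = 0.5) {
  v <- expr_values(fm)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  n_low <- rowSums(v < min_fpkm)
  keep <- n_low < min_fraction * ncol(v)
  constant <- apply(v, 1L, function(r) max(r) == min(r))
  n_const_dropped <- sum(keep & constant)
  if (n_const_dropped > 0L) {
    message("removed ", n_const_dropped,
            " constant-expression gene(s) with undefined correlation")
  }
  keep <- keep & !constant
  if (!any(keep)) stop("all genes removed by expression filter",
                       call. = FALSE)
  prov <- if (inherits(fm, "fpkm_matrix")) fm$provenance
          else list(filters = character())
  prov$filters <- c(prov$filters,
                    sprintf("low_expression(min_fpkm=%g, min_fraction=%g)",
                            min_fpkm, min_fraction))
  new_fpkm_matrix(v[keep, , drop = FALSE], prov)
}

#' Group samples by study and filter per group
#'
#' Normalizes `cm` once to FPKM (totals over the full matrix), clusters
#' samples by their `group_id` (bioproject), drops groups with fewer than
#' `min_libraries` libraries, and low-expression-filters each retained
#' group independently. Per-group filtering is what lets genes expressed
#' only under specific conditions enter the aggregated network.
#'
#' @param cm a [count_matrix()].
#' @param st a [sample_table()] covering every sample of `cm`.
#' @param min_libraries minimum RNA-seq libraries per retained group
#'   (default 6).
#' @param min_fpkm,min_fraction passed to [filter_low_expression()].
#' @return A `grouped_expression` object: `groups` (named list of filtered
#'   `fpkm_matrix`), `fpkm` (the full normalized matrix), `sample_groups`
#'   (named sample -> group vector) and `min_libraries`.
#' @export
group_by_bioproject <- function(cm, st, min_libraries = 6,
                                min_fpkm = 0.5, min_fraction = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  st <- sample_table(as.data.frame(st))
  samples <- colnames(cm$counts)
  missing <- setdiff(samples, st$sample_id)
  if (length(missing)) {
    stop("sample absent from sample table: ", missing[[1L]], call. = FALSE)
  }
  fm <- fpkm_normalize(cm)
  grp <- stats::setNames(st$group_id, st$sample_id)[samples]
  by_group <- split(samples, factor(grp, levels = unique(grp)))
  sizes <- lengths(by_group)
  by_group <- by_group[sizes >= min_libraries]
  if (!length(by_group)) {
    stop("no group with >= ", min_libraries, " libraries", call. = FALSE)
  }
  groups <- list()
  for (g in names(by_group)) {
    sub <- new_fpkm_matrix(fm$values[, by_group[[g]], drop = FALSE],
                           fm$provenance)
    res <- tryCatch(
      filter_low_expression(sub, min_fpkm, min_fraction),
      error = function(e) NULL)
    if (is.null(res)) {
      warning("group ", g, " dropped: all genes filtered", call. = FALSE)
    } else {
      groups[[g]] <- res
    }
  }
  if (!length(groups)) stop("no group survives filtering", call. = FALSE)
  structure(list(groups = groups, fpkm = fm,
                 sample_groups = grp, min_libraries = min_libraries),
            class = "grouped_expression")
}

#' @export
print.grouped_expression <- function(x, ...) {
  cat("Grouped expression: ", length(x$groups), " group(s)\n", sep = "")
  for (g in names(x$groups)) {
    cat("  ", g, ": ", nrow(x$groups[[g]]$values), " genes x ",
        ncol(x$groups[[g]]$values), " libraries\n", sep = "")
  }
  invisible(x)
}
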