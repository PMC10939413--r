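# Degree-based topology summaries of a coexpression network.

#' Node degrees of a network
#'
#' @param net a `gcn` object.
#' @return Named integer vector of degrees over `net$nodes` (isolated
#'   nodes, if any, have degree 0).
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "gcn"))
  ends <- factor(c(net$edges$gene_a, net$edges$gene_b),
                 levels = net$nodes)
  d <- tabulate(ends, nbins = length(net$nodes))
  stats::setNames(as.integer(d), net$nodes)
}

#' Degree statistics of a network
#'
#' Computes the node count, optional percentage of an annotated genome
#' covered, and the min/max/range/mean node degree connectivity.
#'
#' @param net a non-empty `gcn` object.
#' @param genome_gene_total optional total of annotated protein-coding
#'   genes; when given, `pct_of_genome = 100 * n_nodes / genome_gene_total`.
#' @return A `topology_summary` list: `method`, `k`, `n_nodes`,
#'   `pct_of_genome`, `n_edges`, `degree_min`, `degree_max`,
#'   `degree_range`, `degree_mean`.
#' @export
degree_stats <- function(net, genome_gene_total = NULL) {
  stopifnot(inherits(net, "gcn"))
  if (!nrow(net$edges)) stop("empty network", call. = FALSE)
  d <- node_degrees(net)
  structure(list(
    method = net$method, k = net$k,
    n_nodes = length(d),
    pct_of_genome = if (is.null(genome_gene_total)) NA_real_
                    else 100 * length(d) / genome_gene_total,
    n_edges = nrow(net$edges),
    degree_min = min(d),
    degree_max = max(d),
    degree_range = max(d) - min(d),
    degree_mean = mean(d)
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Network topology (", x$method, x$k, ")\n", sep = "")
  cat("  nodes: ", x$n_nodes,
      if (!is.na(x$pct_of_genome))
        sprintf(" (%.1f%% of annotated genes)", x$pct_of_genome) else "",
      "\n", sep = "")
  cat("  edges: ", x$n_edges, "\n", sep = "")
  cat(sprintf("  degree: min %d, max %d (range %d), mean %.1f\n",
              x$degree_min, x$degree_max, x$degree_range, x$degree_mean))
  invisible(x)
}

#' Degree distribution histogram
#'
#' Bins the node degree vector into `n_bins` equal-width bins. The raw
#' degree vector is returned alongside the counts for external plotting
#' (e.g. violin plots of degree connectivity).
#'
#' @param net a `gcn` object.
#' @param n_bins number of bins (>= 1).
#' @return List with `breaks` (length `n_bins + 1`), `counts` (summing to
#'   the node count) and `degrees` (named vector).
#' @export
degree_distribution <- function(net, n_bins = 30L) {
  stopifnot(n_bins >= 1L)
  d <- node_degrees(net)
  lo <- min(d)
  hi <- max(d)
  if (lo == hi) hi <- lo + 1L  # degenerate: all mass in one bin
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- cut(d, breaks = breaks, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bin))
  list(breaks = breaks, counts = counts, degrees = d)
}
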