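# Gene-centered subnetworks and hypergeometric gene-set enrichment with
# Benjamini-Hochberg control, applied within each annotation dataset
# separately.

#' Extract a gene-centered subnetwork
#'
#' The gene-centered network of a focus gene is the set of its first-degree
#' neighbors in the coexpression network (the focus gene itself excluded).
#'
#' @param net a `gcn` object.
#' @param gene focus gene id; must be a network node.
#' @return A `gene_centered_network`: `focus_gene`, `members` (character
#'   vector of neighbors), and source metadata (`method`, `k`, `n_nodes`).
#' @export
gene_centered_network <- function(net, gene) {
  stopifnot(inherits(net, "gcn"))
  gene <- as.character(gene)
  if (!gene %in% net$nodes) {
    stop("gene not in network: ", gene, call. = FALSE)
  }
  e <- net$edges
  members <- c(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene])
  structure(list(focus_gene = gene, members = sort(unique(members)),
                 method = net$method, k = net$k,
                 n_nodes = length(net$nodes)),
            class = "gene_centered_network")
}

#' @export
print.gene_centered_network <- function(x, ...) {
  cat("Gene-centered network of ", x$focus_gene, " (", x$method, x$k,
      "): ", length(x$members), " coexpressed genes\n", sep = "")
  invisible(x)
}

#' Intersect two gene-centered subnetworks
#'
#' Returns the genes coexpressed with both focus genes. The focus genes
#' themselves enter the intersection only when they are coexpressed with
#' each other (i.e. each is a member of the other's neighborhood). An
#' empty intersection is allowed and reported via `message()`.
#'
#' @param a,b `gene_centered_network` objects drawn from the same source
#'   network (same method, k and node count).
#' @return Character vector of shared genes.
#' @export
intersect_subnetworks <- function(a, b) {
  stopifnot(inherits(a, "gene_centered_network"),
            inherits(b, "gene_centered_network"))
  if (!identical(a$method, b$method) || !identical(a$k, b$k) ||
      !identical(a$n_nodes, b$n_nodes)) {
    stop("subnetworks come from different source networks", call. = FALSE)
  }
  shared <- intersect(a$members, b$members)
  if (a$focus_gene %in% b$members && b$focus_gene %in% a$members) {
    shared <- union(shared, c(a$focus_gene, b$focus_gene))
  }
  shared <- sort(shared)
  if (!length(shared)) message("subnetwork intersection is empty")
  shared
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH adjustment (monotone-enforced, order-preserving
#' with the input), delegated to [stats::p.adjust()] after validating the
#' input range.
#'
#' @param p_values numeric vector with all values in (0, 1].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric enrichment of a gene set
#'
#' For every term, computes the upper-tail hypergeometric probability of
#' observing at least the seen overlap between `genes` and the term's
#' genes, given the universe size, the term size in the universe and the
#' set size. Multiple testing is controlled by Benjamini-Hochberg within
#' each annotation dataset separately; terms with `q_value` below
#' `q_threshold` are flagged enriched.
#'
#' @param genes character vector, the gene set to test (must be contained
#'   in `universe`).
#' @param ann an [annotation_collection()] or list of collections (one BH
#'   family per collection).
#' @param universe character vector, the sampling frame. The natural
#'   choice for subnetworks is the source network's node set.
#' @param q_threshold enrichment call threshold on the q-value
#'   (default 0.1).
#' @return `data.frame` with columns `dataset_name`, `term_id`,
#'   `n_term_in_universe`, `n_term_in_set`, `p_value`, `q_value`,
#'   `enriched`. Terms with no gene in the universe are skipped.
#' @export
hypergeometric_enrichment <- function(genes, ann, universe,
                                      q_threshold = 0.1) {
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    stop("gene set not contained in universe (e.g. ", outside[[1L]], ")",
         call. = FALSE)
  }
  if (inherits(ann, "annotation_collection")) ann <- list(ann)
  N <- length(universe)
  n <- length(genes)
  res <- lapply(ann, function(a) {
    term_u <- lapply(a$terms, function(g) intersect(g, universe))
    keep <- lengths(term_u) > 0L
    term_u <- term_u[keep]
    if (!length(term_u)) return(NULL)
    K <- lengths(term_u)
    ov <- vapply(term_u, function(g) length(intersect(g, genes)),
                 integer(1L))
    p <- stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    q <- bh_adjust(p)
    data.frame(dataset_name = a$dataset_name,
               term_id = names(term_u),
               n_term_in_universe = as.integer(K),
               n_term_in_set = ov,
               p_value = p, q_value = q,
               enriched = q < q_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(out)) stop("no testable term in any dataset", call. = FALSE)
  rownames(out) <- NULL
  out
}
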