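# Network inference: Pearson ranks, highest-reciprocal-rank (HRR) scores,
# per-gene top-k HRR networks and their co-occurrence (COO) aggregation
# across study groups.
#
# rank(x, y) is the 1-based position of gene y in gene x's partner list
# sorted by descending Pearson correlation (self excluded); ties broken by
# lexicographic gene id so results are platform-reproducible.
# HRR(x, y) = max(rank(x, y), rank(y, x)) is symmetric; lower is stronger.

#' Pearson correlation ranks between genes
#'
#' Computes the pairwise Pearson correlation of gene expression profiles
#' across samples and, for every gene, the descending-correlation rank of
#' each partner. Equal correlations are ranked by lexicographic gene id.
#'
#' @param fm an `fpkm_matrix` (or plain genes x samples matrix) with at
#'   least 3 samples and no zero-variance genes.
#' @return A `rank_structure`: `gene_ids`, symmetric `pcc` matrix, and an
#'   integer `rank` matrix whose row x holds rank(x, y) (diagonal `NA`).
#' @export
pcc_rank <- function(fm) {
  v <- expr_values(fm)
  if (ncol(v) < 3L) stop("need >= 3 samples to rank correlations",
                         call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene encountered (filter first): ",
         rownames(v)[which(sds == 0)[1L]], call. = FALSE)
  }
  pcc <- stats::cor(t(v))
  ids <- rownames(v)
  G <- length(ids)
  rk <- matrix(NA_integer_, G, G, dimnames = list(ids, ids))
  seq_part <- seq_len(G - 1L)
  for (i in seq_len(G)) {
    p <- pcc[i, ]
    p[i] <- NA_real_
    ord <- order(-p, ids, na.last = TRUE, method = "radix")
    rk[i, ord[seq_part]] <- seq_part
  }
  structure(list(gene_ids = ids, pcc = pcc, rank = rk),
            class = "rank_structure")
}

#' Highest reciprocal rank scores
#'
#' `HRR(x, y) = max(rank(x, y), rank(y, x))`: two genes score well only
#' when each ranks the other highly, which suppresses asymmetric
#' hub-driven correlations.
#'
#' @param rs a `rank_structure` from [pcc_rank()].
#' @return An `hrr_matrix`: `gene_ids` and a symmetric integer `hrr`
#'   matrix (diagonal `NA`).
#' @export
hrr_scores <- function(rs) {
  stopifnot(inherits(rs, "rank_structure"))
  hrr <- pmax(rs$rank, t(rs$rank))
  structure(list(gene_ids = rs$gene_ids, hrr = hrr), class = "hrr_matrix")
}

new_gcn <- function(edges, nodes, method, k, n_groups = NA_integer_) {
  structure(list(edges = edges, nodes = as.character(nodes),
                 method = method, k = as.integer(k),
                 n_groups = as.integer(n_groups)),
            class = "gcn")
}

#' Build an HRR network at sparsity k
#'
#' For every gene its `k` best partners by ascending HRR are selected
#' (ties broken by lexicographic gene id) and the network is the
#' undirected union of these per-gene lists. Consequently the minimum node
#' degree equals `k` whenever there are more than `k + 1` genes, while
#' popular genes can reach far higher degree. The strict mutual variant
#' (`mutual = TRUE`) instead keeps the pairs with `HRR <= k`, i.e. both
#' ranks within the threshold.
#'
#' @param hm an `hrr_matrix` from [hrr_scores()].
#' @param k sparsity threshold: partners retained per gene (100 stringent,
#'   300 relaxed).
#' @param mutual keep only edges with `HRR <= k` instead of the per-gene
#'   top-k union.
#' @return A `gcn` object with edge scores equal to the HRR value.
#' @export
build_hrr_network <- function(hm, k, mutual = FALSE) {
  stopifnot(inherits(hm, "hrr_matrix"), k >= 1)
  H <- hm$hrr
  ids <- hm$gene_ids
  G <- length(ids)
  kk <- as.integer(k)
  if (kk >= G) {
    warning("k >= number of genes; returning the complete graph",
            call. = FALSE)
    kk <- G - 1L
  }
  if (mutual) {
    idx <- which(upper.tri(H) & H <= k, arr.ind = TRUE)
    edges <- canonical_edges(ids[idx[, 1L]], ids[idx[, 2L]],
                             H[idx])
    return(new_gcn(edges, nodes = ids, method = "HRR", k = k))
  }
  take <- seq_len(kk)
  jj <- integer(G * kk)
  for (i in seq_len(G)) {
    h <- H[i, ]
    h[i] <- NA_real_
    ord <- order(h, ids, na.last = TRUE, method = "radix")
    jj[(i - 1L) * kk + take] <- ord[take]
  }
  ii <- rep(seq_len(G), each = kk)
  edges <- canonical_edges(ids[ii], ids[jj], H[cbind(ii, jj)])
  new_gcn(edges, nodes = ids, method = "HRR", k = k)
}

#' Aggregate per-group HRR networks into a co-occurrence network
#'
#' Counts, for every gene pair, the number of group (bioproject) HRR
#' networks containing the edge, then keeps for each gene its `k` best
#' partners by descending co-occurrence frequency. Frequency ties are
#' broken by the lower mean HRR score across the groups containing the
#' edge, then lexicographically. The node universe is the union of the
#' group node sets, so genes expressed only under specific conditions are
#' retained.
#'
#' @param group_networks list of `gcn` objects with method `"HRR"`, all
#'   built at per-group sparsity `k`.
#' @param k sparsity threshold of the aggregated network.
#' @return A `gcn` object with method `"COO"`; edge scores are integer
#'   co-occurrence frequencies in `[1, n_groups]`.
#' @export
build_coo_network <- function(group_networks, k) {
  if (length(group_networks) < 2L) {
    stop("need >= 2 group networks to aggregate", call. = FALSE)
  }
  ok <- vapply(group_networks, function(g)
    inherits(g, "gcn") && identical(g$method, "HRR"), logical(1L))
  if (!all(ok)) stop("group networks must be HRR gcn objects",
                     call. = FALSE)
  ks <- vapply(group_networks, `[[`, integer(1L), "k")
  if (any(ks != as.integer(k))) {
    stop("group networks built at k = ", paste(unique(ks), collapse = ","),
         " but aggregation requested k = ", k, call. = FALSE)
  }
  nodes <- unique(unlist(lapply(group_networks, `[[`, "nodes"),
                         use.names = FALSE))
  all_e <- do.call(rbind, lapply(group_networks, `[[`, "edges"))
  if (is.null(all_e) || !nrow(all_e)) stop("empty edge union",
                                           call. = FALSE)
  key <- paste(all_e$gene_a, all_e$gene_b, sep = "\r")
  freq_m <- rowsum(rep(1L, length(key)), key)
  hrr_m <- rowsum(all_e$score, key)
  first <- match(rownames(freq_m), key)
  ga <- all_e$gene_a[first]
  gb <- all_e$gene_b[first]
  freq <- as.vector(freq_m)
  mean_hrr <- as.vector(hrr_m) / freq

  gene <- c(ga, gb)
  partner <- c(gb, ga)
  f2 <- rep(freq, 2L)
  mh2 <- rep(mean_hrr, 2L)
  o <- order(gene, -f2, mh2, partner, method = "radix")
  gene <- gene[o]; partner <- partner[o]; f2 <- f2[o]
  pos <- stats::ave(seq_along(gene), gene, FUN = seq_along)
  sel <- pos <= k
  edges <- canonical_edges(gene[sel], partner[sel], f2[sel])
  new_gcn(edges, nodes = nodes, method = "COO", k = k,
          n_groups = length(group_networks))
}

#' Fit a gene coexpression network
#'
#' High-level estimator: takes raw fragment counts and returns a coexpression
#' network, either non-aggregated (`method = "HRR"`: pooled libraries,
#' global expression filter, highest-reciprocal-rank top-k union) or
#' aggregated (`method = "COO"`: per-study HRR networks combined by
#' co-occurrence ranking).
#'
#' @param counts a [count_matrix()].
#' @param samples a [sample_table()]; required for `method = "COO"`.
#' @param method `"HRR"` (non-aggregated) or `"COO"` (aggregated).
#' @param k sparsity threshold (100 stringent, 300 relaxed).
#' @param min_fpkm,min_fraction expression filter, see
#'   [filter_low_expression()].
#' @param min_libraries minimum libraries per retained study group (COO).
#' @param mutual strict mutual-rank edge retention, see
#'   [build_hrr_network()].
#' @return A `gcn` object: `edges` (canonical undirected edge list with
#'   scores), `nodes`, `method`, `k`, `n_groups` and the matched `call`.
#' @examples
#' sim <- simulate_dataset(synthetic_config(n_genes = 120, n_groups = 2,
#'   samples_per_group = 6, n_modules = 2, module_size = 10, seed = 1))
#' net <- gcn(sim$counts, sim$samples, method = "COO", k = 10)
#' summary(net)
#' @export
gcn <- function(counts, samples = NULL, method = c("HRR", "COO"), k = 100,
                min_fpkm = 0.5, min_fraction = 0.5, min_libraries = 6,
                mutual = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "count_matrix"))
  if (method == "HRR") {
    fm <- filter_low_expression(fpkm_normalize(counts),
                                min_fpkm, min_fraction)
    net <- build_hrr_network(hrr_scores(pcc_rank(fm)), k, mutual = mutual)
  } else {
    if (is.null(samples)) {
      stop("method 'COO' needs a sample table mapping libraries to groups",
           call. = FALSE)
    }
    ge <- group_by_bioproject(counts, samples, min_libraries,
                              min_fpkm, min_fraction)
    gnets <- lapply(ge$groups, function(g)
      build_hrr_network(hrr_scores(pcc_rank(g)), k, mutual = mutual))
    net <- build_coo_network(gnets, k)
  }
  net$call <- match.call()
  net
}

#' @export
print.gcn <- function(x, ...) {
  cat("Gene coexpression network (", x$method, x$k, ")\n", sep = "")
  cat("  nodes: ", length(x$nodes), "  edges: ", nrow(x$edges), "\n",
      sep = "")
  if (!is.na(x$n_groups)) {
    cat("  aggregated over ", x$n_groups, " group(s)\n", sep = "")
  }
  cat("  edge score: ", score_semantics(x$method), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gcn <- function(object, genome_gene_total = NULL, ...) {
  degree_stats(object, genome_gene_total = genome_gene_total)
}

#' @export
plot.gcn <- function(x, n_bins = 30L, main = NULL, ...) {
  d <- node_degrees(x)
  if (is.null(main)) {
    main <- sprintf("Node degree distribution (%s%d)", x$method, x$k)
  }
  graphics::hist(d, breaks = n_bins, main = main,
                 xlab = "node degree", ...)
  invisible(x)
}
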