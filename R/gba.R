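# Guilt-by-association evaluation: neighbor-voting AUROC per functional
# term, dataset means, bioproject-subset performance curves and
# term-degree diagnostics.
#
# Neighbor voting scores each network gene by the fraction of its
# neighbors annotated to the term; held-out annotated genes are then
# ranked among all non-training genes and the ROC area is computed via
# the rank-sum (Mann-Whitney) identity with mid-ranks for ties.

adjacency_matrix <- function(net) {
  i <- match(net$edges$gene_a, net$nodes)
  j <- match(net$edges$gene_b, net$nodes)
  G <- length(net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                       dims = c(G, G),
                       dimnames = list(net$nodes, net$nodes))
}

# exact ROC area from scores and positive labels (mid-rank convention)
auroc_ranksum <- function(scores, positive) {
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# deterministic per-term seed derived from a base seed and the term id
term_seed <- function(seed, term) {
  v <- utf8ToInt(term)
  h <- sum(v * (seq_along(v) %% 97L)) %% 1000003L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 1009L + h)
}

#' Restrict annotation terms to a network and a size window
#'
#' Term gene-sets are first intersected with the network node set; terms
#' whose intersected size falls outside `[min_size, max_size]` are then
#' dropped (bounds inclusive). The size window guards neighbor voting
#' against unstable tiny terms and uninformative huge ones.
#'
#' @param ann an [annotation_collection()].
#' @param net a `gcn` object.
#' @param min_size,max_size inclusive size bounds (defaults 20 and 1000).
#' @return A filtered [annotation_collection()].
#' @export
filter_terms <- function(ann, net, min_size = 20, max_size = 1000) {
  stopifnot(inherits(ann, "annotation_collection"), inherits(net, "gcn"))
  terms <- lapply(ann$terms, function(g) intersect(g, net$nodes))
  sz <- lengths(terms)
  terms <- terms[sz >= min_size & sz <= max_size]
  if (!length(terms)) {
    stop("no term with ", min_size, "-", max_size,
         " genes in the network", call. = FALSE)
  }
  annotation_collection(ann$dataset_name, terms, ann$labels)
}

#' Neighbor-voting AUROC per term
#'
#' For each term, the annotated network genes are split into `n_folds`
#' cross-validation folds. Per fold, the fold's annotations are hidden;
#' every network gene receives the vote score
#' (number of neighbors among the remaining annotated genes) / (degree),
#' and the hidden positives are ranked among all non-training genes. The
#' ROC area is computed exactly by the rank-sum identity with mid-ranks;
#' the term's AUROC is the mean over folds.
#'
#' @param net a `gcn` object.
#' @param ann an [annotation_collection()], already size-filtered against
#'   `net` (see [filter_terms()]).
#' @param n_folds cross-validation folds (default 3).
#' @param seed integer; per-term fold assignments are drawn from seeds
#'   derived deterministically from it, so results are reproducible and a
#'   term's AUROC does not depend on which other terms are evaluated.
#' @param fold_assignments optional named list (term id -> named integer
#'   vector gene -> fold) overriding the seeded assignment.
#' @return `data.frame` with columns `dataset_name`, `term_id`, `n_genes`,
#'   `auroc`, `mean_degree`. Terms with fewer annotated network genes than
#'   folds are skipped with a warning.
#' @export
neighbor_voting_auroc <- function(net, ann, n_folds = 3, seed = 1,
                                  fold_assignments = NULL) {
  stopifnot(inherits(net, "gcn"), inherits(ann, "annotation_collection"),
            n_folds >= 2)
  A <- adjacency_matrix(net)
  deg <- node_degrees(net)
  if (any(deg == 0L)) {
    stop("network contains isolated nodes; neighbor voting undefined",
         call. = FALSE)
  }
  nodes <- net$nodes
  out <- vector("list", length(ann$terms))
  for (ti in seq_along(ann$terms)) {
    term <- names(ann$terms)[[ti]]
    genes <- intersect(ann$terms[[ti]], nodes)
    if (length(genes) < n_folds) {
      warning("term ", term, " has fewer genes than folds; skipped",
              call. = FALSE)
      next
    }
    if (!is.null(fold_assignments) && !is.null(fold_assignments[[term]])) {
      fold <- fold_assignments[[term]][genes]
    } else {
      set.seed(term_seed(seed, term))
      fold <- stats::setNames(
        sample(rep_len(seq_len(n_folds), length(genes))), genes)
    }
    aucs <- vapply(seq_len(n_folds), function(f) {
      test <- genes[fold == f]
      train <- setdiff(genes, test)
      if (!length(test) || !length(train)) return(NA_real_)
      ind <- as.numeric(nodes %in% train)
      score <- as.vector(A %*% ind) / deg
      cand <- !(nodes %in% train)
      auroc_ranksum(score[cand], nodes[cand] %in% test)
    }, numeric(1L))
    out[[ti]] <- data.frame(
      dataset_name = ann$dataset_name,
      term_id = term,
      n_genes = length(genes),
      auroc = mean(aucs, na.rm = TRUE),
      mean_degree = mean(deg[genes]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res)) {
    stop("no term could be evaluated", call. = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Dataset mean AUROC
#'
#' Unweighted mean of term AUROCs within each annotation dataset, plus the
#' grand average across datasets.
#'
#' @param rows output of [neighbor_voting_auroc()] (possibly row-bound
#'   over several datasets).
#' @return List with `dataset_means` (`data.frame`: `dataset_name`,
#'   `mean_auroc`) and `average` (mean of the dataset means).
#' @export
dataset_mean_auroc <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  agg <- stats::aggregate(auroc ~ dataset_name, data = rows, FUN = mean)
  names(agg)[names(agg) == "auroc"] <- "mean_auroc"
  list(dataset_means = agg, average = mean(agg$mean_auroc))
}

#' Term-degree diagnostic table
#'
#' Pass-through join of term AUROC and mean node degree of the term's
#' genes, for downstream smoothing/plotting of the degree-performance
#' relationship. No smoothing is performed here.
#'
#' @param rows output of [neighbor_voting_auroc()].
#' @return `data.frame` with columns `dataset_name`, `term_id`,
#'   `mean_degree`, `auroc`.
#' @export
term_degree_table <- function(rows) {
  stopifnot(is.data.frame(rows))
  out <- rows[, c("dataset_name", "term_id", "mean_degree", "auroc")]
  rownames(out) <- NULL
  out
}

#' AUROC as a function of the number of aggregated studies
#'
#' Grows, per replicate, a nested random chain of study-group subsets
#' (size 2, then one group added per step) and records the dataset mean
#' neighbor-voting AUROC of every requested network built on each subset.
#' Per-group HRR networks are computed once per sparsity and reused across
#' subsets; pooled (non-aggregated) networks are rebuilt per subset from
#' the pooled libraries.
#'
#' @param ge a `grouped_expression` from [group_by_bioproject()].
#' @param ann an [annotation_collection()] or list of collections.
#' @param methods subset of `c("COO", "HRR")`.
#' @param k_values sparsity thresholds to evaluate.
#' @param sizes integer vector of subset sizes (each >= 2, at most the
#'   number of groups).
#' @param n_replicates independent replicate chains (default 5).
#' @param seed integer master seed; chains and fold assignments derive
#'   from it deterministically.
#' @param n_folds folds for [neighbor_voting_auroc()].
#' @param term_min_size,term_max_size passed to [filter_terms()] per
#'   subset network.
#' @param min_fpkm,min_fraction expression filter for pooled HRR subsets.
#' @return `data.frame` with columns `n_groups`, `replicate`, `method`,
#'   `k`, `dataset_name`, `mean_auroc` (NA when no term survives
#'   filtering for a subset network).
#' @export
bioproject_subset_curve <- function(ge, ann, methods = c("COO", "HRR"),
                                    k_values = 100, sizes,
                                    n_replicates = 5, seed = 1,
                                    n_folds = 3,
                                    term_min_size = 20,
                                    term_max_size = 1000,
                                    min_fpkm = 0.5, min_fraction = 0.5) {
  stopifnot(inherits(ge, "grouped_expression"))
  methods <- match.arg(methods, c("COO", "HRR"), several.ok = TRUE)
  if (inherits(ann, "annotation_collection")) ann <- list(ann)
  group_ids <- names(ge$groups)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 2L)) stop("subset sizes must be >= 2", call. = FALSE)
  if (max(sizes) > length(group_ids)) {
    stop("subset size ", max(sizes), " exceeds the ",
         length(group_ids), " available groups", call. = FALSE)
  }

  group_nets <- list()
  if ("COO" %in% methods) {
    for (k in k_values) {
      group_nets[[as.character(k)]] <- lapply(ge$groups, function(g)
        build_hrr_network(hrr_scores(pcc_rank(g)), k))
    }
  }

  eval_net <- function(net, eval_seed) {
    lapply(ann, function(a) {
      af <- tryCatch(
        filter_terms(a, net, term_min_size, term_max_size),
        error = function(e) NULL)
      if (is.null(af)) {
        return(data.frame(dataset_name = a$dataset_name,
                          mean_auroc = NA_real_,
                          stringsAsFactors = FALSE))
      }
      rows <- neighbor_voting_auroc(net, af, n_folds = n_folds,
                                    seed = eval_seed)
      dm <- dataset_mean_auroc(rows)$dataset_means
      names(dm)[names(dm) == "mean_auroc"] <- "mean_auroc"
      dm
    })
  }

  res <- list()
  for (rep_i in seq_len(n_replicates)) {
    set.seed(as.integer((abs(as.integer(seed)) %% 1000003L) * 97L +
                          rep_i * 1009L))
    chain <- sample(group_ids)
    for (size in sizes) {
      sub <- chain[seq_len(size)]
      for (k in k_values) {
        for (m in methods) {
          net <- if (m == "COO") {
            build_coo_network(group_nets[[as.character(k)]][sub], k)
          } else {
            pool_samples <- names(ge$sample_groups)[
              ge$sample_groups %in% sub]
            fm <- new_fpkm_matrix(
              ge$fpkm$values[, pool_samples, drop = FALSE],
              ge$fpkm$provenance)
            fm <- filter_low_expression(fm, min_fpkm, min_fraction)
            build_hrr_network(hrr_scores(pcc_rank(fm)), k)
          }
          dms <- do.call(rbind, eval_net(net, eval_seed = seed))
          res[[length(res) + 1L]] <- data.frame(
            n_groups = size, replicate = rep_i, method = m,
            k = as.integer(k),
            dataset_name = dms$dataset_name,
            mean_auroc = dms$mean_auroc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
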