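# Independent oracles and small generators used across the suite.
# The oracles deliberately use naive enumeration so they share no code
# path with the package implementation.

# Exact ROC area by enumerating all (positive, negative) pairs;
# ties count 1/2.
oracle_auroc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Brute-force neighbor voting for one train/test split on an edge list.
oracle_nv_fold_auroc <- function(edges, nodes, train, test) {
  neighbors <- function(g) {
    unique(c(edges$gene_b[edges$gene_a == g],
             edges$gene_a[edges$gene_b == g]))
  }
  score <- vapply(nodes, function(g) {
    nb <- neighbors(g)
    sum(nb %in% train) / length(nb)
  }, numeric(1L))
  cand <- setdiff(nodes, train)
  oracle_auroc(score[cand], cand %in% test)
}

# Brute-force union of per-gene k-best-by-HRR lists.
oracle_topk_edges <- function(H, ids, k) {
  pairs <- character(0)
  for (i in seq_along(ids)) {
    h <- H[i, ]
    h[i] <- NA
    ord <- order(h, ids, na.last = TRUE)
    best <- ids[ord[seq_len(min(k, length(ids) - 1L))]]
    pairs <- c(pairs, vapply(best, function(j)
      paste(sort(c(ids[i], j)), collapse = "|"), ""))
  }
  sort(unique(pairs))
}

edge_keys <- function(net) {
  sort(paste(net$edges$gene_a, net$edges$gene_b, sep = "|"))
}

# Random connected-ish test network: a ring (no isolated nodes) plus
# random chords.
random_test_network <- function(n_nodes, n_extra, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  a <- nodes
  b <- nodes[c(2:n_nodes, 1L)]
  if (n_extra > 0L) {
    for (i in seq_len(n_extra)) {
      pick <- sample(nodes, 2L)
      a <- c(a, pick[1L])
      b <- c(b, pick[2L])
    }
  }
  keep <- a != b
  edges <- aggcoex:::canonical_edges(a[keep], b[keep], 1)
  aggcoex:::new_gcn(edges, nodes = nodes, method = "HRR", k = 3L)
}

# Small random expression matrix with named genes/samples.
random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m + 5
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
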