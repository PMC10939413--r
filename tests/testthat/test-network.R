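test_that("correlation ranks sort partners by descending PCC", {
  # identical expression vectors rank each other first with pcc 1
  v <- random_expression(5, 6, seed = 1)
  v["g02", ] <- v["g01", ]
  rs <- pcc_rank(v)
  expect_equal(rs$pcc["g01", "g02"], 1)
  expect_equal(rs$rank["g01", "g02"], 1L)
  expect_equal(rs$rank["g02", "g01"], 1L)

  # rank rows are permutations of 1..G-1 and agree with a direct sort
  m <- random_expression(4, 5, seed = 2)
  rs4 <- pcc_rank(m)
  pc <- cor(t(m))
  for (g in rownames(m)) {
    expect_setequal(rs4$rank[g, setdiff(rownames(m), g)], 1:3)
    row <- pc[g, setdiff(rownames(m), g)]
    expect_equal(names(sort(rank(-row))),
                 names(sort(rs4$rank[g, setdiff(rownames(m), g)])))
  }

  expect_error(pcc_rank(m[, 1:2]), "3 samples")
  mz <- m
  mz["g01", ] <- 4
  expect_error(pcc_rank(mz), "g01")
})

test_that("HRR is the symmetric max of the two directed ranks", {
  rk <- matrix(NA_integer_, 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  rk["a", ] <- c(NA, 1L, 2L)
  rk["b", ] <- c(2L, NA, 1L)
  rk["c", ] <- c(1L, 2L, NA)
  rs <- structure(list(gene_ids = c("a", "b", "c"), pcc = NULL,
                       rank = rk), class = "rank_structure")
  hm <- hrr_scores(rs)
  expect_equal(hm$hrr["a", "b"], 2)  # max(1, 2)
  expect_equal(hm$hrr["a", "c"], 2)  # max(2, 1)
  expect_equal(hm$hrr["b", "c"], 2)

  hm2 <- hrr_scores(pcc_rank(random_expression(8, 6, seed = 3)))
  expect_equal(hm2$hrr, t(hm2$hrr))
  expect_true(all(hm2$hrr >= 1, na.rm = TRUE))
})

test_that("top-k union networks match the exhaustive oracle", {
  fx <- make_fixture("hrr_demo")
  net <- build_hrr_network(fx$hrr, k = fx$k)
  expect_equal(edge_keys(net),
               sub("\\|", "|", oracle_topk_edges(fx$hrr$hrr,
                                                 fx$hrr$gene_ids, fx$k)))

  for (seed in 4:6) {
    hm <- hrr_scores(pcc_rank(random_expression(10, 7, seed = seed)))
    for (k in c(2, 3, 5)) {
      net <- build_hrr_network(hm, k)
      expect_equal(edge_keys(net),
                   oracle_topk_edges(hm$hrr, hm$gene_ids, k))
    }
  }
})

test_that("HRR network edges respect degree floor, nesting, invariances", {
  m <- random_expression(30, 8, seed = 7)
  hm <- hrr_scores(pcc_rank(m))
  n5 <- build_hrr_network(hm, 5)
  n9 <- build_hrr_network(hm, 9)
  expect_equal(min(node_degrees(n5)), 5L)
  expect_equal(min(node_degrees(n9)), 9L)
  # monotone in k
  expect_true(all(edge_keys(n5) %in% edge_keys(n9)))
  # handshake lemma
  expect_equal(sum(node_degrees(n9)), 2L * nrow(n9$edges))

  # invariant under sample permutation and global positive scaling
  perm <- m[, sample(ncol(m))]
  expect_equal(edge_keys(build_hrr_network(
    hrr_scores(pcc_rank(perm)), 5)), edge_keys(n5))
  expect_equal(edge_keys(build_hrr_network(
    hrr_scores(pcc_rank(m * 3.7)), 5)), edge_keys(n5))

  # k >= G -> complete graph with a warning
  expect_warning(full <- build_hrr_network(hm, 30), "complete graph")
  expect_equal(nrow(full$edges), choose(30, 2))

  # strict mutual variant keeps exactly the pairs with HRR <= k
  mut <- build_hrr_network(hm, 5, mutual = TRUE)
  expect_true(all(mut$edges$score <= 5))
  expect_equal(nrow(mut$edges),
               sum(hm$hrr[upper.tri(hm$hrr)] <= 5))
  expect_true(all(edge_keys(mut) %in% edge_keys(n5)))
})

test_that("co-occurrence aggregation counts edge frequency across groups", {
  mk <- function(a, b, score) aggcoex:::new_gcn(
    aggcoex:::canonical_edges(a, b, score),
    nodes = sprintf("g%d", 1:4), method = "HRR", k = 2L)
  # edge g1-g2 present in 3 of 5 groups
  nets <- list(
    mk(c("g1", "g3"), c("g2", "g4"), c(1, 1)),
    mk(c("g1", "g3"), c("g2", "g4"), c(2, 1)),
    mk(c("g1", "g3"), c("g2", "g4"), c(1, 2)),
    mk(c("g1", "g3"), c("g3", "g4"), c(1, 1)),
    mk(c("g2", "g3"), c("g3", "g4"), c(1, 1)))
  coo <- build_coo_network(nets, k = 2)
  e12 <- coo$edges[coo$edges$gene_a == "g1" & coo$edges$gene_b == "g2", ]
  expect_equal(e12$score, 3)
  expect_true(all(coo$edges$score >= 1 & coo$edges$score <= 5))
  expect_true(all(coo$edges$score == round(coo$edges$score)))

  # a gene present in a single group's network enters the COO node set
  extra <- aggcoex:::new_gcn(
    aggcoex:::canonical_edges(c("g5"), c("g1"), 1),
    nodes = c("g1", "g5"), method = "HRR", k = 2L)
  coo2 <- build_coo_network(c(nets, list(extra)), k = 2)
  expect_true("g5" %in% coo2$nodes)

  expect_error(build_coo_network(list(nets[[1]],
    aggcoex:::new_gcn(nets[[2]]$edges, nodes = sprintf("g%d", 1:4),
                      method = "HRR", k = 3L)), k = 2),
    "k")
})

test_that("COO of identical groups reduces to per-gene top-k of the shared set", {
  hm <- hrr_scores(pcc_rank(random_expression(10, 8, seed = 11)))
  g <- build_hrr_network(hm, 4)
  coo <- build_coo_network(list(g, g), k = 4)

  # oracle: every edge has frequency 2; ties broken by mean HRR then id
  long <- rbind(
    data.frame(gene = g$edges$gene_a, partner = g$edges$gene_b,
               hrr = g$edges$score),
    data.frame(gene = g$edges$gene_b, partner = g$edges$gene_a,
               hrr = g$edges$score))
  keep <- character(0)
  for (gene in unique(long$gene)) {
    cand <- long[long$gene == gene, ]
    cand <- cand[order(cand$hrr, cand$partner), ]
    top <- cand[seq_len(min(4, nrow(cand))), ]
    keep <- c(keep, paste(pmin(gene, top$partner),
                          pmax(gene, top$partner), sep = "|"))
  }
  expect_equal(edge_keys(coo), sort(unique(keep)))
  expect_true(all(coo$edges$score == 2))
})

test_that("the gcn() estimator wires counts to networks for both methods", {
  sim <- simulate_dataset(synthetic_config(
    n_genes = 120, n_groups = 2, samples_per_group = 6,
    n_modules = 2, module_size = 10, seed = 13))
  hrr <- suppressMessages(gcn(sim$counts, method = "HRR", k = 8))
  coo <- suppressMessages(gcn(sim$counts, sim$samples, method = "COO",
                              k = 8))
  expect_s3_class(hrr, "gcn")
  expect_equal(hrr$method, "HRR")
  expect_equal(coo$method, "COO")
  expect_equal(coo$n_groups, 2L)
  expect_equal(min(node_degrees(hrr)), 8L)
  expect_equal(min(node_degrees(coo)), 8L)
  expect_error(gcn(sim$counts, method = "COO"), "sample table")
})
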