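test_that("term filtering intersects with the network before sizing", {
  nodes <- sprintf("g%04d", 1:1000)
  net <- aggcoex:::new_gcn(
    aggcoex:::canonical_edges(nodes[1:999], nodes[2:1000],
                              rep(1, 999)),
    nodes = nodes, method = "HRR", k = 1L)
  ann <- annotation_collection("toy", list(
    small = nodes[1:19],                       # 19 in network -> dropped
    edge = nodes[1:20],                        # exactly 20 -> kept
    big = c(nodes[1:900], sprintf("x%d", 1:600))  # 1500, 900 in net
  ))
  out <- filter_terms(ann, net)
  expect_setequal(names(out$terms), c("edge", "big"))
  expect_length(out$terms$big, 900)
  expect_error(filter_terms(annotation_collection("toy",
    list(small = nodes[1:5])), net), "no term")
})

test_that("a planted clique is perfectly recovered by neighbor voting", {
  fx <- make_fixture("gba_demo")
  folds <- list(T1 = c(n1 = 2L, n2 = 2L, n3 = 3L, n4 = 1L))
  rows <- neighbor_voting_auroc(fx$network, fx$annotations,
                                n_folds = 3, fold_assignments = folds)
  expect_equal(rows$auroc, 1.0)
  expect_equal(rows$n_genes, 4L)
})

test_that("neighbor voting equals the exhaustive pairwise oracle", {
  for (seed in 1:8) {
    net <- random_test_network(8 + seed %% 3, 10, seed = 100 + seed)
    set.seed(200 + seed)
    genes <- sample(net$nodes, 4)
    fold <- setNames(c(1L, 1L, 2L, 2L), genes)
    ann <- annotation_collection("toy", list(T = genes))
    rows <- neighbor_voting_auroc(net, ann, n_folds = 2,
                                  fold_assignments = list(T = fold))
    expected <- mean(c(
      oracle_nv_fold_auroc(net$edges, net$nodes,
                           genes[fold == 2], genes[fold == 1]),
      oracle_nv_fold_auroc(net$edges, net$nodes,
                           genes[fold == 1], genes[fold == 2])))
    expect_equal(rows$auroc, expected, tolerance = 1e-12)
  }
})

test_that("random annotations score near 0.5 and seeded runs reproduce", {
  sim <- simulate_dataset(synthetic_config(
    n_genes = 200, n_groups = 1, samples_per_group = 10,
    n_modules = 2, module_size = 15, seed = 31))
  net <- suppressMessages(gcn(sim$counts, method = "HRR", k = 15))
  set.seed(77)
  perm_terms <- lapply(1:60, function(i) sample(net$nodes, 20))
  names(perm_terms) <- sprintf("P%02d", 1:60)
  ann <- annotation_collection("perm", perm_terms)
  rows <- neighbor_voting_auroc(net, ann, n_folds = 3, seed = 5)
  expect_true(abs(mean(rows$auroc) - 0.5) < 0.1)
  expect_true(all(rows$auroc >= 0 & rows$auroc <= 1))

  rows2 <- neighbor_voting_auroc(net, ann, n_folds = 3, seed = 5)
  expect_identical(rows, rows2)
  # a term's AUROC does not depend on which other terms are evaluated
  solo <- neighbor_voting_auroc(net,
    annotation_collection("perm", perm_terms["P07"]), n_folds = 3,
    seed = 5)
  expect_equal(solo$auroc, rows$auroc[rows$term_id == "P07"])
})

test_that("dataset means average terms then datasets", {
  rows <- data.frame(
    dataset_name = c("A", "A", "B"),
    term_id = c("t1", "t2", "t3"),
    n_genes = 20, auroc = c(0.6, 0.8, 0.9), mean_degree = 5)
  dm <- dataset_mean_auroc(rows)
  expect_equal(dm$dataset_means$mean_auroc, c(0.7, 0.9))
  expect_equal(dm$average, 0.8)
  # permutation-invariant over term order
  dm2 <- dataset_mean_auroc(rows[c(3, 1, 2), ])
  expect_equal(dm2$average, dm$average)

  one <- dataset_mean_auroc(rows[1, ])
  expect_equal(one$average, 0.6)
})

test_that("term-degree table echoes AUROC with hand-computed degrees", {
  # 6-node path: degrees 1,2,2,2,2,1
  nodes <- sprintf("m%d", 1:6)
  net <- aggcoex:::new_gcn(
    aggcoex:::canonical_edges(nodes[1:5], nodes[2:6], rep(1, 5)),
    nodes = nodes, method = "HRR", k = 1L)
  ann <- annotation_collection("toy", list(T = c("m1", "m3", "m6")))
  rows <- neighbor_voting_auroc(net, ann, n_folds = 3, seed = 1)
  tab <- term_degree_table(rows)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$mean_degree, mean(c(1, 2, 1)))
  expect_equal(tab$auroc, rows$auroc)
  expect_equal(names(tab),
               c("dataset_name", "term_id", "mean_degree", "auroc"))
})

test_that("subset curves enumerate sizes x replicates x methods and reproduce", {
  sim <- simulate_dataset(synthetic_config(
    n_genes = 120, n_groups = 4, samples_per_group = 6,
    n_modules = 2, module_size = 12, seed = 41))
  ge <- suppressMessages(group_by_bioproject(sim$counts, sim$samples))
  planted <- annotation_collection("planted", sim$truth$modules)
  tab <- suppressWarnings(bioproject_subset_curve(
    ge, planted, methods = c("COO", "HRR"), k_values = 8,
    sizes = 2:4, n_replicates = 2, seed = 9, n_folds = 3,
    term_min_size = 5, term_max_size = 100))
  expect_equal(nrow(tab), 3 * 2 * 2)  # sizes x replicates x methods
  expect_setequal(unique(tab$method), c("COO", "HRR"))
  expect_setequal(unique(tab$n_groups), 2:4)

  tab2 <- suppressWarnings(bioproject_subset_curve(
    ge, planted, methods = c("COO", "HRR"), k_values = 8,
    sizes = 2:4, n_replicates = 2, seed = 9, n_folds = 3,
    term_min_size = 5, term_max_size = 100))
  expect_identical(tab, tab2)

  expect_error(bioproject_subset_curve(ge, planted, sizes = 2:9,
                                       k_values = 8),
               "exceeds")
})
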