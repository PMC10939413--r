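# Synthetic multi-study count data with planted coexpression modules.
#
# Count model: each gene has a log-uniform baseline (FPKM scale); genes of
# a module active in a group share a per-sample latent factor on the log
# scale, inducing a target within-module correlation; counts are drawn
# from a gamma-mixed (negative binomial) distribution with per-gene
# lengths and log-uniform per-sample sequencing depth, so FPKM
# normalization is consequential. This is a generic overdispersed RNA-seq
# emulator, not a model of any particular organism.

#' Configuration for the synthetic data generator
#'
#' Defaults emulate a modest multi-study compendium: 5 study groups of 10
#' libraries, 2000 genes, 10 planted coexpression modules of 30 genes with
#' within-module correlation 0.8 on the log-expression scale, each module
#' active in a group with probability 0.7 (and in at least one group).
#'
#' @param n_genes total genes.
#' @param n_groups study groups (bioprojects).
#' @param samples_per_group libraries per group (>= 6 to survive the
#'   default group filter).
#' @param n_modules,module_size planted module count and size
#'   (`n_modules * module_size <= n_genes`).
#' @param within_module_correlation target pairwise correlation of module
#'   genes' log-expression in active groups, in (0, 1).
#' @param module_presence_probability chance a module is active in a
#'   group; every module is forced active in at least one group.
#' @param noise_dispersion negative-binomial dispersion of counts
#'   (variance = mu + dispersion * mu^2).
#' @param gene_length_range transcript length bounds in bp.
#' @param baseline_expression_range baseline FPKM bounds (log-uniform).
#' @param depth_range per-sample fragment-total bounds (log-uniform; one
#'   decade by default).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, n_groups = 5,
                             samples_per_group = 10,
                             n_modules = 10, module_size = 30,
                             within_module_correlation = 0.8,
                             module_presence_probability = 0.7,
                             noise_dispersion = 0.05,
                             gene_length_range = c(500, 5000),
                             baseline_expression_range = c(1, 100),
                             depth_range = c(2e6, 2e7),
                             seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_groups = as.integer(n_groups),
              samples_per_group = as.integer(samples_per_group),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              within_module_correlation = within_module_correlation,
              module_presence_probability = module_presence_probability,
              noise_dispersion = noise_dispersion,
              gene_length_range = gene_length_range,
              baseline_expression_range = baseline_expression_range,
              depth_range = depth_range,
              seed = as.integer(seed))
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    stop("modules do not fit in the gene pool", call. = FALSE)
  }
  if (cfg$within_module_correlation <= 0 ||
      cfg$within_module_correlation >= 1) {
    stop("within_module_correlation must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(cfg$n_genes > 0, cfg$n_groups > 0, cfg$samples_per_group > 0,
            all(cfg$gene_length_range > 0),
            all(cfg$baseline_expression_range > 0),
            all(cfg$depth_range > 0), cfg$noise_dispersion > 0)
  structure(cfg, class = "synthetic_config")
}

#' Simulate a multi-study count dataset with planted modules
#'
#' @param cfg a [synthetic_config()].
#' @return List with `counts` (a [count_matrix()]), `samples` (a
#'   [sample_table()]), `annotations` (an [annotation_collection()] with
#'   one term per planted module plus an equal number of random decoy
#'   terms), and `truth` (module gene sets, active groups per module,
#'   term-module map, decoy term ids).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  wid <- max(4L, nchar(as.character(cfg$n_genes)))
  gene_ids <- sprintf(paste0("gene%0", wid, "d"), seq_len(cfg$n_genes))
  group_ids <- sprintf("bp%02d", seq_len(cfg$n_groups))
  sample_ids <- as.vector(vapply(group_ids, function(g)
    sprintf("%s_s%02d", g, seq_len(cfg$samples_per_group)),
    character(cfg$samples_per_group)))
  sample_group <- rep(group_ids, each = cfg$samples_per_group)
  n_samples <- length(sample_ids)

  lengths_bp <- sample(seq(cfg$gene_length_range[1L],
                           cfg$gene_length_range[2L]),
                       cfg$n_genes, replace = TRUE)
  names(lengths_bp) <- gene_ids
  lb <- log10(cfg$baseline_expression_range)
  baseline <- 10^stats::runif(cfg$n_genes, lb[1L], lb[2L])
  ld <- log10(cfg$depth_range)
  depth <- 10^stats::runif(n_samples, ld[1L], ld[2L])

  modules <- split(gene_ids[seq_len(cfg$n_modules * cfg$module_size)],
                   rep(seq_len(cfg$n_modules), each = cfg$module_size))
  names(modules) <- sprintf("MOD%02d", seq_len(cfg$n_modules))
  active <- matrix(stats::runif(cfg$n_modules * cfg$n_groups) <
                     cfg$module_presence_probability,
                   nrow = cfg$n_modules,
                   dimnames = list(names(modules), group_ids))
  for (m in seq_len(cfg$n_modules)) {
    if (!any(active[m, ])) {
      active[m, sample.int(cfg$n_groups, 1L)] <- TRUE
    }
  }

  tau <- 1  # log-scale biological sd
  rho <- cfg$within_module_correlation
  log_expr <- matrix(log(baseline), cfg$n_genes, n_samples,
                     dimnames = list(gene_ids, sample_ids))
  module_of <- rep(NA_integer_, cfg$n_genes)
  module_of[seq_len(cfg$n_modules * cfg$module_size)] <-
    rep(seq_len(cfg$n_modules), each = cfg$module_size)
  for (g in seq_along(group_ids)) {
    cols <- which(sample_group == group_ids[g])
    z <- matrix(stats::rnorm(cfg$n_modules * length(cols)),
                cfg$n_modules, length(cols))
    eps <- matrix(stats::rnorm(cfg$n_genes * length(cols)),
                  cfg$n_genes, length(cols))
    for (i in seq_len(cfg$n_genes)) {
      m <- module_of[i]
      if (!is.na(m) && active[m, g]) {
        log_expr[i, cols] <- log_expr[i, cols] +
          tau * (sqrt(rho) * z[m, ] + sqrt(1 - rho) * eps[i, ])
      } else {
        log_expr[i, cols] <- log_expr[i, cols] + tau * eps[i, ]
      }
    }
  }
  mu <- exp(log_expr) *
    outer(as.numeric(lengths_bp), depth) / 1e9
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / cfg$noise_dispersion),
                   nrow = cfg$n_genes,
                   dimnames = dimnames(mu))

  decoys <- lapply(seq_len(cfg$n_modules), function(i)
    sample(gene_ids, cfg$module_size))
  names(decoys) <- sprintf("RND%02d", seq_len(cfg$n_modules))
  ann <- annotation_collection("synthetic", c(modules, decoys))

  st <- sample_table(data.frame(sample_id = sample_ids,
                                group_id = sample_group,
                                stringsAsFactors = FALSE))
  list(counts = count_matrix(counts, lengths_bp),
       samples = st,
       annotations = ann,
       truth = list(modules = modules,
                    active_groups = apply(active, 1L, function(a)
                      group_ids[a], simplify = FALSE),
                    term_module = stats::setNames(names(modules),
                                                  names(modules)),
                    decoy_terms = names(decoys)))
}

#' Small deterministic fixtures for examples and tests
#'
#' @param name one of `"tiny"` (6-gene x 8-sample count bundle in two
#'   groups), `"hrr_demo"` (hand-built 6-gene symmetric HRR matrix),
#'   `"gba_demo"` (8-node network with one planted 4-gene term), or
#'   `"enrich_demo"` (20-gene universe with a fully recovered 5-gene
#'   term).
#' @return A named list; contents depend on the fixture.
#' @export
make_fixture <- function(name = c("tiny", "hrr_demo", "gba_demo",
                                  "enrich_demo")) {
  name <- match.arg(name)
  switch(name,
    tiny = {
      set.seed(42L)
      genes <- sprintf("g%d", 1:6)
      samps <- sprintf("s%d", 1:8)
      counts <- matrix(stats::rnbinom(48, mu = 60, size = 10),
                       6, 8, dimnames = list(genes, samps))
      lengths_bp <- stats::setNames(c(1000, 1500, 2000, 800, 1200, 2500),
                                    genes)
      st <- sample_table(data.frame(
        sample_id = samps,
        group_id = rep(c("bpA", "bpB"), each = 4L),
        stringsAsFactors = FALSE))
      ann <- annotation_collection("toy", list(
        T1 = c("g1", "g2", "g3"), T2 = c("g4", "g5", "g6")))
      list(counts = count_matrix(counts, lengths_bp), samples = st,
           annotations = ann)
    },
    hrr_demo = {
      ids <- sprintf("g%d", 1:6)
      H <- matrix(c(
        NA, 1, 2, 4, 5, 5,
        1, NA, 3, 2, 4, 5,
        2, 3, NA, 1, 5, 4,
        4, 2, 1, NA, 3, 5,
        5, 4, 5, 3, NA, 1,
        5, 5, 4, 5, 1, NA), 6, 6, byrow = TRUE,
        dimnames = list(ids, ids))
      list(hrr = structure(list(gene_ids = ids, hrr = H),
                           class = "hrr_matrix"),
           k = 2L)
    },
    gba_demo = {
      a <- c("n1", "n1", "n1", "n2", "n2", "n3", "n5", "n6", "n7", "n5",
             "n4", "n2")
      b <- c("n2", "n3", "n4", "n3", "n4", "n4", "n6", "n7", "n8", "n8",
             "n5", "n7")
      edges <- canonical_edges(a, b, rep(1, length(a)))
      net <- new_gcn(edges, nodes = sprintf("n%d", 1:8),
                     method = "HRR", k = 3L)
      ann <- annotation_collection("toy",
                                   list(T1 = c("n1", "n2", "n3", "n4")))
      list(network = net, annotations = ann)
    },
    enrich_demo = {
      universe <- sprintf("u%02d", 1:20)
      ann <- annotation_collection("toy", list(T5 = universe[1:5]))
      list(universe = universe, gene_set = universe[1:5],
           annotations = ann)
    })
}
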