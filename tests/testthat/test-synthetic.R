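test_that("generated ontologies honor leaf count, depth and determinism", {
  cfg <- sim_config(n_leaves = 1, seed = 1)
  expect_equal(n_nodes(generate_ontology(cfg)), 1L)

  cfg2 <- sim_config(n_leaves = 8, max_depth = 3, extra_edge_prob = 0, seed = 2)
  dag <- generate_ontology(cfg2)
  tax <- classify_nodes(dag)
  expect_equal(sum(tax$is_leaf), 8L)
  # tree: every non-root node has exactly one parent
  n_parents <- table(dag$edges$child)
  expect_true(all(n_parents == 1L))
  expect_equal(length(n_parents), n_nodes(dag) - 1L)
  # depth bound via longest path in the reachability closure
  g <- igraph::graph_from_data_frame(dag$edges, vertices = dag$nodes)
  d <- igraph::distances(g, mode = "out")
  expect_lte(max(d[is.finite(d)]), 3)

  dag_b <- generate_ontology(cfg2)
  expect_identical(dag, dag_b)

  expect_error(generate_ontology(sim_config(n_leaves = 5, max_depth = 0)),
               "max_depth")
})

test_that("multi-parent edges appear at positive extra_edge_prob", {
  cfg <- sim_config(n_leaves = 12, max_depth = 4, extra_edge_prob = 0.8,
                    n_genes = 80, seed = 6)
  dag <- generate_ontology(cfg)
  expect_true(any(table(dag$edges$child) > 1L))
})

test_that("counts concentrate on the leaf programs in the low-noise limit", {
  cfg <- sim_config(n_leaves = 2, max_depth = 1, n_genes = 12,
                    markers_per_leaf = 3, nb_dispersion = Inf,
                    study_effect_sd = 0, lib_jitter_sd = 0, n_studies = 1,
                    cells_per_study = 5000, extra_edge_prob = 0, seed = 4)
  atlas <- simulate_counts(generate_ontology(cfg), cfg)
  leaf <- rownames(atlas$programs)[1]
  sel <- atlas$cells$true_label == leaf
  expect_gt(sum(sel), 2000)
  m <- colMeans(atlas$counts[sel, ])
  expect_true(all(abs(m - atlas$programs[leaf, ]) / atlas$programs[leaf, ]
                  < 0.05))
})

test_that("zero study effect leaves per-gene means indistinguishable", {
  cfg <- sim_config(n_leaves = 1, max_depth = 0, n_genes = 10,
                    markers_per_leaf = 1, study_effect_sd = 0,
                    n_studies = 2, cells_per_study = 400, seed = 9)
  atlas <- simulate_counts(generate_ontology(cfg), cfg)
  s1 <- atlas$cells$study == "study1"
  p <- vapply(seq_len(ncol(atlas$counts)), function(g)
    stats::t.test(atlas$counts[s1, g], atlas$counts[!s1, g])$p.value,
    numeric(1))
  expect_true(all(p > 0.01 / length(p)))  # Bonferroni at alpha = 0.01
})

test_that("well-separated programs are recoverable by nearest centroid", {
  cfg <- sim_config(n_leaves = 4, max_depth = 2, n_genes = 40,
                    markers_per_leaf = 8, marker_fold = 20,
                    nb_dispersion = Inf, study_effect_sd = 0,
                    lib_jitter_sd = 0, n_studies = 1, cells_per_study = 400,
                    extra_edge_prob = 0, seed = 12)
  atlas <- simulate_counts(generate_ontology(cfg), cfg)
  X <- normalize_counts(atlas$counts)
  cent <- rowsum(X, atlas$cells$true_label) /
    as.vector(table(atlas$cells$true_label))
  d2 <- outer(rowSums(X^2), rowSums(cent^2), "+") - 2 * X %*% t(cent)
  pred <- rownames(cent)[max.col(-d2)]
  leaves <- sort(rownames(atlas$programs))
  cs <- confusion_summary(match(pred, leaves),
                          match(atlas$cells$true_label, leaves),
                          R = NULL, C = length(leaves))
  expect_equal(macro_f1(cs), 1.0)
})

test_that("label coarsening replaces leaves by strict ancestors at rate gamma", {
  cfg <- sim_config(n_leaves = 4, max_depth = 2, n_genes = 40,
                    cells_per_study = 2500, n_studies = 4, seed = 3)
  dag <- generate_ontology(cfg)
  atlas <- simulate_counts(dag, cfg)
  anc <- ancestors(dag)

  a0 <- coarsen_labels(atlas, gamma = 0)
  expect_identical(a0$cells$observed_label, a0$cells$true_label)

  a1 <- coarsen_labels(atlas, gamma = 1)
  expect_true(all(mapply(function(obs, tru) obs %in% anc[[tru]],
                         a1$cells$observed_label, a1$cells$true_label)))

  a5 <- coarsen_labels(atlas, gamma = 0.5)
  frac <- mean(a5$cells$observed_label != a5$cells$true_label)
  expect_gt(frac, 0.48)  # 10,000 cells: binomial bound
  expect_lt(frac, 0.52)
  expect_error(coarsen_labels(atlas, gamma = 1.5), "gamma")
})

test_that("ID/OOD splitting holds out studies and partitions by donor", {
  cfg <- sim_config(n_studies = 3, cells_per_study = 60, n_genes = 40, seed = 5)
  atlas <- simulate_counts(generate_ontology(cfg), cfg)
  sp <- split_id_ood(atlas, "study2")
  expect_setequal(sp$ood_test$cells$cell_id,
                  atlas$cells$cell_id[atlas$cells$study == "study2"])
  expect_length(intersect(sp$train$cells$donor, sp$id_test$cells$donor), 0)
  expect_setequal(c(sp$train$cells$cell_id, sp$id_test$cells$cell_id,
                    sp$ood_test$cells$cell_id), atlas$cells$cell_id)
  expect_error(split_id_ood(atlas, character(0)), "nonempty")
  expect_error(split_id_ood(atlas, paste0("study", 1:3)), "every study")
  expect_error(split_id_ood(atlas, "studyX"), "unknown")
})

test_that("normalization scales to 10,000 counts then log1p", {
  out <- normalize_counts(matrix(c(1, 1, 2), 1))
  expect_equal(as.numeric(out), log(c(2501, 2501, 5001)))
  # all-zero gene column stays zero
  m <- matrix(c(4, 6, 0, 0), 2, 2)
  expect_equal(normalize_counts(m)[, 2], c(0, 0))
  # a cell already summing to the target is only log-transformed
  x <- matrix(c(4000, 6000), 1)
  expect_equal(normalize_counts(x), log1p(x))
  bad <- matrix(c(1, 0, 2, 0), 2, 2, dimnames = list(c("c1", "c2"), NULL))
  expect_error(normalize_counts(bad), "c2")
})

test_that("inclusion filters drop classes under the cell or donor threshold", {
  mk_atlas <- function(n_per_class, donors_per_class) {
    n <- sum(n_per_class)
    lab <- rep(c("A", "B"), n_per_class)
    donor <- unlist(mapply(function(k, nd, cls)
      paste0(cls, "_d", rep(seq_len(nd), length.out = k)),
      n_per_class, donors_per_class, c("A", "B"), SIMPLIFY = FALSE))
    structure(list(counts = matrix(1L, n, 2),
                   cells = data.frame(cell_id = paste0("c", 1:n),
                                      true_label = lab, observed_label = lab,
                                      study = "s1", donor = donor),
                   genes = c("g1", "g2"), programs = NULL,
                   dag = ontology_dag(c("A", "B")), config = NULL),
              class = "synthetic_atlas")
  }
  atlas <- mk_atlas(c(5000, 4999), c(30, 30))
  expect_identical(apply_inclusion_filters(atlas, 0, 0)$cells, atlas$cells)
  kept <- apply_inclusion_filters(atlas, min_cells = 5000, min_donors = 30)
  expect_equal(attr(kept, "dropped"), "B")
  expect_setequal(unique(kept$cells$observed_label), "A")

  atlas2 <- mk_atlas(c(5000, 5000), c(30, 29))
  kept2 <- apply_inclusion_filters(atlas2, min_cells = 5000, min_donors = 30)
  expect_equal(attr(kept2, "dropped"), "B")
  expect_error(apply_inclusion_filters(atlas2, min_cells = 1e6), "every class")
})

test_that("atlas files round-trip through MatrixMarket and TSV", {
  cfg <- sim_config(n_studies = 2, cells_per_study = 30, n_genes = 40, seed = 8)
  atlas <- coarsen_labels(simulate_counts(generate_ontology(cfg), cfg))
  dir <- withr::local_tempdir()
  write_atlas(atlas, dir)
  back <- read_atlas(dir)
  expect_equal(unname(back$counts), unname(atlas$counts))
  expect_equal(back$cells, atlas$cells)
  expect_equal(back$dag$nodes, atlas$dag$nodes)
  expect_equal(back$dag$edges, atlas$dag$edges)
})
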