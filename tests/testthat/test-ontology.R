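test_that("edge-list ingestion builds the declared DAG", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# child\tparent", "B_cell\tlymphocyte", "T_cell\tlymphocyte"), f)
  dag <- load_ontology(f)
  expect_setequal(dag$nodes, c("B_cell", "T_cell", "lymphocyte"))
  expect_equal(nrow(dag$edges), 2L)
  expect_equal(sort(dag$edges$parent), c("lymphocyte", "lymphocyte"))
})

test_that("cyclic input is rejected with the offending cycle named", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA"), f)
  expect_error(load_ontology(f), "cycle.*A.*B|cycle.*B.*A")
  expect_error(ontology_dag("A", data.frame(child = "A", parent = "A")),
               "self-loop")
})

test_that("dangling edge endpoints are rejected", {
  expect_error(ontology_dag("A", data.frame(child = "A", parent = "ghost")),
               "ghost")
})

test_that("OBO ingestion keeps is_a and ignores other relations", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: CL:0000084", "name: T cell",
    "is_a: CL:0000542 ! lymphocyte", "",
    "[Term]", "id: CL:0000542", "name: lymphocyte", "",
    "[Term]", "id: CL:0009999", "name: thymocyte zone cell",
    "relationship: part_of CL:0000084", "",
    "[Typedef]", "id: part_of"
  ), f)
  expect_warning(dag <- load_ontology(f), "part_of")
  expect_equal(n_nodes(dag), 3L)
  expect_equal(nrow(dag$edges), 1L)
  expect_equal(dag$edges$child, "CL:0000084")
  expect_equal(dag$display_names[["CL:0000084"]], "T cell")
})

test_that("edge-list writer round-trips nodes and edges", {
  dag <- random_dag(12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ontology_edgelist(dag, f)
  back <- load_ontology(f)
  expect_equal(back$nodes, dag$nodes)
  expect_equal(back$edges, dag$edges)
})

test_that("pruning to observed labels keeps ancestry with minimal edges", {
  dag <- make_chain()
  pruned <- prune_to_labels(dag, c("A", "C"))
  expect_setequal(pruned$nodes, c("A", "C"))
  expect_equal(pruned$edges, data.frame(child = "C", parent = "A"))

  # observed = all nodes: transitive reduction of a chain is the chain
  full <- prune_to_labels(dag, dag$nodes)
  expect_equal(full$edges, dag$edges)

  single <- prune_to_labels(dag, "B")
  expect_equal(single$nodes, "B")
  expect_equal(nrow(single$edges), 0L)

  expect_error(prune_to_labels(dag, c("A", "Z")), "Z")
})

test_that("pruning preserves the ancestry partial order on random DAGs", {
  set.seed(42)
  for (rep in 1:20) {
    dag <- random_dag(sample(5:25, 1))
    obs <- sample(dag$nodes, max(2, rpois(1, length(dag$nodes) / 2)))
    pruned <- prune_to_labels(dag, obs)
    Rfull <- reachability(dag)[pruned$nodes, pruned$nodes]
    Rpruned <- reachability(pruned)
    expect_identical(Rpruned, Rfull)
  }
})

test_that("reachability matches closed forms on chain and diamond", {
  expect_identical(reachability(ontology_dag("solo")),
                   matrix(1L, 1, 1, dimnames = list("solo", "solo")))
  chainR <- reachability(make_chain())
  expect_identical(unname(chainR),
                   matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L), 3, 3))
  # diamond: D is_a B, D is_a C, B is_a A, C is_a A
  dia <- ontology_dag(c("A", "B", "C", "D"),
                      data.frame(child = c("D", "D", "B", "C"),
                                 parent = c("B", "C", "A", "A")))
  Rd <- reachability(dia)
  expect_identical(Rd["A", "D"], 1L)  # once, despite two paths
  expect_identical(unname(Rd["A", ]), rep(1L, 4))
})

test_that("node taxonomy distinguishes leaf/internal and connected/isolated", {
  tax <- classify_nodes(make_chain())
  expect_true(tax$is_internal[tax$node == "A"])
  expect_true(tax$is_leaf[tax$node == "C"])
  expect_true(all(tax$is_connected))
  expect_true(all(xor(tax$is_leaf, tax$is_internal)))
  expect_true(all(xor(tax$is_connected, tax$is_isolated)))

  solo <- classify_nodes(ontology_dag("solo"))
  expect_true(solo$is_leaf && solo$is_isolated)

  five <- ontology_dag(c("A", "B", "C", "D", "orphan"),
                       data.frame(child = c("B", "C", "D"),
                                  parent = c("A", "A", "B")))
  t5 <- classify_nodes(five)
  expect_equal(sum(t5$is_isolated), 1L)
  expect_equal(t5$node[t5$is_isolated], "orphan")
})
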