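test_that("tree-number prefix truncation yields ancestors, general to specific", {
  expect_equal(ancestors_of("C04.557.337"), c("C04", "C04.557"))
  expect_equal(ancestors_of("C04"), character(0))
  expect_equal(ancestors_of("C14.280.067.845"),
               c("C14", "C14.280", "C14.280.067"))
  expect_error(ancestors_of(""), "non-empty")
})

test_that("descriptor tables parse into a validated ontology", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term_id\tname\ttree_numbers",
               "R\troot\tC",
               "A\talpha\tC.1",
               "B\tbeta\tC.2"), path)
  onto <- parse_descriptor_table(path)
  expect_s3_class(onto, "disease_ontology")
  expect_length(onto$term_id, 3L)
  expect_equal(onto$parents$A, "R")
  expect_equal(onto$parents$B, "R")

  # empty tree_numbers: row dropped with a warning
  writeLines(c("term_id\tname\ttree_numbers",
               "R\troot\tC",
               "X\tnone\t"), path)
  expect_warning(onto2 <- parse_descriptor_table(path), "dropped")
  expect_length(onto2$term_id, 1L)

  # malformed row names its line
  writeLines(c("term_id\tname\ttree_numbers",
               "R\troot\tC",
               "A\tonly-two-fields"), path)
  expect_error(parse_descriptor_table(path), "line 3")

  # duplicate term_id rejected
  writeLines(c("term_id\tname\ttree_numbers",
               "R\troot\tC",
               "R\tagain\tC.9"), path)
  expect_error(parse_descriptor_table(path), "duplicate term_id")
})

test_that("a term with several codes gets all code-derived parents", {
  onto <- disease_ontology(data.frame(
    term_id = c("R", "B", "A"),
    name = c("r", "b", "a"),
    tree_numbers = c("C", "C.2", "C.1;C.2.5")))
  expect_setequal(onto$parents$A, c("R", "B"))
})

test_that("build_dag collects the full ancestor closure with shortest-path layers", {
  chain <- disease_ontology(data.frame(
    term_id = c("R", "A", "C"), name = c("r", "a", "c"),
    tree_numbers = c("C", "C.1", "C.1.1")))
  dag <- build_dag(chain, "C")
  expect_setequal(dag$nodes, c("C", "A", "R"))
  expect_equal(nrow(dag$edges), 2L)
  expect_equal(dag$layer[c("C", "A", "R")], c(C = 0L, A = 1L, R = 2L))

  expect_equal(build_dag(chain, "R")$nodes, "R")
  expect_equal(nrow(build_dag(chain, "R")$edges), 0L)
  expect_error(build_dag(chain, "nope"), "unknown disease")

  # diamond: X below both A and B, layer of the shared root is the shortest path
  diamond <- disease_ontology(data.frame(
    term_id = c("R", "A", "B", "X"), name = c("r", "a", "b", "x"),
    tree_numbers = c("C", "C.1", "C.2", "C.1.1;C.2.1")))
  dag <- build_dag(diamond, "X")
  expect_setequal(dag$nodes, c("X", "A", "B", "R"))
  expect_equal(unname(dag$layer["R"]), 2L)
})

test_that("missing intermediate vocabulary levels bridge to known ancestors", {
  # C.1.1's direct parent C.1 is absent; R should still be reached
  expect_message(
    onto <- disease_ontology(data.frame(
      term_id = c("R", "C"), name = c("r", "c"),
      tree_numbers = c("C", "C.1.1"))),
    "unresolvable")
  dag <- build_dag(onto, "C")
  expect_setequal(dag$nodes, c("C", "R"))
  expect_equal(unname(dag$layer["R"]), 1L)
})

test_that("build_dag matches the prefix-expansion oracle on random ontologies", {
  set.seed(401)
  for (rep in 1:25) {
    onto <- random_ontology(sample(4:12, 1L))
    for (d in onto$term_id) {
      dag <- build_dag(onto, d)
      expect_setequal(dag$nodes, oracle_dag_nodes(onto, d))
      # acyclic with every non-root node reachable: layers are all finite
      expect_false(anyNA(dag$layer))
      # every non-disease node has at least one child inside the DAG
      if (length(dag$nodes) > 1L) {
        expect_setequal(setdiff(dag$nodes, unique(dag$edges[, "parent"])),
                        intersect(dag$nodes, d))
      }
    }
  }
})

test_that("association mapping dedups, merges shared descriptors, drops unmapped", {
  onto <- toy_ontology()
  nm <- c("breast cancer" = "A", "breast carcinoma" = "A", "other" = "B")

  t1 <- map_associations(
    data.frame(lncrna = c("L1", "L1"), disease = c("breast cancer", "Breast Cancer ")),
    nm, onto)
  expect_equal(unname(t1$matrix), matrix(1, 1, 1))

  t2 <- map_associations(
    data.frame(lncrna = c("L1", "L1"), disease = c("breast cancer", "breast carcinoma")),
    nm, onto)
  expect_equal(dim(t2$matrix), c(1L, 1L))

  expect_message(
    t3 <- map_associations(
      data.frame(lncrna = c("L1", "L2"), disease = c("breast cancer", "unknown disease")),
      nm, onto),
    "dropped 1")
  expect_equal(dim(t3$matrix), c(1L, 1L))
  expect_equal(t3$disease_ids, "A")

  expect_error(
    map_associations(data.frame(lncrna = "L1", disease = "unknown"), nm, onto),
    "no associations remain")
})

test_that("association mapping is idempotent on its own output", {
  onto <- toy_ontology()
  nm <- c("a" = "A", "b" = "B", "c" = "C")
  pairs <- data.frame(lncrna = c("L1", "L2", "L1", "L2", "L1"),
                      disease = c("a", "b", "c", "a", "a"))
  t1 <- map_associations(pairs, nm, onto)
  # feed the realized pairs back through an identity name map
  idx <- which(t1$matrix == 1, arr.ind = TRUE)
  pairs2 <- data.frame(lncrna = t1$lncrna_ids[idx[, 1L]],
                       disease = t1$disease_ids[idx[, 2L]])
  id_map <- stats::setNames(t1$disease_ids, tolower(t1$disease_ids))
  t2 <- map_associations(pairs2, id_map, onto)
  expect_equal(t2$matrix, t1$matrix)
})
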