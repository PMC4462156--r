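chain_ontology <- function() {
  disease_ontology(data.frame(
    term_id = c("R", "A", "C"), name = c("r", "a", "c"),
    tree_numbers = c("C", "C.1", "C.1.1")))
}

test_that("model-1 contributions decay with distance and take the max over paths", {
  dag <- build_dag(chain_ontology(), "C")
  c1 <- contribution_model1(dag, delta = 0.5)
  expect_equal(c1$values[c("C", "A", "R")], c(C = 1, A = 0.5, R = 0.25))
  expect_equal(semantic_value(c1), 1.75)

  # decay disabled: every node contributes 1
  c_all1 <- contribution_model1(dag, delta = 1)
  expect_true(all(c_all1$values == 1))

  # diamond: two equal-length paths, max picks the same value
  diamond <- disease_ontology(data.frame(
    term_id = c("R", "A", "B", "X"), name = c("r", "a", "b", "x"),
    tree_numbers = c("C", "C.1", "C.2", "C.1.1;C.2.1")))
  cd <- contribution_model1(build_dag(diamond, "X"), delta = 0.5)
  expect_equal(cd$values[c("X", "A", "B", "R")],
               c(X = 1, A = 0.5, B = 0.5, R = 0.25))

  expect_error(contribution_model1(dag, delta = 0), "delta")
  expect_error(contribution_model1(dag, delta = 1.5), "delta")
})

test_that("model-1 similarity reproduces the worked toy values", {
  onto <- toy_ontology()
  dC <- build_dag(onto, "C"); dA <- build_dag(onto, "A"); dB <- build_dag(onto, "B")
  expect_equal(similarity_model1(dC, dA, 0.5), 2.25 / 3.25)
  expect_equal(similarity_model1(dA, dA, 0.5), 1)
  # disjoint trees share nothing
  two_trees <- disease_ontology(data.frame(
    term_id = c("R1", "R2"), name = c("r1", "r2"),
    tree_numbers = c("C", "F")))
  expect_equal(similarity_model1(build_dag(two_trees, "R1"),
                                 build_dag(two_trees, "R2"), 0.5), 0)
})

test_that("DAG membership counts scan the corpus correctly", {
  onto <- toy_ontology()
  corpus <- lapply(c("R", "A", "B", "C"), build_dag, ontology = onto)
  counts <- dag_membership_counts(corpus)
  expect_equal(counts[c("R", "A", "B", "C")], c(R = 4L, A = 2L, B = 1L, C = 1L))
  expect_true(all(dag_membership_counts(corpus[2]) == 1L))
})

test_that("model-2 contributions are -log frequencies and similarity is 0.5 on the toy", {
  onto <- toy_ontology()
  dags <- lapply(c("R", "A", "B", "C"), build_dag, ontology = onto)
  names(dags) <- c("R", "A", "B", "C")
  counts <- dag_membership_counts(dags)
  cC <- contribution_model2(dags$C, counts, 4)
  expect_equal(cC$values[c("C", "A", "R")],
               c(C = -log(1 / 4), A = -log(2 / 4), R = 0))
  expect_equal(semantic_value(cC), log(4) + log(2))
  cA <- contribution_model2(dags$A, counts, 4)
  expect_equal(similarity_model2(dags$C, dags$A, cC, cA), 0.5)
  expect_equal(similarity_model2(dags$A, dags$A, cA, cA), 1)

  # zero-semantic-value disease: distinct pair scores 0, identity stays 1
  cR <- contribution_model2(dags$R, counts, 4)
  cB <- contribution_model2(dags$B, counts, 4)
  expect_equal(semantic_value(cR), 0)
  expect_equal(similarity_model2(dags$R, dags$B, cR, cB), 0)
  expect_equal(similarity_model2(dags$R, dags$R, cR, cR), 1)

  expect_error(contribution_model2(dags$C, counts["R"], 4), "count")
  bad <- counts; bad["C"] <- 9L
  expect_error(contribution_model2(dags$C, bad, 4), "n_diseases")
})

test_that("similarity matrices are symmetric, unit-diagonal, in [0,1]", {
  onto <- toy_ontology()
  ids <- c("R", "A", "B", "C")
  S1 <- disease_similarity(onto, ids, model = 1, delta = 0.5)
  S2 <- disease_similarity(onto, ids, model = 2)
  expect_similarity_matrix(S1)
  expect_similarity_matrix(S2)
  expect_equal(S1["C", "A"], 2.25 / 3.25)
  expect_equal(S2["C", "A"], 0.5)

  set.seed(77)
  for (rep in 1:10) {
    onto_r <- random_ontology(sample(5:12, 1L))
    Sr <- disease_similarity(onto_r, onto_r$term_id,
                             model = sample(1:2, 1L), delta = runif(1, .1, 1))
    expect_similarity_matrix(Sr)
  }
})

test_that("model-2 similarity is invariant to the logarithm base", {
  onto <- toy_ontology()
  dags <- lapply(c("R", "A", "B", "C"), build_dag, ontology = onto)
  names(dags) <- c("R", "A", "B", "C")
  counts <- dag_membership_counts(dags)
  nat <- lapply(dags, contribution_model2, counts = counts, n_diseases = 4)
  base2 <- lapply(nat, function(cm) { cm$values <- cm$values / log(2); cm })
  for (a in names(dags)) for (b in names(dags)) {
    expect_equal(similarity_model2(dags[[a]], dags[[b]], nat[[a]], nat[[b]]),
                 similarity_model2(dags[[a]], dags[[b]], base2[[a]], base2[[b]]))
  }
})

test_that("model-1 similarity at delta = 1 reduces to the shared-node fraction", {
  # with no decay every node contributes 1, so the similarity must equal
  # 2|shared| / (|DAG(A)| + |DAG(B)|) exactly
  set.seed(99)
  for (rep in 1:8) {
    onto <- random_ontology(sample(6:12, 1L))
    pair <- sample(onto$term_id, 2L)
    d1 <- build_dag(onto, pair[1L]); d2 <- build_dag(onto, pair[2L])
    shared <- length(intersect(d1$nodes, d2$nodes))
    expect_equal(similarity_model1(d1, d2, 1),
                 2 * shared / (length(d1$nodes) + length(d2$nodes)))
  }
})

test_that("tree DAG contributions follow the closed form delta^layer", {
  cfg <- sim_config(depth = 3, branching = 2)
  onto <- simulate_ontology(cfg)
  for (d in sample(onto$term_id, 5L)) {
    dag <- build_dag(onto, d)
    cm <- contribution_model1(dag, delta = 0.37)
    expect_equal(cm$values[dag$nodes], 0.37^dag$layer[dag$nodes])
  }
})

test_that("both models match the brute-force oracles on random ontologies", {
  set.seed(1234)
  for (rep in 1:30) {
    onto <- random_ontology(sample(4:12, 1L))
    ids <- onto$term_id
    S1 <- disease_similarity(onto, ids, model = 1, delta = 0.5)
    S2 <- disease_similarity(onto, ids, model = 2)
    for (a in ids) for (b in ids) {
      expect_equal(S1[a, b], oracle_ss1(onto, a, b, 0.5), tolerance = 1e-12)
      expect_equal(S2[a, b], oracle_ss2(onto, a, b, ids), tolerance = 1e-12)
    }
  }
})
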