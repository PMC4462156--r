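# Shared fixtures and independent brute-force oracles.

# Toy vocabulary: root R with children A and B, C below A.
toy_ontology <- function() {
  disease_ontology(data.frame(
    term_id = c("R", "A", "B", "C"),
    name = c("root", "alpha", "beta", "gamma"),
    tree_numbers = c("C", "C.1", "C.2", "C.1.1"),
    stringsAsFactors = FALSE))
}

# Random fully-resolvable ontology: grow codes under a single root, then merge
# a few leaf codes into other terms so some terms own two codes (diamonds).
random_ontology <- function(n_codes = 10L, merge_frac = 0.25) {
  codes <- "C"
  while (length(codes) < n_codes) {
    parent <- sample(codes, 1L)
    kid_no <- sum(startsWith(codes, paste0(parent, ".")) &
                    !grepl(".", substring(codes, nchar(parent) + 2L),
                           fixed = TRUE)) + 1L
    codes <- c(codes, paste0(parent, ".", kid_no))
  }
  term_of <- stats::setNames(paste0("T", seq_along(codes)), codes)
  # merge: reassign some leaf codes to an unrelated term
  leaves <- codes[!vapply(codes, function(cc)
    any(startsWith(codes, paste0(cc, "."))), logical(1))]
  n_merge <- floor(length(leaves) * merge_frac)
  for (cc in sample(leaves, n_merge)) {
    host_codes <- function(t) names(term_of)[term_of == t]
    ok_hosts <- Filter(function(t) {
      hc <- host_codes(t)
      !any(startsWith(cc, paste0(hc, "."))) && !any(hc == cc) &&
        !any(startsWith(hc, paste0(cc, ".")))
    }, setdiff(unique(term_of), term_of[[cc]]))
    if (length(ok_hosts) > 0L) term_of[[cc]] <- sample(ok_hosts, 1L)
  }
  terms <- unique(term_of)
  disease_ontology(data.frame(
    term_id = terms,
    name = terms,
    tree_numbers = vapply(terms, function(t)
      paste(names(term_of)[term_of == t], collapse = ";"), character(1)),
    stringsAsFactors = FALSE))
}

# --- oracles, computed from tree-number codes only -------------------------

oracle_prefixes <- function(code) {
  parts <- strsplit(code, ".", fixed = TRUE)[[1L]]
  if (length(parts) <= 1L) return(character(0))
  vapply(seq_len(length(parts) - 1L),
         function(k) paste(parts[seq_len(k)], collapse = "."), character(1))
}

# full ancestor closure over term-level edges: a merged ancestor pulls in the
# ancestors of all of its codes, so this must walk edges, not just expand the
# focal term's own prefixes
oracle_dag_nodes <- function(ontology, disease) {
  names(oracle_distances(ontology, disease))
}

# term-level parent->child edges from the +1-segment code relation
oracle_edges <- function(ontology) {
  codes <- names(ontology$code2term)
  edges <- NULL
  for (cc in codes) {
    pre <- oracle_prefixes(cc)
    if (length(pre) == 0L) next
    parent_code <- pre[length(pre)]
    if (parent_code %in% codes) {
      edges <- rbind(edges, c(ontology$code2term[[parent_code]],
                              ontology$code2term[[cc]]))
    }
  }
  edges
}

# shortest downward hop count from every ancestor to `disease` (BFS upward)
oracle_distances <- function(ontology, disease) {
  edges <- oracle_edges(ontology)
  dist <- stats::setNames(0L, disease)
  frontier <- disease
  lev <- 0L
  while (length(frontier) > 0L) {
    lev <- lev + 1L
    up <- unique(edges[edges[, 2L] %in% frontier, 1L])
    up <- setdiff(up, names(dist))
    if (length(up) > 0L) dist[up] <- lev
    frontier <- up
  }
  dist
}

# model 1: contribution = delta^(shortest downward path), the maximum of
# delta^length over all downward paths
oracle_ss1 <- function(ontology, A, B, delta) {
  if (identical(A, B)) return(1)
  nA <- oracle_dag_nodes(ontology, A)
  nB <- oracle_dag_nodes(ontology, B)
  cA <- delta^oracle_distances(ontology, A)[nA]
  cB <- delta^oracle_distances(ontology, B)[nB]
  shared <- intersect(nA, nB)
  if (length(shared) == 0L) return(0)
  sum(cA[shared] + cB[shared]) / (sum(cA) + sum(cB))
}

# model 2: contributions from a direct membership scan over the corpus
oracle_ss2 <- function(ontology, A, B, corpus) {
  node_sets <- lapply(corpus, oracle_dag_nodes, ontology = ontology)
  names(node_sets) <- corpus
  count <- function(t) sum(vapply(node_sets, function(s) t %in% s, logical(1)))
  if (identical(A, B)) return(1)
  cA <- vapply(node_sets[[A]], function(t)
    -log(count(t) / length(corpus)), numeric(1))
  names(cA) <- node_sets[[A]]
  cB <- vapply(node_sets[[B]], function(t)
    -log(count(t) / length(corpus)), numeric(1))
  names(cB) <- node_sets[[B]]
  den <- sum(cA) + sum(cB)
  if (den == 0) return(0)
  shared <- intersect(node_sets[[A]], node_sets[[B]])
  if (length(shared) == 0L) return(0)
  sum(cA[shared] + cB[shared]) / den
}

# Mann-Whitney concordance, averaged over folds, from explicit score lists
oracle_concordance <- function(test_scores, candidate_scores) {
  mean(mapply(function(s, v) {
    (sum(s > v) + 0.5 * sum(s == v)) / length(v)
  }, test_scores, candidate_scores))
}

expect_similarity_matrix <- function(S) {
  expect_true(is.matrix(S))
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_true(all(S >= 0 - 1e-12) && all(S <= 1 + 1e-12))
}
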