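#' Model-1 term contributions within a disease DAG
#'
#' The decay-factor model assigns the disease of interest a contribution of 1
#' and attenuates ancestor contributions by a multiplicative decay factor per
#' step away from it. On general DAGs (a term can have several descendant
#' paths to the disease) the contribution of term `t` is defined recursively
#' as the maximum over `t`'s children inside the DAG of `delta` times the
#' child's contribution, i.e. `delta` raised to the shortest downward path
#' length on trees.
#'
#' @param dag A [build_dag()] result.
#' @param delta Semantic contribution decay factor, in (0, 1]. Default 0.5,
#'   the convention of the decay-factor similarity literature.
#' @return Object of class `contribution_map`: list with `disease`, `values`
#'   (named numeric over the DAG's nodes) and `model`.
#' @export
contribution_model1 <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1) {
    stop("`delta` must lie in (0, 1]", call. = FALSE)
  }
  children <- split(dag$edges[, "child"], dag$edges[, "parent"])
  vals <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  compute <- function(t) {
    if (!is.na(vals[[t]])) return(vals[[t]])
    v <- if (identical(t, dag$disease)) {
      1
    } else {
      ch <- children[[t]]
      if (is.null(ch)) {
        stop("DAG node ", t, " has no downward path to ", dag$disease,
             call. = FALSE)
      }
      delta * max(vapply(ch, compute, numeric(1)))
    }
    vals[[t]] <<- v
    v
  }
  for (t in dag$nodes) compute(t)
  structure(list(disease = dag$disease, values = vals, model = 1L),
            class = "contribution_map")
}

#' Semantic value of a disease
#'
#' The semantic value is the sum of the contributions of all terms in the
#' disease's DAG (the disease itself plus its ancestors). Under model 1 it is
#' at least 1 (the self term); under model 2 it can be 0 when every term in
#' the DAG occurs in all studied diseases' DAGs.
#'
#' @param contribs A `contribution_map` from [contribution_model1()] or
#'   [contribution_model2()].
#' @return A single non-negative number.
#' @export
semantic_value <- function(contribs) {
  stopifnot(inherits(contribs, "contribution_map"))
  sum(contribs$values)
}

#' Model-1 semantic similarity between two diseases
#'
#' Similarity is carried by the terms the two DAGs share: the sum over shared
#' terms of both diseases' contributions, normalized by the sum of the two
#' semantic values. Identical diseases have similarity exactly 1.
#'
#' @param dagA,dagB DAGs built over the same ontology.
#' @param delta Decay factor passed to [contribution_model1()].
#' @return Similarity in \[0, 1\].
#' @export
similarity_model1 <- function(dagA, dagB, delta = 0.5) {
  if (identical(dagA$disease, dagB$disease)) return(1)
  cA <- contribution_model1(dagA, delta)
  cB <- contribution_model1(dagB, delta)
  shared <- intersect(dagA$nodes, dagB$nodes)
  if (length(shared) == 0L) return(0)
  sum(cA$values[shared] + cB$values[shared]) /
    (semantic_value(cA) + semantic_value(cB))
}

#' DAG membership counts over a disease corpus
#'
#' Counts, for every term appearing in any DAG of the corpus, how many of the
#' corpus DAGs contain it. These frequencies drive the model-2 contributions:
#' terms present in few disease DAGs are more specific.
#'
#' @param corpus A non-empty list of [build_dag()] results.
#' @return Named integer vector, term id to count.
#' @export
dag_membership_counts <- function(corpus) {
  stopifnot(is.list(corpus), length(corpus) > 0L)
  tab <- table(unlist(lapply(corpus, function(d) unique(d$nodes)),
                      use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' Model-2 term contributions within a disease DAG
#'
#' Replaces the per-layer decay with a frequency weight: the contribution of
#' term `t` is `-log(count(t) / n_diseases)`, where `count(t)` is the number
#' of studied disease DAGs containing `t`. A term present in every DAG
#' contributes 0; rarer (more specific) terms contribute more. The similarity
#' built from these contributions is invariant to the logarithm base; the
#' natural logarithm is used.
#'
#' @param dag A [build_dag()] result.
#' @param counts Membership counts from [dag_membership_counts()].
#' @param n_diseases Number of diseases in the corpus the counts came from.
#' @return A `contribution_map` with `model = 2`.
#' @export
contribution_model2 <- function(dag, counts, n_diseases) {
  stopifnot(inherits(dag, "disease_dag"),
            is.numeric(n_diseases), n_diseases >= 1)
  missing <- setdiff(dag$nodes, names(counts))
  if (length(missing) > 0L) {
    stop("no membership count for term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  k <- counts[dag$nodes]
  if (any(k <= 0) || any(k > n_diseases)) {
    stop("membership counts must lie in [1, n_diseases]", call. = FALSE)
  }
  structure(list(disease = dag$disease,
                 values = -log(k / n_diseases),
                 model = 2L),
            class = "contribution_map")
}

#' Model-2 semantic similarity between two diseases
#'
#' Same shared-term ratio as model 1, but with frequency-based contributions.
#' Identical diseases score 1. When both semantic values are 0 (both DAGs
#' consist solely of terms present in every studied disease's DAG) the ratio
#' is undefined; distinct diseases are then assigned 0.
#'
#' @param dagA,dagB DAGs built over the same ontology.
#' @param contribsA,contribsB Contribution maps from [contribution_model2()]
#'   computed over a common corpus.
#' @return Similarity in \[0, 1\].
#' @export
similarity_model2 <- function(dagA, dagB, contribsA, contribsB) {
  if (identical(dagA$disease, dagB$disease)) return(1)
  den <- semantic_value(contribsA) + semantic_value(contribsB)
  if (den == 0) return(0)
  shared <- intersect(dagA$nodes, dagB$nodes)
  if (length(shared) == 0L) return(0)
  sum(contribsA$values[shared] + contribsB$values[shared]) / den
}

#' Disease semantic similarity matrix
#'
#' Batch driver over a set of diseases: builds each disease's DAG once and
#' fills the symmetric similarity matrix under the requested model. For model
#' 2 the membership counts are taken over `corpus` (by default the diseases
#' being compared, i.e. the studied disease set, not the whole vocabulary).
#'
#' @param ontology A [disease_ontology()].
#' @param diseases Ordered character vector of term ids.
#' @param model 1 (decay factor) or 2 (DAG frequency).
#' @param delta Decay factor for model 1.
#' @param corpus Term ids defining the model-2 counting corpus; defaults to
#'   `diseases`.
#' @return Square symmetric numeric matrix with unit diagonal and `diseases`
#'   as dimnames.
#' @export
disease_similarity <- function(ontology, diseases, model = 1, delta = 0.5,
                               corpus = diseases) {
  stopifnot(inherits(ontology, "disease_ontology"),
            length(diseases) > 0L, model %in% c(1, 2))
  if (anyDuplicated(diseases)) stop("duplicate disease ids", call. = FALSE)
  dags <- lapply(diseases, build_dag, ontology = ontology)
  names(dags) <- diseases
  n <- length(diseases)
  S <- matrix(0, n, n, dimnames = list(diseases, diseases))
  diag(S) <- 1
  if (model == 1) {
    contribs <- lapply(dags, contribution_model1, delta = delta)
  } else {
    corpus_dags <- if (identical(corpus, diseases)) dags else
      lapply(corpus, build_dag, ontology = ontology)
    counts <- dag_membership_counts(corpus_dags)
    contribs <- lapply(dags, contribution_model2, counts = counts,
                       n_diseases = length(corpus))
  }
  sv <- vapply(contribs, semantic_value, numeric(1))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        shared <- intersect(dags[[i]]$nodes, dags[[j]]$nodes)
        den <- sv[[i]] + sv[[j]]
        s <- if (length(shared) == 0L || den == 0) 0 else
          sum(contribs[[i]]$values[shared] + contribs[[j]]$values[shared]) / den
        S[i, j] <- S[j, i] <- s
      }
    }
  }
  S
}
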