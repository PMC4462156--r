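# Midrank of value s among the candidate scores v (v includes s's own cell
# when the test pair is part of the candidate set).
midrank <- function(s, v) {
  sum(v > s) + (sum(v == s) + 1) / 2
}

#' ROC curve and AUC from leave-one-out ranks
#'
#' Each test sample carries its (mid)rank among `n_candidates + 1` items (the
#' candidate pairs plus itself). Per fold, the fraction of candidates the
#' test sample outranks — counting ties as half — is
#' `(n + 1 - rank) / n`, which is exactly the fold's Mann-Whitney
#' concordance; the reported AUC is the mean of these fold concordances, so
#' tied constant scores give exactly 0.5. The ROC points are built by
#' sweeping integer rank cutoffs (one point per achieved rank, no binning)
#' for plotting; the AUC comes from the exact rank identity rather than from
#' integrating the curve.
#'
#' @param ranks Numeric vector of test-sample ranks (midranks allowed), or a
#'   data frame with columns `rank` and `n_candidates`.
#' @param n_candidates Numeric vector of candidate (negative) counts per
#'   test sample; ignored when `ranks` is a data frame.
#' @return List with `roc_points` (data frame `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1)) and `auc`.
#' @export
roc_auc <- function(ranks, n_candidates = NULL) {
  if (is.data.frame(ranks)) {
    n_candidates <- ranks$n_candidates
    ranks <- ranks$rank
  }
  if (length(ranks) == 0L) stop("no test ranks supplied", call. = FALSE)
  stopifnot(length(ranks) == length(n_candidates),
            all(ranks >= 1), all(ranks <= n_candidates + 1),
            all(n_candidates >= 1))
  auc <- mean((n_candidates + 1 - ranks) / n_candidates)
  cutoffs <- sort(unique(c(0, ceiling(ranks), max(n_candidates) + 1)))
  pts <- vapply(cutoffs, function(cc) {
    hit <- ranks <= cc
    neg_in <- pmin(cc, n_candidates + 1) - hit  # candidates at/above cutoff
    c(fpr = mean(pmin(pmax(neg_in / n_candidates, 0), 1)),
      tpr = mean(hit))
  }, numeric(2))
  roc <- data.frame(fpr = pts["fpr", ], tpr = pts["tpr", ])
  roc <- roc[order(roc$fpr, roc$tpr), , drop = FALSE]
  rownames(roc) <- NULL
  list(roc_points = roc, auc = auc)
}

# Recompute the functional-similarity row of one lncRNA against the current
# groups; used per LOOCV fold where only the test lncRNA's group changes.
fs_update_row <- function(FS, i_id, groups, SS) {
  gi <- groups[[i_id]]
  others <- setdiff(rownames(FS), i_id)
  if (length(gi) == 0L) {
    # lncRNA lost its last disease: drop it from the functional similarity
    keep <- others
    return(FS[keep, keep, drop = FALSE])
  }
  for (j_id in others) {
    FS[i_id, j_id] <- FS[j_id, i_id] <-
      functional_similarity(gi, groups[[j_id]], SS)
  }
  FS
}

#' Leave-one-out cross-validation of the association predictor
#'
#' Withholds each known lncRNA-disease association in turn, rebuilds every
#' association-derived quantity from the reduced matrix (the Gaussian
#' kernels on both axes, and the test lncRNA's disease group for the
#' functional similarity), scores all pairs with the Laplacian-regularized
#' least-squares predictor, and records the withheld pair's midrank among
#' all candidate pairs (the pairs unknown in the reduced matrix). Disease
#' semantic similarity is ontology-derived and does not change across folds.
#'
#' @param assoc An [association_table()] with at least 2 known associations.
#' @param disease_ss Disease semantic similarity matrix over `assoc`'s
#'   diseases; `NULL` runs the kernel-only configuration (no semantic
#'   similarity, no functional similarity).
#' @param expression Optional lncRNA expression matrix (rows must be a
#'   subset of `assoc`'s lncRNAs); adds the expression similarity source.
#' @param gamma_prime Bandwidth numerator for both Gaussian kernels.
#' @param params An [lrls_params()] object.
#' @param scope Candidate set per fold: `"global"` (all unknown pairs, the
#'   default) or `"per-disease"` (unknown pairs of the withheld disease).
#' @param refit_kernels Recompute the Gaussian kernels from the reduced
#'   matrix each fold (default `TRUE`; `FALSE` reuses the full-data kernels
#'   and leaks the withheld association into the similarity).
#' @param shrink_groups Shrink the test lncRNA's disease group before
#'   recomputing its functional similarity row (default `TRUE`; `FALSE`
#'   keeps the full-data group, again a leaky diagnostic).
#' @param holdout Remove the test association from the training matrix
#'   (default `TRUE`; `FALSE` quantifies the leakage ceiling).
#' @param scorer `"lrlslda"` (the predictor), `"random"` (uniform random
#'   scores, a null control) or `"constant"` (all scores equal).
#' @param seed Integer seed for the `"random"` scorer.
#' @param expression_method Rescaling passed to [expression_similarity()].
#' @return Object of class `loocv_result`: list with `folds` (data frame
#'   `lncrna`, `disease`, `score`, `rank`, `n_candidates`), `roc_points`,
#'   `auc`, and the configuration used.
#' @export
loocv <- function(assoc, disease_ss = NULL, expression = NULL,
                  gamma_prime = 1, params = lrls_params(),
                  scope = c("global", "per-disease"),
                  refit_kernels = TRUE, shrink_groups = TRUE, holdout = TRUE,
                  scorer = c("lrlslda", "random", "constant"), seed = NULL,
                  expression_method = "signed") {
  scope <- match.arg(scope)
  scorer <- match.arg(scorer)
  stopifnot(inherits(assoc, "association_table"))
  A <- assoc$matrix
  known <- which(A == 1, arr.ind = TRUE)
  if (nrow(known) < 2L) stop("need at least 2 known associations", call. = FALSE)
  use_lncsim <- !is.null(disease_ss)
  if (use_lncsim && !all(colnames(A) %in% rownames(disease_ss))) {
    stop("`disease_ss` does not cover all diseases", call. = FALSE)
  }
  es <- if (!is.null(expression)) {
    expression_similarity(expression, method = expression_method)
  }
  groups_full <- apply(A, 1L, function(r) colnames(A)[r > 0], simplify = FALSE)
  FS_full <- if (use_lncsim) {
    suppressMessages(functional_similarity_matrix(assoc, disease_ss))
  }
  KL_full <- gaussian_kernel(assoc, "lncrna", gamma_prime)
  KD_full <- gaussian_kernel(assoc, "disease", gamma_prime)
  rng <- if (scorer == "random") local_rng(if (is.null(seed)) 1L else seed)

  folds <- vector("list", nrow(known))
  for (f in seq_len(nrow(known))) {
    i <- known[f, 1L]; j <- known[f, 2L]
    A2 <- A
    if (holdout) A2[i, j] <- 0
    assoc2 <- association_table(A2)

    if (scorer == "lrlslda") {
      KL <- if (refit_kernels) gaussian_kernel(assoc2, "lncrna", gamma_prime)
            else KL_full
      KD <- if (refit_kernels) gaussian_kernel(assoc2, "disease", gamma_prime)
            else KD_full
      FS <- if (use_lncsim) {
        if (holdout && shrink_groups) {
          g2 <- groups_full
          g2[[rownames(A)[i]]] <- colnames(A)[A2[i, ] > 0]
          fs_update_row(FS_full, rownames(A)[i], g2, disease_ss)
        } else FS_full
      }
      sl <- integrate_lncrna_similarity(FS, KL, es)
      sd <- if (use_lncsim) {
        integrate_disease_similarity(disease_ss[colnames(A), colnames(A)], KD)
      } else KD
      scores <- lrls_predict(assoc2, sl, sd, params)
    } else if (scorer == "random") {
      scores <- matrix(rng(length(A)), nrow(A), dimnames = dimnames(A))
    } else {
      scores <- matrix(1, nrow(A), ncol(A), dimnames = dimnames(A))
    }

    cand <- if (scope == "global") which(A2 == 0) else
      (j - 1L) * nrow(A2) + which(A2[, j] == 0)
    v <- scores[cand]
    s <- scores[i, j]
    if (!holdout) v <- c(v, s)           # test cell is not an unknown cell
    folds[[f]] <- data.frame(
      lncrna = rownames(A)[i], disease = colnames(A)[j], score = s,
      rank = midrank(s, v), n_candidates = length(v) - 1L,
      stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  ra <- roc_auc(folds)
  structure(list(folds = folds, roc_points = ra$roc_points, auc = ra$auc,
                 config = list(use_lncsim = use_lncsim,
                               expression = !is.null(expression),
                               gamma_prime = gamma_prime, params = params,
                               scope = scope, refit_kernels = refit_kernels,
                               shrink_groups = shrink_groups,
                               holdout = holdout, scorer = scorer)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("loocv_result:", nrow(x$folds), "folds, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}
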