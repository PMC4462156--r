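#' Parameters for the Laplacian-regularized least-squares predictor
#'
#' @param eta_l,eta_d Positive regularization weights for the lncRNA-space
#'   and disease-space solutions. Default 1.
#' @param w Combination weight in \[0, 1\] on the lncRNA-space solution;
#'   `1 - w` goes to the disease-space solution. Default 0.5.
#' @param jitter Small positive ridge added to the system diagonal before
#'   inversion. Default 1e-8.
#' @return A list of class `lrls_params`.
#' @export
lrls_params <- function(eta_l = 1, eta_d = 1, w = 0.5, jitter = 1e-8) {
  stopifnot(eta_l > 0, eta_d > 0, w >= 0, w <= 1, jitter > 0)
  structure(list(eta_l = eta_l, eta_d = eta_d, w = w, jitter = jitter),
            class = "lrls_params")
}

#' Normalized graph Laplacian of a similarity matrix
#'
#' `L = I - D^{-1/2} S D^{-1/2}` with `D` the diagonal matrix of row sums.
#' Rows with zero sum (isolated entities) get an identity row so `L` stays
#' well defined; the result is symmetric positive semidefinite with
#' eigenvalues in \[0, 2\].
#'
#' @param s Symmetric non-negative similarity matrix.
#' @param normalized If `FALSE`, return the unnormalized Laplacian `D - S`
#'   instead (offered for sensitivity analysis).
#' @return Square matrix of the same dimension as `s`.
#' @export
normalized_laplacian <- function(s, normalized = TRUE) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  if (any(s < 0)) stop("similarity matrix has negative entries", call. = FALSE)
  if (max(abs(s - t(s))) > 1e-10) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  d <- rowSums(s)
  if (!normalized) {
    L <- diag(d) - s
    dimnames(L) <- dimnames(s)
    return(L)
  }
  isq <- ifelse(d > 0, 1 / sqrt(d), 0)
  Snorm <- s * tcrossprod(isq)
  L <- diag(nrow(s)) - Snorm
  L <- (L + t(L)) / 2
  dimnames(L) <- dimnames(s)
  L
}

#' Closed-form Laplacian-regularized least-squares solve
#'
#' Returns `F = K (K + eta * L K + jitter * I)^{-1} Y`, the kernel-representer
#' minimizer of `||Y - F||_F^2 + eta * trace(F' L F)`. With `eta = 0` and no
#' jitter this interpolates `Y` exactly for invertible `K`.
#'
#' @param K Kernel (similarity) matrix.
#' @param L Graph Laplacian of matching size (see [normalized_laplacian()]).
#' @param Y Target matrix with `nrow(K)` rows.
#' @param eta Non-negative regularization weight.
#' @param jitter Non-negative diagonal ridge; raise it if the system is
#'   reported singular.
#' @return Matrix of fitted values, same shape as `Y`.
#' @export
lrls_solve <- function(K, L, Y, eta, jitter = 1e-8) {
  stopifnot(is.matrix(K), is.matrix(L), nrow(K) == ncol(K),
            all(dim(K) == dim(L)), nrow(Y) == nrow(K), eta >= 0, jitter >= 0)
  M <- K + eta * (L %*% K) + jitter * diag(nrow(K))
  Fhat <- tryCatch(K %*% solve(M, Y), error = function(e) {
    stop("LRLS system is numerically singular (", conditionMessage(e),
         "); consider raising `jitter`", call. = FALSE)
  })
  if (!all(is.finite(Fhat))) {
    stop("LRLS solution is not finite; consider raising `jitter`",
         call. = FALSE)
  }
  dimnames(Fhat) <- dimnames(Y)
  Fhat
}

#' Score all lncRNA-disease pairs
#'
#' Solves the Laplacian-regularized least-squares problem twice — once in the
#' lncRNA similarity space on the association matrix and once in the disease
#' similarity space on its transpose — and combines the two score matrices
#' linearly: `w * F_lncrna + (1 - w) * F_disease`. Known-association cells
#' keep their scores; filtering known pairs is the ranker's job, so
#' cross-validation can read the score of a withheld pair directly.
#'
#' @param assoc An [association_table()].
#' @param sl LncRNA similarity matrix over all of `assoc`'s lncRNAs.
#' @param sd Disease similarity matrix over all of `assoc`'s diseases.
#' @param params An [lrls_params()] object.
#' @return Real score matrix with the association table's dimnames.
#' @export
lrls_predict <- function(assoc, sl, sd, params = lrls_params()) {
  stopifnot(inherits(assoc, "association_table"),
            inherits(params, "lrls_params"))
  A <- assoc$matrix
  if (!identical(rownames(sl), rownames(A)) ||
      !identical(rownames(sd), colnames(A))) {
    stop("similarity matrices must index the association table's identifiers",
         call. = FALSE)
  }
  Fl <- lrls_solve(sl, normalized_laplacian(sl), A,
                   eta = params$eta_l, jitter = params$jitter)
  Fd <- t(lrls_solve(sd, normalized_laplacian(sd), t(A),
                     eta = params$eta_d, jitter = params$jitter))
  scores <- params$w * Fl + (1 - params$w) * Fd
  dimnames(scores) <- dimnames(A)
  scores
}

#' Rank candidate lncRNA-disease pairs
#'
#' Ranks the pairs *not* in the known association set by descending score,
#' either within each disease or globally over all unknown pairs. Ties are
#' broken by lncRNA then disease identifier order, which keeps the ranking
#' deterministic; a fully tied input therefore comes back in identifier
#' order.
#'
#' @param scores Score matrix from [lrls_predict()].
#' @param known An [association_table()] with the same shape; cells equal to
#'   1 are excluded from the ranking.
#' @param scope `"per-disease"` or `"global"`.
#' @return Data frame with columns `lncrna`, `disease`, `score`, `rank`
#'   (rank restarts at 1 within each disease under `"per-disease"`).
#' @export
rank_candidates <- function(scores, known, scope = c("per-disease", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(known, "association_table"),
            all(dim(scores) == dim(known$matrix)))
  idx <- which(known$matrix == 0, arr.ind = TRUE)
  out <- data.frame(lncrna = rownames(scores)[idx[, 1L]],
                    disease = colnames(scores)[idx[, 2L]],
                    score = scores[idx], stringsAsFactors = FALSE)
  rank_block <- function(d) {
    d <- d[order(-d$score, d$lncrna, d$disease), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  }
  if (scope == "global") {
    out <- rank_block(out)
  } else {
    out <- do.call(rbind, lapply(split(out, out$disease), rank_block))
    out <- out[order(out$disease, out$rank), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
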