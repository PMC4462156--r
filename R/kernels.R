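#' Gaussian interaction-profile kernel similarity
#'
#' Each entity's interaction profile is its binary association vector against
#' the opposite axis (the row for an lncRNA, the column for a disease). The
#' kernel is `exp(-gamma * ||IP(i) - IP(j)||^2)` with the bandwidth
#' normalized by the data: `gamma = gamma_prime / mean(||IP||^2)` over the
#' entities on the chosen axis. When every profile is all-zero the bandwidth
#' is undefined and the identity matrix is returned with a warning.
#'
#' @param assoc An [association_table()].
#' @param axis `"lncrna"` (profiles are rows) or `"disease"` (columns).
#' @param gamma_prime Positive bandwidth numerator; default 1.
#' @return Symmetric similarity matrix with unit diagonal, entries in (0, 1].
#' @export
gaussian_kernel <- function(assoc, axis = c("lncrna", "disease"),
                            gamma_prime = 1) {
  axis <- match.arg(axis)
  stopifnot(inherits(assoc, "association_table"))
  if (!is.numeric(gamma_prime) || length(gamma_prime) != 1L ||
      gamma_prime <= 0) {
    stop("`gamma_prime` must be a positive number", call. = FALSE)
  }
  P <- if (axis == "lncrna") assoc$matrix else t(assoc$matrix)
  n <- nrow(P)
  norms2 <- rowSums(P^2)
  if (all(norms2 == 0)) {
    warning("all interaction profiles are zero; returning identity kernel",
            call. = FALSE)
    K <- diag(1, n, n)
    dimnames(K) <- list(rownames(P), rownames(P))
    return(K)
  }
  gamma <- gamma_prime / mean(norms2)
  D2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0                      # guard tiny negative round-off
  K <- exp(-gamma * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  K
}

#' Expression similarity between lncRNAs
#'
#' Spearman rank correlation between each pair of expression profiles,
#' rescaled onto \[0, 1\]. The default `"signed"` rescaling maps the
#' correlation `r` to `(r + 1) / 2`, keeping it on the same scale as the
#' other similarity sources; `"absolute"` uses `|r|` instead. Profiles with
#' zero variance have undefined correlation; their `r` is treated as 0 (a
#' message is emitted), so they land mid-scale under the signed map.
#'
#' @param expr Numeric matrix, rows lncRNAs, columns samples (at least 3).
#' @param method `"signed"` or `"absolute"` rescaling.
#' @return Symmetric similarity matrix with unit diagonal over the lncRNAs.
#' @export
expression_similarity <- function(expr, method = c("signed", "absolute")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples per profile", call. = FALSE)
  if (is.null(rownames(expr))) stop("expression matrix needs lncRNA row names",
                                    call. = FALSE)
  constant <- apply(expr, 1L, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(stats::cor(t(expr), method = "spearman"))
  if (any(constant)) {
    message("constant expression profile(s), correlation set to 0: ",
            paste(rownames(expr)[constant], collapse = ", "))
  }
  r[is.na(r)] <- 0
  S <- if (method == "signed") (r + 1) / 2 else abs(r)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Integrate semantic and kernel disease similarity
#'
#' Element-wise mean of the disease semantic similarity and the disease
#' Gaussian interaction-profile kernel.
#'
#' @param ss,kd Similarity matrices with identical dimnames.
#' @return Integrated disease similarity matrix.
#' @export
integrate_disease_similarity <- function(ss, kd) {
  if (!identical(dimnames(ss), dimnames(kd))) {
    stop("similarity matrices have different identifier indices",
         call. = FALSE)
  }
  (ss + kd) / 2
}

#' Integrate the lncRNA similarity sources
#'
#' Averages, per pair, the similarity sources available for that pair: the
#' functional similarity (which may cover only the lncRNAs with known
#' diseases), the Gaussian interaction-profile kernel (always full), and
#' optionally the expression similarity. Pairs missing a source are averaged
#' over the sources present rather than imputing zeros, so lncRNAs outside
#' the functional similarity are not systematically depressed.
#'
#' @param fs Functional similarity matrix over a subset of the lncRNAs, or
#'   `NULL` to omit.
#' @param kl Gaussian kernel matrix over all lncRNAs (defines the output
#'   index).
#' @param es Optional expression similarity matrix over a subset.
#' @return Symmetric similarity matrix over `rownames(kl)` with unit
#'   diagonal.
#' @export
integrate_lncrna_similarity <- function(fs, kl, es = NULL) {
  ids <- rownames(kl)
  total <- kl
  count <- matrix(1, nrow(kl), ncol(kl))
  add <- function(m) {
    if (is.null(m)) return(invisible(NULL))
    sub <- rownames(m)
    if (!all(sub %in% ids)) {
      stop("similarity source indexes lncRNAs absent from the kernel",
           call. = FALSE)
    }
    total[sub, sub] <<- total[sub, sub] + m[sub, sub]
    count[match(sub, ids), match(sub, ids)] <<- count[match(sub, ids),
                                                      match(sub, ids)] + 1
    invisible(NULL)
  }
  add(fs)
  add(es)
  out <- total / count
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(kl)
  out
}
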