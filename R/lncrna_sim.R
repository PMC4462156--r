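#' Similarity between one disease and a disease group
#'
#' The best-match score of disease `d` against a group of diseases: the
#' maximum semantic similarity between `d` and any group member.
#'
#' @param d A disease term id indexed in `SS`.
#' @param group Non-empty character vector of term ids indexed in `SS`.
#' @param SS Disease semantic similarity matrix (see [disease_similarity()]).
#' @return A single similarity value in \[0, 1\].
#' @export
group_similarity <- function(d, group, SS) {
  if (length(group) == 0L) stop("empty disease group", call. = FALSE)
  if (!d %in% rownames(SS) || !all(group %in% colnames(SS))) {
    stop("disease id(s) missing from the similarity matrix", call. = FALSE)
  }
  max(SS[d, group])
}

#' Functional similarity between two lncRNAs
#'
#' Best-match average over the two associated disease groups: every disease
#' in each group takes its maximum similarity against the other group, and
#' the total is normalized by the combined group size. Equal groups score 1;
#' groups from disjoint parts of the vocabulary score 0.
#'
#' @param gu,gv Non-empty character vectors of disease term ids (the disease
#'   groups of the two lncRNAs).
#' @param SS Disease semantic similarity matrix.
#' @return Functional similarity in \[0, 1\].
#' @export
functional_similarity <- function(gu, gv, SS) {
  if (length(gu) == 0L || length(gv) == 0L) {
    stop("empty disease group", call. = FALSE)
  }
  suv <- SS[gu, gv, drop = FALSE]
  (sum(apply(suv, 1L, max)) + sum(apply(suv, 2L, max))) /
    (length(gu) + length(gv))
}

#' LncRNA functional similarity matrix
#'
#' Applies [functional_similarity()] to every pair of lncRNAs in an
#' association table. LncRNAs with no associated disease cannot be scored by
#' this construction and are excluded from the output (with a message); the
#' Gaussian interaction-profile kernel still covers them downstream.
#'
#' @param assoc An [association_table()].
#' @param SS Disease similarity matrix covering all of `assoc`'s diseases.
#' @return Symmetric matrix with unit diagonal over the lncRNAs that have at
#'   least one association.
#' @export
functional_similarity_matrix <- function(assoc, SS) {
  stopifnot(inherits(assoc, "association_table"))
  if (!all(assoc$disease_ids %in% rownames(SS))) {
    stop("similarity matrix does not cover all diseases in the table",
         call. = FALSE)
  }
  A <- assoc$matrix
  groups <- apply(A, 1L, function(r) colnames(A)[r > 0], simplify = FALSE)
  keep <- lengths(groups) > 0L
  if (any(!keep)) {
    message("excluding ", sum(!keep), " lncRNA(s) without associations: ",
            paste(names(groups)[!keep], collapse = ", "))
  }
  groups <- groups[keep]
  ids <- names(groups)
  n <- length(ids)
  if (n == 0L) stop("no lncRNA has any association", call. = FALSE)
  FS <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(FS) <- 1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        FS[i, j] <- FS[j, i] <-
          functional_similarity(groups[[i]], groups[[j]], SS)
      }
    }
  }
  FS
}

#' Combine two functional similarity matrices
#'
#' Element-wise mean, maximum, or minimum of the similarities produced by the
#' two semantic models, preserving symmetry and the unit diagonal.
#'
#' @param fs1,fs2 Similarity matrices with identical dimnames.
#' @param mode One of `"mean"`, `"max"`, `"min"`.
#' @return Combined similarity matrix.
#' @export
combine_similarity <- function(fs1, fs2, mode = c("mean", "max", "min")) {
  mode <- match.arg(mode)
  if (!identical(dimnames(fs1), dimnames(fs2))) {
    stop("similarity matrices have different identifier indices",
         call. = FALSE)
  }
  switch(mode,
         mean = (fs1 + fs2) / 2,
         max  = pmax(fs1, fs2),
         min  = pmin(fs1, fs2))
}

#' Threshold a similarity matrix into a functional network
#'
#' Connects every pair of distinct lncRNAs whose similarity is greater than
#' or equal to the cutoff. All lncRNAs in the matrix appear as nodes, so
#' isolated nodes (degree 0) are retained.
#'
#' @param fs Symmetric similarity matrix.
#' @param cutoff Edge threshold in \[0, 1\]; default 0.3, a permissive value
#'   reflecting how incomplete curated association sets are.
#' @return Object of class `functional_network`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `weight`) and `cutoff`.
#' @export
build_network <- function(fs, cutoff = 0.3) {
  stopifnot(is.matrix(fs), nrow(fs) == ncol(fs))
  ids <- rownames(fs)
  idx <- which(upper.tri(fs) & fs >= cutoff, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      weight = fs[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges, cutoff = cutoff),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat("functional_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges at cutoff", x$cutoff, "\n")
  invisible(x)
}

#' Node degrees of a functional network
#' @param net A [build_network()] result.
#' @return Named integer vector over all nodes (isolated nodes get 0).
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Write a network in SIF format
#'
#' One line per edge: `id1 sim id2`. Isolated nodes are emitted as a single
#' bare identifier line so downstream viewers keep them.
#'
#' @param net A [build_network()] result.
#' @param path Output file path.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "functional_network"))
  lines <- sprintf("%s\tsim\t%s", net$edges$from, net$edges$to)
  isolated <- setdiff(net$nodes, unique(c(net$edges$from, net$edges$to)))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Write a network as a weighted edge list
#'
#' Tab-separated `id1 id2 weight` with a header row.
#'
#' @param net A [build_network()] result.
#' @param path Output file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "functional_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
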