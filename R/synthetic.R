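# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's global RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniform-variate generator on a private stream; each call to the returned
# function advances the stream without touching the global RNG.
local_rng <- function(seed) {
  state <- with_seed(seed, {
    stats::runif(1)
    get(".Random.seed", envir = globalenv())
  })
  function(n) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv())
    assign(".Random.seed", state, envir = globalenv())
    x <- stats::runif(n)
    state <<- get(".Random.seed", envir = globalenv())
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    x
  }
}

#' Simulation configuration
#'
#' Study conditions for the synthetic generators: a complete `branching`-ary
#' disease hierarchy of the given depth, lncRNAs partitioned into clusters
#' that draw their diseases from disjoint subtrees, symmetric bit-flip noise
#' on the association matrix, and cluster-structured expression profiles.
#'
#' The defaults describe the package's reference simulation: a depth-3
#' ternary hierarchy (40 terms), 40 lncRNAs in 4 clusters with 3
#' associations each, and a 5% per-cell flip rate — a noise level at which
#' spurious associations are a substantial minority of the curated set,
#' mirroring how incomplete and noisy curated association databases are.
#'
#' @param depth Tree depth (root at depth 0), at least 1.
#' @param branching Children per internal node, at least 1.
#' @param n_lncrna Number of lncRNAs.
#' @param n_clusters Number of functional clusters.
#' @param assoc_per_lncrna True associations drawn per lncRNA.
#' @param noise_rate Per-cell bit-flip probability in \[0, 1\]; also the
#'   standard deviation of the expression noise.
#' @param n_samples Number of expression samples.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(depth = 3L, branching = 3L, n_lncrna = 40L,
                       n_clusters = 4L, assoc_per_lncrna = 3L,
                       noise_rate = 0.05, n_samples = 20L, seed = 1L) {
  stopifnot(depth >= 1, branching >= 1, n_lncrna >= 1, n_clusters >= 1,
            assoc_per_lncrna >= 1, noise_rate >= 0, noise_rate <= 1,
            n_samples >= 3, is.numeric(seed))
  structure(list(depth = as.integer(depth), branching = as.integer(branching),
                 n_lncrna = as.integer(n_lncrna),
                 n_clusters = as.integer(n_clusters),
                 assoc_per_lncrna = as.integer(assoc_per_lncrna),
                 noise_rate = noise_rate, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a disease ontology
#'
#' Builds a complete `branching`-ary tree of tree-number codes rooted at
#' `"C"` (`"C"`, `"C.1"`, `"C.1.2"`, ...); term ids equal the codes. The
#' construction is deterministic, so the same configuration always yields a
#' byte-identical ontology.
#'
#' @param cfg A [sim_config()].
#' @return A [disease_ontology()] with `(b^(d+1) - 1) / (b - 1)` terms.
#' @export
simulate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  codes <- "C"
  level <- "C"
  for (d in seq_len(cfg$depth)) {
    level <- as.vector(t(outer(level, seq_len(cfg$branching), paste, sep = ".")))
    codes <- c(codes, level)
  }
  disease_ontology(data.frame(term_id = codes,
                              name = paste("disease", codes),
                              tree_numbers = codes,
                              stringsAsFactors = FALSE))
}

# Codes of the subtree rooted at `code`, root included.
subtree_codes <- function(ontology, code) {
  all_codes <- names(ontology$code2term)
  all_codes[all_codes == code | startsWith(all_codes, paste0(code, "."))]
}

#' Simulate a clustered lncRNA-disease association table
#'
#' LncRNAs are partitioned into `n_clusters` groups; each group draws its
#' diseases from one of `n_clusters` disjoint subtrees of the ontology
#' (rooted at the shallowest level wide enough, picked evenly across the
#' level). Each lncRNA receives `assoc_per_lncrna` distinct diseases from
#' its subtree, then every cell of the matrix is flipped independently with
#' probability `noise_rate` — producing both spurious and missing
#' associations. The table's disease columns are the union of the cluster
#' subtrees, i.e. the diseases actually drawn into the study.
#'
#' @param ontology A [simulate_ontology()] result (or compatible ontology).
#' @param cfg A [sim_config()].
#' @return An [association_table()] with attributes `cluster` (named integer
#'   vector, lncRNA to cluster) and `cluster_diseases` (list of term-id
#'   vectors per cluster).
#' @export
simulate_associations <- function(ontology, cfg) {
  stopifnot(inherits(ontology, "disease_ontology"), inherits(cfg, "sim_config"))
  # shallowest level with at least n_clusters nodes
  lev <- NULL
  for (d in seq_len(cfg$depth)) {
    if (cfg$branching^d >= cfg$n_clusters) { lev <- d; break }
  }
  if (is.null(lev)) {
    stop("ontology too shallow for ", cfg$n_clusters, " disjoint subtrees",
         call. = FALSE)
  }
  level_codes <- names(ontology$code2term)
  level_codes <- level_codes[lengths(gregexpr(".", level_codes,
                                              fixed = TRUE)) == lev &
                               grepl(".", level_codes, fixed = TRUE)]
  level_codes <- sort(level_codes)
  pick <- round(seq(1L, length(level_codes), length.out = cfg$n_clusters))
  roots <- level_codes[pick]
  cluster_diseases <- lapply(roots, function(r)
    unname(ontology$code2term[subtree_codes(ontology, r)]))
  small <- lengths(cluster_diseases) < cfg$assoc_per_lncrna
  if (any(small)) {
    stop("cluster subtree smaller than assoc_per_lncrna; reduce ",
         "`assoc_per_lncrna` or deepen the ontology", call. = FALSE)
  }
  cluster <- stats::setNames(
    sort(rep(seq_len(cfg$n_clusters), length.out = cfg$n_lncrna)),
    sprintf("lnc%03d", seq_len(cfg$n_lncrna)))
  diseases <- sort(unique(unlist(cluster_diseases)))
  A <- matrix(0, cfg$n_lncrna, length(diseases),
              dimnames = list(names(cluster), diseases))
  with_seed(cfg$seed, {
    for (l in names(cluster)) {
      pool <- cluster_diseases[[cluster[[l]]]]
      A[l, sample(pool, cfg$assoc_per_lncrna)] <- 1
    }
    if (cfg$noise_rate > 0) {
      flip <- matrix(stats::runif(length(A)) < cfg$noise_rate, nrow(A))
      A[flip] <- 1 - A[flip]
    }
  })
  out <- association_table(A)
  attr(out, "cluster") <- cluster
  attr(out, "cluster_diseases") <- cluster_diseases
  out
}

#' Simulate cluster-structured expression profiles
#'
#' Each cluster gets a latent mean profile drawn from a standard normal per
#' sample; each lncRNA's profile is its cluster mean plus independent
#' Gaussian noise with standard deviation `noise_rate`. With zero noise,
#' profiles within a cluster are identical; as noise grows, within-cluster
#' rank correlation decays toward the between-cluster level.
#'
#' @param assoc A [simulate_associations()] result (its `cluster` attribute
#'   supplies the partition).
#' @param cfg A [sim_config()].
#' @return Numeric matrix, rows lncRNAs, columns samples.
#' @export
simulate_expression <- function(assoc, cfg) {
  stopifnot(inherits(assoc, "association_table"), inherits(cfg, "sim_config"))
  cluster <- attr(assoc, "cluster")
  if (is.null(cluster)) {
    stop("`assoc` carries no cluster attribute; generate it with ",
         "simulate_associations()", call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    means <- matrix(stats::rnorm(cfg$n_clusters * cfg$n_samples),
                    cfg$n_clusters, cfg$n_samples)
    expr <- means[cluster, , drop = FALSE] +
      matrix(stats::rnorm(length(cluster) * cfg$n_samples,
                          sd = cfg$noise_rate),
             length(cluster), cfg$n_samples)
    dimnames(expr) <- list(names(cluster),
                           sprintf("sample%02d", seq_len(cfg$n_samples)))
    expr
  })
}
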