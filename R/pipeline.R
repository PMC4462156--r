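#' Assemble a pipeline run configuration
#'
#' Collects paths and parameters for [run_pipeline()]. Values may come from a
#' YAML file (`config_file`), with explicit arguments taking precedence over
#' the file, and the file over the defaults.
#'
#' @param ... Named overrides of the defaults below.
#' @param config_file Optional YAML file of overrides.
#' @return A list of class `run_config`.
#' @details Recognized fields: `ontology`, `associations`, `expression`
#'   (input paths; `expression` optional), `model` (1 or 2), `delta`,
#'   `gamma_prime`, `eta_l`, `eta_d`, `w`, `jitter`, `cutoff`,
#'   `combine` (`"none"`, `"mean"`, `"max"`, `"min"`), `scope`,
#'   `refit_kernels`, `shrink_groups`, `seed`, `out` (output directory), plus
#'   the [sim_config()] fields (`depth`, `branching`, `n_lncrna`,
#'   `n_clusters`, `assoc_per_lncrna`, `noise_rate`, `n_samples`) used by the
#'   `simulate` command.
#' @export
run_config <- function(..., config_file = NULL) {
  defaults <- list(ontology = NULL, associations = NULL, expression = NULL,
                   model = 1, delta = 0.5, gamma_prime = 1,
                   eta_l = 1, eta_d = 1, w = 0.5, jitter = 1e-8,
                   cutoff = 0.3, combine = "none", scope = "global",
                   refit_kernels = TRUE, shrink_groups = TRUE,
                   seed = 1L, out = ".",
                   depth = 3L, branching = 3L, n_lncrna = 40L,
                   n_clusters = 4L, assoc_per_lncrna = 3L,
                   noise_rate = 0.05, n_samples = 20L)
  cfg <- defaults
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  if (!cfg$model %in% c(1, 2)) stop("`model` must be 1 or 2", call. = FALSE)
  structure(cfg, class = "run_config")
}

pipeline_inputs <- function(cfg) {
  for (field in c("ontology", "associations")) {
    if (is.null(cfg[[field]])) {
      stop("configuration field `", field, "` (input path) is required",
           call. = FALSE)
    }
    if (!file.exists(cfg[[field]])) {
      stop("input file not found: ", cfg[[field]], call. = FALSE)
    }
  }
  list(ontology = parse_descriptor_table(cfg$ontology),
       assoc = read_association_tsv(cfg$associations),
       expr = if (!is.null(cfg$expression)) {
         if (!file.exists(cfg$expression)) {
           stop("input file not found: ", cfg$expression, call. = FALSE)
         }
         read_matrix_tsv(cfg$expression)
       })
}

write_manifest <- function(cfg, command, outputs) {
  inputs <- Filter(Negate(is.null),
                   cfg[c("ontology", "associations", "expression")])
  checksums <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(unlist(inputs)))
  } else list()
  manifest <- list(command = command,
                   package_version = as.character(utils::packageVersion("lncsim")),
                   parameters = unclass(cfg)[setdiff(names(cfg),
                                                     c("ontology", "associations",
                                                       "expression", "out"))],
                   input_checksums = checksums,
                   outputs = outputs)
  path <- file.path(cfg$out, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

pipeline_fs <- function(cfg, inputs) {
  SS <- disease_similarity(inputs$ontology, inputs$assoc$disease_ids,
                           model = cfg$model, delta = cfg$delta)
  if (cfg$combine == "none") {
    list(SS = SS,
         FS = suppressMessages(functional_similarity_matrix(inputs$assoc, SS)))
  } else {
    SS2 <- disease_similarity(inputs$ontology, inputs$assoc$disease_ids,
                              model = if (cfg$model == 1) 2 else 1,
                              delta = cfg$delta)
    fs_a <- suppressMessages(functional_similarity_matrix(inputs$assoc, SS))
    fs_b <- suppressMessages(functional_similarity_matrix(inputs$assoc, SS2))
    list(SS = SS, FS = combine_similarity(fs_a, fs_b, cfg$combine))
  }
}

#' Run one stage of the analysis pipeline
#'
#' Dispatches a named subcommand over a [run_config()], writes the stage's
#' output files under `cfg$out`, and records a JSON manifest (parameters,
#' seed, input checksums, package version) alongside them.
#'
#' Subcommands: `"simulate"` (write synthetic ontology/associations/
#' expression), `"disease-sim"` (disease semantic similarity matrix),
#' `"lncrna-sim"` (functional similarity matrix), `"network"` (thresholded
#' functional network as SIF and edge list), `"predict"` (score matrix and
#' ranked candidate pairs), `"loocv"` (per-fold ranks, ROC points and an AUC
#' summary).
#'
#' @param cfg A [run_config()].
#' @param command Subcommand name.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(cfg, command) {
  stopifnot(inherits(cfg, "run_config"))
  commands <- c("simulate", "disease-sim", "lncrna-sim", "network",
                "predict", "loocv")
  if (!command %in% commands) {
    stop("unknown subcommand `", command, "`; expected one of: ",
         paste(commands, collapse = ", "), call. = FALSE)
  }
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) file.path(cfg$out, name)
  outputs <- character(0)

  if (command == "simulate") {
    scfg <- sim_config(depth = cfg$depth, branching = cfg$branching,
                       n_lncrna = cfg$n_lncrna, n_clusters = cfg$n_clusters,
                       assoc_per_lncrna = cfg$assoc_per_lncrna,
                       noise_rate = cfg$noise_rate, n_samples = cfg$n_samples,
                       seed = cfg$seed)
    onto <- simulate_ontology(scfg)
    assoc <- simulate_associations(onto, scfg)
    expr <- simulate_expression(assoc, scfg)
    outputs <- c(write_descriptor_table(onto, outfile("ontology.tsv")),
                 write_association_tsv(assoc, outfile("associations.tsv")),
                 write_matrix_tsv(expr, outfile("expression.tsv")))
  } else {
    inputs <- pipeline_inputs(cfg)
    params <- lrls_params(eta_l = cfg$eta_l, eta_d = cfg$eta_d, w = cfg$w,
                          jitter = cfg$jitter)
    if (command == "disease-sim") {
      SS <- disease_similarity(inputs$ontology, inputs$assoc$disease_ids,
                               model = cfg$model, delta = cfg$delta)
      outputs <- write_matrix_tsv(SS, outfile("disease_similarity.tsv"))
    } else if (command == "lncrna-sim") {
      fs <- pipeline_fs(cfg, inputs)
      outputs <- write_matrix_tsv(fs$FS, outfile("functional_similarity.tsv"))
    } else if (command == "network") {
      fs <- pipeline_fs(cfg, inputs)
      net <- build_network(fs$FS, cutoff = cfg$cutoff)
      outputs <- c(write_sif(net, outfile("network.sif")),
                   write_edge_list(net, outfile("network_edges.tsv")))
    } else if (command == "predict") {
      fs <- pipeline_fs(cfg, inputs)
      kl <- gaussian_kernel(inputs$assoc, "lncrna", cfg$gamma_prime)
      kd <- gaussian_kernel(inputs$assoc, "disease", cfg$gamma_prime)
      es <- if (!is.null(inputs$expr)) expression_similarity(inputs$expr)
      sl <- integrate_lncrna_similarity(fs$FS, kl, es)
      sd <- integrate_disease_similarity(
        fs$SS[inputs$assoc$disease_ids, inputs$assoc$disease_ids], kd)
      scores <- lrls_predict(inputs$assoc, sl, sd, params)
      ranked <- rank_candidates(scores, inputs$assoc, scope = "per-disease")
      outputs <- c(write_matrix_tsv(scores, outfile("scores.tsv")),
                   outfile("ranked_pairs.tsv"))
      utils::write.table(ranked, outfile("ranked_pairs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else if (command == "loocv") {
      fs <- pipeline_fs(cfg, inputs)
      res <- loocv(inputs$assoc, disease_ss = fs$SS,
                   expression = inputs$expr, gamma_prime = cfg$gamma_prime,
                   params = params, scope = cfg$scope,
                   refit_kernels = cfg$refit_kernels,
                   shrink_groups = cfg$shrink_groups, seed = cfg$seed)
      utils::write.table(res$folds, outfile("loocv_folds.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(res$roc_points, outfile("loocv_roc.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(paste0("AUC\t", format(res$auc, digits = 15)),
                 outfile("loocv_summary.tsv"))
      outputs <- outfile(c("loocv_folds.tsv", "loocv_roc.tsv",
                           "loocv_summary.tsv"))
    }
  }
  write_manifest(cfg, command, basename(outputs))
  invisible(outputs)
}
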