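#' Read and validate a pipeline configuration
#'
#' YAML with the sections below; unknown keys anywhere are rejected so typos
#' cannot silently disable a setting.
#'
#' ```yaml
#' inputs:
#'   species_tree: tree.nwk        # newick, time-calibrated
#'   gene_trees: genes.nwk         # OR gene_matrix: genes.tsv
#'   trait_table: traits.tsv
#'   trait_types: {litter_size: continuous, seasonal_breeding: binary}
#' decomposition: {pseudocount: 1.0e-9, fill: zero, min_coverage: 0.8}
#' model: {folds: 10, seed: 1, one_se: false, traits: [litter_size]}
#' network: {traits: [litter_size, seasonal_breeding], provenance: [...]}
#' coevolution: {pair: [traitA, traitB], mode: ml, iterations: 10000,
#'               restarts: 3, prior_mean: 1.0}
#' output_dir: results
#' ```
#'
#' @param path YAML file, or a list already in this shape.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  .check_keys(cfg, c("inputs", "decomposition", "model", "network",
                     "coevolution", "output_dir"), "top level")
  if (is.null(cfg$inputs)) .stopf("config needs an 'inputs' section")
  .check_keys(cfg$inputs, c("species_tree", "gene_trees", "gene_matrix",
                            "trait_table", "trait_types"), "inputs")
  .check_keys(cfg$decomposition, c("pseudocount", "fill", "min_coverage", "method"),
              "decomposition")
  .check_keys(cfg$model, c("folds", "seed", "one_se", "traits"), "model")
  .check_keys(cfg$network, c("traits", "provenance"), "network")
  .check_keys(cfg$coevolution, c("pair", "mode", "iterations", "restarts",
                                 "prior_mean", "seed"), "coevolution")
  if (is.null(cfg$inputs$species_tree)) .stopf("inputs.species_tree is required")
  if (is.null(cfg$inputs$gene_trees) && is.null(cfg$inputs$gene_matrix))
    .stopf("one of inputs.gene_trees or inputs.gene_matrix is required")
  if (is.null(cfg$inputs$trait_table)) .stopf("inputs.trait_table is required")
  structure(cfg, class = c("pipeline_config", "list"))
}

.check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    .stopf("unknown config key(s) in %s: %s", where, paste(unknown, collapse = ", "))
  invisible()
}

#' Run the full rate-based trait-evolution pipeline
#'
#' Stages, in order: load inputs; decompose branch lengths into branch,
#' gene and interaction effects; build standardized interaction features;
#' fit a LASSO model per requested trait, impute missing terminal values and
#' predict ancestral branch states; compute the partial-correlation /
#' minimum-BIC trait network over terminal + ancestral rows; optionally fit
#' the correlated-evolution model for a named trait pair. Every stage writes
#' its outputs as TSV/JSON under `output_dir`, a failure halts with a
#' stage-named error, and a `run_info.yaml` (resolved config, package
#' version, seeds, md5 of every artifact) plus `pipeline.log` make the run
#' reproducible.
#'
#' @param config a [read_pipeline_config()] result, a path to one, or a list.
#' @param output_dir overrides `config$output_dir`.
#' @return (invisibly) a list with the in-memory stage results and
#'   `output_dir`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  out <- output_dir %||% cfg$output_dir %||% "ratetrait_results"
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  cat(sprintf("# ratetrait %s pipeline run, %s\n",
              as.character(utils::packageVersion("ratetrait")),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)
  log_stage <- function(stage, files) {
    hashes <- tools::md5sum(files[file.exists(files)])
    cat(sprintf("%s\t%s\n", stage,
                paste(sprintf("%s=%s", basename(names(hashes)), hashes), collapse = " ")),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # -- stage: load ---------------------------------------------------------
  inputs <- stage("load", {
    for (f in c(cfg$inputs$species_tree, cfg$inputs$gene_trees,
                cfg$inputs$gene_matrix, cfg$inputs$trait_table)) {
      if (!file.exists(f)) .stopf("input file not found: %s", f)
    }
    tree <- read_species_tree(cfg$inputs$species_tree, time_calibrated = TRUE)
    mincov <- cfg$decomposition$min_coverage %||% 0.8
    M <- if (!is.null(cfg$inputs$gene_matrix))
      read_gene_branch_matrix(cfg$inputs$gene_matrix, tree, min_coverage = mincov)
    else read_gene_trees(cfg$inputs$gene_trees, tree, min_coverage = mincov)
    types <- unlist(cfg$inputs$trait_types) %||% NULL
    traits <- read_trait_table(cfg$inputs$trait_table, types = types)
    list(tree = tree, M = M, traits = traits)
  })
  log_stage("load", c(cfg$inputs$species_tree, cfg$inputs$gene_trees %||% character(0),
                      cfg$inputs$gene_matrix %||% character(0), cfg$inputs$trait_table))

  # -- stage: decompose ----------------------------------------------------
  decomp <- stage("decompose", {
    d <- decompose_rates(inputs$M,
                         pseudocount = cfg$decomposition$pseudocount %||% 1e-9,
                         method = cfg$decomposition$method %||% "ls")
    write_matrix(rbind(branch_effect = d$branch_effect), file.path(out, "branch_effects.tsv"))
    write_matrix(cbind(gene_effect = d$gene_effect), file.path(out, "gene_effects.tsv"))
    write_matrix(d$interaction, file.path(out, "interactions.tsv"))
    d
  })
  log_stage("decompose", file.path(out, c("branch_effects.tsv", "gene_effects.tsv",
                                          "interactions.tsv")))

  # -- stage: features -----------------------------------------------------
  term <- intersect(terminal_branches(inputs$tree), rownames(inputs$traits$values))
  feats <- stage("features", {
    interaction_features(decomp, fit_branches = term,
                         fill = cfg$decomposition$fill %||% "zero")
  })

  # -- stage: fit + predict + impute --------------------------------------
  model_traits <- unlist(cfg$model$traits) %||% names(inputs$traits$values)
  seed <- cfg$model$seed %||% 1L
  fit_res <- stage("fit", {
    traits_aug <- inputs$traits
    models <- list()
    for (tr in model_traits) {
      m <- fit_trait_model(feats, inputs$traits, tr,
                           nfolds = cfg$model$folds %||% 10L,
                           seed = seed, use_1se = isTRUE(cfg$model$one_se))
      models[[tr]] <- m
      write_trait_model(m, file.path(out, sprintf("model_%s.json", tr)))
      traits_aug <- impute_missing_terminals(m, feats, traits_aug)
      anc <- predict_branches(m, feats, internal_branches(inputs$tree))
      write.table(anc, file.path(out, sprintf("ancestral_%s.tsv", tr)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      traits_aug <- add_ancestral_rows(traits_aug, anc)
      sel <- selected_genes(m)
      write.table(sel, file.path(out, sprintf("selected_genes_%s.tsv", tr)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_trait_table(traits_aug, file.path(out, "traits_augmented.tsv"))
    list(models = models, traits_aug = traits_aug)
  })
  log_stage("fit", file.path(out, c(sprintf("model_%s.json", model_traits),
                                    sprintf("ancestral_%s.tsv", model_traits),
                                    sprintf("selected_genes_%s.tsv", model_traits),
                                    "traits_augmented.tsv")))

  # -- stage: network ------------------------------------------------------
  net_traits <- unlist(cfg$network$traits) %||% names(inputs$traits$values)
  network <- NULL
  if (length(net_traits) >= 2L) {
    network <- stage("network", {
      g <- min_bic_forest(fit_res$traits_aug, net_traits,
                          provenance = unlist(cfg$network$provenance) %||%
                            c("observed", "imputed", "predicted-ancestral"))
      write_trait_graph(g, file.path(out, "trait_network.tsv"), "tsv")
      write_trait_graph(g, file.path(out, "trait_network.dot"), "dot")
      g
    })
    log_stage("network", file.path(out, c("trait_network.tsv", "trait_network.dot")))
  }

  # -- stage: coevolve -----------------------------------------------------
  coevolution <- NULL
  if (!is.null(cfg$coevolution$pair)) {
    coevolution <- stage("coevolve", {
      pair <- unlist(cfg$coevolution$pair)
      tipdat <- as.matrix(inputs$traits$values[, pair, drop = FALSE])
      mode <- cfg$coevolution$mode %||% "ml"
      cseed <- cfg$coevolution$seed %||% seed
      fit <- lrt_correlated_evolution(inputs$tree, tipdat,
                                      restarts = cfg$coevolution$restarts %||% 3L,
                                      seed = cseed)
      trace <- NULL
      if (identical(mode, "mcmc")) {
        trace <- run_mcmc(inputs$tree, tipdat, "dependent",
                          prior_mean = cfg$coevolution$prior_mean %||% 1,
                          iterations = cfg$coevolution$iterations %||% 10000L,
                          seed = cseed)
        write.table(cbind(iteration = seq_len(trace$iterations), trace$samples,
                          log_likelihood = trace$log_likelihood),
                    file.path(out, "coevolution_trace.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      report <- transition_rate_report(fit$dependent, trace)
      write.table(report, file.path(out, "coevolution_rates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(lrt = fit, trace = trace, report = report)
    })
    log_stage("coevolve", file.path(out, c("coevolution_rates.tsv",
                                           "coevolution_trace.tsv")))
  }

  # -- reproducibility stamp ----------------------------------------------
  info <- list(package = "ratetrait",
               version = as.character(utils::packageVersion("ratetrait")),
               seed = seed,
               rng = "Mersenne-Twister",
               config = unclass(cfg))
  yaml::write_yaml(info, file.path(out, "run_info.yaml"))

  invisible(list(tree = inputs$tree, matrix = inputs$M,
                 decomposition = decomp, features = feats,
                 models = fit_res$models, traits = fit_res$traits_aug,
                 network = network, coevolution = coevolution,
                 output_dir = out))
}
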