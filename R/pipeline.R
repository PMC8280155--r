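# Allowed keys per run-config section; validation lists offenders by name.
run_config_schema <- function() {
  list(
    seed = NULL,
    stages = NULL,
    screen = c("signatures", "meta", "network", "target", "simulate",
               "mixing_weight", "n_decoy_compounds", "n_partner_genes",
               "n_replicates", "replicate_fidelity",
               "support_threshold", "min_support", "lambda_indirect"),
    panel = c("signatures", "meta", "panel_genes", "perturbations",
              "candidates", "suppression_threshold", "consensus_method"),
    de = c("table_a", "table_b", "simulate", "n_genes", "n_up_shared",
           "n_down_shared", "n_discordant", "n_specific_a", "n_specific_b",
           "fold_threshold", "fdr_threshold", "biotype_filter"),
    gsea = c("ranked", "gmt", "simulate", "n_genes", "planted_set_size",
             "top_fraction", "placement", "n_permutations", "min_size",
             "max_size", "weight_exponent")
  )
}

#' Validate a pipeline run configuration
#'
#' A run config is a named list (typically read from YAML or JSON) with a
#' `seed`, a `stages` character vector (any of `"screen"`, `"panel"`, `"de"`,
#' `"gsea"`), and one parameter block per selected stage. Unknown keys and
#' missing input paths are reported by name.
#'
#' @param config A named list, or a path to a YAML/JSON config file.
#' @return The validated config list, invisibly classed `run_config`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("Config file not found: '%s'.", config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("`config` must be a named list or a config file path.")
  schema <- run_config_schema()
  unknown_top <- setdiff(names(config), names(schema))
  if (length(unknown_top)) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown_top, collapse = ", ")))
  }
  if (is.null(config$seed)) abort("Config must set `seed`.")
  if (is.null(config$stages) || !length(config$stages)) {
    abort("Config must select at least one stage in `stages`.")
  }
  bad_stage <- setdiff(config$stages, c("screen", "panel", "de", "gsea"))
  if (length(bad_stage)) {
    abort(sprintf("Unknown stage(s): %s.", paste(bad_stage, collapse = ", ")))
  }
  for (stage in config$stages) {
    block <- config[[stage]] %||% list()
    unknown <- setdiff(names(block), schema[[stage]])
    if (length(unknown)) {
      abort(sprintf("Unknown key(s) in `%s` block: %s.", stage,
                    paste(unknown, collapse = ", ")))
    }
    paths <- intersect(names(block),
                       c("signatures", "meta", "network", "table_a", "table_b",
                         "ranked", "gmt"))
    for (p in paths) {
      if (!file.exists(block[[p]])) {
        abort(sprintf("Input path for `%s$%s` does not exist: '%s'.",
                      stage, p, block[[p]]))
      }
    }
  }
  invisible(structure(config, class = c("run_config", "list")))
}

#' A small self-contained demonstration configuration
#'
#' Simulates a screen, a DE-table pair and a ranked list, then runs the
#' screening, DE-signature and enrichment stages end to end in well under a
#' minute. Sizes are scaled down from the defaults purely for speed.
#'
#' @param seed Integer seed propagated to every stage.
#' @return A validated `run_config`.
#' @export
demo_run_config <- function(seed = 17L) {
  validate_run_config(list(
    seed = as.integer(seed),
    stages = c("screen", "panel", "de", "gsea"),
    screen = list(simulate = TRUE, mixing_weight = 0.7,
                  n_decoy_compounds = 30L, n_replicates = 1L,
                  replicate_fidelity = 1,
                  support_threshold = 0.3, min_support = 4L),
    panel = list(signatures = system.file("extdata", "table1_consensus_z.tsv",
                                          package = "foxnet"),
                 candidates = c("STL427944", "benzamil"),
                 suppression_threshold = -1),
    de = list(simulate = TRUE, n_genes = 4000L, n_up_shared = 120L,
              n_down_shared = 150L, n_discordant = 20L),
    gsea = list(simulate = TRUE, n_genes = 1500L, planted_set_size = 30L,
                top_fraction = 0.1, placement = "bottom",
                n_permutations = 200L)
  ))
}

#' Run the pipeline described by a configuration
#'
#' Executes the selected stages in order (screen, panel, de, gsea), seeding
#' every stochastic step from `config$seed`, and assembles a machine-readable
#' run report. Rerunning the same config reproduces the report exactly except
#' for its timestamp.
#'
#' @param config A config list or file path accepted by
#'   [validate_run_config()].
#' @param out_dir Optional directory; when given, the report is written there
#'   as `report.json` alongside stage outputs (ranking TSV, DE signature,
#'   GSEA TSV).
#' @return A list of class `run_report`: `parameters`, per-stage `results`,
#'   `software` and `timestamp`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_run_config(config)
  seed <- as.integer(config$seed)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  if ("screen" %in% config$stages) {
    blk <- config$screen %||% list()
    if (isTRUE(blk$simulate)) {
      sim <- simulate_screen(screen_sim_config(
        mixing_weight = blk$mixing_weight %||% 0.7,
        n_decoy_compounds = blk$n_decoy_compounds %||% 49L,
        n_partner_genes = blk$n_partner_genes %||% 5L,
        n_replicates = blk$n_replicates %||% 3L,
        replicate_fidelity = blk$replicate_fidelity %||% 0.8,
        seed = seed
      ))
      collection <- sim$collection; network <- sim$network
      truth <- sim$truth["planted_compound"]
    } else {
      collection <- read_signatures(blk$signatures, blk$meta)
      network <- read_network(blk$network, blk$target)
      truth <- NULL
    }
    kd <- subset_collection(collection, collection$meta$perturbation_type == "knockdown")
    cmp <- subset_collection(collection, collection$meta$perturbation_type == "compound")
    feats <- build_screen_features(cmp, kd, network,
                                   support_threshold = blk$support_threshold %||% 0.3)
    ranking <- rank_candidates(feats,
                               lambda_indirect = blk$lambda_indirect %||% 0.5,
                               min_support = blk$min_support %||% 4L,
                               seed = seed)
    if (!is.null(out_dir)) {
      readr::write_tsv(ranking, file.path(out_dir, "ranking.tsv"), progress = FALSE)
    }
    results$screen <- list(
      n_compounds = length(unique(cmp$meta$perturbation_id)),
      ranking_head = head(as.data.frame(ranking[, c("rank", "compound_id",
                                                    "score", "support_count")]), 5),
      truth = truth
    )
    inform(sprintf("[screen] ranked %d compounds; top hit: %s",
                   nrow(ranking), ranking$compound_id[1]))
  }

  if ("panel" %in% config$stages) {
    blk <- config$panel %||% list()
    collection <- read_signatures(blk$signatures, blk$meta)
    panel <- blk$panel_genes %||% collection$gene_universe
    perts <- blk$perturbations %||% unique(collection$meta$perturbation_id)
    method <- blk$consensus_method %||% "weighted_modz"
    tab <- panel_consensus_table(collection, panel, perts,
                                 consensus_spec(method = method))
    cand <- blk$candidates %||% perts
    comparison <- compare_candidates(tab, cand,
                                     blk$suppression_threshold %||% -1)
    results$panel <- list(table = as.data.frame(tab),
                          comparison = as.data.frame(comparison))
    inform(sprintf("[panel] best candidate: %s (%d/%d panel genes suppressed)",
                   comparison$candidate[1], comparison$n_suppressed[1],
                   nrow(tab)))
  }

  if ("de" %in% config$stages) {
    blk <- config$de %||% list()
    if (isTRUE(blk$simulate)) {
      ng <- blk$n_genes %||% 16275L
      n_up <- blk$n_up_shared %||% 577L
      n_dn <- blk$n_down_shared %||% 687L
      n_dis <- blk$n_discordant %||% 77L
      # model-specific counts default to 250 each but never overflow the universe
      spec_default <- min(250L, max(0L, (ng - n_up - n_dn - n_dis) %/% 4L))
      sim <- simulate_de_tables(de_sim_config(
        n_genes = ng, n_up_shared = n_up, n_down_shared = n_dn,
        n_discordant = n_dis,
        n_specific_a = blk$n_specific_a %||% spec_default,
        n_specific_b = blk$n_specific_b %||% spec_default,
        seed = seed
      ))
      ta <- sim$table_a; tb <- sim$table_b
    } else {
      ta <- read_de_table(blk$table_a)
      tb <- read_de_table(blk$table_b)
    }
    sig <- codirectional_intersection(
      filter_de(ta, blk$fold_threshold %||% 2, blk$fdr_threshold %||% 0.1,
                blk$biotype_filter),
      filter_de(tb, blk$fold_threshold %||% 2, blk$fdr_threshold %||% 0.1,
                blk$biotype_filter)
    )
    if (!is.null(out_dir)) write_de_signature(sig, file.path(out_dir, "de_signature"))
    results$de <- list(venn = as.data.frame(glance(sig)))
    inform(sprintf("[de] combined signature: %d genes (%d up, %d down, %d discordant)",
                   length(sig$combined), length(sig$up_both),
                   length(sig$down_both), length(sig$discordant)))
  }

  if ("gsea" %in% config$stages) {
    blk <- config$gsea %||% list()
    if (isTRUE(blk$simulate)) {
      sim <- simulate_ranked_list(
        n_genes = blk$n_genes %||% 2000L,
        planted_set_size = blk$planted_set_size %||% 30L,
        top_fraction = blk$top_fraction %||% 0.1,
        placement = blk$placement %||% "top",
        seed = seed
      )
      ranked <- sim$ranked
      sets <- list(planted = sim$gene_set)
      # background null sets drawn reproducibly for an FDR denominator
      sets <- c(sets, with_seed_(seed + 1L, {
        setNames(lapply(1:19, function(i) sample(ranked$gene_id, 30)),
                 sprintf("null_%02d", 1:19))
      }))
    } else {
      ranked <- ranked_list(readr::read_tsv(blk$ranked, show_col_types = FALSE,
                                            progress = FALSE))
      sets <- read_gmt(blk$gmt)
    }
    res <- gsea_preranked(ranked, sets,
                          n_permutations = blk$n_permutations %||% 1000L,
                          min_size = blk$min_size %||% 15L,
                          max_size = blk$max_size %||% 500L,
                          seed = seed,
                          weight_exponent = blk$weight_exponent %||% 1)
    if (!is.null(out_dir)) {
      readr::write_tsv(select(res, -"leading_edge"),
                       file.path(out_dir, "gsea_results.tsv"), progress = FALSE)
    }
    results$gsea <- list(
      summary = as.data.frame(glance(res)),
      top = as.data.frame(head(select(res, -"leading_edge"), 5))
    )
    inform(sprintf("[gsea] %d/%d sets at FDR < 0.05",
                   sum(res$fdr_q < 0.05, na.rm = TRUE), nrow(res)))
  }

  report <- structure(
    list(parameters = unclass(config),
         results = results,
         software = list(package = "foxnet",
                         version = as.character(utils::packageVersion("foxnet"))),
         timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_report"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s, stages: %s\n", x$timestamp,
              paste(names(x$results), collapse = ", ")))
  invisible(x)
}

#' Subset a signature collection by a metadata predicate
#'
#' @param collection A [signature_collection()].
#' @param keep Logical vector over signatures (rows of `collection$meta`).
#' @return A [signature_collection()] with the selected signatures.
#' @export
subset_collection <- function(collection, keep) {
  stopifnot(inherits(collection, "signature_collection"))
  signature_collection(collection$values[, keep, drop = FALSE],
                       collection$meta[keep, , drop = FALSE])
}
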