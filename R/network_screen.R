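#' Define a protein-interaction neighborhood around a proxy target
#'
#' The screen compares compound signatures against knockdown of a proxy gene
#' (NPM1 standing in for FOXM1, whose knockdown is absent from LINCS) and,
#' by guilt-by-association, against knockdowns of the proxy's binding
#' partners: a compound that truly disrupts the subnetwork should correlate
#' with several of its members, not just one.
#'
#' @param proxy_target Gene symbol of the proxy knockdown (e.g. `"NPM1"`).
#' @param partners Character vector of partner gene symbols; must not contain
#'   the proxy target.
#' @return A `network_neighborhood` list.
#' @export
network_neighborhood <- function(proxy_target, partners = character()) {
  stopifnot(is.character(proxy_target), length(proxy_target) == 1L)
  partners <- unique(as.character(partners))
  if (proxy_target %in% partners) {
    abort("`proxy_target` must not appear among `partners`.")
  }
  structure(list(proxy_target = proxy_target, partners = partners),
            class = "network_neighborhood")
}

#' Read a network neighborhood from a two-column edge list
#'
#' @param path TSV with two columns (`gene_a`, `gene_b`), one undirected edge
#'   per row.
#' @param target Gene symbol whose neighbors become the partner set.
#' @return A [network_neighborhood()] with `partners` = all genes adjacent to
#'   `target`.
#' @export
read_network <- function(path, target) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(edges) < 2L) abort("Edge list needs two columns (gene_a, gene_b).")
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  partners <- unique(c(b[a == target], a[b == target]))
  network_neighborhood(target, setdiff(partners, target))
}

#' Build per-compound screening features against a knockdown neighborhood
#'
#' For every compound and every cell line in which both a compound signature
#' and a proxy-target knockdown signature exist, computes the direct
#' correlation with the proxy knockdown and the best/mean correlation over
#' available partner knockdowns in the same cell line. Replicates are first
#' collapsed with [consensus_signature()]. Cell lines lacking a knockdown
#' profile are skipped, never zero-filled.
#'
#' @param compound_sigs,kd_sigs [signature_collection()]s sharing a gene
#'   universe; `kd_sigs` holds the knockdown signatures (matched by
#'   `target_gene` metadata, falling back to `perturbation_id`).
#' @param network A [network_neighborhood()].
#' @param support_threshold Correlation at or above which a cell line counts
#'   as supporting the compound (default 0.3, Spearman).
#' @param method Correlation method passed to [signature_similarity()].
#' @param top_n Optional gene restriction passed to [signature_similarity()].
#' @param consensus A [consensus_spec()] for replicate collapsing.
#' @return A tibble of class `screen_features` with one row per compound and
#'   cell line: `compound_id`, `cell_line`, `direct_corr`,
#'   `best_indirect_corr`, `mean_indirect_corr`, `supported`. Compounds with
#'   no overlapping cell line are kept with `n_cell_lines = 0` in
#'   [screen_support()] and trigger a warning here.
#' @export
build_screen_features <- function(compound_sigs, kd_sigs, network,
                                  support_threshold = 0.3,
                                  method = c("spearman", "pearson"),
                                  top_n = NULL,
                                  consensus = consensus_spec()) {
  method <- match.arg(method)
  stopifnot(inherits(network, "network_neighborhood"))
  stopifnot_scalar_number(support_threshold, "support_threshold", -1, 1)

  kd <- collapse_replicates(kd_sigs, consensus)
  kd$meta$gene <- ifelse(is.na(kd$meta$target_gene),
                         kd$meta$perturbation_id, kd$meta$target_gene)
  proxy_cols <- which(kd$meta$gene == network$proxy_target)
  if (!length(proxy_cols)) {
    abort(sprintf("No knockdown signature found for proxy target '%s' in any cell line.",
                  network$proxy_target))
  }
  cmp <- collapse_replicates(compound_sigs, consensus)

  proxy_by_line <- setNames(proxy_cols, kd$meta$cell_line[proxy_cols])
  partner_cols_by_line <- split(
    which(kd$meta$gene %in% network$partners),
    kd$meta$cell_line[kd$meta$gene %in% network$partners]
  )

  rows <- purrr::map(seq_len(ncol(cmp$values)), function(j) {
    line <- cmp$meta$cell_line[j]
    if (!line %in% names(proxy_by_line)) return(NULL)
    sig <- setNames(cmp$values[, j], rownames(cmp$values))
    proxy_sig <- setNames(kd$values[, proxy_by_line[[line]]], rownames(kd$values))
    direct <- signature_similarity(sig, proxy_sig, method = method, top_n = top_n)
    pcols <- partner_cols_by_line[[line]]
    if (length(pcols)) {
      ind <- vapply(pcols, function(k) {
        signature_similarity(sig, setNames(kd$values[, k], rownames(kd$values)),
                             method = method, top_n = top_n)
      }, numeric(1))
      best <- max(ind); mean_ind <- mean(ind)
    } else {
      best <- NA_real_; mean_ind <- NA_real_
    }
    tibble(compound_id = cmp$meta$perturbation_id[j], cell_line = line,
           direct_corr = direct, best_indirect_corr = best,
           mean_indirect_corr = mean_ind)
  })
  out <- bind_rows(rows)
  all_compounds <- unique(cmp$meta$perturbation_id)
  orphans <- setdiff(all_compounds, out$compound_id)
  if (length(orphans)) {
    warn(sprintf("%d compound(s) share no cell line with the proxy knockdown: %s",
                 length(orphans), paste(head(orphans, 5), collapse = ", ")))
  }
  out <- mutate(out, supported = .data$direct_corr >= support_threshold)
  structure(out,
            class = c("screen_features", class(out)),
            support_threshold = support_threshold,
            all_compounds = all_compounds,
            proxy_target = network$proxy_target)
}

#' Summarise per-compound cell-line support
#'
#' @param features A `screen_features` tibble from [build_screen_features()].
#' @return A tibble with one row per compound: `support_count` (cell lines
#'   with direct correlation at or above the support threshold) and
#'   `n_cell_lines` (cell lines with both profiles available). Compounds with
#'   no overlapping cell line appear with zeros.
#' @export
screen_support <- function(features) {
  stopifnot(inherits(features, "screen_features"))
  agg <- features |>
    group_by(.data$compound_id) |>
    summarise(support_count = sum(.data$supported),
              n_cell_lines = n(), .groups = "drop")
  missing <- setdiff(attr(features, "all_compounds"), agg$compound_id)
  if (length(missing)) {
    agg <- bind_rows(agg, tibble(compound_id = missing,
                                 support_count = 0L, n_cell_lines = 0L))
  }
  arrange(agg, .data$compound_id)
}

#' Composite screening score
#'
#' A deterministic stand-in for a trained classifier probability: the mean,
#' over supported cell lines, of
#' `direct_corr + lambda_indirect * best_indirect_corr`. Compounds supported
#' in fewer than `min_support` cell lines (default 4) are flagged unqualified
#' and scored `-Inf` so they always rank below qualified ones.
#'
#' @param features A `screen_features` tibble from [build_screen_features()].
#' @param lambda_indirect Non-negative weight of the guilt-by-association
#'   term (default 0.5).
#' @param min_support Minimum number of supporting cell lines (default 4).
#' @return A tibble: `compound_id`, `score`, `support_count`, `n_cell_lines`,
#'   `qualified`.
#' @export
composite_score <- function(features, lambda_indirect = 0.5, min_support = 4L) {
  stopifnot(inherits(features, "screen_features"))
  stopifnot_scalar_number(lambda_indirect, "lambda_indirect", lower = 0)
  scored <- features |>
    filter(.data$supported) |>
    group_by(.data$compound_id) |>
    summarise(score = mean(.data$direct_corr +
                             lambda_indirect *
                             dplyr::coalesce(.data$best_indirect_corr, 0)),
              .groups = "drop")
  out <- screen_support(features) |>
    left_join(scored, by = "compound_id") |>
    mutate(qualified = .data$support_count >= min_support,
           score = ifelse(.data$qualified, .data$score, -Inf))
  select(out, "compound_id", "score", "support_count", "n_cell_lines", "qualified")
}

#' Rank screening candidates
#'
#' Without training data, ranks by [composite_score()]. With a labeled
#' training set, fits a ridge-regularized logistic model (via \pkg{glmnet})
#' on the flattened per-cell-line feature vectors and ranks by predicted
#' positive-class probability; qualified compounds always outrank unqualified
#' ones, and ties break by `compound_id` for a stable order.
#'
#' @param features A `screen_features` tibble from [build_screen_features()].
#' @param training Optional tibble with columns `compound_id` and `label`
#'   (logical or 0/1); needs at least 2 compounds per class.
#' @param lambda_indirect,min_support Passed to [composite_score()].
#' @param seed Integer seed controlling any stochastic classifier component.
#' @return A tibble of class `candidate_ranking`, ordered by decreasing score:
#'   `rank`, `compound_id`, `score`, `support_count`, `qualified`.
#' @export
rank_candidates <- function(features, training = NULL,
                            lambda_indirect = 0.5, min_support = 4L,
                            seed = 1L) {
  base <- composite_score(features, lambda_indirect, min_support)
  if (!is.null(training)) {
    training <- as_tibble(training)
    lab <- as.integer(training$label)
    if (length(unique(lab)) < 2L || min(table(lab)) < 2L) {
      abort(paste("Degenerate training set (need >= 2 compounds per class);",
                  "fall back to the unsupervised composite_score ranking."))
    }
    X <- flatten_screen_features(features)
    train_idx <- match(training$compound_id, rownames(X))
    if (anyNA(train_idx)) abort("Training compounds missing from the feature table.")
    prob <- with_seed_(seed, ridge_logistic_prob(X[train_idx, , drop = FALSE],
                                                 lab, X))
    base$score <- ifelse(base$qualified,
                         prob[match(base$compound_id, rownames(X))], -Inf)
  }
  out <- base |>
    arrange(desc(.data$qualified), desc(.data$score), .data$compound_id) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "compound_id", "score", "support_count", "qualified")
  structure(out, class = c("candidate_ranking", class(out)))
}

# One row per compound: direct/best/mean-indirect per cell line (0 where the
# cell line is missing) plus support_count.
flatten_screen_features <- function(features) {
  lines <- sort(unique(features$cell_line))
  wide <- features |>
    select("compound_id", "cell_line", "direct_corr",
           "best_indirect_corr", "mean_indirect_corr") |>
    tidyr::pivot_wider(names_from = "cell_line",
                       values_from = c("direct_corr", "best_indirect_corr",
                                       "mean_indirect_corr"),
                       values_fill = 0)
  sup <- screen_support(features)
  wide <- left_join(wide, sup, by = "compound_id")
  X <- as.matrix(wide[, setdiff(names(wide), c("compound_id", "n_cell_lines"))])
  X[is.na(X)] <- 0
  rownames(X) <- wide$compound_id
  X
}

ridge_logistic_prob <- function(X_train, y, X_all, lambda = 0.1) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    abort("The trained-classifier ranking needs the 'glmnet' package.")
  }
  fit <- glmnet::glmnet(X_train, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  as.vector(stats::predict(fit, newx = X_all, type = "response"))
}

#' Consensus z-score table for a gene panel
#'
#' Builds a genes-by-perturbations table of consensus z-scores: entry (g, p)
#' aggregates all signatures of perturbation p (across cell lines and
#' replicates) with the given consensus rule, restricted to gene g. This is
#' the form in which changes of the eight direct FOXM1 target genes (BIRC5,
#' CCNB1, CCNB2, CDK1, CDC20, CDC25A, PLK1, UBE2C) are compared across
#' knockdowns and candidate compounds.
#'
#' @param collection A [signature_collection()].
#' @param panel Ordered character vector of panel gene symbols; all must be in
#'   the collection's gene universe.
#' @param perturbations Ordered perturbation ids; each needs at least one
#'   signature.
#' @param spec A [consensus_spec()]. MODZ weights are computed on the full
#'   gene universe before restricting to the panel.
#' @return A tibble of class `panel_table`: `gene` column plus one numeric
#'   column per perturbation.
#' @export
panel_consensus_table <- function(collection, panel, perturbations,
                                  spec = consensus_spec()) {
  stopifnot(inherits(collection, "signature_collection"))
  missing_genes <- setdiff(panel, collection$gene_universe)
  if (length(missing_genes)) {
    abort(sprintf("Panel gene(s) missing from the collection: %s.",
                  paste(missing_genes, collapse = ", ")))
  }
  cols <- lapply(perturbations, function(p) {
    idx <- which(collection$meta$perturbation_id == p)
    if (!length(idx)) abort(sprintf("No signature for perturbation '%s'.", p))
    unname(consensus_signature(collection$values[, idx, drop = FALSE], spec)[panel])
  })
  out <- tibble(gene = panel)
  for (i in seq_along(perturbations)) out[[perturbations[i]]] <- cols[[i]]
  structure(out, class = c("panel_table", class(out)))
}

#' Compare candidate perturbations on a target panel
#'
#' Scores each candidate column of a panel table by "universality"
#' (`n_suppressed`: panel genes with consensus z at or below the suppression
#' threshold) and "potency" (`mean_z` over the panel), ordering by
#' `n_suppressed` descending then `mean_z` ascending. This is the comparison
#' under which STL427944 outranks benzamil on the FOXM1 target panel.
#'
#' @param table A `panel_table` from [panel_consensus_table()].
#' @param candidates Perturbation ids to compare; must be columns of `table`.
#' @param suppression_threshold Negative z cutoff counting a panel gene as
#'   suppressed (default -1).
#' @return A tibble: `candidate`, `n_suppressed`, `mean_z`, ordered best
#'   first.
#' @export
compare_candidates <- function(table, candidates, suppression_threshold = -1) {
  stopifnot(inherits(table, "panel_table"))
  if (suppression_threshold >= 0) {
    abort("`suppression_threshold` must be negative (a suppressed gene has z < 0).")
  }
  unknown <- setdiff(candidates, names(table))
  if (length(unknown)) {
    abort(sprintf("Unknown candidate id(s): %s.", paste(unknown, collapse = ", ")))
  }
  out <- purrr::map_dfr(candidates, function(p) {
    z <- table[[p]]
    tibble(candidate = p,
           n_suppressed = sum(z <= suppression_threshold),
           mean_z = mean(z))
  })
  arrange(out, desc(.data$n_suppressed), .data$mean_z)
}
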