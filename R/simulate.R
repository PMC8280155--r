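#' Configuration for the LINCS-like screen simulator
#'
#' The generator states a world resembling the L1000 screening regime: ~978
#' landmark-like genes, the seven cell lines the real screen spanned, a proxy
#' knockdown plus partner knockdowns, one planted inhibitor whose signature
#' mixes the proxy knockdown with fresh noise, and pure-noise decoys.
#'
#' @param n_genes Number of genes per signature (default 978).
#' @param cell_lines Character vector of cell lines (default the seven used in
#'   the screen: A549, MCF7, VCAP, HA1E, A375, HCC515, HT29).
#' @param n_decoy_compounds Number of noise-only decoy compounds (default 49).
#' @param n_partner_genes Number of partner knockdowns (default 5).
#' @param mixing_weight Planted-compound mixing weight `alpha` in \[0, 1\]:
#'   planted latent signature = `alpha * KD + sqrt(1 - alpha^2) * noise`, so
#'   its marginal distribution stays standard normal (default 0.7).
#' @param partner_similarity Analogous mixing weight tying each partner
#'   knockdown to the proxy knockdown (default 0.5, a realistic
#'   within-subnetwork transcriptional similarity).
#' @param n_replicates Replicates per perturbation and cell line (default 3).
#' @param replicate_fidelity Fraction of replicate variance carried by the
#'   latent signature: observed replicate =
#'   `sqrt(f) * latent + sqrt(1 - f) * noise` (default 0.8; 1 = exact
#'   copies).
#' @param seed Integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 978L,
                              cell_lines = c("A549", "MCF7", "VCAP", "HA1E",
                                             "A375", "HCC515", "HT29"),
                              n_decoy_compounds = 49L,
                              n_partner_genes = 5L,
                              mixing_weight = 0.7,
                              partner_similarity = 0.5,
                              n_replicates = 3L,
                              replicate_fidelity = 0.8,
                              seed = 1L) {
  stopifnot_scalar_number(mixing_weight, "mixing_weight", 0, 1)
  stopifnot_scalar_number(partner_similarity, "partner_similarity", 0, 1)
  stopifnot_scalar_number(replicate_fidelity, "replicate_fidelity", 0, 1)
  if (n_genes < 10L) abort("`n_genes` must be at least 10.")
  structure(
    list(n_genes = as.integer(n_genes), cell_lines = cell_lines,
         n_decoy_compounds = as.integer(n_decoy_compounds),
         n_partner_genes = as.integer(n_partner_genes),
         mixing_weight = mixing_weight,
         partner_similarity = partner_similarity,
         n_replicates = as.integer(n_replicates),
         replicate_fidelity = replicate_fidelity,
         seed = as.integer(seed)),
    class = "screen_sim_config"
  )
}

#' Simulate a LINCS-like perturbation screen with a planted inhibitor
#'
#' Emits, per cell line: knockdown signatures for the proxy target
#' (`"NPM1"`) and each partner, one planted compound whose latent signature
#' correlates `mixing_weight` with the proxy knockdown, and noise-only decoy
#' compounds. Replicates are noisy copies of the latent signature (see
#' [screen_sim_config()]). The ground truth identifies the planted compound
#' so downstream recovery tests consume only generator outputs.
#'
#' @param config A [screen_sim_config()].
#' @return A list: `collection` (a [signature_collection()]), `truth` (list
#'   with `planted_compound`, `proxy_target`, `partners`, `mixing_weight`),
#'   and `network` (the matching [network_neighborhood()]).
#' @export
simulate_screen <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  if (config$mixing_weight == 0) {
    warn("mixing_weight = 0: the planted compound is indistinguishable from decoys.")
  }
  ng <- config$n_genes
  genes <- sprintf("G%04d", seq_len(ng))
  partners <- sprintf("PARTNER%02d", seq_len(config$n_partner_genes))
  decoys <- sprintf("CPD%03d", seq_len(config$n_decoy_compounds))
  planted <- "CPD_PLANTED"

  mix <- function(base, alpha) alpha * base + sqrt(1 - alpha^2) * rnorm(ng)

  with_seed_(config$seed, {
    cols <- list(); meta <- list(); k <- 0L
    add_pert <- function(pid, line, type, target, latent) {
      for (r in seq_len(config$n_replicates)) {
        f <- config$replicate_fidelity
        obs <- if (f >= 1) latent else sqrt(f) * latent + sqrt(1 - f) * rnorm(ng)
        k <<- k + 1L
        cols[[k]] <<- obs
        meta[[k]] <<- tibble(
          signature_id = sprintf("%s|%s|%d", pid, line, r),
          perturbation_id = pid, cell_line = line,
          perturbation_type = type, target_gene = target, replicate = r
        )
      }
    }
    for (line in config$cell_lines) {
      proxy_latent <- rnorm(ng)
      add_pert("NPM1_KD", line, "knockdown", "NPM1", proxy_latent)
      for (p in partners) {
        add_pert(paste0(p, "_KD"), line, "knockdown", p,
                 mix(proxy_latent, config$partner_similarity))
      }
      add_pert(planted, line, "compound", NA_character_,
               mix(proxy_latent, config$mixing_weight))
      for (d in decoys) {
        add_pert(d, line, "compound", NA_character_, rnorm(ng))
      }
    }
    values <- do.call(cbind, cols)
    meta <- bind_rows(meta)
    rownames(values) <- genes
    colnames(values) <- meta$signature_id
    list(
      collection = signature_collection(values, meta),
      truth = list(planted_compound = planted, proxy_target = "NPM1",
                   partners = partners, mixing_weight = config$mixing_weight),
      network = network_neighborhood("NPM1", partners)
    )
  })
}

#' Configuration for the paired DE-table simulator
#'
#' States the accounting structure of the two-cell-model RNA-seq comparison:
#' counts of genes planted as shared-up, shared-down, discordant, and
#' model-specific significant, inside a protein-coding universe. Defaults
#' mirror the published accounting (16275 genes; 577 shared up, 687 shared
#' down, 77 discordant).
#'
#' @param n_genes Universe size (default 16275).
#' @param n_up_shared,n_down_shared Genes significantly up/down in both
#'   models (defaults 577 and 687).
#' @param n_discordant Genes significant in both models with opposite signs
#'   (default 77).
#' @param n_specific_a,n_specific_b Genes significant in only one model
#'   (defaults 250 each; the paper does not print these margins).
#' @param effect_size Log2 fold-change magnitude of planted genes
#'   (default 2, i.e. 4-fold).
#' @param null_lfc_sd SD of null-gene log2 fold changes (default 0.2).
#' @param seed Integer seed.
#' @return A `de_sim_config` list.
#' @export
de_sim_config <- function(n_genes = 16275L, n_up_shared = 577L,
                          n_down_shared = 687L, n_discordant = 77L,
                          n_specific_a = 250L, n_specific_b = 250L,
                          effect_size = 2, null_lfc_sd = 0.2, seed = 1L) {
  total <- n_up_shared + n_down_shared + n_discordant + n_specific_a + n_specific_b
  if (total > n_genes) abort("Planted gene counts exceed `n_genes`.")
  structure(
    list(n_genes = as.integer(n_genes), n_up_shared = as.integer(n_up_shared),
         n_down_shared = as.integer(n_down_shared),
         n_discordant = as.integer(n_discordant),
         n_specific_a = as.integer(n_specific_a),
         n_specific_b = as.integer(n_specific_b),
         effect_size = effect_size, null_lfc_sd = null_lfc_sd,
         seed = as.integer(seed)),
    class = "de_sim_config"
  )
}

#' Simulate two DE tables with controlled intersection structure
#'
#' Planted shared genes receive a log2 fold change of about
#' `+/- effect_size` in both tables (tight jitter, SD 0.05, so threshold
#' crossings are unambiguous) and p-values uniform on (0, 1e-4); discordant
#' genes get opposite signs in the two tables; model-specific genes are
#' significant in one table and null in the other; the remainder is null
#' (log2FC ~ N(0, `null_lfc_sd`), p ~ U(0, 1)). FDR columns are
#' [benjamini_hochberg()] q-values. Running [filter_de()] and
#' [codirectional_intersection()] on the output at the default thresholds
#' recovers the planted counts exactly.
#'
#' @param config A [de_sim_config()].
#' @return A list: `table_a`, `table_b` (tibbles with `gene_id`, `log2_fc`,
#'   `p_value`, `fdr`, `biotype`), and `truth` (list of planted gene-id
#'   vectors plus the config).
#' @export
simulate_de_tables <- function(config = de_sim_config()) {
  stopifnot(inherits(config, "de_sim_config"))
  ng <- config$n_genes
  genes <- sprintf("ENSG%08d", seq_len(ng))
  with_seed_(config$seed, {
    idx <- seq_len(ng)
    take <- function(n) {
      out <- idx[seq_len(n)]
      idx <<- idx[-seq_len(n)]
      out
    }
    i_up <- take(config$n_up_shared)
    i_down <- take(config$n_down_shared)
    i_dis <- take(config$n_discordant)
    i_a <- take(config$n_specific_a)
    i_b <- take(config$n_specific_b)

    planted_lfc <- function(n, sign) sign * (config$effect_size + rnorm(n, 0, 0.05))
    sig_p <- function(n) runif(n, 0, 1e-4)

    make_table <- function(model) {
      lfc <- rnorm(ng, 0, config$null_lfc_sd)
      p <- runif(ng)
      lfc[i_up] <- planted_lfc(length(i_up), +1)
      lfc[i_down] <- planted_lfc(length(i_down), -1)
      p[c(i_up, i_down)] <- sig_p(length(i_up) + length(i_down))
      half <- seq_len(floor(length(i_dis) / 2))
      dis_sign_a <- rep(-1, length(i_dis)); dis_sign_a[half] <- +1
      dis_sign <- if (model == "a") dis_sign_a else -dis_sign_a
      lfc[i_dis] <- planted_lfc(length(i_dis), dis_sign)
      p[i_dis] <- sig_p(length(i_dis))
      i_own <- if (model == "a") i_a else i_b
      own_sign <- rep_len(c(+1, -1), length(i_own))
      lfc[i_own] <- planted_lfc(length(i_own), own_sign)
      p[i_own] <- sig_p(length(i_own))
      tibble(gene_id = genes, log2_fc = lfc, p_value = p,
             fdr = benjamini_hochberg(p), biotype = "protein_coding")
    }
    table_a <- make_table("a")
    table_b <- make_table("b")
    list(
      table_a = table_a, table_b = table_b,
      truth = list(up_shared = genes[i_up], down_shared = genes[i_down],
                   discordant = genes[i_dis],
                   specific_a = genes[i_a], specific_b = genes[i_b],
                   config = config)
    )
  })
}

#' Simulate a ranked list with a planted enriched gene set
#'
#' Builds a strictly ordered ranked list of `n_genes` and one gene set whose
#' members sit uniformly within the top (or bottom) `top_fraction` of ranks;
#' with `placement = "random"` the set is a null draw over the whole list.
#'
#' @param n_genes List length (default 2000).
#' @param planted_set_size Members of the planted set (default 30).
#' @param top_fraction Fraction of the list the members are confined to
#'   (default 0.1); must satisfy `planted_set_size <= n_genes * top_fraction`
#'   for non-random placement.
#' @param placement `"top"` (positive enrichment, default), `"bottom"`
#'   (negative), or `"random"` (null).
#' @param seed Integer seed.
#' @return A list: `ranked` (a [ranked_list()]), `gene_set` (character
#'   vector), `truth` (placement parameters).
#' @export
simulate_ranked_list <- function(n_genes = 2000L, planted_set_size = 30L,
                                 top_fraction = 0.1,
                                 placement = c("top", "bottom", "random"),
                                 seed = 1L) {
  placement <- match.arg(placement)
  stopifnot_scalar_number(top_fraction, "top_fraction", 0, 1)
  window <- floor(n_genes * top_fraction)
  if (placement != "random" && planted_set_size > window) {
    abort("`planted_set_size` exceeds the number of ranks in `top_fraction`.")
  }
  with_seed_(seed, {
    genes <- sprintf("G%05d", sample.int(n_genes))
    values <- sort(rnorm(n_genes), decreasing = TRUE)
    ranked <- ranked_list(tibble(gene_id = genes, ranking_value = values))
    positions <- switch(
      placement,
      top = sort(sample.int(window, planted_set_size)),
      bottom = sort(n_genes - sample.int(window, planted_set_size) + 1L),
      random = sort(sample.int(n_genes, planted_set_size))
    )
    list(
      ranked = ranked,
      gene_set = ranked$gene_id[positions],
      truth = list(placement = placement, positions = positions,
                   top_fraction = top_fraction, seed = seed)
    )
  })
}
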