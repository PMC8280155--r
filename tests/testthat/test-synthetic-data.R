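test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulate_screen(screen_sim_config(n_genes = 100L, n_decoy_compounds = 4L,
                                         n_partner_genes = 2L, seed = 5L))
  b <- simulate_screen(screen_sim_config(n_genes = 100L, n_decoy_compounds = 4L,
                                         n_partner_genes = 2L, seed = 5L))
  expect_identical(a$collection$values, b$collection$values)

  da <- simulate_de_tables(de_sim_config(n_genes = 500L, n_up_shared = 20L,
                                         n_down_shared = 25L, n_discordant = 5L,
                                         n_specific_a = 10L, n_specific_b = 10L,
                                         seed = 3L))
  db <- simulate_de_tables(de_sim_config(n_genes = 500L, n_up_shared = 20L,
                                         n_down_shared = 25L, n_discordant = 5L,
                                         n_specific_a = 10L, n_specific_b = 10L,
                                         seed = 3L))
  expect_identical(da$table_a, db$table_a)

  ra <- simulate_ranked_list(n_genes = 200L, planted_set_size = 15L, seed = 9L)
  rb <- simulate_ranked_list(n_genes = 200L, planted_set_size = 15L, seed = 9L)
  expect_identical(ra$ranked, rb$ranked)
  expect_identical(ra$gene_set, rb$gene_set)
})

test_that("mixing weight controls the planted compound's correlation", {
  # alpha = 1, exact replicates: perfect correlation in every cell line
  sim1 <- simulate_screen(screen_sim_config(n_genes = 200L,
                                            n_decoy_compounds = 2L,
                                            n_partner_genes = 1L,
                                            mixing_weight = 1,
                                            n_replicates = 1L,
                                            replicate_fidelity = 1, seed = 1L))
  v <- sim1$collection$values
  meta <- sim1$collection$meta
  for (line in unique(meta$cell_line)) {
    cs <- v[, meta$perturbation_id == "CPD_PLANTED" & meta$cell_line == line]
    ks <- v[, meta$perturbation_id == "NPM1_KD" & meta$cell_line == line]
    expect_equal(cor(cs, ks), 1)
  }

  # alpha = 0.7: per-line Pearson about 0.7 within sampling error
  sim7 <- simulate_screen(screen_sim_config(n_genes = 978L,
                                            n_decoy_compounds = 2L,
                                            n_partner_genes = 1L,
                                            mixing_weight = 0.7,
                                            n_replicates = 1L,
                                            replicate_fidelity = 1, seed = 17L))
  v <- sim7$collection$values; meta <- sim7$collection$meta
  cors <- vapply(unique(meta$cell_line), function(line) {
    cor(v[, meta$perturbation_id == "CPD_PLANTED" & meta$cell_line == line],
        v[, meta$perturbation_id == "NPM1_KD" & meta$cell_line == line])
  }, numeric(1))
  expect_equal(unname(mean(cors)), 0.7, tolerance = 0.05)

  # the sqrt(1 - alpha^2) mixing keeps the marginal close to standard normal
  planted <- v[, meta$perturbation_id == "CPD_PLANTED"]
  expect_equal(sd(as.vector(planted)), 1, tolerance = 0.05)

  expect_warning(simulate_screen(screen_sim_config(n_genes = 50L,
                                                   n_decoy_compounds = 1L,
                                                   mixing_weight = 0,
                                                   seed = 1L)),
                 "indistinguishable")
})

test_that("planted-inhibitor rank degrades monotonically as alpha decreases", {
  # scaled-down world (300 genes, 20 decoys, single replicates) for runtime;
  # ranking is by pure mean correlation (support rule disabled) so the
  # alpha = 0 end is exchangeable with the decoys rather than pinned by the
  # qualification tie-break.
  rank_of_planted <- function(alpha, seed) {
    sim <- suppressWarnings(simulate_screen(screen_sim_config(
      n_genes = 300L, n_decoy_compounds = 20L, n_partner_genes = 2L,
      mixing_weight = alpha, n_replicates = 1L, replicate_fidelity = 1,
      seed = seed)))
    suppressWarnings({
      kd <- subset_collection(sim$collection,
                              sim$collection$meta$perturbation_type == "knockdown")
      cmp <- subset_collection(sim$collection,
                               sim$collection$meta$perturbation_type == "compound")
      f <- build_screen_features(cmp, kd, sim$network,
                                 support_threshold = -1)
      r <- rank_candidates(f, min_support = 0L)
    })
    r$rank[r$compound_id == sim$truth$planted_compound]
  }
  alphas <- c(0.8, 0.6, 0.4, 0.2, 0)
  seeds <- 1:20
  med_rank <- vapply(alphas, function(a) {
    median(vapply(seeds, function(s) rank_of_planted(a, s), numeric(1)))
  }, numeric(1))
  expect_equal(med_rank[1], 1)  # alpha = 0.8
  expect_equal(med_rank[2], 1)  # alpha = 0.6
  expect_true(!is.unsorted(med_rank))  # degrades monotonically toward alpha 0
  expect_gt(med_rank[length(alphas)], 3)  # alpha = 0: no better than chance-ish
})

test_that("DE simulation round-trips its planted counts exactly", {
  cfg <- de_sim_config(n_genes = 3000L, n_up_shared = 40L, n_down_shared = 55L,
                       n_discordant = 12L, n_specific_a = 30L,
                       n_specific_b = 25L, seed = 11L)
  sim <- simulate_de_tables(cfg)
  sig <- codirectional_intersection(filter_de(sim$table_a),
                                    filter_de(sim$table_b))
  expect_setequal(sig$up_both, sim$truth$up_shared)
  expect_setequal(sig$down_both, sim$truth$down_shared)
  expect_setequal(sig$discordant, sim$truth$discordant)
  expect_equal(length(sig$combined), 40L + 55L)

  # all counts zero -> empty signature
  empty <- simulate_de_tables(de_sim_config(n_genes = 400L, n_up_shared = 0L,
                                            n_down_shared = 0L,
                                            n_discordant = 0L,
                                            n_specific_a = 0L,
                                            n_specific_b = 0L, seed = 2L))
  esig <- codirectional_intersection(filter_de(empty$table_a),
                                     filter_de(empty$table_b))
  expect_equal(length(esig$combined), 0L)

  # effect below the 2-fold threshold -> planted genes filtered out
  weak <- simulate_de_tables(de_sim_config(n_genes = 400L, n_up_shared = 20L,
                                           n_down_shared = 20L,
                                           n_discordant = 0L,
                                           n_specific_a = 0L,
                                           n_specific_b = 0L,
                                           effect_size = 0.5, seed = 2L))
  wsig <- codirectional_intersection(filter_de(weak$table_a),
                                     filter_de(weak$table_b))
  expect_equal(length(wsig$combined), 0L)

  expect_error(de_sim_config(n_genes = 100L, n_up_shared = 90L,
                             n_down_shared = 20L), "exceed")
})

test_that("ranked-list planting places members where promised", {
  top <- simulate_ranked_list(n_genes = 2000L, planted_set_size = 30L,
                              top_fraction = 0.1, seed = 4L)
  expect_true(all(match(top$gene_set, top$ranked$gene_id) <= 200))
  expect_equal(nrow(top$ranked), 2000L)

  bottom <- simulate_ranked_list(n_genes = 2000L, planted_set_size = 30L,
                                 top_fraction = 0.1, placement = "bottom",
                                 seed = 4L)
  expect_true(all(match(bottom$gene_set, bottom$ranked$gene_id) > 1800))

  expect_error(simulate_ranked_list(n_genes = 100L, planted_set_size = 30L,
                                    top_fraction = 0.1), "exceeds")

  # random placement produces no credible enrichment over seeds
  qs <- vapply(1:5, function(s) {
    sim <- simulate_ranked_list(n_genes = 800L, planted_set_size = 25L,
                                placement = "random", seed = s)
    res <- gsea_preranked(sim$ranked, list(planted = sim$gene_set),
                          n_permutations = 200L, seed = s)
    res$nominal_p
  }, numeric(1))
  expect_gt(mean(qs > 0.05), 0.5)
})
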