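make_screen_world <- function(n_genes = 60, lines = c("L1", "L2", "L3"),
                              compounds = list(), seed = 1) {
  # knockdown collection: one NPM1 KD plus one partner KD per line
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  cols <- list(); meta <- list(); k <- 0
  add <- function(pid, line, type, target, v) {
    k <<- k + 1
    cols[[k]] <<- v
    meta[[k]] <<- tibble::tibble(signature_id = paste(pid, line, sep = "|"),
                                 perturbation_id = pid, cell_line = line,
                                 perturbation_type = type, target_gene = target,
                                 replicate = 1L)
  }
  kd_latent <- list()
  for (line in lines) {
    kd_latent[[line]] <- rnorm(n_genes)
    add("NPM1_KD", line, "knockdown", "NPM1", kd_latent[[line]])
    add("P1_KD", line, "knockdown", "P1",
        0.5 * kd_latent[[line]] + sqrt(0.75) * rnorm(n_genes))
  }
  for (cmp in names(compounds)) {
    for (line in lines) {
      v <- compounds[[cmp]](kd_latent[[line]], n_genes)
      add(cmp, line, "compound", NA_character_, v)
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- genes
  m <- dplyr::bind_rows(meta)
  colnames(values) <- m$signature_id
  all <- foxnet::signature_collection(values, m)
  list(
    kd = subset_collection(all, m$perturbation_type == "knockdown"),
    cmp = subset_collection(all, m$perturbation_type == "compound"),
    net = network_neighborhood("NPM1", "P1")
  )
}

test_that("an exact mimic of the proxy knockdown gets direct_corr 1 everywhere", {
  w <- make_screen_world(compounds = list(mimic = function(kd, n) kd))
  f <- build_screen_features(w$cmp, w$kd, w$net)
  expect_equal(nrow(f), 3L)
  expect_equal(f$direct_corr, rep(1, 3))
  sup <- screen_support(f)
  expect_equal(sup$support_count, 3L)
  expect_equal(sup$n_cell_lines, 3L)
})

test_that("features match brute-force correlations and noise has no support", {
  w <- make_screen_world(
    compounds = list(noise = function(kd, n) rnorm(n)),
    seed = 5
  )
  f <- build_screen_features(w$cmp, w$kd, w$net, support_threshold = 0.3)
  # brute-force recomputation of each correlation
  for (line in c("L1", "L2", "L3")) {
    cv <- w$cmp$values[, paste0("noise|", line)]
    kv <- w$kd$values[, paste0("NPM1_KD|", line)]
    pv <- w$kd$values[, paste0("P1_KD|", line)]
    row <- f[f$cell_line == line, ]
    expect_equal(row$direct_corr, cor(cv, kv, method = "spearman"))
    expect_equal(row$best_indirect_corr, cor(cv, pv, method = "spearman"))
    expect_equal(row$mean_indirect_corr, row$best_indirect_corr)
  }
  expect_equal(screen_support(f)$support_count, 0L)
})

test_that("missing knockdown cell lines are skipped, orphan compounds warned", {
  w <- make_screen_world(compounds = list(mimic = function(kd, n) kd))
  # a compound profiled only in a cell line with no knockdown data
  extra <- matrix(rnorm(60), ncol = 1,
                  dimnames = list(rownames(w$cmp$values), "lonely|L9"))
  cmp2 <- signature_collection(
    cbind(w$cmp$values, extra),
    dplyr::bind_rows(w$cmp$meta,
                     tibble::tibble(signature_id = "lonely|L9",
                                    perturbation_id = "lonely", cell_line = "L9",
                                    perturbation_type = "compound",
                                    target_gene = NA, replicate = 1L)))
  expect_warning(f <- build_screen_features(cmp2, w$kd, w$net), "lonely")
  sup <- screen_support(f)
  expect_equal(sup$n_cell_lines[sup$compound_id == "lonely"], 0L)
  expect_error(
    build_screen_features(w$cmp, w$kd, network_neighborhood("ABSENT", "P1")),
    "ABSENT")
})

test_that("composite_score does the stated arithmetic and support gating", {
  # hand-built features over 4 cell lines
  f <- structure(
    tibble::tibble(
      compound_id = "c1", cell_line = paste0("L", 1:4),
      direct_corr = c(0.5, 0.6, 0.7, 0.8),
      best_indirect_corr = c(0.2, 0.1, 0.4, 0.3),
      mean_indirect_corr = c(0.2, 0.1, 0.4, 0.3),
      supported = TRUE),
    class = c("screen_features", class(tibble::tibble())),
    support_threshold = 0.3, all_compounds = "c1", proxy_target = "NPM1")
  sc <- composite_score(f, lambda_indirect = 0.5, min_support = 4L)
  expect_equal(sc$score, mean(c(0.5, 0.6, 0.7, 0.8) + 0.5 * c(0.2, 0.1, 0.4, 0.3)))
  expect_true(sc$qualified)

  # perfect mimic, lambda 0.5 -> 1.5
  f$direct_corr <- f$best_indirect_corr <- f$mean_indirect_corr <- rep(1, 4)
  expect_equal(composite_score(f, 0.5, 4L)$score, 1.5)

  # support 3 of 4 with min_support 4 -> unqualified, score -Inf
  f$supported <- c(TRUE, TRUE, TRUE, FALSE)
  sc3 <- composite_score(f, 0.5, 4L)
  expect_false(sc3$qualified)
  expect_equal(sc3$score, -Inf)
})

test_that("composite_score is monotone in every per-cell-line correlation", {
  set.seed(3)
  base <- structure(
    tibble::tibble(
      compound_id = "c1", cell_line = paste0("L", 1:5),
      direct_corr = runif(5, 0.3, 0.8),
      best_indirect_corr = runif(5, -0.2, 0.6),
      mean_indirect_corr = runif(5, -0.2, 0.6),
      supported = TRUE),
    class = c("screen_features", class(tibble::tibble())),
    support_threshold = 0.3, all_compounds = "c1", proxy_target = "NPM1")
  s0 <- composite_score(base, 0.5, 4L)$score
  for (col in c("direct_corr", "best_indirect_corr")) {
    for (i in 1:5) {
      bumped <- base
      bumped[[col]][i] <- bumped[[col]][i] + 0.1
      expect_gte(composite_score(bumped, 0.5, 4L)$score, s0)
    }
  }
})

test_that("mimic outranks noise and the planted inhibitor is recovered at rank 1", {
  w <- make_screen_world(compounds = list(
    mimic = function(kd, n) kd,
    noise = function(kd, n) rnorm(n)
  ), seed = 2)
  r <- rank_candidates(build_screen_features(w$cmp, w$kd, w$net),
                       min_support = 3L)
  expect_equal(r$compound_id[1], "mimic")
  expect_true(r$qualified[1])
  expect_false(r$qualified[r$compound_id == "noise"])

  # default-scale synthetic screen, fixed seed: planted inhibitor at rank 1
  sim <- simulate_screen(screen_sim_config(n_decoy_compounds = 49L,
                                           n_replicates = 1L,
                                           replicate_fidelity = 1,
                                           mixing_weight = 0.7, seed = 17L))
  kd <- subset_collection(sim$collection,
                          sim$collection$meta$perturbation_type == "knockdown")
  cmp <- subset_collection(sim$collection,
                           sim$collection$meta$perturbation_type == "compound")
  ranking <- rank_candidates(build_screen_features(cmp, kd, sim$network))
  expect_equal(ranking$compound_id[1], sim$truth$planted_compound)
})

test_that("trained ranking places held-out planted inhibitors near the top", {
  skip_if_not_installed("glmnet")
  screens <- lapply(1:6, function(s) {
    sim <- simulate_screen(screen_sim_config(
      n_genes = 200L, n_decoy_compounds = 15L, n_partner_genes = 2L,
      n_replicates = 1L, replicate_fidelity = 1,
      mixing_weight = 0.7, seed = 100L + s))
    kd <- subset_collection(sim$collection,
                            sim$collection$meta$perturbation_type == "knockdown")
    cmp <- subset_collection(sim$collection,
                             sim$collection$meta$perturbation_type == "compound")
    f <- build_screen_features(cmp, kd, sim$network)
    f$compound_id <- paste0("s", s, "_", f$compound_id)
    list(features = f, planted = paste0("s", s, "_", sim$truth$planted_compound))
  })
  all_f <- do.call(bind_screen_features, lapply(screens, `[[`, "features"))
  train_ids <- unlist(lapply(screens[1:5], function(s) unique(s$features$compound_id)))
  training <- tibble::tibble(
    compound_id = train_ids,
    label = train_ids %in% vapply(screens[1:5], `[[`, "", "planted"))
  ranking <- suppressWarnings(  # glmnet notes the small positive class
    rank_candidates(all_f, training = training, min_support = 0L, seed = 7L))
  held_out <- screens[[6]]$planted
  test_ids <- unique(screens[[6]]$features$compound_id)
  pos <- match(held_out, ranking$compound_id[ranking$compound_id %in% test_ids])
  expect_lte(pos, ceiling(0.1 * length(test_ids)))

  bad <- tibble::tibble(compound_id = train_ids[1:4], label = rep(TRUE, 4))
  expect_error(rank_candidates(all_f, training = bad), "composite_score")
})

test_that("panel consensus reproduces fixtures, means, and column permutation", {
  tab1 <- read_signatures(system.file("extdata", "table1_consensus_z.tsv",
                                      package = "foxnet"))
  perts <- unique(tab1$meta$perturbation_id)
  pt <- panel_consensus_table(tab1, tab1$gene_universe, perts)
  expect_equal(pt$STL427944[pt$gene == "BIRC5"], -6.05)
  expect_equal(pt$benzamil[pt$gene == "CDK1"], 0.29)

  # collection column permutation leaves the table unchanged
  perm <- sample(ncol(tab1$values))
  tab1p <- signature_collection(tab1$values[, perm, drop = FALSE],
                                tab1$meta[perm, ])
  expect_equal(as.data.frame(panel_consensus_table(tab1p, tab1$gene_universe, perts)),
               as.data.frame(pt))

  # two replicates with mean aggregation -> hand-computed means
  v <- matrix(c(1, 3, 2, 4, 10, 20, 30, 40), nrow = 2,
              dimnames = list(c("gA", "gB"),
                              c("p1|r1", "p1|r2", "p2|r1", "p2|r2")))
  meta <- tibble::tibble(signature_id = colnames(v),
                         perturbation_id = rep(c("p1", "p2"), each = 2),
                         replicate = rep(1:2, 2))
  cc <- signature_collection(v, meta)
  pm <- panel_consensus_table(cc, c("gA", "gB"), c("p1", "p2"),
                              consensus_spec(method = "mean"))
  expect_equal(pm$p1, c(1.5, 3.5))
  expect_equal(pm$p2, c(20, 30))
  expect_error(panel_consensus_table(cc, "gZ", "p1"), "gZ")
})

test_that("compare_candidates orders by universality then potency", {
  tab1 <- read_signatures(system.file("extdata", "table1_consensus_z.tsv",
                                      package = "foxnet"))
  pt <- panel_consensus_table(tab1, tab1$gene_universe,
                              unique(tab1$meta$perturbation_id))
  cmp <- compare_candidates(pt, c("benzamil", "STL427944"))
  expect_equal(cmp$candidate[1], "STL427944")

  # invariant to panel gene ordering
  shuffled <- panel_consensus_table(tab1, rev(tab1$gene_universe),
                                    unique(tab1$meta$perturbation_id))
  expect_equal(compare_candidates(shuffled, c("benzamil", "STL427944")),
               cmp)

  # all-zero column; constant shift moves mean_z by exactly the shift
  v <- matrix(c(0, 0, 0, -1, -2, -3, -3, -4, -5), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("zero", "x", "x_shift")))
  cc <- signature_collection(v)
  ptz <- panel_consensus_table(cc, c("a", "b", "c"), colnames(v))
  res <- compare_candidates(ptz, colnames(v))
  zero_row <- res[res$candidate == "zero", ]
  expect_equal(zero_row$n_suppressed, 0L)
  expect_equal(zero_row$mean_z, 0)
  expect_equal(res$mean_z[res$candidate == "x_shift"],
               res$mean_z[res$candidate == "x"] - 2)
  expect_error(compare_candidates(ptz, "nope"), "nope")
  expect_error(compare_candidates(ptz, "x", suppression_threshold = 0.5),
               "negative")
})
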