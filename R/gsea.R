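#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' member gene ids. Members are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A tibble of class `gene_sets` with columns `set_name`,
#'   `description`, and a `members` list-column of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  rows <- purrr::map(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort(sprintf("GMT format error at line %d: need name, description and >= 1 member.", i))
    }
    tibble(set_name = fields[1], description = fields[2],
           members = list(unique(fields[-(1:2)])))
  })
  structure(bind_rows(rows), class = c("gene_sets", "tbl_df", "tbl", "data.frame"))
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_sets` tibble as returned by [read_gmt()] (columns
#'   `set_name`, `description`, `members`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    list(sets$set_name, sets$description, sets$members),
    function(nm, desc, mem) paste(c(nm, desc, mem), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Build a ranked gene list
#'
#' Orders genes by the ranking statistic, descending, breaking ties by
#' `gene_id` lexicographic order so the list is strictly ordered and every
#' downstream permutation is deterministic.
#'
#' @param df A data frame with columns `gene_id` and `ranking_value` (or a
#'   DE table with `log2_fc`, used as the default metric).
#' @param metric Which column ranks the list: `"ranking_value"` if present,
#'   else `"log2_fc"` (default) or `"signed_logp"` (sign of `log2_fc` times
#'   `-log10(p_value)`).
#' @return A tibble of class `ranked_list` with columns `gene_id` and
#'   `ranking_value`, sorted descending.
#' @export
ranked_list <- function(df, metric = c("log2_fc", "signed_logp")) {
  df <- as_tibble(df)
  if (!"ranking_value" %in% names(df)) {
    metric <- match.arg(metric)
    if (metric == "log2_fc") {
      df$ranking_value <- df$log2_fc
    } else {
      df$ranking_value <- sign(df$log2_fc) * -log10(pmax(df$p_value, 1e-300))
    }
  }
  if (anyDuplicated(df$gene_id)) abort("Gene ids in a ranked list must be unique.")
  if (anyNA(df$ranking_value) || any(!is.finite(df$ranking_value))) {
    abort("Ranking values must be finite.")
  }
  out <- df |>
    select("gene_id", "ranking_value") |>
    arrange(desc(.data$ranking_value), .data$gene_id)
  structure(out, class = c("ranked_list", class(out)))
}

# Weighted Kolmogorov-Smirnov running-sum extremum from hit positions only.
# positions: sorted 1-based hit indices in the ranked list; wabs: |ranking
# value|^exponent for every list position; N: list length. Returns the signed
# maximum deviation and the index of the peak.
es_from_positions <- function(positions, wabs, N) {
  nh <- length(positions)
  miss_step <- 1 / (N - nh)
  hw <- wabs[positions]
  tot <- sum(hw)
  # Degenerate: all hit weights zero (e.g. exponent * zero values);
  # fall back to equal hit mass, matching the unweighted statistic.
  if (tot <= 0) { hw <- rep(1, nh); tot <- nh }
  cum_hit <- cumsum(hw) / tot
  j <- seq_len(nh)
  after <- cum_hit - (positions - j) * miss_step         # just after hit j
  before <- c(0, cum_hit[-nh]) - (positions - j) * miss_step  # just before hit j
  hi <- max(after); lo <- min(c(before, 0))
  # exact-magnitude ties (common at weight 0) resolve positive by convention
  if (hi >= -lo - 1e-12) {
    list(es = hi, peak = positions[which.max(after)], sign = 1L)
  } else {
    list(es = lo, peak = positions[which.min(before)], sign = -1L)
  }
}

#' Weighted running-sum enrichment score
#'
#' Classical preranked GSEA statistic: walking down the ranked list, hits
#' (genes in the set) increment the running sum in proportion to
#' `|ranking_value|^weight_exponent` (normalized over hits) and misses
#' decrement it by `1/(N - N_hit)`. The enrichment score is the running-sum
#' value of maximal absolute deviation from zero; the leading edge contains
#' the set members at or before the peak for a positive score, at or after it
#' for a negative one. `weight_exponent = 0` gives the unweighted
#' Kolmogorov-Smirnov statistic.
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector of member gene ids, or one row of a
#'   `gene_sets` tibble.
#' @param weight_exponent Non-negative weighting exponent (default 1).
#' @return A list: `es`, `running_sum` (length-N numeric), `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  members <- extract_members(gene_set)
  stopifnot_scalar_number(weight_exponent, "weight_exponent", lower = 0)
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% members
  nh <- sum(hit)
  if (nh == 0L) abort("No gene-set member present in the ranked list.")
  if (nh >= N) abort("The gene set may not cover the whole ranked list.")
  wabs <- abs(ranked$ranking_value)^weight_exponent
  hw <- wabs * hit
  tot <- sum(hw)
  if (tot <= 0) { hw <- as.numeric(hit); tot <- nh }
  steps <- hw / tot - (!hit) / (N - nh)
  running <- cumsum(steps)
  res <- es_from_positions(which(hit), wabs, N)
  leading <- if (res$sign > 0) {
    ranked$gene_id[which(hit & seq_len(N) <= res$peak)]
  } else {
    ranked$gene_id[which(hit & seq_len(N) >= res$peak)]
  }
  list(es = res$es, running_sum = running, leading_edge = leading)
}

extract_members <- function(gene_set) {
  if (is.character(gene_set)) return(unique(gene_set))
  if (is.data.frame(gene_set) && "members" %in% names(gene_set)) {
    if (nrow(gene_set) != 1L) abort("Pass a single gene set (one row) or a character vector.")
    return(unique(gene_set$members[[1]]))
  }
  if (is.list(gene_set) && !is.null(gene_set$members)) return(unique(gene_set$members))
  abort("`gene_set` must be a character vector or a one-row gene_sets tibble.")
}

#' Preranked gene-set enrichment with permutation NES and FDR
#'
#' For every gene set (restricted to the ranked universe and filtered to
#' `[min_size, max_size]`) computes the weighted running-sum enrichment score,
#' then builds a null distribution by gene-label permutation: in each of
#' `n_permutations` rounds the set labels are reassigned to random list
#' positions while the ranking metric stays put. The normalized score divides
#' each ES by the mean magnitude of same-sign null scores of its own set; the
#' nominal p-value is the same-sign null tail fraction (with a +1 continuity
#' correction), and the FDR q-value follows the canonical pooled-null ratio
#' over all sets, capped at 1.
#'
#' @param ranked A [ranked_list()].
#' @param collection A `gene_sets` tibble (from [read_gmt()]) or a named list
#'   of character vectors.
#' @param n_permutations Number of gene-label permutations (>= 100,
#'   default 1000).
#' @param min_size,max_size Set-size bounds after restriction to the ranked
#'   universe (defaults 15 and 500).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param weight_exponent Passed to the enrichment score (default 1).
#' @return A tibble of class `gsea_result`, sorted by `nes`: `set_name`,
#'   `size`, `es`, `nes`, `nominal_p`, `fdr_q`, `leading_edge` (list-column).
#'   Sets with no overlap are dropped with a message.
#' @export
gsea_preranked <- function(ranked, collection, n_permutations = 1000L,
                           min_size = 15L, max_size = 500L, seed = 1L,
                           weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (n_permutations < 100L) abort("`n_permutations` must be at least 100.")
  sets <- normalize_collection(collection)
  N <- nrow(ranked)
  universe <- ranked$gene_id
  idx_list <- purrr::map(sets$members, function(m) which(universe %in% m))
  sizes <- lengths(idx_list)
  no_overlap <- sizes == 0L
  if (any(no_overlap)) {
    inform(sprintf("%d set(s) share no gene with the ranked list and are excluded.",
                   sum(no_overlap)))
  }
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep)) abort("No gene set left after size filtering.")
  sets <- sets[keep, , drop = FALSE]
  idx_list <- idx_list[keep]
  sizes <- sizes[keep]

  wabs <- abs(ranked$ranking_value)^weight_exponent
  obs <- purrr::map(idx_list, function(idx) es_from_positions(sort(idx), wabs, N))
  es <- vapply(obs, `[[`, numeric(1), "es")

  nset <- length(idx_list)
  null_es <- with_seed_(seed, {
    out <- matrix(NA_real_, nrow = n_permutations, ncol = nset)
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(N)
      for (s in seq_len(nset)) {
        pos <- sort(perm[idx_list[[s]]])
        out[b, s] <- es_from_positions(pos, wabs, N)$es
      }
    }
    out
  })

  pos_mean <- vapply(seq_len(nset), function(s) {
    v <- null_es[, s]; v <- v[v > 0]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  neg_mean <- vapply(seq_len(nset), function(s) {
    v <- null_es[, s]; v <- v[v < 0]
    if (length(v)) mean(abs(v)) else NA_real_
  }, numeric(1))

  nes <- ifelse(es >= 0, es / pos_mean, es / neg_mean)
  nominal_p <- vapply(seq_len(nset), function(s) {
    v <- null_es[, s]
    same <- if (es[s] >= 0) v[v >= 0] else v[v < 0]
    (sum(abs(same) >= abs(es[s])) + 1) / (length(same) + 1)
  }, numeric(1))

  null_nes <- null_es
  for (s in seq_len(nset)) {
    v <- null_es[, s]
    null_nes[, s] <- ifelse(v >= 0, v / pos_mean[s], v / neg_mean[s])
  }
  pool <- as.vector(null_nes)
  pool <- pool[is.finite(pool)]
  fdr_q <- vapply(seq_len(nset), function(s) {
    if (!is.finite(nes[s])) return(NA_real_)
    if (nes[s] >= 0) {
      num_den <- sum(pool >= 0)
      num <- if (num_den) sum(pool >= nes[s]) / num_den else 1
      den <- sum(nes >= nes[s], na.rm = TRUE) / max(1, sum(nes >= 0, na.rm = TRUE))
    } else {
      num_den <- sum(pool < 0)
      num <- if (num_den) sum(pool <= nes[s]) / num_den else 1
      den <- sum(nes <= nes[s], na.rm = TRUE) / max(1, sum(nes < 0, na.rm = TRUE))
    }
    min(1, num / den)
  }, numeric(1))

  out <- tibble(
    set_name = sets$set_name,
    size = sizes,
    es = es,
    nes = nes,
    nominal_p = nominal_p,
    fdr_q = fdr_q,
    leading_edge = purrr::map(seq_len(nset), function(s) {
      r <- obs[[s]]
      idx <- sort(idx_list[[s]])
      if (r$sign > 0) universe[idx[idx <= r$peak]] else universe[idx[idx >= r$peak]]
    })
  )
  out <- arrange(out, .data$nes)
  structure(out, class = c("gsea_result", class(out)),
            n_permutations = n_permutations, seed = seed,
            weight_exponent = weight_exponent)
}

normalize_collection <- function(collection) {
  if (is.data.frame(collection)) {
    stopifnot(all(c("set_name", "members") %in% names(collection)))
    return(as_tibble(collection))
  }
  if (is.list(collection)) {
    if (is.null(names(collection))) abort("A list collection must be named.")
    return(tibble(set_name = names(collection),
                  description = "",
                  members = purrr::map(collection, unique)))
  }
  abort("`collection` must be a gene_sets tibble or a named list of character vectors.")
}

#' One-row summary of a GSEA run
#'
#' @param x A `gsea_result` from [gsea_preranked()].
#' @param alpha FDR significance cutoff (default 0.05).
#' @param ... Unused.
#' @return A one-row tibble: `n_sets`, `n_significant`, `n_negative_nes`,
#'   `n_permutations`.
#' @export
glance.gsea_result <- function(x, alpha = 0.05, ...) {
  tibble(
    n_sets = nrow(x),
    n_significant = sum(x$fdr_q < alpha, na.rm = TRUE),
    n_negative_nes = sum(x$nes < 0, na.rm = TRUE),
    n_permutations = attr(x, "n_permutations")
  )
}
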