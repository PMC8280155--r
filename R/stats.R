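#' Exact two-tailed Mann-Whitney U test
#'
#' U is computed from midranks (ties get 0.5 credit). For combined sample
#' sizes up to `exact_limit` the null distribution of the rank sum is built
#' exactly by dynamic programming over the observed (doubled) midranks, which
#' handles ties without approximation; the two-tailed p-value doubles the
#' smaller tail (capped at 1), the convention that yields the printed
#' p = 0.02857 for two fully separated groups of four. Larger samples use the
#' normal approximation with tie correction and continuity correction,
#' flagged `exact = FALSE`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param two_sided `"double"` (default, twice the smaller one-sided tail) or
#'   `"minlike"` (sum of all outcomes no more likely than the observed one).
#' @param exact_limit Largest `n + m` for which the exact distribution is
#'   enumerated (default 25).
#' @return A list of class `mwu`: `u_statistic` (U of `x`), `p_two_tailed`,
#'   `exact`, `n`, `m`, `method`.
#' @export
#' @examples
#' mwu_exact_two_tailed(c(5, 6, 7, 8), c(1, 2, 3, 4))$p_two_tailed  # 2/70
mwu_exact_two_tailed <- function(x, y, two_sided = c("double", "minlike"),
                                 exact_limit = 25L) {
  two_sided <- match.arg(two_sided)
  if (!length(x) || !length(y)) abort("Both groups must be non-empty.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  u <- w_obs - n * (n + 1) / 2

  if (N <= exact_limit) {
    # Null distribution of the doubled rank sum of the x-group via subset-sum
    # DP over the observed doubled midranks (integers even with ties).
    r2 <- as.integer(round(2 * r))
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
    smin <- sum(sort(r2)[seq_len(n)])
    # dp[k+1, s+1] = number of n-subsets of the first i items with doubled sum s
    dp <- matrix(0, nrow = n + 1L, ncol = smax + 1L)
    dp[1L, 1L] <- 1
    for (i in seq_len(N)) {
      kmax <- min(i, n)
      for (k in kmax:1) {
        v <- r2[i]
        src <- dp[k, seq_len(smax + 1L - v)]
        dp[k + 1L, (v + 1L):(smax + 1L)] <-
          dp[k + 1L, (v + 1L):(smax + 1L)] + src
      }
    }
    counts <- dp[n + 1L, ]
    total <- choose(N, n)
    sums <- seq(0L, smax)
    w2_obs <- as.integer(round(2 * w_obs))
    p_low <- sum(counts[sums <= w2_obs]) / total
    p_high <- sum(counts[sums >= w2_obs]) / total
    if (two_sided == "double") {
      p <- min(1, 2 * min(p_low, p_high))
    } else {
      p_obs <- counts[w2_obs + 1L] / total
      probs <- counts[counts > 0] / total
      p <- sum(probs[probs <= p_obs * (1 + 1e-8)])
    }
    res <- list(u_statistic = u, p_two_tailed = p, exact = TRUE,
                n = n, m = m,
                method = sprintf("exact Mann-Whitney U (%s)", two_sided))
  } else {
    mu <- n * m / 2
    ties <- table(r)
    sigma2 <- n * m / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    res <- list(u_statistic = u, p_two_tailed = p, exact = FALSE,
                n = n, m = m,
                method = "Mann-Whitney U, normal approximation with tie correction")
  }
  structure(res, class = "mwu")
}

#' @export
print.mwu <- function(x, ...) {
  cat(sprintf("%s\nU = %.1f (n = %d, m = %d), two-tailed p = %.5g\n",
              x$method, x$u_statistic, x$n, x$m, x$p_two_tailed))
  invisible(x)
}

#' @rdname mwu_exact_two_tailed
#' @param x A `mwu` object.
#' @param ... Unused.
#' @export
tidy.mwu <- function(x, ...) {
  tibble(u_statistic = x$u_statistic, p_value = x$p_two_tailed,
         exact = x$exact, n = x$n, m = x$m, method = x$method)
}

# Accept amplification efficiency either as percent (95-105) or as
# fold-per-cycle (1.95-2.05); values above 3 are treated as percent.
normalize_efficiency <- function(e, name) {
  if (any(e > 3)) {
    inform(sprintf("`%s` interpreted as percent efficiency (%s%%).",
                   name, paste(format(e), collapse = ", ")))
    e <- 1 + e / 100
  }
  if (any(e <= 1)) abort(sprintf("`%s` must exceed 1 fold per cycle.", name))
  if (any(e > 2.2)) warn(sprintf("`%s` above 2.2 fold per cycle is implausible.", name))
  e
}

#' Pfaffl efficiency-corrected relative quantification
#'
#' Relative expression ratio for RT-qPCR:
#' `ratio = e_target^delta_ct_target / e_ref^delta_ct_ref`, where each delta
#' Ct is control minus treated and each `e` is the amplification efficiency in
#' fold per cycle (a perfect doubling is 2). Efficiencies may also be given as
#' percent (e.g. 95 means 1.95), auto-detected by magnitude. With several
#' reference transcripts (e.g. 18S rRNA and TBP) the per-reference ratios are
#' combined by geometric mean.
#'
#' @param e_target Target amplification efficiency (scalar).
#' @param delta_ct_target Target delta Ct in cycles (control - treated).
#' @param e_ref Reference efficiency; a vector when using several references.
#' @param delta_ct_ref Reference delta Ct(s), same length as `e_ref`.
#' @param combine How to combine multiple references: `"geometric_mean"`
#'   (default) or `"none"` (return per-reference ratios).
#' @return The relative expression ratio (> 0), or a vector when
#'   `combine = "none"`.
#' @export
#' @examples
#' pfaffl_ratio(2, 1, 2, 0)                # 2
#' pfaffl_ratio(1.95, 2, 2.0, 1)           # 1.95^2 / 2 = 1.90125
pfaffl_ratio <- function(e_target, delta_ct_target, e_ref, delta_ct_ref,
                         combine = c("geometric_mean", "none")) {
  combine <- match.arg(combine)
  stopifnot_scalar_number(delta_ct_target, "delta_ct_target")
  if (length(e_ref) != length(delta_ct_ref)) {
    abort("`e_ref` and `delta_ct_ref` must have the same length.")
  }
  e_target <- normalize_efficiency(e_target, "e_target")
  e_ref <- normalize_efficiency(e_ref, "e_ref")
  ratios <- e_target^delta_ct_target / e_ref^delta_ct_ref
  if (combine == "none" || length(ratios) == 1L) {
    if (combine == "geometric_mean" && length(ratios) > 1L) {
      return(exp(mean(log(ratios))))
    }
    return(ratios)
  }
  exp(mean(log(ratios)))
}

#' Relative quantification from a Ct table
#'
#' Convenience wrapper computing Pfaffl ratios from a tidy qPCR table with
#' columns `sample` (`"control"`/`"treated"`), `gene`, `ct`, `efficiency`,
#' `is_reference`. Technical replicates (repeated rows per sample/gene) are
#' averaged on the Ct scale before forming delta Ct values; multiple
#' reference genes are combined by geometric mean.
#'
#' @param ct_table A data frame with the columns above.
#' @return A tibble with one row per non-reference gene: `gene`, `ratio`.
#' @export
pfaffl_from_table <- function(ct_table) {
  ct_table <- as_tibble(ct_table)
  needed <- c("sample", "gene", "ct", "efficiency", "is_reference")
  missing_col <- setdiff(needed, names(ct_table))
  if (length(missing_col)) {
    abort(sprintf("qPCR table lacks column(s): %s.",
                  paste(missing_col, collapse = ", ")))
  }
  per_gene <- ct_table |>
    group_by(.data$gene, .data$sample, .data$is_reference) |>
    summarise(ct = mean(.data$ct), efficiency = mean(.data$efficiency),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "ct",
                       id_cols = c("gene", "is_reference", "efficiency")) |>
    mutate(delta_ct = .data$control - .data$treated)
  refs <- filter(per_gene, .data$is_reference)
  if (!nrow(refs)) abort("No reference gene (is_reference = TRUE) in the table.")
  targets <- filter(per_gene, !.data$is_reference)
  purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    tibble(gene = targets$gene[i],
           ratio = pfaffl_ratio(targets$efficiency[i], targets$delta_ct[i],
                                refs$efficiency, refs$delta_ct))
  })
}
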