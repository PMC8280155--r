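#' Benjamini-Hochberg step-up q-values
#'
#' Implements the BH step-up procedure directly:
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * n / j`, capped at 1,
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order; `q >= p`
#'   elementwise.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values)) abort("`p_values` must be numeric.")
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  n <- length(p_values)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  q_sorted <- rev(cummin(rev(p_sorted * n / seq_len(n))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

#' Read a per-gene differential-expression table
#'
#' Expects a TSV with columns `gene_id, log2_fc, p_value` and optionally
#' `fdr` and `biotype`. A named `col_map` can translate other headers into
#' this layout, e.g. `c(gene_id = "Symbol", log2_fc = "logFC",
#' p_value = "PValue", fdr = "FDR")`.
#'
#' @param path Path to the TSV file.
#' @param col_map Optional named character vector mapping the expected column
#'   names (names of the vector) to the file's column names (values).
#' @return A tibble with the canonical columns.
#' @export
read_de_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(df))
    if (length(missing_src)) {
      abort(sprintf("col_map refers to absent column(s): %s.",
                    paste(missing_src, collapse = ", ")))
    }
    for (canon in names(col_map)) names(df)[names(df) == col_map[[canon]]] <- canon
  }
  needed <- c("gene_id", "log2_fc", "p_value")
  missing_col <- setdiff(needed, names(df))
  if (length(missing_col)) {
    abort(sprintf("DE table lacks column(s): %s.", paste(missing_col, collapse = ", ")))
  }
  as_tibble(df)
}

#' Threshold a DE table into up- and down-regulated gene sets
#'
#' Applies the fold-change and FDR rule used for the RNA-seq screen: a gene is
#' up-regulated when its fold change (`2^log2_fc`) is at least
#' `fold_threshold` and its FDR is strictly below `fdr_threshold`;
#' down-regulated when the fold change is at most `1/fold_threshold` under the
#' same FDR rule. The fold boundary is inclusive ("2-fold or higher") and the
#' FDR boundary strict ("q-value < 0.1"). When the table has no usable `fdr`
#' column it is computed from `p_value` with [benjamini_hochberg()]; when both
#' are present and disagree by more than `1e-6` the supplied column wins with
#' a warning (upstream pipelines may have corrected over a different universe).
#'
#' @param table A tibble with columns `gene_id`, `log2_fc`, `p_value`, and
#'   optionally `fdr` and `biotype`.
#' @param fold_threshold Fold-change cutoff, > 1 (default 2).
#' @param fdr_threshold Strict FDR cutoff (default 0.1).
#' @param biotype_filter If set (e.g. `"protein_coding"`), rows with a
#'   different biotype are dropped before thresholding, mirroring the
#'   exclusion of non-protein-coding genes.
#' @return A list of class `de_calls`: `up` and `down` character vectors of
#'   gene ids, plus `n_universe`, the number of genes evaluated after the
#'   biotype filter.
#' @export
filter_de <- function(table, fold_threshold = 2, fdr_threshold = 0.1,
                      biotype_filter = NULL) {
  stopifnot_scalar_number(fold_threshold, "fold_threshold")
  if (fold_threshold <= 1) abort("`fold_threshold` must be > 1.")
  stopifnot_scalar_number(fdr_threshold, "fdr_threshold", 0, 1)
  table <- as_tibble(table)
  if (!is.null(biotype_filter)) {
    if (!"biotype" %in% names(table)) {
      abort("`biotype_filter` given but the table has no `biotype` column.")
    }
    table <- filter(table, .data$biotype == biotype_filter)
  }
  if (anyDuplicated(table$gene_id)) {
    dup <- table$gene_id[duplicated(table$gene_id)][1L]
    abort(sprintf("Duplicate gene_id in DE table: '%s'.", dup))
  }
  recomputed <- benjamini_hochberg(table$p_value)
  if (!"fdr" %in% names(table) || all(is.na(table$fdr))) {
    fdr <- recomputed
  } else {
    fdr <- table$fdr
    if (max(abs(fdr - recomputed)) > 1e-6) {
      warn(paste("Supplied fdr column differs from recomputed Benjamini-Hochberg",
                 "q-values; trusting the supplied column."))
    }
  }
  lfc_cut <- log2(fold_threshold)
  sig <- fdr < fdr_threshold
  structure(
    list(up = table$gene_id[sig & table$log2_fc >= lfc_cut],
         down = table$gene_id[sig & table$log2_fc <= -lfc_cut],
         n_universe = nrow(table)),
    class = "de_calls"
  )
}

#' Intersect two models' DE calls codirectionally
#'
#' Genes significantly changed in the same direction in both cell models are
#' the reliable responders: `up_both` and `down_both` form the combined
#' signature, while genes significant in both models with opposite signs are
#' reported as `discordant`. On the published STL427944 RNA-seq this
#' accounting reads 1341 both-significant = 577 up + 687 down + 77 discordant,
#' with the 1264-gene combined "STL signature".
#'
#' @param model_a,model_b `de_calls` lists from [filter_de()] (or plain lists
#'   with `up` and `down` character vectors).
#' @return An object of class `de_signature`: `up_both`, `down_both`,
#'   `discordant`, `combined` (union of the first two) and
#'   `per_model_significant`.
#' @export
codirectional_intersection <- function(model_a, model_b) {
  check_calls <- function(m, nm) {
    if (!all(c("up", "down") %in% names(m))) {
      abort(sprintf("`%s` must have `up` and `down` gene sets.", nm))
    }
    both <- intersect(m$up, m$down)
    if (length(both)) {
      abort(sprintf("Gene(s) in both up and down of %s: %s.", nm,
                    paste(head(both, 3), collapse = ", ")))
    }
  }
  check_calls(model_a, "model_a"); check_calls(model_b, "model_b")
  up_both <- intersect(model_a$up, model_b$up)
  down_both <- intersect(model_a$down, model_b$down)
  discordant <- union(intersect(model_a$up, model_b$down),
                      intersect(model_a$down, model_b$up))
  structure(
    list(up_both = up_both, down_both = down_both, discordant = discordant,
         combined = union(up_both, down_both),
         per_model_significant = list(model_a = union(model_a$up, model_a$down),
                                      model_b = union(model_b$up, model_b$down))),
    class = "de_signature"
  )
}

#' @export
print.de_signature <- function(x, ...) {
  cat("<de_signature>\n")
  cat(sprintf("  up in both:   %d\n", length(x$up_both)))
  cat(sprintf("  down in both: %d\n", length(x$down_both)))
  cat(sprintf("  discordant:   %d\n", length(x$discordant)))
  cat(sprintf("  combined signature: %d genes\n", length(x$combined)))
  invisible(x)
}

#' Per-gene membership of a codirectional DE signature
#'
#' @param x A `de_signature` from [codirectional_intersection()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id` and `category` (`up_both`,
#'   `down_both`, `discordant`).
#' @export
tidy.de_signature <- function(x, ...) {
  bind_rows(
    tibble(gene_id = x$up_both, category = "up_both"),
    tibble(gene_id = x$down_both, category = "down_both"),
    tibble(gene_id = x$discordant, category = "discordant")
  )
}

#' One-row summary of a codirectional DE signature
#'
#' @param x A `de_signature` from [codirectional_intersection()].
#' @param ... Unused.
#' @return A one-row tibble: `n_up_both`, `n_down_both`, `n_discordant`,
#'   `n_combined`, `n_both_significant`.
#' @export
glance.de_signature <- function(x, ...) {
  tibble(
    n_up_both = length(x$up_both),
    n_down_both = length(x$down_both),
    n_discordant = length(x$discordant),
    n_combined = length(x$combined),
    n_both_significant = length(x$up_both) + length(x$down_both) +
      length(x$discordant)
  )
}

#' Write a DE signature to disk
#'
#' Writes `signature.json` (all sets plus counts) and three plain-text gene
#' lists (`up_both.txt`, `down_both.txt`, `discordant.txt`) into `dir`.
#'
#' @param x A `de_signature`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_de_signature <- function(x, dir) {
  stopifnot(inherits(x, "de_signature"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(counts = as.list(glance(x)),
         up_both = x$up_both, down_both = x$down_both,
         discordant = x$discordant, combined = x$combined),
    file.path(dir, "signature.json"), auto_unbox = TRUE, digits = NA
  )
  writeLines(x$up_both, file.path(dir, "up_both.txt"))
  writeLines(x$down_both, file.path(dir, "down_both.txt"))
  writeLines(x$discordant, file.path(dir, "discordant.txt"))
  invisible(dir)
}
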