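#' Perturbation signature collections
#'
#' A signature collection holds per-gene differential-expression z-scores for a
#' set of perturbations (gene knockdowns, compound treatments, controls)
#' profiled across cell lines, in the style of the LINCS L1000 compendium.
#' Values are stored as a genes-by-signatures numeric matrix together with a
#' metadata table keyed by signature column.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   signatures in columns (colnames are signature ids). All values must be
#'   finite and there must be at least 2 genes.
#' @param meta A data frame with one row per column of `values`. Recognised
#'   columns: `signature_id`, `perturbation_id`, `cell_line`,
#'   `perturbation_type` (one of `"knockdown"`, `"compound"`, `"control"`),
#'   `target_gene`, `replicate`. Missing metadata columns are filled with
#'   defaults (each column its own perturbation, unknown cell line, compound
#'   type, replicate 1).
#'
#' @return An object of class `signature_collection`: a list with elements
#'   `values` (the matrix), `meta` (a tibble), and `gene_universe`
#'   (the ordered rownames).
#' @export
#' @examples
#' m <- matrix(rnorm(6), nrow = 3,
#'             dimnames = list(c("TP53", "MYC", "PLK1"), c("sig1", "sig2")))
#' sc <- signature_collection(m)
#' sc
signature_collection <- function(values, meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x signatures).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene ids as rownames and signature ids as colnames.")
  }
  if (nrow(values) < 2L) abort("A signature needs at least 2 genes.")
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    abort(sprintf("Duplicate gene id in signature matrix: '%s'.", dup))
  }
  if (anyDuplicated(colnames(values))) {
    abort("Signature ids (column names) must be unique.")
  }
  if (!all(is.finite(values))) abort("All z-score values must be finite.")

  if (is.null(meta)) {
    meta <- tibble(signature_id = colnames(values))
  } else {
    meta <- as_tibble(meta)
    if (!"signature_id" %in% names(meta)) {
      if (!"perturbation_id" %in% names(meta)) {
        abort("`meta` needs a `signature_id` or `perturbation_id` column.")
      }
      meta$signature_id <- meta$perturbation_id
    }
  }
  defaults <- list(
    perturbation_id = meta$signature_id,
    cell_line = "unknown",
    perturbation_type = "compound",
    target_gene = NA_character_,
    replicate = 1L
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(meta)) meta[[nm]] <- defaults[[nm]]
  }
  bad_type <- setdiff(unique(meta$perturbation_type),
                      c("knockdown", "compound", "control"))
  if (length(bad_type)) {
    abort(sprintf("Unknown perturbation_type: %s.",
                  paste(sQuote(bad_type), collapse = ", ")))
  }
  missing_meta <- setdiff(colnames(values), meta$signature_id)
  if (length(missing_meta)) {
    abort(sprintf("Metadata missing for signature(s): %s.",
                  paste(head(missing_meta, 3), collapse = ", ")))
  }
  meta <- meta[match(colnames(values), meta$signature_id), , drop = FALSE]
  key <- paste(meta$perturbation_id, meta$cell_line, meta$replicate)
  if (anyDuplicated(key)) {
    abort("(perturbation_id, cell_line, replicate) must be unique across signatures.")
  }
  structure(
    list(values = values, meta = meta, gene_universe = rownames(values)),
    class = "signature_collection"
  )
}

#' @export
print.signature_collection <- function(x, ...) {
  cat(sprintf("<signature_collection> %d genes x %d signatures\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  cell lines: %s\n",
              paste(sort(unique(x$meta$cell_line)), collapse = ", ")))
  tab <- table(x$meta$perturbation_type)
  cat(sprintf("  perturbation types: %s\n",
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.signature_collection <- function(x) dim(x$values)

#' Turn a signature collection into a long tibble
#'
#' @param x A [signature_collection()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `signature_id`, `z`, joined with
#'   the signature metadata.
#' @export
tidy.signature_collection <- function(x, ...) {
  long <- tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    signature_id = rep(colnames(x$values), each = nrow(x$values)),
    z = as.vector(x$values)
  )
  left_join(long, x$meta, by = "signature_id")
}

#' Read a signature matrix in GCT-like TSV format
#'
#' The expected layout is a tab-separated file whose first column (`gene_id`)
#' holds gene identifiers and whose remaining columns hold one perturbation
#' signature each (z-scores). A companion metadata table
#' (`<path-without-.tsv>.meta.tsv`, or `meta_path`) with columns
#' `perturbation_id, cell_line, perturbation_type, target_gene, replicate`
#' (and optionally `signature_id`) is attached when present.
#'
#' @param path Path to the signature TSV.
#' @param meta_path Optional path to the metadata TSV; defaults to the
#'   companion file next to `path` when it exists.
#' @return A [signature_collection()] whose `gene_universe` preserves the file
#'   row order.
#' @export
read_signatures <- function(path, meta_path = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "gene_id") {
    abort("Malformed header: first column must be named 'gene_id' followed by perturbation columns.")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (anyDuplicated(df$gene_id)) {
    dup <- df$gene_id[duplicated(df$gene_id)][1L]
    abort(sprintf("Duplicate gene id in '%s': '%s'.", path, dup))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (is.null(meta_path)) {
    candidate <- sub("\\.tsv$", ".meta.tsv", path)
    if (candidate != path && file.exists(candidate)) meta_path <- candidate
  }
  meta <- if (!is.null(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  signature_collection(m, meta)
}

#' Write a signature collection as GCT-like TSV
#'
#' Writes the value matrix to `path` and, unless `meta_path` is `NULL`,
#' the metadata to the companion `.meta.tsv`. The canonical number formatting
#' (shortest round-tripping decimal) makes `write_signatures(read_signatures(f))`
#' byte-identical for files produced by this writer.
#'
#' @param x A [signature_collection()].
#' @param path Output TSV path.
#' @param meta_path Output metadata path; default replaces a trailing `.tsv`
#'   with `.meta.tsv`. Use `NULL` to skip writing metadata.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(x, path, meta_path = sub("\\.tsv$", ".meta.tsv", path)) {
  stopifnot(inherits(x, "signature_collection"))
  df <- tibble(gene_id = rownames(x$values))
  for (j in colnames(x$values)) df[[j]] <- x$values[, j]
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(meta_path)) {
    readr::write_tsv(x$meta, meta_path, progress = FALSE)
  }
  invisible(path)
}

#' Specify how replicate signatures are aggregated into a consensus
#'
#' The default is a MODZ-style weighted average in the LINCS tradition: each
#' replicate is weighted by its summed rank correlation with the other
#' replicates (floored, then normalized to sum to 1), so discordant replicates
#' are down-weighted. `median` and `mean` are plain per-gene aggregations.
#'
#' @param method `"weighted_modz"` (default), `"median"` or `"mean"`.
#' @param weight_floor Lower bound applied to each replicate's summed
#'   correlation before normalization; must be positive (default 0.01).
#' @param correlation Correlation used for the weights, `"spearman"`
#'   (default) or `"pearson"`.
#' @return A `consensus_spec` list.
#' @export
consensus_spec <- function(method = c("weighted_modz", "median", "mean"),
                           weight_floor = 0.01,
                           correlation = c("spearman", "pearson")) {
  method <- match.arg(method)
  correlation <- match.arg(correlation)
  stopifnot_scalar_number(weight_floor, "weight_floor")
  if (weight_floor <= 0) abort("`weight_floor` must be > 0.")
  structure(list(method = method, weight_floor = weight_floor,
                 correlation = correlation),
            class = "consensus_spec")
}

#' Aggregate replicate signatures into a consensus signature
#'
#' @param replicates A numeric matrix (genes x replicates, rownames = gene
#'   ids), a data frame of the same shape, or a list of named numeric vectors
#'   sharing the same gene set.
#' @param spec A [consensus_spec()].
#' @return A named numeric vector of consensus z-scores over the shared gene
#'   set. A single replicate is returned unchanged; the result does not depend
#'   on replicate order.
#' @export
#' @examples
#' reps <- cbind(r1 = c(a = 1, b = 2, c = 3), r2 = c(a = 1.2, b = 1.9, c = 3.3))
#' consensus_signature(reps)
consensus_signature <- function(replicates, spec = consensus_spec()) {
  m <- as_replicate_matrix(replicates)
  if (ncol(m) == 0L) abort("Need at least one replicate.")
  if (ncol(m) == 1L) return(setNames(m[, 1L], rownames(m)))
  out <- switch(
    spec$method,
    mean   = rowMeans(m),
    median = apply(m, 1L, median),
    weighted_modz = {
      w <- modz_weights(m, spec)
      as.vector(m %*% w)
    }
  )
  setNames(out, rownames(m))
}

# MODZ replicate weights: w_i proportional to max(floor, sum_{j != i} corr_ij),
# normalized to sum 1.
modz_weights <- function(m, spec = consensus_spec()) {
  cc <- cor(m, method = spec$correlation)
  raw <- colSums(cc) - diag(cc)
  raw[!is.finite(raw)] <- spec$weight_floor
  w <- pmax(raw, spec$weight_floor)
  w / sum(w)
}

as_replicate_matrix <- function(replicates) {
  if (is.list(replicates) && !is.data.frame(replicates)) {
    if (!length(replicates)) abort("Need at least one replicate.")
    genes <- names(replicates[[1L]])
    if (is.null(genes)) abort("Replicate vectors must be named by gene id.")
    for (r in replicates) {
      if (!setequal(names(r), genes)) abort("Replicates must share the same gene set.")
    }
    m <- vapply(replicates, function(r) r[genes], numeric(length(genes)))
    rownames(m) <- genes
    return(m)
  }
  if (is.data.frame(replicates)) replicates <- as.matrix(replicates)
  if (!is.matrix(replicates) || !is.numeric(replicates)) {
    abort("`replicates` must be a numeric matrix, data frame, or list of named vectors.")
  }
  if (is.null(rownames(replicates))) abort("Replicate matrix must have gene rownames.")
  replicates
}

#' Correlation similarity between two signatures
#'
#' Signatures are compared on the intersection of their gene sets (genes absent
#' from either are dropped, never imputed). Spearman (default) uses average
#' ranks for ties, the convention that makes similarity invariant under any
#' strictly monotone transform of either signature.
#'
#' @param a,b Named numeric vectors of z-scores (names are gene ids).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param top_n If set, restrict to the `top_n` genes of `a` by absolute
#'   z-score before intersecting with `b`. Note this breaks symmetry in
#'   `(a, b)`.
#' @return A correlation in \[-1, 1\].
#' @export
#' @examples
#' a <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4, g5 = 5)
#' b <- c(g1 = 1, g2 = 3, g3 = 2, g4 = 5, g5 = 4)
#' signature_similarity(a, b)  # 0.8
signature_similarity <- function(a, b, method = c("spearman", "pearson"),
                                 top_n = NULL) {
  method <- match.arg(method)
  if (is.null(names(a)) || is.null(names(b))) {
    abort("Signatures must be named numeric vectors (names = gene ids).")
  }
  if (!is.null(top_n)) {
    top_n <- min(as.integer(top_n), length(a))
    keep <- names(a)[order(abs(a), decreasing = TRUE)][seq_len(top_n)]
    a <- a[keep]
  }
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) {
    abort(sprintf("Signatures share only %d gene(s); need at least 3.", length(shared)))
  }
  cor(a[shared], b[shared], method = method)
}

# Collapse a collection to one consensus signature per (perturbation_id,
# cell_line) group. Returns a list: values matrix + per-group metadata.
collapse_replicates <- function(collection, spec = consensus_spec()) {
  stopifnot(inherits(collection, "signature_collection"))
  meta <- collection$meta
  key <- paste(meta$perturbation_id, meta$cell_line, sep = "\r")
  groups <- split(seq_len(nrow(meta)), key)
  vals <- vapply(groups, function(idx) {
    consensus_signature(collection$values[, idx, drop = FALSE], spec)
  }, numeric(nrow(collection$values)))
  first <- vapply(groups, `[`, integer(1), 1L)
  gmeta <- meta[first, c("perturbation_id", "cell_line", "perturbation_type",
                         "target_gene")]
  colnames(vals) <- paste(gmeta$perturbation_id, gmeta$cell_line, sep = "|")
  rownames(vals) <- rownames(collection$values)
  list(values = vals, meta = gmeta)
}
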