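# Independent brute-force oracles, deliberately naive implementations.

# Literal BH step-up definition: q_i = min over j with p_(j) >= p_(i) of
# p_(j) * n / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(p[ord] >= p[i] - 1e-15)
    q[i] <- min(1, min(p[ord][js] * n / js))
  }
  q
}

# Exact Mann-Whitney two-tailed p by full enumeration of rank assignments.
mwu_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  subsets <- utils::combn(n + m, n)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  p_low <- mean(w_all <= w_obs + 1e-9)
  p_high <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

# Literal weighted running-sum enrichment score: walk the list one gene at a
# time and keep the signed maximum deviation.
es_oracle <- function(ranked_values, hit, weight_exponent = 1) {
  N <- length(ranked_values)
  nh <- sum(hit)
  w <- abs(ranked_values)^weight_exponent
  hit_mass <- sum(w[hit])
  if (hit_mass <= 0) { w <- rep(1, N); hit_mass <- nh }
  running <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) w[i] / hit_mass else -1 / (N - nh)
    running[i] <- acc
  }
  hi <- max(c(running, 0)); lo <- min(c(running, 0))
  # signed maximum deviation; an exact tie resolves positive by convention
  if (hi >= -lo - 1e-12) hi else lo
}

# MODZ replicate weights computed longhand from the pairwise correlations.
modz_weights_oracle <- function(m, floor = 0.01, method = "spearman") {
  k <- ncol(m)
  raw <- numeric(k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) raw[i] <- raw[i] + cor(m[, i], m[, j], method = method)
    }
  }
  w <- pmax(raw, floor)
  w / sum(w)
}

# Rebuild a screen_features object after row-binding several of them
# (attributes do not survive bind_rows).
bind_screen_features <- function(..., support_threshold = 0.3) {
  parts <- list(...)
  out <- dplyr::bind_rows(lapply(parts, as.data.frame))
  structure(tibble::as_tibble(out),
            class = c("screen_features", class(tibble::tibble())),
            support_threshold = support_threshold,
            all_compounds = unique(out$compound_id),
            proxy_target = attr(parts[[1]], "proxy_target"))
}

# Tiny hand-made signature collection: values is a genes x signatures matrix.
make_collection <- function(values, ...) {
  meta <- tibble::tibble(signature_id = colnames(values), ...)
  foxnet::signature_collection(values, meta)
}
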