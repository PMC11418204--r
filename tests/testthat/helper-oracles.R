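# Independent reference implementations used as oracles. These are written
# directly from the textbook definitions and never call the package code
# paths they check.

# Benjamini-Hochberg step-up, literal definition: sort ascending, the
# adjusted value of the i-th smallest p is min_{j >= i} min(1, N p_(j) / j).
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(pmin(1, n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Step-by-step ROUT reference for the constant model: median fit, RSDR from
# the 68.27th percentile of absolute residuals with the n/(n-K) correction,
# then flag the i-th most extreme residual while its two-sided t p-value
# (df = n - K) stays below i*q/n.
rout_reference <- function(values, q) {
  n <- length(values)
  r <- values - median(values)
  rsdr <- quantile(abs(r), 0.6827, names = FALSE, type = 7) * n / (n - 1)
  flagged <- logical(n)
  if (rsdr > 0) {
    p <- 2 * pt(abs(r) / rsdr, df = n - 1, lower.tail = FALSE)
    ord <- order(p)
    for (i in seq_len(n)) {
      if (p[ord[i]] < q * i / n) flagged[ord[i]] <- TRUE else break
    }
  }
  flagged
}

# Textbook Welch one-way ANOVA.
welch_formula <- function(groups) {
  k <- length(groups)
  ni <- lengths(groups)
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  wi <- ni / vi
  W <- sum(wi)
  mw <- sum(wi * mi) / W
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  tmp <- sum((1 - wi / W)^2 / (ni - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * tmp
  Fv <- A / B
  df2 <- (k^2 - 1) / (3 * tmp)
  list(statistic = Fv, p = pf(Fv, k - 1, df2, lower.tail = FALSE))
}

# Prevalence rule by explicit loops: keep metabolite iff some group detects
# it in at least half its samples.
prevalence_bruteforce <- function(conc, group) {
  keep <- logical(nrow(conc))
  for (i in seq_len(nrow(conc))) {
    for (g in unique(group)) {
      idx <- which(group == g)
      det <- sum(!is.na(conc[i, idx]) & conc[i, idx] > 0)
      if (2 * det >= length(idx)) keep[i] <- TRUE
    }
  }
  keep
}

# Exclusive intersection regions of named sets by direct set algebra.
regions_bruteforce <- function(sets, universe) {
  nm <- names(sets)
  out <- list()
  for (mask in seq_len(2^length(nm) - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_along(nm) - 1)))
    members <- universe
    for (j in seq_along(nm)) {
      members <- if (inset[j]) intersect(members, sets[[j]])
      else setdiff(members, sets[[j]])
    }
    if (length(members))
      out[[paste(nm[inset], collapse = "&")]] <- length(members)
  }
  out
}

# Brute-force per-vitamin S/D aggregation: explicit loop over annotation
# records and TOTAL rows.
aggregate_bruteforce <- function(tab, ann_df) {
  denom <- colSums(tab$abund[is.na(tab$taxon), , drop = FALSE])
  samples <- colnames(tab$abund)
  res <- list()
  for (v in sort(unique(ann_df$vitamin))) {
    for (r in c("S", "D")) {
      acc <- setNames(numeric(length(samples)), samples)
      for (k in seq_len(nrow(ann_df))) {
        if (ann_df$vitamin[k] != v || ann_df$role[k] != r) next
        hit <- which(is.na(tab$taxon) & tab$feature == ann_df$feature_id[k])
        for (h in hit) acc <- acc + tab$abund[h, ]
      }
      res[[paste(v, r)]] <- 100 * acc / denom
    }
  }
  res
}
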