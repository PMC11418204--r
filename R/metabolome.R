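#' @title Metabolome preprocessing and set analysis
#' @description Concentration-table container, group-prevalence filter,
#'   size-factor normalization with log10 transform and per-metabolite
#'   autoscaling, reference-coded differential ranking, Ward-ordered
#'   heatmap row ordering, and set-based classification of
#'   microbiota-dependent metabolites.
#' @name metabolome
NULL

#' Construct a metabolome table
#'
#' @param conc Numeric matrix, metabolites x samples; concentrations
#'   (e.g. nmol per g cecal content, or uM serum); `NA` marks a
#'   non-detected value (a stored 0 is likewise treated as non-detected
#'   by the detection call).
#' @param sample_meta Data frame with columns `sample_id`, `diet_group`,
#'   `colonization`, `compartment` (uniform within a table, `"cecum"` or
#'   `"serum"`), `size_factor` (cecal weight in g, or serum volume in uL;
#'   strictly positive).
#' @return An object of class `metab_table`.
#' @export
metabolome_table <- function(conc, sample_meta) {
  stopifnot(is.matrix(conc), is.numeric(conc), is.data.frame(sample_meta))
  req <- c("sample_id", "diet_group", "colonization", "compartment",
           "size_factor")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    stop("sample_meta missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(rownames(conc)) || anyDuplicated(rownames(conc)))
    stop("`conc` needs unique metabolite row names")
  if (is.null(colnames(conc)) || anyDuplicated(colnames(conc)))
    stop("`conc` needs unique sample column names")
  if (!all(colnames(conc) %in% sample_meta$sample_id))
    stop("sample_meta is missing sample(s): ",
         paste(setdiff(colnames(conc), sample_meta$sample_id), collapse = ", "))
  sample_meta <-
    sample_meta[match(colnames(conc), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  if (any(conc[!is.na(conc)] < 0))
    stop("concentrations must be >= 0 where present")
  if (any(!is.finite(sample_meta$size_factor)) ||
      any(sample_meta$size_factor <= 0))
    stop("size_factor must be > 0 for every sample")
  if (length(unique(sample_meta$compartment)) != 1L)
    stop("compartment must be uniform within a table")
  structure(list(conc = conc, sample_meta = sample_meta),
            class = "metab_table")
}

#' @export
print.metab_table <- function(x, ...) {
  cat("Metabolome table (", x$sample_meta$compartment[1], "): ",
      nrow(x$conc), " metabolites x ", ncol(x$conc), " samples\n", sep = "")
  invisible(x)
}

#' Read a metabolome table from TSV/CSV
#'
#' Wide table: first column the metabolite name, one column per sample;
#' companion metadata TSV with columns `sample_id`, `diet_group`,
#' `colonization`, `compartment`, `size_factor`. Empty cells are read as
#' non-detected.
#'
#' @param path Path to the concentration table (TSV, or CSV if the name
#'   ends in `.csv`).
#' @param meta_path Path to the sample-metadata TSV.
#' @return A `metab_table`.
#' @export
read_metabolome <- function(path, meta_path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                          check.names = FALSE)
  conc <- as.matrix(df[, -1L, drop = FALSE])
  rownames(conc) <- df[[1L]]
  meta <- utils::read.delim(meta_path, sep = "\t", header = TRUE)
  metabolome_table(conc, meta)
}

met_detected <- function(conc) !is.na(conc) & conc > 0

met_group_labels <- function(tab) {
  paste(tab$sample_meta$colonization, tab$sample_meta$diet_group, sep = ":")
}

#' Group-prevalence filter
#'
#' Keeps metabolite m iff there is at least one experimental group g
#' (diet x colonization) in which m is detected in at least half of the
#' samples, i.e. `2 * detected_count(m, g) >= n_g` (the integer
#' inequality avoids float rounding ambiguity). Dropped metabolites are
#' recorded in the `"dropped"` attribute.
#'
#' @param tab A `metab_table` with group labels assigned to all samples.
#' @return The filtered `metab_table`.
#' @export
prevalence_filter <- function(tab) {
  stopifnot(inherits(tab, "metab_table"))
  g <- met_group_labels(tab)
  if (any(is.na(g) | !nzchar(gsub(":", "", g))))
    stop("every sample needs a diet_group and colonization label")
  det <- met_detected(tab$conc)
  keep <- rep(FALSE, nrow(det))
  for (lvl in unique(g)) {
    idx <- g == lvl
    n_g <- sum(idx)
    if (n_g == 0L) stop("empty group: ", lvl)
    keep <- keep | (2L * rowSums(det[, idx, drop = FALSE]) >= n_g)
  }
  dropped <- rownames(tab$conc)[!keep]
  tab$conc <- tab$conc[keep, , drop = FALSE]
  attr(tab, "dropped") <- dropped
  tab
}

#' Normalize, log-transform and autoscale
#'
#' Per sample, concentrations are divided by the size factor (cecal
#' weight or serum volume); non-detected values (missing or zero) are
#' imputed as one-fifth of the metabolite's minimum observed normalized
#' value; values are log10-transformed; each metabolite row is then
#' autoscaled (mean-centered, divided by its sample standard deviation,
#' n-1 denominator). Rows with zero variance after transformation are
#' dropped with a message. Apply [prevalence_filter()] first so every row
#' has at least one observed value.
#'
#' @param tab A `metab_table` (prevalence-filtered).
#' @return A numeric matrix of class `scaled_matrix` with attributes
#'   `provenance` (list: `normalized`, `log_base`, `imputation_rule`) and
#'   `sample_meta`.
#' @export
normalize_log_scale <- function(tab) {
  stopifnot(inherits(tab, "metab_table"))
  mat <- sweep(tab$conc, 2L, tab$sample_meta$size_factor, `/`)
  det <- met_detected(tab$conc)
  if (any(rowSums(det) == 0L))
    stop("metabolite(s) with no observed value: ",
         paste(rownames(mat)[rowSums(det) == 0L], collapse = ", "),
         " (apply prevalence_filter first)")
  for (i in seq_len(nrow(mat))) {
    if (all(det[i, ])) next
    floor_i <- min(mat[i, det[i, ]]) / 5
    mat[i, !det[i, ]] <- floor_i
  }
  lg <- log10(mat)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1L, stats::sd)
  zero_var <- sdv == 0
  if (any(zero_var)) {
    message("dropping zero-variance metabolite row(s): ",
            paste(rownames(lg)[zero_var], collapse = ", "))
    lg <- lg[!zero_var, , drop = FALSE]
    mu <- mu[!zero_var]
    sdv <- sdv[!zero_var]
  }
  z <- (lg - mu) / sdv
  structure(z,
            provenance = list(normalized = TRUE, log_base = 10,
                              imputation_rule = "min_observed/5"),
            sample_meta = tab$sample_meta,
            class = c("scaled_matrix", "matrix", "array"))
}

#' Reference-coded differential ranking
#'
#' Fits, per metabolite, a linear model of the autoscaled value on the
#' group factor (reference-coded with `reference_group` as baseline) and
#' ranks metabolites by the overall F-test p-value, BH-adjusted across
#' metabolites. With `moderation = TRUE` the per-metabolite variances are
#' moderated by empirical-Bayes pooling (limma); otherwise ordinary
#' least-squares F tests are used.
#'
#' @param z A `scaled_matrix`.
#' @param reference_group Baseline group label (a level of `groups`).
#' @param k Number of top metabolites to return (lowest raw p first;
#'   `k` larger than the metabolite count returns all, with a message).
#' @param groups Optional character vector of group labels aligned to the
#'   columns of `z`; defaults to the `diet_group` of the attached sample
#'   metadata.
#' @param moderation Use empirical-Bayes variance moderation?
#' @return Data frame `metabolite`, `statistic` (F), `p_raw`, `p_adj`,
#'   `rank`, ordered by ascending raw p.
#' @export
differential_rank <- function(z, reference_group, k = 50, groups = NULL,
                              moderation = FALSE) {
  stopifnot(inherits(z, "scaled_matrix"))
  if (is.null(groups)) {
    meta <- attr(z, "sample_meta")
    if (is.null(meta)) stop("no `groups` given and no sample_meta attached")
    groups <- meta$diet_group
  }
  if (length(groups) != ncol(z))
    stop("`groups` must align with the columns of `z`")
  if (!(reference_group %in% groups))
    stop("reference_group '", reference_group, "' not present")
  fac <- stats::relevel(factor(groups), ref = reference_group)
  if (nlevels(fac) < 2L) stop("need >= 2 groups")
  X <- stats::model.matrix(~fac)
  n <- ncol(z)
  df1 <- nlevels(fac) - 1L
  df2 <- n - nlevels(fac)
  if (df2 < 1L) stop("no residual degrees of freedom")

  if (moderation) {
    fit <- limma::eBayes(limma::lmFit(unclass(z), X))
    fstat <- fit$F
    pvals <- fit$F.p.value
  } else {
    # ordinary F test, vectorised over rows: compare group-mean fit to
    # intercept-only fit
    H <- X %*% solve(crossprod(X), t(X))
    fitted <- unclass(z) %*% t(H)
    rss1 <- rowSums((unclass(z) - fitted)^2)
    rowmu <- rowMeans(z)
    rss0 <- rowSums((unclass(z) - rowmu)^2)
    fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    pvals <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  res <- data.frame(metabolite = rownames(z), statistic = fstat,
                    p_raw = pvals, p_adj = bh_adjust(pvals),
                    row.names = NULL)
  res <- res[order(res$p_raw, res$metabolite), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  if (k > nrow(res)) {
    message("k = ", k, " exceeds metabolite count; returning all ", nrow(res))
    k <- nrow(res)
  }
  rownames(res) <- NULL
  res[seq_len(k), , drop = FALSE]
}

#' Per-group detection sets and exclusive intersection regions
#'
#' Calls a metabolite "present" in a sample iff its concentration is
#' reported and positive, and "present in a group" iff present in at
#' least one sample of the group. Returns the per-group detected sets and
#' the counts of all exclusive intersection regions (UpSet-style: each
#' metabolite counted in exactly one region).
#'
#' @param tab A `metab_table`, or a named list of `metab_table`s (one per
#'   colonization state) sharing the same metabolite universe.
#' @param diet Optional diet label; samples are restricted to this diet
#'   before computing sets.
#' @param group_by Metadata column defining the sets (default
#'   `"colonization"`).
#' @return An object of class `detection_sets`: list with `sets` (named
#'   list of metabolite character vectors), `regions` (data frame
#'   `region` — set names joined by `&` — and `count`), and `universe`.
#' @export
detection_sets <- function(tab, diet = NULL, group_by = "colonization") {
  if (inherits(tab, "metab_table")) tabs <- split_metab_by(tab, group_by)
  else if (is.list(tab) && all(vapply(tab, inherits, TRUE, "metab_table")))
    tabs <- tab
  else stop("`tab` must be a metab_table or a named list of them")
  if (is.null(names(tabs)) || any(!nzchar(names(tabs))))
    stop("detection sets need named groups")
  universe <- rownames(tabs[[1L]]$conc)
  for (nm in names(tabs)) {
    u <- rownames(tabs[[nm]]$conc)
    if (!identical(sort(u), sort(universe)))
      stop("inconsistent metabolite universe in '", nm, "': differs by ",
           paste(union(setdiff(u, universe), setdiff(universe, u)),
                 collapse = ", "))
  }
  sets <- lapply(tabs, function(t2) {
    keep <- rep(TRUE, ncol(t2$conc))
    if (!is.null(diet)) keep <- t2$sample_meta$diet_group == diet
    if (!any(keep)) stop("no samples for diet '", diet, "'")
    det <- met_detected(t2$conc[, keep, drop = FALSE])
    rownames(t2$conc)[rowSums(det) > 0L]
  })
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = 1L, dimnames = list(NULL, names(sets)))
  pat <- apply(membership, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  in_any <- nzchar(pat)
  counts <- table(pat[in_any])
  regions <- data.frame(region = names(counts),
                        count = as.integer(counts), row.names = NULL)
  structure(list(sets = sets, regions = regions, universe = universe,
                 diet = diet),
            class = "detection_sets")
}

split_metab_by <- function(tab, group_by) {
  lv <- unique(tab$sample_meta[[group_by]])
  out <- lapply(lv, function(l) {
    idx <- tab$sample_meta[[group_by]] == l
    metabolome_table(tab$conc[, idx, drop = FALSE],
                     tab$sample_meta[idx, , drop = FALSE])
  })
  names(out) <- lv
  out
}

#' @export
print.detection_sets <- function(x, ...) {
  cat("Detection sets over", length(x$universe), "metabolites",
      if (!is.null(x$diet)) paste0("(diet ", x$diet, ")"), "\n")
  for (nm in names(x$sets))
    cat("  ", nm, ": ", length(x$sets[[nm]]), " detected\n", sep = "")
  invisible(x)
}

#' Metabolites detected only in colonized hosts
#'
#' Returns `(SPF union 14SM) minus GF`: the metabolites detected in at
#' least one colonized group (conventional SPF or gnotobiotic 14SM) but
#' never in germ-free hosts, for sets built on one diet.
#'
#' @param sets A `detection_sets` containing entries named `SPF`, `14SM`,
#'   and `GF`.
#' @return List with `metabolites` (sorted character vector) and `count`.
#' @export
colonized_only <- function(sets) {
  stopifnot(inherits(sets, "detection_sets"))
  need <- c("SPF", "14SM", "GF")
  miss <- setdiff(need, names(sets$sets))
  if (length(miss))
    stop("missing colonization group(s): ", paste(miss, collapse = ", "))
  res <- sort(setdiff(union(sets$sets$SPF, sets$sets$`14SM`), sets$sets$GF))
  list(metabolites = res, count = length(res))
}

#' Ward-clustering row order
#'
#' Leaf order of agglomerative Ward-linkage clustering (Ward.D2 update on
#' Euclidean row distances), as used to order heatmap rows. The dendrogram
#' is traversed deterministically: at every merge the subtree containing
#' the smallest row label (lexicographically; original row index when rows
#' are unnamed) comes first, so the order is invariant to row permutation
#' whenever merge heights are untied.
#'
#' @param z Numeric matrix (e.g. a `scaled_matrix`); rows are ordered.
#' @return Integer permutation of the row indices.
#' @export
ward_order <- function(z) {
  z <- unclass(z)
  if (!is.matrix(z)) stop("`z` must be a matrix")
  n <- nrow(z)
  if (n < 1L) stop("need >= 1 row")
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "ward.D2")
  labels <- rownames(z)
  if (is.null(labels)) labels <- sprintf("%09d", seq_len(n))
  rec <- function(node) {
    if (node < 0) return(-node)
    kids <- hc$merge[node, ]
    c1 <- rec(kids[1L])
    c2 <- rec(kids[2L])
    if (min(labels[c2]) < min(labels[c1])) c(c2, c1) else c(c1, c2)
  }
  rec(nrow(hc$merge))
}
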