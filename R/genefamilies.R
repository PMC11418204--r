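#' @title Taxon-stratified gene-family tables and the S/D analysis
#' @description Parsers and transforms for taxon-stratified gene-family
#'   abundance tables in the metatranscriptome-profiler dialect (rows
#'   `FEATURE` for the unstratified total and `FEATURE|taxon` for per-taxon
#'   strata), counts-per-million renormalisation, aggregation to
#'   per-vitamin synthesis (S) and downstream-utilization (D) relative
#'   abundances, the log2 S/D ratio with a pseudocount rule, group
#'   comparison, and taxon attribution.
#' @name transcriptsd
NULL

STRAT_UNITS <- c("counts", "cpm", "relab")

#' Construct a stratified abundance table
#'
#' @param abund Numeric matrix, one row per feature or feature stratum,
#'   one column per sample; non-negative.
#' @param feature Character vector of feature IDs, one per row.
#' @param taxon Character vector aligned to rows: `NA` marks the
#'   unstratified TOTAL row of a feature, otherwise a taxon name (the
#'   sentinel `"unclassified"` marks transcripts not attributed to a
#'   taxon).
#' @param units One of `"counts"`, `"cpm"`, `"relab"`.
#' @param sample_meta Optional data frame with columns `sample_id`,
#'   `diet_group`, `colonization` (and optionally `batch`) describing the
#'   columns of `abund`.
#' @return An object of class `strat_abund`.
#' @export
strat_abund <- function(abund, feature, taxon, units = "counts",
                        sample_meta = NULL) {
  stopifnot(is.matrix(abund), is.numeric(abund))
  units <- match.arg(units, STRAT_UNITS)
  if (length(feature) != nrow(abund) || length(taxon) != nrow(abund))
    stop("`feature` and `taxon` must align with the rows of `abund`")
  if (anyNA(abund) || any(abund < 0))
    stop("abundances must be non-negative and non-missing")
  if (is.null(colnames(abund)) || anyDuplicated(colnames(abund)))
    stop("`abund` must have unique sample column names")
  if (!is.null(sample_meta)) {
    stopifnot(is.data.frame(sample_meta), "sample_id" %in% names(sample_meta))
    if (!all(colnames(abund) %in% sample_meta$sample_id))
      stop("sample_meta is missing entries for: ",
           paste(setdiff(colnames(abund), sample_meta$sample_id),
                 collapse = ", "))
    sample_meta <-
      sample_meta[match(colnames(abund), sample_meta$sample_id), , drop = FALSE]
  }
  x <- structure(
    list(abund = abund, feature = as.character(feature),
         taxon = as.character(taxon), units = units,
         sample_meta = sample_meta),
    class = "strat_abund"
  )
  validate_strat_abund(x)
  x
}

validate_strat_abund <- function(x, rel_tol = 1e-6) {
  is_total <- is.na(x$taxon)
  key <- paste(x$feature, ifelse(is_total, "<TOTAL>", x$taxon))
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicated (feature, taxon) row(s): ",
         paste(unique(key[dup]), collapse = "; "))
  strat_feats <- unique(x$feature[!is_total])
  orphan <- setdiff(strat_feats, x$feature[is_total])
  if (length(orphan))
    stop("stratum row(s) without a TOTAL row for feature(s): ",
         paste(orphan, collapse = ", "))
  for (f in strat_feats) {
    tot <- x$abund[is_total & x$feature == f, , drop = FALSE]
    ssum <- colSums(x$abund[!is_total & x$feature == f, , drop = FALSE])
    over <- ssum > tot * (1 + rel_tol) + 1e-12
    if (any(over))
      stop("strata of feature '", f, "' exceed its TOTAL in sample(s): ",
           paste(colnames(x$abund)[over], collapse = ", "))
  }
  invisible(x)
}

#' @export
print.strat_abund <- function(x, ...) {
  cat("Stratified abundance table:", sum(is.na(x$taxon)), "features (",
      sum(!is.na(x$taxon)), "stratum rows ),", ncol(x$abund),
      "samples; units =", x$units, "\n")
  invisible(x)
}

#' Read a stratified gene-family table
#'
#' Parses a wide TSV in the profiler dialect: the header line may begin
#' with `"# Gene Family"`; the first column holds feature IDs with strata
#' encoded as `FEATURE|taxon`; remaining columns are numeric, one per
#' sample. A stratum row without a TOTAL row, a duplicated (feature,
#' taxon) pair, or strata exceeding their TOTAL (1e-6 relative tolerance)
#' are refused. Malformed numeric cells are rejected with their location.
#'
#' @param path Path to the TSV.
#' @param units Units of the stored values (default `"counts"`).
#' @param sample_meta Optional sample metadata (see [strat_abund()]).
#' @return A `strat_abund`.
#' @export
read_genefamilies <- function(path, units = "counts", sample_meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2L) stop("expected an ID column plus >= 1 sample column")
  ids <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 ncol = ncol(mat), dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop("malformed numeric cell(s): ",
         paste(sprintf("row %d ('%s'), sample '%s'", bad[, 1], ids[bad[, 1]],
                       colnames(mat)[bad[, 2]]), collapse = "; "))
  pipe_at <- regexpr("|", ids, fixed = TRUE)
  feature <- ifelse(pipe_at > 0, substr(ids, 1L, pipe_at - 1L), ids)
  taxon <- ifelse(pipe_at > 0, substring(ids, pipe_at + 1L), NA_character_)
  rownames(num) <- ids
  strat_abund(num, feature, taxon, units = units, sample_meta = sample_meta)
}

#' Write a stratified gene-family table
#'
#' Writes the TSV dialect read by [read_genefamilies()]; the header line
#' begins with `# Gene Family`.
#'
#' @param x A `strat_abund`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genefamilies <- function(x, path) {
  stopifnot(inherits(x, "strat_abund"))
  ids <- ifelse(is.na(x$taxon), x$feature, paste0(x$feature, "|", x$taxon))
  df <- data.frame(id = ids, x$abund, check.names = FALSE)
  names(df)[1L] <- "# Gene Family"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Renormalise counts to counts per million
#'
#' Scales each sample so that its TOTAL rows sum to 1e6; stratum rows are
#' scaled by the same per-sample factor, preserving the stratum/TOTAL
#' structure. Refuses tables not in count units (the transform is not
#' idempotent) and samples with zero total.
#'
#' @param x A `strat_abund` with `units == "counts"`.
#' @return A `strat_abund` in CPM units.
#' @export
to_cpm <- function(x) {
  stopifnot(inherits(x, "strat_abund"))
  if (x$units != "counts")
    stop("to_cpm expects count units; table is already in '", x$units, "'")
  tot <- colSums(x$abund[is.na(x$taxon), , drop = FALSE])
  if (any(tot == 0))
    stop("zero total counts in sample(s): ",
         paste(colnames(x$abund)[tot == 0], collapse = ", "))
  x$abund <- sweep(x$abund, 2L, 1e6 / tot, `*`)
  x$units <- "cpm"
  x
}

per_sample_denominator <- function(x) {
  colSums(x$abund[is.na(x$taxon), , drop = FALSE])
}

#' Aggregate transcripts to per-vitamin S/D relative abundances
#'
#' For each sample and vitamin, sums the TOTAL-row abundance of features
#' annotated with role S (synthesis/upstream) and role D (downstream
#' utilization), expressed as percent of all mapped non-host transcripts
#' (the table's TOTAL rows). Per-taxon stratified sums are computed from
#' stratum rows, with the `"unclassified"` stratum carrying any remainder
#' between a feature's TOTAL and its named strata. Transport (T) records
#' are excluded from both sums unless `transport_as_downstream = TRUE`.
#' Annotation records matching no feature in the table are reported with a
#' message, not an error.
#'
#' @param x A `strat_abund` in CPM or relative-abundance units.
#' @param ann A `vitamin_annotation`.
#' @param transport_as_downstream Merge transport (T) records into the
#'   downstream (D) sums? Default `FALSE`.
#' @return An object of class `vitamin_role_abundance`: a list with
#'   `totals` (data frame `sample`, `vitamin`, `role`, `relab` on the
#'   percent scale) and `strata` (the same plus `taxon`), carrying the
#'   table's `sample_meta`.
#' @export
aggregate_vitamin_roles <- function(x, ann, transport_as_downstream = FALSE) {
  stopifnot(inherits(x, "strat_abund"), inherits(ann, "vitamin_annotation"))
  if (x$units == "counts")
    stop("aggregate on CPM or relative-abundance units; call to_cpm() first")
  ann <- as.data.frame(ann)
  role_eff <- ann$role
  if (transport_as_downstream) role_eff[role_eff == "T"] <- "D"
  ann <- ann[role_eff %in% c("S", "D"), , drop = FALSE]
  ann$role <- role_eff[role_eff %in% c("S", "D")]

  absent <- setdiff(unique(ann$feature_id), unique(x$feature))
  if (length(absent))
    message("annotation feature(s) absent from table (ignored): ",
            paste(absent, collapse = ", "))

  denom <- per_sample_denominator(x)
  samples <- colnames(x$abund)
  is_total <- is.na(x$taxon)
  vitamins <- sort(unique(ann$vitamin))

  totals <- list()
  strata <- list()
  for (v in vitamins) {
    for (r in c("S", "D")) {
      feats <- ann$feature_id[ann$vitamin == v & ann$role == r]
      sel_tot <- is_total & x$feature %in% feats
      tot_sum <- colSums(x$abund[sel_tot, , drop = FALSE])
      totals[[paste(v, r)]] <- data.frame(
        sample = samples, vitamin = v, role = r,
        relab = 100 * tot_sum / denom, row.names = NULL
      )
      # stratified attribution with unclassified remainder
      present_feats <- intersect(feats, x$feature[is_total])
      if (length(present_feats)) {
        taxa_sum <- list()
        unclass <- numeric(length(samples))
        any_strata <- FALSE
        for (f in present_feats) {
          f_tot <- x$abund[is_total & x$feature == f, , drop = FALSE][1L, ]
          sel_str <- !is_total & x$feature == f
          if (!any(sel_str)) next
          any_strata <- TRUE
          sub <- x$abund[sel_str, , drop = FALSE]
          taxa <- x$taxon[sel_str]
          remainder <- f_tot - colSums(sub)
          remainder[remainder < 0] <- 0
          unclass <- unclass + remainder
          for (i in seq_along(taxa)) {
            tx <- taxa[i]
            if (tx == "unclassified") {
              unclass <- unclass + sub[i, ]
            } else {
              taxa_sum[[tx]] <- (taxa_sum[[tx]] %||% numeric(length(samples))) +
                sub[i, ]
            }
          }
        }
        if (any_strata) {
          taxa_sum[["unclassified"]] <- unclass
          strata[[paste(v, r)]] <- do.call(rbind, lapply(names(taxa_sum),
            function(tx) data.frame(
              sample = samples, vitamin = v, role = r, taxon = tx,
              relab = 100 * taxa_sum[[tx]] / denom, row.names = NULL
            )))
        }
      }
    }
  }
  empty_totals <- data.frame(sample = character(), vitamin = character(),
                             role = character(), relab = numeric())
  structure(
    list(
      totals = if (length(totals))
        do.call(rbind, c(totals, list(make.row.names = FALSE)))
      else empty_totals,
      strata = if (length(strata))
        do.call(rbind, c(strata, list(make.row.names = FALSE)))
      else
        data.frame(sample = character(), vitamin = character(),
                   role = character(), taxon = character(),
                   relab = numeric()),
      sample_meta = x$sample_meta
    ),
    class = "vitamin_role_abundance"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample log2 S/D ratio with the pseudocount rule
#'
#' Computes, for each sample and vitamin, the log2 ratio of synthesis over
#' downstream-utilization relative abundance. For any vitamin where at
#' least one sample in the analysis set has D == 0, a pseudocount of one
#' is added to S and D of **all** samples for that vitamin before taking
#' the ratio; otherwise the plain log2(S/D) is used. With
#' `scale = "cpm"` the pseudocount is applied on the CPM scale
#' (values = relab/100 * 1e6) instead of the percent scale.
#'
#' @param vra A `vitamin_role_abundance` on the percent scale.
#' @param scale Scale on which values are pseudocounted and ratioed:
#'   `"relab"` (percent, default) or `"cpm"`.
#' @return An object of class `sd_ratio`: a data frame with columns
#'   `sample`, `vitamin`, `S`, `D`, `log2_ratio`, `pseudocount_applied`,
#'   carrying `sample_meta` as an attribute.
#' @export
log2_sd_ratio <- function(vra, scale = c("relab", "cpm")) {
  stopifnot(inherits(vra, "vitamin_role_abundance"))
  scale <- match.arg(scale)
  tot <- vra$totals
  wide <- merge(
    tot[tot$role == "S", c("sample", "vitamin", "relab")],
    tot[tot$role == "D", c("sample", "vitamin", "relab")],
    by = c("sample", "vitamin"), suffixes = c("_S", "_D")
  )
  if (scale == "cpm") {
    wide$relab_S <- wide$relab_S / 100 * 1e6
    wide$relab_D <- wide$relab_D / 100 * 1e6
  }
  out <- list()
  for (v in unique(wide$vitamin)) {
    w <- wide[wide$vitamin == v, , drop = FALSE]
    ps <- any(w$relab_D == 0)
    S <- w$relab_S + if (ps) 1 else 0
    D <- w$relab_D + if (ps) 1 else 0
    stopifnot(all(D > 0)) # guaranteed: pseudocount triggers on any zero D
    out[[v]] <- data.frame(
      sample = w$sample, vitamin = v, S = S, D = D,
      log2_ratio = log2(S / D), pseudocount_applied = ps,
      row.names = NULL
    )
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "sample_meta") <- vra$sample_meta
  attr(res, "scale") <- scale
  class(res) <- c("sd_ratio", "data.frame")
  res
}

sample_group_labels <- function(meta) {
  paste(meta$colonization, meta$diet_group, sep = ":")
}

resolve_groups <- function(obj_meta, samples, groups) {
  if (is.null(groups)) {
    if (is.null(obj_meta))
      stop("no `groups` given and no sample_meta attached")
    g <- sample_group_labels(obj_meta)
    names(g) <- obj_meta$sample_id
    groups <- g
  }
  if (is.null(names(groups)))
    stop("`groups` must be a named vector: sample_id -> group label")
  miss <- setdiff(samples, names(groups))
  if (length(miss))
    stop("no group label for sample(s): ", paste(miss, collapse = ", "))
  groups[samples]
}

#' Compare log2 S/D ratios between two groups
#'
#' Two-sided unpaired t test on the per-sample log2 ratios, per vitamin.
#' Direction is the sign of `mean(group_a) - mean(group_b)`; significance
#' is masked at raw p <= 0.05 (matching an S/D heatmap's gray mask).
#' `p_adj` additionally reports BH adjustment across the vitamins tested.
#' Vitamins with fewer than 2 samples in either group are skipped with a
#' warning.
#'
#' @param sdr An `sd_ratio`.
#' @param group_a,group_b Group labels (`"colonization:diet"` when labels
#'   come from attached sample metadata).
#' @param groups Optional named vector mapping sample IDs to group labels;
#'   defaults to labels derived from the attached sample metadata.
#' @return Data frame with columns `vitamin`, `test_used`, `statistic`,
#'   `p_raw`, `p_adj`, `direction`, `significant`, `n_a`, `n_b`.
#' @export
compare_sd <- function(sdr, group_a, group_b, groups = NULL) {
  stopifnot(inherits(sdr, "sd_ratio"))
  g <- resolve_groups(attr(sdr, "sample_meta"), unique(sdr$sample), groups)
  rows <- list()
  for (v in unique(sdr$vitamin)) {
    w <- sdr[sdr$vitamin == v, , drop = FALSE]
    xa <- w$log2_ratio[g[w$sample] == group_a]
    xb <- w$log2_ratio[g[w$sample] == group_b]
    if (length(xa) < 2L || length(xb) < 2L) {
      warning("vitamin ", v, " skipped: fewer than 2 samples in a group")
      next
    }
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      stat <- if (mean(xa) == mean(xb)) 0 else Inf * sign(mean(xa) - mean(xb))
      p <- if (mean(xa) == mean(xb)) 1 else 0
    } else {
      tt <- stats::t.test(xa, xb, var.equal = FALSE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    rows[[v]] <- data.frame(
      vitamin = v, test_used = "t_unpaired", statistic = stat, p_raw = p,
      direction = sign(mean(xa) - mean(xb)), significant = p <= 0.05,
      n_a = length(xa), n_b = length(xb), row.names = NULL
    )
  }
  if (!length(rows))
    return(data.frame(vitamin = character(), test_used = character(),
                      statistic = numeric(), p_raw = numeric(),
                      p_adj = numeric(), direction = numeric(),
                      significant = logical(), n_a = integer(),
                      n_b = integer()))
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$p_adj <- bh_adjust(res$p_raw)
  res[, c("vitamin", "test_used", "statistic", "p_raw", "p_adj",
          "direction", "significant", "n_a", "n_b")]
}

#' Rank taxon contributors for a vitamin/role
#'
#' Per diet/colonization group, taxa are ranked by the mean stratified
#' relative abundance they contribute to the given vitamin and role;
#' `"unclassified"` is reported as its own row. An empty table (with a
#' message) results when no strata are present.
#'
#' @param vra A `vitamin_role_abundance`.
#' @param vitamin Vitamin code (e.g. `"B2"`).
#' @param role `"S"` or `"D"`.
#' @param groups Optional named vector mapping sample IDs to group labels.
#' @return Data frame with columns `group`, `taxon`, `mean_relab`,
#'   `sd_relab`, `rank` (1 = largest mean within group).
#' @export
taxon_contributions <- function(vra, vitamin, role, groups = NULL) {
  stopifnot(inherits(vra, "vitamin_role_abundance"))
  st <- vra$strata[vra$strata$vitamin == vitamin & vra$strata$role == role, ,
                   drop = FALSE]
  if (!nrow(st)) {
    message("no strata for vitamin ", vitamin, ", role ", role)
    return(data.frame(group = character(), taxon = character(),
                      mean_relab = numeric(), sd_relab = numeric(),
                      rank = integer()))
  }
  g <- resolve_groups(vra$sample_meta, unique(st$sample), groups)
  st$group <- g[st$sample]
  agg_m <- stats::aggregate(relab ~ group + taxon, data = st, FUN = mean)
  agg_s <- stats::aggregate(relab ~ group + taxon, data = st, FUN = stats::sd)
  res <- merge(agg_m, agg_s, by = c("group", "taxon"),
               suffixes = c("_mean", "_sd"))
  names(res)[names(res) == "relab_mean"] <- "mean_relab"
  names(res)[names(res) == "relab_sd"] <- "sd_relab"
  res <- res[order(res$group, -res$mean_relab, res$taxon), , drop = FALSE]
  res$rank <- stats::ave(-res$mean_relab, res$group,
                         FUN = function(z) rank(z, ties.method = "first"))
  rownames(res) <- NULL
  res
}
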