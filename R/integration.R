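#' @title B vitamin / immune-population correlation
#' @description Correlates log-transformed cecal B vitamin concentrations
#'   with immune-population frequencies (% of CD45+ cells), honoring the
#'   matched-versus-pooled sample design: groups whose metabolome and
#'   immune samples share IDs are paired one-to-one, while groups without
#'   matched IDs are pooled by within-group rank after sorting by sample
#'   ID (or dropped, in strict mode).
#' @name integration
NULL

#' Construct an immune-population frequency table
#'
#' @param freq Numeric matrix, populations x samples, values in
#'   \[0, 100\] (% of CD45+ cells).
#' @param sample_meta Data frame with columns `sample_id`, `diet_group`,
#'   `colonization`.
#' @return An object of class `immune_table`.
#' @export
immune_table <- function(freq, sample_meta) {
  stopifnot(is.matrix(freq), is.numeric(freq), is.data.frame(sample_meta))
  if (is.null(rownames(freq)) || anyDuplicated(rownames(freq)))
    stop("`freq` needs unique population row names")
  if (is.null(colnames(freq)) || anyDuplicated(colnames(freq)))
    stop("`freq` needs unique sample column names")
  v <- freq[!is.na(freq)]
  if (any(v < 0 | v > 100))
    stop("frequencies must lie in [0, 100]")
  req <- c("sample_id", "diet_group", "colonization")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    stop("sample_meta missing column(s): ", paste(miss, collapse = ", "))
  if (!all(colnames(freq) %in% sample_meta$sample_id))
    stop("sample_meta is missing sample(s): ",
         paste(setdiff(colnames(freq), sample_meta$sample_id), collapse = ", "))
  sample_meta <-
    sample_meta[match(colnames(freq), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(freq = freq, sample_meta = sample_meta),
            class = "immune_table")
}

#' Read an immune-population frequency table
#'
#' Wide TSV: first column the population name, one column per sample;
#' companion metadata TSV with `sample_id`, `diet_group`, `colonization`.
#'
#' @param path Path to the frequency table.
#' @param meta_path Path to the sample-metadata TSV.
#' @return An `immune_table`.
#' @export
read_immune <- function(path, meta_path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE)
  freq <- as.matrix(df[, -1L, drop = FALSE])
  rownames(freq) <- df[[1L]]
  meta <- utils::read.delim(meta_path, sep = "\t", header = TRUE)
  immune_table(freq, meta)
}

# Assemble (metabolome sample, immune sample) pairs per group.
assemble_pairs <- function(met, imm, pairing) {
  gm <- met_group_labels(met)
  gi <- paste(imm$sample_meta$colonization, imm$sample_meta$diet_group,
              sep = ":")
  pairs <- list()
  modes <- character()
  for (lvl in intersect(unique(gm), unique(gi))) {
    ms <- colnames(met$conc)[gm == lvl]
    is <- colnames(imm$freq)[gi == lvl]
    common <- intersect(ms, is)
    if (length(common)) {
      pairs[[lvl]] <- data.frame(group = lvl, met_sample = common,
                                 imm_sample = common)
      modes[lvl] <- "matched"
    } else if (pairing == "strict") {
      warning("group ", lvl, " dropped: no matched sample IDs (strict mode)")
    } else {
      k <- min(length(ms), length(is))
      if (k == 0L) next
      pairs[[lvl]] <- data.frame(group = lvl,
                                 met_sample = sort(ms)[seq_len(k)],
                                 imm_sample = sort(is)[seq_len(k)])
      modes[lvl] <- "pooled"
    }
  }
  if (!length(pairs)) stop("no usable groups: no ID overlap in any group")
  list(pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
       modes = modes)
}

#' Correlate B vitamin concentrations with immune frequencies
#'
#' Vitamin concentrations are normalized by the sample size factor and
#' log10-transformed; non-detected values are imputed at one-fifth of the
#' vitamin's minimum detected normalized value (`na_action = "impute"`,
#' the default, mirroring the metabolome preprocessing) or dropped
#' pairwise (`na_action = "omit"`). Pearson r and its two-sided p-value
#' are computed per (vitamin, population) over the assembled pairs, BH
#' adjustment is applied across all matrix cells, and cells are flagged
#' significant at adjusted p < 0.05. Zero-variance vectors yield an
#' undefined-correlation sentinel cell (`NA`), never an error.
#'
#' @param met A `metab_table` restricted to the B vitamin rows (any
#'   metabolite rows are accepted; each row becomes a matrix row).
#' @param imm An `immune_table`.
#' @param pairing `"rank"` (pool unmatched groups by within-group rank
#'   after sorting sample IDs) or `"strict"` (drop unmatched groups).
#' @param na_action `"impute"` or `"omit"` for non-detected
#'   concentrations.
#' @return An object of class `cor_matrix`: list with `table` (long data
#'   frame `vitamin`, `population`, `n`, `r`, `p_raw`, `p_adj`,
#'   `significant`), `r` and `p_adj` matrices (vitamins x populations),
#'   and `pairing_modes` (named character vector per group).
#' @export
bvitamin_immune_correlation <- function(met, imm,
                                        pairing = c("rank", "strict"),
                                        na_action = c("impute", "omit")) {
  stopifnot(inherits(met, "metab_table"), inherits(imm, "immune_table"))
  pairing <- match.arg(pairing)
  na_action <- match.arg(na_action)
  asm <- assemble_pairs(met, imm, pairing)
  pr <- asm$pairs

  norm <- sweep(met$conc, 2L, met$sample_meta$size_factor, `/`)
  det <- met_detected(met$conc)
  logc <- matrix(NA_real_, nrow(norm), ncol(norm), dimnames = dimnames(norm))
  for (i in seq_len(nrow(norm))) {
    obs <- det[i, ]
    if (!any(obs)) next
    vals <- norm[i, ]
    if (na_action == "impute") vals[!obs] <- min(vals[obs]) / 5
    else vals[!obs] <- NA_real_
    logc[i, ] <- log10(vals)
  }

  vitamins <- rownames(met$conc)
  populations <- rownames(imm$freq)
  vx <- logc[, pr$met_sample, drop = FALSE]
  px <- imm$freq[, pr$imm_sample, drop = FALSE]

  long <- expand.grid(vitamin = vitamins, population = populations,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$n <- NA_integer_
  long$r <- NA_real_
  long$p_raw <- NA_real_
  for (j in seq_len(nrow(long))) {
    xv <- vx[long$vitamin[j], ]
    yv <- px[long$population[j], ]
    res <- suppressWarnings(pearson_with_p(xv, yv))
    long$n[j] <- res$n
    long$r[j] <- res$r
    long$p_raw[j] <- res$p
  }
  long$p_adj <- bh_adjust(long$p_raw)
  long$significant <- !is.na(long$p_adj) & long$p_adj < 0.05

  rmat <- matrix(long$r, nrow = length(vitamins),
                 dimnames = list(vitamins, populations))
  pmat <- matrix(long$p_adj, nrow = length(vitamins),
                 dimnames = list(vitamins, populations))
  structure(list(table = long, r = rmat, p_adj = pmat,
                 pairing_modes = asm$modes),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat("Correlation matrix:", nrow(x$r), "vitamins x", ncol(x$r),
      "populations;", sum(x$table$significant, na.rm = TRUE),
      "significant cells (adjusted p < 0.05)\n")
  cat("  pairing:", paste(names(x$pairing_modes), x$pairing_modes,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}
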