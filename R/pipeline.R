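#' @title End-to-end pipeline
#' @description Runs the full analysis — metatranscriptome S/D stage,
#'   metabolome stage, and vitamin-immune correlation stage — from either
#'   generated (simulate mode) or on-disk inputs, writing tidy TSV
#'   outputs, a run manifest, and a plain-text summary.
#' @name cli_report
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages, in order: read or generate inputs; `to_cpm` →
#' `aggregate_vitamin_roles` → `log2_sd_ratio` → `compare_sd` →
#' `taxon_contributions`; `prevalence_filter` → `normalize_log_scale` →
#' `differential_rank` → `ward_order` → `detection_sets` →
#' `colonized_only`; `bvitamin_immune_correlation`. Writes eight TSVs
#' (`sd_ratio.tsv`, `sd_tests.tsv`, `taxon_contributions.tsv`,
#' `metabolome_filtered.tsv`, `metabolome_scaled.tsv`,
#' `differential_rank.tsv`, `detection_regions.tsv`,
#' `bvitamin_immune_correlations.tsv`) plus `manifest.txt` (seed,
#' package version, flags in effect — sufficient to reproduce the run)
#' and `summary.txt`. Any stage error aborts with the stage name and
#' cause. Reruns with the same configuration produce byte-identical
#' outputs.
#'
#' @param outdir Output directory (created if needed).
#' @param config A `sim_config` (simulate mode). Ignored when `inputs`
#'   is given.
#' @param inputs Optional named list of paths for real-data mode:
#'   `genefamilies`, `annotation`, `metabolome`, `metabolome_meta`,
#'   `immune`, `immune_meta`. All six are required; validation happens
#'   before any compute.
#' @param compare Character vector of two group labels
#'   (`"colonization:diet"`) for the S/D comparison; default
#'   `c("SPF:IN", "SPF:FF")`.
#' @param taxon_vitamin,taxon_role Vitamin/role whose taxon contributors
#'   are tabulated (default B2 synthesis).
#' @param set_diet Diet on which detection sets and the colonized-only
#'   set are computed (default `"SC1"`; skipped with a note when the
#'   required colonization groups are absent).
#' @param reference_group Reference diet for differential ranking
#'   (default `"FF"`).
#' @param top_k Top metabolites returned by the ranking (default 50).
#' @param pseudocount_scale Scale for the S/D pseudocount, `"relab"` or
#'   `"cpm"`.
#' @param moderation Empirical-Bayes variance moderation in the ranking?
#' @param pairing Pairing mode for the correlation stage (`"rank"` or
#'   `"strict"`).
#' @return Invisibly, a list with the in-memory stage results and
#'   `files` (paths written).
#' @export
run_pipeline <- function(outdir,
                         config = sim_config(),
                         inputs = NULL,
                         compare = c("SPF:IN", "SPF:FF"),
                         taxon_vitamin = "B2", taxon_role = "S",
                         set_diet = "SC1",
                         reference_group = "FF",
                         top_k = 50,
                         pseudocount_scale = c("relab", "cpm"),
                         moderation = FALSE,
                         pairing = c("rank", "strict")) {
  pseudocount_scale <- match.arg(pseudocount_scale)
  pairing <- match.arg(pairing)
  stage <- "configuration"
  run <- function(what, expr) {
    stage <<- what
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  simulate <- is.null(inputs)
  if (!simulate) {
    req <- c("genefamilies", "annotation", "metabolome", "metabolome_meta",
             "immune", "immune_meta")
    miss <- setdiff(req, names(inputs))
    if (length(miss))
      stop("config error: missing input path(s): ",
           paste(miss, collapse = ", "))
    absent <- !vapply(unlist(inputs[req]), file.exists, logical(1))
    if (any(absent))
      stop("config error: input file(s) not found: ",
           paste(unlist(inputs[req])[absent], collapse = ", "))
  } else {
    stopifnot(inherits(config, "sim_config"))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (simulate) {
    mt <- run("simulate-metatranscriptome", gen_metatranscriptome(config))
    gf <- mt$table
    ann <- builtin_demo_annotation()
    met <- run("simulate-metabolome", gen_metabolome(config))$table
    imm <- run("simulate-immune", gen_immune(config, metabolome = met))$table
  } else {
    ann <- run("load-annotation", load_annotation(inputs$annotation))
    gf <- run("read-genefamilies", read_genefamilies(inputs$genefamilies))
    met <- run("read-metabolome",
               read_metabolome(inputs$metabolome, inputs$metabolome_meta))
    imm <- run("read-immune", read_immune(inputs$immune, inputs$immune_meta))
    # gene-family sample labels: from an optional metadata path, else from
    # the metabolome metadata for samples shared between the assays
    if (!is.null(inputs$genefamilies_meta)) {
      gmeta <- utils::read.delim(inputs$genefamilies_meta, sep = "\t",
                                 header = TRUE)
      gf <- run("read-genefamilies",
                strat_abund(gf$abund, gf$feature, gf$taxon,
                            units = gf$units, sample_meta = gmeta))
    } else if (all(colnames(gf$abund) %in% met$sample_meta$sample_id)) {
      idx <- match(colnames(gf$abund), met$sample_meta$sample_id)
      gf$sample_meta <- met$sample_meta[idx, c("sample_id", "diet_group",
                                               "colonization")]
    }
  }

  # --- transcript S/D stage ---
  cpm <- run("to_cpm", if (gf$units == "counts") to_cpm(gf) else gf)
  vra <- run("aggregate_vitamin_roles", aggregate_vitamin_roles(cpm, ann))
  sdr <- run("log2_sd_ratio", log2_sd_ratio(vra, scale = pseudocount_scale))
  sdt <- run("compare_sd", compare_sd(sdr, compare[1], compare[2]))
  tc <- run("taxon_contributions",
            taxon_contributions(vra, taxon_vitamin, taxon_role))

  # --- metabolome stage ---
  filt <- run("prevalence_filter", prevalence_filter(met))
  z <- run("normalize_log_scale", normalize_log_scale(filt))
  dr <- run("differential_rank",
            differential_rank(z, reference_group = reference_group,
                              k = top_k, moderation = moderation))
  ord <- run("ward_order", ward_order(z))
  have_colonizations <- unique(met$sample_meta$colonization)
  sets <- NULL
  conly <- NULL
  if (all(c("SPF", "14SM", "GF") %in% have_colonizations)) {
    sets <- run("detection_sets", detection_sets(met, diet = set_diet))
    conly <- run("colonized_only", colonized_only(sets))
  }

  # --- integration stage ---
  bv <- bvitamin_metabolites()
  vit_rows <- intersect(unname(bv), rownames(met$conc))
  cm <- NULL
  if (length(vit_rows) >= 1L) {
    met_b <- metabolome_table(met$conc[vit_rows, , drop = FALSE],
                              met$sample_meta)
    cm <- run("bvitamin_immune_correlation",
              bvitamin_immune_correlation(met_b, imm, pairing = pairing))
  }

  # --- outputs ---
  stage <- "write-outputs"
  files <- c(
    sd_ratio = write_tsv(as.data.frame(sdr), file.path(outdir, "sd_ratio.tsv")),
    sd_tests = write_tsv(sdt, file.path(outdir, "sd_tests.tsv")),
    taxon_contributions =
      write_tsv(tc, file.path(outdir, "taxon_contributions.tsv")),
    metabolome_filtered = write_tsv(
      data.frame(metabolite = rownames(filt$conc), filt$conc,
                 check.names = FALSE),
      file.path(outdir, "metabolome_filtered.tsv")),
    metabolome_scaled = write_tsv(
      data.frame(metabolite = rownames(z)[ord],
                 unclass(z)[ord, , drop = FALSE], check.names = FALSE),
      file.path(outdir, "metabolome_scaled.tsv")),
    differential_rank =
      write_tsv(dr, file.path(outdir, "differential_rank.tsv")),
    detection_regions = write_tsv(
      if (is.null(sets))
        data.frame(region = character(), count = integer())
      else sets$regions,
      file.path(outdir, "detection_regions.tsv")),
    correlations = write_tsv(
      if (is.null(cm))
        data.frame(vitamin = character(), population = character())
      else {
        tb <- cm$table
        tb$pairing_mode <- paste(names(cm$pairing_modes), cm$pairing_modes,
                                 sep = "=", collapse = ";")
        tb
      },
      file.path(outdir, "bvitamin_immune_correlations.tsv"))
  )

  manifest <- c(
    paste0("package: vitaminSD ",
           as.character(utils::packageVersion("vitaminSD"))),
    paste0("mode: ", if (simulate) "simulate" else "files"),
    if (simulate) paste0("seed: ", config$seed),
    paste0("compare: ", paste(compare, collapse = " vs ")),
    paste0("pseudocount_scale: ", pseudocount_scale),
    paste0("moderation: ", moderation),
    paste0("pairing: ", pairing),
    paste0("reference_group: ", reference_group),
    paste0("top_k: ", top_k),
    paste0("set_diet: ", set_diet)
  )
  writeLines(manifest, file.path(outdir, "manifest.txt"))

  summary_lines <- c(
    sprintf("samples (metatranscriptome): %d", ncol(gf$abund)),
    sprintf("vitamins with S/D ratios: %d", length(unique(sdr$vitamin))),
    sprintf("significant S/D shifts (%s vs %s, p <= 0.05): %s",
            compare[1], compare[2],
            paste(sdt$vitamin[sdt$significant], collapse = ", ")),
    sprintf("metabolites surviving prevalence filter: %d / %d",
            nrow(filt$conc), nrow(met$conc)),
    if (!is.null(conly))
      sprintf("colonized-only metabolites (%s diet): %d", set_diet,
              conly$count),
    if (!is.null(cm))
      sprintf("significant vitamin-immune correlations: %d",
              sum(cm$table$significant, na.rm = TRUE))
  )
  writeLines(summary_lines, file.path(outdir, "summary.txt"))

  invisible(list(sd_ratio = sdr, sd_tests = sdt, taxon_contributions = tc,
                 filtered = filt, scaled = z, differential = dr,
                 ward_order = ord, detection_sets = sets,
                 colonized_only = conly, correlations = cm, files = files))
}
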