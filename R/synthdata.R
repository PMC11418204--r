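#' @title Synthetic multi-omics generator with planted ground truth
#' @description Generates metatranscriptome gene-family tables, cecal and
#'   serum metabolome tables, and immune-population frequency tables with
#'   the group structure of a dietary-fiber mouse study (five diets
#'   SC1/SC2/IN/FS/FF across SPF, 14SM gnotobiotic, and germ-free
#'   colonization states) and planted, recoverable effects: log2 S/D
#'   group differences for selected vitamins, microbiota-dependent
#'   metabolite sets (absent in germ-free hosts), and vitamin-immune
#'   correlations induced through a shared latent factor. All generators
#'   are deterministic under a fixed integer seed.
#' @name synthdata
NULL

#' Names of the B vitamin metabolites
#'
#' Maps vitamin codes to the metabolite names used in concentration
#' tables.
#'
#' @return Named character vector (names = vitamin codes).
#' @export
bvitamin_metabolites <- function() {
  c(B1 = "Thiamine", B2 = "Riboflavin", B3 = "Nicotinate",
    B5 = "Pantothenate", B6 = "Vitamin B6", B7 = "Biotin",
    B9 = "Folate", B12 = "Cobalamin")
}

default_groups <- function() {
  rbind(
    data.frame(diet_group = c("SC1", "SC2", "IN", "FS", "FF"),
               colonization = "SPF", n = 4L),
    data.frame(diet_group = c("SC1", "FF"), colonization = "14SM", n = 4L),
    data.frame(diet_group = c("SC1", "FF"), colonization = "GF", n = 4L)
  )
}

default_sd_effects <- function() {
  data.frame(
    vitamin = c("B2", "B3", "B7", "B9"),
    delta = 2,
    mechanism = c("downstream", "downstream", "downstream", "synthesis")
  )
}

default_correlations <- function() {
  data.frame(
    vitamin = c("B2", "B3", "B5"),
    population = c("Mast cells", "NK cells", "Th17 cells"),
    r = -0.8
  )
}

FIBER_FREE_DIETS <- c("FF", "FS")

#' Simulation configuration
#'
#' Captures every tunable of the synthetic generators. Defaults mirror
#' the emulated study: n = 4 mice per group; downstream-utilization
#' elevation of delta = 2 (log2) in fiber-free-like diets for B2, B3 and
#' B7 and a synthesis reduction for B9; 98 metabolites detected only in
#' colonized SC1-fed hosts of which 66 are also colonized-only under the
#' fiber-free diet; and planted negative vitamin-immune correlations of
#' r = -0.8 for riboflavin/mast cells, nicotinate/NK cells, and
#' pantothenate/Th17 cells.
#'
#' @param seed Integer seed; identical configs give identical outputs.
#' @param groups Data frame `diet_group`, `colonization`, `n`.
#' @param n_features Gene families in the metatranscriptome (annotated
#'   features plus background).
#' @param n_metabolites Metabolite universe size.
#' @param planted_sd_effects Data frame `vitamin`, `delta` (log2 group
#'   difference), `mechanism` (`"downstream"` = D elevated in
#'   fiber-free-like groups, `"synthesis"` = S reduced).
#' @param frac_microbiota_dependent Fraction of the metabolite universe
#'   absent in germ-free samples, in \[0, 1\].
#' @param colonized_only_ff_frac Fraction of the microbiota-dependent set
#'   that is also detected in colonized fiber-free-fed hosts (the rest is
#'   detected only under fiber-containing diets).
#' @param planted_correlations Data frame `vitamin`, `population`, `r`
#'   (target Pearson correlation, |r| < 1).
#' @param noise List of dispersion and missingness parameters:
#'   `dispersion` (negative-binomial overdispersion of counts),
#'   `depth_range` (per-sample sequencing depth, uniform),
#'   `met_sd_log10` (per-sample log10 SD of concentrations),
#'   `missing_rate` (missing-at-random rate for host-derived
#'   metabolites), `immune_mu`, `immune_sd` (planted-population frequency
#'   scale, % of CD45+).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       groups = default_groups(),
                       n_features = 60L,
                       n_metabolites = 220L,
                       planted_sd_effects = default_sd_effects(),
                       frac_microbiota_dependent = 98 / 220,
                       colonized_only_ff_frac = 66 / 98,
                       planted_correlations = default_correlations(),
                       noise = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  if (abs(seed) > .Machine$integer.max - 10L)
    stop("seed too large")
  stopifnot(is.data.frame(groups),
            all(c("diet_group", "colonization", "n") %in% names(groups)))
  if (any(groups$n <= 0)) stop("group sizes must be positive")
  if (n_features <= 0 || n_metabolites <= 0) stop("counts must be positive")
  stopifnot(is.data.frame(planted_sd_effects))
  if (nrow(planted_sd_effects)) {
    stopifnot(all(c("vitamin", "delta", "mechanism") %in%
                    names(planted_sd_effects)))
    if (any(!is.finite(planted_sd_effects$delta)))
      stop("planted delta must be finite")
    if (any(!planted_sd_effects$mechanism %in% c("downstream", "synthesis")))
      stop("mechanism must be 'downstream' or 'synthesis'")
  }
  if (!is.numeric(frac_microbiota_dependent) ||
      frac_microbiota_dependent < 0 || frac_microbiota_dependent > 1)
    stop("frac_microbiota_dependent must lie in [0, 1]")
  if (colonized_only_ff_frac < 0 || colonized_only_ff_frac > 1)
    stop("colonized_only_ff_frac must lie in [0, 1]")
  stopifnot(is.data.frame(planted_correlations))
  if (nrow(planted_correlations)) {
    stopifnot(all(c("vitamin", "population", "r") %in%
                    names(planted_correlations)))
    if (any(abs(planted_correlations$r) >= 1))
      stop("planted |r| must be < 1")
    if (anyDuplicated(planted_correlations$population))
      stop("at most one planted correlation per population")
  }
  defaults <- list(dispersion = 0.05, depth_range = c(5e5, 2e6),
                   met_sd_log10 = 0.2, missing_rate = 0.05,
                   immune_mu = 5, immune_sd = 1.5)
  noise <- utils::modifyList(defaults, noise)
  structure(
    list(seed = seed, groups = groups, n_features = as.integer(n_features),
         n_metabolites = as.integer(n_metabolites),
         planted_sd_effects = planted_sd_effects,
         frac_microbiota_dependent = frac_microbiota_dependent,
         colonized_only_ff_frac = colonized_only_ff_frac,
         planted_correlations = planted_correlations, noise = noise),
    class = "sim_config"
  )
}

sim_samples <- function(groups) {
  ids <- unlist(lapply(seq_len(nrow(groups)), function(i) {
    paste0(groups$colonization[i], "_", groups$diet_group[i], "_",
           seq_len(groups$n[i]))
  }))
  data.frame(
    sample_id = ids,
    diet_group = rep(groups$diet_group, groups$n),
    colonization = rep(groups$colonization, groups$n)
  )
}

#' Generate a taxon-stratified metatranscriptome table
#'
#' Draws gene-family counts from an overdispersed (negative-binomial)
#' model with per-sample depth variation. Features include every enzyme
#' of the bundled demo annotation; for vitamins with a planted effect,
#' the downstream-utilization (mechanism `"downstream"`) or synthesis
#' (mechanism `"synthesis"`) feature means are shifted by `2^delta` in
#' fiber-free-like diets (FF, FS). Annotated features are stratified over
#' a small taxon panel (fiber-degrading taxa dominant under
#' fiber-containing diets, mucin-associated taxa under fiber-free ones)
#' plus an `"unclassified"` share, by exact multinomial splits so strata
#' sum to their TOTAL row. By default only SPF samples on the SC2, IN and
#' FF diets are generated (the diets with metatranscriptomes in the
#' emulated design); if the config contains none of those, all its groups
#' are used.
#'
#' @param cfg A `sim_config`.
#' @return List with `table` (a `strat_abund` in count units) and
#'   `ground_truth` (planted effects and the annotation used).
#' @export
gen_metatranscriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- builtin_demo_annotation()
  planted <- cfg$planted_sd_effects
  if (nrow(planted)) {
    missing_v <- setdiff(planted$vitamin, attr(ann, "vitamins_covered"))
    if (length(missing_v))
      stop("planted delta for vitamin(s) not covered by the annotation: ",
           paste(missing_v, collapse = ", "))
  }
  set.seed(cfg$seed + 1L)

  g <- cfg$groups
  mt_g <- g[g$colonization == "SPF" & g$diet_group %in% c("SC2", "IN", "FF"), ,
            drop = FALSE]
  if (!nrow(mt_g)) mt_g <- g
  meta <- sim_samples(mt_g)
  n_s <- nrow(meta)

  ann_df <- as.data.frame(ann)
  ann_feats <- unique(ann_df$feature_id)
  n_bg <- max(cfg$n_features - length(ann_feats), 5L)
  bg_feats <- sprintf("UniRef90_BG%03d", seq_len(n_bg))
  feats <- c(ann_feats, bg_feats)

  w <- c(stats::rlnorm(length(ann_feats), log(400), 0.5),
         stats::rlnorm(n_bg, log(1e4), 1))
  names(w) <- feats

  # per-sample expected weights with planted diet effects
  W <- matrix(rep(w, n_s), ncol = n_s, dimnames = list(feats, meta$sample_id))
  ff_like <- meta$diet_group %in% FIBER_FREE_DIETS
  if (nrow(planted) && any(ff_like)) {
    for (i in seq_len(nrow(planted))) {
      v <- planted$vitamin[i]
      if (planted$mechanism[i] == "downstream") {
        fv <- ann_df$feature_id[ann_df$vitamin == v & ann_df$role == "D"]
        W[fv, ff_like] <- W[fv, ff_like] * 2^planted$delta[i]
      } else {
        fv <- ann_df$feature_id[ann_df$vitamin == v & ann_df$role == "S"]
        W[fv, ff_like] <- W[fv, ff_like] * 2^-planted$delta[i]
      }
    }
  }

  depth <- stats::runif(n_s, cfg$noise$depth_range[1], cfg$noise$depth_range[2])
  props <- sweep(W, 2L, colSums(W), `/`)
  mu <- sweep(props, 2L, depth, `*`)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$noise$dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )

  # taxon strata for annotated features (exact multinomial split)
  taxa <- c("g__Roseburia.s__Roseburia_intestinalis",
            "g__Eubacterium.s__Eubacterium_rectale",
            "g__Mucispirillum.s__Mucispirillum_schaedleri",
            "g__Clostridium.s__Clostridium_sp_ASF502",
            "unclassified")
  p_fiber <- c(0.35, 0.25, 0.10, 0.10, 0.20)
  p_ff <- c(0.10, 0.10, 0.35, 0.25, 0.20)
  strat_rows <- list()
  for (f in ann_feats) {
    sub <- matrix(0, length(taxa), n_s,
                  dimnames = list(taxa, meta$sample_id))
    for (j in seq_len(n_s)) {
      p <- if (ff_like[j]) p_ff else p_fiber
      sub[, j] <- stats::rmultinom(1L, size = counts[f, j], prob = p)
    }
    strat_rows[[f]] <- sub
  }
  strat_mat <- do.call(rbind, strat_rows)
  strat_feature <- rep(ann_feats, each = length(taxa))
  strat_taxon <- rep(taxa, times = length(ann_feats))

  abund <- rbind(counts, strat_mat)
  feature <- c(feats, strat_feature)
  taxon <- c(rep(NA_character_, length(feats)), strat_taxon)
  rownames(abund) <- ifelse(is.na(taxon), feature,
                            paste0(feature, "|", taxon))

  tab <- strat_abund(abund, feature, taxon, units = "counts",
                     sample_meta = meta)
  list(table = tab,
       ground_truth = list(planted_sd_effects = planted, annotation = ann,
                           ff_like_diets = FIBER_FREE_DIETS,
                           taxa_panel = taxa))
}

#' Generate a metabolome table with planted microbiota dependence
#'
#' Log-normal concentrations over a metabolite universe of B vitamins
#' plus generic metabolites. The microbiota-dependent subset is missing
#' in every germ-free sample; within it, riboflavin and nicotinate and a
#' planted generic core are detected in colonized hosts of all diets,
#' while the remainder is detected only under fiber-containing diets —
#' so the colonized-only sets (SPF union 14SM, minus GF) are exactly the
#' planted sets for each diet. B vitamin concentrations follow the
#' emulated group pattern (elevated in colonized SC1/SC2/IN, depressed in
#' FF/FS, low or absent in germ-free hosts). Host-derived metabolites are
#' present everywhere with missing-at-random dropout, with at least one
#' detected sample guaranteed per group. Per-sample size factors (cecal
#' weight in g or serum volume in uL) are drawn log-normally; stored
#' concentrations are per-sample amounts so that dividing by the size
#' factor recovers the per-gram (or per-uL) value.
#'
#' @param cfg A `sim_config`.
#' @param compartment `"cecum"` (default) or `"serum"` (serum vitamin
#'   means are diet-flat).
#' @return List with `table` (a `metab_table`) and `ground_truth`
#'   (planted colonized-only sets per diet, the microbiota-dependent set,
#'   and the vitamin concentration pattern).
#' @export
gen_metabolome <- function(cfg, compartment = c("cecum", "serum")) {
  stopifnot(inherits(cfg, "sim_config"))
  compartment <- match.arg(compartment)
  set.seed(cfg$seed + if (compartment == "cecum") 2L else 4L)

  meta <- sim_samples(cfg$groups)
  n_s <- nrow(meta)
  bv <- bvitamin_metabolites()
  n_gen <- cfg$n_metabolites - length(bv)
  if (n_gen < 1L) stop("n_metabolites too small for the vitamin panel")
  gen_names <- sprintf("met_%03d", seq_len(n_gen))
  mets <- c(unname(bv), gen_names)

  md_n <- round(cfg$frac_microbiota_dependent * cfg$n_metabolites)
  md_vit <- utils::head(c(bv[["B2"]], bv[["B3"]]), min(md_n, 2L))
  n_md_gen <- max(md_n - length(md_vit), 0L)
  if (n_md_gen > n_gen)
    stop("frac_microbiota_dependent too large for n_metabolites")
  md_gen <- gen_names[seq_len(n_md_gen)]
  c_sc1 <- c(md_vit, md_gen) # colonized-only set under fiber-containing diets
  n_ff <- round(cfg$colonized_only_ff_frac * length(c_sc1))
  c_ff <- c_sc1[seq_len(n_ff)] # also detected in colonized FF-fed hosts

  is_gf <- meta$colonization == "GF"
  is_ff_diet <- meta$diet_group == "FF"

  # per-gram baseline (log10 scale) for generic metabolites
  base_log10 <- stats::rnorm(length(mets), mean = 1, sd = 0.8)
  names(base_log10) <- mets

  # B vitamin group pattern (per-gram concentrations, nmol/g)
  vit_mean <- function(code, diet, colonization) {
    high <- 10
    low <- 0.5
    if (compartment == "serum") return(2) # diet-flat in serum
    m <- switch(code,
      B1 = if (diet %in% c("SC1", "SC2")) high else low,
      B2 = , B3 = , B5 = , B6 =
        if (diet %in% c("SC1", "SC2", "IN")) high else low,
      B7 = , B9 = , B12 = if (diet %in% FIBER_FREE_DIETS) 2 else 4
    )
    if (colonization == "14SM") m <- m * 0.3
    if (colonization == "GF") m <- 0.05
    m
  }

  conc <- matrix(NA_real_, length(mets), n_s,
                 dimnames = list(mets, meta$sample_id))
  sd0 <- cfg$noise$met_sd_log10
  for (j in seq_len(n_s)) {
    lg <- base_log10 + stats::rnorm(length(mets), 0, sd0)
    conc[, j] <- 10^lg
  }
  for (code in names(bv)) {
    m <- vapply(seq_len(n_s), function(j)
      vit_mean(code, meta$diet_group[j], meta$colonization[j]), numeric(1))
    conc[bv[[code]], ] <- 10^(log10(m) + stats::rnorm(n_s, 0, sd0))
  }

  # microbiota dependence: absent in GF; riboflavin/nicotinate carry it
  conc[c_sc1, is_gf] <- NA_real_
  absent_colonized_ff <- setdiff(c_sc1, c_ff)
  if (length(absent_colonized_ff))
    conc[absent_colonized_ff, !is_gf & is_ff_diet] <- NA_real_

  # missing-at-random dropout for host-derived metabolites, with at least
  # one detected sample guaranteed per group
  host <- setdiff(mets, c_sc1)
  grp <- paste(meta$colonization, meta$diet_group)
  drop <- matrix(stats::runif(length(host) * n_s) < cfg$noise$missing_rate,
                 length(host), n_s, dimnames = list(host, NULL))
  for (lvl in unique(grp)) {
    idx <- which(grp == lvl)
    all_gone <- rowSums(!drop[, idx, drop = FALSE]) == 0L
    if (any(all_gone)) drop[all_gone, idx[1L]] <- FALSE
  }
  conc[host, ][drop] <- NA_real_

  size_factor <- if (compartment == "cecum")
    stats::rlnorm(n_s, log(0.25), 0.2)
  else
    stats::rlnorm(n_s, log(30), 0.1)
  conc <- sweep(conc, 2L, size_factor, `*`)

  meta$compartment <- compartment
  meta$size_factor <- size_factor
  tab <- metabolome_table(conc, meta)
  list(table = tab,
       ground_truth = list(
         colonized_only = list(SC1 = sort(c_sc1), FF = sort(c_ff)),
         microbiota_dependent = sort(c_sc1),
         bvitamin_names = bv
       ))
}

#' Generate an immune-population frequency table
#'
#' Population frequencies (% of CD45+ cells) for a panel including the
#' key effector readouts (mast cells, NK cells, Th17 cells, Tregs).
#' Planted correlations are induced against the generated B vitamin
#' concentrations through a shared latent factor: for a target r the
#' planted population is `r * z_v + sqrt(1 - r^2) * noise`, where `z_v`
#' is the standardized log10 normalized vitamin concentration
#' (non-detected values imputed at one-fifth of the detected minimum).
#' Targets with |r| above the attainable bound (0.99, set by the
#' frequency floor) are refused with the bound in the message.
#'
#' @param cfg A `sim_config`.
#' @param metabolome Optional `metab_table` to correlate against;
#'   defaults to `gen_metabolome(cfg)$table` (deterministic, same seed).
#' @return List with `table` (an `immune_table`) and `ground_truth`
#'   (the planted correlation targets).
#' @export
gen_immune <- function(cfg, metabolome = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(metabolome)) metabolome <- gen_metabolome(cfg)$table
  stopifnot(inherits(metabolome, "metab_table"))
  planted <- cfg$planted_correlations
  r_max <- 0.99
  if (nrow(planted) && any(abs(planted$r) > r_max))
    stop("planted |r| exceeds the attainable bound ", r_max,
         " set by the frequency floor")
  set.seed(cfg$seed + 3L)

  meta <- metabolome$sample_meta[, c("sample_id", "diet_group",
                                     "colonization")]
  n_s <- nrow(meta)
  populations <- c("Mast cells", "NK cells", "Th17 cells", "Tregs",
                   "CD8 T cells", "CD4 T cells", "NKT cells", "Neutrophils",
                   "CD11c+ cells", "Ly6C+ monocytes", "M2 macrophages",
                   "B cells")
  populations <- union(populations, planted$population)

  bv <- bvitamin_metabolites()
  norm <- sweep(metabolome$conc, 2L, metabolome$sample_meta$size_factor, `/`)
  latent_for <- function(code) {
    mname <- bv[[code]]
    if (is.null(mname) || !(mname %in% rownames(norm)))
      stop("planted correlation for vitamin ", code,
           " has no metabolite row '", mname, "'")
    v <- norm[mname, ]
    obs <- is.finite(v) & v > 0
    if (!any(obs)) stop("vitamin ", mname, " never detected")
    v[!obs] <- min(v[obs]) / 5
    as.numeric(scale(log10(v)))
  }

  freq <- matrix(NA_real_, length(populations), n_s,
                 dimnames = list(populations, meta$sample_id))
  mu <- cfg$noise$immune_mu
  sdv <- cfg$noise$immune_sd
  for (p in populations) {
    hit <- which(planted$population == p)
    if (length(hit)) {
      r <- planted$r[hit]
      z <- r * latent_for(planted$vitamin[hit]) +
        sqrt(1 - r^2) * stats::rnorm(n_s)
      freq[p, ] <- mu + sdv * z
    } else {
      m <- stats::runif(1L, 1, 10)
      freq[p, ] <- m + 0.3 * m * stats::rnorm(n_s)
    }
  }
  freq[freq < 0.01] <- 0.01
  freq[freq > 100] <- 100

  list(table = immune_table(freq, meta),
       ground_truth = list(planted_correlations = planted))
}
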