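test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9)
  a <- gen_metatranscriptome(cfg)
  b <- gen_metatranscriptome(cfg)
  expect_identical(a$table$abund, b$table$abund)
  m1 <- gen_metabolome(cfg)
  m2 <- gen_metabolome(cfg)
  expect_identical(m1$table$conc, m2$table$conc)
  i1 <- gen_immune(cfg, metabolome = m1$table)
  i2 <- gen_immune(cfg, metabolome = m2$table)
  expect_identical(i1$table$freq, i2$table$freq)
})

test_that("config validation refuses out-of-range parameters", {
  expect_error(sim_config(frac_microbiota_dependent = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(planted_correlations = data.frame(
    vitamin = "B2", population = "Mast cells", r = 1.0
  )), "< 1")
  expect_error(sim_config(groups = data.frame(
    diet_group = "FF", colonization = "SPF", n = 0
  )), "positive")
  bad <- sim_config()
  bad$planted_correlations$r <- -0.999
  expect_error(gen_immune(bad), "attainable bound")
  expect_error(sim_config(planted_sd_effects = data.frame(
    vitamin = "B2", delta = 2, mechanism = "sideways"
  )), "mechanism")
})

test_that("metatranscriptome output respects the stratified-table contract", {
  tab <- gen_metatranscriptome(sim_config(seed = 4))$table
  expect_s3_class(tab, "strat_abund")
  expect_true(all(tab$abund >= 0))
  # strata sum exactly to their TOTAL row (multinomial split)
  is_total <- is.na(tab$taxon)
  for (f in unique(tab$feature[!is_total])) {
    tot <- tab$abund[is_total & tab$feature == f, , drop = FALSE]
    expect_equal(colSums(tab$abund[!is_total & tab$feature == f, ,
                                   drop = FALSE]),
                 tot[1, ])
  }
  expect_true("unclassified" %in% tab$taxon)
  # planted effect for a vitamin the annotation does not cover is refused
  expect_error(gen_metatranscriptome(sim_config(planted_sd_effects =
    data.frame(vitamin = "B4", delta = 2, mechanism = "downstream")
  )), "not covered")
})

test_that("planted colonized-only sets are recovered exactly and GF lacks them", {
  gm <- gen_metabolome(sim_config(seed = 12))
  tab <- gm$table
  truth <- gm$ground_truth
  gf_cols <- tab$sample_meta$colonization == "GF"
  md <- truth$microbiota_dependent
  expect_true(all(is.na(tab$conc[md, gf_cols])))
  for (diet in c("SC1", "FF")) {
    res <- colonized_only(detection_sets(tab, diet = diet))
    expect_identical(res$metabolites, truth$colonized_only[[diet]])
  }
  # prevalence filter retains the planted-signal (B vitamin) metabolites
  bv <- unname(bvitamin_metabolites())
  for (s in 1:10) {
    t2 <- gen_metabolome(sim_config(seed = 200 + s))$table
    expect_true(all(bv %in% rownames(prevalence_filter(t2)$conc)))
  }
})

test_that("immune frequencies stay in range and realize planted correlations", {
  g24 <- expand.grid(diet_group = c("SC1", "FF"),
                     colonization = c("SPF", "14SM", "GF"),
                     stringsAsFactors = FALSE)
  g24$n <- 4L
  bv <- bvitamin_metabolites()
  hits <- 0
  for (s in 1:20) {
    cfg <- sim_config(seed = 300 + s, groups = g24)
    met <- gen_metabolome(cfg)$table
    imm <- gen_immune(cfg, metabolome = met)$table
    expect_true(all(imm$freq >= 0 & imm$freq <= 100))
    # realized r for the (B2, mast cells) plant, recomputed directly
    v <- met$conc["Riboflavin", ] / met$sample_meta$size_factor
    obs <- is.finite(v) & v > 0
    v[!obs] <- min(v[obs]) / 5
    r <- cor(log10(v), imm$freq["Mast cells", ])
    if (r > -0.95 && r < -0.5) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("without planted correlations, spurious strong cells are rare", {
  g24 <- expand.grid(diet_group = c("SC1", "FF"),
                     colonization = c("SPF", "14SM", "GF"),
                     stringsAsFactors = FALSE)
  g24$n <- 4L
  bv <- bvitamin_metabolites()
  strong <- 0
  cells <- 0
  for (s in 1:25) {
    cfg <- sim_config(seed = 400 + s, groups = g24,
                      planted_correlations = default_correlations()[0, ])
    met <- gen_metabolome(cfg)$table
    imm <- gen_immune(cfg, metabolome = met)$table
    met_b <- metabolome_table(met$conc[unname(bv), , drop = FALSE],
                              met$sample_meta)
    cm <- bvitamin_immune_correlation(met_b, imm)
    r <- cm$table$r[!is.na(cm$table$r)]
    strong <- strong + sum(abs(r) >= 0.5)
    cells <- cells + length(r)
  }
  expect_lte(strong / cells, 0.05)
})

test_that("generated tables round-trip through the file readers", {
  cfg <- sim_config(seed = 13, groups = data.frame(
    diet_group = c("IN", "FF"), colonization = "SPF", n = 3L
  ))
  tab <- gen_metatranscriptome(cfg)$table
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genefamilies(tab, f)
  back <- read_genefamilies(f)
  expect_equal(back$abund, tab$abund)
  expect_equal(back$feature, tab$feature)
  expect_equal(back$taxon, tab$taxon)
})
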