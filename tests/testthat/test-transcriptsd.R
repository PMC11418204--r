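write_gf_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(c("# Gene Family\tm1\tm2", lines), f)
  f
}

test_that("stratified gene-family tables parse, validate and round-trip", {
  tab <- read_genefamilies(write_gf_lines(c(
    "featA\t10\t20",
    "featA|g__X.s__x\t6\t12",
    "featB\t5\t5"
  )))
  expect_equal(sum(is.na(tab$taxon)), 2)
  expect_equal(sum(!is.na(tab$taxon)), 1)
  expect_equal(tab$abund["featA|g__X.s__x", "m2"], 12)

  empty <- read_genefamilies(write_gf_lines(character()))
  expect_equal(nrow(empty$abund), 0)

  expect_error(read_genefamilies(write_gf_lines(c(
    "featA\t10\t20", "featA|g__X.s__x\t11\t1"
  ))), "exceed its TOTAL")
  expect_error(read_genefamilies(write_gf_lines(c(
    "featA|g__X.s__x\t1\t1"
  ))), "without a TOTAL")
  expect_error(read_genefamilies(write_gf_lines(c(
    "featA\t10\toops"
  ))), "malformed numeric.*m2")
  expect_error(read_genefamilies(write_gf_lines(c(
    "featA\t1\t1", "featA\t2\t2"
  ))), "duplicated")

  out <- withr::local_tempfile(fileext = ".tsv")
  orig <- read_genefamilies(write_gf_lines(c(
    "featA\t10\t20", "featA|g__X.s__x\t6\t12", "featB\t5\t5"
  )))
  write_genefamilies(orig, out)
  expect_equal(read_genefamilies(out)$abund, orig$abund)
})

test_that("CPM renormalization forces per-sample totals of 1e6", {
  tab <- strat_abund(
    matrix(c(30, 70), 2, 1, dimnames = list(NULL, "s1")),
    feature = c("a", "b"), taxon = c(NA, NA), units = "counts"
  )
  cpm <- to_cpm(tab)
  expect_equal(unname(cpm$abund[, 1]), c(3e5, 7e5))
  expect_equal(cpm$units, "cpm")
  expect_error(to_cpm(cpm), "already")

  set.seed(14)
  for (i in 1:10) {
    m <- matrix(rpois(30, 50) + 1, 6, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
    tab <- strat_abund(m, feature = letters[1:6], taxon = rep(NA, 6),
                       units = "counts")
    expect_equal(unname(colSums(to_cpm(tab)$abund)), rep(1e6, 5),
                 tolerance = 1e-9)
  }
  z <- strat_abund(matrix(c(0, 0), 2, 1, dimnames = list(NULL, "s1")),
                   feature = c("a", "b"), taxon = c(NA, NA))
  expect_error(to_cpm(z), "zero total.*s1")
})

test_that("vitamin/role aggregation matches hand arithmetic and attributes taxa", {
  vra <- aggregate_vitamin_roles(toy_strat(), builtin_demo_annotation())
  tot <- vra$totals
  expect_equal(tot$relab[tot$vitamin == "B2" & tot$role == "S" &
                           tot$sample == "s1"], 0.04)
  expect_equal(tot$relab[tot$vitamin == "B2" & tot$role == "D" &
                           tot$sample == "s1"], 0.01)
  # other vitamins have no features in the table -> 0
  expect_true(all(tot$relab[tot$vitamin != "B2"] == 0))

  st <- vra$strata
  s1 <- st[st$sample == "s1" & st$vitamin == "B2" & st$role == "S", ]
  expect_equal(s1$relab[s1$taxon == "g__A.s__a"] /
                 sum(s1$relab), 0.75)
  # s2: named stratum 200 + unclassified 100 + remainder 100 -> 50/50
  s2 <- st[st$sample == "s2" & st$vitamin == "B2" & st$role == "S", ]
  expect_equal(s2$relab[s2$taxon == "unclassified"],
               s2$relab[s2$taxon == "g__A.s__a"])

  empty_ann <- builtin_demo_annotation()[0, ]
  class(empty_ann) <- c("vitamin_annotation", "data.frame")
  expect_equal(nrow(aggregate_vitamin_roles(toy_strat(), empty_ann)$totals), 0)
})

test_that("aggregation equals a brute-force loop and conserves strata", {
  ann <- builtin_demo_annotation()
  for (s in 1:5) {
    cfg <- sim_config(seed = 100 + s, n_features = 45)
    tab <- to_cpm(gen_metatranscriptome(cfg)$table)
    vra <- aggregate_vitamin_roles(tab, ann)
    ref <- aggregate_bruteforce(tab, as.data.frame(ann))
    for (key in names(ref)) {
      parts <- strsplit(key, " ")[[1]]
      got <- vra$totals[vra$totals$vitamin == parts[1] &
                          vra$totals$role == parts[2], ]
      expect_equal(got$relab[match(names(ref[[key]]), got$sample)],
                   unname(ref[[key]]), tolerance = 1e-12)
      # conservation: stratified taxon sums equal the unstratified value
      st <- vra$strata[vra$strata$vitamin == parts[1] &
                         vra$strata$role == parts[2], ]
      if (nrow(st)) {
        agg <- tapply(st$relab, st$sample, sum)
        expect_equal(as.numeric(agg[got$sample]), got$relab,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("relative abundances are invariant to per-sample scale changes", {
  cfg <- sim_config(seed = 3, n_features = 45)
  raw <- gen_metatranscriptome(cfg)$table
  scaled <- raw
  scaled$abund[, 2] <- scaled$abund[, 2] * 17
  ann <- builtin_demo_annotation()
  v1 <- aggregate_vitamin_roles(to_cpm(raw), ann)
  v2 <- aggregate_vitamin_roles(to_cpm(scaled), ann)
  expect_equal(v1$totals$relab, v2$totals$relab, tolerance = 1e-12)
  expect_equal(log2_sd_ratio(v1)$log2_ratio, log2_sd_ratio(v2)$log2_ratio,
               tolerance = 1e-12)
})

test_that("log2 S/D ratio applies the pseudocount rule per vitamin", {
  vra <- aggregate_vitamin_roles(toy_strat(), builtin_demo_annotation())
  sdr <- log2_sd_ratio(vra)
  b2 <- sdr[sdr$vitamin == "B2", ]
  expect_false(any(b2$pseudocount_applied))
  expect_equal(b2$log2_ratio, rep(log2(4), 2)) # 0.04 / 0.01
  # vitamins with no features: S = D = 0 -> pseudocount -> ratio 0
  b1 <- sdr[sdr$vitamin == "B1", ]
  expect_true(all(b1$pseudocount_applied))
  expect_equal(b1$log2_ratio, rep(0, 2))
  # pseudocount reported values satisfy the stated identity
  expect_equal(sdr$log2_ratio, log2(sdr$S / sdr$D), tolerance = 1e-12)
})

test_that("group comparison of ratios is antisymmetric and handles degeneracy", {
  cfg <- sim_config(seed = 2, groups = data.frame(
    diet_group = c("IN", "FF"), colonization = "SPF", n = 4L
  ))
  sdr <- log2_sd_ratio(aggregate_vitamin_roles(
    to_cpm(gen_metatranscriptome(cfg)$table), builtin_demo_annotation()
  ))
  ab <- compare_sd(sdr, "SPF:IN", "SPF:FF")
  ba <- compare_sd(sdr, "SPF:FF", "SPF:IN")
  expect_equal(ab$p_raw, ba$p_raw)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$direction, -ba$direction)

  # identical groups -> p = 1, not significant
  fake <- sdr
  g <- setNames(rep(c("g1", "g2"), each = 4), unique(sdr$sample))
  fake$log2_ratio <- rep(1, nrow(fake))
  res <- compare_sd(fake, "g1", "g2", groups = g)
  expect_true(all(res$p_raw == 1) && !any(res$significant))

  # degenerate group (n < 2) skipped with warnings, one per vitamin
  g2 <- g
  g2[2:4] <- "g2"
  w <- capture_warnings(res2 <- compare_sd(sdr, "g1", "g2", groups = g2))
  expect_true(length(w) > 0 && all(grepl("fewer than 2", w)))
  expect_equal(nrow(res2), 0)
})

test_that("taxon contributions rank strata and recompute from raw values", {
  vra <- aggregate_vitamin_roles(toy_strat(), builtin_demo_annotation())
  tc <- taxon_contributions(vra, "B2", "S")
  expect_true(all(c("g__A.s__a", "unclassified") %in% tc$taxon))
  in_grp <- tc[tc$group == "SPF:IN", ]
  expect_equal(in_grp$taxon[in_grp$rank == 1], "g__A.s__a")
  expect_equal(in_grp$mean_relab[in_grp$taxon == "g__A.s__a"] /
                 sum(in_grp$mean_relab), 0.75)
  # empty result when no strata exist for the request
  expect_message(tc0 <- taxon_contributions(vra, "B5", "S"), "no strata")
  expect_equal(nrow(tc0), 0)
})
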