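met_group_labels_for_test <- function(tab) {
  paste(tab$sample_meta$colonization, tab$sample_meta$diet_group, sep = ":")
}

test_that("the prevalence filter applies the at-least-half rule and is idempotent", {
  conc <- matrix(c(1, 2, NA, NA,
                   1, NA, NA, NA), 2, 4, byrow = TRUE,
                 dimnames = list(c("kept", "dropped"), paste0("s", 1:4)))
  tab <- toy_metab(conc) # one group of 4
  filt <- prevalence_filter(tab)
  expect_equal(rownames(filt$conc), "kept") # 2 of 4 detected: 2*2 >= 4
  expect_equal(attr(filt, "dropped"), "dropped")

  # detected in 2 of every group of 5 -> dropped (2*2 < 5)
  conc5 <- matrix(rep(c(1, 1, NA, NA, NA), 2), 1, 10,
                  dimnames = list("m", paste0("s", 1:10)))
  tab5 <- toy_metab(conc5, diet = rep(c("A", "B"), each = 5))
  expect_equal(nrow(prevalence_filter(tab5)$conc), 0)

  set.seed(41)
  for (i in 1:200) {
    tab <- random_metab()
    filt <- prevalence_filter(tab)
    keep <- prevalence_bruteforce(tab$conc, met_group_labels_for_test(tab))
    expect_identical(rownames(filt$conc), rownames(tab$conc)[keep])
    # idempotence
    expect_identical(prevalence_filter(filt)$conc, filt$conc)
  }
})

test_that("autoscaling yields exact row moments and a hand-checked toy", {
  conc <- matrix(c(10, 1000), 1, 2, dimnames = list("m", c("s1", "s2")))
  z <- normalize_log_scale(toy_metab(conc))
  expect_equal(unname(z[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    tab <- prevalence_filter(random_metab(n_met = 15))
    z <- normalize_log_scale(tab)
    expect_lt(max(abs(rowMeans(z))), 1e-9)
    expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
    # global size-factor rescale leaves the scaled matrix unchanged
    tab2 <- tab
    tab2$sample_meta$size_factor <- tab2$sample_meta$size_factor * 2
    expect_equal(normalize_log_scale(tab2), z, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("scaled-matrix provenance records the preprocessing choices", {
  z <- normalize_log_scale(toy_metab(
    matrix(c(10, 1000), 1, 2, dimnames = list("m", c("s1", "s2")))
  ))
  prov <- attr(z, "provenance")
  expect_true(prov$normalized)
  expect_equal(prov$log_base, 10)
  expect_equal(prov$imputation_rule, "min_observed/5")
})

test_that("differential ranking finds a planted shift and controls the null", {
  set.seed(55)
  top1 <- 0
  for (s in 1:50) {
    z0 <- matrix(rnorm(40 * 20), 40, 20,
                 dimnames = list(sprintf("m%02d", 1:40), sprintf("s%02d", 1:20)))
    grp <- rep(c("A", "B", "C", "D", "FF"), each = 4)
    z0["m01", grp == "FF"] <- z0["m01", grp == "FF"] + 4
    z <- structure(z0, class = c("scaled_matrix", "matrix", "array"))
    dr <- differential_rank(z, "FF", k = 5, groups = grp)
    if (dr$metabolite[1] == "m01") top1 <- top1 + 1
  }
  expect_gte(top1 / 50, 0.95)

  # all-null: raw p approximately uniform, BH discoveries rare
  set.seed(56)
  disc <- 0
  pall <- c()
  for (s in 1:10) {
    z0 <- matrix(rnorm(300 * 20), 300, 20,
                 dimnames = list(sprintf("m%03d", 1:300), sprintf("s%02d", 1:20)))
    grp <- rep(c("A", "B", "C", "D", "FF"), each = 4)
    z <- structure(z0, class = c("scaled_matrix", "matrix", "array"))
    dr <- differential_rank(z, "FF", k = 300, groups = grp)
    disc <- disc + sum(dr$p_adj <= 0.05)
    pall <- c(pall, dr$p_raw)
  }
  expect_lte(disc / (10 * 300), 0.07)
  expect_gt(ks.test(pall, "punif")$p.value, 0.01)
})

test_that("differential ranking is invariant to sample order and supports moderation", {
  set.seed(57)
  z0 <- matrix(rnorm(30 * 15), 30, 15,
               dimnames = list(sprintf("m%02d", 1:30), sprintf("s%02d", 1:15)))
  grp <- rep(c("A", "B", "FF"), each = 5)
  z0["m05", grp == "A"] <- z0["m05", grp == "A"] + 3
  z <- structure(z0, class = c("scaled_matrix", "matrix", "array"))
  dr <- differential_rank(z, "FF", k = 30, groups = grp)
  perm <- sample(15)
  zp <- structure(z0[, perm], class = c("scaled_matrix", "matrix", "array"))
  drp <- differential_rank(zp, "FF", k = 30, groups = grp[perm])
  expect_equal(dr$metabolite, drp$metabolite)
  expect_equal(dr$p_raw, drp$p_raw, tolerance = 1e-12)

  drm <- differential_rank(z, "FF", k = 5, groups = grp, moderation = TRUE)
  expect_equal(drm$metabolite[1], "m05")
  expect_message(differential_rank(z, "FF", k = 99, groups = grp), "exceeds")
})

test_that("detection sets partition the universe into exclusive regions", {
  conc <- rbind(
    both      = c(1, 1, NA), # SPF & 14SM, absent GF
    everywhere = c(1, 1, 1),
    gf_only   = c(NA, NA, 1),
    nowhere   = c(NA, NA, NA)
  )
  colnames(conc) <- c("a", "b", "c")
  tab <- toy_metab(conc, diet = rep("SC1", 3),
                   colonization = c("SPF", "14SM", "GF"))
  sets <- detection_sets(tab, diet = "SC1")
  expect_true("both" %in% intersect(sets$sets$SPF, sets$sets$`14SM`))
  expect_false("both" %in% sets$sets$GF)
  expect_equal(sets$regions$count[sets$regions$region == "SPF&14SM"], 1L)
  expect_equal(sum(sets$regions$count), 3L) # 'nowhere' in no region

  # identical tables -> everything in the triple intersection
  conc2 <- matrix(1, 2, 3, dimnames = list(c("x", "y"), c("a", "b", "c")))
  tab2 <- toy_metab(conc2, colonization = c("SPF", "14SM", "GF"))
  sets2 <- detection_sets(tab2)
  expect_equal(sets2$regions$region, "SPF&14SM&GF")
  expect_equal(sets2$regions$count, 2L)

  set.seed(60)
  for (i in 1:25) {
    n_met <- 20
    conc <- matrix(ifelse(runif(n_met * 9) < 0.5, 1, NA), n_met, 9,
                   dimnames = list(sprintf("m%02d", 1:n_met),
                                   sprintf("s%d", 1:9)))
    tab <- toy_metab(conc, colonization = rep(c("SPF", "14SM", "GF"), each = 3))
    sets <- detection_sets(tab)
    ref <- regions_bruteforce(sets$sets, rownames(conc))
    got <- setNames(as.list(sets$regions$count), sets$regions$region)
    expect_equal(got[order(names(got))], ref[order(names(ref))])
  }
})

test_that("the colonized-only set equals its set expression for all membership patterns", {
  for (mask in 0:7) {
    inSPF <- bitwAnd(mask, 1) > 0
    in14 <- bitwAnd(mask, 2) > 0
    inGF <- bitwAnd(mask, 4) > 0
    conc <- rbind(
      probe = c(if (inSPF) 1 else NA, if (in14) 1 else NA,
                if (inGF) 1 else NA),
      anchor = c(1, 1, 1)
    )
    colnames(conc) <- c("a", "b", "c")
    tab <- toy_metab(conc, colonization = c("SPF", "14SM", "GF"))
    res <- colonized_only(detection_sets(tab))
    expected <- (inSPF || in14) && !inGF
    expect_equal("probe" %in% res$metabolites, expected,
                 info = paste("mask", mask))
  }
  conc <- matrix(1, 1, 2, dimnames = list("m", c("a", "b")))
  tab <- toy_metab(conc, colonization = c("SPF", "14SM"))
  expect_error(colonized_only(detection_sets(tab)), "missing colonization")
})

test_that("Ward ordering is a deterministic permutation with contiguous structure", {
  set.seed(70)
  m <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(letters[1:8], NULL))
  m["b", ] <- m["a", ] # identical rows merge first
  ord <- ward_order(m)
  expect_setequal(ord, 1:8)
  expect_equal(abs(diff(which(letters[ord] %in% c("a", "b")))), 1)

  # planted correlated blocks stay contiguous
  base1 <- rnorm(10)
  base2 <- rnorm(10) + 8
  blocks <- rbind(
    t(replicate(4, base1 + rnorm(10, 0, 0.1))),
    t(replicate(4, base2 + rnorm(10, 0, 0.1)))
  )
  rownames(blocks) <- sprintf("r%d", 1:8)
  ordb <- ward_order(blocks)
  expect_true(all(diff(sort(match(1:4, ordb))) == 1))

  # invariance to row permutation (labels carried with the rows)
  perm <- sample(8)
  ord1 <- rownames(blocks)[ward_order(blocks)]
  ord2 <- rownames(blocks)[perm][ward_order(blocks[perm, ])]
  expect_equal(ord1, ord2)

  expect_equal(ward_order(matrix(1, 1, 3)), 1L)
})
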