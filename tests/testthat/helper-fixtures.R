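# Small in-code fixtures shared across test files.

demo_ann_df <- function() as.data.frame(builtin_demo_annotation())

# Minimal stratified table: two B2 features (one stratified) plus filler so
# the denominator is non-trivial.
toy_strat <- function() {
  abund <- rbind(
    "EC 2.5.1.9"              = c(s1 = 400, s2 = 400),
    "EC 2.7.1.26"             = c(100, 100),
    "UniRef90_FILL"           = c(999500, 999500),
    "EC 2.5.1.9|g__A.s__a"    = c(300, 200),
    "EC 2.5.1.9|unclassified" = c(100, 100)
  )
  strat_abund(
    abund,
    feature = c("EC 2.5.1.9", "EC 2.7.1.26", "UniRef90_FILL",
                "EC 2.5.1.9", "EC 2.5.1.9"),
    taxon = c(NA, NA, NA, "g__A.s__a", "unclassified"),
    units = "cpm",
    sample_meta = data.frame(sample_id = c("s1", "s2"),
                             diet_group = c("IN", "FF"),
                             colonization = "SPF")
  )
}

# Metabolome toy with explicit group structure for set analysis.
toy_metab <- function(conc, diet = NULL, colonization = NULL) {
  n <- ncol(conc)
  if (is.null(diet)) diet <- rep("SC1", n)
  if (is.null(colonization)) colonization <- rep("SPF", n)
  metabolome_table(conc, data.frame(
    sample_id = colnames(conc), diet_group = diet,
    colonization = colonization, compartment = "cecum", size_factor = 1
  ))
}

random_metab <- function(n_met = 12, groups = c(A = 4, B = 5)) {
  n <- sum(groups)
  conc <- matrix(rlnorm(n_met * n), n_met, n,
                 dimnames = list(sprintf("m%02d", 1:n_met),
                                 sprintf("x%02d", 1:n)))
  conc[runif(length(conc)) < 0.35] <- NA
  toy_metab(conc, diet = rep(names(groups), groups))
}
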