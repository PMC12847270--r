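# In-code fixtures shared across the suite.

# A valid sieve table covering the full 5 x 2 x n design, random masses.
make_sieve_df <- function(n_replicates = 3, seed = 42) {
  withr::with_seed(seed, {
    design <- expand.grid(replicate = seq_len(n_replicates),
                          depth = c("D0_20", "D20_40"),
                          treatment = c("RT", "IRT", "I70", "IS", "IO"),
                          stringsAsFactors = FALSE)
    df <- data.frame(
      sample_id = sprintf("%s_%s_r%02d", design$treatment, design$depth,
                          design$replicate),
      treatment = design$treatment, depth = design$depth,
      replicate = design$replicate, stringsAsFactors = FALSE
    )
    m <- matrix(runif(nrow(df) * 6, 0.5, 20), ncol = 6)
    colnames(m) <- c("class_gt2", "class_1_2", "class_05_1", "class_025_05",
                     "class_0053_025", "class_lt0053")
    cbind(df, as.data.frame(m))
  })
}

make_chem_df <- function(seed = 42) {
  df <- make_sieve_df(seed = seed)[1:4]
  withr::with_seed(seed + 1, {
    df$SOM <- runif(nrow(df), 10, 30)
    df$TN <- runif(nrow(df), 0.5, 2)
    df$TP <- runif(nrow(df), 0.3, 1)
    df$AN <- runif(nrow(df), 50, 150)
    df$AP <- runif(nrow(df), 5, 40)
    df$pH <- runif(nrow(df), 5.5, 8.5)
  })
  df
}

make_counts <- function(n_samples = 4, n_taxa = 6, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_taxa, 30), n_samples, n_taxa,
                dimnames = list(sprintf("S%d", seq_len(n_samples)),
                                sprintf("OTU%d", seq_len(n_taxa))))
    storage.mode(m) <- "integer"
    m
  })
}

# Dominance-calibrated synthetic config: every effect strictly ordered
# IO > IS > IRT > I70 > RT on every index (chemistry, copies, and the
# macroaggregate classes), used for ranking checks.
dominance_config <- function(seed = 1, n_replicates = 200, noise_cv = 0.05) {
  cfg <- default_calibration(seed = seed, n_replicates = n_replicates,
                             noise_cv = noise_cv)
  ord <- c(RT = 1, I70 = 1.1, IRT = 1.25, IS = 1.45, IO = 1.7)
  mult <- cfg$effect_multipliers
  for (v in setdiff(rownames(cfg$baseline_means), "pH")) {
    for (d in colnames(cfg$baseline_means)) {
      mult[v, names(ord), d] <- ord
    }
  }
  mult["pH", , ] <- 1 # pH is not part of the ranked index set
  smult <- cfg$sieve_multipliers
  smult[] <- 1
  for (cl in c("class_gt2", "class_1_2", "class_05_1", "class_025_05")) {
    smult[names(ord), , cl] <- ord
  }
  synth_config(seed = cfg$seed, n_replicates = cfg$n_replicates,
               baseline_means = cfg$baseline_means,
               effect_multipliers = mult, noise_cv = noise_cv,
               sieve_composition = cfg$sieve_composition,
               sieve_multipliers = smult,
               evenness_shift = cfg$evenness_shift)
}
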