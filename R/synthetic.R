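#' Configuration of the synthetic field-experiment generator
#'
#' Describes a randomized-block co-culture fertilization experiment:
#' `treatments` x `depths` x `n_replicates` plot samples, multiplicative
#' treatment effects on strictly positive measurements (lognormal noise with
#' a stated coefficient of variation), Dirichlet-distributed wet-sieve
#' fraction compositions, and Dirichlet-multinomial taxon counts.
#'
#' @param seed integer RNG seed; a fixed seed makes [generate_dataset()]
#'   byte-reproducible.
#' @param n_replicates replicates per treatment x depth (default 3, the
#'   field design).
#' @param treatments,depths design labels.
#' @param baseline_means variables x depths matrix of control (first
#'   treatment) means; rows named by variable, columns by depth.
#' @param effect_multipliers 3-d array `[variable, treatment, depth]` of
#'   multiplicative effects on the baseline mean (control column 1).
#' @param noise_cv coefficient of variation of the lognormal measurement
#'   noise, scalar or named per variable (default 0.08). `0` makes every
#'   replicate equal its expected mean exactly.
#' @param sieve_composition depths x 6 matrix of expected control sieve
#'   fractions (rows sum to 1), descending class order.
#' @param sieve_multipliers 3-d array `[treatment, depth, class]` of
#'   multiplicative shifts applied to the Dirichlet concentration of each
#'   size class.
#' @param sieve_concentration total Dirichlet concentration of the sieve
#'   composition (larger = less compositional noise; default 300).
#' @param total_sieve_mass_g wet-sieved sample mass (default 50 g).
#' @param n_taxa,count_depth taxon count table dimensions (default 200 taxa,
#'   20000 reads per sample).
#' @param count_concentration Dirichlet concentration of the per-sample
#'   composition around the treatment composition (default 500).
#' @param taxa_decay geometric decay of the ranked baseline taxon
#'   abundances, p_i proportional to `taxa_decay^i` (default 0.96).
#' @param evenness_shift treatments x depths matrix of evenness
#'   "temperatures": the treatment composition is the baseline raised to
#'   `1/temperature` and renormalized, so values > 1 flatten the community
#'   (higher Simpson and Pielou). Default all 1.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         n_replicates = 3L,
                         treatments = TREATMENTS,
                         depths = DEPTHS,
                         baseline_means = NULL,
                         effect_multipliers = NULL,
                         noise_cv = 0.08,
                         sieve_composition = NULL,
                         sieve_multipliers = NULL,
                         sieve_concentration = 300,
                         total_sieve_mass_g = 50,
                         n_taxa = 200L,
                         count_depth = 20000L,
                         count_concentration = 500,
                         taxa_decay = 0.96,
                         evenness_shift = NULL) {
  vars <- c(CHEM_VARS, COPY_VARS)
  if (is.null(baseline_means)) {
    baseline_means <- matrix(1, length(vars), length(depths),
                             dimnames = list(vars, depths))
  }
  baseline_means <- as.matrix(baseline_means)
  vars <- rownames(baseline_means)
  if (is.null(effect_multipliers)) {
    effect_multipliers <- array(1, c(length(vars), length(treatments),
                                     length(depths)),
                                dimnames = list(vars, treatments, depths))
  }
  if (is.null(sieve_composition)) {
    sieve_composition <- matrix(1 / 6, length(depths), 6,
                                dimnames = list(depths, SIEVE_CLASSES$column))
  }
  if (is.null(sieve_multipliers)) {
    sieve_multipliers <- array(1, c(length(treatments), length(depths), 6),
                               dimnames = list(treatments, depths,
                                               SIEVE_CLASSES$column))
  }
  if (is.null(evenness_shift)) {
    evenness_shift <- matrix(1, length(treatments), length(depths),
                             dimnames = list(treatments, depths))
  }
  if (length(noise_cv) > 1 && is.null(names(noise_cv))) {
    stop_psq("per-variable noise_cv must be named", class = "psq_config_error")
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_replicates = as.integer(n_replicates),
    treatments = treatments, depths = depths,
    baseline_means = baseline_means,
    effect_multipliers = effect_multipliers,
    noise_cv = noise_cv,
    sieve_composition = as.matrix(sieve_composition),
    sieve_multipliers = sieve_multipliers,
    sieve_concentration = sieve_concentration,
    total_sieve_mass_g = total_sieve_mass_g,
    n_taxa = as.integer(n_taxa), count_depth = as.integer(count_depth),
    count_concentration = count_concentration,
    taxa_decay = taxa_decay,
    evenness_shift = as.matrix(evenness_shift)
  ), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  bad <- function(msg) stop_psq("invalid synthetic config: %s", msg,
                                class = "psq_config_error")
  if (any(cfg$baseline_means <= 0)) bad("baseline means must be positive")
  if (any(cfg$effect_multipliers <= 0)) bad("multipliers must be positive")
  if (any(cfg$noise_cv < 0)) bad("noise_cv must be non-negative")
  if (any(cfg$sieve_composition <= 0) || cfg$sieve_concentration <= 0 ||
      any(cfg$sieve_multipliers <= 0)) {
    bad("Dirichlet parameters must be positive")
  }
  if (any(abs(rowSums(cfg$sieve_composition) - 1) > 1e-8)) {
    bad("sieve composition rows must sum to 1")
  }
  if (cfg$total_sieve_mass_g <= 0) bad("total sieve mass must be positive")
  if (cfg$n_replicates < 1) bad("need at least one replicate")
  if (any(cfg$evenness_shift <= 0)) bad("evenness shifts must be positive")
  if (!setequal(dimnames(cfg$effect_multipliers)[[2]], cfg$treatments) ||
      !setequal(dimnames(cfg$effect_multipliers)[[3]], cfg$depths)) {
    bad("multiplier array dimnames must match treatments and depths")
  }
  cfg
}

per_var_cv <- function(cfg, var) {
  if (length(cfg$noise_cv) == 1) return(unname(cfg$noise_cv))
  unname(cfg$noise_cv[[var]] %||% stop_psq(
    "no noise_cv for variable '%s'", var, class = "psq_config_error"))
}

#' Generate a synthetic experiment dataset
#'
#' Draws the four pipeline input tables from a [synth_config()]: one row per
#' (treatment, depth, replicate) in each sample table. Chemistry and gene
#' copies are lognormal with mean = baseline x multiplier and the configured
#' CV; sieve fraction masses are Dirichlet with treatment-shifted
#' concentrations, scaled to the total sieved mass; taxon counts are
#' Dirichlet-multinomial around a treatment-specific composition. Output is
#' fully reproducible from `config$seed` (the caller's RNG state is left
#' untouched).
#'
#' @param config a [synth_config()].
#' @param tables which tables to generate (subset of `"sieve"`, `"chem"`,
#'   `"copies"`, `"counts"`); generating fewer tables does not change the
#'   draws of the ones generated.
#' @return list with the requested elements `sieve`, `chem`, `copies`
#'   (validated data.frames), `counts` (samples x taxa integer matrix), and
#'   `config`.
#' @export
generate_dataset <- function(config,
                             tables = c("sieve", "chem", "copies", "counts")) {
  stopifnot(inherits(config, "synth_config"))
  tables <- match.arg(tables, several.ok = TRUE)
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        depth = config$depths, treatment = config$treatments,
                        stringsAsFactors = FALSE)
  design <- design[c("treatment", "depth", "replicate")]
  design$sample_id <- sprintf("%s_%s_r%02d", design$treatment, design$depth,
                              design$replicate)
  design <- design[c("sample_id", "treatment", "depth", "replicate")]
  out <- list()
  # independent, order-insensitive substreams per table
  sub_seed <- function(k) as.integer((as.double(config$seed) * 11 + k) %%
                                       2147483647)
  if ("sieve" %in% tables) {
    out$sieve <- withr::with_seed(sub_seed(1L), gen_sieve(config, design))
  }
  if ("chem" %in% tables) {
    out$chem <- withr::with_seed(sub_seed(2L),
                                 gen_lognormal(config, design, CHEM_VARS))
    out$chem <- validate_table(out$chem, "chem", custom_design = TRUE)
  }
  if ("copies" %in% tables) {
    out$copies <- withr::with_seed(sub_seed(3L),
                                   gen_lognormal(config, design, COPY_VARS))
    out$copies <- validate_table(out$copies, "copies", custom_design = TRUE)
  }
  if ("counts" %in% tables) {
    out$counts <- withr::with_seed(sub_seed(4L), gen_counts(config, design))
  }
  out$config <- config
  out
}

gen_lognormal <- function(cfg, design, vars) {
  df <- design
  vars <- intersect(rownames(cfg$baseline_means), vars)
  for (v in vars) {
    mult <- cfg$effect_multipliers[v, , ]
    mu <- cfg$baseline_means[v, design$depth] *
      mult[cbind(design$treatment, design$depth)]
    df[[v]] <- rlnorm_mean(nrow(design), mu, per_var_cv(cfg, v))
  }
  df
}

gen_sieve <- function(cfg, design) {
  n <- nrow(design)
  w <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    alpha <- cfg$sieve_concentration *
      cfg$sieve_composition[design$depth[i], ] *
      cfg$sieve_multipliers[design$treatment[i], design$depth[i], ]
    w[i, ] <- if (all(cfg$noise_cv == 0)) alpha / sum(alpha)
              else rdirichlet(1, alpha)
  }
  m <- w * cfg$total_sieve_mass_g
  colnames(m) <- SIEVE_CLASSES$column
  validate_table(cbind(design, as.data.frame(m)), "sieve",
                 custom_design = TRUE)
}

gen_counts <- function(cfg, design) {
  base <- cfg$taxa_decay^seq_len(cfg$n_taxa)
  base <- base / sum(base)
  counts <- matrix(0L, nrow(design), cfg$n_taxa,
                   dimnames = list(design$sample_id,
                                   sprintf("OTU%03d", seq_len(cfg$n_taxa))))
  for (i in seq_len(nrow(design))) {
    temp <- cfg$evenness_shift[design$treatment[i], design$depth[i]]
    p <- base^(1 / temp)
    p <- p / sum(p)
    p_sample <- if (all(cfg$noise_cv == 0)) p
                else drop(rdirichlet(1, cfg$count_concentration * p))
    counts[i, ] <- stats::rmultinom(1, cfg$count_depth, p_sample)
  }
  as_count_matrix(counts)
}

#' Write a generated dataset to a directory
#'
#' Emits `sieve.csv`, `chem.csv`, `copies.csv`, `counts.tsv` plus a
#' `provenance.json` sidecar echoing the full configuration and seed.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(dataset$sieve)) {
    write_tidy_table(dataset$sieve, file.path(dir, "sieve.csv"))
  }
  if (!is.null(dataset$chem)) {
    write_tidy_table(dataset$chem, file.path(dir, "chem.csv"))
  }
  if (!is.null(dataset$copies)) {
    write_tidy_table(dataset$copies, file.path(dir, "copies.csv"))
  }
  if (!is.null(dataset$counts)) {
    write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  }
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
                       pretty = TRUE)
  invisible(dir)
}
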