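#' Default index set of the treatment-ranking matrix
#'
#' Ten soil-quality indices per depth: the five chemistry variables (pH is
#' excluded by default — it is an optimum-type index, not higher-is-better),
#' the three aggregate-stability indices, and the two gene-copy abundances.
#'
#' @return character vector of variable names.
#' @export
default_gra_variables <- function() {
  c(setdiff(CHEM_VARS, "pH"), "r025", "mwd", "gmd", COPY_VARS)
}

#' Build a treatments x indices matrix from per-sample tables
#'
#' Merges any number of per-sample tables on the design columns, averages
#' each variable within treatment x depth, and spreads depths into separate
#' columns (`<variable>_<depth>`), yielding the matrix grey relational
#' analysis ranks: one row per treatment, treatment-level means as entries.
#'
#' @param ... data.frames sharing `sample_id`, `treatment`, `depth`,
#'   `replicate`.
#' @param variables variable columns to include (default
#'   [default_gra_variables()] intersected with what is present).
#' @param treatments row order (default: order of appearance).
#' @return numeric matrix with treatment rownames.
#' @export
build_gra_matrix <- function(..., variables = NULL, treatments = NULL) {
  tabs <- lapply(list(...), as.data.frame)
  keys <- c("sample_id", "treatment", "depth", "replicate")
  merged <- Reduce(function(a, b) merge(a, b, by = keys, sort = FALSE), tabs)
  if (is.null(variables)) {
    variables <- intersect(default_gra_variables(), names(merged))
  }
  missing <- setdiff(variables, names(merged))
  if (length(missing) > 0) {
    stop_psq("index variable(s) not found: %s",
             paste(missing, collapse = ", "), class = "psq_validation_error")
  }
  treatments <- treatments %||% unique(merged$treatment)
  depths <- unique(merged$depth)
  cols <- as.vector(t(outer(variables, depths, paste, sep = "_")))
  X <- matrix(NA_real_, length(treatments), length(cols),
              dimnames = list(treatments, cols))
  for (v in variables) {
    ag <- stats::aggregate(merged[[v]],
                           by = merged[c("treatment", "depth")], FUN = mean)
    X[cbind(ag$treatment, paste(v, ag$depth, sep = "_"))] <- ag$x
  }
  if (anyNA(X)) {
    stop_psq("missing treatment x depth cells in the index matrix",
             class = "psq_validation_error")
  }
  X
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or simulation), aggregate indices, alpha diversity,
#' treatment-effect summaries, and grey relational treatment ranking, and
#' writes `aggregates.csv`, `diversity.csv`, `effects.csv`, `gra.csv`, a
#' Markdown report, a provenance `config.json`, and a run log to the output
#' directory. Report numbers are the CSV numbers — nothing is recomputed in
#' the report layer.
#'
#' @param config a list with fields:
#'   * exactly one of `inputs` (list of paths `sieve`, `chem`, `copies`,
#'     `counts`) or `simulate` (a [synth_config()], or `TRUE` for
#'     [default_calibration()] at `seed`);
#'   * `out_dir` output directory (required);
#'   * `seed` integer (default 1; forwarded to a `simulate = TRUE` block);
#'   * `control` control treatment (default `"RT"`), `alpha` (default 0.05);
#'   * `gra`: optional list with `mode`, `rho`, `orientation`, `variables`.
#' @return invisible list with all computed tables (`aggregates`,
#'   `diversity`, `effects`, `gra_matrix`, `gra`) and the artifact paths.
#' @export
run_pipeline <- function(config) {
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulate) && !identical(config$simulate, FALSE)
  if (has_inputs == has_sim) {
    stop_psq("config must contain exactly one of 'inputs' or 'simulate'",
             class = "psq_config_error")
  }
  if (is.null(config$out_dir)) {
    stop_psq("config$out_dir is required", class = "psq_config_error")
  }
  seed <- config$seed %||% 1L
  control <- config$control %||% "RT"
  alpha <- config$alpha %||% 0.05
  gra_cfg <- config$gra %||% list()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("paddysoilq %s | R %s.%s",
                         as.character(utils::packageVersion("paddysoilq")),
                         R.version$major, R.version$minor),
                 sprintf("started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("seed %d", as.integer(seed)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_psq("stage '%s' failed: %s", name, conditionMessage(e),
               class = "psq_stage_error")
    })
  }

  ds <- stage("ingest", {
    if (has_sim) {
      cfg <- if (isTRUE(config$simulate)) default_calibration(seed = seed)
             else config$simulate
      generate_dataset(cfg)
    } else {
      list(
        sieve = read_tidy_table(config$inputs$sieve, "sieve"),
        chem = read_tidy_table(config$inputs$chem, "chem"),
        copies = read_tidy_table(config$inputs$copies, "copies"),
        counts = if (!is.null(config$inputs$counts))
          read_count_table(config$inputs$counts)
      )
    }
  })

  aggr <- stage("aggregates", aggregate_indices(ds$sieve))
  divr <- if (!is.null(ds$counts)) {
    stage("diversity", diversity_indices(ds$counts))
  }

  merged <- stage("effects", {
    keys <- c("sample_id", "treatment", "depth", "replicate")
    m <- merge(as.data.frame(ds$chem), as.data.frame(ds$copies), by = keys,
               sort = FALSE)
    m <- merge(m, aggr[c(keys, "r025", "mwd", "gmd")], by = keys, sort = FALSE)
    if (!is.null(divr)) {
      m <- merge(m, divr[c("sample_id", "simpson", "pielou")],
                 by = "sample_id", sort = FALSE)
    }
    m
  })
  eff <- stage("effects", effect_summary(merged, control = control,
                                         alpha = alpha))

  X <- stage("gra", build_gra_matrix(merged,
                                     variables = gra_cfg$variables %||% NULL))
  gres <- stage("gra", gra(X,
                           mode = gra_cfg$mode %||% "deng_standard",
                           orientation = gra_cfg$orientation %||% "benefit",
                           rho = gra_cfg$rho %||% 0.5))

  paths <- list(
    aggregates = file.path(config$out_dir, "aggregates.csv"),
    diversity = file.path(config$out_dir, "diversity.csv"),
    effects = file.path(config$out_dir, "effects.csv"),
    gra = file.path(config$out_dir, "gra.csv"),
    report = file.path(config$out_dir, "report.md"),
    config = file.path(config$out_dir, "config.json"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  write_csv_plain <- function(df, path) {
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  write_csv_plain(aggr, paths$aggregates)
  if (!is.null(divr)) write_csv_plain(divr, paths$diversity)
  write_csv_plain(eff, paths$effects)
  write_csv_plain(gres$ranking, paths$gra)
  echo <- config
  echo$out_dir <- NULL # echo the analysis settings, not the destination
  if (has_sim && !isTRUE(config$simulate)) echo$simulate <- unclass(ds$config)
  jsonlite::write_json(echo, paths$config, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE, force = TRUE)
  write_report(paths$report, aggr, divr, eff, gres, control)
  log_lines <- c(log_lines,
                 sprintf("config md5 %s", unname(tools::md5sum(paths$config))),
                 sprintf("finished %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, paths$log)
  invisible(list(aggregates = aggr, diversity = divr, effects = eff,
                 gra_matrix = X, gra = gres, paths = paths))
}

md_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  c(header, sep, rows)
}

write_report <- function(path, aggr, divr, eff, gres, control) {
  lines <- c("# Soil quality pipeline report", "")
  lines <- c(lines, "## Aggregate stability indices (treatment means)", "")
  am <- stats::aggregate(aggr[c("r025", "mwd", "gmd")],
                         by = aggr[c("treatment", "depth")], FUN = mean)
  lines <- c(lines, md_table(am), "")
  if (!is.null(divr)) {
    lines <- c(lines, "## Alpha diversity (per-sample means)", "",
               sprintf("Mean Simpson %.4f, mean Pielou %.4f over %d samples.",
                       mean(divr$simpson), mean(divr$pielou, na.rm = TRUE),
                       nrow(divr)), "")
  }
  lines <- c(lines,
             sprintf("## Treatment effects (%% change vs %s, Tukey letters)",
                     control), "")
  lines <- c(lines, md_table(eff[c("variable", "depth", "treatment", "mean",
                                   "percent_change", "letter")]), "")
  lines <- c(lines, "## Grey relational ranking", "")
  rk <- gres$ranking[order(gres$ranking$rank), ]
  lines <- c(lines, md_table(rk), "",
             sprintf("Overall ranking: %s.",
                     paste(rk$treatment, collapse = " > ")))
  writeLines(lines, path)
  invisible(path)
}
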