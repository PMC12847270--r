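#' Table schemas used by the pipeline
#'
#' Three tidy sample tables share the design columns `sample_id`,
#' `treatment`, `depth`, `replicate`:
#'
#' * `"sieve"` — wet-sieve fraction masses (g) in six descending size
#'   classes: `class_gt2` (>2 mm), `class_1_2`, `class_05_1`,
#'   `class_025_05`, `class_0053_025`, `class_lt0053` (<0.053 mm).
#' * `"chem"` — soil chemistry: `SOM`, `TN`, `TP`, `AN`, `AP`
#'   (non-negative, units carried as metadata) and `pH` in \[0, 14\].
#' * `"copies"` — qPCR gene copies per g soil: `bacterial_copies`,
#'   `fungal_copies` (strictly positive).
#'
#' @param schema one of `"sieve"`, `"chem"`, `"copies"`.
#' @return character vector of required column names, in order.
#' @export
schema_columns <- function(schema = c("sieve", "chem", "copies")) {
  schema <- match.arg(schema)
  base <- c("sample_id", "treatment", "depth", "replicate")
  c(base, switch(schema,
    sieve = SIEVE_CLASSES$column,
    chem = CHEM_VARS,
    copies = COPY_VARS
  ))
}

# Columns (beyond the design columns) that must parse as numeric.
schema_numeric_columns <- function(schema) {
  setdiff(schema_columns(schema), c("sample_id", "treatment", "depth"))
}

#' Validate a tidy sample table against its schema
#'
#' Checks column presence, numeric parsing, design-key uniqueness, and the
#' per-schema value invariants (non-negative masses, pH in \[0, 14\],
#' positive copy numbers, ...). Rows are never dropped: any violation is an
#' error naming the offending column or `sample_id`.
#'
#' @param df a data.frame.
#' @param schema table kind, see [schema_columns()].
#' @param custom_design if `TRUE`, treatment/depth labels outside the
#'   default design (`RT,IRT,I70,IS,IO` x `D0_20,D20_40`) are allowed.
#' @return `df`, invisibly classed as `psq_<schema>` with the schema stored
#'   in the `"psq_schema"` attribute. Extra columns are preserved untouched.
#' @export
validate_table <- function(df, schema = c("sieve", "chem", "copies"),
                           custom_design = FALSE) {
  schema <- match.arg(schema)
  required <- schema_columns(schema)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_psq("missing required column(s) for schema '%s': %s",
             schema, paste(missing, collapse = ", "),
             class = "psq_schema_error")
  }
  for (col in schema_numeric_columns(schema)) {
    v <- df[[col]]
    if (is.character(v) || is.factor(v)) {
      parsed <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad) > 0) {
        stop_psq("non-numeric value in column '%s' at row %d", col, bad[1],
                 class = "psq_parse_error")
      }
      df[[col]] <- parsed
    }
    if (!is.numeric(df[[col]])) {
      stop_psq("column '%s' is not numeric", col, class = "psq_parse_error")
    }
  }
  if (anyDuplicated(df[c("treatment", "depth", "replicate")])) {
    dup <- df[duplicated(df[c("treatment", "depth", "replicate")]), ]
    stop_psq("duplicate (treatment, depth, replicate) for sample '%s'",
             dup$sample_id[1], class = "psq_validation_error")
  }
  if (!custom_design) {
    bad_t <- setdiff(unique(df$treatment), TREATMENTS)
    bad_d <- setdiff(unique(df$depth), DEPTHS)
    if (length(bad_t) > 0 || length(bad_d) > 0) {
      stop_psq("unknown %s label(s): %s (use custom_design = TRUE to allow)",
               if (length(bad_t) > 0) "treatment" else "depth",
               paste(c(bad_t, bad_d), collapse = ", "),
               class = "psq_validation_error")
    }
  }
  check <- function(ok, what) {
    if (!all(ok)) {
      stop_psq("%s for sample '%s'", what, df$sample_id[which(!ok)[1]],
               class = "psq_validation_error")
    }
  }
  if (schema == "sieve") {
    m <- as.matrix(df[SIEVE_CLASSES$column])
    check(apply(m >= 0, 1, all), "negative sieve fraction mass")
  } else if (schema == "chem") {
    check(apply(as.matrix(df[setdiff(CHEM_VARS, "pH")]) >= 0, 1, all),
          "negative concentration")
    check(df$pH >= 0 & df$pH <= 14, "pH outside [0, 14]")
  } else {
    check(apply(as.matrix(df[COPY_VARS]) > 0, 1, all),
          "non-positive gene copy number")
  }
  check(df$replicate >= 1 & df$replicate == round(df$replicate),
        "replicate is not a positive integer")
  class(df) <- c(paste0("psq_", schema), "data.frame")
  attr(df, "psq_schema") <- schema
  invisible(df)
}

#' Read a tidy sample table
#'
#' Reads a UTF-8 delimited file (comma by default, tab via `sep = "\t"`)
#' with one header row and `.` decimal separator, then validates it with
#' [validate_table()]. Row order is preserved; unknown extra columns pass
#' through untouched.
#'
#' @inheritParams validate_table
#' @param path file path.
#' @param sep field separator, `","` or `"\t"`.
#' @return validated data.frame (see [validate_table()]).
#' @export
read_tidy_table <- function(path, schema = c("sieve", "chem", "copies"),
                            sep = ",", custom_design = FALSE) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    stop_psq("file not found: %s", path, class = "psq_io_error")
  }
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  out <- validate_table(df, schema, custom_design = custom_design)
  out
}

#' Write a tidy sample table
#'
#' Inverse of [read_tidy_table()]: read -> write -> read is the identity up
#' to floating-point formatting (15 significant digits are written).
#'
#' @param df a (validated) sample table.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_tidy_table <- function(df, path, sep = ",") {
  out <- as.data.frame(df)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a dense taxon count table
#'
#' Reads a tab-separated dense matrix with taxa as rows (first column
#' `taxon_id`, remaining columns one per sample) or the transposed layout,
#' and normalizes the orientation to samples x taxa. Counts must be
#' non-negative integers.
#'
#' @param path file path to a TSV matrix.
#' @param orientation `"taxa_rows"` (default, the common OTU-table layout)
#'   or `"samples_rows"`.
#' @return an integer matrix, samples as rows, taxa as columns, both
#'   dimensions named.
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop_psq("file not found: %s", path, class = "psq_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop_psq("empty count matrix: %s", path, class = "psq_validation_error")
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "taxa_rows") m <- t(m)
  as_count_matrix(m)
}

# Shared count-matrix validation: integer-valued, non-negative, unique ids,
# every sample has at least one positive count.
as_count_matrix <- function(m) {
  if (any(is.na(m))) {
    stop_psq("count matrix contains missing values", class = "psq_parse_error")
  }
  if (any(m < 0)) {
    stop_psq("count matrix contains negative values",
             class = "psq_validation_error")
  }
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop_psq("non-integer count %g at sample '%s', taxon '%s'",
             m[bad[1], bad[2]], rownames(m)[bad[1]], colnames(m)[bad[2]],
             class = "psq_validation_error")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop_psq("duplicate sample or taxon ids in count matrix",
             class = "psq_validation_error")
  }
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop_psq("sample '%s' has no positive counts", rownames(m)[zero][1],
             class = "psq_validation_error")
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a taxon count table
#'
#' Writes the samples x taxa matrix in the taxa-as-rows dense TSV layout
#' read back by [read_count_table()].
#'
#' @param counts integer matrix, samples x taxa.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(taxon_id = colnames(counts), t(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
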