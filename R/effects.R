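#' Percent change of a treatment mean versus the control mean
#'
#' 100 * (treatment_mean - control_mean) / control_mean, the convention used
#' to report fertilization effects relative to the control regime.
#'
#' @param treatment_mean,control_mean numeric (vectorized over
#'   `treatment_mean`).
#' @return percent.
#' @export
percent_change <- function(treatment_mean, control_mean) {
  if (any(control_mean == 0)) {
    stop_psq("control mean is zero; percent change undefined",
             class = "psq_domain_error")
  }
  100 * (treatment_mean - control_mean) / control_mean
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA of `values ~ group`, runs Tukey's HSD on all
#' pairwise contrasts, and assigns lowercase letter groups so that two
#' groups share a letter if and only if their Tukey-adjusted p-value is
#' >= `alpha`. Letters are ordered by decreasing group mean ("a" contains
#' the largest mean), the convention used above bar charts in field studies.
#'
#' @param values numeric response.
#' @param group group labels (same length as `values`).
#' @param alpha significance level (default 0.05).
#' @return list with `anova_p`, `f`, `tukey` (the pairwise table), `means`,
#'   and `letters` (named character vector).
#' @export
anova_tukey <- function(values, group, alpha = 0.05) {
  group <- as.character(group)
  n <- table(group)
  if (length(n) < 2) {
    stop_psq("need at least two groups", class = "psq_validation_error")
  }
  if (any(n < 2)) {
    stop_psq("group '%s' has fewer than 2 observations",
             names(n)[n < 2][1], class = "psq_validation_error")
  }
  d <- data.frame(y = values, g = factor(group, levels = unique(group)))
  fit <- stats::aov(y ~ g, data = d)
  av <- summary(fit)[[1]]
  tk <- suppressWarnings(stats::TukeyHSD(fit))$g
  means <- tapply(d$y, d$g, mean)
  # zero residual variance: identical means are indistinguishable (p = 1),
  # distinct means are perfectly separated (p = 0)
  if (!is.na(av[["Mean Sq"]][2]) && av[["Mean Sq"]][2] == 0) {
    tk[, "p adj"] <- ifelse(abs(tk[, "diff"]) < 1e-12, 1, 0)
    av[["Pr(>F)"]][1] <- if (all(abs(tk[, "diff"]) < 1e-12)) 1 else 0
  }
  # pairwise adjusted p-values as a symmetric matrix
  lv <- levels(d$g)
  p <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    p[a, b] <- p[b, a] <- tk[i, "p adj"]
  }
  list(
    anova_p = av[["Pr(>F)"]][1],
    f = av[["F value"]][1],
    tukey = tk,
    means = means,
    letters = compact_letters(p, means, alpha = alpha)
  )
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Enumerates the maximal cliques of the "not significantly different"
#' graph (p >= alpha) and labels them a, b, c, ... in order of the largest
#' group mean they contain; each group receives the sorted letters of the
#' cliques it belongs to. Two groups share a letter iff they are not
#' significantly different.
#'
#' @param p symmetric matrix of pairwise p-values with group names on both
#'   dimensions.
#' @param means named group means (orders the letters).
#' @param alpha significance level.
#' @return named character vector of letter groups.
#' @export
compact_letters <- function(p, means, alpha = 0.05) {
  groups <- rownames(p)
  stopifnot(!is.null(groups), all(groups %in% names(means)))
  k <- length(groups)
  if (k > 15) {
    stop_psq("compact letter display supports at most 15 groups",
             class = "psq_shape_error")
  }
  adj <- p >= alpha
  diag(adj) <- TRUE
  # exhaustive maximal-clique enumeration; k is small (5 in the field design)
  subsets <- lapply(seq_len(2^k - 1), function(code) which(bitwAnd(
    code, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) all(adj[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(other)
      length(other) > length(cliques[[i]]) && all(cliques[[i]] %in% other),
      logical(1)))
  }, logical(1))
  cliques <- cliques[maximal]
  best <- vapply(cliques, function(s) max(means[groups[s]]), numeric(1))
  cliques <- cliques[order(-best)]
  out <- stats::setNames(rep("", k), groups)
  for (i in seq_along(cliques)) {
    members <- groups[cliques[[i]]]
    out[members] <- paste0(out[members], letters[i])
  }
  vapply(out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""),
         character(1))
}

#' Treatment-effect summary per variable and depth
#'
#' For every requested variable within every depth layer: per-treatment n,
#' mean and sd, percent change versus the control treatment, one-way ANOVA
#' p-value, and Tukey compact letter groups. This is the tabular analogue of
#' the "x% higher than control, letter a/b/c" statements of field-study
#' results sections.
#'
#' @param data data.frame with `treatment`, `depth`, `replicate` and the
#'   variable columns (e.g. a chem table, a copies table, or the output of
#'   [aggregate_indices()] merged with a design).
#' @param variables character vector of variable column names; default all
#'   numeric columns other than the design columns.
#' @param control control treatment label (default `"RT"`).
#' @param alpha significance level for the letter display.
#' @return data.frame with one row per variable x depth x treatment.
#' @export
effect_summary <- function(data, variables = NULL, control = "RT",
                           alpha = 0.05) {
  data <- as.data.frame(data)
  if (is.null(variables)) {
    design <- c("sample_id", "treatment", "depth", "replicate")
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
    variables <- setdiff(variables, design)
  }
  if (!control %in% data$treatment) {
    stop_psq("control treatment '%s' not present in data", control,
             class = "psq_validation_error")
  }
  res <- list()
  for (depth in unique(data$depth)) {
    sub <- data[data$depth == depth, , drop = FALSE]
    for (v in variables) {
      at <- anova_tukey(sub[[v]], sub$treatment, alpha = alpha)
      trt <- names(at$means)
      res[[length(res) + 1]] <- data.frame(
        variable = v, depth = depth, treatment = trt,
        n = as.vector(table(sub$treatment)[trt]),
        mean = as.vector(at$means),
        sd = as.vector(tapply(sub[[v]], sub$treatment, stats::sd)[trt]),
        percent_change = percent_change(as.vector(at$means),
                                        at$means[[control]]),
        anova_p = at$anova_p,
        letter = as.vector(at$letters[trt]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson r and two-sided p for every pair of numeric variables, pairwise
#' complete observations. Constant variables get `NA` correlations (flagged
#' with a warning), never an error.
#'
#' @param data data.frame of numeric variables (non-numeric columns are
#'   dropped).
#' @return list with matrices `r`, `p`, `n` (pairwise complete counts).
#' @export
correlation_matrix <- function(data) {
  data <- as.data.frame(data)
  data <- data[vapply(data, is.numeric, logical(1))]
  vars <- names(data)
  k <- length(vars)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 0
  diag(n) <- colSums(!is.na(data))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(data[[i]], data[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3) next
      x <- data[[i]][ok]; y <- data[[j]][ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning(sprintf("constant variable in pair (%s, %s); r undefined",
                        vars[i], vars[j]), call. = FALSE)
        next
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, n = n)
}
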