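#' Simpson diversity of one sample
#'
#' Default variant is the Gini–Simpson index 1 - sum(p_i^2), the probability
#' that two reads drawn at random belong to different taxa (the common
#' amplicon-pipeline default). `"dominance"` returns sum(p_i^2) and
#' `"inverse"` returns 1/sum(p_i^2).
#'
#' @param counts non-negative count vector for one sample.
#' @param variant `"gini"` (default), `"dominance"` or `"inverse"`.
#' @return a single number.
#' @export
simpson <- function(counts, variant = c("gini", "dominance", "inverse")) {
  variant <- match.arg(variant)
  p <- count_props(counts)
  d <- sum(p^2)
  switch(variant, gini = 1 - d, dominance = d, inverse = 1 / d)
}

#' Shannon entropy of one sample (nats)
#'
#' H = -sum(p_i log p_i) over taxa with positive counts, natural log.
#'
#' @inheritParams simpson
#' @export
shannon <- function(counts) {
  p <- count_props(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pielou evenness of one sample
#'
#' J = H / ln(S) with H the Shannon entropy (natural log) and S the observed
#' richness (taxa with positive count). Undefined for S = 1 and returned as
#' `NA` there (a one-taxon sample has no evenness, not zero evenness).
#'
#' @inheritParams simpson
#' @export
pielou <- function(counts) {
  s <- richness(counts)
  if (s < 2) return(NA_real_)
  shannon(counts) / log(s)
}

#' Observed richness of one sample
#' @inheritParams simpson
#' @export
richness <- function(counts) {
  count_props(counts) # validates
  sum(counts > 0)
}

count_props <- function(counts) {
  if (any(counts < 0)) {
    stop_psq("negative counts", class = "psq_validation_error")
  }
  total <- sum(counts)
  if (total <= 0) {
    stop_psq("all-zero count vector", class = "psq_degenerate_error")
  }
  counts / total
}

#' Alpha-diversity indices per sample
#'
#' Richness, Shannon (nats), Simpson and Pielou evenness for every row of a
#' samples x taxa count matrix. Indices are computed on raw counts by
#' default; `rarefy_depth` subsamples every sample to a fixed depth first
#' (without replacement, seeded), dropping samples shallower than the depth.
#'
#' @param counts integer matrix, samples x taxa (see [read_count_table()]).
#' @param variant Simpson variant, see [simpson()].
#' @param rarefy_depth optional fixed subsampling depth.
#' @param seed RNG seed used only when `rarefy_depth` is given.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson`, `pielou` (NA where undefined).
#' @export
diversity_indices <- function(counts, variant = "gini", rarefy_depth = NULL,
                              seed = 1L) {
  counts <- as_count_matrix(as.matrix(counts))
  if (!is.null(rarefy_depth)) {
    keep <- rowSums(counts) >= rarefy_depth
    counts <- counts[keep, , drop = FALSE]
    counts <- withr::with_seed(seed, t(apply(counts, 1, rarefy_one,
                                             depth = rarefy_depth)))
  }
  data.frame(
    sample_id = rownames(counts),
    richness = apply(counts, 1, richness),
    shannon = apply(counts, 1, shannon),
    simpson = apply(counts, 1, simpson, variant = variant),
    pielou = apply(counts, 1, pielou),
    stringsAsFactors = FALSE
  )
}

# Subsample one count vector to `depth` reads without replacement.
rarefy_one <- function(counts, depth) {
  reads <- rep.int(seq_along(counts), counts)
  tabulate(sample(reads, depth), nbins = length(counts))
}
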