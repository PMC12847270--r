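#' Construct a grey-system evaluation matrix
#'
#' Bundles a positive treatments x indices matrix with the settings grey
#' relational analysis needs: per-index orientation (benefit = higher is
#' better, cost = lower is better), the resolution coefficient rho, and the
#' reference constant `a_ref` used by the literal coefficient formula.
#'
#' @param X numeric matrix (or data.frame), rows = treatments (rownames
#'   required), columns = evaluation indices. All entries must be > 0 so the
#'   mean normalization is well defined.
#' @param orientation `"benefit"` or `"cost"`, length 1 or one per column.
#' @param rho resolution coefficient in (0, 1], conventionally 0.5.
#' @param a_ref reference constant of the literal coefficient formula,
#'   conventionally 0.
#' @return object of class `grey_matrix`.
#' @export
grey_matrix <- function(X, orientation = "benefit", rho = 0.5, a_ref = 0) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) {
    stop_psq("grey matrix needs treatment rownames", class = "psq_shape_error")
  }
  if (nrow(X) < 2 || ncol(X) < 1) {
    stop_psq("grey matrix needs >= 2 treatments and >= 1 index",
             class = "psq_shape_error")
  }
  if (any(X <= 0)) {
    stop_psq("grey matrix entries must be positive for mean normalization",
             class = "psq_validation_error")
  }
  if (!(rho > 0 && rho <= 1)) {
    stop_psq("rho must lie in (0, 1]", class = "psq_validation_error")
  }
  orientation <- rep(match.arg(orientation, c("benefit", "cost"),
                               several.ok = TRUE), length.out = ncol(X))
  structure(list(X = X, orientation = orientation, rho = rho, a_ref = a_ref),
            class = "grey_matrix")
}

#' Mean normalization of the raw index matrix
#'
#' Divides every column by its own mean, removing scale and units: each
#' normalized column has mean exactly 1.
#'
#' @param X positive numeric matrix.
#' @return matrix of the same shape.
#' @export
normalize_by_mean <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  if (any(mu <= 0)) {
    bad <- colnames(X)[mu <= 0] %||% which(mu <= 0)
    stop_psq("non-positive column mean for index '%s'", bad[1],
             class = "psq_validation_error")
  }
  sweep(X, 2, mu, "/")
}

#' Min-max rescaling of one normalized column
#'
#' omega_i = (y_max - y_i) / (y_max - y_min): the per-index best value
#' (after orientation) maps to 0 and the worst to 1. Cost-type indices are
#' flipped first so that small raw values count as good.
#'
#' @param y numeric column (mean-normalized values).
#' @param orientation `"benefit"` or `"cost"`.
#' @return vector in \[0, 1\] with min 0 and max 1.
#' @export
rescale_minmax <- function(y, orientation = "benefit") {
  orientation <- match.arg(orientation, c("benefit", "cost"))
  rng <- range(y)
  if (rng[1] == rng[2]) {
    stop_psq("constant index column carries no information",
             class = "psq_degenerate_error")
  }
  w <- (rng[2] - y) / (rng[2] - rng[1])
  if (orientation == "cost") 1 - w else w
}

#' Grey relational coefficients of one column
#'
#' Two constructions are available:
#'
#' * `"paper_literal"` evaluates the printed closed form verbatim on the
#'   supplied column `v`: eps_i = (|a - v_min| + rho |a - v_max|) /
#'   (|a - v_i| + rho |a - v_max|), with the i-th entry read as the
#'   comparison value. With a = 0 on a min-max rescaled column this gives 1
#'   to the best treatment and < 1 to the rest.
#' * `"deng_standard"` is Deng's classical coefficient: given deviations
#'   `v` = Delta_i(k) = |ref(k) - y_i(k)| from the per-index ideal, and the
#'   global extremes `dmin`/`dmax` over the whole deviation matrix,
#'   eps_i = (dmin + rho dmax) / (Delta_i + rho dmax), always in (0, 1].
#'
#' @param v numeric column: transformed values (`paper_literal`) or
#'   deviations from the reference (`deng_standard`).
#' @param rho resolution coefficient in (0, 1].
#' @param a_ref reference constant `a` (paper_literal only).
#' @param mode `"deng_standard"` or `"paper_literal"`.
#' @param dmin,dmax global deviation extremes (deng_standard only); default
#'   to the column extremes.
#' @return coefficient vector.
#' @export
grey_coefficient <- function(v, rho = 0.5, a_ref = 0,
                             mode = c("deng_standard", "paper_literal"),
                             dmin = NULL, dmax = NULL) {
  mode <- match.arg(mode)
  if (!(rho > 0 && rho <= 1)) {
    stop_psq("rho must lie in (0, 1]", class = "psq_validation_error")
  }
  if (mode == "paper_literal") {
    num <- abs(a_ref - min(v)) + rho * abs(a_ref - max(v))
    den <- abs(a_ref - v) + rho * abs(a_ref - max(v))
    if (any(den == 0)) {
      stop_psq("degenerate matrix: zero coefficient denominator",
               class = "psq_degenerate_error")
    }
    num / den
  } else {
    if (any(v < 0)) {
      stop_psq("deviations must be non-negative", class = "psq_domain_error")
    }
    dmin <- dmin %||% min(v)
    dmax <- dmax %||% max(v)
    if (dmax == 0) {
      stop_psq("degenerate matrix: all deviations zero",
               class = "psq_degenerate_error")
    }
    (dmin + rho * dmax) / (v + rho * dmax)
  }
}

#' Grey relational degree
#'
#' The unweighted mean of each treatment's relational coefficients across
#' indices.
#'
#' @param coefficients treatments x indices coefficient matrix.
#' @return named vector, one degree per treatment.
#' @export
grd <- function(coefficients) {
  coefficients <- as.matrix(coefficients)
  rowMeans(coefficients)
}

#' Rank treatments by grey relational degree
#'
#' Higher degree = better = smaller rank (rank 1 is best). Ties keep input
#' order and are flagged.
#'
#' @param grd named numeric vector of grey relational degrees.
#' @return data.frame with `treatment`, `grd`, `rank`, `tied`.
#' @export
rank_treatments <- function(grd) {
  ord <- order(-grd) # stable: ties keep input row order
  rank <- integer(length(grd))
  rank[ord] <- seq_along(grd)
  data.frame(
    treatment = names(grd) %||% as.character(seq_along(grd)),
    grd = as.vector(grd),
    rank = rank,
    tied = duplicated(grd) | duplicated(grd, fromLast = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Grey relational analysis of a treatments x indices matrix
#'
#' Runs the full chain — mean normalization, orientation handling,
#' relational coefficients, grey relational degree, ranking — in one of two
#' modes. `"deng_standard"` (default) is the classical construction:
#' deviations from the per-index ideal of the mean-normalized matrix, global
#' extremes, Deng coefficients in (0, 1]. `"paper_literal"` min-max rescales
#' each normalized column (best -> 0) and evaluates the literal closed form
#' with reference constant `a_ref`; `apply_to = "y"` skips the rescaling and
#' applies the formula to the mean-normalized values directly.
#'
#' @param X a [grey_matrix()], or a positive matrix/data.frame with
#'   treatment rownames.
#' @param mode `"deng_standard"` or `"paper_literal"`.
#' @param apply_to `"omega"` (rescaled, default) or `"y"` (mean-normalized)
#'   — paper_literal only.
#' @param ... passed to [grey_matrix()] when `X` is a plain matrix
#'   (`orientation`, `rho`, `a_ref`).
#' @return object of class `gra_result`: list with `mode`, `normalized`,
#'   `transformed`, `coefficients`, `grd`, `ranking`.
#' @export
gra <- function(X, mode = c("deng_standard", "paper_literal"),
                apply_to = c("omega", "y"), ...) {
  mode <- match.arg(mode)
  apply_to <- match.arg(apply_to)
  gm <- if (inherits(X, "grey_matrix")) X else grey_matrix(X, ...)
  y <- normalize_by_mean(gm$X)
  if (mode == "deng_standard") {
    # per-index ideal after orientation; deviations; global extremes
    ref <- vapply(seq_len(ncol(y)), function(k) {
      if (gm$orientation[k] == "benefit") max(y[, k]) else min(y[, k])
    }, numeric(1))
    delta <- abs(sweep(y, 2, ref))
    eps <- apply(delta, 2, grey_coefficient, rho = gm$rho,
                 mode = "deng_standard", dmin = min(delta), dmax = max(delta))
    transformed <- delta
  } else {
    transformed <- if (apply_to == "omega") {
      vapply(seq_len(ncol(y)), function(k)
        rescale_minmax(y[, k], gm$orientation[k]), numeric(nrow(y)))
    } else {
      y
    }
    dimnames(transformed) <- dimnames(y)
    eps <- apply(transformed, 2, grey_coefficient, rho = gm$rho,
                 a_ref = gm$a_ref, mode = "paper_literal")
  }
  dimnames(eps) <- dimnames(y)
  beta <- grd(eps)
  structure(list(mode = mode, normalized = y, transformed = transformed,
                 coefficients = eps, grd = beta,
                 ranking = rank_treatments(beta)),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat(sprintf("Grey relational analysis (%s mode, %d treatments x %d indices)\n",
              x$mode, nrow(x$coefficients), ncol(x$coefficients)))
  rk <- x$ranking[order(x$ranking$rank), ]
  cat(sprintf("Ranking: %s\n", paste(rk$treatment, collapse = " > ")))
  print(data.frame(treatment = rk$treatment, grd = round(rk$grd, 4),
                   rank = rk$rank, row.names = NULL))
  invisible(x)
}
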