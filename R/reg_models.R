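# Model family: AGL8 = c0(block) + sum_g c(g, stratum) * h(FT inputs, t).
#
# Families share one linear-in-parameters skeleton; only the regulator
# transform h and the grouping of genes into coefficient groups differ:
#   M1  one group, identity sum            M2  {FTc1} vs the other three
#   M3  one group per gene                 M4  sum of squared inputs
#   M5  exp(sum)                           M6  log(sum + eps)
#   M7  time * sum
# Knockout hypotheses H0-H5 are M1 restricted to subsets of the four genes.

.FAMILIES <- paste0("M", 1:7)
.HYPOTHESES <- paste0("H", 0:5)

.hypothesis_genes <- list(
  H0 = .FT_GENES,
  H1 = setdiff(.FT_GENES, "FTa2"),
  H2 = setdiff(.FT_GENES, "FTa1"),
  H3 = setdiff(.FT_GENES, "FTc2"),
  H4 = setdiff(.FT_GENES, "FTc1"),
  H5 = "FTc1"
)

#' Specify a regression model of AGL8 activation
#'
#' Builds a model specification from a family, an included-gene set and a
#' coefficient-sharing scheme. The intercept `c0` always takes a separate
#' value in each of the four vernalization-by-daytime blocks; the regulatory
#' coefficient(s) `c1, c2, ...` are shared across blocks, split by
#' vernalization, or split by time of day according to `c1_varies_by`.
#'
#' @param family One of `"M1"`..`"M7"`. `M2` and `M3` require all four genes.
#' @param genes Included FT-like predictors (subset of [ft_genes()]).
#' @param c1_varies_by Stratifier for the regulatory coefficients: `"none"`,
#'   `"vernalization"` (the default, retained throughout the reference
#'   analysis) or `"daytime"`.
#' @param m4_form For family `M4`: `"sum_of_squares"` (default; sum of squared
#'   inputs) or `"square_of_sum"`.
#' @param label Optional display label (e.g. a hypothesis name).
#' @return An object of class `ft_model_spec`.
#' @seealso [hypothesis_spec()] for the knockout models H0-H5.
#' @export
#' @examples
#' model_spec("M1")
#' count_parameters(model_spec("M3"))
model_spec <- function(family = "M1", genes = ft_genes(),
                       c1_varies_by = c("vernalization", "none", "daytime"),
                       m4_form = c("sum_of_squares", "square_of_sum"),
                       label = NULL) {
  family <- match.arg(family, .FAMILIES)
  c1_varies_by <- match.arg(c1_varies_by)
  m4_form <- match.arg(m4_form)
  genes <- unique(as.character(genes))
  if (length(genes) == 0 || !all(genes %in% .FT_GENES)) {
    stop("genes must be a non-empty subset of: ",
         paste(.FT_GENES, collapse = ", "))
  }
  genes <- .FT_GENES[.FT_GENES %in% genes]
  if (family %in% c("M2", "M3") && length(genes) != 4) {
    stop(family, " requires all four FT-like genes")
  }
  groups <- switch(family,
    M2 = list(FTc1 = "FTc1", FTrest = setdiff(.FT_GENES, "FTc1")),
    M3 = stats::setNames(as.list(genes), genes),
    list(FT = genes)   # M1, M4-M7: one cumulative group
  )
  structure(
    list(family = family, genes = genes, groups = groups,
         c1_varies_by = c1_varies_by, m4_form = m4_form,
         hypothesis = NULL,
         label = if (is.null(label)) family else label),
    class = "ft_model_spec"
  )
}

#' Specify a regulator-knockout hypothesis model
#'
#' The knockout models emulate loss-of-function mutants by dropping genes
#' from the cumulative regulator sum of model M1: `H0` keeps all four genes,
#' `H1`-`H4` each exclude one (`FTa2`, `FTa1`, `FTc2`, `FTc1` respectively),
#' and `H5` keeps only `FTc1`. All six have the same number of free
#' parameters.
#'
#' @param hypothesis One of `"H0"`..`"H5"`.
#' @param c1_varies_by Passed to [model_spec()].
#' @return An `ft_model_spec` with the `hypothesis` field set.
#' @export
#' @examples
#' hypothesis_spec("H4")$genes  # FTc1 excluded
hypothesis_spec <- function(hypothesis,
                            c1_varies_by = c("vernalization", "none",
                                             "daytime")) {
  hypothesis <- match.arg(hypothesis, .HYPOTHESES)
  spec <- model_spec("M1", genes = .hypothesis_genes[[hypothesis]],
                     c1_varies_by = match.arg(c1_varies_by),
                     label = hypothesis)
  spec$hypothesis <- hypothesis
  spec
}

#' @export
print.ft_model_spec <- function(x, ...) {
  cat("<ft_model_spec> ", x$label,
      if (!is.null(x$hypothesis) && x$label != x$hypothesis)
        paste0(" (", x$hypothesis, ")") else "",
      ": family ", x$family,
      ", genes {", paste(x$genes, collapse = ", "), "}",
      ", ", length(x$groups), " group(s), c1 by ", x$c1_varies_by,
      " (k = ", count_parameters(x), ")\n", sep = "")
  invisible(x)
}

.strata_of <- function(spec) {
  switch(spec$c1_varies_by,
         none = "all",
         vernalization = .VERN,
         daytime = .DAYTIME)
}

#' Number of free parameters of a model
#'
#' Four intercepts (one per condition block) plus one regulatory coefficient
#' per (gene group, sharing stratum) combination.
#'
#' @param spec An [model_spec()].
#' @return Integer parameter count `4 + n_groups * n_strata`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "ft_model_spec"))
  4L + length(spec$groups) * length(.strata_of(spec))
}

#' Names of a model's parameter vector
#'
#' Intercepts are named `c0.<block>`; regulatory coefficients
#' `c.<group>.<stratum>`.
#'
#' @param spec An [model_spec()].
#' @return Character vector of length [count_parameters()].
#' @export
param_names <- function(spec) {
  strata <- .strata_of(spec)
  c(paste0("c0.", .BLOCKS),
    as.vector(t(outer(names(spec$groups), strata,
                      function(g, s) paste("c", g, s, sep = ".")))))
}

#' Assemble a parameter vector from intercepts and coefficients
#'
#' @param spec An [model_spec()].
#' @param c0 Intercepts: length 1 (recycled) or 4, ordered as
#'   [condition_blocks()].
#' @param c1 Regulatory coefficients: a single value (recycled over all
#'   groups and strata), one value per stratum (recycled over groups), or a
#'   full `groups x strata` matrix / vector in `param_names()` order.
#' @return Named numeric vector.
#' @export
#' @examples
#' make_params(hypothesis_spec("H5"), c0 = 1, c1 = c(V = 2, N = 1))
make_params <- function(spec, c0, c1) {
  nm <- param_names(spec)
  n_c <- length(nm) - 4L
  c0 <- rep_len(as.numeric(c0), 4L)
  if (length(c1) == length(.strata_of(spec)) && n_c > length(c1)) {
    c1 <- rep(as.numeric(c1), times = length(spec$groups))
  } else {
    c1 <- rep_len(as.numeric(c1), n_c)
  }
  stats::setNames(c(c0, c1), nm)
}

.M6_EPS <- 1e-9
.M5_CLAMP <- 700

# Per-group regulator transform: npts x n_groups matrix.
.regressor_matrix <- function(spec, ft, t) {
  ft <- ft[, spec$genes, drop = FALSE]
  out <- vapply(spec$groups, function(gg) {
    s <- rowSums(ft[, gg, drop = FALSE])
    switch(spec$family,
      M1 = , M2 = , M3 = s,
      M4 = if (spec$m4_form == "sum_of_squares") {
        rowSums(ft[, gg, drop = FALSE]^2)
      } else s^2,
      M5 = exp(pmin(s, .M5_CLAMP)),
      M6 = {
        if (any(s + .M6_EPS <= 0)) {
          stop("M6 regressor: sum of FT levels + eps is not positive")
        }
        log(s + .M6_EPS)
      },
      M7 = t * s
    )
  }, numeric(nrow(ft)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL, names(spec$groups)))
  out
}

#' Evaluate the regulator transform at one point
#'
#' Returns the transformed regulator term of each coefficient group: the
#' plain group sum for M1-M3, the sum of squares for M4, `exp(sum)` for M5,
#' `log(sum + 1e-9)` for M6 and `t * sum` for M7.
#'
#' @param spec An [model_spec()].
#' @param ft_levels Named numeric vector of FT-like expression levels
#'   covering `spec$genes`.
#' @param t Time in days since the block's first sampling term (used by M7).
#' @return Named numeric vector, one entry per group.
#' @export
#' @examples
#' regressor(model_spec("M1"), c(FTc1 = 1, FTa1 = 2, FTc2 = 3, FTa2 = 4))
regressor <- function(spec, ft_levels, t = 0) {
  stopifnot(inherits(spec, "ft_model_spec"))
  if (!all(spec$genes %in% names(ft_levels))) {
    stop("ft_levels must cover: ", paste(spec$genes, collapse = ", "))
  }
  ft <- matrix(as.numeric(ft_levels[.FT_GENES[.FT_GENES %in%
                                                names(ft_levels)]]),
               nrow = 1, dimnames = list(NULL, intersect(.FT_GENES,
                                                         names(ft_levels))))
  miss <- setdiff(.FT_GENES, colnames(ft))
  if (length(miss) > 0) {
    ft <- cbind(ft, matrix(0, 1, length(miss), dimnames = list(NULL, miss)))
  }
  drop(.regressor_matrix(spec, ft, t))
}

#' Predict AGL8 expression at one point
#'
#' `c0[block] + sum over groups of c[group, stratum(block)] * regressor`,
#' with the stratum chosen by the model's sharing scheme.
#'
#' @param spec An [model_spec()].
#' @param params Named parameter vector (see [make_params()]).
#' @param block Block label from [condition_blocks()], or a vernalization /
#'   daytime pair like `"V.morning"`.
#' @param ft_levels Named FT-like expression levels.
#' @param t Time in days (used by M7).
#' @return Predicted AGL8 level (numeric scalar).
#' @export
#' @examples
#' sp <- hypothesis_spec("H5")
#' p <- make_params(sp, c0 = 1, c1 = 2)
#' predict_agl8(sp, p, "V.morning", c(FTc1 = 3))
predict_agl8 <- function(spec, params, block, ft_levels, t = 0) {
  block <- match.arg(block, .BLOCKS)
  g <- regressor(spec, ft_levels, t)
  strata <- .strata_of(spec)
  stratum <- switch(spec$c1_varies_by,
                    none = "all",
                    vernalization = sub("\\..*$", "", block),
                    daytime = sub("^.*\\.", "", block))
  cs <- params[paste("c", names(spec$groups), stratum, sep = ".")]
  unname(params[paste0("c0.", block)] + sum(cs * g))
}

# Fitting skeleton shared by cost/oracle/optimizer: response, weights and the
# fixed design pieces that do not depend on the replicate draw.
.frame_skeleton <- function(points, sd_target, c1_varies_by, sd_floor) {
  blk <- points$block
  s2 <- tapply(pmax(sd_target, sd_floor)^2, blk, sum)
  if (any(s2 <= 0)) {
    stop("block(s) with zero total AGL8 variance: ",
         paste(names(s2)[s2 <= 0], collapse = ", "))
  }
  B <- vapply(.BLOCKS, function(b) as.numeric(blk == b),
              numeric(length(blk)))
  colnames(B) <- paste0("c0.", .BLOCKS)
  masks <- switch(c1_varies_by,
    none = matrix(1, length(blk), 1, dimnames = list(NULL, "all")),
    vernalization = vapply(.VERN, function(v)
      as.numeric(points$vernalization == v), numeric(length(blk))),
    daytime = vapply(.DAYTIME, function(dt)
      as.numeric(points$daytime == dt), numeric(length(blk)))
  )
  # first-term-relative time axis within each block (M7)
  t0 <- tapply(points$time_days, blk, min)
  list(B = B, masks = masks, w = 1 / as.numeric(s2[blk]),
       t = points$time_days - as.numeric(t0[blk]))
}

.design_from_skeleton <- function(spec, skel, ft) {
  G <- .regressor_matrix(spec, ft, skel$t)
  strata <- colnames(skel$masks)
  cols <- lapply(seq_along(spec$groups), function(j) {
    m <- skel$masks * G[, j]
    colnames(m) <- paste("c", names(spec$groups)[j], strata, sep = ".")
    m
  })
  X <- do.call(cbind, c(list(skel$B), cols))
  # param_names order: all groups x strata grouped by group
  X[, param_names(spec), drop = FALSE]
}

# Full model frame for a dataset-like object (means act as the values).
.model_frame <- function(spec, data, sd_floor = 1e-6) {
  stopifnot(inherits(data, "ft_dataset"))
  mats <- .as_matrices(data)
  skel <- .frame_skeleton(mats$points, mats$sd[, .TARGET],
                          spec$c1_varies_by, sd_floor)
  list(X = .design_from_skeleton(spec, skel, mats$mean[, .FT_GENES,
                                                       drop = FALSE]),
       y = mats$mean[, .TARGET], w = skel$w, block = mats$points$block)
}

#' Block-weighted cost of a model on a dataset
#'
#' The fit criterion: the sum over the four vernalization-by-daytime blocks
#' of the block's residual sum of squares divided by the block's *total* AGL8
#' variance,
#' `F = sum_b [ sum_i (AGL8_data - AGL8_model)^2 / sum_i sigma^2 ]`.
#' The denominator is the summed variance of the whole block, not a per-point
#' weight. Points with zero s.d. contribute `sd_floor^2` to the denominator
#' only.
#'
#' @param spec An [model_spec()].
#' @param params Named parameter vector in `param_names(spec)` order.
#' @param data An [ft_dataset()] (observed or dense) or a replicate from
#'   [replicate_dataset()].
#' @param sd_floor Floor applied to AGL8 s.d. inside the denominator
#'   (default `1e-6`).
#' @return The cost `F` (non-negative scalar).
#' @export
cost <- function(spec, params, data, sd_floor = 1e-6) {
  fr <- .model_frame(spec, data, sd_floor)
  params <- params[colnames(fr$X)]
  if (any(is.na(params))) stop("params do not match param_names(spec)")
  sum(fr$w * (fr$y - drop(fr$X %*% params))^2)
}
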