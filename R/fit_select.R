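# Parameter estimation, ensemble summaries, AICc comparison, knockout
# hypothesis tests and block-level defect diagnostics.
#
# Every model family is linear in its parameters (the nonlinearity sits in
# the regressor transform), so the block-weighted cost is a quadratic form
# with a closed-form minimizer. That minimizer doubles as an independent
# oracle and as the default starting point for the Nelder-Mead polish.

# Weighted least squares on pre-scaled (sqrt-weight) design/response.
# Falls back to the SVD pseudo-inverse on rank deficiency.
.wls_solve <- function(Xw, yw) {
  qr_x <- qr(Xw)
  rank_deficient <- qr_x$rank < ncol(Xw)
  if (!rank_deficient) {
    beta <- qr.coef(qr_x, yw)
  } else {
    sv <- svd(Xw)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], yw)) / sv$d[pos])
    beta <- stats::setNames(drop(beta), colnames(Xw))
  }
  list(params = beta, F_min = sum((yw - drop(Xw %*% beta))^2),
       rank_deficient = rank_deficient)
}

#' Exact weighted-least-squares minimizer of the cost
#'
#' Because every model family is linear in its parameters, the block-weighted
#' cost is quadratic and its global minimum is available in closed form from
#' the normal equations with per-point weights `1 / sum(sigma^2)` of the
#' point's block. This serves as an independent oracle for the Nelder-Mead
#' optimizer and as its default initializer.
#'
#' @inheritParams cost
#' @param data An [ft_dataset()] or a [replicate_dataset()].
#' @return A list with `params` (named vector), `F_min`, and
#'   `rank_deficient` (`TRUE` if the design was singular and the
#'   pseudo-inverse solution was returned).
#' @export
wls_oracle <- function(spec, data, sd_floor = 1e-6) {
  fr <- .model_frame(spec, data, sd_floor)
  sqw <- sqrt(fr$w)
  .wls_solve(fr$X * sqw, fr$y * sqw)
}

.default_optim_cfg <- list(reltol = 1e-8, maxit = NULL,
                           n_restarts = 0, restart_range = 10)

#' Fit one model to one dataset by Nelder-Mead minimization
#'
#' Minimizes the block-weighted cost with the Nelder-Mead simplex method.
#' With `init = "auto"` the search starts at the closed-form
#' weighted-least-squares solution, so the returned minimum matches the
#' global quadratic minimum to numerical tolerance; optional random restarts
#' (uniform in `[-restart_range, restart_range]` per coordinate) probe
#' robustness.
#'
#' @inheritParams wls_oracle
#' @param init `"auto"` (weighted-least-squares start) or a named numeric
#'   parameter vector.
#' @param optimizer_cfg List overriding any of `reltol` (default `1e-8`),
#'   `maxit` (default `1e4 * k`), `n_restarts` (default 0), `restart_range`.
#' @param seed Seed used only when `n_restarts > 0`.
#' @return A list with `params`, `F_min`, and `converged`.
#' @export
fit_one <- function(spec, data, init = "auto", optimizer_cfg = list(),
                    sd_floor = 1e-6, seed = 1) {
  cfg <- utils::modifyList(.default_optim_cfg, optimizer_cfg)
  fr <- .model_frame(spec, data, sd_floor)
  sqw <- sqrt(fr$w)
  Xw <- fr$X * sqw
  yw <- fr$y * sqw
  k <- ncol(Xw)
  if (identical(init, "auto")) {
    start <- .wls_solve(Xw, yw)$params
  } else {
    start <- init[colnames(Xw)]
    if (any(is.na(start))) stop("init does not match param_names(spec)")
  }
  maxit <- if (is.null(cfg$maxit)) 1e4 * k else cfg$maxit
  fn <- function(b) sum((yw - drop(Xw %*% b))^2)
  opt <- stats::optim(start, fn, method = "Nelder-Mead",
                      control = list(reltol = cfg$reltol, maxit = maxit))
  best <- opt
  if (cfg$n_restarts > 0) {
    set.seed(as.integer(seed))
    for (i in seq_len(cfg$n_restarts)) {
      alt <- stats::optim(
        stats::runif(k, -cfg$restart_range, cfg$restart_range), fn,
        method = "Nelder-Mead",
        control = list(reltol = cfg$reltol, maxit = maxit))
      if (alt$value < best$value) best <- alt
    }
  }
  list(params = stats::setNames(best$par, colnames(Xw)),
       F_min = best$value, converged = best$convergence == 0L)
}

#' Fit a model across a resampled ensemble
#'
#' Runs one minimization per replicate and summarizes the ensemble of
#' minimizers: per-parameter mean and s.d. plus the distribution of minimal
#' cost values. With `optimizer = "nelder-mead"` (default) each replicate's
#' weighted-least-squares solution is polished by the simplex method; with
#' `optimizer = "wls"` the closed-form solution is used directly (they agree
#' to `1e-6` relative, which large simulation studies exploit).
#'
#' @param spec An [model_spec()].
#' @param resamples An [resample()] ensemble.
#' @param optimizer `"nelder-mead"` or `"wls"`.
#' @param optimizer_cfg Passed to the Nelder-Mead polish, see [fit_one()].
#' @param sd_floor Floor for AGL8 s.d. in cost denominators.
#' @return An object of class `ft_fit`: the spec, an `n x k` matrix of
#'   per-replicate parameters, the `F_min` vector, convergence flags, the
#'   number of data points `m`, and a summary table.
#' @export
#' @examples
#' rs <- resample(interpolate(generate_dataset(make_scenario("Ku_like_SD"))),
#'                n_samples = 20, seed = 1)
#' fit <- fit_ensemble(hypothesis_spec("H0"), rs)
#' fit$summary
fit_ensemble <- function(spec, resamples,
                         optimizer = c("nelder-mead", "wls"),
                         optimizer_cfg = list(), sd_floor = 1e-6) {
  stopifnot(inherits(spec, "ft_model_spec"),
            inherits(resamples, "ft_resamples"))
  optimizer <- match.arg(optimizer)
  cfg <- utils::modifyList(.default_optim_cfg, optimizer_cfg)
  skel <- .frame_skeleton(resamples$points, resamples$sd[, .TARGET],
                          spec$c1_varies_by, sd_floor)
  sqw <- sqrt(skel$w)
  n <- resamples$n_samples
  k <- count_parameters(spec)
  params <- matrix(NA_real_, n, k, dimnames = list(NULL, param_names(spec)))
  F_min <- numeric(n)
  converged <- logical(n)
  maxit <- if (is.null(cfg$maxit)) 1e4 * k else cfg$maxit
  for (r in seq_len(n)) {
    ft <- resamples$values[, .FT_GENES, r, drop = FALSE]
    dim(ft) <- dim(ft)[1:2]
    colnames(ft) <- .FT_GENES
    Xw <- .design_from_skeleton(spec, skel, ft) * sqw
    yw <- resamples$values[, .TARGET, r] * sqw
    sol <- .wls_solve(Xw, yw)
    if (optimizer == "wls") {
      params[r, ] <- sol$params
      F_min[r] <- sol$F_min
      converged[r] <- TRUE   # closed form; deficiency tracked separately
    } else {
      fn <- function(b) sum((yw - drop(Xw %*% b))^2)
      opt <- stats::optim(sol$params, fn, method = "Nelder-Mead",
                          control = list(reltol = cfg$reltol, maxit = maxit))
      params[r, ] <- opt$par
      F_min[r] <- opt$value
      converged[r] <- opt$convergence == 0L
    }
  }
  if (!any(converged)) stop("no replicate converged")
  ok <- converged
  summary <- data.frame(
    parameter = colnames(params),
    mean = colMeans(params[ok, , drop = FALSE]),
    sd = apply(params[ok, , drop = FALSE], 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(spec = spec, params = params, F_min = F_min, converged = converged,
         n_samples = n, m = nrow(resamples$points),
         resample_seed = resamples$seed, summary = summary,
         mean_F = mean(F_min[ok]), optimizer = optimizer),
    class = "ft_fit"
  )
}

#' @export
print.ft_fit <- function(x, ...) {
  cat("<ft_fit> ", x$spec$label, ": ", x$n_samples, " replicates, mean F = ",
      format(x$mean_F, digits = 5), " (", sum(x$converged), " converged)\n",
      sep = "")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = 2k + F_min + (2k^2 + 2k) / (m - k - 1)`, the small-sample AIC with
#' the maximized log-likelihood expressed through the minimized
#' block-weighted cost as `2 log L = -F_min`.
#'
#' @param k Number of free parameters.
#' @param m Number of data points; must exceed `k + 1`.
#' @param F_min Minimized cost value(s).
#' @return AICc value(s).
#' @export
#' @examples
#' aicc(6, 61, 10)  # 12 + 10 + 84/54
aicc <- function(k, m, F_min) {
  if (any(m <= k + 1)) stop("AICc requires m > k + 1")
  2 * k + F_min + (2 * k^2 + 2 * k) / (m - k - 1)
}

.check_same_ensemble <- function(fits) {
  n <- vapply(fits, function(f) f$n_samples, 1L)
  seeds <- vapply(fits, function(f) f$resample_seed, 1L)
  ms <- vapply(fits, function(f) f$m, 1L)
  if (length(unique(n)) != 1 || length(unique(seeds)) != 1 ||
      length(unique(ms)) != 1) {
    stop("fits must come from the same resampled ensemble")
  }
}

#' Compare model structures by AICc
#'
#' Ranks a set of fitted model structures by AICc computed from the
#' ensemble-mean minimized cost (the headline criterion), with the number of
#' data points shared by all fits.
#'
#' @param fits List of [fit_ensemble()] results on the same ensemble.
#' @param m Number of data points; defaults to the count recorded in the
#'   fits.
#' @return A data frame with one row per model: `model`, `k`, `mean_F`,
#'   `AICc`, `delta_AICc` and `rank`, ordered as supplied.
#' @export
compare_structures <- function(fits, m = NULL) {
  .check_same_ensemble(fits)
  if (is.null(m)) m <- fits[[1]]$m
  out <- data.frame(
    model = vapply(fits, function(f) f$spec$label, ""),
    k = vapply(fits, function(f) count_parameters(f$spec), 1L),
    mean_F = vapply(fits, function(f) f$mean_F, 1),
    stringsAsFactors = FALSE
  )
  out$AICc <- aicc(out$k, m, out$mean_F)
  out$delta_AICc <- out$AICc - min(out$AICc)
  out$rank <- rank(out$AICc, ties.method = "min")
  out
}

.stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Test knockout hypotheses against the full model
#'
#' Compares each model's per-replicate minimized-cost distribution with the
#' baseline's, paired across replicate indices (the models share the same
#' resampled datasets). The default test is the two-sided Wilcoxon
#' signed-rank test; Welch's t-test and Holm adjustment are available. The
#' mean-F ratio vs the baseline is reported as the effect size, and
#' significance stars use the 0.05 / 0.01 convention.
#'
#' @param fits Named list of [fit_ensemble()] results on the same ensemble;
#'   must include the baseline (by default `"H0"`, or the first element).
#' @param baseline Name of the reference fit.
#' @param method `"wilcoxon"` (paired signed-rank, default) or `"t"`
#'   (paired t-test).
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (`"none"` by default, matching the raw-star convention).
#' @return A data frame with `model`, `mean_F`, `ratio_vs_baseline`,
#'   `p_value`, `signif` per fit (baseline row has p = 1, ratio = 1).
#' @export
test_hypotheses <- function(fits, baseline = if ("H0" %in% names(fits))
                              "H0" else names(fits)[1],
                            method = c("wilcoxon", "t"), adjust = "none") {
  method <- match.arg(method)
  .check_same_ensemble(fits)
  if (!baseline %in% names(fits)) stop("baseline '", baseline, "' not found")
  F0 <- fits[[baseline]]$F_min
  rows <- lapply(names(fits), function(nm) {
    Fi <- fits[[nm]]$F_min
    d <- Fi - F0
    p <- if (all(abs(d) < 1e-12)) 1 else if (method == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(Fi, F0, paired = TRUE,
                                          exact = FALSE)$p.value)
    } else {
      stats::t.test(Fi, F0, paired = TRUE)$p.value
    }
    data.frame(model = nm, mean_F = mean(Fi),
               ratio_vs_baseline = mean(Fi) / mean(F0),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") {
    keep <- out$model != baseline
    out$p_value[keep] <- stats::p.adjust(out$p_value[keep], method = adjust)
  }
  out$signif <- .stars(out$p_value)
  out
}

#' Per-block cost contributions and standardized residuals
#'
#' Decomposes the cost of a fitted model into the four block contributions
#' (they sum exactly to `F`) and computes per-point standardized residuals.
#' When reference contributions are supplied (typically from the full model
#' H0 on the same data), blocks whose contribution exceeds `flag_factor`
#' times the reference are flagged as pattern defects.
#'
#' @inheritParams cost
#' @param reference Optional: a `ft_block_diag` object or a numeric vector of
#'   four reference block contributions.
#' @param flag_factor Flag threshold as a multiple of the reference
#'   contribution (default 2).
#' @return A data frame of class `ft_block_diag` with one row per block:
#'   `block`, `rss`, `sum_var`, `contribution`, `flagged`; per-point
#'   standardized residuals are attached as attribute `"residuals"`.
#' @export
block_diagnostics <- function(spec, params, data, reference = NULL,
                              flag_factor = 2, sd_floor = 1e-6) {
  fr <- .model_frame(spec, data, sd_floor)
  params <- params[colnames(fr$X)]
  resid <- fr$y - drop(fr$X %*% params)
  mats <- .as_matrices(data)
  sdA <- pmax(mats$sd[, .TARGET], sd_floor)
  rss <- tapply(resid^2, fr$block, sum)
  sum_var <- tapply(sdA^2, fr$block, sum)
  out <- data.frame(
    block = .BLOCKS,
    rss = as.numeric(rss[.BLOCKS]),
    sum_var = as.numeric(sum_var[.BLOCKS]),
    stringsAsFactors = FALSE
  )
  out$contribution <- out$rss / out$sum_var
  ref <- if (inherits(reference, "ft_block_diag")) {
    reference$contribution
  } else reference
  out$flagged <- if (is.null(ref)) {
    rep(FALSE, 4)
  } else out$contribution > flag_factor * ref
  attr(out, "residuals") <- data.frame(
    block = as.character(fr$block),
    time_days = mats$points$time_days,
    data = fr$y, model = drop(fr$X %*% params),
    std_resid = resid / sdA,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ft_block_diag", "data.frame")
  out
}

#' Summarize ensemble parameter estimates
#'
#' One row per (model, coefficient, stratum): ensemble mean and s.d. of the
#' per-replicate estimates, supporting comparisons of intercepts and
#' regulatory coefficients across vernalization and time-of-day strata.
#'
#' @param fits A single [fit_ensemble()] result or a (possibly named) list.
#' @return A data frame with columns `model`, `parameter`, `coefficient`,
#'   `stratum`, `mean`, `sd`.
#' @export
summarize_parameters <- function(fits) {
  if (inherits(fits, "ft_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    s <- f$summary
    parts <- strsplit(s$parameter, ".", fixed = TRUE)
    is_c0 <- vapply(parts, function(p) p[1] == "c0", logical(1))
    data.frame(
      model = f$spec$label,
      parameter = s$parameter,
      coefficient = ifelse(is_c0, "c0",
                           vapply(parts, function(p)
                             paste(p[1], p[2], sep = "."), "")),
      stratum = mapply(function(p, i0) {
        paste(if (i0) p[-1] else p[-(1:2)], collapse = ".")
      }, parts, is_c0, USE.NAMES = FALSE),
      mean = s$mean, sd = s$sd,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
}
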