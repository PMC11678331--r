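# Ground-truth data generator: FT-like expression profiles with the
# qualitative features of the lupin qRT-PCR data (high FTc1/AGL8 vs near-zero
# FTa2/FTc2, vernalization induction, morning/evening differences), plus AGL8
# generated from a known model so recovery can be checked end to end.

.SHAPES <- c("flat_low", "flat_high", "rising", "vernalization_induced",
             "evening_elevated")

#' Expression profile template for one FT-like gene
#'
#' Describes the mean time course of one gene across the four condition
#' blocks. `shape` sets the temporal pattern: `flat_low` and `flat_high` are
#' constant (low vs high expression), `rising` increases linearly threefold
#' over the horizon; `vernalization_induced` and `evening_elevated` are flat
#' profiles whose defining feature comes from a default induction factor
#' (2) or daytime offset (half the base level). Vernalized blocks multiply
#' the mean by `induction_factor`; evening blocks add `daytime_offset`. The
#' recorded s.d. is `noise_cv * mean`, floored at `sd_floor` so that
#' near-zero genes keep a nonzero sigma.
#'
#' @param gene One of [ft_genes()].
#' @param shape One of `"flat_low"`, `"flat_high"`, `"rising"`,
#'   `"vernalization_induced"`, `"evening_elevated"`.
#' @param base_level Baseline mean expression (relative units).
#' @param induction_factor Multiplier (>= 1) applied in vernalized blocks.
#' @param daytime_offset Additive shift applied in evening blocks.
#' @param noise_cv S.d. as a fraction of the mean (>= 0).
#' @param sd_floor Absolute floor for the recorded s.d. (default 0.005).
#' @return An object of class `ft_profile_template`.
#' @export
profile_template <- function(gene, shape, base_level,
                             induction_factor = 1, daytime_offset = 0,
                             noise_cv = 0.1, sd_floor = 0.005) {
  gene <- match.arg(gene, .FT_GENES)
  shape <- match.arg(shape, .SHAPES)
  if (shape == "vernalization_induced" && induction_factor == 1) {
    induction_factor <- 2
  }
  if (shape == "evening_elevated" && daytime_offset == 0) {
    daytime_offset <- base_level / 2
  }
  stopifnot(base_level >= 0, induction_factor >= 1, noise_cv >= 0,
            sd_floor >= 0)
  structure(
    list(gene = gene, shape = shape, base_level = base_level,
         induction_factor = induction_factor,
         daytime_offset = daytime_offset, noise_cv = noise_cv,
         sd_floor = sd_floor),
    class = "ft_profile_template"
  )
}

.template_mean <- function(tpl, t, horizon, vernalized, evening) {
  base <- if (tpl$shape == "rising") {
    tpl$base_level * (1 + 2 * t / horizon)
  } else {
    rep(tpl$base_level, length(t))
  }
  m <- base * if (vernalized) tpl$induction_factor else 1
  if (evening) m <- m + tpl$daytime_offset
  m
}

#' Ground-truth configuration for synthetic data
#'
#' Bundles the generating model (spec and parameters), the FT-like profile
#' templates, the sampling design (2-4 terms over a horizon of about two
#' weeks) and the noise model for the target gene. AGL8 is always generated
#' from the model, never templated; `agl8_cv` only sets its recorded s.d.
#'
#' @param spec The generating [model_spec()].
#' @param params Generating parameter vector (see [make_params()]).
#' @param templates Named list of [profile_template()] objects covering all
#'   four FT-like genes.
#' @param agl8_cv S.d. of the generated AGL8 as a fraction of its mean.
#' @param agl8_sd_floor Absolute floor for the AGL8 s.d.
#' @param n_terms Number of sampling terms per block (2-4).
#' @param horizon_days Time span of the sampling terms (default 14).
#' @param seed Seed (used when `noisy_means = TRUE`).
#' @param line,photoperiod Labels for the generated dataset.
#' @param noisy_means If `TRUE`, Gaussian observation noise is added to the
#'   recorded means (truncated at zero); by default the recorded means are
#'   the noiseless template/model values and all stochasticity comes from the
#'   downstream resampling step.
#' @param clamp_negative If `TRUE`, negative model-implied AGL8 means are
#'   clamped at 0 with a warning; if `FALSE` (default) they are an error.
#' @return An object of class `ft_truth_config`.
#' @export
truth_config <- function(spec, params, templates, agl8_cv = 0.1,
                         agl8_sd_floor = 0.005, n_terms = 4,
                         horizon_days = 14, seed = 1,
                         line = "synthetic", photoperiod = "SD_8h",
                         noisy_means = FALSE, clamp_negative = FALSE) {
  stopifnot(inherits(spec, "ft_model_spec"))
  n_terms <- as.integer(n_terms)
  if (n_terms < 2 || n_terms > 4) stop("n_terms must be 2, 3 or 4")
  if (!all(.FT_GENES %in% names(templates))) {
    stop("templates must cover all four FT-like genes")
  }
  stopifnot(all(vapply(templates, inherits, TRUE, "ft_profile_template")))
  if (is.null(names(params)) ||
      !setequal(names(params), param_names(spec))) {
    stop("params must be named as param_names(spec)")
  }
  structure(
    list(spec = spec, params = params, templates = templates[.FT_GENES],
         agl8_cv = agl8_cv, agl8_sd_floor = agl8_sd_floor,
         n_terms = n_terms, horizon_days = horizon_days,
         seed = as.integer(seed), line = line,
         photoperiod = match.arg(photoperiod, .PHOTOPERIODS),
         noisy_means = isTRUE(noisy_means),
         clamp_negative = isTRUE(clamp_negative)),
    class = "ft_truth_config"
  )
}

.block_table <- function(cfg) {
  t <- seq(0, cfg$horizon_days, length.out = cfg$n_terms)
  expand.grid(
    vernalization = .VERN, daytime = .DAYTIME, time_days = t,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}

#' Generate FT-like gene profiles from a truth configuration
#'
#' Produces the four predictor series for every condition block:
#' `n_terms` equally spaced sampling terms labelled `T1..Tn` over the
#' horizon, means built from each gene's template (vernalization factor in V
#' blocks, daytime offset in the evening), and s.d. `noise_cv * mean` floored
#' at the template's `sd_floor`. Deterministic given the seed.
#'
#' @param cfg An [truth_config()].
#' @return A long data frame of FT-gene rows in the dataset column layout.
#' @export
generate_ft_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "ft_truth_config"))
  grid <- .block_table(cfg)
  t_all <- sort(unique(grid$time_days))
  if (cfg$noisy_means) set.seed(cfg$seed)
  out <- do.call(rbind, lapply(.FT_GENES, function(g) {
    tpl <- cfg$templates[[g]]
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      m <- .template_mean(tpl, grid$time_days[i], cfg$horizon_days,
                          grid$vernalization[i] == "V",
                          grid$daytime[i] == "evening")
      s <- pmax(tpl$noise_cv * m, tpl$sd_floor)
      if (cfg$noisy_means) m <- pmax(m + s * stats::rnorm(1), 0)
      data.frame(
        vernalization = grid$vernalization[i], daytime = grid$daytime[i],
        term = paste0("T", match(grid$time_days[i], t_all)),
        time_days = grid$time_days[i], gene = g, mean = m, sd = s,
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Generate the AGL8 series implied by the truth model
#'
#' At every (block, time) point the AGL8 mean is the truth model's
#' prediction from the FT means; its s.d. is `agl8_cv * mean` floored at
#' `agl8_sd_floor`. With `noisy_means = TRUE` observation noise is added to
#' the recorded mean.
#'
#' @param cfg An [truth_config()].
#' @param ft_data FT-gene rows from [generate_ft_profiles()].
#' @return A long data frame of AGL8 rows.
#' @export
generate_agl8 <- function(cfg, ft_data) {
  stopifnot(inherits(cfg, "ft_truth_config"))
  key <- paste(ft_data$vernalization, ft_data$daytime, ft_data$time_days)
  pts <- !duplicated(key)
  base <- ft_data[pts, c("vernalization", "daytime", "term", "time_days")]
  ukey <- key[pts]
  ft_mat <- vapply(.FT_GENES, function(g) {
    idx <- match(ukey, key[ft_data$gene == g])
    ft_data$mean[ft_data$gene == g][idx]
  }, numeric(nrow(base)))
  blk <- .block_of(base$vernalization, base$daytime)
  t0 <- tapply(base$time_days, blk, min)
  skel_t <- base$time_days - as.numeric(t0[blk])
  G <- .regressor_matrix(cfg$spec, ft_mat, skel_t)
  strata <- .strata_of(cfg$spec)
  stratum <- switch(cfg$spec$c1_varies_by,
                    none = rep("all", nrow(base)),
                    vernalization = base$vernalization,
                    daytime = base$daytime)
  mu <- cfg$params[paste0("c0.", as.character(blk))]
  for (j in seq_along(cfg$spec$groups)) {
    cname <- paste("c", names(cfg$spec$groups)[j], stratum, sep = ".")
    mu <- mu + cfg$params[cname] * G[, j]
  }
  mu <- unname(mu)
  if (any(mu < 0)) {
    if (cfg$clamp_negative) {
      warning("negative model-implied AGL8 means clamped at 0")
      mu <- pmax(mu, 0)
    } else {
      stop("truth model implies negative AGL8 means; ",
           "adjust the configuration or set clamp_negative = TRUE")
    }
  }
  s <- pmax(cfg$agl8_cv * mu, cfg$agl8_sd_floor)
  if (cfg$noisy_means) {
    set.seed(cfg$seed + 1L)
    mu <- pmax(mu + s * stats::rnorm(length(mu)), 0)
  }
  data.frame(
    vernalization = base$vernalization, daytime = base$daytime,
    term = base$term, time_days = base$time_days, gene = .TARGET,
    mean = mu, sd = s, stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: FT profiles plus the model-implied AGL8 series,
#' validated as an [ft_dataset()].
#'
#' @param cfg An [truth_config()] (e.g. from [make_scenario()]).
#' @return An [ft_dataset()].
#' @export
#' @examples
#' ds <- generate_dataset(make_scenario("Pal_like_SD"))
#' ds
generate_dataset <- function(cfg) {
  ft <- generate_ft_profiles(cfg)
  agl8 <- generate_agl8(cfg, ft)
  ft_dataset(cfg$line, cfg$photoperiod, rbind(ft, agl8))
}

#' Canned ground-truth scenarios
#'
#' Reproducible truth configurations emulating the study's qualitative
#' regimes:
#' \describe{
#'   \item{`Ku_like_SD`}{Early-flowering line under short days: AGL8 driven
#'     by `FTc1` alone (H5 truth) with high, evening-elevated, mildly
#'     vernalization-induced `FTc1` and near-zero other genes.}
#'   \item{`Pal_like_SD`}{Intermediate line: `FTc1`-only drive with a
#'     strongly vernalization-dependent regulatory coefficient
#'     (`c1(V) = 2 c1(N)`) and a rising, vernalization-induced `FTc1`.}
#'   \item{`ku_like_LD`}{Wild line under long days: joint `FTc1` + `FTa1`
#'     drive with vernalization-stratified coefficients, 3 sampling terms.}
#'   \item{`null_equal`}{Full-model (H0) truth with four identical FT
#'     templates and equal coefficients across strata; the calibration
#'     scenario for type-I error checks.}
#'   \item{`M1_true_SD`}{Cumulative-input (M1) truth with four distinct,
#'     non-degenerate FT templates; used for structure-selection checks.}
#'   \item{`M7_true_SD`}{Time-modulated (M7) truth on the same templates.}
#' }
#'
#' @param name Scenario name.
#' @param seed Seed stored in the configuration.
#' @param noise_cv If non-`NULL`, overrides the coefficient of variation of
#'   every template and of AGL8 (used in noise-sweep studies).
#' @param n_terms Optional override of the number of sampling terms.
#' @return An [truth_config()].
#' @export
#' @examples
#' cfg <- make_scenario("null_equal", seed = 7)
#' cfg$spec$label
make_scenario <- function(name = c("Ku_like_SD", "Pal_like_SD", "ku_like_LD",
                                   "null_equal", "M1_true_SD", "M7_true_SD"),
                          seed = 1, noise_cv = NULL, n_terms = NULL) {
  name <- match.arg(name)
  tpl <- function(g, shape, base, ind = 1, off = 0, cv = 0.1) {
    profile_template(g, shape, base, induction_factor = ind,
                     daytime_offset = off,
                     noise_cv = if (is.null(noise_cv)) cv else noise_cv)
  }
  low <- function(g, base = 0.03) tpl(g, "flat_low", base)
  cv_agl8 <- function(default) if (is.null(noise_cv)) default else noise_cv
  cfg <- switch(name,
    Ku_like_SD = {
      spec <- hypothesis_spec("H5")
      truth_config(
        spec,
        make_params(spec, c0 = c(0.6, 0.9, 0.5, 0.7),
                    c1 = c(V = 1.6, N = 1.2)),
        list(FTc1 = tpl("FTc1", "rising", 1.6, ind = 1.4, off = 0.6),
             FTa1 = low("FTa1", 0.05), FTc2 = low("FTc2", 0.03),
             FTa2 = low("FTa2", 0.02)),
        agl8_cv = cv_agl8(0.1), seed = seed, line = "Ku_like",
        photoperiod = "SD_8h", n_terms = 4
      )
    },
    Pal_like_SD = {
      spec <- hypothesis_spec("H5")
      truth_config(
        spec,
        make_params(spec, c0 = c(1.0, 1.2, 0.6, 0.8),
                    c1 = c(V = 2.0, N = 1.0)),
        list(FTc1 = tpl("FTc1", "rising", 1.5, ind = 1.8, off = 0.4,
                        cv = 0.05),
             FTa1 = low("FTa1", 0.05), FTc2 = low("FTc2", 0.03),
             FTa2 = low("FTa2", 0.02)),
        agl8_cv = cv_agl8(0.05), seed = seed, line = "Pal_like",
        photoperiod = "SD_8h", n_terms = 4
      )
    },
    ku_like_LD = {
      spec <- model_spec("M1", genes = c("FTc1", "FTa1"), label = "ku_truth")
      truth_config(
        spec,
        make_params(spec, c0 = c(0.8, 1.0, 0.4, 0.5),
                    c1 = c(V = 1.5, N = 0.7)),
        list(FTc1 = tpl("FTc1", "rising", 1.4, ind = 2.2, off = 0.3),
             FTa1 = tpl("FTa1", "rising", 1.2, ind = 1.8, off = 0.5),
             FTc2 = low("FTc2", 0.03), FTa2 = low("FTa2", 0.02)),
        agl8_cv = cv_agl8(0.1), seed = seed, line = "ku_like",
        photoperiod = "LD_16h", n_terms = 3
      )
    },
    null_equal = {
      spec <- hypothesis_spec("H0")
      eq <- function(g) tpl(g, "rising", 1.0, ind = 1.5, off = 0.2)
      truth_config(
        spec,
        make_params(spec, c0 = c(0.8, 0.8, 0.8, 0.8), c1 = c(V = 1, N = 1)),
        list(FTc1 = eq("FTc1"), FTa1 = eq("FTa1"), FTc2 = eq("FTc2"),
             FTa2 = eq("FTa2")),
        agl8_cv = cv_agl8(0.1), seed = seed, line = "null_equal",
        photoperiod = "SD_8h", n_terms = 4
      )
    },
    M1_true_SD = ,
    M7_true_SD = {
      family <- if (name == "M1_true_SD") "M1" else "M7"
      spec <- model_spec(family)
      c1 <- if (family == "M1") c(V = 1.5, N = 0.9) else c(V = 0.25, N = 0.15)
      truth_config(
        spec,
        make_params(spec, c0 = c(0.7, 0.9, 0.5, 0.6), c1 = c1),
        list(FTc1 = tpl("FTc1", "rising", 1.8, ind = 1.6, off = 0.4),
             FTa1 = tpl("FTa1", "rising", 1.0, ind = 1.3, off = 0.2),
             FTc2 = tpl("FTc2", "flat_high", 0.7, ind = 1.2, off = 0.1),
             FTa2 = tpl("FTa2", "rising", 0.5, ind = 1.5, off = 0.15)),
        agl8_cv = cv_agl8(0.1), seed = seed, line = name,
        photoperiod = "SD_8h", n_terms = 4
      )
    }
  )
  if (!is.null(n_terms)) {
    cfg <- truth_config(cfg$spec, cfg$params, cfg$templates,
                        agl8_cv = cfg$agl8_cv,
                        agl8_sd_floor = cfg$agl8_sd_floor,
                        n_terms = n_terms, horizon_days = cfg$horizon_days,
                        seed = cfg$seed, line = cfg$line,
                        photoperiod = cfg$photoperiod,
                        noisy_means = cfg$noisy_means,
                        clamp_negative = cfg$clamp_negative)
  }
  cfg
}
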