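# Numerical gradient of the cost at a point (independent check of the
# normal equations: at the WLS minimum the gradient must vanish).
num_gradient <- function(spec, params, data, h = 1e-6) {
  vapply(seq_along(params), function(j) {
    up <- params; up[j] <- up[j] + h
    dn <- params; dn[j] <- dn[j] - h
    (cost(spec, up, data) - cost(spec, dn, data)) / (2 * h)
  }, numeric(1))
}

test_that("the weighted least-squares oracle satisfies the normal equations", {
  cfg <- make_scenario("M1_true_SD", seed = 4)
  rs <- resample(interpolate(generate_dataset(cfg), 3), 3, seed = 9)
  for (r in 1:3) {
    d <- replicate_dataset(rs, r)
    o <- wls_oracle(model_spec("M1"), d)
    g <- num_gradient(model_spec("M1"), o$params, d)
    expect_true(all(abs(g) < 1e-5))
  }
})

test_that("the oracle agrees with brute-force grid refinement on a symmetric toy", {
  # identical blocks + unstratified c1 make the optimum symmetric, so a 2-D
  # grid over (common intercept, c1) finds the global minimum independently
  h5 <- hypothesis_spec("H5", c1_varies_by = "none")
  ds <- toy_dataset(times = c(0, 7, 14),
                    agl8 = function(t, b) 1 + 0.4 * t,
                    ftc1 = function(t, b) 0.5 + 0.15 * t,
                    sd_agl8 = c(0.5, 0.4, 0.6))
  o <- wls_oracle(h5, ds)
  lims <- list(a = c(-2, 4), b = c(-2, 6))
  for (round in 1:5) {
    aa <- seq(lims$a[1], lims$a[2], length.out = 21)
    bb <- seq(lims$b[1], lims$b[2], length.out = 21)
    Fg <- outer(aa, bb, Vectorize(function(a, b) {
      cost(h5, make_params(h5, c0 = a, c1 = b), ds)
    }))
    ij <- which(Fg == min(Fg), arr.ind = TRUE)[1, ]
    stepa <- diff(lims$a) / 20
    stepb <- diff(lims$b) / 20
    lims <- list(a = aa[ij[1]] + c(-2, 2) * stepa,
                 b = bb[ij[2]] + c(-2, 2) * stepb)
    best <- min(Fg)
  }
  expect_equal(best, o$F_min, tolerance = 1e-4)
  expect_equal(unname(o$params[1:4]), rep(o$params[[1]], 4),
               tolerance = 1e-8)  # symmetry across blocks
})

test_that("a constant-only fit returns the block means via the pseudo-inverse", {
  # with FTc1 identically zero the c1 column vanishes; the flagged
  # pseudo-inverse solution puts each block at its AGL8 mean
  ds <- toy_dataset(agl8 = function(t, b) {
    switch(b, V.morning = c(1, 3), V.evening = c(2, 2),
           N.morning = c(0, 4), N.evening = c(5, 1))
  }, sd_agl8 = 1)
  o <- wls_oracle(hypothesis_spec("H5"), ds)
  expect_true(o$rank_deficient)
  expect_equal(unname(o$params[paste0("c0.", condition_blocks())]),
               c(2, 2, 2, 3), tolerance = 1e-8)
})

test_that("the simplex fit recovers noise-free generating parameters", {
  cfg <- make_scenario("M1_true_SD")
  ds <- generate_dataset(cfg)
  f <- fit_one(cfg$spec, ds)
  expect_true(f$converged)
  expect_lt(f$F_min, 1e-10)
  expect_equal(unname(f$params[names(cfg$params)]), unname(cfg$params),
               tolerance = 1e-6)
})

test_that("the minimized cost never exceeds the cost at the generating truth", {
  cfg <- make_scenario("Pal_like_SD", seed = 8)
  rs <- resample(interpolate(generate_dataset(cfg), 3), 20, seed = 3)
  for (r in c(1, 7, 20)) {
    d <- replicate_dataset(rs, r)
    f <- fit_one(cfg$spec, d)
    expect_lte(f$F_min, cost(cfg$spec, cfg$params, d) + 1e-10)
  }
})

test_that("random-restart fits land on the same quadratic minimum", {
  cfg <- make_scenario("Ku_like_SD", seed = 5)
  rs <- resample(interpolate(generate_dataset(cfg), 3), 2, seed = 4)
  d <- replicate_dataset(rs, 1)
  o <- wls_oracle(hypothesis_spec("H0"), d)
  f <- fit_one(hypothesis_spec("H0"), d, init = "auto",
               optimizer_cfg = list(n_restarts = 2), seed = 6)
  expect_equal(f$F_min, o$F_min, tolerance = 1e-6)
})

test_that("ensemble fitting is deterministic, order-insensitive and noise-aware", {
  cfg <- make_scenario("Ku_like_SD", seed = 2)
  rs <- resample(interpolate(generate_dataset(cfg), 3), 50, seed = 11)
  f1 <- fit_ensemble(cfg$spec, rs)
  f2 <- fit_ensemble(cfg$spec, rs)
  expect_identical(f1$params, f2$params)      # same ensemble, same result
  expect_true(all(f1$F_min >= 0))
  expect_equal(nrow(f1$params), 50)

  # zero-noise replicates give a zero-spread ensemble at the truth
  ds0 <- generate_dataset(cfg)
  d0 <- ds0$data
  d0$sd <- 0
  rs0 <- resample(ft_dataset(ds0$line, ds0$photoperiod, d0), 10, seed = 1)
  f0 <- fit_ensemble(cfg$spec, rs0)
  expect_true(all(abs(f0$summary$sd) < 1e-7))
  expect_equal(unname(f0$summary$mean),
               unname(cfg$params[f0$summary$parameter]), tolerance = 1e-6)
})

test_that("wls and simplex ensembles coincide", {
  cfg <- make_scenario("null_equal", seed = 3)
  rs <- resample(interpolate(generate_dataset(cfg), 3), 30, seed = 5)
  fa <- fit_ensemble(hypothesis_spec("H0"), rs)
  fb <- fit_ensemble(hypothesis_spec("H0"), rs, optimizer = "wls")
  expect_equal(fa$F_min, fb$F_min, tolerance = 1e-6)
})

test_that("AICc follows its formula and guards its domain", {
  expect_equal(aicc(6, 61, 10), 12 + 10 + 84 / 54)
  expect_equal(aicc(0, 10, 0), 0)
  # strictly increasing penalty in k at fixed F_min and m
  ks <- 1:8
  vals <- vapply(ks, function(k) aicc(k, 30, 5), 1)
  expect_true(all(diff(vals) > 0))
  expect_error(aicc(6, 7, 1), "m > k \\+ 1")
  expect_error(aicc(6, 6, 1), "m > k \\+ 1")
})

test_that("structure comparison ranks by AICc and respects nesting", {
  cfg <- make_scenario("M1_true_SD", seed = 6)
  rs <- resample(interpolate(generate_dataset(cfg), 3), 40, seed = 13)
  fits <- list(M1 = fit_ensemble(model_spec("M1"), rs, optimizer = "wls"),
               M3 = fit_ensemble(model_spec("M3"), rs, optimizer = "wls"))
  tab <- compare_structures(fits)
  expect_equal(tab$k, c(6L, 12L))
  expect_equal(tab$AICc, aicc(tab$k, fits$M1$m, tab$mean_F))
  # the gene-specific model nests the cumulative model: per-replicate
  # oracle minima can only improve
  expect_true(all(fits$M3$F_min <= fits$M1$F_min + 1e-8))
  # identical F and k give identical AICc
  expect_equal(aicc(6, 52, 4.2), aicc(6, 52, 4.2))
})

test_that("hypothesis testing pairs replicates and handles the self-comparison", {
  cfg <- make_scenario("Ku_like_SD", seed = 2)
  rs <- resample(interpolate(generate_dataset(cfg), 3), 40, seed = 11)
  f0 <- fit_ensemble(hypothesis_spec("H0"), rs, optimizer = "wls")
  f4 <- fit_ensemble(hypothesis_spec("H4"), rs, optimizer = "wls")
  tab <- test_hypotheses(list(H0 = f0, H0_again = f0, H4 = f4))
  self <- tab[tab$model == "H0_again", ]
  expect_equal(self$p_value, 1)
  expect_equal(self$ratio_vs_baseline, 1)
  expect_lt(tab$p_value[tab$model == "H4"], 0.01)
  expect_gt(tab$ratio_vs_baseline[tab$model == "H4"], 2)
  expect_equal(tab$signif[tab$model == "H4"], "**")
  # Welch-type paired t alternative and Holm adjustment run
  tab_t <- test_hypotheses(list(H0 = f0, H4 = f4), method = "t",
                           adjust = "holm")
  expect_lt(tab_t$p_value[tab_t$model == "H4"], 0.01)
  # mismatched ensembles are rejected
  rs_small <- resample(interpolate(generate_dataset(cfg), 3), 10, seed = 11)
  f_small <- fit_ensemble(hypothesis_spec("H4"), rs_small, optimizer = "wls")
  expect_error(test_hypotheses(list(H0 = f0, H4 = f_small)),
               "same resampled ensemble")
})

test_that("block diagnostics decompose the cost exactly and localize defects", {
  cfg <- make_scenario("Pal_like_SD", seed = 7)
  ds <- generate_dataset(cfg)
  dense <- interpolate(ds, 3)
  o0 <- wls_oracle(hypothesis_spec("H0"), dense)
  d0 <- block_diagnostics(hypothesis_spec("H0"), o0$params, dense)
  expect_equal(sum(d0$contribution), o0$F_min, tolerance = 1e-10)
  expect_false(any(d0$flagged))
  # self-reference never flags
  d0r <- block_diagnostics(hypothesis_spec("H0"), o0$params, dense,
                           reference = d0)
  expect_false(any(d0r$flagged))
  # knocking out the sole driver inflates vernalized blocks vs H0
  o4 <- wls_oracle(hypothesis_spec("H4"), dense)
  d4 <- block_diagnostics(hypothesis_spec("H4"), o4$params, dense,
                          reference = d0)
  expect_equal(sum(d4$contribution), o4$F_min, tolerance = 1e-10)
  expect_true(any(d4$flagged))
})

test_that("parameter summaries are tidy and complete", {
  cfg <- make_scenario("Ku_like_SD", seed = 2)
  rs <- resample(interpolate(generate_dataset(cfg), 3), 10, seed = 1)
  fits <- list(H0 = fit_ensemble(hypothesis_spec("H0"), rs, optimizer = "wls"),
               M3 = fit_ensemble(model_spec("M3"), rs, optimizer = "wls"))
  tab <- summarize_parameters(fits)
  expect_equal(nrow(tab), count_parameters(hypothesis_spec("H0")) +
                 count_parameters(model_spec("M3")))
  expect_setequal(unique(tab$stratum[tab$coefficient == "c0"]),
                  condition_blocks())
  expect_setequal(unique(tab$stratum[tab$coefficient != "c0"]), c("V", "N"))
})
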