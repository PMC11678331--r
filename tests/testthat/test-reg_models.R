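test_that("parameter counts follow the sharing scheme", {
  expect_equal(count_parameters(model_spec("M1")), 6)              # 4 + 1x2
  expect_equal(count_parameters(model_spec("M3")), 12)             # 4 + 4x2
  expect_equal(count_parameters(model_spec("M2")), 8)              # 4 + 2x2
  expect_equal(count_parameters(model_spec("M1", c1_varies_by = "none")), 5)
  ks <- vapply(paste0("H", 0:5),
               function(h) count_parameters(hypothesis_spec(h)), 1L)
  expect_true(all(ks == 6))  # knockouts keep the parameter count
  expect_equal(length(param_names(model_spec("M3"))), 12)
})

test_that("model specs enforce the gene universe and family constraints", {
  expect_error(model_spec("M1", genes = character(0)), "subset")
  expect_error(model_spec("M1", genes = c("FTc1", "AGL8")), "subset")
  expect_error(model_spec("M2", genes = c("FTc1", "FTa1")), "four FT-like")
  expect_error(hypothesis_spec("H7"))
  expect_equal(hypothesis_spec("H4")$genes, c("FTa1", "FTc2", "FTa2"))
  expect_equal(hypothesis_spec("H5")$genes, "FTc1")
})

test_that("regressor transforms match their closed forms", {
  lv <- c(FTc1 = 1, FTa1 = 2, FTc2 = 3, FTa2 = 4)
  expect_equal(unname(regressor(model_spec("M1"), lv)), 10)
  expect_equal(unname(regressor(model_spec("M4"), lv)), 1 + 4 + 9 + 16)
  expect_equal(unname(regressor(model_spec("M4", m4_form = "square_of_sum"),
                                lv)), 100)
  zero <- c(FTc1 = 0, FTa1 = 0, FTc2 = 0, FTa2 = 0)
  expect_equal(unname(regressor(model_spec("M5"), zero)), 1)  # exp(0)
  e_lv <- c(FTc1 = exp(1) - 1e-9, FTa1 = 0, FTc2 = 0, FTa2 = 0)
  expect_equal(unname(regressor(model_spec("M6"), e_lv)), 1)  # log(e)
  expect_error(regressor(model_spec("M6"),
                         c(FTc1 = -1, FTa1 = 0, FTc2 = 0, FTa2 = 0)),
               "not positive")
  expect_equal(unname(regressor(model_spec("M7"), lv, t = 2)), 20)
  expect_equal(unname(regressor(model_spec("M7"), lv, t = 0)), 0)
  # M2 returns one term per coefficient group
  expect_equal(regressor(model_spec("M2"), lv), c(FTc1 = 1, FTrest = 9))
})

test_that("prediction combines block intercepts and stratified coefficients", {
  lv <- c(FTc1 = 1, FTa1 = 2, FTc2 = 3, FTa2 = 4)
  m1 <- model_spec("M1")
  p <- make_params(m1, c0 = 0, c1 = 1)
  expect_equal(predict_agl8(m1, p, "V.morning", lv), 10)
  h5 <- hypothesis_spec("H5")
  p5 <- make_params(h5, c0 = 1, c1 = 2)
  expect_equal(predict_agl8(h5, p5, "N.evening", c(FTc1 = 3)), 7)
  # stratified coefficient picks the block's stratum
  p5v <- make_params(h5, c0 = 0, c1 = c(V = 2, N = 5))
  expect_equal(predict_agl8(h5, p5v, "V.morning", c(FTc1 = 1)), 2)
  expect_equal(predict_agl8(h5, p5v, "N.morning", c(FTc1 = 1)), 5)
})

test_that("excluded genes cannot influence knockout predictions", {
  h4 <- hypothesis_spec("H4")  # FTc1 excluded
  p <- make_params(h4, c0 = 0.5, c1 = c(V = 1.3, N = 0.7))
  lv1 <- c(FTc1 = 0, FTa1 = 2, FTc2 = 3, FTa2 = 4)
  for (block in condition_blocks()) {
    base <- predict_agl8(h4, p, block, lv1)
    for (v in c(-5, 1, 100)) {
      lv2 <- lv1
      lv2["FTc1"] <- v
      expect_identical(predict_agl8(h4, p, block, lv2), base)
    }
  }
})

test_that("cost matches the block-normalized formula on hand-built cases", {
  h5 <- hypothesis_spec("H5")
  # exact reproduction -> F = 0
  cfg <- make_scenario("Ku_like_SD")
  expect_equal(cost(cfg$spec, cfg$params, generate_dataset(cfg)), 0)

  # one block with residuals (1, 1) and sigma^2 (1, 1): F = (1+1)/(1+1) = 1
  p <- make_params(h5, c0 = 2, c1 = 0)
  ds <- toy_dataset(agl8 = function(t, b) if (b == "V.morning") c(3, 3)
                    else c(2, 2), sd_agl8 = 1)
  expect_equal(cost(h5, p, ds), 1)

  # doubling every sigma in a block divides its contribution by 4
  d2 <- ds$data
  sel <- d2$gene == "AGL8" & d2$vernalization == "V" & d2$daytime == "morning"
  d2$sd[sel] <- 2
  ds2 <- ft_dataset(ds$line, ds$photoperiod, d2)
  expect_equal(cost(h5, p, ds2), 0.25)

  # contributions are invariant to point order within a block
  set.seed(5)
  shuf <- ds$data[sample(nrow(ds$data)), ]
  expect_equal(cost(h5, p, ft_dataset(ds$line, ds$photoperiod, shuf)), 1)
})

test_that("cost errors when a block has no usable variance", {
  h5 <- hypothesis_spec("H5")
  p <- make_params(h5, c0 = 1, c1 = 0)
  ds <- toy_dataset(sd_agl8 = 0)
  expect_equal(cost(h5, p, ds), 0)  # floor rescues sd = 0 denominators
  expect_error(cost(h5, p, ds, sd_floor = 0), "zero total")
})
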