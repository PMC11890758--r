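test_that("percent of control matches its definition and identities", {
  expect_equal(percent_of_control(110, 10, 110), 100)  # positive-control identity
  expect_equal(percent_of_control(10, 10, 110), 0)     # blank identity
  expect_equal(percent_of_control(60, 10, 110), 50)
  # unclamped outside [0, 100]
  expect_gt(percent_of_control(150, 10, 110), 100)
  expect_lt(percent_of_control(5, 10, 110), 0)
  expect_error(percent_of_control(50, 10, 10), class = "os_signal_error")
})

test_that("percent of control is invariant under common affine transforms", {
  withr::with_seed(8, {
    for (i in 1:25) {
      s <- runif(3, 10, 1000)  # compound, blank, positive
      a <- runif(1, 0.1, 50)
      b <- runif(1, -100, 100)
      expect_equal(
        percent_of_control(a * s[1] + b, a * s[2] + b, a * s[3] + b),
        percent_of_control(s[1], s[2], s[3]),
        tolerance = 1e-9)
    }
  })
})

test_that("selectivity index ratios, sentinels and monotonicity", {
  expect_equal(selectivity_index(100, 50), 2)
  expect_equal(selectivity_index(80, 80), 1)
  expect_identical(selectivity_index(90, 0), Inf)   # saturated killing
  expect_identical(selectivity_index(90, -5), Inf)
  for (x in c(0.5, 10, 99)) expect_equal(selectivity_index(x, x), 1)
  # monotone: increasing in pc_minus, decreasing in pc_plus
  expect_gt(selectivity_index(90, 40), selectivity_index(80, 40))
  expect_gt(selectivity_index(90, 40), selectivity_index(90, 50))
})

test_that("cancer viability subtracts PBMC background with a zero floor", {
  expect_equal(cancer_viability(1000, 200), 800)
  expect_equal(cancer_viability(200, 200), 0)
  expect_equal(cancer_viability(150, 200), 0)
})

test_that("area filter keeps objects strictly above threshold", {
  obj <- data.frame(id = 1:3, area = c(300, 400, 401))
  expect_equal(filter_objects_by_area(obj)$id, 3L)
  expect_equal(nrow(filter_objects_by_area(obj[0, ])), 0)
  all_big <- data.frame(id = 1:4, area = rep(500, 4))
  expect_equal(nrow(filter_objects_by_area(all_big)), 4)
  expect_error(filter_objects_by_area(data.frame(area = -1)),
               class = "os_value_error")
})

test_that("4PL fit recovers noiseless generating parameters and satisfies the midpoint identity", {
  g <- generate_dose_response(1e-7, top = 100, bottom = 0, hill = 1,
                              noise_cv = 0, seed = 4)
  fit <- fit_4pl(g$data$dose, g$data$response)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 1e-7, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  # response at dose = ic50 is (top + bottom) / 2
  expect_equal(predict(fit, fit$ic50), (fit$top + fit$bottom) / 2,
               tolerance = 1e-9)
  # descending (inhibition) curves fit with negative hill
  d <- 10^seq(-9, -4.5, length.out = 8)
  y <- 100 - 100 / (1 + 10^((log10(3e-7) - log10(d)) * 1.2))
  f2 <- fit_4pl(d, y)
  expect_equal(f2$ic50, 3e-7, tolerance = 1e-6)
  expect_lt(f2$hill, 0)
})

test_that("4PL converged residual never exceeds the truth's residual", {
  withr::with_seed(21, {
    for (i in 1:10) {
      truth_ic50 <- 10^runif(1, -8, -6)
      g <- generate_dose_response(truth_ic50, noise_cv = 0.08, seed = i)
      fit <- fit_4pl(g$data$dose, g$data$response)
      expect_true(fit$converged)
      mu_truth <- 100 / (1 + 10^((log10(truth_ic50) -
                                    log10(g$data$dose)) * 1))
      expect_lte(fit$rss, sum((g$data$response - mu_truth)^2) + 1e-9)
    }
  })
})

test_that("4PL fit rejects insufficient designs", {
  expect_error(fit_4pl(c(1e-8, 1e-7, 1e-6), c(10, 50, 90)),
               class = "os_data_error")
  expect_error(fit_4pl(c(1, 1.5, 2, 2.5) * 1e-7, c(10, 30, 60, 90)),
               class = "os_data_error")  # span < 2 decades
})

test_that("killing-curve AUC is a normalized trapezoid on log dose", {
  expect_equal(killing_curve_auc(c(1, 10, 100), c(100, 100, 100)), 1)
  expect_equal(killing_curve_auc(c(1, 10, 100), c(0, 0, 0)), 0)
  # hand trapezoid: equally log-spaced, {100, 50, 0} -> 0.5
  expect_equal(killing_curve_auc(c(0.1, 1, 10), c(100, 50, 0)), 0.5)
  # antitone: pointwise-lower viability never increases the AUC
  withr::with_seed(31, {
    for (i in 1:20) {
      d <- sort(10^runif(5, -1, 2))
      v <- runif(5, 20, 100)
      lower <- pmax(v - runif(5, 0, 20), 0)
      expect_lte(killing_curve_auc(d, lower), killing_curve_auc(d, v) + 1e-12)
    }
  })
  expect_error(killing_curve_auc(c(1, 3, 2), c(1, 2, 3)),
               class = "os_value_error")
})

test_that("sensitizer nomination is inclusive, ranked and flag-first", {
  res <- data.frame(compound = c("a", "b", "c", "d"),
                    pc_minus = c(100, 95, 90, 100),
                    pc_plus = c(50, 50, 0, 100),
                    selectivity = c(2.0, 1.9, Inf, 1.0))
  hits <- nominate_sensitizers(res, si_cutoff = 2)
  expect_equal(hits$compound, c("c", "a"))  # saturated flag first
  expect_equal(hits$rank, c(1L, 2L))
  none <- nominate_sensitizers(
    data.frame(compound = "x", selectivity = 1), 2)
  expect_equal(nrow(none), 0)
})

test_that("screen scoring recovers exact %C and SI in the noiseless case", {
  truth <- htip_screen_truth(n_compounds = 20, n_sensitizers = 2,
                             true_si = 5, assay_noise_cv = 0,
                             n_replicates = 2, seed = 12)
  d <- generate_htip_screen(truth)
  res <- score_htip_screen(join_plate_map(d$measurements, d$map))
  sens <- res[res$compound %in% d$truth$compound[d$truth$sensitizer], ]
  expect_equal(sens$selectivity, c(5, 5), tolerance = 1e-9)
  expect_equal(sens$pc_minus, c(100, 100), tolerance = 1e-9)
  expect_equal(sens$pc_plus, c(20, 20), tolerance = 1e-9)
  inert <- res[!res$compound %in% sens$compound, ]
  expect_equal(inert$selectivity, rep(1, 18), tolerance = 1e-9)
})
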