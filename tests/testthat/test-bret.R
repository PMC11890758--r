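test_that("channel ratios follow their definitions and guard degenerate signal", {
  expect_equal(bret_ratio(500, 1000), 0.5)
  expect_equal(bret_ratio(0, 1000), 0)
  expect_error(bret_ratio(100, 0), class = "os_signal_error")

  expect_equal(acceptor_donor_ratio(2000, 1000), 2)
  expect_equal(acceptor_donor_ratio(0, 1000), 0)
  expect_error(acceptor_donor_ratio(100, -1), class = "os_signal_error")

  expect_equal(trfret_ratio(50, 100000), 5)
  expect_equal(trfret_ratio(0, 100000), 0)
  expect_error(trfret_ratio(50, 0), class = "os_signal_error")

  expect_equal(trfret_foc(10, 5), 2)
  expect_equal(trfret_foc(7, 7), 1)
  expect_error(trfret_foc(10, 0), class = "os_signal_error")
})

test_that("net BRET is a plain difference and may go negative", {
  expect_equal(net_bret(0.5, 0.5), 0)
  expect_equal(net_bret(0.35, 0.10), 0.25)
  expect_equal(net_bret(0.08, 0.10), -0.02)
  expect_error(net_bret(NaN, 0.1), class = "os_value_error")
})

test_that("negative points are flagged excluded and never enter a fit", {
  pts <- saturation_points(c(0.5, 1, 2, 4, -0.1, 8),
                           c(0.1, 0.15, -0.02, 0.18, 0.05, 0.19))
  expect_equal(pts$excluded, c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  fit <- fit_saturation(pts)
  expect_equal(fit$n_points_used, 4)
  # fit on the manually reduced set must agree exactly
  keep <- !pts$excluded
  fit2 <- fit_saturation(pts$x[keep], pts$y[keep])
  expect_equal(fit$bret_max, fit2$bret_max)
  expect_equal(fit$bret50, fit2$bret50)
})

test_that("saturation fit recovers generating parameters on noiseless data", {
  x <- c(0.25, 0.5, 1, 2, 4, 8)
  for (par in list(c(0.2, 1), c(0.05, 0.3), c(1.5, 5))) {
    fit <- fit_saturation(x, par[1] * x / (par[2] + x))
    expect_true(fit$converged)
    expect_equal(fit$bret_max, par[1], tolerance = 1e-6)
    expect_equal(fit$bret50, par[2], tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
})

test_that("degenerate saturation inputs are handled per contract", {
  x <- c(0.25, 0.5, 1, 2)
  flat <- fit_saturation(x, rep(0, 4))
  expect_equal(flat$bret_max, 0)
  expect_false(flat$converged)
  expect_equal(saturation_auc(flat, 5), 0)
  expect_error(fit_saturation(c(1, 2), c(0.1, 0.2)), class = "os_data_error")
  expect_error(fit_saturation(c(1, 1, 1), c(0.1, 0.2, 0.15)),
               class = "os_data_error")
})

test_that("closed-form AUC matches quadrature and its limiting cases", {
  expect_equal(saturation_auc(1, 1, bret50 = 1), 1 - log(2), tolerance = 1e-12)
  q <- integrate(function(t) t / (1 + t), 0, 1, rel.tol = 1e-12)$value
  expect_equal(saturation_auc(1, 1, bret50 = 1), q, tolerance = 1e-8)
  expect_equal(saturation_auc(0, 10, bret50 = 2), 0)
  # bret50 -> 0+ limit is bmax * x_max
  expect_equal(saturation_auc(0.7, 3, bret50 = 1e-12), 0.7 * 3,
               tolerance = 1e-9)
  expect_error(saturation_auc(1, -1, bret50 = 1), class = "os_value_error")
})

test_that("AUC is monotone in x_max and bret_max, and the curve is nondecreasing", {
  withr::with_seed(11, {
    for (i in 1:50) {
      bmax <- runif(1, 0.01, 1)
      b50 <- exp(runif(1, log(0.1), log(10)))
      xm <- runif(1, 0.5, 10)
      expect_lt(saturation_auc(bmax, xm, bret50 = b50),
                saturation_auc(bmax, xm * 1.5, bret50 = b50))
      expect_lt(saturation_auc(bmax, xm, bret50 = b50),
                saturation_auc(bmax * 1.2, xm, bret50 = b50))
      xs <- sort(runif(20, 0, 10))
      expect_true(all(diff(bmax * xs / (b50 + xs)) >= 0))
    }
  })
})

test_that("FOC definition, invariance and inclusive thresholds hold", {
  s <- score_ppi_auc(rep(4, 4), rep(1, 4), rep(0.8, 4))
  expect_equal(s$foc, 4)
  expect_true(s$is_hit)  # foc boundary inclusive; separated means give p <= 0.001

  # common positive scaling of every AUC leaves FOC unchanged
  withr::with_seed(5, {
    ap <- runif(4, 2, 4); a1 <- runif(4, 0.5, 1); a2 <- runif(4, 0.5, 1)
    base <- score_ppi_auc(ap, a1, a2)$foc
    for (k in c(0.1, 3, 1e4)) {
      expect_equal(score_ppi_auc(k * ap, k * a1, k * a2)$foc, base,
                   tolerance = 1e-12)
    }
  })

  # identical distributions -> foc 1, p near 1, no hit
  ap <- c(1, 1.05, 0.95, 1)
  null <- score_ppi_auc(ap, ap, ap)
  expect_equal(null$foc, 1)
  expect_false(null$is_hit)

  # conjunctive cutoff: huge FOC with weak p is not a hit
  weak <- score_ppi_auc(c(10, 1, 14, 5), c(0.9, 1.1, 1.0, 1.0),
                        c(1.2, 0.9, 0.8, 1.1))
  expect_gt(weak$foc, 4)
  expect_gt(weak$p_foc, 0.001)
  expect_false(weak$is_hit)
})

test_that("p_foc equals the closed-form pooled two-sample t computation", {
  withr::with_seed(101, {
    ap <- 4 + rnorm(4, 0, 0.01)
    ac <- 1 + rnorm(8, 0, 0.01)
  })
  s <- score_ppi_auc(ap, ac[1:4], ac[5:8])
  # independent oracle: pooled-variance t statistic and t CDF
  n1 <- 4; n2 <- 8
  sp2 <- ((n1 - 1) * var(ap) + (n2 - 1) * var(ac)) / (n1 + n2 - 2)
  tstat <- (mean(ap) - mean(ac)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_oracle <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  expect_equal(s$p_foc, p_oracle, tolerance = 1e-10)
})

test_that("non-callable controls are flagged instead of signed FOC", {
  s <- score_ppi_auc(c(1, 1.1, 0.9, 1), c(-0.2, -0.1, -0.3, -0.2),
                     c(-0.1, -0.2, -0.15, -0.25))
  expect_false(s$callable)
  expect_true(is.na(s$foc))
  expect_true(is.na(s$is_hit))
})

test_that("hit calling is inclusive, conjunctive and deterministically ordered", {
  mk <- function(acc, foc, p, hit) {
    data.frame(donor = "D", acceptor = acc, n_rep_ppi = 4, auc_ppi = foc,
               auc_ctrl1 = 1, auc_ctrl2 = 1, x_max = 8, foc = foc,
               p_foc = p, is_hit = hit, callable = TRUE)
  }
  scores <- rbind(mk("A", 4.0, 1e-4, TRUE), mk("B", 3.9, 1e-4, FALSE),
                  mk("C", 10, 0.01, FALSE), mk("D", 6, 1e-6, TRUE),
                  mk("E", 6, 1e-7, TRUE))
  hits <- call_hits(scores)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$acceptor, c("E", "D", "A"))  # foc desc, then smaller p
})

test_that("replicate-level BRET50 recovery stays within 10% median error at 5% noise", {
  n_sim <- 200
  rel_err <- withr::with_seed(2024, {
    vapply(seq_len(n_sim), function(i) {
      curves <- simulate_saturation_curves(0.2, 1, c(0.25, 0.5, 1, 2, 4, 8),
                                           noise_sd = 0.01, n_replicates = 4)
      b50s <- vapply(curves,
                     function(d) fit_saturation(d)$bret50, numeric(1))
      abs(mean(b50s) - 1)
    }, numeric(1))
  })
  expect_lt(median(rel_err), 0.10)
})

test_that("plate pipeline reproduces hand-built curves through the screen path", {
  # two titration points, one gene, minimal two-control screen on one plate
  x_grid <- c(0.5, 1, 2, 4)
  truth <- bret_screen_truth(n_genes = 2, n_interactors = 1,
                             bmax_hit = 0.25, noise_sd_frac = 0,
                             x_grid = x_grid, seed = 99)
  d <- generate_bret_screen(truth)
  ann <- join_plate_map(d$measurements, d$map)
  curves <- bret_screen_curves(ann)
  g1 <- curves[curves$construct == "OI001" & curves$replicate == 1, ]
  expect_equal(sort(g1$x), x_grid, tolerance = 1e-12)
  expect_equal(g1$y, 0.25 * g1$x / (d$truth$bret50[1] + g1$x),
               tolerance = 1e-9)
  scores <- score_bret_screen(curves)
  expect_equal(nrow(scores), 2)
  expect_true(scores$is_hit[scores$acceptor == "OI001"])
  expect_false(scores$is_hit[scores$acceptor == "OI002"])
})
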