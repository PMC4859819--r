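test_that("hill model obeys its identities and monotonicity", {
  expect_equal(hill_model(130, 130, 1, 0.95), 1 - 0.95 / 2)
  expect_equal(hill_model(130, 130, 1, 0.95), 0.525)
  expect_equal(hill_model(1e-9, 130, 1, 0.95), 1, tolerance = 1e-6)
  expect_equal(hill_model(1e12, 130, 1, 0.95), 1 - 0.95, tolerance = 1e-6)

  conc <- exp(seq(log(0.1), log(1e5), length.out = 50))
  for (nh in c(0.6, 1, 1.4)) {
    y <- hill_model(conc, 130, nh, 0.9)
    expect_false(is.unsorted(rev(y)))
  }
  expect_error(hill_model(-1, 130), "> 0")
  expect_error(hill_model(10, -5), "> 0")
})

test_that("noiseless data invert to the generating parameters", {
  conc <- exp(seq(log(1.3), log(13000), length.out = 8))
  pts <- dose_response_points(conc, hill_model(conc, 130, 1, 0.95))
  fit <- fit_hill(pts)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 130, tolerance = 1e-3)
  expect_equal(fit$n_h, 1, tolerance = 1e-3)
  expect_equal(fit$a, 0.95, tolerance = 1e-3)

  # fixed maximal inhibition
  pts1 <- dose_response_points(conc, hill_model(conc, 130, 1, 1))
  fit1 <- fit_hill(pts1, fix_a = TRUE)
  expect_equal(fit1$a, 1.0)
  expect_true(fit1$a_fixed)
  expect_equal(fit1$ic50, 130, tolerance = 1e-3)

  # a steeper, low-IC50 curve (EVT-101-like wild type)
  conc2 <- exp(seq(log(0.12), log(1200), length.out = 8))
  fit2 <- fit_hill(dose_response_points(conc2, hill_model(conc2, 12, 1.2, 0.9)))
  expect_equal(fit2$ic50, 12, tolerance = 1e-3)
  expect_equal(fit2$n_h, 1.2, tolerance = 1e-3)
})

test_that("fit residual at the optimum never exceeds the truth's residual", {
  set.seed(51)
  for (i in 1:5) {
    pts <- make_dose_response(130, 1, 0.95, noise_sd = 0.03, seed = i)
    fit <- fit_hill(pts)
    ssr_truth <- sum((pts$i_rel -
                        hill_model(pts$concentration_nM, 130, 1, 0.95))^2)
    expect_lte(fit$ssr, ssr_truth + 1e-12)
  }
})

test_that("undersized designs and unconverged inputs are rejected", {
  conc <- c(10, 100, 1000)
  pts <- dose_response_points(conc, hill_model(conc, 100, 1, 1))
  expect_error(fit_hill(pts), "4 distinct")          # a free: needs 4
  expect_s3_class(fit_hill(pts, fix_a = TRUE), "hill_fit")
  expect_error(fit_hill(pts[1:2, ], fix_a = TRUE), "3 distinct")

  good <- fit_hill(make_dose_response(100, seed = 1), fix_a = TRUE)
  bad <- good
  bad$converged <- FALSE
  err <- tryCatch(ic50_ratio(bad, good), error = identity)
  expect_s3_class(err, "ligmodes_numeric_error")
})

test_that("Monte-Carlo recovery at 3% noise is accurate and unbiased", {
  errs <- vapply(1:60, function(s) {
    pts <- make_dose_response(130, 1, 0.95, noise_sd = 0.03, seed = s)
    fit_hill(pts)$ic50 / 130 - 1
  }, 1.0)
  expect_lte(median(abs(errs)), 0.05)
  expect_lte(abs(mean(errs)), 0.02)
})

test_that("reference parameter sets are recovered across the IC50 range", {
  panel <- reference_ic50_panel(include_censored = FALSE)
  sets <- unique(panel[, c("ic50_nM", "max_inhib", "a_fixed")])
  sets <- sets[seq_len(min(nrow(sets), 17L)), ]
  hit <- 0L
  total <- 0L
  for (i in seq_len(nrow(sets))) {
    for (s in 1:5) {
      pts <- make_dose_response(sets$ic50_nM[i], 1, sets$max_inhib[i],
                                noise_sd = 0.03, seed = 1000 * i + s)
      fit <- fit_hill(pts, fix_a = sets$a_fixed[i])
      total <- total + 1L
      if (isTRUE(fit$converged) &&
          abs(fit$ic50 / sets$ic50_nM[i] - 1) <= 0.10) {
        hit <- hit + 1L
      }
    }
  }
  expect_gte(hit / total, 0.90)
})

test_that("ratios are exact arithmetic and scale-invariant", {
  mk <- function(ic50) {
    conc <- exp(seq(log(ic50 / 100), log(ic50 * 100), length.out = 8))
    fit_hill(dose_response_points(conc, hill_model(conc, ic50, 1, 1)),
             fix_a = TRUE)
  }
  wt <- mk(130)
  expect_equal(ic50_ratio(wt, wt), 1.0)
  expect_equal(ic50_ratio(mk(856), wt), 856 / 130, tolerance = 1e-4)
  expect_equal(format_fold_change(ic50_ratio(mk(856), wt)), "6.6")
  wt_evt <- mk(12)
  expect_equal(ic50_ratio(mk(9618), wt_evt), 801.5, tolerance = 0.1)
  expect_equal(format_fold_change(801.5), "800")

  # joint rescaling of concentrations leaves the ratio unchanged
  conc <- exp(seq(log(1), log(1e4), length.out = 8))
  f1 <- fit_hill(dose_response_points(conc, hill_model(conc, 50, 1, 1)),
                 fix_a = TRUE)
  f2 <- fit_hill(dose_response_points(conc, hill_model(conc, 400, 1, 1)),
                 fix_a = TRUE)
  g1 <- fit_hill(dose_response_points(conc * 7,
                                      hill_model(conc * 7, 350, 1, 1)),
                 fix_a = TRUE)
  g2 <- fit_hill(dose_response_points(conc * 7,
                                      hill_model(conc * 7, 2800, 1, 1)),
                 fix_a = TRUE)
  expect_equal(ic50_ratio(g2, g1), ic50_ratio(f2, f1), tolerance = 1e-6)
})

test_that("the reference panel is internally consistent", {
  panel <- reference_ic50_panel()
  expect_equal(nrow(panel), 35)  # 18 + 17 rows (one mutant not determined)
  wt_ife <- panel$ic50_nM[panel$receptor == "wt/wt" &
                            panel$compound == "ifenprodil"]
  wt_evt <- panel$ic50_nM[panel$receptor == "wt/wt" &
                            panel$compound == "EVT-101"]
  expect_equal(wt_ife, 130)
  expect_equal(wt_evt, 12)

  # printed ratios match ic50/wt at 2-significant-figure precision
  ok <- !panel$censored & !is.na(panel$ratio_printed)
  wt_of <- ifelse(panel$compound == "ifenprodil", wt_ife, wt_evt)
  implied <- panel$ic50_nM / wt_of
  expect_true(all(abs(implied[ok] - panel$ratio_printed[ok]) <
                    pmax(0.06, 0.05 * panel$ratio_printed[ok])))

  # censored rows carry the bound and are flagged
  expect_true(all(is.na(panel$ratio_printed[panel$censored])))
  expect_false(any(reference_ic50_panel(include_censored = FALSE)$censored))
  # fixed-a rows have maximal inhibition exactly 1
  expect_true(all(panel$max_inhib[panel$a_fixed] == 1))
})

test_that("dose-response CSV round-trips with the declared columns", {
  pts <- make_dose_response(130, 1, 0.95, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dose_csv(pts, f)
  hdr <- names(utils::read.csv(f))
  expect_equal(hdr, c("concentration_nM", "i_rel", "sd", "n"))
  back <- read_dose_csv(f)
  expect_equal(back$concentration_nM, pts$concentration_nM)
  expect_equal(back$i_rel, pts$i_rel)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_s3_class(tryCatch(read_dose_csv(bad), error = identity),
                  "ligmodes_parse_error")
})

test_that("inverse-variance weighting uses the replicate spread", {
  pts <- make_dose_response(130, 1, 0.95, seed = 9)
  fit_u <- fit_hill(pts)
  fit_w <- fit_hill(pts, weights = "inverse_variance")
  expect_true(fit_w$converged)
  # both recover the truth; weighting changes the estimate slightly
  expect_equal(fit_w$ic50, 130, tolerance = 0.15)
  expect_equal(fit_u$ic50, 130, tolerance = 0.15)

  pts0 <- pts
  pts0$sd[1] <- 0
  expect_error(fit_hill(pts0, weights = "inverse_variance"), "positive sd")
})
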