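test_that("QC thresholds are strict inequalities as printed", {
  # 69% accuracy, no nonresponses: accuracy rule fires
  qc <- qc_filter(qc_trials(69, 31, 0), "search")
  expect_false(qc$included)
  expect_identical(qc$reasons, "accuracy")

  # high accuracy but 16% nonresponse: nonresponse rule fires
  qc2 <- qc_filter(qc_trials(80, 4, 16), "search")
  expect_false(qc2$included)
  expect_identical(qc2$reasons, "nonresponse")

  # exactly 70% accuracy and exactly 15% nonresponse: retained
  qc3 <- qc_filter(qc_trials(119, 51, 30), "search")
  expect_true(qc3$included)
  expect_equal(qc3$accuracy, 0.7)
  expect_equal(qc3$nonresponse_rate, 0.15)

  expect_error(qc_filter(qc_trials(0, 0, 0), "search"),
               class = "retest_qc_error")
})

test_that("labeling QC scores accuracy at the overt endpoints only", {
  tr <- simulate_choices(0.05, 0.95, slope = 2, inflection = 8,
                         n_per_morph = 40, seed = 1)
  expect_true(qc_filter(tr, "labeling")$included)

  # flat observer: endpoint accuracy ~50% regardless of mid-continuum
  coin <- simulate_choices(0.5, 0.5, slope = 1, inflection = 8,
                           n_per_morph = 40, seed = 2)
  qc <- qc_filter(coin, "labeling")
  expect_false(qc$included)
  expect_identical(qc$reasons, "accuracy")
})

test_that("4PL fit recovers generating parameters and reads bias", {
  tr <- simulate_choices(0.05, 0.95, slope = 1.2, inflection = 6.5,
                         n_per_morph = 200, seed = 3)
  fit <- fit_4pl(tr)
  expect_true(fit$converged)
  expect_equal(fit$lower, 0.05, tolerance = 0.05)
  expect_equal(fit$upper, 0.95, tolerance = 0.05)
  expect_equal(fit$slope, 1.2, tolerance = 0.35)
  expect_equal(fit$inflection, 6.5, tolerance = 0.3)
  # binomial objective lands in the same place
  fitb <- fit_4pl(tr, objective = "binomial")
  expect_equal(fitb$inflection, fit$inflection, tolerance = 0.15)

  # hostile interpretation bias: inflection below the midpoint
  biased <- simulate_choices(0.05, 0.95, slope = 1, inflection = 5.5,
                             n_per_morph = 200, seed = 4)
  expect_lt(fit_4pl(biased)$inflection, 8)
})

test_that("4PL fit is invariant to trial order and duplication", {
  tr <- simulate_choices(0.05, 0.95, slope = 1, inflection = 8,
                         n_per_morph = 60, seed = 5)
  ref <- fit_4pl(tr)
  shuffled <- tr[withr::with_seed(6, sample(nrow(tr))), ]
  doubled <- dplyr::bind_rows(tr, tr)
  expect_equal(fit_4pl(shuffled)$inflection, ref$inflection)
  expect_equal(fit_4pl(doubled)$inflection, ref$inflection)
})

test_that("degenerate choice data is flagged rather than fitted", {
  tr <- simulate_choices(0.05, 0.95, slope = 1, inflection = 8,
                         n_per_morph = 5, seed = 7)
  tr$response <- "angry"
  fit <- fit_4pl(tr)
  expect_identical(fit$status, "degenerate")
  expect_false(fit$converged)
  expect_error(fit_4pl(tr[tr$morph == 1, ]),
               class = "retest_input_error")
})

test_that("RT morph slopes are exact OLS on noiseless profiles", {
  flat <- simulate_rt("labeling",
                      effects = list(baseline = 600, linear = 0,
                                     quadratic = 0), noise_sd = 0,
                      seed = 8)
  expect_equal(rt_morph_slopes(flat),
               tibble::tibble(linear = 0, quadratic = 0))

  lin <- simulate_rt("labeling",
                     effects = list(baseline = 600, linear = -2,
                                    quadratic = 0), noise_sd = 0,
                     seed = 9)
  sl <- rt_morph_slopes(lin)
  expect_equal(sl$linear, -2)
  expect_equal(sl$quadratic, 0, tolerance = 1e-10)

  # slower at the ambiguous center -> negative quadratic
  invu <- simulate_rt("labeling",
                      effects = list(baseline = 650, linear = 0,
                                     quadratic = -4), noise_sd = 0,
                      seed = 10)
  expect_lt(rt_morph_slopes(invu)$quadratic, 0)

  few <- dplyr::filter(lin, morph %in% 1:2)
  expect_error(rt_morph_slopes(few), class = "retest_input_error")
})

test_that("search metrics are exact on constructed RT structure", {
  s <- simulate_rt("search",
                   effects = list(baseline = 400, log_slope = 100,
                                  angry_offset = 0, happy_offset = 0),
                   noise_sd = 0, accuracy = 1, seed = 11)
  m <- search_rt_metrics(s)
  val <- function(nm) m$value[m$metric_name == nm]
  expect_equal(val("faces_minus_scramble_rt"), 0)
  expect_equal(val("logslope_angry"), 100)
  expect_equal(val("logslope_mean"), 100)

  # slower RT after angry faces -> positive faces-vs-scramble difference
  s2 <- simulate_rt("search",
                    effects = list(baseline = 400, log_slope = 80,
                                   angry_offset = 40, happy_offset = 40),
                    noise_sd = 0, accuracy = 1, seed = 12)
  expect_gt(search_rt_metrics(s2)$value[1], 0)

  # a missing condition yields NA metrics, not an error
  s3 <- dplyr::filter(s, condition != "scrambled")
  m3 <- search_rt_metrics(s3)
  expect_true(is.na(m3$value[m3$metric_name == "faces_minus_scramble_rt"]))
  expect_true(is.na(m3$value[m3$metric_name == "logslope_scramble"]))
  expect_equal(m3$value[m3$metric_name == "logslope_angry"], 100)
})

test_that("session_metrics applies QC and emits one row per metric", {
  add_rt <- function(tr, seed) {
    withr::with_seed(seed, dplyr::mutate(
      tr, rt = ifelse(is.na(response), NA_real_,
                      650 - 3 * (morph - 8)^2 +
                        rnorm(dplyr::n(), 0, 30))))
  }
  combined <- dplyr::bind_rows(
    add_rt(simulate_choices(0.05, 0.95, 1, 8, n_per_morph = 40,
                            subject_id = "s1", session = 1, seed = 13),
           16),
    add_rt(simulate_choices(0.05, 0.95, 1, 7, n_per_morph = 40,
                            subject_id = "s1", session = 2, seed = 14),
           17),
    add_rt(simulate_choices(0.5, 0.5, 1, 8, n_per_morph = 40,
                            subject_id = "s2", session = 1, seed = 15),
           18))
  out <- session_metrics(combined, "labeling")
  expect_identical(sort(unique(out$metrics$metric_name)),
                   sort(c("inflection", "psycho_slope", "rt_linear",
                          "rt_quadratic")))
  # s2 session 1 is the flat observer: excluded, no metric rows
  expect_false(out$qc$included[out$qc$subject_id == "s2"])
  expect_false("s2" %in% out$metrics$subject_id)
  expect_identical(nrow(out$metrics), 8L)
})

test_that("behavioral reliability recovers the metric's generating ICC", {
  des <- simulate_design(design_spec(n_subjects = 40), seed = 18)
  truth <- 0.6
  met <- withr::with_seed(19, {
    u <- rnorm(40, 0, sqrt(truth))
    des |>
      dplyr::mutate(metric_name = "inflection",
                    value = 8 + u[as.integer(factor(subject_id))] +
                      rnorm(dplyr::n(), 0, sqrt(1 - truth)))
  }) |>
    dplyr::select("subject_id", "session", "metric_name", "value")
  icc <- behavioral_reliability(met, des, seed = 20)
  expect_equal(icc$icc_mean, truth, tolerance = 0.15 / truth)

  # metric nearly constant within subject -> ICC near 1
  met1 <- des |>
    dplyr::mutate(metric_name = "m",
                  value = as.integer(factor(subject_id)) +
                    withr::with_seed(21, rnorm(dplyr::n(), 0, 0.01))) |>
    dplyr::select("subject_id", "session", "metric_name", "value")
  expect_gt(behavioral_reliability(met1, des, seed = 22)$icc_mean, 0.95)

  # pure-noise metric -> poor reliability
  met0 <- des |>
    dplyr::mutate(metric_name = "m",
                  value = withr::with_seed(23, rnorm(dplyr::n()))) |>
    dplyr::select("subject_id", "session", "metric_name", "value")
  noise_icc <- behavioral_reliability(met0, des, seed = 24)
  expect_lt(noise_icc$icc_mean, 0.4)
  expect_identical(noise_icc$bin, "poor")
})
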