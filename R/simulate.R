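# Synthetic-data generators reproducing the statistical structure of a
# multi-scanner test-retest study: crossed subject/session/scanner/region
# variance components, morph-continuum choice data, and task reaction times.

#' Design specification for a multi-session, two-scanner study
#'
#' Describes the sampling frame the generators emulate: `n_subjects`
#' participants scanned in up to `n_sessions` sessions on two scanners
#' following alternating orders (default `ABA`/`BAB`, pseudo-randomized and
#' balanced across participants), measured at `n_units` spatial units
#' (voxels or atlas regions; the study design uses 214 regions: 200
#' cortical parcels plus 14 subcortical regions).
#'
#' @param n_subjects Number of participants (default 40, the study sample).
#' @param n_sessions Sessions per participant (default 3; must be >= 2).
#' @param scanner_orders Character vector of scanner-order patterns, each a
#'   string of length `n_sessions` over labels `A`/`B`.
#' @param n_units Number of spatial units (default 214).
#' @param missing_session_rate Probability that a session beyond the second
#'   is lost to dropout/QC; in `[0, 1)`. Subjects always keep >= 2 sessions.
#' @param seed Default integer seed consumed by [simulate_design()].
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_subjects = 40, n_sessions = 3,
                        scanner_orders = c("ABA", "BAB"),
                        n_units = 214, missing_session_rate = 0,
                        seed = NULL) {
  stopifnot(n_subjects >= 1, n_sessions >= 2,
            missing_session_rate >= 0, missing_session_rate < 1)
  if (any(nchar(scanner_orders) != n_sessions) ||
      any(!grepl("^[AB]+$", scanner_orders))) {
    abort("Each scanner-order pattern must have one A/B label per session.",
          class = "retest_spec_error")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 scanner_orders = scanner_orders,
                 n_units = as.integer(n_units),
                 missing_session_rate = missing_session_rate,
                 seed = seed),
            class = "design_spec")
}

#' Effect sizes for the unit-level measurement generator
#'
#' Standard deviations (on the contrast scale) of the Gaussian random
#' components of the crossed design, plus fixed effects. Components mirror
#' the hierarchical decomposition the estimators assume: participant,
#' session, unit main effects and their pairwise interactions, a residual,
#' and optionally a random scanner term (used by the absolute-agreement
#' formulation, where systematic scanner differences count against
#' reliability).
#'
#' Defaults are chosen so that per-unit consistency ICCs fall in the fair
#' to good range and vary across units (through the participant-by-unit
#' component), spanning the conventional reporting bins.
#'
#' @param sd_participant,sd_session,sd_unit SDs of main-effect components.
#' @param sd_participant_x_session,sd_session_x_unit,sd_participant_x_unit
#'   SDs of the pairwise interaction components.
#' @param sd_residual Residual SD (must be > 0 unless all signal SDs are 0).
#' @param sd_scanner SD of a random scanner intercept (default 0; the
#'   scanner effect is a fixed offset unless this is set).
#' @param intercept,scanner_effect,order_effect Fixed effects; scanner and
#'   task-order effects are offsets for scanner `B` and order `second`.
#' @return A `generator_params` list.
#' @export
generator_params <- function(sd_participant = 0.6, sd_session = 0.1,
                             sd_unit = 0.3,
                             sd_participant_x_session = 0.25,
                             sd_session_x_unit = 0.1,
                             sd_participant_x_unit = 0.3,
                             sd_residual = 0.5, sd_scanner = 0,
                             intercept = 0.5, scanner_effect = 0.1,
                             order_effect = 0.05) {
  sds <- c(sd_participant, sd_session, sd_unit, sd_participant_x_session,
           sd_session_x_unit, sd_participant_x_unit, sd_residual,
           sd_scanner)
  # an all-zero parameter set is allowed: it generates the deterministic
  # fixed-effect surface (useful for exactness checks)
  stopifnot(all(is.finite(sds)), all(sds >= 0))
  structure(list(sd_participant = sd_participant, sd_session = sd_session,
                 sd_unit = sd_unit,
                 sd_participant_x_session = sd_participant_x_session,
                 sd_session_x_unit = sd_session_x_unit,
                 sd_participant_x_unit = sd_participant_x_unit,
                 sd_residual = sd_residual, sd_scanner = sd_scanner,
                 intercept = intercept, scanner_effect = scanner_effect,
                 order_effect = order_effect),
            class = "generator_params")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Simulate the subject-by-session design
#'
#' Assigns each subject a scanner-order pattern (balanced across the
#' supplied patterns up to rounding, pseudo-randomized) and a task order
#' (`first`/`second`, counterbalanced, constant within subject across
#' sessions), then drops sessions independently at
#' `missing_session_rate` while never letting a subject fall below two
#' sessions.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; the same seed reproduces the same design.
#' @return A tibble with one row per retained subject-session:
#'   `subject_id`, `session`, `scanner`, `task_order`.
#' @export
simulate_design <- function(spec = design_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "design_spec"))
  with_seed_if(seed, {
    n <- spec$n_subjects
    patterns <- sample(rep_len(spec$scanner_orders, n))
    orders <- sample(rep_len(c("first", "second"), n))
    des <- tidyr::expand_grid(
      subject = seq_len(n),
      session = seq_len(spec$n_sessions)
    ) |>
      dplyr::mutate(
        subject_id = sprintf("S%03d", .data$subject),
        scanner = substr(patterns[.data$subject], .data$session,
                         .data$session),
        task_order = orders[.data$subject]
      )
    if (spec$missing_session_rate > 0) {
      des <- des |>
        dplyr::group_by(.data$subject) |>
        dplyr::mutate(drop = keep_at_least_two(
          runif(dplyr::n()) < spec$missing_session_rate)) |>
        dplyr::ungroup() |>
        dplyr::filter(!.data$drop) |>
        dplyr::select(-"drop")
    }
    dplyr::select(des, "subject_id", "session", "scanner", "task_order")
  })
}

# Rescue randomly-chosen dropped sessions so >= 2 survive per subject.
keep_at_least_two <- function(drop) {
  while (sum(!drop) < 2L) {
    drop[sample(which(drop), 1L)] <- FALSE
  }
  drop
}

#' Simulate unit-level measurements from the crossed variance model
#'
#' Generates one measurement per subject x session x unit according to
#' \deqn{y_{ijk} = b_0 + b_1\,\mathrm{scanner} + b_2\,\mathrm{order}
#'   + \eta_j + \xi_i + \zeta_k + \gamma_{ij} + \mu_{ik} + \nu_{jk}
#'   + \varepsilon_{ijk},}
#' with sessions \eqn{i}, subjects \eqn{j}, units \eqn{k}; every random
#' term is drawn independently Gaussian with the SD given in `params`.
#' When `sd_scanner > 0` an additional random scanner intercept is added.
#'
#' When all interaction SDs are zero, the true consistency ICC of every
#' unit is `sd_participant^2 / (sd_participant^2 + sd_residual^2)`, which
#' downstream estimators are expected to recover.
#'
#' @param design A design tibble from [simulate_design()].
#' @param params A [generator_params()].
#' @param n_units Number of units; defaults to the 214-region layout.
#' @param seed Integer seed for reproducibility.
#' @return A reliability tibble (see [read_long_table()]).
#' @export
simulate_unit_data <- function(design, params = generator_params(),
                               n_units = 214, seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  with_seed_if(seed, {
    units <- sprintf("R%03d", seq_len(n_units))
    grid <- tidyr::expand_grid(
      design |> dplyr::select("subject_id", "session", "scanner",
                              "task_order"),
      unit_id = units
    )
    subj <- sort(unique(grid$subject_id))
    sess <- sort(unique(grid$session))
    eta <- setNames(rnorm(length(subj), 0, params$sd_participant), subj)
    xi <- setNames(rnorm(length(sess), 0, params$sd_session),
                   as.character(sess))
    zeta <- setNames(rnorm(n_units, 0, params$sd_unit), units)
    scan_re <- setNames(rnorm(2, 0, params$sd_scanner), c("A", "B"))
    gkey <- interaction(grid$subject_id, grid$session, drop = TRUE)
    gamma <- rnorm(nlevels(gkey), 0, params$sd_participant_x_session)
    mkey <- interaction(grid$session, grid$unit_id, drop = TRUE)
    mu <- rnorm(nlevels(mkey), 0, params$sd_session_x_unit)
    nkey <- interaction(grid$subject_id, grid$unit_id, drop = TRUE)
    nu <- rnorm(nlevels(nkey), 0, params$sd_participant_x_unit)
    grid$value <- unname(params$intercept +
      params$scanner_effect * (grid$scanner == "B") +
      params$order_effect * (grid$task_order == "second") +
      eta[grid$subject_id] + xi[as.character(grid$session)] +
      zeta[grid$unit_id] + scan_re[grid$scanner] +
      gamma[as.integer(gkey)] + mu[as.integer(mkey)] +
      nu[as.integer(nkey)] +
      rnorm(nrow(grid), 0, params$sd_residual))
    grid
  })
}

#' Simulate morph-continuum choice data from a logistic observer
#'
#' Draws Bernoulli "angry" responses at each of the 15 morph levels
#' (1 = prototypically angry, 15 = prototypically happy) from a
#' four-parameter logistic observer:
#' \deqn{P(\mathrm{angry}\mid m) = l + (u - l) /
#'   (1 + \exp(s\,(m - x_0))),}
#' decreasing along the angry-to-happy continuum. An inflection `x0` at the
#' continuum midpoint (morph 8) with symmetric asymptotes corresponds to an
#' unbiased observer; a lower inflection to a hostile interpretation bias.
#'
#' @param lower,upper Asymptotes, `0 <= lower < upper <= 1`.
#' @param slope Logistic slope, > 0.
#' @param inflection Inflection point in morph units, inside (1, 15).
#' @param n_per_morph Presentations per morph (default 30 as in a single
#'   session of the labeling task).
#' @param missing_rate Probability a trial receives no response.
#' @param subject_id,session Labels stamped on the output rows.
#' @param seed Integer seed.
#' @return A trial tibble with columns `subject_id`, `session`,
#'   `trial_index`, `condition` (`"morph"`), `morph`, `response`
#'   (`"angry"`/`"happy"`/NA), `correct` (defined at the overt endpoints
#'   only), `rt` (NA; use [simulate_rt()] for reaction times).
#' @export
simulate_choices <- function(lower = 0.05, upper = 0.95, slope = 1,
                             inflection = 8, n_per_morph = 30,
                             missing_rate = 0, subject_id = "S001",
                             session = 1L, seed = NULL) {
  # lower == upper is allowed as the degenerate flat curve (coin flips)
  if (!(lower >= 0 && lower <= upper && upper <= 1)) {
    abort("Require 0 <= lower <= upper <= 1.",
          class = "retest_param_error")
  }
  if (slope <= 0 || inflection <= 1 || inflection >= 15) {
    abort("Require slope > 0 and inflection inside (1, 15).",
          class = "retest_param_error")
  }
  with_seed_if(seed, {
    morphs <- rep(1:15, each = n_per_morph)
    p <- four_pl(morphs, lower, upper, slope, inflection)
    angry <- rbinom(length(morphs), 1L, p) == 1L
    resp <- ifelse(angry, "angry", "happy")
    miss <- runif(length(morphs)) < missing_rate
    resp[miss] <- NA_character_
    correct <- dplyr::case_when(
      morphs == 1L ~ resp == "angry",
      morphs == 15L ~ resp == "happy",
      TRUE ~ NA
    )
    tibble(subject_id = subject_id, session = as.integer(session),
           trial_index = seq_along(morphs), condition = "morph",
           morph = morphs, set_size = NA_integer_, response = resp,
           correct = correct, rt = NA_real_)
  })
}

four_pl <- function(m, lower, upper, slope, inflection) {
  lower + (upper - lower) / (1 + exp(slope * (m - inflection)))
}

#' Simulate task reaction times
#'
#' Emits one session of trials for either in-scanner task with the RT
#' structure the behavioral metrics assume.
#'
#' For `task = "search"` (visual search with emotional distractors) the
#' default design crosses 3 cue emotions (angry, happy, scrambled) with 3
#' set sizes (1, 5, 30 bars) at 27 trials per cell (243 trials), and
#' \eqn{RT = \mathrm{baseline} + \beta_{\log}\,\ln(\mathrm{set\ size}) +
#' \mathrm{emotion\ offset} + \epsilon}.
#'
#' For `task = "labeling"` (face-emotion labeling) the default design
#' presents each of 15 morphs 30 times plus 90 fixation trials (540 total),
#' with \eqn{RT = \mathrm{baseline} + \beta_1 (m - 8) +
#' \beta_2 (m - 8)^2 + \epsilon}; a negative quadratic coefficient encodes
#' slower responses to ambiguous mid-continuum morphs.
#'
#' @param task `"search"` or `"labeling"`.
#' @param effects Named list of coefficients. Search:
#'   `baseline`, `log_slope`, `angry_offset`, `happy_offset` (scramble is
#'   the reference). Labeling: `baseline`, `linear`, `quadratic`. Omitted
#'   entries use the defaults below.
#' @param noise_sd Gaussian RT noise SD in ms (>= 0).
#' @param accuracy Probability a trial is answered correctly.
#' @param n_per_cell Trials per condition cell (27 search, 30 labeling).
#' @param truncate If `TRUE`, censor RTs at the 2000 ms response window
#'   (trials exceeding it become nonresponses).
#' @param subject_id,session Labels stamped on the output rows.
#' @param seed Integer seed.
#' @return A trial tibble (see [simulate_choices()] for columns). Fixation
#'   trials in the labeling task have `condition = "fixation"` and no
#'   response.
#' @export
simulate_rt <- function(task = c("search", "labeling"), effects = list(),
                        noise_sd = 100, accuracy = 0.95,
                        n_per_cell = NULL, truncate = FALSE,
                        subject_id = "S001", session = 1L, seed = NULL) {
  task <- match.arg(task)
  stopifnot(noise_sd >= 0, accuracy >= 0, accuracy <= 1)
  with_seed_if(seed, {
    if (task == "search") {
      eff <- utils::modifyList(
        list(baseline = 500, log_slope = 80, angry_offset = 15,
             happy_offset = 5), effects)
      n_per_cell <- n_per_cell %||% 27L
      grid <- tidyr::expand_grid(
        condition = c("angry", "happy", "scrambled"),
        set_size = c(1L, 5L, 30L),
        rep = seq_len(n_per_cell)
      )
      offs <- c(angry = eff$angry_offset, happy = eff$happy_offset,
                scrambled = 0)
      rt <- eff$baseline + eff$log_slope * log(grid$set_size) +
        offs[grid$condition] + rnorm(nrow(grid), 0, noise_sd)
      morph <- NA_integer_
    } else {
      eff <- utils::modifyList(
        list(baseline = 600, linear = 0, quadratic = -3), effects)
      n_per_cell <- n_per_cell %||% 30L
      grid <- tibble(condition = "morph",
                     morph = rep(1:15, each = n_per_cell),
                     set_size = NA_integer_)
      grid <- dplyr::bind_rows(
        grid,
        tibble(condition = "fixation", morph = NA_integer_,
               set_size = NA_integer_, .rows = 90L)
      )
      ctr <- grid$morph - 8
      rt <- eff$baseline + eff$linear * ctr + eff$quadratic * ctr^2 +
        rnorm(nrow(grid), 0, noise_sd)
      rt[grid$condition == "fixation"] <- NA_real_
      morph <- grid$morph
    }
    correct <- runif(nrow(grid)) < accuracy
    out <- tibble(
      subject_id = subject_id, session = as.integer(session),
      trial_index = seq_len(nrow(grid)), condition = grid$condition,
      morph = if (task == "search") NA_integer_ else morph,
      set_size = if (task == "search") grid$set_size else NA_integer_,
      response = ifelse(grid$condition == "fixation", NA_character_,
                        ifelse(correct, "correct_key", "wrong_key")),
      correct = ifelse(grid$condition == "fixation", NA, correct),
      rt = rt
    )
    if (truncate) {
      over <- !is.na(out$rt) & out$rt > 2000
      out$rt[over] <- NA_real_
      out$response[over] <- NA_character_
      out$correct[over] <- NA
    }
    out
  })
}

#' Simulate a stationary signal time series
#'
#' Gaussian series with a fixed mean and noise SD, e.g. a voxel's BOLD
#' signal over volumes; its [compute_tsnr()] converges to
#' `mean_signal / noise_sd`.
#'
#' @param mean_signal Mean signal level.
#' @param noise_sd Noise SD (>= 0; 0 gives a constant series).
#' @param n_volumes Series length (>= 2).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_volumes`.
#' @export
simulate_timeseries <- function(mean_signal, noise_sd, n_volumes,
                                seed = NULL) {
  stopifnot(noise_sd >= 0, n_volumes >= 2)
  with_seed_if(seed, mean_signal + rnorm(n_volumes, 0, noise_sd))
}
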