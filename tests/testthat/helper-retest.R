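# Shared fixture builders. All data is generated in code at test time.

# Balanced one-or-more-unit dataset with a prescribed true consistency ICC
# (participant + residual variance only, no interactions or fixed
# covariate effects).
make_icc_data <- function(n_subjects, true_icc, n_units = 1,
                          design_seed = 1, data_seed = 2) {
  des <- simulate_design(design_spec(n_subjects = n_subjects),
                         seed = design_seed)
  simulate_unit_data(des, generator_params(
    sd_participant = sqrt(true_icc), sd_session = 0, sd_unit = 0,
    sd_participant_x_session = 0, sd_session_x_unit = 0,
    sd_participant_x_unit = 0, sd_residual = sqrt(1 - true_icc),
    scanner_effect = 0, order_effect = 0, intercept = 0),
    n_units = n_units, seed = data_seed)
}

# Minimal hand-built reliability table (2 subjects x 2 sessions x 1 unit).
tiny_reliability <- function() {
  tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 2),
    session = rep(1:2, 2),
    scanner = c("A", "B", "B", "A"),
    task_order = "first",
    unit_id = "u1",
    value = c(1.0, 1.2, 2.0, 2.1)
  )
}

# Trial table for one subject-session with exact accuracy / nonresponse
# composition (search task layout).
qc_trials <- function(n_correct, n_wrong, n_missing) {
  n <- n_correct + n_wrong + n_missing
  resp <- c(rep("correct_key", n_correct), rep("wrong_key", n_wrong),
            rep(NA_character_, n_missing))
  tibble::tibble(
    subject_id = "s1", session = 1L, trial_index = seq_len(n),
    condition = "angry", morph = NA_integer_, set_size = 5L,
    response = resp,
    correct = c(rep(TRUE, n_correct), rep(FALSE, n_wrong),
                rep(NA, n_missing)),
    rt = ifelse(is.na(resp), NA_real_, 500)
  )
}
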