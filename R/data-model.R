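# Long-format data model: reading, validation and writing of the tables the
# estimators consume. A reliability table has one row per
# subject x session x unit with a measurement (contrast value or tSNR); a
# trial table has one row per behavioral trial.

reliability_cols <- c("subject_id", "session", "scanner", "task_order",
                      "unit_id", "value")
trial_cols <- c("subject_id", "session", "trial_index", "condition",
                "morph", "set_size", "response", "correct", "rt")
trial_required <- c("subject_id", "session", "trial_index", "condition")

#' Read a long-format measurement or trial table
#'
#' Reads a UTF-8 CSV (or TSV) into the tidy long format used throughout the
#' package. The `reliability` schema expects one row per
#' subject x session x unit with columns `subject_id`, `session`, `scanner`,
#' `task_order`, `unit_id`, `value`; the `trial` schema expects trial-level
#' behavioral records with columns `subject_id`, `session`, `trial_index`,
#' `condition` and, where applicable, `morph`, `set_size`, `response`,
#' `correct`, `rt`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Either `"reliability"` or `"trial"`.
#' @param delim Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A tibble validated against the schema. For the reliability schema
#'   the key invariants (unique keys, scanner constant within session) are
#'   enforced; violations raise an error.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' d <- simulate_unit_data(simulate_design(design_spec(n_subjects = 3,
#'   n_units = 2, seed = 1)), seed = 2)
#' write_long_table(d, f)
#' read_long_table(f, "reliability")
read_long_table <- function(path, schema = c("reliability", "trial"),
                            delim = ",") {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "retest_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (schema == "reliability") {
    check_columns(raw, reliability_cols)
    out <- tibble(
      subject_id = raw$subject_id,
      session = parse_num_col(raw$session, "session", integer = TRUE),
      scanner = raw$scanner,
      task_order = raw$task_order,
      unit_id = raw$unit_id,
      value = parse_num_col(raw$value, "value")
    )
    stop_on_violations(validate_reliability(out))
    out
  } else {
    check_columns(raw, trial_required)
    out <- tibble(
      subject_id = raw$subject_id,
      session = parse_num_col(raw$session, "session", integer = TRUE),
      trial_index = parse_num_col(raw$trial_index, "trial_index",
                                  integer = TRUE),
      condition = raw$condition,
      morph = if ("morph" %in% names(raw))
        parse_num_col(raw$morph, "morph", integer = TRUE) else NA_integer_,
      set_size = if ("set_size" %in% names(raw))
        parse_num_col(raw$set_size, "set_size", integer = TRUE)
        else NA_integer_,
      response = if ("response" %in% names(raw)) raw$response
        else NA_character_,
      correct = if ("correct" %in% names(raw))
        as.logical(raw$correct) else NA,
      rt = if ("rt" %in% names(raw)) parse_num_col(raw$rt, "rt") else
        NA_real_
    )
    bad_morph <- which(!is.na(out$morph) & (out$morph < 1 | out$morph > 15))
    if (length(bad_morph)) {
      abort(paste0("morph level outside 1..15 at rows: ",
                   paste(utils::head(bad_morph, 5), collapse = ", ")),
            class = "retest_validation_error")
    }
    out
  }
}

#' @rdname read_long_table
#' @param data A tibble in one of the two schemas.
#' @export
write_long_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

check_columns <- function(raw, required) {
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "retest_schema_error")
  }
  invisible(TRUE)
}

parse_num_col <- function(x, name, integer = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    abort(paste0("Non-numeric value in column '", name, "' at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")),
          class = "retest_parse_error")
  }
  if (integer) as.integer(round(out)) else out
}

#' Validate a reliability table
#'
#' Checks the invariants of the long-format reliability schema: unique
#' (subject, session, unit) keys, scanner constant within a session, finite
#' values, and every subject observed in at least two distinct sessions
#' (subjects scanned only once carry no test-retest information and are
#' excluded from reliability analyses).
#'
#' @param data A reliability tibble (see [read_long_table()]).
#' @return A tibble of violations with columns `rule` and `detail`; zero rows
#'   means the table is valid. Single-session subjects are reported under
#'   rule `"single_session"`.
#' @seealso [drop_single_session()] to remove flagged subjects.
#' @export
validate_reliability <- function(data) {
  check_columns(data, reliability_cols)
  v <- list()
  dup <- data |>
    dplyr::count(.data$subject_id, .data$session, .data$unit_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    v[[length(v) + 1L]] <- tibble(
      rule = "duplicate_key",
      detail = paste0("(", dup$subject_id, ", ", dup$session, ", ",
                      dup$unit_id, ") x", dup$n)
    )
  }
  sc <- data |>
    dplyr::distinct(.data$subject_id, .data$session, .data$scanner) |>
    dplyr::count(.data$subject_id, .data$session) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(sc)) {
    v[[length(v) + 1L]] <- tibble(
      rule = "scanner_not_constant",
      detail = paste0("(", sc$subject_id, ", session ", sc$session, ")")
    )
  }
  nonfinite <- which(!is.finite(data$value))
  if (length(nonfinite)) {
    v[[length(v) + 1L]] <- tibble(
      rule = "nonfinite_value",
      detail = paste0("row ", nonfinite)
    )
  }
  single <- data |>
    dplyr::distinct(.data$subject_id, .data$session) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(single)) {
    v[[length(v) + 1L]] <- tibble(
      rule = "single_session",
      detail = single$subject_id
    )
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble(rule = character(), detail = character())
}

stop_on_violations <- function(report) {
  hard <- report[report$rule != "single_session", , drop = FALSE]
  if (nrow(hard)) {
    abort(paste0("Invalid reliability table: ",
                 paste(paste0(hard$rule, " [", hard$detail, "]"),
                       collapse = "; ")),
          class = "retest_validation_error")
  }
  invisible(TRUE)
}

#' Drop subjects with fewer than two sessions
#'
#' @param data A reliability tibble.
#' @return The table without subjects observed in a single session.
#' @export
drop_single_session <- function(data) {
  keep <- data |>
    dplyr::distinct(.data$subject_id, .data$session) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n >= 2L)
  dplyr::semi_join(data, keep, by = "subject_id")
}

#' Write an ICC result table
#'
#' Writes the standard per-unit ICC output (columns `unit_id`,
#' `formulation`, `icc_mean`, `icc_se`, `icc_q025`, `icc_q975`, `bin`) as
#' UTF-8 CSV at full precision.
#'
#' @param icc A tibble of per-unit ICC estimates.
#' @param path Output file path.
#' @export
write_icc_csv <- function(icc, path) {
  cols <- c("unit_id", "formulation", "icc_mean", "icc_se",
            "icc_q025", "icc_q975", "bin")
  present <- intersect(cols, names(icc))
  readr::write_csv(dplyr::select(icc, dplyr::all_of(present),
                                 dplyr::everything()),
                   path, progress = FALSE)
  invisible(path)
}
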