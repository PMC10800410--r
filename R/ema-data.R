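#' Default Likert ranges for the momentary variables
#'
#' Single-item stress and the PANAS subscale means are all on a 1-5 response
#' scale. Pass `ranges = NULL` to [read_ema_long()] to skip range validation,
#' e.g. for simulated panels on a standardized scale.
#'
#' @return Named list of `c(min, max)` ranges for `stress`, `na` and `pa`.
#' @export
likert_ranges <- function() {
  list(stress = c(1, 5), na = c(1, 5), pa = c(1, 5))
}

ema_columns <- function() c("person_id", "day", "slot", "stress", "na", "pa")

new_ema_panel <- function(df, n_days = 21L, slots_per_day = 3L) {
  out <- as_tibble(df)[ema_columns()]
  out$person_id <- as.character(out$person_id)
  out$day <- as.integer(out$day)
  structure(out,
    class = c("ema_panel", class(tibble())),
    n_days = as.integer(n_days),
    slots_per_day = as.integer(slots_per_day)
  )
}

panel_design <- function(panel) {
  n_days <- attr(panel, "n_days") %||% 21L
  list(
    n_days = n_days,
    slots_per_day = attr(panel, "slots_per_day") %||% 3L,
    n_occasions = n_days * (attr(panel, "slots_per_day") %||% 3L)
  )
}

panel_persons <- function(panel) unique(panel$person_id)

validate_ema_records <- function(df, n_days, ranges) {
  bad_day <- which(!is.na(df$day) & (df$day < 0L | df$day >= n_days))
  if (length(bad_day) > 0) {
    abort_integrity(sprintf(
      "`day` out of range [0, %d] in rows: %s", n_days - 1L,
      paste(utils::head(bad_day, 5), collapse = ", ")
    ))
  }
  bad_slot <- which(!df$slot %in% slot_levels())
  if (length(bad_slot) > 0) {
    abort_integrity(sprintf(
      "Unknown `slot` (expected %s) in rows: %s",
      paste(slot_levels(), collapse = "/"),
      paste(utils::head(bad_slot, 5), collapse = ", ")
    ))
  }
  key <- paste(df$person_id, df$day, df$slot)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    abort_integrity(sprintf(
      "Duplicate (person_id, day, slot) records in rows: %s",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  if (!is.null(ranges)) {
    for (v in c("stress", "na", "pa")) {
      r <- ranges[[v]]
      bad <- which(!is.na(df[[v]]) & (df[[v]] < r[1] | df[[v]] > r[2]))
      if (length(bad) > 0) {
        abort_integrity(sprintf(
          "`%s` outside [%g, %g] in rows: %s", v, r[1], r[2],
          paste(utils::head(bad, 5), collapse = ", ")
        ))
      }
    }
  }
  invisible(df)
}

#' Construct an experience-sampling panel from a data frame
#'
#' Validates and classes a long-format table of momentary records. Each row is
#' one answered prompt: a person, a study day (0-based), a within-day slot
#' (`morning`/`afternoon`/`evening`, anchored at 10:00/16:00/22:00) and the
#' momentary stress, negative-affect and positive-affect scores.
#'
#' @param records Data frame with columns `person_id`, `day`, `slot`,
#'   `stress`, `na`, `pa`.
#' @param n_days Number of study days in the design (default 21).
#' @param slots_per_day Prompts per day (default 3).
#' @param ranges Named list of admissible score ranges as in
#'   [likert_ranges()], or `NULL` to skip range checks.
#' @return A tibble of class `ema_panel`.
#' @export
ema_panel <- function(records, n_days = 21L, slots_per_day = 3L,
                      ranges = likert_ranges()) {
  records <- as_tibble(records)
  missing_cols <- setdiff(ema_columns(), names(records))
  if (length(missing_cols) > 0) {
    abort_format(sprintf(
      "Missing required column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  df <- new_ema_panel(records, n_days, slots_per_day)
  validate_ema_records(df, n_days, ranges)
  df
}

#' Read a long-format experience-sampling CSV
#'
#' Expects one row per answered prompt with columns `person_id, day, slot,
#' stress, na, pa` (missing scores as empty fields). Alternative column names
#' are mapped through `dialect`. Out-of-range scores raise an integrity error
#' naming the offending rows; they are never silently clamped.
#'
#' @param path Path to a CSV file.
#' @param dialect Optional named character vector mapping standard names to
#'   the file's column names, e.g. `c(person_id = "subj", na = "negaff")`.
#' @inheritParams ema_panel
#' @return A tibble of class `ema_panel`.
#' @export
read_ema_long <- function(path, dialect = NULL, n_days = 21L,
                          slots_per_day = 3L, ranges = likert_ranges()) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  # parse scores via strtod (correct rounding) rather than the reader's
  # fast path, so write/read cycles are bit-exact
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()
                         ))
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      src <- dialect[[std]]
      if (!src %in% names(raw)) {
        abort_format(sprintf(
          "Dialect maps `%s` to `%s`, which is not a column of %s",
          std, src, path
        ))
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  missing_cols <- setdiff(ema_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort_format(sprintf(
      "Missing required column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  for (v in c("stress", "na", "pa")) raw[[v]] <- as.numeric(raw[[v]])
  ema_panel(raw, n_days = n_days, slots_per_day = slots_per_day,
            ranges = ranges)
}

#' Write an experience-sampling panel to CSV
#'
#' Doubles are written in a shortest round-trippable representation, so a
#' write/read cycle reproduces scores bit-identically. Missing values are
#' written as empty fields.
#'
#' @param panel An `ema_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ema_long <- function(panel, path) {
  out <- as_tibble(panel)
  for (v in c("stress", "na", "pa")) {
    # 17 significant digits round-trip IEEE doubles exactly
    out[[v]] <- ifelse(is.na(out[[v]]), NA_character_,
                       sprintf("%.17g", out[[v]]))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Place a panel on an equally spaced 6-hour latent grid
#'
#' The three daily prompts (10:00, 16:00, 22:00) are 6, 6 and 12 hours apart.
#' Taking 6 hours as the time unit makes the within-day gaps unit steps and
#' the overnight gap exactly two units; one phantom (never-observable) cell at
#' the 04:00 position is inserted per night so that consecutive grid indices
#' are always one unit apart. A prompt on `day` at slot offset `s` (0/1/2)
#' maps to grid index `4 * day + s`; phantom cells sit at offset 3. For the
#' 21-day design each person spans indices 0..82: 83 cells of which 63 are
#' observable and 20 phantom.
#'
#' @param panel An `ema_panel`.
#' @return A tibble of class `ema_grid` with one row per person and grid cell:
#'   `person_id`, `grid_index`, `day`, `slot` (`NA` for phantom cells),
#'   `phantom`, `observed` (record present in the panel), and the `stress`,
#'   `na`, `pa` values (missing where unobserved or phantom).
#' @export
align_time_grid <- function(panel) {
  stopifnot(inherits(panel, "ema_panel"))
  design <- panel_design(panel)
  if (design$slots_per_day != 3L) {
    abort_param("align_time_grid() assumes the fixed 3-prompt daily schedule.")
  }
  n_cells <- 4L * design$n_days - 1L
  persons <- panel_persons(panel)

  grid <- tidyr::expand_grid(
    person_id = persons,
    grid_index = 0:(n_cells - 1L)
  )
  grid$day <- grid$grid_index %/% 4L
  offset <- grid$grid_index %% 4L
  grid$phantom <- offset == 3L
  grid$slot <- ifelse(grid$phantom, NA_character_, slot_levels()[offset + 1L])

  recs <- as_tibble(panel)
  recs$grid_index <- 4L * recs$day + slot_offset(recs$slot)
  recs$observed <- TRUE

  out <- left_join(
    grid,
    recs[c("person_id", "grid_index", "observed", "stress", "na", "pa")],
    by = c("person_id", "grid_index")
  )
  out$observed[is.na(out$observed)] <- FALSE
  out <- out[c("person_id", "grid_index", "day", "slot", "phantom",
               "observed", "stress", "na", "pa")]
  structure(out,
    class = c("ema_grid", class(tibble())),
    n_days = design$n_days,
    slots_per_day = design$slots_per_day
  )
}

#' Recover (day, slot) from grid indices
#'
#' Inverse of the mapping used by [align_time_grid()] for observable cells.
#'
#' @param grid_index Integer vector of grid indices.
#' @return Tibble with `day` and `slot` (`NA` slot for phantom positions).
#' @export
grid_to_day_slot <- function(grid_index) {
  offset <- grid_index %% 4L
  tibble(
    day = as.integer(grid_index %/% 4L),
    slot = ifelse(offset == 3L, NA_character_, slot_levels()[offset + 1L])
  )
}

#' Per-person missingness report
#'
#' For each person, the fraction of the design occasions (e.g. 63) lacking a
#' complete core record (any of stress/na/pa missing or the prompt
#' unanswered). Persons whose missing fraction exceeds `threshold` are flagged
#' for exclusion; the exclusion itself is a separate call
#' ([exclude_flagged()]).
#'
#' @param panel An `ema_panel`.
#' @param threshold Flagging threshold on the missing fraction (default 0.6).
#' @return Tibble with `person_id`, `n_design`, `n_complete`, `frac_missing`,
#'   `flagged`.
#' @export
validate_panel <- function(panel, threshold = 0.6) {
  stopifnot(inherits(panel, "ema_panel"))
  design <- panel_design(panel)
  complete <- as_tibble(panel) |>
    mutate(complete = !is.na(.data$stress) & !is.na(.data$na) &
             !is.na(.data$pa)) |>
    group_by(.data$person_id) |>
    summarise(n_complete = sum(.data$complete), .groups = "drop")
  # keep input person order
  complete <- complete[match(panel_persons(panel), complete$person_id), ]
  complete |>
    mutate(
      n_design = design$n_occasions,
      frac_missing = 1 - .data$n_complete / .data$n_design,
      flagged = .data$frac_missing > threshold
    ) |>
    select("person_id", "n_design", "n_complete", "frac_missing", "flagged")
}

#' Drop persons flagged by the missingness rule
#'
#' @inheritParams validate_panel
#' @return The panel restricted to persons at or below the threshold.
#' @export
exclude_flagged <- function(panel, threshold = 0.6) {
  report <- validate_panel(panel, threshold = threshold)
  keep <- report$person_id[!report$flagged]
  out <- as_tibble(panel) |> filter(.data$person_id %in% keep)
  design <- panel_design(panel)
  new_ema_panel(out, design$n_days, design$slots_per_day)
}
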