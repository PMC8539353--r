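#' Read per-seed mass trajectories from a long CSV table
#'
#' Expects one row per (seed, time) with columns `seed_id`, `time_h` (hours)
#' and `mass_g` (grams); optional columns `protrusion_h`, `diameter_mm` and
#' `sample_id` are carried through. Rows are sorted by seed and time and the
#' result is validated with [validate_trajectories()].
#'
#' @param path Path to a CSV file with a header row, comma separators and dot
#'   decimals.
#' @return A tibble with one row per recording, sorted by `seed_id`, `time_h`.
#' @seealso [write_trajectories()], [normalize_mass()]
#' @export
read_trajectories <- function(path) {
  # numbers are parsed with base strtod (exact to the last ulp) rather than
  # readr's fast path, so write/read round trips are bit-identical
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("seed_id", "time_h", "mass_g")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      paste0("trajectory file lacks required column(s): ",
             paste(missing, collapse = ", ")),
      class = "seedkin_validation_error"
    )
  }
  df <- df |>
    dplyr::mutate(
      dplyr::across(dplyr::any_of(c("time_h", "mass_g", "protrusion_h",
                                    "diameter_mm")), as.numeric)
    ) |>
    dplyr::arrange(.data$seed_id, .data$time_h)
  validate_trajectories(df)
}

#' Write trajectories back to CSV
#'
#' Numeric columns are written with round-trip precision, so
#' `read_trajectories(write_trajectories(x, f))` reproduces `x` exactly.
#'
#' @param data Trajectory tibble as returned by [read_trajectories()].
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_trajectories <- function(data, path) {
  # 17 significant digits guarantee binary round-trip of doubles; R's
  # formatter drops trailing noise whenever a shorter representation
  # reads back to the same value
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_,
             format(.x, digits = 17, trim = TRUE, scientific = FALSE))
  ))
  readr::write_csv(out, path, progress = FALSE, na = "NA")
  invisible(data)
}

#' Validate a trajectory table
#'
#' Checks, per seed: at least 4 recordings (a cubic spline needs 4 knots),
#' strictly increasing times starting at 0, and strictly positive masses.
#' Problems are aggregated across seeds and reported in a single error that
#' names every offending seed.
#'
#' @param data Long trajectory tibble (`seed_id`, `time_h`, `mass_g`, ...).
#' @return `data` invisibly reordered by seed and time, if valid.
#' @export
validate_trajectories <- function(data) {
  data <- dplyr::arrange(data, .data$seed_id, .data$time_h)
  issues <- data |>
    dplyr::group_by(.data$seed_id) |>
    dplyr::summarise(
      too_short = dplyr::n() < 4,
      dup_times = anyDuplicated(.data$time_h) > 0,
      decreasing = is.unsorted(.data$time_h, strictly = TRUE),
      no_zero = .data$time_h[1] != 0,
      bad_mass = any(!is.finite(.data$mass_g) | .data$mass_g <= 0),
      .groups = "drop"
    )
  msgs <- c(
    bad_seeds(issues, "too_short", "fewer than 4 recordings"),
    bad_seeds(issues, "dup_times", "duplicated times"),
    bad_seeds(issues, "decreasing", "non-increasing times"),
    bad_seeds(issues, "no_zero", "first recording not at t = 0"),
    bad_seeds(issues, "bad_mass", "non-positive or non-finite mass")
  )
  if (length(msgs) > 0) {
    abort(c("invalid trajectory data", msgs),
          class = "seedkin_validation_error")
  }
  invisible(data)
}

bad_seeds <- function(issues, col, what) {
  ids <- issues$seed_id[issues[[col]]]
  if (length(ids) == 0) return(character(0))
  paste0(what, ": ", paste(ids, collapse = ", "))
}

#' Read germination/seedling assay counts
#'
#' One row per sample with columns `sample_id`, `n_seeds`, `germinated`,
#' `viable`, `normal`, `abnormal`, `dead`, `hard`, `normal_after_ageing`,
#' `n_ageing`.
#'
#' @param path Path to the assay CSV.
#' @return A validated tibble, one row per sample.
#' @export
read_assays <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_assays(df)
}

#' Validate assay count tables
#'
#' Counts must be non-negative integers; `germinated`, `viable`,
#' `normal + abnormal` cannot exceed `n_seeds`; `normal_after_ageing` cannot
#' exceed `n_ageing`; germinated seeds are a subset of viable seeds.
#'
#' @param data Assay count tibble.
#' @return `data`, invisibly, if valid.
#' @export
validate_assays <- function(data) {
  required <- c("sample_id", "n_seeds", "germinated", "viable", "normal",
                "abnormal", "dead", "hard", "normal_after_ageing", "n_ageing")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("assay table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "seedkin_validation_error")
  }
  cnt <- dplyr::select(data, -"sample_id")
  problems <- character(0)
  if (any(as.matrix(cnt) < 0, na.rm = TRUE)) {
    problems <- c(problems, "negative counts present")
  }
  over <- data$germinated > data$n_seeds | data$viable > data$n_seeds |
    (data$normal + data$abnormal) > data$n_seeds |
    data$normal_after_ageing > data$n_ageing
  if (any(over, na.rm = TRUE)) {
    problems <- c(problems, paste0("counts exceed their denominator for sample(s): ",
                                   paste(data$sample_id[over], collapse = ", ")))
  }
  sub <- data$germinated > data$viable
  if (any(sub, na.rm = TRUE)) {
    problems <- c(problems, paste0("germinated > viable for sample(s): ",
                                   paste(data$sample_id[sub], collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(c("invalid assay data", problems), class = "seedkin_validation_error")
  }
  invisible(data)
}

#' Normalize seed mass by the initial (hygroscopic-equilibrium) mass
#'
#' Adds a dimensionless column `m = mass_g / mass_g[t = 0]` per seed, the
#' quantity whose derivatives define uptake velocity and acceleration. The
#' t = 0 recording is the seed's reference mass, so `m` starts at exactly 1
#' and is invariant to rescaling all masses of a seed by a common factor.
#'
#' @param data Trajectory tibble with `seed_id`, `time_h`, `mass_g`.
#' @return The input tibble with an added `m` column.
#' @export
normalize_mass <- function(data) {
  data |>
    dplyr::group_by(.data$seed_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time_h)
      if (d$time_h[1] != 0) {
        abort(paste0("seed ", key$seed_id, " has no t = 0 recording"),
              class = "seedkin_domain_error")
      }
      m0 <- d$mass_g[1]
      if (!is.finite(m0) || m0 <= 0) {
        abort(paste0("seed ", key$seed_id, " has non-positive initial mass"),
              class = "seedkin_domain_error")
      }
      dplyr::mutate(d, m = .data$mass_g / m0)
    }) |>
    dplyr::ungroup()
}

#' Classify sample quality from germinability and viability
#'
#' Three bands on the germinability (G) and viability (V) percentages:
#' `high` when both exceed 90, `low` when V <= 60 and G <= 50, and
#' `intermediate` otherwise.
#'
#' @param G,V Percentages in `[0, 100]` (vectorized).
#' @return A factor with levels `low`, `intermediate`, `high`.
#' @export
classify_quality <- function(G, V) {
  if (any(G < 0 | G > 100 | V < 0 | V > 100, na.rm = TRUE)) {
    abort("G and V must be percentages in [0, 100]",
          class = "seedkin_domain_error")
  }
  label <- dplyr::case_when(
    G > 90 & V > 90 ~ "high",
    G <= 50 & V <= 60 ~ "low",
    .default = "intermediate"
  )
  factor(label, levels = c("low", "intermediate", "high"))
}
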