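#' Biological activity of a seed sample
#'
#' Combines germinability and viability the way thermodynamic activity
#' combines concentration and an activity coefficient: `A = G * V / 100`,
#' with all three quantities in percent. `A` never exceeds the smaller of
#' `G` and `V`.
#'
#' @param G,V Germinability and viability percentages in `[0, 100]`
#'   (vectorized).
#' @return Biological activity in percent.
#' @examples
#' biological_activity(98, 98) # 96.04
#' @export
biological_activity <- function(G, V) {
  check_percent(G, "G"); check_percent(V, "V")
  G * V / 100
}

#' Seedling vigor index
#'
#' Ratio of normal seedlings obtained from stressed seeds (accelerated
#' ageing) to normal seedlings from non-stressed seeds:
#' `SVI = 100 * AA / NS`, in percent. Values above 100 indicate inconsistent
#' inputs (more normal seedlings after stress than without).
#'
#' @param AA Percent normal seedlings after the accelerated-ageing test.
#' @param NS Percent normal seedlings from non-stressed seeds; must be > 0.
#' @return SVI in percent (unrounded; reports round to 2 decimals).
#' @examples
#' svi(94, 98) # 95.918..., printed as 95.92
#' @export
svi <- function(AA, NS) {
  check_percent(AA, "AA"); check_percent(NS, "NS")
  if (any(NS == 0)) {
    abort("SVI is undefined when NS = 0", class = "seedkin_undefined_index")
  }
  100 * AA / NS
}

#' Seed-seedling transition yield index
#'
#' How many germinated seeds became normal seedlings:
#' `SSYI = 100 * NS / G`, in percent.
#'
#' @param NS Percent normal seedlings from non-stressed seeds.
#' @param G Germinability percent; must be > 0.
#' @return SSYI in percent.
#' @examples
#' ssyi(98, 98) # 100
#' @export
ssyi <- function(NS, G) {
  check_percent(NS, "NS"); check_percent(G, "G")
  if (any(G == 0)) {
    abort("SSYI is undefined when G = 0", class = "seedkin_undefined_index")
  }
  100 * NS / G
}

check_percent <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 100)) {
    abort(paste0(name, " must be a percentage in [0, 100]"),
          class = "seedkin_domain_error")
  }
  invisible(x)
}

#' Summarize assay counts into vigor measurements
#'
#' Converts raw counts to percentages (G, V, NS, AS, DS, AA), derives the
#' biological activity A, the seedling vigor index SVI and the seed-seedling
#' transition yield index SSYI, and classifies sample quality. Index values
#' that are undefined for a sample (G = 0 or NS = 0) are returned as `NA`
#' with the reason recorded in `flags` rather than raised as errors, so
#' degenerate samples survive batch processing.
#'
#' @param counts Assay tibble as returned by [read_assays()] or
#'   [simulate_assay()] (one row per sample).
#' @param digits Decimal places for the reported percentages (default 2,
#'   half-up).
#' @return A tibble with one row per sample: `sample_id`, `n_seeds`, `G`,
#'   `V`, `NS`, `AS`, `DS`, `AA`, `A`, `SVI`, `SSYI`, `quality`, `flags`.
#' @export
summarize_assay <- function(counts, digits = 2) {
  validate_assays(counts)
  counts |>
    dplyr::rowwise() |>
    dplyr::group_map(function(d, ...) {
      pct <- function(x, denom) 100 * x / denom
      G <- pct(d$germinated, d$n_seeds)
      V <- pct(d$viable, d$n_seeds)
      NS <- pct(d$normal, d$n_seeds)
      AS <- pct(d$abnormal, d$n_seeds)
      DS <- pct(d$dead, d$n_seeds)
      AA <- pct(d$normal_after_ageing, d$n_ageing)
      flags <- character(0)
      svi_v <- if (NS > 0) svi(AA, NS) else {
        flags <- c(flags, "svi_undefined"); NA_real_
      }
      ssyi_v <- if (G > 0) ssyi(NS, G) else {
        flags <- c(flags, "ssyi_undefined"); NA_real_
      }
      tibble::tibble(
        sample_id = d$sample_id, n_seeds = d$n_seeds,
        G = round_half_up(G, digits), V = round_half_up(V, digits),
        NS = round_half_up(NS, digits), AS = round_half_up(AS, digits),
        DS = round_half_up(DS, digits), AA = round_half_up(AA, digits),
        A = round_half_up(biological_activity(G, V), digits),
        SVI = round_half_up(svi_v, digits),
        SSYI = round_half_up(ssyi_v, digits),
        quality = classify_quality(G, V),
        flags = paste(flags, collapse = ";")
      )
    }) |>
    dplyr::bind_rows()
}
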