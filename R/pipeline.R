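#' Run the full water-dynamics analysis pipeline
#'
#' End-to-end orchestration: read/validate trajectories (and optionally
#' assays), compute per-seed and per-sample kinetics with bootstrap
#' confidence intervals, fit the spherical Fick model per sample (pooled mean
#' curve) and per seed, summarize assay counts into vigor measurements, and
#' screen residual-standardized correlations among per-seed kinetic traits.
#' Every stage writes a CSV into `out_dir`; a `summary.md` collects the
#' per-sample values in a single table and `run.json` records the
#' configuration, RNG seed, package version and completed stages. A stage
#' failure stops the run with an error after writing the manifest, so partial
#' outputs remain inspectable.
#'
#' @param trajectories Path to a trajectories CSV or a trajectory tibble.
#' @param assays Path to an assay CSV or an assay tibble; `NULL` runs the
#'   kinetics-only pipeline (no vigor stage).
#' @param out_dir Output directory (created if absent).
#' @param t_cut Imbibition window upper end in hours (default 3).
#' @param n_terms Fick series truncation (default 50).
#' @param B Bootstrap resamples (default 1000).
#' @param alpha_kinetics Significance for kinetic CIs (default 0.05).
#' @param alpha_corr Significance for correlation screening (default 0.01).
#' @param seed RNG seed controlling all resampling (default 1).
#' @return Invisibly, a list with the result tables and the manifest.
#' @export
run_pipeline <- function(trajectories, assays = NULL, out_dir,
                         t_cut = 3, n_terms = 50L, B = 1000L,
                         alpha_kinetics = 0.05, alpha_corr = 0.01,
                         seed = 1L) {
  stopifnot(alpha_kinetics > 0, alpha_kinetics < 1,
            alpha_corr > 0, alpha_corr < 1, B >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  completed <- character(0)
  manifest_path <- file.path(out_dir, "run.json")
  results <- list()

  write_manifest <- function() {
    jsonlite::write_json(
      list(
        package = "seedkin",
        version = as.character(utils::packageVersion("seedkin")),
        r_version = R.version.string,
        config = list(t_cut = t_cut, n_terms = n_terms, B = B,
                      alpha_kinetics = alpha_kinetics,
                      alpha_corr = alpha_corr, seed = seed),
        completed_stages = completed
      ),
      manifest_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      write_manifest()
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "seedkin_pipeline_error", parent = e)
    })
    completed <<- c(completed, name)
    out
  }

  traj <- stage("read", {
    if (is.character(trajectories)) read_trajectories(trajectories)
    else validate_trajectories(trajectories)
  })
  if (!"sample_id" %in% names(traj)) traj$sample_id <- "sample"

  results$kinetics <- stage("kinetics", seed_kinetics(traj))
  readr::write_csv(
    dplyr::select(results$kinetics, dplyr::any_of(
      c("sample_id", "seed_id", "n_obs", "tau", "v_m", "a_m"))),
    file.path(out_dir, "kinetics.csv"), progress = FALSE)

  results$cis <- stage("bootstrap", {
    sample_kinetics(traj, B = B, alpha = alpha_kinetics, seed = seed) |>
      dplyr::mutate(seed = seed)
  })
  readr::write_csv(results$cis, file.path(out_dir, "cis.csv"),
                   progress = FALSE)

  results$fick <- stage("fick", {
    traj |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_modify(function(d, key) {
        glance(fit_fick(d, t_cut = t_cut, n_terms = n_terms))
      }) |>
      dplyr::ungroup()
  })
  readr::write_csv(
    dplyr::select(results$fick, "sample_id", "D_over_rho2", "M_inf",
                  "n_terms", "t_cut", "sse", "converged"),
    file.path(out_dir, "fick.csv"), progress = FALSE)

  results$fick_per_seed <- stage("fick_per_seed", {
    traj |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_modify(function(d, key) {
        fit_fick(d, t_cut = t_cut, n_terms = n_terms, per_seed = TRUE)
      }) |>
      dplyr::ungroup()
  })

  if (!is.null(assays)) {
    results$vigor <- stage("vigor", {
      counts <- if (is.character(assays)) read_assays(assays) else {
        validate_assays(assays)
      }
      summarize_assay(counts)
    })
    readr::write_csv(results$vigor, file.path(out_dir, "vigor.csv"),
                     progress = FALSE)
  }

  results$correlations <- stage("correlate", {
    per_seed <- results$kinetics |>
      dplyr::inner_join(
        dplyr::select(results$fick_per_seed, "sample_id", "seed_id",
                      "D_over_rho2"),
        by = c("sample_id", "seed_id")
      ) |>
      dplyr::select("sample_id", "v_m", "a_m", "D_over_rho2")
    correlation_matrix(per_seed, sample = sample_id, alpha = alpha_corr)
  })
  readr::write_csv(results$correlations,
                   file.path(out_dir, "correlations.csv"), progress = FALSE)

  stage("summary", write_summary_md(results, file.path(out_dir, "summary.md")))
  write_manifest()
  invisible(c(results, list(manifest = list(completed_stages = completed))))
}

write_summary_md <- function(results, path) {
  fmt <- function(x, d = 4) formatC(x, digits = d, format = "g")
  lines <- c("# Water-dynamics pipeline summary", "",
             "## Germination sensu stricto", "",
             "| sample | D/rho^2 (1/h) | v_m (g H2O/h) | a_m (g H2O/h^2) |",
             "|---|---|---|---|")
  cis <- results$cis
  for (s in unique(results$fick$sample_id)) {
    fk <- dplyr::filter(results$fick, .data$sample_id == s)
    vv <- dplyr::filter(cis, .data$sample_id == s, .data$statistic == "v_m")
    aa <- dplyr::filter(cis, .data$sample_id == s, .data$statistic == "a_m")
    lines <- c(lines, sprintf(
      "| %s | %s | %s (%s; %s) | %s (%s; %s) |",
      s, fmt(fk$D_over_rho2), fmt(vv$point), fmt(vv$lower), fmt(vv$upper),
      fmt(aa$point), fmt(aa$lower), fmt(aa$upper)))
  }
  if (!is.null(results$vigor)) {
    v <- results$vigor
    lines <- c(lines, "", "## Embryo protrusion and post-germination", "",
               "| sample | G (%) | V (%) | A (%) | NS (%) | AS (%) | DS (%) | AA (%) | SVI (%) | SSYI (%) | quality |",
               "|---|---|---|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(v))) {
      lines <- c(lines, sprintf(
        "| %s | %.2f | %.2f | %.2f | %.2f | %.2f | %.2f | %.2f | %.2f | %.2f | %s |",
        v$sample_id[i], v$G[i], v$V[i], v$A[i], v$NS[i], v$AS[i], v$DS[i],
        v$AA[i], v$SVI[i], v$SSYI[i], as.character(v$quality[i])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
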