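# End-to-end pipeline orchestration: generate -> measure -> cohort-stats ->
# simulate -> report, with file artifacts and full seed determinism.

#' Pipeline run configuration
#'
#' @param seed Root seed; every stage derives its own child seed from it.
#' @param spacing Voxel spacing for mask export, mm.
#' @param out_dir Artifact directory.
#' @param thresholds Classification/diagnosis thresholds: `gothic`, `crenel`
#'   (A/T breakpoints), `haa` (proximal/distal/isthmus Di/AOA cutoffs,
#'   strictly decreasing), `coa` (fraction of reference diameter), `pspg`
#'   (diagnosis cutoffs with/without collaterals).
#' @param solver A [solver_settings()].
#' @param calibrate_pspg Target PSPG in mmHg for the `simulate` stage, or
#'   `NULL` to run the default network without calibration.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, spacing = 0.4, out_dir = tempdir(),
                       thresholds = list(gothic = 0.8, crenel = 0.6,
                                         haa = c(0.60, 0.50, 0.40),
                                         coa = 0.50, pspg = c(20, 10)),
                       solver = solver_settings(),
                       calibrate_pspg = 57.2) {
  stopifnot(thresholds$crenel < thresholds$gothic,
            all(diff(thresholds$haa) < 0),
            thresholds$pspg[1] > thresholds$pspg[2])
  structure(list(seed = as.integer(seed), spacing = spacing,
                 out_dir = out_dir, thresholds = thresholds,
                 solver = solver, calibrate_pspg = calibrate_pspg),
            class = "run_config")
}

#' Run one pipeline stage
#'
#' Stages: `generate` samples the three-group synthetic cohort from the
#' shipped summaries and writes the per-case parameters; `measure` builds
#' every case and writes the morphometric cohort table; `cohort-stats`
#' summarises that table into a three-group comparison; `simulate` runs
#' (optionally calibrates) the reference gothic CoA network and writes the
#' peak-systolic axial profile; `report` collects the artifacts into a
#' single JSON.  Outputs are deterministic given `config$seed`.
#'
#' @param command One of `generate`, `measure`, `cohort-stats`, `simulate`,
#'   `report`.
#' @param config A [run_config()].
#' @return Named character vector of the files written, invisibly.
#' @export
run_pipeline <- function(command = c("generate", "measure", "cohort-stats",
                                     "simulate", "report"),
                         config = run_config()) {
  command <- match.arg(command)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  need <- function(f) {
    if (!file.exists(p(f)))
      stop(sprintf("missing input '%s' for stage '%s': run the earlier ",
                   f, command), "stages first", call. = FALSE)
    p(f)
  }
  out <- switch(
    command,
    "generate" = {
      cohort <- sample_cohort(table1_summaries(), seed = config$seed)
      df <- do.call(rbind, lapply(seq_along(cohort), function(i) {
        cp <- cohort[[i]]
        data.frame(case = i, group = attr(cp, "group"),
                   arch_type = cp$arch_type,
                   height_A = cp$height_A, width_T = cp$width_T,
                   aao_dao_angle = cp$aao_dao_angle,
                   tao_dao_angle = cp$tao_dao_angle,
                   AOA = cp$level_diameters[["AOA"]],
                   D1 = cp$level_diameters[["D1"]],
                   D2 = cp$level_diameters[["D2"]],
                   D3 = cp$level_diameters[["D3"]],
                   D4 = cp$level_diameters[["D4"]],
                   D5 = cp$level_diameters[["D5"]],
                   limb_split = cp$limb_split,
                   age = attr(cp, "age"), weight = attr(cp, "weight"),
                   pspg = attr(cp, "pspg"))
      }))
      utils::write.csv(df, p("cohort_params.csv"), row.names = FALSE)
      c(params = p("cohort_params.csv"))
    },
    "measure" = {
      df <- utils::read.csv(need("cohort_params.csv"))
      meas <- lapply(seq_len(nrow(df)), function(i) {
        r <- df[i, ]
        cp <- arch_params(arch_type = r$arch_type, height_A = r$height_A,
                          width_T = r$width_T,
                          aao_dao_angle = r$aao_dao_angle,
                          tao_dao_angle = r$tao_dao_angle,
                          level_diameters = c(AOA = r$AOA, D1 = r$D1,
                                              D2 = r$D2, D3 = r$D3,
                                              D4 = r$D4, D5 = r$D5),
                          limb_split = r$limb_split,
                          seed = config$seed)
        measure_arch(build_arch(cp))
      })
      mdf <- measurements_to_df(meas, group = df$group)
      mdf$case <- df$case
      mdf$pspg <- df$pspg
      utils::write.csv(mdf, p("cohort_measurements.csv"), row.names = FALSE)
      c(measurements = p("cohort_measurements.csv"))
    },
    "cohort-stats" = {
      mdf <- utils::read.csv(need("cohort_measurements.csv"))
      tab <- build_table1(mdf, group_col = "group",
                          variables = c("D1_AOA", "D2_AOA", "D3_AOA",
                                        "D4_AOA", "D5_AOA", "AAO_DAO",
                                        "TAO_DAO", "A_T", "pspg"),
                          categorical = "coa_flag")
      utils::write.csv(tab, p("table1.csv"), row.names = FALSE)
      c(table1 = p("table1.csv"))
    },
    "simulate" = {
      if (!is.null(config$calibrate_pspg)) {
        cal <- calibrate_stenosis(gothic_coa_network(),
                                  settings = config$solver,
                                  target_pspg = config$calibrate_pspg)
        res <- cal$result; pr <- cal$profiles
        extra <- list(area_ratio = cal$area_ratio,
                      bernoulli_pspg = cal$bernoulli_pspg)
      } else {
        res <- solve_pulsatile(gothic_coa_network(),
                               settings = config$solver)
        pr <- extract_profiles(res)
        extra <- NULL
      }
      utils::write.csv(pr$profile[c("x_mm", "P_mmHg", "v_m_s", "segment")],
                       p("axial_profile.csv"), row.names = FALSE)
      utils::write.csv(data.frame(t_s = res$time, P_in_mmHg = res$P_in,
                                  res$outlet_flows),
                       p("flows.csv"), row.names = FALSE)
      smry <- c(list(delta_p_mmhg = pr$delta_p,
                     v_jet_m_s = pr$v_jet_peak,
                     proximal_v_range = pr$v_proximal_range,
                     p_inlet_mmhg = pr$p_inlet,
                     mass_error = res$mass_error,
                     converged_cycle = res$converged_cycle,
                     coa_diagnosed = pspg_criteria(
                       bernoulli_gradient(pr$v_jet_peak), FALSE)),
                extra)
      jsonlite::write_json(smry, p("hemo_summary.json"), auto_unbox = TRUE,
                           digits = NA)
      c(profile = p("axial_profile.csv"), flows = p("flows.csv"),
        summary = p("hemo_summary.json"))
    },
    "report" = {
      rep <- list(seed = config$seed)
      if (file.exists(p("table1.csv")))
        rep$table1 <- utils::read.csv(p("table1.csv"))
      if (file.exists(p("hemo_summary.json")))
        rep$hemodynamics <- jsonlite::read_json(p("hemo_summary.json"))
      jsonlite::write_json(rep, p("report.json"), auto_unbox = TRUE,
                           digits = NA)
      c(report = p("report.json"))
    })
  invisible(out)
}
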