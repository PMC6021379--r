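#' Configuration for an end-to-end pipeline run
#'
#' Bundles the master seed, cohort size and stage configurations for
#' [run_pipeline()].  Per-stage seeds are derived from the master seed and
#' the stage name via [derive_seed()], so each stage is reproducible in
#' isolation.
#'
#' @param master_seed Integer master seed.
#' @param n_participants Cohort size.
#' @param observer An [observer_model()] for the calibration stage.
#' @param staircase A [staircase_config()].
#' @param agent An [agent_config()].
#' @param attn_sd Between-participant attention variability (see
#'   [simulate_cohort()]).
#' @param presets Encoding specs for the beta-series stage (named list,
#'   default [encoding_presets()]).
#' @param evc An [evc_config()] for the policy-optimization stage.
#' @param out_dir Output directory (created if missing).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1L, n_participants = 8L,
                            observer = observer_model(),
                            staircase = staircase_config(),
                            agent = agent_config(), attn_sd = 0.1,
                            presets = encoding_presets(),
                            evc = evc_config(reward_m = 10, reward_c = 5),
                            out_dir = tempfile("evcddm-run-")) {
  stopifnot(n_participants >= 1, inherits(observer, "observer_model"),
            inherits(staircase, "staircase_config"),
            inherits(agent, "agent_config"), inherits(evc, "evc_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes, in order: psychometric calibration (one staircase per
#' attribute), task-design generation, cohort behavioral simulation,
#' behavioral analyses (choice, RT, psychometric table), beta-series
#' generation and neural analyses (encoding fits, weight-ratio test,
#' rostrocaudal contrasts), and EVC policy optimization.  All tables are
#' written as CSV, summary results as JSON, and a manifest records one
#' entry per stage (name, derived seed, output rows).  Outputs are
#' deterministic in the configuration: re-running with the same config
#' reproduces them byte-for-byte.
#'
#' Any stage failure aborts with the stage name attached (condition class
#' `evcddm_pipeline_error`).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and the manifest
#'   tibble.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()

  stage <- function(name, fun) {
    seed <- derive_seed(config$master_seed, name)
    out <- tryCatch(fun(seed), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "evcddm_pipeline_error")
    })
    manifest[[name]] <<- tibble::tibble(
      stage = name, seed = seed,
      rows = if (is.data.frame(out)) nrow(out) else NA_integer_)
    results[[name]] <<- out
    out
  }

  calib <- stage("calibrate", function(seed) {
    fits <- list(
      motion = run_staircase(config$observer, config$staircase,
                             seed = derive_seed(seed, "motion")),
      color = run_staircase(
        config$observer,
        within_config(config$staircase, start_coherence = 33),
        seed = derive_seed(seed, "color"))
    )
    purrr::imap_dfr(fits, function(f, nm) {
      dplyr::mutate(glance(f), attribute = nm, .before = 1L)
    })
  })
  write_stage_csv(calib, file.path(config$out_dir, "calibration.csv"))

  ladders <- dplyr::bind_rows(
    coherence_ladder(calib$threshold[calib$attribute == "motion"], "motion"),
    coherence_ladder(calib$threshold[calib$attribute == "color"], "color"))
  write_stage_csv(ladders, file.path(config$out_dir, "ladders.csv"))

  cohort <- stage("simulate", function(seed) {
    simulate_cohort(config$n_participants, config$agent,
                    attn_sd = config$attn_sd, seed = seed)
  })
  write_stage_csv(cohort, file.path(config$out_dir, "behavior.csv"))

  behav <- stage("analyze-behavior", function(seed) {
    unequal <- dplyr::filter(cohort, .data$epoch > 1)
    fits <- cohort_fits(unequal, fit_choice_model, frame = "reward")
    rt <- cohort_fits(unequal, fit_rt_model, frame = "reward")
    dplyr::bind_rows(choice = fits, rt = rt, .id = "model")
  })
  write_stage_csv(behav, file.path(config$out_dir, "behavior_fits.csv"))
  behav_group <- group_coefficient_tests(behav)
  write_stage_csv(behav_group, file.path(config$out_dir, "behavior_group.csv"))

  betas <- stage("betas", function(seed) {
    purrr::map_dfr(config$presets, function(sp) {
      generate_roi_betas(cohort, sp, seed = seed)
    })
  })
  write_stage_csv(betas, file.path(config$out_dir, "betas.csv"))

  neural <- stage("analyze-neural", function(seed) {
    unequal <- dplyr::filter(cohort, .data$epoch > 1)
    bsub <- dplyr::semi_join(betas, unequal, by = c("participant", "trial"))
    signed <- fit_encoding_model(
      dplyr::filter(bsub, .data$region %in% c("vmpfc", "dacc")),
      unequal, c("signed_high", "signed_low"))
    unsigned <- fit_encoding_model(
      dplyr::filter(bsub, grepl("^dacc_", .data$region)),
      unequal, c("unsigned_high", "unsigned_low"))
    list(signed = signed, unsigned = unsigned,
         ratio = attribute_weight_ratio(signed, "vmpfc"),
         axis = rostrocaudal_interaction(
           unsigned, rostral = c("dacc_rostral1", "dacc_rostral2"),
           caudal = c("dacc_caudal1", "dacc_caudal2")))
  })
  write_stage_csv(neural$signed$coefficients,
                  file.path(config$out_dir, "encoding_signed.csv"))
  write_stage_csv(neural$unsigned$coefficients,
                  file.path(config$out_dir, "encoding_unsigned.csv"))
  write_stage_csv(neural$axis, file.path(config$out_dir, "rostrocaudal.csv"))

  evc <- stage("evc", function(seed) optimize_policy(config$evc))
  write_stage_csv(evc$grid, file.path(config$out_dir, "evc_grid.csv"))

  jsonlite::write_json(
    list(
      calibration = calib,
      ratio_test = list(region = neural$ratio$region,
                        mean_ratio = neural$ratio$mean_ratio,
                        statistic = neural$ratio$statistic,
                        p.value = neural$ratio$p.value,
                        n = neural$ratio$n,
                        n_excluded = neural$ratio$n_excluded),
      evc_optimum = glance(evc)
    ),
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest_tbl <- dplyr::bind_rows(manifest)
  write_stage_csv(manifest_tbl, file.path(config$out_dir, "manifest.csv"))
  invisible(c(results, list(manifest = manifest_tbl,
                            out_dir = config$out_dir)))
}

# Shallow-update a config-like structured list, preserving its class.
within_config <- function(config, ...) {
  upd <- list(...)
  config[names(upd)] <- upd
  config
}
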