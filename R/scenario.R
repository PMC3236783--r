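#' Load a scenario configuration
#'
#' A scenario is a flat YAML file describing one complete in-silico
#' experiment: cohort composition, input-DNA model, template integrity,
#' noise, the three assays and the calling parameters. Four scenarios ship
#' with the package under `inst/extdata/scenarios/`: `normalized_intact`,
#' `nonnormalized`, `degraded` and `defb4_modal4`.
#'
#' @param config_path Path to a scenario YAML file, or the bare name of a
#'   bundled scenario (e.g. `"nonnormalized"`).
#' @param seed Optional integer overriding the seed stored in the file.
#' @return A list with elements `name`, `config` ([sim_config()]),
#'   `qpcr_target`, `qpcr_reference`, `prt` ([assay_profile()]s) and
#'   `calling` (list with `modal_cn`, `reference_copies`).
#' @export
load_scenario <- function(config_path, seed = NULL) {
  if (!file.exists(config_path)) {
    bundled <- system.file("extdata", "scenarios",
                           paste0(config_path, ".yaml"),
                           package = "cnvassay")
    if (nzchar(bundled)) config_path <- bundled
  }
  if (!file.exists(config_path)) {
    stop("scenario config not found: ", config_path, call. = FALSE)
  }
  y <- yaml::read_yaml(config_path)
  for (f in c("name", "seed", "cohort", "assays", "calling")) {
    if (is.null(y[[f]])) {
      stop("scenario config lacks field '", f, "'", call. = FALSE)
    }
  }
  ch <- y$cohort
  input <- switch(ch$input$type,
    normalized = input_normalized(ch$input$ng),
    lognormal = input_lognormal(ch$input$mean_ng,
                                sdlog = ch$input$sdlog %||% 0.8,
                                min_ng = ch$input$min_ng %||% 2,
                                max_ng = ch$input$max_ng %||% 120),
    stop("unknown input type: ", ch$input$type, call. = FALSE)
  )
  mfl <- if (identical(ch$degradation$type, "intact")) Inf else
    ch$degradation$mean_fragment_length
  noise <- y$noise %||% list()
  cfg <- sim_config(
    n_samples = ch$n_samples,
    cn_distribution = unlist(ch$cn_distribution),
    input_model = input,
    mean_fragment_length = mfl,
    ct_noise_sd = noise$ct_noise_sd %||% 0.08,
    area_noise_cv = noise$area_noise_cv %||% 0.05,
    n_replicates = y$n_replicates %||% 3,
    pcr_cycles = y$pcr_cycles %||% 26,
    seed = seed %||% y$seed,
    cohort_label = y$name
  )
  mk <- function(a, role) {
    assay_profile(a$name, efficiency = a$efficiency,
                  amplicon_length = a$amplicon_length, role = role,
                  paralog_length = a$paralog_length,
                  reference_copies = a$reference_copies)
  }
  list(name = y$name,
       config = cfg,
       qpcr_target = mk(y$assays$qpcr_target, "qpcr_target"),
       qpcr_reference = mk(y$assays$qpcr_reference, "qpcr_reference"),
       prt = mk(y$assays$prt, "prt_pair"),
       calling = list(modal_cn = y$calling$modal_cn,
                      reference_copies = y$calling$reference_copies %||% 2),
       source = normalizePath(config_path))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run a complete simulate-call-compare scenario
#'
#' Chains the whole workflow: simulate a cohort and both assays, call copy
#' numbers with the qPCR and PRT arms, and compare the two call sets. All
#' intermediates are written to `out_dir` as CSV/JSON, and a manifest
#' records the inputs, outputs, seed and configuration digest. Re-running
#' with the same configuration and seed reproduces the six output tables
#' byte for byte.
#'
#' @inheritParams load_scenario
#' @param out_dir Output directory (created if needed).
#' @return The run manifest, invisibly: list with `command`,
#'   `config_hash`, `seed`, `input_files`, `output_files`, `timestamp`,
#'   `package_version`.
#' @export
run_scenario <- function(config_path, out_dir, seed = NULL) {
  sc <- load_scenario(config_path, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("scenario stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", make_cohort(sc$config))
  ct_tab <- stage("simulate",
                  simulate_qpcr_plate(cohort, sc$qpcr_target,
                                      sc$qpcr_reference, sc$config))
  peak_tab <- stage("simulate", simulate_prt_run(cohort, sc$prt, sc$config))

  calls_q <- stage("call-qpcr", call_qpcr(ct_tab, sc$calling$modal_cn))
  calls_p <- stage("call-prt",
                   call_prt(peak_tab, sc$calling$modal_cn,
                            reference_copies = sc$calling$reference_copies))

  cmat <- stage("concord", concordance_matrix(calls_q, calls_p))
  report <- list(
    scenario = sc$name,
    n = cmat$n_total,
    concordance = c(concordance_rates(cmat),
                    list(matrix = cmat$counts,
                         rows = cmat$method_a, columns = cmat$method_b)),
    bland_altman = {
      common <- intersect(calls_q$sample_id, calls_p$sample_id)
      ba <- bland_altman(
        calls_q$continuous_cn[match(common, calls_q$sample_id)],
        calls_p$continuous_cn[match(common, calls_p$sample_id)])
      ba[c("mean_diff", "sd_diff", "loa_low", "loa_high",
           "frac_abs_diff_lt_1", "pearson_r", "n")]
    },
    chi2 = tryCatch(
      distribution_chi2(calls_q, calls_p)[c("chi2", "df", "p_value")],
      error = function(e) list(skipped = conditionMessage(e))
    )
  )

  outputs <- c(truth = "truth.csv", ct_table = "ct_table.csv",
               peak_table = "peak_table.csv", calls_qpcr = "calls_qpcr.csv",
               calls_prt = "calls_prt.csv", report = "report.json")
  paths <- file.path(out_dir, outputs)
  names(paths) <- names(outputs)
  write_table_csv(cohort[c("sample_id", "true_cn", "input_mass",
                           "mean_fragment_length")], paths["truth"])
  write_table_csv(ct_tab, paths["ct_table"])
  write_table_csv(peak_tab, paths["peak_table"])
  write_table_csv(calls_q, paths["calls_qpcr"])
  write_table_csv(calls_p, paths["calls_prt"])
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    command = "run-scenario",
    config_hash = unname(tools::md5sum(sc$source)),
    seed = sc$config$seed,
    input_files = sc$source,
    output_files = unname(paths),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(packageVersion("cnvassay"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
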