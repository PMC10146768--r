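#' Run the full modelling-to-risk pipeline
#'
#' Wires the stages together in their natural order: descriptor
#' screening, stepwise model fitting, validation, prediction, criteria
#' derivation and monitoring-site risk assessment. Every artifact is
#' written under `cfg$out_dir` and listed, with an MD5 content hash, in
#' the returned manifest; the run is deterministic for a fixed config.
#'
#' The config is a nested list (or a path to a YAML file with the same
#' structure):
#' \itemize{
#'   \item `seed` (required), `out_dir` (required),
#'     `train_fraction` (default 80/109)
#'   \item `descriptors`, `responses`: CSV paths; when omitted a
#'     synthetic dataset is generated from `seed`
#'   \item `screening`, `stepwise`: threshold overrides passed to
#'     [screening_config()] / [stepwise_config()]
#'   \item `criteria`: path to a criteria parameter YAML (see
#'     [derive_criteria()]); stage skipped when absent
#'   \item `monitoring`: monitoring CSV (`site_id`, `eec_ng_per_L`);
#'     stage skipped when absent. `awqc_ug_per_L` overrides the derived
#'     criterion as the risk denominator.
#' }
#'
#' @param cfg Config list or YAML path.
#' @return Invisibly, a data frame manifest (`artifact`, `path`, `md5`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg$seed) || is.null(cfg$out_dir)) {
    stop("config error: 'seed' and 'out_dir' are required")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  emit <- function(name, path) artifacts[[name]] <<- path
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- inputs -------------------------------------------------------
  stage("load", {
    if (!is.null(cfg$descriptors)) {
      table <- load_descriptor_table(cfg$descriptors)
      responses <- load_response_table(cfg$responses)
    } else {
      spec <- synthetic_spec(seed = cfg$seed)
      table <- generate_descriptor_matrix(spec)
      responses <- generate_response(table, spec)
    }
    dataset0 <- build_dataset(table, responses,
                              cfg$train_fraction %||% 80 / 109,
                              seed = cfg$seed)
  })

  # --- screen -------------------------------------------------------
  stage("screen", {
    scfg <- do.call(screening_config, cfg$screening %||% list())
    scr <- screen_descriptors(dataset0$table, scfg, dataset0$response)
    dataset <- dataset0
    dataset$table <- scr$table
    p <- file.path(cfg$out_dir, "screened.csv")
    write_descriptor_table(scr$table, p); emit("screened_table", p)
    p <- file.path(cfg$out_dir, "screening_report.json")
    jsonlite::write_json(list(counts = scr$report$counts,
                              removed = scr$report$removed,
                              seed = cfg$seed),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("screening_report", p)
  })

  # --- fit ----------------------------------------------------------
  stage("fit", {
    wcfg <- do.call(stepwise_config, cfg$stepwise %||% list())
    sw <- fit_stepwise(dataset, wcfg)
    p <- file.path(cfg$out_dir, "model.json")
    write_model_json(sw$model, p,
                     extra = list(step_log = sw$log, seed = cfg$seed,
                                  config = unclass(wcfg)))
    emit("model", p)
  })

  # --- validate -----------------------------------------------------
  stage("validate", {
    vrep <- validate_model(sw$model, dataset)
    p <- file.path(cfg$out_dir, "validation.json")
    jsonlite::write_json(
      list(n_terms = vrep$n_terms, r2_train = vrep$r2_train,
           r2_adj = vrep$r2_adj, r2_test = vrep$r2_test,
           rmse_train = vrep$rmse_train, rmsep = vrep$rmsep, dw = vrep$dw,
           vif = as.list(vrep$vif), q2 = vrep$q2, k = vrep$roy$k,
           k_prime = vrep$roy$k_prime, roy_pass = vrep$roy$pass,
           coverage = as.list(vrep$coverage), seed = cfg$seed),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("validation_report", p)
  })

  # --- predict ------------------------------------------------------
  stage("predict", {
    pred <- predict(sw$model, dataset$table)
    out <- data.frame(chem_id = rownames(dataset$table),
                      neg_log_rfd = unname(pred),
                      rfd = neg_log_to_rfd(unname(pred)))
    out$rfd_adopted <- adopt_rfd(out$rfd, cfg$report_sig_figs %||% 1L)
    p <- file.path(cfg$out_dir, "predictions.csv")
    write.csv(out, p, row.names = FALSE); emit("predictions", p)
  })

  # --- derive-awqc --------------------------------------------------
  awqc_value <- cfg$awqc_ug_per_L
  if (!is.null(cfg$criteria)) {
    stage("derive-awqc", {
      if (!file.exists(cfg$criteria)) {
        stop("criteria parameter file not found: ", cfg$criteria)
      }
      crit <- derive_criteria(yaml::read_yaml(cfg$criteria),
                              cfg$report_sig_figs %||% 1L)
      p <- file.path(cfg$out_dir, "awqc.json")
      jsonlite::write_json(crit, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      emit("awqc", p)
      if (is.null(awqc_value)) awqc_value <- crit$awqc_ug_per_L_adopted
    })
  }

  # --- assess-risk --------------------------------------------------
  if (!is.null(cfg$monitoring)) {
    stage("assess-risk", {
      if (is.null(awqc_value)) {
        stop("no criterion available: supply 'criteria' or 'awqc_ug_per_L'")
      }
      samples <- read.csv(cfg$monitoring, stringsAsFactors = FALSE)
      risk <- summarize_sites(samples, awqc_value)
      p <- file.path(cfg$out_dir, "risk.csv")
      write.csv(risk$per_site, p, row.names = FALSE); emit("risk_table", p)
      p <- file.path(cfg$out_dir, "risk_summary.json")
      jsonlite::write_json(
        list(fractions = as.list(risk$fractions),
             median_eec_ng_per_L = risk$median_eec_ng_per_L,
             median_hq = risk$median_hq,
             median_category = risk$median_category,
             awqc_ug_per_L = awqc_value, binning = risk$binning,
             seed = cfg$seed),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      emit("risk_summary", p)
    })
  }

  manifest <- data.frame(
    artifact = names(artifacts),
    path = unlist(artifacts, use.names = FALSE),
    md5 = unname(tools::md5sum(unlist(artifacts, use.names = FALSE))),
    stringsAsFactors = FALSE)
  write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}
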