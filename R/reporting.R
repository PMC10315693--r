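#' Run configuration
#'
#' Configuration for the pipeline entry point [sd_run()], either built
#' directly or read from a YAML file. Fields: `subcommand` (one of
#' `"simulate-dose"`, `"quantify-cohort"`, `"estimate-rate"`,
#' `"make-synthetic"`), `out_dir`, `seed`, and per-subcommand parameters
#' (`fixture`, `ratio`, `n_histories`, `activity`; `cohort_csv`,
#' `confidence`; `successes`, `n`; generator fields of
#' [cohort_gen_spec()]).
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config Named list of configuration fields.
#' @export
validate_run_config <- function(config) {
  subs <- c("simulate-dose", "quantify-cohort", "estimate-rate",
            "make-synthetic")
  if (is.null(config$subcommand) || !config$subcommand %in% subs)
    stop(sprintf("usage error: subcommand must be one of %s",
                 paste(subs, collapse = ", ")))
  if (is.null(config$out_dir)) config$out_dir <- "."
  if (is.null(config$seed)) config$seed <- 1L
  if (identical(config$subcommand, "simulate-dose")) {
    if (is.null(config$n_histories)) config$n_histories <- 1e6
    if (config$n_histories < 1e4)
      stop("usage error: dose runs need n_histories >= 1e4")
    if (is.null(config$fixture)) config$fixture <- "patientE"
    if (is.null(config$ratio)) config$ratio <- 10
  }
  structure(config, class = "run_config")
}

# configuration hash recorded in output metadata
.config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 251)) %%
            .Machine$integer.max)
}

.run_metadata <- function(config) {
  list(package = "skindose",
       version = as.character(utils::packageVersion("skindose")),
       seed = config$seed,
       config_hash = .config_hash(config),
       subcommand = config$subcommand)
}

#' Pipeline entry point
#'
#' Dispatches a [read_run_config()] configuration: `simulate-dose` writes
#' the dose report (JSON + CSV) and layer/mode figures; `quantify-cohort`
#' writes per-patient assessments, the cohort summary and the net-activity
#' histogram; `estimate-rate` writes the exact binomial rate interval;
#' `make-synthetic` writes a generated cohort CSV together with a YAML
#' echo of the generator spec. Every run writes `run_metadata.json` with
#' the seed, a configuration hash and the package version. A thin Rscript
#' wrapper is installed at `system.file("cli", "skindose.R")`.
#'
#' @param config A `run_config`, a list, or a YAML path.
#' @return Invisibly, a named list of the file paths written.
#' @export
sd_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  written <- list()

  if (config$subcommand == "simulate-dose") {
    case <- generate_infiltration_case(
      config$fixture,
      activity = config$activity,
      nuclide = if (is.null(config$nuclide)) "F-18" else config$nuclide,
      ratio = config$ratio,
      effective_half_life = if (is.null(config$effective_half_life)) 30
                            else config$effective_half_life)
    if (!is.null(config$epidermis_thickness))
      case$phantom <- build_default_phantom(config$epidermis_thickness)
    rep <- run_dose_simulation(case$scenario, case$phantom,
                               n_histories = config$n_histories,
                               seed = config$seed)
    write_dose_report(rep, out("dose_report.json"))
    write_dose_report(rep, out("dose_report.csv"))
    p1 <- plot_dose_by_layer(rep)
    ggplot2::ggsave(out("dose_by_layer.png"), p1, width = 7, height = 4,
                    dpi = 150)
    p2 <- plot_mode_breakdown(rep)
    ggplot2::ggsave(out("dose_mode_breakdown.png"), p2, width = 7,
                    height = 4, dpi = 150)
    written <- list(report_json = out("dose_report.json"),
                    report_csv = out("dose_report.csv"),
                    fig_layers = out("dose_by_layer.png"),
                    fig_modes = out("dose_mode_breakdown.png"))
  } else if (config$subcommand == "quantify-cohort") {
    if (is.null(config$cohort_csv))
      stop("usage error: quantify-cohort needs cohort_csv")
    records <- read_cohort_csv(config$cohort_csv)
    conf <- if (is.null(config$confidence)) 0.95 else config$confidence
    summ <- summarize_cohort(records, conf)
    ass <- do.call(rbind, lapply(records, function(r) {
      a <- assess_infiltration(r)
      data.frame(id = as.character(a$id),
                 net_activity_at_imaging_bq = a$net_activity_at_imaging,
                 net_activity_at_injection_bq = a$net_activity_at_injection,
                 percent_injected = a$percent_injected,
                 category = as.character(a$category))
    }))
    write.csv(ass, out("assessments.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n = summ$n, injected_mean_MBq = summ$injected_mean_MBq,
           injected_sd_MBq = summ$injected_sd_MBq,
           category_counts = as.list(summ$category_counts),
           rate_interval = unclass(summ$rate_interval)),
      out("cohort_summary.json"), auto_unbox = TRUE, digits = NA)
    ggplot2::ggsave(out("net_activity_hist.png"),
                    plot_net_activity(summ), width = 7, height = 4,
                    dpi = 150)
    written <- list(assessments = out("assessments.csv"),
                    summary = out("cohort_summary.json"),
                    fig_hist = out("net_activity_hist.png"))
  } else if (config$subcommand == "estimate-rate") {
    ci <- exact_binomial_ci(config$successes, config$n,
                            if (is.null(config$confidence)) 0.95
                            else config$confidence)
    jsonlite::write_json(unclass(ci), out("rate_interval.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- list(rate = out("rate_interval.json"))
  } else if (config$subcommand == "make-synthetic") {
    fields <- intersect(names(config), names(formals(cohort_gen_spec)))
    spec <- do.call(cohort_gen_spec, config[fields])
    records <- generate_cohort(spec)
    write_cohort_csv(records, out("synthetic_cohort.csv"))
    yaml::write_yaml(unclass(spec), out("cohort_spec.yaml"))
    written <- list(cohort = out("synthetic_cohort.csv"),
                    spec_echo = out("cohort_spec.yaml"))
  }

  jsonlite::write_json(.run_metadata(config), out("run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  written$metadata <- out("run_metadata.json")
  invisible(written)
}

# --- figures --------------------------------------------------------------

#' Dose-by-layer figure
#'
#' @param report A `dose_report`.
#' @return A ggplot object: absorbed dose per skin layer (log scale).
#' @export
plot_dose_by_layer <- function(report) {
  df <- report$per_layer
  df$layer <- factor(df$layer, levels = df$layer)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer,
                                   y = .data$dose_Gy * 1e3)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "absorbed dose (mGy)",
      title = sprintf("%s, %.3g MBq infiltrated, %g:1 partition",
                      report$meta$nuclide,
                      report$meta$total_activity_MBq, report$meta$ratio)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Emission-mode breakdown figure
#'
#' @param report A `dose_report`.
#' @return A ggplot object: per-layer dose split into beta / photon /
#'   discrete-electron components (per MBq infiltrated).
#' @export
plot_mode_breakdown <- function(report) {
  md <- report$mode_dose_per_MBq
  df <- data.frame(
    layer = rep(rownames(md), ncol(md)),
    mode = rep(colnames(md), each = nrow(md)),
    dose = as.vector(md))
  df$layer <- factor(df$layer, levels = rownames(md))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$dose * 1e3,
                                   fill = .data$mode)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "dose per activity (mGy/MBq)",
                  fill = "emission mode") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Net injection-site activity histogram
#'
#' @param summary A `cohort_summary`.
#' @return A ggplot object: distribution of decay-corrected net
#'   injection-site activity across the cohort.
#' @export
plot_net_activity <- function(summary) {
  df <- data.frame(net_kBq = summary$net_activity_Bq / 1e3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$net_kBq)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue",
                            colour = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "net injection-site activity (kBq)",
                  y = "patients") +
    ggplot2::theme_minimal()
}
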