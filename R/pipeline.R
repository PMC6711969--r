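# Orchestration: run the stages (simulate | filter | events | rom | enviro |
# gam | report) from one structured config and collect a run manifest.
# Reruns with an identical config are identical because every stochastic
# stage is seeded from the config.

#' Run the telemetry analysis pipeline
#'
#' Executes the requested stages in dependency order on either a synthetic
#' study (the default; see \code{\link{sim_config}}) or files named in
#' \code{config$inputs} (\code{detections}, \code{stations}, \code{tags}
#' paths read by the package's readers). Parameter blocks:
#' \code{config$qc} (\code{max_speed}, \code{orphan_window}),
#' \code{config$events} (see \code{\link{event_params}}),
#' \code{config$gam} (\code{edf_linear_threshold}).
#'
#' @param config list; unrecognized entries are ignored. \code{config$sim}
#'   may hold \code{\link{sim_config}} arguments (e.g. \code{seed},
#'   \code{n_tags}).
#' @param stages subset of
#'   \code{c("simulate","filter","events","rom","enviro","gam","report")}.
#'   Stages are run in canonical order; dependencies of a requested stage
#'   are run implicitly.
#' @param out_dir optional directory for CSV outputs (events, covariate
#'   table, fit summary, manifest).
#' @return list with the artifacts of every executed stage plus
#'   \code{manifest} (data.frame: stage, rows, seconds).
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "filter", "events", "rom",
                                    "enviro", "gam", "report"),
                         out_dir = NULL) {
  all_stages <- c("simulate", "filter", "events", "rom", "enviro", "gam",
                  "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- max(match(stages, all_stages))
  stages <- all_stages[seq_len(need)]   # dependency closure (linear chain)
  res <- list()
  manifest <- list()
  tick <- function(stage, rows, t0) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, rows = rows, seconds = round(as.numeric(
        difftime(Sys.time(), t0, units = "secs")), 2))
  }

  # inputs
  t0 <- Sys.time()
  if (!is.null(config$inputs)) {
    ins <- config$inputs
    for (p in unlist(ins))
      if (is.character(p) && !file.exists(p))
        stop("input path does not exist: ", p)
    res$stations <- read_stations(ins$stations)
    res$detections <- read_detections(ins$detections)
    if (!is.null(ins$tags)) res$tags <- read_tags(ins$tags)
    res$env <- NULL
    tick("load", nrow(res$detections), t0)
  } else if ("simulate" %in% stages) {
    cfg <- do.call(sim_config, config$sim %||% list())
    sim <- simulate_telemetry(cfg)
    res$sim_config <- cfg
    res$stations <- sim$stations
    res$tags <- sim$tags
    res$env <- sim$env
    res$detections <- sim$detections
    res$truth <- sim$truth
    tick("simulate", nrow(res$detections), t0)
  }
  res$dist_matrix <- build_distance_matrix(res$stations)

  if ("filter" %in% stages) {
    t0 <- Sys.time()
    qc_args <- config$qc %||% list()
    qc <- filter_spurious(res$detections, res$dist_matrix,
                          max_speed = qc_args$max_speed %||% 2.0,
                          orphan_window = qc_args$orphan_window %||% 24)
    res$detections <- qc$detections
    res$qc_report <- qc$report
    tick("filter", nrow(res$detections), t0)
  }

  if ("events" %in% stages) {
    t0 <- Sys.time()
    pars <- do.call(event_params, config$events %||% list())
    res$event_params <- pars
    res$bouts <- build_bouts(res$detections, pars)
    ev <- classify_events(res$bouts, res$dist_matrix, pars)
    res$residence <- ev$residence
    res$movements <- ev$movements
    res$residence_summary <- summarize_residence(ev$residence)
    tick("events", nrow(res$bouts), t0)
  }

  if ("rom" %in% stages) {
    t0 <- Sys.time()
    if (nrow(res$movements)) {
      res$rom_summary <- rom_summary(res$movements)
      res$min_transit_hours <- min_transit_time(res$dist_matrix,
                                                res$rom_summary$max)
    }
    tick("rom", NROW(res$movements), t0)
  }

  if ("enviro" %in% stages) {
    t0 <- Sys.time()
    span <- if (!is.null(res$sim_config))
      c(res$sim_config$start, res$sim_config$end)
    else as.Date(range(local_day(res$detections$timestamp)))
    udc <- unique_daily_count(res$detections, span = span)
    daily <- if (!is.null(res$env))
      lapply(res$env, daily_mean)
    else stop("enviro stage needs environmental series (synthetic run)")
    ref <- c(mean(res$stations$lon), mean(res$stations$lat))
    res$covariates <- build_covariate_table(udc, daily, ref[1], ref[2])
    tick("enviro", nrow(res$covariates), t0)
  }

  if ("gam" %in% stages) {
    t0 <- Sys.time()
    tab <- res$covariates
    cand <- c("HR_discharge", "M",
              intersect(c("sst_NH", "sst_OS"), names(tab)))
    cand <- drop_correlated(tab, cand, prefer = "HR_temp")
    full_terms <- c(list(smooth2_term("HR_temp", "P")),
                    lapply(setdiff(cand, "HR_temp"), smooth_term))
    sel <- backwards_select(
      tab, full_terms,
      edf_linear_threshold = (config$gam %||% list())$edf_linear_threshold
      %||% 1.5)
    res$gam_full <- sel$full
    res$gam_final <- sel$final
    res$gam_trace <- sel$trace
    res$gam_ftest <- f_ratio_test(sel$final, sel$full)
    has2 <- any(vapply(sel$final$terms,
                       function(t) t$kind == "smooth2", logical(1)))
    if (has2) res$surface <- interaction_surface(sel$final)
    tick("gam", sel$final$n, t0)
  }

  if ("report" %in% stages) {
    t0 <- Sys.time()
    res$report <- telemetry_report(res)
    tick("report", length(res$report), t0)
  }

  res$manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, nm) if (!is.null(x))
      write.csv(x, file.path(out_dir, nm), row.names = FALSE)
    wr(res$residence, "residence_events.csv")
    wr(res$movements, "movement_events.csv")
    wr(res$covariates, "covariate_table.csv")
    wr(res$gam_trace, "gam_selection_trace.csv")
    wr(res$surface, "interaction_surface.csv")
    wr(res$manifest, "manifest.csv")
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary report of a pipeline run
#'
#' Per-station detection and unique-tag counts, monthly unique counts,
#' residence and movement summaries, and the selected model's headline
#' statistics.
#'
#' @param res result list from \code{\link{run_pipeline}}.
#' @return named list of data.frames / lists; sections whose stage did not
#'   run are omitted (with a message).
#' @export
telemetry_report <- function(res) {
  rep <- list()
  if (!is.null(res$detections) && nrow(res$detections)) {
    det <- res$detections
    per_station <- aggregate(
      list(n_detections = det$tag_id),
      list(station_id = det$station_id), length)
    per_station$n_unique <- vapply(
      per_station$station_id,
      function(s) length(unique(det$tag_id[det$station_id == s])),
      integer(1))
    rep$per_station <- per_station
    mon <- format(local_day(det$timestamp), "%Y-%m")
    rep$monthly_udc <- aggregate(
      list(unique_tags = det$tag_id), list(month = mon),
      function(x) length(unique(x)))
  } else message("report: no detections section")
  if (!is.null(res$residence_summary))
    rep$residence <- res$residence_summary
  else message("report: no residence section")
  if (!is.null(res$rom_summary)) {
    rep$rom <- res$rom_summary
    rep$min_transit_hours <- res$min_transit_hours
  } else message("report: no movement section")
  if (!is.null(res$gam_final)) {
    f <- res$gam_final
    rep$gam <- list(
      terms = vapply(f$terms, term_label, character(1)),
      dev_expl = f$dev_expl, gcv = f$gcv, phi = f$phi, n = f$n,
      f_test = res$gam_ftest)
  } else message("report: no model section")
  rep
}
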