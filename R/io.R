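#' Read and write the tabular exchange formats
#'
#' Thin CSV wrappers fixing the column contracts used across the package:
#' occurrence points (`x,y,date,species`), vegetation surveys
#' (`plot,habitat_class,quadrat,stems`) and flight-arena trial logs
#' (`id,origin,trial,tunnel,behaviour,duration_s,temp_c,rh_pct,insolation`,
#' optionally `target_tunnel`).
#'
#' @param path CSV file path.
#' @param crs CRS tag attached to point sets on read.
#' @param x the data.frame to write.
#' @return the validated data.frame (readers) or `path` invisibly (writer).
#' @export
read_occurrences <- function(path, crs = "local-metric") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "date")
  if (!all(need %in% names(d))) {
    stop("occurrence CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(d$x)) || !all(is.finite(d$y))) {
    stop("occurrence coordinates must be finite")
  }
  attr(d, "crs") <- crs
  d
}

#' @rdname read_occurrences
#' @export
read_veg_survey <- function(path) {
  check_veg_survey(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_occurrences
#' @export
read_trial_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "origin", "trial", "tunnel", "behaviour", "duration_s")
  if (!all(need %in% names(d))) {
    stop("trial-log CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(d$duration_s < 0)) stop("negative event durations")
  d
}

#' @rdname read_occurrences
#' @export
write_csv_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Full time-budget analysis of a flight-arena trial log
#'
#' Runs the complete behavioural analysis on a raw trial log: ethogram
#' pooling, overall and per-tunnel time shares, the three negative-binomial
#' mixed model variants, AIC screening of the abiotic covariates and the
#' departing-minus-navigation contrast. Given the deposited field data this
#' reproduces the published time-budget results; it runs identically on
#' synthetic logs from [generate_trials()].
#'
#' @param events a trial-log data.frame (see [read_trial_log()]) or a path to
#'   its CSV; must carry the target tunnel per trial (column `target_tunnel`)
#'   or `target_tunnel` must be supplied.
#' @param target_tunnel optional single target-tunnel label.
#' @param covariate_screen also fit covariate-augmented variants and screen
#'   them by AIC? (default TRUE when covariate columns are present).
#' @return list of class `timebudget_analysis`: `shares_pct` (category % of
#'   recorded time), `tunnel_minutes` (per-tunnel totals), `fits` (the three
#'   variants), `aic` (covariate screen, if run), `contrast`
#'   (departing - navigation), `marginal_means` (origin x category).
#' @export
reproduce_time_budget <- function(events, target_tunnel = NULL,
                                  covariate_screen = NULL) {
  if (is.character(events) && length(events) == 1L) {
    events <- read_trial_log(events)
  }
  tt <- pool_behaviours(events)
  if (is.null(covariate_screen)) {
    covariate_screen <- all(c("temp_c", "rh_pct", "insolation") %in% names(tt))
  }
  tot <- sum(tt$duration_s)
  shares <- tapply(tt$duration_s, tt$category, sum) / tot * 100
  tunnel_minutes <- sort(tapply(tt$duration_s, tt$tunnel, sum) / 60,
                         decreasing = TRUE)
  agg <- aggregate_by_plant_presence(tt, target_tunnel = target_tunnel)
  fits <- list(
    category_only = fit_timebudget(tt, "category_only"),
    tunnel_interaction = fit_timebudget(agg, "tunnel_interaction"),
    origin_interaction = fit_timebudget(tt, "origin_interaction")
  )
  aic <- NULL
  if (isTRUE(covariate_screen)) {
    aic <- select_by_aic(list(
      base = fits$category_only,
      covariates = fit_timebudget(tt, "category_only", covariates = TRUE)))
  }
  contrast <- if (isTRUE(fits$category_only$converged)) {
    linear_contrast(fits$category_only,
                    c(categorydeparting = 1, categorynavigation = -1))
  }
  mm <- if (isTRUE(fits$origin_interaction$converged)) {
    marginal_means(fits$origin_interaction)
  }
  structure(list(shares_pct = shares, tunnel_minutes = tunnel_minutes,
                 fits = fits, aic = aic, contrast = contrast,
                 marginal_means = mm),
            class = "timebudget_analysis")
}

#' @method print timebudget_analysis
#' @export
print.timebudget_analysis <- function(x, ...) {
  cat("Time-budget analysis\n  shares of recorded time (%):\n")
  print(round(x$shares_pct, 1))
  cat("  per-tunnel minutes:\n")
  print(round(x$tunnel_minutes, 0))
  if (!is.null(x$contrast)) {
    cat("  departing - navigation: ")
    print(x$contrast)
  }
  invisible(x)
}
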