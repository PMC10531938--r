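#' Quadrat-level Shannon index of a host-plant survey plot
#'
#' Spatial evenness of stems within one 20 x 20 m survey plot divided into 16
#' quadrats of 5 x 5 m: `H = -sum(p_q * log(p_q))` in nats, where `p_q` is the
#' share of the plot's stems in quadrat `q` and empty quadrats contribute
#' zero. `H` ranges from 0 (all stems in one quadrat) to `log(16) ~ 2.77`
#' (perfectly even); it is also bounded by `log(total stems)` when stems are
#' few.
#'
#' @param counts numeric vector of per-quadrat stem counts (non-negative; a
#'   standard plot has 16 quadrats).
#' @return `H` in nats, or `NA` with a warning for an all-zero plot.
#' @examples
#' shannon_evenness(rep(2, 16))  # log(16)
#' @export
shannon_evenness <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("quadrat counts must be non-negative and non-missing")
  }
  tot <- sum(counts)
  if (tot == 0) {
    warning("all-zero plot: Shannon index undefined")
    return(NA_real_)
  }
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

# Validate + normalise a long survey table (plot, habitat_class, quadrat, stems).
# counts_nonneg = FALSE admits real-valued responses (the abundance LMM is
# Gaussian and validation simulations feed it continuous data).
check_veg_survey <- function(surveys, counts_nonneg = TRUE) {
  need <- c("plot", "habitat_class", "quadrat", "stems")
  if (!all(need %in% names(surveys))) {
    stop("surveys must have columns: ", paste(need, collapse = ", "))
  }
  if (counts_nonneg && any(surveys$stems < 0, na.rm = TRUE)) {
    stop("negative stem counts")
  }
  bad <- names(which(table(surveys$plot) != 16L))
  if (length(bad)) {
    stop("each plot must have exactly 16 quadrat rows; offending plot(s): ",
         paste(bad, collapse = ", "))
  }
  surveys
}

#' Per-class summary of plot evenness
#'
#' Computes the quadrat-level Shannon index for every plot and summarises it
#' (mean and sample SD) per habitat class (homogeneous vs fragmented). Classes
#' with a single plot report `NA` SD; all-zero plots are dropped with a
#' warning.
#'
#' @param surveys long data.frame with columns `plot`, `habitat_class`,
#'   `quadrat`, `stems` (16 quadrat rows per plot).
#' @return list of class `evenness_summary`: `plots` (per-plot H) and
#'   `classes` (per-class mean, SD, n).
#' @export
class_evenness_summary <- function(surveys) {
  surveys <- check_veg_survey(surveys)
  plots <- do.call(rbind, lapply(split(surveys, surveys$plot), function(s) {
    data.frame(plot = s$plot[1], habitat_class = s$habitat_class[1],
               total_stems = sum(s$stems),
               H = shannon_evenness(s$stems))
  }))
  rownames(plots) <- NULL
  plots <- plots[!is.na(plots$H), , drop = FALSE]
  classes <- do.call(rbind, lapply(split(plots, plots$habitat_class), function(p) {
    data.frame(habitat_class = p$habitat_class[1], n_plots = nrow(p),
               H_mean = mean(p$H),
               H_sd = if (nrow(p) > 1) stats::sd(p$H) else NA_real_)
  }))
  rownames(classes) <- NULL
  structure(list(plots = plots, classes = classes),
            class = "evenness_summary")
}

#' @method print evenness_summary
#' @export
print.evenness_summary <- function(x, ...) {
  cat("Quadrat-level Shannon evenness by habitat class\n")
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Habitat-class contrast in host-plant stem abundance
#'
#' Linear mixed model of per-quadrat stem counts on habitat class with a
#' random intercept per plot, fitted by REML with Satterthwaite degrees of
#' freedom for the class contrast — the standard test of whether fragmented
#' woodlands hold more (if less evenly spread) host-plant stems than
#' homogeneous ones. Numerics are delegated to \pkg{lmerTest}.
#'
#' @param surveys long survey table as in [class_evenness_summary()]; the
#'   habitat class is coded with "homogeneous" as the reference level when
#'   present.
#' @param cap optional stem cap emulating the field protocol of stopping the
#'   count (default `Inf`, no truncation: field data arrive already capped).
#' @param cap_level `"plot"` truncates counts in quadrat order once the
#'   running plot total reaches the cap (a surveyor stopping mid-plot);
#'   `"quadrat"` caps each quadrat independently.
#' @return object of class `stem_abundance_fit`: class effect estimate, SE,
#'   Satterthwaite df, p-value, random-intercept and residual SDs, a
#'   singular-fit flag, and the underlying `lmerModLmerTest` object.
#' @export
fit_stem_abundance <- function(surveys, cap = Inf, cap_level = c("plot", "quadrat")) {
  surveys <- check_veg_survey(surveys, counts_nonneg = FALSE)
  cap_level <- match.arg(cap_level)
  surveys <- apply_stem_cap(surveys, cap, cap_level)
  if (length(unique(surveys$habitat_class)) < 2) {
    stop("need two habitat classes to contrast")
  }
  lv <- unique(as.character(surveys$habitat_class))
  if ("homogeneous" %in% lv) lv <- c("homogeneous", setdiff(lv, "homogeneous"))
  surveys$habitat_class <- factor(surveys$habitat_class, levels = lv)
  if (min(table(unique(surveys[c("plot", "habitat_class")])$habitat_class)) < 2) {
    stop("need at least 2 plots per habitat class")
  }
  fit <- lmerTest::lmer(stems ~ habitat_class + (1 | plot), data = surveys,
                        REML = TRUE)
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    term = rownames(sm)[2],
    estimate = sm[2, "Estimate"], se = sm[2, "Std. Error"],
    df = sm[2, "df"], p = sm[2, "Pr(>|t|)"],
    plot_sd = vc$sdcor[vc$grp == "plot"],
    resid_sd = vc$sdcor[vc$grp == "Residual"],
    singular = lme4::isSingular(fit),
    model = fit
  ), class = "stem_abundance_fit")
}

apply_stem_cap <- function(surveys, cap, cap_level) {
  if (!is.finite(cap)) return(surveys)
  if (cap_level == "quadrat") {
    surveys$stems <- pmin(surveys$stems, cap)
    return(surveys)
  }
  do.call(rbind, lapply(split(surveys, surveys$plot), function(s) {
    s <- s[order(s$quadrat), , drop = FALSE]
    cum <- cumsum(s$stems)
    over <- pmax(cum - cap, 0)
    s$stems <- pmax(s$stems - c(over[1], diff(over)), 0)
    s
  }))
}

#' @method print stem_abundance_fit
#' @export
print.stem_abundance_fit <- function(x, ...) {
  cat("Stem abundance contrast (LMM, REML, Satterthwaite df)\n")
  cat(sprintf("  %s: beta = %.3g (SE %.3g), df = %.2f, p = %.3g\n",
              x$term, x$estimate, x$se, x$df, x$p))
  cat(sprintf("  random plot intercept SD = %.3g, residual SD = %.3g%s\n",
              x$plot_sd, x$resid_sd,
              if (x$singular) "  [singular fit]" else ""))
  invisible(x)
}

#' @export
coef.stem_abundance_fit <- function(object, ...) {
  stats::setNames(object$estimate, object$term)
}
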