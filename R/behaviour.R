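#' Default ethogram pooling map
#'
#' Raw voice-recorded behaviour labels are pooled into the three analysis
#' categories: "departing" (flights into the covering net or toward the sun,
#' read as dispersal initiation), "navigation" (within-habitat routine
#' movements: free petal-like flight, flying over/around the host plant,
#' landing on it, walking) and "resting" (sitting still).
#'
#' @return named character vector: raw label -> category.
#' @export
default_behaviour_mapping <- function() {
  c("net flight" = "departing",
    "sun flight" = "departing",
    "free flight" = "navigation",
    "petal-like flight" = "navigation",
    "flight around host plant" = "navigation",
    "landing on host plant" = "navigation",
    "walking" = "navigation",
    "sitting still" = "resting")
}

behaviour_categories <- c("resting", "departing", "navigation")
tunnel_levels <- c("N", "E", "S", "W")

#' Pool raw ethogram events into per-trial category totals
#'
#' Sums event durations per (butterfly, trial, tunnel, category) and completes
#' the table with explicit zero rows for every tunnel x category cell of each
#' trial, so that time budgets are well defined (a tunnel never entered is 0 s
#' in every category). Trial covariates (temperature, humidity, insolation)
#' and the target-tunnel label, when present, are carried through.
#'
#' @param events data.frame with columns `id`, `origin`, `trial`, `tunnel`,
#'   `behaviour`, `duration_s`, optionally `temp_c`, `rh_pct`, `insolation`,
#'   `target_tunnel`.
#' @param mapping named character vector raw label -> category
#'   (default [default_behaviour_mapping()]); every raw label in `events`
#'   must be present.
#' @return data.frame of class `trial_table`: one row per
#'   (id, trial, tunnel, category) with `duration_s` in whole seconds.
#' @export
pool_behaviours <- function(events, mapping = default_behaviour_mapping()) {
  need <- c("id", "origin", "trial", "tunnel", "behaviour", "duration_s")
  if (!all(need %in% names(events))) {
    stop("events must have columns: ", paste(need, collapse = ", "))
  }
  if (any(events$duration_s < 0)) stop("negative event durations")
  unmapped <- setdiff(unique(as.character(events$behaviour)), names(mapping))
  if (length(unmapped)) {
    stop("unmapped behaviour label(s): ", paste(unmapped, collapse = ", "))
  }
  events$category <- unname(mapping[as.character(events$behaviour)])

  covars <- intersect(c("temp_c", "rh_pct", "insolation", "target_tunnel"),
                      names(events))
  trials <- unique(events[, c("id", "origin", "trial", covars), drop = FALSE])
  if (anyDuplicated(trials[, c("id", "trial")])) {
    stop("inconsistent origin/covariates within a (id, trial)")
  }
  tun <- sort(unique(as.character(events$tunnel)))
  if (all(tun %in% tunnel_levels)) tun <- tunnel_levels
  full <- merge(trials,
                expand.grid(tunnel = tun, category = behaviour_categories,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  agg <- stats::aggregate(duration_s ~ id + trial + tunnel + category,
                          data = events, FUN = sum)
  out <- merge(full, agg, by = c("id", "trial", "tunnel", "category"),
               all.x = TRUE)
  out$duration_s[is.na(out$duration_s)] <- 0
  out$category <- factor(out$category, levels = behaviour_categories)
  out <- out[order(out$id, out$trial, out$tunnel, out$category), ]
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Aggregate a trial table by host-plant presence
#'
#' Pools the three control tunnels of each trial into a single "control" row
#' per category, keeps the target tunnel (the one holding the host plant) as
#' "target", and attaches the exposure offset `log(3)` to control rows —
#' pooled control time covers three tunnels, so a count model needs this
#' offset for coefficients to compare per-tunnel rates.
#'
#' @param tt a `trial_table` from [pool_behaviours()].
#' @param target_tunnel the target tunnel: a single label applying to all
#'   trials, or omitted when `tt` carries a `target_tunnel` column.
#' @return data.frame of class `trial_table` with `tunnel_type`
#'   ("target"/"control") and `exposure_offset` columns.
#' @export
aggregate_by_plant_presence <- function(tt, target_tunnel = NULL) {
  if (is.null(target_tunnel)) {
    if (!"target_tunnel" %in% names(tt)) {
      stop("supply `target_tunnel` or include a target_tunnel column")
    }
  } else {
    tt$target_tunnel <- target_tunnel
  }
  ok <- vapply(split(tt, paste(tt$id, tt$trial)), function(s) {
    length(unique(s$target_tunnel)) == 1L &&
      sum(unique(as.character(s$tunnel)) == as.character(s$target_tunnel[1])) == 1L
  }, logical(1))
  if (!all(ok)) {
    stop("each trial must have exactly one target tunnel among its tunnels")
  }
  tt$tunnel_type <- ifelse(as.character(tt$tunnel) ==
                             as.character(tt$target_tunnel),
                           "target", "control")
  covars <- intersect(c("temp_c", "rh_pct", "insolation"), names(tt))
  keys <- c("id", "origin", "trial", "tunnel_type", "category", covars)
  out <- stats::aggregate(duration_s ~ ., data = tt[, c(keys, "duration_s")],
                          FUN = sum)
  out$tunnel_type <- factor(out$tunnel_type, levels = c("control", "target"))
  out$category <- factor(out$category, levels = behaviour_categories)
  out$exposure_offset <- ifelse(out$tunnel_type == "control", log(3), 0)
  out <- out[order(out$id, out$trial, out$tunnel_type, out$category), ]
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Negative-binomial mixed time-budget model
#'
#' Fits one of three negative-binomial (log link, estimated dispersion) mixed
#' models of behavioural time budgets, with durations in whole seconds as
#' counts. Numerics are delegated to \pkg{glmmTMB} (family `nbinom2`).
#'
#' \describe{
#'   \item{`category_only`}{`duration_s ~ category (+ covariates) +
#'     (1|trial) + (1|id)` — do the three behaviours differ in total time?}
#'   \item{`tunnel_interaction`}{`duration_s ~ tunnel_type * category
#'     (+ covariates) + offset(exposure_offset) + (1|trial) + (1|id)` on a
#'     plant-presence aggregated table — does the host-plant tunnel hold more
#'     time, per behaviour, than a control tunnel? The `log(3)` offset absorbs
#'     the three-fold exposure of the pooled control rows.}
#'   \item{`origin_interaction`}{`duration_s ~ origin * category + (1|trial) +
#'     (1|id) + (1|tunnel)` on the non-aggregated table — do butterflies from
#'     fragmented woodlands budget their time differently, in particular
#'     spending more time in departing flight?}
#' }
#'
#' Reference levels are "resting" (category), "control" (tunnel type) and
#' "homogeneous" (origin), so interaction terms read as log rate ratios
#' against resting in the baseline group.
#'
#' @param tt a `trial_table` (aggregated by plant presence for
#'   `tunnel_interaction`).
#' @param variant model variant, see Details.
#' @param covariates include temperature/humidity/insolation fixed effects?
#'   (default `FALSE`; the final models drop them).
#' @return object of class `timebudget_fit`: coefficient table (`estimate`,
#'   `se`, `z`, `p`), random-effect SDs, NB dispersion, AIC, convergence flag
#'   and the underlying \pkg{glmmTMB} fit.
#' @export
fit_timebudget <- function(tt,
                           variant = c("category_only", "tunnel_interaction",
                                       "origin_interaction"),
                           covariates = FALSE) {
  variant <- match.arg(variant)
  if (any(tt$duration_s %% 1 != 0)) {
    stop("durations must be whole seconds (integer counts)")
  }
  tt$duration_s <- as.integer(round(tt$duration_s))
  tt$category <- factor(as.character(tt$category), levels = behaviour_categories)
  tt$id <- factor(tt$id)
  tt$trial <- factor(paste(tt$id, tt$trial, sep = "/"))
  if (nlevels(droplevels(tt$category)) < 2) stop("need >= 2 behaviour categories")

  cov_terms <- if (covariates) {
    present <- intersect(c("temp_c", "rh_pct", "insolation"), names(tt))
    if (!length(present)) stop("covariates requested but none present")
    paste("+", paste(present, collapse = " + "))
  } else ""
  form <- switch(variant,
    category_only = sprintf(
      "duration_s ~ category %s + (1 | trial) + (1 | id)", cov_terms),
    tunnel_interaction = {
      if (!all(c("tunnel_type", "exposure_offset") %in% names(tt))) {
        stop("tunnel_interaction needs a plant-presence aggregated table ",
             "(see aggregate_by_plant_presence)")
      }
      tt$tunnel_type <- factor(as.character(tt$tunnel_type),
                               levels = c("control", "target"))
      sprintf(paste("duration_s ~ tunnel_type * category %s +",
                    "offset(exposure_offset) + (1 | trial) + (1 | id)"),
              cov_terms)
    },
    origin_interaction = {
      if (!"tunnel" %in% names(tt)) {
        stop("origin_interaction needs the non-aggregated table with tunnel ids")
      }
      lv <- unique(as.character(tt$origin))
      if ("homogeneous" %in% lv) lv <- c("homogeneous", setdiff(lv, "homogeneous"))
      tt$origin <- factor(as.character(tt$origin), levels = lv)
      tt$tunnel <- factor(tt$tunnel)
      sprintf(
        "duration_s ~ origin * category %s + (1 | trial) + (1 | id) + (1 | tunnel)",
        cov_terms)
    })

  fit <- tryCatch(
    glmmTMB::glmmTMB(stats::as.formula(form), data = tt,
                     family = glmmTMB::nbinom2()),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(variant = variant, formula = form, converged = FALSE,
                          error = conditionMessage(fit), data = tt),
                     class = "timebudget_fit"))
  }
  sm <- summary(fit)
  co <- sm$coefficients$cond
  coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      z = co[, 3], p = co[, 4], row.names = NULL)
  vc <- lapply(glmmTMB::VarCorr(fit)$cond, function(m) sqrt(diag(m)))
  ranef_sd <- vapply(vc, function(v) unname(v[1]), numeric(1))
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  structure(list(
    variant = variant, formula = form, coefficients = coefs,
    ranef_sd = ranef_sd, dispersion = stats::sigma(fit),
    aic = as.numeric(stats::AIC(fit)), converged = conv,
    n = nrow(tt), model = fit, data = tt
  ), class = "timebudget_fit")
}

#' @method print timebudget_fit
#' @export
print.timebudget_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Negative-binomial mixed time-budget model [%s]\n", x$variant))
  if (!isTRUE(x$converged) && is.null(x$model)) {
    cat("  fit failed:", x$error, "\n")
    return(invisible(x))
  }
  co <- x$coefficients
  co[-1] <- lapply(co[-1], signif, digits)
  print(co, row.names = FALSE)
  cat(sprintf("random-effect SDs: %s\n",
              paste(sprintf("%s %.3g", names(x$ranef_sd), x$ranef_sd),
                    collapse = ", ")))
  cat(sprintf("NB dispersion %.3g, AIC %.1f%s\n", x$dispersion, x$aic,
              if (!x$converged) "  [did not converge]" else ""))
  invisible(x)
}

#' @method summary timebudget_fit
#' @export
summary.timebudget_fit <- function(object, ...) {
  print(object, ...)
  invisible(object$coefficients)
}

#' @export
coef.timebudget_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.timebudget_fit <- function(object, ...) {
  stats::vcov(object$model)$cond
}

#' @export
AIC.timebudget_fit <- function(object, ...) object$aic

#' @export
residuals.timebudget_fit <- function(object, type = "pearson", ...) {
  stats::residuals(object$model, type = type)
}

#' @export
simulate.timebudget_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::simulate(object$model, nsim = nsim, ...)
}

#' Wald test of a linear combination of time-budget coefficients
#'
#' `mu = w' beta` with its standard error from the fixed-effect covariance
#' and a two-sided Wald z p-value; e.g. the departing-minus-navigation
#' contrast asking whether the two flight categories differ.
#'
#' @param fit a converged [fit_timebudget()] object.
#' @param weights numeric vector, one weight per fixed-effect coefficient
#'   (or a named vector matching a subset of coefficient names, the rest 0).
#' @return object of class `timebudget_contrast` with `mu`, `se`, `z`, `p`.
#' @export
linear_contrast <- function(fit, weights) {
  beta <- coef(fit)
  if (!is.null(names(weights))) {
    unknown <- setdiff(names(weights), names(beta))
    if (length(unknown)) stop("unknown coefficient(s): ",
                              paste(unknown, collapse = ", "))
    w <- stats::setNames(numeric(length(beta)), names(beta))
    w[names(weights)] <- weights
    weights <- w
  }
  if (length(weights) != length(beta)) {
    stop("weight vector length (", length(weights),
         ") must equal coefficient count (", length(beta), ")")
  }
  if (all(weights == 0)) stop("zero contrast: SE undefined")
  V <- vcov(fit)
  mu <- sum(weights * beta)
  se <- sqrt(drop(t(weights) %*% V %*% weights))
  z <- mu / se
  structure(list(mu = mu, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)), weights = weights),
            class = "timebudget_contrast")
}

#' @method print timebudget_contrast
#' @export
print.timebudget_contrast <- function(x, ...) {
  cat(sprintf("Linear contrast: mu = %.3g (SE %.3g), z = %.2f, p = %.3g\n",
              x$mu, x$se, x$z, x$p))
  invisible(x)
}

#' Response-scale marginal means with fixed-effect CIs
#'
#' Model-predicted mean seconds per factor-level combination, with 95%
#' confidence intervals from the fixed-effect covariance only (random-effect
#' variance excluded): `exp(eta +/- 1.96 se)` on the linear predictor at
#' offset 0 and covariates held at their sample means.
#'
#' @param fit a converged [fit_timebudget()] object.
#' @param grid data.frame of factor-level combinations; by default the full
#'   cross of the factors in the fixed-effect formula.
#' @param level confidence level (default 0.95).
#' @return data.frame: the grid plus `mean`, `lwr`, `upr` (seconds).
#' @export
marginal_means <- function(fit, grid = NULL, level = 0.95) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  tt <- fit$data
  # fixed-effect terms only: strip random effects, then offsets
  fixed <- lme4::nobars(stats::formula(fit$model))
  labs <- attr(stats::terms(fixed), "term.labels")
  vars <- unique(unlist(lapply(labs, function(l) all.vars(stats::as.formula(
    paste("~", l))))))
  fcts <- vars[vapply(vars, function(v) is.factor(tt[[v]]), logical(1))]
  nums <- setdiff(vars, fcts)
  if (is.null(grid)) {
    grid <- expand.grid(lapply(stats::setNames(fcts, fcts),
                               function(v) levels(tt[[v]])),
                        KEEP.OUT.ATTRS = FALSE)
  } else {
    for (v in fcts) {
      if (!v %in% names(grid)) stop("grid is missing factor: ", v)
      bad <- setdiff(unique(as.character(grid[[v]])), levels(tt[[v]]))
      if (length(bad)) stop("unknown level(s) for ", v, ": ",
                            paste(bad, collapse = ", "))
      grid[[v]] <- factor(as.character(grid[[v]]), levels = levels(tt[[v]]))
    }
  }
  for (v in nums) grid[[v]] <- mean(tt[[v]])
  ff <- stats::reformulate(labs)
  X <- stats::model.matrix(ff, grid)
  beta <- coef(fit)
  X <- X[, names(beta), drop = FALSE]
  V <- vcov(fit)
  eta <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- grid[, fcts, drop = FALSE]
  out$mean <- exp(eta)
  out$lwr <- exp(eta - zq * se)
  out$upr <- exp(eta + zq * se)
  out
}

#' AIC model selection over candidate time-budget fits
#'
#' Ranks fits of the same data rows (e.g. with and without the
#' temperature/humidity/insolation covariates) by AIC and returns the winner
#' with a delta-AIC table.
#'
#' @param fits list of [fit_timebudget()] objects fitted to identical rows.
#' @param labels optional names for the delta table.
#' @return list of class `aic_selection`: `best` (the min-AIC fit) and
#'   `table` (label, AIC, delta_aic, sorted).
#' @export
select_by_aic <- function(fits, labels = NULL) {
  if (inherits(fits, "timebudget_fit")) fits <- list(fits)
  if (!length(fits)) stop("no fits supplied")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("fits compare different data (row counts differ: ",
         paste(unique(ns), collapse = ", "), ")")
  }
  ys <- lapply(fits, function(f) f$data$duration_s)
  if (!all(vapply(ys[-1], identical, logical(1), ys[[1]]))) {
    stop("fits compare different data (responses differ)")
  }
  if (is.null(labels)) {
    labels <- names(fits)
    if (is.null(labels)) {
      labels <- vapply(fits, function(f) {
        paste0(f$variant, if (grepl("temp_c|rh_pct|insolation", f$formula))
          "+covariates" else "")
      }, character(1))
    }
  }
  aics <- vapply(fits, AIC, numeric(1))
  tab <- data.frame(model = labels, aic = aics, delta_aic = aics - min(aics))
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  structure(list(best = fits[[which.min(aics)]], table = tab),
            class = "aic_selection")
}

#' @method print aic_selection
#' @export
print.aic_selection <- function(x, ...) {
  cat("AIC model selection\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
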