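#' Neutral-landscape generator with controlled fragmentation
#'
#' Random-cluster growth: `n_seeds` pixels are scattered uniformly and grown
#' by repeatedly converting a random 4-neighbour of the current habitat set
#' until exactly `round(p * n_pixels)` pixels are habitat, so the realised
#' habitat proportion matches `p` to within one pixel. The fragmentation
#' parameter `f` sets the seed density: `f = 0` grows one compact block,
#' `f = 1` scatters every habitat pixel independently; intermediate values
#' give the patchy woodland mosaics typical of fragmented agricultural
#' regions.
#'
#' @param nrow,ncol grid shape in pixels.
#' @param p habitat proportion in (0, 1); 1 is allowed and fills the grid.
#' @param f fragmentation in `[0, 1]`.
#' @param res pixel size, metres (default 10).
#' @param seed integer seed (reproducible; same seed, same raster).
#' @param crs,epoch passed to [habitat_raster()].
#' @return a [habitat_raster].
#' @export
generate_landscape <- function(nrow, ncol, p = 0.3, f = 0.2, res = 10,
                               seed = NULL, crs = "local-metric", epoch = "") {
  if (length(p) != 1 || p <= 0 || p > 1) stop("`p` must be in (0, 1]")
  if (length(f) != 1 || f < 0 || f > 1) stop("`f` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow * ncol
  n_hab <- max(1L, round(p * n))
  g <- matrix(0L, nrow, ncol)
  if (n_hab == n) {
    g[] <- 1L
    return(habitat_raster(g, res = res, crs = crs, epoch = epoch))
  }
  n_seeds <- max(1L, round(1 + f * (n_hab - 1)))
  seeds <- sample.int(n, n_seeds)
  g[seeds] <- 1L
  placed <- min(n_seeds, n_hab)
  if (n_seeds > n_hab) {
    # more seeds than target (possible only at extreme f): keep a subset
    g[] <- 0L
    g[seeds[seq_len(n_hab)]] <- 1L
    placed <- n_hab
  }
  # frontier = 4-neighbours of habitat, possibly stale; resampled lazily
  frontier <- neighbours4(which(g == 1L), nrow, ncol)
  while (placed < n_hab) {
    frontier <- frontier[g[frontier] == 0L]
    if (!length(frontier)) { # habitat is saturated locally; reseed
      frontier <- which(g == 0L)
    }
    i <- frontier[sample.int(length(frontier), 1L)]
    if (g[i] == 0L) {
      g[i] <- 1L
      placed <- placed + 1L
      frontier <- c(frontier, neighbours4(i, nrow, ncol))
    }
  }
  habitat_raster(g, res = res, crs = crs, epoch = epoch)
}

# Column-major indices of the 4-neighbours of pixels `idx`.
neighbours4 <- function(idx, nr, nc) {
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  out <- c(
    ifelse(row > 1L, idx - 1L, NA_integer_),
    ifelse(row < nr, idx + 1L, NA_integer_),
    ifelse(col > 1L, idx - nr, NA_integer_),
    ifelse(col < nc, idx + nr, NA_integer_)
  )
  out[!is.na(out)]
}

#' Progressive habitat-loss epoch series
#'
#' Starting from a base landscape, each epoch removes a fraction of the
#' remaining habitat pixels, preferentially from patch boundaries (smallest
#' interior edge distance first, ties broken at random), emulating the
#' nibbling-away of woodland over successive land-cover epochs. Habitat is
#' monotone non-increasing across the series.
#'
#' @param base a [habitat_raster].
#' @param loss fraction of habitat removed per epoch, in `[0, 1)`.
#' @param n_epochs number of epochs returned, including the base (>= 2).
#' @param seed integer seed.
#' @return list of [habitat_raster]s, epoch labels "1" ... `n_epochs`.
#' @export
generate_epoch_series <- function(base, loss = 0.15, n_epochs = 4, seed = NULL) {
  stopifnot(inherits(base, "habitat_raster"), n_epochs >= 2)
  if (loss < 0 || loss >= 1) stop("`loss` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_epochs)
  cur <- base
  cur$epoch <- "1"
  out[[1]] <- cur
  for (e in seq_len(n_epochs)[-1]) {
    g <- cur$grid
    hab <- which(!is.na(g) & g == 1L)
    n_rm <- round(loss * length(hab))
    if (n_rm > 0 && length(hab)) {
      d <- dist_to_set_px(g == 0L)     # interior distance of habitat pixels
      ord <- order(d[hab] + stats::runif(length(hab)) * 1e-3)
      g[hab[ord[seq_len(n_rm)]]] <- 0L
    }
    cur <- habitat_raster(g, res = base$res, origin = base$origin,
                          crs = base$crs, epoch = as.character(e))
    out[[e]] <- cur
  }
  out
}

#' Edge-biased occurrence generator
#'
#' Samples point records whose signed edge distances follow a target normal
#' distribution (default mean -34 m, SD 106 m: records concentrated just
#' inside the forest edge), by drawing a target distance and placing the
#' point uniformly among pixels whose distance matches it to within one pixel.
#' A `background` fraction of records is placed uniformly over all non-NoData
#' pixels instead, diluting the edge signal.
#'
#' @param habitat a [habitat_raster] with both classes present.
#' @param n number of records.
#' @param edge_mean,edge_sd target normal of signed distances, metres.
#' @param background fraction in `[0, 1]` of uniformly placed records.
#' @param years year range records are dated into (uniformly).
#' @param species species tag.
#' @param seed integer seed.
#' @param max_iter rejection attempts per point before erroring.
#' @return data.frame `x`, `y`, `date`, `species` with a `"crs"` attribute.
#' @export
generate_occurrences <- function(habitat, n = 500, edge_mean = -34,
                                 edge_sd = 106, background = 0,
                                 years = 1970:2019, species = "focal",
                                 seed = NULL, max_iter = 200) {
  stopifnot(inherits(habitat, "habitat_raster"), n >= 1)
  if (background < 0 || background > 1) stop("`background` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  dist <- signed_edge_distance(habitat)
  ok_idx <- which(!is.na(dist$grid))
  dvals <- dist$grid[ok_idx]
  n_bg <- round(n * background)
  n_focal <- n - n_bg
  tol <- habitat$res
  pick <- integer(0)
  for (k in seq_len(n_focal)) {
    found <- FALSE
    for (it in seq_len(max_iter)) {
      target <- stats::rnorm(1, edge_mean, edge_sd)
      hit <- which(abs(dvals - target) <= tol)
      if (length(hit)) {
        pick <- c(pick, ok_idx[hit[sample.int(length(hit), 1L)]])
        found <- TRUE
        break
      }
    }
    if (!found) {
      stop("could not match target edge distances after ", max_iter,
           " attempts; placed ", length(pick), " of ", n_focal,
           " focal points (landscape too small for the requested regime?)")
    }
  }
  if (n_bg > 0) {
    pick <- c(pick, ok_idx[sample.int(length(ok_idx), n_bg, replace = TRUE)])
  }
  nr <- nrow(habitat$grid)
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  xy <- raster_xy(habitat, row, col)
  jit <- matrix(stats::runif(2 * length(pick), -0.5, 0.5), ncol = 2) * habitat$res
  yr <- sample(years, length(pick), replace = TRUE)
  out <- data.frame(x = xy[, "x"] + jit[, 1], y = xy[, "y"] + jit[, 2],
                    date = sprintf("%d-07-15", yr), species = species)
  attr(out, "crs") <- habitat$crs
  out
}

#' Synthetic host-plant survey generator
#'
#' Plot stem totals are drawn negative-binomially around a class mean and
#' split over the 16 quadrats by a symmetric Dirichlet-multinomial whose
#' concentration controls spatial clumping: low `alpha` piles the stems into
#' few quadrats (the fragmented-woodland pattern), high `alpha` spreads them
#' evenly (the homogeneous pattern). Totals above `cap` are truncated to it,
#' reflecting the field protocol of stopping the count.
#'
#' @param n_plots named vector, plots per class, e.g.
#'   `c(homogeneous = 6, fragmented = 4)`.
#' @param mean_stems named vector of NB mean plot totals per class.
#' @param alpha named vector of Dirichlet concentrations per class.
#' @param nb_size NB size (inverse overdispersion) of plot totals.
#' @param cap per-plot stem cap (default 25; `Inf` disables).
#' @param n_quadrats quadrats per plot (default 16).
#' @param seed integer seed.
#' @return long data.frame `plot`, `habitat_class`, `quadrat`, `stems`.
#' @export
generate_veg_surveys <- function(n_plots = c(homogeneous = 6, fragmented = 4),
                                 mean_stems = c(homogeneous = 16, fragmented = 22),
                                 alpha = c(homogeneous = 20, fragmented = 0.6),
                                 nb_size = 15, cap = 25, n_quadrats = 16,
                                 seed = NULL) {
  classes <- names(n_plots)
  if (is.null(classes) || !all(classes %in% names(mean_stems)) ||
      !all(classes %in% names(alpha))) {
    stop("`n_plots`, `mean_stems` and `alpha` must share class names")
  }
  if (any(alpha <= 0)) stop("Dirichlet concentrations must be positive")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (cl in classes) {
    for (i in seq_len(n_plots[[cl]])) {
      tot <- 0
      while (tot == 0) tot <- stats::rnbinom(1, mu = mean_stems[[cl]], size = nb_size)
      tot <- min(tot, cap)
      w <- stats::rgamma(n_quadrats, shape = alpha[[cl]])
      stems <- as.integer(stats::rmultinom(1, tot, w / sum(w)))
      rows[[length(rows) + 1L]] <- data.frame(
        plot = sprintf("%s_%02d", substr(cl, 1, 4), i), habitat_class = cl,
        quadrat = seq_len(n_quadrats), stems = stems)
    }
  }
  do.call(rbind, rows)
}

#' Gaussian stem-count simulator with known class difference
#'
#' Direct simulation from the abundance model itself (class mean difference +
#' plot random intercept + residual noise), used to validate
#' [fit_stem_abundance()] recovery of a known effect.
#'
#' @param delta true class difference added to the fragmented class.
#' @param plot_sd,resid_sd random-intercept and residual SDs.
#' @param n_plots named vector of plots per class.
#' @param baseline mean of the homogeneous class.
#' @param n_quadrats quadrats per plot.
#' @param seed integer seed.
#' @return long survey data.frame (continuous `stems`).
#' @export
simulate_stem_counts <- function(delta = 6, plot_sd = 1, resid_sd = 3,
                                 n_plots = c(homogeneous = 6, fragmented = 4),
                                 baseline = 5, n_quadrats = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (cl in names(n_plots)) {
    mu_cl <- baseline + if (cl == "fragmented") delta else 0
    for (i in seq_len(n_plots[[cl]])) {
      b <- stats::rnorm(1, 0, plot_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        plot = sprintf("%s_%02d", substr(cl, 1, 4), i), habitat_class = cl,
        quadrat = seq_len(n_quadrats),
        stems = mu_cl + b + stats::rnorm(n_quadrats, 0, resid_sd))
    }
  }
  do.call(rbind, rows)
}

#' Trial-simulation specification
#'
#' Bundles the design of a synthetic flight-arena experiment. Defaults mirror
#' the study conditions: 10 butterflies of homogeneous and 4 of fragmented
#' origin, two 30 min trials each, a strongly resting-dominant time budget and
#' a fragmented-origin multiplier `exp(1.16)` on the departing share (shares
#' are renormalised, so the multiplier is exactly the origin-by-departing
#' log-rate-ratio relative to resting). The baseline (homogeneous-origin)
#' shares are calibrated so that the expected pooled budget over the 10:4
#' origin mix reproduces the observed overall split of 90.9% resting, 5.1%
#' departing and 4.0% navigation.
#'
#' @param n_homogeneous,n_fragmented butterflies per origin.
#' @param trials_per_butterfly repeated trials per individual.
#' @param trial_length_s trial duration, seconds (30 min).
#' @param base_shares named, non-negative, sums to 1.
#' @param origin_multiplier multiplier on the fragmented departing share.
#' @param precision Dirichlet precision of per-trial share variation (lower =
#'   more overdispersion between trials).
#' @param target_pref relative weight of the target tunnel when splitting
#'   category time over the four tunnels.
#' @param seed integer seed.
#' @return list of class `trial_sim_spec`.
#' @export
trial_sim_spec <- function(n_homogeneous = 10, n_fragmented = 4,
                           trials_per_butterfly = 2, trial_length_s = 1800,
                           base_shares = c(resting = 0.9269, departing = 0.0327,
                                           navigation = 0.0404),
                           origin_multiplier = exp(1.16), precision = 30,
                           target_pref = 2, seed = NULL) {
  if (any(base_shares < 0) || abs(sum(base_shares) - 1) > 1e-8) {
    stop("`base_shares` must be non-negative and sum to 1")
  }
  if (!setequal(names(base_shares), behaviour_categories)) {
    stop("`base_shares` must be named ",
         paste(behaviour_categories, collapse = ", "))
  }
  structure(as.list(environment()), class = "trial_sim_spec")
}

#' Synthetic ethogram-event generator
#'
#' Simulates raw flight-arena trial logs. Per trial, category seconds follow
#' a Dirichlet-multinomial over the trial length (the Dirichlet stage injects
#' the between-trial overdispersion a negative-binomial model absorbs), with
#' the fragmented-origin departing share multiplied and all shares
#' renormalised; category time is then split across the four tunnels with a
#' preference for the target tunnel, and each (tunnel, category) cell is
#' emitted as one or two raw-labelled events together with trial covariates.
#'
#' @param spec a [trial_sim_spec()].
#' @return data.frame of raw events: `id`, `origin`, `trial`, `tunnel`,
#'   `behaviour`, `duration_s`, `temp_c`, `rh_pct`, `insolation`,
#'   `target_tunnel`.
#' @export
generate_trials <- function(spec = trial_sim_spec()) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  labels_of <- split(names(default_behaviour_mapping()),
                     unname(default_behaviour_mapping()))
  ids <- c(sprintf("H%02d", seq_len(spec$n_homogeneous)),
           sprintf("F%02d", seq_len(spec$n_fragmented)))
  origin <- rep(c("homogeneous", "fragmented"),
                c(spec$n_homogeneous, spec$n_fragmented))
  target <- sample(tunnel_levels, length(ids), replace = TRUE)
  rows <- list()
  for (b in seq_along(ids)) {
    shares <- spec$base_shares[behaviour_categories]
    if (origin[b] == "fragmented") {
      shares["departing"] <- shares["departing"] * spec$origin_multiplier
      shares <- shares / sum(shares)
    }
    for (tr in seq_len(spec$trials_per_butterfly)) {
      p <- stats::rgamma(3, shape = spec$precision * shares)
      p <- p / sum(p)
      secs <- as.integer(stats::rmultinom(1, spec$trial_length_s, p))
      names(secs) <- behaviour_categories
      w <- ifelse(tunnel_levels == target[b], spec$target_pref, 1)
      temp <- round(stats::rnorm(1, 24, 1.5), 1)
      rh <- round(stats::rnorm(1, 65, 8), 1)
      ins <- round(stats::runif(1), 2)
      for (cat in behaviour_categories) {
        if (secs[[cat]] == 0) next
        per_tun <- as.integer(stats::rmultinom(1, secs[[cat]], w / sum(w)))
        for (tn in seq_along(tunnel_levels)) {
          if (per_tun[tn] == 0) next
          labs <- labels_of[[cat]]
          n_ev <- if (per_tun[tn] > 60 && length(labs) > 1) 2L else 1L
          dur <- if (n_ev == 2L) {
            a <- sample.int(per_tun[tn] - 1L, 1L)
            c(a, per_tun[tn] - a)
          } else per_tun[tn]
          rows[[length(rows) + 1L]] <- data.frame(
            id = ids[b], origin = origin[b], trial = tr,
            tunnel = tunnel_levels[tn],
            behaviour = sample(labs, n_ev, replace = n_ev > length(labs)),
            duration_s = dur, temp_c = temp, rh_pct = rh, insolation = ins,
            target_tunnel = target[b])
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Direct negative-binomial time-budget simulators
#'
#' Simulate aggregated trial tables straight from the count model that
#' [fit_timebudget()] assumes, for parameter-recovery and offset validation.
#' `simulate_timebudget_trials()` produces the per-tunnel (origin design)
#' table with a known origin-by-departing log effect;
#' `simulate_timebudget_exposure()` produces the plant-presence aggregated
#' table in which control rows have exactly `exposure_ratio` times the
#' exposure of target rows (and no true tunnel-type effect unless
#' `tunnel_effect` is set).
#'
#' @param n_homogeneous,n_fragmented butterflies per origin.
#' @param trials_per_butterfly trials per individual.
#' @param intercept log mean resting seconds per tunnel.
#' @param cat_effects named log effects of departing/navigation vs resting.
#' @param origin_effect log effect of fragmented origin on resting.
#' @param interaction named origin-by-category log effects (the
#'   origin-by-departing entry is the quantity recovery tests target).
#' @param re_sd named random-effect SDs (`trial`, `id`, `tunnel`).
#' @param dispersion NB size parameter (smaller = more overdispersion).
#' @param seed integer seed.
#' @return a `trial_table` ready for [fit_timebudget()].
#' @export
simulate_timebudget_trials <- function(n_homogeneous = 10, n_fragmented = 4,
                                       trials_per_butterfly = 3,
                                       intercept = log(400),
                                       cat_effects = c(departing = -3,
                                                       navigation = -2.6),
                                       origin_effect = 0,
                                       interaction = c(departing = 1.2,
                                                       navigation = 0),
                                       re_sd = c(trial = 0.1, id = 0.1,
                                                 tunnel = 0.05),
                                       dispersion = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- c(sprintf("H%02d", seq_len(n_homogeneous)),
           sprintf("F%02d", seq_len(n_fragmented)))
  origin <- rep(c("homogeneous", "fragmented"), c(n_homogeneous, n_fragmented))
  u_id <- stats::rnorm(length(ids), 0, re_sd[["id"]])
  u_tun <- stats::setNames(stats::rnorm(4, 0, re_sd[["tunnel"]]), tunnel_levels)
  rows <- list()
  for (b in seq_along(ids)) {
    for (tr in seq_len(trials_per_butterfly)) {
      u_tr <- stats::rnorm(1, 0, re_sd[["trial"]])
      for (tn in tunnel_levels) {
        for (cat in behaviour_categories) {
          eta <- intercept + u_id[b] + u_tr + u_tun[[tn]]
          if (cat != "resting") eta <- eta + cat_effects[[cat]]
          if (origin[b] == "fragmented") {
            eta <- eta + origin_effect +
              if (cat != "resting") interaction[[cat]] else 0
          }
          rows[[length(rows) + 1L]] <- data.frame(
            id = ids[b], origin = origin[b], trial = tr, tunnel = tn,
            category = cat,
            duration_s = stats::rnbinom(1, mu = exp(eta), size = dispersion))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = behaviour_categories)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' @rdname simulate_timebudget_trials
#' @param exposure_ratio true exposure of control rows relative to target.
#' @param tunnel_effect true log effect of the target tunnel (0 = null).
#' @export
simulate_timebudget_exposure <- function(n_homogeneous = 10, n_fragmented = 4,
                                         trials_per_butterfly = 2,
                                         intercept = log(120),
                                         cat_effects = c(departing = -1.5,
                                                         navigation = -1.8),
                                         exposure_ratio = 3, tunnel_effect = 0,
                                         re_sd = c(trial = 0.1, id = 0.1),
                                         dispersion = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- c(sprintf("H%02d", seq_len(n_homogeneous)),
           sprintf("F%02d", seq_len(n_fragmented)))
  origin <- rep(c("homogeneous", "fragmented"), c(n_homogeneous, n_fragmented))
  u_id <- stats::rnorm(length(ids), 0, re_sd[["id"]])
  rows <- list()
  for (b in seq_along(ids)) {
    for (tr in seq_len(trials_per_butterfly)) {
      u_tr <- stats::rnorm(1, 0, re_sd[["trial"]])
      for (tt in c("control", "target")) {
        for (cat in behaviour_categories) {
          eta <- intercept + u_id[b] + u_tr +
            if (cat != "resting") cat_effects[[cat]] else 0
          if (tt == "target") eta <- eta + tunnel_effect
          if (tt == "control") eta <- eta + log(exposure_ratio)
          rows[[length(rows) + 1L]] <- data.frame(
            id = ids[b], origin = origin[b], trial = tr, tunnel_type = tt,
            category = cat,
            duration_s = stats::rnbinom(1, mu = exp(eta), size = dispersion),
            exposure_offset = if (tt == "control") log(exposure_ratio) else 0)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = behaviour_categories)
  out$tunnel_type <- factor(out$tunnel_type, levels = c("control", "target"))
  class(out) <- c("trial_table", "data.frame")
  out
}
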