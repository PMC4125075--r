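# Seeded generators for synthetic strain panels and regulon-structured
# expression datasets -- the study conditions for every pipeline here.

#' Specification of a synthetic strain panel
#'
#' Describes a panel of simulated bacterial strains: each strain is the
#' batch-growth model with its kinetic constants jittered by a
#' strain-specific factor, grown under one or more perturbation
#' conditions, with replicate wells carrying multiplicative measurement
#' noise (plate-reader error grows with signal; default 2% CV).
#'
#' @param n_strains number of strains (>= 2).
#' @param replicates replicate wells per strain and condition (>= 2).
#' @param jitter relative parameter perturbation per strain (0.15 = each
#'   kinetic constant scaled by a factor uniform in 1 +/- 0.15).
#' @param noise multiplicative OD noise CV per sample.
#' @param conditions subset of `control`, `plasmid`, `low_temperature`,
#'   `low_nutrient`.
#' @param dt sampling interval in hours (default 1/6 h = 10 min).
#' @param horizon record length in hours.
#' @param od0 inoculum optical density.
#' @return object of class `strain_panel_spec`.
#' @export
strain_panel_spec <- function(n_strains = 4, replicates = 3, jitter = 0.15,
                              noise = 0.02,
                              conditions = c("control", "plasmid",
                                             "low_temperature", "low_nutrient"),
                              dt = 1 / 6, horizon = 14, od0 = 0.05) {
  stopifnot(n_strains >= 2, replicates >= 2, jitter >= 0, noise >= 0,
            dt > 0, horizon > 1)
  conditions <- match.arg(conditions, several.ok = TRUE)
  structure(list(n_strains = n_strains, replicates = replicates,
                 jitter = jitter, noise = noise, conditions = conditions,
                 dt = dt, horizon = horizon, od0 = od0),
            class = "strain_panel_spec")
}

# Jittered strain model; resamples (with a log) if the jittered parameter
# set fails to integrate.
.jitter_model <- function(spec, max_tries = 20) {
  for (i in seq_len(max_tries)) {
    f <- 1 + spec$jitter * stats::runif(8, -1, 1)
    m <- growth_model(params = growth_model()$params * f)
    ok <- tryCatch({
      simulate_growth(m, t_end = spec$horizon, dt = spec$dt, od0 = spec$od0)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(m)
    message("make_strain_panel: unstable jittered parameter set resampled")
  }
  stop("make_strain_panel: could not draw a stable strain model")
}

#' Generate a synthetic strain panel
#'
#' For each strain, draws a jittered growth-model parameter set; for each
#' requested condition applies the matching perturbation
#' ([apply_perturbation()]); simulates; and emits replicate growth curves
#' with multiplicative measurement noise at 10-minute sampling. The
#' result is a pure function of `(spec, seed)`.
#'
#' @param spec a [strain_panel_spec()].
#' @param seed integer seed.
#' @return list of [growth_curve()] objects with `strain` = `"S1"...`,
#'   `condition`, and `well` labels.
#' @export
make_strain_panel <- function(spec = strain_panel_spec(), seed = 1) {
  stopifnot(inherits(spec, "strain_panel_spec"))
  set.seed(seed)
  curves <- list()
  widx <- 0L
  for (si in seq_len(spec$n_strains)) {
    base <- .jitter_model(spec)
    for (cond in spec$conditions) {
      m <- if (cond == "control") base else apply_perturbation(base, cond)
      sim <- simulate_growth(m, t_end = spec$horizon, dt = spec$dt,
                             od0 = spec$od0)
      for (r in seq_len(spec$replicates)) {
        widx <- widx + 1L
        od <- sim$od * (1 + spec$noise * stats::rnorm(length(sim$od)))
        od <- pmax(od, 1e-6)
        curves[[widx]] <- growth_curve(sim$times, od,
                                       strain = paste0("S", si),
                                       condition = cond,
                                       well = sprintf("W%03d", widx))
      }
    }
  }
  curves
}

#' Generate a synthetic regulon expression dataset
#'
#' Emulates promoter-activity time series in which groups of co-regulated
#' promoters share a latent condition-specific regulator signal. Each
#' (group, condition) pair draws a latent profile — a localized burst with
#' a group-specific dominant period and peak time — and each promoter
#' reports `gain * latent + noise` with a promoter-specific gain (strong
#' versus weak regulation within the same regulon).
#'
#' @param n_groups number of regulons (>= 2).
#' @param promoters_per_group promoters per regulon.
#' @param conditions number of growth conditions (profiles per promoter).
#' @param seed integer seed.
#' @param n_time samples per profile.
#' @param dt sampling interval (hours).
#' @param noise residual noise, as a fraction of the latent signal's SD.
#' @param gain_range range of promoter gains.
#' @return list with `profiles` (list over conditions of
#'   promoters x time matrices), `groups` (true regulon per promoter),
#'   `dt`, and `latents` (list over conditions of group x time matrices).
#' @export
make_expression_dataset <- function(n_groups = 3, promoters_per_group = 6,
                                    conditions = 6, seed = 1, n_time = 96,
                                    dt = 1 / 6, noise = 0.2,
                                    gain_range = c(0.4, 1.6)) {
  stopifnot(n_groups >= 2, promoters_per_group >= 2, conditions >= 1)
  set.seed(seed)
  tt <- dt * (seq_len(n_time) - 1)
  horizon <- max(tt)
  n_prom <- n_groups * promoters_per_group
  groups <- rep(seq_len(n_groups), each = promoters_per_group)
  gains <- stats::runif(n_prom, gain_range[1], gain_range[2])
  profiles <- vector("list", conditions)
  latents <- vector("list", conditions)
  for (cd in seq_len(conditions)) {
    lat <- matrix(0, n_groups, n_time)
    for (g in seq_len(n_groups)) {
      period <- stats::runif(1, 8 * dt, horizon / 2)
      center <- stats::runif(1, 0.2 * horizon, 0.8 * horizon)
      width <- stats::runif(1, 0.1 * horizon, 0.25 * horizon)
      lat[g, ] <- exp(-(tt - center)^2 / (2 * width^2)) *
        sin(2 * pi * tt / period)
    }
    pm <- matrix(0, n_prom, n_time)
    for (i in seq_len(n_prom)) {
      base <- lat[groups[i], ]
      pm[i, ] <- gains[i] * base + noise * stats::sd(base) *
        stats::rnorm(n_time)
    }
    rownames(pm) <- paste0("prom", seq_len(n_prom))
    profiles[[cd]] <- pm
    latents[[cd]] <- lat
  }
  list(profiles = profiles, groups = groups, dt = dt, latents = latents)
}
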