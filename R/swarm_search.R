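# Swarm-based reverse engineering of growth models: particle-swarm
# parameter fitting and stochastic structure search over a library of
# twelve basic equation components.

#' The twelve-component equation library
#'
#' Term templates covering the common formulations of reaction kinetics —
#' power law, mass action, and enzymatic (Michaelis-Menten) kinetics.
#' Six functional forms, each usable as production or consumption:
#' constant `c`, linear `c*X`, quadratic `c*X^2`, product `c*X*Y`,
#' saturating activation `c*X/(K+X)`, and saturating repression
#' `c*K/(K+X)`.
#'
#' @return data frame with columns `id`, `form`, `role`, `n_params`,
#'   `needs_y`; exactly 12 rows.
#' @export
component_library <- function() {
  forms <- data.frame(
    form = c("const", "linear", "quadratic", "product", "mm_act", "mm_rep"),
    n_params = c(1L, 1L, 1L, 1L, 2L, 2L),
    needs_y = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  out <- rbind(cbind(forms, role = "production"),
               cbind(forms, role = "consumption"))
  out$id <- paste(out$form, ifelse(out$role == "production", "+", "-"),
                  sep = "")
  rownames(out) <- NULL
  out[, c("id", "form", "role", "n_params", "needs_y")]
}

# Evaluate one term's rate given state values and its parameter(s).
.term_rate <- function(form, x, y, par) {
  switch(form,
    const = par[1],
    linear = par[1] * x,
    quadratic = par[1] * x^2,
    product = par[1] * x * y,
    mm_act = par[1] * x / (par[2] + x),
    mm_rep = par[1] * par[2] / (par[2] + x),
    stop("unknown term form: ", form))
}

#' Define an equation term
#'
#' @param form one of the six functional forms of [component_library()].
#' @param role `"production"` or `"consumption"` (sign of the term).
#' @param target state the term acts on.
#' @param x primary state slot.
#' @param y secondary state slot (only for `product`).
#' @return a `swarm_term` list.
#' @export
swarm_term <- function(form, role, target, x = NULL, y = NULL) {
  lib <- component_library()
  row <- lib[lib$form == form & lib$role == role, ]
  if (nrow(row) != 1) stop("swarm_term: unknown form/role")
  if (row$needs_y && is.null(y)) stop("swarm_term: '", form, "' needs y")
  if (row$form != "const" && is.null(x)) stop("swarm_term: '", form, "' needs x")
  structure(list(form = form, role = role, target = target,
                 x = x, y = y, n_params = row$n_params),
            class = "swarm_term")
}

#' Assemble a candidate growth-model structure
#'
#' A candidate is the three-variable growth skeleton (G, P, Q and a single
#' consumable substrate N, with \eqn{\mu = G}) whose equations are sums of
#' library terms. Parameters of all terms are concatenated in term order.
#'
#' @param terms list of [swarm_term()].
#' @param init named initial state `(G, P, Q, N)`.
#' @return object of class `candidate_structure` with `terms`, `n_params`,
#'   `init`.
#' @export
candidate_structure <- function(terms,
                                init = c(G = 0.02, P = 0.05, Q = 0.05, N = 1)) {
  stopifnot(length(terms) >= 1,
            all(vapply(terms, inherits, logical(1), "swarm_term")))
  structure(list(terms = terms,
                 n_params = sum(vapply(terms, `[[`, integer(1), "n_params")),
                 init = init,
                 rhs = .compile_structure_rhs(terms),
                 table = .term_table(terms)),
            class = "candidate_structure")
}

# Integer term table consumed by the compiled RK4 kernel.
.term_table <- function(terms) {
  forms <- c(const = 0L, linear = 1L, quadratic = 2L, product = 3L,
             mm_act = 4L, mm_rep = 5L)
  sidx <- c(G = 0L, P = 1L, Q = 2L, N = 3L)
  tab <- matrix(0L, length(terms), 6L)
  off <- 0L
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    tab[i, ] <- c(forms[[tm$form]],
                  if (tm$role == "production") 1L else -1L,
                  sidx[[tm$target]],
                  if (is.null(tm$x)) -1L else sidx[[tm$x]],
                  if (is.null(tm$y)) -1L else sidx[[tm$y]],
                  off)
    off <- off + tm$n_params
  }
  tab
}

# Build a fast parsed right-hand-side closure for a term list once, so the
# integrator does not re-interpret the structure at every step.
.compile_structure_rhs <- function(terms) {
  sidx <- c(G = 1L, P = 2L, Q = 3L, N = 4L)
  yref <- function(s) sprintf("y%d", sidx[[s]])
  dexpr <- c(G = "0", P = "0", Q = "0", N = "0")
  off <- 0L
  for (tm in terms) {
    i1 <- off + 1L; i2 <- off + 2L
    off <- off + tm$n_params
    e <- switch(tm$form,
      const = sprintf("p[[%d]]", i1),
      linear = sprintf("p[[%d]]*%s", i1, yref(tm$x)),
      quadratic = sprintf("p[[%d]]*%s^2", i1, yref(tm$x)),
      product = sprintf("p[[%d]]*%s*%s", i1, yref(tm$x), yref(tm$y)),
      mm_act = sprintf("p[[%d]]*%s/(p[[%d]]+%s)", i1, yref(tm$x), i2,
                       yref(tm$x)),
      mm_rep = sprintf("p[[%d]]*p[[%d]]/(p[[%d]]+%s)", i1, i2, i2,
                       yref(tm$x)),
      stop("unknown term form: ", tm$form))
    op <- if (tm$role == "production") "+" else "-"
    dexpr[tm$target] <- paste0(dexpr[tm$target], op, "(", e, ")")
  }
  src <- sprintf(
    "function(t, y, p) {
       y1 <- max(y[[1L]], 0); y2 <- max(y[[2L]], 0)
       y3 <- max(y[[3L]], 0); y4 <- max(y[[4L]], 0)
       list(c(%s, %s, %s, %s))
     }", dexpr[["G"]], dexpr[["P"]], dexpr[["Q"]], dexpr[["N"]])
  eval(parse(text = src)[[1]])
}

#' @export
print.candidate_structure <- function(x, ...) {
  cat(sprintf("<candidate_structure> %d terms, %d parameters\n",
              length(x$terms), x$n_params))
  for (tm in x$terms)
    cat(sprintf("  d%s/dt %s %s(%s%s)\n", tm$target,
                if (tm$role == "production") "+=" else "-=", tm$form,
                if (is.null(tm$x)) "" else tm$x,
                if (is.null(tm$y)) "" else paste0(",", tm$y)))
  invisible(x)
}

.structure_rhs <- function(t, y, pars) {
  st <- pars$structure
  p <- pars$params
  d <- c(G = 0, P = 0, Q = 0, N = 0)
  yv <- pmax(y, 0)
  off <- 0L
  for (tm in st$terms) {
    par <- p[off + seq_len(tm$n_params)]
    off <- off + tm$n_params
    xv <- if (is.null(tm$x)) 0 else yv[tm$x]
    yv2 <- if (is.null(tm$y)) 0 else yv[tm$y]
    r <- .term_rate(tm$form, xv, yv2, par)
    d[tm$target] <- d[tm$target] + if (tm$role == "production") r else -r
  }
  list(d)
}

#' Simulated growth-rate trajectory of a candidate
#'
#' Integrates a candidate structure (or the native [growth_model()]
#' skeleton when `structure` is a `growth_model`) and returns mu = G
#' interpolated onto the requested times. Integration failure returns
#' `NULL`.
#'
#' @param structure `candidate_structure` or `growth_model`.
#' @param params parameter vector (for a `growth_model`, its `k1..k8`).
#' @param times output times (hours).
#' @param init optional initial-state override (e.g. a reduced initial
#'   nutrient for a low-nutrient condition).
#' @return numeric mu vector or `NULL`.
#' @export
candidate_mu <- function(structure, params, times, init = NULL) {
  dt <- min(diff(times))
  grid <- seq(0, max(times), by = dt)
  # lsoda's Fortran core prints directly on pathological parameter sets;
  # capture and discard, the NULL return carries the failure
  capture <- utils::capture.output(sim <- tryCatch({
    if (inherits(structure, "growth_model")) {
      m <- structure
      m$params[] <- params
      y0 <- if (is.null(init)) m$init else init
      sol <- deSolve::lsoda(y0, grid, .growth_rhs,
                            list(p = m$params, ks = m$sat),
                            rtol = 1e-6, atol = 1e-8)
      if (nrow(sol) < length(grid) || any(!is.finite(sol))) NULL
      else list(times = grid, mu = pmax(sol[, "G"], 0))
    } else {
      y0 <- if (is.null(init)) structure$init else init
      g <- structure_mu_rk4(structure$table, params, as.numeric(y0),
                            dt, length(grid), substeps = 2L)
      if (any(is.na(g))) NULL
      else list(times = grid, mu = pmax(g, 0))
    }
  }, error = function(e) NULL, warning = function(w) NULL))
  if (is.null(sim)) return(NULL)
  stats::approx(sim$times, sim$mu, xout = times, rule = 2)$y
}

# Fitness: mean |mu_sim - mu_data| per time point, averaged over series.
# A series may carry an `init` field overriding the structure's initial
# state (condition-specific inoculum or nutrient).
.swarm_fitness <- function(structure, params, data_list) {
  errs <- vapply(data_list, function(d) {
    mu <- candidate_mu(structure, params, d$times, init = d$init)
    if (is.null(mu)) return(Inf)
    mean(abs(mu - d$mu))
  }, numeric(1))
  mean(errs)
}

#' Swarm configuration defaults
#'
#' Standard constriction-style particle-swarm settings: inertia 0.72,
#' cognitive and social accelerations 1.49, 50 particles. Parameters are
#' searched in log10 space over `bounds` (log-uniform initialization).
#'
#' @param n_particles swarm size.
#' @param n_iters iterations.
#' @param inertia,c_personal,c_global velocity update coefficients.
#' @param bounds parameter bounds (linear scale).
#' @param seed integer seed.
#' @return named list.
#' @export
swarm_config <- function(n_particles = 50, n_iters = 300, inertia = 0.72,
                         c_personal = 1.49, c_global = 1.49,
                         bounds = c(1e-3, 10), seed = 1) {
  stopifnot(n_particles >= 2, n_iters >= 0, all(is.finite(bounds)),
            bounds[1] > 0, bounds[2] > bounds[1])
  list(n_particles = n_particles, n_iters = n_iters, inertia = inertia,
       c_personal = c_personal, c_global = c_global, bounds = bounds,
       seed = seed)
}

#' Fit parameters of a fixed structure by particle swarm
#'
#' Standard PSO: each particle's velocity is updated as
#' `inertia*v + c_p*r1*(pbest - x) + c_g*r2*(gbest - x)` with positions
#' clipped to bounds (in log10 parameter space). The fitness of a
#' parameter vector is the mean absolute growth-rate error per time point,
#' averaged over the supplied strains; candidates whose integration fails
#' score `+Inf` rather than aborting the swarm.
#'
#' @param structure `candidate_structure` or `growth_model`.
#' @param data a [growth_rate_series()] or list of them.
#' @param config a [swarm_config()].
#' @return list: `params` (best, linear scale), `fitness`, `trace`
#'   (per-iteration best fitness, monotone non-increasing).
#' @export
swarm_fit_params <- function(structure, data, config = swarm_config()) {
  if (inherits(data, "growth_rate_series")) data <- list(data)
  n_par <- if (inherits(structure, "growth_model"))
    length(structure$params) else structure$n_params
  obj <- function(x) .swarm_fitness(structure, 10^x, data)
  res <- .pso(obj, n_par, lb = log10(config$bounds[1]),
              ub = log10(config$bounds[2]), config = config)
  list(params = 10^res$x, fitness = res$f, trace = res$trace)
}

# Generic particle swarm over a box [lb, ub]^n_par; non-finite objective
# values are treated as +Inf.
.pso <- function(obj, n_par, lb, ub, config = swarm_config()) {
  set.seed(config$seed)
  np <- config$n_particles
  score <- function(x) { v <- obj(x); if (is.finite(v)) v else Inf }
  X <- matrix(stats::runif(np * n_par, lb, ub), np, n_par)
  V <- matrix(0, np, n_par)
  fit <- apply(X, 1, score)
  Pb <- X; pbf <- fit
  g <- which.min(fit)
  gb <- X[g, ]; gbf <- fit[g]
  trace <- numeric(config$n_iters)
  for (it in seq_len(config$n_iters)) {
    r1 <- matrix(stats::runif(np * n_par), np, n_par)
    r2 <- matrix(stats::runif(np * n_par), np, n_par)
    V <- config$inertia * V + config$c_personal * r1 * (Pb - X) +
      config$c_global * r2 * sweep(-X, 2, gb, `+`)
    X <- pmin(pmax(X + V, lb), ub)
    fit <- apply(X, 1, score)
    upd <- fit < pbf
    Pb[upd, ] <- X[upd, ]; pbf[upd] <- fit[upd]
    g <- which.min(pbf)
    if (pbf[g] < gbf) { gbf <- pbf[g]; gb <- Pb[g, ] }
    trace[it] <- gbf
  }
  list(x = gb, f = gbf, trace = trace)
}

#' Enumerate structures over per-slot component options
#'
#' Deterministic, duplicate-free Cartesian enumeration: each slot offers a
#' list of alternative terms (or `NULL` for an empty slot) and a structure
#' picks one option per slot on top of a fixed backbone of terms.
#'
#' @param slot_options list of slots; each slot is a list of
#'   [swarm_term()] options (may include `NULL`).
#' @param backbone list of [swarm_term()] present in every structure.
#' @param init initial state passed to [candidate_structure()].
#' @param max_structures refuse (with the count) beyond this cap.
#' @return list of `candidate_structure`; each carries a `choice`
#'   attribute with its per-slot option indices.
#' @export
enumerate_structures <- function(slot_options, backbone = list(),
                                 init = c(G = 0.02, P = 0.05, Q = 0.05, N = 1),
                                 max_structures = 10000) {
  stopifnot(length(slot_options) >= 1)
  counts <- vapply(slot_options, length, integer(1))
  total <- prod(counts)
  if (total > max_structures)
    stop("enumerate_structures: ", total, " structures exceed the cap of ",
         max_structures)
  grid <- expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    choice <- as.integer(grid[i, ])
    terms <- backbone
    for (s in seq_along(slot_options)) {
      opt <- slot_options[[s]][[choice[s]]]
      if (!is.null(opt)) terms <- c(terms, list(opt))
    }
    st <- candidate_structure(terms, init = init)
    attr(st, "choice") <- choice
    st
  })
}

#' Evolve growth-model structures with an outer swarm
#'
#' Maintains a population of candidate structures over the slot space.
#' Each outer round fits every structure's parameters with an inner
#' particle swarm ([swarm_fit_params()]), ranks structures by fitness
#' (mean absolute growth-rate error per time point, averaged over
#' strains; ties within `1e-4` broken toward fewer terms, the parsimony
#' rule), then evolves every non-best structure toward the best: each
#' differing slot adopts the best structure's component with probability
#' `p_adopt`, otherwise resamples from that slot's options.
#'
#' @param data a [growth_rate_series()] or list of them (panel of
#'   strains/conditions); the structure is shared and one parameter vector
#'   is fitted jointly through the averaged fitness (a series may carry an
#'   `init` field for condition-specific initial states).
#' @param slot_options,backbone,init structure space, as in
#'   [enumerate_structures()].
#' @param n_models population size.
#' @param n_outer_iters outer evolution rounds (0 = score the initial
#'   population only).
#' @param p_adopt adoption probability during evolution.
#' @param inner_config [swarm_config()] for the parameter fits.
#' @param n_restarts inner-swarm restarts per structure (best fit kept).
#' @param seed integer seed.
#' @return list: `structure` (best `candidate_structure`), `choice`,
#'   `fit` (its [swarm_fit_params()] result), `history` (best fitness per
#'   outer round), `population` (final choices and fitnesses).
#' @export
swarm_search_structure <- function(data, slot_options, backbone = list(),
                                   init = c(G = 0.02, P = 0.05, Q = 0.05, N = 1),
                                   n_models = 6, n_outer_iters = 3,
                                   p_adopt = 0.5,
                                   inner_config = swarm_config(n_particles = 20,
                                                               n_iters = 60),
                                   n_restarts = 2, seed = 1) {
  if (inherits(data, "growth_rate_series")) data <- list(data)
  stopifnot(n_models >= 2)
  counts <- vapply(slot_options, length, integer(1))
  build <- function(choice) {
    terms <- backbone
    for (s in seq_along(slot_options)) {
      opt <- slot_options[[s]][[choice[s]]]
      if (!is.null(opt)) terms <- c(terms, list(opt))
    }
    st <- candidate_structure(terms, init = init)
    attr(st, "choice") <- choice
    st
  }
  # A structure's fitness is a deterministic, memoized function of
  # (structure, data, seed): the inner swarm is seeded by the structure's
  # identity, so re-encountered structures are never refitted and ranking
  # is reproducible.
  cache <- new.env(parent = emptyenv())
  evaluate <- function(choice) {
    key <- paste(choice, collapse = "-")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    st <- build(choice)
    base <- (seed %% 100000L) * 13L + sum(choice * 7L^seq_along(choice))
    fits <- lapply(seq_len(n_restarts), function(r) {
      cfg <- inner_config
      cfg$seed <- base + r
      swarm_fit_params(st, data, cfg)
    })
    f <- fits[[which.min(vapply(fits, `[[`, numeric(1), "fitness"))]]
    out <- list(structure = st, fit = f, n_terms = length(st$terms))
    cache[[key]] <- out
    out
  }
  best_of <- function(evals) {
    fs <- vapply(evals, function(e) e$fit$fitness, numeric(1))
    cand <- which(fs <= min(fs) + 1e-4)   # parsimony tie-break
    cand[which.min(vapply(evals[cand], `[[`, numeric(1), "n_terms"))]
  }
  set.seed(seed)
  choices <- replicate(n_models,
                       vapply(counts, function(k) sample.int(k, 1), integer(1)),
                       simplify = FALSE)
  evals <- lapply(choices, evaluate)
  history <- numeric(0)
  for (round in seq_len(max(n_outer_iters, 0))) {
    b <- best_of(evals)
    history <- c(history, evals[[b]]$fit$fitness)
    best_choice <- attr(evals[[b]]$structure, "choice")
    for (i in seq_len(n_models)) {
      if (i == b) next
      ch <- attr(evals[[i]]$structure, "choice")
      for (s in seq_along(ch)) {
        if (ch[s] != best_choice[s]) {
          ch[s] <- if (stats::runif(1) < p_adopt) best_choice[s]
                   else sample.int(counts[s], 1)
        }
      }
      if (all(ch == best_choice)) {
        # exploration kick: a member that has fully converged onto the
        # best structure resamples one random slot instead of freezing
        s <- sample.int(length(ch), 1)
        ch[s] <- sample.int(counts[s], 1)
      }
      choices[[i]] <- ch
      evals[[i]] <- evaluate(ch)
    }
  }
  b <- best_of(evals)
  history <- c(history, evals[[b]]$fit$fitness)
  list(structure = evals[[b]]$structure,
       choice = attr(evals[[b]]$structure, "choice"),
       fit = evals[[b]]$fit, history = history,
       population = list(choices = lapply(evals, function(e)
         attr(e$structure, "choice")),
         fitness = vapply(evals, function(e) e$fit$fitness, numeric(1))))
}

#' A small benchmark structure space with an identifiable truth
#'
#' A three-option structure space used to validate the structure search
#' against exhaustive enumeration: the growth backbone (autocatalytic G
#' production from a latent nutrient-driven pool P, single consumable
#' substrate) is fixed, and the open slot is the consumption law of the
#' observed growth modulator G — quadratic (growth dilution), linear
#' (first-order turnover), or saturating. Because the slot acts on the
#' observed variable, the decay-tail shape (power law, exponential, or
#' finite-time ramp) identifies the component; the latent dynamics cannot
#' mimic it.
#'
#' @param truth_params parameter vector of the generating (quadratic)
#'   structure, ordered as backbone terms then slot term.
#' @param t_end,dt data grid (hours).
#' @param low_nutrient_fraction second condition's initial-nutrient
#'   fraction (two conditions are generated; joint fitting over both is
#'   what makes the slot identifiable).
#' @return list: `backbone`, `slots`, `truth_index` (option index of the
#'   generating slot), `truth` (structure), `data` (list of two noiseless
#'   [growth_rate_series()] with `init` fields).
#' @export
toy_structure_space <- function(truth_params = c(0.8, 1.2, 0.3, 0.8, 0.5, 1.0),
                                t_end = 14, dt = 1 / 6,
                                low_nutrient_fraction = 0.5) {
  backbone <- list(
    swarm_term("product", "production", "G", x = "P", y = "G"),
    swarm_term("mm_act", "production", "P", x = "N"),
    swarm_term("linear", "consumption", "P", x = "P"),
    swarm_term("product", "consumption", "N", x = "P", y = "N"))
  slots <- list(list(
    swarm_term("quadratic", "consumption", "G", x = "G"),
    swarm_term("linear", "consumption", "G", x = "G"),
    swarm_term("mm_act", "consumption", "G", x = "G")))
  truth <- candidate_structure(c(backbone, list(slots[[1]][[1]])))
  tt <- seq(dt, t_end, by = dt)
  i2 <- truth$init
  i2["N"] <- i2["N"] * low_nutrient_fraction
  mu1 <- candidate_mu(truth, truth_params, tt)
  mu2 <- candidate_mu(truth, truth_params, tt, init = i2)
  if (is.null(mu1) || is.null(mu2))
    stop("toy_structure_space: truth parameters fail to integrate")
  d1 <- growth_rate_series(tt, mu1, strain = "S", condition = "control")
  d2 <- growth_rate_series(tt, mu2, strain = "S", condition = "low_nutrient")
  d2$init <- i2
  list(backbone = backbone, slots = slots, truth_index = 1L, truth = truth,
       data = list(d1, d2))
}
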