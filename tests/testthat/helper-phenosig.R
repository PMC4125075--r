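# Shared fixtures, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small strain panel (single condition) for pipeline tests.
quiet_panel <- function(seed = 1, ...) {
  suppressMessages(make_strain_panel(
    strain_panel_spec(conditions = "control", ...), seed = seed))
}

# A deterministic growth curve from the default model.
default_curve <- function(noise = 0, seed = 1, t_end = 14) {
  sim <- simulate_growth(growth_model(), t_end = t_end)
  od <- sim$od
  if (noise > 0) {
    set.seed(seed)
    od <- pmax(od * (1 + noise * rnorm(length(od))), 1e-6)
  }
  growth_curve(sim$times, od, strain = "mg", condition = "ctrl", well = "A1")
}

# From-definition Davies-Bouldin reimplementation (independent oracle).
db_brute <- function(features, labels) {
  features <- as.matrix(features)
  labs <- sort(unique(labels))
  K <- length(labs)
  cent <- lapply(labs, function(g) colMeans(features[labels == g, , drop = FALSE]))
  S <- sapply(seq_len(K), function(i) {
    m <- features[labels == labs[i], , drop = FALSE]
    mean(apply(m, 1, function(r) sqrt(sum((r - cent[[i]])^2))))
  })
  tot <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      r <- if (M == 0) Inf else (S[i] + S[j]) / M
      worst <- max(worst, r)
    }
    tot <- tot + worst
  }
  tot / K
}

# Exhaustive-permutation misclassification count (independent oracle).
misclass_brute <- function(pred, true) {
  p <- as.integer(factor(pred)); g <- as.integer(factor(true))
  m <- max(max(p), max(g))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (r in perms(v[-i])) out <- c(out, list(c(v[i], r)))
    out
  }
  best <- Inf
  for (pp in perms(seq_len(m))) best <- min(best, sum(pp[p] != g))
  best
}
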