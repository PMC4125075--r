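# End-to-end strain classification workflow: curves -> growth rates ->
# scaleograms -> period selection -> clustering -> misclassification.

#' Growth-rate series for a set of curves
#'
#' Optionally denoises each OD curve (db4 universal soft threshold) before
#' taking central differences.
#'
#' @param curves list of [growth_curve()].
#' @param denoise denoise OD before differentiating.
#' @param method growth-rate variant, see [compute_growth_rate()].
#' @return list of [growth_rate_series()].
#' @export
panel_growth_rates <- function(curves, denoise = TRUE,
                               method = c("od", "log")) {
  method <- match.arg(method)
  lapply(curves, function(cv) {
    if (denoise) cv <- growth_curve(cv$times, pmax(denoise_curve(cv$od), 1e-6),
                                    strain = cv$strain,
                                    condition = cv$condition, well = cv$well)
    compute_growth_rate(cv, method = method)
  })
}

#' Classify a panel of growth curves by wavelet signatures
#'
#' The complete signature workflow: compute specific growth rates
#' (denoised OD), wavelet-transform each series on a shared period grid,
#' select the most informative period by Davies-Bouldin score against the
#' known strain labels, cluster the signature vectors at that period with
#' average-linkage hierarchical clustering, and count permutation-minimal
#' misclassifications. With `use_raw = TRUE` the growth-rate vectors
#' themselves are clustered instead (the conventional comparison).
#'
#' @param curves list of [growth_curve()] (one condition; use
#'   [multiplex()] upstream for multi-condition series).
#' @param k number of clusters; defaults to the number of distinct strains.
#' @param use_raw cluster raw growth-rate vectors instead of signatures.
#' @param denoise denoise OD curves before computing growth rates.
#' @param periods optional shared period grid.
#' @param exclude optional period-exclusion mask, see [choose_period()].
#' @return list: `features`, `clustering` ([hcluster()] result),
#'   `n_misclassified`, `true_strains`, and for the wavelet branch
#'   `period` (chosen), `db_by_period`, `signatures`.
#' @export
classify_panel <- function(curves, k = NULL, use_raw = FALSE, denoise = TRUE,
                           periods = NULL, exclude = NULL) {
  stopifnot(length(curves) >= 2)
  strains <- vapply(curves, `[[`, character(1), "strain")
  if (is.null(k)) k <- length(unique(strains))
  rates <- panel_growth_rates(curves, denoise = denoise)
  if (use_raw) {
    feats <- do.call(rbind, lapply(rates, `[[`, "mu"))
    rownames(feats) <- make.unique(strains)
    cl <- hcluster(feats, k)
    return(list(features = feats, clustering = cl,
                n_misclassified = misclassification_count(cl$labels, strains),
                true_strains = strains))
  }
  sigs <- lapply(rates, wavelet_transform, periods = periods)
  sel <- choose_period(sigs, strains, exclude = exclude)
  feats <- do.call(rbind, lapply(sigs, signature_vector, period = sel$period))
  rownames(feats) <- make.unique(strains)
  cl <- hcluster(feats, k)
  list(features = feats, clustering = cl,
       n_misclassified = misclassification_count(cl$labels, strains),
       true_strains = strains, period = sel$period,
       db_by_period = sel$db_by_period, periods = sel$periods,
       signatures = sigs)
}

#' Multiplexed growth-rate series per strain
#'
#' Groups a panel's growth-rate series by (strain, replicate) and
#' concatenates each strain-replicate's series across conditions in a
#' fixed condition order.
#'
#' @param curves list of [growth_curve()] spanning several conditions with
#'   matching replicate structure.
#' @param conditions condition order to concatenate in.
#' @param denoise denoise OD before computing rates.
#' @return list of multiplexed [growth_rate_series()], one per
#'   strain-replicate.
#' @export
multiplex_panel <- function(curves,
                            conditions = c("control", "plasmid",
                                           "low_temperature", "low_nutrient"),
                            denoise = TRUE) {
  rates <- panel_growth_rates(curves, denoise = denoise)
  strains <- vapply(curves, `[[`, character(1), "strain")
  conds <- vapply(curves, `[[`, character(1), "condition")
  out <- list()
  for (s in unique(strains)) {
    per_cond <- lapply(conditions, function(cd) rates[strains == s & conds == cd])
    n_rep <- unique(vapply(per_cond, length, integer(1)))
    if (length(n_rep) != 1)
      stop("multiplex_panel: unbalanced replicates across conditions for ", s)
    for (r in seq_len(n_rep)) {
      out[[length(out) + 1]] <- multiplex(lapply(per_cond, `[[`, r))
    }
  }
  out
}
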