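#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a VIF-screened Cox model
#'
#' One row per retained covariate with the hazard ratio and its 95%
#' confidence interval.
#'
#' @param x a `cohort_cox` from [cox_ph()].
#' @param conf.level confidence level (default 0.95).
#' @param ... unused.
#' @return tibble: term, estimate (log HR), hr, conf.low, conf.high
#'   (HR scale), statistic, p.value.
#' @export
tidy.cohort_cox <- function(x, conf.level = 0.95, ...) {
  s <- summary(x$fit, conf.int = conf.level)
  co <- s$coefficients
  ci <- s$conf.int
  tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hr = ci[, 1],
    conf.low = ci[, 3],
    conf.high = ci[, 4],
    statistic = co[, "z"],
    p.value = co[, "Pr(>|z|)"]
  )
}

#' @rdname tidy.cohort_cox
#' @return `glance()`: one row with n, events, concordance, likelihood-ratio
#'   statistic/p, and the number of VIF-dropped covariates.
#' @export
glance.cohort_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n, events = x$events,
    concordance = unname(s$concordance[1]),
    logtest_stat = unname(s$logtest["test"]),
    logtest_p = unname(s$logtest["pvalue"]),
    n_dropped_vif = nrow(x$dropped)
  )
}

#' Tidy consensus-clustering results
#'
#' @param x a `hox_consensus` from [consensus_cluster()].
#' @param ... unused.
#' @return per-sample tibble (sample_id, majority_label, switch_freq,
#'   retained).
#' @export
tidy.hox_consensus <- function(x, ...) x$samples

#' @rdname tidy.hox_consensus
#' @return `glance()`: one row with n, n_runs, n_excluded, and the label
#'   split among retained samples.
#' @export
glance.hox_consensus <- function(x, ...) {
  s <- x$samples
  tibble(
    n = nrow(s), n_runs = x$params$n_runs,
    n_excluded = sum(!s$retained),
    n_high = sum(s$retained & s$majority_label == "HOX-high"),
    n_low = sum(s$retained & s$majority_label == "HOX-low")
  )
}

#' Tidy an arm-dosage profile
#'
#' @param x an `arm_dosage` from [infer_arm_dosage()].
#' @param ... unused.
#' @return per cluster x arm tibble with score and call.
#' @export
tidy.arm_dosage <- function(x, ...) x$cluster_arms

#' @rdname tidy.arm_dosage
#' @export
glance.arm_dosage <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_metacells = sum(x$clusters$n_metacells),
    tau = x$params$tau,
    window = x$params$window
  )
}
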