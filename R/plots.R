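#' @importFrom ggplot2 ggplot aes geom_point geom_histogram geom_vline
#'   geom_tile labs scale_fill_gradient2 theme_minimal autoplot facet_wrap
#'   geom_step
NULL

#' @export
ggplot2::autoplot

#' Plot consensus-clustering results
#'
#' The last run's 2-D embedding, colored by majority label, with excluded
#' (unstable) samples marked.
#'
#' @param object a `hox_consensus`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hox_consensus <- function(object, ...) {
  df <- tibble(
    x = object$embedding[, 1], y = object$embedding[, 2],
    label = object$samples$majority_label,
    retained = object$samples$retained
  )
  ggplot(df, aes(.data$x, .data$y, colour = .data$label,
                 shape = .data$retained)) +
    geom_point(size = 1.8, alpha = 0.8) +
    labs(x = "UMAP 1", y = "UMAP 2", colour = "consensus",
         shape = "retained",
         title = "Consensus pan-HOX methylation clusters") +
    theme_minimal()
}

#' Plot signature calls against the threshold
#'
#' Histogram of per-sample signature values split by expression status,
#' with the hypermethylation threshold marked.
#'
#' @param object a `signature_calls` from [classify_signature()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.signature_calls <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot(as_tibble(object), aes(.data$signature,
                                fill = .data$expression_status)) +
    geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    geom_vline(xintercept = thr, linetype = 2) +
    labs(x = "three-probe gene-body signature (beta)", y = "patients",
         fill = "expression",
         title = sprintf("Hypermethylation threshold %.4f",
                         truncate_decimals(thr))) +
    theme_minimal()
}

#' Heatmap of arm-level dosage scores per cluster
#'
#' @param object an `arm_dosage`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.arm_dosage <- function(object, ...) {
  ggplot(object$cluster_arms,
         aes(.data$arm, .data$cluster, fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = "chromosome arm", y = "cluster",
         fill = "log2 dosage",
         title = "Inferred arm-level relative dosage") +
    theme_minimal()
}

#' Kaplan-Meier curves for a dichotomized biomarker
#'
#' @param data data frame with time, event and group columns.
#' @param time,event,group column names.
#' @return a ggplot of the Kaplan-Meier estimates per group.
#' @export
plot_survival <- function(data, time = "os_time", event = "os_event",
                          group) {
  g <- as.factor(data[[group]])
  fit <- survival::survfit(
    survival::Surv(data[[time]], data[[event]]) ~ g)
  strata <- rep(names(fit$strata), fit$strata)
  df <- tibble(time = fit$time, surv = fit$surv,
               group = sub("^g=", "", strata))
  ggplot(df, aes(.data$time, .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "years", y = "overall survival", colour = group) +
    theme_minimal()
}
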