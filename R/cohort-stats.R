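#' Log-rank test between two groups
#'
#' Standard log-rank chi-square on the pooled event times with the p-value
#' from a 1-df chi-square. The statistic is invariant to swapping group
#' labels.
#'
#' @param data data frame with one row per patient.
#' @param time,event,group column names (strings) for follow-up time,
#'   event indicator (logical/0-1), and the two-level grouping.
#' @return one-row tibble: statistic, df, p, n per group, events per group.
#' @export
logrank_test <- function(data, time = "os_time", event = "os_event",
                         group) {
  t <- data[[time]]; e <- data[[event]]; g <- as.factor(data[[group]])
  keep <- complete.cases(t, e, g)
  t <- t[keep]; e <- e[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2) abort("`group` must have exactly 2 non-empty levels.")
  if (sum(e) < 1) abort("need at least one event.")
  fit <- survival::survdiff(survival::Surv(t, e) ~ g)
  tibble(
    statistic = fit$chisq, df = 1,
    p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
    n1 = sum(g == levels(g)[1]), n2 = sum(g == levels(g)[2]),
    events1 = fit$obs[1], events2 = fit$obs[2]
  )
}

# VIF by auxiliary regressions on the (dummy-coded) design matrix
design_vif <- function(mm) {
  vapply(seq_len(ncol(mm)), function(j) {
    others <- mm[, -j, drop = FALSE]
    if (!ncol(others)) return(1)
    fit <- stats::lm.fit(cbind(1, others), mm[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((mm[, j] - mean(mm[, j]))^2)
    if (r2 >= 1) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Cox proportional-hazards regression with VIF screening
#'
#' Computes the variance inflation factor of every covariate column of the
#' dummy-coded design matrix by auxiliary linear regressions. Columns
#' exceeding `vif_cutoff` (default 10) are eliminated sequentially -- the
#' worst offender first, VIFs recomputed after each removal, so one copy of
#' a duplicated covariate survives -- and reported; the Cox model is fitted
#' on the remainder with Efron's tie handling.
#'
#' @param data data frame with one row per patient.
#' @param time,event column names for follow-up time and event indicator.
#' @param covariates character vector of covariate column names.
#' @param vif_cutoff VIF above which a covariate is omitted (default 10).
#' @return object of class `cohort_cox`: the `survival::coxph` fit plus a
#'   `dropped` tibble (term, vif). Use [generics::tidy()] for hazard
#'   ratios with confidence intervals.
#' @export
cox_ph <- function(data, time = "os_time", event = "os_event",
                   covariates, vif_cutoff = 10) {
  if (!length(covariates)) abort("need at least one covariate.")
  df <- data[, c(time, event, covariates)]
  df <- df[complete.cases(df), ]
  mm <- stats::model.matrix(
    stats::reformulate(covariates), data = df)[, -1, drop = FALSE]
  vif0 <- design_vif(mm)
  X <- mm
  dropped <- tibble(term = character(), vif = numeric())
  repeat {
    vif <- design_vif(X)
    if (ncol(X) == 1 || max(vif) <= vif_cutoff) break
    j <- which.max(vif)
    dropped <- bind_rows(dropped,
                         tibble(term = colnames(X)[j], vif = vif[j]))
    X <- X[, -j, drop = FALSE]
  }
  if (sum(df[[event]]) < ncol(X)) {
    abort("fewer events than covariates after the VIF screen.")
  }
  fit_df <- cbind(df[, c(time, event)], as.data.frame(X))
  colnames(fit_df) <- c(".time", ".event", colnames(X))
  fml <- stats::reformulate(
    sprintf("`%s`", colnames(X)), response = "survival::Surv(.time, .event)")
  fit <- survival::coxph(fml, data = fit_df, ties = "efron")
  structure(list(fit = fit, dropped = dropped,
                 vif = setNames(vif0, colnames(mm)),
                 n = nrow(df), events = sum(df[[event]])),
            class = "cohort_cox")
}

#' @export
print.cohort_cox <- function(x, ...) {
  cat("<cohort_cox> n =", x$n, ", events =", x$events, "\n")
  if (nrow(x$dropped)) {
    cat("dropped (VIF):", paste(x$dropped$term, collapse = ", "), "\n")
  }
  print(x$fit)
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by summing the probabilities of all margin-preserving
#' tables no more probable than the observed one (the enumeration
#' definition). Negative entries are rejected; a zero margin gives p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return one-row tibble: p, odds_ratio.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) abort("`tab` must be 2x2.")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must contain non-negative integers.")
  }
  ft <- stats::fisher.test(tab)
  tibble(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Mann-Whitney U test
#'
#' Wrapper with the exact null distribution below `exact_max` observations
#' (ties permitting) and the normal approximation above.
#'
#' @param x,y numeric samples.
#' @param exact_max use the exact distribution when both samples are at
#'   most this large and untied (default 50).
#' @return one-row tibble: U statistic and p.
#' @export
mann_whitney <- function(x, y, exact_max = 50) {
  exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  tibble(U = unname(wt$statistic), p = wt$p.value)
}

#' Pearson correlation with its t-based p-value
#'
#' @param x,y numeric vectors.
#' @return one-row tibble: r, p, n.
#' @export
pearson <- function(x, y) {
  keep <- complete.cases(x, y)
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Benjamini-Hochberg FDR
#'
#' Step-up adjustment with monotonicity enforcement; a single p-value is
#' returned unchanged.
#'
#' @param p vector of p-values.
#' @return vector of FDR values.
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")

#' Normality and unimodality tests
#'
#' Shapiro-Wilk for normality and Hartigan's dip (Monte Carlo calibrated
#' against the uniform null, see [dip_test()]) for unimodality. Constant
#' input is flagged undefined rather than tested.
#'
#' @param x numeric vector (n >= 8).
#' @param n_sim Monte Carlo replicates for the dip p-value.
#' @param seed seed for the Monte Carlo null.
#' @return one-row tibble: shapiro_p, dip_p, dip_stat, status.
#' @export
normality_unimodality <- function(x, n_sim = 1000, seed = 1) {
  x <- x[!is.na(x)]
  if (length(x) < 8) abort("need at least 8 observations.")
  if (sd(x) == 0) {
    return(tibble(shapiro_p = NA_real_, dip_p = NA_real_,
                  dip_stat = NA_real_, status = "degenerate"))
  }
  sw <- stats::shapiro.test(x)
  dt <- dip_test(x, n_sim = n_sim, seed = seed)
  tibble(shapiro_p = sw$p.value, dip_p = dt$p, dip_stat = dt$statistic,
         status = "ok")
}

#' Call chromosome 15q loss
#'
#' 15q is lost iff strictly more than half of its genes are lost.
#'
#' @param lost logical vector, one entry per gene on 15q.
#' @return logical scalar.
#' @export
#' @examples
#' call_15q_loss(rep(c(TRUE, FALSE), c(60, 40)))  # TRUE
#' call_15q_loss(rep(c(TRUE, FALSE), c(50, 50)))  # FALSE: not "more than half"
call_15q_loss <- function(lost) {
  lost <- lost[!is.na(lost)]
  if (!length(lost)) abort("need at least one gene on 15q.")
  mean(lost) > 0.5
}

#' Call CDKN2A homozygous deletion
#'
#' Homozygous deletion iff at least two of the three per-version GISTIC
#' scores equal -2.
#'
#' @param scores integer vector of exactly 3 GISTIC scores.
#' @return logical scalar.
#' @export
#' @examples
#' call_cdkn2a_homdel(c(-2, -2, 0))  # TRUE
#' call_cdkn2a_homdel(c(-2, 0, 0))   # FALSE
call_cdkn2a_homdel <- function(scores) {
  if (length(scores) != 3) abort("exactly three per-version scores required.")
  sum(scores == -2, na.rm = TRUE) >= 2
}

#' Label adjuvant chemotherapy/radiation from treatment records
#'
#' A patient's treatment is adjuvant when its regimen label equals
#' "ADJUVANT", or when it started within `cutoff_days` of diagnosis
#' (default 244 days, i.e. 8 months at 30.5 days/month) and was the first
#' treatment administered. Records carrying neither a label nor a start
#' day are left unlabeled (`NA`), never forced to `FALSE`.
#'
#' @param treatments data frame with sample_id, regimen_label, start_day,
#'   order_index (start days relative to diagnosis, must be >= 0).
#' @param cutoff_days the "8 months" cutoff in days (default 244).
#' @return tibble with sample_id and adjuvant (logical) per patient: TRUE
#'   if any record qualifies.
#' @export
label_adjuvant <- function(treatments, cutoff_days = 244) {
  if (any(treatments$start_day < 0, na.rm = TRUE)) {
    abort("treatment start days must be non-negative.")
  }
  rec <- treatments |>
    mutate(adj = dplyr::case_when(
      !is.na(.data$regimen_label) & .data$regimen_label == "ADJUVANT" ~ TRUE,
      !is.na(.data$start_day) &
        .data$start_day <= cutoff_days & .data$order_index == 1 ~ TRUE,
      is.na(.data$regimen_label) & is.na(.data$start_day) ~ NA,
      TRUE ~ FALSE
    ))
  rec |>
    group_by(.data$sample_id) |>
    summarise(adjuvant = if (all(is.na(.data$adj))) NA else
      any(.data$adj, na.rm = TRUE), .groups = "drop")
}
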