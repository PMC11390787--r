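#' The three HOXD12 gene-body signature probes
#'
#' @return character vector of probe ids.
#' @export
hoxd12_signature_probes <- function() .HOXD12_BODY_PROBES

#' Correlate methylation probes with expression
#'
#' Pearson correlation between each probe's beta values and a per-sample
#' expression vector, with the p-value from the standard t transform of r.
#' Probes (or an expression vector) with zero variance are flagged
#' `"degenerate"` rather than silently reported as r = 0.
#'
#' @param beta samples x probes matrix of beta values in `[0, 1]`.
#' @param expr named numeric vector of expression values (names = sample
#'   ids) or a data frame with `sample_id` and a value column.
#' @param probes probe ids to test; default all columns of `beta`.
#' @return tibble with probe_id, n, r, p, status ("ok" or "degenerate").
#' @export
correlate_probes_with_expression <- function(beta, expr, probes = NULL) {
  check_beta_matrix(beta)
  if (is.data.frame(expr)) {
    val_col <- setdiff(names(expr), c("sample_id", "gene"))[1]
    expr <- setNames(expr[[val_col]], expr$sample_id)
  }
  probes <- probes %||% colnames(beta)
  common <- intersect(rownames(beta), names(expr))
  purrr::map_dfr(probes, function(p) {
    x <- beta[common, p]
    y <- expr[common]
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3) {
      return(tibble(probe_id = p, n = length(x), r = NA_real_,
                    p = NA_real_, status = "too_few"))
    }
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(probe_id = p, n = length(x), r = NA_real_,
                    p = NA_real_, status = "degenerate"))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble(probe_id = p, n = length(x), r = unname(ct$estimate),
           p = ct$p.value, status = "ok")
  })
}

#' Screen probes for age, survival, and multivariate survival association
#'
#' Each probe is dichotomized at its cohort median beta; age association is
#' tested by Mann-Whitney across the split, univariate survival by the
#' log-rank test, and multivariate survival by a Cox model on the
#' continuous beta adjusting for age and grade. A probe passes when all
#' three p-values fall below `alpha`. Degenerate dichotomizations (all
#' samples on one side) fail with a reason code.
#'
#' @param beta samples x probes matrix.
#' @param clinical data frame with sample_id, age, grade, os_time, os_event.
#' @param probes probe ids to screen; default all.
#' @param alpha significance level applied to every test (default 0.05).
#' @return tibble with probe_id, age_p, surv_p, multiv_p, passed, reason.
#' @export
screen_probes <- function(beta, clinical, probes = NULL, alpha = 0.05) {
  check_beta_matrix(beta)
  stopifnot(all(c("sample_id", "age", "grade", "os_time", "os_event") %in%
                  names(clinical)))
  probes <- probes %||% colnames(beta)
  cl <- clinical[match(rownames(beta), clinical$sample_id), ]
  purrr::map_dfr(probes, function(p) {
    b <- beta[, p]
    keep <- complete.cases(b, cl$age, cl$os_time, cl$os_event)
    b <- b[keep]
    dat <- cl[keep, ]
    hi <- b > median(b)
    if (all(hi) || !any(hi)) {
      return(tibble(probe_id = p, age_p = NA_real_, surv_p = NA_real_,
                    multiv_p = NA_real_, passed = FALSE,
                    reason = "degenerate"))
    }
    age_p <- stats::wilcox.test(dat$age[hi], dat$age[!hi])$p.value
    sd_fit <- survival::survdiff(
      survival::Surv(dat$os_time, dat$os_event) ~ hi)
    surv_p <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
    cox <- tryCatch(
      survival::coxph(survival::Surv(dat$os_time, dat$os_event) ~
                        b + dat$age + factor(dat$grade)),
      error = function(e) NULL, warning = function(w) suppressWarnings(
        survival::coxph(survival::Surv(dat$os_time, dat$os_event) ~
                          b + dat$age + factor(dat$grade))))
    multiv_p <- if (is.null(cox)) NA_real_ else
      summary(cox)$coefficients["b", "Pr(>|z|)"]
    passed <- !anyNA(c(age_p, surv_p, multiv_p)) &&
      age_p < alpha && surv_p < alpha && multiv_p < alpha
    tibble(probe_id = p, age_p = age_p, surv_p = surv_p,
           multiv_p = multiv_p, passed = passed,
           reason = if (passed) NA_character_ else "not_significant")
  })
}

#' Three-probe gene-body methylation signature
#'
#' The signature of a sample is the arithmetic mean of the beta values of
#' the three gene-body probes. A sample missing any of the three probes
#' receives an explicit `NA` signature, never an imputed value; a probe
#' absent from the matrix is an error naming the probe.
#'
#' @param beta samples x probes matrix.
#' @param probes the signature probes (default the HOXD12 gene-body trio).
#' @return tibble with sample_id and signature.
#' @export
#' @examples
#' m <- matrix(c(0.2, 0.3, 0.4), 1,
#'             dimnames = list("s1", hoxd12_signature_probes()))
#' signature_value(m)$signature  # 0.3
signature_value <- function(beta, probes = hoxd12_signature_probes()) {
  check_beta_matrix(beta)
  missing <- setdiff(probes, colnames(beta))
  if (length(missing)) {
    abort(sprintf("signature probe(s) missing from matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  tibble(sample_id = rownames(beta),
         signature = unname(rowMeans(beta[, probes, drop = FALSE])))
}

#' Derive the hypermethylation threshold from status-group means
#'
#' The threshold is the midpoint of the mean signature among
#' expression-negative samples and the mean signature among
#' expression-positive samples. Full precision is used internally; the
#' reported value is conventionally truncated to four decimals with
#' [truncate_decimals()] (midpoint 0.35775 reported as 0.3577).
#'
#' @param data data frame with a signature column and a status column, or a
#'   numeric signature vector (then `status` must be a vector too).
#' @param signature,status column names (tidy-style, as strings) when
#'   `data` is a data frame.
#' @param positive value of `status` identifying the positive group.
#' @return double: the midpoint threshold at full precision, with the two
#'   group means in attribute `"group_means"`.
#' @export
#' @examples
#' derive_threshold(data.frame(sig = c(0.3034, 0.4121),
#'                             st = c("negative", "positive")),
#'                  signature = "sig", status = "st")
derive_threshold <- function(data, signature = "signature",
                             status = "expression_status",
                             positive = "positive") {
  if (is.data.frame(data)) {
    sig <- data[[signature]]
    st <- data[[status]]
  } else {
    sig <- data
    st <- signature
  }
  pos <- st == positive
  keep <- !is.na(sig) & !is.na(pos)
  sig <- sig[keep]; pos <- pos[keep]
  if (!any(pos) || all(pos)) {
    abort("both status groups must be non-empty to derive a threshold.")
  }
  m <- c(negative = mean(sig[!pos]), positive = mean(sig[pos]))
  structure(unname(mean(m)), group_means = m)
}

#' Call hypermethylation against a threshold
#'
#' A sample is hypermethylated iff its signature strictly exceeds the
#' threshold; a signature exactly at the threshold is hypomethylated.
#'
#' @param signature numeric vector of signature values.
#' @param threshold the hypermethylation threshold.
#' @return logical vector (NA where the signature is missing).
#' @export
call_hypermethylation <- function(signature, threshold) {
  if (length(threshold) != 1 || is.na(threshold)) {
    abort("`threshold` must be a single finite value.")
  }
  signature > threshold
}

#' Dichotomize expression into elevated/low at the cohort median
#'
#' A sample is `"elevated"` (positive) iff its value strictly exceeds the
#' cohort median; when the median is zero this reduces to "non-zero".
#' Negative values are rejected: TPM is non-negative.
#'
#' @param values numeric vector of non-negative expression values.
#' @return character vector of "elevated"/"low".
#' @export
#' @examples
#' call_expression_status(c(0, 0, 0, 5, 9))
call_expression_status <- function(values) {
  if (any(values < 0, na.rm = TRUE)) abort("expression values must be >= 0.")
  med <- median(values, na.rm = TRUE)
  ifelse(is.na(values), NA_character_,
         ifelse(values > med, "elevated", "low"))
}

#' Full signature pipeline: per-sample calls table
#'
#' Computes the three-probe signature, derives the midpoint threshold from
#' the expression status groups, and emits the per-sample calls table.
#'
#' @param beta samples x probes matrix.
#' @param expression data frame with sample_id and tpm (one gene).
#' @param probes signature probes.
#' @return object of class `signature_calls`: a tibble (sample_id,
#'   signature, threshold, hypermethylated, expression_status) with the
#'   threshold and group means as attributes.
#' @export
classify_signature <- function(beta, expression,
                               probes = hoxd12_signature_probes()) {
  sig <- signature_value(beta, probes)
  expr <- expression[match(sig$sample_id, expression$sample_id), ]
  status <- call_expression_status(expr$tpm)
  status <- ifelse(status == "elevated", "positive",
                   ifelse(status == "low", "negative", NA))
  thr <- derive_threshold(sig$signature, status)
  out <- sig |>
    mutate(threshold = as.numeric(thr),
           hypermethylated = call_hypermethylation(.data$signature, thr),
           expression_status = status)
  structure(out, threshold = as.numeric(thr),
            group_means = attr(thr, "group_means"),
            class = c("signature_calls", class(out)))
}

#' @export
print.signature_calls <- function(x, ...) {
  cat(sprintf("Signature calls: threshold %.4f (reported %s)\n",
              attr(x, "threshold"),
              format(truncate_decimals(attr(x, "threshold")))))
  NextMethod()
}
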