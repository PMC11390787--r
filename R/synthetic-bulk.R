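#' Planted truth for a synthetic bulk oligodendroglioma cohort
#'
#' Describes the generative model behind [gen_bulk_cohort()]: a bimodal
#' patient-age mixture, a logistic link from age to a binary HOXD12
#' expression status, group-specific Beta distributions for the three
#' gene-body signature probes, exponential survival with a planted hazard
#' ratio for positive versus negative status, and grade/treatment fields.
#'
#' Defaults emulate the structure of a TCGA-sized oligodendroglioma cohort:
#' 171 patients, age modes near 38 and 60 years, gene-body beta means
#' 0.3034 (negative) and 0.4121 (positive), and a hazard ratio of 9.3 for
#' positive expression status. The Beta concentration (default 50) is a
#' free dispersion parameter: only the group means are pinned down by the
#' cohort the generator emulates.
#'
#' @param n number of patients.
#' @param age_means,age_sds two-component age mixture parameters (years).
#' @param age_weight mixing weight of the first (younger) component.
#' @param pos_intercept,pos_slope logistic-regression coefficients linking
#'   age (years) to the probability of HOXD12-positive expression status.
#' @param body_beta_means beta-value means of the three gene-body probes for
#'   the (negative, positive) groups.
#' @param beta_concentration Beta-distribution concentration (mean * conc,
#'   (1-mean) * conc shape parameterization) for all probes.
#' @param survival_hr hazard ratio, positive vs negative status; must be > 0.
#' @param baseline_hazard exponential hazard (1/years) in the negative group.
#' @param censor_horizon administrative censoring time (years).
#' @param grade3_prob_by_status probability of CNS WHO grade 3 for the
#'   (negative, positive) groups.
#' @param seed integer seed; identical truth objects generate byte-identical
#'   cohorts.
#' @return an object of class `bulk_cohort_truth`.
#' @seealso [gen_bulk_cohort()]
#' @export
bulk_cohort_truth <- function(n = 171,
                              age_means = c(38, 60),
                              age_sds = c(7, 9),
                              age_weight = 0.55,
                              pos_intercept = -4.6,
                              pos_slope = 0.09,
                              body_beta_means = c(0.3034, 0.4121),
                              beta_concentration = 50,
                              survival_hr = 9.3,
                              baseline_hazard = 0.03,
                              censor_horizon = 15,
                              grade3_prob_by_status = c(0.22, 0.5),
                              seed = 1L) {
  if (length(n) != 1 || n < 0 || n != round(n)) {
    abort("`n` must be a single non-negative integer.")
  }
  check_prob(age_weight, "age_weight")
  check_prob(grade3_prob_by_status, "grade3_prob_by_status")
  if (any(body_beta_means <= 0 | body_beta_means >= 1)) {
    abort("`body_beta_means` must lie strictly inside (0, 1).")
  }
  if (survival_hr <= 0) abort("`survival_hr` must be positive.")
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be positive.")
  structure(
    list(
      n = as.integer(n), age_means = age_means, age_sds = age_sds,
      age_weight = age_weight, pos_intercept = pos_intercept,
      pos_slope = pos_slope, body_beta_means = body_beta_means,
      beta_concentration = beta_concentration, survival_hr = survival_hr,
      baseline_hazard = baseline_hazard, censor_horizon = censor_horizon,
      grade3_prob_by_status = grade3_prob_by_status, seed = as.integer(seed)
    ),
    class = "bulk_cohort_truth"
  )
}

# the three gene-body probes of the signature plus 11 further probes
# annotated to the same gene: a realistic 14-probe 450K footprint
.HOXD12_BODY_PROBES <- c("cg23130254", "cg03964958", "cg03371669")

hoxd12_probe_manifest <- function() {
  other <- sprintf("cg%08d", c(4210771, 8123407, 11902411, 15530003,
                               17219046, 20881332, 23411189, 24990455,
                               26013804, 27350912, 29145068))
  tibble(
    probe_id = c(.HOXD12_BODY_PROBES, other),
    gene = "HOXD12",
    region = c(rep("Body", 3),
               c("TSS1500", "TSS1500", "TSS200", "TSS200", "5UTR", "5UTR",
                 "Body", "3UTR", "TSS1500", "5UTR", "3UTR")),
    chrom_arm = "2q",
    pos = 176964000L + seq(0L, by = 180L, length.out = 14L)
  )
}

rbeta_mean <- function(n, mean, conc) {
  rbeta(n, shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

#' Generate a synthetic bulk cohort with planted truth
#'
#' Draws a clinical table, a 14-probe HOXD12 methylation matrix with its
#' manifest, and a small TPM expression table from the generative model in
#' a [bulk_cohort_truth()]. Expression status is planted through the
#' logistic age link; only the three gene-body probes separate the status
#' groups strongly, six further probes separate weakly and five not at all,
#' mirroring a probe footprint in which only the gene body tracks
#' expression.
#'
#' @param truth a [bulk_cohort_truth()].
#' @return a list of class `bulk_cohort` with elements `clinical` (tibble:
#'   sample_id, age, grade, os_time, os_event, expression_status),
#'   `treatments` (long tibble of treatment records), `beta` (samples x
#'   probes matrix), `manifest` (probe annotation tibble), `expression`
#'   (tibble: sample_id, gene, tpm), and `truth`.
#' @export
#' @examples
#' cohort <- gen_bulk_cohort(bulk_cohort_truth(n = 50, seed = 7))
#' dim(cohort$beta)
gen_bulk_cohort <- function(truth) {
  stopifnot(inherits(truth, "bulk_cohort_truth"))
  manifest <- hoxd12_probe_manifest()
  n <- truth$n
  if (n == 0) {
    return(structure(list(
      clinical = tibble(sample_id = character(), age = numeric(),
                        grade = integer(), os_time = numeric(),
                        os_event = logical(), expression_status = character()),
      treatments = tibble(sample_id = character(), regimen_label = character(),
                          drug = character(), start_day = numeric(),
                          order_index = integer()),
      beta = matrix(numeric(), 0, nrow(manifest),
                    dimnames = list(NULL, manifest$probe_id)),
      manifest = manifest,
      expression = tibble(sample_id = character(), gene = character(),
                          tpm = numeric()),
      truth = truth
    ), class = "bulk_cohort"))
  }
  withr::with_seed(truth$seed, {
    ids <- sprintf("S%04d", seq_len(n))
    comp <- rbinom(n, 1, 1 - truth$age_weight) + 1
    age <- round(rnorm(n, truth$age_means[comp], truth$age_sds[comp]), 1)
    age <- pmin(pmax(age, 18), 89)
    p_pos <- plogis(truth$pos_intercept + truth$pos_slope * age)
    status <- rbinom(n, 1, p_pos)

    # TPM: negatives are exact zeros (the cohort median is zero whenever
    # positives are a minority), positives log-normal
    tpm <- ifelse(status == 1, rlnorm(n, meanlog = 0.4, sdlog = 0.8), 0)

    conc <- truth$beta_concentration
    means_body <- truth$body_beta_means
    beta <- matrix(NA_real_, n, nrow(manifest),
                   dimnames = list(ids, manifest$probe_id))
    for (j in 1:3) {
      beta[, j] <- rbeta_mean(n, means_body[status + 1], conc)
    }
    # weakly separated (probes 4-9) and unseparated (10-14) companions
    base_logit <- qlogis(0.35)
    weak_delta <- 0.18
    for (j in 4:14) {
      delta <- if (j <= 9) weak_delta else 0
      mu <- plogis(base_logit + delta * status)
      beta[, j] <- rbeta_mean(n, mu, conc)
    }

    haz <- truth$baseline_hazard * truth$survival_hr^status
    t_event <- rexp(n, rate = haz)
    os_time <- pmin(t_event, truth$censor_horizon)
    os_event <- t_event <= truth$censor_horizon

    grade <- 2L + rbinom(n, 1, truth$grade3_prob_by_status[status + 1])

    # simple treatment records: one or two lines per treated patient
    n_tx <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.45, 0.30))
    m <- sum(n_tx)
    pat <- rep(seq_len(n), n_tx)
    treatments <- tibble(
      sample_id = ids[pat],
      regimen_label = sample(c("ADJUVANT", "OTHER", NA_character_), m,
                             replace = TRUE, prob = c(0.35, 0.35, 0.30)),
      drug = sample(c("LOMUSTINE", "PROCARBAZINE", "VINCRISTINE",
                      "TEMOZOLOMIDE"), m, replace = TRUE),
      start_day = as.numeric(sample(30:700, m, replace = TRUE)),
      order_index = unlist(lapply(n_tx[n_tx > 0], seq_len), use.names = FALSE)
    ) |>
      group_by(.data$sample_id) |>
      mutate(start_day = sort(.data$start_day)) |>
      ungroup()

    clinical <- tibble(
      sample_id = ids, age = age, grade = grade,
      os_time = os_time, os_event = os_event,
      expression_status = ifelse(status == 1, "positive", "negative")
    )
    expression <- tibble(sample_id = ids, gene = "HOXD12", tpm = tpm)

    structure(list(clinical = clinical, treatments = treatments,
                   beta = beta, manifest = manifest,
                   expression = expression, truth = truth),
              class = "bulk_cohort")
  })
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat("<bulk_cohort> ", nrow(x$clinical), " patients, ",
      ncol(x$beta), " probes (seed ", x$truth$seed, ")\n", sep = "")
  invisible(x)
}
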