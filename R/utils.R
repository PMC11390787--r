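#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n across all_of pull rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rbinom rbeta rexp rlnorm rpois rnbinom runif
#'   median quantile sd var cor kmeans p.adjust plogis qlogis setNames
#'   complete.cases
#' @importFrom utils head tail
NULL

# beta values live on (0,1); clip before logit so batch adjustment and
# differential tests never see +/-Inf
.BETA_EPS <- 1e-6

logit_beta <- function(beta, eps = .BETA_EPS) {
  stats::qlogis(pmin(pmax(beta, eps), 1 - eps))
}

expit_beta <- function(x) stats::plogis(x)

#' Truncate (not round) to a fixed number of decimals
#'
#' Reported beta-value thresholds are truncated, so that the midpoint
#' 0.35775 is displayed as 0.3577. Internal comparisons always use full
#' precision; this helper only formats reported values.
#'
#' @param x numeric vector.
#' @param digits decimals kept (default 4).
#' @return numeric vector truncated towards zero.
#' @export
#' @examples
#' truncate_decimals(0.35775)  # 0.3577
truncate_decimals <- function(x, digits = 4) {
  as.vector(trunc(x * 10^digits) / 10^digits)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

check_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort("`beta` must be a numeric samples-by-probes matrix.")
  }
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    abort("beta values must lie in [0, 1].")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort("`beta` needs sample row names and probe column names.")
  }
  invisible(beta)
}

# centered running mean that shrinks the window at the edges; used for
# genomic smoothing of dosage log-ratios
running_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 1) return(x)
  w <- min(w, n)
  half <- (w - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
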