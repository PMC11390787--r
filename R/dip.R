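#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical cdf and any unimodal cdf (convex up to a mode, concave after).
#' Computed by the classic iterative greatest-convex-minorant /
#' least-concave-majorant algorithm: the candidate modal interval is
#' narrowed while the deviations of the empirical cdf from the convex fit
#' on the left and the concave fit on the right accumulate into the dip.
#' The minimum attainable value for n distinct points is `1/(2n)`; a
#' constant sample has dip 0 by the degenerate-unimodal convention.
#'
#' @param x numeric vector.
#' @return the dip statistic (scalar).
#' @export
dip_stat <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(0)
  low <- 1L; high <- n
  dip <- 1  # in count units; rescaled to /(2n) on return

  for (iter in seq_len(n)) {
    # greatest convex minorant: predecessor links on [low, high]
    mn <- integer(n)
    mn[low] <- low
    if (high > low) for (j in (low + 1L):high) {
      mn[j] <- j - 1L
      repeat {
        mnj <- mn[j]
        if (mnj == low) break
        mnmnj <- mn[mnj]
        if ((x[j] - x[mnj]) * (mnj - mnmnj) <
            (x[mnj] - x[mnmnj]) * (j - mnj)) break
        mn[j] <- mnmnj
      }
    }
    # least concave majorant: successor links
    mj <- integer(n)
    mj[high] <- high
    if (high > low) for (j in (high - 1L):low) {
      mj[j] <- j + 1L
      repeat {
        mjj <- mj[j]
        if (mjj == high) break
        mjmjj <- mj[mjj]
        if ((x[j] - x[mjj]) * (mjj - mjmjj) <
            (x[mjj] - x[mjmjj]) * (j - mjj)) break
        mj[j] <- mjmjj
      }
    }
    # touch-point sequences: gcm decreasing from high, lcm increasing
    gcm <- high
    while (gcm[length(gcm)] > low) gcm <- c(gcm, mn[gcm[length(gcm)]])
    ic <- length(gcm)
    lcm <- low
    while (lcm[length(lcm)] < high) lcm <- c(lcm, mj[lcm[length(lcm)]])
    icl <- length(lcm)

    if (ic == 2 && icl == 2) {
      d <- 1
      ig <- ic; ih <- 1L
    } else {
      # largest distance between the two hulls
      ix <- ic - 1L; iv <- 2L; d <- 0
      ig <- ic; ih <- 1L
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > icl) iv <- icl
        if (gcm[ix] == lcm[iv]) break
      }
    }
    if (d <= dip) break

    # dip of the left region [low, gcm[ig]] against the convex fit
    dip_l <- 0
    if (ig <= ic - 1L) for (k in ig:(ic - 1L)) {
      max_t <- 1
      j_l <- gcm[k + 1L]; j_u <- gcm[k]
      if (j_u - j_l > 1 && x[j_u] != x[j_l]) {
        C <- (j_u - j_l) / (x[j_u] - x[j_l])
        for (j in j_l:j_u) {
          t <- (j - j_l + 1) - (x[j] - x[j_l]) * C
          if (t > max_t) max_t <- t
        }
      }
      if (max_t > dip_l) dip_l <- max_t
    }
    # dip of the right region [lcm[ih], high] against the concave fit
    dip_u <- 0
    if (ih <= icl - 1L) for (k in ih:(icl - 1L)) {
      max_t <- 1
      j_l <- lcm[k]; j_u <- lcm[k + 1L]
      if (j_u - j_l > 1 && x[j_u] != x[j_l]) {
        C <- (j_u - j_l) / (x[j_u] - x[j_l])
        for (j in j_l:j_u) {
          t <- (j_u - j + 1) - (x[j_u] - x[j]) * C
          if (t > max_t) max_t <- t
        }
      }
      if (max_t > dip_u) dip_u <- max_t
    }
    dip <- max(dip, dip_l, dip_u)
    new_low <- gcm[ig]; new_high <- lcm[ih]
    if (new_low == low && new_high == high) break
    low <- new_low; high <- new_high
  }
  dip / (2 * n)
}

#' Hartigan's dip test of unimodality
#'
#' Monte Carlo calibration of [dip_stat()] against samples of the same
#' size from the uniform distribution (the standard least-favorable
#' unimodal null), with the add-one p-value correction.
#'
#' @param x numeric vector.
#' @param n_sim Monte Carlo replicates (default 1000).
#' @param seed seed for the null draws.
#' @return one-row tibble: statistic, p, n, n_sim.
#' @export
dip_test <- function(x, n_sim = 1000, seed = 1) {
  x <- x[!is.na(x)]
  n <- length(x)
  obs <- dip_stat(x)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(i) dip_stat(runif(n)), numeric(1))
  })
  tibble(statistic = obs, p = (1 + sum(null >= obs)) / (1 + n_sim),
         n = n, n_sim = n_sim)
}
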