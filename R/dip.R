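# Hartigan & Hartigan's dip statistic: the maximum difference between the
# empirical distribution function and the unimodal distribution function
# minimizing that difference, computed via the iterative greatest-convex-
# minorant / least-concave-majorant (GCM/LCM) modal-interval algorithm.

#' Hartigan's dip statistic
#'
#' Computes the dip of a sample: the ECDF's sup-distance to the closest
#' unimodal distribution, found by iteratively fitting the greatest convex
#' minorant below the candidate modal interval and the least concave
#' majorant above it and shrinking the modal interval until the fit stops
#' improving. A perfectly antimodal two-point distribution (half the mass
#' at each of two values) attains the maximum dip of 0.25; samples from a
#' unimodal law give values near the lower bound `1/(2n)`.
#'
#' @param x Numeric vector (n >= 2, finite).
#' @return The dip statistic (scalar in `[1/(2n), 0.25]`).
#' @export
dip_stat <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2L) stop("need at least 2 values")
  if (anyNA(x) || any(!is.finite(x))) stop("values must be finite")
  if (x[1] == x[n]) return(0)

  # mn[j]: leftmost index joined with j in the convex minorant touch chain
  mn <- integer(n)
  mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  # mj[k]: rightmost index joined with k in the concave majorant chain
  mj <- integer(n)
  mj[n] <- n
  for (k in (n - 1L):1L) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  low <- 1L
  high <- n
  dip <- 1           # in count units; 1 <=> 1/(2n) after scaling
  repeat {
    # GCM touchpoints from high down to low, LCM from low up to high
    gcm <- high
    while (gcm[length(gcm)] > low) gcm <- c(gcm, mn[gcm[length(gcm)]])
    l_gcm <- length(gcm)               # gcm[1] = high ... gcm[l_gcm] = low
    lcm <- low
    while (lcm[length(lcm)] < high) lcm <- c(lcm, mj[lcm[length(lcm)]])
    l_lcm <- length(lcm)               # lcm[1] = low ... lcm[l_lcm] = high

    ix <- l_gcm - 1L
    iv <- 2L
    ig <- l_gcm
    ih <- l_lcm
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      repeat {
        gcmix <- gcm[ix]
        lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          # the minorant runs below; largest gap at the LCM point lcm[iv]
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1L) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv - 1L
          }
        } else {
          # largest gap at the GCM point gcm[ix]
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1L)
          ix <- ix - 1L
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv
          }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else {
      d <- 1
    }
    if (d < dip) break

    # dip within the convex-minorant side (ECDF above the GCM chords)
    dip_l <- 0
    if (ig < l_gcm) for (j in ig:(l_gcm - 1L)) {
      jb <- gcm[j + 1L]
      je <- gcm[j]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (jj in jb:je) {
          t <- (jj - jb + 1L) - (x[jj] - x[jb]) * C
          if (t > dip_l) dip_l <- t
        }
      }
    }
    # dip within the concave-majorant side (ECDF below the LCM chords)
    dip_u <- 0
    if (ih < l_lcm) for (j in ih:(l_lcm - 1L)) {
      jb <- lcm[j]
      je <- lcm[j + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (jj in jb:je) {
          t <- (x[jj] - x[jb]) * C - (jj - jb - 1L)
          if (t > dip_u) dip_u <- t
        }
      }
    }
    dipnew <- max(dip_l, dip_u)
    if (dipnew > dip) dip <- dipnew
    if (low == gcm[ig] && high == lcm[ih]) break
    low <- gcm[ig]
    high <- lcm[ih]
  }
  dip / (2 * n)
}

#' Dip test of unimodality with a Monte-Carlo null
#'
#' Computes [dip_stat()] for the sample and a Monte-Carlo p-value: the
#' fraction of `n_boot` samples of the same size drawn from the uniform
#' (0,1) distribution (the classical calibration null) whose dip is at
#' least as large as the observed one.
#'
#' @param values Numeric vector, at least 4 finite values.
#' @param n_boot Number of uniform null samples (default 2000).
#' @param null_dips Optional precomputed vector of null dip values for this
#'   sample size, reused instead of drawing `n_boot` fresh samples.
#' @return List with `dip`, `p_value`, `n`, `n_boot`.
#' @export
dip_test <- function(values, n_boot = 2000L, null_dips = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 4L) stop("need at least 4 finite values")
  d <- dip_stat(x)
  if (is.null(null_dips)) {
    null_dips <- vapply(seq_len(n_boot),
                        function(i) dip_stat(stats::runif(length(x))),
                        numeric(1))
  }
  p <- (1 + sum(null_dips >= d)) / (1 + length(null_dips))
  list(dip = d, p_value = p, n = length(x), n_boot = length(null_dips))
}

#' Null dip distribution for a sample size
#'
#' @param n Sample size.
#' @param n_boot Number of uniform samples.
#' @return Numeric vector of dips, reusable via `dip_test(null_dips = )`.
#' @export
dip_null_distribution <- function(n, n_boot = 2000L) {
  vapply(seq_len(n_boot), function(i) dip_stat(stats::runif(n)), numeric(1))
}
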