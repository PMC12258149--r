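# Evolutionary strata: changepoint boundary detection on windowed SNP
# density, between-stratum divergence comparison, and conversion of
# synonymous divergence into ages and degeneration rates.

#' Detect an evolutionary-stratum boundary by changepoint analysis
#'
#' Finds a single changepoint in a series of per-window values (typically
#' female SNP density along the candidate sex-linked region) under a
#' Gaussian cost in which both the mean and the variance may shift:
#' `C(seg) = n * log(sigma2_mle)` per segment. `mode = "force_one"` returns
#' the split minimizing total cost over all split points; `mode =
#' "penalized"` accepts the split only if the cost reduction exceeds
#' `penalty` (default `3 * log(n)`, three extra parameters).
#'
#' The boundary index is the last window of the left segment. Cost ties are
#' broken toward the smaller position.
#'
#' @param values Numeric vector of window values (>= 4 windows).
#' @param mode `"force_one"` or `"penalized"`.
#' @param penalty Penalty for the extra segment in penalized mode.
#' @param min_seg Minimum windows per segment (default 2, so the segment
#'   variance is defined).
#' @return List with `changepoint` (index of last left window, or `NA` when
#'   a penalized split is rejected), `cost0`, `cost1`, `improvement`,
#'   `left_mean`, `right_mean`, `left_var`, `right_var`, and `flat`
#'   (`TRUE` when the series admits no cost improvement).
#' @export
detect_stratum_boundary <- function(values, mode = c("force_one", "penalized"),
                                    penalty = NULL, min_seg = 2L) {
  mode <- match.arg(mode)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 4L) stop("need at least 4 windows")
  if (anyNA(x)) stop("window values must not contain NA")
  if (is.null(penalty)) penalty <- 3 * log(n)

  seg_cost <- function(v) {
    s2 <- mean((v - mean(v))^2)     # MLE variance
    length(v) * log(max(s2, 1e-300))
  }
  cost0 <- seg_cost(x)
  ks <- seq.int(min_seg, n - min_seg)
  costs <- vapply(ks, function(k) seg_cost(x[1:k]) + seg_cost(x[(k + 1):n]),
                  numeric(1))
  best <- ks[which.min(costs)]      # which.min takes the first = smaller pos
  cost1 <- min(costs)
  improvement <- cost0 - cost1
  # floating-point summation order can leave a vanishing "improvement" on
  # constant series; treat those as flat
  flat <- improvement <= 1e-8 * max(1, abs(cost0))
  cp <- best
  if (mode == "penalized" && improvement <= penalty) cp <- NA_integer_
  left <- x[seq_len(best)]
  right <- x[(best + 1):n]
  list(changepoint = cp, cost0 = cost0, cost1 = cost1,
       improvement = improvement,
       left_mean = mean(left), right_mean = mean(right),
       left_var = mean((left - mean(left))^2),
       right_var = mean((right - mean(right))^2),
       flat = flat)
}

#' Compare divergence between strata
#'
#' Summarizes per-region mean Ka and Ks and runs pairwise two-sided
#' Mann-Whitney U tests on Ks between all region pairs (midrank ties; exact
#' p for small samples without ties, normal approximation with tie
#' correction otherwise, as in [stats::wilcox.test()]).
#'
#' @param records data.frame as returned by [kaks_table()], with `region`,
#'   `ka`, `ks` columns. Saturated records (`saturated == TRUE`) are
#'   excluded by default.
#' @param value Column to test (default `"ks"`).
#' @param include_saturated Keep saturated records (default FALSE).
#' @return List with `summary` (per-region n, mean_ka, mean_ks) and `tests`
#'   (region pair, U statistic, p).
#' @export
compare_strata <- function(records, value = "ks", include_saturated = FALSE) {
  if (!all(c("region", "ka", "ks") %in% names(records))) {
    stop("records must have region, ka and ks columns")
  }
  if ("defective" %in% names(records)) {
    records <- records[!records$defective, , drop = FALSE]
  }
  if (!include_saturated && "saturated" %in% names(records)) {
    records <- records[!records$saturated, , drop = FALSE]
  }
  records <- records[!is.na(records$region), , drop = FALSE]
  counts <- table(records$region)
  if (any(counts < 2)) {
    drop <- names(counts)[counts < 2]
    warning("excluding region(s) with fewer than 2 records: ",
            paste(drop, collapse = ", "))
    records <- records[!(records$region %in% drop), , drop = FALSE]
  }
  regions <- unique(records$region)
  if (length(regions) < 2L) stop("need at least 2 regions with >= 2 records")
  summ <- do.call(rbind, lapply(regions, function(r) {
    sub <- records[records$region == r, ]
    data.frame(region = r, n = nrow(sub),
               mean_ka = mean(sub$ka, na.rm = TRUE),
               mean_ks = mean(sub$ks, na.rm = TRUE))
  }))
  pairs <- utils::combn(regions, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    x <- records[[value]][records$region == p[1]]
    y <- records[[value]][records$region == p[2]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
    data.frame(region_a = p[1], region_b = p[2],
               U = unname(wt$statistic), p = wt$p.value)
  }))
  list(summary = summ, tests = tests)
}

#' Divergence rate and stratum ages from synonymous divergence
#'
#' Converts an inter-species synonymous divergence and a known species split
#' time into a per-site per-year divergence rate, then dates each stratum by
#' dividing its Z-W Ks by that rate (Z and W are assumed to diverge at the
#' same rate as the two species).
#'
#' @param ks_interspecies Synonymous divergence between the two species.
#' @param t_split_years Species split time in years (> 0).
#' @param ks_by_stratum Named numeric vector of per-stratum Z-W Ks values.
#' @return List with `rate` (substitutions/site/year), `ages_years` and
#'   `ages_my` (named per stratum), and `ratio_to_interspecies` (stratum Ks
#'   as a fraction of the inter-species value).
#' @examples
#' divergence_rate_and_ages(0.048, 4.2e6, c(stratum1 = 0.035))
#' @export
divergence_rate_and_ages <- function(ks_interspecies, t_split_years,
                                     ks_by_stratum) {
  if (!is.numeric(ks_interspecies) || ks_interspecies <= 0) {
    stop("ks_interspecies must be > 0")
  }
  if (!is.numeric(t_split_years) || t_split_years <= 0) {
    stop("t_split_years must be > 0")
  }
  if (any(ks_by_stratum < 0)) stop("stratum Ks values must be >= 0")
  rate <- ks_interspecies / t_split_years
  ages <- ks_by_stratum / rate
  list(rate = rate, ages_years = ages, ages_my = ages / 1e6,
       ratio_to_interspecies = ks_by_stratum / ks_interspecies)
}

#' Degeneration rates per million years and per million generations
#'
#' @param pct_lof Percentage of genes nonfunctional on the W (0-100).
#' @param age_my Stratum age in million years (> 0).
#' @param generation_time_years Generation time in years.
#' @return List with `per_my` (% per million years) and `per_mgen`
#'   (% per million generations).
#' @examples
#' degeneration_rates(54.4, 3, 1.5)
#' @export
degeneration_rates <- function(pct_lof, age_my, generation_time_years = 1) {
  if (any(age_my <= 0)) stop("age_my must be > 0")
  if (any(pct_lof < 0)) stop("pct_lof must be >= 0")
  per_my <- pct_lof / age_my
  list(per_my = per_my, per_mgen = per_my * generation_time_years)
}
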