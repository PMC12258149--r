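# Evolutionary strata: changepoint boundary, NG86 Ka/Ks, between-stratum
# tests, RBH pairing, dating and degeneration-rate arithmetic.

# independent exhaustive single-changepoint oracle (Gaussian mean+variance
# cost), written directly from the segment-cost definition
cp_oracle <- function(x, min_seg = 2L) {
  n <- length(x)
  cost <- function(v) length(v) * log(max(mean((v - mean(v))^2), 1e-300))
  ks <- min_seg:(n - min_seg)
  tot <- sapply(ks, function(k) cost(x[1:k]) + cost(x[(k + 1):n]))
  ks[which.min(tot)]
}

test_that("changepoint detection finds a clean step exactly", {
  x <- c(rep(1, 50), rep(5, 50))
  res <- detect_stratum_boundary(x)
  expect_identical(res$changepoint, 50L)
  expect_equal(res$left_mean, 1)
  expect_equal(res$right_mean, 5)
  expect_error(detect_stratum_boundary(c(1, 2, 3)), "at least 4")
})

test_that("changepoint equals the exhaustive oracle on random series", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(8:200, 1)
    x <- stats::rnorm(n) + c(rep(0, n %/% 2), rep(stats::runif(1, 0, 3),
                                                  n - n %/% 2))
    expect_identical(detect_stratum_boundary(x)$changepoint,
                     as.integer(cp_oracle(x)))
  }
})

test_that("changepoint localizes a noisy planted step within two windows", {
  set.seed(23)
  hits <- replicate(200, {
    truth <- 60L
    x <- c(stats::rnorm(truth, mean = 2, sd = 1),
           stats::rnorm(40, mean = 6, sd = 1))
    abs(detect_stratum_boundary(x)$changepoint - truth) <= 2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("penalized mode rejects splits in featureless series", {
  set.seed(3)
  x <- stats::rnorm(60)
  res <- detect_stratum_boundary(x, mode = "penalized",
                                 penalty = 10 * log(60))
  expect_true(is.na(res$changepoint))
  # constant series is flagged
  res2 <- detect_stratum_boundary(rep(1, 20))
  expect_true(res2$flat)
})

test_that("NG86 reproduces the hand-counted worked example", {
  z <- paste(rep("TTT", 10), collapse = "")
  w <- paste(c(rep("TTT", 9), "TTC"), collapse = "")
  k <- ng86_kaks(z, w)
  expect_equal(k$sd, 1)
  expect_equal(k$S, 10 / 3, tolerance = 1e-12)
  expect_equal(k$ps, 0.3, tolerance = 1e-12)
  expect_equal(k$ks, -0.75 * log(1 - 0.4), tolerance = 1e-9)  # 0.3831
  expect_equal(k$ka, 0)

  ident <- ng86_kaks(z, z)
  expect_equal(ident$ks, 0)
  expect_equal(ident$ka, 0)
  expect_error(ng86_kaks(z, paste0(w, "AAA")), "length")
})

test_that("NG86 is symmetric and flags saturation", {
  set.seed(2)
  a <- random_cds(80)
  b <- evolve_cds(a, 0.08, 0.6)$derived
  k1 <- ng86_kaks(a, b)
  k2 <- ng86_kaks(b, a)
  expect_equal(k1$ks, k2$ks, tolerance = 1e-12)
  expect_equal(k1$ka, k2$ka, tolerance = 1e-12)

  # unrelated sequences: pS beyond the Jukes-Cantor domain
  x <- random_cds(60)
  y <- random_cds(60)
  ksat <- suppressWarnings(ng86_kaks(x, y))
  expect_true(ksat$saturated || ksat$ks > 0.5)
})

test_that("pathway counting matches brute-force enumeration on codon pairs", {
  # independent oracle: average syn/nonsyn steps over all substitution
  # orders, skipping orders that pass through a stop codon
  gc_tab <- Biostrings::GENETIC_CODE
  oracle <- function(c1, c2) {
    b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
    pos <- which(b1 != b2)
    perms <- if (length(pos) == 1) list(pos) else
      if (length(pos) == 2) list(pos, rev(pos)) else {
        out <- list()
        for (p in list(c(1,2,3),c(1,3,2),c(2,1,3),c(2,3,1),c(3,1,2),c(3,2,1)))
          out[[length(out)+1]] <- pos[p]
        out
      }
    res <- list()
    for (ord in perms) {
      cur <- b1; sd <- nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- b2[p]
        if (gc_tab[[paste(nxt, collapse = "")]] == "*") { ok <- FALSE; break }
        if (gc_tab[[paste(cur, collapse = "")]] ==
            gc_tab[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) res[[length(res) + 1]] <- c(sd, nd)
    }
    Reduce(`+`, res) / length(res)
  }
  cases <- list(c("TTT", "GTA"), c("ATG", "ACC"), c("AAA", "AGG"),
                c("CCC", "GGG"), c("TGT", "AGA"))
  for (cs in cases) {
    got <- zwscan:::codon_pair_diffs(cs[1], cs[2])
    want <- oracle(cs[1], cs[2])
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 label = paste(cs, collapse = "->"))
  }
})

test_that("Ks is non-decreasing in planted synonymous substitutions", {
  # glycine repeats: every third position is four-fold degenerate, so each
  # planted change is synonymous and the proportion stays below saturation
  anc <- strrep("GGC", 12)
  cur <- anc
  last <- -1
  for (i in 1:4) {
    substr(cur, 3 * i, 3 * i) <- "A"   # GGC -> GGA, synonymous
    k <- ng86_kaks(anc, cur)
    expect_gt(k$ks, last)
    expect_identical(k$nd, 0)
    last <- k$ks
  }
})

test_that("the Ks estimator is calibrated across the divergence range", {
  set.seed(11)
  for (ds_true in c(0.01, 0.035, 0.08)) {
    ks <- replicate(60, {
      a <- random_cds(300)
      ng86_kaks(a, evolve_cds(a, ds_true, 0.5)$derived)$ks
    })
    # 5% relative bias plus Monte-Carlo allowance at this sample size
    mc <- 3 * stats::sd(ks) / sqrt(length(ks))
    expect_lt(abs(mean(ks) - ds_true), 0.05 * ds_true + mc)
  }
})

test_that("strata comparison: ties, exact enumeration and power", {
  recs <- data.frame(region = rep(c("S1", "S2"), each = 3),
                     ka = 0, ks = c(4, 5, 6, 1, 2, 3), saturated = FALSE)
  res <- compare_strata(recs)
  expect_equal(res$tests$U, 9)        # all S1 > all S2: U = n1*n2
  expect_equal(res$tests$p, 0.1)      # exact two-sided 2/20
  expect_equal(res$summary$mean_ks[res$summary$region == "S1"], 5)

  same <- data.frame(region = rep(c("A", "B"), each = 4),
                     ka = 0, ks = rep(1:4, 2), saturated = FALSE)
  expect_equal(compare_strata(same)$tests$p, 1)
})

test_that("simulated strata separate significantly at alpha 0.01", {
  set.seed(6)
  p_vals <- replicate(5, {
    ks1 <- replicate(25, {
      a <- random_cds(200); ng86_kaks(a, evolve_cds(a, 0.035, 0.5)$derived)$ks
    })
    ks2 <- replicate(50, {
      a <- random_cds(200); ng86_kaks(a, evolve_cds(a, 0.020, 0.5)$derived)$ks
    })
    recs <- data.frame(region = rep(c("S1", "S2"), c(25, 50)),
                       ka = 0, ks = c(ks1, ks2), saturated = FALSE)
    compare_strata(recs)$tests$p
  })
  expect_true(all(p_vals < 0.01))
})

test_that("reciprocal-best-hit pairing is exact on identical sets and drops ties", {
  prots <- c(pA = "MKVLITAGPTREQ", pB = "MLYWWAGHHKKLM", pC = "MEEDDRRKKPPQ")
  self <- rbh_pairs(prots, prots)
  expect_identical(nrow(self), 3L)
  expect_identical(self$a, self$b)

  # one query best-hitting two equal-score subjects is ambiguous
  a <- c(q = "MKVLITAGPTREQ")
  b <- c(t1 = "MKVLITAGPTREQ", t2 = "MKVLITAGPTREQ")
  expect_identical(nrow(rbh_pairs(a, b)), 0L)
})

test_that("RBH recovers gametolog pairs among decoys", {
  set.seed(14)
  n <- 6
  z_cds <- lapply(1:n, function(i) random_cds(120))
  w_cds <- lapply(z_cds, function(cds) evolve_cds(cds, 0.05, 0.8)$derived)
  drop_stop <- function(s) substr(s, 1, nchar(s) - 3)
  z_prot <- vapply(z_cds, function(s) zwscan:::translate_cds(drop_stop(s)),
                   character(1))
  w_prot <- vapply(w_cds, function(s) zwscan:::translate_cds(drop_stop(s)),
                   character(1))
  decoys_a <- vapply(1:5, function(i)
    zwscan:::translate_cds(drop_stop(random_cds(120))), character(1))
  decoys_b <- vapply(1:5, function(i)
    zwscan:::translate_cds(drop_stop(random_cds(120))), character(1))
  a <- stats::setNames(c(z_prot, decoys_a),
                       c(sprintf("z%d", 1:n), sprintf("dA%d", 1:5)))
  b <- stats::setNames(c(w_prot, decoys_b),
                       c(sprintf("w%d", 1:n), sprintf("dB%d", 1:5)))
  pairs <- rbh_pairs(a, b)
  true_pairs <- pairs[grepl("^z", pairs$a), ]
  expect_identical(sort(true_pairs$a), sprintf("z%d", 1:n))
  expect_identical(sub("w", "z", true_pairs$b), true_pairs$a)
})

test_that("divergence dating arithmetic behaves", {
  res <- divergence_rate_and_ages(0.048, 4.2e6, c(S1 = 0.035, S2 = 0.02))
  expect_equal(res$rate, 0.048 / 4.2e6)
  expect_equal(unname(res$ages_my["S1"]), 0.035 / (0.048 / 4.2e6) / 1e6)
  expect_equal(unname(divergence_rate_and_ages(0.048, 4.2e6,
                                               c(x = 0))$ages_my), 0)
  # scale invariance: doubling both Ks values preserves age ratios
  r2 <- divergence_rate_and_ages(0.096, 4.2e6, c(S1 = 0.07, S2 = 0.04))
  expect_equal(unname(r2$ages_my["S1"] / r2$ages_my["S2"]),
               unname(res$ages_my["S1"] / res$ages_my["S2"]))
  expect_error(divergence_rate_and_ages(0.048, 0, c(S1 = 0.035)),
               "t_split_years")
})

test_that("degeneration-rate arithmetic behaves", {
  r <- degeneration_rates(0, 3, 1.5)
  expect_equal(r$per_my, 0)
  expect_equal(r$per_mgen, 0)
  expect_error(degeneration_rates(10, 0), "age_my")
  expect_equal(degeneration_rates(30, 3, 2)$per_mgen, 20)
})
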