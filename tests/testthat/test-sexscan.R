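# Sex-linked region discovery: variant criterion, Weir-Cockerham FST,
# female:male log2 ratios, LD profiling, k-mer markers, haplotig phasing.

test_that("sex-linked variant scan recovers the truth exactly on clean data", {
  ds <- clean_dataset()
  nf <- ds$config$n_females
  res <- find_sex_linked_variants(ds$genotypes, min_het = nf,
                                  hom_policy = "all")
  tv <- ds$truth$variants
  truth_keys <- paste(tv$chrom[tv$sex_linked], tv$pos[tv$sex_linked])
  found_keys <- paste(res$variants$chrom, res$variants$pos)
  expect_setequal(found_keys, truth_keys)
  expect_false(any(res$variants$chrom == "chrA"))   # no autosomal calls
  expect_identical(res$heterogamety$call, "ZW")
  expect_true(all(res$variants$class == "ZW-like"))
})

test_that("variant scan boundary conditions behave", {
  gm <- toy_genotypes(matrix(c(0L, 0L, 2L, 2L,
                               2L, 2L, 0L, 0L), nrow = 2, byrow = TRUE),
                      c("F", "F", "M", "M"))
  res <- find_sex_linked_variants(gm, min_het = 2)
  expect_identical(nrow(res$variants), 0L)
  expect_identical(res$heterogamety$call, "undetermined")

  expect_error(find_sex_linked_variants(gm, min_het = 0), "min_het")
  one_sex <- toy_genotypes(matrix(1L, 2, 2), c("F", "F"))
  expect_error(find_sex_linked_variants(one_sex, min_het = 1), "both sexes")
})

test_that("sex-label permutation reduces calls to the chance level", {
  ds <- clean_dataset()
  gm <- ds$genotypes
  set.seed(99)
  gm$samples$sex <- sample(gm$samples$sex)
  res <- find_sex_linked_variants(gm, min_het = ds$config$n_females,
                                  hom_policy = "all")
  # qualifying requires all het individuals on one side of the permutation:
  # probability ~ 1/choose(24,12) per W variant, expectation << 1
  expect_lte(nrow(res$variants), 2L)
})

test_that("per-variant FST matches the Weir-Cockerham oracle and its limits", {
  # fixed difference between the sexes -> estimate ~1
  fixed <- toy_genotypes(matrix(c(rep(0L, 12), rep(2L, 12)), nrow = 1),
                         rep(c("F", "M"), each = 12))
  expect_gt(per_variant_fst(fixed), 0.999)

  # identical genotype vectors in both sexes -> estimate <= 0
  same <- toy_genotypes(matrix(rep(c(0L, 1L, 2L, 1L, 0L, 1L), 4), nrow = 1),
                        rep(c("F", "M"), each = 12))
  expect_lte(per_variant_fst(same), 0)

  # 3-variant toy window equals the independent WC84 oracle
  set.seed(21)
  dos <- matrix(sample(0:2, 3 * 20, replace = TRUE), nrow = 3)
  storage.mode(dos) <- "integer"
  sexes <- rep(c("F", "M"), each = 10)
  gm <- toy_genotypes(dos, sexes, pos = c(5L, 15L, 25L))
  comps <- lapply(1:3, function(i) wc84_oracle_fst(dos[i, 1:10], dos[i, 11:20]))
  expected <- sum(vapply(comps, `[[`, numeric(1), "a")) /
    sum(vapply(comps, function(x) x$a + x$b + x$c, numeric(1)))
  win <- windowed_fst(gm, window = 50L)
  expect_equal(win$fst[1], expected, tolerance = 1e-12)
  expect_identical(win$n_variants[1], 3L)
})

test_that("windowed FST separates the sex-linked region from the autosome", {
  ds <- clean_dataset()
  fst <- windowed_fst(ds$genotypes, window = ds$config$window)
  slr <- fst$chrom == "chrZ" & fst$window_start > ds$config$par_end
  expect_gt(mean(fst$fst[slr], na.rm = TRUE), 0.4)
  expect_lt(abs(mean(fst$fst[fst$chrom == "chrA"], na.rm = TRUE)), 0.05)
  expect_error(windowed_fst(ds$genotypes, window = 0), "window")
})

test_that("female:male log2 ratio handles equal, halved and zero windows", {
  vals <- data.frame(
    chrom = "chr1",
    window_start = rep(c(1L, 51L, 101L), each = 4),
    window_end = rep(c(51L, 101L, 151L), each = 4),
    sample = rep(c("f1", "f2", "m1", "m2"), 3),
    mean_depth = c(10, 10, 10, 10,    # equal
                   5, 5, 10, 10,      # females at half
                   0, 0, 10, 10))     # zero-mean window
  sexes <- c(f1 = "F", f2 = "F", m1 = "M", m2 = "M")
  r <- fm_log2_windows(vals, sexes)
  expect_equal(r$log2_fm[r$window_start == 1], 0)
  expect_equal(r$log2_fm[r$window_start == 51], -1)
  expect_true(is.na(r$log2_fm[r$window_start == 101]))
  vals$mean_depth[1] <- -1
  expect_error(fm_log2_windows(vals, sexes), "negative")
})

test_that("planted W deletions halve female coverage in their windows", {
  ds <- deletion_dataset()
  tw <- ds$truth$windows
  expect_gt(sum(tw$factor_female == 0.5), 0)
  sexes <- stats::setNames(ds$genotypes$samples$sex, ds$genotypes$samples$id)
  r <- fm_log2_windows(ds$coverage, sexes)
  key_r <- paste(r$chrom, r$window_start)
  key_t <- paste(tw$chrom, tw$window_start)
  fac <- tw$factor_female[match(key_r, key_t)]
  del <- which(fac == 0.5)
  flat <- which(fac == 1)
  expect_lt(max(abs(r$log2_fm[del] + 1)), 0.25)     # ~ -1 within Poisson error
  expect_lt(max(abs(r$log2_fm[flat])), 0.25)        # ~ 0 elsewhere
})

test_that("female SNP density is elevated only in the sex-linked region", {
  ds <- clean_dataset()
  dens <- snp_density_windows(ds$genotypes, window = ds$config$window)
  sexes <- stats::setNames(ds$genotypes$samples$sex, ds$genotypes$samples$id)
  r <- fm_log2_windows(dens, sexes, value_col = "snp_density")
  slr <- r$chrom == "chrZ" & r$window_start > ds$config$par_end
  auto <- r$chrom == "chrA"
  expect_gt(mean(r$log2_fm[slr], na.rm = TRUE), 1)
  expect_lt(abs(mean(r$log2_fm[auto], na.rm = TRUE)), 0.2)
})

test_that("r2 profile: duplicated variants, null level, sparse windows", {
  set.seed(5)
  n <- 24L
  # two identical variant columns plus independent HWE variants
  base <- as.integer(stats::rbinom(n, 2, 0.5))
  indep <- t(vapply(1:30, function(i) as.integer(stats::rbinom(n, 2, 0.5)),
                    integer(n)))
  dos <- rbind(base, base, indep)
  storage.mode(dos) <- "integer"
  pos <- as.integer(c(1, 15001, seq(30001, by = 15000, length.out = 30)))
  gm <- toy_genotypes(dos, rep(c("F", "M"), each = n / 2), pos = pos)
  prof <- ld_profile(gm, "chr1", maf_min = 0.05, thin = 10000L,
                     window = 1e6L)
  # the duplicated pair survives thinning and gives r2 = 1
  expect_equal(max(prof$window_pairs$second_max_r2, na.rm = TRUE) >= 0,
               TRUE)
  r2_dup <- suppressWarnings(stats::cor(dos[1, ], dos[2, ]))^2
  expect_equal(r2_dup, 1)
  # mean r2 of independent variants ~ 1/n
  mean_null <- sum(prof$decay$mean_r2 * prof$decay$n) / sum(prof$decay$n)
  expect_lt(mean_null, 3 / n)
  expect_gt(mean_null, 1 / (4 * n))

  # a window with fewer than 2 post-thinning variants yields no statistic
  gm2 <- toy_genotypes(dos[1:2, , drop = FALSE],
                       rep(c("F", "M"), each = n / 2),
                       pos = c(1L, 5000L))  # both thin to one variant
  prof2 <- ld_profile(gm2, "chr1", maf_min = 0.05)
  expect_identical(nrow(prof2$window_pairs), 0L)
})

test_that("k-mer markers land only inside the planted male-specific insert", {
  set.seed(77)
  mk <- simulate_marker_reads(genome_length = 20000L, insert_length = 2000L,
                              read_length = 100L, coverage = 6,
                              dropout_males = 1L)
  res <- kmer_sex_markers(mk$reads, mk$sex, target_sex = "M", k = 31L,
                          min_target_presence = 11L)
  expect_gt(length(res$markers), 0)
  # truth interval: the insert plus a k-1 flank (junction k-mers overlap it)
  k <- 31L
  lo <- mk$insert_interval[1] - (k - 1L)
  hi <- mk$insert_interval[2] + (k - 1L)
  region <- substr(mk$male_hap, lo, hi)
  region_rev <- zwscan:::revcomp_chr(region)
  inside <- vapply(res$markers, function(m) {
    grepl(m, region, fixed = TRUE) || grepl(m, region_rev, fixed = TRUE)
  }, logical(1))
  expect_true(all(inside))
  # and never in sequence shared with females
  in_backbone <- vapply(res$markers, function(m) {
    grepl(m, mk$backbone, fixed = TRUE) ||
      grepl(m, zwscan:::revcomp_chr(mk$backbone), fixed = TRUE)
  }, logical(1))
  expect_false(any(in_backbone))
  # carrier reads all contain a marker
  expect_gt(sum(lengths(res$carrier_reads)), 0)

  # swapped sexes: a male-specific scan on relabeled data finds nothing
  swapped <- ifelse(mk$sex == "M", "F", "M")
  names(swapped) <- names(mk$sex)
  res_sw <- kmer_sex_markers(mk$reads, swapped, target_sex = "M", k = 31L,
                             min_target_presence = 11L)
  expect_length(res_sw$markers, 0)
})

test_that("k-mer scan is invariant to read order and orientation", {
  set.seed(12)
  mk <- simulate_marker_reads(genome_length = 8000L, insert_length = 1000L,
                              n_males = 4L, n_females = 4L,
                              read_length = 80L, coverage = 6,
                              dropout_males = 0L)
  base <- kmer_sex_markers(mk$reads, mk$sex, target_sex = "M", k = 21L,
                           min_target_presence = 4L)
  perturbed <- lapply(mk$reads, function(r) {
    r <- sample(r)
    flip <- seq_along(r) %% 2 == 0
    r[flip] <- zwscan:::revcomp_chr(r[flip])
    r
  })
  pert <- kmer_sex_markers(perturbed, mk$sex, target_sex = "M", k = 21L,
                           min_target_presence = 4L)
  expect_identical(base$markers, pert$markers)

  # identical read sets for everyone -> no marker
  same <- lapply(mk$reads, function(r) mk$reads[[1]])
  res_same <- kmer_sex_markers(same, mk$sex, target_sex = "M", k = 21L,
                               min_target_presence = 4L)
  expect_length(res_same$markers, 0)
  expect_error(kmer_sex_markers(mk$reads, mk$sex, k = 1001L), "read length")
  expect_error(kmer_sex_markers(mk$reads, mk$sex, k = 30L), "odd")
})

test_that("haplotig assignment applies the phase-confidence threshold", {
  pure <- data.frame(contig = "c1", site = 1:100,
                     allele_origin = rep("W", 100))
  r1 <- assign_haplotigs(pure)
  expect_identical(r1$label, "W")
  expect_equal(r1$confidence, 1)

  mixed <- data.frame(contig = "c2", site = 1:100,
                      allele_origin = rep(c("W", "Z"), 50))
  expect_identical(assign_haplotigs(mixed)$label, "unassigned")

  # 1% switched sites: confidence 0.99 below the 0.9977 threshold
  chimera <- data.frame(contig = "c3", site = 1:200,
                        allele_origin = c(rep("W", 198), "Z", "Z"))
  r3 <- assign_haplotigs(chimera)
  expect_equal(r3$confidence, 0.99)
  expect_identical(r3$label, "unassigned")
  # and it passes with a laxer threshold
  expect_identical(assign_haplotigs(chimera, min_confidence = 0.98)$label, "W")
})
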