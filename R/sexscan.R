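# Sex-linked region discovery: per-variant sex-linkage criterion,
# Weir-Cockerham FST in windows, female:male log2 window ratios, LD
# profiling, and haplotig Z/W phase assignment.

#' Find sex-linked variants and call the heterogamety type
#'
#' A variant qualifies ZW-like when at least `min_het` females are
#' heterozygous and males are homozygous (per `hom_policy`), and XY-like
#' symmetrically. Missing genotypes never qualify (they count neither as
#' heterozygous nor homozygous). Indels in the input are handled exactly
#' like SNPs. The heterogamety call is the majority class when it reaches
#' `call_threshold` of qualifying variants.
#'
#' @param gm A `zw_genotypes` object.
#' @param min_het Minimum heterozygote count in the heterogametic sex.
#' @param hom_policy `"all"`: every non-missing genotype in the other sex
#'   must be homozygous; `"min_count"`: at least `min_het` homozygotes
#'   suffice.
#' @param call_threshold Majority fraction required for the system call.
#' @return List with `variants` (data.frame of qualifying variants with
#'   per-sex het/hom/missing counts and class) and `heterogamety` (list
#'   with `call` in `ZW`/`XY`/`undetermined` and class counts).
#' @export
find_sex_linked_variants <- function(gm, min_het = 18L,
                                     hom_policy = c("all", "min_count"),
                                     call_threshold = 0.8) {
  hom_policy <- match.arg(hom_policy)
  stopifnot(inherits(gm, "zw_genotypes"))
  if (min_het < 1L) stop("config error: min_het must be >= 1")
  f <- gm$samples$sex == "F"
  m <- gm$samples$sex == "M"
  if (!any(f) || !any(m)) stop("both sexes must be present in the cohort")
  if (min_het > max(sum(f), sum(m))) {
    stop("config error: min_het exceeds both sex sample sizes")
  }
  df <- gm$dosage[, f, drop = FALSE]
  dm <- gm$dosage[, m, drop = FALSE]
  het_f <- rowSums(df == 1L, na.rm = TRUE)
  hom_f <- rowSums(df == 0L | df == 2L, na.rm = TRUE)
  mis_f <- rowSums(is.na(df))
  het_m <- rowSums(dm == 1L, na.rm = TRUE)
  hom_m <- rowSums(dm == 0L | dm == 2L, na.rm = TRUE)
  mis_m <- rowSums(is.na(dm))

  # "all": every individual of the homozygous sex observed homozygous
  # (missing counts as non-qualifying); "min_count": at least min_het
  # observed homozygotes, no observed heterozygote
  if (hom_policy == "all") {
    zw <- het_f >= min_het & hom_m == sum(m)
    xy <- het_m >= min_het & hom_f == sum(f)
  } else {
    zw <- het_f >= min_het & hom_m >= min_het & het_m == 0L
    xy <- het_m >= min_het & hom_f >= min_het & het_f == 0L
  }

  keep <- zw | xy
  variants <- data.frame(gm$variants[keep, , drop = FALSE],
                         het_count_F = het_f[keep], hom_count_F = hom_f[keep],
                         missing_F = mis_f[keep],
                         het_count_M = het_m[keep], hom_count_M = hom_m[keep],
                         missing_M = mis_m[keep],
                         class = ifelse(zw[keep], "ZW-like", "XY-like"),
                         stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  n_zw <- sum(zw); n_xy <- sum(xy)
  call <- "undetermined"
  if (n_zw + n_xy > 0) {
    if (n_zw / (n_zw + n_xy) >= call_threshold) call <- "ZW"
    if (n_xy / (n_zw + n_xy) >= call_threshold) call <- "XY"
  }
  list(variants = variants,
       heterogamety = list(call = call, n_zw_like = n_zw, n_xy_like = n_xy))
}

# Weir & Cockerham (1984) variance components for one biallelic variant and
# two populations; returns c(a, b, c).
#' @noRd
wc84_components <- function(dos_f, dos_m) {
  d1 <- dos_f[!is.na(dos_f)]
  d2 <- dos_m[!is.na(dos_m)]
  n1 <- length(d1); n2 <- length(d2)
  if (n1 < 1 || n2 < 1) return(c(a = NA, b = NA, c = NA))
  r <- 2
  p1 <- mean(d1) / 2; p2 <- mean(d2) / 2
  h1 <- mean(d1 == 1L); h2 <- mean(d2 == 1L)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST between the sexes
#'
#' Per-variant Weir & Cockerham (1984) components `a`, `b`, `c` for the
#' two-population (female vs male) case, combined per window as the
#' weighted estimator `sum(a) / sum(a + b + c)` over the variants in the
#' window. Windows tile each chromosome as half-open `[start, start +
#' window)` intervals; windows without variants are reported with `NA`.
#'
#' @param gm A `zw_genotypes` object.
#' @param window Window size in bp (> 0).
#' @return data.frame with `chrom`, `window_start`, `window_end`
#'   (exclusive), `n_variants`, `fst`.
#' @export
windowed_fst <- function(gm, window = 50000L) {
  stopifnot(inherits(gm, "zw_genotypes"))
  if (window <= 0) stop("config error: window must be > 0")
  f <- gm$samples$sex == "F"
  m <- gm$samples$sex == "M"
  if (sum(f) < 2 || sum(m) < 2) stop("need >= 2 individuals per sex")
  comps <- t(vapply(seq_len(nrow(gm$variants)), function(i) {
    wc84_components(gm$dosage[i, f], gm$dosage[i, m])
  }, numeric(3)))
  out <- list()
  for (ch in unique(gm$variants$chrom)) {
    on_ch <- gm$variants$chrom == ch
    maxpos <- max(gm$variants$pos[on_ch])
    starts <- seq(1L, maxpos, window)
    win <- findInterval(gm$variants$pos[on_ch], starts)
    a <- tapply(comps[on_ch, 1], win, sum, na.rm = TRUE)
    abc <- tapply(rowSums(comps[on_ch, , drop = FALSE]), win, sum, na.rm = TRUE)
    nv <- tapply(rep(1, sum(on_ch)), win, sum)
    fst <- rep(NA_real_, length(starts))
    cnt <- rep(0L, length(starts))
    idx <- as.integer(names(a))
    fst[idx] <- ifelse(abc == 0, NA_real_, a / abc)
    cnt[idx] <- as.integer(nv)
    out[[ch]] <- data.frame(chrom = ch, window_start = starts,
                            window_end = starts + window,
                            n_variants = cnt, fst = unname(fst))
  }
  do.call(rbind, out)
}

#' Per-variant Weir-Cockerham FST estimate
#'
#' @param gm A `zw_genotypes` object.
#' @return Numeric vector `a / (a + b + c)` per variant (`NA` when the
#'   denominator is 0).
#' @export
per_variant_fst <- function(gm) {
  f <- gm$samples$sex == "F"
  m <- gm$samples$sex == "M"
  vapply(seq_len(nrow(gm$variants)), function(i) {
    cc <- wc84_components(gm$dosage[i, f], gm$dosage[i, m])
    s <- sum(cc)
    if (is.na(s) || s == 0) NA_real_ else cc[["a"]] / s
  }, numeric(1))
}

#' Female:male log2 ratio of per-window values
#'
#' Computes `log2(mean over females) - log2(mean over males)` of any
#' per-sample per-window quantity (SNP density, coverage). Windows where
#' either sex has mean zero are reported as `NA` rather than infinite.
#'
#' @param values data.frame with `chrom`, `window_start`, `window_end`,
#'   `sample`, and a value column.
#' @param sexes Named character vector mapping sample id to `"F"`/`"M"`.
#' @param value_col Name of the value column (default `"mean_depth"`).
#' @return data.frame with `chrom`, `window_start`, `window_end`,
#'   `mean_F`, `mean_M`, `log2_fm`.
#' @export
fm_log2_windows <- function(values, sexes, value_col = "mean_depth") {
  if (any(values[[value_col]] < 0, na.rm = TRUE)) {
    stop("negative values are not allowed")
  }
  if (!all(values$sample %in% names(sexes))) {
    stop("sex labeling error: unknown sample(s) ",
         paste(setdiff(unique(values$sample), names(sexes)), collapse = ", "))
  }
  values$sex <- unname(sexes[values$sample])
  key <- interaction(values$chrom, values$window_start, drop = TRUE)
  agg <- function(sx) {
    v <- values[values$sex == sx, ]
    tapply(v[[value_col]], interaction(v$chrom, v$window_start, drop = FALSE,
                                       lex.order = TRUE), mean)
  }
  uf <- values[!duplicated(key), c("chrom", "window_start", "window_end")]
  uf <- uf[order(uf$chrom, uf$window_start), ]
  kf <- interaction(uf$chrom, uf$window_start, drop = FALSE, lex.order = TRUE)
  mf <- agg("F")[as.character(kf)]
  mm <- agg("M")[as.character(kf)]
  if (all(is.na(mf)) || all(is.na(mm))) stop("both sexes must be present")
  log2fm <- ifelse(!is.na(mf) & !is.na(mm) & mf > 0 & mm > 0,
                   log2(mf) - log2(mm), NA_real_)
  data.frame(uf, mean_F = unname(mf), mean_M = unname(mm),
             log2_fm = unname(log2fm), row.names = NULL)
}

#' Per-sample SNP density in windows
#'
#' Counts heterozygous calls per sample in half-open windows, as input for
#' [fm_log2_windows()] (per-sample SNP density contrasts).
#'
#' @param gm A `zw_genotypes` object.
#' @param window Window size in bp.
#' @param chrom Restrict to one chromosome (default: all).
#' @return data.frame with `chrom`, `window_start`, `window_end`, `sample`,
#'   `snp_density` (het calls per bp).
#' @export
snp_density_windows <- function(gm, window = 50000L, chrom = NULL) {
  v <- gm$variants
  keep <- if (is.null(chrom)) rep(TRUE, nrow(v)) else v$chrom %in% chrom
  out <- list()
  for (ch in unique(v$chrom[keep])) {
    on_ch <- which(v$chrom == ch & keep)
    maxpos <- max(v$pos[on_ch])
    starts <- seq(1L, maxpos, window)
    win <- findInterval(v$pos[on_ch], starts)
    for (s in seq_len(nrow(gm$samples))) {
      het <- gm$dosage[on_ch, s] == 1L
      cnt <- tapply(as.integer(het), win, sum, na.rm = TRUE)
      full <- rep(0, length(starts))
      full[as.integer(names(cnt))] <- cnt
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, window_start = starts, window_end = starts + window,
        sample = gm$samples$id[s], snp_density = full / window)
    }
  }
  do.call(rbind, out)
}

#' Linkage-disequilibrium profile of a region
#'
#' Filters variants (minor-allele frequency, missingness), thins to at most
#' one variant per `thin` bp (first by position), computes `r^2` as the
#' squared Pearson correlation of diploid dosages over complete cases, and
#' summarizes the second-largest `r^2` for every pair of `window`-sized
#' windows, plus a decay curve of mean `r^2` binned by pairwise distance.
#'
#' @param gm A `zw_genotypes` object.
#' @param chrom Chromosome to profile.
#' @param from,to Region bounds (default: whole chromosome).
#' @param maf_min Minor-allele-frequency filter (default 0.15).
#' @param max_missing Maximum missing fraction per variant (default 0).
#' @param thin Thinning distance in bp (default 10000).
#' @param window Window size for the pairwise summary (default 100000).
#' @param decay_bin Bin width (bp) for the decay curve.
#' @return List with `window_pairs` (win_a, win_b, second_max_r2, n_pairs)
#'   and `decay` (distance_bin, mean_r2, n).
#' @export
ld_profile <- function(gm, chrom, from = 1L, to = NULL, maf_min = 0.15,
                       max_missing = 0, thin = 10000L, window = 100000L,
                       decay_bin = 10000L) {
  v <- gm$variants
  if (is.null(to)) to <- max(v$pos[v$chrom == chrom])
  idx <- which(v$chrom == chrom & v$pos >= from & v$pos <= to)
  if (length(idx) == 0L) stop("region is empty")
  dos <- gm$dosage[idx, , drop = FALSE]
  pos <- v$pos[idx]
  miss <- rowMeans(is.na(dos))
  alt <- rowSums(dos, na.rm = TRUE)
  called <- 2 * rowSums(!is.na(dos))
  maf <- ifelse(called > 0, pmin(alt, called - alt) / called, 0)
  keep <- miss <= max_missing & maf >= maf_min
  dos <- dos[keep, , drop = FALSE]; pos <- pos[keep]
  if (length(pos) == 0L) stop("region is empty after filters")
  # thin: first variant per thin-bp bin
  bin <- (pos - 1L) %/% thin
  first <- !duplicated(bin)
  dos <- dos[first, , drop = FALSE]; pos <- pos[first]

  n <- length(pos)
  if (n < 2L) {
    return(list(window_pairs = data.frame(win_a = integer(0), win_b = integer(0),
                                          second_max_r2 = numeric(0),
                                          n_pairs = integer(0)),
                decay = data.frame(distance_bin = numeric(0),
                                   mean_r2 = numeric(0), n = integer(0))))
  }
  r2 <- suppressWarnings(stats::cor(t(dos), use = "pairwise.complete.obs"))^2
  pair_i <- rep(seq_len(n), times = n)
  pair_j <- rep(seq_len(n), each = n)
  up <- pair_i < pair_j
  pi <- pair_i[up]; pj <- pair_j[up]
  r2v <- r2[cbind(pi, pj)]
  ok <- !is.na(r2v)   # monomorphic-after-filter pairs are skipped
  pi <- pi[ok]; pj <- pj[ok]; r2v <- r2v[ok]

  wa <- (pos[pi] - 1L) %/% window + 1L
  wb <- (pos[pj] - 1L) %/% window + 1L
  keypair <- paste(wa, wb)
  second_max <- function(x) if (length(x) >= 2L) sort(x, decreasing = TRUE)[2L] else NA_real_
  wp <- data.frame(
    win_a = as.integer(vapply(strsplit(unique(keypair), " "), `[`, character(1), 1)),
    win_b = as.integer(vapply(strsplit(unique(keypair), " "), `[`, character(1), 2)),
    second_max_r2 = as.numeric(tapply(r2v, keypair, second_max)[unique(keypair)]),
    n_pairs = as.integer(tapply(r2v, keypair, length)[unique(keypair)]))

  dist <- pos[pj] - pos[pi]
  dbin <- (dist - 1L) %/% decay_bin * decay_bin + decay_bin / 2
  decay <- data.frame(
    distance_bin = sort(unique(dbin)),
    mean_r2 = as.numeric(tapply(r2v, dbin, mean)[as.character(sort(unique(dbin)))]),
    n = as.integer(tapply(r2v, dbin, length)[as.character(sort(unique(dbin)))]))
  list(window_pairs = wp, decay = decay)
}

#' Assign haplotigs to the Z or W haplotype
#'
#' Each contig carries allele observations at informative (W-specific)
#' sites; the confidence is the fraction of sites matching the contig's
#' majority haplotype. Contigs reaching `min_confidence` are labeled with
#' the majority haplotype; others (including exact 50/50 mixtures) are
#' unassigned.
#'
#' @param observations data.frame with `contig`, `site`, `allele_origin`
#'   (`"W"` or `"Z"`: which haplotype the observed allele matches).
#' @param min_confidence Minimum phase confidence (default 0.9977).
#' @return data.frame with `contig`, `n_sites`, `n_w`, `n_z`, `label`
#'   (`W`/`Z`/`unassigned`), `confidence` (`NA` for contigs with no
#'   informative site).
#' @export
assign_haplotigs <- function(observations, min_confidence = 0.9977) {
  stopifnot(all(c("contig", "allele_origin") %in% names(observations)))
  out <- lapply(split(observations, observations$contig), function(o) {
    n_w <- sum(o$allele_origin == "W")
    n_z <- sum(o$allele_origin == "Z")
    n <- n_w + n_z
    if (n == 0L) {
      return(data.frame(contig = o$contig[1], n_sites = 0L, n_w = 0L,
                        n_z = 0L, label = "unassigned",
                        confidence = NA_real_))
    }
    conf <- max(n_w, n_z) / n
    lab <- if (conf >= min_confidence && n_w != n_z) {
      if (n_w > n_z) "W" else "Z"
    } else "unassigned"
    data.frame(contig = o$contig[1], n_sites = n, n_w = n_w, n_z = n_z,
               label = lab, confidence = conf)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
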