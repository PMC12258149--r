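# Orchestration of the synthetic ZW dataset: sequences, gene models, sexed
# cohort genotypes, coverage, reads, expression, gene trees, truth table.
#
# All randomness comes from the single global RNG seeded from config$seed;
# submodules draw in a fixed documented order (genome, gene placement, W
# evolution, LoF planting, cohort genotypes, coverage, reads, expression,
# gene trees), so identical seed + config gives byte-identical outputs.

#' Simulate a complete synthetic ZW dataset
#'
#' Generates a Z chromosome partitioned PAR / Stratum 2 / Stratum 1, a W
#' haplotype diverged from it at the per-region synonymous divergence
#' settings, gene models with planted loss-of-function events at the
#' per-region rates, a genotyped sexed cohort (ZW females heterozygous at
#' W-specific sites, ZZ males homozygous), an autosomal control chromosome,
#' window coverage summaries with halved female coverage over planted W
#' deletions, per-individual reads, allele-tagged expression counts with
#' configurable compensation states, planted gametolog gene trees, and a
#' truth table covering every emitted variant, gene, window and tree.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `zw_dataset` with elements `z_seq`, `w_seq`
#'   (character scalars), `genes` (gene-model data.frame), `z_cds`, `w_cds`,
#'   `w_region` (named character vectors), `genotypes` (a `zw_genotypes`
#'   object), `coverage`, `expression` (data.frames), `reads` (named list of
#'   character vectors per individual), `trees` (data.frame with newick and
#'   class), `truth` (list of truth tables) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "zw_sim_config"))
  set.seed(config$seed)
  cfg <- config

  ## 1. genome backbone -----------------------------------------------------
  z_vec <- sample(NUCS, cfg$chrom_length, replace = TRUE)
  a_vec <- sample(NUCS, cfg$autosome_length, replace = TRUE)

  ## 2. gene placement ------------------------------------------------------
  genes <- place_genes(cfg)
  # write gene sequences (exons = CDS, introns with GT..AG termini) into Z
  z_cds <- stats::setNames(character(nrow(genes)), genes$gene)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cds <- random_cds(g$cds_len %/% 3L)
    z_cds[[g$gene]] <- cds
    z_vec <- write_gene_into(z_vec, g, cds)
  }

  ## 3. W evolution (substitutions only; coordinates preserved) -------------
  w_vec <- z_vec
  w_cds <- z_cds
  evo <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ev <- evolve_cds(z_cds[[g$gene]], cfg$dS_true[[g$region]],
                     cfg$omega[[g$region]])
    evo[[i]] <- ev
    w_cds[[g$gene]] <- ev$derived
    w_vec <- write_cds_into(w_vec, g, ev$derived)
  }
  # intergenic SLR divergence at the regional synonymous (neutral) rate;
  # exons and intron termini (splice dinucleotides) are excluded so that
  # neutral divergence never mimics a loss-of-function event
  exonic <- c(exonic_positions(genes), splice_site_positions(genes))
  for (r in c("S2", "S1")) {
    span <- if (r == "S2") (cfg$par_end + 1L):cfg$s2_end else
      (cfg$s2_end + 1L):cfg$chrom_length
    free <- setdiff(span, exonic)
    n_mut <- stats::rpois(1L, length(free) * cfg$dS_true[[r]])
    if (n_mut > 0) {
      at <- sample(free, min(n_mut, length(free)))
      for (p in at) w_vec[p] <- sample(setdiff(NUCS, w_vec[p]), 1L)
    }
  }

  ## 4. LoF planting --------------------------------------------------------
  genes$true_class <- "intact"
  genes$lof_detail <- ""
  del_spans <- list()          # genomic W deletion intervals (Z coordinates)
  w_dropped <- rep(FALSE, cfg$chrom_length)  # W positions with no sequence
  w_ins <- list()              # W insertions (after Z position, sequence)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (stats::runif(1) >= cfg$lof_prob[[g$region]]) next
    cls <- sample(LOF_CLASSES, 1L, prob = cfg$lof_class_weights)
    pl <- plant_lof(list(n_exons = g$n_exons,
                         exon_lengths = genes$exon_lengths[[i]]),
                    w_cds[[g$gene]], cls)
    genes$true_class[i] <- cls
    genes$lof_detail[i] <- pl$detail
    w_cds[[g$gene]] <- pl$w_cds
    res <- realize_lof(w_vec, w_dropped, genes, i, pl)
    w_vec <- res$w_vec
    w_dropped <- res$w_dropped
    if (!is.null(res$ins)) w_ins[[length(w_ins) + 1L]] <- res$ins
    if (cls == "sequence_loss") {
      del_spans[[length(del_spans) + 1L]] <- c(g$start, g$end)
    }
  }
  genes$w_factor <- ifelse(genes$true_class == "intact", 1, 0)
  genes$compensated <- genes$w_factor == 0 &
    stats::runif(nrow(genes)) < cfg$compensated_fraction

  ## 5. cohort genotypes ----------------------------------------------------
  gm <- build_cohort(cfg, z_vec, a_vec, w_vec, w_dropped)

  ## 6. coverage ------------------------------------------------------------
  cov <- simulate_coverage(cfg, gm$samples, del_spans)

  ## 7. reads ---------------------------------------------------------------
  reads <- simulate_reads(cfg, gm$samples, z_vec, w_vec, w_dropped)

  ## 8. expression ----------------------------------------------------------
  expr <- simulate_expression(genes, cfg)

  ## 9. gene trees ----------------------------------------------------------
  trees <- simulate_gene_trees(cfg$gene_tree_counts)

  truth <- list(
    variants = gm$truth_variants,
    genes = data.frame(gene = genes$gene, region = genes$region,
                       true_class = genes$true_class,
                       w_factor = genes$w_factor,
                       compensated = genes$compensated,
                       lof_detail = genes$lof_detail,
                       stringsAsFactors = FALSE),
    windows = cov$truth_windows,
    trees = data.frame(tree = trees$tree, true_class = trees$true_class,
                       stringsAsFactors = FALSE),
    deletions = if (length(del_spans)) {
      data.frame(start = vapply(del_spans, `[`, numeric(1), 1),
                 end = vapply(del_spans, `[`, numeric(1), 2))
    } else data.frame(start = numeric(0), end = numeric(0)),
    note = paste("All distributional choices are generator stand-ins;",
                 "no empirical generative model is implied.")
  )

  w_seq <- splice_w(w_vec, w_dropped, w_ins, 1L, cfg$chrom_length)
  out <- list(z_seq = paste(z_vec, collapse = ""),
              a_seq = paste(a_vec, collapse = ""),
              w_seq = w_seq,
              genes = genes, z_cds = z_cds, w_cds = w_cds,
              w_region = extract_w_regions(w_vec, w_dropped, genes, w_ins),
              genotypes = gm$genotypes, coverage = cov$coverage,
              reads = reads, expression = expr, trees = trees,
              truth = truth, config = cfg)
  class(out) <- "zw_dataset"
  out
}

# --- internals -------------------------------------------------------------

#' @noRd
place_genes <- function(cfg) {
  rows <- list()
  bounds <- list(PAR = c(1L, cfg$par_end),
                 S2 = c(cfg$par_end + 1L, cfg$s2_end),
                 S1 = c(cfg$s2_end + 1L, cfg$chrom_length))
  gid <- 0L
  for (r in REGIONS) {
    n <- cfg$n_genes[[r]]
    if (n == 0L) next
    lo <- bounds[[r]][1]; hi <- bounds[[r]][2]
    slot <- (hi - lo + 1L) %/% n
    for (k in seq_len(n)) {
      gid <- gid + 1L
      cds_len <- 3L * (sample(cfg$gene_length_range[1]:cfg$gene_length_range[2],
                              1L) %/% 3L)
      n_ex <- sample(cfg$exons_per_gene_range[1]:cfg$exons_per_gene_range[2], 1L)
      # split CDS into n_ex exon lengths, each >= 30 bp
      cuts <- sort(sample(seq(30L, cds_len - 30L), n_ex - 1L))
      ex_len <- diff(c(0L, cuts, cds_len))
      while (any(ex_len < 30L)) {   # re-draw rare degenerate splits
        cuts <- sort(sample(seq(30L, cds_len - 30L), n_ex - 1L))
        ex_len <- diff(c(0L, cuts, cds_len))
      }
      intron_len <- sample(80:300, n_ex - 1L, replace = TRUE)
      span <- cds_len + sum(intron_len)
      slot_lo <- lo + (k - 1L) * slot
      start <- slot_lo + sample.int(max(1L, slot - span - 200L), 1L)
      rows[[gid]] <- data.frame(
        gene = sprintf("g%03d", gid), chrom = "chrZ", region = r,
        start = start, end = start + span - 1L, strand = "+",
        cds_len = cds_len, n_exons = n_ex,
        exon_lengths = I(list(as.integer(ex_len))),
        intron_lengths = I(list(as.integer(intron_len))))
    }
  }
  do.call(rbind, rows)
}

# genomic exon intervals of one gene (list of c(start, end))
#' @noRd
gene_exon_intervals <- function(g, exon_lengths, intron_lengths) {
  pos <- g$start
  out <- list()
  for (j in seq_along(exon_lengths)) {
    out[[j]] <- c(pos, pos + exon_lengths[j] - 1L)
    pos <- pos + exon_lengths[j]
    if (j <= length(intron_lengths)) pos <- pos + intron_lengths[j]
  }
  out
}

#' @noRd
splice_site_positions <- function(genes) {
  unlist(lapply(seq_len(nrow(genes)), function(i) {
    iv <- gene_exon_intervals(genes[i, ], genes$exon_lengths[[i]],
                              genes$intron_lengths[[i]])
    if (length(iv) < 2L) return(integer(0))
    unlist(lapply(seq_len(length(iv) - 1L), function(j) {
      c(iv[[j]][2] + 1L, iv[[j]][2] + 2L,          # GT donor
        iv[[j + 1L]][1] - 2L, iv[[j + 1L]][1] - 1L) # AG acceptor
    }))
  }))
}

#' @noRd
exonic_positions <- function(genes) {
  unlist(lapply(seq_len(nrow(genes)), function(i) {
    iv <- gene_exon_intervals(genes[i, ], genes$exon_lengths[[i]],
                              genes$intron_lengths[[i]])
    unlist(lapply(iv, function(x) x[1]:x[2]))
  }))
}

#' @noRd
write_gene_into <- function(vec, g, cds) {
  ex_len <- if (is.list(g$exon_lengths)) g$exon_lengths[[1]] else g$exon_lengths
  in_len <- if (is.list(g$intron_lengths)) g$intron_lengths[[1]] else g$intron_lengths
  iv <- gene_exon_intervals(g, ex_len, in_len)
  cds_chars <- strsplit(cds, "")[[1]]
  off <- 0L
  for (j in seq_along(iv)) {
    span <- iv[[j]][1]:iv[[j]][2]
    vec[span] <- cds_chars[(off + 1L):(off + length(span))]
    off <- off + length(span)
    if (j < length(iv)) {    # intron: random interior, canonical termini
      istart <- iv[[j]][2] + 1L
      iend <- iv[[j + 1L]][1] - 1L
      vec[istart] <- "G"; vec[istart + 1L] <- "T"
      vec[iend - 1L] <- "A"; vec[iend] <- "G"
    }
  }
  vec
}

# overwrite only exon positions with a same-length CDS (post-evolution)
#' @noRd
write_cds_into <- function(vec, g, cds) {
  write_gene_into(vec, g, cds)   # termini rewritten identically; harmless
}

# map a CDS offset range to genomic W positions and apply a LoF edit
#' @noRd
realize_lof <- function(w_vec, w_dropped, genes, i, pl) {
  g <- genes[i, ]
  ex_len <- genes$exon_lengths[[i]]
  in_len <- genes$intron_lengths[[i]]
  iv <- gene_exon_intervals(g, ex_len, in_len)
  cds_to_genomic <- unlist(lapply(iv, function(x) x[1]:x[2]))
  ed <- pl$edit
  if (ed$type %in% c("del", "exon")) {
    span <- cds_to_genomic[ed$cds_start:(ed$cds_start + ed$cds_len - 1L)]
    w_dropped[span] <- TRUE
  } else if (ed$type == "sub") {
    w_vec[cds_to_genomic[ed$cds_pos]] <- ed$to
  } else if (ed$type == "stop") {
    span <- cds_to_genomic[((ed$codon - 1L) * 3L + 1L):((ed$codon) * 3L)]
    w_vec[span] <- c("T", "A", "A")
  } else if (ed$type == "ins") {
    # insertions have no Z coordinate; record them for W sequence assembly
    ins <- list(pos = cds_to_genomic[ed$cds_start], seq = ed$seq)
  } else if (ed$type == "splice") {
    if (ed$end == "donor") {
      p <- iv[[ed$intron]][2] + 1L          # first intron base (G of GT)
      w_vec[p] <- "C"
    } else {
      p <- iv[[ed$intron + 1L]][1] - 1L     # last intron base (G of AG)
      w_vec[p] <- "C"
    }
  }
  if (!exists("ins", inherits = FALSE)) ins <- NULL
  list(w_vec = w_vec, w_dropped = w_dropped, ins = ins)
}

# assemble the W sequence over [lo, hi]: drop deleted positions, splice in
# insertions (after their anchor position)
#' @noRd
splice_w <- function(w_vec, w_dropped, w_ins, lo, hi) {
  idx <- lo:hi
  keepmask <- !w_dropped[idx]
  s <- paste(w_vec[idx][keepmask], collapse = "")
  ins <- Filter(function(e) e$pos >= lo && e$pos <= hi, w_ins)
  if (length(ins)) {
    cum <- cumsum(keepmask)
    ord <- order(vapply(ins, function(e) e$pos, numeric(1)), decreasing = TRUE)
    for (e in ins[ord]) {
      off <- cum[e$pos - lo + 1L]
      s <- paste0(substr(s, 1L, off), e$seq, substring(s, off + 1L))
    }
  }
  s
}

#' @noRd
extract_w_regions <- function(w_vec, w_dropped, genes, w_ins = list()) {
  out <- stats::setNames(character(nrow(genes)), genes$gene)
  for (i in seq_len(nrow(genes))) {
    out[i] <- splice_w(w_vec, w_dropped, w_ins, genes$start[i], genes$end[i])
  }
  out
}

#' @noRd
build_cohort <- function(cfg, z_vec, a_vec, w_vec, w_dropped) {
  samples <- data.frame(
    id = c(sprintf("F%02d", seq_len(cfg$n_females)),
           sprintf("M%02d", seq_len(cfg$n_males))),
    sex = c(rep("F", cfg$n_females), rep("M", cfg$n_males)),
    stringsAsFactors = FALSE)
  n <- nrow(samples)

  # W-specific SNPs: Z/W single-base differences outside dropped spans,
  # restricted to the non-recombining region (PAR gametolog differences
  # reflect population diversity, not sex linkage, and PAR variation is
  # emitted via the HWE polymorphism below instead)
  wdiff <- which(z_vec != w_vec & !w_dropped)
  wdiff <- wdiff[wdiff > cfg$par_end]
  v_w <- if (length(wdiff)) {
    data.frame(chrom = "chrZ", pos = wdiff, ref = z_vec[wdiff],
               alt = w_vec[wdiff], origin = "W", stringsAsFactors = FALSE)
  } else NULL

  # neutral polymorphism: PAR and the autosome, HWE at par_diversity
  hwe_sites <- function(chrom, lo, hi, vec) {
    len <- hi - lo + 1L
    # allele frequencies ~ U(0.05, 0.95): mean heterozygosity ~= 0.35, so
    # the site density is par_diversity / 0.35
    n_sites <- stats::rpois(1L, len * cfg$par_diversity / 0.35)
    if (n_sites == 0L) return(NULL)
    pos <- sort(sample(lo:hi, min(n_sites, len)))
    p <- stats::runif(length(pos), 0.05, 0.95)
    ref <- vec[pos - lo + 1L]
    alt <- vapply(ref, function(b) sample(setdiff(NUCS, b), 1L), character(1))
    list(df = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         origin = "polymorphism", stringsAsFactors = FALSE),
         p = p)
  }
  par_sites <- hwe_sites("chrZ", 1L, cfg$par_end, z_vec)
  auto_sites <- hwe_sites("chrA", 1L, cfg$autosome_length, a_vec)

  # Z-linked polymorphism inside the SLR: the Z copies still segregate in
  # the population (males 2 draws, females 1 draw plus the fixed W allele),
  # at a quarter of the PAR diversity so W-specific density dominates
  slr_len <- cfg$chrom_length - cfg$par_end
  n_zpoly <- stats::rpois(1L, slr_len * cfg$par_diversity * 0.25 / 0.35)
  zpoly <- NULL
  if (n_zpoly > 0L) {
    pool <- setdiff(seq.int(cfg$par_end + 1L, cfg$chrom_length), wdiff)
    zpos <- sort(sample(pool, min(n_zpoly, length(pool))))
    # alt frequencies kept at or below 0.5: a Z allele near fixation with a
    # reference-state W would be indistinguishable from a W-specific site
    zp <- stats::runif(length(zpos), 0.05, 0.5)
    zref <- z_vec[zpos]
    zalt <- vapply(zref, function(b) sample(setdiff(NUCS, b), 1L), character(1))
    zpoly <- list(df = data.frame(chrom = "chrZ", pos = zpos, ref = zref,
                                  alt = zalt, origin = "Zpoly",
                                  stringsAsFactors = FALSE),
                  p = zp)
  }

  variants <- rbind(v_w,
                    if (!is.null(zpoly)) zpoly$df,
                    if (!is.null(par_sites)) par_sites$df,
                    if (!is.null(auto_sites)) auto_sites$df)
  ord <- order(match(variants$chrom, c("chrZ", "chrA")), variants$pos)
  variants <- variants[ord, ]
  rownames(variants) <- NULL

  dos <- matrix(0L, nrow(variants), n,
                dimnames = list(NULL, samples$id))
  is_w <- variants$origin == "W"
  is_zpoly <- variants$origin == "Zpoly"
  dos[is_w, samples$sex == "F"] <- 1L      # females Z/W heterozygous
  # HWE genotypes for polymorphic sites
  poly_rows <- which(!is_w)
  pvec <- c(if (!is.null(zpoly)) zpoly$p,
            if (!is.null(par_sites)) par_sites$p,
            if (!is.null(auto_sites)) auto_sites$p)
  # align p with sorted variant order
  poly_src <- rbind(if (!is.null(zpoly)) zpoly$df,
                    if (!is.null(par_sites)) par_sites$df,
                    if (!is.null(auto_sites)) auto_sites$df)
  if (length(poly_rows)) {
    key_sorted <- paste(variants$chrom[poly_rows], variants$pos[poly_rows])
    key_src <- paste(poly_src$chrom, poly_src$pos)
    p_sorted <- pvec[match(key_sorted, key_src)]
    female <- samples$sex == "F"
    for (k in seq_along(poly_rows)) {
      row <- poly_rows[k]
      if (is_zpoly[row]) {
        # one segregating Z per female (the W allele carries the reference)
        dos[row, female] <- stats::rbinom(sum(female), 1L, p_sorted[k])
        dos[row, !female] <- stats::rbinom(sum(!female), 2L, p_sorted[k])
      } else {
        dos[row, ] <- stats::rbinom(n, 2L, p_sorted[k])
      }
    }
  }

  # genotyping error then missingness
  if (cfg$genotype_error_rate > 0) {
    err <- which(matrix(stats::runif(length(dos)) < cfg$genotype_error_rate,
                        nrow(dos)))
    for (e in err) {
      dos[e] <- sample(setdiff(0:2, dos[e]), 1L)
    }
  }
  if (cfg$missing_rate > 0) {
    dos[matrix(stats::runif(length(dos)) < cfg$missing_rate,
               nrow(dos))] <- NA_integer_
  }

  gm <- new_genotypes(variants[, c("chrom", "pos", "ref", "alt")],
                      dos, samples)
  truth_variants <- data.frame(variants[, c("chrom", "pos", "ref", "alt")],
                               sex_linked = is_w,
                               origin = variants$origin,
                               stringsAsFactors = FALSE)
  list(genotypes = gm, samples = samples, truth_variants = truth_variants)
}

#' @noRd
simulate_coverage <- function(cfg, samples, del_spans) {
  tile <- function(chrom, len) {
    starts <- seq(1L, len, cfg$window)
    data.frame(chrom = chrom, window_start = starts,
               window_end = pmin(starts + cfg$window, len + 1L))
  }
  wins <- rbind(tile("chrZ", cfg$chrom_length), tile("chrA", cfg$autosome_length))
  factor_f <- rep(1, nrow(wins))
  if (length(del_spans)) {
    for (sp in del_spans) {
      hit <- wins$chrom == "chrZ" &
        wins$window_start <= sp[2] & (wins$window_end - 1L) >= sp[1]
      factor_f[hit] <- 0.5
    }
  }
  rows <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    fac <- if (samples$sex[s] == "F") factor_f else rep(1, nrow(wins))
    wlen <- wins$window_end - wins$window_start
    n_reads <- stats::rpois(nrow(wins),
                            cfg$depth_mean * fac * wlen / cfg$read_length)
    rows[[s]] <- data.frame(wins, sample = samples$id[s],
                            mean_depth = n_reads * cfg$read_length / wlen)
  }
  list(coverage = do.call(rbind, rows),
       truth_windows = data.frame(wins, factor_female = factor_f))
}

# reads tile a fixed subregion of Stratum 1 (both haplotypes per individual)
#' @noRd
simulate_reads <- function(cfg, samples, z_vec, w_vec, w_dropped,
                           region_length = 30000L, coverage = 2) {
  lo <- cfg$s2_end + 1L
  hi <- min(cfg$chrom_length, lo + region_length - 1L)
  zr <- paste(z_vec[lo:hi], collapse = "")
  keep <- lo:hi
  keep <- keep[!w_dropped[keep]]
  wr <- paste(w_vec[keep], collapse = "")
  out <- stats::setNames(vector("list", nrow(samples)), samples$id)
  for (s in seq_len(nrow(samples))) {
    haps <- if (samples$sex[s] == "F") c(zr, wr) else c(zr, zr)
    rds <- unlist(lapply(haps, function(h) {
      n <- max(1L, round(coverage * nchar(h) / (2 * cfg$read_length)))
      st <- sample.int(nchar(h) - cfg$read_length + 1L, n, replace = TRUE)
      substring(h, st, st + cfg$read_length - 1L)
    }))
    flip <- stats::runif(length(rds)) < 0.5
    rds[flip] <- revcomp_chr(rds[flip])
    out[[s]] <- rds
  }
  out
}

#' Simulate allele-tagged expression counts
#'
#' Draws negative-binomial counts per gene and sample: male totals with mean
#' `2u`, female Z-allele counts with mean `u` (uncompensated) or `2u`
#' (compensated), and female W-allele counts with mean `w_factor * u`
#' (`w_factor = 0` silences the W copy). `u` is a per-gene baseline drawn
#' once around `config$expr_baseline`.
#'
#' Sex-linked gene counts are accompanied by `n_ref` autosomal reference
#' genes expressed equally in both sexes; they anchor the TPM library the
#' way the rest of the transcriptome does in real data (without them,
#' within-sample normalization would cancel the global halving of female
#' sex-linked output). Reference rows carry `sex_linked = FALSE`.
#'
#' @param genes Gene-model data.frame with `gene`, `w_factor`,
#'   `compensated` columns (as produced by [simulate_dataset()]; any table
#'   with these columns works).
#' @param config A [sim_config()].
#' @param n_ref Number of autosomal reference genes added to the table
#'   (default 2000; 0 disables them).
#' @return data.frame with `gene`, `sample`, `sex`, `z_count`, `w_count`,
#'   `total_count`, `length_bp` (CDS length when available) and
#'   `sex_linked`.
#' @export
simulate_expression <- function(genes, config, n_ref = 2000L) {
  cfg <- config
  u <- cfg$expr_baseline * exp(stats::rnorm(nrow(genes), 0, 0.4))
  u_ref <- if (n_ref > 0) {
    cfg$expr_baseline * exp(stats::rnorm(n_ref, 0, 0.4))
  } else numeric(0)
  ref_len <- if (n_ref > 0) {
    as.integer(round(1200 * exp(stats::rnorm(n_ref, 0, 0.3))))
  } else integer(0)
  samples <- data.frame(
    id = c(sprintf("eF%d", seq_len(cfg$n_expr_reps)),
           sprintf("eM%d", seq_len(cfg$n_expr_reps))),
    sex = rep(c("F", "M"), each = cfg$n_expr_reps))
  rows <- vector("list", nrow(samples))
  glen <- if ("cds_len" %in% names(genes)) genes$cds_len else
    rep(1000L, nrow(genes))
  for (s in seq_len(nrow(samples))) {
    if (samples$sex[s] == "M") {
      tot <- stats::rnbinom(nrow(genes), size = cfg$nb_size, mu = 2 * u)
      z <- tot
      w <- rep(0L, nrow(genes))
    } else {
      zmu <- ifelse(genes$compensated, 2 * u, u)
      z <- stats::rnbinom(nrow(genes), size = cfg$nb_size, mu = zmu)
      wmu <- genes$w_factor * u
      w <- ifelse(wmu > 0,
                  stats::rnbinom(nrow(genes), size = cfg$nb_size, mu = wmu), 0L)
      tot <- z + w
    }
    slr <- data.frame(gene = genes$gene, sample = samples$id[s],
                      sex = samples$sex[s], z_count = z, w_count = w,
                      total_count = tot, length_bp = glen,
                      sex_linked = TRUE)
    if (n_ref > 0) {
      rtot <- stats::rnbinom(n_ref, size = cfg$nb_size, mu = 2 * u_ref)
      ref <- data.frame(gene = sprintf("ref%04d", seq_len(n_ref)),
                        sample = samples$id[s], sex = samples$sex[s],
                        z_count = rtot, w_count = 0L, total_count = rtot,
                        length_bp = ref_len, sex_linked = FALSE)
      slr <- rbind(slr, ref)
    }
    rows[[s]] <- slr
  }
  do.call(rbind, rows)
}

#' Simulate rooted gametolog gene trees with planted topology classes
#'
#' Emits Newick strings realizing the three scenarios after rooting on the
#' outgroup: Z-W sister, sister-species grouping with Z (W loss), and
#' sister-species grouping with W (Z loss). Branch lengths are positive
#' draws; child order is shuffled so classification cannot rely on string
#' layout.
#'
#' @param counts Numeric vector of three planted class counts
#'   `(n_zw_sister, n_w_loss, n_z_loss)` (names optional).
#' @param taxa Named character vector with labels `z`, `w`,
#'   `sister_species`, `outgroup`.
#' @return data.frame with `tree` id, `newick`, `true_class`.
#' @export
simulate_gene_trees <- function(counts,
                                taxa = c(z = "sajori_Z", w = "sajori_W",
                                         sister_species = "intermedius",
                                         outgroup = "georgii")) {
  if (length(counts) != 3L || any(counts < 0)) {
    stop("counts must be three nonnegative values")
  }
  need <- c("z", "w", "sister_species", "outgroup")
  if (!all(need %in% names(taxa))) {
    stop("taxa must name: ", paste(setdiff(need, names(taxa)), collapse = ", "))
  }
  bl <- function() stats::runif(1, 0.01, 0.2)
  cherry <- function(a, b) {
    pair <- sample(c(sprintf("%s:%.4f", a, bl()), sprintf("%s:%.4f", b, bl())))
    sprintf("(%s,%s):%.4f", pair[1], pair[2], bl())
  }
  make <- function(class) {
    inner <- switch(class,
      ZW_sister = cherry(taxa[["z"]], taxa[["w"]]),
      W_loss = cherry(taxa[["z"]], taxa[["sister_species"]]),
      Z_loss = cherry(taxa[["w"]], taxa[["sister_species"]]))
    third <- switch(class,
      ZW_sister = taxa[["sister_species"]],
      W_loss = taxa[["w"]],
      Z_loss = taxa[["z"]])
    trip <- sample(c(inner, sprintf("%s:%.4f", third, bl())))
    top <- sample(c(sprintf("(%s,%s):%.4f", trip[1], trip[2], bl()),
                    sprintf("%s:%.4f", taxa[["outgroup"]], bl())))
    sprintf("(%s,%s);", top[1], top[2])
  }
  classes <- rep(c("ZW_sister", "W_loss", "Z_loss"), times = counts)
  data.frame(tree = sprintf("t%03d", seq_along(classes)),
             newick = vapply(classes, function(cl) make(cl), character(1)),
             true_class = classes, row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate reads for a male-specific-marker (XY-like) scenario
#'
#' Builds a small reference genome, inserts a male-specific segment into the
#' male haplotype, and tiles reads for a sexed cohort, for validating the
#' k-mer sex-marker scan: every marker k-mer should fall inside the planted
#' insert.
#'
#' @param genome_length Background genome length (bp).
#' @param insert_length Male-specific insert length (bp).
#' @param n_males,n_females Cohort sizes.
#' @param read_length Read length (bp).
#' @param coverage Haploid coverage of the tiling reads.
#' @param dropout_males Number of males whose reads omit the insert
#'   (to exercise the at-least-11-of-12 presence rule).
#' @return List with `reads` (named list per individual), `sex` (named
#'   vector), `insert` (the insert sequence) and `insert_interval` (position
#'   of the insert in the male haplotype).
#' @export
simulate_marker_reads <- function(genome_length = 50000L,
                                  insert_length = 5000L,
                                  n_males = 12L, n_females = 12L,
                                  read_length = 100L, coverage = 4,
                                  dropout_males = 1L) {
  backbone <- paste(sample(NUCS, genome_length, replace = TRUE), collapse = "")
  insert <- paste(sample(NUCS, insert_length, replace = TRUE), collapse = "")
  at <- genome_length %/% 2L
  male_hap <- paste0(substr(backbone, 1, at), insert,
                     substr(backbone, at + 1, genome_length))
  ids <- c(sprintf("M%02d", seq_len(n_males)), sprintf("F%02d", seq_len(n_females)))
  sex <- stats::setNames(rep(c("M", "F"), c(n_males, n_females)), ids)
  drop_ids <- sprintf("M%02d", seq_len(dropout_males))
  tile <- function(h, cov) {
    n <- max(1L, round(cov * nchar(h) / read_length))
    st <- sample.int(nchar(h) - read_length + 1L, n, replace = TRUE)
    rds <- substring(h, st, st + read_length - 1L)
    flip <- stats::runif(length(rds)) < 0.5
    rds[flip] <- revcomp_chr(rds[flip])
    rds
  }
  reads <- lapply(ids, function(id) {
    h <- if (sex[[id]] == "M" && !(id %in% drop_ids)) male_hap else backbone
    tile(h, coverage)
  })
  names(reads) <- ids
  list(reads = reads, sex = sex, insert = insert, backbone = backbone,
       male_hap = male_hap, insert_interval = c(at + 1L, at + insert_length))
}
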