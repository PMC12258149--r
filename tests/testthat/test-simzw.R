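# Synthetic ZW generator: configuration validation, determinism, truth-table
# guarantees, CDS evolution and loss-of-function planting.

test_that("configuration validation names the offending field", {
  expect_error(sim_config(par_end = 5e5, s2_end = 4e5), "par_end/s2_end")
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(lof_prob = c(PAR = 0, S2 = -0.1, S1 = 0.5)),
               "lof_prob")
  expect_error(sim_config(lof_class_weights = c(sequence_loss = 0.5,
                                                exon_loss = 0.5,
                                                orf_disrupt = 0.5,
                                                splice = 0.5)),
               "lof_class_weights")
  expect_error(sim_config(exons_per_gene_range = c(1, 3)), "exons_per_gene")
})

test_that("identical seed and config give byte-identical VCF output", {
  cfg <- test_config(seed = 77, chrom_length = 15e4, par_end = 5e4,
                     s2_end = 1e5, autosome_length = 5e4,
                     n_genes = c(PAR = 2, S2 = 2, S1 = 2))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(d1$genotypes, f1)
  write_vcf(d2$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(d1$w_seq, d2$w_seq)
  expect_identical(d1$trees$newick, d2$trees$newick)
})

test_that("lof_prob of zero leaves every gene intact and dS of zero leaves no W-specific variants", {
  cfg <- test_config(seed = 5, chrom_length = 15e4, par_end = 5e4,
                     s2_end = 1e5, autosome_length = 5e4,
                     n_genes = c(PAR = 2, S2 = 3, S1 = 3),
                     lof_prob = c(PAR = 0, S2 = 0, S1 = 0))
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$truth$genes$true_class == "intact"))

  cfg0 <- test_config(seed = 6, chrom_length = 15e4, par_end = 5e4,
                      s2_end = 1e5, autosome_length = 5e4,
                      n_genes = c(PAR = 2, S2 = 3, S1 = 3),
                      dS_true = c(PAR = 0, S2 = 0, S1 = 0),
                      lof_prob = c(PAR = 0, S2 = 0, S1 = 0))
  ds0 <- simulate_dataset(cfg0)
  expect_identical(sum(ds0$truth$variants$sex_linked), 0L)
})

test_that("every emitted variant, gene and tree has exactly one truth record", {
  ds <- clean_dataset()
  expect_identical(nrow(ds$truth$variants), nrow(ds$genotypes$variants))
  expect_identical(sort(ds$truth$genes$gene), sort(ds$genes$gene))
  expect_identical(nrow(ds$truth$trees), nrow(ds$trees))
  expect_false(any(duplicated(ds$truth$genes$gene)))
})

test_that("evolve_cds respects its boundary cases and errors", {
  set.seed(1)
  a <- random_cds(100)
  expect_identical(evolve_cds(a, 0)$derived, a)
  e <- evolve_cds(a, 0.05, omega = 0)
  expect_identical(e$n_nonsyn, 0L)
  k <- ng86_kaks(a, e$derived)
  expect_identical(k$nd, 0)
  expect_error(evolve_cds(a, -0.1), "dS_target")
  bad <- paste0("ATG", "TAA", "TTTTAA")  # internal stop
  expect_error(evolve_cds(bad, 0.1), "internal stop")
})

test_that("evolved sequences recover the target synonymous divergence", {
  set.seed(42)
  ks <- replicate(60, {
    a <- random_cds(400)
    ng86_kaks(a, evolve_cds(a, 0.035, 0.5)$derived)$ks
  })
  # Monte-Carlo tolerance: se of the mean ~ sqrt(dS/S)/sqrt(60) ~ 0.0008
  expect_lt(abs(mean(ks) - 0.035), 0.003)
})

test_that("plant_lof realizes each loss-of-function class", {
  set.seed(9)
  gene <- list(n_exons = 3L, exon_lengths = c(120L, 300L, 180L))
  cds <- random_cds(200)  # 600 bp

  seq_loss <- plant_lof(gene, cds, "sequence_loss")
  expect_lte(nchar(seq_loss$w_cds), 0.5 * nchar(cds))

  ex_loss <- plant_lof(gene, cds, "exon_loss")
  expect_identical(nchar(ex_loss$w_cds),
                   nchar(cds) - gene$exon_lengths[ex_loss$lost_exon])

  # a planted premature stop shortens the translated W product
  repeat {
    orf <- plant_lof(gene, cds, "orf_disrupt")
    if (orf$edit$type == "stop") break
  }
  tr <- strsplit(zwscan:::translate_cds(orf$w_cds), "")[[1]]
  expect_lt(which(tr == "*")[1], length(tr))

  sp <- plant_lof(gene, cds, "splice")
  expect_match(sp$splice_site, "^intron[12]_(donor|acceptor)$")
  expect_identical(sp$w_cds, cds)  # splice events live in the introns

  expect_error(plant_lof(list(n_exons = 1L, exon_lengths = 600L), cds,
                         "splice"), ">= 2 exons")
})

test_that("a planted splice event corrupts exactly one intron terminus", {
  cfg <- test_config(seed = 33, chrom_length = 15e4, par_end = 5e4,
                     s2_end = 1e5, autosome_length = 5e4,
                     n_genes = c(PAR = 0, S2 = 3, S1 = 3),
                     lof_prob = c(PAR = 0, S2 = 1, S1 = 1),
                     lof_class_weights = c(sequence_loss = 0, exon_loss = 0,
                                           orf_disrupt = 0, splice = 1))
  ds <- simulate_dataset(cfg)
  tg <- ds$truth$genes
  splice_genes <- tg$gene[tg$true_class == "splice"]
  expect_identical(length(splice_genes), 6L)
  for (g in splice_genes) {
    i <- which(ds$genes$gene == g)
    wr <- ds$w_region[[g]]
    ex <- ds$genes$exon_lengths[[i]]
    inl <- ds$genes$intron_lengths[[i]]
    bad <- 0L
    pos <- 0L
    for (j in seq_along(inl)) {
      pos <- pos + ex[j]
      donor <- substr(wr, pos + 1L, pos + 2L)
      acceptor <- substr(wr, pos + inl[j] - 1L, pos + inl[j])
      bad <- bad + (donor != "GT") + (acceptor != "AG")
      pos <- pos + inl[j]
    }
    expect_identical(bad, 1L)
  }
})

test_that("loss-of-function classes are drawn at the configured weights", {
  set.seed(31)
  w <- c(sequence_loss = 0.24, exon_loss = 0.09, orf_disrupt = 0.46,
         splice = 0.21)
  n <- 1000L
  gene <- list(n_exons = 4L, exon_lengths = c(90L, 150L, 150L, 210L))
  cds <- random_cds(200)
  cls <- character(n)
  for (i in seq_len(n)) {
    cls[i] <- sample(names(w), 1L, prob = w)
    res <- plant_lof(gene, cds, cls[i])
    expect_false(is.null(res$edit))
  }
  cnt <- table(factor(cls, levels = names(w)))
  for (k in names(w)) {
    sd_k <- sqrt(n * w[[k]] * (1 - w[[k]]))
    expect_lt(abs(cnt[[k]] - n * w[[k]]), 3 * sd_k)
  }
})

test_that("expression counts follow the compensation model", {
  set.seed(8)
  genes <- data.frame(gene = sprintf("g%03d", 1:300),
                      w_factor = 0, compensated = FALSE,
                      cds_len = 1200L)
  cfg <- sim_config(expr_baseline = 500, n_expr_reps = 2)
  ex <- simulate_expression(genes, cfg, n_ref = 0)
  expect_true(all(ex$w_count[ex$sex == "F"] == 0))   # silenced W
  fz <- tapply(ex$z_count[ex$sex == "F"], ex$gene[ex$sex == "F"], mean)
  mt <- tapply(ex$total_count[ex$sex == "M"], ex$gene[ex$sex == "M"], mean)
  ratio <- fz[names(mt)] / mt
  expect_lt(abs(stats::median(ratio) - 0.5), 0.06)

  genes$compensated <- TRUE
  set.seed(9)
  ex2 <- simulate_expression(genes, cfg, n_ref = 0)
  fz2 <- tapply(ex2$z_count[ex2$sex == "F"], ex2$gene[ex2$sex == "F"], mean)
  mt2 <- tapply(ex2$total_count[ex2$sex == "M"], ex2$gene[ex2$sex == "M"], mean)
  expect_lt(abs(stats::median(fz2[names(mt2)] / mt2) - 1), 0.1)
})

test_that("simulate_gene_trees plants the requested topologies", {
  set.seed(3)
  tr <- simulate_gene_trees(c(1, 0, 0))
  expect_identical(nrow(tr), 1L)
  ph <- ape::read.tree(text = tr$newick)
  expect_true(ape::is.monophyletic(ph, c("sajori_Z", "sajori_W")))

  expect_error(simulate_gene_trees(c(-1, 0, 0)), "nonnegative")
  expect_error(simulate_gene_trees(c(1, 1, 1),
                                   taxa = c(z = "z", w = "w",
                                            sister_species = "s")),
               "outgroup")
})

test_that("cohort genotypes honor the ZW inheritance model", {
  ds <- clean_dataset()
  tv <- ds$truth$variants
  gm <- ds$genotypes
  wrows <- which(tv$sex_linked)
  males <- gm$samples$sex == "M"
  females <- gm$samples$sex == "F"
  # no male carries a W-origin allele; every female is heterozygous
  expect_true(all(gm$dosage[wrows, males] == 0L))
  expect_true(all(gm$dosage[wrows, females] == 1L))
})
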