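# Configuration for the synthetic ZW-system generator.

REGIONS <- c("PAR", "S2", "S1")
LOF_CLASSES <- c("sequence_loss", "exon_loss", "orf_disrupt", "splice")

#' Configuration for the synthetic ZW dataset generator
#'
#' Builds a validated configuration describing a desk-scale ZW system: a
#' chromosome partitioned into a pseudo-autosomal region (PAR), a younger
#' stratum (S2) and an older stratum (S1), with per-region Z-W synonymous
#' divergence, Ka/Ks, gene content and loss-of-function rates, a sexed
#' cohort, sequencing depth, and expression/compensation settings.
#'
#' Defaults emulate the study system at reduced scale: a 2 Mb chromosome
#' (PAR up to 0.6 Mb, Stratum 2 to 1.4 Mb, Stratum 1 to the end), per-region
#' synonymous divergence 0.016/0.020/0.035 with Ka/Ks below 1, ZW females
#' and ZZ males (12 of each), ~10x depth, and loss-of-function rates of
#' 0/0.271/0.544 with class weights proportional to the observed
#' sequence-loss / exon-loss / ORF-disruption / splice mix.
#'
#' @param chrom_length Chromosome length in bp.
#' @param par_end,s2_end 1-based inclusive boundaries: PAR = `[1, par_end]`,
#'   Stratum 2 = `(par_end, s2_end]`, Stratum 1 = `(s2_end, chrom_length]`.
#' @param dS_true Named per-region synonymous divergence (PAR, S2, S1).
#' @param omega Named per-region Ka/Ks ratio in `[0, Inf)`.
#' @param n_genes Named per-region gene counts.
#' @param gene_length_range CDS length range in bp (rounded to codons).
#' @param exons_per_gene_range Exon count range (minimum 2).
#' @param lof_prob Named per-region probability that a gene's W copy carries
#'   a planted loss-of-function event.
#' @param lof_class_weights Nonnegative weights for the four event classes
#'   `sequence_loss`, `exon_loss`, `orf_disrupt`, `splice`; must sum to 1.
#' @param n_females,n_males Cohort sizes.
#' @param missing_rate,genotype_error_rate Per-genotype missingness and
#'   error probabilities.
#' @param depth_mean Mean sequencing depth (reads per site).
#' @param par_diversity Per-site heterozygosity for PAR/autosome variation.
#' @param autosome_length Length of the autosomal control chromosome.
#' @param read_length Read length in bp.
#' @param expr_baseline Expected per-allele expression counts (u).
#' @param nb_size Negative-binomial dispersion (size) for counts.
#' @param n_expr_reps Expression replicates per sex.
#' @param compensated_fraction Fraction of W-silenced genes whose Z allele
#'   is upregulated in females.
#' @param gene_tree_counts Named counts `(n_zw_sister, n_w_loss, n_z_loss)`
#'   of planted gene-tree topologies.
#' @param window Analysis window size in bp (half-open tiling).
#' @param seed Integer seed; identical seed and config give identical
#'   output.
#' @return An object of class `zw_sim_config` (validated list).
#' @export
sim_config <- function(chrom_length = 2e6,
                       par_end = 6e5,
                       s2_end = 1.4e6,
                       dS_true = c(PAR = 0.016, S2 = 0.020, S1 = 0.035),
                       omega = c(PAR = 0.31, S2 = 0.45, S1 = 0.51),
                       n_genes = c(PAR = 20, S2 = 20, S1 = 20),
                       gene_length_range = c(900, 1800),
                       exons_per_gene_range = c(2, 6),
                       lof_prob = c(PAR = 0, S2 = 0.271, S1 = 0.544),
                       lof_class_weights = c(sequence_loss = 0.241,
                                             exon_loss = 0.090,
                                             orf_disrupt = 0.455,
                                             splice = 0.214),
                       n_females = 12, n_males = 12,
                       missing_rate = 0.02,
                       genotype_error_rate = 0.002,
                       depth_mean = 10,
                       par_diversity = 0.005,
                       autosome_length = 1e6,
                       read_length = 150,
                       expr_baseline = 100,
                       nb_size = 10,
                       n_expr_reps = 2,
                       compensated_fraction = 0.1,
                       gene_tree_counts = c(n_zw_sister = 164,
                                            n_w_loss = 20,
                                            n_z_loss = 6),
                       window = 50000,
                       seed = 1L) {
  fail <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
      fail(field, "must be in [0, 1]")
    }
  }
  if (!(par_end >= 1 && par_end < s2_end && s2_end < chrom_length)) {
    fail("par_end/s2_end", "need 1 <= par_end < s2_end < chrom_length")
  }
  named_region <- function(x, field) {
    if (is.null(names(x)) || !setequal(names(x), REGIONS)) {
      fail(field, "must be named with PAR, S2, S1")
    }
    x[REGIONS]
  }
  dS_true <- named_region(dS_true, "dS_true")
  omega <- named_region(omega, "omega")
  n_genes <- named_region(n_genes, "n_genes")
  lof_prob <- named_region(lof_prob, "lof_prob")
  if (any(dS_true < 0)) fail("dS_true", "must be >= 0")
  if (any(omega < 0)) fail("omega", "must be >= 0")
  chk_prob(lof_prob, "lof_prob")
  if (is.null(names(lof_class_weights)) ||
      !setequal(names(lof_class_weights), LOF_CLASSES)) {
    fail("lof_class_weights", "must be named with the four event classes")
  }
  lof_class_weights <- lof_class_weights[LOF_CLASSES]
  if (any(lof_class_weights < 0) ||
      abs(sum(lof_class_weights) - 1) > 1e-6) {
    fail("lof_class_weights", "must be nonnegative and sum to 1")
  }
  chk_prob(missing_rate, "missing_rate")
  chk_prob(genotype_error_rate, "genotype_error_rate")
  chk_prob(par_diversity, "par_diversity")
  chk_prob(compensated_fraction, "compensated_fraction")
  if (n_females < 1 || n_males < 1) fail("n_females/n_males", "must be >= 1")
  if (exons_per_gene_range[1] < 2) fail("exons_per_gene_range", "minimum is 2")
  if (gene_length_range[1] < 90) fail("gene_length_range", "minimum CDS is 90 bp")
  if (any(gene_tree_counts < 0)) fail("gene_tree_counts", "must be >= 0")
  if (window <= 0) fail("window", "must be > 0")
  if (depth_mean <= 0) fail("depth_mean", "must be > 0")

  cfg <- list(chrom_length = as.integer(chrom_length),
              par_end = as.integer(par_end), s2_end = as.integer(s2_end),
              dS_true = dS_true, omega = omega, n_genes = n_genes,
              gene_length_range = as.integer(gene_length_range),
              exons_per_gene_range = as.integer(exons_per_gene_range),
              lof_prob = lof_prob, lof_class_weights = lof_class_weights,
              n_females = as.integer(n_females), n_males = as.integer(n_males),
              missing_rate = missing_rate,
              genotype_error_rate = genotype_error_rate,
              depth_mean = depth_mean, par_diversity = par_diversity,
              autosome_length = as.integer(autosome_length),
              read_length = as.integer(read_length),
              expr_baseline = expr_baseline, nb_size = nb_size,
              n_expr_reps = as.integer(n_expr_reps),
              compensated_fraction = compensated_fraction,
              gene_tree_counts = gene_tree_counts,
              window = as.integer(window), seed = as.integer(seed))
  class(cfg) <- "zw_sim_config"
  cfg
}

#' Region label for positions on the simulated Z chromosome
#' @param pos Integer positions (1-based).
#' @param config A `zw_sim_config` or a list with `par_end`/`s2_end`.
#' @return Character vector with values `PAR`, `S2`, `S1`.
#' @export
region_of <- function(pos, config) {
  ifelse(pos <= config$par_end, "PAR",
         ifelse(pos <= config$s2_end, "S2", "S1"))
}

#' Read a generator configuration from YAML
#' @param path YAML file with keys matching [sim_config()] arguments.
#' @return A validated `zw_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("dS_true", "omega", "n_genes", "lof_prob",
               "lof_class_weights", "gene_tree_counts")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}

#' Write a generator configuration to YAML
#' @param config A `zw_sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "zw_sim_config"))
  x <- unclass(config)
  x$dS_true <- as.list(x$dS_true)
  x$omega <- as.list(x$omega)
  x$n_genes <- as.list(x$n_genes)
  x$lof_prob <- as.list(x$lof_prob)
  x$lof_class_weights <- as.list(x$lof_class_weights)
  x$gene_tree_counts <- as.list(x$gene_tree_counts)
  yaml::write_yaml(x, path)
  invisible(path)
}
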