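# Shared fixtures: small synthetic datasets memoized across test files so
# expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

# reduced-scale study configuration: same structure as the defaults, sized
# for fast tests
test_config <- function(seed = 101, ...) {
  args <- list(chrom_length = 6e5, par_end = 2e5, s2_end = 4e5,
               autosome_length = 3e5,
               n_genes = c(PAR = 8, S2 = 10, S1 = 10),
               missing_rate = 0, genotype_error_rate = 0,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# error-free dataset used by sexscan/degeneration/dosage tests
clean_dataset <- function() {
  if (is.null(.fixtures$clean)) {
    .fixtures$clean <- simulate_dataset(test_config(seed = 101))
  }
  .fixtures$clean
}

# dataset guaranteed to contain planted W deletions (halved female coverage)
deletion_dataset <- function() {
  if (is.null(.fixtures$deletion)) {
    cfg <- test_config(seed = 202,
                       lof_prob = c(PAR = 0, S2 = 0.4, S1 = 0.8),
                       lof_class_weights = c(sequence_loss = 1,
                                             exon_loss = 0,
                                             orf_disrupt = 0, splice = 0))
    .fixtures$deletion <- simulate_dataset(cfg)
  }
  .fixtures$deletion
}

# shared null dip distribution (n = 300) for calibration/power checks
null_dips_300 <- function() {
  if (is.null(.fixtures$null300)) {
    set.seed(4242)
    .fixtures$null300 <- dip_null_distribution(300, n_boot = 1500)
  }
  .fixtures$null300
}

# independent Weir-Cockerham (1984) two-population oracle, written from the
# published variance-component formulas without reference to the package
# implementation
wc84_oracle_fst <- function(geno_f, geno_m) {
  n1 <- length(geno_f); n2 <- length(geno_m)
  p1 <- sum(geno_f) / (2 * n1); p2 <- sum(geno_m) / (2 * n2)
  h1 <- mean(geno_f == 1); h2 <- mean(geno_m == 1)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# small genotype-matrix constructor for hand-built cases
toy_genotypes <- function(dosage, sexes, chrom = "chr1",
                          pos = seq_len(nrow(dosage))) {
  ids <- sprintf("s%02d", seq_along(sexes))
  colnames(dosage) <- ids
  new_genotypes(
    data.frame(chrom = chrom, pos = pos,
               ref = rep("A", nrow(dosage)), alt = rep("T", nrow(dosage))),
    dosage,
    data.frame(id = ids, sex = sexes))
}
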