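# Dosage-compensation testing: TPM normalization, allele-specific
# expression ratios, W:Z category partition, and the dip/GMM battery.

#' Transcripts-per-million normalization
#'
#' `rate = count / length_kb; tpm = rate * 1e6 / sum(rate)` per sample, so
#' each sample's TPM values sum to one million over the quantified genes.
#'
#' @param counts Numeric matrix or data.frame, genes x samples.
#' @param lengths_bp Gene lengths in bp (> 0), recycled by row.
#' @return Matrix of TPM values with the input dimnames.
#' @export
tpm_normalize <- function(counts, lengths_bp) {
  m <- as.matrix(counts)
  if (any(lengths_bp <= 0)) stop("gene lengths must be > 0")
  if (length(lengths_bp) != nrow(m)) stop("one length per gene required")
  rate <- m / (lengths_bp / 1000)
  lib <- colSums(rate)
  if (any(lib == 0)) {
    stop("zero library: sample(s) ",
         paste(colnames(m)[lib == 0], collapse = ", "))
  }
  sweep(rate, 2, lib, "/") * 1e6
}

#' Allele-specific expression ratios and W:Z categories
#'
#' From an allele-tagged counts table builds, per sex-linked gene:
#' `wz_female` (mean over female samples of W/Z count ratio; a sample with
#' zero Z counts for the gene is excluded from that gene's mean),
#' `zf_zzm` (mean female Z-allele TPM over mean male total TPM, with the
#' female Z TPM computed as the Z-allele fraction times the gene's total
#' TPM), and the W:Z category: 1 when `wz = 0`, 2 when `0 < wz < 0.256`,
#' 3 when `0.256 <= wz < 0.667`, 4 when `wz >= 0.667`.
#'
#' TPM is computed over every gene in `counts` (so autosomal reference
#' genes anchor the library), but ratio records are reported only for the
#' sex-linked genes.
#'
#' @param counts data.frame with `gene`, `sample`, `sex`, `z_count`,
#'   `w_count`, `total_count`, `length_bp`; an optional logical
#'   `sex_linked` column marks the genes to report.
#' @param sex_linked Optional character vector of gene ids to report;
#'   overrides the column. Default: the `sex_linked` column when present,
#'   otherwise all genes.
#' @param male_tpm_floor Genes with mean male TPM below this are excluded
#'   (default 1).
#' @param cat_bounds The two W:Z category boundaries (default 0.256,
#'   0.667).
#' @return data.frame with `gene`, `wz_female`, `zf_zzm`, `category`.
#' @export
build_ratios <- function(counts, sex_linked = NULL, male_tpm_floor = 1,
                         cat_bounds = c(0.256, 0.667)) {
  need <- c("gene", "sample", "sex", "z_count", "w_count", "total_count")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  if (!any(counts$sex == "F") || !any(counts$sex == "M")) {
    stop("need at least one sample of each sex")
  }
  if (!"length_bp" %in% names(counts)) counts$length_bp <- 1000L
  genes <- unique(counts$gene)
  samples <- unique(counts$sample)
  cmat <- matrix(0, length(genes), length(samples),
                 dimnames = list(genes, samples))
  idx <- cbind(match(counts$gene, genes), match(counts$sample, samples))
  cmat[idx] <- counts$total_count
  glen <- counts$length_bp[match(genes, counts$gene)]
  tpm <- tpm_normalize(cmat, glen)

  sex_of <- counts$sex[match(samples, counts$sample)]
  f_samples <- samples[sex_of == "F"]
  m_samples <- samples[sex_of == "M"]

  zfrac <- matrix(NA_real_, length(genes), length(samples),
                  dimnames = list(genes, samples))
  zfrac[idx] <- ifelse(counts$total_count > 0,
                       counts$z_count / counts$total_count, NA_real_)
  wz <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  wz[idx] <- ifelse(counts$z_count > 0,
                    counts$w_count / counts$z_count, NA_real_)

  wz_female <- rowMeans(wz[, f_samples, drop = FALSE], na.rm = TRUE)
  zf_tpm <- rowMeans(zfrac[, f_samples, drop = FALSE] *
                       tpm[, f_samples, drop = FALSE], na.rm = TRUE)
  m_tpm <- rowMeans(tpm[, m_samples, drop = FALSE])
  zf_zzm <- ifelse(m_tpm > 0, zf_tpm / m_tpm, NA_real_)
  zf_zzm[m_tpm < male_tpm_floor] <- NA_real_

  category <- ifelse(is.na(wz_female), NA_integer_,
              ifelse(wz_female == 0, 1L,
              ifelse(wz_female < cat_bounds[1], 2L,
              ifelse(wz_female < cat_bounds[2], 3L, 4L))))
  out <- data.frame(gene = genes, wz_female = unname(wz_female),
                    zf_zzm = unname(zf_zzm), category = unname(category),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(sex_linked) && "sex_linked" %in% names(counts)) {
    sex_linked <- unique(counts$gene[counts$sex_linked])
  }
  if (!is.null(sex_linked)) out <- out[out$gene %in% sex_linked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dosage-compensation test battery per W:Z category
#'
#' Runs the dip test of unimodality on the `zf_zzm` ratios of each W:Z
#' category and, for the low-W-expression categories (W:Z below the first
#' boundary, i.e. categories 1 and 2), a 1-vs-2 component Gaussian mixture
#' decomposition.
#'
#' @param ratios data.frame from [build_ratios()].
#' @param n_boot Monte-Carlo samples for the dip p-value.
#' @param min_n Minimum genes per category to test (default 8).
#' @return List keyed by category with `n`, `dip`, `p_value`, and (low-W
#'   categories only) `gmm` (see [gmm_bic()]).
#' @export
dosage_report <- function(ratios, n_boot = 2000L, min_n = 8L) {
  out <- list()
  for (cat in sort(unique(stats::na.omit(ratios$category)))) {
    v <- ratios$zf_zzm[ratios$category == cat]
    v <- v[is.finite(v)]
    entry <- list(n = length(v))
    if (length(v) >= max(4L, min_n)) {
      dt <- dip_test(v, n_boot = n_boot)
      entry$dip <- dt$dip
      entry$p_value <- dt$p_value
      if (cat %in% c(1L, 2L) && length(v) >= 8L) {
        entry$gmm <- gmm_bic(v)
      }
    }
    out[[as.character(cat)]] <- entry
  }
  out
}
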