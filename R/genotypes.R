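# Genotype matrix container and VCF input/output.

#' Construct a genotype matrix for a sexed cohort
#'
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`;
#'   biallelic records with positions strictly increasing within chromosome.
#' @param dosage Integer matrix, variants x samples, values 0/1/2 or `NA`
#'   for missing.
#' @param samples data.frame with `id` and `sex` (`"F"` or `"M"`).
#' @return Object of class `zw_genotypes`.
#' @export
new_genotypes <- function(variants, dosage, samples) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            is.matrix(dosage), nrow(dosage) == nrow(variants),
            ncol(dosage) == nrow(samples))
  if (!all(samples$sex %in% c("F", "M"))) {
    stop("every sample needs a sex label in {F, M}")
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  bad <- !dosage %in% c(0L, 1L, 2L, NA)
  if (any(bad, na.rm = TRUE)) stop("dosages must be 0, 1, 2 or NA")
  structure(list(variants = variants, dosage = dosage, samples = samples),
            class = "zw_genotypes")
}

#' @export
print.zw_genotypes <- function(x, ...) {
  cat("zw_genotypes:", nrow(x$variants), "variants x",
      nrow(x$samples), "samples (",
      sum(x$samples$sex == "F"), "F /", sum(x$samples$sex == "M"), "M )\n")
  invisible(x)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCFv4.x file (GT field required), applies record-level filters
#' and returns a [new_genotypes()] object plus a filter report. Phased
#' separators (`|`) are accepted; phase is ignored.
#'
#' @param path VCF path (plain or gzipped).
#' @param sex_map Named character vector or two-column data.frame (`id`,
#'   `sex`) assigning `"F"`/`"M"` to every sample in the file.
#' @param maf_min Minimum minor-allele frequency (computed on non-missing
#'   alleles); default 0 keeps everything.
#' @param max_missing Maximum fraction of missing genotypes per record.
#' @param biallelic Drop records with more than one ALT allele (default
#'   TRUE).
#' @return List with `genotypes` (`zw_genotypes`) and `report` (input,
#'   retained and per-filter rejection counts; retained + rejected =
#'   input).
#' @export
read_vcf <- function(path, sex_map, maf_min = 0, max_missing = 1,
                     biallelic = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- v@gt[, "FORMAT", drop = TRUE]
  if (length(fmt) && !all(grepl("GT", fmt))) {
    stop("VCF format error: GT field missing from FORMAT")
  }
  ids <- colnames(v@gt)[-1]
  if (is.data.frame(sex_map)) {
    sex_map <- stats::setNames(as.character(sex_map$sex), sex_map$id)
  }
  if (!all(ids %in% names(sex_map))) {
    stop("sex labeling error: no sex for sample(s) ",
         paste(setdiff(ids, names(sex_map)), collapse = ", "))
  }
  samples <- data.frame(id = ids, sex = unname(sex_map[ids]),
                        stringsAsFactors = FALSE)
  if (!all(samples$sex %in% c("F", "M"))) {
    stop("sex labeling error: labels must be F or M")
  }

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  gt_raw <- v@gt[, -1, drop = FALSE]
  gt <- sub(":.*$", "", gt_raw)     # keep GT only
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- if (biallelic) sum(multi) else 0L
  keep <- if (biallelic) !multi else rep(TRUE, n_in)

  miss_frac <- rowMeans(is.na(dos))
  n_miss <- sum(keep & miss_frac > max_missing)
  keep <- keep & miss_frac <= max_missing

  alt_cnt <- rowSums(dos, na.rm = TRUE)
  called <- 2 * rowSums(!is.na(dos))
  maf <- ifelse(called > 0, pmin(alt_cnt, called - alt_cnt) / called, 0)
  n_maf <- sum(keep & maf < maf_min)
  keep <- keep & maf >= maf_min

  variants <- data.frame(chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         ref = fix$REF[keep], alt = fix$ALT[keep],
                         stringsAsFactors = FALSE)
  dosage <- dos[keep, , drop = FALSE]
  colnames(dosage) <- ids
  report <- list(input = n_in, retained = sum(keep),
                 rejected_multiallelic = n_multi,
                 rejected_missing = n_miss, rejected_maf = n_maf)
  list(genotypes = new_genotypes(variants, dosage, samples),
       report = report)
}

#' Write a genotype matrix as VCFv4.2 (GT-only FORMAT)
#'
#' @param gm A `zw_genotypes` object.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "zw_genotypes"))
  gt_str <- matrix("./.", nrow(gm$variants), nrow(gm$samples))
  gt_str[which(gm$dosage == 0L)] <- "0/0"
  gt_str[which(gm$dosage == 1L)] <- "0/1"
  gt_str[which(gm$dosage == 2L)] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples$id), collapse = "\t"))
  body <- paste(gm$variants$chrom, gm$variants$pos, ".", gm$variants$ref,
                gm$variants$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
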