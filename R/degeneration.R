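# W-allele degeneration: exon-aware alignment of Z coding sequences to the
# W haplotype, loss-of-function classification, and per-stratum summaries.

#' Align a Z coding sequence to its W region, exon by exon
#'
#' Performs a semi-global alignment (exon global, region local) of each Z
#' exon against the W gene region. An exon is flagged lost when less than
#' 20% of its bases align to region sequence or the aligned part falls
#' below 60% identity (a full-length alignment against unrelated sequence
#' shows ~25% identity, so the identity gate separates genuine absence from
#' forced alignment). Overall query coverage and identity are computed over
#' present exons.
#'
#' @param z_cds Character scalar; the Z coding sequence.
#' @param w_region Character scalar; W sequence spanning the gene (may be
#'   empty when the region was deleted).
#' @param gene Gene-model row with `exon_lengths` (CDS bp per exon, 5'->3').
#' @param match,mismatch,gap_opening,gap_extension Nucleotide alignment
#'   scoring parameters.
#' @return List with `query_coverage`, `identity`, `exons` (per-exon
#'   data.frame: aligned_fraction, identity, lost, subject_start,
#'   subject_end, net_indel), `net_indel` (summed over present exons),
#'   `w_cds_reconstructed` (subject bases of present exons, gaps removed).
#' @export
align_cds_to_region <- function(z_cds, w_region, gene,
                                match = 2, mismatch = -3,
                                gap_opening = 10, gap_extension = 0.2) {
  ex_len <- if (is.list(gene$exon_lengths)) gene$exon_lengths[[1]] else gene$exon_lengths
  stopifnot(sum(ex_len) == nchar(z_cds))
  n_ex <- length(ex_len)
  ends <- cumsum(ex_len)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  empty <- is.null(w_region) || !nzchar(w_region)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  rows <- vector("list", n_ex)
  recon <- character(n_ex)
  for (j in seq_len(n_ex)) {
    exon_seq <- substr(z_cds, starts[j], ends[j])
    if (empty || nchar(w_region) < 10L) {
      rows[[j]] <- data.frame(exon = j, aligned_fraction = 0, identity = 0,
                              lost = TRUE, subject_start = NA_integer_,
                              subject_end = NA_integer_, net_indel = 0L)
      recon[j] <- ""
      next
    }
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(exon_seq), Biostrings::DNAString(w_region),
      type = "global-local", substitutionMatrix = sm,
      gapOpening = gap_opening, gapExtension = gap_extension)
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    aligned_cols <- pat != "-" & sub != "-"
    matches <- sum(aligned_cols & pat == sub)
    aligned_fraction <- sum(aligned_cols) / nchar(exon_seq)
    identity <- if (sum(aligned_cols) > 0) matches / sum(aligned_cols) else 0
    # matched fraction guards short exons against chance alignments in
    # unrelated sequence (a present exon matches nearly all of its bases)
    matched_fraction <- matches / nchar(exon_seq)
    lost <- aligned_fraction < 0.2 || identity < 0.6 || matched_fraction < 0.5
    sspan <- c(BiocGenerics::start(Biostrings::subject(al)),
               BiocGenerics::end(Biostrings::subject(al)))
    rows[[j]] <- data.frame(
      exon = j, aligned_fraction = aligned_fraction, identity = identity,
      lost = lost, subject_start = sspan[1], subject_end = sspan[2],
      net_indel = (sspan[2] - sspan[1] + 1L) - nchar(exon_seq))
    recon[j] <- if (lost) "" else paste(sub[sub != "-"], collapse = "")
  }
  exons <- do.call(rbind, rows)
  present <- !exons$lost
  cds_len <- sum(ex_len)
  query_coverage <- sum(exons$aligned_fraction[present] * ex_len[present]) /
    cds_len
  tot_cols <- sum(exons$aligned_fraction[present] * ex_len[present])
  identity <- if (tot_cols > 0) {
    sum(exons$identity[present] * exons$aligned_fraction[present] *
          ex_len[present]) / tot_cols
  } else 0
  list(query_coverage = query_coverage, identity = identity, exons = exons,
       net_indel = sum(exons$net_indel[present]),
       w_cds_reconstructed = paste(recon, collapse = ""))
}

#' Classify a W-linked gene copy by loss-of-function evidence
#'
#' Applies the mutually exclusive precedence order:
#' \enumerate{
#'   \item `sequence_loss`: query coverage < 0.5 or identity < 0.6;
#'   \item `exon_loss`: at least `min_lost_exons` complete exons lost;
#'   \item `orf_disrupt`: start codon absent, an in-frame premature stop,
#'     or a net indel length not divisible by 3;
#'   \item `splice_disrupt`: any checkable intron terminus differs from the
#'     canonical GT donor / AG acceptor;
#'   \item `intact` otherwise.
#' }
#'
#' @param alignment Result of [align_cds_to_region()].
#' @param gene Gene-model row with `exon_lengths`.
#' @param w_region The W gene region sequence (used for splice dinucleotide
#'   checks).
#' @param min_lost_exons Lost-exon count triggering `exon_loss` (default
#'   1).
#' @return List (class `w_allele_status`) with `class`, `query_coverage`,
#'   `identity`, `evidence` (character vector; empty only for intact).
#' @export
classify_w_allele <- function(alignment, gene, w_region,
                              min_lost_exons = 1L) {
  al <- alignment
  ev <- character(0)
  cls <- NULL

  if (al$query_coverage < 0.5 || al$identity < 0.6) {
    cls <- "sequence_loss"
    ev <- sprintf("coverage=%.2f identity=%.2f", al$query_coverage, al$identity)
  }
  n_lost <- sum(al$exons$lost)
  if (is.null(cls) && n_lost >= min_lost_exons) {
    cls <- "exon_loss"
    ev <- sprintf("lost exon(s) %s",
                  paste(al$exons$exon[al$exons$lost], collapse = ","))
  }
  if (is.null(cls)) {
    w_cds <- al$w_cds_reconstructed
    orf_ev <- character(0)
    if (nchar(w_cds) >= 3L && substr(w_cds, 1, 3) != "ATG") {
      orf_ev <- c(orf_ev, sprintf("start codon %s", substr(w_cds, 1, 3)))
    }
    if (al$net_indel %% 3L != 0L) {
      orf_ev <- c(orf_ev, sprintf("net indel %+d bp", al$net_indel))
    }
    # in-frame premature stop at least one codon before the annotated stop
    n_full <- nchar(w_cds) %/% 3L
    if (n_full >= 2L) {
      cods <- substring(w_cds, seq(1L, (n_full - 1L) * 3L, 3L),
                        seq(3L, (n_full - 1L) * 3L, 3L))
      aa <- codon_tables()$aa[cods]
      stop_at <- which(!is.na(aa) & aa == "*")
      if (length(stop_at)) {
        orf_ev <- c(orf_ev, sprintf("premature stop at codon %d", stop_at[1]))
      }
    }
    if (length(orf_ev)) {
      cls <- "orf_disrupt"
      ev <- orf_ev
    }
  }
  if (is.null(cls)) {
    sp <- check_splice_sites(al, gene, w_region)
    if (length(sp)) {
      cls <- "splice_disrupt"
      ev <- sp
    }
  }
  if (is.null(cls)) cls <- "intact"
  structure(list(class = cls, query_coverage = al$query_coverage,
                 identity = al$identity, evidence = ev),
            class = "w_allele_status")
}

# canonical GT..AG check on the W region between consecutive present exons
#' @noRd
check_splice_sites <- function(alignment, gene, w_region) {
  ex <- alignment$exons
  bad <- character(0)
  if (is.null(w_region) || !nzchar(w_region)) return(bad)
  n <- nchar(w_region)
  for (j in seq_len(nrow(ex) - 1L)) {
    if (ex$lost[j] || ex$lost[j + 1L]) next
    donor_at <- ex$subject_end[j] + 1L
    accept_at <- ex$subject_start[j + 1L] - 2L
    # skip degenerate geometry (acceptor not downstream of donor)
    if (donor_at + 1L > n || accept_at < 1L || accept_at <= donor_at) next
    donor <- substr(w_region, donor_at, donor_at + 1L)
    acceptor <- substr(w_region, accept_at, accept_at + 1L)
    if (donor != "GT") bad <- c(bad, sprintf("intron %d donor %s", j, donor))
    if (acceptor != "AG") bad <- c(bad, sprintf("intron %d acceptor %s", j, acceptor))
  }
  bad
}

#' Classify every gene's W copy in a dataset
#'
#' Convenience wrapper running [align_cds_to_region()] and
#' [classify_w_allele()] over a gene table.
#'
#' @param z_cds Named character vector of Z coding sequences.
#' @param w_regions Named character vector of W gene-region sequences.
#' @param genes Gene-model data.frame with `gene` and `exon_lengths`.
#' @param min_lost_exons Passed to [classify_w_allele()].
#' @return data.frame with `gene`, `class`, `query_coverage`, `identity`,
#'   `evidence` (collapsed string).
#' @export
classify_w_alleles <- function(z_cds, w_regions, genes, min_lost_exons = 1L) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    al <- align_cds_to_region(z_cds[[g$gene]], w_regions[[g$gene]],
                              list(exon_lengths = genes$exon_lengths[[i]]))
    st <- classify_w_allele(al, g, w_regions[[g$gene]], min_lost_exons)
    data.frame(gene = g$gene, class = st$class,
               query_coverage = st$query_coverage, identity = st$identity,
               evidence = paste(st$evidence, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize W degeneration by stratum
#'
#' Counts nonfunctional W copies (any class other than `intact`) per
#' region, computes percentages, an SLR-wide total over the sex-linked
#' strata, and, when stratum ages are supplied, degeneration rates via
#' [degeneration_rates()].
#'
#' @param statuses data.frame with `gene` and `class`.
#' @param regions Named character vector mapping gene id to region (`PAR`,
#'   `S2`, `S1`); every gene must be mapped.
#' @param ages_my Optional named numeric vector of stratum ages (million
#'   years) for rate columns.
#' @param generation_time_years Generation time for per-generation rates.
#' @return data.frame with one row per region plus an `SLR` total row:
#'   `region`, `n_genes`, `n_nonfunctional`, `percent`, and (with ages)
#'   `age_my`, `pct_per_my`, `pct_per_mgen`.
#' @export
summarize_degeneration <- function(statuses, regions, ages_my = NULL,
                                   generation_time_years = 1.5) {
  unmapped <- setdiff(statuses$gene, names(regions))
  if (length(unmapped)) {
    stop("gene(s) outside the partition: ", paste(unmapped, collapse = ", "))
  }
  statuses$region <- unname(regions[statuses$gene])
  per <- lapply(split(statuses, statuses$region), function(s) {
    data.frame(region = s$region[1], n_genes = nrow(s),
               n_nonfunctional = sum(s$class != "intact"))
  })
  tab <- do.call(rbind, per)
  slr <- tab[tab$region %in% c("S1", "S2"), ]
  if (nrow(slr)) {
    tab <- rbind(tab, data.frame(region = "SLR",
                                 n_genes = sum(slr$n_genes),
                                 n_nonfunctional = sum(slr$n_nonfunctional)))
  }
  tab$percent <- 100 * tab$n_nonfunctional / tab$n_genes
  if (!is.null(ages_my)) {
    tab$age_my <- unname(ages_my[tab$region])
    rates <- degeneration_rates(tab$percent[!is.na(tab$age_my)],
                                tab$age_my[!is.na(tab$age_my)],
                                generation_time_years)
    tab$pct_per_my <- NA_real_
    tab$pct_per_mgen <- NA_real_
    tab$pct_per_my[!is.na(tab$age_my)] <- rates$per_my
    tab$pct_per_mgen[!is.na(tab$age_my)] <- rates$per_mgen
  }
  rownames(tab) <- NULL
  tab[order(match(tab$region, c("PAR", "S2", "S1", "SLR"))), ]
}
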