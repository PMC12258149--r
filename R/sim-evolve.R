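# Sequence evolution for the synthetic generator: random coding sequences,
# divergence of a W copy from its Z ancestor at a target synonymous
# divergence, and planting of loss-of-function events.

#' Random coding sequence without internal stops
#'
#' @param n_codons Number of codons including the start (ATG) and the
#'   terminal stop.
#' @return Character scalar of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  if (n_codons < 3) stop("need at least start + 1 codon + stop")
  tab <- codon_tables()
  sense <- setdiff(tab$codons, tab$stops)
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  stop_cd <- sample(tab$stops, 1L)
  paste(c("ATG", body, stop_cd), collapse = "")
}

#' Evolve a derived coding sequence at a target synonymous divergence
#'
#' Plants substitutions on an ancestral coding sequence so that the expected
#' realized synonymous divergence per synonymous site equals `dS_target`.
#' Synonymous and nonsynonymous event counts are drawn as
#' `Poisson(dS_target * S)` and `Poisson(omega * dS_target * N)` where S and
#' N are the Nei-Gojobori fractional site counts of the ancestor; events are
#' placed uniformly over single-nucleotide changes of the requested type
#' under a Jukes-Cantor-like model (all three alternative nucleotides
#' equally likely), avoiding changes that create a premature stop codon.
#' Multiple hits at one site can occur, which is what the downstream
#' Jukes-Cantor correction accounts for.
#'
#' @param ancestral_cds Character scalar; length divisible by 3, no internal
#'   stop codons.
#' @param dS_target Target synonymous divergence (substitutions per
#'   synonymous site), >= 0.
#' @param omega Ka/Ks ratio scaling the nonsynonymous event rate.
#' @return List with `derived` (character), `n_syn`, `n_nonsyn` (planted
#'   event counts).
#' @export
evolve_cds <- function(ancestral_cds, dS_target, omega = 0.5) {
  if (!is.numeric(dS_target) || dS_target < 0) stop("dS_target must be >= 0")
  if (!is.numeric(omega) || omega < 0) stop("omega must be >= 0")
  if (nchar(ancestral_cds) %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (has_internal_stop(ancestral_cds)) stop("ancestor has an internal stop codon")
  tab <- codon_tables()
  cods <- split_codons(toupper(ancestral_cds))
  L <- length(cods)

  S <- sum(tab$syn_sites[cods], na.rm = TRUE)
  N <- 3 * sum(!is.na(tab$syn_sites[cods])) - S

  n_syn <- stats::rpois(1L, dS_target * S)
  n_non <- if (omega > 0) stats::rpois(1L, omega * dS_target * N) else 0L
  if (n_syn + n_non == 0L) {
    return(list(derived = ancestral_cds, n_syn = 0L, n_nonsyn = 0L))
  }

  types <- sample(c(rep("s", n_syn), rep("n", n_non)))
  cur <- cods
  terminal_stop <- tab$aa[cur[L]] == "*"
  has_start <- cur[1] == "ATG"
  for (tp in types) {
    placed <- FALSE
    for (attempt in 1:500) {
      ci <- sample.int(L, 1L)
      if (terminal_stop && ci == L) next   # keep the terminal stop intact
      if (has_start && ci == 1L) next      # the start codon is conserved
      pos <- sample.int(3L, 1L)
      base <- strsplit(cur[ci], "")[[1]]
      alt_nt <- sample(setdiff(NUCS, base[pos]), 1L)
      alt <- base
      alt[pos] <- alt_nt
      alt_cd <- paste(alt, collapse = "")
      if (tab$aa[alt_cd] == "*") next
      syn <- tab$aa[alt_cd] == tab$aa[cur[ci]]
      if ((tp == "s") != syn) next
      cur[ci] <- alt_cd
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place a ", if (tp == "s") "synonymous" else "nonsynonymous",
           " substitution; sequence too constrained")
    }
  }
  list(derived = paste(cur, collapse = ""), n_syn = n_syn, n_nonsyn = n_non)
}

#' Plant a loss-of-function event on a W gene copy
#'
#' Mutates a W coding/genic sequence to realize one of four
#' loss-of-function classes:
#' \describe{
#'   \item{sequence_loss}{deletes at least half of the CDS;}
#'   \item{exon_loss}{removes one complete exon;}
#'   \item{orf_disrupt}{start-codon loss, a premature stop, or a frameshift
#'     indel (length not divisible by 3), chosen at random;}
#'   \item{splice}{mutates one GT donor or AG acceptor dinucleotide.}
#' }
#'
#' @param gene A gene-model row (list/data.frame row) with at least
#'   `n_exons` and `exon_lengths` (integer vector, CDS bp per exon).
#' @param w_cds Character scalar; the W CDS before the event.
#' @param class One of `sequence_loss`, `exon_loss`, `orf_disrupt`,
#'   `splice`.
#' @return List with `w_cds` (mutated CDS; for `exon_loss` the exon is
#'   removed), `lost_exon` (index or NA), `splice_site` (affected intron
#'   index and end, or NA), `detail` (free-text evidence),
#'   `intron_defunct` (for `splice`: which intron terminus to corrupt when
#'   writing the W gene region).
#' @export
plant_lof <- function(gene, w_cds, class) {
  class <- match.arg(class, LOF_CLASSES)
  n_exons <- gene$n_exons
  exon_lengths <- if (is.list(gene$exon_lengths)) gene$exon_lengths[[1]] else gene$exon_lengths
  if (class %in% c("exon_loss", "splice") && n_exons < 2) {
    stop("class '", class, "' requires a gene with >= 2 exons")
  }
  L <- nchar(w_cds)
  out <- list(w_cds = w_cds, lost_exon = NA_integer_,
              splice_site = NA_character_, detail = "", edit = NULL)
  if (class == "sequence_loss") {
    # delete a contiguous block covering >= 50% of the CDS
    del_len <- ceiling(L * stats::runif(1, 0.5, 0.9))
    start <- sample.int(L - del_len + 1L, 1L)
    out$w_cds <- paste0(substr(w_cds, 1L, start - 1L),
                        substr(w_cds, start + del_len, L))
    out$detail <- sprintf("deleted %d of %d bp at offset %d", del_len, L, start)
    out$edit <- list(type = "del", cds_start = start, cds_len = del_len)
  } else if (class == "exon_loss") {
    # lose an exon covering at most half the CDS, so the event stays in the
    # exon-loss evidence bucket rather than shading into sequence loss
    small <- which(exon_lengths <= 0.5 * L)
    ex <- if (length(small) == 1L) small else sample(small, 1L)
    ends <- cumsum(exon_lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    out$w_cds <- paste0(substr(w_cds, 1L, starts[ex] - 1L),
                        substr(w_cds, ends[ex] + 1L, L))
    out$lost_exon <- ex
    out$detail <- sprintf("lost exon %d (%d bp)", ex, exon_lengths[ex])
    out$edit <- list(type = "exon", exon = ex,
                     cds_start = starts[ex], cds_len = exon_lengths[ex])
  } else if (class == "orf_disrupt") {
    kind <- sample(c("start_loss", "premature_stop", "frameshift"), 1L)
    if (kind == "start_loss") {
      out$w_cds <- paste0("ATA", substr(w_cds, 4L, L))
      out$detail <- "start codon ATG->ATA"
      out$edit <- list(type = "sub", cds_pos = 3L, to = "A")
    } else if (kind == "premature_stop") {
      n_cod <- L %/% 3L
      ci <- sample(2:(max(3L, n_cod - 1L)), 1L)
      out$w_cds <- paste0(substr(w_cds, 1L, (ci - 1L) * 3L), "TAA",
                          substr(w_cds, ci * 3L + 1L, L))
      out$detail <- sprintf("premature stop at codon %d of %d", ci, n_cod)
      out$edit <- list(type = "stop", codon = ci)
    } else {
      indel_len <- sample(c(1L, 2L, 4L), 1L)   # not divisible by 3
      # keep indels clear of exon junctions so the planted event stays an
      # unambiguous ORF disruption rather than shading into a splice defect
      bounds <- cumsum(exon_lengths)
      ok <- setdiff(4:(L - 6L),
                    unlist(lapply(bounds, function(b) (b - 5L):(b + 5L))))
      at <- if (length(ok)) sample(ok, 1L) else sample(4:(L - 6L), 1L)
      if (stats::runif(1) < 0.5) {
        ins <- paste(sample(NUCS, indel_len, replace = TRUE), collapse = "")
        out$w_cds <- paste0(substr(w_cds, 1L, at), ins,
                            substr(w_cds, at + 1L, L))
        out$detail <- sprintf("insertion of %d bp at offset %d", indel_len, at)
        out$edit <- list(type = "ins", cds_start = at, cds_len = indel_len,
                         seq = ins)
      } else {
        out$w_cds <- paste0(substr(w_cds, 1L, at),
                            substr(w_cds, at + indel_len + 1L, L))
        out$detail <- sprintf("deletion of %d bp at offset %d", indel_len, at)
        out$edit <- list(type = "del", cds_start = at + 1L, cds_len = indel_len)
      }
    }
  } else { # splice
    intron <- sample.int(n_exons - 1L, 1L)
    end <- sample(c("donor", "acceptor"), 1L)
    out$splice_site <- sprintf("intron%d_%s", intron, end)
    out$detail <- sprintf("mutated %s of intron %d", end, intron)
    out$edit <- list(type = "splice", intron = intron, end = end)
  }
  out
}
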