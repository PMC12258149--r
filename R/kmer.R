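# Reference-free k-mer sex-marker discovery: canonical k-mers present in
# (almost) all individuals of one sex and absent from the other.

#' Canonical k-mers of a set of reads
#'
#' Enumerates all k-mers of each read and canonicalizes each one as the
#' lexicographic minimum of the k-mer and its reverse complement, so the
#' result is invariant to read orientation.
#'
#' @param reads Character vector of reads (A/C/G/T).
#' @param k Odd k-mer length (odd k makes a k-mer never its own reverse
#'   complement, so canonicalization is unambiguous).
#' @return Character vector of unique canonical k-mers.
#' @export
canonical_kmers <- function(reads, k = 31L) {
  if (k %% 2L == 0L) stop("k must be odd")
  reads <- reads[nchar(reads) >= k]
  if (length(reads) == 0L) return(character(0))
  km <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    substring(r, 1:(n - k + 1L), k:n)
  }))
  km <- unique(km)
  rc <- revcomp_chr(km)
  unique(pmin(km, rc))
}

#' Sex-specific marker k-mers
#'
#' Finds canonical k-mers present (>= 1 occurrence) in at least
#' `min_target_presence` individuals of the target sex and in at most
#' `max_other_presence` individuals of the other sex, then extracts the
#' carrier reads of the target sex: every read containing at least one
#' marker in forward or reverse-complement orientation.
#'
#' @param reads_by_individual Named list of read vectors, one per
#'   individual.
#' @param sexes Named character vector (`"F"`/`"M"`) for each individual.
#' @param target_sex Sex whose specific k-mers are sought (default `"M"`).
#' @param k Odd k-mer length (default 31).
#' @param min_target_presence Minimum individuals of the target sex
#'   carrying the k-mer (default 11).
#' @param max_other_presence Maximum individuals of the other sex carrying
#'   it (default 0).
#' @return List with `markers` (character vector of canonical k-mers) and
#'   `carrier_reads` (named list per target individual).
#' @export
kmer_sex_markers <- function(reads_by_individual, sexes, target_sex = "M",
                             k = 31L, min_target_presence = 11L,
                             max_other_presence = 0L) {
  if (k %% 2L == 0L) stop("k must be odd")
  if (any(!lengths(reads_by_individual))) stop("every individual needs reads")
  rl <- range(nchar(unlist(reads_by_individual, use.names = FALSE)))
  if (k > rl[1]) stop("k exceeds the read length")
  ids <- names(reads_by_individual)
  if (!all(ids %in% names(sexes))) stop("missing sex label for some individuals")
  tgt <- ids[sexes[ids] == target_sex]
  oth <- ids[sexes[ids] != target_sex]

  # presence = >= 1 occurrence: tabulate each individual's k-mer set once
  tab <- function(ids) {
    sets <- lapply(ids, function(id) canonical_kmers(reads_by_individual[[id]], k))
    all_km <- unlist(sets, use.names = FALSE)
    table(all_km)
  }
  t_tab <- tab(tgt)
  o_tab <- if (length(oth)) tab(oth) else integer(0)
  cand <- names(t_tab)[t_tab >= min_target_presence]
  if (length(cand) && length(o_tab)) {
    o_hits <- o_tab[cand]
    o_hits[is.na(o_hits)] <- 0L
    cand <- cand[o_hits <= max_other_presence]
  }
  markers <- sort(unname(cand))

  carrier_reads <- stats::setNames(vector("list", length(tgt)), tgt)
  if (length(markers)) {
    for (id in tgt) {
      rds <- reads_by_individual[[id]]
      hit <- vapply(rds, function(r) {
        kms <- canonical_kmers(r, k)
        any(kms %in% markers)
      }, logical(1), USE.NAMES = FALSE)
      carrier_reads[[id]] <- rds[hit]
    }
  } else {
    for (id in tgt) carrier_reads[[id]] <- character(0)
  }
  list(markers = markers, carrier_reads = carrier_reads)
}
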