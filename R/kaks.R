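# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction for gametolog pairs,
# plus reciprocal-best-hit pairing of Z and W protein sets.

#' Nei-Gojobori (1986) Ka/Ks for one aligned codon pair
#'
#' Computes synonymous (`Ks`) and nonsynonymous (`Ka`) substitutions per site
#' between two aligned coding sequences using fractional site counting and
#' shortest-pathway averaging of multi-substitution codons, with the
#' Jukes-Cantor multiple-hit correction `d = -(3/4) log(1 - 4p/3)`.
#'
#' Codons containing an alignment gap in either sequence are excluded
#' pairwise; codons that are stops in both sequences are skipped with a
#' warning. Proportions `p >= 3/4` cannot be corrected and are flagged as
#' saturated (`NA` divergence).
#'
#' @param seq1,seq2 Character scalars; aligned coding sequences of equal
#'   length divisible by 3 (A/C/G/T plus `-` for gaps).
#' @return A list with elements `ka`, `ks`, `S`, `N` (fractional site
#'   counts), `sd`, `nd` (observed substitution counts), `ps`, `pn`
#'   (uncorrected proportions) and logical `saturated`.
#' @examples
#' z <- paste(rep("TTT", 10), collapse = "")
#' w <- paste(c(rep("TTT", 9), "TTC"), collapse = "")
#' ng86_kaks(z, w)$ks  # 0.3831
#' @export
ng86_kaks <- function(seq1, seq2) {
  if (!is.character(seq1) || !is.character(seq2) ||
      length(seq1) != 1L || length(seq2) != 1L) {
    stop("seq1 and seq2 must be single character strings")
  }
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("aligned sequences differ in length")
  tab <- codon_tables()
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)

  gap <- grepl("-", c1, fixed = TRUE) | grepl("-", c2, fixed = TRUE)
  c1 <- c1[!gap]; c2 <- c2[!gap]
  bad <- !(c1 %in% tab$codons) | !(c2 %in% tab$codons)
  c1 <- c1[!bad]; c2 <- c2[!bad]
  both_stop <- tab$aa[c1] == "*" & tab$aa[c2] == "*"
  if (any(both_stop)) {
    # a shared terminal stop is ordinary; shared internal stops are odd
    if (any(both_stop[-length(both_stop)])) {
      warning(sum(both_stop[-length(both_stop)]),
              " internal codon(s) are stops in both sequences; skipped")
    }
    c1 <- c1[!both_stop]; c2 <- c2[!both_stop]
  }
  # a stop in only one sequence cannot be pathway-counted cleanly; skip too
  one_stop <- tab$aa[c1] == "*" | tab$aa[c2] == "*"
  c1 <- c1[!one_stop]; c2 <- c2[!one_stop]
  if (length(c1) == 0L) stop("no comparable codons after gap/stop exclusion")

  S <- (sum(tab$syn_sites[c1]) + sum(tab$syn_sites[c2])) / 2
  N <- 3 * length(c1) - S

  diff <- which(c1 != c2)
  sd <- nd <- 0
  for (i in diff) {
    d <- codon_pair_diffs(c1[i], c2[i])
    sd <- sd + d[["sd"]]
    nd <- nd + d[["nd"]]
  }
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps); ka <- jc(pn)
  list(ka = ka, ks = ks, S = S, N = N, sd = sd, nd = nd,
       ps = ps, pn = pn, saturated = is.na(ks) || is.na(ka))
}

#' Ka/Ks for a table of gametolog pairs
#'
#' Applies [ng86_kaks()] to each Z/W coding-sequence pair and returns a
#' divergence record table suitable for strata comparison. Pairs whose
#' sequences differ in length (typically W copies carrying deletions or
#' frameshifts) cannot be codon-compared without a frameshift-aware
#' alignment; they are flagged `defective` with `NA` divergence and belong
#' to the degeneration analysis instead.
#'
#' @param z_cds,w_cds Named character vectors of aligned coding sequences;
#'   names are gene ids and must match.
#' @param positions Optional named numeric vector of Z-assembly positions
#'   (bp) per gene.
#' @param region Optional named character vector of region labels per gene.
#' @return A data.frame with one row per gene: `gene`, `z_pos`, `region`,
#'   `ka`, `ks`, `S`, `N`, `sd`, `nd`, `saturated`, `defective`.
#' @export
kaks_table <- function(z_cds, w_cds, positions = NULL, region = NULL) {
  genes <- intersect(names(z_cds), names(w_cds))
  if (length(genes) == 0L) stop("no shared gene ids between z_cds and w_cds")
  rows <- lapply(genes, function(g) {
    base <- data.frame(gene = g,
                       z_pos = if (is.null(positions)) NA_real_ else
                         unname(positions[g]),
                       region = if (is.null(region)) NA_character_ else
                         unname(region[g]))
    if (nchar(z_cds[[g]]) != nchar(w_cds[[g]])) {
      return(data.frame(base, ka = NA_real_, ks = NA_real_, S = NA_real_,
                        N = NA_real_, sd = NA_real_, nd = NA_real_,
                        saturated = NA, defective = TRUE))
    }
    k <- ng86_kaks(z_cds[[g]], w_cds[[g]])
    data.frame(base, ka = k$ka, ks = k$ks, S = k$S, N = k$N, sd = k$sd,
               nd = k$nd, saturated = k$saturated, defective = FALSE)
  })
  do.call(rbind, rows)
}

#' Reciprocal-best-hit pairing of two protein sets
#'
#' Scores all cross pairs by global protein alignment (BLOSUM62, affine
#' gaps) and keeps a pair when each sequence is the other's unique best hit,
#' query coverage is at least `min_query_coverage` in both directions, and
#' neither member occurs in any other retained pair (many-to-one
#' relationships removed). Score ties for the best hit make the hit
#' ambiguous and the pair is dropped.
#'
#' @param a,b Named character vectors of protein sequences.
#' @param min_query_coverage Minimum aligned fraction of the query, both
#'   ways (default 0.6).
#' @param gap_opening,gap_extension Affine gap penalties passed to the
#'   aligner.
#' @return data.frame with columns `a`, `b`, `score`, `coverage_a`,
#'   `coverage_b`; zero rows when nothing qualifies.
#' @export
rbh_pairs <- function(a, b, min_query_coverage = 0.6,
                      gap_opening = 10, gap_extension = 0.5) {
  if (length(a) == 0L || length(b) == 0L) stop("both protein sets must be nonempty")
  if (is.null(names(a)) || is.null(names(b))) stop("protein sets must be named")
  score <- matrix(NA_real_, length(a), length(b), dimnames = list(names(a), names(b)))
  cov_a <- cov_b <- score
  # pairwiseAlignment is vectorized over patterns against one subject
  for (j in seq_along(b)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(unname(a)), Biostrings::AAString(b[[j]]),
      substitutionMatrix = "BLOSUM62", type = "global",
      gapOpening = gap_opening, gapExtension = gap_extension)
    score[, j] <- Biostrings::score(al)
    # global alignment spans both sequences; coverage = non-gap fraction of
    # each sequence that sits in aligned (non-gap-to-gap) columns
    pat <- as.character(Biostrings::alignedPattern(al))
    sub <- as.character(Biostrings::alignedSubject(al))
    both <- mapply(function(p, s) {
      pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
      aligned <- pc != "-" & sc != "-"
      c(sum(aligned) / sum(pc != "-"), sum(aligned) / sum(sc != "-"))
    }, pat, sub)
    cov_a[, j] <- both[1, ]
    cov_b[, j] <- both[2, ]
  }
  best_of <- function(v) {
    m <- max(v)
    idx <- which(v == m)
    if (length(idx) == 1L) idx else NA_integer_  # tie -> ambiguous
  }
  best_b_for_a <- apply(score, 1, best_of)
  best_a_for_b <- apply(score, 2, best_of)
  keep <- list()
  for (i in seq_along(a)) {
    j <- best_b_for_a[i]
    if (is.na(j)) next
    if (is.na(best_a_for_b[j]) || best_a_for_b[j] != i) next
    if (cov_a[i, j] < min_query_coverage || cov_b[i, j] < min_query_coverage) next
    keep[[length(keep) + 1L]] <- data.frame(
      a = names(a)[i], b = names(b)[j], score = score[i, j],
      coverage_a = cov_a[i, j], coverage_b = cov_b[i, j])
  }
  if (length(keep) == 0L) {
    return(data.frame(a = character(0), b = character(0), score = numeric(0),
                      coverage_a = numeric(0), coverage_b = numeric(0)))
  }
  out <- do.call(rbind, keep)
  # reciprocal uniqueness already guarantees one-to-one, but guard anyway
  out[!duplicated(out$a) & !duplicated(out$b), , drop = FALSE]
}
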