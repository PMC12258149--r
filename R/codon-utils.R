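# Codon-level bookkeeping shared by the sequence simulator and the Ka/Ks
# estimator: fractional synonymous site counts and shortest-pathway
# substitution counting in the Nei-Gojobori (1986) framework.

NUCS <- c("A", "C", "G", "T")

.codon_cache <- new.env(parent = emptyenv())

#' @noRd
codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)

  # Fractional synonymous sites per codon: at each of the three positions,
  # the fraction of the three single-nucleotide changes that are synonymous.
  # Changes to stop codons count as nonsynonymous (they never preserve the
  # protein), matching common NG86 implementations.
  syn_sites <- stats::setNames(rep(NA_real_, 64L), codons)
  syn_changes <- stats::setNames(vector("list", 64L), codons)
  for (cd in codons) {
    if (gc_tab[[cd]] == "*") next
    s <- 0
    ch <- character(0)
    base <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (nt in setdiff(NUCS, base[pos])) {
        alt <- base
        alt[pos] <- nt
        alt_cd <- paste(alt, collapse = "")
        if (gc_tab[[alt_cd]] == "*") next
        if (gc_tab[[alt_cd]] == gc_tab[[cd]]) {
          s <- s + 1 / 3
          ch <- c(ch, alt_cd)
        }
      }
    }
    syn_sites[cd] <- s
    syn_changes[[cd]] <- ch
  }

  .codon_cache$tab <- list(
    codons = codons,
    aa = stats::setNames(aa, codons),
    stops = codons[aa == "*"],
    syn_sites = syn_sites,
    syn_changes = syn_changes
  )
  .codon_cache$tab
}

#' @noRd
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length must be divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all shortest substitution pathways, skipping pathways that pass through a
# stop codon (all pathways used if every one is blocked).  Memoized.
#' @noRd
codon_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .codon_cache$pairs[[key]]
  if (!is.null(hit)) return(hit)
  tab <- codon_tables()
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  res <- if (length(pos) == 0L) {
    c(sd = 0, nd = 0)
  } else {
    paths <- if (length(pos) == 1L) list(pos) else {
      perms <- if (length(pos) == 2L) list(c(1L, 2L), c(2L, 1L)) else {
        idx <- list()
        for (i in 1:3) for (j in setdiff(1:3, i)) {
          idx[[length(idx) + 1L]] <- c(i, j, setdiff(1:3, c(i, j)))
        }
        idx
      }
      lapply(perms, function(p) pos[p])
    }
    step_counts <- function(order) {
      cur <- b1
      sd <- nd <- 0
      for (p in order) {
        nxt <- cur
        nxt[p] <- b2[p]
        from <- paste(cur, collapse = "")
        to <- paste(nxt, collapse = "")
        if (tab$aa[[to]] == "*" || tab$aa[[from]] == "*") return(NULL)
        if (tab$aa[[from]] == tab$aa[[to]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    counts <- Filter(Negate(is.null), lapply(paths, step_counts))
    if (length(counts) == 0L) {
      # every pathway passes through a stop; fall back to ignoring the block
      counts <- lapply(paths, function(order) {
        cur <- b1
        sd <- nd <- 0
        for (p in order) {
          nxt <- cur
          nxt[p] <- b2[p]
          if (tab$aa[[paste(cur, collapse = "")]] ==
              tab$aa[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        c(sd = sd, nd = nd)
      })
    }
    Reduce(`+`, counts) / length(counts)
  }
  if (is.null(.codon_cache$pairs)) .codon_cache$pairs <- new.env(parent = emptyenv())
  assign(key, res, envir = .codon_cache$pairs)
  res
}

#' @noRd
translate_cds <- function(seq) {
  tab <- codon_tables()
  paste(tab$aa[split_codons(seq)], collapse = "")
}

#' @noRd
has_internal_stop <- function(seq) {
  tab <- codon_tables()
  cods <- split_codons(seq)
  any(tab$aa[cods[-length(cods)]] == "*")
}

#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
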