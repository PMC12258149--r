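# Readers and writers for the remaining pipeline formats: coverage and
# counts TSVs, FASTA, GFF3 subset, Newick lists, truth-table JSON.  All
# tables are tab-separated with a header line.

#' Read a per-window coverage table
#'
#' Expected columns: `chrom`, `window_start`, `window_end` (half-open
#' window, 1-based start), `sample`, `mean_depth`.
#'
#' @param path TSV path.
#' @return data.frame with typed columns; depths validated nonnegative.
#' @export
read_coverage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "window_start", "window_end", "sample", "mean_depth")
  if (!all(need %in% names(df))) {
    stop("coverage table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$mean_depth < 0)) {
    stop("parse error: negative depth at line ",
         which(df$mean_depth < 0)[1] + 1L)
  }
  df
}

#' Write a per-window coverage table
#' @param coverage data.frame as in [read_coverage()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  utils::write.table(coverage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an allele-tagged expression counts table
#'
#' Expected columns: `gene`, `sample`, `sex`, `z_count`, `w_count`,
#' `total_count`; optional `length_bp`. An empty table with a header is
#' valid.
#'
#' @param path TSV path.
#' @return data.frame; counts validated as nonnegative integers.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "sex", "z_count", "w_count", "total_count")
  if (!all(need %in% names(df))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  }
  for (cl in c("z_count", "w_count", "total_count")) {
    x <- df[[cl]]
    if (length(x) && (any(x < 0) || any(x != round(x)))) {
      stop("parse error in ", cl, ": counts must be nonnegative integers (line ",
           which(x < 0 | x != round(x))[1] + 1L, ")")
    }
  }
  df
}

#' Write an allele-tagged expression counts table
#' @param counts data.frame as in [read_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a list of Newick trees
#'
#' One tree per line. Unbalanced parentheses are reported with the
#' offending line; parsing is delegated to [ape::read.tree()].
#'
#' @param path Newick file.
#' @return List of `phylo` objects.
#' @export
read_newick_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    ln <- lines[i]
    opens <- lengths(regmatches(ln, gregexpr("(", ln, fixed = TRUE)))
    closes <- lengths(regmatches(ln, gregexpr(")", ln, fixed = TRUE)))
    if (opens != closes) {
      stop("parse error at line ", i, ": unbalanced parentheses (",
           opens, " '(' vs ", closes, " ')')")
    }
    tr <- tryCatch(ape::read.tree(text = ln),
                   error = function(e) NULL)
    if (is.null(tr)) stop("parse error at line ", i, ": malformed Newick")
    tr
  })
}

#' Write a list of Newick strings or trees
#' @param trees Character vector of Newick strings or list of `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick_list <- function(trees, path) {
  if (is.character(trees)) {
    writeLines(trees, path)
  } else {
    writeLines(vapply(trees, ape::write.tree, character(1)), path)
  }
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a GFF3 gene-model subset
#'
#' Accepts gene/mRNA/exon/CDS features; exons are validated to lie inside
#' their gene span and to be non-overlapping.
#'
#' @param path GFF3 file.
#' @return data.frame with one row per gene: `gene`, `chrom`, `strand`,
#'   `start`, `end`, `n_exons`, and list-columns `exon_starts`,
#'   `exon_ends` (1-based inclusive).
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  exons <- df[df$type == "exon", ]
  if (nrow(genes) == 0L) stop("GFF contains no gene features")
  parent_of <- function(e) {
    p <- e$Parent
    if (is.list(p) || inherits(p, "List")) p <- unlist(p)
    sub("\\.mrna$", "", sub("^mRNA:", "", as.character(p)))
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- as.character(g$ID)
    ex <- exons[parent_of(exons) %in% c(gid, paste0(gid, ".m")), ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) == 0L) stop("gene ", gid, " has no exons")
    if (any(ex$start < g$start | ex$end > g$end)) {
      stop("validation error: exon outside gene span for ", gid)
    }
    if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("validation error: overlapping exons for ", gid)
    }
    data.frame(gene = gid, chrom = as.character(g$seqnames),
               strand = as.character(g$strand), start = g$start, end = g$end,
               n_exons = nrow(ex),
               exon_starts = I(list(ex$start)), exon_ends = I(list(ex$end)))
  })
  do.call(rbind, out)
}

#' Write gene models as a GFF3 subset
#'
#' Emits gene, mRNA, exon and CDS features (CDS = exons, phase 0 chain).
#'
#' @param genes Gene-model data.frame as produced by [simulate_dataset()]
#'   (columns `gene`, `chrom`, `strand`, `start`, `end`, `exon_lengths`,
#'   `intron_lengths`) or by [read_gff()] (`exon_starts`/`exon_ends`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if ("exon_starts" %in% names(genes)) {
      es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    } else {
      iv <- gene_exon_intervals(g, genes$exon_lengths[[i]],
                                genes$intron_lengths[[i]])
      es <- vapply(iv, `[`, numeric(1), 1)
      ee <- vapply(iv, `[`, numeric(1), 2)
    }
    gid <- g$gene
    mk <- function(type, s, e, attr) {
      paste(g$chrom, "zwscan", type, s, e, ".", g$strand, if (type == "CDS") "0" else ".",
            attr, sep = "\t")
    }
    lines <- c(lines,
               mk("gene", g$start, g$end, sprintf("ID=%s", gid)),
               mk("mRNA", g$start, g$end,
                  sprintf("ID=%s.m;Parent=%s", gid, gid)),
               unlist(lapply(seq_along(es), function(j) {
                 c(mk("exon", es[j], ee[j],
                      sprintf("ID=%s.e%d;Parent=%s.m", gid, j, gid)),
                   mk("CDS", es[j], ee[j],
                      sprintf("ID=%s.c%d;Parent=%s.m", gid, j, gid)))
               })))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a truth table as JSON
#' @param truth Truth list from [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write every artifact of a synthetic dataset to a directory
#'
#' Emits VCF (cohort genotypes), FASTA (Z, W, autosome, per-gene CDS), a
#' GFF3 subset, the coverage and counts TSVs, reads FASTA per individual,
#' Newick gene trees, the truth-table JSON and the YAML configuration.
#'
#' @param ds A `zw_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "zw_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  paths <- list(
    vcf = write_vcf(ds$genotypes, p("cohort.vcf")),
    genome = write_fasta(c(chrZ = ds$z_seq, chrW = ds$w_seq,
                           chrA = ds$a_seq), p("genome.fa")),
    z_cds = write_fasta(ds$z_cds, p("z_cds.fa")),
    w_cds = write_fasta(ds$w_cds, p("w_cds.fa")),
    w_region = write_fasta(ds$w_region, p("w_region.fa")),
    gff = write_gff(ds$genes, p("genes.gff3")),
    coverage = write_coverage(ds$coverage, p("coverage.tsv")),
    counts = write_counts(ds$expression, p("counts.tsv")),
    trees = write_newick_list(ds$trees$newick, p("genetrees.nwk")),
    truth = write_truth(ds$truth, p("truth.json")),
    config = write_sim_config(ds$config, p("config.yaml")),
    sex_map = {
      utils::write.table(ds$genotypes$samples, p("sex_map.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      p("sex_map.tsv")
    },
    reads = {
      rp <- p("reads")
      dir.create(rp, showWarnings = FALSE)
      for (id in names(ds$reads)) {
        rd <- ds$reads[[id]]
        write_fasta(stats::setNames(rd, sprintf("%s_r%05d", id, seq_along(rd))),
                    file.path(rp, paste0(id, ".fa")))
      }
      rp
    })
  invisible(paths)
}
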