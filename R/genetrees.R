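# Gametolog gene-tree topology classification: did the Z and W diverge
# after the species split (Z-W sister), or does the sister species group
# with one gametolog (implying loss of the other in that lineage)?

#' Classify one rooted gametolog gene tree
#'
#' Roots the tree on the outgroup, prunes to the four decisive taxa, and
#' classifies: when the smallest clade containing Z and W excludes the
#' sister species the tree is `ZW_sister`; otherwise the sister species
#' forms a cherry with Z (`W_loss`) or with W (`Z_loss`). Polytomies that
#' break the rule give `unclassifiable`.
#'
#' @param tree A `phylo` object or Newick string.
#' @param labels Named character vector with entries `z`, `w`,
#'   `sister_species`, `outgroup` giving the tip labels.
#' @return One of `"ZW_sister"`, `"W_loss"`, `"Z_loss"`,
#'   `"unclassifiable"`.
#' @export
classify_gametolog_tree <- function(tree, labels) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  need <- c("z", "w", "sister_species", "outgroup")
  miss <- setdiff(need, names(labels))
  if (length(miss)) stop("labels must name: ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(labels[need]), tree$tip.label)
  if (length(absent)) {
    stop("labeled taxon missing from tree: ", paste(absent, collapse = ", "))
  }
  if (labels[["outgroup"]] %in% labels[c("z", "w", "sister_species")]) {
    stop("outgroup label must differ from the focal labels")
  }
  tree <- ape::keep.tip(tree, unname(labels[need]))
  tree <- ape::root(tree, outgroup = labels[["outgroup"]],
                    resolve.root = TRUE)
  z <- labels[["z"]]; w <- labels[["w"]]; s <- labels[["sister_species"]]

  mrca_tips <- function(a, b) {
    node <- ape::getMRCA(tree, c(a, b))
    ape::extract.clade(tree, node)$tip.label
  }
  zw <- mrca_tips(z, w)
  if (!(s %in% zw)) return("ZW_sister")
  zs <- mrca_tips(z, s)
  ws <- mrca_tips(w, s)
  if (!(w %in% zs) && (z %in% ws)) return("W_loss")
  if (!(z %in% ws) && (w %in% zs)) return("Z_loss")
  "unclassifiable"
}

#' Summarize gene-tree topology classes
#'
#' @param classes Character vector of per-tree classes (output of
#'   [classify_gametolog_tree()]).
#' @return data.frame with `class`, `count`, `percent` (rounded to the
#'   nearest integer), ordered ZW_sister, W_loss, Z_loss, unclassifiable.
#' @export
summarize_topologies <- function(classes) {
  if (length(classes) == 0L) stop("need at least one classified tree")
  lev <- c("ZW_sister", "W_loss", "Z_loss", "unclassifiable")
  tab <- table(factor(classes, levels = lev))
  out <- data.frame(class = names(tab), count = as.integer(tab),
                    percent = as.integer(round(100 * as.integer(tab) /
                                                 length(classes))))
  out[out$count > 0 | out$class != "unclassifiable", , drop = FALSE]
}

#' Classify a list of gene trees
#'
#' @param trees Character vector of Newick strings or list of `phylo`
#'   objects.
#' @param labels As in [classify_gametolog_tree()].
#' @return data.frame with `tree` index and `class`, plus a `summary`
#'   attribute from [summarize_topologies()].
#' @export
classify_gametolog_trees <- function(trees, labels) {
  cls <- vapply(seq_along(trees), function(i) {
    classify_gametolog_tree(if (is.list(trees) && !inherits(trees, "phylo"))
      trees[[i]] else trees[i], labels)
  }, character(1))
  out <- data.frame(tree = seq_along(trees), class = cls)
  attr(out, "summary") <- summarize_topologies(cls)
  out
}
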