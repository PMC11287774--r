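# Per-internode gene-tree concordance and conflict counting against a
# reference tree, with internode certainty (ICA) computed over all observed
# conflicting bipartitions. Bipartitions are root-free: each internal edge
# of an unrooted tree splits the taxa two ways; the side not containing a
# fixed anchor taxon is the canonical representation.

# tip sets descending from each internal edge of a phylo tree
edge_tip_sets <- function(tree) {
  trav <- tree_traversal(tree)
  ntip <- trav$ntip
  sets <- vector("list", ntip + trav$tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- trav$tree$tip.label[i]
  for (e in seq_len(nrow(trav$edge))) {
    par <- trav$edge[e, 1L]; chi <- trav$edge[e, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  list(trav = trav, sets = sets)
}

canonical_bip <- function(side, taxa, anchor) {
  side <- sort(side)
  if (anchor %in% side) side <- sort(setdiff(taxa, side))
  side
}

bip_key <- function(side) paste(side, collapse = "|")

#' Informative bipartitions of a tree
#'
#' One bipartition per internal edge (unrooted semantics); only informative
#' splits (both sides with >= 2 taxa) are returned, canonicalized as the
#' side not containing the anchor taxon.
#'
#' @param tree a `phylo`.
#' @param anchor anchor taxon (default: first tip label alphabetically).
#' @return named list of character vectors (canonical sides); names are
#'   `|`-joined keys; attribute `taxa` carries the tree's leaf set.
#' @export
tree_bipartitions <- function(tree, anchor = min(tree$tip.label)) {
  et <- edge_tip_sets(tree)
  taxa <- sort(tree$tip.label)
  ntip <- et$trav$ntip
  root <- et$trav$root
  out <- list()
  for (e in seq_len(nrow(et$trav$edge))) {
    chi <- et$trav$edge[e, 2L]
    if (chi <= ntip) next                       # trivial split
    side <- et$sets[[chi]]
    if (length(side) < 2L || length(side) > length(taxa) - 2L) next
    cb <- canonical_bip(side, taxa, anchor)
    out[[bip_key(cb)]] <- cb
  }
  # for rooted trees the two root edges induce the same split; dedup by key
  attr(out, "taxa") <- taxa
  out
}

# are two splits of the same taxon set compatible?
splits_compatible <- function(a, b, taxa) {
  ac <- setdiff(taxa, a); bc <- setdiff(taxa, b)
  !length(intersect(a, b)) || !length(intersect(a, bc)) ||
    !length(intersect(ac, b)) || !length(intersect(ac, bc))
}

#' Collapse weakly supported edges to polytomies
#'
#' Internal edges whose numeric support (node label) is below `threshold`
#' are contracted; `threshold = 0` is the identity. Edges without a numeric
#' support value are kept.
#'
#' @param tree a `phylo` with supports as internal node labels.
#' @param threshold support threshold on the same scale as the labels.
#' @return a `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold = 0) {
  if (threshold <= 0) return(tree)
  sup <- node_supports(tree)
  if (all(is.na(sup)) )
    stop("threshold > 0 but tree has no numeric support values")
  ntip <- length(tree$tip.label)
  # internal (non-root) edges whose child node has support < threshold
  drop_nodes <- which(!is.na(sup) & sup < threshold) + ntip
  drop_nodes <- setdiff(drop_nodes, ntip + 1L)  # never contract the root
  if (!length(drop_nodes)) return(tree)
  work <- tree
  sel <- work$edge[, 2L] %in% drop_nodes
  work$edge.length <- rep(1, nrow(work$edge))
  work$edge.length[sel] <- 0
  out <- ape::di2multi(work, tol = 1e-9)
  if (!is.null(tree$edge.length)) {
    # restore original lengths where edges survive (match by split content)
    key_of <- function(tr) {
      et <- edge_tip_sets(tr)
      vapply(seq_len(nrow(et$trav$edge)), function(e)
        bip_key(sort(et$sets[[et$trav$edge[e, 2L]]])), character(1L))
    }
    k_new <- key_of(out); k_old <- key_of(tree)
    trav_old <- tree_traversal(tree); trav_new <- tree_traversal(out)
    m <- match(k_new, k_old)
    out <- trav_new$tree
    out$edge.length <- ifelse(is.na(m), 0, trav_old$len[m])
  } else out$edge.length <- NULL
  out
}

#' Assess one reference bipartition against one gene tree
#'
#' The reference split is restricted to the gene tree's taxa. If either
#' restricted side has fewer than 2 taxa the gene tree is uninformative for
#' this internode; if the restricted split occurs among the gene tree's
#' splits it is concordant; if any gene-tree split is incompatible with it
#' the gene tree conflicts (the incompatible split is recorded); otherwise
#' the gene tree is unresolved there, hence uninformative.
#'
#' @param ref_side canonical reference side (character vector of taxa).
#' @param ref_taxa reference leaf set.
#' @param gene_tree a `phylo` whose taxa are a subset of `ref_taxa`.
#' @param anchor anchor taxon for canonicalization.
#' @return list with `status` (`"concordant"`, `"conflicting"`,
#'   `"uninformative"`) and `conflict_with` (canonical key or `NA`).
#' @export
assess_node <- function(ref_side, ref_taxa, gene_tree,
                        anchor = min(ref_taxa)) {
  gtaxa <- sort(gene_tree$tip.label)
  if (length(gtaxa) < 4L)
    return(list(status = "uninformative", conflict_with = NA_character_))
  side <- intersect(ref_side, gtaxa)
  other <- setdiff(gtaxa, side)
  if (length(side) < 2L || length(other) < 2L)
    return(list(status = "uninformative", conflict_with = NA_character_))
  ganchor <- min(gtaxa)
  target <- canonical_bip(side, gtaxa, ganchor)
  gbips <- tree_bipartitions(gene_tree, anchor = ganchor)
  tkey <- bip_key(target)
  if (tkey %in% names(gbips))
    return(list(status = "concordant", conflict_with = NA_character_))
  for (gb in gbips) {
    if (!splits_compatible(target, gb, gtaxa)) {
      # record the conflicting split in reference-anchor coordinates
      conf <- canonical_bip(gb, gtaxa, ganchor)
      return(list(status = "conflicting", conflict_with = bip_key(conf)))
    }
  }
  list(status = "uninformative", conflict_with = NA_character_)
}

#' Internode certainty over all conflicting bipartitions (ICA)
#'
#' With the reference count `c0` and conflicting-bipartition counts
#' `c1..cm`, let `n = m + 1` and `p_i = c_i / sum(c)`. Then
#' `ICA = 1 + sum(p_i * log_n(p_i))`, defined as 1 when there is no
#' conflict, and negated when the reference count is not the strict
#' maximum.
#'
#' @param counts numeric vector: reference count first, then one count per
#'   distinct conflicting bipartition.
#' @return ICA in `[-1, 1]`, or `NA` when all counts are zero.
#' @export
ica <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0")
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  counts <- counts[counts > 0 | seq_along(counts) == 1L]
  n <- length(counts)
  if (n == 1L) return(1)
  p <- counts / sum(counts)
  p <- p[p > 0]
  val <- 1 + sum(p * log(p) / log(n))
  if (max(counts[-1L]) >= counts[1L]) val <- -val
  val + 0  # normalizes IEEE negative zero
}

#' Per-internode concordance analysis of gene trees against a reference
#'
#' PhyParts-style counting: for every informative internode of the
#' reference tree, each gene tree is concordant, conflicting (with a
#' recorded bipartition) or uninformative; the most frequent conflicting
#' bipartition is the "top conflict" and the ICA score is computed over the
#' reference and all observed conflicting bipartitions.
#'
#' @param ref reference `phylo`.
#' @param gene_trees list of `phylo`; taxa may be subsets of the
#'   reference's.
#' @param support_threshold collapse gene-tree edges below this support
#'   before counting (default 0 = no collapsing).
#' @param anchor anchor taxon for canonical bipartitions (default: first
#'   reference tip alphabetically; use the outgroup for readable output).
#' @return data.frame of class `node_concordance`: one row per reference
#'   internode with `bipartition`, `clade`, `concordant`, `top_conflict`,
#'   `top_conflict_n`, `other_conflict`, `uninformative`, `ica`.
#' @export
concordance_analysis <- function(ref, gene_trees, support_threshold = 0,
                                 anchor = min(ref$tip.label)) {
  if (!length(gene_trees)) stop("need >= 1 gene tree")
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  rtaxa <- sort(ref$tip.label)
  rbips <- tree_bipartitions(ref, anchor = anchor)
  if (support_threshold > 0)
    gene_trees <- lapply(gene_trees, collapse_low_support,
                         threshold = support_threshold)
  rows <- lapply(rbips, function(side) {
    conc <- 0L; uninf <- 0L
    conflicts <- character(0L)
    for (gt in gene_trees) {
      extra <- setdiff(gt$tip.label, rtaxa)
      if (length(extra))
        stop("gene tree has taxa absent from the reference: ",
             paste(extra, collapse = ", "))
      a <- assess_node(side, rtaxa, gt, anchor = anchor)
      if (a$status == "concordant") conc <- conc + 1L
      else if (a$status == "conflicting") conflicts <- c(conflicts, a$conflict_with)
      else uninf <- uninf + 1L
    }
    ctab <- sort(table(conflicts), decreasing = TRUE)
    ica_val <- ica(c(conc, as.numeric(ctab)))
    data.frame(bipartition = bip_key(side),
               clade = paste(side, collapse = ","),
               concordant = conc,
               top_conflict = if (length(ctab)) names(ctab)[1L] else NA_character_,
               top_conflict_n = if (length(ctab)) as.integer(ctab[1L]) else 0L,
               other_conflict = if (length(ctab) > 1L)
                 as.integer(sum(ctab[-1L])) else 0L,
               uninformative = uninf,
               ica = ica_val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("node_concordance", "data.frame")
  attr(out, "n_gene_trees") <- length(gene_trees)
  out
}

#' Write a node-concordance table as TSV
#' @param nc a `node_concordance` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(nc, path) {
  utils::write.table(nc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
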