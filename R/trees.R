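#' Read newick trees
#'
#' Thin wrapper over [ape::read.tree()] that trims whitespace from tip
#' labels and always returns a list of `phylo` objects. Internal node labels
#' are kept and interpreted as support values by downstream stages.
#'
#' @param path newick file (one or more trees).
#' @return list of `phylo` trees.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in ", path)
  if (inherits(tr, "phylo")) tr <- list(tr)
  lapply(tr, function(t) { t$tip.label <- trimws(t$tip.label); t })
}

#' Write trees to newick
#'
#' Branch lengths are serialized with enough digits to round-trip; internal
#' node labels (supports) are preserved.
#'
#' @param trees a `phylo` or list of `phylo`.
#' @param path output path; if `NULL`, returns newick text.
#' @return newick string(s), invisibly when written to file.
#' @export
write_newick <- function(trees, path = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(t) ape::write.tree(t, digits = 12), character(1L))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Numeric node support values of a tree
#'
#' Reads internal node labels as numeric supports; empty or non-numeric
#' labels give `NA`.
#'
#' @param tree a `phylo`.
#' @return numeric vector of length `tree$Nnode`.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Bundle alternative topology hypotheses for a focal clade
#'
#' Labeled alternative resolutions (`T1` ... `Tk`) of one focal clade, all
#' over the same leaf set. The first label is the reference against which
#' the signal deltas are taken.
#'
#' @param focal_name name of the focal clade (e.g. `"Gymnogynum"`).
#' @param trees named list of `phylo` trees (names `T1`, `T2`, ...). If
#'   unnamed, labels `T1..Tk` are assigned in order.
#' @param reference_label label treated as the reference (default first).
#' @return an object of class `topology_set`.
#' @export
topology_set <- function(focal_name, trees, reference_label = NULL) {
  if (length(trees) < 2L) stop("need at least two hypotheses")
  if (is.null(names(trees)) || any(names(trees) == ""))
    names(trees) <- paste0("T", seq_along(trees))
  leaf_sets <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(trees)[-1L]) {
    if (!identical(leaf_sets[[i]], leaf_sets[[1L]]))
      stop("hypothesis trees do not share one leaf set (",
           names(trees)[1L], " vs ", names(trees)[i], ")")
  }
  if (is.null(reference_label)) reference_label <- names(trees)[1L]
  if (!reference_label %in% names(trees))
    stop("reference_label not among hypothesis labels")
  structure(list(focal_name = focal_name, trees = trees,
                 reference_label = reference_label),
            class = "topology_set")
}

#' @export
print.topology_set <- function(x, ...) {
  cat(sprintf("topology_set '%s': %d hypotheses (%s), reference %s, %d taxa\n",
              x$focal_name, length(x$trees),
              paste(names(x$trees), collapse = ", "),
              x$reference_label, length(x$trees[[1L]]$tip.label)))
  invisible(x)
}

#' Labels of a topology set, reference first
#' @param hyps a [topology_set()].
#' @return character vector.
#' @export
hypothesis_labels <- function(hyps) {
  c(hyps$reference_label, setdiff(names(hyps$trees), hyps$reference_label))
}
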