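# Felsenstein pruning engine: per-site log-likelihoods of a fixed topology
# under GTR+Gamma, with per-node rescaling against underflow and site-pattern
# compression for speed.

# Compress alignment columns into unique site patterns.
# Returns list(patterns = ntaxa x npat character matrix, map = site -> pattern).
compress_patterns <- function(aln) {
  m <- unclass(aln)
  keys <- do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
  u <- !duplicated(keys)
  map <- match(keys, keys[u])
  list(patterns = m[, u, drop = FALSE], map = map)
}

# Tip partial likelihoods: list (per taxon) of npat x 4 matrices.
tip_partials <- function(patterns) {
  bad <- setdiff(unique(as.vector(patterns)), rownames(iupac_partials))
  if (length(bad))
    stop("unknown sequence symbol(s): ", paste(bad, collapse = " "))
  lapply(seq_len(nrow(patterns)), function(i)
    iupac_partials[patterns[i, ], , drop = FALSE])
}

# Postorder edge traversal info for a phylo tree.
tree_traversal <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree, edge = tree$edge, len = tree$edge.length,
       ntip = length(tree$tip.label), root = length(tree$tip.label) + 1L)
}

# Per-pattern log-likelihood for one rate category.
# partials: list of tip partial matrices indexed by tip number.
prune_patterns_one_rate <- function(trav, partials, model, rate) {
  npat <- nrow(partials[[1L]])
  nnode <- trav$ntip + trav$tree$Nnode
  L <- vector("list", nnode)
  L[seq_len(trav$ntip)] <- partials
  scaler <- numeric(npat)
  edge <- trav$edge
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; chi <- edge[e, 2L]
    P <- transition_matrix(model, trav$len[e] * rate)
    contrib <- L[[chi]] %*% t(P)
    if (is.null(L[[par]])) L[[par]] <- contrib
    else L[[par]] <- L[[par]] * contrib
    if (chi > trav$ntip) L[chi] <- list(NULL)  # free internal child
    # rescale parent when complete enough; cheap to do every edge touch
    mx <- .rowMaxs(L[[par]])
    if (any(mx < 1e-80)) mx[mx < 1e-80] <- 1e-80
    L[[par]] <- L[[par]] / mx
    scaler <- scaler + log(mx)
  }
  root_l <- as.vector(L[[trav$root]] %*% model$freqs)
  log(root_l) + scaler
}

.rowMaxs <- function(m) {
  out <- m[, 1L]
  for (j in 2L:ncol(m)) { w <- m[, j] > out; out[w] <- m[w, j] }
  out
}

# Per-pattern log-likelihood averaged over Gamma categories.
prune_patterns <- function(trav, partials, model) {
  npat <- nrow(partials[[1L]])
  per_cat <- vapply(model$cat_rates,
                    function(r) prune_patterns_one_rate(trav, partials, model, r),
                    numeric(npat))
  if (model$k == 1L) return(as.vector(per_cat))
  per_cat <- matrix(per_cat, nrow = npat)
  m <- apply(per_cat, 1L, max)
  m + log(rowMeans(exp(per_cat - m)))
}

check_leaf_match <- function(tree, aln) {
  a <- sort(tree$tip.label); b <- sort(rownames(aln))
  if (!identical(a, b)) {
    only_tree <- setdiff(a, b); only_aln <- setdiff(b, a)
    stop("tree/alignment taxon mismatch; only in tree: {",
         paste(only_tree, collapse = ", "), "}; only in alignment: {",
         paste(only_aln, collapse = ", "), "}")
  }
}

#' Per-site log-likelihood under a fixed tree
#'
#' Felsenstein pruning under GTR+Gamma. Missing symbols (`-`, `?`, `N`)
#' contribute partial likelihood 1 for every state; the site likelihood is
#' the mean over Gamma categories of the category likelihoods.
#'
#' @param tree `phylo` with branch lengths, leaf set equal to the alignment
#'   taxa.
#' @param aln a [dna_alignment()].
#' @param model a [gtr_model()].
#' @return numeric vector of per-site log-likelihoods, with attribute
#'   `total` (their sum).
#' @export
site_loglik <- function(tree, aln, model) {
  check_leaf_match(tree, aln)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths on every edge")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  cp <- compress_patterns(aln)
  trav <- tree_traversal(tree)
  # order tip partials by the tree's tip numbering
  idx <- match(trav$tree$tip.label, rownames(aln))
  partials <- tip_partials(cp$patterns)[idx]
  pat_ll <- prune_patterns(trav, partials, model)
  out <- pat_ll[cp$map]
  attr(out, "total") <- sum(out)
  out
}

# total log-likelihood given precomputed traversal/partials (internal,
# used by the optimizers; edge lengths taken from `len`)
total_loglik_fast <- function(trav, partials, model, len, weights) {
  trav$len <- len
  sum(prune_patterns(trav, partials, model) * weights)
}

# ---- two-pass machinery for fast single-branch optimization -------------
#
# Down pass: per rate category, conditional likelihoods D[v] of the data
# below each node given its state (rescaled per node, log-scalers S[v]
# accumulated per pattern) and per-edge contributions
# C[e] = D[child] %*% t(P(t_e)). The likelihood as a function of one
# branch length then needs only D[child], the parent's upward partial and
# the sibling contributions, making per-branch optimization O(1) passes.

engine_children <- function(trav) {
  nnode <- trav$ntip + trav$tree$Nnode
  ch <- vector("list", nnode)
  for (e in seq_len(nrow(trav$edge))) {
    p <- trav$edge[e, 1L]
    ch[[p]] <- c(ch[[p]], e)
  }
  ch
}

engine_down_pass <- function(trav, partials, model, len) {
  npat <- nrow(partials[[1L]])
  nnode <- trav$ntip + trav$tree$Nnode
  nedge <- nrow(trav$edge)
  lapply(seq_len(model$k), function(cc) {
    rate <- model$cat_rates[cc]
    D <- vector("list", nnode)
    S <- vector("list", nnode)
    C <- vector("list", nedge)
    for (i in seq_len(trav$ntip)) { D[[i]] <- partials[[i]]; S[[i]] <- numeric(npat) }
    for (e in seq_len(nedge)) {
      par <- trav$edge[e, 1L]; chi <- trav$edge[e, 2L]
      if (chi > trav$ntip) {  # internal child now complete: rescale
        mx <- .rowMaxs(D[[chi]])
        mx[mx < 1e-100] <- 1e-100
        D[[chi]] <- D[[chi]] / mx
        S[[chi]] <- S[[chi]] + log(mx)
      }
      P <- transition_matrix(model, len[e] * rate)
      C[[e]] <- D[[chi]] %*% t(P)
      if (is.null(D[[par]])) { D[[par]] <- C[[e]]; S[[par]] <- S[[chi]] }
      else { D[[par]] <- D[[par]] * C[[e]]; S[[par]] <- S[[par]] + S[[chi]] }
    }
    list(D = D, S = S, C = C)
  })
}

# edges on the path from the root down to `node` (root end first)
engine_root_path <- function(trav, parent_edge, node) {
  path <- integer(0L)
  v <- node
  while (v != trav$root) {
    e <- parent_edge[v]
    path <- c(e, path)
    v <- trav$edge[e, 1L]
  }
  path
}

# upward partial U[par] (and its log-scaler) for the parent of edge `eopt`,
# per category, from the current down-pass structures
engine_up_for_edge <- function(trav, down, model, len, children, parent_edge,
                               eopt) {
  par_target <- trav$edge[eopt, 1L]
  npat <- nrow(down[[1L]]$D[[1L]])
  lapply(seq_len(model$k), function(cc) {
    rate <- model$cat_rates[cc]
    dc <- down[[cc]]
    U <- matrix(rep(model$freqs, each = npat), npat, 4L)
    SU <- numeric(npat)
    path <- engine_root_path(trav, parent_edge, par_target)
    for (e in path) {
      par <- trav$edge[e, 1L]; chi <- trav$edge[e, 2L]
      W <- U
      for (se in children[[par]]) {
        if (se == e) next
        W <- W * dc$C[[se]]
        SU <- SU + dc$S[[trav$edge[se, 2L]]]
      }
      P <- transition_matrix(model, len[e] * rate)
      U <- W %*% P
      mx <- .rowMaxs(U)
      mx[mx < 1e-100] <- 1e-100
      U <- U / mx
      SU <- SU + log(mx)
    }
    # multiply in siblings of the optimized edge at the target parent
    for (se in children[[par_target]]) {
      if (se == eopt) next
      U <- U * dc$C[[se]]
      SU <- SU + dc$S[[trav$edge[se, 2L]]]
    }
    list(U = U, SU = SU)
  })
}

# total lnL as a function of the length of edge `eopt`
engine_edge_loglik <- function(t, trav, down, up, model, eopt, weights) {
  chi <- trav$edge[eopt, 2L]
  npat <- length(weights)
  per_cat <- matrix(NA_real_, npat, model$k)
  for (cc in seq_len(model$k)) {
    P <- transition_matrix(model, t * model$cat_rates[cc])
    lik <- rowSums((down[[cc]]$D[[chi]] %*% t(P)) * up[[cc]]$U)
    lik[lik < 1e-300] <- 1e-300
    per_cat[, cc] <- log(lik) + down[[cc]]$S[[chi]] + up[[cc]]$SU
  }
  if (model$k == 1L) return(sum(per_cat[, 1L] * weights))
  m <- .rowMaxs(per_cat)
  sum((m + log(rowMeans(exp(per_cat - m)))) * weights)
}

#' Optimize branch lengths on a fixed topology
#'
#' Round-robin single-branch maximization (Brent's method per branch on the
#' interval `[1e-6, 10]`) repeated until the total log-likelihood improves
#' by less than `tol` or `max_sweeps` is reached.
#'
#' @param topology `phylo`; existing branch lengths are the starting point,
#'   missing ones start at 0.1.
#' @param aln a [dna_alignment()].
#' @param model a [gtr_model()].
#' @param tol convergence tolerance on the total log-likelihood
#'   (default 1e-6).
#' @param max_sweeps maximum optimization sweeps (default 100).
#' @return the tree with optimized `edge.length` and attributes `loglik`
#'   (total), `converged` (logical) and `sweeps`.
#' @export
optimize_branch_lengths <- function(topology, aln, model, tol = 1e-6,
                                    max_sweeps = 100L) {
  check_leaf_match(topology, aln)
  cp <- compress_patterns(aln)
  trav <- tree_traversal(topology)
  idx <- match(trav$tree$tip.label, rownames(aln))
  partials <- tip_partials(cp$patterns)[idx]
  weights <- tabulate(cp$map, nbins = ncol(cp$patterns))
  len <- trav$len
  if (is.null(len) || !length(len)) len <- rep(0.1, nrow(trav$edge))
  len[is.na(len) | len <= 0] <- 0.1
  len <- pmin(pmax(len, 1e-6), 10)
  ll <- total_loglik_fast(trav, partials, model, len, weights)
  converged <- FALSE
  sweeps <- 0L
  children <- engine_children(trav)
  parent_edge <- integer(trav$ntip + trav$tree$Nnode)
  for (e in seq_len(nrow(trav$edge))) parent_edge[trav$edge[e, 2L]] <- e
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    ll_start <- ll
    for (e in seq_along(len)) {
      down <- engine_down_pass(trav, partials, model, len)
      up <- engine_up_for_edge(trav, down, model, len, children,
                               parent_edge, e)
      f <- function(lt) engine_edge_loglik(exp(lt), trav, down, up, model,
                                           e, weights)
      opt <- stats::optimize(f, interval = log(c(1e-6, 10)), maximum = TRUE,
                             tol = 1e-4)
      if (opt$objective > ll) { len[e] <- exp(opt$maximum); ll <- opt$objective }
    }
    if (ll - ll_start < tol) { converged <- TRUE; break }
  }
  ll <- total_loglik_fast(trav, partials, model, len, weights)
  out <- trav$tree
  out$edge.length <- len
  attr(out, "loglik") <- ll
  attr(out, "converged") <- converged
  attr(out, "sweeps") <- sweeps
  if (!converged)
    warning("branch-length optimization did not converge in ", max_sweeps,
            " sweeps")
  out
}

#' Fit GTR+Gamma free parameters on a fixed tree
#'
#' Alternates branch-length optimization with numerical maximization of the
#' exchangeabilities (GT fixed at 1) and Gamma shape. Base frequencies are
#' empirical counts (the common ML practice).
#'
#' @param topology `phylo` starting tree.
#' @param aln a [dna_alignment()].
#' @param model starting [gtr_model()]; its `k` is kept.
#' @param rounds alternation rounds (default 2).
#' @param estimate_alpha optimize the Gamma shape (default TRUE when
#'   `model$k > 1`).
#' @return list with `model` (fitted), `tree` (optimized lengths) and
#'   `loglik`.
#' @export
fit_gtr_model <- function(topology, aln, model = gtr_model(), rounds = 2L,
                          estimate_alpha = model$k > 1L) {
  freqs <- empirical_freqs(aln)
  model <- gtr_model(model$rates, freqs, model$alpha, model$k)
  tree <- topology
  ll <- NA_real_
  for (r in seq_len(rounds)) {
    tree <- optimize_branch_lengths(tree, aln, model, tol = 1e-4)
    cp <- compress_patterns(aln)
    trav <- tree_traversal(tree)
    idx <- match(trav$tree$tip.label, rownames(aln))
    partials <- tip_partials(cp$patterns)[idx]
    weights <- tabulate(cp$map, nbins = ncol(cp$patterns))
    npar <- if (estimate_alpha) 6L else 5L
    start <- c(log(pmax(model$rates[1:5] / model$rates[6L], 1e-4)),
               if (estimate_alpha) log(model$alpha))
    obj <- function(p) {
      rates <- c(exp(p[1:5]), 1)
      alpha <- if (estimate_alpha) exp(p[6L]) else model$alpha
      if (alpha > 100 || any(rates > 1e4)) return(1e10)
      m2 <- gtr_model(rates, freqs, alpha, model$k)
      -total_loglik_fast(trav, partials, m2, trav$len, weights)
    }
    fit <- stats::nlminb(start, obj, control = list(rel.tol = 1e-8))
    rates <- c(exp(fit$par[1:5]), 1)
    alpha <- if (estimate_alpha) exp(fit$par[6L]) else model$alpha
    model <- gtr_model(rates, freqs, alpha, model$k)
    ll <- -fit$objective
  }
  tree <- optimize_branch_lengths(tree, aln, model, tol = 1e-5)
  list(model = model, tree = tree, loglik = attr(tree, "loglik"))
}

#' Per-site log-likelihoods under each topology hypothesis
#'
#' For each hypothesis independently, branch lengths are optimized on the
#' full concatenation and the per-site log-likelihoods recorded. By default
#' the substitution model's free parameters are estimated once on the
#' reference hypothesis and held fixed across hypotheses, isolating the
#' topological signal; pass a ready [gtr_model()] to skip estimation, or set
#' `estimate_model = TRUE` with a supplied model to force re-estimation on
#' the reference.
#'
#' @param aln a [dna_alignment()].
#' @param part a [partition_map()] over `aln`.
#' @param hyps a [topology_set()]; every tree's leaf set must equal the
#'   alignment's taxa.
#' @param model a [gtr_model()], or `NULL` to estimate on the reference
#'   hypothesis.
#' @param estimate_model force model estimation on the reference hypothesis
#'   even when `model` is supplied (used as the starting point).
#' @param optimize optimize branch lengths per hypothesis (default TRUE;
#'   FALSE evaluates the trees' own lengths).
#' @param tol branch-length optimization tolerance.
#' @return object of class `site_likelihood_matrix`: a sites x hypotheses
#'   numeric matrix of log-likelihoods with attributes `partition`, `trees`
#'   (optimized, per hypothesis), `model` and `labels` (reference first).
#' @export
per_hypothesis_site_loglik <- function(aln, part, hyps, model = NULL,
                                       estimate_model = is.null(model),
                                       optimize = TRUE, tol = 1e-6) {
  labels <- hypothesis_labels(hyps)
  for (lab in labels) check_leaf_match(hyps$trees[[lab]], aln)
  if (estimate_model) {
    fit <- fit_gtr_model(hyps$trees[[labels[1L]]], aln,
                         model = if (is.null(model)) gtr_model() else model)
    model <- fit$model
  }
  out <- matrix(NA_real_, nrow = ncol(aln), ncol = length(labels),
                dimnames = list(NULL, labels))
  trees <- list()
  for (lab in labels) {
    tr <- hyps$trees[[lab]]
    if (optimize) tr <- optimize_branch_lengths(tr, aln, model, tol = tol)
    out[, lab] <- as.vector(site_loglik(tr, aln, model))
    trees[[lab]] <- tr
  }
  structure(out, class = c("site_likelihood_matrix", "matrix"),
            partition = part, trees = trees, model = model, labels = labels,
            focal_name = hyps$focal_name)
}

#' @export
print.site_likelihood_matrix <- function(x, ...) {
  cat(sprintf("site_likelihood_matrix: %d sites x %d hypotheses (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  cat(sprintf("  total lnL: %s\n",
              paste(sprintf("%s=%.3f", colnames(x), colSums(x)),
                    collapse = "  ")))
  invisible(x)
}

#' Write a site-likelihood matrix as TSV
#'
#' Layout mirrors the site-likelihood tables of standard ML software: one
#' row per site with its 1-based index, owning locus, and one
#' log-likelihood column per hypothesis.
#'
#' @param slm a `site_likelihood_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_likelihoods <- function(slm, path) {
  part <- attr(slm, "partition")
  df <- data.frame(site = seq_len(nrow(slm)),
                   locus = site_locus_index(part, nrow(slm)),
                   as.data.frame(unclass(slm)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
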