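# Synthetic-data generators: alignments evolved on mixtures of conflicting
# topologies, discrete traits under the equal-rates Markov model, and
# circular genomes with planted repeat pairs. Everything is a pure function
# of its arguments plus a seed; per-locus child seeds are derived from the
# root seed by a fixed counter scheme so locus i is reproducible regardless
# of how many loci are requested.

#' Derive a child seed from a root seed and a counter
#'
#' Deterministic 31-bit mixing of `(seed, i)`; used so that each locus,
#' replicate or trait draws from an independent, individually reproducible
#' stream.
#'
#' @param seed integer root seed.
#' @param i non-negative integer counter.
#' @return integer in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, i) {
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(i) * 16807 + 12345
  as.integer(x %% 2147483647)
}

#' Simulate sites along a tree under GTR+Gamma
#'
#' Root states are drawn from the stationary frequencies; each branch then
#' evolves every site independently through the model's transition matrix.
#' Gamma rate categories are drawn i.i.d. per site.
#'
#' @param tree `phylo` with branch lengths (>= 0) on every edge.
#' @param model a [gtr_model()].
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed (sets the RNG).
#' @return a [dna_alignment()] with the tree's tips as taxa.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) "all"
           else paste(which(is.na(tree$edge.length)), collapse = ",")
    stop("missing branch length on edge(s): ", bad)
  }
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  trav <- tree_traversal(tree)
  ntip <- trav$ntip
  nnode <- ntip + trav$tree$Nnode
  cat_of_site <- if (model$k > 1L) sample.int(model$k, n_sites, replace = TRUE)
                 else rep(1L, n_sites)
  states <- matrix(NA_integer_, nrow = nnode, ncol = n_sites)
  states[trav$root, ] <- sample.int(4L, n_sites, replace = TRUE,
                                    prob = model$freqs)
  # preorder = reversed postorder edge list
  for (e in rev(seq_len(nrow(trav$edge)))) {
    par <- trav$edge[e, 1L]; chi <- trav$edge[e, 2L]
    child_states <- integer(n_sites)
    for (k in unique(cat_of_site)) {
      P <- transition_matrix(model, trav$len[e] * model$cat_rates[k])
      in_cat <- which(cat_of_site == k)
      ps <- states[par, in_cat]
      u <- stats::runif(length(in_cat))
      cum <- t(apply(P, 1L, cumsum))
      child_states[in_cat] <- 1L + rowSums(u > cum[ps, , drop = FALSE])
    }
    states[chi, ] <- child_states
  }
  m <- matrix(DNA_STATES[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(m) <- trav$tree$tip.label
  dna_alignment(m)
}

#' Specification for a conflicting-locus generator
#'
#' Bundles the topology hypotheses, their mixture weights, locus count and
#' length distribution, substitution model and branch scaling used by
#' [simulate_conflicting_loci()].
#'
#' @param hypotheses a [topology_set()] whose trees carry branch lengths.
#' @param mixture probability per hypothesis, in `names(hypotheses$trees)`
#'   order; non-negative, summing to 1 (within 1e-12).
#' @param n_loci number of loci (>= 1).
#' @param locus_length a single length (fixed) or `c(min, max)` for uniform
#'   integer lengths, in bp.
#' @param model a [gtr_model()].
#' @param branch_scale multiplier applied to all branch lengths (> 0).
#' @param seed root seed.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(hypotheses, mixture, n_loci,
                           locus_length = c(200L, 2000L),
                           model = gtr_model(), branch_scale = 1, seed = 1L) {
  if (length(mixture) != length(hypotheses$trees))
    stop("mixture length must match number of hypotheses")
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-12)
    stop("mixture entries must be >= 0 and sum to 1")
  if (n_loci < 1L) stop("n_loci must be >= 1")
  if (branch_scale <= 0) stop("branch_scale must be > 0")
  if (!length(locus_length) %in% 1:2 || any(locus_length < 1))
    stop("locus_length must be a length or c(min, max)")
  structure(list(hypotheses = hypotheses, mixture = mixture,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 model = model, branch_scale = branch_scale,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Simulate a concatenation of loci evolved on conflicting topologies
#'
#' Each locus's generating hypothesis is drawn from the mixture; the locus
#' is then simulated on that hypothesis tree (branch lengths scaled by
#' `branch_scale`) and the loci are concatenated in generation order.
#'
#' @param spec a [generator_spec()].
#' @return list with `alignment`, `partition`, and `truth` (a data.frame
#'   with columns `locus`, `hypothesis`, `length`).
#' @export
simulate_conflicting_loci <- function(spec) {
  set.seed(spec$seed)
  labs <- names(spec$hypotheses$trees)
  gen <- sample(labs, spec$n_loci, replace = TRUE, prob = spec$mixture)
  lens <- if (length(spec$locus_length) == 1L)
    rep(spec$locus_length, spec$n_loci)
  else sample(spec$locus_length[1L]:spec$locus_length[2L], spec$n_loci,
              replace = TRUE)
  blocks <- vector("list", spec$n_loci)
  for (i in seq_len(spec$n_loci)) {
    tr <- spec$hypotheses$trees[[gen[i]]]
    tr$edge.length <- tr$edge.length * spec$branch_scale
    blocks[[i]] <- unclass(simulate_alignment(tr, spec$model, lens[i],
                                              seed = child_seed(spec$seed, i)))
  }
  taxa <- rownames(blocks[[1L]])
  m <- do.call(cbind, lapply(blocks, function(b) b[taxa, , drop = FALSE]))
  ends <- cumsum(lens)
  starts <- ends - lens
  loci <- lapply(seq_len(spec$n_loci), function(i) c(starts[i], ends[i]))
  names(loci) <- sprintf("locus%03d", seq_len(spec$n_loci))
  list(alignment = dna_alignment(m),
       partition = partition_map(loci),
       truth = data.frame(locus = names(loci), hypothesis = gen,
                          length = lens, stringsAsFactors = FALSE))
}

#' Inject missing data into an alignment
#'
#' Masks whole locus-by-taxon blocks with `?`, emulating degraded herbarium
#' samples that fail to assemble some loci.
#'
#' @param aln a [dna_alignment()].
#' @param part a [partition_map()].
#' @param prob probability that a given taxon is missing a given locus.
#' @param seed integer seed.
#' @return masked [dna_alignment()].
#' @export
mask_missing_loci <- function(aln, part, prob = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(aln)
  for (nm in locus_names(part)) {
    drop <- stats::runif(nrow(m)) < prob
    if (any(drop)) m[drop, locus_sites(part, nm) + 1L] <- "?"
  }
  dna_alignment(m)
}

#' Simulate a discrete trait under the equal-rates Markov model
#'
#' Root state uniform over the states; each branch applies the ER
#' transition probabilities (see [er_transition()]).
#'
#' @param tree `phylo` with branch lengths.
#' @param states character vector of state labels (>= 2).
#' @param q transition rate per unit branch length (> 0).
#' @param seed integer seed.
#' @return named character vector: tip label -> state.
#' @export
simulate_trait <- function(tree, states, q, seed = NULL) {
  if (length(states) < 2L) stop("need >= 2 states")
  if (q <= 0) stop("q must be > 0")
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 tips")
  if (!is.null(seed)) set.seed(seed)
  k <- length(states)
  trav <- tree_traversal(tree)
  nnode <- trav$ntip + trav$tree$Nnode
  st <- integer(nnode)
  st[trav$root] <- sample.int(k, 1L)
  for (e in rev(seq_len(nrow(trav$edge)))) {
    P <- er_transition(k, q, trav$len[e])
    st[trav$edge[e, 2L]] <- sample.int(k, 1L, prob = P[st[trav$edge[e, 1L]], ])
  }
  stats::setNames(states[st[seq_len(trav$ntip)]], trav$tree$tip.label)
}

#' Synthesize a circular genome with planted repeat pairs
#'
#' The background is uniform random DNA, rejection-sampled so it contains no
#' chance exact repeat of at least `clean_min_len` bp (direct or inverted,
#' circular); planted pairs are then written as exact copies
#' (reverse-complemented for inverted pairs) at recorded coordinates.
#'
#' @param length genome length in bp.
#' @param planted list of `list(length =, orientation =)` entries,
#'   `orientation` one of `"direct"`, `"inverted"`; may be empty.
#' @param seed integer seed.
#' @param clean_min_len background cleanliness threshold in bp (default 500,
#'   matching the classifier's default minimum repeat length).
#' @return list with `sequence` (single character string), `planted`
#'   (data.frame of 0-based circular coordinates `start1`, `start2`,
#'   `length`, `orientation`).
#' @export
synth_plastome <- function(length, planted = list(), seed = 1L,
                           clean_min_len = 500L) {
  set.seed(seed)
  n <- as.integer(length)
  lens <- vapply(planted, function(p) as.integer(p$length), integer(1L))
  if (sum(lens) * 2L + 200L * (length(planted) * 2L) > n)
    stop("planted repeats cannot be placed in a genome of length ", n)
  for (attempt in 1:50) {
    bg <- sample(DNA_STATES, n, replace = TRUE)
    if (!has_chance_repeat(bg, clean_min_len)) break
    if (attempt == 50L) stop("failed to generate clean background")
  }
  seqv <- bg
  rec <- data.frame(start1 = integer(0), start2 = integer(0),
                    length = integer(0), orientation = character(0),
                    stringsAsFactors = FALSE)
  if (length(planted)) {
    # place copy1 of every repeat, then copy2 of every repeat, clockwise
    # with equal gaps, so the two copies of each pair sit far apart
    m <- length(planted)
    gap <- (n - 2L * sum(lens)) %/% (2L * m)
    if (gap < 50L) stop("planted repeats cannot be placed: too little spacing")
    order_lens <- c(lens, lens)  # placement order r1c1..rmc1, r1c2..rmc2
    pos <- cumsum(c(0L, head(order_lens + gap, -1L)))
    for (i in seq_len(m)) {
      unit <- sample(DNA_STATES, lens[i], replace = TRUE)
      s1 <- pos[i]
      s2 <- pos[m + i]
      seqv[(s1:(s1 + lens[i] - 1L)) %% n + 1L] <- unit
      copy2 <- if (planted[[i]]$orientation == "inverted") rev(COMPLEMENT[unit])
               else unit
      seqv[(s2:(s2 + lens[i] - 1L)) %% n + 1L] <- copy2
      rec <- rbind(rec, data.frame(start1 = s1, start2 = s2,
                                   length = lens[i],
                                   orientation = planted[[i]]$orientation,
                                   stringsAsFactors = FALSE))
    }
  }
  list(sequence = paste(seqv, collapse = ""), planted = rec)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# quick screen for chance exact repeats >= min_len in a circular background:
# any such repeat implies a duplicated k-mer (k = min(min_len, 31)) within
# the doubled sequence or between it and its reverse complement
has_chance_repeat <- function(seqv, min_len) {
  k <- min(min_len, 31L)
  s <- paste(c(seqv, seqv[seq_len(min(k, length(seqv)))]), collapse = "")
  rc <- paste(rev(COMPLEMENT[seqv]), collapse = "")
  starts <- seq_len(length(seqv))
  kmers <- substring(s, starts, starts + k - 1L)
  if (anyDuplicated(kmers)) return(TRUE)
  rc_kmers <- substring(rc, seq_len(nchar(rc) - k + 1L),
                        seq_len(nchar(rc) - k + 1L) + k - 1L)
  any(kmers %in% rc_kmers)
}
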