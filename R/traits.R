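# Equal-rates Mk model for discrete characters: transition probabilities in
# closed form, rate estimation by pruning, marginal ancestral states by
# two-pass dynamic programming, and stochastic character mapping by joint
# conditional sampling with uniformization along branches.

#' ER transition probability matrix
#'
#' For the k-state equal-rates Markov chain with off-diagonal rate `q`:
#' `P_ii(t) = 1/k + (k-1)/k * exp(-k q t)` and
#' `P_ij(t) = 1/k - 1/k * exp(-k q t)`.
#'
#' @param k number of states (>= 2).
#' @param q transition rate (>= 0).
#' @param t elapsed branch length (>= 0).
#' @return k x k row-stochastic matrix.
#' @export
er_transition <- function(k, q, t) {
  if (q < 0 || t < 0) stop("q and t must be >= 0")
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

#' Discrete trait table
#'
#' @param states character vector of state labels.
#' @param tips named character vector: tip label -> state (or `NA` for
#'   missing).
#' @return object of class `discrete_trait`.
#' @export
discrete_trait <- function(states, tips) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state labels")
  bad <- setdiff(stats::na.omit(unique(unname(tips))), states)
  if (length(bad))
    stop("tip states not in the state set: ", paste(bad, collapse = ", "))
  structure(list(states = states, tips = tips), class = "discrete_trait")
}

#' Read a two-column tip/state TSV as a discrete trait
#' @param path TSV with columns `tip` and `state` (header optional).
#' @param states state labels (default: sorted unique observed states).
#' @return a [discrete_trait()].
#' @export
read_trait_table <- function(path, states = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("tip", "state") %in% names(df))) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "",
                            col.names = c("tip", "state"))
  }
  tips <- stats::setNames(df$state, trimws(df$tip))
  if (is.null(states)) states <- sort(unique(stats::na.omit(df$state)))
  discrete_trait(states, tips)
}

# tip partial-likelihood matrix (ntip x k) for a trait on a tree
trait_tip_partials <- function(tree, trait) {
  k <- length(trait$states)
  ntip <- length(tree$tip.label)
  L <- matrix(1, ntip, k)
  obs <- trait$tips[tree$tip.label]
  known <- !is.na(obs) & tree$tip.label %in% names(trait$tips)
  for (i in which(known)) {
    L[i, ] <- 0
    L[i, match(obs[i], trait$states)] <- 1
  }
  L
}

# downward conditional likelihoods for all nodes; returns list(trav, down)
# where down[[v]] is the k-vector of P(tip data below v | state of v)
mk_down_pass <- function(tree, trait, q) {
  k <- length(trait$states)
  trav <- tree_traversal(tree)
  nnode <- trav$ntip + trav$tree$Nnode
  tipL <- trait_tip_partials(trav$tree, trait)
  down <- vector("list", nnode)
  for (i in seq_len(trav$ntip)) down[[i]] <- tipL[i, ]
  scale_log <- 0
  for (e in seq_len(nrow(trav$edge))) {
    par <- trav$edge[e, 1L]; chi <- trav$edge[e, 2L]
    P <- er_transition(k, q, trav$len[e])
    contrib <- as.vector(P %*% down[[chi]])
    down[[par]] <- if (is.null(down[[par]])) contrib else down[[par]] * contrib
  }
  list(trav = trav, down = down, k = k)
}

# total log-likelihood of the trait under ER(q), uniform root prior
mk_loglik <- function(tree, trait, q) {
  dp <- mk_down_pass(tree, trait, q)
  log(mean(dp$down[[dp$trav$root]]))
}

#' Fit the ER rate by maximum likelihood
#'
#' Maximizes the pruning likelihood (uniform root frequencies) over
#' `log(q)` by Brent's method.
#'
#' @param tree `phylo` with branch lengths.
#' @param trait a [discrete_trait()] (or named tip-state vector plus the
#'   states inferred from it).
#' @param interval search interval for `q` (default `[1e-8, 1e3]`).
#' @param tol optimization tolerance on `log(q)` (default 1e-8).
#' @return list with `q`, `loglik`, `k`, `warning` (set when the estimate
#'   hit the lower bound, e.g. for an invariant trait).
#' @export
fit_er_rate <- function(tree, trait, interval = c(1e-8, 1e3), tol = 1e-8) {
  if (!inherits(trait, "discrete_trait"))
    trait <- discrete_trait(sort(unique(stats::na.omit(trait))), trait)
  n_obs <- length(unique(stats::na.omit(trait$tips[tree$tip.label])))
  opt <- stats::optimize(function(lq) mk_loglik(tree, trait, exp(lq)),
                         interval = log(interval), maximum = TRUE, tol = tol)
  warn <- NULL
  if (n_obs < 2L || opt$maximum < log(interval[1L]) + 1e-3) {
    warn <- "rate estimate at lower bound (trait nearly invariant)"
    warning(warn)
  }
  list(q = exp(opt$maximum), loglik = opt$objective,
       k = length(trait$states), warning = warn)
}

# upward partials: up[[v]][s] = P(data outside the clade of v | parent-side
# state context), combined with down to give marginals
mk_marginals <- function(tree, trait, q) {
  dp <- mk_down_pass(tree, trait, q)
  trav <- dp$trav
  k <- dp$k
  nnode <- trav$ntip + trav$tree$Nnode
  root <- trav$root
  prior <- rep(1 / k, k)
  up <- vector("list", nnode)
  up[[root]] <- prior
  edge <- trav$edge
  children_of <- split(seq_len(nrow(edge)), edge[, 1L])
  # preorder over edges
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1L]; chi <- edge[e, 2L]
    sibs <- setdiff(children_of[[as.character(par)]], e)
    par_ctx <- up[[par]]
    for (se in sibs) {
      Ps <- er_transition(k, q, trav$len[se])
      par_ctx <- par_ctx * as.vector(Ps %*% dp$down[[edge[se, 2L]]])
    }
    P <- er_transition(k, q, trav$len[e])
    up[[chi]] <- as.vector(t(P) %*% par_ctx)
  }
  marg <- matrix(NA_real_, nnode, k)
  for (v in seq_len(nnode)) {
    m <- up[[v]] * dp$down[[v]]
    marg[v, ] <- m / sum(m)
  }
  list(trav = trav, marginals = marg, down = dp$down, k = k)
}

#' Marginal ancestral state reconstruction under Mk-ER
#'
#' Two-pass (down/up) dynamic programming with a uniform root prior (the ER
#' stationary distribution). Missing tip states are uninformative.
#'
#' @param tree `phylo` with branch lengths.
#' @param trait a [discrete_trait()].
#' @param q ER rate; if `NULL`, fitted by [fit_er_rate()].
#' @return object of class `ancestral_reconstruction`: list with
#'   `node_probs` (internal nodes x states matrix, rows sum to 1, row
#'   names = ape node numbers), `states`, `q`, `loglik`, `method`
#'   (`"marginal"`), `tree` (the postorder tree the node numbers refer to).
#' @export
marginal_asr <- function(tree, trait, q = NULL) {
  if (!inherits(trait, "discrete_trait"))
    trait <- discrete_trait(sort(unique(stats::na.omit(trait))), trait)
  if (is.null(q)) q <- fit_er_rate(tree, trait)$q
  mm <- mk_marginals(tree, trait, q)
  ntip <- mm$trav$ntip
  nodes <- (ntip + 1L):(ntip + mm$trav$tree$Nnode)
  probs <- mm$marginals[nodes, , drop = FALSE]
  dimnames(probs) <- list(nodes, trait$states)
  structure(list(node_probs = probs, states = trait$states, q = q,
                 loglik = mk_loglik(tree, trait, q), method = "marginal",
                 tree = mm$trav$tree),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("ancestral_reconstruction (%s): %d nodes, states %s, q = %g\n",
              x$method, nrow(x$node_probs),
              paste(x$states, collapse = "/"), x$q))
  invisible(x)
}

# sample one state history on the tree conditional on the tip data;
# returns list(states = node states, transitions = count of state changes)
sample_history <- function(mm, q) {
  trav <- mm$trav
  k <- mm$k
  nnode <- trav$ntip + trav$tree$Nnode
  root <- trav$root
  st <- integer(nnode)
  w <- mm$down[[root]] / k
  st[root] <- sample.int(k, 1L, prob = w / sum(w))
  edge <- trav$edge
  n_trans <- 0L
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1L]; chi <- edge[e, 2L]
    P <- er_transition(k, q, trav$len[e])
    w <- P[st[par], ] * mm$down[[chi]]
    st[chi] <- sample.int(k, 1L, prob = w / sum(w))
    n_trans <- n_trans + count_branch_transitions(k, q, trav$len[e],
                                                  st[par], st[chi])
  }
  list(states = st, transitions = n_trans)
}

# number of actual state changes along one branch conditional on the
# endpoint states, sampled by uniformization
count_branch_transitions <- function(k, q, t, a, b) {
  if (t == 0 || q == 0) return(if (a == b) 0L else stop("impossible endpoint"))
  omega <- (k - 1) * q            # uniformization rate
  R <- diag(k) + er_rate_matrix(k, q) / omega
  Pab <- er_transition(k, q, t)[a, b]
  # sample N (number of candidate jumps) by sequential search
  u <- stats::runif(1L) * Pab
  acc <- 0
  Rn <- diag(k)
  n <- 0L
  pois <- exp(-omega * t)
  repeat {
    acc <- acc + pois * Rn[a, b]
    if (acc >= u || n > 10000L) break
    n <- n + 1L
    pois <- pois * omega * t / n
    Rn <- Rn %*% R
  }
  if (n == 0L) return(0L)
  # sample the chain of candidate states by backward filtering
  Rpow <- vector("list", n + 1L)
  Rpow[[1L]] <- diag(k)
  for (i in seq_len(n)) Rpow[[i + 1L]] <- Rpow[[i]] %*% R
  states <- integer(n + 2L)
  states[1L] <- a; states[n + 2L] <- b
  for (i in seq_len(n)) {
    w <- R[states[i], ] * Rpow[[n - i + 1L]][, b]
    states[i + 1L] <- sample.int(k, 1L, prob = w / sum(w))
  }
  sum(states[-1L] != states[-(n + 2L)])
}

er_rate_matrix <- function(k, q) {
  Q <- matrix(q, k, k)
  diag(Q) <- -(k - 1) * q
  Q
}

#' Stochastic character mapping under Mk-ER
#'
#' Samples full character histories conditional on the tip data: node
#' states from the joint conditional distribution, then realized change
#' counts per branch by uniformization. Node state frequencies across
#' simulations estimate the marginal ancestral probabilities.
#'
#' @param tree `phylo` with branch lengths.
#' @param trait a [discrete_trait()].
#' @param q ER rate; if `NULL`, fitted first.
#' @param n_sims number of sampled histories (>= 1).
#' @param seed integer seed.
#' @return `ancestral_reconstruction` with `method = "stochastic-map"`,
#'   plus `n_sims`, `seed` and `expected_transitions` (mean number of state
#'   changes per history).
#' @export
stochastic_maps <- function(tree, trait, q = NULL, n_sims = 100L,
                            seed = NULL) {
  if (!inherits(trait, "discrete_trait"))
    trait <- discrete_trait(sort(unique(stats::na.omit(trait))), trait)
  if (n_sims < 1L) stop("n_sims must be >= 1")
  if (is.null(q)) q <- fit_er_rate(tree, trait)$q
  if (!is.null(seed)) set.seed(seed)
  mm <- mk_marginals(tree, trait, q)
  ntip <- mm$trav$ntip
  nodes <- (ntip + 1L):(ntip + mm$trav$tree$Nnode)
  k <- mm$k
  freq <- matrix(0, length(nodes), k, dimnames = list(nodes, trait$states))
  trans <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    h <- sample_history(mm, q)
    for (j in seq_along(nodes))
      freq[j, h$states[nodes[j]]] <- freq[j, h$states[nodes[j]]] + 1
    trans[s] <- h$transitions
  }
  structure(list(node_probs = freq / n_sims, states = trait$states, q = q,
                 loglik = mk_loglik(tree, trait, q),
                 method = "stochastic-map", tree = mm$trav$tree,
                 n_sims = n_sims, seed = seed,
                 expected_transitions = mean(trans)),
            class = "ancestral_reconstruction")
}

#' Write an ancestral reconstruction as TSV
#'
#' One row per internal node, keyed by the sorted tip content of its clade,
#' with one probability column per state.
#'
#' @param asr an `ancestral_reconstruction`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asr <- function(asr, path) {
  tree <- asr$tree
  et <- edge_tip_sets(tree)
  ntip <- length(tree$tip.label)
  nodes <- as.integer(rownames(asr$node_probs))
  et$sets[[et$trav$root]] <- tree$tip.label
  clade <- vapply(nodes, function(v)
    paste(sort(et$sets[[v]]), collapse = ","), character(1L))
  df <- data.frame(node = nodes, clade = clade,
                   asr$node_probs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
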