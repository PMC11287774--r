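# Independent oracles used by the tests. These deliberately avoid the
# package's own algorithms: likelihoods by exhaustive enumeration over
# internal-node states, ancestral probabilities by enumeration with the ER
# closed form, repeats by a quadratic shift-and-compare scan.

# per-site log-likelihood by brute-force enumeration over all internal-node
# state assignments and rate categories
brute_force_site_loglik <- function(tree, aln, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1L):nnode
  root <- ntip + 1L
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  partial_row <- function(sym) {
    tab <- list(A = 1L, C = 2L, G = 3L, T = 4L)
    if (sym %in% names(tab)) tab[[sym]] else 0L  # 0 = missing (all states)
  }
  vapply(seq_len(ncol(m)), function(s) {
    tot <- 0
    for (rate in model$cat_rates) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
        transition_matrix(model, tree$edge.length[e] * rate))
      grid <- expand.grid(rep(list(1:4), length(internal)))
      lsum <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nnode)
        st[internal] <- as.integer(grid[g, ])
        p <- model$freqs[st[root]]
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
          if (chi <= ntip) {
            obs <- partial_row(m[chi, s])
            p <- p * if (obs == 0L) 1 else Ps[[e]][st[par], obs]
          } else p <- p * Ps[[e]][st[par], st[chi]]
        }
        lsum <- lsum + p
      }
      tot <- tot + lsum / model$k
    }
    log(tot)
  }, numeric(1L))
}

# marginal ancestral probabilities under ER by enumeration over all node
# states (tips fixed to their observed state, missing tips summed out)
brute_force_er_marginals <- function(tree, trait, q) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  k <- length(trait$states)
  internal <- (ntip + 1L):nnode
  obs <- trait$tips[tree$tip.label]
  tip_choices <- lapply(seq_len(ntip), function(i) {
    if (is.na(obs[i]) || !(tree$tip.label[i] %in% names(trait$tips))) 1:k
    else match(obs[i], trait$states)
  })
  grid <- expand.grid(c(tip_choices, rep(list(1:k), length(internal))))
  root <- ntip + 1L
  joint <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    st <- as.integer(grid[g, ])
    p <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
      P <- er_transition(k, q, tree$edge.length[e])
      p <- p * P[st[par], st[chi]]
    }
    joint[g] <- p
  }
  probs <- matrix(0, length(internal), k,
                  dimnames = list(internal, trait$states))
  for (j in seq_along(internal)) {
    col <- ntip + j
    for (s in 1:k)
      probs[j, s] <- sum(joint[grid[[col]] == s])
  }
  probs / rowSums(probs)
}

rc_string <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "", fixed = TRUE)[[1L]]])), collapse = "")
}

# quadratic repeat scan: for every circular shift compare the sequence with
# its rotation (direct) or the rotation of its reverse complement
# (inverted); maximal exact runs >= min_len become repeat pairs
brute_force_repeats <- function(seq, min_len) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  u <- rev(unname(comp[v]))   # reverse complement, forward coordinates
  runs_of <- function(match_vec) {
    # circular runs of TRUE of length >= min_len; returns list of c(start0, len)
    if (all(match_vec)) return(list(c(0L, n)))
    # rotate so position 0 is FALSE
    f <- which(!match_vec)[1L] - 1L
    mv <- if (f == 0L) match_vec else match_vec[c((f + 1L):n, seq_len(f))]
    r <- rle(mv)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths          # 0-based in the rotated frame
    sel <- which(r$values & r$lengths >= min_len)
    lapply(sel, function(i) c((starts[i] + f) %% n, r$lengths[i]))
  }
  pairs <- list()
  v2 <- c(v, v)
  u2 <- c(u, u)
  for (d in 1:(n - 1L)) {
    mv <- v == v2[(d + 1L):(d + n)]
    if (sum(mv) < min_len) next
    for (run in runs_of(mv)) {
      if (run[2L] >= min_len) {
        s1 <- run[1L]; s2 <- (run[1L] + d) %% n
        key <- paste(c(sort(c(s1, s2)), run[2L], "direct"), collapse = "_")
        pairs[[key]] <- data.frame(start1 = min(s1, s2), start2 = max(s1, s2),
                                   length = run[2L], orientation = "direct",
                                   stringsAsFactors = FALSE)
      }
    }
  }
  for (d in 0:(n - 1L)) {
    mv <- v == u2[(d + 1L):(d + n)]
    if (sum(mv) < min_len) next
    for (run in runs_of(mv)) {
      if (run[2L] >= min_len) {
        s1 <- run[1L]; L <- run[2L]
        # v[s1..s1+L-1] matches u[s1+d .. s1+d+L-1]; u position p is the
        # complement of forward position (n-1-p)
        s2 <- (n - (s1 + d + L)) %% n
        key <- paste(c(sort(c(s1, s2)), L, "inverted"), collapse = "_")
        pairs[[key]] <- data.frame(start1 = min(s1, s2), start2 = max(s1, s2),
                                   length = L, orientation = "inverted",
                                   stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pairs))
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      length = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, pairs))
  rownames(out) <- NULL
  out[order(out$orientation, out$start1), , drop = FALSE]
}

# independent ICA evaluation: 1 + sum p_i log_n p_i
hand_ica <- function(counts) {
  counts <- counts[counts > 0]
  n <- length(counts)
  if (n <= 1L) return(1)
  p <- counts / sum(counts)
  1 + sum(p * log(p, base = n))
}
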