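test_that("ER transition matrices follow the closed form", {
  for (k in 2:4) {
    expect_equal(er_transition(k, 0.7, 0), diag(k), tolerance = 1e-12)
    P <- er_transition(k, 2, 50)
    expect_lt(max(abs(P - 1 / k)), 1e-12)
    set.seed(3)
    for (i in 1:5) {
      q <- stats::runif(1, 0, 3); t <- stats::runif(1, 0, 2)
      P <- er_transition(k, q, t)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
      expect_equal(P[1, 1], 1 / k + (k - 1) / k * exp(-k * q * t),
                   tolerance = 1e-12)
    }
  }
})

test_that("marginal reconstruction equals exhaustive enumeration", {
  set.seed(111)
  for (i in 1:6) {
    nt <- sample(3:5, 1)
    tr <- random_tree(nt, 0.1, 1.5)
    k <- sample(2:3, 1)
    states <- letters[1:k]
    tips <- stats::setNames(sample(states, nt, replace = TRUE), tr$tip.label)
    if (i == 4) tips[1] <- NA  # missing tip state
    trait <- discrete_trait(states, tips)
    q <- stats::runif(1, 0.2, 2)
    mine <- marginal_asr(tr, trait, q = q)
    oracle <- brute_force_er_marginals(tr, trait, q)
    o <- oracle[rownames(mine$node_probs), colnames(mine$node_probs)]
    expect_lt(max(abs(mine$node_probs - o)), 1e-10)
    expect_lt(max(abs(rowSums(mine$node_probs) - 1)), 1e-9)
  }
})

test_that("marginal probabilities match ape::ace on a variable trait", {
  skip_if_not_installed("phytools")
  set.seed(113)
  tr <- random_tree(8, 0.1, 1)
  trait_v <- simulate_trait(tr, c("A", "B", "C"), q = 1.5, seed = 7)
  trait <- discrete_trait(c("A", "B", "C"), trait_v)
  fit <- phytools::fitMk(tr, trait_v[tr$tip.label], model = "ER", pi = "equal")
  q_ref <- fit$rates[1]
  mine <- marginal_asr(tr, trait, q = q_ref)
  expect_equal(mk_ll <- mine$loglik, fit$logLik, tolerance = 1e-4)
  anc <- phytools::ancr(fit)$ace
  expect_lt(max(abs(mine$node_probs - anc[, colnames(mine$node_probs)])), 1e-3)
})

test_that("rate fitting recovers q and scales inversely with branch lengths", {
  set.seed(115)
  tr <- ape::rtree(64)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1)
  q_true <- 0.6
  qs <- replicate(10, {
    tv <- simulate_trait(tr, c("x", "y"), q_true)
    fit_er_rate(tr, discrete_trait(c("x", "y"), tv))$q
  })
  expect_lt(abs(stats::median(qs) - q_true) / q_true, 0.5)

  tv <- simulate_trait(tr, c("x", "y"), 0.3, seed = 9)
  trait <- discrete_trait(c("x", "y"), tv)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  # the likelihood depends on q * t only ...
  for (q in c(0.1, 0.5, 2))
    expect_equal(phylodissect:::mk_loglik(tr, trait, q),
                 phylodissect:::mk_loglik(tr2, trait, q / 2),
                 tolerance = 1e-12)
  # ... so doubling all branch lengths halves the rate estimate
  q1 <- fit_er_rate(tr, trait)$q
  q2 <- fit_er_rate(tr2, trait)$q
  expect_equal(q2, q1 / 2, tolerance = 0.02)
})

test_that("limits: q -> 0 pins nodes to the monomorphic state, q -> Inf to
           uniform; invariant traits warn", {
  tr <- random_tree(5, 0.2, 1)
  states <- c("u", "v")
  mono <- discrete_trait(states, stats::setNames(rep("u", 5), tr$tip.label))
  asr0 <- marginal_asr(tr, mono, q = 1e-9)
  expect_lt(max(abs(asr0$node_probs[, "u"] - 1)), 1e-6)
  vary <- discrete_trait(states, stats::setNames(c("u", "v", "u", "v", "u"),
                                                 tr$tip.label))
  asr_inf <- marginal_asr(tr, vary, q = 1e4)
  expect_lt(max(abs(asr_inf$node_probs - 0.5)), 1e-6)
  expect_warning(fit_er_rate(tr, mono), "lower bound")

  star <- ape::stree(4, "star"); star$edge.length <- rep(1, 4)
  one_var <- discrete_trait(states, stats::setNames(c("v", "u", "u", "u"),
                                                    star$tip.label))
  fit <- fit_er_rate(star, one_var)
  expect_gt(fit$q, 0)
  expect_true(is.finite(fit$q))
})

test_that("marginal probabilities are invariant to child order in the file", {
  trait <- discrete_trait(c("p", "q"),
                          c(a = "p", b = "q", c = "p", d = "q"))
  t1 <- ape::read.tree(text = "((a:0.3,b:0.5):0.2,(c:0.4,d:0.1):0.3);")
  t2 <- ape::read.tree(text = "((d:0.1,c:0.4):0.3,(b:0.5,a:0.3):0.2);")
  a1 <- marginal_asr(t1, trait, q = 0.8)
  a2 <- marginal_asr(t2, trait, q = 0.8)
  key <- function(asr) {
    tree <- asr$tree
    et <- phylodissect:::edge_tip_sets(tree)
    nodes <- as.integer(rownames(asr$node_probs))
    cl <- vapply(nodes, function(v)
      paste(sort(if (v == et$trav$root) tree$tip.label else et$sets[[v]]),
            collapse = ","), character(1))
    rownames(asr$node_probs) <- cl
    asr$node_probs[order(cl), ]
  }
  expect_equal(key(a1), key(a2), tolerance = 1e-12)
})

test_that("stochastic-map frequencies converge to the marginals and respect
           the seed", {
  set.seed(117)
  tr <- random_tree(5, 0.3, 1)
  tv <- simulate_trait(tr, c("A", "B"), q = 0.8, seed = 12)
  trait <- discrete_trait(c("A", "B"), tv)
  q <- 0.8
  marg <- marginal_asr(tr, trait, q = q)
  n_sims <- 2000L
  sm <- stochastic_maps(tr, trait, q = q, n_sims = n_sims, seed = 5)
  mc_se <- sqrt(pmax(marg$node_probs * (1 - marg$node_probs), 1e-4) / n_sims)
  expect_true(all(abs(sm$node_probs - marg$node_probs) <= 3 * mc_se + 1e-9))

  sm2 <- stochastic_maps(tr, trait, q = q, n_sims = 50L, seed = 42)
  sm3 <- stochastic_maps(tr, trait, q = q, n_sims = 50L, seed = 42)
  expect_identical(sm2$node_probs, sm3$node_probs)
  expect_identical(sm2$expected_transitions, sm3$expected_transitions)

  mono <- discrete_trait(c("A", "B"),
                         stats::setNames(rep("A", 5), tr$tip.label))
  sm0 <- stochastic_maps(tr, mono, q = 1e-8, n_sims = 20L, seed = 1)
  expect_equal(sm0$expected_transitions, 0)
})

test_that("study-style codings map to 3 habit and 4 structure states", {
  tips <- c(Afroselaginella = "NR", Megaloselaginella = "DR-IR",
            Ericetorum = "DR", Gymnogynum = "DR", Bryodesma = "IR",
            Lepidoselaginella = "IR")
  trait <- discrete_trait(c("DR", "IR", "NR", "DR-IR"), tips)
  expect_length(trait$states, 4L)
  habit <- discrete_trait(c("hydrophytes", "xerophytes", "mesophytes"),
                          c(Ericetorum = "mesophytes",
                            Bryodesma = "xerophytes"))
  expect_length(habit$states, 3L)
  expect_error(discrete_trait(c("DR", "IR"), c(a = "NR")), "state set")
})
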