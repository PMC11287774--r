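test_that("transition matrices are stochastic, reversible, and stationary", {
  set.seed(5)
  for (i in 1:10) {
    model <- random_model()
    t <- stats::runif(1, 0, 3)
    P <- transition_matrix(model, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0))
    # detailed balance pi_i P_ij = pi_j P_ji
    db <- model$freqs * P - t(model$freqs * P)
    expect_lt(max(abs(db)), 1e-10)
  }
  model <- random_model()
  expect_equal(transition_matrix(model, 0), diag(4), ignore_attr = TRUE,
               tolerance = 1e-12)
  Pinf <- transition_matrix(model, 100)
  expect_lt(max(abs(sweep(Pinf, 2, model$freqs))), 1e-8)
  expect_error(transition_matrix(model, -0.1), ">= 0")
})

test_that("Jukes-Cantor closed form is reproduced", {
  jc <- gtr_model(rep(1, 6), rep(0.25, 4), alpha = 1, k = 1L)
  for (t in c(0.01, 0.3, 1.5)) {
    P <- transition_matrix(jc, t)
    expect_lt(abs(P[1, 1] - (0.25 + 0.75 * exp(-4 * t / 3))), 1e-10)
    expect_lt(abs(P[1, 2] - (0.25 - 0.25 * exp(-4 * t / 3))), 1e-10)
  }
})

test_that("discrete-Gamma category rates have mean 1 and match phangorn", {
  skip_if_not_installed("phangorn")
  for (alpha in c(0.2, 0.7, 1.3, 5)) {
    r <- discrete_gamma_rates(alpha, 4L)
    expect_equal(mean(r), 1, tolerance = 1e-10)
    expect_equal(r, phangorn::discrete.gamma(alpha, 4L), tolerance = 1e-8)
  }
})

test_that("pruning equals brute-force enumeration on small random instances", {
  set.seed(42)
  for (i in 1:20) {
    tr <- random_tree(sample(3:5, 1))
    model <- random_model()
    aln <- simulate_alignment(tr, model, sample(1:3, 1), seed = i)
    if (i %% 4 == 0) {  # inject missing data
      m <- unclass(aln); m[1, 1] <- sample(c("-", "?", "N"), 1)
      aln <- dna_alignment(m)
    }
    expect_lt(max(abs(site_loglik(tr, aln, model) -
                        brute_force_site_loglik(tr, aln, model))), 1e-8)
  }
})

test_that("two identical taxa at zero distance give lnL = log(pi)", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  model <- gtr_model(freqs = c(0.4, 0.3, 0.2, 0.1), k = 1L)
  aln <- dna_alignment(c(a = "A", b = "A"))
  expect_equal(as.vector(site_loglik(tr, aln, model)), log(0.4),
               tolerance = 1e-12)
})

test_that("site order permutation permutes the log-likelihood vector", {
  set.seed(8)
  tr <- random_tree(5)
  model <- random_model()
  aln <- simulate_alignment(tr, model, 30, seed = 3)
  ll <- site_loglik(tr, aln, model)
  perm <- sample(30)
  aln2 <- dna_alignment(unclass(aln)[, perm])
  expect_equal(as.vector(site_loglik(tr, aln2, model)), as.vector(ll)[perm],
               tolerance = 1e-12)
})

test_that("total lnL is invariant to rerooting (pulley principle)", {
  set.seed(12)
  tr <- random_tree(7, 0.05, 0.5)
  model <- random_model()
  aln <- simulate_alignment(tr, model, 60, seed = 4)
  base <- sum(site_loglik(tr, aln, model))
  for (og in tr$tip.label[c(2, 5)]) {
    tr2 <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_lt(abs(sum(site_loglik(tr2, aln, model)) - base), 1e-8)
  }
})

test_that("a fully-missing taxon row leaves site likelihoods unchanged", {
  set.seed(13)
  tr <- random_tree(6, 0.05, 0.5)
  model <- random_model()
  aln <- simulate_alignment(tr, model, 40, seed = 5)
  ll <- site_loglik(tr, aln, model)
  m <- unclass(aln)
  m["t3", ] <- "?"
  # compare against the 5-taxon tree without t3
  tr5 <- ape::drop.tip(tr, "t3")
  ll5 <- site_loglik(tr5, dna_alignment(m[tr5$tip.label, ]), model)
  expect_lt(max(abs(as.vector(site_loglik(tr, dna_alignment(m), model)) -
                      as.vector(ll5))), 1e-10)
})

test_that("total lnL agrees with phangorn's pml on a shared model", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  tr <- random_tree(6, 0.05, 0.5)
  model <- gtr_model(rates = c(1.2, 2.5, 0.8, 1.1, 3.0, 1),
                     freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 0.6, k = 4L)
  aln <- simulate_alignment(tr, model, 200, seed = 11)
  fit <- phangorn::pml(tr, phangorn::phyDat(unclass(aln)), bf = model$freqs,
                       Q = model$rates, shape = model$alpha, k = 4L)
  expect_equal(sum(site_loglik(tr, aln, model)), fit$logLik,
               tolerance = 1e-8)
})

test_that("branch-length optimization recovers simulated lengths", {
  set.seed(31)
  tr <- ape::read.tree(text = "((a:0.15,b:0.4):0.1,(c:0.05,d:0.8):0.2);")
  model <- gtr_model(alpha = 1, k = 1L)
  aln <- simulate_alignment(tr, model, 10000, seed = 17)
  opt <- optimize_branch_lengths(tr, aln, model)
  truth <- tr$edge.length
  est <- opt$edge.length
  # compare per-split lengths (same postorder topology)
  trav_t <- ape::reorder.phylo(tr, "postorder")
  expect_equal(length(est), length(trav_t$edge.length))
  rel <- abs(est - trav_t$edge.length) / trav_t$edge.length
  expect_true(all(rel[trav_t$edge.length >= 0.05] < 0.15))
  expect_gte(attr(opt, "loglik"), sum(site_loglik(tr, aln, model)))
})

test_that("identical sequences optimize to the branch-length lower bound", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  aln <- dna_alignment(c(a = paste(rep("ACGT", 25), collapse = ""),
                         b = paste(rep("ACGT", 25), collapse = "")))
  model <- gtr_model(k = 1L)
  opt <- optimize_branch_lengths(tr, aln, model)
  expect_lte(sum(opt$edge.length), 3e-6)
})

test_that("optimization from different starting points agrees in lnL", {
  set.seed(41)
  tr <- random_tree(5, 0.05, 0.4)
  model <- gtr_model(alpha = 0.8)
  aln <- simulate_alignment(tr, model, 500, seed = 19)
  o1 <- optimize_branch_lengths(tr, aln, model, tol = 1e-6)
  tr2 <- tr; tr2$edge.length <- rep(0.5, nrow(tr$edge))
  o2 <- optimize_branch_lengths(tr2, aln, model, tol = 1e-6)
  expect_lt(abs(attr(o1, "loglik") - attr(o2, "loglik")), 1e-5 * 10)
})

test_that("per-hypothesis matrix prefers the generating topology and is
           invariant to duplicated hypotheses", {
  set.seed(51)
  hyps <- gymnogynoideae_hypotheses("Gymnogynum")
  model <- gtr_model(alpha = 0.8)
  spec <- generator_spec(hyps, c(1, 0, 0, 0), n_loci = 10,
                         locus_length = 300, model = model, seed = 6)
  sim <- simulate_conflicting_loci(spec)
  slm <- per_hypothesis_site_loglik(sim$alignment, sim$partition, hyps,
                                    model = model, tol = 1e-3)
  totals <- colSums(slm)
  expect_equal(names(which.max(totals)), "T1")

  dup <- topology_set("dup", list(T1 = hyps$trees$T1, T2 = hyps$trees$T1))
  slm2 <- per_hypothesis_site_loglik(sim$alignment, sim$partition, dup,
                                     model = model, tol = 1e-4)
  expect_lt(max(abs(slm2[, 1] - slm2[, 2])), 1e-3)
})

test_that("taxon mismatch between tree and alignment is reported", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGT", z = "ACGT"))
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  expect_error(site_loglik(tr, aln, gtr_model()), "mismatch")
})

test_that("model estimation on the reference hypothesis improves the fit", {
  set.seed(61)
  tr <- random_tree(5, 0.05, 0.4)
  truth <- gtr_model(rates = c(1, 4, 1, 1, 4, 1), freqs = c(0.35, 0.2, 0.15, 0.3),
                     alpha = 0.7, k = 4L)
  aln <- simulate_alignment(tr, truth, 2000, seed = 23)
  fit <- fit_gtr_model(tr, aln, model = gtr_model(), rounds = 1L)
  # estimated frequencies are the empirical counts
  expect_equal(fit$model$freqs, empirical_freqs(aln), tolerance = 1e-12)
  # the fitted model beats the naive starting model on its own tree
  naive <- optimize_branch_lengths(tr, aln, gtr_model())
  expect_gt(fit$loglik, attr(naive, "loglik"))
  # transition/transversion structure is recovered qualitatively
  rates <- fit$model$rates / fit$model$rates[6]
  expect_gt(rates[2], rates[1])  # AG >> AC
  expect_gt(rates[5], rates[3])  # CT >> AT
})
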