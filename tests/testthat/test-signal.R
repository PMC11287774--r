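# build a site_likelihood_matrix by hand for bookkeeping tests
fake_slm <- function(m, part, labels = colnames(m)) {
  structure(m, class = c("site_likelihood_matrix", "matrix"),
            partition = part, trees = list(), model = NULL,
            labels = labels, focal_name = "test")
}

test_that("gene and site votes follow the argmax with the tie rule", {
  part <- partition_map(list(g1 = c(0L, 2L), g2 = c(2L, 4L)))
  m <- rbind(c(-50, -50.5, -51), c(-50, -50.5, -51),
             c(-40, -39, -41), c(-40, -39, -41))
  colnames(m) <- c("T1", "T2", "T3")
  sig <- compute_signal(fake_slm(m, part))
  expect_equal(sig$locus$vote, c("T1", "T2"))
  expect_equal(sig$locus$dGLS_T2, c(1, -2))
  expect_equal(sig$locus$dGLS_T3, c(2, 2))
  expect_equal(sig$locus$mean_dSLS_T2, c(0.5, -1))
  # per-locus dGLS equals the sum of its sites' dSLS
  for (nm in c("g1", "g2")) {
    s <- sig$site[sig$site$locus == nm, ]
    expect_equal(sum(s$dSLS_T2),
                 sig$locus$dGLS_T2[sig$locus$locus == nm], tolerance = 1e-9)
  }

  m2 <- cbind(T1 = c(-10, -10), T2 = c(-10, -10))
  part1 <- partition_map(list(g = c(0L, 2L)))
  sig2 <- compute_signal(fake_slm(m2, part1))
  expect_equal(sig2$locus$vote, "ambiguous")
  expect_true(all(sig2$site$vote == "ambiguous"))
})

test_that("vote proportions normalize over non-ambiguous votes and pool by
           summing counts", {
  part <- partition_map(stats::setNames(
    lapply(0:9, function(i) c(i, i + 1L)), paste0("g", 1:10)))
  m <- cbind(T1 = rep(0, 10), T2 = rep(-1, 10))
  m[8:10, "T2"] <- 1  # three loci vote T2
  sig <- compute_signal(fake_slm(m, part))
  pr <- summarize_proportions(sig, level = "gene")
  expect_equal(pr$T1, 0.7)
  expect_equal(pr$T2, 0.3)
  expect_equal(pr$T1 + pr$T2, 1)

  pooled <- summarize_proportions(list(a = sig, b = sig), level = "gene",
                                  pooling = "pooled")
  expect_equal(pooled$T1, pr$T1)
  perds <- summarize_proportions(list(a = sig, b = sig), level = "gene",
                                 pooling = "per-dataset")
  expect_equal(perds$T1, c(0.7, 0.7))
})

test_that("boxplot outliers use type-7 quartiles and the 1.5 IQR fences", {
  part <- partition_map(stats::setNames(
    lapply(0:9, function(i) c(i, i + 1L)), paste0("g", 1:10)))
  # single-site loci with dSLS values 1..9 and 100
  vals <- c(1:9, 100)
  m <- cbind(T1 = rep(0, 10), T2 = -vals)
  sig <- compute_signal(fake_slm(m, part))
  rep <- find_outliers(sig)
  expect_equal(rep$per_comparison$q1, 3.25)
  expect_equal(rep$per_comparison$q3, 7.75)
  expect_equal(rep$per_comparison$lower, -3.5)
  expect_equal(rep$per_comparison$upper, 14.5)
  expect_equal(rep$flagged, "g10")

  m_flat <- cbind(T1 = rep(0, 10), T2 = rep(-2, 10))
  expect_length(find_outliers(compute_signal(fake_slm(m_flat, part)))$flagged, 0L)

  small <- partition_map(list(g1 = c(0L, 1L), g2 = c(1L, 2L), g3 = c(2L, 3L)))
  m3 <- cbind(T1 = rep(0, 3), T2 = rep(-1, 3))
  expect_error(find_outliers(compute_signal(fake_slm(m3, small))), ">= 4")
})

test_that("pruning removes exactly the flagged loci and logs provenance", {
  ds <- tiny_dataset()
  rep_g <- structure(list(per_comparison = NULL, flagged = "g1"),
                     class = "outlier_report")
  rep_e <- structure(list(per_comparison = NULL, flagged = character(0)),
                     class = "outlier_report")
  pr <- prune_dataset(ds$alignment, ds$partition,
                      list(RG = rep_g, RE = rep_e), mode = "RG")
  expect_equal(locus_names(pr$partition), "g2")
  expect_equal(ncol(pr$alignment), 4L)
  expect_equal(pr$removed$locus, "g1")

  # empty report is the identity
  pr0 <- prune_dataset(ds$alignment, ds$partition, list(RE = rep_e),
                       mode = "RE")
  expect_identical(unclass(pr0$alignment), unclass(ds$alignment))

  # REG log is the union of the single-clade logs
  rep_e2 <- structure(list(per_comparison = NULL, flagged = "g2"),
                      class = "outlier_report")
  expect_error(prune_dataset(ds$alignment, ds$partition,
                             list(RG = rep_g, RE = rep_e2), mode = "REG"),
               "every locus")
})

test_that("removing outliers leaves the remaining loci's deltas untouched", {
  set.seed(71)
  hyps <- gymnogynoideae_hypotheses("Gymnogynum")
  model <- gtr_model(alpha = 0.8)
  spec <- generator_spec(hyps, c(0.8, 0.2, 0, 0), n_loci = 8,
                         locus_length = 150, model = model, seed = 15)
  sim <- simulate_conflicting_loci(spec)
  slm <- per_hypothesis_site_loglik(sim$alignment, sim$partition, hyps,
                                    model = model, tol = 1e-3)
  sig <- compute_signal(slm)
  drop <- sig$locus$locus[1:2]
  keep <- setdiff(sig$locus$locus, drop)
  ex <- extract_sites(sim$alignment, sim$partition, loci = keep)
  # per-site likelihoods are a pure subset: recomputing them on the pruned
  # alignment with the same trees must reproduce the same deltas
  slm2 <- structure(unclass(slm)[unlist(lapply(keep, function(nm)
    locus_sites(sim$partition, nm) + 1L)), ],
    class = c("site_likelihood_matrix", "matrix"),
    partition = ex$partition, labels = colnames(slm), focal_name = "x")
  sig2 <- compute_signal(slm2)
  merged <- merge(sig$locus, sig2$locus, by = "locus")
  expect_equal(merged$dGLS_T2.x, merged$dGLS_T2.y, tolerance = 1e-9)
  expect_true(all(sign(merged$dGLS_T3.x) == sign(merged$dGLS_T3.y)))
})

test_that("the dataset ladder enumerates 16 datasets for 4 basics and reuses
           clean derivatives", {
  set.seed(81)
  gym <- gymnogynoideae_hypotheses("Gymnogynum")
  eri <- gymnogynoideae_hypotheses("Ericetorum")
  model <- gtr_model(alpha = 0.8)
  mk <- function(seed) {
    spec <- generator_spec(gym, c(1, 0, 0, 0), n_loci = 5, locus_length = 80,
                           model = model, seed = seed)
    simulate_conflicting_loci(spec)[c("alignment", "partition")]
  }
  datasets <- list(d1 = mk(1), d2 = mk(2), d3 = mk(3), d4 = mk(4))
  lad <- run_dataset_ladder(datasets,
                            list(Gymnogynum = gym, Ericetorum = eri),
                            model = model, tol = 1e-2)
  expect_equal(nrow(lad$manifest), 16L)
  expect_equal(sum(is.na(lad$manifest$parent)), 4L)
  # per clade: basic + own-pruned + union = 12 analyses
  gym_analyses <- grep("\\.Gymnogynum$", names(lad$analyses), value = TRUE)
  eri_analyses <- grep("\\.Ericetorum$", names(lad$analyses), value = TRUE)
  expect_length(gym_analyses, 12L)
  expect_length(eri_analyses, 12L)
  # determinism: rerun matches the manifest
  lad2 <- run_dataset_ladder(datasets,
                             list(Gymnogynum = gym, Ericetorum = eri),
                             model = model, tol = 1e-2)
  expect_identical(lad$manifest, lad2$manifest)
})
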