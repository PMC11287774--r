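# Replicated validation experiments, packaged so tests and reports can run
# the exact same protocol.

#' Planted-outlier detection experiment
#'
#' In each replicate, `n_null` loci are simulated on the reference
#' resolution of the Gymnogynoideae preset (hypotheses T1 vs T2) and two
#' outlier loci are planted: one simulated on the reference and one on the
#' alternative, each with the internode that discriminates the two
#' resolutions inflated `inflate`-fold so its per-site signal is roughly
#' `inflate` times stronger. The boxplot rule is then asked to flag the
#' outliers, and the replicate is scored on whether the planted pair was
#' recovered (recall) and whether nothing else was flagged (exact).
#'
#' @param n_replicates number of replicate seeds (default 20).
#' @param seed root seed.
#' @param n_null null loci per replicate (default 50).
#' @param locus_length locus length in bp (default 300).
#' @param inflate inflation factor for the discriminating internode
#'   (default 10).
#' @return list with `exact_successes`, `recall_successes`,
#'   `false_flag_total`, `n_replicates` and `per_replicate` (data.frame of
#'   flagged sets).
#' @export
outlier_planting_experiment <- function(n_replicates = 20L, seed = 3000L,
                                        n_null = 50L, locus_length = 300L,
                                        inflate = 10) {
  hyps_full <- gymnogynoideae_hypotheses("Gymnogynum")
  hyps <- topology_set("Gymnogynum", hyps_full$trees[c("T1", "T2")])
  model <- gtr_model(alpha = 0.5)
  ntip <- length(hyps$trees$T1$tip.label)
  inflate_edge <- function(tree) {
    # the discriminating internode carries the preset length 0.08
    e <- which(abs(tree$edge.length - 0.08) < 1e-9 &
                 tree$edge[, 2L] > ntip)[1L]
    tree$edge.length[e] <- tree$edge.length[e] * inflate
    tree
  }
  t_up <- inflate_edge(hyps$trees$T1)
  t_dn <- inflate_edge(hyps$trees$T2)
  planted <- c("planted1", "planted2")
  rows <- vector("list", n_replicates)
  exact <- 0L; recall <- 0L; false_total <- 0L
  for (rep in seq_len(n_replicates)) {
    rseed <- child_seed(seed, rep)
    spec <- generator_spec(hyps, c(1, 0), n_loci = n_null,
                           locus_length = locus_length, model = model,
                           seed = rseed)
    sim <- simulate_conflicting_loci(spec)
    o1 <- simulate_alignment(t_up, model, locus_length,
                             seed = child_seed(rseed, 101))
    o2 <- simulate_alignment(t_dn, model, locus_length,
                             seed = child_seed(rseed, 102))
    taxa <- rownames(sim$alignment)
    m <- cbind(unclass(sim$alignment), unclass(o1)[taxa, ],
               unclass(o2)[taxa, ])
    n0 <- ncol(sim$alignment)
    loci <- c(lapply(locus_names(sim$partition),
                     function(nm) sim$partition$loci[[nm]]),
              list(cbind(n0, n0 + locus_length),
                   cbind(n0 + locus_length, n0 + 2L * locus_length)))
    names(loci) <- c(locus_names(sim$partition), planted)
    slm <- per_hypothesis_site_loglik(dna_alignment(m), partition_map(loci),
                                      hyps, model = model, tol = 1e-3)
    fl <- find_outliers(compute_signal(slm))$flagged
    got_both <- all(planted %in% fl)
    extra <- setdiff(fl, planted)
    recall <- recall + got_both
    exact <- exact + (got_both && !length(extra))
    false_total <- false_total + length(extra)
    rows[[rep]] <- data.frame(replicate = rep,
                              flagged = paste(fl, collapse = ","),
                              recall = got_both,
                              exact = got_both && !length(extra),
                              stringsAsFactors = FALSE)
  }
  list(exact_successes = exact, recall_successes = recall,
       false_flag_total = false_total, n_replicates = n_replicates,
       per_replicate = do.call(rbind, rows))
}

#' Reference plastome fixtures for structure typing
#'
#' Five synthetic circular genomes with known architecture: no repeat (NR),
#' a large inverted pair (IR), a large direct pair (DR), one of each
#' (DR-IR), and an IR genome rotated so one repeat copy straddles the
#' origin.
#'
#' @param seed root seed.
#' @return named list of `synth_plastome()` results (`$sequence`,
#'   `$planted`).
#' @export
acceptance_plastome_fixtures <- function(seed = 900L) {
  rot <- function(g, k) {
    g$sequence <- paste0(substring(g$sequence, k + 1L),
                         substring(g$sequence, 1L, k))
    g
  }
  list(
    nr = synth_plastome(6000, seed = child_seed(seed, 1)),
    ir = synth_plastome(12000,
                        list(list(length = 2000, orientation = "inverted")),
                        seed = child_seed(seed, 2)),
    dr = synth_plastome(12000,
                        list(list(length = 2000, orientation = "direct")),
                        seed = child_seed(seed, 3)),
    dr_ir = synth_plastome(18000,
                           list(list(length = 1500, orientation = "direct"),
                                list(length = 1200, orientation = "inverted")),
                           seed = child_seed(seed, 4)),
    ir_origin = rot(synth_plastome(9000,
                                   list(list(length = 800,
                                             orientation = "inverted")),
                                   seed = child_seed(seed, 5)), 400))
}
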