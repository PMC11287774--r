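# End-to-end pipeline drivers. Each driver reads its inputs, delegates to
# the analysis modules, writes TSV/FASTA/newick artifacts plus a JSON
# manifest (inputs, output hashes, seeds, settings) into an output
# directory, and never mutates its inputs.

#' Read a flat key-value run configuration file
#'
#' Lines of `key = value` with optional `[section]` headers; section names
#' prefix keys as `section.key`. Blank lines and `#` comments ignored.
#'
#' @param path config file path.
#' @return named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+?)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln)
    key <- if (nzchar(section)) paste(section, kv[2L], sep = ".") else kv[2L]
    out[[key]] <- kv[3L]
  }
  out
}

write_manifest <- function(out_dir, stage, settings, files, warnings = character(0)) {
  files <- files[file.exists(file.path(out_dir, files))]
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("phylodissect")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    settings = settings,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)),
    warnings = warnings)
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic study bundle
#'
#' Writes a conflicting-locus alignment (FASTA), its partition file, the
#' locus truth table (TSV), the hypothesis trees (newick) and a JSON echo
#' of the generator settings.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [generator_spec()]; default is a Gymnogynoideae-like
#'   preset: 74 loci of 200-2000 bp on the four alternative resolutions of
#'   *Gymnogynum* with an 85/5/5/5 mixture.
#' @param seed root seed (overrides `spec$seed` when given).
#' @return list of written paths, invisibly.
#' @export
simulate_study <- function(out_dir, spec = NULL, seed = NULL) {
  if (is.null(spec)) {
    hyps <- gymnogynoideae_hypotheses("Gymnogynum")
    spec <- generator_spec(hyps, mixture = c(0.85, 0.05, 0.05, 0.05),
                           n_loci = 74L, locus_length = c(200L, 2000L),
                           model = gtr_model(alpha = 0.5),
                           seed = if (is.null(seed)) 1L else seed)
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_conflicting_loci(spec)
  paths <- list(
    alignment = file.path(out_dir, "alignment.fasta"),
    partitions = file.path(out_dir, "partitions.txt"),
    truth = file.path(out_dir, "truth.tsv"),
    hypotheses = file.path(out_dir, "hypotheses.nwk"))
  write_fasta_alignment(sim$alignment, paths$alignment)
  write_partitions(sim$partition, paths$partitions)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_newick(spec$hypotheses$trees, paths$hypotheses)
  settings <- list(seed = spec$seed, n_loci = spec$n_loci,
                   locus_length = spec$locus_length,
                   mixture = spec$mixture,
                   hypotheses = names(spec$hypotheses$trees),
                   focal_name = spec$hypotheses$focal_name,
                   branch_scale = spec$branch_scale,
                   model = list(rates = spec$model$rates,
                                freqs = spec$model$freqs,
                                alpha = spec$model$alpha, k = spec$model$k))
  write_manifest(out_dir, "simulate", settings, basename(unlist(paths)))
  invisible(paths)
}

#' Run the signal-dissection pipeline on one dataset
#'
#' Computes the site-likelihood matrix for the hypothesis set, the signal
#' table, vote proportions, the outlier report, and the pruned dataset,
#' writing every artifact plus a manifest to `out_dir`.
#'
#' @param aln a [dna_alignment()] or FASTA path.
#' @param part a [partition_map()] or partition file path.
#' @param hyps a [topology_set()], or a newick path whose trees get labels
#'   `T1..Tk` with `T1` the reference.
#' @param out_dir output directory.
#' @param model a [gtr_model()] or `NULL` (estimate on the reference).
#' @param focal_name focal clade name used when reading trees from file.
#' @param tie_tol vote tie tolerance (lnL units).
#' @param tol branch-length optimization tolerance.
#' @return list with `slm`, `signal`, `outliers`, `proportions`, `pruned`,
#'   invisibly.
#' @export
run_signal_pipeline <- function(aln, part, hyps, out_dir, model = NULL,
                                focal_name = "focal", tie_tol = 1e-6,
                                tol = 1e-4) {
  if (!inherits(aln, "dna_alignment")) aln <- read_fasta_alignment(aln)
  if (!inherits(part, "partition_map")) part <- read_partitions(part)
  if (!inherits(hyps, "topology_set"))
    hyps <- topology_set(focal_name, read_newick(hyps))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  slm <- withCallingHandlers(
    per_hypothesis_site_loglik(aln, part, hyps, model = model, tol = tol),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sig <- compute_signal(slm, tie_tol = tie_tol)
  outl <- find_outliers(sig)
  prop_gene <- summarize_proportions(sig, level = "gene")
  prop_site <- summarize_proportions(sig, level = "site")
  pruned <- prune_dataset(aln, part, list(R = outl), mode = "REG")

  write_site_likelihoods(slm, file.path(out_dir, "site_likelihoods.tsv"))
  utils::write.table(sig$locus, file.path(out_dir, "signal_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(outl$per_comparison,
                     file.path(out_dir, "outliers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rbind(cbind(level = "gene", prop_gene),
                           cbind(level = "site", prop_site)),
                     file.path(out_dir, "proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta_alignment(pruned$alignment,
                        file.path(out_dir, "pruned_alignment.fasta"))
  write_partitions(pruned$partition,
                   file.path(out_dir, "pruned_partitions.txt"))
  settings <- list(focal_name = hyps$focal_name,
                   hypotheses = names(hyps$trees),
                   reference = hyps$reference_label,
                   tie_tol = tie_tol, tol = tol,
                   model_estimated = is.null(model),
                   flagged_loci = outl$flagged)
  write_manifest(out_dir, "signal", settings,
                 c("site_likelihoods.tsv", "signal_loci.tsv", "outliers.tsv",
                   "proportions.tsv", "pruned_alignment.fasta",
                   "pruned_partitions.txt"), warnings_log)
  invisible(list(slm = slm, signal = sig, outliers = outl,
                 proportions = list(gene = prop_gene, site = prop_site),
                 pruned = pruned))
}

#' Run the gene-tree concordance pipeline
#'
#' @param ref reference tree (`phylo` or newick path).
#' @param gene_trees list of `phylo` or newick path (may hold many trees).
#' @param out_dir output directory.
#' @param support_threshold collapse gene-tree edges below this support.
#' @param anchor anchor taxon for canonical bipartitions.
#' @return the `node_concordance` table, invisibly.
#' @export
run_concordance_pipeline <- function(ref, gene_trees, out_dir,
                                     support_threshold = 0,
                                     anchor = NULL) {
  if (is.character(ref)) ref <- read_newick(ref)[[1L]]
  if (is.character(gene_trees)) gene_trees <- read_newick(gene_trees)
  if (is.null(anchor)) anchor <- min(ref$tip.label)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nc <- concordance_analysis(ref, gene_trees,
                             support_threshold = support_threshold,
                             anchor = anchor)
  write_concordance(nc, file.path(out_dir, "concordance.tsv"))
  write_manifest(out_dir, "concord",
                 list(n_gene_trees = length(gene_trees),
                      support_threshold = support_threshold,
                      anchor = anchor),
                 "concordance.tsv")
  invisible(nc)
}

#' Run the ancestral-state reconstruction pipeline
#'
#' Fits the ER rate, computes marginal ancestral states and stochastic-map
#' node frequencies, and writes both node tables plus a manifest.
#'
#' @param tree `phylo` or newick path.
#' @param trait a [discrete_trait()] or trait-table TSV path.
#' @param out_dir output directory.
#' @param n_sims stochastic maps to sample (default 1000).
#' @param seed integer seed for the maps.
#' @return list with `fit`, `marginal`, `maps`, invisibly.
#' @export
run_asr_pipeline <- function(tree, trait, out_dir, n_sims = 1000L,
                             seed = 1L) {
  if (is.character(tree)) tree <- read_newick(tree)[[1L]]
  if (is.character(trait)) trait <- read_trait_table(trait)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- fit_er_rate(tree, trait)
  marg <- marginal_asr(tree, trait, q = fit$q)
  maps <- stochastic_maps(tree, trait, q = fit$q, n_sims = n_sims,
                          seed = seed)
  write_asr(marg, file.path(out_dir, "asr_marginal.tsv"))
  write_asr(maps, file.path(out_dir, "asr_stochastic_map.tsv"))
  write_manifest(out_dir, "asr",
                 list(q = fit$q, loglik = fit$loglik, k = fit$k,
                      n_sims = n_sims, seed = seed,
                      expected_transitions = maps$expected_transitions),
                 c("asr_marginal.tsv", "asr_stochastic_map.tsv"))
  invisible(list(fit = fit, marginal = marg, maps = maps))
}

#' Run the plastome typing pipeline
#'
#' @param genomes named character vector of sequences or a FASTA path.
#' @param out_dir output directory.
#' @param min_len minimum qualifying repeat length (bp).
#' @param max_mismatch_frac repeat mismatch tolerance.
#' @return the feature table, invisibly.
#' @export
run_plastome_pipeline <- function(genomes, out_dir, min_len = 500L,
                                  max_mismatch_frac = 0) {
  if (is.character(genomes) && length(genomes) == 1L &&
      file.exists(genomes))
    genomes <- read_genomes(genomes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- classify_plastomes(genomes, min_len = min_len,
                            max_mismatch_frac = max_mismatch_frac)
  utils::write.table(tab, file.path(out_dir, "plastome_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "plastome",
                 list(min_len = min_len,
                      max_mismatch_frac = max_mismatch_frac,
                      n_genomes = nrow(tab)),
                 "plastome_features.tsv")
  invisible(tab)
}
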