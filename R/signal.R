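# Signal dissection: per-locus and per-site log-likelihood differences
# between the reference resolution and each alternative, votes, vote
# proportions, boxplot outlier loci, and the pruned dataset ladder.

#' Compute the signal table from a site-likelihood matrix
#'
#' Per locus: the log-likelihood under each hypothesis (summed over its
#' sites), the delta gene-wise support `dGLS_j = lnL(ref) - lnL(Tj)` for
#' each alternative `j`, the length-corrected mean delta site-wise score
#' `mean dSLS_j = dGLS_j / locus length`, and the gene vote (argmax
#' hypothesis, or `"ambiguous"` when the top two are within `tie_tol` lnL
#' units). Per site: `dSLS_j` and the site vote under the same rule.
#' Positive deltas support the reference.
#'
#' @param slm a `site_likelihood_matrix` from
#'   [per_hypothesis_site_loglik()].
#' @param tie_tol lnL tie tolerance for votes (default 1e-6).
#' @return object of class `signal_table`: list with `locus` (data.frame),
#'   `site` (data.frame), `labels`, `reference`.
#' @export
compute_signal <- function(slm, tie_tol = 1e-6) {
  part <- attr(slm, "partition")
  labels <- colnames(slm)
  if (length(labels) < 2L) stop("need >= 2 hypothesis columns")
  ref <- labels[1L]
  alts <- labels[-1L]
  lens <- locus_lengths(part)
  if (any(lens == 0L)) stop("locus of length 0")
  m <- unclass(slm)

  vote_of <- function(x) {
    o <- order(x, decreasing = TRUE)
    if (length(x) > 1L && x[o[1L]] - x[o[2L]] <= tie_tol) "ambiguous"
    else labels[o[1L]]
  }

  locus_ll <- t(vapply(locus_names(part), function(nm)
    colSums(m[locus_sites(part, nm) + 1L, , drop = FALSE]),
    numeric(length(labels))))
  colnames(locus_ll) <- labels
  dgls <- locus_ll[, ref] - locus_ll[, alts, drop = FALSE]
  colnames(dgls) <- paste0("dGLS_", alts)
  mdsls <- dgls / lens
  colnames(mdsls) <- paste0("mean_dSLS_", alts)
  locus <- data.frame(locus = locus_names(part), length = unname(lens),
                      locus_ll, dgls, mdsls,
                      vote = apply(locus_ll, 1L, vote_of),
                      row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)

  site_d <- m[, ref] - m[, alts, drop = FALSE]
  colnames(site_d) <- paste0("dSLS_", alts)
  site <- data.frame(site = seq_len(nrow(m)),
                     locus = site_locus_index(part, nrow(m)),
                     site_d,
                     vote = apply(m, 1L, vote_of),
                     row.names = NULL, check.names = FALSE,
                     stringsAsFactors = FALSE)
  structure(list(locus = locus, site = site, labels = labels,
                 reference = ref,
                 focal_name = attr(slm, "focal_name")),
            class = "signal_table")
}

#' @export
print.signal_table <- function(x, ...) {
  cat(sprintf("signal_table (%s): %d loci, %d sites, hypotheses %s\n",
              if (is.null(x$focal_name)) "?" else x$focal_name,
              nrow(x$locus), nrow(x$site),
              paste(x$labels, collapse = ", ")))
  print(table(gene_vote = x$locus$vote))
  invisible(x)
}

#' Summarize vote proportions over one or more signal tables
#'
#' Fractions of gene (locus) or site votes per hypothesis. Ambiguous votes
#' are excluded from the denominator but counted. `pooling = "pooled"` sums
#' vote counts across tables before normalizing; `"per-dataset"` returns
#' one row of fractions per table.
#'
#' @param tables a `signal_table` or list of them.
#' @param level `"gene"` or `"site"`.
#' @param pooling `"pooled"` or `"per-dataset"`.
#' @return data.frame with columns `dataset` (or `"pooled"`), one fraction
#'   column per hypothesis, `n_votes`, `n_ambiguous`.
#' @export
summarize_proportions <- function(tables, level = c("gene", "site"),
                                  pooling = c("pooled", "per-dataset")) {
  level <- match.arg(level)
  pooling <- match.arg(pooling)
  if (inherits(tables, "signal_table")) tables <- list(tables)
  labels <- tables[[1L]]$labels
  for (t in tables)
    if (!identical(t$labels, labels))
      stop("signal tables have mismatched hypothesis labels")
  if (is.null(names(tables)))
    names(tables) <- paste0("dataset", seq_along(tables))
  count_votes <- function(t) {
    v <- if (level == "gene") t$locus$vote else t$site$vote
    c(vapply(labels, function(l) sum(v == l), numeric(1L)),
      ambiguous = sum(v == "ambiguous"))
  }
  counts <- t(vapply(tables, count_votes, numeric(length(labels) + 1L)))
  frac_row <- function(cnt) {
    tot <- sum(cnt[labels])
    f <- if (tot > 0) cnt[labels] / tot else rep(NA_real_, length(labels))
    c(f, n_votes = tot, n_ambiguous = unname(cnt["ambiguous"]))
  }
  if (pooling == "pooled") {
    out <- data.frame(dataset = "pooled",
                      t(frac_row(colSums(counts))), check.names = FALSE)
  } else {
    out <- data.frame(dataset = names(tables),
                      t(apply(counts, 1L, frac_row)), check.names = FALSE,
                      row.names = NULL)
  }
  out
}

#' Identify outlier loci by the boxplot rule
#'
#' For each reference-vs-alternative comparison, computes the quartiles of
#' the per-locus mean dSLS values (linear interpolation, quantile type 7)
#' and flags loci outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. A locus flagged
#' in any comparison enters the outlier set.
#'
#' @param table a `signal_table` with at least 4 loci.
#' @return object of class `outlier_report`: list with `per_comparison`
#'   (data.frame of Q1, Q3, IQR, bounds, flagged loci) and `flagged`
#'   (character vector, union over comparisons).
#' @export
find_outliers <- function(table) {
  loc <- table$locus
  if (nrow(loc) < 4L) stop("need >= 4 loci for boxplot outlier detection")
  cols <- grep("^mean_dSLS_", names(loc), value = TRUE)
  per <- lapply(cols, function(cl) {
    x <- loc[[cl]]
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    lo <- q[1L] - 1.5 * iqr
    hi <- q[2L] + 1.5 * iqr
    flagged <- loc$locus[x < lo | x > hi]
    list(comparison = sub("^mean_dSLS_", "", cl), q1 = q[1L], q3 = q[2L],
         iqr = iqr, lower = lo, upper = hi, flagged = flagged)
  })
  per_df <- data.frame(
    comparison = vapply(per, `[[`, character(1L), "comparison"),
    q1 = vapply(per, `[[`, numeric(1L), "q1"),
    q3 = vapply(per, `[[`, numeric(1L), "q3"),
    iqr = vapply(per, `[[`, numeric(1L), "iqr"),
    lower = vapply(per, `[[`, numeric(1L), "lower"),
    upper = vapply(per, `[[`, numeric(1L), "upper"),
    flagged = vapply(per, function(p) paste(p$flagged, collapse = ","),
                     character(1L)),
    stringsAsFactors = FALSE)
  structure(list(per_comparison = per_df,
                 flagged = sort(unique(unlist(lapply(per, `[[`, "flagged")))),
                 focal_name = table$focal_name),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report (%s): %d flagged loci%s\n",
              if (is.null(x$focal_name)) "?" else x$focal_name,
              length(x$flagged),
              if (length(x$flagged))
                paste0(": ", paste(x$flagged, collapse = ", ")) else ""))
  invisible(x)
}

#' Prune outlier loci from a dataset
#'
#' Removes loci flagged for the focal clade(s) selected by `mode`: `"RG"`
#' removes the first report's outliers, `"RE"` the second's, `"REG"` their
#' union (mirroring the removed-Gymnogynum / removed-Ericetorum /
#' removed-both dataset ladder).
#'
#' @param aln a [dna_alignment()].
#' @param part a [partition_map()].
#' @param reports a single `outlier_report` or a named list of them; for
#'   `"RG"`/`"RE"` with a list, names `"RG"`/`"RE"` (or the focal clade
#'   order: first = G-analysis, second = E-analysis) select the report.
#' @param mode `"RG"`, `"RE"` or `"REG"`.
#' @return list with `alignment`, `partition`, `removed` (data.frame:
#'   locus, flagged_by).
#' @export
prune_dataset <- function(aln, part, reports, mode = c("RG", "RE", "REG")) {
  mode <- match.arg(mode)
  if (inherits(reports, "outlier_report")) reports <- list(reports)
  if (is.null(names(reports)) || !all(nzchar(names(reports))))
    names(reports) <- c("RG", "RE")[seq_along(reports)]
  pick <- switch(mode,
                 RG = reports["RG"], RE = reports["RE"], REG = reports)
  pick <- pick[!vapply(pick, is.null, logical(1L))]
  if (!length(pick)) stop("no report available for mode ", mode)
  removed <- data.frame(locus = character(0), flagged_by = character(0),
                        stringsAsFactors = FALSE)
  for (nm in names(pick)) {
    fl <- pick[[nm]]$flagged
    missing_loci <- setdiff(fl, locus_names(part))
    if (length(missing_loci))
      stop("report references unknown loci: ",
           paste(missing_loci, collapse = ", "))
    if (length(fl))
      removed <- rbind(removed, data.frame(locus = fl, flagged_by = nm,
                                           stringsAsFactors = FALSE))
  }
  drop <- unique(removed$locus)
  keep <- setdiff(locus_names(part), drop)
  if (!length(keep)) stop("pruning would remove every locus")
  if (!length(drop))
    return(list(alignment = aln, partition = part, removed = removed))
  ex <- extract_sites(aln, part, loci = keep)
  list(alignment = ex$alignment, partition = ex$partition, removed = removed)
}

#' Run the full basic-to-pruned dataset ladder
#'
#' For each basic dataset and each focal clade: compute the
#' site-likelihood matrix and signal table, find outlier loci, build the
#' pruned derivatives (own-clade pruned and both-clades pruned), and
#' recompute the signal on each derivative. Each clade is analyzed on its
#' basic, own-pruned and both-pruned datasets (so 4 basic datasets yield 12
#' analyses per clade over 16 distinct datasets).
#'
#' @param datasets named list; each element `list(alignment =, partition =)`.
#' @param hypotheses named list of [topology_set()], one per focal clade
#'   (e.g. `list(Gymnogynum = ..., Ericetorum = ...)`); suffix letters for
#'   pruned datasets are taken from the first letter of each clade name
#'   (`R<G>`, `R<E>`, `R<EG...>` for the union).
#' @param model a [gtr_model()] shared by all analyses, or `NULL` to
#'   estimate per dataset on the reference hypothesis.
#' @param tie_tol vote tie tolerance.
#' @param tol branch-length optimization tolerance.
#' @return object of class `ladder_result`: list with `analyses` (named
#'   `dataset.clade` -> list(slm, signal, outliers)), `datasets` (all basic
#'   and derived datasets), `manifest` (data.frame provenance: dataset,
#'   parent, clade_pruned, loci, sites, removed).
#' @export
run_dataset_ladder <- function(datasets, hypotheses, model = NULL,
                               tie_tol = 1e-6, tol = 1e-4) {
  if (!length(datasets)) stop("need >= 1 basic dataset")
  clades <- names(hypotheses)
  letters1 <- toupper(substr(clades, 1L, 1L))
  if (anyDuplicated(letters1))
    stop("focal clade names must differ in first letter")
  analyses <- list()
  all_datasets <- datasets
  manifest <- data.frame(dataset = names(datasets),
                         parent = NA_character_,
                         pruned_for = NA_character_,
                         n_loci = vapply(datasets, function(d)
                           length(locus_names(d$partition)), integer(1L)),
                         n_sites = vapply(datasets, function(d)
                           ncol(d$alignment), integer(1L)),
                         removed = "", stringsAsFactors = FALSE)

  analyse <- function(ds, ds_name, clade, with_outliers = TRUE) {
    slm <- per_hypothesis_site_loglik(ds$alignment, ds$partition,
                                      hypotheses[[clade]], model = model,
                                      tol = tol)
    sig <- compute_signal(slm, tie_tol = tie_tol)
    list(slm = slm, signal = sig,
         outliers = if (with_outliers) find_outliers(sig) else NULL)
  }

  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    base_an <- lapply(clades, function(cl) analyse(ds, ds_name, cl))
    names(base_an) <- clades
    for (cl in clades)
      analyses[[paste(ds_name, cl, sep = ".")]] <- base_an[[cl]]
    reports <- lapply(base_an, `[[`, "outliers")
    names(reports) <- paste0("R", letters1)
    # derived datasets: one per clade (own outliers) plus the union
    union_suffix <- paste0("R", paste(sort(letters1), collapse = ""))
    derived_specs <- c(stats::setNames(as.list(names(reports)),
                                       names(reports)),
                       stats::setNames(list(names(reports)), union_suffix))
    for (sfx in names(derived_specs)) {
      use <- reports[derived_specs[[sfx]]]
      flagged <- unique(unlist(lapply(use, `[[`, "flagged")))
      der_name <- paste(ds_name, sfx, sep = "_")
      if (!length(flagged)) {
        all_datasets[[der_name]] <- ds
        manifest <- rbind(manifest, data.frame(
          dataset = der_name, parent = ds_name,
          pruned_for = paste(derived_specs[[sfx]], collapse = "+"),
          n_loci = length(locus_names(ds$partition)),
          n_sites = ncol(ds$alignment), removed = "",
          stringsAsFactors = FALSE))
        # identical to parent: reuse the basic analyses
        for (cl in clades_for_suffix(sfx, clades, letters1))
          analyses[[paste(der_name, cl, sep = ".")]] <- base_an[[cl]]
        next
      }
      # `use` is already the subset of reports to apply; "REG" mode applies
      # every report in the list
      pruned <- prune_dataset(ds$alignment, ds$partition, use, mode = "REG")
      all_datasets[[der_name]] <- pruned[c("alignment", "partition")]
      manifest <- rbind(manifest, data.frame(
        dataset = der_name, parent = ds_name,
        pruned_for = paste(derived_specs[[sfx]], collapse = "+"),
        n_loci = length(locus_names(pruned$partition)),
        n_sites = ncol(pruned$alignment),
        removed = paste(unique(pruned$removed$locus), collapse = ","),
        stringsAsFactors = FALSE))
      for (cl in clades_for_suffix(sfx, clades, letters1))
        analyses[[paste(der_name, cl, sep = ".")]] <-
          analyse(all_datasets[[der_name]], der_name, cl,
                  with_outliers = FALSE)
    }
  }
  structure(list(analyses = analyses, datasets = all_datasets,
                 manifest = manifest),
            class = "ladder_result")
}

# which clades are re-analyzed on a pruned dataset: the union dataset for
# all clades, a single-clade pruned dataset for its own clade only
clades_for_suffix <- function(sfx, clades, letters1) {
  if (sfx %in% paste0("R", letters1)) clades[paste0("R", letters1) == sfx]
  else clades
}

#' @export
print.ladder_result <- function(x, ...) {
  cat(sprintf("ladder_result: %d datasets, %d signal analyses\n",
              length(x$datasets), length(x$analyses)))
  print(x$manifest)
  invisible(x)
}
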