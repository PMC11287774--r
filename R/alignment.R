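#' Construct a multiple sequence alignment object
#'
#' A `dna_alignment` is a taxa x sites character matrix of upper-case DNA
#' symbols (`A`, `C`, `G`, `T`, IUPAC ambiguity codes, `-`, `?`, `N`) with
#' unique taxon labels as row names. It is the shared container for all
#' alignment-based stages of the pipeline.
#'
#' @param matrix character matrix (taxa x sites) or a named character vector
#'   of equal-length sequence strings.
#' @return an object of class `dna_alignment`.
#' @export
dna_alignment <- function(matrix) {
  if (is.character(matrix) && is.null(dim(matrix))) {
    taxa <- names(matrix)
    if (is.null(taxa)) stop("sequences must be named by taxon")
    lens <- nchar(matrix)
    if (length(unique(lens)) > 1L) {
      bad <- taxa[lens != lens[1L]][1L]
      stop("alignment rows have unequal length; offending taxon: ", bad)
    }
    matrix <- do.call(rbind, strsplit(unname(matrix), "", fixed = TRUE))
    rownames(matrix) <- taxa
  }
  if (!is.matrix(matrix) || !is.character(matrix))
    stop("matrix must be a character matrix")
  taxa <- rownames(matrix)
  if (is.null(taxa)) stop("alignment must have taxon row names")
  taxa <- trimws(taxa)
  if (anyDuplicated(taxa))
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1L])
  if (ncol(matrix) < 1L) stop("alignment must have at least one site")
  matrix[] <- toupper(matrix)
  rownames(matrix) <- taxa
  structure(matrix, class = c("dna_alignment", "matrix"))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d taxa x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' All records must have the same length; symbols are upper-cased on input.
#' Row order follows file order.
#'
#' @param path path to a FASTA file of aligned sequences.
#' @return a [dna_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  labs <- trimws(sub("\\s.*$", "", names(seqs)))
  if (anyDuplicated(labs))
    stop("duplicate taxon label in ", path, ": ", labs[duplicated(labs)][1L])
  v <- as.character(seqs)
  lens <- nchar(v)
  if (length(unique(lens)) > 1L) {
    bad <- labs[lens != lens[1L]][1L]
    stop("unequal sequence lengths in ", path, "; offending taxon: ", bad)
  }
  names(v) <- labs
  dna_alignment(v)
}

#' Write an alignment to FASTA
#'
#' @param aln a [dna_alignment()].
#' @param path output path.
#' @param width line wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, width = 80L) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' Relaxed PHYLIP: header "ntaxa nsites", then one `label  sequence` line per
#' taxon. Write-only convenience for interoperability.
#'
#' @inheritParams write_fasta_alignment
#' @return `path`, invisibly.
#' @export
write_phylip_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(aln), ncol(aln)), con)
  writeLines(sprintf("%s  %s", names(seqs), seqs), con)
  invisible(path)
}

#' Construct a partition map
#'
#' A `partition_map` assigns named loci to site ranges of a concatenated
#' alignment. Ranges are 0-based half-open internally; a locus may own
#' several disjoint ranges (e.g. codon positions 1+2).
#'
#' @param loci named list; each element is an integer matrix with columns
#'   `start`, `end` (0-based half-open rows), or a length-2 vector.
#' @return an object of class `partition_map`.
#' @export
partition_map <- function(loci) {
  if (length(loci) == 0L) stop("partition map needs at least one locus")
  if (is.null(names(loci)) || any(names(loci) == ""))
    stop("all loci must be named")
  if (anyDuplicated(names(loci)))
    stop("duplicate locus name: ", names(loci)[duplicated(names(loci))][1L])
  loci <- lapply(loci, function(r) {
    if (is.null(dim(r))) r <- matrix(as.integer(r), ncol = 2L)
    else r <- matrix(as.integer(r), ncol = 2L, dimnames = NULL)
    colnames(r) <- c("start", "end")
    if (any(r[, "end"] <= r[, "start"]))
      stop("empty or reversed range in partition map")
    r
  })
  # overlap check across all ranges of all loci
  all_r <- do.call(rbind, loci)
  ord <- order(all_r[, "start"])
  all_r <- all_r[ord, , drop = FALSE]
  if (nrow(all_r) > 1L) {
    ov <- which(all_r[-1L, "start"] < all_r[-nrow(all_r), "end"])
    if (length(ov)) {
      owner <- rep(names(loci), vapply(loci, nrow, 1L))[ord]
      stop(sprintf("overlapping ranges between loci '%s' and '%s'",
                   owner[ov[1L]], owner[ov[1L] + 1L]))
    }
  }
  structure(list(loci = loci), class = "partition_map")
}

#' @export
print.partition_map <- function(x, ...) {
  cat(sprintf("partition_map: %d loci, %d sites\n",
              length(x$loci), sum(locus_lengths(x))))
  invisible(x)
}

#' Locus names of a partition map
#' @param part a [partition_map()].
#' @return character vector.
#' @export
locus_names <- function(part) names(part$loci)

#' Locus lengths (total sites per locus)
#' @param part a [partition_map()].
#' @return named integer vector.
#' @export
locus_lengths <- function(part) {
  vapply(part$loci, function(r) sum(r[, "end"] - r[, "start"]), integer(1L))
}

#' 0-based site indices of one locus, in range order
#' @param part a [partition_map()].
#' @param name locus name.
#' @return integer vector of 0-based site indices.
#' @export
locus_sites <- function(part, name) {
  r <- part$loci[[name]]
  if (is.null(r)) stop("unknown locus: ", name)
  unlist(lapply(seq_len(nrow(r)), function(i) seq.int(r[i, 1L], r[i, 2L] - 1L)),
         use.names = FALSE)
}

#' Per-site locus assignment
#' @param part a [partition_map()].
#' @param n_sites total alignment length.
#' @return character vector of length `n_sites` (NA for uncovered sites).
#' @export
site_locus_index <- function(part, n_sites) {
  out <- rep(NA_character_, n_sites)
  for (nm in locus_names(part)) out[locus_sites(part, nm) + 1L] <- nm
  out
}

#' Read a RAxML-style partition file
#'
#' Parses lines of the form `DNA, name = a-b[, c-d ...]` with an optional
#' codon-stride suffix `\3` on each range. On-disk coordinates are 1-based
#' inclusive and converted to the internal 0-based half-open convention at
#' this single boundary. A stride suffix expands the range to every third
#' site starting at `a`.
#'
#' @param path partition file path.
#' @return a [partition_map()]. Strided ranges are stored as the exploded
#'   set of unit ranges merged into maximal runs.
#' @export
read_partitions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no partitions in ", path)
  loci <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^[A-Za-z0-9]+\\s*,\\s*([^=]+?)\\s*=\\s*(.+)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse partition line: ", ln)
    nm <- m[2L]
    ranges <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
    sites <- integer(0L)
    for (rg in ranges) {
      rm <- regmatches(rg, regexec("^(\\d+)\\s*-\\s*(\\d+)\\s*(\\\\3)?$", rg))[[1L]]
      if (length(rm) < 3L) stop("cannot parse range '", rg, "' in line: ", ln)
      a <- as.integer(rm[2L]); b <- as.integer(rm[3L])
      if (b < a) stop("range end before start (", a, "-", b, ") in line: ", ln)
      idx <- if (length(rm) >= 4L && rm[4L] == "\\3") seq.int(a, b, by = 3L) else a:b
      sites <- c(sites, idx - 1L)  # to 0-based
    }
    loci[[nm]] <- sites_to_ranges(sort(sites))
  }
  partition_map(loci)
}

#' Write a partition map in the RAxML dialect
#'
#' @param part a [partition_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(part, path) {
  lines <- vapply(locus_names(part), function(nm) {
    r <- part$loci[[nm]]
    rng <- paste(sprintf("%d-%d", r[, "start"] + 1L, r[, "end"]), collapse = ", ")
    sprintf("DNA, %s = %s", nm, rng)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# collapse a sorted 0-based site index vector into half-open ranges
sites_to_ranges <- function(sites) {
  if (!length(sites)) stop("empty site set")
  breaks <- c(0L, which(diff(sites) != 1L), length(sites))
  out <- cbind(start = sites[breaks[-length(breaks)] + 1L],
               end   = sites[breaks[-1L]] + 1L)
  out
}

#' Extract loci and/or codon positions from a partitioned alignment
#'
#' Builds a new concatenated alignment from a subset of loci, optionally
#' restricted to codon positions 1 and 2 within each locus, preserving locus
#' order. Reading frame starts at each locus's first site; for loci whose
#' length is not divisible by three, trailing sites take positions by
#' `index mod 3`.
#'
#' @param aln a [dna_alignment()].
#' @param part a [partition_map()] over `aln`.
#' @param loci character vector of locus names to keep (default: all).
#' @param codon `NULL` for all positions, or an integer subset of `1:3`
#'   (e.g. `c(1, 2)` for the codon12 dataset).
#' @return list with elements `alignment` (new [dna_alignment()]) and
#'   `partition` (new [partition_map()] in the reduced coordinates).
#' @export
extract_sites <- function(aln, part, loci = locus_names(part), codon = NULL) {
  if (!length(loci)) stop("empty locus selection")
  unknown <- setdiff(loci, locus_names(part))
  if (length(unknown)) stop("unknown loci: ", paste(unknown, collapse = ", "))
  mx <- max(vapply(part$loci, function(r) max(r[, "end"]), integer(1L)))
  if (mx > ncol(aln)) stop("partition map exceeds alignment bounds")
  if (!is.null(codon)) {
    codon <- as.integer(codon)
    if (!length(codon) || !all(codon %in% 1:3)) stop("codon must be a subset of 1:3")
  }
  cols <- integer(0L)
  new_loci <- list()
  off <- 0L
  for (nm in loci) {
    s <- locus_sites(part, nm)
    if (!is.null(codon)) s <- s[(seq_along(s) - 1L) %% 3L %in% (codon - 1L)]
    if (!length(s)) next
    cols <- c(cols, s + 1L)
    new_loci[[nm]] <- cbind(start = off, end = off + length(s))
    off <- off + length(s)
  }
  if (!length(cols)) stop("selection produced an empty alignment")
  out <- unclass(aln)[, cols, drop = FALSE]
  list(alignment = dna_alignment(out), partition = partition_map(new_loci))
}
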