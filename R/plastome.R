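# Plastome repeat-architecture typing: find long (near-)exact repeat pairs
# in a circular genome, classify the master structure as NR / IR / DR /
# DR-IR, report the expected conformation count and the single-copy
# segment lengths, and summarize genome features.

#' Read circular genome sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
read_genomes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- trimws(sub("\\s.*$", "", names(seqs)))
  out
}

revcomp <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  paste(rev(unname(COMPLEMENT[v])), collapse = "")
}

#' Find long repeat pairs in a circular sequence
#'
#' Reports maximal pairs of (near-)exact matches of at least `min_len` bp
#' between the sequence and itself (direct) and between the sequence and
#' its reverse complement (inverted). The search is circular-aware (seeds
#' are collected on the doubled sequence and coordinates deduplicated
#' modulo the genome length); the trivial full-length self match is
#' excluded and overlapping seed hits are merged to maximal extents.
#'
#' @param seq genome sequence (single character string over A/C/G/T/N).
#' @param min_len minimum repeat length in bp (default 500; >= 50).
#' @param max_mismatch_frac allowed mismatch fraction within a merged
#'   repeat (default 0 = exact; <= 0.05).
#' @param seed_len k-mer seed length (default `min(min_len, 31)`).
#' @return data.frame of class `repeat_pairs`: columns `start1`, `start2`
#'   (0-based circular offsets of the two copies; for inverted pairs
#'   `start2` is the offset of the reverse-complemented copy on the forward
#'   strand), `length`, `orientation`, `identity`.
#' @export
find_long_repeats <- function(seq, min_len = 500L,
                              max_mismatch_frac = 0,
                              seed_len = min(min_len, 31L)) {
  if (min_len < 50L) stop("min_len must be >= 50")
  if (max_mismatch_frac < 0 || max_mismatch_frac > 0.05)
    stop("max_mismatch_frac must be in [0, 0.05]")
  n <- nchar(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  empty <- data.frame(start1 = integer(0), start2 = integer(0),
                      length = integer(0), orientation = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  if (n < 2L * min_len) return(structure(empty, class = c("repeat_pairs", "data.frame")))
  k <- as.integer(seed_len)
  # forward k-mers on the doubled sequence: position i (0-based, mod n)
  dbl <- c(v, v[seq_len(min(k - 1L, n))])
  fwd <- substring(paste(dbl, collapse = ""), seq_len(n), seq_len(n) + k - 1L)
  rcv <- rev(unname(COMPLEMENT[v]))
  dbl_rc <- c(rcv, rcv[seq_len(min(k - 1L, n))])
  rc <- substring(paste(dbl_rc, collapse = ""), seq_len(n), seq_len(n) + k - 1L)

  pairs <- list()
  # direct: duplicated forward k-mers
  dup <- split(seq_len(n) - 1L, fwd)
  dup <- dup[lengths(dup) > 1L]
  for (grp in dup) {
    cmb <- utils::combn(grp, 2L)
    for (j in seq_len(ncol(cmb)))
      pairs[[length(pairs) + 1L]] <- c(cmb[1L, j], cmb[2L, j], 0L)
  }
  # inverted: forward k-mer equals a k-mer of the reverse complement;
  # rc position p (0-based on rc strand) covers forward positions
  # (n - p - k) .. (n - p - 1)
  common <- intersect(unique(fwd), unique(rc))
  if (length(common)) {
    fidx <- split(seq_len(n) - 1L, fwd)
    ridx <- split(seq_len(n) - 1L, rc)
    for (km in common) {
      for (p1 in fidx[[km]]) for (p2 in ridx[[km]]) {
        f2 <- (n - p2 - k) %% n   # forward-strand start of the rc hit
        pairs[[length(pairs) + 1L]] <- c(p1, f2, 1L)
      }
    }
  }
  if (!length(pairs)) return(structure(empty, class = c("repeat_pairs", "data.frame")))
  pm <- unique(do.call(rbind, pairs))
  # seeds of one underlying repeat lie on a common diagonal: constant
  # (p2 - p1) mod n for direct pairs, constant (p1 + p2) mod n for
  # inverted ones; keep one representative per contiguous diagonal run so
  # extension work is proportional to the number of repeats, not seeds
  pm <- thin_seed_diagonals(pm, n)

  # extend each seed pair to its maximal extent, then merge duplicates
  res <- list()
  for (r in seq_len(nrow(pm))) {
    p1 <- pm[r, 1L]; p2 <- pm[r, 2L]; inv <- pm[r, 3L] == 1L
    if (!inv && p1 == p2) next                    # self match
    ext <- extend_pair(v, p1, p2, k, inv, max_mismatch_frac)
    if (is.null(ext) || ext$length < min_len) next
    if (ext$length >= n) next                     # trivial full-length match
    # canonical ordering of the two copies
    s1 <- ext$start1; s2 <- ext$start2
    if (!inv && s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp }
    if (inv) { lo <- min(s1, s2); hi <- max(s1, s2); s1 <- lo; s2 <- hi }
    res[[length(res) + 1L]] <- data.frame(
      start1 = s1, start2 = s2, length = ext$length,
      orientation = if (inv) "inverted" else "direct",
      identity = ext$identity, stringsAsFactors = FALSE)
  }
  if (!length(res)) return(structure(empty, class = c("repeat_pairs", "data.frame")))
  out <- unique(do.call(rbind, res))
  # drop pairs contained in a longer pair of the same orientation
  out <- out[order(-out$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (out$orientation[i] == out$orientation[j] &&
          circ_contains(out$start1[j], out$length[j], out$start1[i],
                        out$length[i], n) &&
          circ_contains(out$start2[j], out$length[j], out$start2[i],
                        out$length[i], n)) {
        keep[i] <- FALSE; break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("repeat_pairs", "data.frame"))
}

# one representative seed per contiguous diagonal run
thin_seed_diagonals <- function(pm, n) {
  key <- ifelse(pm[, 3L] == 1L,
                paste0("i", (pm[, 1L] + pm[, 2L]) %% n),
                paste0("d", (pm[, 2L] - pm[, 1L]) %% n))
  keep <- logical(nrow(pm))
  for (grp in split(seq_len(nrow(pm)), key)) {
    p1 <- pm[grp, 1L]
    o <- order(p1)
    run_start <- c(TRUE, diff(p1[o]) != 1L)
    keep[grp[o][run_start]] <- TRUE
  }
  pm[keep, , drop = FALSE]
}

# does circular interval (s1, len1) contain (s2, len2)?
circ_contains <- function(s1, len1, s2, len2, n) {
  off <- (s2 - s1) %% n
  off + len2 <= len1
}

# maximal extension of a seeded match; positions 0-based; returns starts,
# length, identity (mismatch-tolerant extension merges runs while the
# overall mismatch fraction stays within the budget)
extend_pair <- function(v, p1, p2, k, inv, max_mm) {
  n <- length(v)
  at <- function(pos) v[pos %% n + 1L]
  at_rc <- function(pos) COMPLEMENT[v[pos %% n + 1L]]
  # For direct: copy2 position offset j matches copy1 offset j.
  # For inverted: forward-strand segment starting at p2 of length L equals
  # revcomp(segment at p1 of length L); seed gives p2 as forward start of
  # the rc-matching window of length k. Offset j on copy1 pairs with
  # offset (L-1-j) on copy2; extend by moving both boundaries.
  max_steps <- n - 1L
  if (!inv) {
    # extend left
    left <- 0L
    mism <- 0L
    len <- k
    budget <- function(l) floor(max_mm * l)
    while (left < max_steps) {
      c1 <- at(p1 - left - 1L); c2 <- at(p2 - left - 1L)
      if (identical(c1, c2)) left <- left + 1L
      else if (mism + 1L <= budget(len + left + 1L)) {
        mism <- mism + 1L; left <- left + 1L
      } else break
      if (left + len >= n) break
    }
    right <- 0L
    while (left + len + right < n) {
      c1 <- at(p1 + len + right); c2 <- at(p2 + len + right)
      if (identical(c1, c2)) right <- right + 1L
      else if (mism + 1L <= budget(len + left + right + 1L)) {
        mism <- mism + 1L; right <- right + 1L
      } else break
    }
    total <- len + left + right
    list(start1 = (p1 - left) %% n, start2 = (p2 - left) %% n,
         length = total, identity = 1 - mism / total)
  } else {
    # inverted: extending copy1 rightwards extends copy2 leftwards
    mism <- 0L
    len <- k
    budget <- function(l) floor(max_mm * l)
    left <- 0L   # extend copy1 left = copy2 right
    while (left < max_steps) {
      c1 <- at(p1 - left - 1L)
      c2 <- at_rc(p2 + len + left)
      if (identical(unname(c2), c1)) left <- left + 1L
      else if (mism + 1L <= budget(len + left + 1L)) {
        mism <- mism + 1L; left <- left + 1L
      } else break
      if (left + len >= n) break
    }
    right <- 0L  # extend copy1 right = copy2 left
    while (left + len + right < n) {
      c1 <- at(p1 + len + right)
      c2 <- at_rc(p2 - right - 1L)
      if (identical(unname(c2), c1)) right <- right + 1L
      else if (mism + 1L <= budget(len + left + right + 1L)) {
        mism <- mism + 1L; right <- right + 1L
      } else break
    }
    total <- len + left + right
    list(start1 = (p1 - left) %% n, start2 = (p2 - right) %% n,
         length = total, identity = 1 - mism / total)
  }
}

#' Classify the plastome master structure
#'
#' Given the qualifying repeat pairs of a circular genome: no repeat gives
#' NR (1 conformation); only inverted gives IR (2 conformations, via
#' recombination between the two copies); only direct gives DR (1
#' conformation); both orientations give DR-IR (3 conformations). The
#' longest pair per orientation defines the architecture; the single-copy
#' segments between the two copies of the dominant pair are labeled LSC
#' (longer) and SSC (shorter).
#'
#' @param repeats a `repeat_pairs` data.frame from [find_long_repeats()].
#' @param genome_length genome length in bp.
#' @param min_identity minimum identity for a qualifying pair
#'   (default 0.99).
#' @return object of class `structure_call`: list with `type`,
#'   `conformations`, `segments` (named numeric, LSC >= SSC; for NR one
#'   segment = whole genome), `dominant` (the defining pair or `NULL`),
#'   `repeats` (all qualifying pairs).
#' @export
classify_structure <- function(repeats, genome_length,
                               min_identity = 0.99) {
  q <- repeats[repeats$identity >= min_identity, , drop = FALSE]
  if (nrow(q)) {
    cover <- 2 * max(q$length)
    if (cover > 0.9 * genome_length)
      stop("repeat copies cover > 90% of the genome; degenerate input")
  }
  has_dir <- any(q$orientation == "direct")
  has_inv <- any(q$orientation == "inverted")
  type <- if (!nrow(q)) "NR"
          else if (has_dir && has_inv) "DR-IR"
          else if (has_inv) "IR"
          else "DR"
  conformations <- c(NR = 1L, IR = 2L, DR = 1L, `DR-IR` = 3L)[[type]]
  if (type == "NR") {
    segments <- c(SC = genome_length)
    dominant <- NULL
  } else {
    dominant <- q[which.max(q$length), , drop = FALSE]
    s1 <- dominant$start1; s2 <- dominant$start2; L <- dominant$length
    seg1 <- (s2 - (s1 + L)) %% genome_length
    seg2 <- (s1 - (s2 + L)) %% genome_length
    segments <- sort(c(seg1, seg2), decreasing = TRUE)
    names(segments) <- c("LSC", "SSC")
  }
  structure(list(type = type, conformations = conformations,
                 segments = segments, dominant = dominant, repeats = q),
            class = "structure_call")
}

#' @export
print.structure_call <- function(x, ...) {
  cat(sprintf("structure_call: %s (%d conformation%s); segments: %s\n",
              x$type, x$conformations,
              if (x$conformations > 1L) "s" else "",
              paste(sprintf("%s=%d", names(x$segments),
                            as.integer(x$segments)), collapse = ", ")))
  invisible(x)
}

#' Summarize genome features
#'
#' Genome length, GC fraction (over non-N positions), repeat and
#' single-copy lengths, and — when an annotation table is given — counts
#' of genes, tRNAs and rRNAs plus the ribosomal-operon copy number (rRNA
#' clusters separated by > `operon_gap` bp).
#'
#' @param seq genome sequence (character string).
#' @param call a [classify_structure()] result.
#' @param annotations optional data.frame with columns `name`, `type`
#'   (`CDS`/`tRNA`/`rRNA`), `start`, `end` (1-based inclusive).
#' @param operon_gap maximum within-cluster gap between rRNAs (default
#'   5000 bp).
#' @return one-row data.frame: `length`, `gc`, `type`, `conformations`,
#'   `repeat_length`, `lsc`, `ssc`, and (with annotations) `n_genes`,
#'   `n_trna`, `n_rrna`, `n_rrna_operons`.
#' @export
summarize_features <- function(seq, call, annotations = NULL,
                               operon_gap = 5000L) {
  n <- nchar(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  non_n <- v != "N"
  gc <- sum(v %in% c("G", "C")) / sum(non_n)
  out <- data.frame(length = n, gc = gc, type = call$type,
                    conformations = call$conformations,
                    repeat_length = if (is.null(call$dominant)) 0L
                                    else as.integer(call$dominant$length),
                    lsc = as.integer(call$segments[1L]),
                    ssc = if (length(call$segments) > 1L)
                      as.integer(call$segments[2L]) else NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    if (any(annotations$start < 1L) || any(annotations$end > n))
      stop("annotation coordinates out of range")
    out$n_genes <- sum(annotations$type == "CDS")
    out$n_trna <- sum(annotations$type == "tRNA")
    out$n_rrna <- sum(annotations$type == "rRNA")
    rr <- annotations[annotations$type == "rRNA", , drop = FALSE]
    out$n_rrna_operons <- count_rrna_operons(rr, n, operon_gap)
  }
  out
}

# cluster rRNA annotations on the circle; clusters separated by more than
# `gap` bp count as separate operon copies
count_rrna_operons <- function(rr, genome_length, gap) {
  if (!nrow(rr)) return(0L)
  rr <- rr[order(rr$start), , drop = FALSE]
  if (nrow(rr) == 1L) return(1L)
  gaps <- c(rr$start[-1L] - rr$end[-nrow(rr)],
            rr$start[1L] + genome_length - rr$end[nrow(rr)])
  n_breaks <- sum(gaps > gap)
  max(1L, n_breaks)
}

#' Batch-classify plastomes into a feature table
#'
#' @param genomes named character vector of sequences (e.g. from
#'   [read_genomes()]).
#' @param min_len minimum qualifying repeat length (default 500).
#' @param max_mismatch_frac see [find_long_repeats()].
#' @return data.frame, one row per genome (`id` column first).
#' @export
classify_plastomes <- function(genomes, min_len = 500L,
                               max_mismatch_frac = 0) {
  rows <- lapply(names(genomes), function(id) {
    rp <- find_long_repeats(genomes[[id]], min_len = min_len,
                            max_mismatch_frac = max_mismatch_frac)
    call <- classify_structure(rp, nchar(genomes[[id]]))
    cbind(data.frame(id = id, stringsAsFactors = FALSE),
          summarize_features(genomes[[id]], call))
  })
  do.call(rbind, rows)
}
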