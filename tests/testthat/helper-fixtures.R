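# Shared fixtures, all generated in code.

random_model <- function() {
  f <- stats::runif(4, 0.1, 1)
  gtr_model(rates = stats::runif(6, 0.3, 3), freqs = f / sum(f),
            alpha = stats::runif(1, 0.2, 2), k = 4L)
}

random_tree <- function(ntip, min_len = 0.01, max_len = 1) {
  tr <- ape::rtree(ntip)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# tiny two-locus alignment with a partition
tiny_dataset <- function() {
  aln <- dna_alignment(c(a = "ACGTACGTAC", b = "ACGTACTTAC",
                         c = "AGGTACGTAA", d = "ACGAACGTAC"))
  part <- partition_map(list(g1 = c(0L, 6L), g2 = c(6L, 10L)))
  list(alignment = aln, partition = part)
}

quartet_trees <- function() {
  list(ab_cd = ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"),
       ac_bd = ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);"),
       ad_bc = ape::read.tree(text = "((a:1,d:1):1,(b:1,c:1):1);"))
}
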