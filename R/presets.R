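# Study-scale presets: alternative resolutions of the two contentious
# genera of Gymnogynoideae (Selaginellaceae), used as the default topology
# hypotheses of the synthetic generator. One tip per genus plus an
# outgroup keeps desk-scale runs fast; `n_per_genus` expands each genus
# into a clade for larger fixtures.

GENERA <- c("Bryodesma", "Lepidoselaginella", "Megaloselaginella",
            "Afroselaginella", "Ericetorum", "Gymnogynum")

# newick skeletons: moderately divergent tips (0.1-0.2 subst/site) with
# internodes of 0.08-0.1, so a few-hundred-bp locus typically carries
# recoverable signal about the focal resolution
.eri_skeletons <- c(
  T1 = "(Isoetes:0.2,((Bryodesma:0.12,Lepidoselaginella:0.12)BL:0.1,((Ericetorum:0.12,(Megaloselaginella:0.1,Afroselaginella:0.1)MA:0.08)EMA:0.08,Gymnogynum:0.12)core:0.1)ing:0.1);",
  T2 = "(Isoetes:0.2,(Ericetorum:0.12,((Bryodesma:0.12,Lepidoselaginella:0.12)BL:0.1,((Megaloselaginella:0.1,Afroselaginella:0.1)MA:0.08,Gymnogynum:0.12)MAG:0.08)rest:0.1)ing:0.1);",
  T3 = "(Isoetes:0.2,((Bryodesma:0.12,Lepidoselaginella:0.12)BL:0.1,((Ericetorum:0.12,Gymnogynum:0.12)EG:0.08,(Megaloselaginella:0.1,Afroselaginella:0.1)MA:0.08)core:0.1)ing:0.1);")

.gym_skeletons <- c(
  T1 = "(Isoetes:0.2,((Bryodesma:0.12,Lepidoselaginella:0.12)BL:0.1,(Gymnogynum:0.12,(Ericetorum:0.12,(Megaloselaginella:0.1,Afroselaginella:0.1)MA:0.08)EMA:0.08)core:0.1)ing:0.1);",
  T2 = "(Isoetes:0.2,((Bryodesma:0.12,Lepidoselaginella:0.12)BL:0.1,((Gymnogynum:0.12,Ericetorum:0.12)GE:0.08,(Megaloselaginella:0.1,Afroselaginella:0.1)MA:0.08)core:0.1)ing:0.1);",
  T3 = "(Isoetes:0.2,((Gymnogynum:0.12,(Bryodesma:0.12,Lepidoselaginella:0.12)BL:0.08)GBL:0.08,(Ericetorum:0.12,(Megaloselaginella:0.1,Afroselaginella:0.1)MA:0.08)EMA:0.1)ing:0.1);",
  T4 = "(Isoetes:0.2,((Bryodesma:0.12,Lepidoselaginella:0.12)BL:0.1,((Gymnogynum:0.12,(Megaloselaginella:0.1,Afroselaginella:0.1)MA:0.08)GMA:0.08,Ericetorum:0.12)core:0.1)ing:0.1);")

expand_genus <- function(tree, n_per_genus) {
  if (n_per_genus <= 1L) return(tree)
  ladder <- function(tips, bl = 0.03) {
    txt <- tips[1L]
    for (i in seq_along(tips)[-1L])
      txt <- sprintf("(%s:%g,%s:%g)", txt, bl, tips[i], bl)
    txt
  }
  for (g in GENERA) {
    tips <- paste0(g, "_", seq_len(n_per_genus))
    sub <- ape::read.tree(text = paste0(ladder(tips), ";"))
    if (is.null(sub$edge.length)) sub$edge.length <- numeric(0)
    tree <- ape::bind.tree(tree, sub, where = which(tree$tip.label == g))
  }
  tree
}

#' Alternative topology hypotheses for a Gymnogynoideae-like clade set
#'
#' Returns the labeled alternative resolutions of the placement of
#' *Ericetorum* (three hypotheses) or *Gymnogynum* (four hypotheses) over a
#' fixed taxon set (one tip per genus plus an *Isoetes* outgroup), with
#' realistic branch lengths in substitutions/site. `T1` is the reference
#' (the maximum-likelihood resolution).
#'
#' @param clade `"Ericetorum"` or `"Gymnogynum"`.
#' @param n_per_genus tips per genus (default 1; larger values expand each
#'   genus into a rake of tips 0.03 subst/site deep).
#' @return a [topology_set()].
#' @export
gymnogynoideae_hypotheses <- function(clade = c("Gymnogynum", "Ericetorum"),
                                      n_per_genus = 1L) {
  clade <- match.arg(clade)
  skel <- if (clade == "Ericetorum") .eri_skeletons else .gym_skeletons
  trees <- lapply(skel, function(s) {
    tr <- ape::read.tree(text = s)
    tr$node.label <- NULL
    expand_genus(tr, n_per_genus)
  })
  names(trees) <- names(skel)
  topology_set(clade, trees, reference_label = "T1")
}
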