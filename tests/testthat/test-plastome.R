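test_that("clean random genomes carry no qualifying repeat and type NR", {
  g <- synth_plastome(8000, seed = 301)
  rp <- find_long_repeats(g$sequence, min_len = 500)
  expect_equal(nrow(rp), 0L)
  call <- classify_structure(rp, nchar(g$sequence))
  expect_equal(call$type, "NR")
  expect_equal(call$conformations, 1L)
  expect_equal(unname(call$segments), 8000)
})

test_that("planted pairs are recovered with their orientation and length", {
  g_dr <- synth_plastome(12000, list(list(length = 2000, orientation = "direct")),
                         seed = 302)
  rp <- find_long_repeats(g_dr$sequence, min_len = 500)
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$orientation, "direct")
  expect_gte(rp$length, 2000L)
  call <- classify_structure(rp, 12000)
  expect_equal(call$type, "DR")
  expect_equal(call$conformations, 1L)

  g_ir <- synth_plastome(12000, list(list(length = 2000, orientation = "inverted")),
                         seed = 303)
  call_ir <- classify_structure(find_long_repeats(g_ir$sequence, 500), 12000)
  expect_equal(call_ir$type, "IR")
  expect_equal(call_ir$conformations, 2L)
  expect_gte(call_ir$segments["LSC"], call_ir$segments["SSC"])

  g_both <- synth_plastome(20000,
                           list(list(length = 2000, orientation = "direct"),
                                list(length = 1500, orientation = "inverted")),
                           seed = 304)
  call_b <- classify_structure(find_long_repeats(g_both$sequence, 500), 20000)
  expect_equal(call_b$type, "DR-IR")
  expect_equal(call_b$conformations, 3L)
})

test_that("conformation counts are fixed by type", {
  expect_equal(classify_structure(
    data.frame(start1 = 0, start2 = 5000, length = 800,
               orientation = "direct", identity = 1), 12000)$conformations, 1L)
  expect_equal(classify_structure(
    data.frame(start1 = 0, start2 = 5000, length = 800,
               orientation = "inverted", identity = 1), 12000)$conformations, 2L)
  expect_equal(classify_structure(
    data.frame(start1 = c(0, 3000), start2 = c(5000, 9000),
               length = c(800, 700), orientation = c("direct", "inverted"),
               identity = c(1, 1)), 12000)$conformations, 3L)
  # classification must refuse degenerate near-full-genome repeats
  expect_error(classify_structure(
    data.frame(start1 = 0, start2 = 6000, length = 5900,
               orientation = "direct", identity = 1), 12000), "90%")
})

test_that("IR geometry splits the single copy into LSC and SSC", {
  rp <- data.frame(start1 = 2000, start2 = 8000, length = 2000,
                   orientation = "inverted", identity = 1)
  call <- classify_structure(rp, 12000)
  expect_equal(unname(call$segments), c(4000, 4000))
})

test_that("repeats straddling the origin are found with modular coordinates", {
  set.seed(305)
  # build a genome whose second repeat copy wraps around position 0
  n <- 9000L
  repeat {
    bg <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    if (!phylodissect:::has_chance_repeat(bg, 400L)) break
  }
  unit <- sample(c("A", "C", "G", "T"), 800, replace = TRUE)
  v <- bg
  v[3001:3800] <- unit
  idx <- ((n - 400L):(n + 399L) %% n) + 1L  # wraps 8601..9000,1..400
  v[idx] <- unit
  g <- paste(v, collapse = "")
  rp <- find_long_repeats(g, min_len = 500, seed_len = 31L)
  expect_equal(nrow(rp), 1L)
  expect_gte(rp$length, 800L)
  starts <- sort(c(rp$start1, rp$start2))
  expect_equal(starts[1], 3000)
  expect_equal(starts[2], n - 400L)
})

test_that("the seed-and-extend finder agrees with the quadratic oracle", {
  fixtures <- list(
    synth_plastome(6000, seed = 306),
    synth_plastome(6000, list(list(length = 900, orientation = "direct")),
                   seed = 307),
    synth_plastome(6000, list(list(length = 700, orientation = "inverted")),
                   seed = 308),
    synth_plastome(9000, list(list(length = 800, orientation = "direct"),
                              list(length = 600, orientation = "inverted")),
                   seed = 309))
  for (g in fixtures) {
    mine <- find_long_repeats(g$sequence, min_len = 500)
    oracle <- brute_force_repeats(g$sequence, min_len = 500)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(mine)) {
      key <- function(df) sort(paste(pmin(df$start1, df$start2),
                                     pmax(df$start1, df$start2),
                                     df$length, df$orientation))
      expect_equal(key(mine), key(oracle))
    }
  }
})

test_that("classification is invariant to rotation and reverse complement", {
  g <- synth_plastome(10000, list(list(length = 1200, orientation = "inverted")),
                      seed = 310)
  s <- g$sequence
  rot <- function(s, k) paste0(substring(s, k + 1), substring(s, 1, k))
  base <- classify_structure(find_long_repeats(s, 500), nchar(s))
  for (k in c(137, 5000, 9000)) {
    cl <- classify_structure(find_long_repeats(rot(s, k), 500), nchar(s))
    expect_equal(cl$type, base$type)
    expect_equal(cl$conformations, base$conformations)
    expect_equal(unname(cl$segments), unname(base$segments))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
  cl_rc <- classify_structure(find_long_repeats(rc, 500), nchar(s))
  expect_equal(cl_rc$type, base$type)
  expect_equal(unname(cl_rc$segments), unname(base$segments))
})

test_that("feature summaries report GC, lengths and rRNA operon counts", {
  call_gc <- structure(list(type = "NR", conformations = 1L,
                            segments = c(SC = 8), dominant = NULL,
                            repeats = NULL), class = "structure_call")
  expect_equal(summarize_features("GGCCGGCC", call_gc)$gc, 1)
  s5050 <- paste(rep("GA", 2000), collapse = "")
  call <- structure(list(type = "NR", conformations = 1L,
                         segments = c(SC = 4000), dominant = NULL,
                         repeats = NULL), class = "structure_call")
  expect_equal(summarize_features(s5050, call)$gc, 0.5)

  ann <- data.frame(name = c(paste0("rrn", 1:4), "psbA", "trnH"),
                    type = c(rep("rRNA", 4), "CDS", "tRNA"),
                    start = c(100, 600, 1100, 1600, 3000, 3900),
                    end = c(500, 1000, 1500, 2000, 3800, 3970))
  feats <- summarize_features(s5050, call, annotations = ann)
  expect_equal(feats$n_rrna, 4L)
  expect_equal(feats$n_genes, 1L)
  expect_equal(feats$n_trna, 1L)
  expect_equal(feats$n_rrna_operons, 1L)
  # two clusters on opposite sides of the circle
  ann2 <- ann[ann$type == "rRNA", ]
  ann2$start[3:4] <- c(7000, 7500)
  ann2$end[3:4] <- c(7400, 7900)
  s_long <- paste(rep("GA", 8000), collapse = "")
  call2 <- call; call2$segments <- c(SC = 16000)
  expect_equal(summarize_features(s_long, call2,
                                  annotations = ann2)$n_rrna_operons, 2L)
  expect_error(summarize_features(s5050, call,
                                  annotations = transform(ann, end = 99999)),
               "out of range")
})

test_that("batch classification produces one typed row per genome", {
  genomes <- c(
    nr = synth_plastome(6000, seed = 311)$sequence,
    ir = synth_plastome(8000, list(list(length = 900, orientation = "inverted")),
                        seed = 312)$sequence,
    dri = synth_plastome(9000, list(list(length = 800, orientation = "direct"),
                                    list(length = 600, orientation = "inverted")),
                         seed = 313)$sequence)
  tab <- classify_plastomes(genomes, min_len = 500)
  expect_equal(tab$id, c("nr", "ir", "dri"))
  expect_equal(tab$type, c("NR", "IR", "DR-IR"))
  expect_equal(tab$conformations, c(1L, 2L, 3L))
})
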