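# IR detection, canonical orientation, statistics panel.

test_that("a constructed LSC+IR+SSC+revcomp(IR) layout is recovered exactly", {
  withr::with_seed(1, {
    L <- paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE), collapse = "")
    I <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    S <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  })
  # guard junctions so the construction is exactly maximal
  S <- paste0(substr(S, 1, 149), setdiff(c("A", "C", "G", "T"),
                                         c(revcomp(substr(S, 1, 1))))[1])
  L <- paste0(setdiff(c("A", "C", "G", "T"),
                      revcomp(substr(L, 700, 700)))[1], substr(L, 2, 700))
  g <- paste0(L, I, S, revcomp(I))
  part <- detect_inverted_repeat(g)
  expect_equal(part$length[part$region == "IRb"], 200L)
  expect_equal(part$length[part$region == "SSC"], 150L)
  expect_equal(substr(g, part$start[part$region == "SSC"] + 1,
                      part$end[part$region == "SSC"]), S)
})

test_that("detection is invariant under rotation and reverse complement", {
  p <- make_plastome(seed = 17)
  n <- nchar(p$seq)
  base <- detect_inverted_repeat(p$seq)
  rot <- paste0(substr(p$seq, 138, n), substr(p$seq, 1, 137))
  part_rot <- detect_inverted_repeat(rot)
  expect_equal(sort(part_rot$length), sort(base$length))
  part_rc <- detect_inverted_repeat(revcomp(p$seq))
  expect_equal(sort(part_rc$length), sort(base$length))
})

test_that("isolated mismatches in one IR copy are tolerated at the stated rate", {
  p <- make_plastome(seed = 23)
  part <- p$truth$partition
  ira <- part[part$region == "IRa", ]
  x <- seq_chars(p$seq)
  # plant two well-separated substitutions inside IRa
  pos <- ira$start + c(200L, 500L)
  for (q in pos) {
    x[q + 1L] <- setdiff(c("A", "C", "G", "T"), x[q + 1L])[1L]
  }
  mutated <- paste(x, collapse = "")
  part2 <- detect_inverted_repeat(mutated, max_mismatch_rate = 0.01)
  expect_equal(part2$length[part2$region == "IRb"], 700L)
  expect_equal(part2$length[part2$region == "SSC"], 250L)
})

test_that("a sequence without an inverted repeat signals no quadripartite structure", {
  withr::with_seed(2, {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  })
  expect_error(detect_inverted_repeat(s), class = "plastomics_no_quadripartite")
})

test_that("seeded detection agrees with the exhaustive anti-diagonal oracle", {
  for (s in 1:5) {
    p <- make_plastome(lsc_len = 900L, ir_len = 350L, ssc_len = 150L,
                       n_protein = 4L, n_trna = 2L, n_rrna = 1L, seed = s)
    o <- oracle_max_inverted_repeat(p$seq)
    d <- detect_inverted_repeat(p$seq)
    expect_equal(d$length[d$region == "IRb"], o$len)
    expect_true(o$start %in% d$start[d$region %in% c("IRb", "IRa")])
  }
})

test_that("canonicalize is the identity on canonical input and preserves content", {
  p <- make_plastome(seed = 31)
  can <- canonicalize(p$seq, p$truth$partition, p$features)
  expect_equal(can$seq, p$seq)
  expect_equal(can$partition, p$truth$partition)
  expect_equal(can$features, p$features)

  # rotated input comes back to the same canonical sequence, and features
  # still extract the same content
  n <- nchar(p$seq)
  rot <- 1234L
  seq2 <- paste0(substr(p$seq, rot + 1L, n), substr(p$seq, 1L, rot))
  feats2 <- p$features
  feats2$start <- (p$features$start - rot) %% n
  feats2$end <- (p$features$end - 1L - rot) %% n + 1L
  part2 <- detect_inverted_repeat(seq2)
  can2 <- canonicalize(seq2, part2, feats2)
  expect_equal(can2$seq, p$seq)
  for (id in unique(p$features$feature_id)) {
    expect_equal(
      extract_feature_sequence(can2$seq, can2$features[can2$features$feature_id == id, ],
                               circular = TRUE),
      extract_feature_sequence(p$seq, p$features[p$features$feature_id == id, ],
                               circular = TRUE)
    )
  }
  # double application is idempotent
  can3 <- canonicalize(can2$seq, can2$partition, can2$features)
  expect_equal(can3$seq, can2$seq)
  expect_equal(can3$partition, can2$partition)
})

test_that("published size arithmetic reproduces the printed percentages", {
  # region sizes of the Musa plastome: percentages recompute at 1 decimal
  expect_equal(round_half_up(100 * 88338 / 169972, 1), 52.0)
  expect_equal(round_half_up(100 * 10768 / 169972, 1), 6.3)
  expect_equal(round_half_up(100 * 100277 / 169972, 1), 59.0)
  expect_equal(88338 + 10768 + 2 * 35433, 169972)
})

test_that("partition statistics match the generator's bookkeeping", {
  p <- make_plastome(seed = 37)
  st <- partition_stats(p$seq, p$truth$partition, p$features)
  val <- function(m) st$value[st$metric == m]
  expect_equal(val("genome"), nchar(p$seq))
  expect_equal(val("lsc") + val("ssc") + 2 * val("ir"), val("genome"))
  expect_equal(val("coding") + val("intron") + val("IGS"), val("genome"))
  expect_equal(val("protein") + val("rRNA") + val("tRNA"), val("coding"))
  expect_equal(val("n_genes"),
               val("n_protein_genes") + val("n_trna_genes") + val("n_rrna_genes"))
  # truth bookkeeping: distinct genes and IR-duplicated genes
  expect_equal(val("n_genes"), length(unique(p$features$gene)))
  dup <- table(p$features$gene[!duplicated(p$features$feature_id)])
  expect_equal(val("n_ir_duplicated"), sum(dup >= 2))
  # percentages recompute exactly from sizes
  sizes <- st[!is.na(st$percent), ]
  expect_equal(sizes$percent, round_half_up(100 * sizes$value / nchar(p$seq), 1))
})

test_that("internal stop codons are counted in frame, excluding the terminus", {
  expect_equal(detect_internal_stops("ATGTAATAA"), 1L)
  expect_equal(detect_internal_stops("ATGAAATAA"), 0L)
  expect_warning(n <- detect_internal_stops("ATGTAATA"), "frame-broken")
  expect_equal(n, 1L)
  # 300-codon ORF with 5 planted stops
  withr::with_seed(5, {
    codons <- sample(setdiff(names(plastid_genetic_code()),
                             c("TAA", "TAG", "TGA")), 299, replace = TRUE)
    stops <- sample(2:298, 5)
    codons[stops] <- sample(c("TAA", "TAG", "TGA"), 5, replace = TRUE)
    orf <- paste0(paste(codons, collapse = ""), "TAA")
  })
  expect_equal(detect_internal_stops(orf), 5L)
})
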