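# Microsatellite and minisatellite scanning.

flank <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

test_that("microsatellite thresholds are sharp at the copy-number boundary", {
  left <- "GCTAGCTTGCAGTCCTG"   # must not end in A
  right <- "CCTGATCGTAGGCTAGTC" # must not start with A
  expect_equal(nrow(find_microsatellites(paste0(left, strrep("A", 10), right))), 1L)
  hit <- find_microsatellites(paste0(left, strrep("A", 10), right))
  expect_equal(hit$copies, 10)
  expect_equal(hit$unit, "A")
  expect_equal(nrow(find_microsatellites(paste0(left, strrep("A", 9), right))), 0L)
})

test_that("a dinucleotide array is reported once under its primitive unit", {
  s <- paste0("GCTGGCTTGC", strrep("AT", 5), "GCCTGTCGTC")
  hits <- find_microsatellites(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit_len, 2L)
  expect_equal(hits$copies, 5)
})

test_that("minisatellite rules: unit >= 10, at least two tandem copies", {
  u12 <- "AATCGGATCGTC"  # primitive 12-mer
  # "G" guards stop the flanks from extending the planted period
  s <- paste0(flank(40, 1), "G", strrep(u12, 3), "G", flank(40, 2))
  hits <- find_minisatellites(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit_len, 12L)
  expect_equal(hits$copies, 3)
  # 9-mer repeats are below the unit-size rule
  s9 <- paste0(flank(40, 3), strrep("AATCGGATC", 5), flank(40, 4))
  expect_equal(nrow(find_minisatellites(s9)), 0L)
})

test_that("the extreme published array shape (14 units of 30 bp) is detected", {
  withr::with_seed(8, {
    u30 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  })
  stopifnot(nrow(find_microsatellites(strrep(u30, 2))) == 0L)  # unit interior clean
  guard <- setdiff(c("A", "C", "G", "T"),
                   c(substr(u30, 30, 30), substr(u30, 1, 1)))[1]
  s <- paste0(flank(60, 5), guard, strrep(u30, 14), guard, flank(60, 6))
  hits <- find_minisatellites(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit_len, 30L)
  expect_equal(hits$copies, 14)
})

test_that("planted loci in a synthetic plastome are recovered exactly", {
  pr <- tibble::tibble(
    motif = c("A", "AT", "AGC", "AATCG", "AATCGGATCGTC"),
    copies = c(12, 6, 5, 3, 3),
    region = c("LSC", "LSC", "SSC", "LSC", "LSC")
  )
  p <- make_plastome(seed = 41, planted_repeats = pr)
  loci <- dplyr::bind_rows(find_microsatellites(p$seq), find_minisatellites(p$seq))
  truth <- p$truth$repeats
  for (i in seq_len(nrow(truth))) {
    m <- loci[loci$start == truth$start[i] & loci$end == truth$end[i], ]
    expect_equal(nrow(m), 1L)
    expect_equal(m$copies, truth$copies[i])
    expect_equal(m$repeat_class, truth$repeat_class[i])
  }
})

test_that("scanning agrees with the quadratic brute-force oracle", {
  min_rep <- c(10, 5, 4, 3, 3, 3)
  for (s in c(41, 42)) {
    pr <- tibble::tibble(
      motif = c("A", "AT", "AATC", "AATCGGATCGTC"),
      copies = c(11, 7, 4, 2),
      region = c("LSC", "SSC", "LSC", "LSC")
    )
    p <- make_plastome(seed = s, planted_repeats = pr)
    mic <- find_microsatellites(p$seq)
    # every reported micro locus is an oracle candidate with identical extent
    cand <- oracle_tandem_arrays(p$seq, 1:6)
    for (i in seq_len(nrow(mic))) {
      m <- cand[cand$start == mic$start[i] & cand$end == mic$end[i] &
                  cand$unit_len == mic$unit_len[i], ]
      expect_equal(nrow(m), 1L)
    }
    # every above-threshold primitive oracle candidate not contained in a
    # longer candidate is reported
    keep <- cand[cand$copies >= min_rep[cand$unit_len] &
                   vapply(cand$unit, plastomics:::is_primitive_unit, logical(1)), ]
    for (i in seq_len(nrow(keep))) {
      contained <- any(keep$start <= keep$start[i] & keep$end >= keep$end[i] &
                         keep$unit_len != keep$unit_len[i])
      if (!contained) {
        expect_true(any(mic$start == keep$start[i] & mic$end == keep$end[i]))
      }
    }
    # minisatellites against the oracle at unit sizes 10-60
    mini <- find_minisatellites(p$seq)
    cand_m <- oracle_tandem_arrays(p$seq, 10:60)
    for (i in seq_len(nrow(mini))) {
      m <- cand_m[cand_m$start == mini$start[i] & cand_m$end == mini$end[i], ]
      expect_gte(nrow(m), 1L)
    }
  }
})

test_that("reverse-complement scanning mirrors coordinates and motifs", {
  pr <- tibble::tibble(motif = c("AT", "AGC"), copies = c(6, 5),
                       region = c("LSC", "SSC"))
  p <- make_plastome(seed = 43, planted_repeats = pr)
  n <- nchar(p$seq)
  fwd <- find_microsatellites(p$seq)
  rev <- find_microsatellites(revcomp(p$seq))
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- tibble::tibble(start = n - rev$end, end = n - rev$start,
                             canonical_motif = rev$canonical_motif)
  mirrored <- mirrored[order(mirrored$start), ]
  fwd <- fwd[order(fwd$start), ]
  expect_equal(fwd$start, mirrored$start)
  expect_equal(fwd$end, mirrored$end)
  expect_equal(fwd$canonical_motif, mirrored$canonical_motif)
})

test_that("no two reported loci of one class overlap", {
  pr <- tibble::tibble(motif = c("A", "AT", "AATCGGATCGTC", "ATCGGCTAGGCTT"),
                       copies = c(14, 8, 3, 2), region = c("LSC", "LSC", "LSC", "SSC"))
  p <- make_plastome(seed = 44, planted_repeats = pr)
  for (loci in list(find_microsatellites(p$seq), find_minisatellites(p$seq))) {
    if (nrow(loci) < 2L) next
    loci <- loci[order(loci$start), ]
    expect_true(all(loci$start[-1L] >= loci$end[-nrow(loci)]))
  }
})

test_that("IR copies of a repeat are deduplicated to the IRb copy", {
  pr <- tibble::tibble(motif = "AATCGGATCGTC", copies = 3, region = "IRb")
  p <- make_plastome(seed = 45, planted_repeats = pr)
  part <- p$truth$partition
  loci <- assign_regions(find_minisatellites(p$seq), part)
  expect_setequal(loci$region, c("IRb", "IRa"))
  dd <- dedup_ir(loci, part)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$region, "IRb")
  # LSC loci are unaffected
  pr2 <- tibble::tibble(motif = c("AT", "AATCGGATCGTC"), copies = c(6, 3),
                        region = c("LSC", "IRb"))
  p2 <- make_plastome(seed = 46, planted_repeats = pr2)
  all2 <- assign_regions(dplyr::bind_rows(find_microsatellites(p2$seq),
                                          find_minisatellites(p2$seq)),
                         p2$truth$partition)
  dd2 <- dedup_ir(all2, p2$truth$partition)
  expect_true(any(dd2$region == "LSC"))
  expect_false(any(dd2$region == "IRa" & !dd2$junction_spanning))
})

test_that("junction-spanning loci are kept and flagged", {
  part <- dplyr::bind_rows(
    tibble::tibble(region = "LSC", start = 0L, end = 500L, length = 500L),
    tibble::tibble(region = "IRb", start = 500L, end = 700L, length = 200L),
    tibble::tibble(region = "SSC", start = 700L, end = 800L, length = 100L),
    tibble::tibble(region = "IRa", start = 800L, end = 1000L, length = 200L)
  )
  loci <- tibble::tibble(start = 690L, end = 715L, unit = "AATCGGATCGTC",
                         unit_len = 12L, copies = 2.1, repeat_class = "mini",
                         canonical_motif = canonical_motif("AATCGGATCGTC"))
  out <- dedup_ir(assign_regions(loci, part), part)
  expect_equal(nrow(out), 1L)
  expect_true(out$junction_spanning)
})

test_that("flank extraction honours circularity and degenerate lengths", {
  withr::with_seed(7, {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  })
  loci <- tibble::tibble(start = 100L, end = 130L)
  fl <- extract_flanks(loci, s, flank_len = 50L)
  expect_equal(fl$left_flank, substr(s, 51, 100))
  expect_equal(fl$right_flank, substr(s, 131, 180))
  # locus near the origin wraps
  loci0 <- tibble::tibble(start = 10L, end = 40L)
  fl0 <- extract_flanks(loci0, s, flank_len = 50L)
  expect_equal(fl0$left_flank, paste0(substr(s, 961, 1000), substr(s, 1, 10)))
  expect_equal(nchar(fl0$left_flank), 50L)
  # zero-length flanks and over-long flanks
  expect_equal(extract_flanks(loci, s, flank_len = 0L)$left_flank, "")
  expect_error(extract_flanks(loci, s, flank_len = 990L), "full length")
})
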