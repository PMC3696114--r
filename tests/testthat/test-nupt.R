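# Plastid-insertion (NUPT) detection, profiles, summaries.

test_that("stripping one IR keeps LSC+IRb+SSC and maps back to both copies", {
  p <- make_plastome(lsc_len = 600L, ir_len = 200L, ssc_len = 120L,
                     n_protein = 3L, n_trna = 2L, n_rrna = 1L, seed = 2)
  st <- strip_one_ir(p$seq, p$truth$partition)
  expect_equal(st$length, 1120L - 200L)
  expect_equal(st$seq, substr(p$seq, 1, 920))
  # an interval inside IRb maps to both IR copies
  mb <- st$map_back(650L, 700L)
  expect_equal(nrow(mb), 2L)
  expect_equal(mb$start[mb$region == "direct"], 650L)
  # the IRa mirror of IRb [650,700) (IRb spans [600,800))
  expect_equal(mb$start[mb$region == "IRa-mirror"], 920L + (800L - 700L))
  expect_equal(mb$end[mb$region == "IRa-mirror"], 920L + (800L - 650L))
  # stripping an already-stripped sequence errors
  expect_error(strip_one_ir(st$seq, p$truth$partition), "stripped")
})

test_that("planted insertions are recovered with full recall and precision", {
  p <- make_plastome(seed = 3)
  part <- p$truth$partition
  st <- strip_one_ir(p$seq, part)
  for (s in c(11, 12)) {
    nuc <- make_nuclear_with_nupts(p$seq, part, n_insertions = 5,
                                   divergence_rate = 0, seed = s)
    hits <- find_insertions(nuc$chromosomes, st, min_len = 100)
    truth <- nuc$truth[nuc$truth$length > 100, ]
    # recall: every planted fragment > 100 bp yields a hit at its exact extent
    for (i in seq_len(nrow(truth))) {
      m <- hits[hits$chrom == truth$chrom[i] &
                  hits$q_start == truth$q_start[i] &
                  hits$q_end == truth$q_end[i], ]
      expect_equal(nrow(m), 1L)
      expect_equal(m$identity, 100)
    }
    # precision: every reported hit intersects a planted fragment
    for (i in seq_len(nrow(hits))) {
      expect_true(any(hits$chrom[i] == nuc$truth$chrom &
                        hits$nuc_start[i] < nuc$truth$nuc_end &
                        nuc$truth$nuc_start < hits$nuc_end[i]))
    }
  }
})

test_that("a diverged fragment is found as one hit covering most of its extent", {
  p <- make_plastome(seed = 3)
  part <- p$truth$partition
  st <- strip_one_ir(p$seq, part)
  nuc <- make_nuclear_with_nupts(p$seq, part, n_insertions = 1,
                                 len_range = c(500L, 500L),
                                 divergence_rate = 0.02, seed = 5)
  hits <- find_insertions(nuc$chromosomes, st, min_len = 100)
  expect_equal(nrow(hits), 1L)
  expect_gte(hits$length, 0.95 * nuc$truth$length)
  expect_gte(hits$identity, 95)
})

test_that("stringency filters are strict inequalities", {
  tab <- tibble::tibble(
    chrom = "chr01", nuc_start = c(0L, 500L, 1000L), nuc_end = c(100L, 650L, 1200L),
    strand = "+", q_start = c(0L, 0L, 0L), q_end = c(100L, 150L, 200L),
    length = c(100L, 150L, 200L), identity = 100,
    evalue = c(1e-30, 1e-5, 1e-30)
  )
  out <- find_insertions(hits = tab, min_len = 100, max_e = 1e-5)
  # length exactly 100 excluded; e-value exactly 1e-5 excluded
  expect_equal(out$length, 200L)
  expect_error(find_insertions(), "provide either")
})

test_that("insertion profiles count covering hits and halve the IR display", {
  p <- make_plastome(lsc_len = 600L, ir_len = 200L, ssc_len = 120L,
                     n_protein = 3L, n_trna = 2L, n_rrna = 1L, seed = 2)
  part <- p$truth$partition
  h <- tibble::tibble(chrom = "c", nuc_start = 0L, nuc_end = 10L, strand = "+",
                      q_start = c(10L, 15L, 650L), q_end = c(20L, 25L, 700L),
                      length = 10L, identity = 100, bitscore = 1, evalue = 0)
  prof <- insertion_profile(h, p$seq, part)
  v <- prof$stripped$value
  expect_equal(v[11:15], rep(1L, 5))   # [10,15) covered once
  expect_equal(v[16:20], rep(2L, 5))   # overlap covered twice
  expect_equal(v[21:25], rep(1L, 5))
  expect_equal(sum(v), sum(h$q_end - h$q_start))  # profile mass == hit lengths
  # IR halving mirrored onto both copies
  d <- prof$display$value
  expect_equal(d[651:700], v[651:700] / 2)
  expect_equal(d[921:1120], rev(d[601:800]))
  expect_error(insertion_profile(
    tibble::tibble(chrom = "c", nuc_start = 0L, nuc_end = 1L, strand = "+",
                   q_start = 900L, q_end = 1000L, length = 100L,
                   identity = 100, bitscore = 1, evalue = 0),
    p$seq, part), "bounds")
})

test_that("covered fraction equals the truth coverage at divergence zero", {
  p <- make_plastome(seed = 3)
  part <- p$truth$partition
  st <- strip_one_ir(p$seq, part)
  nuc <- make_nuclear_with_nupts(p$seq, part, n_insertions = 4,
                                 divergence_rate = 0, seed = 21)
  hits <- find_insertions(nuc$chromosomes, st, min_len = 100)
  prof <- insertion_profile(hits, p$seq, part)
  covered <- rep(FALSE, st$length)
  tr <- nuc$truth[nuc$truth$length > 100, ]
  for (i in seq_len(nrow(tr))) {
    covered[(tr$q_start[i] + 1L):tr$q_end[i]] <- TRUE
  }
  expect_equal(prof$covered_fraction, 100 * mean(covered))
})

test_that("chromosome summaries merge overlaps like a per-base oracle", {
  lens <- c(chr01 = 5000L, chr02 = 4000L)
  hits <- tibble::tibble(
    chrom = c("chr01", "chr01", "chr01", "chr02"),
    nuc_start = c(100L, 350L, 150L, 0L),
    nuc_end = c(200L, 550L, 400L, 300L),
    strand = "+", q_start = 0L, q_end = 1L, length = 1L, identity = 100,
    bitscore = 1, evalue = 0
  )
  sm <- chromosome_summary(hits, lens)
  # per-base brute force union
  oracle_bases <- function(ch) {
    v <- rep(FALSE, lens[ch])
    h <- hits[hits$chrom == ch, ]
    for (i in seq_len(nrow(h))) v[(h$nuc_start[i] + 1L):h$nuc_end[i]] <- TRUE
    sum(v)
  }
  expect_equal(sm$n_bases[sm$chrom == "chr01"], oracle_bases("chr01"))
  expect_equal(sm$n_bases[sm$chrom == "chr02"], oracle_bases("chr02"))
  expect_equal(sm$n_bases[sm$chrom == "total"],
               oracle_bases("chr01") + oracle_bases("chr02"))
  expect_equal(sum(sm$prop_insertions_pct[sm$chrom != "total"]), 100,
               tolerance = 0.02)
  # disjoint hits sum plainly
  h2 <- tibble::tibble(chrom = "chr01", nuc_start = c(0L, 200L),
                       nuc_end = c(100L, 400L), strand = "+", q_start = 0L,
                       q_end = 1L, length = 1L, identity = 100, bitscore = 1,
                       evalue = 0)
  expect_equal(chromosome_summary(h2, lens)$n_bases[1L], 300L)
  expect_error(chromosome_summary(
    dplyr::mutate(h2, chrom = "chrX"), lens), "unknown")
})
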