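# Junction profiles and parsimony mapping of IR boundary events.

toy_partition2 <- function() {
  dplyr::bind_rows(
    tibble::tibble(region = "LSC", start = 0L, end = 1000L, length = 1000L),
    tibble::tibble(region = "IRb", start = 1000L, end = 1400L, length = 400L),
    tibble::tibble(region = "SSC", start = 1400L, end = 1600L, length = 200L),
    tibble::tibble(region = "IRa", start = 1600L, end = 2000L, length = 400L)
  )
}

feat_row <- function(gene, start, end, id = gene, strand = "+") {
  tibble::tibble(feature_id = id, gene = gene, gene_class = "protein",
                 strand = strand, start = start, end = end, part = 1L,
                 pseudo = FALSE, anticodon = NA_character_)
}

test_that("gene states reflect IR membership, with partial genes at junctions", {
  part <- toy_partition2()
  feats <- dplyr::bind_rows(
    feat_row("rps15", 1050L, 1150L),                 # inside IRb
    feat_row("rps15", 1850L, 1950L, id = "rps15b"),  # inside IRa
    feat_row("ndhH", 1200L, 1300L),
    feat_row("ycf1", 1650L, 1800L),
    feat_row("ndhA", 1550L, 1700L),                  # spans SSC/IRa (JSA)
    feat_row("psbA", 100L, 400L)                     # single copy
  )
  prof <- profile_boundaries(feats, part, taxon = "toy")
  state <- stats::setNames(prof$state, prof$gene)
  expect_equal(unname(state[c("rps15", "ndhH", "ycf1")]),
               rep("complete_IR", 3))
  expect_equal(unname(state["ndhA"]), "partial_IR")
  expect_equal(prof$junction[prof$gene == "ndhA"], "JSA")
  expect_equal(unname(state["psbA"]), "SC")
  jg <- attr(prof, "junction_genes")
  expect_equal(jg$gene[jg$junction == "JSA"], "ndhA")
})

test_that("all-single-copy annotations profile as SC", {
  part <- toy_partition2()
  feats <- dplyr::bind_rows(feat_row("a", 10L, 100L), feat_row("b", 200L, 500L))
  prof <- profile_boundaries(feats, part)
  expect_true(all(prof$state == "SC"))
})

test_that("a gene across two junctions is a validation error", {
  part <- toy_partition2()
  expect_error(profile_boundaries(feat_row("huge", 900L, 1500L), part),
               "two junctions")
})

test_that("synthetic genomes profile according to generator truth", {
  p <- make_plastome(seed = 27)
  prof <- profile_boundaries(p$features, p$truth$partition, taxon = "sim")
  # rRNA genes were placed in the IR (both copies): complete_IR
  rrna <- unique(p$features$gene[p$features$gene_class == "rRNA"])
  expect_true(all(prof$state[prof$gene %in% rrna] == "complete_IR"))
  expect_true(all(prof$state[!prof$gene %in% rrna] == "SC"))
})

test_that("profile diffs report transitions, losses and gains", {
  ref <- tibble::tibble(gene = c("rps15", "ndhF", "accD"),
                        state = c("SC", "SC", "SC"))
  obs <- tibble::tibble(gene = c("rps15", "ndhF", "trnX"),
                        state = c("complete_IR", "SC", "SC"),
                        junction = c("JSA", NA, NA))
  expect_equal(nrow(diff_profiles(ref, ref)), 0L)
  d <- diff_profiles(obs, ref)
  expect_equal(d$change[d$gene == "rps15"], "transition")
  expect_equal(d$obs_state[d$gene == "rps15"], "complete_IR")
  expect_equal(d$change[d$gene == "accD"], "gene_loss")
  expect_equal(d$change[d$gene == "trnX"], "gene_gain")
})

test_that("simple topologies place events on the expected branches", {
  prof <- tibble::tibble(taxon = c("A", "B", "C"), gene = "g",
                         state = c("complete_IR", "complete_IR", "SC"))
  ev <- infer_events(prof, "((A,B),C);")
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$lengths$parsimony_length, 2)
  # the event sits on the stem of the (A,B) clade, not a terminal branch
  expect_false(ev$events$branch %in% c("A", "B", "C"))

  same <- tibble::tibble(taxon = c("A", "B", "C"), gene = "g", state = "SC")
  expect_equal(nrow(infer_events(same, "((A,B),C);")$events), 0L)

  star <- tibble::tibble(taxon = c("A", "B", "C"), gene = "g",
                         state = c("complete_IR", "SC", "SC"))
  evs <- infer_events(star, "(A,B,C);")
  expect_equal(evs$events$branch, "A")
  expect_equal(evs$lengths$parsimony_length, 2)
})

test_that("parsimony length equals exhaustive enumeration on trees up to 8 tips", {
  states <- c("SC", "partial_IR", "complete_IR")
  for (case in 1:12) {
    ntips <- 4L + (case %% 5L)
    tr <- random_tree(ntips, seed = 100 + case)
    withr::with_seed(200 + case, {
      tip_states <- sample(0:2, ntips, replace = TRUE)
    })
    prof <- tibble::tibble(taxon = tr$tip.label, gene = "g",
                           state = states[tip_states + 1L])
    ev <- infer_events(prof, tr, root_state = "SC")
    oracle <- oracle_parsimony_length(
      stats::setNames(tip_states, tr$tip.label)[tr$tip.label], tr, 0L, 3L)
    expect_equal(ev$lengths$parsimony_length, oracle)
    # the reported assignment's event costs sum to the parsimony length
    expect_equal(sum(ev$events$cost[ev$events$gene == "g"]),
                 as.integer(oracle))
  }
})

test_that("co-optimal assignments are counted and enumerable at equal cost", {
  # star with one complete, one SC and one partial tip has two optimal root
  # states (SC or partial_IR), both of length 3
  prof <- tibble::tibble(taxon = c("A", "B", "C"), gene = "g",
                         state = c("complete_IR", "SC", "partial_IR"))
  ev <- infer_events(prof, "(A,B,C);", enumerate = TRUE)
  expect_equal(ev$lengths$parsimony_length, 3)
  expect_equal(ev$lengths$n_optima, 2)
  opts <- ev$optima$g
  expect_equal(length(opts), 2L)
  costs <- vapply(opts, function(e) sum(e$cost), numeric(1))
  expect_true(all(costs == 3))
  # the reported (late-as-possible) optimum keeps the root at the reference
  expect_false("root-reference" %in% ev$events$parent)
})

test_that("the monocot fixture recovers three independent IR/SSC gains", {
  # topology following the monocot clades discussed for rps15: gains in the
  # derived Araceae, in Musa, and on the Poaceae stem
  tree <- paste0(
    "(Amborella,(Acorus,((Colocasia,Wolffia),(Dioscorea,(Musa,(Typha,",
    "(Anomochloa,(Panicoideae,(Bambusoideae,(Pooideae,Ehrhartoideae))))))))));"
  )
  complete <- c("Wolffia", "Musa", "Anomochloa", "Panicoideae", "Bambusoideae",
                "Pooideae", "Ehrhartoideae")
  taxa <- c("Amborella", "Acorus", "Colocasia", "Wolffia", "Dioscorea", "Musa",
            "Typha", "Anomochloa", "Panicoideae", "Bambusoideae", "Pooideae",
            "Ehrhartoideae")
  prof <- tibble::tibble(
    taxon = taxa, gene = "rps15",
    state = ifelse(taxa %in% complete, "complete_IR", "SC")
  )
  ev <- infer_events(prof, tree, root_state = "SC")
  gains <- ev$events[ev$events$to == "complete_IR", ]
  expect_equal(nrow(gains), 3L)
  expect_true("Wolffia" %in% gains$branch)
  expect_true("Musa" %in% gains$branch)
  # the third gain is on an internal (Poaceae stem) branch
  internal <- setdiff(gains$branch, c("Wolffia", "Musa"))
  expect_length(internal, 1L)
  expect_false(internal %in% taxa)
})
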