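# Deterministic synthetic-data generators.
#
# Every stage of the pipeline is testable without downloads: the generators
# produce a quadripartite circular plastome (desk-scale, about 1/50 of a real
# plastome: LSC 1.8 kb, IR 700 bp, SSC 250 bp by default, same topology),
# mate pairs drawn from the two SSC-orientation isoforms, nuclear chromosomes
# with planted plastid insertions, genotype tables, and read sets — each with
# its ground truth, and each a pure function of (parameters, seed).
#
# The generators guard the bases flanking planted structures (IR junctions,
# tandem arrays) so that the planted element is exactly maximal: the base
# just outside a planted IR never complements its mirror partner, and the
# base just outside a tandem array never continues the period. Without the
# guards, chance agreement (~25% per base) would extend detected elements a
# few bases past the planted truth.

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

random_bases <- function(n, base_comp) {
  sample(BASES, n, replace = TRUE, prob = base_comp)
}

# pick a base different from every base in `avoid`
base_not <- function(avoid) {
  sample(setdiff(BASES, avoid), 1L)
}

# sample `k` non-overlapping placement starts (0-based, local to a region of
# length region_len) for slots of the given lengths, with a 2-base margin
# between slots and to the region edges; `occupied` carries slots already
# placed in this region (repeats placed before genes, and vice versa)
allocate_slots <- function(region_len, lens) {
  k <- length(lens)
  if (k == 0L) return(integer(0))
  free <- region_len - sum(lens) - 2L * (k + 1L)
  if (free < 0L) stop("planted material exceeds region capacity", call. = FALSE)
  # stick-breaking: distribute the free bases over the k+1 gaps, place the
  # slots left to right in a random order
  gaps <- as.integer(stats::rmultinom(1L, free, rep(1, k + 1L)))
  perm <- sample.int(k)
  starts <- integer(k)
  cur <- 2L + gaps[1L]
  for (j in seq_len(k)) {
    starts[perm[j]] <- cur
    cur <- cur + lens[perm[j]] + 2L + gaps[j + 1L]
  }
  starts
}

random_cds <- function(n_codons) {
  paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Simulate a quadripartite circular plastome with ground truth
#'
#' Lays out `LSC + IRb + SSC + IRa` with IRa the exact reverse complement of
#' IRb, places non-overlapping genes (protein-coding genes in the LSC and
#' SSC, tRNA genes in the LSC, rRNA genes inside the IR and therefore
#' duplicated), and inserts the requested tandem repeats at recorded
#' positions. The same seed always yields identical bytes.
#'
#' @param lsc_len,ir_len,ssc_len region lengths in bases.
#' @param n_protein,n_trna,n_rrna gene counts per class.
#' @param intron_genes how many protein genes get two exons.
#' @param planted_repeats optional tibble with columns `motif`, `copies`
#'   (integer), `region` (`"LSC"`, `"SSC"` or `"IRb"`).
#' @param base_comp sampling probabilities for A, C, G, T.
#' @param seed mandatory integer seed.
#' @return a list with `seq` (the genome string), `features` (feature
#'   tibble), and `truth` (list: `partition`, `genes`, `repeats`).
#' @export
make_plastome <- function(lsc_len = 1800L, ir_len = 700L, ssc_len = 250L,
                          n_protein = 8L, n_trna = 4L, n_rrna = 2L,
                          intron_genes = 1L, planted_repeats = NULL,
                          base_comp = c(A = 0.31, C = 0.19, G = 0.18, T = 0.32),
                          seed) {
  stopifnot(lsc_len > 0L, ir_len > 0L, ssc_len > 0L,
            abs(sum(base_comp) - 1) < 1e-8)
  local_seed(seed, stream = 1L)
  lsc <- random_bases(lsc_len, base_comp)
  irb <- random_bases(ir_len, base_comp)
  ssc <- random_bases(ssc_len, base_comp)
  regions <- list(LSC = lsc, IRb = irb, SSC = ssc)

  # --- slot bookkeeping ----------------------------------------------------
  # all placements in a region (repeat arrays and gene slots) are requested
  # together and laid out by stick-breaking, so dense regions never fail
  n_ssc_protein <- min(2L, n_protein, max(0L, (ssc_len - 20L) %/% 200L))
  n_lsc_protein <- n_protein - n_ssc_protein
  cds_codons <- sample(25:45, n_protein, replace = TRUE)
  intron_lens <- integer(n_protein)
  if (intron_genes > 0L) intron_lens[seq_len(min(intron_genes, n_lsc_protein))] <-
    sample(30:80, min(intron_genes, n_lsc_protein), replace = TRUE)
  prot_slots_lsc <- 3L * cds_codons[seq_len(n_lsc_protein)] +
    intron_lens[seq_len(n_lsc_protein)]
  trna_len <- 72L
  rrna_len <- min(120L, max(60L, (ir_len - 20L) %/% max(1L, n_rrna) - 10L))

  if (!is.null(planted_repeats) && nrow(planted_repeats) > 0L) {
    planted_repeats <- dplyr::mutate(
      planted_repeats,
      unit_len = nchar(.data$motif),
      array_len = as.integer(ceiling(.data$unit_len * .data$copies))
    )
  } else {
    planted_repeats <- NULL
  }
  rep_lens <- function(reg) {
    if (is.null(planted_repeats)) integer(0) else
      planted_repeats$array_len[planted_repeats$region == reg]
  }
  region_lens <- list(
    LSC = c(rep_lens("LSC"), prot_slots_lsc, rep(trna_len, n_trna)),
    IRb = c(rep_lens("IRb"), rep(rrna_len, n_rrna)),
    SSC = c(rep_lens("SSC"),
            if (n_ssc_protein > 0L) 3L * cds_codons[n_lsc_protein + seq_len(n_ssc_protein)]
            else integer(0))
  )
  slot_starts <- purrr::imap(region_lens,
                             ~ allocate_slots(length(regions[[.y]]), .x))

  # --- plant tandem repeats ------------------------------------------------
  rep_truth <- NULL
  if (!is.null(planted_repeats)) {
    rep_rows <- list()
    used <- c(LSC = 0L, IRb = 0L, SSC = 0L)
    for (i in seq_len(nrow(planted_repeats))) {
      reg <- planted_repeats$region[i]
      used[reg] <- used[reg] + 1L
      s <- slot_starts[[reg]][used[reg]]
      u <- planted_repeats$unit_len[i]
      alen <- planted_repeats$array_len[i]
      motif <- seq_chars(planted_repeats$motif[i])
      array <- rep(motif, length.out = alen)
      regions[[reg]][s + seq_len(alen)] <- array
      # period-breaking guards on both flanks
      regions[[reg]][s] <- base_not(motif[u])
      regions[[reg]][s + alen + 1L] <- base_not(array[alen - u + 1L])
      rep_rows[[length(rep_rows) + 1L]] <- tibble::tibble(
        motif = planted_repeats$motif[i], unit_len = u,
        copies = planted_repeats$copies[i], region = reg, local_start = s
      )
    }
    rep_truth <- dplyr::bind_rows(rep_rows)
  }
  gene_starts <- purrr::imap(slot_starts, function(st, reg) {
    nrep <- length(rep_lens(reg))
    if (nrep > 0L) st[-seq_len(nrep)] else st
  })

  # --- place genes ---------------------------------------------------------
  feats <- list()
  add_feature <- function(id, gene, cls, strand, starts, ends, anticodon = NA_character_) {
    df <- tibble::tibble(
      feature_id = id, gene = gene, gene_class = cls, strand = strand,
      start = as.integer(starts), end = as.integer(ends),
      part = seq_along(starts), pseudo = FALSE, anticodon = anticodon
    )
    if (strand == "-") df$part <- rev(df$part)
    feats[[length(feats) + 1L]] <<- df
  }
  write_gene <- function(reg, local_start, cds, strand, intron_len = 0L, exon1 = NULL) {
    # returns local half-open exon intervals after writing the sequence
    chars <- seq_chars(if (strand == "-") revcomp(cds) else cds)
    if (intron_len == 0L) {
      regions[[reg]][local_start + seq_along(chars)] <<- chars
      list(starts = local_start, ends = local_start + length(chars))
    } else {
      # genomic layout: exon_a | intron | exon_b; on "-" the 5' exon is exon_b
      e1 <- exon1
      ga <- local_start
      gb <- local_start + e1 + intron_len
      regions[[reg]][ga + seq_len(e1)] <<- chars[seq_len(e1)]
      regions[[reg]][gb + seq_len(length(chars) - e1)] <<- chars[-seq_len(e1)]
      list(starts = c(ga, gb), ends = c(ga + e1, gb + length(chars) - e1))
    }
  }

  lsc_starts <- gene_starts[["LSC"]]
  anticodons <- sample(c("CAT", "TAA", "GAA", "TTC", "GCT", "TGC", "GTG", "TCT"),
                       n_trna)
  gi <- 0L
  for (i in seq_len(n_lsc_protein)) {
    gi <- gi + 1L
    strand <- sample(c("+", "-"), 1L)
    cds <- random_cds(cds_codons[i])
    e1 <- if (intron_lens[i] > 0L) 3L * sample(10:(cds_codons[i] - 10L), 1L) else NULL
    iv <- write_gene("LSC", lsc_starts[i], cds, strand, intron_lens[i], e1)
    add_feature(sprintf("g%02d", gi), sprintf("psb%02d", gi), "protein", strand,
                iv$starts, iv$ends)
  }
  for (j in seq_len(n_trna)) {
    gi <- gi + 1L
    strand <- sample(c("+", "-"), 1L)
    s <- lsc_starts[n_lsc_protein + j]
    add_feature(sprintf("g%02d", gi), sprintf("trn%02d", j), "tRNA", strand,
                s, s + trna_len, anticodon = anticodons[j])
  }
  if (n_ssc_protein > 0L) {
    ssc_idx <- n_lsc_protein + seq_len(n_ssc_protein)
    ssc_starts <- gene_starts[["SSC"]]
    for (i in seq_len(n_ssc_protein)) {
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1L)
      cds <- random_cds(cds_codons[ssc_idx[i]])
      iv <- write_gene("SSC", ssc_starts[i], cds, strand)
      add_feature(sprintf("g%02d", gi), sprintf("ndh%02d", i), "protein", strand,
                  iv$starts, iv$ends)
    }
  }
  rrna_local <- gene_starts[["IRb"]]
  for (i in seq_len(n_rrna)) {
    gi <- gi + 1L
    strand <- sample(c("+", "-"), 1L)
    s <- rrna_local[i]
    seqr <- random_bases(rrna_len, base_comp)
    regions[["IRb"]][s + seq_len(rrna_len)] <- seqr
    add_feature(sprintf("g%02d", gi), sprintf("rrn%02d", i), "rRNA", strand,
                s, s + rrna_len)
  }

  # --- junction guards, assembly, coordinates ------------------------------
  # break chance complementarity across both IR junction pairs so the
  # detected IR equals the planted IR exactly
  regions$LSC[1L] <- base_not(COMP[regions$LSC[lsc_len]])
  regions$SSC[ssc_len] <- base_not(COMP[regions$SSC[1L]])
  irb_str <- paste(regions$IRb, collapse = "")
  genome <- paste0(paste(regions$LSC, collapse = ""), irb_str,
                   paste(regions$SSC, collapse = ""), revcomp(irb_str))
  n <- nchar(genome)
  offs <- c(LSC = 0L, IRb = lsc_len, SSC = lsc_len + ir_len)

  # features were added with region-local coordinates; shift by region offset
  to_genome <- function(df, reg) {
    df$start <- df$start + offs[[reg]]
    df$end <- df$end + offs[[reg]]
    df
  }
  regions_of_feats <- c(rep("LSC", n_lsc_protein + n_trna),
                        rep("SSC", n_ssc_protein), rep("IRb", n_rrna))
  features <- dplyr::bind_rows(purrr::map2(feats, regions_of_feats, to_genome))
  # mirror IR genes into IRa (same name, new feature id, flipped strand)
  ira_start <- lsc_len + ir_len + ssc_len
  irb_start <- lsc_len
  ir_feats <- features[features$start >= irb_start &
                         features$end <= irb_start + ir_len, , drop = FALSE]
  if (nrow(ir_feats) > 0L) {
    mirrored <- ir_feats
    mirrored$feature_id <- paste0(ir_feats$feature_id, "_ira")
    news <- ira_start + (irb_start + ir_len - ir_feats$end)
    newe <- ira_start + (irb_start + ir_len - ir_feats$start)
    mirrored$start <- as.integer(news)
    mirrored$end <- as.integer(newe)
    mirrored$strand <- ifelse(ir_feats$strand == "+", "-", "+")
    features <- dplyr::bind_rows(features, mirrored)
  }
  features <- dplyr::arrange(features, .data$start, .data$feature_id, .data$part)

  partition <- dplyr::bind_rows(
    region_tbl("LSC", 0L, lsc_len, n),
    region_tbl("IRb", lsc_len, ir_len, n),
    region_tbl("SSC", lsc_len + ir_len, ssc_len, n),
    region_tbl("IRa", ira_start, ir_len, n)
  )
  if (!is.null(rep_truth)) {
    rep_truth$start <- as.integer(rep_truth$local_start + offs[rep_truth$region])
    rep_truth$end <- as.integer(rep_truth$start + rep_truth$unit_len * rep_truth$copies)
    rep_truth$repeat_class <- ifelse(rep_truth$unit_len <= 6L, "micro", "mini")
    rep_truth$local_start <- NULL
  }
  list(
    seq = genome,
    features = features,
    truth = list(partition = partition, genes = features, repeats = rep_truth)
  )
}

#' Simulate SSC-orientation isoform mate pairs
#'
#' Each pair is drawn (by a seeded coin with probability `form_b_fraction`)
#' from form A — the reference layout — or form B, the molecule with its SSC
#' reverse-complemented in place. Inserts bridge the LSC and the SSC across
#' IRb, so one mate lies wholly in the LSC and the other wholly in the SSC.
#' Mates are reported as alignments to the form-A reference with identity
#' 100 and full coverage; form-B SSC mates therefore map at the mirrored SSC
#' position with flipped strand, producing FF/RR orientation classes.
#'
#' @param genome plastome string in canonical orientation.
#' @param partition its partition tibble.
#' @param n_pairs number of mate pairs.
#' @param form_b_fraction probability a pair comes from form B.
#' @param insert_len physical insert length (defaults to a value that spans
#'   IRb with both mates inside their single-copy regions).
#' @param read_len mate length.
#' @param seed integer seed.
#' @return list with `alignments` (tibble: `pair_id`, `mate`, `start`,
#'   `end`, `strand`, `identity`, `coverage`, `n_loci`) and `truth`
#'   (tibble: `pair_id`, `form`).
#' @export
make_isoform_mate_pairs <- function(genome, partition, n_pairs = 200L,
                                    form_b_fraction = 0.5, insert_len = NULL,
                                    read_len = 100L, seed) {
  stopifnot(form_b_fraction >= 0, form_b_fraction <= 1)
  n <- nchar(genome)
  L <- region_interval(partition, "LSC")$length
  I <- region_interval(partition, "IRb")$length
  S <- region_interval(partition, "SSC")$length
  if (is.null(insert_len)) insert_len <- I + 2L * read_len + max(10L, S %/% 4L)
  if (insert_len > n) stop("insert_len exceeds genome length", call. = FALSE)
  a_lo <- max(0L, L + I + read_len - insert_len)
  a_hi <- min(L - read_len, L + I + S - insert_len)
  if (a_hi < a_lo) {
    stop("insert_len cannot bridge LSC and SSC with both mates in single-copy regions",
         call. = FALSE)
  }
  local_seed(seed, stream = 2L)
  a <- resample(a_lo:a_hi, n_pairs, replace = TRUE)
  plus <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
  form_b <- stats::runif(n_pairs) < form_b_fraction
  ssc_start <- L + I
  ssc_end <- L + I + S

  s1 <- a; e1 <- a + read_len
  st1 <- ifelse(plus, "F", "R")
  s2 <- a + insert_len - read_len; e2 <- a + insert_len
  st2 <- ifelse(plus, "R", "F")
  # form B: mirror the SSC mate within the SSC and flip its strand
  s2b <- ssc_start + (ssc_end - e2)
  e2b <- ssc_start + (ssc_end - s2)
  s2 <- ifelse(form_b, s2b, s2)
  e2 <- ifelse(form_b, e2b, e2)
  st2 <- ifelse(form_b, ifelse(st2 == "F", "R", "F"), st2)

  pair_id <- sprintf("pair%04d", seq_len(n_pairs))
  # randomise which mate is listed first so classification cannot depend on
  # file order
  first_is_lsc <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
  aln <- tibble::tibble(
    pair_id = rep(pair_id, each = 2L),
    mate = rep(1:2, n_pairs),
    start = as.integer(ifelse(rep(first_is_lsc, each = 2L) == (rep(1:2, n_pairs) == 1L),
                              rep(s1, each = 2L), rep(s2, each = 2L))),
    end = as.integer(ifelse(rep(first_is_lsc, each = 2L) == (rep(1:2, n_pairs) == 1L),
                            rep(e1, each = 2L), rep(e2, each = 2L))),
    strand = ifelse(rep(first_is_lsc, each = 2L) == (rep(1:2, n_pairs) == 1L),
                    rep(st1, each = 2L), rep(st2, each = 2L)),
    identity = 100, coverage = 1, n_loci = 1L
  )
  list(alignments = aln,
       truth = tibble::tibble(pair_id = pair_id, form = ifelse(form_b, "B", "A")))
}

mutate_fragment <- function(frag, rate) {
  if (rate == 0) return(frag)
  ch <- seq_chars(frag)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- base_not(ch[i])
  paste(ch, collapse = "")
}

#' Simulate nuclear chromosomes with planted plastid insertions (NUPTs)
#'
#' Draws fragments from the IR-stripped plastome (LSC+IRb+SSC), mutates them
#' with substitutions at `divergence_rate`, and splices them into random
#' background chromosomes at recorded positions. Truth lists both coordinate
#' systems.
#'
#' @param genome plastome string in canonical orientation.
#' @param partition its partition tibble.
#' @param n_chrom,chrom_len background chromosome count and length.
#' @param n_insertions number of planted fragments.
#' @param len_range fragment length range (sampled uniformly).
#' @param divergence_rate per-base substitution rate (< 0.2).
#' @param seed integer seed.
#' @return list with `chromosomes` (tibble `id`, `seq`, `length`) and
#'   `truth` (tibble: `chrom`, `nuc_start`, `nuc_end`, `q_start`, `q_end`,
#'   `strand`, `length`).
#' @export
make_nuclear_with_nupts <- function(genome, partition, n_chrom = 2L,
                                    chrom_len = 6000L, n_insertions = 6L,
                                    len_range = c(150L, 600L),
                                    divergence_rate = 0.02, seed) {
  stopifnot(divergence_rate < 0.2)
  if (max(len_range) > chrom_len) stop("insertion longer than chromosome", call. = FALSE)
  local_seed(seed, stream = 3L)
  stripped_len <- sum(partition$length) - region_interval(partition, "IRa")$length
  stripped <- substr(genome, 1L, stripped_len)
  backgrounds <- purrr::map(seq_len(n_chrom),
                            ~ random_bases(chrom_len, rep(0.25, 4L)))
  truth <- NULL
  if (n_insertions > 0L) {
    lens <- resample(len_range[1L]:len_range[2L], n_insertions, replace = TRUE)
    chrom <- sample(n_chrom, n_insertions, replace = TRUE)
    qs <- vapply(lens, function(l) resample(0:(stripped_len - l)), integer(1))
    strand <- sample(c("+", "-"), n_insertions, replace = TRUE)
    # splice points in background coordinates, kept apart per chromosome
    truth <- tibble::tibble(chrom_i = chrom, chrom = sprintf("chr%02d", chrom_i),
                            q_start = qs, q_end = qs + lens, strand = strand,
                            length = lens)
    truth <- truth[order(truth$chrom_i), , drop = FALSE]
    nuc_start <- integer(nrow(truth))
    chroms <- list()
    for (ci in seq_len(n_chrom)) {
      rows <- which(truth$chrom_i == ci)
      k <- length(rows)
      bg <- backgrounds[[ci]]
      if (k == 0L) {
        chroms[[ci]] <- paste(bg, collapse = "")
        next
      }
      cuts <- sort(sample(100:(chrom_len - 100L), k))
      pieces <- character(0)
      prev <- 0L
      added <- 0L
      for (j in seq_len(k)) {
        qs <- truth$q_start[rows[j]]
        qe <- truth$q_end[rows[j]]
        frag <- substr(stripped, qs + 1L, qe)
        minus <- truth$strand[rows[j]] == "-"
        if (minus) frag <- revcomp(frag)
        frag <- mutate_fragment(frag, divergence_rate)
        # continuation guards: the background bases flanking the splice must
        # not extend the alignment into the query, so the planted fragment
        # is exactly maximal
        qprev <- if (qs > 1L) seq_chars(substr(stripped, qs - 1L, qs)) else NULL
        qnext <- if (qe + 2L <= stripped_len) {
          seq_chars(substr(stripped, qe + 1L, qe + 2L))
        } else {
          NULL
        }
        # two guard bases per flank: crossing them costs two mismatches,
        # which the X-drop extension essentially never recovers from
        left_avoid <- if (minus) rev(unname(COMP[qnext])) else qprev
        right_avoid <- if (minus) rev(unname(COMP[qprev])) else qnext
        if (!is.null(left_avoid)) {
          bg[cuts[j]] <- base_not(left_avoid[2L])
          bg[cuts[j] - 1L] <- base_not(left_avoid[1L])
        }
        if (!is.null(right_avoid)) {
          bg[cuts[j] + 1L] <- base_not(right_avoid[1L])
          bg[cuts[j] + 2L] <- base_not(right_avoid[2L])
        }
        pieces <- c(pieces, paste(bg[(prev + 1L):cuts[j]], collapse = ""), frag)
        nuc_start[rows[j]] <- cuts[j] + added
        added <- added + nchar(frag)
        prev <- cuts[j]
      }
      pieces <- c(pieces, paste(bg[(prev + 1L):chrom_len], collapse = ""))
      chroms[[ci]] <- paste(pieces, collapse = "")
    }
    truth$nuc_start <- nuc_start
    truth$nuc_end <- nuc_start + truth$length
    truth$chrom_i <- NULL
    truth <- truth[, c("chrom", "nuc_start", "nuc_end", "q_start", "q_end",
                       "strand", "length")]
  } else {
    chroms <- purrr::map(backgrounds, paste, collapse = "")
  }
  chromosomes <- tibble::tibble(
    id = sprintf("chr%02d", seq_len(n_chrom)),
    seq = unlist(chroms),
    length = nchar(unlist(chroms))
  )
  list(chromosomes = chromosomes, truth = truth)
}

#' Simulate a genotype table with nested accession groups
#'
#' Accession groups are nested (each group is a prefix of the previous one,
#' mirroring a taxonomy such as family > section > species > cytoplasm
#' group). For each marker a planted number of distinct alleles is assigned
#' within the outermost group, every planted allele appearing at least once.
#'
#' @param n_markers number of markers.
#' @param group_sizes nested group sizes, non-increasing; the first is the
#'   total accession count.
#' @param allele_pool integer fragment lengths to draw alleles from.
#' @param n_alleles optional planted distinct-allele count per marker in the
#'   outermost group (defaults to a seeded draw from 2:5).
#' @param seed integer seed.
#' @return list with `table` (tibble, accessions x markers), `groups`
#'   (named list of accession ids), `truth` (tibble: `marker`,
#'   `n_alleles_outer`).
#' @export
make_genotype_table <- function(n_markers = 12L, group_sizes = c(10L, 9L, 8L, 6L),
                                allele_pool = 180:260, n_alleles = NULL, seed) {
  stopifnot(all(group_sizes >= 1L), all(diff(group_sizes) <= 0L))
  local_seed(seed, stream = 4L)
  n_acc <- group_sizes[1L]
  acc <- sprintf("acc%02d", seq_len(n_acc))
  if (is.null(n_alleles)) {
    n_alleles <- sample(2:min(5L, n_acc), n_markers, replace = TRUE)
  }
  stopifnot(length(n_alleles) == n_markers, all(n_alleles <= n_acc))
  markers <- sprintf("mk%02d", seq_len(n_markers))
  cols <- purrr::map(seq_len(n_markers), function(j) {
    k <- n_alleles[j]
    alleles <- sample(allele_pool, k)
    assign_to <- sample(n_acc)
    out <- integer(n_acc)
    out[assign_to[seq_len(k)]] <- alleles
    rest <- assign_to[-seq_len(k)]
    if (length(rest) > 0L) out[rest] <- sample(alleles, length(rest), replace = TRUE)
    out
  })
  tbl <- tibble::as_tibble(stats::setNames(cols, markers))
  tbl <- dplyr::bind_cols(tibble::tibble(accession = acc), tbl)
  groups <- stats::setNames(
    purrr::map(group_sizes, ~ acc[seq_len(.x)]),
    paste0("group", seq_along(group_sizes))
  )
  list(table = tbl, groups = groups,
       truth = tibble::tibble(marker = markers, n_alleles_outer = n_alleles))
}

#' Simulate a labelled read set from plastid and nuclear sources
#'
#' Single-end reads drawn from the (circularly doubled) plastome or from
#' nuclear chromosomes, with seeded substitution errors and truth origin
#' labels.
#'
#' @param genome plastome string (circular).
#' @param nuclear optional chromosome tibble (`id`, `seq`); a random decoy
#'   chromosome is generated when absent.
#' @param plastid_fraction fraction of reads of plastid origin (in (0,1)).
#' @param n_reads,read_len read count and length.
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return tibble with `read_id`, `seq`, `origin`.
#' @export
make_read_set <- function(genome, nuclear = NULL, plastid_fraction = 0.5,
                          n_reads = 400L, read_len = 100L, error_rate = 0,
                          seed) {
  stopifnot(plastid_fraction > 0, plastid_fraction < 1)
  n <- nchar(genome)
  if (read_len > n) stop("read_len exceeds source length", call. = FALSE)
  local_seed(seed, stream = 5L)
  if (is.null(nuclear)) {
    nuclear <- tibble::tibble(
      id = "decoy01",
      seq = paste(random_bases(5000L, rep(0.25, 4L)), collapse = "")
    )
  }
  if (read_len > min(nchar(nuclear$seq))) {
    stop("read_len exceeds source length", call. = FALSE)
  }
  doubled <- paste0(genome, genome)
  is_plastid <- stats::runif(n_reads) < plastid_fraction
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (is_plastid[i]) {
      s <- resample(0:(n - 1L))
      r <- substr(doubled, s + 1L, s + read_len)
    } else {
      ci <- sample(nrow(nuclear), 1L)
      cl <- nchar(nuclear$seq[ci])
      s <- resample(0:(cl - read_len))
      r <- substr(nuclear$seq[ci], s + 1L, s + read_len)
    }
    if (sample(c(TRUE, FALSE), 1L)) r <- revcomp(r)
    reads[i] <- mutate_fragment(r, error_rate)
  }
  tibble::tibble(
    read_id = sprintf("read%05d", seq_len(n_reads)),
    seq = reads,
    origin = ifelse(is_plastid, "plastid", "nuclear")
  )
}
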