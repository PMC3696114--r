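# Quadripartite structure: IR detection, canonical orientation, statistics.
#
# Plastomes carry two near-identical inverted repeats (IRa/IRb) separating a
# large and a small single-copy region. detect_inverted_repeat() finds the
# maximal pair of disjoint intervals whose sequences are reverse complements
# of each other (within a mismatch tolerance) by exact k-mer seeding against
# the reverse complement followed by ungapped extension along the
# anti-diagonal. The shorter gap between the two copies is the SSC, the
# longer the LSC; "IRb" is the copy that follows the LSC in canonical
# orientation.

region_tbl <- function(region, start, length, n) {
  tibble::tibble(
    region = region,
    start = as.integer(start %% n),
    end = as.integer((start + length - 1L) %% n + 1L),
    length = as.integer(length)
  )
}

#' Detect the inverted-repeat pair of a circular plastome
#'
#' Seeds exact `k`-mer matches between the sequence and its reverse
#' complement, groups them by anti-diagonal, and extends the longest exact
#' run on each anti-diagonal across isolated mismatches while the overall
#' mismatch rate stays at or below `max_mismatch_rate` and the two mirror
#' copies stay disjoint. Ties on IR length are broken by fewest mismatches,
#' then smallest start. The result is invariant (up to rotation) to where
#' the circular record starts.
#'
#' @param seq circular genome sequence (single string).
#' @param min_ir_len minimum IR length to accept (>= 50).
#' @param max_mismatch_rate tolerated mismatch fraction inside the IR.
#' @param k seed k-mer length.
#' @return a partition tibble with rows `LSC`, `IRb`, `SSC`, `IRa` and
#'   columns `region`, `start`, `end` (0-based half-open, `end <= start`
#'   denotes an origin-wrapping interval), `length`.
#' @export
detect_inverted_repeat <- function(seq, min_ir_len = 50L, max_mismatch_rate = 0.005,
                                   k = 21L) {
  n <- nchar(seq)
  stopifnot(min_ir_len >= 50L, n > 2L * k)
  x <- seq_chars(seq)
  cx <- comp_chars(x)
  doubled <- paste0(seq, substr(seq, 1L, k))
  kmers <- substring(doubled, 1:n, 1:n + k - 1L)
  rc <- revcomp(seq)
  rc_doubled <- paste0(rc, substr(rc, 1L, k))
  rc_kmers <- substring(rc_doubled, 1:n, 1:n + k - 1L)

  # seed pairs (i, j), 0-based: seq[i, i+k) == revcomp(seq[j, j+k)).
  # position p (0-based) on the reverse complement corresponds to
  # j = n - p - k (mod n) on the forward sequence; every matched pair lies on
  # the anti-diagonal d = i + j + k (mod n), which is invariant under
  # extension.
  idx <- split(0:(n - 1L), kmers)
  hit <- rc_kmers %in% names(idx)
  if (!any(hit)) stop_no_quadripartite()
  diagonals <- integer(0)
  for (p in which(hit) - 1L) {
    j <- (n - p - k) %% n
    i <- idx[[rc_kmers[p + 1L]]]
    diagonals <- c(diagonals, (i + j + k) %% n)
  }
  diag_tab <- sort(table(diagonals), decreasing = TRUE)
  diag_ids <- as.integer(names(diag_tab))
  # cap the anti-diagonals examined; the IR diagonal dominates the seed count
  diag_ids <- utils::head(diag_ids, 50L)

  best <- NULL
  for (d in diag_ids) {
    cand <- best_ir_on_diagonal(x, cx, d, n, max_mismatch_rate)
    if (is.null(cand)) next
    if (is.null(best) ||
        cand$len > best$len ||
        (cand$len == best$len && cand$mm < best$mm) ||
        (cand$len == best$len && cand$mm == best$mm && cand$a < best$a)) {
      best <- cand
    }
  }
  if (is.null(best) || best$len < min_ir_len) stop_no_quadripartite()
  partition_from_pair(best$a, best$len, best$d, n)
}

stop_no_quadripartite <- function() {
  rlang::abort("no quadripartite structure: no inverted repeat at or above min_ir_len",
               class = "plastomics_no_quadripartite")
}

# Best tolerated inverted-repeat window on anti-diagonal d.
# The anti-diagonal match profile m[t] (0-based t) tells whether base t pairs
# with the complement of base (d - t - 1) mod n. The profile is symmetric
# under the mirror t -> d - 1 - t, so a window and its mirror image are the
# two IR copies; extension stops before the copies would collide.
best_ir_on_diagonal <- function(x, cx, d, n, rate) {
  t <- 0:(n - 1L)
  u <- (d - t - 1L) %% n
  m <- x[t + 1L] == cx[u + 1L]
  if (!any(m)) return(NULL)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], len = r$lengths[r$values])
  if (nrow(runs) == 0L) return(NULL)
  # circular wrap: merge a run touching position n with one starting at 1
  if (m[1L] && m[n] && nrow(runs) > 1L) {
    first <- which(runs$start == 1L)
    last <- which(runs$start + runs$len - 1L == n)
    if (length(first) == 1L && length(last) == 1L && first != last) {
      runs$len[last] <- runs$len[last] + runs$len[first]
      runs <- runs[-first, , drop = FALSE]
    }
  }
  seedrow <- which.max(runs$len)
  a <- runs$start[seedrow] - 1L     # 0-based inclusive window start
  len <- runs$len[seedrow]
  mm <- 0L
  ok <- function(a, len, mm) {
    # window [a, a+len) (mod n) and its mirror must be disjoint and the
    # mismatch budget respected
    if (mm > rate * len) return(FALSE)
    b <- a + len - 1L                       # inclusive end (not reduced mod n)
    a2 <- (d - 1L - b) %% n                 # mirror start
    if (len > n %/% 2L) return(FALSE)
    gap1 <- (a2 - (b %% n) - 1L) %% n       # bases strictly between the copies
    gap2 <- n - 2L * len - gap1
    gap1 >= 0L && gap2 >= 0L && (gap1 + gap2 + 2L * len == n)
  }
  if (!ok(a, len, mm)) {
    # degenerate seed (self-overlapping palindromic window): shrink
    while (len > 0L && !ok(a, len, mm)) len <- len - 2L
    if (len <= 0L) return(NULL)
  }
  # greedy bridge: absorb the nearest mismatch gap plus following exact run,
  # on whichever side keeps the mismatch rate within budget
  repeat {
    extended <- FALSE
    for (side in c("right", "left")) {
      b <- a + len                          # next position to the right (0-based)
      probe <- if (side == "right") b else a - 1L
      pm <- m[(probe %% n) + 1L]
      if (isTRUE(pm)) {
        # adjacent exact base (possible after wrap merge edge cases)
        if (ok(if (side == "left") a - 1L else a, len + 1L, mm)) {
          if (side == "left") a <- a - 1L
          len <- len + 1L
          extended <- TRUE
          next
        }
      }
      # look past a short mismatch gap for the next exact run
      g <- 0L
      while (g < 10L && !isTRUE(m[((probe + if (side == "right") g else -g) %% n) + 1L])) {
        g <- g + 1L
      }
      if (g == 0L || g >= 10L) next
      run <- 0L
      repeat {
        pos <- if (side == "right") probe + g + run else probe - g - run
        if (!isTRUE(m[(pos %% n) + 1L])) break
        run <- run + 1L
        if (run + len + g >= n %/% 2L) break
      }
      # only bridge a mismatch gap when the exact run beyond it is long
      # enough to be signal rather than the ~25% background identity of
      # unrelated sequence; this stops extension dead at the true IR boundary
      if (run < max(2L * g, 10L)) next
      new_len <- len + g + run
      new_a <- if (side == "left") a - g - run else a
      if (ok(new_a, new_len, mm + g)) {
        a <- new_a
        len <- new_len
        mm <- mm + g
        extended <- TRUE
      }
    }
    if (!extended) break
  }
  list(a = a %% n, len = len, mm = mm, d = d)
}

# build the canonical partition tibble from one IR copy [a, a+len) on
# anti-diagonal d of a circle of size n
partition_from_pair <- function(a, len, d, n) {
  b <- a + len - 1L
  a2 <- (d - 1L - b) %% n
  gap1 <- (a2 - ((b + 1L) %% n)) %% n      # after copy 1, before copy 2
  gap2 <- n - 2L * len - gap1              # after copy 2, before copy 1
  ir1 <- a
  ir2 <- a2
  if (gap1 <= gap2) {
    # gap1 is the SSC: layout ... LSC, IR1(=IRb), SSC, IR2(=IRa) ...
    lsc_start <- (ir2 + len) %% n
    dplyr::arrange(
      dplyr::bind_rows(
        region_tbl("LSC", lsc_start, gap2, n),
        region_tbl("IRb", ir1, len, n),
        region_tbl("SSC", (ir1 + len) %% n, gap1, n),
        region_tbl("IRa", ir2, len, n)
      ),
      factor(.data$region, levels = c("LSC", "IRb", "SSC", "IRa"))
    )
  } else {
    lsc_start <- (ir1 + len) %% n
    dplyr::arrange(
      dplyr::bind_rows(
        region_tbl("LSC", lsc_start, gap1, n),
        region_tbl("IRb", ir2, len, n),
        region_tbl("SSC", (ir2 + len) %% n, gap2, n),
        region_tbl("IRa", ir1, len, n)
      ),
      factor(.data$region, levels = c("LSC", "IRb", "SSC", "IRa"))
    )
  }
}

partition_genome_length <- function(partition) {
  sum(partition$length)
}

region_interval <- function(partition, region) {
  r <- partition[partition$region == region, , drop = FALSE]
  list(start = r$start, end = r$end, length = r$length)
}

#' Rotate a circular record into canonical orientation
#'
#' Rotates the sequence so the layout along the forward strand is
#' `LSC, IRb, SSC, IRa` with the LSC starting at position 0, and remaps the
#' partition and all features accordingly. Content is preserved up to
#' rotation; applying the function to an already-canonical record is the
#' identity. The two flip-flop forms of the SSC are both valid canonical
#' layouts (the orientation of the SSC is not an invariant of the molecule).
#'
#' @param seq genome sequence.
#' @param partition partition tibble from [detect_inverted_repeat()].
#' @param features optional feature tibble to remap.
#' @return a list with `seq`, `partition`, `features`, `rotation` (bases the
#'   origin moved by).
#' @export
canonicalize <- function(seq, partition, features = NULL) {
  n <- nchar(seq)
  stopifnot(partition_genome_length(partition) == n)
  r <- region_interval(partition, "LSC")$start
  new_seq <- if (r == 0L) seq else
    paste0(substr(seq, r + 1L, n), substr(seq, 1L, r))
  shift <- function(start, end) {
    ns <- (start - r) %% n
    ne <- (end - 1L - r) %% n + 1L
    list(start = as.integer(ns), end = as.integer(ne))
  }
  part2 <- partition
  for (i in seq_len(nrow(part2))) {
    s <- shift(part2$start[i], part2$end[i])
    part2$start[i] <- s$start
    part2$end[i] <- s$end
  }
  feats2 <- features
  if (!is.null(features) && nrow(features) > 0L) {
    moved <- purrr::map(seq_len(nrow(features)),
                        ~ shift(features$start[.x], features$end[.x]))
    feats2$start <- vapply(moved, `[[`, integer(1), "start")
    feats2$end <- vapply(moved, `[[`, integer(1), "end")
  }
  list(seq = new_seq, partition = part2, features = feats2, rotation = r)
}

#' Count in-frame internal stop codons of a CDS
#'
#' Counts `TAA`/`TAG`/`TGA` in frame 0, excluding the final codon. A length
#' that is not a multiple of 3 is flagged "frame-broken" with a warning and
#' counted after truncation. One or more internal stops is the package's
#' pseudogene diagnostic.
#'
#' @param cds coding sequence (single string).
#' @return integer count of internal stop codons.
#' @export
detect_internal_stops <- function(cds) {
  n <- nchar(cds)
  broken <- n %% 3L != 0L
  if (broken) {
    warning("frame-broken CDS: length not divisible by 3; counting with truncation",
            call. = FALSE)
    n <- n - n %% 3L
  }
  if (n < 3L) return(0L)
  # a frame-broken CDS has no terminal stop: every complete codon is internal
  last <- if (broken) n - 2L else n - 5L
  if (last < 1L) return(0L)
  starts <- seq.int(1L, last, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  sum(codons %in% c("TAA", "TAG", "TGA"))
}

#' Quadripartite statistics panel
#'
#' Computes the standard plastome characteristics table: region sizes and
#' percentages, sizes and GC content of the sequence classes, and gene
#' counts. Every base is assigned exactly one class with priority
#' exon (protein > tRNA > rRNA) > intron > intergenic spacer (IGS); an
#' intron is the gap between consecutive exons of one feature. IR copies of
#' a gene share a name and are counted once; "duplicated by IR" means at
#' least two copies lie entirely within the IR intervals. Pseudogenes are
#' excluded from gene counts and their exons are not coding.
#'
#' @param seq genome sequence (canonical orientation).
#' @param partition partition tibble.
#' @param features feature tibble.
#' @return a tibble with columns `metric`, `value`, `percent` (percent of
#'   genome size, 1 decimal, half away from zero, where applicable).
#' @export
partition_stats <- function(seq, partition, features) {
  n <- nchar(seq)
  stopifnot(partition_genome_length(partition) == n)
  x <- seq_chars(seq)
  # class codes: 0 IGS, 1 intron, 2 rRNA, 3 tRNA, 4 protein
  cls <- integer(n)
  feats <- features[!features$pseudo, , drop = FALSE]
  prio <- c(protein = 4L, tRNA = 3L, rRNA = 2L)
  # lay down introns first, then exons by increasing priority so that higher
  # priority classes overwrite lower ones
  for (fid in unique(feats$feature_id)) {
    df <- feats[feats$feature_id == fid, , drop = FALSE]
    if (nrow(df) < 2L) next
    df <- df[order(df$start), , drop = FALSE]
    for (i in seq_len(nrow(df) - 1L)) {
      gap_start <- df$end[i]
      gap_end <- df$start[i + 1L]
      if (gap_end > gap_start) cls[gap_start:(gap_end - 1L) + 1L] <- 1L
    }
  }
  overlap_warned <- FALSE
  for (code in c(2L, 3L, 4L)) {
    sel <- feats[prio[feats$gene_class] == code, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      pos <- interval_positions(sel$start[i], sel$end[i], n) + 1L
      if (!overlap_warned && any(cls[pos] >= 2L & cls[pos] != code)) {
        warning("overlapping exons of different gene classes; priority protein > tRNA > rRNA",
                call. = FALSE)
        overlap_warned <- TRUE
      }
      cls[pos] <- pmax(cls[pos], code)
    }
  }
  class_seq <- function(code) paste(x[cls == code], collapse = "")
  sizes <- c(
    genome = n,
    lsc = region_interval(partition, "LSC")$length,
    ssc = region_interval(partition, "SSC")$length,
    ir = region_interval(partition, "IRb")$length,
    coding = sum(cls >= 2L),
    protein = sum(cls == 4L),
    intron = sum(cls == 1L),
    rRNA = sum(cls == 2L),
    tRNA = sum(cls == 3L),
    IGS = sum(cls == 0L)
  )
  gc_of <- function(code) {
    s <- class_seq(code)
    if (nzchar(gsub("[^ACGT]", "", s))) gc_content(s) else NA_real_
  }
  gcs <- c(
    gc_overall = gc_content(seq),
    gc_protein = gc_of(4L), gc_intron = gc_of(1L), gc_IGS = gc_of(0L),
    gc_rRNA = gc_of(2L), gc_tRNA = gc_of(3L)
  )
  # gene counts on distinct names, IR copies collapsed
  ir_iv <- list(region_interval(partition, "IRb"), region_interval(partition, "IRa"))
  in_ir <- function(start, end) {
    any(vapply(ir_iv, function(iv) {
      pos <- interval_positions(start, end, n)
      all(pos %in% interval_positions(iv$start, iv$end, n))
    }, logical(1)))
  }
  by_copy <- dplyr::summarise(
    dplyr::group_by(feats, .data$gene, .data$feature_id),
    gene_class = .data$gene_class[1L],
    n_parts = dplyr::n(),
    all_in_ir = all(purrr::map2_lgl(.data$start, .data$end, in_ir)),
    .groups = "drop"
  )
  by_gene <- dplyr::summarise(
    dplyr::group_by(by_copy, .data$gene),
    gene_class = .data$gene_class[1L],
    n_copies_in_ir = sum(.data$all_in_ir),
    has_intron = any(.data$n_parts > 1L),
    .groups = "drop"
  )
  counts <- c(
    n_genes = nrow(by_gene),
    n_protein_genes = sum(by_gene$gene_class == "protein"),
    n_trna_genes = sum(by_gene$gene_class == "tRNA"),
    n_rrna_genes = sum(by_gene$gene_class == "rRNA"),
    n_ir_duplicated = sum(by_gene$n_copies_in_ir >= 2L),
    n_intron_genes = sum(by_gene$has_intron)
  )
  tibble::tibble(
    metric = c(names(sizes), names(gcs), names(counts)),
    value = unname(c(sizes, gcs, counts)),
    percent = unname(c(round_half_up(100 * sizes / n, 1),
                       rep(NA_real_, length(gcs) + length(counts))))
  )
}
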