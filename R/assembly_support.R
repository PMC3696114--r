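# Assembly support: reference-similarity read binning and iterative
# consensus elongation of contig ends.
#
# Binning keeps a read when its best local-alignment score against the
# circularly doubled reference (either strand) reaches a fraction of the
# read's maximal self-score. Elongation repeatedly collects reads whose
# prefix overlaps a contig's terminal window (anchored with at most two
# mismatches), takes the base-wise majority of their overhangs, and extends
# while enough reads agree; branch points (such as single-copy/IR
# junctions, where two read populations disagree) are explicit "ambiguous"
# stops rather than forced calls, and circularization is detected when the
# two contig ends overlap.

local_score_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = FALSE)
}

best_local_scores <- function(seqs, subject_str, mat) {
  subj <- Biostrings::DNAString(subject_str)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs), subject = subj, type = "local",
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 2,
    scoreOnly = TRUE
  )
}

#' Bin reads by similarity to a reference plastome
#'
#' @param reads tibble with `read_id`, `seq`.
#' @param reference reference plastome string (any related plastome; it is
#'   circularly doubled internally).
#' @param min_score_fraction keep a read when its best local score (match
#'   +1, mismatch -2, gaps 4/2, either strand) reaches this fraction of the
#'   read's self-score (its length).
#' @return the subset of `reads` that binned as plastid, with a `score`
#'   column.
#' @export
bin_plastid_reads <- function(reads, reference, min_score_fraction = 0.5) {
  if (nrow(reads) == 0L) stop("empty read set", call. = FALSE)
  mat <- local_score_matrix()
  doubled <- paste0(reference, reference)
  fw <- best_local_scores(reads$seq, doubled, mat)
  rv <- best_local_scores(reads$seq, revcomp(doubled), mat)
  score <- pmax(fw, rv)
  out <- reads[score >= min_score_fraction * nchar(reads$seq), , drop = FALSE]
  out$score <- score[score >= min_score_fraction * nchar(reads$seq)]
  out
}

# mismatches between two equal-length character vectors
n_mismatch <- function(a, b) sum(a != b)

# one right-end extension round; works on character vectors.
# oriented_reads: list of base vectors (both orientations of every read).
extend_right_once <- function(contig_ch, oriented_reads, window, min_support,
                              min_agree, min_overlap, max_mismatch) {
  clen <- length(contig_ch)
  w <- min(window, clen)
  tail_ch <- contig_ch[(clen - w + 1L):clen]
  overhangs <- list()
  for (r in oriented_reads) {
    rl <- length(r)
    amax <- min(w, rl - 1L)
    if (amax < min_overlap) next
    for (a in amax:min_overlap) {
      if (n_mismatch(r[seq_len(a)], tail_ch[(w - a + 1L):w]) <= max_mismatch) {
        overhangs[[length(overhangs) + 1L]] <- r[(a + 1L):rl]
        break
      }
    }
  }
  if (length(overhangs) == 0L) {
    return(list(ext = character(0), reason = "no_support"))
  }
  max_oh <- max(lengths(overhangs))
  ext <- character(0)
  reason <- "support_exhausted"
  for (p in seq_len(max_oh)) {
    bases <- vapply(overhangs, function(o) if (length(o) >= p) o[p] else NA_character_,
                    character(1))
    bases <- bases[!is.na(bases)]
    if (length(bases) < min_support) {
      reason <- if (p == 1L) "no_support" else "support_exhausted"
      break
    }
    tab <- sort(table(bases), decreasing = TRUE)
    if (tab[1L] / length(bases) < min_agree) {
      reason <- "ambiguous"
      break
    }
    ext <- c(ext, names(tab)[1L])
  }
  list(ext = ext, reason = reason)
}

# detect an end-to-end overlap of at least `window` bases (<= max_mismatch)
# and return the trimmed circular sequence, or NULL
detect_circularization <- function(contig_ch, window, max_mismatch, max_probe = 500L) {
  clen <- length(contig_ch)
  for (a in window:min(max_probe, clen - 1L)) {
    if (n_mismatch(contig_ch[seq_len(a)], contig_ch[(clen - a + 1L):clen]) <= max_mismatch) {
      return(contig_ch[seq_len(clen - a)])
    }
  }
  NULL
}

#' Iteratively elongate both ends of a contig from a read set
#'
#' Per round and per end: reads whose prefix overlaps the contig's terminal
#' window (overlap between `min_overlap` and `window` bases, at most
#' `max_mismatch` anchor mismatches, both read orientations tried) vote on
#' the overhang; the consensus is appended while at least `min_support`
#' reads cover a position and the majority base reaches `min_agree`.
#' Existing contig bases are never rewritten. Stop reasons per end are
#' `no_support`, `support_exhausted` (extension shorter than the overhang
#' supply) or `ambiguous` (a branch point); the whole run stops on
#' `circularized` (the two ends overlap by at least `window` bases),
#' `max_rounds`, or when neither end can extend.
#'
#' @param contig starting contig string.
#' @param reads tibble with `seq` (reads of length >= `min_overlap + 1`).
#' @param window terminal window length in bases.
#' @param min_support minimum reads covering an extended position.
#' @param min_agree minimum majority fraction per position.
#' @param max_rounds safety bound on rounds.
#' @param min_overlap minimum read-prefix overlap with the window.
#' @param max_mismatch anchor mismatches tolerated.
#' @return a list of class `elongation_state`: `contig`, `rounds` (tibble
#'   `round`, `end`, `extension`), `stop_reason` (overall), `stop_right`,
#'   `stop_left`, `circularized`.
#' @export
elongate_contig <- function(contig, reads, window = 100L, min_support = 5L,
                            min_agree = 0.8, max_rounds = 200L,
                            min_overlap = 30L, max_mismatch = 2L) {
  oriented <- c(lapply(reads$seq, seq_chars),
                lapply(reads$seq, function(s) seq_chars(revcomp(s))))
  contig_ch <- seq_chars(contig)
  rounds <- list()
  stop_right <- stop_left <- NA_character_
  circular <- FALSE
  overall <- "max_rounds"
  for (round in seq_len(max_rounds)) {
    trimmed <- detect_circularization(contig_ch, window, max_mismatch)
    if (!is.null(trimmed)) {
      contig_ch <- trimmed
      circular <- TRUE
      overall <- "circularized"
      break
    }
    extended_any <- FALSE
    # right end
    if (!identical(stop_right, "ambiguous") && !identical(stop_right, "no_support")) {
      res <- extend_right_once(contig_ch, oriented, window, min_support,
                               min_agree, min_overlap, max_mismatch)
      if (length(res$ext) > 0L) {
        contig_ch <- c(contig_ch, res$ext)
        extended_any <- TRUE
        rounds[[length(rounds) + 1L]] <-
          tibble::tibble(round = round, end = "right", extension = length(res$ext))
      }
      stop_right <- res$reason
    }
    # left end: extend the right end of the reverse complement
    if (!identical(stop_left, "ambiguous") && !identical(stop_left, "no_support")) {
      rc_ch <- seq_chars(revcomp(paste(contig_ch, collapse = "")))
      res <- extend_right_once(rc_ch, oriented, window, min_support,
                               min_agree, min_overlap, max_mismatch)
      if (length(res$ext) > 0L) {
        contig_ch <- seq_chars(revcomp(paste(c(rc_ch, res$ext), collapse = "")))
        extended_any <- TRUE
        rounds[[length(rounds) + 1L]] <-
          tibble::tibble(round = round, end = "left", extension = length(res$ext))
      }
      stop_left <- res$reason
    }
    halted <- function(r) identical(r, "ambiguous") || identical(r, "no_support")
    if (!extended_any && (halted(stop_right) || is.na(stop_right)) &&
        (halted(stop_left) || is.na(stop_left))) {
      overall <- if (identical(stop_right, "ambiguous") ||
                       identical(stop_left, "ambiguous")) "ambiguous" else "no_support"
      break
    }
    if (!extended_any) {
      overall <- "no_support"
      break
    }
  }
  out <- list(
    contig = paste(contig_ch, collapse = ""),
    rounds = if (length(rounds) > 0L) dplyr::bind_rows(rounds) else
      tibble::tibble(round = integer(), end = character(), extension = integer()),
    stop_reason = overall,
    stop_right = stop_right,
    stop_left = stop_left,
    circularized = circular
  )
  class(out) <- "elongation_state"
  out
}

#' @export
print.elongation_state <- function(x, ...) {
  cat(sprintf("<elongation_state> %d bp, stop: %s (right: %s, left: %s)\n",
              nchar(x$contig), x$stop_reason, x$stop_right, x$stop_left))
  invisible(x)
}

#' Order and orient contigs against a reference plastome
#'
#' Each contig is locally aligned (both strands) to the circularly doubled
#' reference; contigs are placed by the midpoint of their best hit and
#' oriented by its strand. With a partition given, contigs lying wholly
#' within an IR are flagged `duplicated` and placed at the IRb slot.
#' Contigs without a credible hit are left unplaced.
#'
#' @param contigs tibble with `contig_id`, `seq`.
#' @param reference reference plastome string.
#' @param partition optional partition tibble of the reference.
#' @param min_score_fraction minimal best-score fraction of contig length
#'   to accept a placement.
#' @return tibble: `contig_id`, `placed`, `strand`, `ref_start`, `ref_end`,
#'   `midpoint`, `duplicated`, `order`.
#' @export
order_contigs <- function(contigs, reference, partition = NULL,
                          min_score_fraction = 0.3) {
  n <- nchar(reference)
  mat <- local_score_matrix()
  doubled <- Biostrings::DNAString(paste0(reference, reference))
  place_one <- function(s) {
    alns <- lapply(c(s, revcomp(s)), function(q) {
      Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(q), subject = doubled, type = "local",
        substitutionMatrix = mat, gapOpening = 4, gapExtension = 2
      )
    })
    scores <- vapply(alns, Biostrings::score, numeric(1))
    best <- which.max(scores)
    if (scores[best] < min_score_fraction * nchar(s)) {
      return(tibble::tibble(placed = FALSE, strand = NA_character_,
                            ref_start = NA_integer_, ref_end = NA_integer_,
                            midpoint = NA_real_, duplicated = FALSE))
    }
    sub <- Biostrings::subject(alns[[best]])
    rs <- (Biostrings::start(sub) - 1L) %% n
    re <- rs + Biostrings::nchar(sub)
    mid <- (rs + Biostrings::nchar(sub) / 2) %% n
    dup <- FALSE
    if (!is.null(partition)) {
      irb <- region_interval(partition, "IRb")
      ira <- region_interval(partition, "IRa")
      if (iv_within(rs, re, ira$start, ira$end)) {
        # mirror an IRa-only placement onto the IRb slot
        new_rs <- irb$start + (ira$end - re)
        re <- irb$start + (ira$end - rs)
        rs <- new_rs
        mid <- (rs + re) / 2
        dup <- TRUE
      } else if (iv_within(rs, re, irb$start, irb$end)) {
        dup <- TRUE
      }
    }
    tibble::tibble(placed = TRUE, strand = c("+", "-")[best],
                   ref_start = as.integer(rs), ref_end = as.integer(re),
                   midpoint = mid, duplicated = dup)
  }
  out <- dplyr::bind_cols(
    tibble::tibble(contig_id = contigs$contig_id),
    purrr::map_dfr(contigs$seq, place_one)
  )
  out$order <- NA_integer_
  placed <- which(out$placed)
  out$order[placed[order(out$midpoint[placed])]] <- seq_along(placed)
  dplyr::arrange(out, is.na(.data$order), .data$order)
}
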