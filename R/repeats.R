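# Tandem-repeat scanning: microsatellites (MISA-style thresholds) and
# minisatellites (unit >= 10 bp, at least two tandem copies).
#
# Only perfect repeats are detected. A maximal perfect tandem array of
# period u is a maximal run of positions t with s[t] == s[t+u]; the array is
# reported under its smallest primitive unit, and copies may be fractional
# (a partial final copy contributes `length/unit_len`). Unit sizes 7-9 bp
# fall in neither repeat class and are ignored by design.

is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  divisors <- which(u %% seq_len(u - 1L) == 0L)
  !any(vapply(divisors, function(d) {
    unit == strrep(substr(unit, 1L, d), u %/% d)
  }, logical(1)))
}

#' Canonical representative of a repeat motif
#'
#' The lexicographic minimum over all rotations of the motif and of its
#' reverse complement, so that equivalent repeats compare equal across
#' strands and phases.
#'
#' @param motif repeat unit string.
#' @return the canonical motif.
#' @export
canonical_motif <- function(motif) {
  rots <- function(m) {
    u <- nchar(m)
    d <- paste0(m, m)
    substring(d, 1:u, 1:u + u - 1L)
  }
  min(c(rots(motif), rots(revcomp(motif))))
}

# maximal perfect tandem arrays of period u in x (a base vector);
# returns 0-based half-open intervals with copies = length / u
tandem_arrays <- function(x, u) {
  n <- length(x)
  if (n < 2L * u) {
    return(tibble::tibble(start = integer(), end = integer(), unit = character(),
                          unit_len = integer(), copies = numeric()))
  }
  b <- x[seq_len(n - u)] == x[seq_len(n - u) + u]
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= u   # at least two full copies
  if (!any(keep)) {
    return(tibble::tibble(start = integer(), end = integer(), unit = character(),
                          unit_len = integer(), copies = numeric()))
  }
  s0 <- starts[keep] - 1L             # 0-based array start
  alen <- r$lengths[keep] + u         # full array extent including last unit
  tibble::tibble(
    start = s0,
    end = s0 + alen,
    unit = vapply(s0, function(s) paste(x[s + seq_len(u)], collapse = ""), character(1)),
    unit_len = u,
    copies = alen / u
  )
}

# greedy overlap resolution: longest array first, then smallest start;
# keeps the reported loci of one class non-overlapping
resolve_overlaps <- function(loci) {
  if (nrow(loci) == 0L) return(loci)
  loci <- loci[order(-(loci$end - loci$start), loci$start, loci$unit_len), , drop = FALSE]
  kept <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!kept[i]) next
    if (i < nrow(loci)) {
      later <- (i + 1L):nrow(loci)
      ov <- iv_overlaps(loci$start[later], loci$end[later], loci$start[i], loci$end[i])
      kept[later][ov] <- FALSE
    }
  }
  out <- loci[kept, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Find microsatellites (unit size 1-6)
#'
#' Maximal perfect tandem runs whose copy number reaches the per-unit-length
#' threshold, reported under their smallest primitive unit; runs contained
#' in a longer reported run of a different unit are suppressed, so e.g. the
#' mononucleotide runs inside a dinucleotide array are not double-reported.
#'
#' @param seq sequence string.
#' @param min_repeats minimum copy numbers for unit sizes 1-6 (MISA-style).
#' @return tibble of loci: `start`, `end` (0-based half-open), `unit`,
#'   `unit_len`, `copies`, `repeat_class`, `canonical_motif`.
#' @export
find_microsatellites <- function(seq, min_repeats = c(10, 5, 4, 3, 3, 3)) {
  stopifnot(length(min_repeats) == 6L)
  x <- seq_chars(seq)
  loci <- purrr::map_dfr(1:6, function(u) {
    arr <- tandem_arrays(x, u)
    arr[arr$copies >= min_repeats[u] &
          vapply(arr$unit, is_primitive_unit, logical(1)), , drop = FALSE]
  })
  loci <- resolve_overlaps(loci)
  if (nrow(loci) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), unit = character(),
                          unit_len = integer(), copies = numeric(),
                          repeat_class = character(), canonical_motif = character()))
  }
  loci$repeat_class <- "micro"
  loci$canonical_motif <- unname(vapply(loci$unit, canonical_motif, character(1)))
  loci
}

#' Find minisatellites (unit size >= 10)
#'
#' Maximal perfect tandem arrays of a primitive unit in
#' `[min_unit, max_unit]` with at least `min_copies` copies; a partial final
#' copy contributes fractionally. Overlapping candidates are resolved by
#' longest array, then smallest start.
#'
#' @param seq sequence string.
#' @param min_unit,max_unit unit-size bounds (`min_unit >= 10`).
#' @param min_copies minimum (possibly fractional) copy number.
#' @return tibble of loci as in [find_microsatellites()].
#' @export
find_minisatellites <- function(seq, min_unit = 10L, max_unit = 60L,
                                min_copies = 2.0) {
  stopifnot(min_unit >= 10L)
  x <- seq_chars(seq)
  loci <- purrr::map_dfr(min_unit:max_unit, function(u) {
    arr <- tandem_arrays(x, u)
    arr[arr$copies >= min_copies &
          vapply(arr$unit, is_primitive_unit, logical(1)), , drop = FALSE]
  })
  loci <- resolve_overlaps(loci)
  if (nrow(loci) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), unit = character(),
                          unit_len = integer(), copies = numeric(),
                          repeat_class = character(), canonical_motif = character()))
  }
  loci$repeat_class <- "mini"
  loci$canonical_motif <- unname(vapply(loci$unit, canonical_motif, character(1)))
  loci
}

#' Assign each repeat locus to its quadripartite region
#'
#' A locus wholly inside a region gets that region's label; a locus
#' straddling a junction is labelled with the region holding its start and
#' flagged `junction_spanning`.
#'
#' @param loci repeat locus tibble.
#' @param partition partition tibble (canonical orientation).
#' @return `loci` with `region` and `junction_spanning` columns.
#' @export
assign_regions <- function(loci, partition) {
  if (nrow(loci) == 0L) {
    loci$region <- character(0)
    loci$junction_spanning <- logical(0)
    return(loci)
  }
  reg_of <- function(start, end) {
    for (i in seq_len(nrow(partition))) {
      if (iv_within(start, end, partition$start[i], partition$end[i])) {
        return(c(partition$region[i], "FALSE"))
      }
    }
    holder <- partition$region[partition$start <= start & start < partition$end][1L]
    c(holder, "TRUE")
  }
  ans <- t(vapply(seq_len(nrow(loci)),
                  function(i) reg_of(loci$start[i], loci$end[i]), character(2)))
  loci$region <- ans[, 1L]
  loci$junction_spanning <- as.logical(ans[, 2L])
  loci
}

#' Deduplicate inverted-repeat copies of repeat loci
#'
#' A locus in IRa whose reverse-complement twin exists in IRb at the
#' mirrored offset is dropped in favour of the IRb copy (IR loci are counted
#' once). Junction-spanning loci are kept and flagged; LSC/SSC loci are
#' unaffected.
#'
#' @param loci repeat locus tibble (regions assigned, canonical orientation).
#' @param partition partition tibble.
#' @return the deduplicated locus tibble.
#' @export
dedup_ir <- function(loci, partition) {
  if (!"region" %in% names(loci)) loci <- assign_regions(loci, partition)
  if (nrow(loci) == 0L) return(loci)
  irb <- region_interval(partition, "IRb")
  ira <- region_interval(partition, "IRa")
  in_ira <- loci$region == "IRa" & !loci$junction_spanning
  drop <- rep(FALSE, nrow(loci))
  for (i in which(in_ira)) {
    mir_start <- irb$start + (ira$end - loci$end[i])
    mir_end <- irb$start + (ira$end - loci$start[i])
    twin <- which(loci$region == "IRb" &
                    loci$start == mir_start & loci$end == mir_end &
                    loci$canonical_motif == loci$canonical_motif[i])
    if (length(twin) > 0L) drop[i] <- TRUE
  }
  loci[!drop, , drop = FALSE]
}

#' Extract flanking sequence around a repeat locus
#'
#' Honours circularity: flanks wrap around the origin on circular records.
#' A flank longer than the rest of the genome is an error.
#'
#' @param loci repeat locus tibble (uses `start`/`end`).
#' @param seq genome sequence.
#' @param flank_len flank length in bases (0 gives empty flanks).
#' @param circular is the record circular?
#' @return `loci` with `left_flank` and `right_flank` columns.
#' @export
extract_flanks <- function(loci, seq, flank_len = 200L, circular = TRUE) {
  n <- nchar(seq)
  if (nrow(loci) == 0L) {
    loci$left_flank <- character(0)
    loci$right_flank <- character(0)
    return(loci)
  }
  if (any(flank_len > n - (loci$end - loci$start))) {
    stop("flank would cross the genome's full length", call. = FALSE)
  }
  get_flank <- function(start, end) {
    if (flank_len == 0L) return(c("", ""))
    ls <- start - flank_len
    if (ls < 0L) {
      if (!circular) stop("flank crosses the origin of a linear record", call. = FALSE)
      ls <- ls %% n
    }
    re <- end + flank_len
    if (re > n) {
      if (!circular) stop("flank crosses the origin of a linear record", call. = FALSE)
    }
    c(circular_substr(seq, ls, start %% n, n),
      circular_substr(seq, end %% n, re %% n, n))
  }
  fl <- t(vapply(seq_len(nrow(loci)),
                 function(i) get_flank(loci$start[i], loci$end[i]), character(2)))
  loci$left_flank <- fl[, 1L]
  loci$right_flank <- fl[, 2L]
  loci
}
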