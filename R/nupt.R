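# Plastid insertions in the nuclear genome (NUPTs).
#
# The plastome with one IR removed (LSC+IRb+SSC) is compared against nuclear
# chromosomes; hits passing the stringency filters (alignment length
# strictly greater than min_len, e-value strictly below max_e) are profiled
# per plastid base and summarised per chromosome. The internal aligner is a
# seed-and-extend local aligner over exact k-mer seeds with ungapped,
# substitution-tolerant extension and a Karlin-Altschul-style e-value with
# fixed documented constants; externally produced tabular hits are accepted
# in its place and their e-values trusted.

#' Remove one inverted repeat from a canonical plastome
#'
#' Returns the LSC+IRb+SSC concatenation (IRa removed) plus the coordinate
#' map back to the full genome; IRb coordinates map to both IR copies.
#' Applying the function to an already-stripped sequence errors (the
#' partition no longer matches).
#'
#' @param seq plastome string in canonical orientation.
#' @param partition its partition tibble.
#' @return list with `seq` (stripped), `length`, and `map_back(start, end)`
#'   returning the full-genome interval(s) of a stripped-coordinate
#'   interval.
#' @export
strip_one_ir <- function(seq, partition) {
  n <- nchar(seq)
  if (partition_genome_length(partition) != n) {
    stop("partition does not match sequence length (already stripped?)", call. = FALSE)
  }
  if (region_interval(partition, "LSC")$start != 0L) {
    stop("sequence must be in canonical orientation (LSC at position 0)", call. = FALSE)
  }
  irb <- region_interval(partition, "IRb")
  ira <- region_interval(partition, "IRa")
  stripped_len <- n - ira$length
  map_back <- function(start, end) {
    out <- list(tibble::tibble(start = start, end = end, region = "direct"))
    if (iv_overlaps(start, end, irb$start, irb$end)) {
      os <- max(start, irb$start) - irb$start
      oe <- min(end, irb$end) - irb$start
      out[[2L]] <- tibble::tibble(start = ira$start + (irb$length - oe),
                                  end = ira$start + (irb$length - os),
                                  region = "IRa-mirror")
    }
    dplyr::bind_rows(out)
  }
  list(seq = substr(seq, 1L, stripped_len), length = stripped_len,
       map_back = map_back)
}

# ungapped X-drop extension of a seed segment on one diagonal.
# q, s are base vectors; returns 0-based half-open intervals plus scores.
extend_seed <- function(q, s, q0, s0, seed_len, match = 1, mismatch = -2,
                        xdrop = 20) {
  nq <- length(q)
  ns <- length(s)
  score <- seed_len * match
  best <- score
  # right extension
  qi <- q0 + seed_len
  si <- s0 + seed_len
  best_r <- 0L
  r <- 0L
  while (qi + r < nq && si + r < ns) {
    score <- score + if (q[qi + r + 1L] == s[si + r + 1L]) match else mismatch
    r <- r + 1L
    if (score > best) {
      best <- score
      best_r <- r
    }
    if (score < best - xdrop) break
  }
  score <- best
  # left extension
  l <- 0L
  best_l <- 0L
  while (q0 - l > 0L && s0 - l > 0L) {
    score <- score + if (q[q0 - l] == s[s0 - l]) match else mismatch
    l <- l + 1L
    if (score > best) {
      best <- score
      best_l <- l
    }
    if (score < best - xdrop) break
  }
  qs <- q0 - best_l
  qe <- q0 + seed_len + best_r
  ss <- s0 - best_l
  se <- s0 + seed_len + best_r
  len <- qe - qs
  nid <- sum(q[(qs + 1L):qe] == s[(ss + 1L):se])
  list(q_start = qs, q_end = qe, s_start = ss, s_end = se,
       length = len, n_ident = nid, score = nid * match + (len - nid) * mismatch)
}

# seed-and-extend one chromosome strand against the query
align_one_strand <- function(qch, sch, k, min_raw_score) {
  nq <- length(qch)
  ns <- length(sch)
  if (ns < k || nq < k) return(NULL)
  qstr <- paste(qch, collapse = "")
  sstr <- paste(sch, collapse = "")
  qk <- substring(qstr, 1:(nq - k + 1L), 1:(nq - k + 1L) + k - 1L)
  sk <- substring(sstr, 1:(ns - k + 1L), 1:(ns - k + 1L) + k - 1L)
  idx <- split(0:(nq - k), qk)
  hit <- which(sk %in% names(idx)) - 1L
  if (length(hit) == 0L) return(NULL)
  seeds <- purrr::map_dfr(hit, function(p) {
    tibble::tibble(s0 = p, q0 = idx[[sk[p + 1L]]])
  })
  seeds$diag <- seeds$s0 - seeds$q0
  hits <- list()
  for (d in unique(seeds$diag)) {
    sd <- seeds[seeds$diag == d, , drop = FALSE]
    sd <- sd[order(sd$q0), , drop = FALSE]
    # cluster seeds separated by less than 3k into one segment
    grp <- cumsum(c(1L, diff(sd$q0) > 3L * k))
    for (g in unique(grp)) {
      qlo <- min(sd$q0[grp == g])
      qhi <- max(sd$q0[grp == g])
      ext <- extend_seed(qch, sch, qlo, qlo + d, qhi - qlo + k)
      if (ext$score >= min_raw_score) hits[[length(hits) + 1L]] <- ext
    }
  }
  if (length(hits) == 0L) return(NULL)
  out <- dplyr::bind_rows(purrr::map(hits, tibble::as_tibble))
  # collapse duplicates from different seed clusters extending to one local
  # alignment
  dplyr::distinct(out)
}

#' Find plastid insertions in nuclear chromosomes
#'
#' Either aligns the IR-stripped plastome against the chromosomes with the
#' internal seed-and-extend aligner, or filters a provided tabular hit
#' table. Filters are strict: alignment length `> min_len` and e-value
#' `< max_e`.
#'
#' E-values use `E = K * m * n * exp(-lambda * S)` with the package's fixed
#' ungapped-scoring constants `lambda = 1.33`, `K = 0.62` (match +1,
#' mismatch -2).
#'
#' @param nuclear chromosome tibble (`id`, `seq`).
#' @param query IR-stripped plastome (string or [strip_one_ir()] result).
#' @param min_len hit-length filter (strict).
#' @param max_e e-value filter (strict).
#' @param k seed k-mer size of the internal aligner.
#' @param hits optional externally produced hit tibble with columns `chrom`,
#'   `nuc_start`, `nuc_end`, `q_start`, `q_end`, `strand`, `length`,
#'   `identity`, `evalue`; when given, sequences are not aligned.
#' @return hit tibble: `chrom`, `nuc_start`, `nuc_end`, `strand`,
#'   `q_start`, `q_end` (stripped plastome coordinates, 0-based half-open),
#'   `length`, `identity`, `bitscore`, `evalue`.
#' @export
find_insertions <- function(nuclear = NULL, query = NULL, min_len = 100L,
                            max_e = 1e-5, k = 15L, hits = NULL) {
  lambda <- 1.33
  kconst <- 0.62
  if (is.null(hits)) {
    if (is.null(nuclear) || is.null(query)) {
      stop("provide either sequences (nuclear + query) or a hit table", call. = FALSE)
    }
    qseq <- if (is.list(query)) query$seq else query
    qch <- seq_chars(qseq)
    m <- length(qch)
    all_hits <- purrr::map_dfr(seq_len(nrow(nuclear)), function(ci) {
      sch <- seq_chars(nuclear$seq[ci])
      ns <- length(sch)
      fw <- align_one_strand(qch, sch, k, min_raw_score = 25)
      rv <- align_one_strand(qch, seq_chars(revcomp(nuclear$seq[ci])), k,
                             min_raw_score = 25)
      rows <- list()
      if (!is.null(fw)) {
        fw$chrom <- nuclear$id[ci]
        fw$strand <- "+"
        fw$nuc_start <- fw$s_start
        fw$nuc_end <- fw$s_end
        rows[[1L]] <- fw
      }
      if (!is.null(rv)) {
        rv$chrom <- nuclear$id[ci]
        rv$strand <- "-"
        rv$nuc_start <- ns - rv$s_end
        rv$nuc_end <- ns - rv$s_start
        rows[[2L]] <- rv
      }
      dplyr::bind_rows(rows)
    })
    if (nrow(all_hits) == 0L) return(empty_hits())
    all_hits$identity <- 100 * all_hits$n_ident / all_hits$length
    total_n <- sum(nchar(nuclear$seq))
    all_hits$bitscore <- (lambda * all_hits$score - log(kconst)) / log(2)
    all_hits$evalue <- kconst * m * total_n * exp(-lambda * all_hits$score)
    hits <- dplyr::select(all_hits, "chrom", "nuc_start", "nuc_end", "strand",
                          "q_start", "q_end", "length", "identity", "bitscore",
                          "evalue")
  } else {
    if (!"bitscore" %in% names(hits)) hits$bitscore <- NA_real_
  }
  out <- hits[hits$length > min_len & hits$evalue < max_e, , drop = FALSE]
  dplyr::arrange(tibble::as_tibble(out), .data$chrom, .data$nuc_start)
}

empty_hits <- function() {
  tibble::tibble(chrom = character(), nuc_start = integer(), nuc_end = integer(),
                 strand = character(), q_start = integer(), q_end = integer(),
                 length = integer(), identity = numeric(), bitscore = numeric(),
                 evalue = numeric())
}

#' Per-base insertion profile of the plastome
#'
#' `value(b)` counts the hits whose plastome interval covers base `b` of the
#' IR-stripped genome. For display the profile is projected onto the full
#' genome with the IR values divided by two and applied to both IR copies;
#' the covered fraction is computed on the IR-stripped genome.
#'
#' @param hits hit tibble from [find_insertions()] (stripped coordinates).
#' @param seq full plastome string (canonical orientation).
#' @param partition partition tibble.
#' @return an object of class `nupt_profile`: list with `stripped`
#'   (tibble `pos`, `value` over the IR-stripped genome), `display`
#'   (tibble `pos`, `value` over the full genome, IR halved and mirrored),
#'   `covered_fraction` (percent).
#' @export
insertion_profile <- function(hits, seq, partition) {
  n <- nchar(seq)
  irb <- region_interval(partition, "IRb")
  ira <- region_interval(partition, "IRa")
  ns <- n - ira$length
  if (nrow(hits) > 0L && (min(hits$q_start) < 0L || max(hits$q_end) > ns)) {
    stop("hit outside query bounds", call. = FALSE)
  }
  v <- integer(ns)
  for (i in seq_len(nrow(hits))) {
    idx <- (hits$q_start[i] + 1L):hits$q_end[i]
    v[idx] <- v[idx] + 1L
  }
  display <- numeric(n)
  display[seq_len(ns)] <- v
  ir_idx <- (irb$start + 1L):irb$end
  display[ir_idx] <- v[ir_idx] / 2
  display[(ira$start + 1L):ira$end] <- rev(display[ir_idx])
  out <- list(
    stripped = tibble::tibble(pos = 0:(ns - 1L), value = v),
    display = tibble::tibble(pos = 0:(n - 1L), value = display),
    covered_fraction = 100 * mean(v > 0L)
  )
  class(out) <- "nupt_profile"
  out
}

#' @export
print.nupt_profile <- function(x, ...) {
  cat(sprintf("<nupt_profile> %d plastid bases (IR-stripped), %.1f%% covered\n",
              nrow(x$stripped), x$covered_fraction))
  invisible(x)
}

#' Per-chromosome insertion summary
#'
#' Hit counts and cumulative nuclear bases covered per chromosome, with
#' overlapping nuclear hit intervals merged before summing, plus a totals
#' row, the proportion of all insertion bases per chromosome, and the
#' per-mille of the nuclear genome covered.
#'
#' @param hits hit tibble from [find_insertions()].
#' @param nuclear_lengths named integer vector of chromosome lengths.
#' @return tibble: `chrom`, `n_hits`, `n_bases`, `prop_insertions_pct`,
#'   `per_mille_of_chrom`, with a final `total` row.
#' @export
chromosome_summary <- function(hits, nuclear_lengths) {
  unknown <- setdiff(unique(hits$chrom), names(nuclear_lengths))
  if (length(unknown) > 0L) {
    stop("hit on unknown chromosome: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  per <- purrr::map_dfr(names(nuclear_lengths), function(ch) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    nb <- if (nrow(h) == 0L) 0L else {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = h$nuc_start + 1L, end = h$nuc_end)
      )))
    }
    tibble::tibble(chrom = ch, n_hits = nrow(h), n_bases = nb,
                   chrom_len = unname(nuclear_lengths[ch]))
  })
  total_bases <- sum(per$n_bases)
  per$prop_insertions_pct <- if (total_bases > 0) {
    round_half_up(100 * per$n_bases / total_bases, 2)
  } else {
    0
  }
  per$per_mille_of_chrom <- round_half_up(1000 * per$n_bases / per$chrom_len, 2)
  total <- tibble::tibble(
    chrom = "total", n_hits = sum(per$n_hits), n_bases = total_bases,
    chrom_len = sum(per$chrom_len),
    prop_insertions_pct = if (total_bases > 0) 100 else 0,
    per_mille_of_chrom = round_half_up(1000 * total_bases / sum(per$chrom_len), 2)
  )
  dplyr::bind_rows(dplyr::select(per, -"chrom_len"),
                   dplyr::select(total, -"chrom_len"))
}
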