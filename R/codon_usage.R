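# Codon usage: counts, RSCU, within-amino-acid frequencies, and
# codon-anticodon recognition.
#
# RSCU (relative synonymous codon usage) for codon c is count(c) divided by
# the mean count over c's synonymous family; 1 means no bias. The three stop
# codons are treated as one synonymous family. Terminal stop codons ARE
# counted: each CDS contributes its stop, so the stop-family total equals
# the number of CDS. The genetic code is the standard plastid/bacterial
# code, whose codon-to-amino-acid map equals the standard code.

#' The plastid genetic code
#'
#' @return a named character vector mapping the 64 codons to one-letter
#'   amino acids, `*` for stop.
#' @export
plastid_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc[ALL_CODONS]), ALL_CODONS)
}

#' Count codons over a set of coding sequences
#'
#' Frame-0 triplets are counted, including the terminal stop codon of each
#' CDS. The caller excludes pseudogenes and contributes each IR-duplicated
#' gene once. A CDS containing an internal stop codon is rejected with its
#' name (it is a pseudogene diagnostic, not countable usage).
#'
#' @param cds_list character vector of CDS (optionally named by gene).
#' @return tibble with one row per codon: `codon`, `amino_acid`, `count`;
#'   the total is `sum(count)`.
#' @export
count_codons <- function(cds_list) {
  stopifnot(length(cds_list) > 0L)
  nm <- names(cds_list) %||% sprintf("cds%03d", seq_along(cds_list))
  bad_len <- nchar(cds_list) %% 3L != 0L
  if (any(bad_len)) {
    stop("CDS length not divisible by 3: ", paste(nm[bad_len], collapse = ", "),
         call. = FALSE)
  }
  stops <- vapply(cds_list, detect_internal_stops, integer(1))
  if (any(stops > 0L)) {
    stop("internal stop codon in CDS: ", paste(nm[stops > 0L], collapse = ", "),
         call. = FALSE)
  }
  codons <- unlist(lapply(cds_list, function(s) {
    starts <- seq.int(1L, nchar(s), by = 3L)
    substring(s, starts, starts + 2L)
  }))
  counts <- table(factor(codons, levels = ALL_CODONS))
  code <- plastid_genetic_code()
  tibble::tibble(
    codon = ALL_CODONS,
    amino_acid = unname(code[ALL_CODONS]),
    count = as.integer(counts)
  )
}

# normalise count input: accept the count_codons() tibble or a named vector
as_codon_counts <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("codon", "count") %in% names(counts)))
    v <- stats::setNames(as.numeric(counts$count), counts$codon)
  } else {
    v <- counts
  }
  out <- stats::setNames(rep(0, length(ALL_CODONS)), ALL_CODONS)
  out[names(v)] <- v
  out
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) / mean(count over the synonymous family of c)`. A
#' family with zero total yields RSCU 0 for all members, flagged in
#' `family_total`. Values are unrounded; report with
#' [round_half_up()] at 2 decimals to match printed tables.
#'
#' @param counts a [count_codons()] tibble or named codon-count vector.
#' @return tibble: `codon`, `amino_acid`, `count`, `family_size`,
#'   `family_total`, `rscu`.
#' @export
rscu <- function(counts) {
  v <- as_codon_counts(counts)
  code <- plastid_genetic_code()
  fam <- split(ALL_CODONS, code[ALL_CODONS])
  purrr::map_dfr(fam, function(codons) {
    total <- sum(v[codons])
    k <- length(codons)
    tibble::tibble(
      codon = codons,
      amino_acid = unname(code[codons]),
      count = unname(v[codons]),
      family_size = k,
      family_total = total,
      rscu = if (total > 0) unname(v[codons]) / (total / k) else 0
    )
  })
}

#' Codon frequency within its amino acid, in percent
#'
#' `100 * count(c) / family total`; undefined (NA, flagged) for a family
#' with zero total.
#'
#' @inheritParams rscu
#' @return tibble: `codon`, `amino_acid`, `count`, `family_total`,
#'   `freq_within_aa`.
#' @export
aa_frequency <- function(counts) {
  r <- rscu(counts)
  r$freq_within_aa <- ifelse(r$family_total > 0,
                             100 * r$count / r$family_total, NA_real_)
  dplyr::select(r, "codon", "amino_acid", "count", "family_total", "freq_within_aa")
}

#' Codons recognized by a tRNA set
#'
#' The recognized codon is the strict Watson-Crick reverse complement of the
#' anticodon (read 5'->3'); wobble pairing is deliberately not applied,
#' matching the convention of marking in a codon-usage table exactly those
#' codons that complement an encoded anticodon. When `counts` is supplied
#' the recognized codons are joined with the most-common-in-family flags
#' (ties all flagged) and the overlap is counted.
#'
#' @param trna_features feature tibble rows of class `tRNA` (distinct
#'   anticodons are used), or a character vector of anticodons.
#' @param counts optional codon counts for the most-common comparison.
#' @return a list with `codons` (recognized codon set) and, when `counts`
#'   is given, `table` (per-codon tibble with `recognized_by_trna` and
#'   `most_common_in_aa`) and `n_recognized_most_common`.
#' @export
anticodon_recognition <- function(trna_features, counts = NULL) {
  ac <- if (is.data.frame(trna_features)) {
    unique(trna_features$anticodon[!is.na(trna_features$anticodon)])
  } else {
    unique(trna_features)
  }
  if (any(grepl("[^ACGT]", ac))) {
    stop("anticodon with residue outside {A,C,G,T}", call. = FALSE)
  }
  codons <- unique(revcomp_all(ac))
  if (is.null(counts)) return(list(codons = codons))
  tab <- rscu(counts)
  tab <- dplyr::mutate(
    dplyr::group_by(tab, .data$amino_acid),
    most_common_in_aa = .data$family_total > 0 & .data$count == max(.data$count),
    .groups = "drop"
  )
  tab <- dplyr::ungroup(tab)
  tab$recognized_by_trna <- tab$codon %in% codons
  list(
    codons = codons,
    table = tab,
    n_recognized_most_common = sum(tab$recognized_by_trna & tab$most_common_in_aa &
                                     tab$family_size > 1L)
  )
}

#' Full codon-usage table
#'
#' One row per codon in the layout of a published codon-usage panel:
#' count, RSCU, frequency within the amino acid, the most-common flag, and
#' (when anticodons are supplied) the recognized-by-tRNA flag.
#'
#' @inheritParams rscu
#' @param anticodons optional anticodon character vector or tRNA feature rows.
#' @return a 64-row tibble.
#' @export
codon_usage_table <- function(counts, anticodons = NULL) {
  r <- rscu(counts)
  f <- aa_frequency(counts)
  out <- dplyr::left_join(r, dplyr::select(f, "codon", "freq_within_aa"),
                          by = "codon")
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$amino_acid),
    most_common_in_aa = .data$family_total > 0 & .data$count == max(.data$count)
  )
  out <- dplyr::ungroup(out)
  if (!is.null(anticodons)) {
    rec <- anticodon_recognition(anticodons)
    out$recognized_by_trna <- out$codon %in% rec$codons
  }
  dplyr::arrange(out, .data$amino_acid, .data$codon)
}
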