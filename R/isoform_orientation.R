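# SSC-orientation isoform detection from mate-pair orientations.
#
# Plastomes co-exist as two "flip-flop" conformations differing by the
# orientation of the SSC relative to the LSC. On the form-A reference, mate
# pairs with one mate wholly in the LSC and the other wholly in the SSC fall
# in orientation class FR or RF when the molecule was form A, and FF or RR
# when it was form B (the SSC mate then maps at the mirrored position with
# flipped strand). Classes are written LSC-mate first; only the
# {FR,RF} vs {FF,RR} split carries biological meaning.

#' Classify mate pairs by orientation on the form-A reference
#'
#' A pair is `filtered` (with a reason) unless both mates pass the identity
#' and coverage thresholds, map to a single locus, and one lies wholly in
#' the SSC while the other lies wholly in the LSC; mates touching an IR are
#' ambiguous (IR repeats make placement unreliable near junctions) and are
#' filtered. The class is the ordered strand pair with the LSC mate first,
#' so classification is symmetric in mate file order.
#'
#' @param alignments tibble with columns `pair_id`, `mate`, `start`, `end`
#'   (0-based half-open on the form-A reference), `strand` (`"F"`/`"R"`),
#'   `identity` (percent), `coverage` (aligned fraction of the mate), and
#'   optionally `n_loci`.
#' @param partition partition tibble (canonical orientation).
#' @param min_identity minimum percent identity (strict `>=`).
#' @param min_cov minimum aligned fraction (strict `>=`).
#' @return tibble: `pair_id`, `class` (`FR`, `RF`, `FF`, `RR` or
#'   `filtered`), `filter_reason`, `region_mate1`, `region_mate2`.
#' @export
classify_mate_pairs <- function(alignments, partition, min_identity = 90,
                                min_cov = 0.60) {
  if (!"n_loci" %in% names(alignments)) alignments$n_loci <- 1L
  a <- alignments
  # vectorised per-alignment annotation: containing region and IR contact
  reg <- rep(NA_character_, nrow(a))
  for (i in seq_len(nrow(partition))) {
    w <- is.na(reg) & a$start >= partition$start[i] & a$end <= partition$end[i]
    reg[w] <- partition$region[i]
  }
  ir <- partition[partition$region %in% c("IRb", "IRa"), , drop = FALSE]
  touches <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(ir))) {
    touches <- touches | (a$start < ir$end[i] & ir$start[i] < a$end)
  }
  groups <- split(seq_len(nrow(a)), a$pair_id)
  res <- vapply(groups, function(idx) {
    r <- reg[idx]
    out <- c("filtered", NA_character_, r[1L], if (length(idx) >= 2L) r[2L] else NA)
    if (length(idx) != 2L) {
      out[2L] <- "mate-count"
    } else if (any(a$n_loci[idx] > 1L)) {
      out[2L] <- "multi-mapping"
    } else if (any(a$identity[idx] < min_identity)) {
      out[2L] <- "identity"
    } else if (any(a$coverage[idx] < min_cov)) {
      out[2L] <- "coverage"
    } else if (any(touches[idx])) {
      out[2L] <- "IR-ambiguous"
    } else if (sum(r == "LSC", na.rm = TRUE) != 1L ||
               sum(r == "SSC", na.rm = TRUE) != 1L) {
      out[2L] <- "region"
    } else {
      out[1L] <- paste0(a$strand[idx][r == "LSC"], a$strand[idx][r == "SSC"])
    }
    out
  }, character(4))
  tibble::tibble(
    pair_id = names(groups),
    class = unname(res[1L, ]),
    filter_reason = unname(res[2L, ]),
    region_mate1 = unname(res[3L, ]),
    region_mate2 = unname(res[4L, ])
  )
}

#' Summarise orientation classes into isoform support
#'
#' FR and RF pairs support form A, FF and RR form B. The form-B fraction
#' comes with an exact (Clopper-Pearson) binomial confidence interval; the
#' verdict is `two_forms` when both forms reach `min_support` classified
#' pairs (guarding against isolated chimeric clones), otherwise the single
#' supported form.
#'
#' @param classifications output of [classify_mate_pairs()].
#' @param ci_level confidence level for the binomial interval.
#' @param min_support minimum pairs per form to call co-existence.
#' @return a one-row tibble: class counts, `form_A_support`,
#'   `form_B_support`, `form_b_fraction`, `ci_lower`, `ci_upper`,
#'   `verdict`.
#' @export
summarize_forms <- function(classifications, ci_level = 0.95, min_support = 3L) {
  cls <- classifications$class
  n_classified <- sum(cls != "filtered")
  if (n_classified == 0L) {
    rlang::abort("no informative pairs", class = "plastomics_no_pairs")
  }
  counts <- vapply(c("FR", "RF", "FF", "RR"), function(k) sum(cls == k), integer(1))
  form_a <- counts[["FR"]] + counts[["RF"]]
  form_b <- counts[["FF"]] + counts[["RR"]]
  bt <- stats::binom.test(form_b, form_a + form_b, conf.level = ci_level)
  verdict <- if (form_a >= min_support && form_b >= min_support) {
    "two_forms"
  } else if (form_b > form_a) "single_form_B" else "single_form_A"
  out <- tibble::tibble(
    n_FR = counts[["FR"]], n_RF = counts[["RF"]],
    n_FF = counts[["FF"]], n_RR = counts[["RR"]],
    n_filtered = sum(cls == "filtered"),
    form_A_support = form_a, form_B_support = form_b,
    form_b_fraction = form_b / (form_a + form_b),
    ci_lower = bt$conf.int[1L], ci_upper = bt$conf.int[2L],
    verdict = verdict
  )
  class(out) <- c("forms_summary", class(out))
  out
}

#' @method tidy forms_summary
#' @export
tidy.forms_summary <- function(x, ...) {
  tibble::tibble(
    class = c("FR", "RF", "FF", "RR"),
    n = c(x$n_FR, x$n_RF, x$n_FF, x$n_RR),
    form = c("A", "A", "B", "B")
  )
}

#' @method glance forms_summary
#' @export
glance.forms_summary <- function(x, ...) {
  tibble::as_tibble(x[, c("form_A_support", "form_B_support", "form_b_fraction",
                          "ci_lower", "ci_upper", "verdict")])
}
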