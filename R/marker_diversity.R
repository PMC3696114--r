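# Marker allele diversity: distinct alleles per marker within accession
# groups, and group averages.

#' Tally distinct alleles per marker and accession group
#'
#' Alleles are compared as exact integer fragment lengths; an optional
#' binning tolerance (off by default) single-link-clusters alleles within
#' `bin_tolerance` base pairs before counting, to absorb capillary sizing
#' noise. Missing alleles (NA) are ignored; a marker with all-missing data
#' in a group counts 0 and is flagged.
#'
#' @param genotypes a wide tibble (first column `accession`, one column per
#'   marker) or a long tibble with columns `accession`, `marker`, `allele`.
#' @param groups named list of accession-id vectors (possibly nested).
#' @param bin_tolerance allele-length binning tolerance in bp (0 = exact).
#' @return a tibble of class `allele_tally`: `marker`, `group`,
#'   `n_alleles`, `all_missing`; use [generics::glance()] for per-group
#'   means.
#' @export
tally_alleles <- function(genotypes, groups, bin_tolerance = 0L) {
  stopifnot(length(groups) > 0L, all(lengths(groups) >= 1L))
  long <- if (all(c("marker", "allele") %in% names(genotypes))) {
    genotypes
  } else {
    tidyr::pivot_longer(genotypes, -"accession", names_to = "marker",
                        values_to = "allele")
  }
  count_distinct <- function(a) {
    a <- sort(unique(a[!is.na(a)]))
    if (length(a) == 0L) return(0L)
    if (bin_tolerance > 0L && length(a) > 1L) {
      sum(c(TRUE, diff(a) > bin_tolerance))
    } else {
      length(a)
    }
  }
  out <- purrr::map_dfr(names(groups), function(gname) {
    sub <- long[long$accession %in% groups[[gname]], , drop = FALSE]
    dplyr::summarise(dplyr::group_by(sub, .data$marker),
                     group = gname,
                     n_alleles = count_distinct(.data$allele),
                     all_missing = all(is.na(.data$allele)),
                     .groups = "drop")
  })
  out <- dplyr::arrange(out, factor(.data$group, levels = names(groups)),
                        .data$marker)
  class(out) <- c("allele_tally", class(out))
  out
}

#' @method glance allele_tally
#' @export
glance.allele_tally <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$group),
                   n_markers = dplyr::n(),
                   mean_alleles = mean(.data$n_alleles),
                   .groups = "drop")
}
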