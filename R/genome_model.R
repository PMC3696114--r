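# Sequence + feature data model and file I/O.
#
# Conventions used throughout the package:
#   * internal coordinates are 0-based half-open; all file I/O is 1-based
#     inclusive (GFF3, feature tables, reported loci);
#   * a feature tibble has one row per exon: feature_id, gene, gene_class
#     ("protein", "tRNA", "rRNA"), strand ("+"/"-"), start, end, part (5'->3'
#     order on the coding strand), pseudo, anticodon;
#   * circular features wrap the origin when end < start (circular records
#     only) rather than via a duplicated sequence, so region sizes always sum
#     exactly to the genome size;
#   * the alphabet is strict {A,C,G,T,N}; U is mapped to T with a warning and
#     any other ambiguity code is rejected, which keeps GC and codon
#     arithmetic exact.

FEATURE_COLS <- c("feature_id", "gene", "gene_class", "strand",
                  "start", "end", "part", "pseudo", "anticodon")

empty_features <- function() {
  tibble::tibble(
    feature_id = character(), gene = character(), gene_class = character(),
    strand = character(), start = integer(), end = integer(),
    part = integer(), pseudo = logical(), anticodon = character()
  )
}

validate_sequence <- function(seq, id = "sequence") {
  if (!nzchar(seq)) {
    stop(sprintf("record '%s' is empty", id), call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("record '%s': illegal residue '%s' at position %d",
                 id, substr(seq, bad, bad), bad), call. = FALSE)
  }
  invisible(seq)
}

#' Read sequences from a FASTA file
#'
#' Returns one row per record. Lowercase is mapped to uppercase and `U` to
#' `T` (with a warning); residues outside `{A,C,G,T,N}` are a format error
#' naming the offending position.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `seq`, `length`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) stop("FASTA format error: first line is not a header", call. = FALSE)
  grp <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- vapply(split(lines[!is_header], grp[!is_header]),
                 paste, character(1), collapse = "")
  # records with a header and no sequence lines
  if (length(seqs) < length(ids)) {
    full <- rep("", length(ids))
    full[as.integer(names(seqs))] <- seqs
    seqs <- full
  }
  seqs <- toupper(unname(seqs))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    warning("RNA residue U mapped to T", call. = FALSE)
    seqs <- chartr("U", "T", seqs)
  }
  purrr::walk2(seqs, ids, validate_sequence)
  tibble::tibble(id = ids, seq = seqs, length = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x a tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path output path.
#' @param width line width for wrapping.
#' @return `x`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  out <- purrr::map2(x$id, x$seq, function(id, s) {
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, n)))
  })
  writeLines(unlist(out), path)
  invisible(x)
}

# order exon rows of one feature 5'->3' on the coding strand; trans-spliced
# features with mixed strands keep their declared (file) order.
order_parts <- function(df) {
  strands <- unique(df$strand)
  if (length(strands) == 1L) {
    df <- df[order(df$start, decreasing = identical(strands, "-")), , drop = FALSE]
  }
  df$part <- seq_len(nrow(df))
  df
}

parse_gff3_attrs <- function(a) {
  kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) >= 2L) p[2L] else "", character(1))
  stats::setNames(vals, vapply(kv, `[`, character(1), 1L))
}

#' Read gene features from an annotation file
#'
#' Both dialects use 1-based inclusive coordinates; features are returned in
#' the package's 0-based half-open convention, with the exons of multi-exon
#' genes grouped into one feature and ordered 5' to 3' on the coding strand.
#'
#' The `feature_table` dialect is a minimal tab-separated table with columns
#' name, class, strand, comma-separated 1-based exon ranges (`start..end`),
#' pseudo flag (0/1), and optionally anticodon (`-` for none) and feature id.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"feature_table"`.
#' @param genome_length optional; exon bounds are validated against it.
#' @return a feature tibble (one row per exon).
#' @export
read_annotation <- function(path, dialect = c("gff3", "feature_table"),
                            genome_length = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_features())
  rows <- if (dialect == "gff3") {
    purrr::map_dfr(lines, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 9L) stop("GFF3 format error: fewer than 9 columns", call. = FALSE)
      at <- parse_gff3_attrs(f[9L])
      cls <- switch(f[3L], CDS = "protein", tRNA = "tRNA", rRNA = "rRNA",
                    stop("unsupported GFF3 feature type: ", f[3L], call. = FALSE))
      tibble::tibble(
        feature_id = unname(at["ID"]),
        gene = unname(at["gene"] %|NA|% at["Name"]),
        gene_class = cls, strand = f[7L],
        start1 = as.integer(f[4L]), end1 = as.integer(f[5L]),
        pseudo = identical(unname(at["pseudo"]), "true"),
        anticodon = unname(at["anticodon"])
      )
    })
  } else {
    purrr::map_dfr(lines, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 5L) stop("feature table error: fewer than 5 columns", call. = FALSE)
      ranges <- strsplit(strsplit(f[4L], ",", fixed = TRUE)[[1]], "..", fixed = TRUE)
      tibble::tibble(
        feature_id = if (length(f) >= 7L) f[7L] else f[1L],
        gene = f[1L], gene_class = f[2L], strand = f[3L],
        start1 = vapply(ranges, function(r) as.integer(r[1L]), integer(1)),
        end1 = vapply(ranges, function(r) as.integer(r[2L]), integer(1)),
        pseudo = f[5L] %in% c("1", "true", "TRUE"),
        anticodon = if (length(f) >= 6L && f[6L] != "-") f[6L] else NA_character_
      )
    })
  }
  if (any(is.na(rows$start1) | is.na(rows$end1))) {
    stop("annotation error: non-numeric coordinate", call. = FALSE)
  }
  if (any(rows$end1 < rows$start1)) {
    stop("annotation error: exon of length 0 or negative extent", call. = FALSE)
  }
  if (!is.null(genome_length) && any(rows$start1 < 1L | rows$end1 > genome_length)) {
    stop("annotation error: exon outside sequence bounds", call. = FALSE)
  }
  rows$start <- rows$start1 - 1L
  rows$end <- rows$end1
  rows$start1 <- rows$end1 <- NULL
  rows <- dplyr::group_modify(dplyr::group_by(rows, .data$feature_id),
                              ~ order_parts(.x))
  rows <- dplyr::ungroup(rows)
  rows <- dplyr::arrange(rows, .data$start)
  dplyr::select(rows, dplyr::all_of(FEATURE_COLS))
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Write gene features to an annotation file
#'
#' Inverse of [read_annotation()]; writers are byte-deterministic given a
#' fixed feature order.
#'
#' @inheritParams read_annotation
#' @param features a feature tibble.
#' @param seqid sequence id used in the GFF3 first column.
#' @return `features`, invisibly.
#' @export
write_annotation <- function(features, path, dialect = c("gff3", "feature_table"),
                             seqid = "genome") {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    type <- c(protein = "CDS", tRNA = "tRNA", rRNA = "rRNA")[features$gene_class]
    attrs <- sprintf("ID=%s;gene=%s%s%s", features$feature_id, features$gene,
                     ifelse(features$pseudo, ";pseudo=true", ""),
                     ifelse(is.na(features$anticodon), "",
                            paste0(";anticodon=", features$anticodon)))
    writeLines(c("##gff-version 3",
                 sprintf("%s\tplastomics\t%s\t%d\t%d\t.\t%s\t.\t%s",
                         seqid, type, features$start + 1L, features$end,
                         features$strand, attrs)), path)
  } else {
    by_feat <- dplyr::group_split(dplyr::group_by(features, .data$feature_id))
    lines <- vapply(by_feat, function(df) {
      df <- df[order(df$part), , drop = FALSE]
      sprintf("%s\t%s\t%s\t%s\t%d\t%s\t%s",
              df$gene[1L], df$gene_class[1L], df$strand[1L],
              paste(sprintf("%d..%d", df$start + 1L, df$end), collapse = ","),
              as.integer(df$pseudo[1L]),
              ifelse(is.na(df$anticodon[1L]), "-", df$anticodon[1L]),
              df$feature_id[1L])
    }, character(1))
    writeLines(lines, path)
  }
  invisible(features)
}

#' Extract the spliced sequence of one feature
#'
#' Exon sequences are concatenated in their declared 5'->3' part order, each
#' reverse-complemented when its strand is `-`. Parts may wrap the origin
#' (`end < start`) on circular records only.
#'
#' @param seq genome sequence (single string).
#' @param feature exon rows of one feature (a feature tibble subset).
#' @param circular is the record circular?
#' @return the spliced feature sequence.
#' @export
extract_feature_sequence <- function(seq, feature, circular = FALSE) {
  n <- nchar(seq)
  feature <- feature[order(feature$part), , drop = FALSE]
  pieces <- purrr::pmap_chr(
    list(feature$start, feature$end, feature$strand),
    function(start, end, strand) {
      if (end <= start && !circular) {
        stop("origin-wrapping part on a non-circular record", call. = FALSE)
      }
      if (start < 0L || start >= n || end > n || end < 0L) {
        stop("feature part outside sequence bounds", call. = FALSE)
      }
      s <- circular_substr(seq, start, end, n)
      if (strand == "-") revcomp(s) else s
    }
  )
  paste(pieces, collapse = "")
}

#' GC content of a sequence, in percent
#'
#' `N` residues are excluded from both numerator and denominator.
#'
#' @param seq a DNA string.
#' @return percent GC on the `{A,C,G,T}` positions.
#' @export
#' @examples
#' gc_content("ATGC")
gc_content <- function(seq) {
  stopifnot(nzchar(seq))
  gc <- nchar(gsub("[^GC]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  if (acgt == 0L) stop("GC content undefined: no unambiguous residues", call. = FALSE)
  100 * gc / acgt
}
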