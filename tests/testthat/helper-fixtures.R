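# Shared fixtures and independent oracles for the test suite.

# The published Musa acuminata chloroplast codon-usage panel: per-codon
# counts with the printed RSCU and within-amino-acid frequency values
# (2 decimals). Used to check that the package's RSCU/frequency arithmetic
# reproduces the printed panel from the printed counts.
published_codon_table <- function() {
  tibble::tribble(
    ~amino_acid, ~codon, ~count, ~rscu_printed, ~freq_printed,
    "F", "TTT", 839, 1.28, 64.19,
    "F", "TTC", 468, 0.72, 35.81,
    "L", "TTA", 750, 1.91, 31.91,
    "L", "TTG", 497, 1.27, 21.15,
    "L", "CTT", 465, 1.19, 19.79,
    "L", "CTC", 158, 0.40, 6.72,
    "L", "CTA", 324, 0.83, 13.79,
    "L", "CTG", 156, 0.40, 6.64,
    "I", "ATT", 980, 1.47, 48.98,
    "I", "ATC", 384, 0.58, 19.19,
    "I", "ATA", 637, 0.96, 31.83,
    "M", "ATG", 546, 1.00, 100.00,
    "V", "GTT", 468, 1.42, 35.51,
    "V", "GTC", 168, 0.51, 12.75,
    "V", "GTA", 505, 1.53, 38.32,
    "V", "GTG", 177, 0.54, 13.43,
    "S", "TCT", 512, 1.72, 28.72,
    "S", "TCC", 290, 0.98, 16.26,
    "S", "TCA", 342, 1.15, 19.18,
    "S", "TCG", 161, 0.54, 9.03,
    "S", "AGT", 390, 1.31, 21.87,
    "S", "AGC", 88, 0.30, 4.94,
    "P", "CCT", 374, 1.57, 39.33,
    "P", "CCC", 196, 0.82, 20.61,
    "P", "CCA", 280, 1.18, 29.44,
    "P", "CCG", 101, 0.42, 10.62,
    "T", "ACT", 454, 1.54, 38.41,
    "T", "ACC", 235, 0.80, 19.88,
    "T", "ACA", 366, 1.24, 30.96,
    "T", "ACG", 127, 0.43, 10.74,
    "A", "GCT", 575, 1.85, 46.18,
    "A", "GCC", 195, 0.63, 15.66,
    "A", "GCA", 353, 1.13, 28.35,
    "A", "GCG", 122, 0.39, 9.80,
    "Y", "TAT", 682, 1.58, 78.75,
    "Y", "TAC", 184, 0.42, 21.25,
    "H", "CAT", 432, 1.55, 77.56,
    "H", "CAC", 125, 0.45, 22.44,
    "Q", "CAA", 640, 1.54, 77.11,
    "Q", "CAG", 190, 0.46, 22.89,
    "N", "AAT", 850, 1.55, 77.27,
    "N", "AAC", 250, 0.45, 22.73,
    "K", "AAA", 907, 1.51, 75.52,
    "K", "AAG", 294, 0.49, 24.48,
    "D", "GAT", 763, 1.61, 80.32,
    "D", "GAC", 187, 0.39, 19.68,
    "E", "GAA", 976, 1.50, 74.90,
    "E", "GAG", 327, 0.50, 25.10,
    "C", "TGT", 200, 1.49, 74.35,
    "C", "TGC", 69, 0.51, 25.65,
    "W", "TGG", 394, 1.00, 100.00,
    "R", "CGT", 326, 1.39, 23.24,
    "R", "CGC", 76, 0.33, 5.42,
    "R", "CGA", 312, 1.33, 22.24,
    "R", "CGG", 105, 0.45, 7.48,
    "R", "AGA", 441, 1.89, 31.43,
    "R", "AGG", 143, 0.61, 10.19,
    "G", "GGT", 539, 1.38, 34.46,
    "G", "GGC", 154, 0.39, 9.85,
    "G", "GGA", 643, 1.64, 41.11,
    "G", "GGG", 228, 0.58, 14.58,
    "*", "TAA", 41, 1.56, 51.90,
    "*", "TAG", 20, 0.76, 25.32,
    "*", "TGA", 18, 0.68, 22.78
  )
}

# ---- independent oracles ---------------------------------------------------

# Exhaustive maximal exact inverted repeat: scans every anti-diagonal of the
# circular sequence and returns the longest window whose mirror is disjoint.
# O(n^2); independent of the seeded detector.
oracle_max_inverted_repeat <- function(seq) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  cx <- unname(comp[x])
  n <- length(x)
  best_len <- 0L
  best <- NULL
  for (d in 0:(n - 1L)) {
    t <- 0:(n - 1L)
    u <- (d - t - 1L) %% n
    m <- x[t + 1L] == cx[u + 1L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # merge a wrap-around run
    runs <- data.frame(start = starts[r$values] - 1L, len = r$lengths[r$values])
    if (nrow(runs) == 0L) next
    if (m[1L] && m[n] && nrow(runs) > 1L) {
      first <- which(runs$start == 0L)
      last <- which(runs$start + runs$len == n)
      if (length(first) == 1L && length(last) == 1L && first != last) {
        runs$len[last] <- runs$len[last] + runs$len[first]
        runs <- runs[-first, , drop = FALSE]
      }
    }
    for (i in seq_len(nrow(runs))) {
      a <- runs$start[i]
      len <- runs$len[i]
      # shrink until the window and its mirror are disjoint
      while (len > 0L) {
        b <- a + len - 1L
        a2 <- (d - 1L - b) %% n
        gap1 <- (a2 - ((b + 1L) %% n)) %% n
        gap2 <- n - 2L * len - gap1
        if (len <= n %/% 2L && gap2 >= 0L && gap1 + gap2 + 2L * len == n) break
        len <- len - 2L
      }
      if (len > best_len) {
        best_len <- len
        best <- list(start = a %% n, len = len, diag = d)
      }
    }
  }
  best
}

# Quadratic brute-force maximal perfect tandem arrays: every (start, unit)
# pair is tried directly; returns candidate arrays before any threshold or
# overlap policy.
oracle_tandem_arrays <- function(seq, unit_lens) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  out <- list()
  for (u in unit_lens) {
    t <- 1L
    while (t + 2L * u - 1L <= n) {
      # maximality on the left
      if (t > 1L && x[t - 1L] == x[t - 1L + u]) {
        t <- t + 1L
        next
      }
      e <- t
      while (e + u <= n && x[e] == x[e + u]) e <- e + 1L
      alen <- (e - t) + u
      if (alen >= 2L * u) {
        out[[length(out) + 1L]] <- tibble::tibble(
          start = t - 1L, end = t - 1L + alen,
          unit = paste(x[t:(t + u - 1L)], collapse = ""),
          unit_len = u, copies = alen / u
        )
      }
      t <- e + 1L
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), unit = character(),
                          unit_len = integer(), copies = numeric()))
  }
  dplyr::bind_rows(out)
}

# Brute-force small parsimony of an ordered character: enumerates all
# internal-node state assignments.
oracle_parsimony_length <- function(tip_states, tree, root_state, k) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  grid <- expand.grid(rep(list(seq_len(k) - 1L), nnode))
  best <- Inf
  tip_states <- unname(tip_states)
  for (i in seq_len(nrow(grid))) {
    states <- c(tip_states, as.integer(grid[i, ]))
    cost <- abs(states[root] - root_state)
    cost <- cost + sum(abs(states[tree$edge[, 1L]] - states[tree$edge[, 2L]]))
    if (cost < best) best <- cost
  }
  best
}

# small random tree with named tips
random_tree <- function(ntips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(ntips, br = NULL)
    tr$tip.label <- paste0("t", seq_len(ntips))
    tr
  })
}
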