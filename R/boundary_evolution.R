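# IR boundary evolution: junction gene-content profiles and parsimony
# mapping of expansion/contraction events onto a phylogeny.
#
# Each gene is scored against the IR intervals as SC (single copy),
# partial_IR (spans a junction) or complete_IR. Across taxa the three
# states form an ordered ladder SC <-> partial_IR <-> complete_IR with unit
# step costs (a direct SC -> complete change costs 2, reflecting stepwise
# junction migration); events are the minimal-change state transitions on
# the branches of a given tree (small parsimony, Sankoff recursion), with
# ties resolved deterministically by placing changes as late (tipward) as
# possible and all co-optimal assignments countable and enumerable.

JUNCTIONS <- c("JLB", "JSB", "JSA", "JLA")

#' Profile IR membership of every gene
#'
#' @param features feature tibble (canonical orientation; IR copies of a
#'   gene share its name).
#' @param partition partition tibble.
#' @param taxon optional taxon label stored in the output.
#' @return tibble: `taxon`, `gene`, `state` (`SC`, `partial_IR`,
#'   `complete_IR`), `junction` (for partial genes, which junction is
#'   spanned). The attribute `junction_genes` holds the gene at each of the
#'   four junctions (JLB, JSB, JSA, JLA) or NA.
#' @export
profile_boundaries <- function(features, partition, taxon = NA_character_) {
  n <- partition_genome_length(partition)
  irb <- region_interval(partition, "IRb")
  ira <- region_interval(partition, "IRa")
  ir_pos <- c(interval_positions(irb$start, irb$end, n),
              interval_positions(ira$start, ira$end, n))
  junction_pos <- c(JLB = irb$start, JSB = irb$end %% n,
                    JSA = ira$start, JLA = ira$end %% n)
  per_copy <- purrr::map_dfr(split(features, features$feature_id), function(df) {
    pos <- unlist(purrr::map2(df$start, df$end, ~ interval_positions(.x, .y, n)))
    inside <- sum(pos %in% ir_pos)
    state <- if (inside == length(pos)) "complete_IR"
             else if (inside > 0L) "partial_IR" else "SC"
    junction <- NA_character_
    if (state == "partial_IR") {
      ext_start <- min(df$start)
      ext_end <- max(df$end)
      spanned <- names(junction_pos)[junction_pos > ext_start & junction_pos < ext_end]
      if (length(spanned) > 1L) {
        stop("gene '", df$gene[1L], "' overlaps two junctions", call. = FALSE)
      }
      junction <- if (length(spanned) == 1L) spanned else NA_character_
    }
    tibble::tibble(gene = df$gene[1L], state = state, junction = junction)
  })
  rank <- c(SC = 0L, partial_IR = 1L, complete_IR = 2L)
  out <- dplyr::summarise(
    dplyr::group_by(per_copy, .data$gene),
    state = names(rank)[max(rank[.data$state]) + 1L],
    junction = {
      j <- .data$junction[!is.na(.data$junction)]
      if (length(j) > 0L) j[1L] else NA_character_
    },
    .groups = "drop"
  )
  out <- dplyr::bind_cols(tibble::tibble(taxon = rep(taxon, nrow(out))), out)
  jg <- vapply(JUNCTIONS, function(jn) {
    holder <- out$gene[!is.na(out$junction) & out$junction == jn]
    if (length(holder) > 0L) holder[1L] else NA_character_
  }, character(1))
  attr(out, "junction_genes") <- tibble::tibble(junction = JUNCTIONS,
                                                gene = unname(jg))
  out
}

#' Diff a boundary profile against a reference architecture
#'
#' @param profile,reference_profile tibbles with `gene`, `state` columns
#'   (and optionally `junction`).
#' @return tibble of per-gene transitions: `gene`, `ref_state`,
#'   `obs_state`, `change` (`transition`, `gene_loss`, `gene_gain`),
#'   `junction` (attributed from the observed profile). Identical profiles
#'   give an empty diff.
#' @export
diff_profiles <- function(profile, reference_profile) {
  obs <- dplyr::select(profile, "gene", obs_state = "state",
                       dplyr::any_of("junction"))
  ref <- dplyr::select(reference_profile, "gene", ref_state = "state")
  j <- dplyr::full_join(ref, obs, by = "gene")
  if (!"junction" %in% names(j)) j$junction <- NA_character_
  j$change <- dplyr::case_when(
    is.na(j$obs_state) ~ "gene_loss",
    is.na(j$ref_state) ~ "gene_gain",
    j$ref_state != j$obs_state ~ "transition",
    TRUE ~ "none"
  )
  out <- j[j$change != "none", , drop = FALSE]
  dplyr::select(out, "gene", "ref_state", "obs_state", "change", "junction")
}

# Sankoff small parsimony for one ordered character.
# Returns minimal length, the late-as-possible optimal assignment, and the
# number of co-optimal assignments (with optional full enumeration).
sankoff_ordered <- function(tip_states, tree, root_state, k, enumerate = FALSE,
                            enum_cap = 5000L) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  root <- ntip + 1L
  edge <- tree$edge
  cost <- matrix(Inf, nrow = total, ncol = k)
  for (i in seq_len(ntip)) cost[i, tip_states[i] + 1L] <- 0
  po <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(edge[, 2L], edge[, 1L])
  # unit-step ordered-character cost between states
  step <- abs(outer(seq_len(k), seq_len(k), "-"))
  # internal nodes in postorder of their appearance as parents
  parents_po <- unique(po[, 1L])
  for (v in parents_po) {
    kids <- children[[as.character(v)]]
    cv <- rep(0, k)
    for (ch in kids) {
      cv <- cv + vapply(seq_len(k), function(s) min(cost[ch, ] + step[s, ]),
                        numeric(1))
    }
    cost[v, ] <- cv
  }
  rs <- root_state + 1L
  root_tot <- cost[root, ] + step[rs, ]
  len <- min(root_tot)
  # counting co-optimal assignments
  cnt <- matrix(0, nrow = total, ncol = k)
  cnt[seq_len(ntip), ] <- ifelse(is.finite(cost[seq_len(ntip), , drop = FALSE]), 1, 0)
  for (v in parents_po) {
    kids <- children[[as.character(v)]]
    for (s in seq_len(k)) {
      prod <- 1
      for (ch in kids) {
        opts <- cost[ch, ] + step[s, ]
        prod <- prod * sum(cnt[ch, opts == min(opts)])
      }
      cnt[v, s] <- prod
    }
  }
  n_optima <- sum(cnt[root, root_tot == len])
  # late-as-possible preferred assignment: keep the parent's state whenever
  # optimal, else smallest step, else lowest state
  assign <- integer(total)
  pick <- function(opts_cost, prefer) {
    best <- which(opts_cost == min(opts_cost))
    if (prefer %in% best) return(prefer)
    best[order(abs(best - prefer), best)][1L]
  }
  assign[root] <- pick(root_tot, rs)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre))) {
    v <- pre[e, 1L]
    ch <- pre[e, 2L]
    opts <- cost[ch, ] + step[assign[v], ]
    assign[ch] <- pick(opts, assign[v])
  }
  optima <- NULL
  if (enumerate && n_optima <= enum_cap) {
    optima <- list()
    # walk edges in preorder so every parent is assigned before its children
    recurse <- function(i, v_states) {
      if (i > nrow(pre)) {
        optima[[length(optima) + 1L]] <<- v_states
        return(invisible(NULL))
      }
      v <- pre[i, 1L]
      ch <- pre[i, 2L]
      opts <- cost[ch, ] + step[v_states[v], ]
      for (s in which(opts == min(opts))) {
        vs <- v_states
        vs[ch] <- s
        recurse(i + 1L, vs)
      }
    }
    for (s in which(root_tot == len)) {
      init <- rep(NA_integer_, total)
      init[root] <- s
      recurse(1L, init)
    }
  }
  list(length = len, assign = assign, n_optima = n_optima, optima = optima,
       root = root)
}

node_label <- function(tree, v) {
  ntip <- length(tree$tip.label)
  if (v <= ntip) tree$tip.label[v] else paste0("node", v)
}

#' Infer IR boundary expansion/contraction events on a tree
#'
#' Per-gene ordered-character parsimony (`SC` = 0, `partial_IR` = 1,
#' `complete_IR` = 2 with unit step costs; contractions cost the same as
#' expansions) over the given tree, with the root constrained to the
#' reference architecture. Each state change along a branch is emitted as
#' an event; among co-optimal reconstructions the reported one places
#' changes as late (tipward) as possible, and the number of co-optima is
#' reported (optionally enumerated). Gene presence/absence is a separate
#' binary character: use `states = c("absent", "present")`.
#'
#' @param profiles tibble with `taxon`, `gene`, `state` (and optionally
#'   `junction`).
#' @param tree an `ape::phylo` object or a newick string; tips must match
#'   the taxa.
#' @param root_state reference (root) architecture state, by default `SC`.
#' @param states the ordered state ladder.
#' @param enumerate also enumerate all co-optimal event placements.
#' @return list of class `boundary_events`: `events` (tibble `gene`,
#'   `parent`, `branch`, `from`, `to`, `cost`, `junction`), `lengths`
#'   (tibble `gene`, `parsimony_length`, `n_optima`), and `optima` (list
#'   of alternative event tibbles per gene when `enumerate = TRUE`).
#' @export
infer_events <- function(profiles, tree, root_state = "SC",
                         states = c("SC", "partial_IR", "complete_IR"),
                         enumerate = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  taxa <- unique(profiles$taxon)
  if (!setequal(taxa, tree$tip.label)) {
    stop("tree tips do not match profile taxa", call. = FALSE)
  }
  k <- length(states)
  junction_of <- dplyr::summarise(
    dplyr::group_by(profiles, .data$gene),
    junction = {
      j <- if ("junction" %in% names(profiles)) .data$junction[!is.na(.data$junction)]
           else character(0)
      if (length(j) > 0L) j[1L] else NA_character_
    },
    .groups = "drop"
  )
  genes <- unique(profiles$gene)
  events <- list()
  lengths <- list()
  optima_all <- list()
  for (g in genes) {
    pg <- profiles[profiles$gene == g, , drop = FALSE]
    st <- stats::setNames(match(pg$state, states) - 1L, pg$taxon)
    if (any(is.na(st))) stop("unknown state for gene ", g, call. = FALSE)
    tip_states <- st[tree$tip.label]
    if (any(is.na(tip_states))) {
      stop("taxon missing state for gene ", g, call. = FALSE)
    }
    rs <- match(root_state, states) - 1L
    res <- sankoff_ordered(tip_states, tree, rs, k, enumerate = enumerate)
    assign_to_events <- function(assign) {
      ev <- list()
      if (assign[res$root] != rs + 1L) {
        ev[[1L]] <- tibble::tibble(
          gene = g, parent = "root-reference", branch = node_label(tree, res$root),
          from = states[rs + 1L], to = states[assign[res$root]],
          cost = abs(assign[res$root] - rs - 1L)
        )
      }
      for (e in seq_len(nrow(tree$edge))) {
        v <- tree$edge[e, 1L]
        ch <- tree$edge[e, 2L]
        if (assign[v] != assign[ch]) {
          ev[[length(ev) + 1L]] <- tibble::tibble(
            gene = g, parent = node_label(tree, v), branch = node_label(tree, ch),
            from = states[assign[v]], to = states[assign[ch]],
            cost = abs(assign[ch] - assign[v])
          )
        }
      }
      if (length(ev) == 0L) return(NULL)
      dplyr::bind_rows(ev)
    }
    ev <- assign_to_events(res$assign)
    if (!is.null(ev)) events[[g]] <- ev
    lengths[[g]] <- tibble::tibble(gene = g, parsimony_length = res$length,
                                   n_optima = res$n_optima)
    if (enumerate && !is.null(res$optima)) {
      optima_all[[g]] <- purrr::compact(purrr::map(res$optima, assign_to_events))
    }
  }
  ev_tbl <- if (length(events) > 0L) dplyr::bind_rows(events) else
    tibble::tibble(gene = character(), parent = character(), branch = character(),
                   from = character(), to = character(), cost = integer())
  ev_tbl <- dplyr::left_join(ev_tbl, junction_of, by = "gene")
  out <- list(events = ev_tbl, lengths = dplyr::bind_rows(lengths),
              optima = if (enumerate) optima_all else NULL)
  class(out) <- "boundary_events"
  out
}

#' @export
print.boundary_events <- function(x, ...) {
  cat(sprintf("<boundary_events> %d events over %d genes (total length %d)\n",
              nrow(x$events), nrow(x$lengths), sum(x$lengths$parsimony_length)))
  invisible(x)
}

#' @method tidy boundary_events
#' @export
tidy.boundary_events <- function(x, ...) x$events

#' @method glance boundary_events
#' @export
glance.boundary_events <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$events),
    n_genes = nrow(x$lengths),
    total_length = sum(x$lengths$parsimony_length)
  )
}
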