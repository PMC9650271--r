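#' Anchoring configuration
#'
#' Collects every free threshold of the anchoring pipeline in one place so
#' a run is reproducible from its configuration alone.
#'
#' @param min_mapq Minimum marker alignment mapping quality.
#' @param min_identity Minimum marker alignment identity.
#' @param min_fraction Minimum linkage-group plurality fraction.
#' @param min_markers Minimum markers for linkage-group assignment.
#' @param max_end_dist Maximum alignment-to-terminus distance (bp).
#' @param min_overhang Minimum read overhang beyond a terminus (bp).
#' @param min_reads Minimum supporting reads/pairs per end link.
#' @param gap_length Gap (bp of `N`) inserted between joined scaffolds.
#' @return A list of class `anchor_config`.
#' @export
anchor_config <- function(min_mapq = 0, min_identity = 0.9,
                          min_fraction = 0.6, min_markers = 2L,
                          max_end_dist = 500, min_overhang = 150,
                          min_reads = 3L, gap_length = 100L) {
  cfg <- list(min_mapq = min_mapq, min_identity = min_identity,
              min_fraction = min_fraction, min_markers = min_markers,
              max_end_dist = max_end_dist, min_overhang = min_overhang,
              min_reads = min_reads, gap_length = gap_length)
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x >= 0, logical(1))))
  structure(cfg, class = "anchor_config")
}

#' Build the typed evidence graph over scaffold ends
#'
#' Every scaffold contributes two nodes (its `L` and `R` ends); edges are
#' end links from long reads and BAC pairs plus `marker_adjacency` edges
#' joining the facing ends of consecutive scaffolds in map order within
#' each linkage group. Duplicate links (same end pair, same source) are
#' merged with supports summed.
#'
#' @param assignments Tibble from [assign_linkage_groups()] covering the
#'   full scaffold set.
#' @param map_stats Tibble from [scaffold_map_stats()].
#' @param links Link tibble(s) from [build_end_links()] /
#'   [bac_end_links()], row-bound.
#' @param scaffold_lens Named numeric vector of scaffold lengths (used for
#'   deterministic tie-breaks in map order).
#' @return A list of class `evidence_graph` with tibbles `nodes` and
#'   `edges`.
#' @export
build_graph <- function(assignments, map_stats, links = NULL,
                        scaffold_lens = NULL) {
  links <- links %||% empty_links()
  unknown <- setdiff(c(links$scaffold_a, links$scaffold_b),
                     assignments$scaffold)
  if (length(unknown) > 0L) {
    abort(sprintf("link names unknown scaffold: %s", unknown[1]))
  }
  nodes <- assignments |>
    dplyr::left_join(map_stats, by = "scaffold") |>
    tidyr::crossing(end = c("L", "R")) |>
    dplyr::arrange(.data$scaffold, .data$end)
  if (!is.null(scaffold_lens)) {
    nodes$length <- unname(scaffold_lens[nodes$scaffold])
  } else {
    nodes$length <- NA_real_
  }
  self_loop <- links$scaffold_a == links$scaffold_b
  if (any(self_loop)) abort("link joins the two ends of one scaffold")
  edges <- links |>
    dplyr::group_by(.data$scaffold_a, .data$end_a, .data$scaffold_b,
                    .data$end_b, .data$source) |>
    dplyr::summarise(support = sum(.data$support), .groups = "drop")
  adj <- marker_adjacency_edges(nodes)
  edges <- dplyr::bind_rows(edges, adj) |>
    dplyr::arrange(.data$scaffold_a, .data$end_a, .data$scaffold_b,
                   .data$end_b, .data$source)
  structure(list(nodes = nodes, edges = edges), class = "evidence_graph")
}

# Facing ends of consecutive scaffolds in cM order within each LG: the
# trailing end of the first (R if "+", L if "-") meets the leading end of
# the next (L if "+", R if "-").
marker_adjacency_edges <- function(nodes) {
  ordered <- nodes |>
    dplyr::filter(.data$end == "L", !is.na(.data$linkage_group),
                  !is.na(.data$median_cM)) |>
    dplyr::mutate(orientation = ifelse(.data$orientation_score < 0, "-", "+")) |>
    dplyr::arrange(.data$linkage_group, .data$median_cM,
                   dplyr::desc(.data$length), .data$scaffold) |>
    dplyr::group_by(.data$linkage_group)
  if (dplyr::n_groups(ordered) == 0L) return(empty_links())
  adj <- ordered |>
    dplyr::reframe(
      scaffold_a = head(.data$scaffold, -1),
      end_a = ifelse(head(.data$orientation, -1) == "+", "R", "L"),
      scaffold_b = tail(.data$scaffold, -1),
      end_b = ifelse(tail(.data$orientation, -1) == "+", "L", "R")
    ) |>
    dplyr::select(-"linkage_group")
  if (nrow(adj) == 0L) return(empty_links())
  canonical_links(adj) |>
    dplyr::mutate(support = 1L, source = "marker_adjacency")
}

#' Classify scaffold-pair evidence concordance
#'
#' Reduces the edge multiset to one verdict per scaffold pair: pairs whose
#' edges agree on a single end pairing and draw on two or more evidence
#' sources are `concordant`; pairs with one source are `single_source`;
#' pairs whose edges imply incompatible end pairings are `conflicting`.
#'
#' @param graph An `evidence_graph` from [build_graph()].
#' @return A tibble with columns `scaffold_a`, `scaffold_b`, `n_sources`,
#'   `n_end_pairings`, `status`.
#' @export
classify_concordance <- function(graph) {
  edges <- graph$edges
  if (nrow(edges) == 0L) {
    return(tibble::tibble(scaffold_a = character(), scaffold_b = character(),
                          n_sources = integer(), n_end_pairings = integer(),
                          status = character()))
  }
  edges |>
    dplyr::group_by(.data$scaffold_a, .data$scaffold_b) |>
    dplyr::summarise(
      n_sources = dplyr::n_distinct(.data$source),
      n_end_pairings = dplyr::n_distinct(paste(.data$end_a, .data$end_b)),
      .groups = "drop"
    ) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_end_pairings > 1L ~ "conflicting",
      .data$n_sources >= 2L ~ "concordant",
      TRUE ~ "single_source"
    ))
}

#' Order and orient marker-assigned scaffolds per linkage group
#'
#' Within each linkage group, scaffolds are sorted by ascending median
#' centimorgan position; ties fall back to longer-scaffold-first, then
#' lexicographic name, so output is fully deterministic. Orientation
#' follows the sign of the rank-correlation orientation score; a zero
#' score (typically a single marker) is placed `+` and flagged. Scaffolds
#' with no linkage-group assignment go to the unplaced set.
#'
#' @param graph An `evidence_graph` from [build_graph()].
#' @param config An [anchor_config()].
#' @return A list of class `chromosome_builds`: `entries` (tibble with
#'   `linkage_group`, `rank`, `scaffold`, `orientation`, `placed_by`,
#'   `median_cM`, `orientation_flagged`) and `unplaced` (character).
#' @export
order_and_orient <- function(graph, config = anchor_config()) {
  scafs <- graph$nodes |> dplyr::filter(.data$end == "L")
  placed <- scafs |>
    dplyr::filter(!is.na(.data$linkage_group), !is.na(.data$median_cM)) |>
    dplyr::mutate(
      orientation = dplyr::case_when(.data$orientation_score > 0 ~ "+",
                                     .data$orientation_score < 0 ~ "-",
                                     TRUE ~ "+"),
      orientation_flagged = .data$orientation_score == 0,
      placed_by = "marker"
    ) |>
    dplyr::arrange(.data$linkage_group, .data$median_cM,
                   dplyr::desc(.data$length), .data$scaffold) |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("linkage_group", "rank", "scaffold", "orientation",
                  "placed_by", "median_cM", "orientation_flagged")
  if (any(placed$orientation_flagged)) {
    warn(sprintf(
      "%d scaffold(s) with zero orientation score placed '+' by convention",
      sum(placed$orientation_flagged)))
  }
  unplaced <- sort(setdiff(scafs$scaffold, placed$scaffold))
  structure(list(entries = placed, unplaced = unplaced),
            class = "chromosome_builds")
}

#' Insert marker-less scaffolds beside their linked partners
#'
#' Each unplaced scaffold with exactly one non-conflicting long-read link
#' to one placed scaffold is inserted adjacent to that scaffold on the
#' linked side, oriented so its linking end faces its partner. Marker
#' ordering is authoritative: insertion never reorders placed entries, and
#' BAC links never trigger insertion (they participate in concordance
#' classification only). Scaffolds with zero, multiple, or conflicting
#' links remain unplaced.
#'
#' @param builds A `chromosome_builds` from [order_and_orient()].
#' @param graph The `evidence_graph` the builds came from.
#' @param config An [anchor_config()].
#' @return The updated `chromosome_builds`, inserted entries carrying
#'   `placed_by = "overlap"`.
#' @export
insert_unplaced <- function(builds, graph, config = anchor_config()) {
  conc <- classify_concordance(graph)
  conflicted <- conc |> dplyr::filter(.data$status == "conflicting")
  lr <- graph$edges |>
    dplyr::filter(.data$source == "long_read") |>
    dplyr::anti_join(conflicted, by = c("scaffold_a", "scaffold_b"))
  entries <- builds$entries
  still_unplaced <- character(0)
  for (x in builds$unplaced) {
    cand <- dplyr::bind_rows(
      lr |> dplyr::filter(.data$scaffold_a == x) |>
        dplyr::transmute(x_end = .data$end_a, partner = .data$scaffold_b,
                         p_end = .data$end_b),
      lr |> dplyr::filter(.data$scaffold_b == x) |>
        dplyr::transmute(x_end = .data$end_b, partner = .data$scaffold_a,
                         p_end = .data$end_a)
    ) |>
      dplyr::filter(.data$partner %in% entries$scaffold) |>
      dplyr::distinct()
    if (nrow(cand) != 1L) {
      still_unplaced <- c(still_unplaced, x)
      next
    }
    p <- entries[entries$scaffold == cand$partner, ]
    # global side: the partner's R end points downstream when placed "+",
    # upstream when placed "-"
    after <- (cand$p_end == "R") == (p$orientation == "+")
    orient <- if (after) {
      if (cand$x_end == "L") "+" else "-"
    } else {
      if (cand$x_end == "R") "+" else "-"
    }
    idx <- which(entries$scaffold == cand$partner)
    new_row <- tibble::tibble(
      linkage_group = p$linkage_group, rank = NA_integer_, scaffold = x,
      orientation = orient, placed_by = "overlap", median_cM = NA_real_,
      orientation_flagged = FALSE
    )
    pos <- if (after) idx else idx - 1L
    entries <- dplyr::bind_rows(
      entries[seq_len(pos), , drop = FALSE],
      new_row,
      if (pos < nrow(entries)) entries[(pos + 1L):nrow(entries), , drop = FALSE]
    )
  }
  entries <- entries |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  structure(list(entries = entries, unplaced = still_unplaced),
            class = "chromosome_builds")
}

#' Anchor scaffolds to linkage groups end to end
#'
#' Runs the full anchoring pipeline: marker placement, linkage-group
#' assignment, map statistics, end-link construction from long reads and
#' BAC pairs, evidence-graph assembly, concordance classification,
#' ordering/orientation, and overlap-based insertion of marker-less
#' scaffolds.
#'
#' @param scaffolds Tibble of scaffold sequences (`name`, `seq`), or a
#'   named numeric vector of scaffold lengths.
#' @param marker_aln PAF tibble of marker alignments.
#' @param marker_map Genetic map tibble ([read_marker_map()]).
#' @param read_aln Optional PAF tibble of long-read alignments.
#' @param bac_aln Optional PAF tibble of BAC end alignments.
#' @param config An [anchor_config()].
#' @return An object of class `anchor_result`: list with `builds`,
#'   `graph`, `concordance`, `placements`, `assignments`, `map_stats`,
#'   `links`, `scaffold_lens`, `config`.
#' @export
anchor_scaffolds <- function(scaffolds, marker_aln, marker_map,
                             read_aln = NULL, bac_aln = NULL,
                             config = anchor_config()) {
  scaffold_lens <- if (is.data.frame(scaffolds)) {
    setNames(nchar(scaffolds$seq), scaffolds$name)
  } else scaffolds
  placements <- place_markers(marker_aln, marker_map,
                              min_mapq = config$min_mapq,
                              min_identity = config$min_identity)
  assignments <- assign_linkage_groups(placements,
                                       scaffolds = names(scaffold_lens),
                                       min_fraction = config$min_fraction,
                                       min_markers = config$min_markers)
  map_stats <- scaffold_map_stats(placements, assignments)
  links <- empty_links()
  if (!is.null(read_aln) && nrow(read_aln) > 0L) {
    hits <- detect_overhangs(read_aln, max_end_dist = config$max_end_dist,
                             min_overhang = config$min_overhang)
    links <- dplyr::bind_rows(links,
                              build_end_links(hits, min_reads = config$min_reads))
  }
  if (!is.null(bac_aln) && nrow(bac_aln) > 0L) {
    links <- dplyr::bind_rows(
      links, bac_end_links(bac_aln, min_reads = config$min_reads))
  }
  graph <- build_graph(assignments, map_stats, links, scaffold_lens)
  builds <- order_and_orient(graph, config) |>
    insert_unplaced(graph, config)
  structure(list(
    builds = builds, graph = graph,
    concordance = classify_concordance(graph),
    placements = placements, assignments = assignments,
    map_stats = map_stats, links = links,
    scaffold_lens = scaffold_lens, config = config
  ), class = "anchor_result")
}

#' @export
print.anchor_result <- function(x, ...) {
  e <- x$builds$entries
  cat(sprintf(
    "<anchor_result> %d linkage group(s), %d placed scaffold(s) (%d by overlap), %d unplaced\n",
    dplyr::n_distinct(e$linkage_group), nrow(e),
    sum(e$placed_by == "overlap"), length(x$builds$unplaced)))
  invisible(x)
}

#' @export
print.chromosome_builds <- function(x, ...) {
  cat(sprintf("<chromosome_builds> %d entries across %d LG(s), %d unplaced\n",
              nrow(x$entries), dplyr::n_distinct(x$entries$linkage_group),
              length(x$unplaced)))
  invisible(x)
}
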