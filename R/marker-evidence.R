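#' Place genetic-map markers on scaffolds
#'
#' Joins marker-to-scaffold alignments with the genetic map and reduces
#' them to at most one placement per marker: alignments failing the mapping
#' quality or identity filters are dropped, and for each surviving marker
#' only the single best alignment (highest matching-base count) is kept.
#' Markers whose best score is tied across alignments are excluded as
#' ambiguous — repeat-borne markers must not create false joins. The
#' placement position is the midpoint of the target interval, which keeps
#' short-marker bookkeeping strand-free.
#'
#' @param alignments PAF tibble of marker alignments (query = marker).
#' @param map Genetic map tibble from [read_marker_map()].
#' @param min_mapq Minimum mapping quality (default 0: keep all).
#' @param min_identity Minimum `n_match / aln_len` (default 0).
#' @return A tibble with columns `marker_id`, `scaffold`, `scaffold_pos`
#'   (0-based target midpoint), `strand`, `linkage_group`, `pos_cM`.
#'   Exclusion counts are attached as attribute `"log"`.
#' @export
place_markers <- function(alignments, map, min_mapq = 0, min_identity = 0) {
  aln <- alignments
  n_unknown <- sum(!aln$qname %in% map$marker_id)
  aln <- aln |> dplyr::filter(.data$qname %in% map$marker_id)
  n_filtered <- sum(aln$mapq < min_mapq | aln$n_match / aln$aln_len < min_identity)
  aln <- aln |>
    dplyr::filter(.data$mapq >= min_mapq,
                  .data$n_match / .data$aln_len >= min_identity)
  best <- if (nrow(aln) == 0L) aln else {
    aln |>
      dplyr::group_by(.data$qname) |>
      dplyr::filter(.data$n_match == max(.data$n_match)) |>
      dplyr::ungroup()
  }
  tie_counts <- dplyr::count(best, .data$qname)
  ambiguous <- tie_counts$qname[tie_counts$n > 1]
  placements <- best |>
    dplyr::filter(!.data$qname %in% ambiguous) |>
    dplyr::transmute(
      marker_id = .data$qname,
      scaffold = .data$tname,
      scaffold_pos = floor((.data$tstart + .data$tend) / 2),
      strand = .data$strand
    ) |>
    dplyr::inner_join(map, by = "marker_id") |>
    dplyr::arrange(.data$scaffold, .data$scaffold_pos)
  attr(placements, "log") <- list(
    n_unknown_marker = n_unknown,
    n_filtered = n_filtered,
    ambiguous = ambiguous
  )
  placements
}

#' Assign scaffolds to linkage groups by marker plurality
#'
#' A scaffold is assigned to the linkage group carrying a plurality of its
#' placed markers, provided that plurality reaches `min_fraction` of the
#' scaffold's markers and the scaffold carries at least `min_markers`
#' markers; otherwise it is reported `UNASSIGNED` with a reason
#' (`ambiguous` or `no_markers`). A single stray marker therefore never
#' anchors a scaffold.
#'
#' @param placements Tibble from [place_markers()].
#' @param scaffolds Optional character vector of all scaffold names, so
#'   marker-less scaffolds appear with reason `no_markers`.
#' @param min_fraction Minimum plurality fraction (default 0.6).
#' @param min_markers Minimum marker count for assignment (default 2).
#' @return A tibble with columns `scaffold`, `linkage_group` (or `NA` when
#'   unassigned), `n_markers`, `majority_fraction`, `reason`.
#' @export
assign_linkage_groups <- function(placements, scaffolds = NULL,
                                  min_fraction = 0.6, min_markers = 2L) {
  counts <- placements |>
    dplyr::count(.data$scaffold, .data$linkage_group, name = "n_lg") |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(
      n_markers = sum(.data$n_lg),
      top_n = max(.data$n_lg),
      n_top_lgs = sum(.data$n_lg == max(.data$n_lg)),
      top_lg = .data$linkage_group[which.max(.data$n_lg)],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      majority_fraction = .data$top_n / .data$n_markers,
      assigned = .data$n_top_lgs == 1L &
        .data$majority_fraction >= min_fraction &
        .data$n_markers >= min_markers,
      linkage_group = ifelse(.data$assigned, .data$top_lg, NA_character_),
      reason = ifelse(.data$assigned, NA_character_, "ambiguous")
    ) |>
    dplyr::select("scaffold", "linkage_group", "n_markers",
                  "majority_fraction", "reason")
  if (!is.null(scaffolds)) {
    missing <- setdiff(scaffolds, counts$scaffold)
    counts <- dplyr::bind_rows(counts, tibble::tibble(
      scaffold = missing, linkage_group = NA_character_,
      n_markers = 0L, majority_fraction = NA_real_, reason = "no_markers"
    ))
  }
  dplyr::arrange(counts, .data$scaffold)
}

#' Per-scaffold map position and orientation score
#'
#' For each assigned scaffold, reduces its on-linkage-group marker
#' placements to a median centimorgan position (used for ordering) and an
#' orientation score: the Spearman rank correlation between base-pair
#' position on the scaffold and map position, in \eqn{[-1, 1]}. Rank
#' correlation is robust to nonuniform cM/bp scaling. A scaffold with a
#' single usable marker gets score 0 (orientation unknowable); downstream
#' such scaffolds are placed `+` with a warning flag.
#'
#' @param placements Tibble from [place_markers()].
#' @param assignments Tibble from [assign_linkage_groups()]; placements on
#'   a linkage group other than the scaffold's assigned one are excluded.
#' @return A tibble with columns `scaffold`, `median_cM`,
#'   `orientation_score`, `n_used`.
#' @export
scaffold_map_stats <- function(placements, assignments) {
  assigned <- assignments |>
    dplyr::filter(!is.na(.data$linkage_group)) |>
    dplyr::select("scaffold", "linkage_group")
  placements |>
    dplyr::inner_join(assigned, by = c("scaffold", "linkage_group")) |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(
      median_cM = median(.data$pos_cM),
      orientation_score = rank_orientation(.data$scaffold_pos, .data$pos_cM),
      n_used = dplyr::n(),
      .groups = "drop"
    )
}

rank_orientation <- function(bp, cm) {
  if (length(bp) < 2L) return(0)
  r <- suppressWarnings(cor(bp, cm, method = "spearman"))
  if (is.na(r)) 0 else r
}
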