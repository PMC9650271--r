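#' Reverse-complement DNA strings
#'
#' @param seq Character vector over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
seq_revcomp <- function(seq) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

#' Materialize a chromosome build as AGP rows
#'
#' Produces alternating component (`W`) and gap (`U`) rows per linkage
#' group, 1-based inclusive coordinates, object named after the linkage
#' group. Gap rows carry `gap_type = "scaffold"`, `linkage = "yes"` and an
#' evidence field recording provenance: `"map"` for joins between
#' marker-ordered scaffolds, `"paired-ends"` where either flank was
#' inserted by overlap evidence.
#'
#' @param builds A `chromosome_builds` from [order_and_orient()] /
#'   [insert_unplaced()].
#' @param scaffold_lens Named numeric vector of scaffold lengths.
#' @param gap_length Gap size in bp of `N` (default 100, the conventional
#'   unknown-gap size).
#' @return A tibble of AGP rows suitable for [write_agp()] /
#'   [agp2fasta()].
#' @export
make_agp <- function(builds, scaffold_lens, gap_length = 100L) {
  entries <- builds$entries
  if (nrow(entries) == 0L) abort("empty build: nothing to write")
  missing <- setdiff(entries$scaffold, names(scaffold_lens))
  if (length(missing) > 0L) {
    abort(sprintf("no length known for scaffold %s", missing[1]))
  }
  rows <- entries |>
    dplyr::group_split(.data$linkage_group) |>
    purrr::map(function(e) {
      lens <- as.numeric(unname(scaffold_lens[e$scaffold]))
      n <- nrow(e)
      gap_length <- as.numeric(gap_length)
      gap_evidence <- if (n > 1) {
        ifelse(e$placed_by[-n] == "overlap" | e$placed_by[-1] == "overlap",
               "paired-ends", "map")
      } else character(0)
      part_lens <- as.vector(rbind(lens, c(rep(gap_length, n - 1), NA)))
      part_lens <- part_lens[!is.na(part_lens)]
      ends <- cumsum(part_lens)
      begs <- ends - part_lens + 1
      is_w <- seq_along(part_lens) %% 2 == 1
      tibble::tibble(
        object = e$linkage_group[1],
        object_beg = begs, object_end = ends,
        part_number = seq_along(part_lens),
        component_type = ifelse(is_w, "W", "U"),
        component_id = ifelse(is_w, rep_interleave(e$scaffold, n), NA),
        component_beg = ifelse(is_w, 1, NA),
        component_end = ifelse(is_w, rep_interleave(lens, n), NA),
        orientation = ifelse(is_w, rep_interleave(e$orientation, n), NA),
        gap_length = ifelse(is_w, NA, gap_length),
        gap_type = ifelse(is_w, NA, "scaffold"),
        linkage = ifelse(is_w, NA, "yes"),
        evidence = ifelse(is_w, NA, rep_interleave_gap(gap_evidence, n))
      )
    }) |>
    purrr::list_rbind()
  validate_agp(rows)
  rows
}

# interleave component values with NA gap slots: c(v1, NA, v2, NA, ..., vn)
rep_interleave <- function(v, n) {
  out <- rep(NA, 2 * n - 1)
  out[seq(1, 2 * n - 1, by = 2)] <- v
  out
}

rep_interleave_gap <- function(g, n) {
  out <- rep(NA, 2 * n - 1)
  if (n > 1) out[seq(2, 2 * n - 2, by = 2)] <- g
  out
}

#' Stitch AGP rows and component sequences into pseudomolecules
#'
#' Component rows contribute the referenced substring (1-based inclusive),
#' reverse-complemented when the orientation is `-`; gap rows contribute
#' `gap_length` `N` bases. The output length of each object equals its
#' final `object_end`.
#'
#' @param agp A tibble of AGP rows.
#' @param scaffolds Tibble of component sequences (`name`, `seq`).
#' @return A tibble of stitched sequences (`name`, `seq`), one per AGP
#'   object.
#' @export
agp2fasta <- function(agp, scaffolds) {
  validate_agp(agp)
  seqs <- setNames(scaffolds$seq, scaffolds$name)
  missing <- setdiff(agp$component_id[agp$component_type == "W"], names(seqs))
  if (length(missing) > 0L) {
    abort(sprintf("component %s not found among scaffolds", missing[1]))
  }
  out <- unique(agp$object) |>
    purrr::map(function(o) {
      rows <- agp[agp$object == o, , drop = FALSE]
      pieces <- purrr::pmap_chr(rows, function(component_type, component_id,
                                               component_beg, component_end,
                                               orientation, gap_length, ...) {
        if (component_type == "W") {
          piece <- substr(seqs[[component_id]], component_beg, component_end)
          if (orientation == "-") seq_revcomp(piece) else piece
        } else {
          strrep("N", gap_length)
        }
      })
      tibble::tibble(name = rows$object[1],
                     seq = paste(pieces, collapse = ""))
    }) |>
    purrr::list_rbind()
  stopifnot(nchar(out$seq) ==
              tapply(agp$object_end, factor(agp$object, levels = out$name), max))
  out
}
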