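#' Detect long reads overhanging scaffold termini
#'
#' A read alignment supports a scaffold end when it reaches within
#' `max_end_dist` of the terminus and the read carries at least
#' `min_overhang` unaligned bases extending beyond it. On the `+` strand
#' the sequence beyond the right terminus is the read tail (`qlen - qend`)
#' and the sequence before the left terminus is the read head (`qstart`);
#' on the `-` strand the two are swapped. One read may hit ends of several
#' scaffolds (a split alignment across a junction); interior alignments are
#' ignored.
#'
#' @param alignments PAF tibble of long-read-to-scaffold alignments.
#' @param max_end_dist Maximum distance (bp) between the alignment terminus
#'   and the scaffold terminus (default 500, tolerating ragged scaffold
#'   ends).
#' @param min_overhang Minimum unaligned read extension beyond the terminus
#'   (default 150).
#' @return A tibble with columns `read_id`, `scaffold`, `end` (`"L"` or
#'   `"R"`), `aligned_span`, `overhang_len`, `strand`.
#' @export
detect_overhangs <- function(alignments, max_end_dist = 500,
                             min_overhang = 150) {
  aln <- alignments |>
    dplyr::mutate(
      head_ext = ifelse(.data$strand == "+", .data$qstart,
                        .data$qlen - .data$qend),
      tail_ext = ifelse(.data$strand == "+", .data$qlen - .data$qend,
                        .data$qstart),
      near_l = .data$tstart <= max_end_dist,
      near_r = .data$tend >= .data$tlen - max_end_dist
    )
  hit_l <- aln |>
    dplyr::filter(.data$near_l, .data$head_ext >= min_overhang) |>
    dplyr::transmute(read_id = .data$qname, scaffold = .data$tname,
                     end = "L", aligned_span = .data$tend - .data$tstart,
                     overhang_len = .data$head_ext, strand = .data$strand)
  hit_r <- aln |>
    dplyr::filter(.data$near_r, .data$tail_ext >= min_overhang) |>
    dplyr::transmute(read_id = .data$qname, scaffold = .data$tname,
                     end = "R", aligned_span = .data$tend - .data$tstart,
                     overhang_len = .data$tail_ext, strand = .data$strand)
  dplyr::bind_rows(hit_l, hit_r) |>
    dplyr::arrange(.data$read_id, .data$scaffold, .data$end)
}

canonical_links <- function(cand) {
  flip <- paste(cand$scaffold_a, cand$end_a) > paste(cand$scaffold_b, cand$end_b)
  out <- cand
  out$scaffold_a <- ifelse(flip, cand$scaffold_b, cand$scaffold_a)
  out$end_a <- ifelse(flip, cand$end_b, cand$end_a)
  out$scaffold_b <- ifelse(flip, cand$scaffold_a, cand$scaffold_b)
  out$end_b <- ifelse(flip, cand$end_a, cand$end_b)
  out
}

aggregate_links <- function(cand, min_reads, source) {
  canonical_links(cand) |>
    dplyr::distinct(.data$read_id, .data$scaffold_a, .data$end_a,
                    .data$scaffold_b, .data$end_b) |>
    dplyr::count(.data$scaffold_a, .data$end_a, .data$scaffold_b,
                 .data$end_b, name = "support") |>
    dplyr::filter(.data$support >= min_reads) |>
    dplyr::mutate(source = source) |>
    dplyr::arrange(.data$scaffold_a, .data$end_a, .data$scaffold_b,
                   .data$end_b)
}

empty_links <- function() {
  tibble::tibble(scaffold_a = character(), end_a = character(),
                 scaffold_b = character(), end_b = character(),
                 support = integer(), source = character())
}

#' Build weighted end-to-end links from overhang hits
#'
#' Each read whose overhang hits implicate exactly two scaffolds
#' contributes one candidate adjacency between the two implicated ends;
#' reads hitting more than two scaffolds are discarded as unreliable.
#' Candidates are aggregated over distinct reads (a read is never counted
#' twice for one link) and links supported by fewer than `min_reads` reads
#' are dropped. End pairs are canonicalized lexicographically so output is
#' independent of input order.
#'
#' @param hits Tibble from [detect_overhangs()].
#' @param min_reads Minimum distinct supporting reads (default 3).
#' @return A link tibble with columns `scaffold_a`, `end_a`, `scaffold_b`,
#'   `end_b`, `support`, `source` (`"long_read"`).
#' @export
build_end_links <- function(hits, min_reads = 3L) {
  if (nrow(hits) == 0L) return(empty_links())
  per_read <- hits |>
    # one hit per read+scaffold: keep the longest-aligned one
    dplyr::group_by(.data$read_id, .data$scaffold) |>
    dplyr::slice_max(.data$aligned_span, n = 1L, with_ties = FALSE) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(dplyr::n() == 2L) |>
    dplyr::summarise(
      scaffold_a = .data$scaffold[1], end_a = .data$end[1],
      scaffold_b = .data$scaffold[2], end_b = .data$end[2],
      .groups = "drop"
    )
  if (nrow(per_read) == 0L) return(empty_links())
  aggregate_links(per_read, min_reads, "long_read")
}

#' Build end links from BAC end mate pairs
#'
#' Mates are paired by a shared name stem (trailing `/1`, `/2`, `_1`,
#' `_2`, `.1`, `.2`, `_F`, `_R` suffixes are stripped). Pairs whose mates
#' best-align (highest matching-base count) to different scaffolds yield a
#' candidate link between the scaffold ends nearest each mate; aggregation
#' and support thresholding mirror [build_end_links()]. Unpaired names are
#' skipped and counted in the attached `"log"` attribute.
#'
#' @param alignments PAF tibble of BAC end alignments.
#' @param min_reads Minimum distinct supporting pairs (default 3).
#' @return A link tibble with `source = "bac"`.
#' @export
bac_end_links <- function(alignments, min_reads = 3L) {
  if (nrow(alignments) == 0L) return(empty_links())
  best <- alignments |>
    dplyr::mutate(stem = bac_stem(.data$qname)) |>
    dplyr::group_by(.data$qname) |>
    dplyr::slice_max(.data$n_match, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  mates <- best |>
    dplyr::group_by(.data$stem) |>
    dplyr::filter(dplyr::n_distinct(.data$qname) == 2L) |>
    dplyr::arrange(.data$qname, .by_group = TRUE) |>
    dplyr::summarise(
      scaffold_a = .data$tname[1],
      end_a = nearest_end(.data$tstart[1], .data$tend[1], .data$tlen[1]),
      scaffold_b = .data$tname[2],
      end_b = nearest_end(.data$tstart[2], .data$tend[2], .data$tlen[2]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$scaffold_a != .data$scaffold_b) |>
    dplyr::rename(read_id = "stem")
  n_unpaired <- dplyr::n_distinct(best$stem) - dplyr::n_distinct(mates$read_id)
  out <- if (nrow(mates) == 0L) empty_links() else {
    aggregate_links(mates, min_reads, "bac")
  }
  attr(out, "log") <- list(n_unpaired_or_same = n_unpaired)
  out
}

bac_stem <- function(qname) {
  sub("[/_.](1|2|F|R)$", "", qname)
}

nearest_end <- function(tstart, tend, tlen) {
  ifelse((tstart + tend) / 2 < tlen / 2, "L", "R")
}
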