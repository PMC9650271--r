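#' Run the anchoring pipeline over files
#'
#' File-level front end: reads a scaffold FASTA, marker PAF, and genetic
#' map (long-read and BAC PAFs optional), runs [anchor_scaffolds()], and
#' writes a build table, concordance report, AGP, and stitched
#' pseudomolecule FASTA. Outputs are deterministic for identical inputs
#' and carry a versioned header comment.
#'
#' @param scaffold_fa Path to the scaffold FASTA (required).
#' @param marker_paf Path to the marker alignment PAF (required).
#' @param marker_map Path to the genetic map TSV (required).
#' @param read_paf,bac_paf Optional paths to long-read / BAC end PAFs.
#' @param out_dir Output directory (created if needed).
#' @param config An [anchor_config()].
#' @return Invisibly, the `anchor_result`, with written paths attached as
#'   attribute `"paths"`.
#' @export
run_anchor <- function(scaffold_fa, marker_paf, marker_map,
                       read_paf = NULL, bac_paf = NULL,
                       out_dir = ".", config = anchor_config()) {
  for (f in c(scaffold_fa, marker_paf, marker_map)) {
    if (!file.exists(f)) {
      abort(sprintf("mandatory input missing: %s", f),
            class = "linkanchor_missing_input")
    }
  }
  scaffolds <- read_fasta(scaffold_fa)
  m_aln <- read_paf(marker_paf)
  map <- read_marker_map(marker_map)
  r_aln <- if (!is.null(read_paf)) read_paf(read_paf) else NULL
  b_aln <- if (!is.null(bac_paf)) read_paf(bac_paf) else NULL
  res <- anchor_scaffolds(scaffolds, m_aln, map, read_aln = r_aln,
                          bac_aln = b_aln, config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# linkanchor %s",
                 as.character(utils::packageVersion("linkanchor")))
  paths <- list(
    build = file.path(out_dir, "build.tsv"),
    concordance = file.path(out_dir, "concordance.tsv"),
    agp = file.path(out_dir, "super_scaffolds.agp"),
    fasta = file.path(out_dir, "super_scaffolds.fa")
  )
  write_tsv_commented(tidy(res), paths$build, hdr)
  write_tsv_commented(res$concordance, paths$concordance, hdr)
  agp <- make_agp(res$builds, res$scaffold_lens,
                  gap_length = config$gap_length)
  write_agp(agp, paths$agp)
  write_fasta(agp2fasta(agp, scaffolds), paths$fasta)
  attr(res, "paths") <- paths
  invisible(res)
}

write_tsv_commented <- function(tbl, path, header) {
  writeLines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @method tidy anchor_result
#' @export
tidy.anchor_result <- function(x, ...) {
  x$builds$entries |>
    dplyr::select("linkage_group", "rank", "scaffold", "orientation",
                  "placed_by", "median_cM")
}

#' @method glance anchor_result
#' @export
glance.anchor_result <- function(x, ...) {
  e <- x$builds$entries
  tibble::tibble(
    n_linkage_groups = dplyr::n_distinct(e$linkage_group),
    n_placed = nrow(e),
    n_by_marker = sum(e$placed_by == "marker"),
    n_by_overlap = sum(e$placed_by == "overlap"),
    n_unplaced = length(x$builds$unplaced),
    n_markers_placed = nrow(x$placements),
    n_links = nrow(x$links),
    n_concordant = sum(x$concordance$status == "concordant"),
    n_conflicting = sum(x$concordance$status == "conflicting")
  )
}

#' @method tidy qv_report
#' @export
tidy.qv_report <- function(x, ...) {
  tibble::tibble(k = x$k, k_asm_total = x$k_asm_total,
                 k_asm_only = x$k_asm_only, error_rate = x$error_rate,
                 qv = x$qv, completeness = x$completeness,
                 no_observed_error = x$no_observed_error)
}

#' @method glance qv_report
#' @export
glance.qv_report <- function(x, ...) {
  tibble::tibble(qv = x$qv, error_rate = x$error_rate,
                 completeness = x$completeness)
}

#' @method tidy assembly_stats
#' @export
tidy.assembly_stats <- function(x, ...) {
  tibble::tibble(length = x$lengths) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  cumulative = cumsum(.data$length))
}

#' @method glance assembly_stats
#' @export
glance.assembly_stats <- function(x, ...) {
  tibble::tibble(n_seqs = x$n_seqs, total_bp = x$total_bp,
                 n50_bp = x$n50_bp, ng50_bp = x$ng50_bp,
                 ng50_defined = x$ng50_defined, largest_bp = x$largest_bp,
                 genome_size_bp = x$genome_size_bp)
}

#' @method tidy bac_classification
#' @export
tidy.bac_classification <- function(x, ...) {
  tibble::tibble(
    category = c("same_scaffold", "different_scaffold", "unmapped",
                 "half_mapped"),
    count = c(x$same_scaffold, x$different_scaffold, x$unmapped,
              x$half_mapped),
    in_total = c(TRUE, TRUE, TRUE, FALSE)
  )
}
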