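#' Read a PAF alignment file
#'
#' Parses the pairwise alignment format emitted by minimap2 and friends: at
#' least 12 tab-separated columns, query and target intervals 0-based
#' half-open. Optional SAM-style tags after column 12 are ignored.
#'
#' @param path Path to a PAF file.
#' @return A tibble with one row per alignment and columns `qname`, `qlen`,
#'   `qstart`, `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`,
#'   `n_match`, `aln_len`, `mapq`.
#' @export
#' @examples
#' paf <- tempfile(fileext = ".paf")
#' writeLines("r1\t1000\t0\t900\t+\ts1\t5000\t100\t1000\t850\t900\t60", paf)
#' read_paf(paf)
read_paf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  fields <- stringr::str_split(lines, "\t")
  bad <- which(lengths(fields) < 12L)
  if (length(bad) > 0L) {
    abort(sprintf("PAF parse error at line %d: fewer than 12 columns", bad[1]))
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  paf <- tibble::tibble(
    qname  = mat[, 1],
    qlen   = as.numeric(mat[, 2]),
    qstart = as.numeric(mat[, 3]),
    qend   = as.numeric(mat[, 4]),
    strand = mat[, 5],
    tname  = mat[, 6],
    tlen   = as.numeric(mat[, 7]),
    tstart = as.numeric(mat[, 8]),
    tend   = as.numeric(mat[, 9]),
    n_match = as.numeric(mat[, 10]),
    aln_len = as.numeric(mat[, 11]),
    mapq   = as.numeric(mat[, 12])
  )
  validate_paf(paf)
  paf
}

empty_paf <- function() {
  tibble::tibble(
    qname = character(), qlen = numeric(), qstart = numeric(),
    qend = numeric(), strand = character(), tname = character(),
    tlen = numeric(), tstart = numeric(), tend = numeric(),
    n_match = numeric(), aln_len = numeric(), mapq = numeric()
  )
}

validate_paf <- function(paf) {
  num_cols <- c("qlen", "qstart", "qend", "tlen", "tstart", "tend",
                "n_match", "aln_len", "mapq")
  if (anyNA(paf[num_cols])) {
    abort(sprintf("PAF parse error at line %d: non-numeric coordinate field",
                  which(rowSums(is.na(paf[num_cols])) > 0)[1]))
  }
  ok <- paf$qstart >= 0 & paf$qstart < paf$qend & paf$qend <= paf$qlen &
    paf$tstart >= 0 & paf$tstart < paf$tend & paf$tend <= paf$tlen &
    paf$n_match <= paf$aln_len & paf$strand %in% c("+", "-")
  if (!all(ok)) {
    abort(sprintf(
      "PAF validation error at line %d: invalid interval or strand",
      which(!ok)[1]
    ))
  }
  invisible(paf)
}

#' Write alignments as PAF
#'
#' @param paf A tibble as returned by [read_paf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_paf <- function(paf, path) {
  validate_paf(paf)
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "n_match", "aln_len", "mapq")
  lines <- do.call(paste, c(lapply(cols, function(cl) {
    v <- paf[[cl]]
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else v
  }), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genetic map table
#'
#' Expects a tab-separated file with header `marker_id`, `linkage_group`,
#' `cM`. Records are returned sorted by linkage group, then map position.
#'
#' @param path Path to the marker map TSV.
#' @return A tibble with columns `marker_id`, `linkage_group`, `pos_cM`.
#' @export
read_marker_map <- function(path) {
  stopifnot(file.exists(path))
  map <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    linkage_group = readr::col_character(),
    cM = readr::col_double()
  ))
  if (!all(c("marker_id", "linkage_group", "cM") %in% names(map))) {
    abort("marker map must have columns marker_id, linkage_group, cM")
  }
  if (anyDuplicated(map$marker_id)) {
    abort(sprintf("duplicate marker_id in map: %s",
                  map$marker_id[duplicated(map$marker_id)][1]))
  }
  if (any(!is.finite(map$cM)) || any(map$cM < 0)) {
    abort("marker map cM positions must be finite and nonnegative")
  }
  map |>
    dplyr::rename(pos_cM = "cM") |>
    dplyr::arrange(.data$linkage_group, .data$pos_cM)
}

#' Write a genetic map table
#'
#' @param map A tibble with columns `marker_id`, `linkage_group`, `pos_cM`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_map <- function(map, path) {
  out <- tibble::tibble(marker_id = map$marker_id,
                        linkage_group = map$linkage_group,
                        cM = map$pos_cM)
  readr::write_tsv(out, path)
  invisible(path)
}

agp_cols <- c("object", "object_beg", "object_end", "part_number",
              "component_type", "component_id", "component_beg",
              "component_end", "orientation", "gap_length", "gap_type",
              "linkage", "evidence")

validate_agp <- function(agp) {
  stopifnot(all(agp_cols %in% names(agp)))
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, ]
    if (!identical(as.integer(rows$part_number), seq_len(nrow(rows)))) {
      abort(sprintf("AGP object %s: part numbers not consecutive from 1", obj))
    }
    gap_runs <- rle(rows$component_type)
    if (any(gap_runs$lengths[gap_runs$values == "U"] > 1)) {
      abort(sprintf("AGP object %s: adjacent gap rows", obj))
    }
    span <- ifelse(rows$component_type == "W",
                   rows$component_end - rows$component_beg + 1,
                   rows$gap_length)
    if (!all(rows$object_end - rows$object_beg + 1 == span)) {
      abort(sprintf("AGP object %s: object span does not match component span",
                    obj))
    }
  }
  invisible(agp)
}

#' Write an AGP v2.1 file
#'
#' Components (`W` rows) and gaps (`U` rows) describing how scaffolds
#' compose pseudomolecules. Coordinates are 1-based inclusive. The paired
#' reader [read_agp()] inverts this writer exactly.
#'
#' @param agp A tibble of AGP rows as produced by [make_agp()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_agp <- function(agp, path) {
  validate_agp(agp)
  w <- agp$component_type == "W"
  f6 <- ifelse(w, agp$component_id, as.character(agp$gap_length))
  f7 <- ifelse(w, as.character(agp$component_beg), agp$gap_type)
  f8 <- ifelse(w, as.character(agp$component_end), agp$linkage)
  f9 <- ifelse(w, agp$orientation, agp$evidence)
  lines <- paste(agp$object, agp$object_beg, agp$object_end,
                 agp$part_number, agp$component_type, f6, f7, f8, f9,
                 sep = "\t")
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' Read an AGP v2.1 file
#'
#' @param path Path to an AGP file written by [write_agp()] or a compatible
#'   producer.
#' @return A tibble of AGP rows (see [make_agp()] for the column contract).
#' @export
read_agp <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- stringr::str_split(lines, "\t")
  if (any(lengths(fields) != 9L)) {
    abort("AGP parse error: every row must have 9 tab-separated columns")
  }
  mat <- t(vapply(fields, identity, character(9)))
  w <- mat[, 5] == "W"
  num_col <- function(values, mask) {
    out <- rep(NA_real_, length(mask))
    out[mask] <- as.numeric(values[mask])
    out
  }
  chr_col <- function(values, mask) {
    out <- rep(NA_character_, length(mask))
    out[mask] <- values[mask]
    out
  }
  agp <- tibble::tibble(
    object = mat[, 1],
    object_beg = as.numeric(mat[, 2]),
    object_end = as.numeric(mat[, 3]),
    part_number = as.integer(mat[, 4]),
    component_type = mat[, 5],
    component_id = chr_col(mat[, 6], w),
    component_beg = num_col(mat[, 7], w),
    component_end = num_col(mat[, 8], w),
    orientation = chr_col(mat[, 9], w),
    gap_length = num_col(mat[, 6], !w),
    gap_type = chr_col(mat[, 7], !w),
    linkage = chr_col(mat[, 8], !w),
    evidence = chr_col(mat[, 9], !w)
  )
  validate_agp(agp)
  agp
}

#' Read sequences from a FASTA file
#'
#' Sequences are folded to uppercase; characters outside `{A,C,G,T,N}` are
#' rejected so unexpected inputs fail fast rather than propagating.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `seq`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  tbl <- tibble::tibble(name = names(seqs), seq = unname(seqs))
  validate_seqs(tbl)
  tbl
}

validate_seqs <- function(tbl) {
  stopifnot(all(c("name", "seq") %in% names(tbl)))
  if (any(!nzchar(tbl$name)) || anyDuplicated(tbl$name)) {
    abort("sequence names must be nonempty and unique")
  }
  if (any(nchar(tbl$seq) < 1)) abort("zero-length sequence")
  bad <- stringr::str_detect(tbl$seq, "[^ACGTN]")
  if (any(bad)) {
    abort(sprintf("sequence %s contains characters outside {A,C,G,T,N}",
                  tbl$name[bad][1]))
  }
  invisible(tbl)
}

#' Write sequences to a FASTA file
#'
#' Lines are wrapped at 60 columns; [read_fasta()] inverts this writer.
#'
#' @param seqs A tibble with columns `name` and `seq`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  validate_seqs(seqs)
  ss <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$name))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a k-mer tally dump
#'
#' Plain `kmer<TAB>count` dumps, one canonical k-mer per line, as produced
#' by k-mer counters or by [count_kmers()].
#'
#' @param path Path to the tally TSV (no header).
#' @return A tibble with columns `kmer` and `count`.
#' @export
read_kmer_tally <- function(path) {
  stopifnot(file.exists(path))
  tal <- readr::read_tsv(path, col_names = c("kmer", "count"),
                         col_types = "cd")
  if (nrow(tal) > 0 && length(unique(nchar(tal$kmer))) != 1L) {
    abort("k-mer tally mixes k-mer sizes")
  }
  tal
}

#' Convert between 0-based half-open and 1-based inclusive intervals
#'
#' PAF uses 0-based half-open coordinates, AGP 1-based inclusive. These two
#' converters are exact inverses for any valid interval.
#'
#' @param start,end Interval bounds in the source convention.
#' @return A list with elements `start` and `end` in the target convention.
#' @export
interval_0h_to_1c <- function(start, end) {
  stopifnot(all(start < end), all(start >= 0))
  list(start = start + 1, end = end)
}

#' @rdname interval_0h_to_1c
#' @export
interval_1c_to_0h <- function(start, end) {
  stopifnot(all(start >= 1), all(start <= end))
  list(start = start - 1, end = end)
}
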