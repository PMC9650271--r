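#' Phred quality-value arithmetic
#'
#' `phred_error()` converts a Phred-scaled quality value to an error rate,
#' \eqn{E = 10^{-QV/10}}; `phred_qv()` is its inverse,
#' \eqn{QV = -10 \log_{10} E}.
#'
#' @param qv Quality value(s), nonnegative.
#' @param error_rate Error rate(s) in (0, 1].
#' @return Numeric vector.
#' @export
#' @examples
#' phred_error(48.9101) # ~1.29e-5
#' phred_error(21.5304) # ~0.007
phred_error <- function(qv) {
  if (any(qv < 0)) abort("quality values must be nonnegative")
  10^(-qv / 10)
}

#' @rdname phred_error
#' @export
phred_qv <- function(error_rate) {
  if (any(error_rate <= 0 | error_rate > 1)) {
    abort("error rate must lie in (0, 1]")
  }
  -10 * log10(error_rate)
}

#' Bases per error at a given error rate
#'
#' The expected spacing between consecutive errors, `floor(1 / E)`.
#'
#' @param error_rate Error rate in (0, 1].
#' @return Integer number of bases per error.
#' @export
#' @examples
#' error_interval(phred_error(21.5304)) # 142
error_interval <- function(error_rate) {
  if (any(error_rate <= 0 | error_rate > 1)) {
    abort("error rate must lie in (0, 1] (zero rate has no finite interval)")
  }
  floor(1 / error_rate)
}

#' k-mer-based assembly consensus quality
#'
#' Estimates the assembly base error rate from the fraction of assembly
#' k-mer positions whose k-mer is absent from the read set (singleton,
#' "erroneous" k-mers): a base error corrupts up to k overlapping k-mers,
#' so \eqn{E = 1 - (1 - a/t)^{1/k}} where `a` is the erroneous count and
#' `t` the total. The quality value is the Phred transform of `E`. With no
#' observed erroneous k-mers the QV is reported at a configured cap and
#' flagged.
#'
#' @param k_asm_only Assembly k-mer positions absent from the reads.
#' @param k_asm_total Total assembly k-mer positions.
#' @param k k-mer size.
#' @param completeness Optional fraction of reliable read k-mers found in
#'   the assembly, carried through to the report.
#' @param qv_cap QV reported when no erroneous k-mer is seen (default 99).
#' @return A list of class `qv_report`: `k`, `k_asm_total`, `k_asm_only`,
#'   `error_rate`, `qv`, `completeness`, `no_observed_error`.
#' @export
kmer_qv <- function(k_asm_only, k_asm_total, k = 21L, completeness = NA_real_,
                    qv_cap = 99) {
  if (k_asm_total <= 0) abort("k_asm_total must be positive")
  stopifnot(k_asm_only >= 0, k_asm_only <= k_asm_total, k >= 1)
  e <- 1 - (1 - k_asm_only / k_asm_total)^(1 / k)
  no_err <- k_asm_only == 0
  qv <- if (no_err) qv_cap else phred_qv(e)
  structure(list(k = k, k_asm_total = k_asm_total, k_asm_only = k_asm_only,
                 error_rate = e, qv = qv, completeness = completeness,
                 no_observed_error = no_err),
            class = "qv_report")
}

#' @export
print.qv_report <- function(x, ...) {
  cat(sprintf("<qv_report> k=%d  QV=%.4g  error rate=%.4g%s%s\n", x$k, x$qv,
              x$error_rate,
              if (!is.na(x$completeness))
                sprintf("  completeness=%.4g", x$completeness) else "",
              if (x$no_observed_error) "  [no observed error; QV capped]" else ""))
  invisible(x)
}

#' Count canonical k-mers of sequences
#'
#' Tallies the distinct canonical k-mers (a k-mer and its reverse
#' complement are identified; the lexicographically smaller spelling is
#' kept) across a set of sequences. Intended for fixture-scale inputs;
#' real assemblies are tallied by external counters and read back with
#' [read_kmer_tally()]. k-mers containing `N` are skipped.
#'
#' @param seqs Tibble of sequences (`name`, `seq`) or character vector.
#' @param k k-mer size; odd by default (21) so no k-mer is its own
#'   reverse complement.
#' @return A tibble with columns `kmer`, `count`.
#' @export
count_kmers <- function(seqs, k = 21L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  km <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  km <- km[!stringr::str_detect(km, "N")]
  canon <- pmin(km, seq_revcomp(km))
  tal <- table(canon)
  tibble::tibble(kmer = names(tal), count = as.numeric(tal))
}

#' Total k-mer positions of sequences
#'
#' Number of k-mer windows (with multiplicity) across the sequences,
#' i.e. `sum(len - k + 1)` over sequences of length at least `k`.
#'
#' @inheritParams count_kmers
#' @return Numeric count.
#' @export
kmer_positions <- function(seqs, k = 21L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  lens <- nchar(seqs)
  sum(pmax(lens - k + 1, 0))
}

#' Compare two k-mer tallies
#'
#' Set comparison over distinct canonical k-mers: counts shared between
#' and unique to each tally, and the shared percentage of the union.
#'
#' @param tally_a,tally_b Tibbles with columns `kmer`, `count` (equal k).
#' @return A list: `shared_count`, `unique_a`, `unique_b`,
#'   `shared_percent`.
#' @export
kmer_set_compare <- function(tally_a, tally_b) {
  ka <- unique(nchar(tally_a$kmer))
  kb <- unique(nchar(tally_b$kmer))
  if (length(ka) > 1 || length(kb) > 1 ||
      (length(ka) == 1 && length(kb) == 1 && ka != kb)) {
    abort("tallies use different k-mer sizes")
  }
  a <- unique(tally_a$kmer)
  b <- unique(tally_b$kmer)
  shared <- length(intersect(a, b))
  ua <- length(setdiff(a, b))
  ub <- length(setdiff(b, a))
  list(shared_count = shared, unique_a = ua, unique_b = ub,
       shared_percent = 100 * shared / (shared + ua + ub))
}

#' Classify BAC end pairs by best-alignment placement
#'
#' Mates are paired by name stem; each mate's best alignment is the one
#' with the highest matching-base count. Pairs fall into three printed
#' categories — both mates best on the same scaffold, on different
#' scaffolds, or both unmapped — plus a separately reported `half_mapped`
#' count for pairs with exactly one aligned mate, which is excluded from
#' the three categories rather than forced into one.
#'
#' @param alignments PAF tibble of BAC end alignments.
#' @param pairs Optional character vector of all pair stems in the
#'   library; stems absent from the alignments count as unmapped. When
#'   `NULL`, only stems seen in the alignments are classified.
#' @return A list of class `bac_classification`: `same_scaffold`,
#'   `different_scaffold`, `unmapped`, `half_mapped`, `total`.
#' @export
classify_bac_pairs <- function(alignments, pairs = NULL) {
  best <- alignments |>
    dplyr::mutate(stem = bac_stem(.data$qname)) |>
    dplyr::group_by(.data$qname) |>
    dplyr::slice_max(.data$n_match, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  per_pair <- best |>
    dplyr::group_by(.data$stem) |>
    dplyr::summarise(n_mates = dplyr::n_distinct(.data$qname),
                     n_scaffolds = dplyr::n_distinct(.data$tname),
                     .groups = "drop")
  pairs <- pairs %||% per_pair$stem
  per_pair <- per_pair[per_pair$stem %in% pairs, , drop = FALSE]
  same <- sum(per_pair$n_mates == 2 & per_pair$n_scaffolds == 1)
  diff <- sum(per_pair$n_mates == 2 & per_pair$n_scaffolds > 1)
  half <- sum(per_pair$n_mates == 1)
  unmapped <- length(setdiff(pairs, per_pair$stem))
  structure(list(same_scaffold = same, different_scaffold = diff,
                 unmapped = unmapped, half_mapped = half,
                 total = same + diff + unmapped),
            class = "bac_classification")
}

#' @export
print.bac_classification <- function(x, ...) {
  cat(sprintf(
    "<bac_classification> same=%d different=%d unmapped=%d (half-mapped: %d)\n",
    x$same_scaffold, x$different_scaffold, x$unmapped, x$half_mapped))
  invisible(x)
}

#' Assembly contiguity statistics
#'
#' N50 is the length of the sequence at which the cumulative
#' sorted-descending length first reaches half the assembly length; NG50
#' replaces the assembly length with an assumed genome size, and is
#' reported as 0 with `ng50_defined = FALSE` when the assembly is too
#' small to reach half the genome.
#'
#' @param lengths Positive sequence lengths (bp), or a sequence tibble
#'   (`name`, `seq`).
#' @param genome_size Assumed genome size for NG50 (default 420 Mbp).
#' @return A list of class `assembly_stats`: `n_seqs`, `total_bp`,
#'   `n50_bp`, `ng50_bp`, `ng50_defined`, `largest_bp`, `genome_size_bp`,
#'   `lengths`.
#' @export
assembly_stats <- function(lengths, genome_size = 420e6) {
  if (is.data.frame(lengths)) lengths <- nchar(lengths$seq)
  if (length(lengths) == 0L) abort("no sequence lengths given")
  stopifnot(all(lengths > 0))
  sorted <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(sorted)
  total <- cum[length(cum)]
  n50 <- sorted[which(cum >= total / 2)[1]]
  ng_reachable <- total >= genome_size / 2
  ng50 <- if (ng_reachable) sorted[which(cum >= genome_size / 2)[1]] else 0
  structure(list(n_seqs = length(lengths), total_bp = total, n50_bp = n50,
                 ng50_bp = ng50, ng50_defined = ng_reachable,
                 largest_bp = sorted[1], genome_size_bp = genome_size,
                 lengths = sorted),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "<assembly_stats> %d seqs, %.4g bp total, N50 %.4g bp, NG50 %s (G=%.4g bp)\n",
    x$n_seqs, x$total_bp, x$n50_bp,
    if (x$ng50_defined) sprintf("%.4g bp", x$ng50_bp) else "undefined",
    x$genome_size_bp))
  invisible(x)
}

#' Haplotype-purge accounting
#'
#' Contig and base totals after removing whole remnant-haplotype contigs
#' and purged bases from an assembly.
#'
#' @param n_before,bp_before Contig count and size before purging.
#' @param n_removed_whole Contigs removed in their entirety.
#' @param bp_removed Total bases removed.
#' @return A list: `n_after`, `bp_after`.
#' @export
#' @examples
#' purge_accounting(283, 419.1, 25, 5.6) # 258 contigs, 413.5 Mbp
purge_accounting <- function(n_before, bp_before, n_removed_whole,
                             bp_removed) {
  n_after <- n_before - n_removed_whole
  bp_after <- bp_before - bp_removed
  if (n_after < 0 || bp_after < 0) {
    abort("cannot remove more than the assembly contains")
  }
  list(n_after = n_after, bp_after = bp_after)
}

#' Scaled summary ratios with explicit rounding
#'
#' Published summary ratios use inconsistent rounding conventions, so the
#' rounding mode is an explicit argument rather than a hidden default.
#'
#' @param numerator,denominator Ratio terms; `denominator` must be
#'   positive.
#' @param mode `"round"`, `"floor"`, or `"none"`.
#' @param scale Multiplier applied before rounding (100 for percent).
#' @return Numeric scalar.
#' @export
#' @examples
#' summary_ratios(8899606, 9.2e6, mode = "round", scale = 100) # 97
summary_ratios <- function(numerator, denominator,
                           mode = c("round", "floor", "none"), scale = 1) {
  mode <- match.arg(mode)
  if (denominator <= 0) abort("denominator must be positive")
  x <- scale * numerator / denominator
  switch(mode, round = round(x), floor = floor(x), none = x)
}

#' Assembly consensus quality against a read k-mer set
#'
#' Convenience wrapper for fixture-scale inputs: tallies canonical k-mers
#' of the assembly and of the read set, counts assembly k-mer positions
#' whose k-mer never occurs in the reads (the erroneous singletons), and
#' reduces them through [kmer_qv()]. Completeness is the fraction of
#' distinct read k-mers found in the assembly.
#'
#' @param assembly,reads Sequence tibbles (`name`, `seq`) or character
#'   vectors.
#' @param k k-mer size (default 21).
#' @param qv_cap Passed to [kmer_qv()].
#' @return A `qv_report`.
#' @export
compare_assembly_to_reads <- function(assembly, reads, k = 21L,
                                      qv_cap = 99) {
  asm_tally <- count_kmers(assembly, k)
  read_tally <- count_kmers(reads, k)
  total <- sum(asm_tally$count)
  only <- sum(asm_tally$count[!asm_tally$kmer %in% read_tally$kmer])
  completeness <- mean(read_tally$kmer %in% asm_tally$kmer)
  kmer_qv(only, total, k = k, completeness = completeness, qv_cap = qv_cap)
}
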