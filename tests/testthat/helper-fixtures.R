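# small constructors used across the suite

paf_row <- function(qname = "r1", qlen = 1000, qstart = 0, qend = 900,
                    strand = "+", tname = "s1", tlen = 5000, tstart = 100,
                    tend = 1000, n_match = NULL, aln_len = NULL,
                    mapq = 60) {
  aln_len <- aln_len %||% (qend - qstart)
  n_match <- n_match %||% aln_len
  tibble::tibble(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
                 strand = strand, tname = tname, tlen = tlen,
                 tstart = tstart, tend = tend, n_match = n_match,
                 aln_len = aln_len, mapq = mapq)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

marker_row <- function(marker_id, linkage_group = "LG1", pos_cM = 1) {
  tibble::tibble(marker_id = marker_id, linkage_group = linkage_group,
                 pos_cM = pos_cM)
}

# a random valid chromosome_builds over random scaffolds, for round-trip
# property tests
random_build <- function(n_lg = 2, n_per_lg = 3, seed = 1) {
  set.seed(seed)
  n <- n_lg * n_per_lg
  lens <- sample(10:200, n, replace = TRUE)
  scafs <- sprintf("s%02d", seq_len(n))
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  entries <- tibble::tibble(
    linkage_group = rep(sprintf("LG%d", seq_len(n_lg)), each = n_per_lg),
    rank = rep(seq_len(n_per_lg), n_lg),
    scaffold = scafs,
    orientation = sample(c("+", "-"), n, replace = TRUE),
    placed_by = sample(c("marker", "overlap"), n, replace = TRUE,
                       prob = c(0.8, 0.2)),
    median_cM = NA_real_,
    orientation_flagged = FALSE
  )
  list(
    builds = structure(list(entries = entries, unplaced = character(0)),
                       class = "chromosome_builds"),
    scaffolds = tibble::tibble(name = scafs, seq = seqs),
    lens = stats::setNames(lens, scafs)
  )
}

# a minimal noise-free anchoring fixture shared by several test files
make_fixture <- function(seed = 7, n_frags_per_lg = 6, flip_prob = 0.5,
                         marker_spacing = 2000, n_lg = 7, ...) {
  truth <- simulate_genome(seed, n_lg = n_lg,
                           marker_spacing = marker_spacing, ...)
  frag <- fragment_genome(truth, n_frags_per_lg = n_frags_per_lg,
                          flip_prob = flip_prob, seed = seed + 1)
  list(truth = truth, frag = frag,
       marker_paf = simulate_marker_alignments(truth, frag))
}

# truth order/orientation comparison: fraction of concordant scaffold
# pairs per LG ((Kendall tau + 1) / 2), averaged over LGs
ordering_accuracy <- function(entries, frags) {
  truth <- frags[order(frags$linkage_group, frags$truth_rank), ]
  by_lg <- split(entries, entries$linkage_group)
  accs <- vapply(names(by_lg), function(lg) {
    got <- by_lg[[lg]]$scaffold
    want_rank <- truth$truth_rank[match(got, truth$scaffold)]
    if (length(got) < 2) return(1)
    tau <- stats::cor(seq_along(got), want_rank, method = "kendall")
    (tau + 1) / 2
  }, numeric(1))
  mean(accs)
}

orientation_accuracy <- function(entries, frags, min_markers_tbl = NULL) {
  want <- frags$orientation[match(entries$scaffold, frags$scaffold)]
  mean(entries$orientation == want)
}
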