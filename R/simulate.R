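#' Simulate a truth genome with a collinear genetic map
#'
#' Generates one sequence per linkage group with i.i.d. bases at the given
#' GC content, and a marker panel on a regular grid with map positions
#' strictly collinear with physical position (a linear 0.02 cM/kb scale;
#' no recombination hot spots — sufficient for ordering and orientation
#' tests). All simulators here are pure functions of their parameters and
#' seed.
#'
#' @param seed Integer RNG seed.
#' @param n_lg Number of linkage groups (default 7).
#' @param lg_len Length of each linkage group in bp (default 200 kb).
#' @param gc GC content (default 0.36).
#' @param marker_spacing Spacing between consecutive markers in bp
#'   (default 5 kb).
#' @param marker_len Marker (EST) length in bp (default 500).
#' @param cm_per_bp Map scale in cM per bp (default 2e-5, i.e. 0.02
#'   cM/kb).
#' @return A list of class `fixture_truth`: `genome` (tibble `name`,
#'   `seq`), `markers` (tibble `marker_id`, `linkage_group`, `pos_cM`,
#'   `truth_bp`, `marker_len`), `params`.
#' @export
simulate_genome <- function(seed, n_lg = 7L, lg_len = 200e3, gc = 0.36,
                            marker_spacing = 5e3, marker_len = 500L,
                            cm_per_bp = 2e-5) {
  stopifnot(lg_len >= 10e3)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- tibble::tibble(
    name = paste0("LG", seq_len(n_lg)),
    seq = vapply(seq_len(n_lg), function(i) {
      paste(sample(names(p), lg_len, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  )
  starts <- seq(marker_spacing, lg_len - marker_len, by = marker_spacing)
  markers <- tidyr::crossing(linkage_group = genome$name,
                             truth_bp = starts) |>
    dplyr::arrange(.data$linkage_group, .data$truth_bp) |>
    dplyr::mutate(
      marker_id = sprintf("m_%s_%05d", .data$linkage_group,
                          dplyr::row_number()),
      pos_cM = .data$truth_bp * cm_per_bp,
      marker_len = marker_len
    ) |>
    dplyr::select("marker_id", "linkage_group", "pos_cM", "truth_bp",
                  "marker_len")
  structure(list(genome = genome, markers = markers,
                 params = list(seed = seed, n_lg = n_lg, lg_len = lg_len,
                               gc = gc, marker_spacing = marker_spacing,
                               marker_len = marker_len,
                               cm_per_bp = cm_per_bp)),
            class = "fixture_truth")
}

#' Fragment a truth genome into shuffled, randomly oriented scaffolds
#'
#' Each linkage group is cut at random breakpoints (minimum fragment
#' 5 kb); each fragment is independently reverse-complemented with
#' probability `flip_prob` and fragments get shuffled anonymous scaffold
#' names, so nothing about truth order or orientation leaks through
#' naming.
#'
#' @param truth A `fixture_truth` from [simulate_genome()].
#' @param n_frags_per_lg Fragments per linkage group.
#' @param flip_prob Probability a fragment is reverse-complemented.
#' @param seed Integer RNG seed.
#' @param min_frag Minimum fragment length in bp (default 5 kb).
#' @return A list: `scaffolds` (tibble `name`, `seq`), `frags` (tibble
#'   `scaffold`, `linkage_group`, `truth_start`, `truth_end` 0-based
#'   half-open, `orientation`, `truth_rank`), `truth_agp` (AGP rows
#'   reassembling the genome from the scaffolds, gap-free).
#' @export
fragment_genome <- function(truth, n_frags_per_lg = 6L, flip_prob = 0.5,
                            seed = 1L, min_frag = 5e3) {
  set.seed(seed)
  lg_len <- truth$params$lg_len
  stopifnot(n_frags_per_lg * min_frag <= lg_len)
  frags <- purrr::map(truth$genome$name, function(lg) {
    n <- n_frags_per_lg
    extra <- lg_len - n * min_frag
    w <- runif(n)
    lens <- min_frag + floor(w / sum(w) * extra)
    lens[n] <- lens[n] + (lg_len - sum(lens))
    ends <- cumsum(lens)
    tibble::tibble(
      linkage_group = lg,
      truth_start = ends - lens,
      truth_end = ends,
      orientation = ifelse(runif(n) < flip_prob, "-", "+"),
      truth_rank = seq_len(n)
    )
  }) |> purrr::list_rbind()
  frags$scaffold <- sprintf("scaffold_%03d", sample(nrow(frags)))
  seqs <- setNames(truth$genome$seq, truth$genome$name)
  frags$seq <- purrr::pmap_chr(
    frags[c("linkage_group", "truth_start", "truth_end", "orientation")],
    function(linkage_group, truth_start, truth_end, orientation) {
      s <- substr(seqs[[linkage_group]], truth_start + 1, truth_end)
      if (orientation == "-") seq_revcomp(s) else s
    })
  scaffolds <- frags |>
    dplyr::arrange(.data$scaffold) |>
    dplyr::select(name = "scaffold", "seq")
  truth_agp <- frags |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::arrange(.data$truth_rank, .by_group = TRUE) |>
    dplyr::mutate(
      object = .data$linkage_group,
      object_beg = .data$truth_start + 1,
      object_end = .data$truth_end,
      part_number = dplyr::row_number(),
      component_type = "W",
      component_id = .data$scaffold,
      component_beg = 1,
      component_end = .data$truth_end - .data$truth_start,
      gap_length = NA_real_, gap_type = NA_character_,
      linkage = NA_character_, evidence = NA_character_
    ) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(agp_cols))
  frags$seq <- NULL
  list(scaffolds = scaffolds, frags = frags, truth_agp = truth_agp)
}

# map a truth-coordinate interval (0-based half-open) lying inside one
# fragment onto that fragment's scaffold coordinates and strand
truth_to_scaffold <- function(frag, start, end) {
  flen <- frag$truth_end - frag$truth_start
  if (frag$orientation == "+") {
    list(tstart = start - frag$truth_start, tend = end - frag$truth_start,
         strand = "+")
  } else {
    list(tstart = flen - (end - frag$truth_start),
         tend = flen - (start - frag$truth_start), strand = "-")
  }
}

#' Emit truth marker alignments against fragmented scaffolds
#'
#' Produces the PAF an exact aligner would: one perfect full-length hit
#' per marker on the fragment containing it. Markers straddling a
#' fragment boundary are dropped (as real terminal markers would fail to
#' align full-length).
#'
#' @param truth A `fixture_truth`.
#' @param frag A fragmentation from [fragment_genome()].
#' @return A PAF tibble.
#' @export
simulate_marker_alignments <- function(truth, frag) {
  frags <- frag$frags
  rows <- purrr::pmap(truth$markers, function(marker_id, linkage_group,
                                              pos_cM, truth_bp, marker_len) {
    f <- frags[frags$linkage_group == linkage_group &
                 frags$truth_start <= truth_bp &
                 frags$truth_end >= truth_bp + marker_len, ]
    if (nrow(f) != 1L) return(NULL)
    m <- truth_to_scaffold(f, truth_bp, truth_bp + marker_len)
    tibble::tibble(qname = marker_id, qlen = marker_len, qstart = 0,
                   qend = marker_len, strand = m$strand, tname = f$scaffold,
                   tlen = f$truth_end - f$truth_start, tstart = m$tstart,
                   tend = m$tend, n_match = marker_len, aln_len = marker_len,
                   mapq = 60)
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0L) empty_paf() else out
}

#' Add Gaussian jitter to marker map positions
#'
#' Perturbs a random fraction of marker map positions with Gaussian noise
#' (clamped at 0 cM), emulating genetic-map measurement error.
#'
#' @param markers Marker tibble with `pos_cM`.
#' @param sd Jitter standard deviation in cM (default 0.5).
#' @param frac Fraction of markers perturbed (default 0.1).
#' @param seed Integer RNG seed.
#' @return The marker tibble with perturbed `pos_cM`.
#' @export
jitter_marker_map <- function(markers, sd = 0.5, frac = 0.1, seed = 1L) {
  set.seed(seed)
  n <- nrow(markers)
  hit <- sample(n, size = round(frac * n))
  markers$pos_cM[hit] <- pmax(0, markers$pos_cM[hit] + rnorm(length(hit), 0, sd))
  markers
}

#' Simulate junction-spanning long reads with truth alignments
#'
#' Draws reads centered (with jitter) on each boundary between truth-
#' adjacent fragments, clamped to the two flanking fragments so every
#' junction read aligns to exactly two scaffolds, plus background reads
#' interior to single fragments. Reads are emitted in truth (`+`)
#' orientation with optional substitution noise. A truth PAF of split
#' alignments accompanies the reads so no external aligner is needed.
#'
#' @param truth A `fixture_truth`.
#' @param frag A fragmentation from [fragment_genome()].
#' @param read_len Read length in bp (default 10 kb).
#' @param reads_per_junction Spanning reads per junction (default 5).
#' @param n_background Interior (non-junction) reads (default 20).
#' @param sub_rate Substitution rate applied to read bases (default 0).
#' @param seed Integer RNG seed.
#' @return A list: `reads` (tibble `name`, `seq`), `paf` (truth PAF
#'   tibble), `junctions` (tibble of truth-adjacent scaffold ends).
#' @export
simulate_junction_reads <- function(truth, frag, read_len = 10e3,
                                    reads_per_junction = 5L,
                                    n_background = 20L, sub_rate = 0,
                                    seed = 1L) {
  set.seed(seed)
  frags <- frag$frags |>
    dplyr::arrange(.data$linkage_group, .data$truth_rank)
  seqs <- setNames(truth$genome$seq, truth$genome$name)
  juncs <- frags |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::reframe(
      left = head(.data$scaffold, -1),
      left_end = ifelse(head(.data$orientation, -1) == "+", "R", "L"),
      right = tail(.data$scaffold, -1),
      right_end = ifelse(tail(.data$orientation, -1) == "+", "L", "R"),
      boundary = head(.data$truth_end, -1)
    )
  reads <- list(); paf <- list()
  ri <- 0L
  half <- read_len / 2
  jitter_max <- max(half - 1000, 0)
  emit_read <- function(lg, rs, re, name) {
    s <- substr(seqs[[lg]], rs + 1, re)
    if (sub_rate > 0) s <- mutate_seq(s, sub_rate)
    covered <- frags[frags$linkage_group == lg &
                       frags$truth_start < re & frags$truth_end > rs, ]
    recs <- purrr::map(seq_len(nrow(covered)), function(i) {
      f <- covered[i, ]
      ps <- max(rs, f$truth_start); pe <- min(re, f$truth_end)
      m <- truth_to_scaffold(f, ps, pe)
      tibble::tibble(qname = name, qlen = re - rs, qstart = ps - rs,
                     qend = pe - rs, strand = m$strand, tname = f$scaffold,
                     tlen = f$truth_end - f$truth_start, tstart = m$tstart,
                     tend = m$tend, n_match = pe - ps, aln_len = pe - ps,
                     mapq = 60)
    })
    list(read = tibble::tibble(name = name, seq = s),
         paf = purrr::list_rbind(recs))
  }
  for (j in seq_len(nrow(juncs))) {
    lg <- juncs$linkage_group[j]
    b <- juncs$boundary[j]
    lf <- frags[frags$linkage_group == lg & frags$truth_end == b, ]
    rf <- frags[frags$linkage_group == lg & frags$truth_start == b, ]
    for (r in seq_len(reads_per_junction)) {
      ri <- ri + 1L
      center <- b + round(runif(1, -jitter_max, jitter_max))
      rs <- max(center - half, lf$truth_start)
      re <- min(center + half, rf$truth_end)
      out <- emit_read(lg, rs, re, sprintf("read_j%03d_%02d", j, r))
      reads[[ri]] <- out$read; paf[[ri]] <- out$paf
    }
  }
  lg_len <- truth$params$lg_len
  for (r in seq_len(n_background)) {
    ri <- ri + 1L
    repeat {
      lg <- sample(truth$genome$name, 1)
      f <- frags[frags$linkage_group == lg, ]
      f <- f[sample(nrow(f), 1), ]
      flen <- f$truth_end - f$truth_start
      blen <- min(read_len, max(flen - 200, 1000))
      if (flen > blen) break
    }
    rs <- f$truth_start + round(runif(1, 0, flen - blen))
    out <- emit_read(lg, rs, rs + blen, sprintf("read_bg%03d", r))
    reads[[ri]] <- out$read; paf[[ri]] <- out$paf
  }
  list(reads = purrr::list_rbind(reads),
       paf = if (ri > 0) purrr::list_rbind(paf) else empty_paf(),
       junctions = juncs)
}

#' Simulate BAC end mate pairs with truth alignments
#'
#' Draws fixed-insert mate pairs from truth coordinates (insert length
#' Gaussian around `insert_mean`) and emits truth PAF alignments against
#' either the fragmented scaffolds or the intact linkage-group sequences.
#' Pairs whose mates fall in different fragments are truth
#' "different-scaffold" pairs on the fragmented assembly; an optional
#' count of contaminant pairs receives no alignments at all (unmapped on
#' every assembly).
#'
#' @param truth A `fixture_truth`.
#' @param frag A fragmentation from [fragment_genome()].
#' @param n_pairs Number of genuine pairs.
#' @param insert_mean,insert_sd Insert size distribution in bp (default
#'   100 kb, 10 kb).
#' @param mate_len Mate sequence length in bp (default 500).
#' @param n_unmapped Contaminant pairs with no alignment (default 0).
#' @param seed Integer RNG seed.
#' @return A list: `paf_fragments`, `paf_genome` (truth PAF tibbles),
#'   `pairs` (tibble with `stem` and truth category on the fragmented
#'   assembly), `pair_ids` (all stems incl. contaminants).
#' @export
simulate_bac_pairs <- function(truth, frag, n_pairs = 100L,
                               insert_mean = 100e3, insert_sd = 10e3,
                               mate_len = 500L, n_unmapped = 0L,
                               seed = 1L) {
  set.seed(seed)
  lg_len <- truth$params$lg_len
  frags <- frag$frags
  paf_f <- list(); paf_g <- list(); pairs <- list()
  mate_paf_fragments <- function(lg, s, e, qname, strand) {
    covered <- frags[frags$linkage_group == lg &
                       frags$truth_start < e & frags$truth_end > s, ]
    purrr::map(seq_len(nrow(covered)), function(i) {
      f <- covered[i, ]
      ps <- max(s, f$truth_start); pe <- min(e, f$truth_end)
      m <- truth_to_scaffold(f, ps, pe)
      st <- if (strand == "-") flip_strand(m$strand) else m$strand
      tibble::tibble(qname = qname, qlen = mate_len, qstart = ps - s,
                     qend = pe - s, strand = st, tname = f$scaffold,
                     tlen = f$truth_end - f$truth_start, tstart = m$tstart,
                     tend = m$tend, n_match = pe - ps, aln_len = pe - ps,
                     mapq = 60)
    }) |> purrr::list_rbind()
  }
  for (i in seq_len(n_pairs)) {
    repeat {
      ins <- round(rnorm(1, insert_mean, insert_sd))
      if (ins > 2 * mate_len && ins <= lg_len) break
    }
    lg <- sample(truth$genome$name, 1)
    p <- round(runif(1, 0, lg_len - ins))
    stem <- sprintf("bac%04d", i)
    m1 <- c(p, p + mate_len)
    m2 <- c(p + ins - mate_len, p + ins)
    paf_f[[i]] <- dplyr::bind_rows(
      mate_paf_fragments(lg, m1[1], m1[2], paste0(stem, "/1"), "+"),
      mate_paf_fragments(lg, m2[1], m2[2], paste0(stem, "/2"), "-"))
    paf_g[[i]] <- tibble::tibble(
      qname = paste0(stem, c("/1", "/2")), qlen = mate_len, qstart = 0,
      qend = mate_len, strand = c("+", "-"), tname = lg, tlen = lg_len,
      tstart = c(m1[1], m2[1]), tend = c(m1[2], m2[2]),
      n_match = mate_len, aln_len = mate_len, mapq = 60)
    # truth category by mate midpoint: the fragment holding the midpoint
    # also holds the larger aligned piece, so best-alignment
    # classification agrees by construction
    mid1 <- (m1[1] + m1[2]) / 2
    mid2 <- (m2[1] + m2[2]) / 2
    scaf1 <- frags$scaffold[frags$linkage_group == lg &
                              frags$truth_start <= mid1 &
                              frags$truth_end > mid1]
    scaf2 <- frags$scaffold[frags$linkage_group == lg &
                              frags$truth_start <= mid2 &
                              frags$truth_end > mid2]
    pairs[[i]] <- tibble::tibble(
      stem = stem, linkage_group = lg, insert = ins,
      truth_category = ifelse(scaf1 == scaf2, "same_scaffold",
                              "different_scaffold"))
  }
  pairs <- purrr::list_rbind(pairs)
  pair_ids <- pairs$stem
  if (n_unmapped > 0L) {
    contam <- sprintf("bacX%04d", seq_len(n_unmapped))
    pair_ids <- c(pair_ids, contam)
  }
  list(paf_fragments = purrr::list_rbind(paf_f),
       paf_genome = purrr::list_rbind(paf_g),
       pairs = pairs, pair_ids = pair_ids)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

mutate_seq <- function(s, sub_rate) {
  n <- nchar(s)
  hit <- which(runif(n) < sub_rate)
  if (length(hit) == 0L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

#' Introduce random substitutions into an assembly
#'
#' Applies i.i.d. substitutions (always to a different base) at the given
#' rate; used to inject a known error rate for consensus-quality recovery
#' tests.
#'
#' @param seqs Tibble of sequences (`name`, `seq`).
#' @param sub_rate Per-base substitution probability.
#' @param seed Integer RNG seed.
#' @return The tibble with mutated `seq`.
#' @export
mutate_assembly <- function(seqs, sub_rate, seed = 1L) {
  set.seed(seed)
  seqs$seq <- vapply(seqs$seq, function(s) mutate_seq(s, sub_rate),
                     character(1), USE.NAMES = FALSE)
  seqs
}

#' Write a complete fixture bundle to a directory
#'
#' Materializes truth genome, fragmented scaffolds, marker map and
#' alignments, junction reads, and BAC pairs as FASTA/PAF/TSV/AGP files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed driving all generators.
#' @param n_frags_per_lg,flip_prob Fragmentation parameters.
#' @param ... Passed to [simulate_genome()].
#' @return Invisibly, a named list of written paths.
#' @export
write_fixture_bundle <- function(dir, seed = 1L, n_frags_per_lg = 6L,
                                 flip_prob = 0.5, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_genome(seed, ...)
  frag <- fragment_genome(truth, n_frags_per_lg = n_frags_per_lg,
                          flip_prob = flip_prob, seed = seed + 1L)
  marker_paf <- simulate_marker_alignments(truth, frag)
  rj <- simulate_junction_reads(truth, frag, seed = seed + 2L)
  bac <- simulate_bac_pairs(truth, frag, seed = seed + 3L)
  paths <- list(
    genome = file.path(dir, "truth_genome.fa"),
    scaffolds = file.path(dir, "scaffolds.fa"),
    marker_map = file.path(dir, "marker_map.tsv"),
    marker_paf = file.path(dir, "markers.paf"),
    reads = file.path(dir, "junction_reads.fa"),
    read_paf = file.path(dir, "reads.paf"),
    bac_paf = file.path(dir, "bac_pairs.paf"),
    truth_agp = file.path(dir, "truth.agp")
  )
  write_fasta(truth$genome, paths$genome)
  write_fasta(frag$scaffolds, paths$scaffolds)
  write_marker_map(truth$markers, paths$marker_map)
  write_paf(marker_paf, paths$marker_paf)
  write_fasta(rj$reads, paths$reads)
  write_paf(rj$paf, paths$read_paf)
  write_paf(bac$paf_fragments, paths$bac_paf)
  write_agp(frag$truth_agp, paths$truth_agp)
  invisible(paths)
}
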