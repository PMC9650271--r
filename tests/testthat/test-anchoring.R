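mini_assignments <- function(scafs, lgs) {
  tibble::tibble(scaffold = scafs, linkage_group = lgs,
                 n_markers = ifelse(is.na(lgs), 0L, 3L),
                 majority_fraction = ifelse(is.na(lgs), NA_real_, 1),
                 reason = ifelse(is.na(lgs), "no_markers", NA_character_))
}

mini_stats <- function(scafs, med, score = 1) {
  tibble::tibble(scaffold = scafs, median_cM = med,
                 orientation_score = rep_len(score, length(scafs)),
                 n_used = 3L)
}

link <- function(sa, ea, sb, eb, support = 3L, source = "long_read") {
  tibble::tibble(scaffold_a = sa, end_a = ea, scaffold_b = sb, end_b = eb,
                 support = support, source = source)
}

test_that("evidence graph has two nodes per scaffold and map-order edges", {
  asg <- mini_assignments(c("s1", "s2", "s3"), rep("LG1", 3))
  st <- mini_stats(c("s1", "s2", "s3"), c(1, 2, 3))
  g <- build_graph(asg, st, scaffold_lens = c(s1 = 100, s2 = 100, s3 = 100))
  expect_equal(nrow(g$nodes), 6)
  expect_equal(sum(g$edges$source == "marker_adjacency"), 2)
  # consecutive in cM order, all "+": R end meets L end
  adj <- g$edges[g$edges$source == "marker_adjacency", ]
  expect_setequal(paste(adj$scaffold_a, adj$end_a, adj$scaffold_b, adj$end_b),
                  c("s1 R s2 L", "s2 R s3 L"))

  empty <- build_graph(mini_assignments(character(0), character(0)),
                       mini_stats(character(0), numeric(0)))
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)

  # duplicate links (same ends, same source) merge with supports summed
  g2 <- build_graph(asg, st,
                    dplyr::bind_rows(link("s1", "R", "s2", "L", 3),
                                     link("s1", "R", "s2", "L", 2)))
  lr <- g2$edges[g2$edges$source == "long_read", ]
  expect_equal(lr$support, 5)

  expect_error(build_graph(asg, st, link("s1", "R", "nope", "L")),
               "unknown scaffold")
  expect_error(build_graph(asg, st, link("s1", "R", "s1", "L")),
               "one scaffold")
})

test_that("concordance separates multi-source, single-source, conflicting", {
  asg <- mini_assignments(c("A", "B"), c("LG1", "LG1"))
  st <- mini_stats(c("A", "B"), c(1, 2))
  # marker adjacency gives A.R-B.L; a long-read link agreeing on the same
  # end pairing makes the pair concordant
  g <- build_graph(asg, st, link("A", "R", "B", "L"))
  cc <- classify_concordance(g)
  expect_equal(cc$status, "concordant")
  expect_equal(cc$n_sources, 2)

  # long-read evidence alone on an unassigned pair
  asg2 <- mini_assignments(c("A", "B"), c(NA, NA))
  g2 <- build_graph(asg2, mini_stats(character(0), numeric(0)),
                    link("A", "R", "B", "L"))
  expect_equal(classify_concordance(g2)$status, "single_source")

  # incompatible end pairings for one scaffold pair conflict
  g3 <- build_graph(asg2, mini_stats(character(0), numeric(0)),
                    dplyr::bind_rows(
                      link("A", "R", "B", "L"),
                      link("A", "L", "B", "L", source = "bac")))
  expect_equal(classify_concordance(g3)$status, "conflicting")
})

test_that("ordering sorts by median cM with documented tie-breaks", {
  asg <- mini_assignments(c("x", "y", "z"), rep("LG1", 3))
  st <- mini_stats(c("x", "y", "z"), c(3.1, 1.0, 2.2))
  g <- build_graph(asg, st, scaffold_lens = c(x = 10, y = 10, z = 10))
  b <- order_and_orient(g)
  expect_equal(b$entries$scaffold, c("y", "z", "x"))
  expect_equal(b$entries$rank, 1:3)

  # equal medians: longer scaffold first, then name
  asg2 <- mini_assignments(c("a", "b"), rep("LG1", 2))
  st2 <- mini_stats(c("a", "b"), c(1, 1))
  g2 <- build_graph(asg2, st2, scaffold_lens = c(a = 5000, b = 9000))
  expect_equal(order_and_orient(g2)$entries$scaffold, c("b", "a"))

  # negative score flips, zero score is "+" with a warning
  st3 <- mini_stats(c("a", "b"), c(1, 2), score = c(-0.8, 0))
  g3 <- build_graph(asg2, st3, scaffold_lens = c(a = 10, b = 10))
  expect_warning(b3 <- order_and_orient(g3), "zero orientation")
  expect_equal(b3$entries$orientation, c("-", "+"))
  expect_equal(b3$entries$orientation_flagged, c(FALSE, TRUE))
})

test_that("marker-less scaffolds insert on the linked side, facing partner", {
  base_asg <- mini_assignments(c("s1", "s2", "s3", "X"),
                               c("LG1", "LG1", "LG1", NA))
  st <- mini_stats(c("s1", "s2", "s3"), c(1, 2, 3))
  lens <- c(s1 = 100, s2 = 100, s3 = 100, X = 50)

  # X.L links to s2.R; s2 placed "+" mid-build: X lands right after s2, "+"
  g <- build_graph(base_asg, st, link("X", "L", "s2", "R"), lens)
  b <- insert_unplaced(order_and_orient(g), g)
  expect_equal(b$entries$scaffold, c("s1", "s2", "X", "s3"))
  expect_equal(b$entries$orientation[3], "+")
  expect_equal(b$entries$placed_by[3], "overlap")
  expect_equal(b$unplaced, character(0))
  expect_equal(b$entries$rank, 1:4)

  # X.R links to s2.R: the facing rule forces a flip
  g2 <- build_graph(base_asg, st, link("X", "R", "s2", "R"), lens)
  b2 <- insert_unplaced(order_and_orient(g2), g2)
  expect_equal(b2$entries$scaffold, c("s1", "s2", "X", "s3"))
  expect_equal(b2$entries$orientation[3], "-")

  # X.L links to s2.L: X lands before s2, "-" so its L end faces s2
  g3 <- build_graph(base_asg, st, link("X", "L", "s2", "L"), lens)
  b3 <- insert_unplaced(order_and_orient(g3), g3)
  expect_equal(b3$entries$scaffold, c("s1", "X", "s2", "s3"))
  expect_equal(b3$entries$orientation[2], "-")

  # links to two different placed scaffolds: stays unplaced
  g4 <- build_graph(base_asg, st,
                    dplyr::bind_rows(link("X", "L", "s1", "R"),
                                     link("X", "R", "s3", "L")), lens)
  b4 <- insert_unplaced(order_and_orient(g4), g4)
  expect_equal(b4$unplaced, "X")

  # BAC links never trigger insertion
  g5 <- build_graph(base_asg, st, link("X", "L", "s2", "R", source = "bac"),
                    lens)
  b5 <- insert_unplaced(order_and_orient(g5), g5)
  expect_equal(b5$unplaced, "X")

  # insertion preserves the relative order of previously placed entries
  placed_before <- order_and_orient(g)$entries$scaffold
  expect_equal(b$entries$scaffold[b$entries$placed_by == "marker"],
               placed_before)
})

test_that("every scaffold lands in exactly one build or the unplaced set", {
  fx <- make_fixture(seed = 41)
  rj <- simulate_junction_reads(fx$truth, fx$frag, seed = 42)
  res <- anchor_scaffolds(fx$frag$scaffolds, fx$marker_paf,
                          fx$truth$markers, read_aln = rj$paf)
  got <- c(res$builds$entries$scaffold, res$builds$unplaced)
  expect_setequal(got, fx$frag$scaffolds$name)
  expect_equal(anyDuplicated(got), 0)
})

test_that("anchoring is deterministic under input permutation", {
  fx <- make_fixture(seed = 51, n_lg = 3)
  rj <- simulate_junction_reads(fx$truth, fx$frag, seed = 52)
  res1 <- anchor_scaffolds(fx$frag$scaffolds, fx$marker_paf,
                           fx$truth$markers, read_aln = rj$paf)
  set.seed(99)
  res2 <- anchor_scaffolds(
    fx$frag$scaffolds[sample(nrow(fx$frag$scaffolds)), ],
    fx$marker_paf[sample(nrow(fx$marker_paf)), ],
    fx$truth$markers[sample(nrow(fx$truth$markers)), ],
    read_aln = rj$paf[sample(nrow(rj$paf)), ])
  expect_equal(res1$builds$entries, res2$builds$entries)
  expect_equal(res1$builds$unplaced, res2$builds$unplaced)
})

test_that("noise-free fixtures recover truth order and orientation exactly", {
  fx <- make_fixture(seed = 61)
  res <- anchor_scaffolds(fx$frag$scaffolds, fx$marker_paf, fx$truth$markers)
  expect_equal(ordering_accuracy(res$builds$entries, fx$frag$frags), 1)
  multi <- res$builds$entries |>
    dplyr::filter(!orientation_flagged)
  expect_equal(orientation_accuracy(multi, fx$frag$frags), 1)
})

test_that("modest cM jitter leaves ordering nearly intact", {
  accs <- vapply(1:3, function(s) {
    fx <- make_fixture(seed = 100 + s)
    noisy <- jitter_marker_map(fx$truth$markers, sd = 0.5, frac = 0.1,
                               seed = 200 + s)
    res <- suppressWarnings(
      anchor_scaffolds(fx$frag$scaffolds, fx$marker_paf, noisy))
    ordering_accuracy(res$builds$entries, fx$frag$frags)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})
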