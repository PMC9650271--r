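test_that("Phred conversions reproduce published quality arithmetic", {
  expect_equal(signif(phred_error(48.9101), 3), 1.29e-5)
  expect_equal(round(phred_error(21.5304), 3), 0.007)
  expect_equal(round(phred_error(9.74458), 3), 0.106)
  expect_equal(phred_error(0), 1)
  expect_error(phred_error(-1), "nonnegative")
})

test_that("phred_qv and phred_error are mutual inverses", {
  q <- seq(0, 100, by = 0.37)
  expect_equal(phred_qv(phred_error(q)), q, tolerance = 1e-9)
  expect_error(phred_qv(0), "0, 1")
})

test_that("error_interval floors the reciprocal error rate", {
  expect_equal(error_interval(phred_error(21.5304)), 142)
  expect_equal(error_interval(1), 1)
  expect_equal(error_interval(1.2854e-5), 77796)
  expect_error(error_interval(0), "finite")
})

test_that("kmer_qv follows the k-th-root error model", {
  r <- kmer_qv(1, 100, k = 21)
  # frozen from evaluating 1 - (1 - 1/100)^(1/21) at double precision
  expect_equal(r$error_rate, 4.78472916903e-4, tolerance = 1e-9)
  expect_equal(r$qv, 33.2014, tolerance = 1e-4)
  expect_false(r$no_observed_error)

  capped <- kmer_qv(0, 1e6, k = 21)
  expect_equal(capped$qv, 99)
  expect_true(capped$no_observed_error)
  expect_equal(capped$error_rate, 0)

  expect_error(kmer_qv(1, 0), "positive")

  # monotone: more erroneous k-mers never raises the QV
  qvs <- vapply(c(1, 10, 100, 1000, 1e4), function(a) {
    kmer_qv(a, 1e5, k = 21)$qv
  }, numeric(1))
  expect_true(all(diff(qvs) < 0))
})

test_that("k-mer QV recovers the realized substitution rate", {
  truth <- simulate_genome(17, n_lg = 1, lg_len = 200e3)
  mutated <- mutate_assembly(truth$genome, sub_rate = 1e-4, seed = 18)
  rep <- compare_assembly_to_reads(mutated, truth$genome, k = 21)
  # the estimator should hit the Phred QV of the rate actually realized by
  # the mutation draw (the draw itself carries Poisson noise around 1e-4)
  a <- strsplit(truth$genome$seq, "")[[1]]
  b <- strsplit(mutated$seq, "")[[1]]
  realized <- sum(a != b) / length(a)
  expect_lt(abs(rep$qv - phred_qv(realized)), 0.3)
  # and a clean assembly hits the cap with full completeness
  clean <- compare_assembly_to_reads(truth$genome, truth$genome, k = 21)
  expect_true(clean$no_observed_error)
  expect_equal(clean$completeness, 1)
})

test_that("count_kmers canonicalizes and matches a brute-force oracle", {
  # brute force via Biostrings on a tiny string
  s <- "ACGTACGTTN AGG"
  s <- gsub(" ", "", s)
  k <- 3
  oracle <- local({
    kms <- character(0)
    for (i in 1:(nchar(s) - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("N", km)) next
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(km)))
      kms <- c(kms, min(km, rc))
    }
    table(kms)
  })
  got <- count_kmers(s, k = 3)
  expect_equal(got$kmer, names(oracle))
  expect_equal(got$count, as.numeric(oracle))
  expect_equal(kmer_positions(s, 3), nchar(s) - 2)
})

test_that("k-mer set comparison computes shared percentages", {
  mk_tally <- function(kmers) tibble::tibble(kmer = kmers,
                                             count = rep(1, length(kmers)))
  a <- mk_tally(c("AAAAA", "CCCCC", "GGGGG"))
  expect_equal(kmer_set_compare(a, a)$shared_percent, 100)
  b <- mk_tally(c("TTTTT", "ATATA"))
  expect_equal(kmer_set_compare(a, b)$shared_percent, 0)

  # constructed three-way split |A∩B| = 55, |A\B| = 25, |B\A| = 20
  pool <- apply(expand.grid(rep(list(c("A","C","G","T")), 4)), 1, paste,
                collapse = "")
  sh <- pool[1:55]; ua <- pool[56:80]; ub <- pool[81:100]
  res <- kmer_set_compare(mk_tally(c(sh, ua)), mk_tally(c(sh, ub)))
  expect_equal(res$shared_count, 55)
  expect_equal(res$unique_a, 25)
  expect_equal(res$unique_b, 20)
  expect_equal(res$shared_percent, 55)

  expect_error(kmer_set_compare(a, mk_tally("ACG")), "sizes")
})

test_that("BAC pair classification covers the three printed categories", {
  mate <- function(stem, suffix, scaf, nm = 480) {
    paf_row(paste0(stem, suffix), qlen = 500, qstart = 0, qend = 500,
            tname = scaf, tlen = 10000, tstart = 100, tend = 600,
            n_match = nm, aln_len = 500)
  }
  aln <- dplyr::bind_rows(
    mate("same1", "/1", "S"), mate("same1", "/2", "S"),
    mate("diff1", "/1", "S"), mate("diff1", "/2", "T"),
    mate("half1", "/1", "S"),
    # the best alignment decides: /2 hits T weakly and S strongly
    mate("best1", "/1", "S"), mate("best1", "/2", "T", nm = 100),
    mate("best1", "/2", "S", nm = 400)
  )
  cl <- classify_bac_pairs(aln, pairs = c("same1", "diff1", "half1",
                                          "best1", "gone1"))
  expect_equal(cl$same_scaffold, 2) # same1 and best1
  expect_equal(cl$different_scaffold, 1)
  expect_equal(cl$unmapped, 1)
  expect_equal(cl$half_mapped, 1)
  expect_equal(cl$same_scaffold + cl$different_scaffold + cl$unmapped,
               cl$total)

  # order invariance
  set.seed(4)
  cl2 <- classify_bac_pairs(aln[sample(nrow(aln)), ],
                            pairs = c("same1", "diff1", "half1", "best1",
                                      "gone1"))
  expect_equal(tidy(cl2), tidy(cl))
})

test_that("N50/NG50 match the cumulative-length definitions", {
  st <- assembly_stats(c(5, 4, 3, 2, 1) * 1e6, genome_size = 20e6)
  expect_equal(st$n50_bp, 4e6)  # cumulative 5, 9 >= 7.5
  expect_equal(st$ng50_bp, 3e6) # cumulative 5, 9, 12 >= 10
  expect_equal(st$largest_bp, 5e6)
  expect_equal(st$total_bp, 15e6)

  one <- assembly_stats(7e6, genome_size = 10e6)
  expect_equal(one$n50_bp, 7e6)
  expect_equal(one$ng50_bp, 7e6)

  small <- assembly_stats(c(1e6, 2e6), genome_size = 10e6)
  expect_false(small$ng50_defined)
  expect_equal(small$ng50_bp, 0)

  expect_error(assembly_stats(numeric(0)), "no sequence")
})

test_that("N50 equals a brute-force prefix oracle on random length lists", {
  brute_n50 <- function(lengths, half) {
    sorted <- sort(lengths, decreasing = TRUE)
    run <- 0
    for (l in sorted) {
      run <- run + l
      if (run >= half) return(l)
    }
    NA_real_
  }
  set.seed(77)
  for (i in 1:50) {
    lens <- sample.int(1e6, sample(1:200, 1), replace = TRUE)
    st <- assembly_stats(lens, genome_size = sum(lens) * runif(1, 0.5, 1.5))
    expect_equal(st$n50_bp, brute_n50(lens, sum(lens) / 2))
    if (st$ng50_defined) {
      expect_equal(st$ng50_bp, brute_n50(lens, st$genome_size_bp / 2))
    }
    if (sum(lens) >= st$genome_size_bp) expect_gte(st$ng50_bp, st$n50_bp)
  }
})

test_that("purge accounting subtracts whole contigs and purged bases", {
  out <- purge_accounting(283, 419.1, 25, 5.6)
  expect_equal(out$n_after, 258)
  expect_equal(out$bp_after, 413.5)
  expect_equal(purge_accounting(10, 100, 0, 0), list(n_after = 10,
                                                     bp_after = 100))
  expect_error(purge_accounting(10, 100, 11, 0), "more than")
})

test_that("summary ratios honor the explicit rounding mode", {
  expect_equal(summary_ratios(8899606, 9.2e6, "round", 100), 97)
  expect_equal(summary_ratios(308804, 437586, "floor", 100), 70)
  expect_equal(summary_ratios(308804, 24955, "round"), 12)
  expect_equal(summary_ratios(23.2e9, 420e6, "none"), 55.238, tolerance = 1e-4)
  expect_error(summary_ratios(1, 0), "positive")
})
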