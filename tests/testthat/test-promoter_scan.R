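test_that("promoter extraction follows the strand-aware window convention", {
  set.seed(21)
  chrom <- random_dna_seq(2000)
  genome <- c(chr1 = chrom)
  tss <- data.frame(gene_id = c("gplus", "gminus"),
                    chrom = "chr1", tss = c(1000L, 1000L),
                    strand = c("+", "-"))
  ps <- extract_promoters(genome, tss, window_up = 450, window_down = 50,
                          one_based = FALSE)
  expect_equal(ps$window_up, 450L)
  expect_equal(nchar(ps$sequences[["gplus"]]), 500L)
  # + strand: genome[550, 1050) in 0-based half-open coordinates
  expect_equal(ps$sequences[["gplus"]], substr(chrom, 551, 1050))
  # - strand: reverse complement of genome[950, 1450)
  expect_equal(ps$sequences[["gminus"]],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chrom, 951, 1450)))))
})

test_that("planted markers land at the expected offsets after extraction", {
  marker <- "ACGTACGTTT"
  chrom <- paste0(strrep("A", 560), marker, strrep("C", 600))
  # TSS at 1000 (0-based), + strand: window starts at 550, marker at 560
  ps <- extract_promoters(c(c1 = chrom),
                          data.frame(gene_id = "g1", chrom = "c1",
                                     tss = 1000L, strand = "+"),
                          one_based = FALSE)
  expect_equal(substr(ps$sequences[["g1"]], 11, 20), marker)
})

test_that("boundary windows are skipped with a warning; unknown chrom errors", {
  genome <- c(chr1 = random_dna_seq(600))
  tss <- data.frame(gene_id = c("ok", "edge"), chrom = "chr1",
                    tss = c(500L, 100L), strand = "+")
  expect_warning(ps <- extract_promoters(genome, tss, one_based = FALSE),
                 "boundary")
  expect_equal(names(ps$sequences), "ok")
  expect_error(extract_promoters(genome,
                                 data.frame(gene_id = "x", chrom = "chrX",
                                            tss = 500L, strand = "+")),
               "chrX")
})

test_that("consensus sites score exactly 1 and worst sequences exactly 0", {
  set.seed(22)
  m <- simulate_motif(8, concentration = 0.1, motif_id = "C1")
  sm <- to_scoring_matrix(m)
  cons <- consensus(m)
  for (pos in c(1, 20, 43)) {
    s <- random_dna_seq(50)
    substr(s, pos, pos + 7) <- cons
    expect_equal(best_site_score(s, sm), 1.0)
  }
  # reverse-complement placement scores 1 when both strands are scanned
  s <- random_dna_seq(50)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  substr(s, 10, 17) <- rc
  expect_equal(best_site_score(s, sm, both_strands = TRUE), 1.0)

  # the per-position minimal bases over a single window, single strand -> 0
  worst <- paste(c("A", "C", "G", "T")[apply(sm$logodds, 1, which.min)],
                 collapse = "")
  expect_equal(best_site_score(worst, sm, both_strands = FALSE), 0.0)
})

test_that("short sequences and degenerate matrices are errors", {
  m <- simulate_motif(8, concentration = 0.1, motif_id = "E1")
  sm <- to_scoring_matrix(m)
  expect_error(best_site_score("ACGT", sm), "shorter")
  u <- to_scoring_matrix(motif_matrix("U", "", matrix(1, 6, 4)))
  expect_error(best_site_score(random_dna_seq(50), u), "degenerate")
})

test_that("scanner agrees with the brute-force enumeration oracle", {
  set.seed(23)
  for (i in 1:25) {
    L <- sample(4:12, 1)
    m <- simulate_motif(L, concentration = runif(1, 0.1, 1),
                        motif_id = "O1")
    sm <- to_scoring_matrix(m)
    if (sm$degenerate) next
    s <- random_dna_seq(sample(30:120, 1))
    expect_equal(best_site_score(s, sm, both_strands = TRUE),
                 oracle_best_score(s, m, both_strands = TRUE),
                 tolerance = 1e-12)
    expect_equal(best_site_score(s, sm, both_strands = FALSE),
                 oracle_best_score(s, m, both_strands = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("ambiguity codes score as the background expectation", {
  m <- motif_matrix("N1", "", matrix(c(10, 1, 1, 1), 1, 4, byrow = TRUE))
  sm <- to_scoring_matrix(m)
  # single-position motif on a single-base sequence: N must equal bg expectation
  raw_n <- (best_site_score("N", sm, both_strands = FALSE) *
              (sm$score_max - sm$score_min)) + sm$score_min
  expect_equal(raw_n, sum(0.25 * sm$logodds[1, ]))
})

test_that("catalog scanning reduces to best_site_score and is order-equivariant", {
  set.seed(24)
  catalog <- lapply(1:5, function(i)
    to_scoring_matrix(simulate_motif(6, 0.2, motif_id = sprintf("S%d", i))))
  seqs <- setNames(vapply(1:20, function(i) random_dna_seq(60), ""),
                   sprintf("g%02d", 1:20))
  st <- scan_catalog(seqs, catalog)
  expect_equal(dim(st), c(20L, 5L))
  expect_equal(st["g01", "S3"], best_site_score(seqs[["g01"]], catalog[[3]]))
  # cellwise agreement with the element-wise scorer (itself oracle-verified)
  for (j in 1:5) {
    expect_equal(unname(st[, j]),
                 unname(vapply(seqs, best_site_score, 0, sm = catalog[[j]])))
  }
  perm <- sample(names(seqs))
  st2 <- scan_catalog(seqs[perm], catalog)
  expect_equal(st2, st[perm, ])
})

test_that("N-rich promoters are masked and degenerate motifs dropped", {
  catalog <- list(to_scoring_matrix(motif_matrix("good", "",
                    matrix(c(20, 1, 1, 1), 4, 4, byrow = TRUE))),
                  to_scoring_matrix(motif_matrix("flat", "", matrix(1, 4, 4))))
  seqs <- c(ok = random_dna_seq(40),
            bad = paste0(strrep("N", 10), random_dna_seq(30)))
  expect_warning(expect_warning(st <- scan_catalog(seqs, catalog),
                                "degenerate"), "ambiguous")
  expect_equal(colnames(st), "good")
  expect_true(is.na(st["bad", "good"]))
  expect_false(is.na(st["ok", "good"]))
})

test_that("appending non-improving sequence never changes the best score", {
  set.seed(25)
  m <- simulate_motif(8, 0.1, motif_id = "M1")
  sm <- to_scoring_matrix(m)
  s <- random_dna_seq(60)
  substr(s, 5, 12) <- consensus(m)  # best score is already maximal
  base <- best_site_score(s, sm)
  expect_equal(best_site_score(paste0(s, random_dna_seq(100)), sm), base)
})
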