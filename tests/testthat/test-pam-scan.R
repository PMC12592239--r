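sth1 <- pam_sth1_consensus()

test_that("find_pam_sites reports direct matches and handles short genomes", {
  g <- genome_table(c(chr = "CCAGAAA"))  # W = A
  sites <- find_pam_sites(g, sth1)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$strand, "+")
  expect_equal(sites$pam_start, 1)
  expect_equal(sites$pam_end, 7)
  expect_equal(sites$pam_seq, "CCAGAAA")

  expect_equal(nrow(find_pam_sites(genome_table(c(chr = "ACGT")), sth1)), 0)
})

test_that("find_pam_sites equals the all-windows brute-force oracle", {
  withr::local_seed(7)
  for (i in 1:10) {
    seqstr <- random_dna(2000, gc = 0.6)
    sites <- find_pam_sites(genome_table(c(chr = seqstr)), sth1)
    expect_identical(sort(paste0(sites$pam_start, ":", sites$strand)),
                     oracle_scan(seqstr, "NNAGAAW"))
  }
  # genomes with N: ambiguous windows never match
  seqn <- paste0("CCAGAAA", "NNAGAAT", "CCNGAAA", "GGAGAAN")
  sites <- find_pam_sites(genome_table(c(chr = seqn)), sth1)
  expect_identical(sort(paste0(sites$pam_start, ":", sites$strand)),
                   oracle_scan(seqn, "NNAGAAW"))
})

test_that("scanning the reverse complement mirrors sites with strands swapped", {
  withr::local_seed(21)
  seqstr <- random_dna(3000)
  n <- nchar(seqstr)
  fwd <- find_pam_sites(genome_table(c(chr = seqstr)), sth1)
  rev <- find_pam_sites(genome_table(c(chr = reverse_complement(seqstr))), sth1)
  mirrored <- paste0(n - rev$pam_start - nchar("NNAGAAW") + 2, ":",
                     ifelse(rev$strand == "+", "-", "+"))
  expect_setequal(paste0(fwd$pam_start, ":", fwd$strand), mirrored)
})

test_that("spacer extraction uses the 5' flank on the protospacer strand", {
  withr::local_seed(5)
  left <- random_dna(100)
  pam <- "AAAGAAT"
  g <- genome_table(c(chr = paste0(left, pam, random_dna(50))))
  guides <- enumerate_guides(g, sth1, spacer_len = 22)
  plus <- guides[guides$strand == "+" & guides$pam_start == 101, ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$spacer_start, 79)   # [79, 100] immediately 5' of PAM
  expect_equal(plus$spacer_end, 100)
  expect_equal(plus$spacer_seq, substr(left, 79, 100))
})

test_that("minus-strand spacers match the whole-contig revcomp oracle", {
  withr::local_seed(9)
  seqstr <- random_dna(4000)
  n <- nchar(seqstr)
  g <- enumerate_guides(genome_table(c(chr = seqstr)), sth1, spacer_len = 22)
  g_rc <- enumerate_guides(genome_table(c(chr = reverse_complement(seqstr))),
                           sth1, spacer_len = 22)
  minus <- g[g$strand == "-", ]
  expect_gt(nrow(minus), 0)
  # a "-" guide corresponds to a "+" guide on the reverse-complemented contig
  plus_rc <- g_rc[g_rc$strand == "+", ]
  m <- match(n - minus$spacer_end + 1, plus_rc$spacer_start)
  expect_false(anyNA(m))
  expect_identical(minus$spacer_seq, plus_rc$spacer_seq[m])
})

test_that("guides overlapping linear contig ends are dropped and counted", {
  g <- genome_table(c(chr = paste0(strrep("C", 10), "AAAGAAT", strrep("C", 10))))
  guides <- enumerate_guides(g, sth1, spacer_len = 22)
  expect_equal(nrow(guides), 0)
  attrition <- attr(guides, "attrition")
  expect_equal(attrition$n[attrition$stage == "insufficient_flank"], 1)
  expect_error(enumerate_guides(g, sth1, spacer_len = 0), "positive")
})

test_that("every emitted spacer re-extracts identically from the genome", {
  withr::local_seed(13)
  seqstr <- random_dna(5000)
  g <- genome_table(c(chr = seqstr))
  guides <- enumerate_guides(g, sth1, spacer_len = 22)
  expect_gt(nrow(guides), 0)
  re <- substr(rep(seqstr, nrow(guides)), guides$spacer_start, guides$spacer_end)
  re[guides$strand == "-"] <- reverse_complement(re[guides$strand == "-"])
  expect_identical(guides$spacer_seq, re)
})

test_that("concatenating a contig with itself at least doubles interior guides", {
  withr::local_seed(17)
  seqstr <- random_dna(2000)
  g1 <- enumerate_guides(genome_table(c(chr = seqstr)), sth1)
  g2 <- enumerate_guides(genome_table(c(chr = paste0(seqstr, seqstr))), sth1)
  expect_gte(nrow(g2), 2 * nrow(g1))
})

test_that("circular contigs are scanned across the origin", {
  withr::local_seed(19)
  # place a PAM so that it spans the origin when circular
  body <- random_dna(200)
  seqstr <- paste0("AAT", body, "CCAG")  # wrap gives CCAG|AAT = CCAGAAT
  lin <- find_pam_sites(genome_table(c(chr = seqstr)), sth1)
  circ <- find_pam_sites(genome_table(c(chr = seqstr), circular = TRUE), sth1)
  extra <- dplyr::anti_join(circ, lin,
                            by = c("seqid", "strand", "pam_start", "pam_end"))
  expect_true(any(extra$pam_start == nchar(seqstr) - 3 & extra$strand == "+"))
  # and the wrapped site's spacer comes from the other side of the origin
  gc <- enumerate_guides(genome_table(c(chr = seqstr), circular = TRUE), sth1)
  wrapped <- gc[gc$pam_start == nchar(seqstr) - 3 & gc$strand == "+", ]
  expect_equal(nrow(wrapped), 1)
  expect_equal(nchar(wrapped$spacer_seq), 22)
  expect_equal(wrapped$spacer_end, nchar(seqstr) - 4)
})

test_that("multiple patterns hitting one site collapse to a single PamSite", {
  g <- genome_table(c(chr = paste0(strrep("C", 30), "CCAGAAA", strrep("C", 30))))
  spec2 <- pam_spec(c("NNAGAAW", "NNAGAAA"), name = "overlapping")
  sites <- find_pam_sites(g, spec2)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$matched_pattern, "NNAGAAA;NNAGAAW")
})
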