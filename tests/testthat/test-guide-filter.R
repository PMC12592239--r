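fake_guides <- function(spacers, pams = NULL) {
  tibble::tibble(
    guide_id = paste0("chr:", seq_along(spacers) * 100, ":+"),
    seqid = "chr", strand = "+",
    spacer_start = seq_along(spacers) * 100L,
    spacer_end = seq_along(spacers) * 100L + nchar(spacers) - 1L,
    spacer_seq = spacers,
    pam_seq = pams %||% rep("AAAGAAT", length(spacers))
  )
}

test_that("filter_motifs rejects motif-bearing spacers with named flags", {
  sp <- c(paste0(strrep("A", 8), "CTGCAG", strrep("A", 8)),   # PstI-like site
          paste0(strrep("A", 8), "GTCGAT", strrep("A", 8)),   # RTCGAY expansion
          strrep("A", 22))
  out <- filter_motifs(fake_guides(sp))
  expect_equal(out$motif_hit, c("CTGCAG", "RTCGAY", NA))
  # reverse-complemented occurrence is also caught
  out_rc <- filter_motifs(fake_guides(reverse_complement(sp[2])))
  expect_equal(out_rc$motif_hit, "RTCGAY")
  expect_error(motif_set(character(0)), "nonempty")
})

test_that("filter_motifs is idempotent and order-independent", {
  withr::local_seed(23)
  sp <- vapply(1:20, function(i) random_dna(22), character(1))
  g <- fake_guides(sp)
  once <- filter_motifs(g)
  twice <- filter_motifs(once)
  expect_identical(once$motif_hit, twice$motif_hit)
  perm <- sample(nrow(g))
  shuffled <- filter_motifs(g[perm, ])
  expect_identical(shuffled$motif_hit, once$motif_hit[perm])
})

test_that("single- and double-strand motif scanning agree on an RC-closed set", {
  withr::local_seed(29)
  ms <- motif_set_bbreve()
  wins <- vapply(1:300, function(i) random_dna(22, gc = 0.7), character(1))
  dbl <- !is.na(crispridesign:::motif_hits(wins, ms))
  # forward-strand-only scan, done independently with Biostrings
  subj <- Biostrings::DNAStringSet(wins)
  sgl <- Reduce(`|`, lapply(ms$motifs, function(m)
    Biostrings::vcountPattern(Biostrings::DNAString(m), subj,
                              fixed = "subject") > 0))
  expect_identical(dbl, sgl)
})

test_that("spacer_multiplicity counts duplicated blocks and flags non-unique guides", {
  sim <- small_sim(seed = 2)
  guides <- enumerate_guides(sim$genome, pam_sth1_consensus())
  guides <- spacer_multiplicity(guides, sim$genome)
  truth <- sim$truth$guides
  dup_ids <- truth$guide_id[truth$expected == "non_unique_rejected"]
  expect_setequal(guides$guide_id[guides$non_unique], dup_ids)
  expect_true(all(guides$multiplicity[guides$guide_id %in% dup_ids] == 2))
  expect_true(all(guides$multiplicity[!guides$guide_id %in% dup_ids] == 1))
})

test_that("a palindromic spacer at one locus has multiplicity 1", {
  half <- "ACGTACGTACG"
  palin <- paste0(half, reverse_complement(half))
  expect_identical(palin, reverse_complement(palin))
  g <- genome_table(c(chr = paste0(strrep("C", 40), palin, strrep("C", 40))))
  guides <- fake_guides(palin)
  guides$spacer_start <- 41L; guides$spacer_end <- 62L
  out <- spacer_multiplicity(guides, g)
  expect_equal(out$multiplicity, 1L)
  expect_false(out$non_unique)
})

test_that("pam_adjacent mode counts only PAM-flanked occurrences", {
  withr::local_seed(31)
  sp <- random_dna(22)
  # one copy with a valid PAM, one without
  g <- genome_table(c(chr = paste0(strrep("C", 30), sp, "AAAGAAT",
                                   strrep("C", 30), sp, "CCCCCCC",
                                   strrep("C", 30))))
  guides <- fake_guides(sp)
  guides$spacer_start <- 31L; guides$spacer_end <- 52L
  seqmode <- spacer_multiplicity(guides, g, mode = "sequence")
  pammode <- spacer_multiplicity(guides, g, mode = "pam_adjacent",
                                 pam = pam_sth1_consensus())
  expect_equal(seqmode$multiplicity, 2L)
  expect_equal(pammode$multiplicity, 1L)
})

test_that("find_offtargets reports the on-target hit and matches multiplicity at 0 mm", {
  sim <- small_sim(seed = 3)
  guides <- enumerate_guides(sim$genome, pam_sth1_consensus())
  guides <- spacer_multiplicity(guides, sim$genome)
  some <- guides[seq(1, nrow(guides), by = 3), ]
  for (i in seq_len(nrow(some))) {
    hits <- find_offtargets(some[i, ], sim$genome, max_mismatches = 0)
    expect_equal(nrow(hits), some$multiplicity[i])
    own <- hits[hits$start == some$spacer_start[i] & hits$strand == some$strand[i], ]
    expect_equal(nrow(own), 1)
    expect_equal(own$mismatches, 0)
    expect_length(own$mismatch_positions[[1]], 0)
  }
})

test_that("find_offtargets agrees with the naive Hamming oracle", {
  withr::local_seed(37)
  seqstr <- random_dna(2000)
  g <- genome_table(c(chr = seqstr))
  for (k in 0:3) {
    sp <- substr(seqstr, 501, 522)
    guide <- fake_guides(sp)
    hits <- find_offtargets(guide, g, max_mismatches = k)
    oracle <- oracle_offtargets(sp, seqstr, k)
    expect_identical(
      sort(paste(hits$start, hits$strand, hits$mismatches)),
      sort(paste(oracle$start, oracle$strand, oracle$mismatches)))
  }
  expect_error(find_offtargets(fake_guides("ACGT"), g, max_mismatches = -1), ">= 0")
})

test_that("planted two-mismatch decoys are found with correct PAM-proximal positions", {
  sim <- small_sim(seed = 4)
  dec <- sim$truth$decoys
  truth <- sim$truth$guides
  src <- truth[truth$guide_id == dec$source_guide_id[1], ]
  guide <- tibble::tibble(guide_id = src$guide_id, spacer_seq = src$spacer_seq)
  hit2 <- find_offtargets(guide, sim$genome, max_mismatches = 2)
  decoy_hit <- hit2[hit2$start == dec$start[1] & hit2$strand == dec$strand[1], ]
  expect_equal(nrow(decoy_hit), 1)
  expect_equal(decoy_hit$mismatches, 2)
  expect_identical(decoy_hit$mismatch_positions[[1]], dec$mismatch_positions[[1]])
  expect_true(decoy_hit$pam_adjacent)
  hit1 <- find_offtargets(guide, sim$genome, max_mismatches = 1)
  expect_false(any(hit1$start == dec$start[1] & hit1$strand == dec$strand[1]))
})
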