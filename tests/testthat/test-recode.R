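AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]

find_motif_occurrences_test <- function(cds, motifs = motif_set_bbreve()) {
  crispridesign:::find_motif_occurrences(cds, motifs)
}


test_that("translate_cds translates, consumes terminal stops and names internal stops", {
  expect_identical(translate_cds("ATG"), "M")
  expect_identical(translate_cds("ATGTAA"), "M")
  expect_identical(translate_cds("ATGGCTCTGCAG"), "MALQ")
  expect_error(translate_cds("ATGTAAGCT"), "internal stop codon at codon index 2")
  expect_error(translate_cds("ATGC"), "multiple of 3")
  expect_error(translate_cds("ATGNNN"), "A/C/G/T")
})

test_that("codon_optimize uses the argmax codon with lexicographic ties", {
  expect_identical(codon_optimize("M"), "ATGTAA")  # Met has one codon
  withr::local_seed(53)
  p <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
  expect_equal(nchar(codon_optimize(p)), 3 * nchar(p) + 3)
  expect_identical(translate_cds(codon_optimize(p, codon_usage_gc_biased())), p)
  expect_error(codon_optimize("MBZ"), "unknown residue")

  # under a uniform table the output is the lexicographically smallest
  # synonymous CDS: check against brute-force enumeration for a short protein
  gc11 <- Biostrings::getGeneticCode("11")
  for (prot in c("LSR", "GPW", "IVF")) {
    syn <- lapply(strsplit(prot, "")[[1]],
                  function(a) names(gc11)[gc11 == a])
    all_cds <- apply(expand.grid(syn, stringsAsFactors = FALSE), 1,
                     paste, collapse = "")
    expect_identical(codon_optimize(prot, codon_usage_uniform()),
                     paste0(min(all_cds), "TAA"))
  }
})

test_that("codon tables validate their invariants", {
  tbl <- codon_usage_gc_biased()
  sums <- tapply(tbl$freq[tbl$amino_acid != "*"],
                 tbl$amino_acid[tbl$amino_acid != "*"], sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(sum(tbl$amino_acid != "*"), 61)
  # reader rejects incomplete tables
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl[1:10, ], path)
  expect_error(read_codon_table(path), "missing")
  # and round-trips complete ones
  readr::write_tsv(tbl, path)
  expect_equal(read_codon_table(path)$freq, tbl$freq)
})

test_that("remove_motifs breaks a motif by one synonymous swap", {
  r <- remove_motifs("CTGCAG", motif_set_bbreve())  # Leu-Gln
  expect_true(r$success)
  expect_equal(nrow(r$substitutions), 1)
  expect_identical(translate_cds(r$cds), "LQ")
  expect_equal(nrow(find_motif_occurrences_test(r$cds)), 0)
})

test_that("remove_motifs is the identity on motif-free input", {
  withr::local_seed(59)
  p <- paste(sample(AA20, 50, replace = TRUE), collapse = "")
  cds <- codon_optimize(p, codon_usage_uniform())
  r1 <- remove_motifs(cds)
  if (r1$success) {
    r2 <- remove_motifs(r1$cds)
    expect_identical(r2$cds, r1$cds)
    expect_equal(nrow(r2$substitutions), 0)
  }
})

test_that("remove_motifs reports unbreakable occurrences as residual", {
  # ATG GAT = Met-Asp; Met has one codon and both Asp codons start GA,
  # so the contrived motif ATGGA cannot be broken
  r <- remove_motifs("ATGGAT", motif_set("ATGGA", name = "contrived"))
  expect_false(r$success)
  expect_equal(r$residual_motifs$start[1], 1)
  expect_identical(translate_cds(r$cds), translate_cds("ATGGAT"))
})

test_that("recoding preserves translation and clears both strands (property)", {
  withr::local_seed(61)
  ms <- motif_set_bbreve()
  for (i in 1:10) {
    p <- paste(sample(AA20, 120, replace = TRUE), collapse = "")
    r <- remove_motifs(codon_optimize(p, codon_usage_gc_biased()),
                       ms, codon_usage_gc_biased())
    expect_true(r$success)
    expect_identical(translate_cds(r$cds), p)
    expect_equal(nrow(find_motif_occurrences_test(r$cds)), 0)
    expect_equal(nrow(find_motif_occurrences_test(reverse_complement(r$cds))), 0)
  }
})

test_that("spacers drawn from a recoded CDS always pass the motif filter", {
  withr::local_seed(67)
  ms <- motif_set_bbreve()
  p <- paste(sample(AA20, 200, replace = TRUE), collapse = "")
  r <- remove_motifs(codon_optimize(p, codon_usage_gc_biased()),
                     ms, codon_usage_gc_biased())
  expect_true(r$success)
  starts <- seq(1, nchar(r$cds) - 21, by = 7)
  wins <- substring(r$cds, starts, starts + 21)
  hits <- crispridesign:::motif_hits(wins, ms)
  expect_true(all(is.na(hits)))
})
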