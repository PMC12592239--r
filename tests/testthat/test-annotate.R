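# fixture: one contig, two genes on opposite strands, hand-placed guides
annot_fixture <- function() {
  genome <- genome_table(c(chr = random_dna(5000)))
  features <- gene_table(seqid = "chr", start = c(1000, 3000), end = c(2000, 3800),
                         strand = c("+", "-"), locus_tag = c("GENE_A", "GENE_B"),
                         genome = genome)
  list(genome = genome, features = features)
}

mk_guide <- function(spacer_start, strand, id = NULL) {
  tibble::tibble(
    guide_id = id %||% paste0("chr:", spacer_start, ":", strand),
    seqid = "chr", strand = strand,
    spacer_start = as.integer(spacer_start),
    spacer_end = as.integer(spacer_start + 21L),
    spacer_seq = strrep("A", 22), pam_seq = "AAAGAAT")
}

test_that("strand classification follows the convention and its inversion swaps labels", {
  expect_equal(classify_target_strand("-", "+"), "non_template")
  expect_equal(classify_target_strand("+", "+"), "template")
  expect_equal(classify_target_strand("+", "+", "same_strand"), "non_template")
  expect_equal(classify_target_strand("-", "+", "same_strand"), "template")
})

test_that("guides are assigned by midpoint with signed offsets from the start codon", {
  withr::local_seed(41)
  fx <- annot_fixture()
  # gene body: protospacer [1079,1100] on "+", PAM-proximal end 1100
  g1 <- assign_to_genes(mk_guide(1079, "+"), fx$features, fx$genome)
  expect_equal(g1$gene, "GENE_A")
  expect_equal(g1$offset_from_start, 100)
  expect_equal(g1$strand_class, "template")

  # 5' UTR: midpoint in [900, 999] -> negative offset
  g2 <- assign_to_genes(mk_guide(930, "-"), fx$features, fx$genome)
  expect_equal(g2$gene, "GENE_A")
  expect_lt(g2$offset_from_start, 0)
  expect_equal(g2$strand_class, "non_template")

  # far from any gene window -> intergenic
  g3 <- assign_to_genes(mk_guide(500, "+"), fx$features, fx$genome)
  expect_true(is.na(g3$gene))
  expect_equal(g3$strand_class, "intergenic")

  # "-" gene: start codon at gene end; PAM-proximal end of a "+" protospacer
  # is its spacer_end (3771), so the offset is 3800 - 3771
  g4 <- assign_to_genes(mk_guide(3750, "+"), fx$features, fx$genome)
  expect_equal(g4$gene, "GENE_B")
  expect_equal(g4$offset_from_start, 29)
  expect_equal(g4$strand_class, "non_template")
})

test_that("flipping the strand convention exactly exchanges class counts", {
  sim <- small_sim(seed = 5)
  guides <- enumerate_guides(sim$genome, pam_sth1_consensus())
  a <- assign_to_genes(guides, sim$features, sim$genome,
                       nontemplate_when = "opposite_strand")
  b <- assign_to_genes(guides, sim$features, sim$genome,
                       nontemplate_when = "same_strand")
  ta <- table(factor(a$strand_class, c("non_template", "template", "intergenic")))
  tb <- table(factor(b$strand_class, c("non_template", "template", "intergenic")))
  expect_equal(unname(ta["non_template"]), unname(tb["template"]))
  expect_equal(unname(ta["template"]), unname(tb["non_template"]))
  expect_equal(unname(ta["intergenic"]), unname(tb["intergenic"]))
})

test_that("targetability report counts covered genes and exact density", {
  withr::local_seed(43)
  genome <- genome_table(c(chr = random_dna(11000)))
  features <- gene_table(seqid = "chr", start = seq(1000, 10000, by = 1000),
                         end = seq(1400, 10400, by = 1000),
                         strand = rep(c("+", "-"), 5),
                         locus_tag = sprintf("G%02d", 1:10), genome = genome)
  # one guide in each of the first 9 genes
  guides <- dplyr::bind_rows(lapply(seq(1000, 9000, by = 1000) + 100,
                                    mk_guide, strand = "+"))
  rep9 <- targetability_report(guides, features, genome)
  expect_equal(rep9$n_genes, 10)
  expect_equal(rep9$n_targetable, 9)
  expect_equal(rep9$bp_per_guide * rep9$n_guides, rep9$genome_length)
  expect_lte(sum(rep9$per_gene$n_guides), rep9$n_guides)

  rep0 <- targetability_report(mk_guide(100, "+")[0, ], features, genome)
  expect_equal(rep0$n_guides, 0)
  expect_true(is.na(rep0$bp_per_guide))
  g <- glance(rep9)
  expect_equal(g$n_targetable, 9)
  expect_equal(nrow(tidy(rep9)), 9)
})

test_that("targetable-gene count shrinks monotonically as filters tighten", {
  sim <- small_sim(seed = 6)
  guides <- enumerate_guides(sim$genome, pam_sth1_consensus())
  n_t <- function(g, rule = "any_strand")
    targetability_report(g, sim$features, sim$genome, rule = rule)$n_targetable
  after_motif <- dplyr::filter(filter_motifs(guides), is.na(.data$motif_hit))
  after_unique <- dplyr::filter(spacer_multiplicity(after_motif, sim$genome),
                                !.data$non_unique)
  expect_gte(n_t(guides), n_t(after_motif))
  expect_gte(n_t(after_motif), n_t(after_unique))
  expect_gte(n_t(after_unique), n_t(after_unique, rule = "non_template"))
})

test_that("per-gene selection ranks 5'-proximal non-template guides deterministically", {
  withr::local_seed(47)
  fx <- annot_fixture()
  # five non-template guides of GENE_A ("+" gene -> protospacer "-") whose
  # PAM-proximal end (spacer_start) sits at offsets -20, 5, 40, 300, 900
  offs <- c(-20, 5, 40, 300, 900)
  guides <- dplyr::bind_rows(lapply(offs, function(o) mk_guide(1000 + o, "-")))
  ann <- assign_to_genes(guides, fx$features, fx$genome)
  expect_equal(sort(ann$offset_from_start), sort(offs))
  sel <- select_guides_per_gene(ann, fx$features, n_per_gene = 3)
  expect_equal(sel$offset_from_start, c(-20, 5, 40))
  expect_equal(sel$rank, 1:3)
  expect_equal(uncovered_genes(sel), "GENE_B")

  # a gene with only template-strand guides selects nothing
  tmpl <- assign_to_genes(mk_guide(1200, "+"), fx$features, fx$genome)
  sel2 <- select_guides_per_gene(tmpl, fx$features, n_per_gene = 3)
  expect_equal(nrow(sel2), 0)
  expect_setequal(uncovered_genes(sel2), c("GENE_A", "GENE_B"))
  expect_error(select_guides_per_gene(ann, fx$features, 0), ">= 1")
})

test_that("selection is a subset of input and respects the per-gene cap", {
  for (seed in 7:9) {
    sim <- small_sim(seed = seed)
    d <- run_guide_design(sim$genome, sim$features, n_per_gene = 2)
    sel <- d$selected
    expect_true(all(sel$guide_id %in% d$guides$guide_id))
    expect_true(all(table(sel$gene) <= 2))
    expect_true(all(sel$strand_class == "non_template"))
  }
})
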