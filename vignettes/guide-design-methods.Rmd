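---
title: "Methods: CRISPRi guide design with restriction-motif avoidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPRi guide design with restriction-motif avoidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispridesign)
```

## The problem

CRISPR interference (CRISPRi) represses a bacterial gene by parking a
catalytically dead Cas9 (dCas9) on its DNA, where it blocks RNA polymerase.
Two properties of the effector decide which sequences can be targeted:

* the protospacer-adjacent motif (PAM), a short sequence that must sit
  immediately 3' of the genomic protospacer on the protospacer-bearing
  strand. The *Streptococcus thermophilus* CRISPR1 (Sth1) dCas9 used in
  GC-rich hosts such as bifidobacteria recognises the degenerate consensus
  `NNAGAAW`, and tolerates relaxed variants of it;
* the strand geometry: an elongation block requires the guide RNA to anneal
  to the **non-template** (coding) strand of the gene, which places the PAM
  on the template strand.

Guide choice in a real host is further constrained by its
restriction–modification (R-M) systems: a guide cassette carrying an R-M
recognition site (for *B. breve* UCC2003: `CTGCAG`, `RTCGAY`, `GGCGCC`) is
cleaved during cloning or transformation, so such guides are discarded. And
a guide whose spacer occurs more than once in the genome has no unique
target. The package implements this whole decision procedure, genome-wide,
plus the mirror-image problem for synthetic constructs: recoding a coding
sequence so it contains no R-M site while preserving its protein.

## Pipeline

`run_guide_design()` composes five stages, each available separately:

1. **PAM scan** (`find_pam_sites()`). Every window on either strand whose
   5'→3' reading matches any pattern of the `pam_spec()` is a site; a window
   hit by several patterns is one site. Matching is degenerate on the pattern
   side only; an `N` in the genome never matches any pattern position, because
   an ambiguous base cannot be confirmed as a target.
2. **Spacer extraction** (`enumerate_guides()`). The spacer is the
   `spacer_len` bases (default 22, the Sth1 CRISPRi targeting-region length)
   immediately 5' of the PAM on the protospacer strand. Sites whose flank
   runs off a linear contig, or whose spacer contains `N`, are dropped and
   counted, never silently lost.
3. **Motif filter** (`filter_motifs()`). A guide is flagged when any motif of
   the set — or its reverse complement — occurs in the window. The default
   window is the spacer only (the sequence that is cloned into the guide
   cassette); `spacer_plus_pam` is available for analyses of the genomic
   locus. Both strands are always scanned so non-palindromic user motif sets
   behave correctly; on the RC-closed default set this is provably equivalent
   to a single-strand scan, and a regression test asserts it.
4. **Uniqueness filter** (`spacer_multiplicity()`). Multiplicity counts exact
   occurrences of the spacer across all contigs and both strands
   (`mode = "sequence"`, the default and stricter reading of "redundant or
   repeat sequences"); `mode = "pam_adjacent"` counts only PAM-flanked
   occurrences, the biologically minimal criterion, for sensitivity
   analyses. All copies of a repeated guide are dropped (each carries the
   `non_unique` flag); a palindromic spacer at one locus is one physical
   footprint and counts once.
5. **Annotation and reporting** (`assign_to_genes()`,
   `targetability_report()`, `select_guides_per_gene()`). A guide belongs to
   the gene whose strand-aware interval `[start − upstream_window, end]`
   (default window 100 bp, to keep 5' UTR guides in scope) contains the
   protospacer midpoint; ties go to the smallest absolute offset, then the
   lexicographically smallest locus tag, so per-gene sums stay
   interpretable. `offset_from_start` is measured to the PAM-proximal end of
   the protospacer because the dCas9 roadblock sits PAM-proximally.

Off-target enumeration (`find_offtargets()`) is a separate audit tool: all
windows within a Hamming distance (no indels) of the spacer, on both
strands, optionally restricted to PAM-flanked windows. Mismatch positions
are indexed PAM-proximally (position 1 adjacent to the PAM) because that is
where mismatches are least tolerated; mismatched guides can still act, and
guides with close relatives elsewhere in the genome deserve scrutiny. The
search is an exhaustive scan, not an index: desk-scale bacterial genomes
(≤ ~10 Mb) do not justify the extra machinery, and the scan is directly
checkable against a naive per-window oracle.

## Strand convention

"Targeting strand X" is used in both senses in the CRISPRi literature. Here
the mechanistic convention is the default: the guide base-pairs with the
strand complementary to the PAM-bearing protospacer strand, so a guide is
`non_template` exactly when its protospacer strand is opposite the gene's
coding strand. The convention is one switch (`nontemplate_when`), flipping
it exactly exchanges the two labels (a tested invariant), and every report
records which convention produced it.

The targetability report supports two rules: `any_strand` (a gene counts as
targetable if any retained guide maps to it — the permissive "possible
target sites" reading) and `non_template` (only guides expected to repress).
Library selection (`select_guides_per_gene()`) always uses the strict rule
and ranks 5'-proximal guides first: upstream-window guides by distance to
the start codon, then gene-body guides by ascending offset, ties by guide
id, so selections are deterministic.

## Coordinates

All tables use 1-based inclusive coordinates, the native R/Bioconductor
convention, end to end; only the BED writer converts to the format's 0-based
half-open intervals. Circular contigs are scanned across the origin by
virtually appending the first pattern-length − 1 bases; wrapped coordinates
are reported modulo the contig length (`spacer_end < spacer_start` marks a
wrapped guide, which the BED writer skips with a warning since BED cannot
represent it).

## Construct recoding

`codon_optimize()` uses the deterministic argmax strategy: each residue gets
its highest-frequency codon in the usage table, ties broken
lexicographically, and a terminal stop is appended (default `TAA`).
Published optimizers implement many strategies; this one is chosen because
it is deterministic and testable — under a uniform table the output is
provably the lexicographically smallest synonymous CDS, which the tests
exploit. GC content and RNA structure are deliberately not optimised.

`remove_motifs()` then eliminates R-M sites: find the leftmost motif
occurrence on either strand; among the codons overlapping it, apply the
synonymous substitution with the highest usage frequency that kills the
occurrence and introduces no new occurrence within the surrounding window
(the occurrence padded by one motif length each side); repeat to fixpoint,
with an iteration cap of 10 × the initial occurrence count to prevent
oscillation between overlapping sites. Occurrences that no synonymous
substitution can break (for instance a motif pinned by Met/Trp codons) are
reported as `residual_motifs` and the result is marked unsuccessful —
never silently returned. Translation invariance is an explicit postcondition
and a tested property; the terminal stop may be swapped for a synonymous
stop. Codon usage tables are tabular text (`read_codon_table()`); since
measured usage for a specific host is an input, the package ships only
generated tables — `codon_usage_uniform()` and `codon_usage_gc_biased()`
(frequencies ∝ strength^(G+C), emulating a GC-rich host; the copy under
`inst/extdata` is labelled synthetic accordingly).

## The synthetic-genome generator

`simulate_genome()` exists so that every stage has exact, recomputable
ground truth without downloading a reference genome. It builds a random
background (default 50% GC), removes every accidental PAM register from it,
then plants guide footprints whose truth table records position, strand,
sequence and the expected pipeline outcome:

* 20 clean guides spread over gene bodies (both strand classes), 5' UTR
  windows and intergenic space → expected **retained**;
* 5 guides whose spacer carries an R-M motif → expected **motif-rejected**;
* a 400-bp block containing 2 extra guides, copied verbatim once → those
  guides and their copies have multiplicity 2, expected
  **uniqueness-rejected**;
* 3 decoy protospacers, each a two-mismatch variant of a planted guide with
  its own PAM, planted intergenically → found by `find_offtargets()` at
  exactly the planted PAM-proximal positions (4 and 11), absent at
  `max_mismatches = 1`.

Defaults (10 genes × 900 bp, 300 bp intergenic, ~13.8 kb genome) are chosen
as the smallest layout in which all planting categories coexist without
crowding: one plausible operon-scale gene size, intergenic gaps wide enough
that a 100-bp upstream window never bridges two genes on the tested strand
layout, and a tail region that keeps duplicated-block and decoy plantings
away from every gene window. One seeded RNG stream drives the whole
construction; regeneration from a seed is byte-identical.

Sanitisation is what makes the truth exact: spacers are drawn to contain no
PAM core, no motif (either strand) and no palindrome; concrete PAMs are
rejected if they would create a second register inside the footprint; and a
final scan mutates one constrained base of any spurious register outside
the planted footprints. What the fixture therefore does **not** emulate is
real genome composition — codon structure, skew, repeats beyond the planted
block, or PAM density of a GC-rich chromosome (the report's density on
random 50% GC sequence, one site per ~270 bp, is far sparser than a relaxed
PAM set achieves on a real genome). Passing on fixtures demonstrates the
correctness of the algorithms, not the biology of any particular strain.

## Numerical and degenerate-input choices

* Empty motif set: an error, never a silent no-op filter.
* A guide whose own spacer cannot be found in its genome: corrupt input, an
  error.
* `n_guides = 0`: the report's `bp_per_guide` is `NA`, not `Inf`;
  `bp_per_guide × n_guides = genome_length` holds exactly whenever defined,
  and rounding happens only at printing.
* Gene/CDS pairs sharing a locus tag collapse to the gene row; locus tags
  fall back `locus_tag` → `ID` → `Name`; duplicates are an error naming the
  offenders.
* All output tables are sorted on fixed keys and carry no timestamps, so
  reruns are byte-identical.

## Paper-scale benchmark

`targetability_benchmark()` runs the pipeline on a deposited genome +
annotation with a user-supplied relaxed PAM config, and prints the exact PAM
pattern list and the feature-type filter next to the results. Both are
printed because published library figures for *B. breve* UCC2003 (about
28,000 sites, one per ~86 bp, 1793 of 1824 genes) depend on the precise
relaxed PAM list and annotation version used, which are not shipped with
the package; discrepancies must be attributable. Guide counts are per
(position, strand): the two strands of one locus are two sites. The genome
and annotation (BioProject PRJNA13487) must be downloaded by the user.

## Known limitations

* Motif occurrences spanning the junction between a spacer and the vector
  scaffold are out of scope: no scaffold sequence is modelled.
* No thermodynamic or machine-learned off-target scoring, no bulge-tolerant
  alignment, no methylation-state modelling; PAMs are binary
  permissible/not, as the filtering procedure treats them.
* 5'-PAM effectors (Cas12a-type) are not supported; the PAM side is fixed
  3'.
* No operon or TSS inference: "upstream" means upstream of the annotated
  start codon.

## A worked example

```{r example}
sim <- simulate_genome(seed = 1)
design <- run_guide_design(sim$genome, sim$features, n_per_gene = 3)
design
glance(design)
head(tidy(design$report))
```

```{r plot, fig.width=6, fig.height=3.5}
ggplot2::autoplot(design$report)
```
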