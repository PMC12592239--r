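Package: crispridesign
Title: CRISPRi Guide Design for Bacterial Genomes with
    Restriction-Modification Motif Avoidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide design of single guide RNAs for CRISPR
    interference (CRISPRi) in bacteria with dCas9 variants recognising
    degenerate protospacer-adjacent motifs (PAMs), such as the
    Streptococcus thermophilus CRISPR1 (Sth1) dCas9 and its NNAGAAW
    consensus. Scans both strands of a genome for PAM sites, extracts
    fixed-length spacers, removes guides carrying host
    restriction-modification recognition motifs, removes guides whose
    spacer is not unique in the genome, enumerates mismatched off-target
    sites, assigns guides to annotated genes with template/non-template
    strand classification, and summarises genome-wide targetability
    (guide density, per-gene coverage). Also recodes coding sequences for
    a host by codon optimisation with restriction-motif exclusion, and
    simulates synthetic genomes with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
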