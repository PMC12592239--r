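# End-to-end guide design: scan -> motif filter -> uniqueness -> annotate ->
# report -> optional per-gene selection, with a per-stage attrition audit.

#' Run the full CRISPRi guide-design pipeline
#'
#' Stages, in order: PAM scan + spacer extraction ([enumerate_guides()]),
#' restriction-motif exclusion ([filter_motifs()]), spacer-uniqueness filter
#' ([spacer_multiplicity()]), gene assignment and strand classification
#' ([assign_to_genes()]), targetability report ([targetability_report()]) and
#' optionally per-gene library selection ([select_guides_per_gene()]).
#' Attrition is conserved at every stage: input = kept + rejected.
#'
#' @param genome Genome tibble ([read_genome_fasta()] / [genome_table()]).
#' @param features Gene feature tibble ([read_gene_gff3()] / [gene_table()]);
#'   may be `NULL` for an annotation-free run (report then has 0 genes).
#' @param pam [pam_spec()] (default Sth1 consensus NNAGAAW).
#' @param motifs [motif_set()] (default B. breve UCC2003 triple).
#' @param spacer_len Spacer length (default 22).
#' @param motif_window Window for the motif filter, see [filter_motifs()].
#' @param uniqueness_mode Multiplicity mode, see [spacer_multiplicity()].
#' @param upstream_window bp upstream of a start codon still assigned to the
#'   gene (default 100).
#' @param nontemplate_when Strand convention, see [classify_target_strand()].
#' @param rule Targetability rule, see [targetability_report()].
#' @param n_per_gene If not `NULL`, also select up to this many non-template
#'   guides per gene.
#' @return A `guide_design` list: `guides` (retained, annotated), `rejected`
#'   (with `reject_reason`), `report`, `selected` (or `NULL`), `audit`
#'   (per-stage counts) and `params`. `tidy()` returns the retained guides,
#'   `glance()` the report summary.
#' @export
run_guide_design <- function(genome, features = NULL,
                             pam = pam_sth1_consensus(),
                             motifs = motif_set_bbreve(),
                             spacer_len = 22L,
                             motif_window = "spacer_only",
                             uniqueness_mode = "sequence",
                             upstream_window = 100L,
                             nontemplate_when = "opposite_strand",
                             rule = "any_strand",
                             n_per_gene = NULL) {
  guides <- enumerate_guides(genome, pam, spacer_len)
  scan_attrition <- attr(guides, "attrition")

  guides <- filter_motifs(guides, motifs, window = motif_window)
  rej_motif <- dplyr::filter(guides, !is.na(.data$motif_hit))
  kept <- dplyr::filter(guides, is.na(.data$motif_hit))

  kept <- spacer_multiplicity(kept, genome, mode = uniqueness_mode, pam = pam)
  rej_dup <- dplyr::filter(kept, .data$non_unique)
  kept <- dplyr::filter(kept, !.data$non_unique)

  if (is.null(features))
    features <- gene_table(character(0), integer(0), integer(0), character(0),
                           character(0), feature_types = "none")
  for (a in c("spacer_len", "pam_spec")) attr(kept, a) <- attr(guides, a)
  kept <- assign_to_genes(kept, features, genome,
                          upstream_window = upstream_window,
                          nontemplate_when = nontemplate_when)
  report <- targetability_report(kept, features, genome, rule = rule)
  selected <- if (!is.null(n_per_gene))
    select_guides_per_gene(kept, features, n_per_gene = n_per_gene) else NULL

  rejected <- dplyr::bind_rows(
    dplyr::mutate(rej_motif, reject_reason = paste0("motif_hit:", .data$motif_hit)),
    dplyr::mutate(rej_dup, reject_reason = "non_unique")
  )
  audit <- dplyr::bind_rows(
    scan_attrition,
    tibble::tibble(stage = c("motif_rejected", "non_unique_rejected", "retained"),
                   n = c(nrow(rej_motif), nrow(rej_dup), nrow(kept)))
  )
  structure(list(
    guides = kept, rejected = rejected, report = report, selected = selected,
    audit = audit,
    params = list(pam_set = pam$name, pam_patterns = pam$patterns,
                  motif_set = motifs$name, motifs = motifs$motifs,
                  spacer_len = as.integer(spacer_len),
                  motif_window = motif_window,
                  uniqueness_mode = uniqueness_mode,
                  upstream_window = as.integer(upstream_window),
                  nontemplate_when = nontemplate_when, rule = rule,
                  feature_types = attr(features, "feature_types") %||% "unspecified")
  ), class = "guide_design")
}

#' @export
print.guide_design <- function(x, ...) {
  cat("CRISPRi guide design\n")
  cat(sprintf("  PAM set %s (%s); motif set %s; spacer %d bp\n",
              x$params$pam_set, paste(x$params$pam_patterns, collapse = ","),
              x$params$motif_set, x$params$spacer_len))
  a <- rlang::set_names(x$audit$n, x$audit$stage)
  cat(sprintf("  sites %d -> guides %d -> motif-rejected %d -> non-unique %d -> retained %d\n",
              a[["pam_sites"]], a[["guides"]], a[["motif_rejected"]],
              a[["non_unique_rejected"]], a[["retained"]]))
  print(x$report)
  invisible(x)
}

#' @rdname run_guide_design
#' @param x A `guide_design`.
#' @param ... Unused.
#' @method tidy guide_design
#' @export
tidy.guide_design <- function(x, ...) x$guides

#' @rdname run_guide_design
#' @method glance guide_design
#' @export
glance.guide_design <- function(x, ...) glance(x$report)

#' Write a guide table as TSV (1-based inclusive coordinates)
#'
#' @param guides Guide tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guide_tsv <- function(guides, path) {
  out <- dplyr::rename(guides, spacer_start_1based = "spacer_start",
                       spacer_end_1based = "spacer_end")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write protospacer intervals as BED6 (0-based half-open)
#'
#' The score column carries the spacer multiplicity when present (0
#' otherwise). Origin-wrapping guides on circular contigs are skipped with a
#' warning (BED cannot represent them).
#' @param guides Guide tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides_bed <- function(guides, path) {
  wrapped <- guides$spacer_end < guides$spacer_start
  if (any(wrapped)) {
    warning(sprintf("%d origin-wrapping guide(s) not representable in BED, skipped",
                    sum(wrapped)))
    guides <- guides[!wrapped, , drop = FALSE]
  }
  bed <- tibble::tibble(
    chrom = guides$seqid, start = guides$spacer_start - 1L,
    end = guides$spacer_end, name = guides$guide_id,
    score = if ("multiplicity" %in% names(guides)) guides$multiplicity else 0L,
    strand = guides$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write spacer sequences as FASTA
#'
#' @param guides Guide tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spacers_fasta <- function(guides, path) {
  set <- Biostrings::DNAStringSet(rlang::set_names(guides$spacer_seq,
                                                   guides$guide_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write all design artifacts to a directory
#'
#' Writes `guides.tsv`, `rejected.tsv`, `guides.bed`, `spacers.fasta`,
#' `report.json` and `audit.json` (plus `selected.tsv` when a selection was
#' made). Outputs are deterministic: fixed ordering, no timestamps.
#'
#' @param design A `guide_design` from [run_guide_design()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_design_outputs <- function(design, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_guide_tsv(dplyr::mutate(design$guides,
                                mismatch_positions = NULL), p("guides.tsv"))
  write_guide_tsv(design$rejected, p("rejected.tsv"))
  write_guides_bed(design$guides, p("guides.bed"))
  write_spacers_fasta(design$guides, p("spacers.fasta"))
  rep <- design$report
  jsonlite::write_json(list(
    n_guides = rep$n_guides, genome_length = rep$genome_length,
    bp_per_guide = rep$bp_per_guide, n_genes = rep$n_genes,
    n_targetable = rep$n_targetable, params = c(rep$params, design$params)
  ), p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(rlang::set_names(as.list(design$audit$n),
                                        design$audit$stage),
                       p("audit.json"), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(design$selected))
    write_guide_tsv(design$selected, p("selected.tsv"))
  invisible(out_dir)
}

#' Paper-scale targetability benchmark on a downloaded genome
#'
#' Convenience wrapper for benchmarking the pipeline on a real deposited
#' genome + annotation (e.g. B. breve UCC2003): runs [run_guide_design()]
#' with a user-supplied relaxed PAM config and prints the PAM pattern list
#' and the annotation feature-type filter alongside the results, so that any
#' discrepancy with published counts is attributable to the PAM list or
#' annotation version used. Guide counts are per (position, strand): the two
#' strands of one locus are two sites.
#'
#' @param genome_fasta,annotation_gff3 Paths to the deposited genome and
#'   annotation.
#' @param pam_config Path to the relaxed PAM pattern list (one IUPAC pattern
#'   per line), see [read_pam_config()].
#' @param ... Passed to [run_guide_design()].
#' @return The `guide_design`, printed.
#' @export
targetability_benchmark <- function(genome_fasta, annotation_gff3, pam_config, ...) {
  genome <- read_genome_fasta(genome_fasta)
  features <- read_gene_gff3(annotation_gff3, genome)
  design <- run_guide_design(genome, features, pam = read_pam_config(pam_config), ...)
  print(design)
  invisible(design)
}
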