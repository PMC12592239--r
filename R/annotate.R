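# Gene assignment, template/non-template classification, per-gene guide
# selection and the genome-wide targetability report.
#
# Strand convention: CRISPRi blocks elongation when the guide RNA anneals to
# the non-template (coding) strand of a gene. The guide base-pairs with the
# strand complementary to the PAM-bearing protospacer strand, so under the
# default convention a guide is "non_template" when its protospacer strand is
# opposite the gene's coding strand. Because the literature uses "targets
# strand X" in both senses, the convention is a single switch
# (`nontemplate_when`) and every report records which convention produced it.

#' Classify guides as template or non-template for a gene
#'
#' @param protospacer_strand,gene_strand Character vectors of `"+"`/`"-"`.
#' @param nontemplate_when `"opposite_strand"` (default: non-template when
#'   the protospacer strand differs from the gene strand) or `"same_strand"`
#'   (the inverted convention). Flipping the switch exactly exchanges the two
#'   labels.
#' @return Character vector, `"non_template"` or `"template"`.
#' @export
classify_target_strand <- function(protospacer_strand, gene_strand,
                                   nontemplate_when = c("opposite_strand", "same_strand")) {
  nontemplate_when <- match.arg(nontemplate_when)
  opp <- protospacer_strand != gene_strand
  if (nontemplate_when == "same_strand") opp <- !opp
  ifelse(opp, "non_template", "template")
}

# guide midpoint, robust to origin-wrapped circular intervals
guide_midpoint <- function(spacer_start, spacer_end, contig_len) {
  w <- ifelse(spacer_end >= spacer_start, spacer_end - spacer_start + 1L,
              contig_len - spacer_start + 1L + spacer_end)
  as.integer(((spacer_start - 1L + (w - 1L) %/% 2L) %% contig_len) + 1L)
}

#' Assign guides to genes and classify targeting strand
#'
#' A guide is assigned to the gene whose strand-aware interval
#' `[start - upstream_window, end]` (for `+` genes; mirrored for `-` genes)
#' contains the protospacer midpoint. `offset_from_start` is the signed
#' distance from the gene's translational start to the PAM-proximal end of
#' the protospacer (negative = upstream, i.e. 5' UTR targeting). Ties between
#' overlapping genes go to the smallest `|offset_from_start|`, then the
#' lexicographically smallest locus tag; with `multi_assign = TRUE` every
#' overlap is reported (extra rows, for reporting only).
#'
#' @param guides Guide tibble.
#' @param features Gene feature tibble ([gene_table()] / [read_gene_gff3()]).
#' @param genome Genome tibble (for contig lengths; needed for circular
#'   midpoints).
#' @param upstream_window bp upstream of the start codon still assigned to
#'   the gene (default 100).
#' @param nontemplate_when Strand convention switch, see
#'   [classify_target_strand()].
#' @param multi_assign Report all overlapping genes instead of one.
#' @return `guides` with added columns `gene` (locus tag or `NA`),
#'   `gene_strand`, `strand_class` (`non_template`/`template`/`intergenic`)
#'   and `offset_from_start`.
#' @export
assign_to_genes <- function(guides, features, genome, upstream_window = 100L,
                            nontemplate_when = c("opposite_strand", "same_strand"),
                            multi_assign = FALSE) {
  nontemplate_when <- match.arg(nontemplate_when)
  stopifnot(upstream_window >= 0)
  glen <- rlang::set_names(genome$length, genome$id)
  mid <- guide_midpoint(guides$spacer_start, guides$spacer_end, glen[guides$seqid])
  pam_proximal <- ifelse(guides$strand == "+", guides$spacer_end, guides$spacer_start)

  win <- dplyr::mutate(
    features,
    win_start = ifelse(.data$strand == "+", .data$start - upstream_window, .data$start),
    win_end = ifelse(.data$strand == "+", .data$end, .data$end + upstream_window)
  )

  cand <- dplyr::inner_join(
    tibble::tibble(.row = seq_len(nrow(guides)), seqid = guides$seqid,
                   mid = mid, pp = pam_proximal,
                   protospacer_strand = guides$strand),
    dplyr::select(win, "seqid", "win_start", "win_end",
                  gene = "locus_tag", gene_strand = "strand",
                  gstart = "start", gend = "end"),
    by = "seqid", relationship = "many-to-many"
  )
  cand <- dplyr::filter(cand, .data$mid >= .data$win_start, .data$mid <= .data$win_end)
  cand <- dplyr::mutate(
    cand,
    offset_from_start = ifelse(.data$gene_strand == "+",
                               .data$pp - .data$gstart, .data$gend - .data$pp)
  )
  if (!multi_assign) {
    cand <- dplyr::arrange(cand, .data$.row, abs(.data$offset_from_start), .data$gene)
    cand <- dplyr::distinct(cand, .data$.row, .keep_all = TRUE)
  }
  cand <- dplyr::mutate(
    cand,
    strand_class = classify_target_strand(.data$protospacer_strand,
                                          .data$gene_strand, nontemplate_when)
  )
  keep <- dplyr::select(cand, ".row", "gene", "gene_strand",
                        "strand_class", "offset_from_start")
  out <- dplyr::left_join(
    dplyr::mutate(guides, .row = dplyr::row_number()), keep, by = ".row",
    relationship = if (multi_assign) "one-to-many" else "one-to-one"
  )
  out <- dplyr::mutate(
    out,
    gene = as.character(.data$gene),
    gene_strand = as.character(.data$gene_strand),
    strand_class = dplyr::coalesce(as.character(.data$strand_class), "intergenic"),
    offset_from_start = as.integer(.data$offset_from_start),
    .row = NULL
  )
  attr(out, "spacer_len") <- attr(guides, "spacer_len")
  attr(out, "pam_spec") <- attr(guides, "pam_spec")
  attr(out, "nontemplate_when") <- nontemplate_when
  attr(out, "upstream_window") <- as.integer(upstream_window)
  out
}

#' Genome-wide targetability report
#'
#' Summarises a set of retained (filtered) guides: total count, guide
#' density (bp per guide), and per-gene coverage under a targetability rule.
#'
#' @param guides Annotated guide tibble ([assign_to_genes()]); if not yet
#'   annotated, `features`/`genome` are used to annotate with defaults.
#' @param features Gene feature tibble.
#' @param genome Genome tibble.
#' @param rule `"any_strand"` (default: any retained guide assigned to the
#'   gene makes it targetable — the permissive "possible target sites"
#'   reading) or `"non_template"` (only non-template guides count — the
#'   strict CRISPRi-effective rule).
#' @return A `targetability_report`: `glance()` gives the one-row summary,
#'   `tidy()` the per-gene table. `bp_per_guide` is exact
#'   (`genome_length / n_guides`); rounding happens only when printing.
#' @export
targetability_report <- function(guides, features, genome,
                                 rule = c("any_strand", "non_template")) {
  rule <- match.arg(rule)
  if (!"gene" %in% names(guides))
    guides <- assign_to_genes(guides, features, genome)
  genome_length <- sum(genome$length)
  n_guides <- nrow(guides)
  eligible <- dplyr::filter(guides, !is.na(.data$gene))
  if (rule == "non_template")
    eligible <- dplyr::filter(eligible, .data$strand_class == "non_template")
  per_gene <- dplyr::summarise(
    dplyr::group_by(eligible, locus_tag = .data$gene),
    n_guides = dplyr::n(),
    best_offset = .data$offset_from_start[rank_guide_order(.data$offset_from_start,
                                                           .data$guide_id)][1],
    .groups = "drop"
  )
  structure(list(
    n_guides = n_guides,
    genome_length = genome_length,
    bp_per_guide = if (n_guides > 0) genome_length / n_guides else NA_real_,
    n_genes = nrow(features),
    n_targetable = nrow(per_gene),
    per_gene = per_gene,
    params = list(
      rule = rule,
      feature_types = attr(features, "feature_types") %||% "unspecified",
      nontemplate_when = attr(guides, "nontemplate_when") %||% "opposite_strand",
      pam_set = (attr(guides, "pam_spec") %||% list(name = "unspecified"))$name,
      pam_patterns = (attr(guides, "pam_spec") %||% list(patterns = NA))$patterns
    )
  ), class = "targetability_report")
}

#' @export
print.targetability_report <- function(x, ...) {
  cat("Targetability report\n")
  cat(sprintf("  retained guides:   %d\n", x$n_guides))
  cat(sprintf("  genome length:     %d bp\n", x$genome_length))
  cat(sprintf("  guide density:     %s\n",
              if (is.na(x$bp_per_guide)) "undefined (no guides)"
              else sprintf("one per %.1f bp", x$bp_per_guide)))
  cat(sprintf("  targetable genes:  %d of %d (rule: %s)\n",
              x$n_targetable, x$n_genes, x$params$rule))
  cat(sprintf("  feature types:     %s\n",
              paste(x$params$feature_types, collapse = ", ")))
  cat(sprintf("  PAM set:           %s (%s)\n", x$params$pam_set,
              paste(x$params$pam_patterns, collapse = ", ")))
  cat(sprintf("  strand convention: non_template = PAM strand %s gene strand\n",
              if (x$params$nontemplate_when == "opposite_strand") "opposite to" else "same as"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname targetability_report
#' @param x A `targetability_report`.
#' @param ... Unused.
#' @method tidy targetability_report
#' @export
tidy.targetability_report <- function(x, ...) x$per_gene

#' @rdname targetability_report
#' @method glance targetability_report
#' @export
glance.targetability_report <- function(x, ...) {
  tibble::tibble(n_guides = x$n_guides, genome_length = x$genome_length,
                 bp_per_guide = x$bp_per_guide, n_genes = x$n_genes,
                 n_targetable = x$n_targetable, rule = x$params$rule,
                 nontemplate_when = x$params$nontemplate_when)
}

# ranking order for guides within a gene: upstream (negative offset) guides
# first by |offset| (closest to the start codon first), then gene-body guides
# by ascending offset; guide_id breaks ties.
rank_guide_order <- function(offset, guide_id) {
  order(offset >= 0, ifelse(offset < 0, abs(offset), offset), guide_id)
}

#' Select top guides per gene for a CRISPRi library
#'
#' For each gene, up to `n_per_gene` non-template-strand guides ranked 5'
#' proximal first: upstream-window guides by distance to the start codon,
#' then gene-body guides by ascending offset from the start. Deterministic
#' (ties by guide id).
#'
#' @param guides Annotated guide tibble.
#' @param features Gene feature tibble (defines the gene universe for the
#'   uncovered-genes attribute).
#' @param n_per_gene Maximum guides per gene (default 3).
#' @return Selected guides with a `rank` column, sorted by (gene, rank);
#'   `attr(, "uncovered_genes")` lists locus tags with no non-template guide.
#' @export
select_guides_per_gene <- function(guides, features, n_per_gene = 3L) {
  if (n_per_gene < 1) stop("n_per_gene must be >= 1", call. = FALSE)
  if (!"gene" %in% names(guides))
    stop("guides must be annotated with assign_to_genes() first", call. = FALSE)
  nt <- dplyr::filter(guides, .data$strand_class == "non_template", !is.na(.data$gene))
  sel <- dplyr::group_by(nt, .data$gene)
  sel <- dplyr::mutate(sel, rank = match(dplyr::row_number(),
                                         rank_guide_order(.data$offset_from_start,
                                                          .data$guide_id)))
  sel <- dplyr::ungroup(dplyr::filter(sel, .data$rank <= n_per_gene))
  sel <- dplyr::arrange(sel, .data$gene, .data$rank)
  attr(sel, "uncovered_genes") <- setdiff(features$locus_tag, sel$gene)
  sel
}

#' Genes with no selected guide under the strict rule
#'
#' @param selected Output of [select_guides_per_gene()].
#' @return Character vector of locus tags.
#' @export
uncovered_genes <- function(selected) attr(selected, "uncovered_genes")
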