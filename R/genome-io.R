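# Genome and annotation input/output. Genomes are plain tibbles (one row per
# contig) so they pipe through dplyr; conversion to Biostrings objects happens
# at the matching boundary. All coordinates in tables are 1-based inclusive;
# only the BED writer emits 0-based half-open intervals.

#' Build a genome table from character sequences
#'
#' @param seqs Named character vector of contig sequences (names become
#'   contig ids; unnamed contigs are called `contig_1`, ...). Sequences are
#'   uppercased and must use only A, C, G, T, N.
#' @param circular Logical, recycled per contig. Circular contigs are scanned
#'   across the origin and coordinates wrap modulo the contig length.
#' @return A tibble with columns `id`, `seq`, `length`, `circular`.
#' @examples
#' genome_table(c(chr = "ACGTACGT"))
#' @export
genome_table <- function(seqs, circular = FALSE) {
  stopifnot(is.character(seqs), length(seqs) > 0)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("contig_", seq_along(seqs))
  ids[ids == ""] <- paste0("contig_", which(ids == ""))
  if (anyDuplicated(ids)) stop("duplicate contig ids", call. = FALSE)
  seqs <- toupper(unname(seqs))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      stop(sprintf("record '%s' has an empty sequence", ids[i]), call. = FALSE)
    off <- stringr::str_locate(seqs[i], "[^ACGTN]")[, "start"]
    if (!is.na(off))
      stop(sprintf("illegal character '%s' in record '%s' at offset %d",
                   substr(seqs[i], off, off), ids[i], off), call. = FALSE)
  }
  tibble::tibble(
    id = ids, seq = seqs, length = nchar(seqs),
    circular = rep_len(as.logical(circular), length(seqs))
  )
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased on read; characters outside A/C/G/T/N are
#' rejected with the record name and offset.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param circular Logical topology flag, recycled across records.
#' @return A genome tibble (see [genome_table()]), records in file order.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  first <- head_lines[nzchar(trimws(head_lines))][1]
  if (is.na(first) || !startsWith(first, ">"))
    stop(sprintf("not FASTA: first non-blank line of %s lacks '>'", path),
         call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))  # id = first token of header
  genome_table(seqs, circular = circular)
}

#' Write a genome table to FASTA
#'
#' @param genome A genome tibble.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(rlang::set_names(genome$seq, genome$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

as_dnastringset <- function(genome) {
  Biostrings::DNAStringSet(rlang::set_names(genome$seq, genome$id))
}

#' Build a gene feature table
#'
#' @param seqid,start,end,strand,locus_tag,product Per-feature vectors;
#'   coordinates are 1-based inclusive, strand is `"+"` or `"-"`.
#' @param genome Optional genome tibble used to validate coordinates.
#' @param feature_types Character label(s) recorded as the feature-type
#'   filter in downstream reports.
#' @return A tibble with columns `seqid`, `start`, `end`, `strand`,
#'   `locus_tag`, `product`.
#' @export
gene_table <- function(seqid, start, end, strand, locus_tag, product = NA_character_,
                       genome = NULL, feature_types = "gene") {
  feats <- tibble::tibble(
    seqid = as.character(seqid), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    locus_tag = as.character(locus_tag),
    product = rep_len(as.character(product), length(seqid))
  )
  validate_features(feats, genome)
  attr(feats, "feature_types") <- feature_types
  feats
}

validate_features <- function(feats, genome = NULL) {
  if (!all(feats$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'", call. = FALSE)
  if (any(is.na(feats$locus_tag) | feats$locus_tag == ""))
    stop("empty locus_tag", call. = FALSE)
  dup <- unique(feats$locus_tag[duplicated(feats$locus_tag)])
  if (length(dup) > 0)
    stop(sprintf("duplicate locus_tag(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  if (any(feats$start < 1L) || any(feats$start > feats$end))
    stop("feature coordinates must satisfy 1 <= start <= end", call. = FALSE)
  if (!is.null(genome)) {
    unknown <- setdiff(feats$seqid, genome$id)
    if (length(unknown) > 0)
      stop(sprintf("unknown seqid(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    len <- rlang::set_names(genome$length, genome$id)
    over <- feats$end > len[feats$seqid]
    if (any(over))
      stop(sprintf("feature(s) beyond contig end: %s",
                   paste(feats$locus_tag[over], collapse = ", ")), call. = FALSE)
  }
  invisible(feats)
}

#' Read gene features from a GFF3 file
#'
#' Features are filtered to the requested types; when a gene and a child CDS
#' describe the same locus (same locus tag) the gene row wins. The locus tag
#' is taken from the `locus_tag` attribute, falling back to `ID`, then
#' `Name`.
#'
#' @param path Path to a GFF3 file.
#' @param genome Genome tibble the annotation refers to (used to validate
#'   seqids and coordinates); optional but recommended.
#' @param feature_types Feature types to keep, in order of preference when
#'   several describe one locus. Default `c("gene", "CDS")`.
#' @return A gene feature tibble (see [gene_table()]), sorted by
#'   (seqid, start), with the feature-type filter recorded in
#'   `attr(, "feature_types")`.
#' @export
read_gene_gff3 <- function(path, genome = NULL, feature_types = c("gene", "CDS")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type %in% feature_types, , drop = FALSE]
  if (nrow(df) == 0)
    stop(sprintf("no features of type(s) %s in %s",
                 paste(feature_types, collapse = "/"), path), call. = FALSE)
  pick <- function(col) if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, nrow(df))
  tag <- dplyr::coalesce(pick("locus_tag"), pick("ID"), pick("Name"))
  if (any(is.na(tag)))
    stop("feature without locus_tag/ID/Name attribute", call. = FALSE)
  feats <- tibble::tibble(
    seqid = as.character(df$seqnames), start = as.integer(df$start),
    end = as.integer(df$end), strand = as.character(df$strand),
    locus_tag = tag, product = pick("product"),
    type = as.character(df$type)
  )
  # gene wins over CDS (and generally: earlier feature_types win)
  feats$type <- factor(feats$type, levels = feature_types)
  feats <- dplyr::slice_min(dplyr::group_by(feats, .data$locus_tag),
                            .data$type, n = 1, with_ties = FALSE)
  feats <- dplyr::arrange(dplyr::ungroup(feats), .data$seqid, .data$start)
  feats$type <- NULL
  validate_features(feats, genome)
  attr(feats, "feature_types") <- feature_types
  feats
}

# Strand-aware circular-safe substring: returns the forward-strand substring
# [start, end] of one contig row, wrapping across the origin when the contig
# is circular. start/end are 1-based; for wrapped intervals start > end.
substring_circular <- function(seq, len, start, end, circular) {
  if (start >= 1 && end <= len && start <= end) return(substr(seq, start, end))
  if (!circular) return(NA_character_)
  norm <- function(p) ((p - 1) %% len) + 1
  s <- norm(start); e <- norm(end)
  if (s <= e) substr(seq, s, e) else paste0(substr(seq, s, len), substr(seq, 1, e))
}
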