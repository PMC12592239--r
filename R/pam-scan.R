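# PAM-site scanning and spacer extraction. A PAM specification is a set of
# equal-length degenerate IUPAC patterns matched 3' of the protospacer (the
# Cas9 geometry). Matching is delegated to Biostrings::matchPattern with a
# degenerate pattern over a fixed subject; windows containing N are discarded
# afterwards because an ambiguous genome position can never be confirmed as a
# target.

#' Define a PAM specification
#'
#' @param patterns Character vector of degenerate IUPAC patterns, all the
#'   same length.
#' @param name Label used in reports.
#' @return An object of class `pam_spec`.
#' @examples
#' pam_spec("NNAGAAW", name = "sth1_consensus")
#' @export
pam_spec <- function(patterns, name = "custom") {
  if (length(patterns) == 0) stop("PAM pattern set must be nonempty", call. = FALSE)
  patterns <- assert_iupac(patterns, "PAM pattern")
  if (length(unique(nchar(patterns))) != 1)
    stop("all PAM patterns must have the same length", call. = FALSE)
  structure(list(name = name, patterns = unique(patterns),
                 length = nchar(patterns[1]), side = "3prime"),
            class = "pam_spec")
}

#' @export
print.pam_spec <- function(x, ...) {
  cat(sprintf("PAM spec '%s' (3' of protospacer): %s\n",
              x$name, paste(x$patterns, collapse = ", ")))
  invisible(x)
}

#' The consensus Sth1 dCas9 PAM (NNAGAAW)
#'
#' The Streptococcus thermophilus CRISPR1 Cas9 consensus PAM. Relaxed PAM
#' variants tolerated by Sth1 dCas9 are strain/reference specific and are
#' supplied as a config file via [read_pam_config()].
#' @return A `pam_spec`.
#' @export
pam_sth1_consensus <- function() pam_spec("NNAGAAW", name = "sth1_consensus")

#' Read a PAM pattern list from a plain-text config file
#'
#' One IUPAC pattern per line; blank lines and `#` comments ignored.
#' @param path Config file path.
#' @param name Label for the resulting spec (default: file base name).
#' @return A `pam_spec`.
#' @export
read_pam_config <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pam_spec(lines, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

# match starts of one degenerate pattern in one subject string (both given
# as characters); N-containing windows dropped.
match_pattern_starts <- function(pattern, subject) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(subject),
                                   fixed = "subject")
  s <- Biostrings::start(hits)
  if (length(s) == 0) return(integer(0))
  win <- substring(subject, s, s + nchar(pattern) - 1L)
  s[!stringr::str_detect(win, "N")]
}

#' Find all PAM sites on both strands
#'
#' Every genomic window whose strand-oriented 5'-to-3' reading matches any
#' pattern of the spec is reported once per (position, strand); a window hit
#' by several patterns is one site listing all of them. Circular contigs are
#' scanned across the origin and wrapped coordinates reported modulo the
#' contig length.
#'
#' @param genome Genome tibble ([genome_table()]).
#' @param spec A [pam_spec()].
#' @return Tibble with columns `seqid`, `strand`, `pam_start`, `pam_end`
#'   (1-based inclusive; `pam_end < pam_start` marks an origin-wrapping site
#'   on a circular contig), `pam_seq` (strand-oriented) and
#'   `matched_pattern` (";"-joined), sorted by (seqid, pam_start, strand).
#' @export
find_pam_sites <- function(genome, spec) {
  stopifnot(inherits(spec, "pam_spec"))
  L <- spec$length
  per_contig <- purrr::pmap(genome, function(id, seq, length, circular, ...) {
    ext <- if (circular && length >= L) paste0(seq, substr(seq, 1L, L - 1L)) else seq
    rows <- purrr::map(spec$patterns, function(p) {
      fwd <- match_pattern_starts(p, ext)
      rev <- match_pattern_starts(reverse_complement(p), ext)
      dplyr::bind_rows(
        tibble::tibble(start = fwd, strand = "+", matched_pattern = p),
        tibble::tibble(start = rev, strand = "-", matched_pattern = p)
      )
    })
    rows <- dplyr::bind_rows(rows)
    rows <- rows[rows$start <= length, , drop = FALSE]  # wrapped dups off
    if (nrow(rows) == 0) return(NULL)
    win <- substring(ext, rows$start, rows$start + L - 1L)
    tibble::tibble(
      seqid = id, strand = rows$strand,
      pam_start = as.integer(rows$start),
      pam_end = as.integer(((rows$start + L - 2L) %% length) + 1L),
      pam_seq = ifelse(rows$strand == "+", win, reverse_complement(win)),
      matched_pattern = rows$matched_pattern
    )
  })
  sites <- dplyr::bind_rows(per_contig)
  if (nrow(sites) == 0) {
    return(tibble::tibble(seqid = character(), strand = character(),
                          pam_start = integer(), pam_end = integer(),
                          pam_seq = character(), matched_pattern = character()))
  }
  sites <- dplyr::summarise(
    dplyr::group_by(sites, .data$seqid, .data$strand, .data$pam_start,
                    .data$pam_end, .data$pam_seq),
    matched_pattern = paste(sort(unique(.data$matched_pattern)), collapse = ";"),
    .groups = "drop"
  )
  dplyr::arrange(sites, .data$seqid, .data$pam_start, .data$strand)
}

#' Enumerate guide candidates (spacer + PAM) genome-wide
#'
#' Composes [find_pam_sites()] with spacer extraction: the spacer is the
#' `spacer_len` bases immediately 5' of the PAM, read 5'-to-3' on the
#' protospacer strand (on "-" sites this is the reverse complement of the
#' genomic window 3' of the PAM in genome coordinates). Sites whose flank
#' runs off a linear contig, or whose spacer contains N, are dropped and
#' counted in the attrition attribute.
#'
#' @param genome Genome tibble.
#' @param spec A [pam_spec()].
#' @param spacer_len Spacer length in bp (default 22, the Sth1 CRISPRi
#'   targeting-region length).
#' @return Guide tibble with columns `guide_id`, `seqid`, `strand`,
#'   `spacer_start`, `spacer_end`, `spacer_seq`, `pam_start`, `pam_end`,
#'   `pam_seq`, `matched_pattern`; `attr(, "attrition")` counts dropped
#'   sites. `guide_id` is `seqid:spacer_start:strand`.
#' @export
enumerate_guides <- function(genome, spec, spacer_len = 22L) {
  if (!is.numeric(spacer_len) || spacer_len < 1)
    stop("spacer_len must be a positive integer", call. = FALSE)
  spacer_len <- as.integer(spacer_len)
  sites <- find_pam_sites(genome, spec)
  glen <- rlang::set_names(genome$length, genome$id)
  gseq <- rlang::set_names(genome$seq, genome$id)
  gcirc <- rlang::set_names(genome$circular, genome$id)

  n_sites <- nrow(sites)
  if (n_sites == 0) {
    g <- tibble::tibble(guide_id = character(), seqid = character(),
                        strand = character(), spacer_start = integer(),
                        spacer_end = integer(), spacer_seq = character(),
                        pam_start = integer(), pam_end = integer(),
                        pam_seq = character(), matched_pattern = character())
    attr(g, "attrition") <- tibble::tibble(
      stage = c("pam_sites", "insufficient_flank", "ambiguous_spacer", "guides"),
      n = c(0L, 0L, 0L, 0L))
    return(g)
  }

  len <- glen[sites$seqid]
  circ <- gcirc[sites$seqid]
  # raw (possibly out-of-range) flank coordinates; "+": 5' flank left of PAM,
  # "-": 5' flank of the protospacer strand is genomic-right of the PAM.
  raw_start <- ifelse(sites$strand == "+", sites$pam_start - spacer_len,
                      sites$pam_start + spec$length)
  raw_end <- raw_start + spacer_len - 1L
  spacer <- purrr::pmap_chr(
    list(sites$seqid, raw_start, raw_end),
    function(id, s, e) {
      out <- substring_circular(gseq[[id]], glen[[id]], s, e, gcirc[[id]])
      if (is.null(out)) NA_character_ else out
    })
  flank_ok <- !is.na(spacer)
  spacer_fwd <- spacer
  spacer[flank_ok & sites$strand == "-"] <-
    reverse_complement(spacer_fwd[flank_ok & sites$strand == "-"])
  amb <- flank_ok & stringr::str_detect(spacer, "N")
  keep <- flank_ok & !amb

  norm <- function(p, l) as.integer(((p - 1L) %% l) + 1L)
  g <- tibble::tibble(
    seqid = sites$seqid[keep], strand = sites$strand[keep],
    spacer_start = norm(raw_start[keep], len[keep]),
    spacer_end = norm(raw_end[keep], len[keep]),
    spacer_seq = spacer[keep],
    pam_start = sites$pam_start[keep], pam_end = sites$pam_end[keep],
    pam_seq = sites$pam_seq[keep], matched_pattern = sites$matched_pattern[keep]
  )
  g <- dplyr::mutate(g, guide_id = paste(.data$seqid, .data$spacer_start,
                                         .data$strand, sep = ":"),
                     .before = 1)
  g <- dplyr::arrange(g, .data$seqid, .data$spacer_start, .data$strand)
  attr(g, "attrition") <- tibble::tibble(
    stage = c("pam_sites", "insufficient_flank", "ambiguous_spacer", "guides"),
    n = c(n_sites, sum(!flank_ok), sum(amb), nrow(g))
  )
  attr(g, "spacer_len") <- spacer_len
  attr(g, "pam_spec") <- spec
  g
}
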