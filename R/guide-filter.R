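# Guide-level filters: restriction-modification motif exclusion, spacer
# uniqueness (multiplicity), and mismatched off-target enumeration.

#' Define a restriction-modification motif set
#'
#' @param motifs Character vector of degenerate IUPAC motifs.
#' @param name Label used in flags and reports.
#' @param source Free-text provenance.
#' @return An object of class `motif_set`; the expanded concrete sequence set
#'   and its reverse-complement closure are precomputed.
#' @export
motif_set <- function(motifs, name = "custom", source = NA_character_) {
  if (length(motifs) == 0) stop("motif set must be nonempty", call. = FALSE)
  motifs <- assert_iupac(motifs, "motif")
  expanded <- sort(unique(unlist(lapply(motifs, iupac_expand))))
  structure(list(name = name, motifs = motifs, source = source,
                 expanded = expanded,
                 rc_closure = sort(unique(c(expanded, reverse_complement(expanded))))),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("Motif set '%s': %s (%d concrete sequences, %d with RC closure)\n",
              x$name, paste(x$motifs, collapse = ", "),
              length(x$expanded), length(x$rc_closure)))
  invisible(x)
}

#' Restriction-modification recognition motifs of B. breve UCC2003
#'
#' The three recognition sequences of the Bifidobacterium breve UCC2003
#' restriction-modification systems used to exclude uncloneable guides:
#' CTGCAG, RTCGAY and GGCGCC. This set is closed under reverse
#' complementation. Other strains' motif sets can be built with
#' [motif_set()] or read from a file with [read_motif_config()].
#' @return A `motif_set`.
#' @export
motif_set_bbreve <- function() {
  motif_set(c("CTGCAG", "RTCGAY", "GGCGCC"), name = "bbreve_ucc2003",
            source = "B. breve UCC2003 restriction-modification recognition sites")
}

#' Read a motif set from a plain-text config file
#'
#' One IUPAC motif per line; blank lines and `#` comments ignored.
#' @param path Config file path.
#' @param name Label (default: file base name).
#' @return A `motif_set`.
#' @export
read_motif_config <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  motif_set(lines, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

# which motif names (";"-joined, NA if none) hit each window, scanning the
# window and its reverse complement so non-palindromic user motifs behave.
motif_hits <- function(windows, motifs) {
  stopifnot(inherits(motifs, "motif_set"))
  if (length(windows) == 0) return(character(0))
  subj <- Biostrings::DNAStringSet(windows)
  subj_rc <- Biostrings::reverseComplement(subj)
  hit <- matrix(FALSE, nrow = length(windows), ncol = length(motifs$motifs))
  for (j in seq_along(motifs$motifs)) {
    m <- Biostrings::DNAString(motifs$motifs[j])
    hit[, j] <- Biostrings::vcountPattern(m, subj, fixed = "subject") > 0 |
      Biostrings::vcountPattern(m, subj_rc, fixed = "subject") > 0
  }
  out <- apply(hit, 1, function(h) {
    if (any(h)) paste(motifs$motifs[h], collapse = ";") else NA_character_
  })
  as.character(out)
}

#' Flag guides containing restriction-modification motifs
#'
#' A guide is flagged when any motif of the set (or its reverse complement)
#' occurs as a substring of the chosen window. Flagged guides are kept in the
#' table so that the kept/rejected split (`is.na(motif_hit)`) conserves the
#' input.
#'
#' @param guides Guide tibble from [enumerate_guides()].
#' @param motifs A [motif_set()]; an empty set is an error, never a silent
#'   no-op.
#' @param window `"spacer_only"` (the sequence that will be cloned into the
#'   guide cassette; default) or `"spacer_plus_pam"` (the genomic
#'   protospacer+PAM locus).
#' @return `guides` with an added `motif_hit` column (";"-joined motif names,
#'   `NA` when the guide is clean).
#' @export
filter_motifs <- function(guides, motifs = motif_set_bbreve(),
                          window = c("spacer_only", "spacer_plus_pam")) {
  window <- match.arg(window)
  win <- switch(window,
                spacer_only = guides$spacer_seq,
                spacer_plus_pam = paste0(guides$spacer_seq, guides$pam_seq))
  dplyr::mutate(guides, motif_hit = motif_hits(win, motifs))
}

#' Count genomic occurrences of every spacer
#'
#' Multiplicity is the number of exact occurrences of the spacer sequence
#' across all contigs, both strands (`mode = "sequence"`), or only
#' occurrences flanked 3' by a permissible PAM (`mode = "pam_adjacent"`). A
#' spacer equal to its own reverse complement at one locus counts once (one
#' physical footprint). Every guide's own site counts, so multiplicity is at
#' least 1.
#'
#' @param guides Guide tibble.
#' @param genome Genome tibble the guides were extracted from.
#' @param mode Counting mode; `"sequence"` (default) is the stricter
#'   redundancy criterion.
#' @param pam [pam_spec()] used for `mode = "pam_adjacent"` (defaults to the
#'   spec recorded on `guides`).
#' @return `guides` with added `multiplicity` and `non_unique` (logical)
#'   columns.
#' @export
spacer_multiplicity <- function(guides, genome,
                                mode = c("sequence", "pam_adjacent"),
                                pam = NULL) {
  mode <- match.arg(mode)
  if (nrow(guides) == 0)
    return(dplyr::mutate(guides, multiplicity = integer(0), non_unique = logical(0)))
  w <- unique(nchar(guides$spacer_seq))
  stopifnot(length(w) == 1)
  spacers <- unique(guides$spacer_seq)
  if (mode == "sequence") {
    subj_seqs <- ifelse(genome$circular,
                        paste0(genome$seq, substr(genome$seq, 1L, w - 1L)),
                        genome$seq)
    subj <- Biostrings::DNAStringSet(subj_seqs)
    pd <- Biostrings::PDict(spacers)
    cnt <- rowSums(Biostrings::vcountPDict(pd, subj)) +
      rowSums(Biostrings::vcountPDict(pd, Biostrings::reverseComplement(subj)))
    palin <- spacers == reverse_complement(spacers)
    cnt[palin] <- cnt[palin] %/% 2L
  } else {
    pam <- pam %||% attr(guides, "pam_spec")
    if (is.null(pam)) stop("mode 'pam_adjacent' needs a pam_spec", call. = FALSE)
    cnt <- vapply(spacers, count_pam_adjacent, integer(1),
                  genome = genome, pam = pam, USE.NAMES = FALSE)
  }
  mult <- rlang::set_names(as.integer(cnt), spacers)[guides$spacer_seq]
  if (any(mult < 1L))
    stop(sprintf("guide(s) whose own site is not found in the genome: %s",
                 paste(guides$guide_id[mult < 1L], collapse = ", ")),
         call. = FALSE)
  dplyr::mutate(guides, multiplicity = unname(mult),
                non_unique = .data$multiplicity > 1L)
}

# occurrences of one spacer that are flanked 3' by a permissible PAM,
# counting each physical footprint once.
count_pam_adjacent <- function(spacer, genome, pam) {
  w <- nchar(spacer)
  L <- pam$length
  total <- 0L
  pam_ok <- function(win) {
    !is.na(win) && any(vapply(pam$patterns, function(p)
      iupac_window_match(win, p), logical(1)))
  }
  for (i in seq_len(nrow(genome))) {
    seq <- genome$seq[i]; len <- genome$length[i]; circ <- genome$circular[i]
    ext <- if (circ) paste0(seq, substr(seq, 1L, w - 1L)) else seq
    occ <- tibble::tibble(start = integer(0), strand = character(0))
    fs <- Biostrings::start(Biostrings::matchPattern(spacer, Biostrings::DNAString(ext)))
    rs <- Biostrings::start(Biostrings::matchPattern(reverse_complement(spacer),
                                                     Biostrings::DNAString(ext)))
    fs <- fs[fs <= len]; rs <- rs[rs <= len]
    if (spacer == reverse_complement(spacer)) rs <- integer(0)  # same footprint
    for (s in fs) {  # protospacer on "+": PAM window right of the spacer
      win <- substring_circular(seq, len, s + w, s + w + L - 1L, circ)
      if (pam_ok(win)) total <- total + 1L
    }
    for (s in rs) {  # protospacer on "-": PAM window genomic-left, revcomp
      win <- substring_circular(seq, len, s - L, s - 1L, circ)
      if (!is.na(win)) win <- reverse_complement(win)
      if (pam_ok(win)) total <- total + 1L
    }
  }
  total
}

#' Enumerate mismatched off-target sites for guides
#'
#' Finds all genomic windows on both strands within a Hamming distance of
#' `max_mismatches` of each guide's spacer (no insertions or deletions).
#' Mismatch positions are reported PAM-proximally: position 1 is the spacer
#' base adjacent to the PAM, where mismatches are least tolerated. The
#' guide's own site appears with 0 mismatches.
#'
#' @param guides Guide tibble (or any tibble with `guide_id` and
#'   `spacer_seq`).
#' @param genome Genome tibble.
#' @param max_mismatches Maximum Hamming distance searched (0 to spacer
#'   length).
#' @param require_pam If `TRUE`, keep only windows flanked 3' by a
#'   permissible PAM.
#' @param pam [pam_spec()] used to test PAM adjacency (defaults to the spec
#'   recorded on `guides`).
#' @return Tibble with columns `guide_id`, `seqid`, `strand`, `start`, `end`
#'   (protospacer interval, 1-based), `mismatches`, `mismatch_positions`
#'   (list column of PAM-proximal offsets) and `pam_adjacent`.
#' @export
find_offtargets <- function(guides, genome, max_mismatches = 2L,
                            require_pam = FALSE, pam = NULL) {
  if (max_mismatches < 0) stop("max_mismatches must be >= 0", call. = FALSE)
  pam <- pam %||% attr(guides, "pam_spec") %||% pam_sth1_consensus()
  rows <- purrr::map(seq_len(nrow(guides)), function(gi) {
    offtargets_one(guides$guide_id[gi], guides$spacer_seq[gi], genome,
                   as.integer(max_mismatches), pam)
  })
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0) {
    return(tibble::tibble(guide_id = character(), seqid = character(),
                          strand = character(), start = integer(),
                          end = integer(), mismatches = integer(),
                          mismatch_positions = list(), pam_adjacent = logical()))
  }
  if (require_pam) hits <- dplyr::filter(hits, .data$pam_adjacent)
  dplyr::arrange(hits, .data$guide_id, .data$seqid, .data$start, .data$strand)
}

offtargets_one <- function(guide_id, spacer, genome, k, pam) {
  w <- nchar(spacer)
  L <- pam$length
  spl <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
  sp_chars <- spl(spacer)
  palin <- spacer == reverse_complement(spacer)
  out <- list()
  for (i in seq_len(nrow(genome))) {
    seq <- genome$seq[i]; len <- genome$length[i]; circ <- genome$circular[i]
    ext <- if (circ) paste0(seq, substr(seq, 1L, w - 1L)) else seq
    subj <- Biostrings::DNAString(ext)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacer else reverse_complement(spacer)
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                    max.mismatch = k)
      s <- Biostrings::start(m)
      s <- s[s <= len]
      if (length(s) == 0) next
      if (palin && strand == "-") next  # same footprints as "+"
      win <- substring(ext, s, s + w - 1L)
      for (j in seq_along(s)) {
        wc <- spl(win[j])
        # PAM-proximal mismatch offsets: "+": spacer index i_5p -> w - i + 1;
        # "-": window index equals the PAM-proximal offset directly.
        if (strand == "+") {
          mm_idx <- which(wc != sp_chars)
          mm_pos <- sort(w - mm_idx + 1L)
        } else {
          mm_pos <- sort(which(spl(reverse_complement(win[j])) != sp_chars))
          mm_pos <- sort(w - mm_pos + 1L)  # map 5'->3' spacer index to PAM-proximal
        }
        if (length(mm_pos) > k) next  # N-containing windows can exceed k
        st <- as.integer(((s[j] - 1L) %% len) + 1L)
        en <- as.integer(((s[j] + w - 2L) %% len) + 1L)
        pam_win <- if (strand == "+") {
          substring_circular(seq, len, s[j] + w, s[j] + w + L - 1L, circ)
        } else {
          v <- substring_circular(seq, len, s[j] - L, s[j] - 1L, circ)
          if (!is.na(v)) reverse_complement(v) else v
        }
        padj <- !is.na(pam_win) &&
          any(vapply(pam$patterns, function(p) iupac_window_match(pam_win, p),
                     logical(1)))
        out[[length(out) + 1L]] <- tibble::tibble(
          guide_id = guide_id, seqid = genome$id[i], strand = strand,
          start = st, end = en, mismatches = length(mm_pos),
          mismatch_positions = list(as.integer(mm_pos)), pam_adjacent = padj)
      }
    }
  }
  dplyr::bind_rows(out)
}
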