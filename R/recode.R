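# Host-aware construct recoding: translation, codon optimisation (argmax
# usage frequency) and restriction-motif removal by synonymous substitution.

genetic_code_tbl <- function(code = "11") {
  gc <- Biostrings::getGeneticCode(code)
  tibble::tibble(codon = names(gc), amino_acid = unname(gc))
}

new_codon_table <- function(freq_tbl, organism, genetic_code = "11") {
  code <- genetic_code_tbl(genetic_code)
  sense <- code$codon[code$amino_acid != "*"]
  missing <- setdiff(sense, freq_tbl$codon)
  if (length(missing) > 0)
    stop(sprintf("codon usage table is missing %d sense codon(s): %s ...",
                 length(missing), paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  if (any(freq_tbl$freq < 0)) stop("negative codon frequency", call. = FALSE)
  tbl <- dplyr::inner_join(code, dplyr::select(freq_tbl, "codon", "freq"),
                           by = "codon")
  sums <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(tbl, .data$amino_acid != "*"), .data$amino_acid),
    s = sum(.data$freq), .groups = "drop")
  off <- sums$amino_acid[abs(sums$s - 1) > 1e-9]
  if (length(off) > 0)
    stop(sprintf("synonymous frequencies do not sum to 1 for: %s",
                 paste(off, collapse = ", ")), call. = FALSE)
  structure(tbl, class = c("codon_table", class(tbl)),
            organism = organism, genetic_code = genetic_code)
}

#' Read a codon usage table from tabular text
#'
#' Expects a TSV with columns `codon`, `amino_acid`, `freq`, where `freq` is
#' the relative frequency of the codon within its synonymous class (summing
#' to 1 per amino acid). All 61 sense codons must be present; stop-codon rows
#' are optional.
#'
#' @param path TSV path.
#' @param organism Label (default: file base name).
#' @param genetic_code NCBI translation table id (default `"11"`, bacterial).
#' @return A `codon_table` tibble.
#' @export
read_codon_table <- function(path, organism = NULL, genetic_code = "11") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("codon", "freq") %in% names(raw)))
  new_codon_table(raw, organism %||% sub("\\.[^.]*$", "", basename(path)),
                  genetic_code)
}

#' Uniform codon usage table
#'
#' Every synonymous codon of an amino acid gets equal frequency. Under this
#' table [codon_optimize()] returns the lexicographically smallest synonymous
#' coding sequence.
#' @param genetic_code NCBI translation table id.
#' @return A `codon_table`.
#' @export
codon_usage_uniform <- function(genetic_code = "11") {
  tbl <- genetic_code_tbl(genetic_code)
  tbl <- dplyr::mutate(dplyr::group_by(tbl, .data$amino_acid),
                       freq = 1 / dplyr::n())
  new_codon_table(dplyr::ungroup(tbl), "uniform", genetic_code)
}

#' GC-biased codon usage table
#'
#' Synonymous frequencies proportional to `strength^(G+C count of the
#' codon)`, emulating the codon preferences of a GC-rich host such as a
#' bifidobacterium. A synthetic table, not measured usage.
#'
#' @param strength Multiplicative preference per G/C base (default 3).
#' @param genetic_code NCBI translation table id.
#' @return A `codon_table`.
#' @export
codon_usage_gc_biased <- function(strength = 3, genetic_code = "11") {
  tbl <- genetic_code_tbl(genetic_code)
  gcn <- stringr::str_count(tbl$codon, "[GC]")
  tbl$freq <- strength^gcn
  tbl <- dplyr::mutate(dplyr::group_by(tbl, .data$amino_acid),
                       freq = .data$freq / sum(.data$freq))
  new_codon_table(dplyr::ungroup(tbl),
                  sprintf("gc_biased_%g", strength), genetic_code)
}

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Translate a coding sequence
#'
#' @param cds DNA string with length divisible by 3, over A/C/G/T.
#' @param genetic_code NCBI translation table id (default `"11"`).
#' @return Protein string; a terminal stop codon is consumed (not included).
#'   An internal stop is an error naming the codon index.
#' @export
translate_cds <- function(cds, genetic_code = "11") {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0)
    stop("coding sequence length is not a multiple of 3", call. = FALSE)
  if (stringr::str_detect(cds, "[^ACGT]"))
    stop("coding sequence must be over A/C/G/T", call. = FALSE)
  gc <- Biostrings::getGeneticCode(genetic_code)
  aa <- unname(gc[split_codons(cds)])
  stops <- which(aa == "*")
  if (any(stops < length(aa)))
    stop(sprintf("internal stop codon at codon index %d", stops[1]), call. = FALSE)
  paste(aa[aa != "*"], collapse = "")
}

# per-amino-acid codon list ranked by descending frequency, ties lexicographic
ranked_codons <- function(table) {
  stopifnot(inherits(table, "codon_table"))
  tbl <- dplyr::arrange(table, .data$amino_acid, dplyr::desc(.data$freq), .data$codon)
  split(tbl[, c("codon", "freq")], tbl$amino_acid)
}

#' Codon-optimize a protein for a host
#'
#' Deterministic argmax strategy: every residue is encoded by its
#' highest-frequency codon in the usage table (ties broken lexicographically)
#' and a terminal stop codon is appended.
#'
#' @param protein Protein string over the 20 amino acids, optionally ending
#'   in `"*"`.
#' @param table A `codon_table` (default [codon_usage_uniform()]).
#' @param stop_codon Terminal stop codon to append (default `"TAA"`).
#' @return DNA string of length `3 * nchar(protein) + 3`.
#' @export
codon_optimize <- function(protein, table = codon_usage_uniform(),
                           stop_codon = "TAA") {
  protein <- toupper(sub("\\*$", "", protein))
  if (nchar(protein) == 0) stop("empty protein", call. = FALSE)
  ranked <- ranked_codons(table)
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  unknown <- setdiff(aas, names(ranked))
  if (length(unknown) > 0)
    stop(sprintf("unknown residue(s): %s", paste(unique(unknown), collapse = ", ")),
         call. = FALSE)
  best <- vapply(ranked, function(x) x$codon[1], character(1))
  paste0(paste(best[aas], collapse = ""), stop_codon)
}

# all motif occurrences on a sequence, both strands, as forward intervals
find_motif_occurrences <- function(seq, motifs) {
  subj <- Biostrings::DNAString(seq)
  rows <- purrr::map(motifs$motifs, function(m) {
    occ <- purrr::map(c("+", "-"), function(strand) {
      pat <- if (strand == "+") m else reverse_complement(m)
      s <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::DNAString(pat), subj, fixed = "subject"))
      tibble::tibble(start = as.integer(s), end = as.integer(s + nchar(m) - 1L),
                     motif = m, strand = strand)
    })
    dplyr::bind_rows(occ)
  })
  out <- dplyr::bind_rows(rows)
  # palindromic motifs hit both strands at one footprint: one occurrence
  out <- dplyr::distinct(out, .data$start, .data$end, .data$motif, .keep_all = TRUE)
  dplyr::arrange(out, .data$start, .data$motif, .data$strand)
}

#' Remove restriction-modification motifs from a CDS by synonymous recoding
#'
#' Repeatedly locates the leftmost motif occurrence (on either strand) and,
#' among the codons overlapping it, applies the synonymous substitution with
#' the highest usage frequency that eliminates the occurrence without
#' introducing a new one in the surrounding window. Occurrences that no
#' synonymous substitution can break are reported in `residual_motifs`.
#' Translation is preserved exactly; the terminal stop codon may be swapped
#' for a synonymous stop.
#'
#' @param cds Coding sequence (length divisible by 3, may include the
#'   terminal stop codon).
#' @param motifs A [motif_set()].
#' @param table A `codon_table` supplying substitution preferences.
#' @param max_iter Iteration cap (default `10 *` initial occurrence count).
#' @return A `recode_result`: list with `cds`, `substitutions` (tibble:
#'   `codon_index`, `old_codon`, `new_codon`, `motif`), `residual_motifs`
#'   (tibble, empty on success), `success`, `n_iterations`. `tidy()` returns
#'   the substitutions, `glance()` the one-row summary.
#' @export
remove_motifs <- function(cds, motifs = motif_set_bbreve(),
                          table = codon_usage_uniform(), max_iter = NULL) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0)
    stop("coding sequence length is not a multiple of 3", call. = FALSE)
  gc <- Biostrings::getGeneticCode(attr(table, "genetic_code") %||% "11")
  codons <- split_codons(cds)
  aa <- unname(gc[codons])
  if (any(aa[-length(aa)] == "*"))
    stop(sprintf("internal stop codon at codon index %d", which(aa == "*")[1]),
         call. = FALSE)
  # synonymous candidates per amino acid incl. stop (uniform freq for stops
  # absent from the table)
  syn <- split(tibble::tibble(codon = names(gc), freq = NA_real_), unname(gc))
  freq_map <- rlang::set_names(table$freq, table$codon)
  syn <- lapply(syn, function(x) {
    x$freq <- unname(freq_map[x$codon])
    x$freq[is.na(x$freq)] <- 1 / nrow(x)
    x[order(-x$freq, x$codon), ]
  })
  maxlen <- max(nchar(motifs$motifs))

  occ0 <- find_motif_occurrences(cds, motifs)
  max_iter <- max_iter %||% max(10L, 10L * nrow(occ0))
  subs <- list()
  stuck <- tibble::tibble(start = integer(), end = integer(),
                          motif = character(), strand = character())
  iter <- 0L
  repeat {
    occ <- find_motif_occurrences(cds, motifs)
    open <- dplyr::anti_join(occ, stuck, by = c("start", "end", "motif", "strand"))
    if (nrow(open) == 0 || iter >= max_iter) break
    iter <- iter + 1L
    target <- open[1, ]
    idx <- (((target$start - 1L) %/% 3L) + 1L):(((target$end - 1L) %/% 3L) + 1L)
    idx <- idx[idx >= 1 & idx <= length(codons)]
    cands <- dplyr::bind_rows(lapply(idx, function(i) {
      s <- syn[[aa[i]]]
      s <- s[s$codon != codons[i], , drop = FALSE]
      if (nrow(s) == 0) return(NULL)
      tibble::tibble(codon_index = i, new_codon = s$codon, freq = s$freq)
    }))
    applied <- FALSE
    if (nrow(cands) > 0) {
      cands <- cands[order(-cands$freq, cands$new_codon, cands$codon_index), ]
      win_lo <- max(1L, target$start - maxlen + 1L)
      win_hi <- min(nchar(cds), target$end + maxlen - 1L)
      in_win <- function(o) o[o$end >= win_lo & o$start <= win_hi, , drop = FALSE]
      before <- in_win(occ)
      before_keys <- setdiff(
        paste(before$start, before$end, before$motif, before$strand),
        paste(target$start, target$end, target$motif, target$strand))
      for (ci in seq_len(nrow(cands))) {
        i <- cands$codon_index[ci]
        trial <- codons
        trial[i] <- cands$new_codon[ci]
        trial_cds <- paste(trial, collapse = "")
        after <- in_win(find_motif_occurrences(trial_cds, motifs))
        after_keys <- paste(after$start, after$end, after$motif, after$strand)
        target_key <- paste(target$start, target$end, target$motif, target$strand)
        if (!(target_key %in% after_keys) && all(after_keys %in% before_keys)) {
          subs[[length(subs) + 1L]] <- tibble::tibble(
            codon_index = i, old_codon = codons[i],
            new_codon = cands$new_codon[ci], motif = target$motif)
          codons <- trial
          cds <- trial_cds
          applied <- TRUE
          break
        }
      }
    }
    if (!applied) stuck <- dplyr::bind_rows(stuck, target)
  }
  residual <- find_motif_occurrences(cds, motifs)
  structure(list(
    cds = cds,
    substitutions = if (length(subs) > 0) dplyr::bind_rows(subs) else
      tibble::tibble(codon_index = integer(), old_codon = character(),
                     new_codon = character(), motif = character()),
    residual_motifs = residual,
    success = nrow(residual) == 0,
    n_iterations = iter
  ), class = "recode_result")
}

#' @export
print.recode_result <- function(x, ...) {
  cat(sprintf("Recode result: %s\n", if (x$success) "success" else "FAILED"))
  cat(sprintf("  substitutions:   %d\n", nrow(x$substitutions)))
  cat(sprintf("  residual motifs: %d\n", nrow(x$residual_motifs)))
  if (nrow(x$residual_motifs) > 0) {
    r <- x$residual_motifs[1, ]
    cat(sprintf("  first stuck occurrence: %s at %d..%d (%s strand)\n",
                r$motif, r$start, r$end, r$strand))
  }
  invisible(x)
}

#' @rdname remove_motifs
#' @param x A `recode_result`.
#' @param ... Unused.
#' @method tidy recode_result
#' @export
tidy.recode_result <- function(x, ...) x$substitutions

#' @rdname remove_motifs
#' @method glance recode_result
#' @export
glance.recode_result <- function(x, ...) {
  tibble::tibble(success = x$success, n_substitutions = nrow(x$substitutions),
                 n_residual_motifs = nrow(x$residual_motifs),
                 n_iterations = x$n_iterations, cds_length = nchar(x$cds))
}
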