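# IUPAC degenerate nucleotide alphabet: expansion, complementation and
# position-wise matching shared by the PAM scanner, the motif filter and
# the synthetic-genome generator.

IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

assert_iupac <- function(x, what = "pattern") {
  bad <- stringr::str_locate(toupper(x), "[^ACGTRYSWKMBDHVN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    stop(sprintf("non-IUPAC character in %s '%s' at position %d",
                 what, x[i], bad[i]), call. = FALSE)
  }
  invisible(toupper(x))
}

#' Reverse complement of DNA/IUPAC strings
#'
#' Complements every IUPAC code (degenerate codes map to their degenerate
#' complements, e.g. R to Y, W to W) and reverses the string, so that
#' `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param x Character vector of DNA strings over the 15 IUPAC codes
#'   (case-insensitive; returned uppercase).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("CTGCAG")   # palindromic motif
#' reverse_complement("NNAGAAW")  # "WTTCTNN"
#' @export
reverse_complement <- function(x) {
  x <- assert_iupac(x, "sequence")
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Expand a degenerate IUPAC pattern to concrete sequences
#'
#' @param pattern A single IUPAC pattern string (e.g. `"RTCGAY"`).
#' @return Character vector of all concrete A/C/G/T sequences matching the
#'   pattern, sorted; its length is the product of per-position degeneracies.
#' @examples
#' iupac_expand("RTCGAY")  # 4 sequences
#' length(iupac_expand("NNAGAAW"))  # 32
#' @export
iupac_expand <- function(pattern) {
  stopifnot(length(pattern) == 1L)
  pattern <- assert_iupac(pattern)
  sets <- IUPAC_BASES[strsplit(pattern, "", fixed = TRUE)[[1]]]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = ""))
}

# Position-wise degenerate match of concrete windows against one IUPAC
# pattern. Windows must have nchar == nchar(pattern). An N (or any non-ACGT
# character) in the window never matches, whatever the pattern says.
iupac_window_match <- function(windows, pattern) {
  n <- nchar(pattern)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, length(windows))
  for (i in seq_len(n)) {
    wc <- substr(windows, i, i)
    ok <- ok & wc %in% IUPAC_BASES[[pat[i]]]
  }
  ok & nchar(windows) == n
}
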