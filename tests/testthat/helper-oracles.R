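# Independent oracles, deliberately naive: a per-position IUPAC table and
# all-window scans that share no code with the package implementation.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# window matches pattern position-wise; N (or any ambiguity) in the window
# never matches
oracle_match <- function(window, pattern) {
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (length(w) != length(p)) return(FALSE)
  all(vapply(seq_along(p), function(i)
    w[i] %in% c("A", "C", "G", "T") && w[i] %in% ORACLE_IUPAC[[p[i]]],
    logical(1)))
}

# brute-force scan of every window on both strands; returns "start:strand" keys
oracle_scan <- function(seqstr, pattern) {
  L <- nchar(pattern)
  n <- nchar(seqstr)
  keys <- character(0)
  if (n < L) return(keys)
  for (s in 1:(n - L + 1)) {
    win <- substr(seqstr, s, s + L - 1)
    if (oracle_match(win, pattern)) keys <- c(keys, paste0(s, ":+"))
    if (oracle_match(oracle_revcomp(win), pattern)) keys <- c(keys, paste0(s, ":-"))
  }
  sort(keys)
}

# naive Hamming off-target scan; returns tibble(start, strand, mismatches)
oracle_offtargets <- function(spacer, seqstr, k) {
  w <- nchar(spacer)
  n <- nchar(seqstr)
  sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
  rows <- list()
  palindrome <- spacer == oracle_revcomp(spacer)
  for (s in 1:(n - w + 1)) {
    win <- substr(seqstr, s, s + w - 1)
    d_f <- sum(strsplit(win, "", fixed = TRUE)[[1]] != sp)
    if (d_f <= k)
      rows[[length(rows) + 1]] <- data.frame(start = s, strand = "+", mismatches = d_f)
    if (!palindrome) {
      d_r <- sum(strsplit(oracle_revcomp(win), "", fixed = TRUE)[[1]] != sp)
      if (d_r <= k)
        rows[[length(rows) + 1]] <- data.frame(start = s, strand = "-", mismatches = d_r)
    }
  }
  do.call(rbind, rows)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a quick small simulated genome for tests that do not need the full defaults
small_sim <- function(seed = 1, ...) {
  simulate_genome(n_genes = 4, gene_len = 500, intergenic_len = 300,
                  n_planted_guides = 8, n_motif_guides = 2,
                  duplicate_block = TRUE, n_decoys = 1, seed = seed, ...)
}
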