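# Synthetic genomes with planted ground truth. The generator builds a random
# background, removes every accidental PAM site from it, then plants guide
# footprints (spacer + concrete PAM) whose positions, strands, sequences and
# expected filter outcomes are recorded exactly in a truth table. With a
# sanitised background the scanner must recover precisely the planted guides,
# which makes every pipeline stage testable without any reference download.

pattern_regex <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(c) {
    b <- IUPAC_BASES[[c]]
    if (length(b) == 1) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# overlapping match starts of a degenerate pattern in a plain string
regex_starts <- function(seqstr, pattern) {
  m <- gregexpr(paste0("(?=", pattern_regex(pattern), ")"), seqstr, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# all PAM matches (start, strand, pattern-as-read-forward) in a plain string
scan_pam_matches <- function(seqstr, pam) {
  rows <- purrr::map(pam$patterns, function(p) {
    dplyr::bind_rows(
      tibble::tibble(start = regex_starts(seqstr, p), strand = "+", fwd_pattern = p),
      tibble::tibble(start = regex_starts(seqstr, reverse_complement(p)),
                     strand = "-", fwd_pattern = reverse_complement(p))
    )
  })
  dplyr::bind_rows(rows)
}

rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# does a spacer avoid PAM cores (AGAA/TTCT for the Sth1 consensus; computed
# generically from the spec patterns), R-M motifs on both strands, and
# palindromy?
spacer_clean <- function(spacer, pam, motifs) {
  for (p in pam$patterns) {
    if (length(regex_starts(spacer, p)) > 0) return(FALSE)
    if (length(regex_starts(spacer, reverse_complement(p))) > 0) return(FALSE)
    # also refuse the constrained core anywhere (junction safety)
    core <- core_of(p)
    if (grepl(pattern_regex(core), spacer) ||
        grepl(pattern_regex(reverse_complement(core)), spacer)) return(FALSE)
  }
  if (!is.na(motif_hits(spacer, motifs))) return(FALSE)
  if (spacer == reverse_complement(spacer)) return(FALSE)
  TRUE
}

# the maximal run of constrained (non-N) positions of a pattern, and its
# offset within the pattern
core_of <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  keep <- vapply(chars, function(c) length(IUPAC_BASES[[c]]) < 4, logical(1))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  i <- which(r$values)[which.max(r$lengths[r$values])]
  paste(chars[(ends[i] - r$lengths[i] + 1):ends[i]], collapse = "")
}

core_offset <- function(pattern) {
  as.integer(regexpr(core_of(pattern), pattern, fixed = TRUE))
}

# a footprint (spacer + concrete PAM, protospacer orientation) is safe when
# the constrained core of every pattern occurs only at its intended register
# and never on the opposite strand: any other interior core would be a PAM
# site buried inside protected bases that sanitisation could not remove.
footprint_ok <- function(fp, pam, spacer_len) {
  for (p in pam$patterns) {
    co <- core_of(p)
    cs <- regex_starts(fp, co)
    if (length(cs) > 0 && !all(cs == spacer_len + core_offset(p))) return(FALSE)
    if (length(regex_starts(fp, reverse_complement(co))) > 0) return(FALSE)
  }
  TRUE
}

make_clean_spacer <- function(spacer_len, gc, pam, motifs, taken) {
  for (try in 1:500) {
    sp <- paste(rand_bases(spacer_len, gc), collapse = "")
    if (spacer_clean(sp, pam, motifs) &&
        !(sp %in% taken) && !(reverse_complement(sp) %in% taken)) return(sp)
  }
  stop("could not draw a clean spacer; relax constraints", call. = FALSE)
}

make_concrete_pam <- function(pam) {
  pat <- strsplit(pam$patterns[1], "", fixed = TRUE)[[1]]
  paste(vapply(pat, function(c) {
    b <- IUPAC_BASES[[c]]
    if (length(b) == 1) b else sample(b, 1)
  }, character(1)), collapse = "")
}

# draw a concrete PAM whose footprint with this spacer is register-safe
make_safe_pam <- function(spacer, pam) {
  for (try in 1:500) {
    pseq <- make_concrete_pam(pam)
    if (footprint_ok(paste0(spacer, pseq), pam, nchar(spacer))) return(pseq)
  }
  stop("could not draw a register-safe concrete PAM", call. = FALSE)
}

#' Simulate a bacterial genome with planted guide ground truth
#'
#' Generates a linear contig carrying `n_genes` genes of alternating strand,
#' separated by intergenic spacers, on a random background from which every
#' accidental PAM site has been removed. Guide footprints (spacer + concrete
#' PAM) are planted at known positions: clean guides distributed over gene
#' bodies (both strand classes), 5' UTR windows and intergenic space;
#' motif-bearing guides whose spacer contains an R-M recognition site; a
#' duplicated block whose guides are exact two-copy repeats; and two-mismatch
#' decoy sites for off-target validation. Regeneration from the same seed is
#' byte-identical.
#'
#' @param n_genes,gene_len,intergenic_len Gene layout (defaults 10 x 900 bp,
#'   300 bp intergenic).
#' @param gc Background GC fraction (0 < gc < 1).
#' @param n_planted_guides Clean, unique, motif-free guides (expected to be
#'   retained by the pipeline).
#' @param n_motif_guides Guides whose spacer contains the first motif of
#'   `motifs` (expected motif-rejected).
#' @param duplicate_block If `TRUE`, a 400-bp block carrying 2 extra guides
#'   is planted and copied once, so those guides (and their copies) have
#'   multiplicity 2 (expected uniqueness-rejected).
#' @param n_decoys Two-mismatch decoy protospacers (PAM-adjacent) planted for
#'   the first `n_decoys` clean guides; each decoy is itself a clean planted
#'   guide.
#' @param seed Integer seed; the single source of randomness.
#' @param spacer_len Spacer length (default 22).
#' @param pam [pam_spec()] to plant (default Sth1 consensus).
#' @param motifs [motif_set()] used for motif-bearing spacers and spacer
#'   sanitisation (default B. breve UCC2003 set).
#' @return A list with `genome` (genome tibble), `features` (gene tibble) and
#'   `truth` (list: `seed`, `guides` — tibble of every planted guide with
#'   `guide_id`, `category`, `expected` in retained/motif_rejected/
#'   non_unique_rejected —, `duplicated_block`, `decoys`).
#' @export
simulate_genome <- function(n_genes = 10L, gene_len = 900L, intergenic_len = 300L,
                            gc = 0.5, n_planted_guides = 20L, n_motif_guides = 5L,
                            duplicate_block = TRUE, n_decoys = 3L, seed = 1L,
                            spacer_len = 22L, pam = pam_sth1_consensus(),
                            motifs = motif_set_bbreve()) {
  stopifnot(n_genes >= 1, gene_len >= 200, intergenic_len >= 120,
            gc > 0, gc < 1, n_planted_guides >= 0, n_motif_guides >= 0,
            n_decoys >= 0, spacer_len >= 10)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    simulate_genome_impl(n_genes, gene_len, intergenic_len, gc,
                         n_planted_guides, n_motif_guides, duplicate_block,
                         n_decoys, as.integer(seed), spacer_len, pam, motifs)
  })
}

simulate_genome_impl <- function(n_genes, gene_len, intergenic_len, gc,
                                 n_planted_guides, n_motif_guides,
                                 duplicate_block, n_decoys, seed,
                                 spacer_len, pam, motifs) {
  n_genes <- as.integer(n_genes)
  n_planted_guides <- as.integer(n_planted_guides)
  n_motif_guides <- as.integer(n_motif_guides)
  n_decoys <- as.integer(n_decoys)
  spacer_len <- as.integer(spacer_len)
  I <- as.integer(intergenic_len); G <- as.integer(gene_len); L <- pam$length
  fp_len <- spacer_len + L
  gene_start <- (seq_len(n_genes) - 1L) * (I + G) + I + 1L
  gene_end <- gene_start + G - 1L
  gene_strand <- rep(c("+", "-"), length.out = n_genes)
  E <- n_genes * (I + G)

  n_genic <- 0L  # filled below by category cycle
  cats <- if (n_planted_guides > 0)
    rep(c("genic_nontemplate", "genic_template", "utr", "intergenic"),
        length.out = n_planted_guides) else character(0)
  n_intergenic <- sum(cats == "intergenic")
  tail_start <- E + 150L
  block_len <- 400L
  block_start <- tail_start + 50L
  after_block <- block_start + block_len + 50L
  intergenic_pos <- after_block + (seq_len(max(n_intergenic, 0L)) - 1L) * 70L
  decoy_region <- after_block + n_intergenic * 70L
  decoy_pos <- decoy_region + (seq_len(max(n_decoys, 0L)) - 1L) * 70L
  copy_start <- decoy_region + n_decoys * 70L + 50L
  total_len <- copy_start + block_len + 100L

  # gene-interior slots: footprints at gene_start + 50 + k*70
  slots_per_gene <- (G - 100L - fp_len) %/% 70L + 1L
  slot_counter <- integer(n_genes)
  utr_used <- logical(n_genes)

  chars <- rand_bases(total_len, gc)

  protected <- logical(total_len)
  truth_rows <- list()
  taken_spacers <- character(0)

  genome_str <- function() paste(chars, collapse = "")

  plant <- function(fp_start, strand, spacer, pam_seq, category, expected) {
    fp <- fp_start:(fp_start + fp_len - 1L)
    if (fp_start < 1L || max(fp) > total_len || any(protected[fp]))
      stop("requested plantings exceed genome capacity", call. = FALSE)
    oriented <- if (strand == "+") paste0(spacer, pam_seq) else
      reverse_complement(paste0(spacer, pam_seq))
    chars[fp] <<- strsplit(oriented, "", fixed = TRUE)[[1]]
    protected[fp] <<- TRUE
    sp_start <- if (strand == "+") fp_start else fp_start + L
    truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
      guide_id = paste("chr_sim", sp_start, strand, sep = ":"),
      category = category, strand = strand,
      spacer_start = as.integer(sp_start),
      spacer_end = as.integer(sp_start + spacer_len - 1L),
      pam_start = as.integer(if (strand == "+") fp_start + spacer_len else fp_start),
      spacer_seq = spacer, pam_seq = pam_seq, expected = expected)
    taken_spacers <<- c(taken_spacers, spacer)
    invisible(sp_start)
  }

  genic_plant <- function(category, spacer) {
    # next free slot over genes, round-robin
    for (shift in 0:(n_genes - 1L)) {
      g <- ((sum(slot_counter) + shift) %% n_genes) + 1L
      if (slot_counter[g] < slots_per_gene) {
        slot_counter[g] <<- slot_counter[g] + 1L
        fp <- gene_start[g] + 50L + (slot_counter[g] - 1L) * 70L
        # protospacer strand: opposite of gene for non-template, same for template
        strand <- if (category == "genic_nontemplate") {
          if (gene_strand[g] == "+") "-" else "+"
        } else if (category == "genic_template") {
          gene_strand[g]
        } else "+"
        plant(fp, strand, spacer, make_safe_pam(spacer, pam), category,
              if (category == "motif") "motif_rejected" else "retained")
        return(invisible(NULL))
      }
    }
    stop("requested plantings exceed genome capacity", call. = FALSE)
  }

  utr_plant <- function(spacer) {
    g <- which(!utr_used)[1]
    if (is.na(g)) stop("requested plantings exceed genome capacity", call. = FALSE)
    utr_used[g] <<- TRUE
    if (gene_strand[g] == "+") {
      plant(gene_start[g] - fp_len - 19L, "-", spacer,
            make_safe_pam(spacer, pam), "utr", "retained")
    } else {
      plant(gene_end[g] + 20L, "+", spacer,
            make_safe_pam(spacer, pam), "utr", "retained")
    }
  }

  ig_i <- 0L
  for (cat in cats) {
    sp <- make_clean_spacer(spacer_len, gc, pam, motifs, taken_spacers)
    if (cat %in% c("genic_nontemplate", "genic_template")) {
      genic_plant(cat, sp)
    } else if (cat == "utr") {
      utr_plant(sp)
    } else {
      ig_i <- ig_i + 1L
      plant(intergenic_pos[ig_i], "+", sp, make_safe_pam(spacer = sp, pam),
            "intergenic", "retained")
    }
  }

  # motif-bearing guides: first motif of the set embedded mid-spacer
  motif_str <- iupac_expand(motifs$motifs[1])[1]
  for (m in seq_len(n_motif_guides)) {
    sp <- NULL
    for (try in 1:500) {
      cand <- make_clean_spacer(spacer_len, gc, pam, motifs, taken_spacers)
      pos <- 9L
      substr(cand, pos, pos + nchar(motif_str) - 1L) <- motif_str
      ok_core <- all(vapply(pam$patterns, function(p) {
        co <- core_of(p)
        !grepl(pattern_regex(co), cand) &&
          !grepl(pattern_regex(reverse_complement(co)), cand)
      }, logical(1)))
      if (ok_core && !(cand %in% taken_spacers) &&
          !(reverse_complement(cand) %in% taken_spacers) &&
          cand != reverse_complement(cand)) { sp <- cand; break }
    }
    if (is.null(sp)) stop("could not build motif-bearing spacer", call. = FALSE)
    genic_plant("motif", sp)
  }

  # duplicated block: two extra clean guides inside [block_start, +400), the
  # block is copied verbatim to copy_start after all other edits
  block_truth_idx <- integer(0)
  if (duplicate_block) {
    for (off in c(60L, 230L)) {
      sp <- make_clean_spacer(spacer_len, gc, pam, motifs, taken_spacers)
      plant(block_start + off, "+", sp, make_safe_pam(spacer = sp, pam),
            "duplicated_block", "non_unique_rejected")
      block_truth_idx <- c(block_truth_idx, length(truth_rows))
    }
  }

  # decoys: 2-mismatch variants of the first clean genic guides, planted as
  # their own (retained) guides; mismatch positions are PAM-proximal
  decoy_rows <- list()
  mm_pam_proximal <- c(4L, 11L)
  if (n_decoys > 0) {
    sources <- which(vapply(truth_rows, function(r)
      r$category %in% c("genic_nontemplate", "genic_template"), logical(1)))
    if (length(sources) < n_decoys)
      stop("not enough clean genic guides to derive decoys from", call. = FALSE)
    for (d in seq_len(n_decoys)) {
      src <- truth_rows[[sources[d]]]
      idx5p <- spacer_len - mm_pam_proximal + 1L  # spacer 5'->3' indices
      sp <- NULL
      bases <- c("A", "C", "G", "T")
      for (try in 1:200) {
        cand <- src$spacer_seq
        for (i in idx5p) {
          cur <- substr(cand, i, i)
          substr(cand, i, i) <- sample(setdiff(bases, cur), 1)
        }
        if (spacer_clean(cand, pam, motifs) && !(cand %in% taken_spacers) &&
            !(reverse_complement(cand) %in% taken_spacers)) { sp <- cand; break }
      }
      if (is.null(sp)) stop("could not build decoy spacer", call. = FALSE)
      sp_start <- plant(decoy_pos[d], "+", sp, make_safe_pam(spacer = sp, pam),
                        "decoy", "retained")
      decoy_rows[[d]] <- tibble::tibble(
        source_guide_id = src$guide_id, seqid = "chr_sim",
        strand = "+", start = as.integer(sp_start),
        end = as.integer(sp_start + spacer_len - 1L),
        mismatch_positions = list(sort(mm_pam_proximal)))
    }
  }

  # expected PAM registers: everything else found by a scan is spurious
  expected_pam <- function() {
    tr <- dplyr::bind_rows(truth_rows)
    paste(tr$pam_start, tr$strand)
  }

  sanitize <- function(extra_expected = character(0), frozen = logical(total_len)) {
    for (iter in 1:300) {
      m <- scan_pam_matches(genome_str(), pam)
      if (nrow(m) > 0) {
        keys <- paste(m$start, m$strand)
        m <- m[!(keys %in% c(expected_pam(), extra_expected)), , drop = FALSE]
      }
      if (nrow(m) == 0) return(invisible(NULL))
      hit <- m[1, ]
      pat <- strsplit(hit$fwd_pattern, "", fixed = TRUE)[[1]]
      fixed <- FALSE
      for (k in seq_along(pat)) {
        b <- IUPAC_BASES[[pat[k]]]
        posn <- hit$start + k - 1L
        if (length(b) < 4 && posn <= total_len &&
            !protected[posn] && !frozen[posn]) {
          chars[posn] <<- sample(setdiff(c("A", "C", "G", "T"), b), 1)
          fixed <- TRUE
          break
        }
      }
      if (!fixed)
        stop("spurious PAM site could not be removed from the background",
             call. = FALSE)
    }
    stop("background sanitisation did not converge", call. = FALSE)
  }

  sanitize()

  # copy the block and fix any site created at the copy junctions
  if (duplicate_block) {
    block <- chars[block_start:(block_start + block_len - 1L)]
    chars[copy_start:(copy_start + block_len - 1L)] <- block
    frozen <- logical(total_len)
    frozen[block_start:(block_start + block_len - 1L)] <- TRUE
    frozen[copy_start:(copy_start + block_len - 1L)] <- TRUE
    shift <- copy_start - block_start
    copy_expected <- unlist(lapply(truth_rows[block_truth_idx], function(r)
      paste(r$pam_start + shift, r$strand)))
    sanitize(extra_expected = copy_expected, frozen = frozen)
    # copied guides join the truth table
    for (i in block_truth_idx) {
      r <- truth_rows[[i]]
      r$spacer_start <- r$spacer_start + shift
      r$spacer_end <- r$spacer_end + shift
      r$pam_start <- r$pam_start + shift
      r$guide_id <- paste("chr_sim", r$spacer_start, r$strand, sep = ":")
      truth_rows[[length(truth_rows) + 1L]] <- r
    }
  }

  genome <- genome_table(c(chr_sim = genome_str()))
  features <- gene_table(seqid = "chr_sim", start = gene_start, end = gene_end,
                         strand = gene_strand,
                         locus_tag = sprintf("SYN_%04d", seq_len(n_genes)),
                         genome = genome, feature_types = "gene")
  truth_guides <- dplyr::arrange(dplyr::bind_rows(truth_rows),
                                 .data$spacer_start, .data$strand)
  # multiplicity audit: every planted spacer occurs exactly as often as the
  # truth table says (guards against background collisions)
  gstr <- genome$seq[1]
  for (i in seq_len(nrow(truth_guides))) {
    sp <- truth_guides$spacer_seq[i]
    n_occ <- length(regex_starts(gstr, sp)) +
      length(regex_starts(gstr, reverse_complement(sp)))
    want <- if (truth_guides$expected[i] == "non_unique_rejected") 2L else 1L
    if (n_occ != want)
      stop(sprintf("planted spacer %s occurs %d times (expected %d)",
                   sp, n_occ, want), call. = FALSE)
  }

  list(
    genome = genome,
    features = features,
    truth = list(
      seed = seed,
      guides = truth_guides,
      duplicated_block = if (duplicate_block)
        c(start = block_start, end = block_start + block_len - 1L,
          copy_start = copy_start) else NULL,
      decoys = if (n_decoys > 0) dplyr::bind_rows(decoy_rows) else NULL
    )
  )
}
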