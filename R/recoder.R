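#' Construct a coding sequence
#'
#' @param nucleotides Character string over A/C/G/T, length divisible by 3.
#' @param seq_id Identifier.
#' @param allow_internal_stop Permit internal stop codons (default FALSE).
#' @return An object of class `coding_sequence`.
#' @export
coding_sequence <- function(nucleotides, seq_id = "cds",
                            allow_internal_stop = FALSE) {
  nucleotides <- toupper(nucleotides)
  if (nchar(nucleotides) == 0L || nchar(nucleotides) %% 3L != 0L) {
    stop("coding sequence length must be a positive multiple of 3")
  }
  if (grepl("[^ACGT]", nucleotides)) {
    stop("coding sequence may contain only A, C, G, T")
  }
  cods <- codon_split(nucleotides)
  aa <- Biostrings::GENETIC_CODE[cods]
  if (!allow_internal_stop && any(aa[-length(aa)] == "*")) {
    stop("internal stop codon in coding sequence")
  }
  structure(list(seq_id = seq_id, nucleotides = nucleotides),
            class = "coding_sequence")
}

codon_split <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

codon_gc <- function(cod) {
  vapply(strsplit(cod, ""), function(ch) sum(ch %in% c("G", "C")), 0L)
}

codon_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# synonym sets of the standard genetic code, keyed by codon
.syn_sets <- local({
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  stats::setNames(lapply(names(gc), function(cod) by_aa[[gc[[cod]]]]),
                  names(gc))
})

# per codon: the synonymous codons at maximal Hamming distance (precomputed)
.max_syn <- local({
  out <- list()
  for (cod in names(.syn_sets)) {
    syn <- .syn_sets[[cod]]
    d <- vapply(syn, codon_hamming, 0L, a = cod)
    out[[cod]] <- syn[d == max(d)]
  }
  out
})

# precomputed A/T count per codon
.codon_at <- local({
  cods <- names(Biostrings::GENETIC_CODE)
  stats::setNames(3L - codon_gc(cods), cods)
})

# static per-codon choices among maximal-distance synonyms
.pick_min_at <- local({
  vapply(names(.max_syn), function(cod) {
    cc <- .max_syn[[cod]]
    gcc <- codon_gc(cc)
    g <- vapply(strsplit(cc, ""), function(ch) sum(ch == "G"), 0L)
    cc[order(-gcc, -g, -xtfrm(cc))][1L]
  }, "")
})
.pick_neutral <- local({
  vapply(names(.max_syn), function(cod) {
    cc <- .max_syn[[cod]]
    dat <- abs(.codon_at[cc] - .codon_at[[cod]])
    cc[order(dat, cc)][1L]
  }, "")
})

max_distance_synonyms <- function(cod) .max_syn[[cod]]

at_fraction <- function(x) {
  ch <- strsplit(toupper(x), "")[[1]]
  mean(ch %in% c("A", "T"))
}

#' Synonymously recode an ORF, maximizing nucleotide divergence
#'
#' Replaces every codon by a synonymous codon at maximal Hamming distance
#' from the original (codons with no synonym, Met and Trp, stay). Two
#' modes govern the choice among equally divergent alternatives:
#'
#' * `neutral_AT`: keep the global A/T fraction of the recoded sequence
#'   within `at_tolerance` of the original. The achievable A/T totals of
#'   the per-codon maximal-distance synonym sets are enumerated exactly
#'   (a dynamic programme over partial sums), the achievable total
#'   closest to the original composition is selected, and codon choices
#'   realizing it are backtracked (ties: smallest per-codon A/T shift,
#'   then alphabetical). `at_feasible = FALSE` therefore certifies that
#'   no maximal-divergence recoding meets the tolerance; the closest
#'   achievable composition is returned and never silently violated.
#' * `min_AT`: prefer the G/C-richest maximal-distance synonym (ties to
#'   the G-richer, then alphabetically last codon), emulating a fully
#'   recoded element with markedly reduced A/T content.
#'
#' The translation is preserved exactly in both modes; the algorithm is
#' deterministic.
#'
#' @param cds A [coding_sequence()] (or a plain nucleotide string).
#' @param mode `"neutral_AT"` or `"min_AT"`.
#' @param at_tolerance Maximum allowed |AT(recoded) - AT(original)| in
#'   `neutral_AT` mode (fraction; default 0.01).
#' @return An object of class `recoded_sequence`: list with `original`,
#'   `recoded` (both `coding_sequence`), `nt_identity`, `codons_changed`,
#'   `at_original`, `at_recoded`, `mode`, `at_feasible`.
#' @examples
#' r <- recode_orf(coding_sequence("ATGTTACGT"), mode = "min_AT")
#' r$recoded$nucleotides
#' @export
recode_orf <- function(cds, mode = c("neutral_AT", "min_AT"),
                       at_tolerance = 0.01) {
  mode <- match.arg(mode)
  if (is.character(cds)) cds <- coding_sequence(cds)
  stopifnot(inherits(cds, "coding_sequence"))
  orig <- codon_split(cds$nucleotides)
  at_orig <- at_fraction(cds$nucleotides)

  cand <- .max_syn[orig]
  pick <- if (mode == "min_AT") unname(.pick_min_at[orig])
          else unname(.pick_neutral[orig])

  at_feasible <- TRUE
  if (mode == "neutral_AT") {
    # exact composition search: dynamic programme over achievable A/T
    # totals of the maximal-distance synonym sets, then backtrack the
    # total closest to the original composition
    n_nt <- nchar(cds$nucleotides)
    n_cod <- length(orig)
    target_at <- sum(.codon_at[orig])
    at_opts <- lapply(cand, function(cc) sort(unique(.codon_at[cc])))
    # reach[[i]][s + 1]: can the first i codons sum to A/T count s
    reach <- vector("list", n_cod + 1L)
    reach[[1L]] <- c(TRUE, rep(FALSE, 3L * n_cod))
    for (i in seq_len(n_cod)) {
      prev <- reach[[i]]
      cur <- rep(FALSE, length(prev))
      for (a in at_opts[[i]]) {
        idx <- which(prev) + a
        cur[idx] <- TRUE
      }
      reach[[i + 1L]] <- cur
    }
    totals <- which(reach[[n_cod + 1L]]) - 1L
    total <- totals[order(abs(totals - target_at), totals)][1L]
    if (abs(total - target_at) / n_nt > at_tolerance) {
      at_feasible <- FALSE
      warning("neutral_AT tolerance infeasible under maximal-divergence ",
              "recoding; closest achievable composition returned")
    }
    remaining <- total
    for (i in rev(seq_len(n_cod))) {
      cc <- cand[[i]]
      ats <- .codon_at[cc]
      idx <- remaining - ats + 1L
      ok <- idx >= 1L
      ok[ok] <- reach[[i]][idx[ok]]
      # deterministic tie-break: lowest achievable A/T shift from the
      # original codon, then alphabetical
      sel <- cc[ok]
      sel_at <- ats[ok]
      j <- order(abs(sel_at - .codon_at[[orig[i]]]), sel)[1L]
      pick[i] <- sel[j]
      remaining <- remaining - sel_at[j]
    }
  }

  rec_nt <- paste(pick, collapse = "")
  rec <- coding_sequence(rec_nt, seq_id = paste0(cds$seq_id, "_recoded"),
                         allow_internal_stop = TRUE)
  st <- recode_stats(cds, rec)
  structure(
    c(list(original = cds, recoded = rec), st,
      list(mode = mode, at_feasible = at_feasible)),
    class = "recoded_sequence"
  )
}

#' @export
print.recoded_sequence <- function(x, ...) {
  cat("recoded_sequence (", x$mode, "): ", nchar(x$original$nucleotides) / 3,
      " codons, ", x$codons_changed, " changed, nt identity ",
      sprintf("%.3f", x$nt_identity), ", A/T ",
      sprintf("%.3f -> %.3f", x$at_original, x$at_recoded), "\n", sep = "")
  invisible(x)
}

#' Divergence and composition statistics of a recoding
#'
#' @param original,recoded [coding_sequence()] objects (or strings) of
#'   equal length.
#' @return List: `nt_identity` (positionwise identical fraction),
#'   `codons_changed`, `at_original`, `at_recoded`.
#' @export
recode_stats <- function(original, recoded) {
  a <- if (is.character(original)) original else original$nucleotides
  b <- if (is.character(recoded)) recoded else recoded$nucleotides
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  list(
    nt_identity = mean(ca == cb),
    codons_changed = sum(codon_split(a) != codon_split(b)),
    at_original = at_fraction(a),
    at_recoded = at_fraction(b)
  )
}

#' Translate a coding sequence
#'
#' @param cds A [coding_sequence()] or nucleotide string.
#' @return Amino-acid string (standard genetic code).
#' @export
translate_cds <- function(cds) {
  nt <- if (is.character(cds)) toupper(cds) else cds$nucleotides
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE))
}

#' Count IUPAC motif matches before and after recoding
#'
#' Counts occurrences of each catalog motif (IUPAC degenerate patterns
#' allowed) in the original and recoded sequences, optionally on both
#' strands, and reports the net number of sites disrupted (negative when
#' recoding creates sites).
#'
#' @param original,recoded [coding_sequence()] objects or strings.
#' @param catalog data.frame with columns `motif_name`, `pattern`.
#' @param both_strands Also count matches on the reverse complement.
#' @return data.frame: `motif_name`, `pattern`, `count_original`,
#'   `count_recoded`, `disrupted`.
#' @export
motif_disruption <- function(original, recoded, catalog,
                             both_strands = TRUE) {
  if (is.null(catalog) || !nrow(catalog)) stop("motif catalog is empty")
  stopifnot(all(c("motif_name", "pattern") %in% names(catalog)))
  a <- if (is.character(original)) toupper(original) else original$nucleotides
  b <- if (is.character(recoded)) toupper(recoded) else recoded$nucleotides
  iupac <- paste0("[^", paste(names(Biostrings::IUPAC_CODE_MAP),
                              collapse = ""), "]")
  count_both <- function(pat, subj) {
    s <- Biostrings::DNAString(subj)
    n <- Biostrings::countPattern(Biostrings::DNAString(pat), s,
                                  fixed = FALSE)
    if (both_strands) {
      n <- n + Biostrings::countPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(pat)), s,
        fixed = FALSE)
    }
    n
  }
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    pat <- toupper(catalog$pattern[i])
    if (grepl(iupac, pat)) stop("invalid IUPAC pattern: ", pat)
    co <- count_both(pat, a)
    cr <- count_both(pat, b)
    data.frame(motif_name = catalog$motif_name[i], pattern = pat,
               count_original = co, count_recoded = cr,
               disrupted = co - cr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
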