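#' Reference full-length L1 element
#'
#' Constructs the coordinate frame (and optionally a synthetic sequence) of a
#' full-length mouse LINE-1 element of the T_F subfamily. All element-internal
#' positions in this package are 1-based coordinates on the SENSE strand of
#' this reference, the convention used when citing antisense-promoter
#' landmarks such as splice donors or transcription start sites, even though
#' the fusion transcripts themselves read antisense.
#'
#' The synthetic sequence carries the landmarks the downstream feature
#' operations look for, at the canonical coordinates:
#' \itemize{
#'   \item the major antisense splice donor \code{GATGgtgag} at sense
#'     coordinate 1838 and the minor donor \code{TCAGgtgtg} at 1892 (the
#'     donor 9-mers read on the antisense transcript strand);
#'   \item exactly eight antisense-strand ATG codons, spanning at least two
#'     reading frames, inside the start of ORF1 (sense window 2124-2244);
#'   \item a candidate antisense TATAA box ending at sense coordinate 2698.
#' }
#' Outside these islands the sequence is random (seeded), so it is a
#' synthetic stand-in for a real element: positions are faithful, sequence
#' context is not.
#'
#' @param length Total element length in nt (default 7000, the approximate
#'   full length of a mouse L1).
#' @param seed Integer seed for the random sequence fill.
#' @param with_sequence If `FALSE`, return a coordinate-only reference
#'   (`sense_sequence = NULL`); sequence-dependent operations then error.
#' @return An object of class `l1_reference`: a list with `name`, `length`,
#'   `sense_sequence` (character or `NULL`), `landmarks` (data.frame of
#'   region start/end in sense coordinates), and `donors` (data.frame of
#'   known antisense splice donors: `motif`, `l1_coord`).
#' @examples
#' ref <- l1_reference(seed = 1)
#' substr(ref$sense_sequence, 1833, 1841)  # reverse complement of GATGgtgag
#' @export
l1_reference <- function(length = 7000L, seed = 1L, with_sequence = TRUE) {
  length <- as.integer(length)
  if (length < 3600L) stop("reference length must be at least 3600 nt")
  landmarks <- data.frame(
    region = c("utr5", "orf1", "orf2", "utr3"),
    start  = c(1L, 2124L, 3310L, length - 200L + 1L),
    end    = c(2123L, 3245L, length - 200L, length),
    stringsAsFactors = FALSE
  )
  donors <- data.frame(
    motif    = c("GATGgtgag", "TCAGgtgtg"),
    l1_coord = c(1838L, 1892L),
    stringsAsFactors = FALSE
  )
  seq <- NULL
  if (with_sequence) {
    seq <- withr::with_seed(as.integer(seed), {
      s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      # antisense splice donors: sense strand carries the reverse complement
      # of the 9-mer, ending at the cited junction coordinate + 3
      for (i in seq_len(nrow(donors))) {
        d <- donors$l1_coord[i]
        rc <- .revcomp_chr(toupper(donors$motif[i]))
        s[(d - 5L):(d + 3L)] <- strsplit(rc, "")[[1]]
      }
      # antisense TATAA whose first transcribed base sits at sense 2698
      s[2694L:2698L] <- strsplit(.revcomp_chr("TATAA"), "")[[1]]
      # exactly eight antisense ATGs (sense "CAT" trigrams) in sense window
      # 2124-2244, in at least two antisense frames; first scrub the window
      # of accidental CATs, then plant
      win <- 2124L:2244L
      for (p in win[-c(length(win) - 1L, length(win))]) {
        if (s[p] == "C" && s[p + 1L] == "A" && s[p + 2L] == "T") {
          s[p + 1L] <- "G"
        }
      }
      atg_at <- c(2130L, 2141L, 2151L, 2160L, 2175L, 2190L, 2205L, 2220L)
      for (p in atg_at) s[p:(p + 2L)] <- c("C", "A", "T")
      paste(s, collapse = "")
    })
  }
  structure(
    list(name = "L1ref_synthetic", length = length, sense_sequence = seq,
         landmarks = landmarks, donors = donors),
    class = "l1_reference"
  )
}

#' @export
print.l1_reference <- function(x, ...) {
  cat("L1 reference '", x$name, "': ", x$length, " nt, sequence ",
      if (is.null(x$sense_sequence)) "absent" else "present", "\n", sep = "")
  cat("landmarks (sense coords):\n")
  print(x$landmarks, row.names = FALSE)
  invisible(x)
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Convert genomic positions to L1 element sense coordinates
#'
#' Maps 1-based genomic positions falling inside an L1 integrant to 1-based
#' positions on the element's sense strand: for a plus-strand integrant the
#' element coordinate increases with the genomic coordinate
#' (`pos - start + 1`), for a minus-strand integrant it decreases
#' (`end - pos + 1`).
#'
#' @param pos Integer vector of 1-based genomic positions.
#' @param l1_start,l1_end 1-based inclusive genomic interval of the integrant.
#' @param l1_strand `"+"` or `"-"`: genomic strand of the element's sense
#'   (coding) strand.
#' @return Integer vector of 1-based element sense coordinates.
#' @seealso [l1_to_genomic()] for the inverse.
#' @export
genomic_to_l1 <- function(pos, l1_start, l1_end, l1_strand) {
  stopifnot(l1_strand %in% c("+", "-"))
  if (any(pos < l1_start | pos > l1_end)) {
    stop("position outside the L1 integrant interval")
  }
  if (l1_strand == "+") as.integer(pos - l1_start + 1L)
  else as.integer(l1_end - pos + 1L)
}

#' Convert L1 element sense coordinates to genomic positions
#'
#' Inverse of [genomic_to_l1()].
#'
#' @param coord Integer vector of 1-based element sense coordinates.
#' @inheritParams genomic_to_l1
#' @return Integer vector of 1-based genomic positions.
#' @export
l1_to_genomic <- function(coord, l1_start, l1_end, l1_strand) {
  stopifnot(l1_strand %in% c("+", "-"))
  len <- l1_end - l1_start + 1L
  if (any(coord < 1L | coord > len)) {
    stop("element coordinate outside [1, element length]")
  }
  if (l1_strand == "+") as.integer(l1_start + coord - 1L)
  else as.integer(l1_end - coord + 1L)
}
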