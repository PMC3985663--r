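#' Construct an aligned transcript clone
#'
#' A clone is a cDNA or 5' RACE product aligned to the genome as one or
#' more blocks. Blocks are stored in transcript order (5' to 3'); for a
#' plus-strand alignment that is ascending genomic order, for a
#' minus-strand alignment descending. The clone's 5'-most aligned base is
#' derived from the first block and the strand unless given explicitly.
#'
#' @param clone_id Clone identifier.
#' @param tissue,strain Sample labels.
#' @param blocks data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), rows in transcript order, non-overlapping.
#' @param strand Alignment strand of the transcript, `"+"` or `"-"`.
#' @param has_polyA Whether the clone carries a poly(A) tail.
#' @param five_prime_genomic Optional explicit 1-based genomic position of
#'   the 5'-most aligned base.
#' @return An object of class `transcript_clone`.
#' @export
transcript_clone <- function(clone_id, tissue = NA_character_,
                             strain = NA_character_, blocks, strand,
                             has_polyA = FALSE,
                             five_prime_genomic = NULL) {
  stopifnot(is.data.frame(blocks), nrow(blocks) >= 1L,
            all(c("chrom", "start", "end") %in% names(blocks)),
            strand %in% c("+", "-"),
            all(blocks$start <= blocks$end))
  if (nrow(blocks) > 1L) {
    o <- order(blocks$start)
    if (any(blocks$end[o][-nrow(blocks)] >= blocks$start[o][-1L])) {
      stop("clone blocks overlap")
    }
  }
  if (is.null(five_prime_genomic)) {
    five_prime_genomic <- if (strand == "+") blocks$start[1L]
                          else blocks$end[1L]
  }
  b1 <- blocks[1L, ]
  if (five_prime_genomic < b1$start || five_prime_genomic > b1$end) {
    stop("five_prime_genomic must fall in the first (5') block")
  }
  structure(
    list(clone_id = clone_id, tissue = tissue, strain = strain,
         blocks = blocks, strand = strand, has_polyA = isTRUE(has_polyA),
         spliced = nrow(blocks) >= 2L,
         five_prime_genomic = as.integer(five_prime_genomic)),
    class = "transcript_clone"
  )
}

#' @export
print.transcript_clone <- function(x, ...) {
  cat("transcript_clone ", x$clone_id, " (", x$tissue, "/", x$strain,
      "): ", nrow(x$blocks), " block(s), strand ", x$strand,
      if (x$has_polyA) ", polyA" else "", "\n", sep = "")
  invisible(x)
}

# index (into l1 rows) of the integrant overlapping a genomic point, or NA.
# When several overlap, an element antisense to `clone_strand` (i.e. one the
# transcript could have initiated from) is preferred; remaining ties go to
# the smallest l1_id.
overlapping_l1 <- function(chrom, pos, l1, clone_strand = NULL) {
  hit <- which(l1$chrom == chrom & l1$start <= pos & l1$end >= pos)
  if (!length(hit)) return(NA_integer_)
  if (!is.null(clone_strand)) {
    anti <- hit[l1$strand[hit] != clone_strand]
    if (length(anti)) hit <- anti
  }
  hit[order(l1$l1_id[hit])][1L]
}

#' Classify a transcript clone
#'
#' Assigns exactly one label. A clone whose first (5') block overlaps an L1
#' integrant antisense to the clone's reading direction is an antisense
#' (AS) clone; an AS clone with a second block outside that element is a
#' spliced AS fusion transcript; an AS single-block clone extending past
#' the element's 5' end into flanking sequence is an unspliced AS fusion
#' transcript; a sense-oriented clone contained in an element with a
#' poly(A) tail is a prematurely polyadenylated sense transcript; anything
#' else (including clones touching no element) is `OTHER`.
#'
#' @param clone A [transcript_clone()].
#' @param l1 The `l1` data.frame of a `genome_annotation` (columns
#'   `l1_id`, `chrom`, `start`, `end`, `strand`, ...).
#' @return One of `"SPLICED_AS_RIFT"`, `"UNSPLICED_AS_RIFT"`,
#'   `"PREMATURE_SENSE_POLYA"`, `"OTHER"`.
#' @export
classify_clone <- function(clone, l1) {
  stopifnot(inherits(clone, "transcript_clone"))
  b1 <- clone$blocks[1L, ]
  # elements overlapping the 5' block at all
  ov <- which(l1$chrom == b1$chrom & l1$start <= b1$end & l1$end >= b1$start)
  if (!length(ov)) return("OTHER")
  # prefer the element containing the 5' end itself
  at5 <- overlapping_l1(b1$chrom, clone$five_prime_genomic, l1, clone$strand)
  i <- if (!is.na(at5)) at5 else ov[order(l1$l1_id[ov])][1L]
  e <- l1[i, ]

  antisense <- clone$strand != e$strand
  if (antisense) {
    if (clone$spliced) {
      outside <- clone$blocks$start > e$end | clone$blocks$end < e$start
      if (any(outside[-1L])) return("SPLICED_AS_RIFT")
    } else {
      # past the element's 5' end: below start for a plus element, above
      # end for a minus element
      past5 <- if (e$strand == "+") b1$start < e$start else b1$end > e$end
      if (past5) return("UNSPLICED_AS_RIFT")
    }
    return("OTHER")
  }
  contained <- b1$start >= e$start & b1$end <= e$end
  if (!clone$spliced && contained && clone$has_polyA) {
    return("PREMATURE_SENSE_POLYA")
  }
  "OTHER"
}

#' Map clone 5' ends to L1 element sense coordinates
#'
#' Locates the integrant containing each clone's 5'-most aligned base and
#' converts that genomic position to the element's 1-based sense
#' coordinate ([genomic_to_l1()]), then aggregates clone counts per tissue
#' and coordinate. Clones whose 5' end falls in no annotated element are
#' skipped and reported in the `skipped` attribute.
#'
#' @param clones List of [transcript_clone()] objects.
#' @param l1 The `l1` data.frame of a `genome_annotation`.
#' @param ref An [l1_reference()] (used to bound coordinates).
#' @return A data.frame of class `tss_distribution`: `tissue`,
#'   `l1_coord`, `count`; attribute `skipped` holds skipped clone ids.
#' @export
map_tss <- function(clones, l1, ref = l1_reference(with_sequence = FALSE)) {
  rows <- list()
  skipped <- character()
  for (cl in clones) {
    i <- overlapping_l1(cl$blocks$chrom[1L], cl$five_prime_genomic, l1, cl$strand)
    if (is.na(i)) {
      skipped <- c(skipped, cl$clone_id)
      next
    }
    e <- l1[i, ]
    coord <- genomic_to_l1(cl$five_prime_genomic, e$start, e$end, e$strand)
    # a 5' end mapping past the element reference length is still reported;
    # bound check only guards the converter's contract
    rows[[length(rows) + 1L]] <- data.frame(
      tissue = cl$tissue, l1_coord = coord, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    out <- data.frame(tissue = character(), l1_coord = integer(),
                      count = integer(), stringsAsFactors = FALSE)
  } else {
    d <- do.call(rbind, rows)
    agg <- stats::aggregate(list(count = rep(1L, nrow(d))),
                            by = list(tissue = d$tissue,
                                      l1_coord = d$l1_coord), FUN = sum)
    out <- agg[order(agg$tissue, agg$l1_coord), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("tss_distribution", "data.frame")
  out
}

#' Extract the antisense splice donor of a spliced clone
#'
#' At the junction between the clone's element block and the next block,
#' reports the last four transcript nucleotides on the exonic side (upper
#' case) and the first five intronic nucleotides past the junction on the
#' transcript strand (lower case), read from the element reference
#' sequence. The junction position is the element sense coordinate of the
#' last exonic base of the element block. Canonical donors begin their
#' intronic side with `gt`; non-canonical junctions are returned with
#' `valid = FALSE`.
#'
#' @param clone A spliced [transcript_clone()].
#' @param l1 The `l1` data.frame of a `genome_annotation`.
#' @param ref An [l1_reference()] with `sense_sequence`.
#' @return One-row data.frame (`clone_id`, `exonic4`, `intronic5`,
#'   `l1_sense_coord`, `valid`), or `NULL` for unspliced clones or clones
#'   whose 5' block lies in no element.
#' @export
find_splice_donors <- function(clone, l1, ref) {
  stopifnot(inherits(clone, "transcript_clone"))
  if (!clone$spliced) return(NULL)
  if (is.null(ref$sense_sequence)) {
    stop("reference carries no sense_sequence")
  }
  b1 <- clone$blocks[1L, ]
  i <- overlapping_l1(b1$chrom, clone$five_prime_genomic, l1, clone$strand)
  if (is.na(i)) return(NULL)
  e <- l1[i, ]
  # antisense transcript: reads toward decreasing element sense coordinate;
  # the last exonic base of the element block is its transcript-3' end
  if (clone$strand == e$strand) return(NULL)
  last_exonic_genomic <- if (clone$strand == "+") b1$end else b1$start
  d <- genomic_to_l1(last_exonic_genomic, e$start, e$end, e$strand)
  if (d + 3L > ref$length || d - 5L < 1L) {
    stop("junction too close to the element edge for motif extraction")
  }
  s <- ref$sense_sequence
  exonic4 <- .revcomp_chr(substr(s, d, d + 3L))
  intronic5 <- tolower(.revcomp_chr(substr(s, d - 5L, d - 1L)))
  data.frame(clone_id = clone$clone_id,
             exonic4 = toupper(exonic4), intronic5 = intronic5,
             l1_sense_coord = d,
             valid = startsWith(intronic5, "gt"),
             stringsAsFactors = FALSE)
}

#' Scan a reference window for antisense ATG codons
#'
#' Reverse-complements the sense window `[lo, hi]` (so the scan reads in
#' the direction of the antisense transcript) and reports every ATG with
#' its offset in the antisense sequence, its reading frame (0/1/2 relative
#' to the window's antisense 5' end), and the element sense coordinate of
#' the A.
#'
#' @param ref An [l1_reference()] with `sense_sequence`.
#' @param window Integer pair `(lo, hi)` of sense coordinates.
#' @return data.frame: `as_offset` (1-based), `frame`, `l1_sense_coord`.
#' @export
scan_atg <- function(ref, window) {
  if (is.null(ref$sense_sequence)) stop("reference carries no sense_sequence")
  lo <- as.integer(window[1]); hi <- as.integer(window[2])
  if (lo < 1L || hi > ref$length || lo > hi) {
    stop("window outside the reference")
  }
  as_seq <- .revcomp_chr(substr(ref$sense_sequence, lo, hi))
  m <- Biostrings::matchPattern("ATG", Biostrings::DNAString(as_seq))
  off <- BiocGenerics::start(m)
  data.frame(
    as_offset = as.integer(off),
    frame = as.integer((off - 1L) %% 3L),
    l1_sense_coord = as.integer(hi - off + 1L),
    stringsAsFactors = FALSE
  )
}

#' Tabulate splice-donor usage
#'
#' Counts each observed donor 9-mer (exonic 4-mer + intronic 5-mer) over a
#' set of donor calls and reports its percent of all spliced clones,
#' rounded half away from zero to the nearest integer.
#'
#' @param calls data.frame rbind of [find_splice_donors()] rows.
#' @return data.frame: `donor`, `l1_sense_coord`, `count`, `percent`,
#'   sorted by descending count.
#' @export
summarize_donor_usage <- function(calls) {
  if (is.null(calls) || !nrow(calls)) {
    return(data.frame(donor = character(), l1_sense_coord = integer(),
                      count = integer(), percent = integer(),
                      stringsAsFactors = FALSE))
  }
  donor <- paste0(calls$exonic4, calls$intronic5)
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(calls))),
    by = list(donor = donor, l1_sense_coord = calls$l1_sense_coord),
    FUN = sum
  )
  total <- nrow(calls)
  agg$percent <- vapply(agg$count, proportion_summary, 0L,
                        denominator = total)
  agg <- agg[order(-agg$count, agg$donor), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
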