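#' Configuration for the synthetic genome and array generator
#'
#' Bundles every tunable of the synthetic-data module. The defaults describe
#' the study conditions the downstream caller was designed for: a
#' single-chromosome genome of multi-exon genes, a background of normalized
#' log2 exon-probe intensities around 7 at threshold (background mean 6,
#' SD 1, so mean + 1 SD is about 7), planted antisense-L1 fusion transcripts
#' whose 5' ends fall in the element window 2201-2244, and five inbred mouse
#' strains by two tissues.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_l1 Number of L1 integrants (eligible initiators plus decoys).
#' @param n_rifts Number of fusion transcripts (RIFTs) to plant.
#' @param exons_per_gene Exons per gene.
#' @param exon_length Exon length, bp.
#' @param intron_length Intron length, bp. Must exceed the longest
#'   full-length integrant so intronic elements fit.
#' @param gene_spacing Intergenic gap, bp. The default (150 kb) exceeds the
#'   caller's 100-kb probe-join window so that an integrant inside one gene
#'   can never satisfy the distance clause for a run in a neighbouring gene,
#'   keeping the planted truth unambiguous.
#' @param probes_per_exon Probes per exon (the exon-array design density is
#'   not standardized; 4 is typical).
#' @param background_mean,background_sd Mean and SD of background log2
#'   probe intensity.
#' @param signal_shift Log2 units added to probes of exons downstream of a
#'   planted initiating element, in samples where the transcript is present.
#' @param tss_window Integer pair: element sense-coordinate window for
#'   planted transcription start sites (default 2201-2244, the antisense
#'   promoter region inside ORF1).
#' @param l1_length_range Length range, bp, of full-length integrants.
#' @param short_length_range Length range, bp, of truncated decoy elements.
#' @param frac_eligible Fraction of `n_l1` placed as eligible initiators
#'   (full-length, allowed subfamily, antisense, intronic); the remainder
#'   are decoys that each fail at least one caller filter.
#' @param subfamily_mix Named numeric vector of RepeatMasker-style subfamily
#'   weights for eligible elements.
#' @param polymorphic_frac Fraction of eligible elements polymorphic across
#'   strains (always present in the reference strain `strains[1]`).
#' @param strains,tissues Character vectors of strain and tissue labels.
#'   One sample per (strain, tissue) pair.
#' @param p_spliced Probability a planted RIFT is spliced (vs unspliced,
#'   reading through the element 5' UTR into flanking sequence).
#' @param donor_weights Named weights over antisense splice-donor 9-mers
#'   for spliced RIFTs; defaults proportional to observed usage (44:13).
#' @param clone_counts Named integer vector: cDNA/RACE clones to emit per
#'   tissue.
#' @param clone_class_probs Probabilities of clone classes
#'   (spliced antisense, unspliced antisense, premature sense-polyA decoy).
#' @param l1_ref_length Element reference length, nt.
#' @param chrom_length Chromosome length; `NULL` sizes it to fit.
#' @param seed Integer seed; identical configs generate identical data.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 200L,
                             n_l1 = 60L,
                             n_rifts = 20L,
                             exons_per_gene = 6L,
                             exon_length = 200L,
                             intron_length = 12000L,
                             gene_spacing = 150000L,
                             probes_per_exon = 4L,
                             background_mean = 6,
                             background_sd = 1,
                             signal_shift = 6,
                             tss_window = c(2201L, 2244L),
                             l1_length_range = c(6000L, 7000L),
                             short_length_range = c(500L, 3000L),
                             frac_eligible = 0.5,
                             subfamily_mix = c(L1Md_T = 0.5, L1Md_Gf = 0.2,
                                               L1Md_A = 0.2, L1Md_F = 0.1),
                             polymorphic_frac = 0.3,
                             strains = c("B6", "DBA", "129", "AJ", "CAST"),
                             tissues = c("testis", "thymus"),
                             p_spliced = 0.78,
                             donor_weights = c(GATGgtgag = 44, TCAGgtgtg = 13),
                             clone_counts = c(testis = 27L, thymus = 13L),
                             clone_class_probs = c(spliced = 0.70,
                                                   unspliced = 0.15,
                                                   polyA = 0.15),
                             l1_ref_length = 7000L,
                             chrom_length = NULL,
                             seed = 1L) {
  # tolerate named lists (e.g. from YAML round-trips)
  subfamily_mix <- unlist(subfamily_mix)
  donor_weights <- unlist(donor_weights)
  clone_counts <- unlist(clone_counts)
  clone_class_probs <- unlist(clone_class_probs)
  strains <- unlist(strains)
  tissues <- unlist(tissues)
  cfg <- list(
    n_genes = as.integer(n_genes), n_l1 = as.integer(n_l1),
    n_rifts = as.integer(n_rifts),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    gene_spacing = as.integer(gene_spacing),
    probes_per_exon = as.integer(probes_per_exon),
    background_mean = background_mean, background_sd = background_sd,
    signal_shift = signal_shift,
    tss_window = as.integer(tss_window),
    l1_length_range = as.integer(l1_length_range),
    short_length_range = as.integer(short_length_range),
    frac_eligible = frac_eligible,
    subfamily_mix = subfamily_mix,
    polymorphic_frac = polymorphic_frac,
    strains = strains, tissues = tissues,
    p_spliced = p_spliced, donor_weights = donor_weights,
    clone_counts = clone_counts, clone_class_probs = clone_class_probs,
    l1_ref_length = as.integer(l1_ref_length),
    chrom_length = if (is.null(chrom_length)) NULL else as.integer(chrom_length),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_genes < 0L || cfg$n_l1 < 0L) {
    stop("gene and L1 counts must be non-negative")
  }
  if (cfg$exons_per_gene < 1L || cfg$exon_length < 1L ||
      cfg$intron_length < 1L || cfg$probes_per_exon < 1L) {
    stop("gene structure parameters must be positive")
  }
  if (cfg$background_sd < 0) stop("background_sd must be non-negative")
  if (cfg$signal_shift < 0) stop("signal_shift must be non-negative")
  if (length(cfg$tss_window) != 2L || cfg$tss_window[1] > cfg$tss_window[2] ||
      cfg$tss_window[1] < 1L || cfg$tss_window[2] > cfg$l1_ref_length) {
    stop("tss_window must lie within the element reference")
  }
  if (cfg$intron_length <= cfg$l1_length_range[2]) {
    stop("intron_length must exceed the maximum full-length element length")
  }
  if (length(cfg$strains) < 1L || length(cfg$tissues) < 1L) {
    stop("need at least one strain and one tissue")
  }
  invisible(cfg)
}

gene_span_length <- function(cfg) {
  cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
}

#' Generate a synthetic genome annotation
#'
#' Lays out `n_genes` non-overlapping multi-exon genes on one chromosome and
#' places `n_l1` L1 integrants: a configurable fraction are *eligible*
#' initiators (full-length, >5 kb, active subfamily, intronic and antisense
#' to their host gene, at most one per gene), the rest are decoys that each
#' fail at least one caller filter (truncated, sense-oriented, inactive
#' subfamily, or intergenic). A fraction of eligible elements are
#' polymorphic: present in the reference strain but absent from a random
#' subset of the others.
#'
#' @param config A [generator_config()].
#' @return An object of class `genome_annotation`: list with
#'   `genes` (data.frame: gene_id, chrom, start, end, strand),
#'   `exons` (data.frame: gene_id, exon_rank in transcription order, chrom,
#'   start, end), `l1` (data.frame: l1_id, chrom, start, end, strand,
#'   subfamily, full_length, present_in as comma-separated strains), and
#'   `chrom_lengths`. All intervals 1-based inclusive.
#' @export
gen_genome <- function(config) {
  cfg <- validate_generator_config(config)
  withr::with_seed(cfg$seed, .gen_genome_impl(cfg))
}

.gen_genome_impl <- function(cfg) {
  span <- gene_span_length(cfg)
  pitch <- span + cfg$gene_spacing
  chrom <- "chrS1"

  if (cfg$n_genes > 0L) {
    gstart <- cfg$gene_spacing + (seq_len(cfg$n_genes) - 1L) * pitch + 1L
    gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
      chrom = chrom, start = gstart, end = gstart + span - 1L,
      strand = gstrand, stringsAsFactors = FALSE
    )
    ex_off <- (seq_len(cfg$exons_per_gene) - 1L) *
      (cfg$exon_length + cfg$intron_length)
    exons <- data.frame(
      gene_id = rep(genes$gene_id, each = cfg$exons_per_gene),
      genomic_index = rep(seq_len(cfg$exons_per_gene), cfg$n_genes),
      chrom = chrom,
      start = rep(gstart, each = cfg$exons_per_gene) + ex_off,
      end = rep(gstart, each = cfg$exons_per_gene) + ex_off +
        cfg$exon_length - 1L,
      stringsAsFactors = FALSE
    )
    # exon_rank counts from the transcription 5' end
    plus <- rep(genes$strand == "+", each = cfg$exons_per_gene)
    exons$exon_rank <- ifelse(plus, exons$genomic_index,
                              cfg$exons_per_gene + 1L - exons$genomic_index)
    exons <- exons[, c("gene_id", "exon_rank", "chrom", "start", "end")]
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = character(), exon_rank = integer(),
                        chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  }

  n_elig <- min(cfg$n_genes, round(cfg$frac_eligible * cfg$n_l1))
  n_decoy <- cfg$n_l1 - n_elig
  l1 <- list()

  if (n_elig > 0L) {
    host <- sort(sample(seq_len(cfg$n_genes), n_elig))
    len <- sample(seq(cfg$l1_length_range[1], cfg$l1_length_range[2]),
                  n_elig, replace = TRUE)
    subfam <- sample(names(cfg$subfamily_mix), n_elig, replace = TRUE,
                     prob = cfg$subfamily_mix)
    # position chosen so that at least ceil(min_run/probes_per_exon) exons
    # lie downstream of the element in transcription direction; when no
    # interior intron leaves enough downstream exons, the element sits just
    # upstream of the gene (rank_after = 0) and all exons are downstream
    min_down <- min(cfg$exons_per_gene,
                    max(2L, as.integer(ceiling(5 / cfg$probes_per_exon))))
    hi_rank <- cfg$exons_per_gene - min_down
    allowed <- seq(0L, max(0L, hi_rank))
    if (any(allowed >= 2L)) allowed <- allowed[allowed >= 2L]
    rank_after <- allowed[sample.int(length(allowed), n_elig, replace = TRUE)]
    poly <- stats::runif(n_elig) < cfg$polymorphic_frac
    rows <- lapply(seq_len(n_elig), function(i) {
      g <- genes[host[i], ]
      gx <- exons[exons$gene_id == g$gene_id, ]
      if (rank_after[i] == 0L) {
        # just upstream of the gene, in the 5' flank
        gap <- 500L + sample.int(1500L, 1L)
        s <- if (g$strand == "+") max(1L, g$start - gap - len[i] + 1L)
             else g$end + gap
      } else {
        # genomic gap between transcription-order exons rank_after and +1
        r1 <- gx[gx$exon_rank == rank_after[i], ]
        r2 <- gx[gx$exon_rank == rank_after[i] + 1L, ]
        lo <- min(r1$end, r2$end) + 1L
        hi <- max(r1$start, r2$start) - 1L
        slack <- (hi - lo + 1L) - len[i]
        s <- lo + sample.int(slack, 1L)
      }
      present <- cfg$strains
      if (poly[i] && length(cfg$strains) > 1L) {
        others <- cfg$strains[-1]
        keep <- others[stats::runif(length(others)) < 0.4]
        present <- c(cfg$strains[1], keep)
      }
      data.frame(
        l1_id = sprintf("L1elig%03d", i), chrom = chrom,
        start = s, end = s + len[i] - 1L,
        strand = if (g$strand == "+") "-" else "+",
        subfamily = subfam[i], full_length = TRUE,
        present_in = paste(present, collapse = ","),
        host_gene = g$gene_id, stringsAsFactors = FALSE
      )
    })
    l1$eligible <- do.call(rbind, rows)
  }

  if (n_decoy > 0L) {
    types <- rep(c("short", "sense", "badfam", "intergenic"),
                 length.out = n_decoy)
    # intronic decoys go to genes without an eligible element so that
    # elements never nest inside one another
    free_genes <- if (n_elig > 0L) setdiff(seq_len(cfg$n_genes), host)
                  else seq_len(cfg$n_genes)
    rows <- lapply(seq_len(n_decoy), function(i) {
      ty <- types[i]
      if (ty == "intergenic" || cfg$n_genes == 0L ||
          length(free_genes) == 0L) {
        len <- sample(seq(cfg$short_length_range[1],
                          cfg$short_length_range[2]), 1L)
        gap_i <- sample.int(max(1L, cfg$n_genes + 1L), 1L)
        s <- (gap_i - 1L) * pitch + 2000L + sample.int(2000L, 1L)
        return(data.frame(
          l1_id = sprintf("L1decoy%03d", i), chrom = chrom,
          start = s, end = s + len - 1L,
          strand = sample(c("+", "-"), 1L),
          subfamily = "Lx5", full_length = FALSE,
          present_in = paste(cfg$strains, collapse = ","),
          host_gene = NA_character_, stringsAsFactors = FALSE
        ))
      }
      g <- genes[free_genes[sample.int(length(free_genes), 1L)], ]
      gx <- exons[exons$gene_id == g$gene_id, ]
      len <- switch(ty,
        short = sample(seq(cfg$short_length_range[1],
                           cfg$short_length_range[2]), 1L),
        sample(seq(cfg$l1_length_range[1], cfg$l1_length_range[2]), 1L))
      o <- order(gx$start)
      k <- sample.int(nrow(gx) - 1L, 1L)
      lo <- gx$end[o][k] + 1L
      hi <- gx$start[o][k + 1L] - 1L
      slack <- (hi - lo + 1L) - len
      s <- lo + sample.int(max(1L, slack), 1L)
      strand <- switch(ty,
        sense = g$strand,
        if (g$strand == "+") "-" else "+")
      subfam <- if (ty == "badfam") "Lx5" else
        sample(names(cfg$subfamily_mix), 1L, prob = cfg$subfamily_mix)
      data.frame(
        l1_id = sprintf("L1decoy%03d", i), chrom = chrom,
        start = s, end = s + len - 1L, strand = strand,
        subfamily = subfam, full_length = len > 5000L,
        present_in = paste(cfg$strains, collapse = ","),
        host_gene = NA_character_, stringsAsFactors = FALSE
      )
    })
    l1$decoy <- do.call(rbind, rows)
  }

  l1 <- if (length(l1)) do.call(rbind, l1) else
    data.frame(l1_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), subfamily = character(),
               full_length = logical(), present_in = character(),
               host_gene = character(), stringsAsFactors = FALSE)
  rownames(l1) <- NULL
  l1 <- l1[order(l1$start), , drop = FALSE]
  rownames(l1) <- NULL

  chrom_len <- if (!is.null(cfg$chrom_length)) cfg$chrom_length else
    as.integer((max(1L, cfg$n_genes) + 1L) * pitch)

  structure(
    list(genes = genes, exons = exons, l1 = l1,
         chrom_lengths = stats::setNames(chrom_len, chrom)),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,", nrow(x$exons),
      "exons,", nrow(x$l1), "L1 integrants on",
      length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

strain_set <- function(x) strsplit(x, ",", fixed = TRUE)

#' Plant antisense-L1 fusion transcripts (truth set)
#'
#' Selects up to `n_rifts` eligible integrants (full-length, allowed
#' subfamily, antisense and intronic to a host gene) and records for each a
#' ground-truth fusion transcript: a transcription start site drawn from the
#' configured element window, a splice donor (or none, for unspliced
#' read-through transcripts), the host-gene exons downstream of the element
#' in transcription direction (where array signal will appear), a tissue,
#' and the strains carrying the element.
#'
#' @param annotation A `genome_annotation` from [gen_genome()].
#' @param config The same [generator_config()].
#' @return A data.frame of class `planted_rifts`: rift_id, gene_id, l1_id,
#'   tss_l1_coord (1-based element sense coordinate), spliced, donor_motif,
#'   donor_l1_coord, affected_exons (comma list of exon ranks), tissue,
#'   strains (comma list). Zero rows (with a warning) if nothing is eligible.
#' @export
plant_rifts <- function(annotation, config) {
  cfg <- validate_generator_config(config)
  withr::with_seed(cfg$seed + 1L, .plant_rifts_impl(annotation, cfg))
}

.plant_rifts_impl <- function(annotation, cfg) {
  l1 <- annotation$l1
  elig <- l1[!is.na(l1$host_gene), , drop = FALSE]
  empty <- data.frame(
    rift_id = character(), gene_id = character(), l1_id = character(),
    tss_l1_coord = integer(), spliced = logical(),
    donor_motif = character(), donor_l1_coord = integer(),
    affected_exons = character(), tissue = character(),
    strains = character(), stringsAsFactors = FALSE
  )
  if (nrow(elig) == 0L) {
    warning("no eligible antisense full-length L1 integrant; nothing planted")
    return(structure(empty, class = c("planted_rifts", "data.frame")))
  }
  n <- min(cfg$n_rifts, nrow(elig))
  pick <- elig[sort(sample.int(nrow(elig), n)), , drop = FALSE]
  donors <- l1_reference(cfg$l1_ref_length, with_sequence = FALSE)$donors
  dw <- cfg$donor_weights[donors$motif]
  dw[is.na(dw)] <- 0

  rows <- lapply(seq_len(n), function(i) {
    e <- pick[i, ]
    g <- annotation$genes[annotation$genes$gene_id == e$host_gene, ]
    gx <- annotation$exons[annotation$exons$gene_id == e$host_gene, ]
    downstream <- if (g$strand == "+") gx$start > e$end else gx$end < e$start
    aff <- sort(gx$exon_rank[downstream])
    spliced <- stats::runif(1) < cfg$p_spliced
    di <- if (spliced) sample.int(nrow(donors), 1L, prob = dw) else NA_integer_
    data.frame(
      rift_id = sprintf("rift%03d", i),
      gene_id = e$host_gene, l1_id = e$l1_id,
      tss_l1_coord = sample(seq(cfg$tss_window[1], cfg$tss_window[2]), 1L),
      spliced = spliced,
      donor_motif = if (spliced) donors$motif[di] else NA_character_,
      donor_l1_coord = if (spliced) donors$l1_coord[di] else NA_integer_,
      affected_exons = paste(aff, collapse = ","),
      tissue = sample(cfg$tissues, 1L),
      strains = e$present_in,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("planted_rifts", "data.frame"))
}

#' Generate a probe intensity matrix with planted signal
#'
#' Tiles every exon with `probes_per_exon` probes and draws log2 background
#' intensities from Normal(`background_mean`, `background_sd`), one sample
#' per (strain, tissue) pair. For each planted fusion transcript,
#' `signal_shift` log2 units are added to the probes of its affected exons
#' in the samples whose tissue matches and whose strain carries the
#' initiating element.
#'
#' @param annotation A `genome_annotation`.
#' @param planted A `planted_rifts` data.frame (may be zero rows).
#' @param config The same [generator_config()].
#' @return An object of class `probe_matrix`: list with `probes`
#'   (data.frame: probe_id, chrom, start, end, gene_id), `samples`
#'   (data.frame: sample_id, strain, tissue) and `intensities`
#'   (probes x samples numeric matrix, log2 units).
#' @export
gen_probe_matrix <- function(annotation, planted, config) {
  cfg <- validate_generator_config(config)
  withr::with_seed(cfg$seed + 2L, .gen_probe_matrix_impl(annotation, planted, cfg))
}

.gen_probe_matrix_impl <- function(annotation, planted, cfg) {
  ex <- annotation$exons
  ex <- ex[order(ex$chrom, ex$start), , drop = FALSE]
  ppe <- cfg$probes_per_exon
  n_probe <- nrow(ex) * ppe
  # probes evenly spaced within each exon
  off <- as.integer(floor((seq_len(ppe) - 0.5) / ppe * cfg$exon_length))
  pstart <- rep(ex$start, each = ppe) + off
  probes <- data.frame(
    probe_id = sprintf("p%06d", seq_len(max(0L, n_probe))),
    chrom = rep(ex$chrom, each = ppe),
    start = pstart,
    end = pmin(pstart + 24L, rep(ex$end, each = ppe)),
    gene_id = rep(ex$gene_id, each = ppe),
    exon_rank = rep(ex$exon_rank, each = ppe),
    stringsAsFactors = FALSE
  )
  probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
  rownames(probes) <- NULL

  samples <- expand.grid(strain = cfg$strains, tissue = cfg$tissues,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(samples$strain, samples$tissue, sep = "_"),
    strain = samples$strain, tissue = samples$tissue,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(samples$sample_id)) stop("sample labels are not unique")

  m <- matrix(stats::rnorm(n_probe * nrow(samples), cfg$background_mean,
                           cfg$background_sd),
              nrow = n_probe, ncol = nrow(samples),
              dimnames = list(probes$probe_id, samples$sample_id))

  if (!is.null(planted) && nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      r <- planted[i, ]
      aff <- as.integer(strsplit(r$affected_exons, ",")[[1]])
      pr <- which(probes$gene_id == r$gene_id & probes$exon_rank %in% aff)
      strains <- strsplit(r$strains, ",")[[1]]
      sm <- which(samples$tissue == r$tissue & samples$strain %in% strains)
      if (length(pr) && length(sm)) {
        m[pr, sm] <- m[pr, sm] + cfg$signal_shift
      }
    }
  }

  structure(list(probes = probes, samples = samples, intensities = m),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("probe_matrix:", nrow(x$probes), "probes x", nrow(x$samples),
      "samples (log2 intensities)\n")
  invisible(x)
}

#' Generate transcript clone alignments (5' RACE / cDNA clones)
#'
#' Emits aligned clone records emulating 5' RACE products and phage cDNA
#' clones: spliced antisense fusion clones (first block inside the
#' initiating element, antisense to it, spliced at the planted donor to the
#' first downstream host-gene exon), unspliced antisense clones (a single
#' block reading from the TSS antiparallel through the element 5' UTR into
#' flanking sequence), and premature sense-polyA decoy clones fully inside
#' an element. Clone 5' ends are jittered within the configured TSS window.
#'
#' @param annotation A `genome_annotation`.
#' @param planted A `planted_rifts` truth table.
#' @param config The same [generator_config()].
#' @param flank_bp Read-through distance beyond the element 5' end for
#'   unspliced clones, bp.
#' @return A list of `transcript_clone` objects (see [transcript_clone()]).
#' @export
gen_transcript_clones <- function(annotation, planted, config,
                                  flank_bp = 500L) {
  cfg <- validate_generator_config(config)
  withr::with_seed(cfg$seed + 3L,
    .gen_clones_impl(annotation, planted, cfg, as.integer(flank_bp)))
}

.gen_clones_impl <- function(annotation, planted, cfg, flank_bp) {
  counts <- cfg$clone_counts
  if (sum(counts) == 0L) return(list())
  l1 <- annotation$l1
  full <- l1[l1$full_length, , drop = FALSE]
  clones <- list()
  k <- 0L
  probs <- cfg$clone_class_probs / sum(cfg$clone_class_probs)
  for (tissue in names(counts)) {
    n <- as.integer(counts[[tissue]])
    if (n <= 0L) next
    cand <- planted[planted$tissue == tissue, , drop = FALSE]
    cls <- sample(names(probs), n, replace = TRUE, prob = probs)
    if (nrow(cand) == 0L) cls[cls != "polyA"] <- "polyA"
    for (j in seq_len(n)) {
      k <- k + 1L
      id <- sprintf("clone%03d", k)
      if (cls[j] == "polyA" || nrow(full) == 0L) {
        e <- full[sample.int(nrow(full), 1L), ]
        blk_len <- min(1500L, e$end - e$start)
        b <- if (e$strand == "+") c(e$start, e$start + blk_len)
             else c(e$end - blk_len, e$end)
        clones[[k]] <- transcript_clone(
          clone_id = id, tissue = tissue,
          strain = sample(strsplit(e$present_in, ",")[[1]], 1L),
          blocks = data.frame(chrom = e$chrom, start = b[1], end = b[2]),
          strand = e$strand, has_polyA = TRUE
        )
        next
      }
      r <- cand[sample.int(nrow(cand)), , drop = FALSE][1L, ]
      e <- l1[l1$l1_id == r$l1_id, ]
      tss <- sample(seq(cfg$tss_window[1], cfg$tss_window[2]), 1L)
      tstrand <- if (e$strand == "+") "-" else "+"
      if (cls[j] == "spliced" && r$spliced) {
        d <- r$donor_l1_coord
        g1 <- l1_to_genomic(d, e$start, e$end, e$strand)
        g2 <- l1_to_genomic(tss, e$start, e$end, e$strand)
        blk1 <- data.frame(chrom = e$chrom, start = min(g1, g2),
                           end = max(g1, g2))
        aff1 <- as.integer(strsplit(r$affected_exons, ",")[[1]])[1]
        gx <- annotation$exons[annotation$exons$gene_id == r$gene_id &
                                 annotation$exons$exon_rank == aff1, ]
        blk2 <- data.frame(chrom = gx$chrom, start = gx$start, end = gx$end)
        blocks <- rbind(blk1, blk2)
      } else {
        g2 <- l1_to_genomic(tss, e$start, e$end, e$strand)
        if (e$strand == "+") {
          blocks <- data.frame(chrom = e$chrom,
                               start = e$start - flank_bp, end = g2)
        } else {
          blocks <- data.frame(chrom = e$chrom,
                               start = g2, end = e$end + flank_bp)
        }
      }
      clones[[k]] <- transcript_clone(
        clone_id = id, tissue = tissue,
        strain = sample(strsplit(r$strains, ",")[[1]], 1L),
        blocks = blocks, strand = tstrand, has_polyA = FALSE
      )
    }
  }
  clones
}
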