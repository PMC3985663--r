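# Shared fixtures and independent oracles used across the suite.

# Minimal probe matrix built directly (bypasses the generator) from a
# per-gene layout: `genes` is a named list gene_id -> number of probes.
make_probe_matrix <- function(genes, intensities, chrom = "chrT",
                              sample_id = "s1", strain = "B6",
                              tissue = "testis", probe_start = NULL) {
  gene_id <- rep(names(genes), unlist(genes))
  n <- length(gene_id)
  start <- if (is.null(probe_start)) seq_len(n) * 1000L else probe_start
  probes <- data.frame(
    probe_id = sprintf("p%04d", seq_len(n)), chrom = chrom,
    start = start, end = start + 24L, gene_id = gene_id,
    stringsAsFactors = FALSE
  )
  m <- matrix(intensities, nrow = n,
              dimnames = list(probes$probe_id, sample_id))
  structure(list(
    probes = probes,
    samples = data.frame(sample_id = sample_id, strain = strain,
                         tissue = tissue, stringsAsFactors = FALSE),
    intensities = m
  ), class = "probe_matrix")
}

# Independent brute-force oracle for maximal high-probe runs: scans every
# contiguous window within each gene and keeps all-TRUE windows that
# cannot be extended on either side.
brute_force_runs <- function(gene_id, flags, min_run) {
  out <- list()
  for (g in unique(gene_id)) {
    idx <- which(gene_id == g)
    f <- flags[idx]
    n <- length(f)
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (all(f[i:j]) && (j - i + 1L) >= min_run &&
            (i == 1L || !f[i - 1L]) && (j == n || !f[j + 1L])) {
          out[[length(out) + 1L]] <- list(gene_id = g, len = j - i + 1L,
                                          local_start = i)
        }
      }
    }
  }
  out
}

# Independent Venn oracle: per-element membership enumeration.
brute_force_venn <- function(catalogs) {
  labels <- names(catalogs)
  catalogs <- lapply(catalogs, unique)
  universe <- unique(unlist(catalogs, use.names = FALSE))
  sig_of <- vapply(universe, function(el) {
    paste(labels[vapply(catalogs, function(s) el %in% s, TRUE)],
          collapse = "&")
  }, "")
  table(sig_of)
}

# Small annotation with one gene and hand-placed L1s, for caller
# filter-by-filter tests. Gene: chrT plus strand, 6 exons of 200 bp
# every 10 kb starting at 100,001.
make_toy_annotation <- function(l1_rows) {
  starts <- 100001L + (0:5) * 10000L
  exons <- data.frame(
    gene_id = "geneA", exon_rank = 1:6, chrom = "chrT",
    start = starts, end = starts + 199L, stringsAsFactors = FALSE
  )
  genes <- data.frame(gene_id = "geneA", chrom = "chrT",
                      start = min(exons$start), end = max(exons$end),
                      strand = "+", stringsAsFactors = FALSE)
  l1 <- do.call(rbind, l1_rows)
  structure(list(genes = genes, exons = exons, l1 = l1,
                 chrom_lengths = c(chrT = 10000000L)),
            class = "genome_annotation")
}

l1_row <- function(l1_id, start, end, strand = "-", subfamily = "L1Md_T",
                   full_length = TRUE, present_in = "B6,DBA",
                   chrom = "chrT") {
  data.frame(l1_id = l1_id, chrom = chrom, start = start, end = end,
             strand = strand, subfamily = subfamily,
             full_length = full_length, present_in = present_in,
             host_gene = NA_character_, stringsAsFactors = FALSE)
}

# Reference with a hand-authored sense sequence (coordinate frame only as
# large as the sequence provided).
make_ref <- function(sense_sequence, name = "toy") {
  structure(list(
    name = name, length = nchar(sense_sequence),
    sense_sequence = sense_sequence,
    landmarks = data.frame(region = "all", start = 1L,
                           end = nchar(sense_sequence)),
    donors = data.frame(motif = character(), l1_coord = integer())
  ), class = "l1_reference")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

codon_vec <- function(x) {
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

# random ORF without internal stops, as a nucleotide string
random_orf <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
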