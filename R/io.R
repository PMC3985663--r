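#' Read gene models from GFF3 or BED12
#'
#' GFF3 files are read through rtracklayer (1-based coordinates, native);
#' exon features are grouped into genes by their `gene_id` attribute,
#' falling back to `Parent` then `ID`. BED12 files are read through
#' rtracklayer with blocks expanded to exons (0-based half-open on disk,
#' converted to the package's 1-based inclusive convention by the parser).
#'
#' @param path File path ending in `.gff3`/`.gff` or `.bed`.
#' @return A list with `genes` and `exons` data.frames in the
#'   `genome_annotation` layout (exon_rank in transcription order).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    meta <- S4Vectors::mcols(ex)
    gid <- if (!is.null(meta$gene_id)) as.character(meta$gene_id)
      else if (!is.null(meta$Parent)) {
        as.character(S4Vectors::unstrsplit(meta$Parent, ","))
      } else as.character(meta$ID)
    if (anyNA(gid)) stop("GFF3 exon without gene_id/Parent/ID attribute")
    exons <- data.frame(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(ex)),
      start = BiocGenerics::start(ex), end = BiocGenerics::end(ex),
      strand = as.character(BiocGenerics::strand(ex)),
      stringsAsFactors = FALSE
    )
  } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    blocks <- gr$blocks
    if (is.null(blocks)) {
      blocks <- IRanges::IRangesList(lapply(seq_along(gr), function(i) {
        IRanges::IRanges(1L, BiocGenerics::width(gr)[i])
      }))
    }
    rows <- lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      data.frame(
        gene_id = gr$name[i],
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        start = BiocGenerics::start(gr)[i] + BiocGenerics::start(b) - 1L,
        end = BiocGenerics::start(gr)[i] + BiocGenerics::end(b) - 1L,
        strand = as.character(BiocGenerics::strand(gr))[i],
        stringsAsFactors = FALSE
      )
    })
    exons <- do.call(rbind, rows)
  } else {
    stop("unrecognized gene model format (want .gff3/.gff or .bed): ", path)
  }
  exons_to_models(exons)
}

# exons (gene_id, chrom, start, end, strand) -> genes + ranked exons
exons_to_models <- function(exons) {
  if (!nrow(exons)) {
    return(list(
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), stringsAsFactors = FALSE),
      exons = data.frame(gene_id = character(), exon_rank = integer(),
                         chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
    ))
  }
  sp <- split(exons, exons$gene_id)
  genes <- do.call(rbind, lapply(sp, function(d) {
    if (length(unique(d$chrom)) != 1L || length(unique(d$strand)) != 1L) {
      stop("gene ", d$gene_id[1], " spans chromosomes or strands")
    }
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
  ex <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop("gene ", d$gene_id[1], " has overlapping exons")
    }
    rank <- if (d$strand[1] == "+") seq_len(nrow(d))
            else rev(seq_len(nrow(d)))
    data.frame(gene_id = d$gene_id, exon_rank = rank, chrom = d$chrom,
               start = d$start, end = d$end, stringsAsFactors = FALSE)
  }))
  rownames(genes) <- rownames(ex) <- NULL
  list(genes = genes, exons = ex)
}

#' Write gene models as GFF3 or BED12
#'
#' @param annotation A `genome_annotation` (or list with `genes`, `exons`).
#' @param path Output path; format chosen by extension.
#' @export
write_gene_models <- function(annotation, path) {
  genes <- annotation$genes
  exons <- annotation$exons
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = exons$chrom,
      ranges = IRanges::IRanges(exons$start, exons$end),
      strand = genes$strand[match(exons$gene_id, genes$gene_id)],
      type = "exon", gene_id = exons$gene_id,
      ID = paste0(exons$gene_id, ":exon", exons$exon_rank)
    )
    rtracklayer::export(gr, path, format = "gff3")
  } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    grl <- lapply(seq_len(nrow(genes)), function(i) {
      d <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      GenomicRanges::GRanges(
        seqnames = genes$chrom[i],
        ranges = IRanges::IRanges(d$start, d$end),
        strand = genes$strand[i]
      )
    })
    names(grl) <- genes$gene_id
    bed <- rtracklayer::asBED(GenomicRanges::GRangesList(grl))
    rtracklayer::export(bed, path, format = "bed")
  } else {
    stop("unrecognized gene model format: ", path)
  }
  invisible(path)
}

#' Read L1 integrant annotations
#'
#' Accepts the package's BED6+ extension: a tab-separated table with
#' columns chrom, start (0-based), end, name, score, strand, subfamily,
#' full_length, present_in (comma-separated strains), with or without a
#' `#`-prefixed header. `full_length` is derived from the element length
#' (> 5 kb) when the column is absent. Unknown subfamilies are kept with
#' `subfamily_canonical = NA` (the caller then never accepts them).
#'
#' @param path File path.
#' @param subfamily_map Pattern table, see [default_subfamily_map()].
#' @param strains Fallback `present_in` value when the column is absent.
#' @return data.frame in the `genome_annotation$l1` layout, plus a
#'   `subfamily_canonical` column.
#' @export
read_l1_annotations <- function(path, subfamily_map = default_subfamily_map(),
                                strains = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    return(data.frame(l1_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), subfamily = character(),
                      full_length = logical(), present_in = character(),
                      subfamily_canonical = character(),
                      stringsAsFactors = FALSE))
  }
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "l1_id", "score", "strand",
            "subfamily", "full_length", "present_in")
  names(d) <- cols[seq_len(min(ncol(d), length(cols)))]
  if (is.null(d$subfamily)) d$subfamily <- NA_character_
  if (is.null(d$present_in)) {
    d$present_in <- paste(strains, collapse = ",")
  }
  d$start <- d$start + 1L  # BED 0-based half-open -> 1-based inclusive
  if (is.null(d$full_length)) {
    d$full_length <- (d$end - d$start + 1L) > 5000L
  } else {
    d$full_length <- as.logical(d$full_length)
  }
  d$subfamily_canonical <- canonical_subfamily(d$subfamily, subfamily_map)
  d[, c("l1_id", "chrom", "start", "end", "strand", "subfamily",
        "full_length", "present_in", "subfamily_canonical")]
}

#' Write L1 integrant annotations (BED6+ extension)
#'
#' @param l1 The `l1` data.frame of a `genome_annotation`.
#' @param path Output path.
#' @export
write_l1_annotations <- function(l1, path) {
  hdr <- "#chrom\tstart\tend\tname\tscore\tstrand\tsubfamily\tfull_length\tpresent_in"
  d <- data.frame(chrom = l1$chrom, start = l1$start - 1L, end = l1$end,
                  name = l1$l1_id, score = 0L, strand = l1$strand,
                  subfamily = l1$subfamily,
                  full_length = l1$full_length,
                  present_in = l1$present_in, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(d, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read a probe intensity matrix (TSV)
#'
#' One row per probe: probe_id, chrom, start, end, gene_id, exon_rank,
#' then one intensity column per sample named `strain_tissue`.
#'
#' @param matrix A `probe_matrix`.
#' @param path Output path.
#' @export
write_probe_matrix <- function(matrix, path) {
  d <- cbind(matrix$probes,
             as.data.frame(matrix$intensities, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_matrix
#' @param sample_meta Optional data.frame (sample_id, strain, tissue);
#'   reconstructed from `strain_tissue` column names when omitted.
#' @export
read_probe_matrix <- function(path, sample_meta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  fixed <- c("probe_id", "chrom", "start", "end", "gene_id", "exon_rank")
  fixed <- intersect(fixed, names(d))
  sample_ids <- setdiff(names(d), fixed)
  if (is.null(sample_meta)) {
    parts <- regmatches(sample_ids,
                        regexpr("_[^_]+$", sample_ids))
    sample_meta <- data.frame(
      sample_id = sample_ids,
      strain = sub("_[^_]+$", "", sample_ids),
      tissue = sub("^_", "", parts),
      stringsAsFactors = FALSE
    )
  }
  m <- as.matrix(d[, sample_ids, drop = FALSE])
  rownames(m) <- d$probe_id
  structure(list(probes = d[, fixed, drop = FALSE],
                 samples = sample_meta, intensities = m),
            class = "probe_matrix")
}

#' Write and read transcript clones (JSON, with BED12 sidecar)
#'
#' The JSON file is the round-trip format (it keeps tissue, strain and
#' poly(A) status); a BED12 file with the same basename is written
#' alongside for genome-browser interoperability.
#'
#' @param clones List of [transcript_clone()] objects.
#' @param path Output path ending in `.json`.
#' @export
write_clones <- function(clones, path) {
  stopifnot(grepl("\\.json$", path))
  recs <- lapply(clones, function(cl) {
    list(clone_id = cl$clone_id, tissue = cl$tissue, strain = cl$strain,
         strand = cl$strand, has_polyA = cl$has_polyA,
         five_prime_genomic = cl$five_prime_genomic,
         blocks = cl$blocks[, c("chrom", "start", "end")])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  # BED12 sidecar
  bed_path <- sub("\\.json$", ".bed", path)
  if (length(clones)) {
    grl <- GenomicRanges::GRangesList(lapply(clones, function(cl) {
      b <- cl$blocks[order(cl$blocks$start), , drop = FALSE]
      GenomicRanges::GRanges(seqnames = b$chrom,
                             ranges = IRanges::IRanges(b$start, b$end),
                             strand = cl$strand)
    }))
    names(grl) <- vapply(clones, `[[`, "", "clone_id")
    rtracklayer::export(rtracklayer::asBED(grl), bed_path, format = "bed")
  } else {
    file.create(bed_path)
  }
  invisible(path)
}

#' @rdname write_clones
#' @export
read_clones <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    blocks <- do.call(rbind, lapply(r$blocks, function(b) {
      data.frame(chrom = b$chrom, start = as.integer(b$start),
                 end = as.integer(b$end), stringsAsFactors = FALSE)
    }))
    transcript_clone(
      clone_id = r$clone_id, tissue = r$tissue, strain = r$strain,
      blocks = blocks, strand = r$strand, has_polyA = r$has_polyA,
      five_prime_genomic = as.integer(r$five_prime_genomic)
    )
  })
}

#' Write and read a generator configuration (YAML)
#'
#' @param config A [generator_config()].
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  # named numeric vectors must become YAML maps, or their names are lost
  for (f in c("subfamily_mix", "donor_weights", "clone_counts",
              "clone_class_probs")) {
    x[[f]] <- as.list(x[[f]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(generator_config, x)
}
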