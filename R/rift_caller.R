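#' Parameters of the RIFT-calling rule set
#'
#' Houses every numeric filter of the fusion-transcript caller: probes are
#' "high" when their log2 intensity strictly exceeds the per-sample mean
#' plus `sd_multiplier` standard deviations; a gene is a candidate when it
#' carries a maximal run of at least `min_run` consecutive high probes; and
#' the run is scored a RIFT when a candidate initiating L1 integrant lies
#' within `gene_distance_kb` of the gene span and/or within
#' `probe_distance_kb` of the run's probes, is longer than
#' `min_l1_length_bp`, belongs to an allowed (retrotranspositionally
#' active) subfamily, and is antisense to the gene.
#'
#' @param sd_multiplier SD multiplier for the intensity threshold.
#' @param min_run Minimum number of consecutive high probes per gene.
#' @param gene_distance_kb Maximum element-to-gene nearest-edge distance, kb.
#' @param probe_distance_kb Maximum element-to-run-probe nearest-edge
#'   distance, kb.
#' @param min_l1_length_bp Minimum initiating element length, bp (strictly
#'   greater than).
#' @param allowed_subfamilies Canonical subfamily names accepted as
#'   initiators.
#' @param require_antisense Require the element antisense to the gene.
#' @param distance_mode `"or"` (default): the gene clause and/or the probe
#'   clause may qualify a candidate; `"and"`: both must hold.
#' @param subfamily_map Named character vector mapping case-insensitive
#'   regular expressions over RepeatMasker-style names to canonical
#'   subfamily names; overridable.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(sd_multiplier = 1,
                          min_run = 5L,
                          gene_distance_kb = 30,
                          probe_distance_kb = 100,
                          min_l1_length_bp = 5000L,
                          allowed_subfamilies = c("T_F", "A", "G_F", "F"),
                          require_antisense = TRUE,
                          distance_mode = c("or", "and"),
                          subfamily_map = default_subfamily_map()) {
  distance_mode <- match.arg(distance_mode)
  p <- list(sd_multiplier = sd_multiplier, min_run = as.integer(min_run),
            gene_distance_kb = gene_distance_kb,
            probe_distance_kb = probe_distance_kb,
            min_l1_length_bp = as.integer(min_l1_length_bp),
            allowed_subfamilies = allowed_subfamilies,
            require_antisense = isTRUE(require_antisense),
            distance_mode = distance_mode,
            subfamily_map = subfamily_map)
  if (p$min_run < 1L) stop("min_run must be at least 1")
  if (p$gene_distance_kb <= 0 || p$probe_distance_kb <= 0 ||
      p$min_l1_length_bp <= 0) {
    stop("distance and length thresholds must be positive")
  }
  structure(p, class = "caller_params")
}

#' Default mapping from RepeatMasker-style L1 names to canonical subfamilies
#'
#' First matching (case-insensitive) regular expression wins; names with no
#' match have no canonical subfamily and are never accepted as initiators.
#'
#' @return Named character vector: regex pattern -> canonical name.
#' @export
default_subfamily_map <- function() {
  c("^L1Md_T"  = "T_F",
    "^L1Md_Gf" = "G_F",
    "^L1Md_A"  = "A",
    "^L1Md_F"  = "F",
    "^L1_Mus"  = "F",
    "^T_F$"    = "T_F",
    "^G_F$"    = "G_F",
    "^A$"      = "A",
    "^F$"      = "F")
}

#' Canonicalize L1 subfamily names
#'
#' @param x Character vector of subfamily names as annotated (e.g.
#'   RepeatMasker names like `L1Md_T`).
#' @param map Pattern table as in [default_subfamily_map()].
#' @return Character vector of canonical names (`NA` where unmapped).
#' @export
canonical_subfamily <- function(x, map = default_subfamily_map()) {
  out <- rep(NA_character_, length(x))
  for (i in seq_along(map)) {
    hit <- is.na(out) & grepl(names(map)[i], x, ignore.case = TRUE)
    out[hit] <- map[[i]]
  }
  out
}

#' Per-sample high-expression intensity threshold
#'
#' Mean plus `sd_multiplier` sample standard deviations (n-1 denominator)
#' over all probes of one sample. Under the generator defaults
#' (background mean 6, SD 1) this lands near log2 intensity 7.
#'
#' @param matrix A `probe_matrix`.
#' @param sample_id Sample to threshold.
#' @param params A [caller_params()].
#' @return Threshold in log2 units.
#' @export
compute_threshold <- function(matrix, sample_id, params = caller_params()) {
  x <- sample_intensities(matrix, sample_id)
  if (length(x) < 2L) stop("need at least 2 probes to estimate a threshold")
  mean(x) + params$sd_multiplier * stats::sd(x)
}

sample_intensities <- function(matrix, sample_id) {
  stopifnot(inherits(matrix, "probe_matrix"))
  if (!sample_id %in% colnames(matrix$intensities)) {
    stop("unknown sample: ", sample_id)
  }
  matrix$intensities[, sample_id]
}

#' Flag high-expression probes
#'
#' Strict comparison: a probe exactly at the threshold is not high.
#'
#' @inheritParams compute_threshold
#' @param threshold Log2 threshold, typically from [compute_threshold()].
#' @return Logical vector along the probe rows of `matrix`.
#' @export
call_high_probes <- function(matrix, sample_id, threshold) {
  stopifnot(is.finite(threshold) || is.infinite(threshold))
  as.vector(sample_intensities(matrix, sample_id) > threshold)
}

#' Find maximal runs of consecutive high probes per gene
#'
#' Probes are ordered genomically within each gene (the matrix keeps them
#' sorted by chromosome and start); "consecutive" means adjacent in that
#' per-gene probe order, irrespective of exon boundaries. All maximal runs
#' of length at least `params$min_run` are returned; probes without a gene
#' assignment are ignored.
#'
#' @inheritParams compute_threshold
#' @param high_flags Logical vector from [call_high_probes()].
#' @return A data.frame of run calls: `gene_id`, `sample_id`, `run_length`,
#'   and `probe_indices` (list column of row indices into `matrix$probes`,
#'   contiguous in the gene's probe order).
#' @export
find_runs <- function(matrix, sample_id, high_flags,
                      params = caller_params()) {
  stopifnot(inherits(matrix, "probe_matrix"),
            length(high_flags) == nrow(matrix$probes))
  gid <- matrix$probes$gene_id
  keep <- !is.na(gid) & gid != ""
  idx_by_gene <- split(which(keep), gid[keep])
  out <- list()
  for (g in names(idx_by_gene)) {
    idx <- idx_by_gene[[g]]
    r <- rle(high_flags[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= params$min_run)
    for (s in sel) {
      out[[length(out) + 1L]] <- list(
        gene_id = g, sample_id = sample_id,
        run_length = r$lengths[s],
        probe_indices = idx[starts[s]:ends[s]]
      )
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), sample_id = character(),
                      run_length = integer(),
                      probe_indices = I(list()),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    gene_id = vapply(out, `[[`, "", "gene_id"),
    sample_id = vapply(out, `[[`, "", "sample_id"),
    run_length = vapply(out, `[[`, 0L, "run_length"),
    probe_indices = I(lapply(out, `[[`, "probe_indices")),
    stringsAsFactors = FALSE
  )
}

# nearest-edge (gap) distance in bp between closed intervals: number of
# intervening bases, 0 when overlapping or book-ended (IRanges convention)
edge_distance <- function(q_start, q_end, s_start, s_end) {
  pmax(pmax(q_start - s_end, s_start - q_end) - 1L, 0L)
}

#' Match a probe run to its candidate initiating L1 integrant
#'
#' Applies the element-side filters to every annotated integrant: length
#' strictly above `min_l1_length_bp` and annotated full-length; canonical
#' subfamily in the allowed set; antisense to the run's gene (when
#' required); present in the queried strain (when given); and the distance
#' rule - nearest-edge distance to the gene span within
#' `gene_distance_kb`, and/or nearest-edge distance to any run probe within
#' `probe_distance_kb`. Among surviving candidates the one nearest to the
#' run's probes wins, ties broken by lexicographically smaller `l1_id`.
#'
#' @param run One row of the data.frame from [find_runs()].
#' @param matrix The `probe_matrix` the run was called on.
#' @param annotation A `genome_annotation`.
#' @param params A [caller_params()].
#' @param strain Optional strain label: integrants whose `present_in` set
#'   lacks it are not candidates.
#' @return A one-row data.frame (`l1_id`, `dist_l1_gene_bp`,
#'   `dist_l1_probe_bp`), or `NULL` when no integrant qualifies.
#' @export
find_initiating_l1 <- function(run, matrix, annotation,
                               params = caller_params(), strain = NULL) {
  gene <- annotation$genes[annotation$genes$gene_id == run$gene_id, ]
  if (nrow(gene) != 1L) stop("run gene not in annotation: ", run$gene_id)
  probes <- matrix$probes[unlist(run$probe_indices), , drop = FALSE]
  l1 <- annotation$l1
  if (!nrow(l1)) return(NULL)

  ok <- l1$chrom == gene$chrom &
    (l1$end - l1$start + 1L) > params$min_l1_length_bp &
    l1$full_length
  fam <- canonical_subfamily(l1$subfamily, params$subfamily_map)
  ok <- ok & !is.na(fam) & fam %in% params$allowed_subfamilies
  if (params$require_antisense) ok <- ok & l1$strand != gene$strand
  if (!is.null(strain)) {
    ok <- ok & vapply(strain_set(l1$present_in),
                      function(s) strain %in% s, TRUE)
  }
  cand <- l1[ok, , drop = FALSE]
  if (!nrow(cand)) return(NULL)

  d_gene <- edge_distance(cand$start, cand$end, gene$start, gene$end)
  d_probe <- vapply(seq_len(nrow(cand)), function(i) {
    min(edge_distance(probes$start, probes$end, cand$start[i], cand$end[i]))
  }, 0)
  gene_ok <- d_gene <= params$gene_distance_kb * 1000
  probe_ok <- d_probe <= params$probe_distance_kb * 1000
  pass <- if (params$distance_mode == "or") gene_ok | probe_ok
          else gene_ok & probe_ok
  if (!any(pass)) return(NULL)

  cand <- cand[pass, , drop = FALSE]
  d_gene <- d_gene[pass]
  d_probe <- d_probe[pass]
  best <- order(d_probe, cand$l1_id)[1]
  data.frame(l1_id = cand$l1_id[best],
             dist_l1_gene_bp = as.integer(d_gene[best]),
             dist_l1_probe_bp = as.integer(d_probe[best]),
             stringsAsFactors = FALSE)
}

#' Call retrotransposon-initiated fusion transcripts
#'
#' Full composition of the calling rule set, per sample: compute the
#' per-sample threshold, flag high probes, find maximal qualifying runs per
#' gene, and match each run to an initiating antisense L1 integrant.
#' Strain-aware: an integrant absent from a sample's strain is never a
#' candidate for that sample.
#'
#' @param matrix A `probe_matrix`.
#' @param annotation A `genome_annotation` on the same chromosomes.
#' @param params A [caller_params()].
#' @return A data.frame of class `rift_calls`, one row per (gene, sample,
#'   maximal qualifying run) with a matched element: `gene_id`,
#'   `sample_id`, `strain`, `tissue`, `l1_id`, `run_length`,
#'   `probe_indices` (list column), `dist_l1_gene_bp`, `dist_l1_probe_bp`,
#'   `threshold`. The per-stage attrition log (probes high, runs found,
#'   runs matched, per sample) is attached as attribute `attrition`.
#' @export
call_rifts <- function(matrix, annotation, params = caller_params()) {
  stopifnot(inherits(matrix, "probe_matrix"),
            inherits(annotation, "genome_annotation"))
  shared <- intersect(unique(matrix$probes$chrom),
                      unique(c(annotation$genes$chrom, annotation$l1$chrom)))
  if (nrow(matrix$probes) && !length(shared)) {
    stop("probe matrix and annotation share no chromosome")
  }
  calls <- list()
  attrition <- list()
  for (si in seq_len(nrow(matrix$samples))) {
    smp <- matrix$samples[si, ]
    thr <- compute_threshold(matrix, smp$sample_id, params)
    high <- call_high_probes(matrix, smp$sample_id, thr)
    runs <- find_runs(matrix, smp$sample_id, high, params)
    n_matched <- 0L
    if (nrow(runs)) {
      for (ri in seq_len(nrow(runs))) {
        hit <- find_initiating_l1(runs[ri, ], matrix, annotation, params,
                                  strain = smp$strain)
        if (is.null(hit)) next
        n_matched <- n_matched + 1L
        calls[[length(calls) + 1L]] <- data.frame(
          gene_id = runs$gene_id[ri], sample_id = smp$sample_id,
          strain = smp$strain, tissue = smp$tissue,
          l1_id = hit$l1_id, run_length = runs$run_length[ri],
          probe_indices = I(runs$probe_indices[ri]),
          dist_l1_gene_bp = hit$dist_l1_gene_bp,
          dist_l1_probe_bp = hit$dist_l1_probe_bp,
          threshold = thr, stringsAsFactors = FALSE
        )
      }
    }
    attrition[[smp$sample_id]] <- data.frame(
      sample_id = smp$sample_id, threshold = thr,
      n_probes_high = sum(high), n_runs = nrow(runs),
      n_runs_matched = n_matched, stringsAsFactors = FALSE
    )
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gene_id = character(), sample_id = character(),
               strain = character(), tissue = character(),
               l1_id = character(), run_length = integer(),
               probe_indices = I(list()), dist_l1_gene_bp = integer(),
               dist_l1_probe_bp = integer(), threshold = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "attrition") <- do.call(rbind, c(attrition,
                                             make.row.names = FALSE))
  class(out) <- c("rift_calls", "data.frame")
  out
}

#' Compare calls against a planted truth set
#'
#' Expands the truth table to the sample level (a planted fusion transcript
#' is expected in every sample whose tissue matches and whose strain
#' carries the element) and scores the called (gene, element, sample)
#' triples against it.
#'
#' @param calls A `rift_calls` data.frame.
#' @param planted A `planted_rifts` truth table.
#' @param matrix The `probe_matrix` (for the sample sheet).
#' @return List: `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
evaluate_calls <- function(calls, planted, matrix) {
  expected <- character()
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      r <- planted[i, ]
      strains <- strsplit(r$strains, ",")[[1]]
      sm <- matrix$samples[matrix$samples$tissue == r$tissue &
                             matrix$samples$strain %in% strains, ]
      if (nrow(sm)) {
        expected <- c(expected,
                      paste(r$gene_id, r$l1_id, sm$sample_id, sep = "|"))
      }
    }
  }
  got <- if (nrow(calls)) {
    unique(paste(calls$gene_id, calls$l1_id, calls$sample_id, sep = "|"))
  } else character()
  tp <- sum(got %in% expected)
  fp <- length(got) - tp
  fn <- length(setdiff(expected, got))
  list(precision = if (length(got)) tp / length(got) else NA_real_,
       recall = if (length(expected)) tp / length(expected) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
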