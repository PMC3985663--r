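#' Exhaustive Venn region counts over 2-5 catalogs
#'
#' Given named sets of fusion-transcript identity keys (one per tissue or
#' strain), counts the members of every disjoint region of the Venn
#' diagram: all `2^k - 1` non-empty group-membership signatures.
#'
#' @param catalogs Named list of 2-5 character vectors (duplicate elements
#'   within a set are collapsed; duplicate group labels are an error).
#' @return data.frame: one logical membership column per group, plus
#'   `signature` (group labels joined by `&`) and `count`. Rows cover all
#'   non-empty signatures, including regions with count 0.
#' @examples
#' venn_counts(list(t1 = c("a", "b"), t2 = c("b", "c")))
#' @export
venn_counts <- function(catalogs) {
  k <- length(catalogs)
  if (k < 2L || k > 5L) stop("venn_counts takes 2 to 5 catalogs")
  labels <- names(catalogs)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    stop("catalogs must have unique non-empty names")
  }
  catalogs <- lapply(catalogs, unique)
  universe <- unique(unlist(catalogs, use.names = FALSE))
  member <- vapply(catalogs, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  if (length(universe) == 0L) {
    member <- matrix(logical(), nrow = 0L, ncol = k)
  }
  colnames(member) <- labels

  sigs <- expand.grid(rep(list(c(FALSE, TRUE)), k),
                      KEEP.OUT.ATTRS = FALSE)
  names(sigs) <- labels
  sigs <- sigs[rowSums(sigs) > 0L, , drop = FALSE]
  sigs$signature <- apply(sigs[, labels, drop = FALSE], 1L, function(r) {
    paste(labels[as.logical(r)], collapse = "&")
  })
  sigs$count <- apply(sigs[, labels, drop = FALSE], 1L, function(r) {
    if (!nrow(member)) return(0L)
    sum(apply(member, 1L, function(m) all(m == as.logical(r))))
  })
  rownames(sigs) <- NULL
  sigs
}

#' Build fusion-transcript catalogs from calls
#'
#' Collapses a `rift_calls` table into per-group identity sets for Venn
#' comparison. Identity of a fusion transcript across groups defaults to
#' the (gene, element) pair; set `key = "l1_id"` to compare by initiating
#' element alone.
#'
#' @param calls A `rift_calls` data.frame (from [call_rifts()]).
#' @param by Grouping column: `"tissue"` or `"strain"`.
#' @param key `"gene_l1"` (default) or `"l1_id"`.
#' @return Named list of character vectors, one per group level present.
#' @export
rift_catalog <- function(calls, by = c("tissue", "strain"),
                         key = c("gene_l1", "l1_id")) {
  by <- match.arg(by)
  key <- match.arg(key)
  if (!nrow(calls)) return(list())
  id <- if (key == "gene_l1") paste(calls$gene_id, calls$l1_id, sep = ":")
        else calls$l1_id
  lapply(split(id, calls[[by]]), unique)
}

#' Integer percentage of a count pair
#'
#' `round(100 * numerator / denominator)` with halves rounded away from
#' zero (so 44 of 65 is 68, 13 of 65 is 20, 363 of 940 is 39).
#'
#' @param numerator,denominator Non-negative counts,
#'   `numerator <= denominator`, `denominator > 0`.
#' @return Integer percent.
#' @export
proportion_summary <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator < 0 || numerator > denominator) {
    stop("numerator must lie in [0, denominator]")
  }
  as.integer(floor(100 * numerator / denominator + 0.5))
}

#' Contamination-corrected reporter transcript ratio
#'
#' Ratio of reporter to beta-actin transcript concentration after
#' subtracting the no-reverse-transcriptase signal (residual plasmid or
#' genomic DNA amplification); a negative corrected value is clamped to 0.
#'
#' @param tem1_rt_plus Reporter concentration with reverse transcriptase.
#' @param tem1_rt_minus Reporter concentration without (contamination).
#' @param actin Beta-actin concentration (must be positive).
#' @return Normalized ratio (vectorized).
#' @export
normalized_reporter_ratio <- function(tem1_rt_plus, tem1_rt_minus, actin) {
  if (any(actin <= 0)) stop("actin concentration must be positive")
  if (any(tem1_rt_plus < 0 | tem1_rt_minus < 0)) {
    stop("concentrations must be non-negative")
  }
  pmax(tem1_rt_plus - tem1_rt_minus, 0) / actin
}

#' Retrotransposition frequency relative to a control
#'
#' Ratio of colony frequencies (colonies per cell plated) between a test
#' and a control construct.
#'
#' @param test_colonies,test_cells Test construct counts.
#' @param control_colonies,control_cells Control construct counts.
#' @return Fold change (test over control).
#' @export
relative_frequency <- function(test_colonies, test_cells,
                               control_colonies, control_cells) {
  if (any(test_cells <= 0 | control_cells <= 0)) {
    stop("cells plated must be positive")
  }
  if (any(test_colonies < 0)) stop("colony counts must be non-negative")
  if (any(control_colonies <= 0)) {
    stop("control colony count is zero; relative frequency undefined")
  }
  (test_colonies / test_cells) / (control_colonies / control_cells)
}
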