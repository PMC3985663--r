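# one plus-strand and one minus-strand element on a toy chromosome
toy_l1 <- rbind(
  l1_row("L1plus", 10001L, 17000L, strand = "+"),
  l1_row("L1minus", 50001L, 57000L, strand = "-")
)

test_that("element coordinate conversion round-trips on both strands", {
  set.seed(101)
  for (i in 1:200) {
    e <- toy_l1[sample(1:2, 1), ]
    pos <- sample(e$start:e$end, 50)
    coord <- genomic_to_l1(pos, e$start, e$end, e$strand)
    expect_true(all(coord >= 1 & coord <= e$end - e$start + 1))
    expect_identical(l1_to_genomic(coord, e$start, e$end, e$strand), pos)
  }
  # boundary cases (plus element starting at 1001: genomic 1001 -> coord 1)
  expect_identical(genomic_to_l1(1001L, 1001L, 8000L, "+"), 1L)
  # minus element occupying [1001, 8000]: genomic 5800 -> coord 2201
  expect_identical(genomic_to_l1(5800L, 1001L, 8000L, "-"), 2201L)
  expect_error(genomic_to_l1(999L, 1001L, 8000L, "+"), "outside")
  expect_error(l1_to_genomic(0L, 1001L, 8000L, "+"), "outside")
})

test_that("clone classification covers all four labels and is total", {
  # spliced AS over the plus element: transcript on minus strand,
  # element block then a downstream exon block outside the element
  spliced <- transcript_clone(
    "c1", "testis", "B6",
    blocks = data.frame(chrom = "chrT", start = c(11838L, 5000L),
                        end = c(12201L, 5200L)),
    strand = "-")
  expect_identical(classify_clone(spliced, toy_l1), "SPLICED_AS_RIFT")

  # unspliced AS: single minus-strand block crossing the element 5' end
  unspliced <- transcript_clone(
    "c2", "testis", "B6",
    blocks = data.frame(chrom = "chrT", start = 9500L, end = 12201L),
    strand = "-")
  expect_identical(classify_clone(unspliced, toy_l1), "UNSPLICED_AS_RIFT")

  # premature sense polyA: sense strand, contained, polyadenylated
  polya <- transcript_clone(
    "c3", "testis", "B6",
    blocks = data.frame(chrom = "chrT", start = 10001L, end = 11500L),
    strand = "+", has_polyA = TRUE)
  expect_identical(classify_clone(polya, toy_l1), "PREMATURE_SENSE_POLYA")

  # no element overlap -> OTHER, not an error
  stray <- transcript_clone(
    "c4", "testis", "B6",
    blocks = data.frame(chrom = "chrT", start = 30000L, end = 30500L),
    strand = "+")
  expect_identical(classify_clone(stray, toy_l1), "OTHER")

  # sense, contained, but no polyA -> OTHER
  nopolya <- transcript_clone(
    "c5", "testis", "B6",
    blocks = data.frame(chrom = "chrT", start = 10001L, end = 11500L),
    strand = "+")
  expect_identical(classify_clone(nopolya, toy_l1), "OTHER")

  # every clone gets exactly one of the four labels
  for (cl in list(spliced, unspliced, polya, stray, nopolya)) {
    expect_true(classify_clone(cl, toy_l1) %in%
                  c("SPLICED_AS_RIFT", "UNSPLICED_AS_RIFT",
                    "PREMATURE_SENSE_POLYA", "OTHER"))
  }

  # the mirror cases on the minus-strand element
  spliced_m <- transcript_clone(
    "c6", "testis", "B6",
    blocks = data.frame(chrom = "chrT", start = c(54800L, 60000L),
                        end = c(55163L, 60200L)),
    strand = "+")
  expect_identical(classify_clone(spliced_m, toy_l1), "SPLICED_AS_RIFT")
  unspliced_m <- transcript_clone(
    "c7", "testis", "B6",
    blocks = data.frame(chrom = "chrT", start = 54800L, end = 57500L),
    strand = "+")
  expect_identical(classify_clone(unspliced_m, toy_l1), "UNSPLICED_AS_RIFT")
})

test_that("5' ends map into the element TSS window and counts are conserved", {
  cfg <- generator_config(n_genes = 50, n_l1 = 30, n_rifts = 12,
                          clone_counts = c(testis = 30, thymus = 15),
                          seed = 19)
  ann <- gen_genome(cfg)
  pl <- plant_rifts(ann, cfg)
  cl <- gen_transcript_clones(ann, pl, cfg)
  ref <- l1_reference(cfg$l1_ref_length, seed = cfg$seed)
  tss <- map_tss(cl, ann$l1, ref)
  # count conservation: every clone 5' end falls in some element here
  expect_identical(sum(tss$count), length(cl) - length(attr(tss, "skipped")))
  # antisense clones (the planted transcripts) map into the TSS window
  as_clones <- Filter(function(x) !x$has_polyA, cl)
  tss_as <- map_tss(as_clones, ann$l1, ref)
  expect_true(all(tss_as$l1_coord >= 2201 & tss_as$l1_coord <= 2244))
  # sense polyA decoys start at the element 5' end (coordinate 1)
  sense <- Filter(function(x) x$has_polyA, cl)
  if (length(sense)) {
    tss_s <- map_tss(sense, ann$l1, ref)
    expect_true(all(tss_s$l1_coord == 1))
  }
  # a clone outside every element is skipped and logged
  stray <- transcript_clone(
    "stray", "testis", "B6",
    blocks = data.frame(chrom = "chrNo", start = 5L, end = 100L),
    strand = "+")
  tss2 <- map_tss(c(as_clones, list(stray)), ann$l1, ref)
  expect_identical(attr(tss2, "skipped"), "stray")
  expect_identical(sum(tss2$count), sum(tss_as$count))
})

test_that("splice donors reproduce the canonical 9-mers at their coordinates", {
  ref <- l1_reference(seed = 1)
  # sense sequence around the donors is the reverse complement of the
  # antisense 9-mers
  expect_identical(substr(ref$sense_sequence, 1833, 1841),
                   revcomp("GATGGTGAG"))
  expect_identical(substr(ref$sense_sequence, 1887, 1895),
                   revcomp("TCAGGTGTG"))

  cfg <- generator_config(n_genes = 50, n_l1 = 40, n_rifts = 16,
                          p_spliced = 1,
                          clone_counts = c(testis = 40, thymus = 20),
                          seed = 19)
  ann <- gen_genome(cfg)
  pl <- plant_rifts(ann, cfg)
  cl <- gen_transcript_clones(ann, pl, cfg)
  calls <- do.call(rbind, Filter(Negate(is.null), lapply(
    cl, find_splice_donors, l1 = ann$l1, ref = ref)))
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$valid))
  expect_true(all(startsWith(calls$intronic5, "gt")))
  expect_setequal(unique(paste0(calls$exonic4, calls$intronic5)),
                  c("GATGgtgag", "TCAGgtgtg"))
  expect_true(all(calls$l1_sense_coord[
    paste0(calls$exonic4, calls$intronic5) == "GATGgtgag"] == 1838))
  expect_true(all(calls$l1_sense_coord[
    paste0(calls$exonic4, calls$intronic5) == "TCAGgtgtg"] == 1892))

  # unspliced clone -> no donor call
  uns <- Filter(function(x) !x$spliced & !x$has_polyA,
                gen_transcript_clones(ann, pl,
                  generator_config(n_genes = 50, n_l1 = 40, n_rifts = 16,
                                   p_spliced = 0,
                                   clone_counts = c(testis = 10,
                                                    thymus = 5),
                                   seed = 19)))
  if (length(uns)) {
    expect_null(find_splice_donors(uns[[1]], ann$l1, ref))
  }

  # a non-GT junction is flagged invalid, not dropped
  ref2 <- make_ref(paste(rep("A", 3000), collapse = ""))
  e <- toy_l1[1, ]  # plus element at 10001
  clone <- transcript_clone(
    "cx", "testis", "B6",
    blocks = data.frame(chrom = "chrT", start = c(11000L, 5000L),
                        end = c(11200L, 5100L)),
    strand = "-")
  res <- find_splice_donors(clone, toy_l1, ref2)
  expect_false(res$valid)
  expect_identical(res$l1_sense_coord, 1000L)
})

test_that("antisense ATG scanning finds planted starts with frames", {
  # AS sequence "CATGG" corresponds to sense revcomp "CCATG"
  ref <- make_ref("CCATG")
  hits <- scan_atg(ref, c(1, 5))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$as_offset, 2L)
  expect_identical(hits$frame, 1L)
  expect_identical(hits$l1_sense_coord, 4L)

  # no A or T in the window -> nothing
  ref0 <- make_ref("GGCCGGCC")
  expect_identical(nrow(scan_atg(ref0, c(1, 8))), 0L)
  expect_error(scan_atg(ref0, c(0, 8)), "window")

  # synthetic ORF1 window carries exactly eight AS ATGs in >= 2 frames
  ref1 <- l1_reference(seed = 1)
  hits1 <- scan_atg(ref1, c(2124, 2244))
  expect_identical(nrow(hits1), 8L)
  expect_gte(length(unique(hits1$frame)), 2L)
  # the same eight under a different random fill
  ref2 <- l1_reference(seed = 99)
  expect_identical(nrow(scan_atg(ref2, c(2124, 2244))), 8L)
})

test_that("donor usage summary reports integer percents of spliced clones", {
  calls <- data.frame(
    clone_id = sprintf("c%02d", 1:65),
    exonic4 = c(rep("GATG", 44), rep("TCAG", 13), rep("AAAA", 8)),
    intronic5 = c(rep("gtgag", 44), rep("gtgtg", 13), rep("gtaaa", 8)),
    l1_sense_coord = c(rep(1838L, 44), rep(1892L, 13), rep(500L, 8)),
    valid = TRUE, stringsAsFactors = FALSE
  )
  tab <- summarize_donor_usage(calls)
  expect_identical(tab$donor[1], "GATGgtgag")
  expect_identical(tab$count[1], 44L)
  expect_identical(tab$percent[1], 68L)
  expect_identical(tab$percent[tab$donor == "TCAGgtgtg"], 20L)
  expect_identical(sum(tab$count), 65L)
  expect_identical(nrow(summarize_donor_usage(NULL)), 0L)
})
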