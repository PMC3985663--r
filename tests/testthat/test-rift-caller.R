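test_that("threshold is mean + k*SD with sample SD, cross-checked two-pass", {
  m <- make_probe_matrix(list(gA = 5), c(5, 6, 7, 8, 9))
  thr <- compute_threshold(m, "s1")
  # independent two-pass mean/SD
  x <- c(5, 6, 7, 8, 9)
  mu <- sum(x) / length(x)
  s2 <- sum((x - mu)^2) / (length(x) - 1)
  expect_equal(thr, mu + sqrt(s2))
  expect_equal(thr, 8.5811, tolerance = 1e-4)

  m0 <- make_probe_matrix(list(gA = 4), rep(6, 4))
  expect_equal(compute_threshold(m0, "s1"), 6)

  m1 <- make_probe_matrix(list(gA = 1), 6)
  expect_error(compute_threshold(m1, "s1"), "at least 2")
  expect_error(compute_threshold(m, "nope"), "unknown sample")
})

test_that("high-probe flags use a strict comparison", {
  m <- make_probe_matrix(list(gA = 5), c(5, 6, 7, 8, 9))
  thr <- compute_threshold(m, "s1")
  high <- call_high_probes(m, "s1", thr)
  expect_identical(sum(high), 1L)   # only the 9
  expect_identical(which(high), 5L)
  # a probe exactly at the threshold is not high
  m2 <- make_probe_matrix(list(gA = 2), c(7, 7))
  expect_identical(call_high_probes(m2, "s1", 7), c(FALSE, FALSE))
  expect_true(all(call_high_probes(m2, "s1", -Inf)))
})

test_that("maximal run detection matches hand-worked cases", {
  flags <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  m <- make_probe_matrix(list(gA = 6), rep(6, 6))
  runs <- find_runs(m, "s1", flags)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$run_length, 5L)

  expect_identical(nrow(find_runs(m, "s1", rep(FALSE, 6))), 0L)

  flags2 <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  m2 <- make_probe_matrix(list(gA = 9), rep(6, 9))
  runs2 <- find_runs(m2, "s1", flags2)
  expect_identical(nrow(runs2), 1L)
  expect_identical(runs2$run_length, 6L)
  expect_identical(runs2$probe_indices[[1]], 4:9)

  # runs do not cross gene boundaries
  m3 <- make_probe_matrix(list(gA = 3, gB = 3), rep(6, 6))
  expect_identical(nrow(find_runs(m3, "s1", rep(TRUE, 6))), 0L)
  runs3 <- find_runs(m3, "s1", rep(TRUE, 6), caller_params(min_run = 3))
  expect_identical(nrow(runs3), 2L)
})

test_that("find_runs equals the brute-force window scan on random instances", {
  set.seed(401)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    n_genes <- sample(1:4, 1)
    gid <- sort(sample(paste0("g", seq_len(n_genes)), n, replace = TRUE))
    flags <- stats::runif(n) < 0.5
    min_run <- sample(1:6, 1)
    m <- make_probe_matrix(as.list(table(gid)), rep(6, n))
    got <- find_runs(m, "s1", flags, caller_params(min_run = min_run))
    want <- brute_force_runs(m$probes$gene_id, flags, min_run)
    expect_identical(nrow(got), length(want))
    if (length(want)) {
      got_key <- paste(got$gene_id, got$run_length,
                       vapply(got$probe_indices, min, 0L))
      want_key <- vapply(want, function(w) {
        first_global <- which(m$probes$gene_id == w$gene_id)[w$local_start]
        paste(w$gene_id, w$len, first_global)
      }, "")
      expect_setequal(got_key, want_key)
    }
  }
})

test_that("element matching applies length, subfamily, orientation and distance filters", {
  # gene [100001, 150200] plus strand; run on all probes
  run_matrix <- make_probe_matrix(list(geneA = 6), rep(10, 6),
                                  probe_start = 100001L + (0:5) * 10000L)
  run <- find_runs(run_matrix, "s1", rep(TRUE, 6), caller_params())[1, ]

  ok_l1 <- l1_row("L1ok", 125000L, 131999L)           # intronic, 7 kb, AS
  ann <- make_toy_annotation(list(ok_l1))
  hit <- find_initiating_l1(run, run_matrix, ann, caller_params())
  expect_identical(hit$l1_id, "L1ok")
  expect_identical(hit$dist_l1_gene_bp, 0L)

  # same element but 4 kb long -> rejected
  ann2 <- make_toy_annotation(list(l1_row("L1short", 125000L, 128999L)))
  expect_null(find_initiating_l1(run, run_matrix, ann2, caller_params()))

  # sense-oriented -> rejected; accepted when orientation not required
  ann3 <- make_toy_annotation(list(l1_row("L1sense", 125000L, 131999L,
                                          strand = "+")))
  expect_null(find_initiating_l1(run, run_matrix, ann3, caller_params()))
  expect_identical(
    find_initiating_l1(run, run_matrix, ann3,
                       caller_params(require_antisense = FALSE))$l1_id,
    "L1sense")

  # unknown subfamily -> rejected
  ann4 <- make_toy_annotation(list(l1_row("L1odd", 125000L, 131999L,
                                          subfamily = "Lx5")))
  expect_null(find_initiating_l1(run, run_matrix, ann4, caller_params()))

  # both distance clauses fail: element ~110 kb past the last probe and
  # ~110 kb from the gene span
  far <- l1_row("L1far", 260300L, 267299L)
  ann5 <- make_toy_annotation(list(far))
  expect_null(find_initiating_l1(run, run_matrix, ann5, caller_params()))

  # probe clause alone rescues an element 31 kb from the gene span
  near_probe <- l1_row("L1np", 181300L, 188299L)
  ann6 <- make_toy_annotation(list(near_probe))
  expect_identical(
    find_initiating_l1(run, run_matrix, ann6, caller_params())$l1_id,
    "L1np")
  expect_gt(find_initiating_l1(run, run_matrix, ann6,
                               caller_params())$dist_l1_gene_bp, 30000L)
  # but not in AND mode
  expect_null(find_initiating_l1(run, run_matrix, ann6,
                                 caller_params(distance_mode = "and")))

  # strain filter
  poly <- l1_row("L1poly", 125000L, 131999L, present_in = "B6")
  ann7 <- make_toy_annotation(list(poly))
  expect_identical(
    find_initiating_l1(run, run_matrix, ann7, caller_params(),
                       strain = "B6")$l1_id, "L1poly")
  expect_null(find_initiating_l1(run, run_matrix, ann7, caller_params(),
                                 strain = "DBA"))

  # tie-break: nearest to the run probes, then lexicographic id
  two <- list(l1_row("L1b", 125000L, 131999L),
              l1_row("L1a", 125000L, 131999L))
  ann8 <- make_toy_annotation(two)
  expect_identical(
    find_initiating_l1(run, run_matrix, ann8, caller_params())$l1_id,
    "L1a")
})

test_that("subfamily names canonicalize through the default pattern table", {
  expect_identical(
    canonical_subfamily(c("L1Md_T", "L1Md_Gf", "L1Md_A", "L1Md_F2",
                          "L1_Mus3", "Lx5", "T_F")),
    c("T_F", "G_F", "A", "F", "F", NA, "T_F"))
  # user-overridable table
  expect_identical(canonical_subfamily("Lx5", c("^Lx" = "F")), "F")
})

test_that("end-to-end calling recovers exactly the planted truth under strong signal", {
  cfg <- generator_config(n_genes = 60, n_l1 = 30, n_rifts = 10,
                          signal_shift = 6, background_sd = 1, seed = 23)
  ann <- gen_genome(cfg)
  pl <- plant_rifts(ann, cfg)
  m <- gen_probe_matrix(ann, pl, cfg)
  calls <- call_rifts(m, ann)
  ev <- evaluate_calls(calls, pl, m)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # attrition log is attached per sample
  att <- attr(calls, "attrition")
  expect_identical(nrow(att), nrow(m$samples))
  expect_true(all(att$n_runs >= att$n_runs_matched))
})

test_that("a polymorphic element yields calls only in carrier strains", {
  cfg <- generator_config(n_genes = 30, n_l1 = 16, n_rifts = 6,
                          polymorphic_frac = 1, seed = 31)
  ann <- gen_genome(cfg)
  pl <- plant_rifts(ann, cfg)
  m <- gen_probe_matrix(ann, pl, cfg)
  calls <- call_rifts(m, ann)
  ev <- evaluate_calls(calls, pl, m)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  for (i in seq_len(nrow(pl))) {
    carriers <- strsplit(pl$strains[i], ",")[[1]]
    got <- calls[calls$l1_id == pl$l1_id[i], ]
    expect_setequal(unique(got$strain), carriers)
  }
  # removing a strain from present_in removes exactly that strain's calls
  target <- pl$l1_id[1]
  carriers <- strsplit(pl$strains[1], ",")[[1]]
  expect_true("B6" %in% carriers)
  ann2 <- ann
  i <- which(ann2$l1$l1_id == target)
  ann2$l1$present_in[i] <- paste(setdiff(carriers, "B6"), collapse = ",")
  if (ann2$l1$present_in[i] == "") {
    ann2$l1$present_in[i] <- "none"
  }
  calls2 <- call_rifts(m, ann2)
  key <- function(d) paste(d$gene_id, d$l1_id, d$sample_id, sep = "|")
  lost <- setdiff(key(calls), key(calls2))
  expect_gt(length(lost), 0)
  lost_parts <- strsplit(lost, "|", fixed = TRUE)
  expect_true(all(vapply(lost_parts, `[[`, "", 2) == target))
  expect_true(all(startsWith(vapply(lost_parts, `[[`, "", 3), "B6_")))
  expect_identical(setdiff(key(calls2), key(calls)), character(0))
})

test_that("call counts respond monotonically to parameter tightening", {
  cfg <- generator_config(n_genes = 40, n_l1 = 24, n_rifts = 8,
                          signal_shift = 3, background_sd = 1, seed = 37)
  ann <- gen_genome(cfg)
  pl <- plant_rifts(ann, cfg)
  m <- gen_probe_matrix(ann, pl, cfg)
  n_calls <- function(p) nrow(call_rifts(m, ann, p))
  base <- n_calls(caller_params())
  expect_lte(n_calls(caller_params(min_run = 7)), base)
  expect_lte(n_calls(caller_params(sd_multiplier = 2)), base)
  expect_gte(n_calls(caller_params(min_run = 4)), base)
  expect_gte(n_calls(caller_params(gene_distance_kb = 60,
                                   probe_distance_kb = 200)), base)
})

test_that("chromosome mismatch between matrix and annotation errors", {
  cfg <- generator_config(n_genes = 5, n_l1 = 4, seed = 2)
  ann <- gen_genome(cfg)
  m <- gen_probe_matrix(ann, NULL, cfg)
  m$probes$chrom <- "chrOther"
  expect_error(call_rifts(m, ann), "chromosome")
})
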