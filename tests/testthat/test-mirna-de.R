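make_alignments <- function() {
  ann <- data.frame(precursor_id = c("pre1", "pre2"),
                    mature_start = c(10L, 20L), mature_end = c(31L, 41L),
                    star_start = c(50L, NA), star_end = c(71L, NA),
                    stringsAsFactors = FALSE)
  al <- data.frame(
    read_id = sprintf("r%02d", 1:10),
    precursor_id = c(rep("pre1", 7), rep("pre2", 2), "unknown"),
    start = c(8L, 7L, 15L, 16L, 48L, 55L, 56L, 18L, 25L, 1L),
    library_id = c(rep("M2", 5), rep("F2", 4), "M2"),
    stringsAsFactors = FALSE)
  list(ann = ann, al = al)
}

test_that("read quantification applies the -2/+5 start window", {
  x <- make_alignments()
  msgs <- capture_messages(
    q <- quantify_reads(x$al, x$ann))
  expect_match(paste(msgs, collapse = ""), "1 reads")
  cm <- q$counts
  # pre1 mature window [8, 15]: starts 8 and 15 counted; 7 and 16 not
  expect_equal(cm["pre1/mature", "M2"], 2L)
  # pre1 star window [48, 55]: 48 and 55 counted (55 in F2), 56 not
  expect_equal(cm["pre1/star", "M2"], 1L)
  expect_equal(cm["pre1/star", "F2"], 1L)
  # pre2 has no star arm; start 18 and 25 in [18, 25]
  expect_equal(cm["pre2/mature", "F2"], 2L)
  # each read counted at most once
  expect_equal(sum(cm), 6L)
})

test_that("window boundaries and mature/star tie-breaking match a per-read oracle", {
  set.seed(5)
  ann <- data.frame(precursor_id = "p",
                    mature_start = 10L, mature_end = 31L,
                    star_start = 14L, star_end = 35L)  # overlapping windows
  al <- data.frame(read_id = sprintf("r%03d", 1:200),
                   precursor_id = "p",
                   start = sample(1:40, 200, replace = TRUE),
                   library_id = sample(c("M2", "F2"), 200, replace = TRUE),
                   stringsAsFactors = FALSE)
  q <- quantify_reads(al, ann)
  orc <- quantify_oracle(al, ann)
  for (key in names(orc)) {
    parts <- strsplit(key, "@")[[1]]
    expect_equal(q$counts[parts[1], parts[2]], unname(orc[[key]]),
                 info = key)
  }
  expect_equal(sum(q$counts), Reduce(`+`, orc))
  # equidistant tie goes to mature: start 12 is 2 from both
  tie <- quantify_reads(
    data.frame(read_id = "t", precursor_id = "p", start = 12L,
               library_id = "M2"), ann)
  expect_equal(tie$counts["p/mature", "M2"], 1L)
  expect_equal(tie$counts["p/star", "M2"], 0L)
})

test_that("minimum-read filter keeps rows with >= k in both gender libraries of a dpf", {
  counts <- rbind(a = c(0L, 0L, 0L, 0L, 0L, 0L),
                  b = c(4L, 4L, 0L, 0L, 0L, 0L),
                  c = c(4L, 3L, 3L, 4L, 2L, 1L),
                  d = c(100L, 5L, 9L, 12L, 4L, 4L))
  meta <- data.frame(library_id = c("M2", "F2", "M5", "F5", "M9", "F9"),
                     gender = rep(c("male", "female"), 3),
                     dpf = rep(c(2L, 5L, 9L), each = 2))
  colnames(counts) <- meta$library_id
  x <- structure(list(counts = counts,
                      library_sizes = setNames(rep(1e6, 6), meta$library_id),
                      meta = meta), class = "mirna_counts")
  xf <- filter_min_reads(x, k = 4L)
  expect_equal(rownames(xf$counts), c("b", "d"))
  expect_equal(unname(xf$eligible["b", ]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(xf$eligible["d", ]), c(TRUE, TRUE, TRUE))
  # brute-force scan agrees on random matrices
  set.seed(6)
  cm <- matrix(rpois(600, 3), 100, 6, dimnames = list(sprintf("m%03d", 1:100),
                                                      meta$library_id))
  x2 <- structure(list(counts = cm, library_sizes = x$library_sizes,
                       meta = meta), class = "mirna_counts")
  kept <- rownames(filter_min_reads(x2, 4L)$counts)
  brute <- rownames(cm)[apply(cm, 1, function(r)
    any(sapply(c(2, 5, 9), function(t)
      all(r[meta$library_id[meta$dpf == t]] >= 4))))]
  expect_equal(kept, brute)
})

test_that("RPM normalization scales by library size", {
  meta <- data.frame(library_id = c("M2", "F2"), gender = c("male", "female"),
                     dpf = 2L)
  x <- structure(list(counts = matrix(c(1L, 32L), 1, 2,
                                      dimnames = list("m", meta$library_id)),
                      library_sizes = c(M2 = 1e6, F2 = 32e6), meta = meta),
                 class = "mirna_counts")
  rpm <- rpm_normalize(x)
  expect_equal(unname(rpm["m", ]), c(1, 1))
  x$library_sizes["M2"] <- 0
  expect_error(rpm_normalize(x), "positive")
})

test_that("deviation test standardizes per dpf and flags planted outliers", {
  set.seed(7)
  n <- 100
  rpm <- cbind(M2 = 2^rnorm(n, 5, 0.3), F2 = 2^rnorm(n, 5, 0.3))
  rownames(rpm) <- sprintf("m%03d", 1:n)
  # plant one deviation at mean + 8 sd of the remainder
  d <- log2(rpm[, "F2"]) - log2(rpm[, "M2"])
  rpm[1, "F2"] <- rpm[1, "M2"] * 2^(mean(d[-1]) + 8 * sd(d[-1]))
  meta <- data.frame(library_id = c("M2", "F2"),
                     gender = c("male", "female"), dpf = 2L)
  rec <- deviation_test(rpm, meta, 2L)
  expect_equal(mean(rec$z), 0, tolerance = 1e-10)
  expect_equal(sd(rec$z), 1, tolerance = 1e-10)
  expect_true(rec$significant[rec$mirna_id == "m001"])
  expect_equal(rec$direction[rec$mirna_id == "m001"], "up-in-female")
  expect_equal(rec$p_tail, pnorm(-abs(rec$z)))
  # zero variance errors
  rpm0 <- cbind(M2 = rep(4, 20), F2 = rep(8, 20))
  rownames(rpm0) <- sprintf("x%02d", 1:20)
  expect_error(deviation_test(rpm0, meta, 2L), "zero variance")
})

test_that("the 4-SD tail probability and empirical tail FDR arithmetic", {
  rec <- data.frame(mirna_id = sprintf("m%d", 1:2008),
                    dpf = rep(c(2L, 5L), 1004),
                    z = rep(0, 2008), significant = FALSE)
  rec$significant[1:9] <- TRUE
  fdr <- empirical_tail_fdr(rec, z_threshold = 4)
  pooled <- fdr[fdr$scope == "pooled", ]
  expect_equal(pooled$expected_by_chance, 2008 * 2 * pnorm(-4))
  expect_equal(pooled$fdr, 2008 * 2 * pnorm(-4) / 9, tolerance = 1e-12)
  expect_equal(pooled$fdr, 0.0141, tolerance = 0.01)
  one <- empirical_tail_fdr(
    data.frame(mirna_id = "m", dpf = 2L, z = 5, significant = TRUE), 4)
  expect_equal(one$fdr[one$scope == "pooled"], 2 * pnorm(-4))
  none <- empirical_tail_fdr(
    data.frame(mirna_id = "m", dpf = 2L, z = 0, significant = FALSE), 4)
  expect_true(is.na(none$fdr[none$scope == "pooled"]))
})

test_that("unique significant miRNAs deduplicate across timepoints", {
  rec <- data.frame(
    mirna_id = c("a", "a", "b", "c", "c"),
    dpf = c(2L, 5L, 2L, 5L, 9L),
    log_ratio = log2(c(0.4, 0.5, 3.8, 2, 2)),
    ratio_female_male = c(0.4, 0.5, 3.8, 2, 2),
    z = c(-5, -4.5, 6, 4.2, 4.1), p_tail = 1e-6,
    significant = TRUE,
    direction = c("up-in-male", "up-in-male", "up-in-female",
                  "up-in-female", "up-in-female"))
  u <- unique_significant_mirnas(rec)
  expect_equal(nrow(u), 3L)
  expect_equal(u$n_dpf_significant[u$mirna_id == "a"], 2)
  expect_equal(u$ratio_dpf2[u$mirna_id == "a"], 0.4)
  expect_true(is.na(u$ratio_dpf9[u$mirna_id == "a"]))
  # disjoint sets across dpf: union size = sum
  rec2 <- rec; rec2$mirna_id <- letters[1:5]
  expect_equal(nrow(unique_significant_mirnas(rec2)), 5L)
})

test_that("null libraries produce 4-SD calls at about the normal rate", {
  calls <- vapply(1:25, function(s) {
    libs <- generate_mirna_libraries(mirna_sim_config(n_de = 0L, seed = s))
    sum(mirna_de_pipeline(libs)$records$significant)
  }, numeric(1))
  lam <- 25 * 3 * 700 * 2 * pnorm(-4)   # all rows pass the filter at depth 2e7
  expect_lte(sum(calls), qpois(0.999, lam * 1.5))
})

test_that("pipeline output is invariant to row order", {
  libs <- generate_mirna_libraries(mirna_sim_config(n_mirnas = 150L,
                                                    seed = 13L))
  md1 <- mirna_de_pipeline(libs)
  libs2 <- libs
  perm <- sample(nrow(libs$counts))
  libs2$counts <- libs$counts[perm, ]
  md2 <- mirna_de_pipeline(libs2)
  r1 <- md1$records[order(md1$records$mirna_id, md1$records$dpf), ]
  r2 <- md2$records[order(md2$records$mirna_id, md2$records$dpf), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2, tolerance = 1e-12)
})
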