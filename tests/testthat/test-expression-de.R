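test_that("loess normalization removes planted intensity-dependent bias", {
  # identity: equal channels give M = 0 before and after
  A <- seq(6, 12, length.out = 200)
  expect_equal(loess_normalize(rep(0, 200), A, delta = 0), rep(0, 200),
               tolerance = 1e-12)
  # a smooth (linear) trend is reproduced exactly by the local linear fit
  set.seed(1)
  A <- runif(300, 6, 14)
  M <- 0.5 + 0.1 * A
  out <- loess_normalize(M, A, delta = 0)
  expect_lt(max(abs(out)), 1e-6)
})

test_that("loess normalization equals a brute-force tricube local fit", {
  set.seed(7)
  for (n in c(60L, 237L)) {
    A <- rnorm(n, 9, 1.5)
    M <- sin(A) + rnorm(n, 0, 0.3)
    out <- loess_normalize(M, A, span = 0.3, delta = 0)
    expect_equal(out, M - lowess_oracle(A, M, 0.3), tolerance = 1e-8)
  }
})

test_that("aquantile normalization equalizes per-rank A-values exactly", {
  expect_equal(unname(aquantile_normalize(cbind(a = c(1, 2, 3),
                                                b = c(3, 4, 5)))),
               cbind(c(2, 3, 4), c(2, 3, 4)))
  set.seed(2)
  A <- matrix(rnorm(500 * 6, 9), 500, 6)
  out <- aquantile_normalize(A)
  sorted <- apply(out, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  # already identical distributions unchanged
  A2 <- cbind(A[, 1], A[order(A[, 1], decreasing = TRUE), 1])
  out2 <- aquantile_normalize(A2)
  expect_equal(sort(out2[, 1]), sort(A2[, 1]), tolerance = 1e-12)
  expect_error(aquantile_normalize(matrix(1, 3, 1)), ">= 2")
})

test_that("single-channel split doubles columns and preserves M", {
  ex <- generate_microarray_experiment(small_array_cfg(n_probes = 100L))
  M <- log2(ex$R) - log2(ex$G)
  A <- (log2(ex$R) + log2(ex$G)) / 2
  E <- split_single_channel(M, A, ex$targets)
  expect_equal(ncol(E), 2L * ncol(ex$R))
  expect_equal(E[, ex$targets$red_sample[3]] - E[, ex$targets$green_sample[3]],
               M[, 3])
  expect_equal(length(unique(ex$design$dye)), 2L)
  bad <- ex$targets; bad$red_sample[2] <- NA
  expect_error(split_single_channel(M, A, bad), "red and a green")
})

test_that("replicate collapsing takes the per-sample median", {
  m <- matrix(c(3, 5, 100, 7), 4, 2, dimnames = list(NULL, c("s1", "s2")))
  m[, 2] <- c(2, 4, 9, 9)
  out <- collapse_replicates(m, c("g1", "g1", "g1", "g2"))
  expect_equal(out["g1", ], c(s1 = 5, s2 = 4))
  out2 <- collapse_replicates(m[1:2, , drop = FALSE], c("g", "g"))
  expect_equal(out2["g", "s1"], 4)  # even group: mean of middle values
  single <- collapse_replicates(m, paste0("p", 1:4))
  expect_equal(unname(single[paste0("p", 1:4), ]), unname(m))
  expect_error(collapse_replicates(m, c("a", "a", "a", NA)), "NA")
})

test_that("probe model reduces to the classical t-test and matches a pseudoinverse oracle", {
  set.seed(3)
  design <- data.frame(sample_id = paste0("s", 1:12),
                       gender = rep(c("female", "male"), each = 6))
  y <- rnorm(12) + rep(c(0.8, 0), each = 6)
  fit <- fit_probe_model(y, design)
  tt <- t.test(y[1:6], y[7:12], var.equal = TRUE)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
  expect_equal(fit$estimate, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  expect_equal(fit$lsmean_female, mean(y[1:6]), tolerance = 1e-10)

  # oracle equivalence on small multi-factor instances, incl. rank-deficient
  for (s in 1:5) {
    set.seed(s)
    d <- data.frame(sample_id = paste0("s", 1:12),
                    slide = rep(c("sl1", "sl2"), 6),
                    array = rep(paste0("a", 1:3), each = 4),
                    dye = rep(c("Cy3", "Cy5"), 6),
                    gender = rep(c("female", "male"), each = 6),
                    sire = rep(c("F1", "F2", "M1", "M2"), each = 3),
                    dpf = rep(c(2, 5, 9), 4))
    y <- rnorm(12)
    fit <- fit_probe_model(y, d)
    X <- sexdimorph:::build_design_matrix(d)$X
    expect_equal(unname(fit$coefficients), unname(pinv_lm_oracle(X, y)),
                 tolerance = 1e-8)
  }
})

test_that("lsmeans match emmeans on a full-rank design", {
  skip_if_not_installed("emmeans")
  set.seed(4)
  d <- data.frame(sample_id = paste0("s", 1:24),
                  dye = rep(c("Cy3", "Cy5"), 12),
                  gender = rep(c("female", "male"), each = 12),
                  dpf = factor(rep(c(2, 5, 9), 8)))
  y <- rnorm(24) + (d$gender == "female") * 0.6 + as.numeric(d$dpf) * 0.3
  fit <- fit_probe_model(y, d)
  lm_fit <- lm(y ~ dye + gender + dpf, data = d,
               contrasts = list(dye = "contr.sum", gender = "contr.sum",
                                dpf = "contr.sum"))
  em <- as.data.frame(emmeans::emmeans(lm_fit, "gender"))
  expect_equal(fit$lsmean_female, em$emmean[em$gender == "female"],
               tolerance = 1e-8)
  expect_equal(fit$lsmean_male, em$emmean[em$gender == "male"],
               tolerance = 1e-8)
  ctr <- as.data.frame(graphics::pairs(emmeans::emmeans(lm_fit, "gender")))
  expect_equal(fit$p, ctr$p.value, tolerance = 1e-8)
})

test_that("null probes keep nominal type-I error", {
  set.seed(6)
  ex <- generate_microarray_experiment(small_array_cfg(n_probes = 50L))
  design <- ex$design
  Y <- matrix(rnorm(10000 * nrow(design)), 10000,
              dimnames = list(sprintf("N%05d", 1:10000), design$sample_id))
  fit <- sexdimorph:::fit_gender_matrix(Y, design)
  for (alpha in c(0.05, 0.01, 1e-3)) {
    frac <- mean(fit$p < alpha)
    bound <- 2.58 * sqrt(alpha * (1 - alpha) / 10000)
    expect_lt(abs(frac - alpha), bound + 1e-12)
  }
})

test_that("degenerate zero-variance probes are flagged with p = 0", {
  design <- data.frame(sample_id = paste0("s", 1:8),
                       gender = rep(c("female", "male"), each = 4))
  fit <- fit_probe_model(rep(c(1, 0), each = 4), design)
  expect_true(fit$degenerate)
  expect_equal(fit$p, 0)
})

test_that("empirical FDR follows the expected/observed rank rule", {
  one <- empirical_fdr(1)
  expect_equal(one$E, 1); expect_equal(one$fdr, 1)

  p <- c(1e-4, runif(999, 0.2, 1))
  fd <- empirical_fdr(p)
  expect_equal(fd$E[1], 0.1)
  expect_equal(fd$fdr[1], 0.1)
  expect_true(all(fd$fdr >= 0 & fd$fdr <= 1))
  # ties share the largest rank of the tied block
  fd2 <- empirical_fdr(c(0.01, 0.01, 0.5))
  expect_equal(fd2$rank[1:2], c(2L, 2L))
  # monotone variant is a running minimum from the largest p
  set.seed(8)
  p3 <- runif(200)
  raw <- empirical_fdr(p3)$fdr
  mono <- empirical_fdr(p3, monotone = TRUE)$fdr
  expect_true(all(mono <= raw + 1e-12))
  o <- order(p3)
  expect_true(all(diff(mono[o]) >= -1e-12))
  expect_error(empirical_fdr(numeric(0)), "empty")
  expect_error(empirical_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("uniform null p-values give median FDR near 1", {
  set.seed(9)
  meds <- vapply(1:5, function(i) median(empirical_fdr(runif(10000))$fdr),
                 numeric(1))
  expect_true(all(meds >= 0.9 & meds <= 1.0))
})

test_that("Poisson family-wise correction has its closed form and bounds", {
  expect_equal(poisson_bonferroni(0), 0)
  expect_equal(poisson_bonferroni(log(2)), 0.5)
  expect_equal(poisson_bonferroni(0.01), 0.00995, tolerance = 1e-3)
  expect_lt(abs(poisson_bonferroni(0.01) - 0.01) / 0.01, 0.005)
  E <- c(0, 10^seq(-8, 2, length.out = 50))
  pb <- poisson_bonferroni(E)
  expect_true(all(pb >= 0 & pb <= 1))
  expect_true(all(pb <= pmin(1, E) + 1e-15))
  expect_error(poisson_bonferroni(-1), ">= 0")
})

test_that("pipeline recovers planted probes and estimates their fold change", {
  ex <- generate_microarray_experiment(
    small_array_cfg(n_probes = 2000L, n_de_probes = 10L, seed = 21L))
  de <- suppressMessages(gender_de_pipeline(ex))
  expect_true(all(ex$truth$probe_id %in% de$significant$probe_id))
  m <- merge(de$results, ex$truth, by = "probe_id")
  # estimated fold change tracks the planted one (both on female/male scale)
  expect_gt(cor(log2(m$fc.x), m$lfc), 0.98)

  # planted single-probe fold change 3.5 estimated within [3.0, 4.0]
  fcs <- vapply(1:6, function(s) {
    exi <- generate_microarray_experiment(
      small_array_cfg(n_probes = 800L, n_de_probes = 1L,
                      fc_range = c(3.5, 3.5), seed = 100L + s))
    dei <- suppressMessages(gender_de_pipeline(exi))
    fc <- dei$results$fc[dei$results$probe_id == exi$truth$probe_id]
    if (exi$truth$lfc < 0) 1 / fc else fc
  }, numeric(1))
  expect_true(all(fcs > 3.0 & fcs < 4.0))
})

test_that("pipeline output is invariant to probe and array order", {
  ex <- generate_microarray_experiment(
    small_array_cfg(n_probes = 400L, n_de_probes = 5L, seed = 31L))
  de1 <- suppressMessages(gender_de_pipeline(ex))
  perm <- sample(nrow(ex$R)); aperm_ <- sample(ncol(ex$R))
  ex2 <- ex
  ex2$R <- ex$R[perm, aperm_]; ex2$G <- ex$G[perm, aperm_]
  ex2$targets <- ex$targets[aperm_, ]
  de2 <- suppressMessages(gender_de_pipeline(ex2))
  r1 <- de1$results[order(de1$results$probe_id), ]
  r2 <- de2$results[order(de2$results$probe_id), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("null experiments rarely call anything significant", {
  zeros <- vapply(1:10, function(s) {
    ex <- generate_microarray_experiment(
      small_array_cfg(n_probes = 5000L, n_de_probes = 0L, seed = 200L + s))
    nrow(suppressMessages(gender_de_pipeline(ex))$significant)
  }, numeric(1))
  expect_gte(mean(zeros == 0), 0.9)
})

test_that("nonpositive intensities are excluded and heavy missingness drops probes", {
  ex <- generate_microarray_experiment(
    small_array_cfg(n_probes = 300L, n_de_probes = 0L, seed = 41L))
  ex$R[1, ] <- -1                    # probe 1 missing everywhere -> dropped
  ex$R[2, 1] <- 0                    # probe 2 missing in 1/28 arrays -> kept
  msgs <- capture_messages(de <- gender_de_pipeline(ex))
  expect_match(paste(msgs, collapse = " "), "dropped")
  expect_false("P00001" %in% de$results$probe_id)
  expect_true("P00002" %in% de$results$probe_id)
  expect_equal(de$n_tested, 299L)
})

test_that("profile correlations recover planted cross-dpf structure", {
  # identical and sign-flipped difference vectors
  d <- cbind(dpf2 = 1:10, dpf5 = 1:10, dpf9 = -(1:10))
  pc <- profile_correlations(d)
  expect_equal(pc$r[pc$dpf_a == "dpf2" & pc$dpf_b == "dpf5"], 1)
  expect_equal(pc$r[pc$dpf_a == "dpf2" & pc$dpf_b == "dpf9"], -1)
  # zero-variance profile flagged
  d0 <- cbind(dpf2 = rep(1, 5), dpf5 = 1:5)
  pc0 <- profile_correlations(d0)
  expect_true(pc0$degenerate[1]); expect_true(is.na(pc0$r[1]))

  # attenuation: r -> var_s / (var_s + var_e) for shared signal + noise
  var_s <- 1; var_e <- 0.5
  theo <- var_s / (var_s + var_e)
  set.seed(10)
  rs <- replicate(100, {
    s <- rnorm(59, 0, sqrt(var_s))
    m <- cbind(s + rnorm(59, 0, sqrt(var_e)), s + rnorm(59, 0, sqrt(var_e)),
               s + rnorm(59, 0, sqrt(var_e)))
    colnames(m) <- paste0("dpf", c(2, 5, 9))
    mean(profile_correlations(m)$r)
  })
  expect_lt(abs(mean(rs) - theo), 0.1)
})
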