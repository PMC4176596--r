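# Two-color microarray normalization and per-probe differential expression
# between genders: within-array loess on (M, A), between-array quantile
# normalization of A, single-channel expansion, a fixed-effects linear model
# per probe with least-squares gender means, an empirical rank-based FDR and
# a Poisson family-wise correction.

#' Within-array loess normalization of M on A
#'
#' Fits a tricube-weighted local linear regression of the log ratio
#' M = log2(R/G) on the average intensity A = (log2 R + log2 G)/2 and
#' subtracts the fit, removing intensity-dependent dye bias. Non-finite
#' (M, A) pairs are excluded from the fit and returned as NA.
#'
#' @param M numeric vector of log2 ratios.
#' @param A numeric vector of average log2 intensities (same length).
#' @param span fraction of points in each local neighborhood (default 0.3).
#' @param iterations robustifying iterations (0 = plain local regression).
#' @param delta interpolation speed-up passed to \code{\link[stats]{lowess}};
#'   NULL uses the lowess default (1 percent of the A range), 0 evaluates
#'   the exact local fit at every point.
#' @return numeric vector of normalized M values.
#' @export
loess_normalize <- function(M, A, span = 0.3, iterations = 0L,
                            delta = NULL) {
  if (length(M) != length(A)) fail("M and A must have equal length")
  ok <- is.finite(M) & is.finite(A)
  if (sum(ok) < 10L) fail("need at least 10 finite (M, A) pairs")
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    message(sprintf("loess_normalize: %d non-finite pairs excluded", n_bad))
  if (is.null(delta)) delta <- 0.01 * diff(range(A[ok]))
  lw <- stats::lowess(A[ok], M[ok], f = span, iter = iterations,
                      delta = delta)
  fit <- numeric(sum(ok))
  fit[order(A[ok])] <- lw$y
  out <- rep(NA_real_, length(M))
  out[ok] <- M[ok] - fit
  out
}

#' Between-array quantile normalization of average intensities
#'
#' Makes the distribution of A-values identical across arrays: after
#' normalization the k-th smallest A of every array equals the mean of the
#' k-th smallest values over arrays. Within-array log ratios M are not
#' touched by this step.
#'
#' @param A numeric matrix of A-values, probes x arrays (>= 2 columns,
#'   identical probe set by construction).
#' @return matrix of the same shape with quantile-normalized columns.
#' @export
aquantile_normalize <- function(A) {
  if (!is.matrix(A) || ncol(A) < 2L)
    fail("need a matrix of A-values with >= 2 arrays")
  out <- limma::normalizeQuantiles(A, ties = TRUE)
  dimnames(out) <- dimnames(A)
  out
}

#' Expand two-color arrays into single-channel samples
#'
#' Reconstructs per-channel log2 intensities from normalized (M, A):
#' red = A + M/2, green = A - M/2, one column per sample-channel, so that
#' each hybridized sample enters the linear model as its own observation
#' with dye as a fixed effect.
#'
#' @param M,A probes x arrays matrices of normalized values.
#' @param targets data frame with columns \code{array}, \code{red_sample},
#'   \code{green_sample} mapping each array's channels to sample ids.
#' @return probes x samples matrix of log2 intensities.
#' @export
split_single_channel <- function(M, A, targets) {
  need <- c("array", "red_sample", "green_sample")
  if (!all(need %in% names(targets)))
    fail("targets must have columns: %s", paste(need, collapse = ", "))
  if (anyNA(targets$red_sample) || anyNA(targets$green_sample))
    fail("every array needs a red and a green sample assignment")
  idx <- match(targets$array, colnames(M))
  if (anyNA(idx)) fail("targets reference arrays absent from the matrices")
  E <- cbind(A[, idx, drop = FALSE] + M[, idx, drop = FALSE] / 2,
             A[, idx, drop = FALSE] - M[, idx, drop = FALSE] / 2)
  colnames(E) <- c(targets$red_sample, targets$green_sample)
  E
}

#' Collapse replicated probes to their median expression
#'
#' @param mat probes x samples matrix.
#' @param groups vector (length \code{nrow(mat)}) assigning each probe row
#'   to a replicate group; the group value is the per-sample median of its
#'   members (mean of the two middle values for even-sized groups).
#' @return matrix with one row per group, rownames the group labels.
#' @export
collapse_replicates <- function(mat, groups) {
  if (length(groups) != nrow(mat))
    fail("'groups' must assign every probe row to a group")
  if (anyNA(groups)) fail("empty (NA) group assignment")
  ix <- split(seq_len(nrow(mat)), groups)
  singles <- lengths(ix) == 1L
  out <- matrix(NA_real_, length(ix), ncol(mat),
                dimnames = list(names(ix), colnames(mat)))
  if (any(singles))
    out[singles, ] <- mat[unlist(ix[singles]), , drop = FALSE]
  for (g in which(!singles))
    out[g, ] <- apply(mat[ix[[g]], , drop = FALSE], 2, stats::median)
  out
}

# ---- design matrix ---------------------------------------------------------

# Sum-to-zero coding for the model factors so that least-squares means are
# directly the balanced marginal means. Sire is coded nested within gender:
# within-gender sum-to-zero dummies, zero for the other gender. Returns the
# matrix plus block metadata used to build lsmean/contrast rows.
build_design_matrix <- function(design) {
  if (!"gender" %in% names(design)) fail("design must contain 'gender'")
  n <- nrow(design)
  gl <- sort(unique(as.character(design$gender)))
  if (length(gl) != 2L) fail("gender must have exactly 2 levels")
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  blocks <- list()

  add_sum_factor <- function(X, blocks, name) {
    v <- as.character(design[[name]])
    lev <- sort(unique(v))
    if (length(lev) < 2L) return(list(X = X, blocks = blocks))
    C <- stats::contr.sum(length(lev))
    rownames(C) <- lev
    colnames(C) <- paste0(name, lev[-length(lev)])
    X <- cbind(X, C[v, , drop = FALSE])
    blocks[[name]] <- list(type = "sum", levels = lev, coding = C,
                           cols = colnames(C))
    list(X = X, blocks = blocks)
  }

  for (f in c("slide", "array", "dye")) if (f %in% names(design)) {
    r <- add_sum_factor(X, blocks, f); X <- r$X; blocks <- r$blocks
  }
  r <- add_sum_factor(X, blocks, "gender"); X <- r$X; blocks <- r$blocks
  if (length(blocks$gender$cols) == 0L)
    fail("gender factor is constant")

  if ("sire" %in% names(design)) {
    sg <- table(design$sire, design$gender)
    if (any(rowSums(sg > 0) > 1L))
      fail("invalid factor structure: a sire appears in both genders")
    for (g in gl) {
      sires <- sort(unique(as.character(design$sire[design$gender == g])))
      if (length(sires) < 2L) next
      C <- stats::contr.sum(length(sires))
      rownames(C) <- sires
      cols <- paste0("sire_", g, seq_len(ncol(C)))
      B <- matrix(0, n, ncol(C), dimnames = list(NULL, cols))
      in_g <- design$gender == g
      B[in_g, ] <- C[as.character(design$sire[in_g]), , drop = FALSE]
      X <- cbind(X, B)
      blocks[[paste0("sire_", g)]] <-
        list(type = "nested", gender = g, levels = sires, coding = C,
             cols = cols)
    }
  }
  for (f in c("dpf", "dam")) if (f %in% names(design)) {
    r <- add_sum_factor(X, blocks, f); X <- r$X; blocks <- r$blocks
  }
  rownames(X) <- design$sample_id
  list(X = X, blocks = blocks, gender_levels = gl, n = n)
}

# Model-matrix row of the least-squares mean for one gender: every
# sum-to-zero factor averages to 0 over its levels, nested sire dummies
# average to 0 within the gender, leaving intercept + gender coding.
lsmean_row <- function(dm, gender) {
  x <- stats::setNames(numeric(ncol(dm$X)), colnames(dm$X))
  x["(Intercept)"] <- 1
  gb <- dm$blocks$gender
  x[gb$cols] <- gb$coding[gender, ]
  x
}

# Contrast vector for lsmean(female-level) - lsmean(male-level); the second
# sorted gender level is taken as the reference "male" only if literally
# named so, otherwise the contrast is second minus first alphabetical level.
gender_contrast <- function(dm) {
  gl <- dm$gender_levels
  hi <- if ("female" %in% gl) "female" else gl[2]
  lo <- setdiff(gl, hi)[1]
  lsmean_row(dm, hi) - lsmean_row(dm, lo)
}

# ---- model fitting ---------------------------------------------------------

# Fit all probe rows of Y against one design; minimum-norm least squares via
# the pseudoinverse so rank-deficient (aliased) designs are handled
# explicitly. Returns per-probe estimates for the gender contrast.
fit_gender_matrix <- function(Y, design) {
  dm <- build_design_matrix(design)
  X <- dm$X
  if (!is.null(rownames(X)) && !is.null(colnames(Y))) {
    if (!setequal(rownames(X), colnames(Y)))
      fail("design samples and expression columns disagree")
    Y <- Y[, rownames(X), drop = FALSE]
  }
  qx <- qr(X)
  rk <- qx$rank
  df <- nrow(X) - rk
  if (df < 1L) fail("no residual degrees of freedom")
  aliased <- if (rk < ncol(X)) colnames(X)[qx$pivot[(rk + 1L):ncol(X)]]
  else character(0)

  Xp <- pinv(X)                       # p x n
  Beta <- Y %*% t(Xp)                 # probes x p
  resid <- Y - Beta %*% t(X)
  rss <- rowSums(resid^2)
  sigma2 <- rss / df

  cv <- gender_contrast(dm)
  w <- drop(crossprod(cv, Xp))        # length n
  vfac <- sum(w^2)
  est <- drop(Beta %*% cv)
  se <- sqrt(sigma2 * vfac)
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- sigma2 <= .Machine$double.eps * mean(abs(Y))^2
  p[degenerate & est != 0] <- 0
  p[degenerate & est == 0] <- 1

  hi <- if ("female" %in% dm$gender_levels) "female" else dm$gender_levels[2]
  lo <- setdiff(dm$gender_levels, hi)[1]
  res <- data.frame(
    probe_id = rownames(Y) %||% sprintf("P%05d", seq_len(nrow(Y))),
    lsmean_male = drop(Beta %*% lsmean_row(dm, lo)),
    lsmean_female = drop(Beta %*% lsmean_row(dm, hi)),
    estimate = est, se_diff = se, t = tstat, df = df, p = p,
    degenerate = degenerate, stringsAsFactors = FALSE)
  attr(res, "aliased") <- aliased
  attr(res, "rank") <- rk
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the per-probe fixed-effects model for one expression row
#'
#' Ordinary least squares with sum-to-zero contrasts for whichever of the
#' factors slide, array, dye, gender, sire (nested within gender), dpf and
#' dam are present in the design. Gender least-squares means are the
#' model-based marginal means averaging over the other factors with equal
#' weights; the p-value comes from the t distribution of the lsmean
#' difference over its standard error with residual degrees of freedom.
#' Rank-deficient designs are fit by the minimum-norm (pseudoinverse)
#' solution and the aliased coefficients are reported.
#'
#' @param y numeric expression vector (one probe, one value per sample).
#' @param design data frame with one row per sample (factor columns as
#'   above; \code{gender} mandatory with exactly two levels).
#' @return list with elements \code{coefficients}, \code{aliased},
#'   \code{lsmean_male}, \code{lsmean_female}, \code{estimate} (female -
#'   male, log2), \code{se_diff}, \code{t}, \code{df}, \code{p} and
#'   \code{degenerate} (zero residual variance flag).
#' @export
fit_probe_model <- function(y, design) {
  if (length(y) != nrow(design)) fail("length(y) must equal nrow(design)")
  Y <- matrix(as.numeric(y), 1L, length(y),
              dimnames = list("probe", design$sample_id))
  res <- fit_gender_matrix(Y, design)
  dm <- build_design_matrix(design)
  beta <- drop(pinv(dm$X) %*% as.numeric(y))  # X rows follow design order
  names(beta) <- colnames(dm$X)
  list(coefficients = beta, aliased = attr(res, "aliased"),
       lsmean_male = res$lsmean_male, lsmean_female = res$lsmean_female,
       estimate = res$estimate, se_diff = res$se_diff, t = res$t,
       df = res$df, p = res$p, degenerate = res$degenerate)
}

#' Empirical rank-based false discovery rate
#'
#' For each probe, E is the number of probes expected at or below its
#' p-value under the global null (N times the p-value) and the FDR is the
#' ratio of expected to observed counts, E divided by the probe's ascending
#' p-value rank, capped at 1. Tied p-values share the largest rank of the
#' tied block.
#'
#' @param p vector of p-values in [0, 1].
#' @param monotone if TRUE, apply a step-up monotone adjustment (running
#'   minimum from the largest p-value); default FALSE reports the raw
#'   expected/observed ratio.
#' @return data frame (rank, E, fdr) aligned with \code{p}.
#' @export
empirical_fdr <- function(p, monotone = FALSE) {
  if (length(p) == 0L) fail("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) fail("p-values must lie in [0, 1]")
  N <- length(p)
  rk <- rank(p, ties.method = "max")
  E <- N * p
  fdr <- pmin(1, E / rk)
  if (monotone) {
    o <- order(p)
    f <- fdr[o]
    fdr[o] <- rev(cummin(rev(f)))
  }
  data.frame(rank = rk, E = E, fdr = fdr)
}

#' Poisson family-wise error probability
#'
#' The probability of at least one significant probe given an expected
#' count E of probes at the threshold under the null, computed as one minus
#' the Poisson probability of zero: 1 - exp(-E). Approaches the classical
#' Bonferroni bound N*p as E tends to 0 and is bounded by min(1, E)
#' everywhere.
#'
#' @param E expected count(s), >= 0.
#' @return probabilities in [0, 1].
#' @export
poisson_bonferroni <- function(E) {
  if (any(E < 0)) fail("E must be >= 0")
  -expm1(-E)
}

# ---- pipeline --------------------------------------------------------------

#' Differential expression between genders for a two-color experiment
#'
#' Chains within-array loess normalization, between-array quantile
#' normalization of A, single-channel expansion, optional replicate-probe
#' collapsing (median), the per-probe fixed-effects model, the empirical
#' FDR and the Poisson family-wise correction. Fold change is reported as
#' the female/male ratio on the natural scale, 2^(lsmean_female -
#' lsmean_male).
#'
#' @param experiment a \code{two_color_experiment} (see
#'   \code{\link{generate_microarray_experiment}}) or a list with raw
#'   intensity matrices \code{R}, \code{G}, a \code{targets} frame and a
#'   per-sample \code{design} sheet.
#' @param fdr_threshold significance cut-off on the empirical FDR
#'   (default 0.05).
#' @param span loess span.
#' @param iterations loess robustifying iterations.
#' @param replicate_groups optional probe -> replicate-group vector;
#'   replicated probes are collapsed to their median after normalization.
#' @param monotone_fdr use the monotone step-up FDR variant.
#' @param max_missing drop probes with non-positive/missing intensities in
#'   more than this fraction of samples (default 0.2).
#' @return object of class \code{gender_de}: list with the full
#'   \code{results} table (probe_id, lsmean_male, lsmean_female, fc,
#'   se_diff, p, rank, E, fdr, bonferroni, significant), the
#'   \code{significant} subset, per-dpf gender-difference profiles for the
#'   significant probes, the normalized single-channel matrix and fit
#'   metadata.
#' @export
gender_de_pipeline <- function(experiment, fdr_threshold = 0.05, span = 0.3,
                               iterations = 0L, replicate_groups = NULL,
                               monotone_fdr = FALSE, max_missing = 0.2) {
  R <- experiment$R; G <- experiment$G
  targets <- experiment$targets; design <- experiment$design
  if (is.null(R) || is.null(G) || is.null(targets) || is.null(design))
    fail("experiment must provide R, G, targets and design")

  bad <- !(R > 0 & G > 0 & is.finite(R) & is.finite(G))
  if (any(bad))
    message(sprintf("gender_de_pipeline: %d non-positive intensities set NA",
                    sum(bad)))
  R[bad] <- NA; G[bad] <- NA
  keep <- rowMeans(bad) <= max_missing
  if (!all(keep))
    message(sprintf("gender_de_pipeline: %d probes dropped (> %.0f%% missing)",
                    sum(!keep), 100 * max_missing))
  R <- R[keep, , drop = FALSE]; G <- G[keep, , drop = FALSE]

  M <- log2(R) - log2(G)
  A <- (log2(R) + log2(G)) / 2
  for (j in seq_len(ncol(M)))
    M[, j] <- loess_normalize(M[, j], A[, j], span = span,
                              iterations = iterations)
  A <- aquantile_normalize(A)
  E_mat <- split_single_channel(M, A, targets)
  if (!is.null(replicate_groups))
    E_mat <- collapse_replicates(E_mat, replicate_groups[keep])

  # complete-case fast path; probes with missing values are refit on their
  # observed samples only
  cc <- rowSums(is.na(E_mat)) == 0L
  fits <- vector("list", 2L)
  aliased <- character(0)
  if (any(cc)) {
    fits[[1L]] <- fit_gender_matrix(E_mat[cc, , drop = FALSE], design)
    aliased <- attr(fits[[1L]], "aliased")
  }
  if (any(!cc)) {
    part <- lapply(which(!cc), function(i) {
      obs <- !is.na(E_mat[i, ])
      f <- fit_gender_matrix(E_mat[i, obs, drop = FALSE],
                             design[match(colnames(E_mat)[obs],
                                          design$sample_id), , drop = FALSE])
      f$probe_id <- rownames(E_mat)[i]
      f
    })
    fits[[2L]] <- do.call(rbind, part)
  }
  fit <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  fit <- fit[match(rownames(E_mat), fit$probe_id), , drop = FALSE]

  fd <- empirical_fdr(fit$p, monotone = monotone_fdr)
  results <- data.frame(
    probe_id = fit$probe_id,
    lsmean_male = fit$lsmean_male, lsmean_female = fit$lsmean_female,
    fc = 2^(fit$lsmean_female - fit$lsmean_male),
    se_diff = fit$se_diff, p = fit$p,
    rank = fd$rank, E = fd$E, fdr = fd$fdr,
    bonferroni = poisson_bonferroni(fd$E),
    significant = fd$fdr <= fdr_threshold,
    stringsAsFactors = FALSE)

  # raw per-dpf gender-difference profiles on the normalized matrix
  dpfs <- sort(unique(design$dpf))
  diffs <- sapply(dpfs, function(t) {
    f <- design$sample_id[design$gender == "female" & design$dpf == t]
    m <- design$sample_id[design$gender == "male" & design$dpf == t]
    rowMeans(E_mat[, f, drop = FALSE]) - rowMeans(E_mat[, m, drop = FALSE])
  })
  colnames(diffs) <- paste0("dpf", dpfs)

  structure(list(results = results,
                 significant = results[results$significant, , drop = FALSE],
                 dpf_differences = diffs, normalized = E_mat,
                 design = design, aliased = aliased,
                 params = list(fdr_threshold = fdr_threshold, span = span,
                               iterations = iterations,
                               monotone_fdr = monotone_fdr,
                               max_missing = max_missing),
                 n_tested = nrow(results)),
            class = "gender_de")
}

#' @export
print.gender_de <- function(x, ...) {
  cat(sprintf("Gender differential expression: %d probes tested\n",
              x$n_tested))
  cat(sprintf("  significant at FDR <= %.3g: %d\n",
              x$params$fdr_threshold, nrow(x$significant)))
  if (length(x$aliased))
    cat(sprintf("  aliased coefficients: %s\n",
                paste(x$aliased, collapse = ", ")))
  invisible(x)
}

#' @export
summary.gender_de <- function(object, n = 10L, ...) {
  s <- object$significant
  s <- s[order(s$p), , drop = FALSE]
  cat(sprintf("%d/%d probes significant at FDR <= %.3g\n", nrow(s),
              object$n_tested, object$params$fdr_threshold))
  if (nrow(s)) {
    cat(sprintf("fold change (female/male) range: %.2f-%.2f\n",
                min(pmin(s$fc, 1 / s$fc)), max(pmax(s$fc, 1 / s$fc))))
    print(utils::head(s[, c("probe_id", "fc", "p", "fdr", "bonferroni")], n),
          row.names = FALSE)
  }
  invisible(s)
}

#' Pearson correlations of gender-difference profiles across dpf
#'
#' For the significant probes, correlates the per-probe gender-difference
#' vectors between each pair of embryonic ages.
#'
#' @param x a \code{gender_de} object or a probes x dpf matrix of gender
#'   differences (>= 3 rows).
#' @return data frame (dpf_a, dpf_b, r, n_probes, degenerate); a
#'   zero-variance profile yields NA with \code{degenerate = TRUE}.
#' @export
profile_correlations <- function(x) {
  d <- if (inherits(x, "gender_de")) {
    sig <- x$results$significant
    x$dpf_differences[sig, , drop = FALSE]
  } else as.matrix(x)
  if (nrow(d) < 3L) fail("need >= 3 significant probes")
  cmb <- utils::combn(ncol(d), 2L)
  out <- data.frame(dpf_a = colnames(d)[cmb[1, ]],
                    dpf_b = colnames(d)[cmb[2, ]],
                    r = NA_real_, n_probes = nrow(d), degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(cmb))) {
    a <- d[, cmb[1, k]]; b <- d[, cmb[2, k]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      out$degenerate[k] <- TRUE
    } else out$r[k] <- stats::cor(a, b)
  }
  out
}
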