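# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity with different code paths from
# the package internals.

# Tricube-weighted local linear regression evaluated at every point, with
# the nearest-neighbour bandwidth and weight clamps of the classical
# scatterplot smoother.
lowess_oracle <- function(x, y, f) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]; n <- length(xs)
  ns <- min(n, max(2L, floor(f * n + 1e-7)))
  fit <- numeric(n)
  for (i in seq_len(n)) {
    l <- i; r <- i
    while (r - l + 1L < ns) {
      if (l == 1L) r <- r + 1L
      else if (r == n) l <- l - 1L
      else if (xs[i] - xs[l - 1L] <= xs[r + 1L] - xs[i]) l <- l - 1L
      else r <- r + 1L
    }
    h <- max(xs[i] - xs[l], xs[r] - xs[i])
    d <- abs(xs[l:r] - xs[i])
    w <- ifelse(d <= 0.001 * h, 1,
                ifelse(d <= 0.999 * h, (1 - (d / h)^3)^3, 0))
    xx <- xs[l:r]; yy <- ys[l:r]
    w <- w / sum(w)
    xb <- sum(w * xx)
    b2 <- sum(w * (xx - xb)^2)
    fit[i] <- if (sqrt(b2) > 1e-7 * diff(range(xs))) {
      slope <- sum(w * (xx - xb) * yy) / b2
      sum(w * yy) + slope * (xs[i] - xb)
    } else sum(w * yy)
  }
  out <- numeric(n)
  out[o] <- fit
  out
}

# Minimum-norm least squares via an explicit normal-equations pseudoinverse
# (eigen decomposition of X'X), independent of the package's SVD route.
pinv_lm_oracle <- function(X, y) {
  XtX <- crossprod(X)
  e <- eigen(XtX, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  XtX_inv <- e$vectors[, pos, drop = FALSE] %*%
    diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
  drop(XtX_inv %*% crossprod(X, y))
}

# Translation with Biostrings::translate (different code path from the
# package's codon-table loop), clipped at the first stop.
translate_oracle <- function(nt) {
  n3 <- (nchar(nt) %/% 3L) * 3L
  if (n3 < 3L) return(list(protein = "", hit_stop = FALSE))
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(nt, 1L, n3)),
                          if.fuzzy.codon = "X")))
  pos <- regexpr("*", aa, fixed = TRUE)
  if (pos > 0) list(protein = substr(aa, 1L, pos - 1L), hit_stop = TRUE)
  else list(protein = aa, hit_stop = FALSE)
}

# Character-by-character protein diff (prefix/suffix trim), written as an
# explicit loop over split vectors.
protein_diff_oracle <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  na <- length(va); nb <- length(vb)
  k <- 0L
  while (k < min(na, nb) && va[k + 1L] == vb[k + 1L]) k <- k + 1L
  s <- 0L
  while (s < min(na, nb) - k && va[na - s] == vb[nb - s]) s <- s + 1L
  c(deleted = na - k - s, novel = nb - k - s)
}

# Exhaustive enumeration of all 2^n equiprobable direction outcomes.
sign_test_oracle <- function(k, n) {
  hits <- 0L
  for (code in 0:(2^n - 1)) {
    bits <- sum(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (bits >= k) hits <- hits + 1L
  }
  hits / 2^n
}

# Closed-form simple linear regression.
ols_oracle <- function(x, y) {
  sx <- x - mean(x)
  slope <- sum(sx * y) / sum(sx^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Window-rule read counting by per-read loop.
quantify_oracle <- function(alignments, annotations) {
  counts <- list()
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    ann <- annotations[annotations$precursor_id == a$precursor_id, ]
    if (nrow(ann) == 0L) next
    in_m <- a$start >= ann$mature_start - 2 & a$start <= ann$mature_start + 5
    in_s <- !is.na(ann$star_start) &&
      a$start >= ann$star_start - 2 & a$start <= ann$star_start + 5
    arm <- if (in_m && in_s) {
      if (abs(a$start - ann$star_start) < abs(a$start - ann$mature_start))
        "star" else "mature"
    } else if (in_m) "mature" else if (in_s) "star" else NA
    if (is.na(arm)) next
    key <- paste0(a$precursor_id, "/", arm, "@", a$library_id)
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small standard design shared by expression tests.
small_array_cfg <- function(...) {
  args <- list(n_probes = 1500L, n_de_probes = 8L, fc_range = c(4, 4),
               seed = 42L)
  do.call(array_sim_config, utils::modifyList(args, list(...)))
}
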