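# Small-RNA quantification against miRNA precursors and the z-deviation
# test for sexually differentially expressed miRNAs with an empirical tail
# FDR.

#' Quantify reads against mature/star windows of miRNA precursors
#'
#' A read is counted for the mature (or star) sequence of its precursor iff
#' its start position lies within two nucleotides upstream to five
#' nucleotides downstream of that sequence's start,
#' [span_start - 2, span_start + 5]. A read eligible for both arms of one
#' precursor is assigned to the arm with the nearer start (tie goes to the
#' mature arm). Each read contributes to at most one row.
#'
#' @param alignments data frame (read_id, precursor_id, start, library_id)
#'   of 1-based read start positions on the precursor forward strand.
#' @param annotations data frame (precursor_id, mature_start, mature_end,
#'   star_start, star_end), 1-based inclusive.
#' @param library_sizes named vector of total reads per library; defaults
#'   to the per-library alignment counts.
#' @return object of class \code{mirna_counts} with a counts matrix whose
#'   rows are \code{<precursor>/mature} and \code{<precursor>/star}.
#' @export
quantify_reads <- function(alignments, annotations, library_sizes = NULL) {
  need <- c("read_id", "precursor_id", "start", "library_id")
  if (!all(need %in% names(alignments)))
    fail("alignments must have columns: %s", paste(need, collapse = ", "))
  known <- alignments$precursor_id %in% annotations$precursor_id
  if (!all(known))
    message(sprintf("quantify_reads: %d reads on unknown precursors skipped",
                    sum(!known)))
  al <- alignments[known, , drop = FALSE]
  ix <- match(al$precursor_id, annotations$precursor_id)
  ms <- annotations$mature_start[ix]
  ss <- annotations$star_start[ix]
  in_m <- al$start >= ms - 2L & al$start <= ms + 5L
  in_s <- !is.na(ss) & al$start >= ss - 2L & al$start <= ss + 5L
  both <- in_m & in_s
  # nearer start wins; tie -> mature
  to_star <- in_s & (!in_m | (both & abs(al$start - ss) < abs(al$start - ms)))
  to_mat <- in_m & !to_star
  arm <- ifelse(to_mat, "mature", ifelse(to_star, "star", NA))
  keep <- !is.na(arm)
  rows <- paste0(al$precursor_id[keep], "/", arm[keep])
  libs <- sort(unique(alignments$library_id))
  all_rows <- c(paste0(annotations$precursor_id, "/mature"),
                paste0(annotations$precursor_id[!is.na(annotations$star_start)],
                       "/star"))
  counts <- matrix(0L, length(all_rows), length(libs),
                   dimnames = list(sort(all_rows), libs))
  if (any(keep)) {
    tb <- table(rows, al$library_id[keep])
    counts[rownames(tb), colnames(tb)] <-
      counts[rownames(tb), colnames(tb)] +
      matrix(as.integer(tb), nrow(tb), ncol(tb))
  }
  if (is.null(library_sizes))
    library_sizes <- stats::setNames(
      as.integer(table(factor(alignments$library_id, levels = libs))), libs)
  structure(list(counts = counts, library_sizes = library_sizes,
                 meta = NULL, truth = NULL), class = "mirna_counts")
}

#' Filter miRNAs by a minimum read count
#'
#' A (miRNA, dpf) pair is tested only when both gender libraries of that
#' dpf have at least \code{k} reads; rows failing the rule at every dpf are
#' removed, and the per-dpf eligibility mask is attached so downstream
#' testing can skip pairs that fail at individual timepoints.
#'
#' @param x a \code{mirna_counts} object with library \code{meta}.
#' @param k minimum raw read count (default 4).
#' @return the filtered \code{mirna_counts} with an \code{eligible}
#'   logical matrix (miRNAs x dpf).
#' @export
filter_min_reads <- function(x, k = 4L) {
  stopifnot(inherits(x, "mirna_counts"))
  if (is.null(x$meta)) fail("library metadata (gender, dpf) required")
  dpfs <- sort(unique(x$meta$dpf))
  elig <- sapply(dpfs, function(t) {
    cols <- x$meta$library_id[x$meta$dpf == t]
    rowSums(x$counts[, cols, drop = FALSE] >= k) == length(cols)
  })
  colnames(elig) <- as.character(dpfs)
  keep <- rowSums(elig) > 0L
  x$counts <- x$counts[keep, , drop = FALSE]
  x$eligible <- elig[keep, , drop = FALSE]
  x$min_reads <- as.integer(k)
  x
}

#' Reads-per-million normalization
#'
#' @param x a \code{mirna_counts} object.
#' @return matrix of RPM values (count x 1e6 / library size, per column).
#' @export
rpm_normalize <- function(x) {
  stopifnot(inherits(x, "mirna_counts"))
  ls <- x$library_sizes[colnames(x$counts)]
  if (any(is.na(ls) | ls <= 0)) fail("library sizes must be positive")
  sweep(x$counts, 2L, ls / 1e6, "/")
}

#' z-deviation test for gender-biased miRNA expression at one dpf
#'
#' The per-miRNA deviation is d = log2(RPM female) - log2(RPM male); each
#' deviation is standardized against the mean and SD of all tested
#' deviations at that dpf, and |z| >= \code{z_threshold} (default 4 SD) is
#' called significant, with the one-sided normal tail probability at |z|
#' attached (3.17e-5 at the 4 SD threshold).
#'
#' @param rpm RPM matrix (rows miRNAs, columns libraries).
#' @param meta library metadata (library_id, gender, dpf).
#' @param dpf the timepoint to test.
#' @param eligible optional logical vector selecting the rows tested at
#'   this dpf (from \code{\link{filter_min_reads}}).
#' @param z_threshold significance threshold in SD units.
#' @param robust use median/MAD instead of mean/SD for standardization.
#' @return data frame (mirna_id, dpf, log_ratio, ratio_female_male, z,
#'   p_tail, significant, direction).
#' @export
deviation_test <- function(rpm, meta, dpf, eligible = NULL, z_threshold = 4,
                           robust = FALSE) {
  fcol <- meta$library_id[meta$gender == "female" & meta$dpf == dpf]
  mcol <- meta$library_id[meta$gender == "male" & meta$dpf == dpf]
  if (length(fcol) != 1L || length(mcol) != 1L)
    fail("need exactly one female and one male library at dpf %s", dpf)
  if (is.null(eligible)) eligible <- rep(TRUE, nrow(rpm))
  ids <- rownames(rpm)[eligible]
  if (length(ids) < 10L) fail("need >= 10 miRNAs for SD estimation")
  d <- log2(rpm[eligible, fcol]) - log2(rpm[eligible, mcol])
  ctr <- if (robust) stats::median(d) else mean(d)
  sc <- if (robust) stats::mad(d) else stats::sd(d)
  if (sc == 0) fail("degenerate input: zero variance of deviations")
  z <- (d - ctr) / sc
  data.frame(mirna_id = ids, dpf = dpf, log_ratio = d,
             ratio_female_male = 2^d, z = z,
             p_tail = stats::pnorm(-abs(z)),
             significant = abs(z) >= z_threshold,
             direction = ifelse(z > 0, "up-in-female", "up-in-male"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical tail FDR for the z-deviation calls
#'
#' Compares the realized number of deviations at or beyond the threshold
#' with the number expected under a standard normal: expected =
#' 2 * pnorm(-z_threshold) * number of tested (miRNA, dpf) pairs; FDR =
#' expected / observed. Reported per dpf and pooled.
#'
#' @param records row-bound output of \code{\link{deviation_test}} across
#'   dpf.
#' @param z_threshold the threshold used for the calls.
#' @return data frame (scope, n_tested, n_significant, expected_by_chance,
#'   fdr); FDR is NA where nothing was called.
#' @export
empirical_tail_fdr <- function(records, z_threshold = 4) {
  p2 <- 2 * stats::pnorm(-z_threshold)
  one <- function(scope, rec) {
    ns <- sum(rec$significant)
    exp_ <- nrow(rec) * p2
    data.frame(scope = scope, n_tested = nrow(rec), n_significant = ns,
               expected_by_chance = exp_,
               fdr = if (ns > 0) exp_ / ns else NA_real_,
               stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(split(records, records$dpf), function(r)
    one(paste0("dpf", r$dpf[1]), r)))
  rbind(per, one("pooled", records))
}

#' Unique sex-biased miRNAs across timepoints
#'
#' Deduplicates significant calls by miRNA and lays out the female/male
#' expression ratio per dpf (significant calls only, natural scale).
#'
#' @param records row-bound \code{\link{deviation_test}} output.
#' @return data frame with one row per miRNA significant at >= 1 dpf:
#'   direction, number of significant dpf, and one ratio column per dpf.
#' @export
unique_significant_mirnas <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  dpfs <- sort(unique(records$dpf))
  ids <- unique(sig$mirna_id)
  out <- data.frame(mirna_id = ids, stringsAsFactors = FALSE)
  out$direction <- vapply(ids, function(i)
    sig$direction[sig$mirna_id == i][1], character(1))
  for (t in dpfs)
    out[[paste0("ratio_dpf", t)]] <- vapply(ids, function(i) {
      r <- sig$ratio_female_male[sig$mirna_id == i & sig$dpf == t]
      if (length(r)) r[1] else NA_real_
    }, numeric(1))
  out$n_dpf_significant <- rowSums(!is.na(
    out[, paste0("ratio_dpf", dpfs), drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Full miRNA differential-expression pipeline
#'
#' Applies the minimum-read filter, RPM normalization and the per-dpf
#' z-deviation test, then summarizes the empirical tail FDR and the unique
#' significant miRNAs.
#'
#' @param x a \code{mirna_counts} object with library \code{meta}.
#' @param min_reads minimum raw count in both gender libraries of a dpf.
#' @param z_threshold significance threshold in SD units.
#' @param robust robust standardization (median/MAD).
#' @return object of class \code{mirna_de}: records, fdr summary, unique
#'   significant miRNAs, parameters.
#' @export
mirna_de_pipeline <- function(x, min_reads = 4L, z_threshold = 4,
                              robust = FALSE) {
  stopifnot(inherits(x, "mirna_counts"))
  xf <- filter_min_reads(x, k = min_reads)
  rpm <- rpm_normalize(xf)
  dpfs <- sort(unique(xf$meta$dpf))
  records <- do.call(rbind, lapply(dpfs, function(t)
    deviation_test(rpm, xf$meta, t,
                   eligible = xf$eligible[, as.character(t)],
                   z_threshold = z_threshold, robust = robust)))
  structure(list(records = records,
                 fdr = empirical_tail_fdr(records, z_threshold),
                 unique_significant = unique_significant_mirnas(records),
                 params = list(min_reads = min_reads,
                               z_threshold = z_threshold, robust = robust)),
            class = "mirna_de")
}

#' @export
print.mirna_de <- function(x, ...) {
  cat(sprintf("miRNA gender deviation test (|z| >= %g):\n",
              x$params$z_threshold))
  for (i in seq_len(nrow(x$fdr)))
    cat(sprintf("  %s: %d tested, %d significant (FDR %.3g)\n",
                x$fdr$scope[i], x$fdr$n_tested[i], x$fdr$n_significant[i],
                x$fdr$fdr[i]))
  cat(sprintf("  unique significant miRNAs: %d\n",
              nrow(x$unique_significant)))
  invisible(x)
}
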