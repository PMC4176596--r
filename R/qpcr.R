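# Absolute qPCR quantification: standard curves from dilution series,
# Ct -> input amount, reference-gene normalization, female/male fold
# changes and genomic copy-number ratios.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(quantity) over a dilution series.
#' The amplification efficiency is 10^(-1/slope) - 1 (a slope of -3.3219
#' corresponds to perfect doubling, 100 percent efficiency).
#'
#' @param quantity template quantities (> 0, >= 3 distinct values).
#' @param Ct threshold cycles (same length).
#' @param gene_id optional assay label.
#' @return object of class \code{standard_curve}: slope, intercept, r2,
#'   efficiency, n.
#' @export
fit_standard_curve <- function(quantity, Ct, gene_id = NA_character_) {
  if (length(quantity) != length(Ct)) fail("quantity and Ct lengths differ")
  if (any(quantity <= 0)) fail("quantities must be positive")
  if (length(unique(quantity)) < 3L)
    fail("need >= 3 distinct quantities")
  x <- log10(quantity)
  fit <- stats::lm(Ct ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0)
    fail("non-amplifying assay: flat Ct over the dilution series")
  structure(list(gene_id = gene_id, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared,
                 efficiency = 10^(-1 / slope) - 1, n = length(Ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve%s: Ct = %.4f + %.4f x log10(quantity)\n",
    if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
    x$intercept, x$slope))
  cat(sprintf("  R2 = %.4f, efficiency = %.1f%% (n = %d)\n", x$r2,
              100 * x$efficiency, x$n))
  invisible(x)
}

#' Back-calculate the input amount from a Ct value
#'
#' IA = 10^((Ct - intercept)/slope), in the quantity units of the curve.
#'
#' @param Ct threshold cycle(s).
#' @param curve a \code{\link{fit_standard_curve}} object (or a list with
#'   slope and intercept).
#' @return input amounts.
#' @export
input_amount <- function(Ct, curve) {
  if (is.null(curve$slope) || curve$slope == 0)
    fail("curve slope must be non-zero")
  10^((Ct - curve$intercept) / curve$slope)
}

#' Reference-normalized expression from qPCR wells
#'
#' Converts every well's Ct to an input amount with its gene's standard
#' curve, averages IA across replicates per (sample, gene), and reports
#' each sample's target mean IA divided by its reference-gene mean IA
#' (e.g. gapdh for cDNA, rpp30 for gDNA). Wells with missing Ct are
#' dropped from the replicate mean and flagged; samples without a
#' reference measurement are excluded with a message.
#'
#' @param wells data frame (sample_id, gene_id, Ct, and optionally
#'   replicate, template_kind).
#' @param curves named list of standard curves, one per gene.
#' @param reference reference gene id.
#' @return data frame (sample_id, gene_id, IA_mean, n_replicates,
#'   had_missing, normalized) for the target genes.
#' @export
normalized_expression <- function(wells, curves, reference = "gapdh") {
  need <- c("sample_id", "gene_id", "Ct")
  if (!all(need %in% names(wells)))
    fail("wells must have columns: %s", paste(need, collapse = ", "))
  if (!reference %in% wells$gene_id)
    fail("no wells for reference gene '%s'", reference)
  genes <- unique(wells$gene_id)
  if (!all(genes %in% names(curves)))
    fail("missing standard curve for: %s",
         paste(setdiff(genes, names(curves)), collapse = ", "))
  wells$IA <- NA_real_
  for (g in genes) {
    sel <- wells$gene_id == g
    wells$IA[sel] <- input_amount(wells$Ct[sel], curves[[g]])
  }
  agg <- do.call(rbind, lapply(
    split(wells, list(wells$sample_id, wells$gene_id), drop = TRUE),
    function(w) data.frame(
      sample_id = w$sample_id[1], gene_id = w$gene_id[1],
      IA_mean = mean(w$IA, na.rm = TRUE), n_replicates = sum(!is.na(w$IA)),
      had_missing = anyNA(w$IA), stringsAsFactors = FALSE)))
  ref <- agg[agg$gene_id == reference, c("sample_id", "IA_mean")]
  tgt <- agg[agg$gene_id != reference, , drop = FALSE]
  ri <- match(tgt$sample_id, ref$sample_id)
  if (anyNA(ri)) {
    message(sprintf("normalized_expression: %d sample/gene rows without %s excluded",
                    sum(is.na(ri)), reference))
    tgt <- tgt[!is.na(ri), , drop = FALSE]
    ri <- ri[!is.na(ri)]
  }
  tgt$normalized <- tgt$IA_mean / ref$IA_mean[ri]
  rownames(tgt) <- NULL
  tgt
}

#' Female/male expression fold change
#'
#' Ratio of the mean normalized value over female samples to the mean over
#' male samples; when a timepoint column is given, per-sex means are taken
#' over timepoint means first.
#'
#' @param values data frame (sample_id, normalized, sex, and optionally
#'   timepoint).
#' @return the female/male ratio.
#' @export
fold_change_female_male <- function(values) {
  if (!all(c("normalized", "sex") %in% names(values)))
    fail("values must have 'normalized' and 'sex'")
  if (!all(c("female", "male") %in% values$sex))
    fail("both sexes must be represented")
  mean_sex <- function(s) {
    v <- values[values$sex == s, , drop = FALSE]
    if ("timepoint" %in% names(v))
      mean(tapply(v$normalized, v$timepoint, mean))
    else mean(v$normalized)
  }
  mean_sex("female") / mean_sex("male")
}

#' Genomic copy-number ratio between sexes
#'
#' Reference-normalized genomic quantities per sex for a target gene
#' (reference rpp30 by default), their female/male ratio and a Welch
#' t-test on the per-sample normalized values.
#'
#' @param wells gDNA qPCR wells (sample_id, gene_id, Ct, ...).
#' @param sample_sex data frame (sample_id, sex).
#' @param target target gene id.
#' @param curves named list of standard curves.
#' @param reference reference gene id (default "rpp30").
#' @return list (per_sample, mean_female, mean_male, ratio, p_value).
#' @export
cnv_ratio <- function(wells, sample_sex, target, curves,
                      reference = "rpp30") {
  norm <- normalized_expression(wells, curves, reference = reference)
  norm <- norm[norm$gene_id == target, , drop = FALSE]
  norm$sex <- sample_sex$sex[match(norm$sample_id, sample_sex$sample_id)]
  if (anyNA(norm$sex)) fail("samples without sex assignment")
  f <- norm$normalized[norm$sex == "female"]
  m <- norm$normalized[norm$sex == "male"]
  if (!length(f) || !length(m)) fail("both sexes need gDNA wells")
  p <- if (length(f) > 1L && length(m) > 1L)
    tryCatch(stats::t.test(f, m)$p.value, error = function(e) NA_real_)
  else NA_real_
  list(per_sample = norm, mean_female = mean(f), mean_male = mean(m),
       ratio = mean(f) / mean(m), p_value = p)
}
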