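# Concordance of sex-biased miRNAs with their predicted gene targets.
# A pair is concordant when the miRNA and its target are regulated in
# opposite directions, consistent with miRNA-mediated repression; the
# chance probability of the observed concordance is a one-sided binomial
# sign test at rate 1/2.

#' Score miRNA-target concordance
#'
#' @param mirna_calls data frame (entity_id, direction) of miRNA direction
#'   calls; direction is \code{"up-in-male"} or \code{"up-in-female"}.
#' @param gene_calls data frame (entity_id, direction) of gene calls.
#' @param pairs data frame (mirna_id, gene_id) of predicted target pairs
#'   (prediction itself is upstream input).
#' @return \code{pairs} with columns \code{mirna_direction},
#'   \code{gene_direction} and logical \code{concordant} (TRUE iff the
#'   directions are opposite).
#' @export
score_concordance <- function(mirna_calls, gene_calls, pairs) {
  dirs <- c("up-in-male", "up-in-female")
  check_calls <- function(calls, what) {
    if (anyDuplicated(calls$entity_id))
      fail("duplicate %s direction calls", what)
    if (!all(calls$direction %in% dirs))
      fail("%s directions must be one of: %s", what,
           paste(dirs, collapse = ", "))
  }
  check_calls(mirna_calls, "miRNA"); check_calls(gene_calls, "gene")
  mi <- match(pairs$mirna_id, mirna_calls$entity_id)
  gi <- match(pairs$gene_id, gene_calls$entity_id)
  missing <- unique(c(pairs$mirna_id[is.na(mi)], pairs$gene_id[is.na(gi)]))
  if (length(missing))
    fail("unresolvable IDs in direction tables: %s",
         paste(missing, collapse = ", "))
  pairs$mirna_direction <- mirna_calls$direction[mi]
  pairs$gene_direction <- gene_calls$direction[gi]
  pairs$concordant <- pairs$mirna_direction != pairs$gene_direction
  pairs
}

#' One-sided binomial sign test for concordant targets
#'
#' Probability of observing at least \code{n_concordant} concordant pairs
#' among \code{n_targets} under independent equiprobable directions,
#' P(X >= k) for X ~ Binomial(n, 1/2). Perfect concordance gives (1/2)^n.
#'
#' @param n_concordant number of concordant pairs observed.
#' @param n_targets total number of scored pairs (> 0).
#' @return the tail probability.
#' @export
sign_test <- function(n_concordant, n_targets) {
  if (n_targets <= 0) fail("n_targets must be > 0")
  if (n_concordant < 0 || n_concordant > n_targets)
    fail("n_concordant must lie in [0, n_targets]")
  stats::pbinom(n_concordant - 1L, n_targets, 0.5, lower.tail = FALSE)
}

#' Per-miRNA concordance report
#'
#' Aggregates scored pairs by miRNA, attaches the sign-test probability
#' (full precision plus a display value truncated to three decimals, the
#' convention of printed tables) and flags miRNAs with perfect inverse
#' correlation (all targets concordant, >= 2 targets).
#'
#' @param scored output of \code{\link{score_concordance}}.
#' @return data frame (mirna_id, n_targets, n_concordant, rate, p_sign,
#'   p_sign_display, perfect) sorted by ascending p_sign.
#' @export
concordance_report <- function(scored) {
  if (nrow(scored) == 0L) fail("no scored pairs")
  sp <- split(scored, scored$mirna_id)
  out <- do.call(rbind, lapply(sp, function(s) {
    k <- sum(s$concordant); n <- nrow(s)
    data.frame(mirna_id = s$mirna_id[1], n_targets = n, n_concordant = k,
               rate = k / n, p_sign = sign_test(k, n),
               stringsAsFactors = FALSE)
  }))
  out$p_sign_display <- truncate_decimal(out$p_sign, 3L)
  out$perfect <- out$rate == 1 & out$n_targets >= 2L
  out <- out[order(out$p_sign, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("concordance_report", "data.frame")
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("miRNA-target concordance:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (any(x$perfect))
    cat(sprintf("perfect inverse correlation: %s\n",
                paste(x$mirna_id[x$perfect], collapse = ", ")))
  invisible(x)
}

#' Direction calls from pipeline results
#'
#' Convenience extractors turning a \code{gender_de} or \code{mirna_de}
#' object into the (entity_id, direction) table consumed by
#' \code{\link{score_concordance}}.
#'
#' @param x a \code{gender_de} or \code{mirna_de} object.
#' @return data frame (entity_id, kind, direction) of significant entities.
#' @export
direction_calls <- function(x) {
  if (inherits(x, "gender_de")) {
    s <- x$significant
    data.frame(entity_id = s$probe_id, kind = "gene",
               direction = ifelse(s$fc > 1, "up-in-female", "up-in-male"),
               stringsAsFactors = FALSE)
  } else if (inherits(x, "mirna_de")) {
    u <- x$unique_significant
    data.frame(entity_id = u$mirna_id, kind = "miRNA",
               direction = u$direction, stringsAsFactors = FALSE)
  } else fail("expected a gender_de or mirna_de object")
}

#' Minimal seed-complementarity target finder
#'
#' A labelled convenience utility, not a reproduction of energy-based
#' target predictors: reports (miRNA, gene) pairs whose 3' region contains
#' an exact reverse complement of the miRNA seed (positions 2-8 by
#' default). When a gene's 3'UTR is unknown, the first
#' \code{region_length} nt of the supplied downstream sequence are scanned
#' (default 2,482 nt, the third quartile of known tilapia 3'UTR lengths).
#'
#' @param mirna_seqs named character vector of mature miRNA sequences
#'   (5'->3', RNA or DNA alphabet).
#' @param utr_seqs named character vector of 3' regions (DNA).
#' @param seed_start,seed_length seed interval on the miRNA (default 2, 7).
#' @param region_length maximum scanned 3'-region length in nt.
#' @return data frame (mirna_id, gene_id, n_sites) of pairs with >= 1 site.
#' @export
find_seed_matches <- function(mirna_seqs, utr_seqs, seed_start = 2L,
                              seed_length = 7L, region_length = 2482L) {
  out <- list()
  for (m in names(mirna_seqs)) {
    seq <- chartr("Uu", "Tt", mirna_seqs[[m]])
    seed <- toupper(substr(seq, seed_start, seed_start + seed_length - 1L))
    site <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seed)))
    for (g in names(utr_seqs)) {
      region <- toupper(substr(utr_seqs[[g]], 1L, region_length))
      n <- Biostrings::countPattern(site, Biostrings::DNAString(region))
      if (n > 0)
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = m, gene_id = g, n_sites = n, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(mirna_id = character(), gene_id = character(),
                      n_sites = integer()))
  do.call(rbind, out)
}
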