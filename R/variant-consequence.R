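# Deletion detection between paralogous/allelic sequences, frameshift
# consequence prediction on a CDS model, and marker-sex concordance for
# linkage assignment.

#' Amplicon length difference
#'
#' The deletion size implied by two amplicon lengths (reference minus
#' variant), e.g. 1,048 bp vs 815 bp fragments implying a 233 bp deletion.
#'
#' @param reference_amplicon_length,variant_amplicon_length lengths in bp.
#' @return the difference in nt.
#' @export
amplicon_deletion_size <- function(reference_amplicon_length,
                                   variant_amplicon_length) {
  if (reference_amplicon_length <= 0 || variant_amplicon_length <= 0)
    fail("amplicon lengths must be positive")
  d <- reference_amplicon_length - variant_amplicon_length
  if (d < 0) fail("variant amplicon longer than reference")
  d
}

#' Infer a deletion from a reference/variant sequence pair
#'
#' Global alignment with affine gap penalties (defaults favor one long gap
#' over scattered gaps); the single largest gap run in the variant is
#' reported as the deletion, with point substitutions listed separately.
#'
#' @param reference,variant nucleotide strings (>= 50 nt; variant no longer
#'   than reference).
#' @param match,mismatch,gap_opening,gap_extension alignment parameters.
#' @param min_identity minimum percent identity of the aligned (non-gap)
#'   positions for the pair to be considered alignable.
#' @param ambiguity_ratio a second gap at least this fraction of the
#'   largest is reported as an ambiguity error.
#' @return list with \code{deletion_span} (1-based inclusive on the
#'   reference; NULL when no deletion), \code{deletion_length},
#'   \code{substitutions} (data frame position/ref/alt) and
#'   \code{identity}.
#' @export
infer_deletion <- function(reference, variant, match = 2, mismatch = -3,
                           gap_opening = 10, gap_extension = 0.5,
                           min_identity = 80, ambiguity_ratio = 0.5) {
  if (nchar(reference) < 50L || nchar(variant) < 50L)
    fail("sequences must be >= 50 nt")
  if (nchar(variant) > nchar(reference))
    fail("variant longer than reference")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(variant),
    subject = Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_opening, gapExtension = gap_extension)

  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- cumsum(sub != "-")

  # identity over aligned non-gap columns
  both <- pat != "-" & sub != "-"
  ident <- 100 * sum(pat[both] == sub[both]) / sum(both)
  if (ident < min_identity)
    fail("no alignable identity (%.1f%% < %g%%)", ident, min_identity)

  gaps <- rle(pat == "-")
  ends <- cumsum(gaps$lengths)
  starts <- ends - gaps$lengths + 1L
  gi <- which(gaps$values)
  if (length(gi) == 0L) {
    span <- NULL; len <- 0L
  } else {
    lens <- gaps$lengths[gi]
    o <- order(lens, decreasing = TRUE)
    if (length(o) > 1L && lens[o[2]] >= ambiguity_ratio * lens[o[1]])
      fail("ambiguous deletion: gap runs of length %s are comparable",
           paste(sort(lens[lens >= ambiguity_ratio * lens[o[1]]],
                      decreasing = TRUE), collapse = ", "))
    big <- gi[o[1]]
    span <- c(ref_pos[starts[big]], ref_pos[ends[big]])
    len <- gaps$lengths[gi[o[1]]]
  }
  mism <- which(both & pat != sub)
  subs <- data.frame(position = ref_pos[mism], ref = sub[mism],
                     alt = pat[mism], stringsAsFactors = FALSE)
  list(deletion_span = span, deletion_length = as.integer(len),
       substitutions = subs, identity = ident)
}

#' Build a CDS model
#'
#' @param sequence nucleotide string.
#' @param frame_offset 0-based position where translation starts.
#' @param stop_position 1-based position of the first nt of the annotated
#'   stop codon; defaults to the last codon of the sequence.
#' @param domain_spans named list of 1-based inclusive nt intervals of
#'   protein domains (e.g. \code{list("TGF-beta" = c(600, 858))}).
#' @return object of class \code{cds_model}.
#' @export
cds_model <- function(sequence, frame_offset = 0L, stop_position = NULL,
                      domain_spans = list()) {
  n <- nchar(sequence)
  if (is.null(stop_position)) stop_position <- n - 2L
  if ((stop_position - 1L - frame_offset) %% 3L != 0L)
    fail("stop_position is not in frame with frame_offset")
  for (d in domain_spans)
    if (d[1] < 1 || d[2] > n || d[1] > d[2])
      fail("domain span outside the sequence")
  structure(list(sequence = toupper(sequence),
                 frame_offset = as.integer(frame_offset),
                 stop_position = as.integer(stop_position),
                 domain_spans = domain_spans), class = "cds_model")
}

#' Predict the translation consequence of a deletion
#'
#' Translates the reference and the deleted sequence from the model's frame
#' offset with the standard genetic code. Reference residues with no
#' counterpart in the variant polypeptide are counted as deleted; variant
#' residues after the deletion junction, read in the (possibly shifted)
#' frame until the first stop, are counted as novel. A codon spanning the
#' junction counts its reference residue as deleted and its variant residue
#' as novel when they differ. A deletion whose length is not a multiple of
#' 3 is a frameshift; the annotated stop is flagged disrupted when it is no
#' longer reached in frame. Domain loss is reported as the overlap fraction
#' of each domain with the affected region (the deletion itself plus, for
#' frameshifts, everything downstream of the junction).
#'
#' @param cds a \code{\link{cds_model}}.
#' @param deletion_span 1-based inclusive interval on the reference, or
#'   NULL/zero-length for no deletion.
#' @return object of class \code{deletion_consequence}.
#' @export
predict_consequence <- function(cds, deletion_span) {
  stopifnot(inherits(cds, "cds_model"))
  seqn <- cds$sequence
  n <- nchar(seqn)
  empty <- is.null(deletion_span) ||
    (length(deletion_span) == 2L && deletion_span[2] < deletion_span[1])
  if (!empty && (deletion_span[1] < 1L || deletion_span[2] > n))
    fail("deletion outside the sequence")
  cod_start <- cds$frame_offset + 1L
  translated_end <- cds$stop_position + 2L
  out_of_cds <- !empty &&
    (deletion_span[2] < cod_start || deletion_span[1] > translated_end)

  ref_cds <- substr(seqn, cod_start, n)
  tr_ref <- codon_translate(ref_cds)
  if (tr_ref$hit_stop) {
    first_stop_nt <- cod_start + 3L * nchar(tr_ref$protein)
    if (first_stop_nt < cds$stop_position)
      fail("internal stop codon in reference at position %d", first_stop_nt)
  }
  del_len <- if (empty) 0L else deletion_span[2] - deletion_span[1] + 1L

  if (empty || out_of_cds) {
    res <- list(deletion_span = if (empty) NULL else deletion_span,
                deletion_length = del_len, frameshift = FALSE,
                deleted_residues = 0L, novel_residues = 0L,
                stop_disrupted = FALSE, runthrough = FALSE,
                domains_lost = list(), outside_cds = out_of_cds,
                reference_protein = tr_ref$protein,
                variant_protein = tr_ref$protein)
    class(res) <- "deletion_consequence"
    return(res)
  }

  var_seq <- paste0(substr(seqn, 1L, deletion_span[1] - 1L),
                    substr(seqn, deletion_span[2] + 1L, n))
  var_cds <- substr(var_seq, cod_start, nchar(var_seq))
  tr_var <- codon_translate(var_cds)
  p_ref <- tr_ref$protein; p_var <- tr_var$protein

  d <- protein_diff(p_ref, p_var)
  frameshift <- del_len %% 3L != 0L
  deleted <- d$deleted
  novel <- d$novel
  stop_disrupted <- frameshift ||
    deletion_span[2] >= cds$stop_position ||
    !tr_var$hit_stop

  affected <- if (frameshift) c(deletion_span[1], n)
  else deletion_span
  domains_lost <- lapply(cds$domain_spans, function(d) {
    ov <- max(0L, min(d[2], affected[2]) - max(d[1], affected[1]) + 1L)
    ov / (d[2] - d[1] + 1L)
  })
  domains_lost <- domains_lost[vapply(domains_lost, function(f) f > 0,
                                      logical(1))]

  res <- list(deletion_span = deletion_span, deletion_length = del_len,
              frameshift = frameshift, deleted_residues = deleted,
              novel_residues = novel, stop_disrupted = stop_disrupted,
              runthrough = !tr_var$hit_stop, domains_lost = domains_lost,
              outside_cds = FALSE, reference_protein = p_ref,
              variant_protein = p_var)
  class(res) <- "deletion_consequence"
  res
}

#' @export
print.deletion_consequence <- function(x, ...) {
  if (is.null(x$deletion_span)) {
    cat("No deletion: consequence-free\n")
    return(invisible(x))
  }
  cat(sprintf("Deletion %d-%d (%d nt)%s\n", x$deletion_span[1],
              x$deletion_span[2], x$deletion_length,
              if (x$outside_cds) " outside the translated region" else ""))
  cat(sprintf("  frameshift: %s; residues deleted: %d, novel: %d\n",
              x$frameshift, x$deleted_residues, x$novel_residues))
  cat(sprintf("  stop codon disrupted: %s%s\n", x$stop_disrupted,
              if (x$runthrough) " (no in-frame stop in variant)" else ""))
  if (length(x$domains_lost))
    for (d in names(x$domains_lost))
      cat(sprintf("  domain %s affected: %.0f%%\n", d,
                  100 * x$domains_lost[[d]]))
  invisible(x)
}

#' Marker-sex concordance
#'
#' Tests whether a marker (e.g. a male-specific gene duplication fragment
#' or a sex-linked microsatellite allele) segregates with phenotypic sex:
#' an individual is concordant when male and carrying the marker, or
#' female and lacking it. The chance probability is the one-sided binomial
#' tail at rate 1/2.
#'
#' @param records data frame (individual_id, sex, marker_present); records
#'   with missing sex or marker are excluded with a message.
#' @return list (n_concordant, n_total, rate, p_value, n_excluded).
#' @export
marker_sex_concordance <- function(records) {
  ok <- !is.na(records$sex) & !is.na(records$marker_present)
  if (sum(!ok) > 0)
    message(sprintf("marker_sex_concordance: %d incomplete records excluded",
                    sum(!ok)))
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) == 0L) fail("no complete records")
  conc <- (rec$sex == "male" & rec$marker_present) |
    (rec$sex == "female" & !rec$marker_present)
  n <- nrow(rec); k <- sum(conc)
  list(n_concordant = k, n_total = n, rate = k / n,
       p_value = stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE),
       n_excluded = sum(!ok))
}
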