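# Synthetic-data generators. Every downstream stage of the package can be
# exercised on the output of these functions, which plant known effects and
# return truth tables alongside the raw data. All generators are pure
# functions of their configuration, including the seed.

#' Configuration for a synthetic two-color microarray experiment
#'
#' Describes an experiment shaped like a 4 x 44k two-color array study of
#' monosex embryo pools: arrays grouped on slides, each array hybridizing a
#' male against a female cDNA pool of the same embryonic age (days post
#' fertilization, dpf), with dye swaps, sires nested within gender (all-male
#' broods from YY sires, all-female broods from sex-reversed XX sires) and
#' dams crossed over both brood types.
#'
#' @param n_probes number of probes on the array.
#' @param n_arrays number of two-color arrays (two samples each).
#' @param n_slides number of slides; must divide \code{n_arrays}.
#' @param n_sires_per_gender sires per gender (nested factor).
#' @param n_dams number of dams, crossed with sires of both genders.
#' @param dpf_levels embryonic ages sampled, in days post fertilization.
#' @param n_de_probes number of probes with a planted gender effect.
#' @param fc_range length-2 vector, lower/upper bound of planted fold
#'   changes (natural scale, both >= 1); planted values are log-uniform in
#'   this range with random direction.
#' @param noise_sd residual SD on the log2-intensity scale.
#' @param effect_sd SD of the random level effects of the nuisance factors
#'   (slide, array, dye, sire, dam, dpf); defaults to \code{noise_sd} so the
#'   linear model is non-trivially exercised.
#' @param dye_bias polynomial coefficients (intercept first) of the
#'   intensity-dependent dye bias added to M as a function of centered A,
#'   the target of within-array loess normalization.
#' @param baseline_mean,baseline_sd mean and SD of per-probe baseline
#'   log2 intensity.
#' @param seed integer seed.
#' @return an object of class \code{array_sim_config}.
#' @export
array_sim_config <- function(n_probes = 43210L, n_arrays = 28L, n_slides = 7L,
                             n_sires_per_gender = 2L, n_dams = 4L,
                             dpf_levels = c(2L, 5L, 9L),
                             n_de_probes = 59L, fc_range = c(1.2, 4.2),
                             noise_sd = 0.2, effect_sd = noise_sd,
                             dye_bias = c(0.3, -0.05),
                             baseline_mean = 8, baseline_sd = 1,
                             seed = 1L) {
  if (n_de_probes > n_probes) fail("n_de_probes (%d) exceeds n_probes (%d)",
                                   n_de_probes, n_probes)
  if (length(fc_range) != 2L || any(fc_range < 1) || fc_range[2] < fc_range[1])
    fail("fc_range must be (low, high) with low >= 1 and high >= low")
  if (n_arrays %% n_slides != 0L)
    fail("n_slides must divide n_arrays")
  if (n_sires_per_gender < 1L || n_dams < 1L || length(dpf_levels) < 1L)
    fail("all factor level counts must be >= 1")
  if (noise_sd < 0 || effect_sd < 0) fail("SDs must be non-negative")
  structure(list(n_probes = as.integer(n_probes),
                 n_arrays = as.integer(n_arrays),
                 n_slides = as.integer(n_slides),
                 n_sires_per_gender = as.integer(n_sires_per_gender),
                 n_dams = as.integer(n_dams), dpf_levels = dpf_levels,
                 n_de_probes = as.integer(n_de_probes), fc_range = fc_range,
                 noise_sd = noise_sd, effect_sd = effect_sd,
                 dye_bias = dye_bias, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = as.integer(seed)),
            class = "array_sim_config")
}

#' Generate a synthetic two-color microarray experiment
#'
#' Per-channel log2 intensities are the sum of a per-probe baseline, scalar
#' level effects of slide, array, dye, sire-within-gender, dam and dpf, the
#' planted gender effect (differentially expressed probes only, split
#' +/- half the log2 fold change between the female and male channel) and
#' Gaussian noise. An intensity-dependent dye bias (polynomial in centered
#' A) is then folded into the two channels so that within-array loess
#' normalization has a real trend to remove.
#'
#' @param cfg an \code{\link{array_sim_config}}.
#' @return an object of class \code{two_color_experiment}: list with raw
#'   (natural-scale) intensity matrices \code{R} and \code{G}
#'   (probes x arrays), an array-level \code{targets} frame (array, slide,
#'   dpf, dye assignment, sample ids per channel), the 56-row (in the
#'   default design) per-sample \code{design} sheet, and a \code{truth}
#'   table of planted probes with signed fold changes.
#' @export
generate_microarray_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "array_sim_config"))
  with_local_seed(cfg$seed, {
    nA <- cfg$n_arrays
    probes <- sprintf("P%05d", seq_len(cfg$n_probes))
    ndpf <- length(cfg$dpf_levels)

    # array layout: slides in order, dpf cycling, dye swap alternating
    arrays <- data.frame(
      array = sprintf("A%02d", seq_len(nA)),
      slide = sprintf("SL%d", rep(seq_len(cfg$n_slides),
                                  each = nA / cfg$n_slides)),
      dpf   = cfg$dpf_levels[(seq_len(nA) - 1L) %% ndpf + 1L],
      female_channel = ifelse(seq_len(nA) %% 2L == 1L, "red", "green"),
      stringsAsFactors = FALSE)

    # random family (sire x dam) assignment per sample avoids structural
    # confounding of the nested sire factor with array/dye parity
    sire_pick <- matrix(sample.int(cfg$n_sires_per_gender, 2L * nA,
                                   replace = TRUE), nA, 2L)
    dam_pick <- matrix(sample.int(cfg$n_dams, 2L * nA, replace = TRUE),
                       nA, 2L)
    mk_sample <- function(i, gender) {
      a <- arrays[i, ]
      gcol <- if (gender == "female") 1L else 2L
      sire <- paste0(toupper(substr(gender, 1, 1)), "sire",
                     sire_pick[i, gcol])
      dam <- paste0("dam", dam_pick[i, gcol])
      dye <- if ((gender == "female") == (a$female_channel == "red"))
        "Cy5" else "Cy3"
      data.frame(sample_id = sprintf("%s_%s", a$array, substr(gender, 1, 1)),
                 slide = a$slide, array = a$array, dye = dye,
                 gender = gender, sire = sire, dam = dam, dpf = a$dpf,
                 stringsAsFactors = FALSE)
    }
    design <- do.call(rbind, c(lapply(seq_len(nA), mk_sample, "female"),
                               lapply(seq_len(nA), mk_sample, "male")))
    rownames(design) <- NULL
    arrays$red_sample <- ifelse(arrays$female_channel == "red",
                                paste0(arrays$array, "_f"),
                                paste0(arrays$array, "_m"))
    arrays$green_sample <- ifelse(arrays$female_channel == "red",
                                  paste0(arrays$array, "_m"),
                                  paste0(arrays$array, "_f"))

    # scalar level effects for nuisance factors
    eff <- function(levels) stats::setNames(
      stats::rnorm(length(levels), 0, cfg$effect_sd), levels)
    slide_e <- eff(unique(design$slide)); array_e <- eff(unique(design$array))
    dye_e <- eff(unique(design$dye)); sire_e <- eff(unique(design$sire))
    dam_e <- eff(unique(design$dam))
    dpf_e <- eff(as.character(cfg$dpf_levels))

    baseline <- stats::rnorm(cfg$n_probes, cfg$baseline_mean, cfg$baseline_sd)

    # planted gender effects (log2 female - male), random direction
    lfc <- numeric(cfg$n_probes)
    de_idx <- integer(0)
    if (cfg$n_de_probes > 0L) {
      de_idx <- sort(sample.int(cfg$n_probes, cfg$n_de_probes))
      mag <- exp(stats::runif(cfg$n_de_probes,
                              log(cfg$fc_range[1]), log(cfg$fc_range[2])))
      sgn <- sample(c(-1, 1), cfg$n_de_probes, replace = TRUE)
      lfc[de_idx] <- sgn * log2(mag)
    }
    truth <- data.frame(probe_id = probes[de_idx],
                        lfc = lfc[de_idx], fc = 2^lfc[de_idx],
                        direction = ifelse(lfc[de_idx] > 0,
                                           "up-in-female", "up-in-male"),
                        stringsAsFactors = FALSE)

    sample_shift <- slide_e[design$slide] + array_e[design$array] +
      dye_e[design$dye] + sire_e[design$sire] + dam_e[design$dam] +
      dpf_e[as.character(design$dpf)]
    names(sample_shift) <- design$sample_id
    gender_half <- ifelse(design$gender == "female", 0.5, -0.5)
    names(gender_half) <- design$sample_id

    # per-sample log2 intensity matrix
    Y <- matrix(baseline, cfg$n_probes, nrow(design)) +
      matrix(sample_shift, cfg$n_probes, nrow(design), byrow = TRUE) +
      outer(lfc, gender_half[design$sample_id]) +
      matrix(stats::rnorm(cfg$n_probes * nrow(design), 0, cfg$noise_sd),
             cfg$n_probes, nrow(design))
    colnames(Y) <- design$sample_id
    rownames(Y) <- probes

    Rlog <- Y[, arrays$red_sample, drop = FALSE]
    Glog <- Y[, arrays$green_sample, drop = FALSE]
    A <- (Rlog + Glog) / 2
    bias <- matrix(0, nrow(A), ncol(A))
    ac <- A - cfg$baseline_mean
    for (k in seq_along(cfg$dye_bias))
      bias <- bias + cfg$dye_bias[k] * ac^(k - 1L)
    M <- (Rlog - Glog) + bias
    R <- 2^(A + M / 2); G <- 2^(A - M / 2)
    colnames(R) <- colnames(G) <- arrays$array
    rownames(R) <- rownames(G) <- probes

    structure(list(R = R, G = G, targets = arrays, design = design,
                   truth = truth, cfg = cfg),
              class = "two_color_experiment")
  })
}

#' @export
print.two_color_experiment <- function(x, ...) {
  cat(sprintf("Two-color experiment: %d probes x %d arrays (%d samples)\n",
              nrow(x$R), ncol(x$R), nrow(x$design)))
  cat(sprintf("  planted DE probes: %d (fold change %.3g-%.3g)\n",
              nrow(x$truth),
              if (nrow(x$truth)) min(x$truth$fc) else NA,
              if (nrow(x$truth)) max(x$truth$fc) else NA))
  invisible(x)
}

#' Configuration for synthetic small-RNA libraries
#'
#' Emulates six sequencing libraries (2 genders x 3 dpf) of mature/star
#' miRNA counts at a depth comparable to real embryo libraries (tens of
#' millions of reads). Counts are negative binomial around library-scaled
#' expected RPM; a shared log-normal biological fluctuation per
#' (miRNA, library) makes the gender log-ratio distribution approximately
#' normal, as observed for real deviations. Planted miRNAs receive a
#' multiplicative female-side offset of \code{effect_sd_units} null SDs at
#' their designated dpf.
#'
#' @param n_mirnas number of mature/star sequences.
#' @param n_timepoints number of embryonic ages (default 3: 2, 5, 9 dpf).
#' @param library_sizes reads per library (recycled to
#'   \code{2 * n_timepoints} libraries).
#' @param n_de number of planted sex-biased miRNAs (default 9); the planted
#'   set is structured so that (when \code{n_de >= 9}) two are biased at all
#'   timepoints, two at two timepoints and the rest at one.
#' @param effect_sd_units planted deviation in multiples of the null SD of
#'   the gender log2 ratio.
#' @param baseline_dispersion negative-binomial dispersion (0 = Poisson).
#' @param abundance_mean,abundance_sd mean and SD of log2 expected RPM.
#' @param bio_sd SD (log2) of the shared per-library biological fluctuation.
#' @param seed integer seed.
#' @return an object of class \code{mirna_sim_config}.
#' @export
mirna_sim_config <- function(n_mirnas = 700L, n_timepoints = 3L,
                             library_sizes = 2e7, n_de = 9L,
                             effect_sd_units = 8, baseline_dispersion = 0.02,
                             abundance_mean = 5, abundance_sd = 1.5,
                             bio_sd = 0.35, seed = 1L) {
  if (n_de > n_mirnas) fail("n_de exceeds n_mirnas")
  if (any(library_sizes <= 0)) fail("library_sizes must be > 0")
  if (effect_sd_units <= 0) fail("effect_sd_units must be > 0")
  if (baseline_dispersion < 0) fail("baseline_dispersion must be >= 0")
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_timepoints = as.integer(n_timepoints),
                 library_sizes = rep_len(library_sizes, 2L * n_timepoints),
                 n_de = as.integer(n_de), effect_sd_units = effect_sd_units,
                 baseline_dispersion = baseline_dispersion,
                 abundance_mean = abundance_mean, abundance_sd = abundance_sd,
                 bio_sd = bio_sd, seed = as.integer(seed)),
            class = "mirna_sim_config")
}

# Assign planted miRNAs to timepoints: first two at all timepoints, next two
# at two timepoints, the remainder at a single (cycling) timepoint.
planted_timepoints <- function(n_de, n_tp) {
  out <- vector("list", n_de)
  for (i in seq_len(n_de)) {
    out[[i]] <- if (i <= 2L) seq_len(n_tp)
    else if (i <= 4L) sort(((i + seq_len(2L)) %% n_tp) + 1L)
    else ((i - 5L) %% n_tp) + 1L
  }
  out
}

#' Generate synthetic small-RNA count libraries
#'
#' @param cfg a \code{\link{mirna_sim_config}}.
#' @return an object of class \code{mirna_counts}: list with integer
#'   \code{counts} (miRNAs x 6 libraries), \code{library_sizes}, a library
#'   \code{meta} frame (library_id, gender, dpf) and the \code{truth} table
#'   of planted miRNAs (mirna_id, dpf, planted log2 offset).
#' @export
generate_mirna_libraries <- function(cfg) {
  stopifnot(inherits(cfg, "mirna_sim_config"))
  with_local_seed(cfg$seed, {
    dpf <- c(2L, 5L, 9L)[seq_len(cfg$n_timepoints)]
    meta <- data.frame(
      library_id = paste0(rep(c("M", "F"), cfg$n_timepoints),
                          rep(dpf, each = 2L)),
      gender = rep(c("male", "female"), cfg$n_timepoints),
      dpf = rep(dpf, each = 2L), stringsAsFactors = FALSE)
    libsize <- stats::setNames(cfg$library_sizes, meta$library_id)
    ids <- sprintf("mir-%04d", seq_len(cfg$n_mirnas))

    base_rpm <- 2^stats::rnorm(cfg$n_mirnas, cfg$abundance_mean,
                               cfg$abundance_sd)
    # analytic null SD of the gender log2 ratio (delta method on the
    # negative-binomial + shared biological components)
    mu_typ <- base_rpm * mean(libsize) / 1e6
    var_i <- 2 * cfg$bio_sd^2 +
      (1 / log(2)^2) * (2 / mu_typ + 2 * cfg$baseline_dispersion)
    sd_null <- sqrt(mean(var_i))

    slots <- planted_timepoints(cfg$n_de, cfg$n_timepoints)
    truth <- do.call(rbind, lapply(seq_len(cfg$n_de), function(i)
      data.frame(mirna_id = ids[i], dpf = dpf[slots[[i]]],
                 log2_offset = cfg$effect_sd_units * sd_null,
                 stringsAsFactors = FALSE)))
    if (is.null(truth))
      truth <- data.frame(mirna_id = character(), dpf = integer(),
                          log2_offset = numeric())

    counts <- matrix(0, cfg$n_mirnas, nrow(meta),
                     dimnames = list(ids, meta$library_id))
    for (j in seq_len(nrow(meta))) {
      mu <- base_rpm * libsize[j] / 1e6 *
        2^stats::rnorm(cfg$n_mirnas, 0, cfg$bio_sd)
      if (meta$gender[j] == "female") {
        pl <- match(truth$mirna_id[truth$dpf == meta$dpf[j]], ids)
        mu[pl] <- mu[pl] * 2^(cfg$effect_sd_units * sd_null)
      }
      counts[, j] <- if (cfg$baseline_dispersion > 0)
        stats::rnbinom(cfg$n_mirnas, mu = mu,
                       size = 1 / cfg$baseline_dispersion)
      else stats::rpois(cfg$n_mirnas, mu)
    }
    storage.mode(counts) <- "integer"
    structure(list(counts = counts, library_sizes = libsize, meta = meta,
                   truth = truth, cfg = cfg), class = "mirna_counts")
  })
}

#' @export
print.mirna_counts <- function(x, ...) {
  cat(sprintf("Small-RNA count set: %d miRNAs x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  planted sex-biased miRNAs: %d\n",
              length(unique(x$truth$mirna_id))))
  invisible(x)
}

#' Configuration for a synthetic CDS/deletion pair
#'
#' @param cds_length CDS length in nt, a multiple of 3 (includes start and
#'   stop codons).
#' @param deletion_start 1-based first deleted nucleotide.
#' @param deletion_length deletion length in nt.
#' @param domain_span 1-based inclusive nt interval of a protein-domain
#'   coding region (e.g. a TGF-beta domain), or NULL.
#' @param seed integer seed.
#' @return an object of class \code{seq_sim_config}.
#' @export
seq_sim_config <- function(cds_length = 1048L %/% 3L * 3L,
                           deletion_start = 600L, deletion_length = 233L,
                           domain_span = NULL, seed = 1L) {
  if (cds_length %% 3L != 0L || cds_length < 9L)
    fail("cds_length must be a multiple of 3 and >= 9")
  if (deletion_start < 1L ||
      deletion_start + deletion_length - 1L > cds_length)
    fail("deletion interval outside the sequence")
  if (!is.null(domain_span) &&
      (length(domain_span) != 2L || domain_span[1] < 1 ||
         domain_span[2] > cds_length || domain_span[1] > domain_span[2]))
    fail("domain_span must be a 1-based inclusive interval inside the CDS")
  structure(list(cds_length = as.integer(cds_length),
                 deletion_start = as.integer(deletion_start),
                 deletion_length = as.integer(deletion_length),
                 domain_span = domain_span, seed = as.integer(seed)),
            class = "seq_sim_config")
}

# Translate an in-frame nucleotide string codon by codon with the standard
# genetic code, stopping at (and excluding) the first stop codon. Returns
# list(protein, hit_stop). Used both by the generator truth and as a slow
# reference in tests.
codon_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  aa <- character(n)
  code <- Biostrings::GENETIC_CODE
  hit <- FALSE
  for (i in seq_len(n)) {
    cod <- substr(nt, 3L * i - 2L, 3L * i)
    a <- unname(code[cod])
    if (is.na(a)) a <- "X"
    if (a == "*") { aa <- aa[seq_len(i - 1L)]; hit <- TRUE; break }
    aa[i] <- a
  }
  list(protein = paste(aa, collapse = ""), hit_stop = hit)
}

# Residue-level diff of two polypeptides: residues outside the longest
# common prefix and the longest common suffix of the remainders have no
# counterpart. Returns counts of reference residues lost (deleted) and
# variant residues gained (novel).
protein_diff <- function(p_ref, p_var) {
  nr <- nchar(p_ref); nv <- nchar(p_var)
  k <- 0L
  while (k < min(nr, nv) &&
         substr(p_ref, k + 1L, k + 1L) == substr(p_var, k + 1L, k + 1L))
    k <- k + 1L
  s <- 0L
  while (s < min(nr, nv) - k &&
         substr(p_ref, nr - s, nr - s) == substr(p_var, nv - s, nv - s))
    s <- s + 1L
  list(deleted = nr - k - s, novel = nv - k - s)
}

#' Generate a reference CDS and a deletion variant
#'
#' Builds a random CDS (ATG ... internal sense codons ... stop) and the
#' variant with the configured interval excised. The returned truth
#' consequence is computed by brute-force translation of both sequences and
#' comparison of the proteins, independently of
#' \code{\link{predict_consequence}}.
#'
#' @param cfg a \code{\link{seq_sim_config}}.
#' @return list with \code{reference}, \code{variant} (character nucleotide
#'   strings), \code{deletion_span}, and \code{truth} (frameshift flag,
#'   deleted/novel residue counts, stop_disrupted flag).
#' @export
generate_cds_with_deletion <- function(cfg) {
  stopifnot(inherits(cfg, "seq_sim_config"))
  with_local_seed(cfg$seed, {
    n_codons <- cfg$cds_length %/% 3L
    stops <- c("TAA", "TAG", "TGA")
    all_cod <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T")), 1, paste,
                     collapse = "")
    sense <- setdiff(all_cod, stops)
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    ref <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")

    span <- c(cfg$deletion_start,
              cfg$deletion_start + cfg$deletion_length - 1L)
    var <- paste0(substr(ref, 1L, span[1] - 1L),
                  substr(ref, span[2] + 1L, nchar(ref)))

    tr_ref <- codon_translate(ref)
    tr_var <- codon_translate(var)
    d <- protein_diff(tr_ref$protein, tr_var$protein)
    truth <- list(
      deletion_span = span, deletion_length = cfg$deletion_length,
      frameshift = cfg$deletion_length %% 3L != 0L,
      deleted_residues = d$deleted,
      novel_residues = d$novel,
      stop_disrupted = !tr_var$hit_stop ||
        (cfg$deletion_length %% 3L != 0L) ||
        span[2] >= nchar(ref) - 2L,
      runthrough = !tr_var$hit_stop)
    list(reference = ref, variant = var, deletion_span = span, truth = truth,
         cfg = cfg)
  })
}

#' Generate a qPCR Ct table with a dilution series
#'
#' Ct values follow the linear standard-curve model
#' \code{Ct = intercept + slope * log10(quantity) + noise}.
#'
#' @param slope Ct change per log10 quantity (negative for an amplifying
#'   assay; -3.3219 corresponds to 100 percent efficiency).
#' @param intercept Ct at quantity 1.
#' @param quantities vector of template quantities (> 0).
#' @param replicates technical replicates per quantity.
#' @param ct_noise_sd SD of Gaussian Ct noise.
#' @param seed integer seed.
#' @return data frame (quantity, replicate, Ct).
#' @export
generate_qpcr_run <- function(slope, intercept, quantities, replicates = 3L,
                              ct_noise_sd = 0, seed = 1L) {
  if (slope == 0) fail("slope must be non-zero")
  if (any(quantities <= 0)) fail("quantities must be positive")
  with_local_seed(seed, {
    q <- rep(quantities, each = replicates)
    data.frame(quantity = q, replicate = rep(seq_len(replicates),
                                             length(quantities)),
               Ct = intercept + slope * log10(q) +
                 stats::rnorm(length(q), 0, ct_noise_sd))
  })
}

#' Generate a genotype/sex table for marker concordance testing
#'
#' @param n_male_carriers males carrying the marker (concordant).
#' @param n_female_noncarriers females lacking the marker (concordant).
#' @param n_discordant individuals with sex/marker mismatch, split as evenly
#'   as possible between male non-carriers and female carriers.
#' @param seed integer seed; rows are shuffled deterministically.
#' @return data frame (individual_id, sex, marker_present).
#' @export
generate_genotype_table <- function(n_male_carriers, n_female_noncarriers,
                                    n_discordant = 0L, seed = 1L) {
  counts <- c(n_male_carriers, n_female_noncarriers, n_discordant)
  if (any(counts < 0)) fail("counts must be >= 0")
  if (sum(counts) == 0) fail("at least one individual required")
  n_md <- n_discordant %/% 2L
  n_fd <- n_discordant - n_md
  tab <- data.frame(
    sex = c(rep("male", n_male_carriers), rep("female", n_female_noncarriers),
            rep("male", n_md), rep("female", n_fd)),
    marker_present = c(rep(TRUE, n_male_carriers),
                       rep(FALSE, n_female_noncarriers),
                       rep(FALSE, n_md), rep(TRUE, n_fd)),
    stringsAsFactors = FALSE)
  with_local_seed(seed, {
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
  })
  tab <- cbind(individual_id = sprintf("ind%03d", seq_len(nrow(tab))), tab)
  rownames(tab) <- NULL
  tab
}

#' Write a FASTA file wrapped at 60 columns
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
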