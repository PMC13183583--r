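# Synthetic transcription-factor datasets with planted disorder structure.

#' Simulation settings for a synthetic TF disorder dataset
#'
#' Each synthetic protein gets a length, an NLS placed uniformly along the
#' sequence, and a per-residue disorder profile equal to a clipped
#' protein-specific baseline plus an additive elevation
#' `region_disorder_delta` inside the NLS-to-closest-terminus region plus
#' Gaussian residue noise. Scores are clipped to [0, 1] (1 = fully
#' disordered). The baseline varies between proteins
#' (`baseline_disorder_sd`), mirroring the broad spread of overall
#' disorder across real transcription factors; without that spread the
#' per-protein mean disorder would be nearly constant across a dataset,
#' which real surveys never are. Defaults give a survey-sized dataset
#' (300 proteins) with human-TF-like lengths and a moderate planted
#' elevation.
#'
#' @param n_proteins number of records.
#' @param length_range integer range of sequence lengths, residues.
#' @param nls_length_range integer range of NLS lengths, residues.
#' @param baseline_disorder_mean mean baseline disorder level in [0, 1].
#' @param baseline_disorder_sd between-protein standard deviation of the
#'   baseline (Gaussian, clipped with the profile).
#' @param region_disorder_delta additive elevation inside the terminal
#'   region (may be 0 for null datasets; baseline + delta must stay within
#'   [0, 1] after clipping).
#' @param noise_sd per-residue score noise (Gaussian, before clipping).
#' @param with_sequence also generate random amino-acid sequences (off by
#'   default; the survey itself runs on scores and intervals).
#' @param seed integer seed.
#' @return object of class `tf_sim_spec`.
#' @export
tf_sim_spec <- function(n_proteins = 300,
                        length_range = c(150, 1200),
                        nls_length_range = c(7, 20),
                        baseline_disorder_mean = 0.45,
                        baseline_disorder_sd = 0.1,
                        region_disorder_delta = 0.15,
                        noise_sd = 0.12,
                        with_sequence = FALSE,
                        seed = 1L) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (any(length_range < 1) || length_range[1] > length_range[2])
    stop("invalid length_range")
  if (any(nls_length_range < 1) ||
      nls_length_range[2] >= length_range[1])
    stop("invalid nls_length_range")
  if (baseline_disorder_mean < 0 || baseline_disorder_mean > 1)
    stop("baseline_disorder_mean must be in [0, 1]")
  if (baseline_disorder_sd < 0 || noise_sd < 0)
    stop("baseline_disorder_sd and noise_sd must be >= 0")
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 nls_length_range = nls_length_range,
                 baseline_disorder_mean = baseline_disorder_mean,
                 baseline_disorder_sd = baseline_disorder_sd,
                 region_disorder_delta = region_disorder_delta,
                 noise_sd = noise_sd,
                 with_sequence = isTRUE(with_sequence),
                 seed = as.integer(seed)),
            class = "tf_sim_spec")
}

#' Build a transcription-factor record
#'
#' @param id accession or name.
#' @param length sequence length, residues.
#' @param nls NLS interval `c(start, end)`, 1-based inclusive.
#' @param disorder per-residue disorder scores in [0, 1], one per residue.
#' @param nls_score predictor score of the NLS (optional).
#' @param sequence amino-acid string (optional; scores may stand alone).
#' @return object of class `tf_record`.
#' @export
tf_record <- function(id, length, nls, disorder, nls_score = NA_real_,
                      sequence = NULL) {
  length <- as.integer(length)
  if (!is.null(sequence) && nchar(sequence) != length)
    stop("sequence length mismatch")
  if (length(disorder) != length)
    stop("disorder profile must have one score per residue")
  if (any(disorder < 0 | disorder > 1)) stop("disorder scores must be in [0, 1]")
  if (!is.null(nls)) {
    nls <- as.integer(nls)
    if (length(nls) != 2 || nls[1] < 1 || nls[2] > length || nls[1] > nls[2])
      stop("invalid NLS interval")
  }
  structure(list(id = id, length = length, nls = nls,
                 nls_score = nls_score, disorder = disorder,
                 sequence = sequence), class = "tf_record")
}

#' Generate a synthetic TF dataset with known ground truth
#'
#' @param spec a [tf_sim_spec()].
#' @return list of [tf_record()]s; each carries a `truth` attribute with
#'   the planted region boundaries (`region`), side, and delta.
#' @examples
#' recs <- gen_tf_dataset(tf_sim_spec(n_proteins = 5, seed = 2))
#' recs[[1]]$nls
#' @export
gen_tf_dataset <- function(spec) {
  stopifnot(inherits(spec, "tf_sim_spec"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(spec$seed, lapply(seq_len(spec$n_proteins), function(i) {
    L <- sample(spec$length_range[1]:spec$length_range[2], 1)
    nl <- sample(spec$nls_length_range[1]:spec$nls_length_range[2], 1)
    s <- sample(1:(L - nl + 1), 1)
    nls <- c(s, s + nl - 1L)
    reg <- .terminal_region_interval(L, nls)
    base <- spec$baseline_disorder_mean +
      if (spec$baseline_disorder_sd > 0)
        stats::rnorm(1, sd = spec$baseline_disorder_sd) else 0
    prof <- rep(base, L)
    prof[reg$range[1]:reg$range[2]] <-
      prof[reg$range[1]:reg$range[2]] + spec$region_disorder_delta
    if (spec$noise_sd > 0) prof <- prof + stats::rnorm(L, sd = spec$noise_sd)
    prof <- pmin(pmax(prof, 0), 1)
    rec <- tf_record(id = sprintf("TF%04d", i), length = L, nls = nls,
                     disorder = prof, nls_score = stats::runif(1, 2, 12),
                     sequence = if (spec$with_sequence)
                       paste(sample(aa, L, replace = TRUE), collapse = "")
                     else NULL)
    attr(rec, "truth") <- list(region = reg$range, side = reg$side,
                               delta = spec$region_disorder_delta)
    rec
  }))
}
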