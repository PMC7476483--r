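# Spectrum data model and the evaluation function.
#
# A 1H line spectrum is a plain numeric vector of chemical shifts (ppm), one
# entry per proton; peak degeneracy is kept, not merged, and the order never
# matters (all comparisons treat the vector as a multiset).

WD_ZERO_TOL <- 1e-12  # distances below this are treated as exact matches

validate_spectrum <- function(x, what = "spectrum") {
  if (length(x) == 0L) stop_empty_input(what)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_domain(sprintf("%s must be a numeric vector of finite shifts", what))
  invisible(x)
}

#' Read a line spectrum from a text file
#'
#' One chemical shift (ppm) per line; `#` starts a comment; blank lines are
#' ignored. Order is preserved as read.
#'
#' @param path Path to the file.
#' @return Numeric vector of shifts.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(stripped))
  if (length(keep) == 0L) stop_empty_input(sprintf("spectrum file '%s'", path))
  values <- suppressWarnings(as.numeric(stripped[keep]))
  if (anyNA(values)) {
    bad <- keep[which(is.na(values))[1]]
    stop_nmrts("nmrts_parse_error",
               sprintf("cannot parse shift on line %d of '%s': '%s'",
                       bad, path, stripped[bad == keep][1]),
               line = bad)
  }
  values
}

#' Write a line spectrum to a text file
#'
#' Shifts are written sorted descending (NMR convention), four decimal
#' places, one per line.
#'
#' @param shifts Numeric vector of chemical shifts (ppm).
#' @param path Output path.
#' @export
write_spectrum <- function(shifts, path) {
  validate_spectrum(shifts)
  writeLines(sprintf("%.4f", sort(shifts, decreasing = TRUE)), path)
  invisible(path)
}

#' First Wasserstein distance between two line spectra
#'
#' Each spectrum is treated as an empirical distribution placing mass `1/n`
#' on each of its `n` shifts, so molecules with different proton counts are
#' comparable (the hydrogen-count mismatch is punished separately by the
#' atom penalty, not by the distance). The distance is computed in closed
#' form as the integral of the absolute difference of the two quantile
#' functions, evaluated exactly over the merged set of probability
#' breakpoints.
#'
#' @param a,b Numeric vectors of chemical shifts (ppm), non-empty.
#' @return The distance in ppm (symmetric, zero iff the normalized multisets
#'   coincide).
#' @export
wasserstein_distance <- function(a, b) {
  validate_spectrum(a, "spectrum a")
  validate_spectrum(b, "spectrum b")
  a <- sort(a); b <- sort(b)
  na <- length(a); nb <- length(b)
  qs <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  widths <- diff(c(0, qs))
  mids <- qs - widths / 2
  ia <- pmin(na, ceiling(mids * na))
  ib <- pmin(nb, ceiling(mids * nb))
  sum(widths * abs(a[ia] - b[ib]))
}

#' Atom-count penalty
#'
#' The absolute difference in carbon counts plus the absolute difference in
#' hydrogen counts between a generated molecule and the target.
#'
#' @param generated_c,generated_h Counts of the generated molecule.
#' @param target_c,target_h Counts of the target molecule.
#' @return Non-negative integer penalty.
#' @export
atom_penalty <- function(generated_c, generated_h, target_c, target_h) {
  counts <- c(generated_c, generated_h, target_c, target_h)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_domain("atom counts must be non-negative integers")
  abs(generated_c - target_c) + abs(generated_h - target_h)
}

#' Evaluation score of a candidate molecule
#'
#' `1 - tanh(wd + alpha * penalty)`: 1.0 for an exact spectral and
#' atom-count match, decaying towards 0 as the Wasserstein distance and the
#' atom-count penalty grow. Strictly decreasing in both arguments for
#' `alpha > 0`. Distances below `1e-12` ppm are treated as zero so an exact
#' match scores exactly 1.0.
#'
#' @param wd Wasserstein distance in ppm (>= 0; vectorized).
#' @param penalty Non-negative atom-count penalty (vectorized).
#' @param alpha Penalty strength in ppm-equivalents per mismatched atom.
#' @return Score(s) in `[0, 1]`.
#' @export
evaluation_score <- function(wd, penalty = 0, alpha = 0.1) {
  if (any(!is.finite(wd)) || any(wd < 0))
    stop_domain("wasserstein distance must be finite and non-negative")
  if (any(penalty < 0) || alpha < 0)
    stop_domain("penalty and alpha must be non-negative")
  wd <- ifelse(wd < WD_ZERO_TOL, 0, wd)
  1 - tanh(wd + alpha * penalty)
}

#' Assemble a score result
#'
#' Container for one candidate evaluation: Wasserstein distance, atom-count
#' penalty, final score and the candidate's canonical SMILES. Failed
#' evaluations carry a `reason` code and score 0.
#'
#' @param candidate_canonical Canonical SMILES, or `NA` for unparseable input.
#' @param wasserstein_distance,atom_penalty,score Components of the evaluation.
#' @param reason `NA` for success, otherwise a failure code such as
#'   `"invalid_smiles"`.
#' @return A list of class `score_result`.
#' @export
score_result <- function(candidate_canonical, wasserstein_distance,
                         atom_penalty, score, reason = NA_character_) {
  structure(list(candidate_canonical = candidate_canonical,
                 wasserstein_distance = wasserstein_distance,
                 atom_penalty = atom_penalty,
                 score = score,
                 reason = reason),
            class = "score_result")
}

failed_score_result <- function(reason, candidate_canonical = NA_character_) {
  score_result(candidate_canonical, NA_real_, NA_integer_, 0, reason)
}

#' @export
print.score_result <- function(x, ...) {
  if (is.na(x$reason)) {
    cat(sprintf("<score_result> %s  score=%.4f  wd=%.4f ppm  penalty=%d\n",
                x$candidate_canonical, x$score, x$wasserstein_distance,
                as.integer(x$atom_penalty)))
  } else {
    cat(sprintf("<score_result> failed (%s) score=0\n", x$reason))
  }
  invisible(x)
}
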