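# Pluggable spectrum-prediction oracle.
#
# The original workflow scores candidates with a DFT-computed (GIAO,
# TMS-referenced) line spectrum. That computation is treated here as a black
# box behind a predictor interface: any object with a deterministic
# `predict(canonical_smiles) -> shifts` function will do. Two
# implementations are bundled: a deterministic surrogate based on typical
# 1H shift ranges per proton environment (for desk-scale runs and tests)
# and a file-exchange adapter for external quantum-chemistry backends.

#' Default shift table of the surrogate predictor
#'
#' Base chemical shifts (ppm) per proton environment class and additive
#' increments for neighboring groups. The values are modeling constants
#' chosen inside typical 1H ranges (aliphatic CH around 0.9 ppm, aromatic
#' CH around 7.2 ppm, aldehyde CH around 9.6 ppm, O-H/N-H in 1-5 ppm); they
#' are not fitted to any reference data and can be overridden.
#'
#' @return A list with elements `base`, `increment` and `jitter_amplitude`.
#' @export
surrogate_shift_table <- function() {
  list(
    base = c(aliphatic_ch = 0.90,   # sp3 C-H
             alkyne_ch    = 2.40,   # C-H on triple-bonded carbon
             vinylic_ch   = 5.60,   # C-H on non-ring double-bonded carbon
             aromatic_ch  = 7.20,   # C-H on ring sp2 carbon
             aldehyde_ch  = 9.60,   # C-H on carbonyl carbon
             hydroxyl     = 3.00,   # O-H
             amine        = 1.80),  # N-H
    increment = c(oxy_neighbor = 2.40,   # O bonded to the carbon bearing H
                  aza_neighbor = 1.50,   # N bonded to that carbon
                  unsat_neighbor = 0.70, # sp2/sp carbon bonded to that carbon
                  acyl_oxygen = 8.50,    # O-H whose O sits on a carbonyl C
                                         # (carboxylic protons around 11.5)
                  aryl_oxygen = 1.80,    # O-H whose O sits on an aromatic C
                  aryl_nitrogen = 1.60,  # N-H whose N sits on an aromatic C
                  amide_nitrogen = 4.00),# N-H whose N sits on a carbonyl C
    jitter_amplitude = 0.30
  )
}

# Deterministic non-cryptographic string hash (polynomial, mod 2^31 - 1).
stable_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  h
}

atom_descriptor <- function(g, i) {
  paste0(g$elements[i], if (g$in_ring[i]) "r" else "")
}

# Radius-2 environment fingerprint of hydrogen h (attached to heavy atom a):
# class of a, then the sorted multiset of (bond order, neighbor descriptor,
# sorted second-shell descriptors) over a's other neighbors. Symmetric
# protons share a fingerprint; the fingerprint seeds the deterministic
# jitter so distinct environments get distinguishable shifts.
environment_fingerprint <- function(g, h, heavy) {
  shell1 <- character()
  for (y in graph_neighbors(g, heavy)) {
    if (y == h) next
    second <- character()
    for (z in graph_neighbors(g, y)) {
      if (z == heavy) next
      second <- c(second, paste0(graph_order(g, y, z), atom_descriptor(g, z)))
    }
    shell1 <- c(shell1, paste0(graph_order(g, heavy, y), ":",
                               atom_descriptor(g, y), "{",
                               paste(sort(second, method = "radix"),
                                     collapse = ""), "}"))
  }
  # radix sort: fingerprints (hence jitters) must not depend on the locale
  paste(atom_descriptor(g, heavy),
        paste(sort(shell1, method = "radix"), collapse = ","), sep = "|")
}

carbon_is_unsaturated <- function(g, i) {
  g$elements[i] == "C" && any(g$bond_order[[i]] >= 2L)
}

proton_base_shift <- function(g, h, heavy, table) {
  el <- g$elements[heavy]
  nb <- setdiff(graph_neighbors(g, heavy), h)
  ords <- vapply(nb, function(j) graph_order(g, heavy, j), integer(1))
  base <- table$base; inc <- table$increment
  if (el == "O") {
    shift <- base[["hydroxyl"]]
    for (j in nb) {
      if (g$elements[j] != "C") next
      if (any(g$elements[g$adj[[j]]] == "O" &
              g$bond_order[[j]] == 2L)) shift <- shift + inc[["acyl_oxygen"]]
      else if (g$in_ring[j] && carbon_is_unsaturated(g, j))
        shift <- shift + inc[["aryl_oxygen"]]
    }
    return(shift)
  }
  if (el == "N") {
    shift <- base[["amine"]]
    for (j in nb) {
      if (g$elements[j] != "C") next
      if (any(g$elements[g$adj[[j]]] == "O" &
              g$bond_order[[j]] == 2L)) shift <- shift + inc[["amide_nitrogen"]]
      else if (g$in_ring[j] && carbon_is_unsaturated(g, j))
        shift <- shift + inc[["aryl_nitrogen"]]
    }
    return(shift)
  }
  # hydrogen on carbon
  dbl_o <- any(g$elements[nb] == "O" & ords == 2L)
  dbl_cn <- any(g$elements[nb] %in% c("C", "N") & ords == 2L)
  triple <- any(ords == 3L)
  if (dbl_o) return(base[["aldehyde_ch"]])
  if (dbl_cn && g$in_ring[heavy]) return(base[["aromatic_ch"]])
  if (dbl_cn) return(base[["vinylic_ch"]])
  if (triple) return(base[["alkyne_ch"]])
  shift <- base[["aliphatic_ch"]]
  for (j in nb) {
    if (g$elements[j] == "O") shift <- shift + inc[["oxy_neighbor"]]
    else if (g$elements[j] == "N") shift <- shift + inc[["aza_neighbor"]]
    else if (carbon_is_unsaturated(g, j)) shift <- shift + inc[["unsat_neighbor"]]
  }
  shift
}

#' Surrogate prediction of a 1H line spectrum
#'
#' Deterministic stand-in for a quantum-chemical shift computation: each
#' proton's shift is a base value for its environment class (aliphatic /
#' vinylic / aromatic / aldehyde C-H, O-H, N-H, with neighbor-group
#' increments) plus a small deterministic jitter (at most 0.3 ppm) derived
#' from a stable hash of the proton's radius-2 atomic environment, so that
#' distinct environments are distinguishable while symmetric protons
#' coincide exactly. Identical canonical SMILES always yield bit-identical
#' spectra.
#'
#' @param smiles_canonical SMILES of a molecule with at least one hydrogen.
#' @param shift_table Lookup table, see [surrogate_shift_table()].
#' @return Numeric vector with one shift (ppm) per hydrogen.
#' @examples
#' surrogate_predict("C")        # methane: four identical shifts
#' surrogate_predict("c1ccccc1") # benzene: six identical aromatic shifts
#' @export
surrogate_predict <- function(smiles_canonical,
                              shift_table = surrogate_shift_table()) {
  g <- mol_graph(smiles_canonical)
  hs <- which(g$elements == "H")
  if (length(hs) == 0L)
    stop_nmrts("nmrts_empty_spectrum",
               sprintf("molecule '%s' has no hydrogens", smiles_canonical))
  amp <- shift_table$jitter_amplitude
  vapply(hs, function(h) {
    heavy <- graph_neighbors(g, h)[1]
    fp <- environment_fingerprint(g, h, heavy)
    jitter <- (stable_hash(fp) %% 6001L - 3000) / 3000 * amp
    proton_base_shift(g, h, heavy, shift_table) + jitter
  }, numeric(1))
}

#' Construct the surrogate predictor
#'
#' Wraps [surrogate_predict()] in the predictor interface used by the
#' search: a list with a deterministic `predict` function mapping canonical
#' SMILES to a spectrum.
#'
#' @param shift_table Lookup table, see [surrogate_shift_table()].
#' @return Object of class `nmr_predictor`.
#' @export
surrogate_predictor <- function(shift_table = surrogate_shift_table()) {
  structure(list(name = "surrogate", deterministic = TRUE,
                 predict = function(smiles_canonical)
                   surrogate_predict(smiles_canonical, shift_table)),
            class = "nmr_predictor")
}

#' Create an empty spectrum/score cache
#'
#' Because prediction is deterministic, every canonical SMILES needs to be
#' predicted at most once per run. The cache stores one [score_result()] per
#' canonical SMILES and counts hits and misses.
#'
#' @return Object of class `spectrum_cache`.
#' @export
spectrum_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$entries <- new.env(hash = TRUE, parent = emptyenv())
  e$raw_map <- new.env(hash = TRUE, parent = emptyenv())  # spelling -> key
  e$hits <- 0L
  e$misses <- 0L
  class(e) <- "spectrum_cache"
  e
}

#' Cache counters
#' @param cache A [spectrum_cache()].
#' @return List with `hits`, `misses` and `size`.
#' @export
cache_stats <- function(cache) {
  list(hits = cache$hits, misses = cache$misses,
       size = length(ls(cache$entries)))
}

#' Evaluate one candidate SMILES against a target spectrum
#'
#' Canonicalizes the candidate, consults the cache, otherwise predicts its
#' spectrum and scores it (Wasserstein distance plus atom-count penalty
#' through the tanh score). All failures — unparseable SMILES, prediction
#' errors, hydrogen-free molecules — are encoded as score-0 results with a
#' reason code; nothing escapes as an error, so the search loop never dies
#' on a bad candidate.
#'
#' @param smiles Candidate SMILES (any spelling; possibly invalid).
#' @param target Target line spectrum (numeric, non-empty).
#' @param target_c,target_h Carbon/hydrogen counts of the target molecule.
#' @param predictor An `nmr_predictor`.
#' @param cache Optional [spectrum_cache()] keyed by canonical SMILES.
#' @param alpha Penalty strength of the score.
#' @return A [score_result()].
#' @export
evaluate_candidate <- function(smiles, target, target_c, target_h,
                               predictor = surrogate_predictor(),
                               cache = NULL, alpha = 0.1) {
  validate_spectrum(target, "target spectrum")
  raw_key <- paste0("r", smiles)
  if (!is.null(cache)) {
    # a spelling seen before maps straight to its stored result, skipping
    # re-canonicalization
    known <- get0(raw_key, envir = cache$raw_map, inherits = FALSE)
    if (!is.null(known)) {
      hit <- get0(known, envir = cache$entries, inherits = FALSE)
      if (!is.null(hit)) {
        cache$hits <- cache$hits + 1L
        return(hit)
      }
    }
  }
  canonical <- tryCatch(canonicalize_smiles(smiles), error = function(e) NULL)
  key <- if (is.null(canonical)) paste0("\x01invalid\x01", smiles) else canonical
  if (!is.null(cache)) {
    assign(raw_key, key, envir = cache$raw_map)
    hit <- get0(key, envir = cache$entries, inherits = FALSE)
    if (!is.null(hit)) {
      cache$hits <- cache$hits + 1L
      return(hit)
    }
    cache$misses <- cache$misses + 1L
  }
  res <- if (is.null(canonical)) {
    failed_score_result("invalid_smiles")
  } else {
    counts <- count_atoms(canonical)
    predicted <- tryCatch(predictor$predict(canonical), error = identity)
    if (inherits(predicted, "error")) {
      reason <- if (inherits(predicted, "nmrts_empty_spectrum"))
        "no_hydrogens" else "prediction_failed"
      failed_score_result(reason, canonical)
    } else {
      wd <- wasserstein_distance(predicted, target)
      pen <- atom_penalty(counts[["carbon"]], counts[["hydrogen"]],
                          target_c, target_h)
      score_result(canonical, wd, pen, evaluation_score(wd, pen, alpha))
    }
  }
  if (!is.null(cache)) assign(key, res, envir = cache$entries)
  res
}

#' File-exchange round trip with an external spectrum backend
#'
#' Contract for plugging in an external (e.g. quantum-chemistry) shift
#' computation without linking to it: a request JSON
#' `{"id": ..., "smiles": ...}` is written into the exchange directory, and
#' a response file `<id>.response.json` containing
#' `{"id": ..., "shifts_ppm": [...]}` (already TMS-referenced, one value
#' per proton) is awaited. The shift count is validated against the
#' molecule's hydrogen count.
#'
#' @param smiles_canonical Canonical SMILES of the molecule.
#' @param exchange_dir Writable directory shared with the backend.
#' @param request_id Identifier used in the file names; derived from the
#'   SMILES by default.
#' @param timeout Seconds to wait for the response.
#' @param poll Poll interval in seconds.
#' @return Numeric vector of shifts (ppm).
#' @export
external_backend_roundtrip <- function(smiles_canonical, exchange_dir,
                                       request_id = NULL,
                                       timeout = 30, poll = 0.05) {
  h_count <- count_atoms(smiles_canonical)[["hydrogen"]]
  if (is.null(request_id))
    request_id <- sprintf("req-%d", stable_hash(smiles_canonical))
  req_path <- file.path(exchange_dir, paste0(request_id, ".request.json"))
  resp_path <- file.path(exchange_dir, paste0(request_id, ".response.json"))
  jsonlite::write_json(list(id = request_id, smiles = smiles_canonical),
                       req_path, auto_unbox = TRUE)
  deadline <- Sys.time() + timeout
  while (!file.exists(resp_path)) {
    if (Sys.time() > deadline)
      stop_nmrts("nmrts_backend_timeout",
                 sprintf("no response for request '%s' within %g s",
                         request_id, timeout))
    Sys.sleep(poll)
  }
  resp <- jsonlite::read_json(resp_path)
  shifts <- as.numeric(unlist(resp$shifts_ppm))
  if (length(shifts) != h_count)
    stop_nmrts("nmrts_backend_integrity",
               sprintf("backend returned %d shifts for '%s' but the molecule has %d hydrogens",
                       length(shifts), smiles_canonical, h_count))
  shifts
}

#' Predictor backed by an external file-exchange backend
#'
#' @param exchange_dir Writable directory shared with the backend.
#' @param timeout,poll Passed to [external_backend_roundtrip()].
#' @return Object of class `nmr_predictor`.
#' @export
external_predictor <- function(exchange_dir, timeout = 30, poll = 0.05) {
  structure(list(name = "external", deterministic = TRUE,
                 predict = function(smiles_canonical)
                   external_backend_roundtrip(smiles_canonical, exchange_dir,
                                              timeout = timeout, poll = poll)),
            class = "nmr_predictor")
}
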