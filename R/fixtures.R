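# Synthetic SMILES corpus generation.
#
# The corpus stands in for a reference database of small organic molecules:
# uncharged, C/H/N/O only, molecular weight below 500, deduplicated after
# canonicalization. Molecules are enumerated from a documented
# combinatorial scheme — alkyl chains and small aromatic cores decorated
# with common oxygen/nitrogen substituents — then canonicalized, filtered
# and sampled in a seed-shuffled order, so corpora are reproducible and
# every stage of the pipeline is testable without downloads.

#' Combinatorial scheme of the corpus generator
#'
#' Defines the enumerable chemical space: carbon chain skeletons of the
#' given lengths and aromatic ring cores, each bearing up to `max_subs`
#' substituents at distinct positions. All placements are valence-safe by
#' construction (at most one substituent per position).
#'
#' @param chain_lengths Chain skeleton lengths (number of carbons).
#' @param chain_subs Substituents attachable to chain positions.
#' @param ring_cores Aromatic cores as token vectors (ring-bond digits kept
#'   with their atom).
#' @param ring_subs Substituents attachable to ring carbon positions.
#' @param max_subs Maximum substituents per molecule.
#' @return A list describing the scheme.
#' @export
corpus_scheme <- function(chain_lengths = 1:8,
                          chain_subs = c("O", "N", "C", "CC", "OC",
                                         "=O", "C(=O)O", "C#N", "N(C)C"),
                          ring_cores = list(
                            benzene = list(tokens = c("c1", "c", "c", "c", "c", "c1"),
                                           slots = 2:5),
                            pyridine = list(tokens = c("c1", "c", "c", "n", "c", "c1"),
                                            slots = c(2, 3, 5)),
                            furan = list(tokens = c("c1", "c", "c", "o", "c1"),
                                         slots = 2:3)),
                          ring_subs = c("C", "CC", "O", "OC", "N",
                                        "C=O", "C(=O)O", "C#N", "C(C)C"),
                          max_subs = 2) {
  list(chain_lengths = chain_lengths, chain_subs = chain_subs,
       ring_cores = ring_cores, ring_subs = ring_subs,
       max_subs = as.integer(max_subs))
}

assemble_substituted <- function(tokens, positions, subs) {
  if (length(positions)) {
    for (j in seq_along(positions))
      tokens[positions[j]] <- paste0(tokens[positions[j]], "(", subs[j], ")")
  }
  paste0(tokens, collapse = "")
}

sub_combinations <- function(slots, subs, max_subs) {
  out <- list(list(positions = integer(), subs = character()))
  if (max_subs >= 1) {
    for (p in slots) for (s in subs)
      out[[length(out) + 1L]] <- list(positions = p, subs = s)
  }
  if (max_subs >= 2 && length(slots) >= 2) {
    pairs <- utils::combn(slots, 2, simplify = FALSE)
    for (pp in pairs) for (s1 in subs) for (s2 in subs)
      out[[length(out) + 1L]] <- list(positions = pp, subs = c(s1, s2))
  }
  out
}

enumerate_scheme <- function(scheme) {
  out <- character()
  for (L in scheme$chain_lengths) {
    tokens <- rep("C", L)
    for (combo in sub_combinations(seq_len(L), scheme$chain_subs,
                                   min(scheme$max_subs, L)))
      out <- c(out, assemble_substituted(tokens, combo$positions, combo$subs))
  }
  for (core in scheme$ring_cores) {
    for (combo in sub_combinations(core$slots, scheme$ring_subs,
                                   scheme$max_subs))
      out <- c(out, assemble_substituted(core$tokens, combo$positions,
                                         combo$subs))
  }
  unique(out)
}

#' Admissibility filter of the corpus chemical space
#'
#' A molecule is admissible if it parses, contains only C, H, N and O,
#' carries no formal charges, has molecular weight below 500 and at least
#' one hydrogen (a proton spectrum needs protons).
#'
#' @param smiles A SMILES string.
#' @return `TRUE` or `FALSE`.
#' @export
is_corpus_admissible <- function(smiles) {
  props <- tryCatch(molecule_properties(smiles), error = function(e) NULL)
  if (is.null(props)) return(FALSE)
  if (grepl("[+.-]", props$canonical, perl = TRUE)) return(FALSE)
  elems <- names(props$formula)
  if (!all(elems %in% c("C", "H", "N", "O"))) return(FALSE)
  if (!("H" %in% elems) || props$formula[["H"]] < 1L) return(FALSE)
  if (props$mw >= 500) return(FALSE)
  TRUE
}

#' Generate a synthetic SMILES corpus
#'
#' Enumerates the combinatorial scheme, shuffles the enumeration with the
#' seed, and walks it collecting molecules that pass the admissibility
#' filter, deduplicated by canonical SMILES, until exactly `n` are found.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed; the same seed reproduces the same corpus.
#' @param scheme A [corpus_scheme()].
#' @return Object of class `fixture_corpus`: `smiles` (canonical,
#'   length `n`) and `provenance` (n, seed, scheme).
#' @export
generate_corpus <- function(n, seed = 1, scheme = corpus_scheme()) {
  if (n < 1) stop_config("n must be >= 1")
  raw <- enumerate_scheme(scheme)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  raw <- raw[sample.int(length(raw))]
  seen <- new.env(hash = TRUE, parent = emptyenv())
  smiles <- character(0)
  for (s in raw) {
    canonical <- tryCatch(canonicalize_smiles(s), error = function(e) NULL)
    if (is.null(canonical)) next
    if (!is.null(get0(canonical, envir = seen, inherits = FALSE))) next
    assign(canonical, TRUE, envir = seen)
    if (!is_corpus_admissible(canonical)) next
    smiles <- c(smiles, canonical)
    if (length(smiles) == n) break
  }
  if (length(smiles) < n)
    stop_nmrts("nmrts_capacity_error",
               sprintf("scheme capacity exhausted: %d admissible molecules available, %d requested",
                       length(smiles), n),
               capacity = length(smiles))
  structure(list(smiles = smiles,
                 provenance = list(n = n, seed = seed, scheme = scheme)),
            class = "fixture_corpus")
}

#' @export
print.fixture_corpus <- function(x, ...) {
  cat(sprintf("<fixture_corpus> %d molecules (seed %s)\n",
              length(x$smiles), format(x$provenance$seed)))
  invisible(x)
}

#' Write a corpus as one SMILES per line
#' @param corpus A `fixture_corpus` or character vector.
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  if (is.list(corpus) && !is.null(corpus$smiles)) corpus <- corpus$smiles
  writeLines(corpus, path)
  invisible(path)
}

#' Read a one-SMILES-per-line corpus file
#' @param path Input path.
#' @return Character vector of SMILES.
#' @export
read_corpus <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines)]
}

#' Hold one molecule out as an identification case
#'
#' The held-out molecule's predicted spectrum and atom counts become the
#' search target, and the molecule is removed from the corpus used for
#' policy training and trie preloading — reproducing the protocol in which
#' targets are absent from the reference database.
#'
#' @param corpus A `fixture_corpus`.
#' @param held_out_index Index of the molecule to hold out.
#' @param predictor An `nmr_predictor`.
#' @return List: `target_smiles`, `spectrum`, `carbon_count`,
#'   `hydrogen_count`, and the reduced `corpus`.
#' @export
make_identification_case <- function(corpus, held_out_index,
                                     predictor = surrogate_predictor()) {
  stopifnot(inherits(corpus, "fixture_corpus"))
  n <- length(corpus$smiles)
  if (held_out_index < 1 || held_out_index > n)
    stop_config(sprintf("held_out_index must be in [1, %d]", n))
  target <- corpus$smiles[held_out_index]
  counts <- count_atoms(target)
  reduced <- corpus
  reduced$smiles <- corpus$smiles[-held_out_index]
  list(target_smiles = target,
       spectrum = predictor$predict(target),
       carbon_count = counts[["carbon"]],
       hydrogen_count = counts[["hydrogen"]],
       corpus = reduced)
}
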