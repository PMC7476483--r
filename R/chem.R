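# SMILES handling: validity, canonicalization, atom counting, tokenization.
# Structure perception (parsing, implicit hydrogens, aromaticity) is delegated
# to OpenBabel through ChemmineOB; this module owns the interface contract.

BOS_TOKEN <- "<bos>"
EOS_TOKEN <- "<eos>"

# Cheap syntactic screen used to reject obviously malformed strings before
# handing them to OpenBabel (which reports parse failures on stderr). The
# screen only rejects strings that violate SMILES syntax necessities; it
# never rejects a valid string.
smiles_prescreen <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) return(FALSE)
  if (!nzchar(smiles)) return(FALSE)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0L) return(FALSE)
  if (grepl("\\(\\)", smiles)) return(FALSE)
  if (grepl("^[=#)(0-9]", smiles)) return(FALSE)
  if (grepl("[=#]$", smiles)) return(FALSE)
  # ring-bond digits outside brackets must pair up
  outside <- gsub("\\[[^]]*\\]", "", smiles)
  digits <- strsplit(gsub("[^0-9]", "", outside), "", fixed = TRUE)[[1]]
  if (length(digits) && any(table(digits) %% 2L != 0L)) return(FALSE)
  TRUE
}

ob_convert <- function(from, to, source, options = NULL) {
  out <- if (is.null(options)) {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = source))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = source,
                                               options = options))
  }
  if (is.null(out)) "" else out
}

#' Canonicalize a SMILES string
#'
#' Converts any valid spelling of a molecule to OpenBabel's canonical SMILES
#' form, so that all spellings of the same molecular graph map to a single
#' key. Canonicalization is idempotent and stable across runs; the whole
#' package keys caches, deduplication and identity checks on this form.
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES string.
#' @examples
#' canonicalize_smiles("OCC")  # "CCO"
#' @export
canonicalize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop_invalid_molecule(paste(smiles, collapse = ","), "expected one SMILES string")
  if (!smiles_prescreen(smiles))
    stop_invalid_molecule(smiles, "fails SMILES syntax screen")
  out <- ob_convert("SMI", "CAN", smiles)
  out <- strsplit(out, "[ \t\r\n]", perl = TRUE)[[1]][1]
  if (is.na(out) || !nzchar(out))
    stop_invalid_molecule(smiles)
  out
}

#' Test whether a string is valid SMILES
#'
#' @param smiles A single string.
#' @return `TRUE` if the string parses as a molecule.
#' @export
is_valid_smiles <- function(smiles) {
  !inherits(tryCatch(canonicalize_smiles(smiles), error = identity), "error")
}

parse_molecular_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula, perl = TRUE)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  elems <- sub("\\d+$", "", parts)
  counts <- as.integer(sub("^[A-Za-z]+", "", paste0(parts, "")))
  counts[is.na(counts)] <- 1L
  counts <- vapply(split(counts, elems), sum, integer(1))
  counts
}

# One OpenBabel property call: canonical SMILES, molecular formula, weight.
molecule_properties <- function(smiles) {
  canonical <- canonicalize_smiles(smiles)
  props <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", canonical, identity))
  list(canonical = canonical,
       formula = parse_molecular_formula(props$formula[1]),
       mw = as.numeric(props$MW[1]))
}

#' Count carbon and hydrogen atoms
#'
#' Counts all carbons (aromatic and aliphatic) and all hydrogens, including
#' implicit hydrogens completed by standard valence rules. These counts
#' constrain the size of generated molecules via the atom-count penalty.
#'
#' @param smiles A single valid SMILES string.
#' @return Named integer vector `c(carbon = ..., hydrogen = ...)`.
#' @examples
#' count_atoms("C")   # methane: carbon 1, hydrogen 4
#' count_atoms("O")   # water:   carbon 0, hydrogen 2
#' @export
count_atoms <- function(smiles) {
  f <- molecule_properties(smiles)$formula
  c(carbon = if ("C" %in% names(f)) f[["C"]] else 0L,
    hydrogen = if ("H" %in% names(f)) f[["H"]] else 0L)
}

#' Build a molecule record
#'
#' Canonicalizes a SMILES string and attaches its carbon and hydrogen counts.
#'
#' @param smiles A single valid SMILES string.
#' @return A list of class `molecule_record` with fields `smiles_raw`,
#'   `smiles_canonical`, `carbon_count`, `hydrogen_count`.
#' @export
molecule_record <- function(smiles) {
  canonical <- canonicalize_smiles(smiles)
  counts <- count_atoms(canonical)
  structure(list(smiles_raw = smiles,
                 smiles_canonical = canonical,
                 carbon_count = unname(counts["carbon"]),
                 hydrogen_count = unname(counts["hydrogen"])),
            class = "molecule_record")
}

# SMILES lexer: bracket atoms, two-letter organic-subset elements and
# two-digit ring bonds are kept whole (longest match); everything else is a
# single character. For the corpora this package targets the alphabet is in
# practice single characters only.
lex_smiles <- function(smiles) {
  if (!nzchar(smiles)) return(character())
  pattern <- "\\[[^]]*\\]|Cl|Br|%\\d{2}|."
  m <- gregexpr(pattern, smiles, perl = TRUE)[[1]]
  regmatches(smiles, list(m))[[1]]
}

#' Build a vocabulary from a SMILES corpus
#'
#' Collects every token occurring in the corpus and adds a begin-of-sequence
#' and an end-of-sequence marker. The token set is always corpus-derived,
#' never hard-coded.
#'
#' @param corpus Character vector of SMILES strings.
#' @return Object of class `nmr_vocabulary` with fields `symbols` (ordered,
#'   markers first), `bos`, `eos`.
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0L) stop_empty_input("corpus")
  # radix sort: byte-order collation, independent of the session locale,
  # so vocabularies (and everything keyed on their order) replay anywhere
  tokens <- sort(unique(unlist(lapply(corpus, lex_smiles))), method = "radix")
  structure(list(symbols = c(BOS_TOKEN, EOS_TOKEN, tokens),
                 bos = BOS_TOKEN, eos = EOS_TOKEN),
            class = "nmr_vocabulary")
}

#' @export
print.nmr_vocabulary <- function(x, ...) {
  cat("<nmr_vocabulary>", length(x$symbols), "symbols:",
      paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

#' Tokenize a SMILES string against a vocabulary
#'
#' Splits a SMILES string into vocabulary tokens (longest match) and appends
#' the end-of-sequence marker. Concatenating the returned tokens minus the
#' marker reproduces the input exactly.
#'
#' @param smiles The string to tokenize (may be empty).
#' @param vocab An `nmr_vocabulary`.
#' @return Character vector of tokens ending in the end marker.
#' @export
tokenize_smiles <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "nmr_vocabulary"))
  toks <- lex_smiles(smiles)
  bad <- which(!(toks %in% vocab$symbols))
  if (length(bad))
    stop_vocabulary(toks[bad[1]], bad[1], smiles)
  c(toks, vocab$eos)
}

#' Reassemble a SMILES string from tokens
#'
#' Drops begin/end markers and concatenates.
#'
#' @param tokens Character vector of tokens.
#' @return The SMILES string.
#' @export
detokenize <- function(tokens) {
  paste0(tokens[!(tokens %in% c(BOS_TOKEN, EOS_TOKEN))], collapse = "")
}
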