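# Random alternative SMILES spellings of a molecule, produced by a
# depth-first walk of the heavy-atom graph from a random root with shuffled
# neighbor order. Aromatic systems are written in their Kekulé form (valid
# SMILES; canonicalization restores aromatic perception). Every variant is
# validated by a canonical round trip before being returned, so the output
# always respells the same molecular graph. Used to augment policy training
# corpora: next-symbol statistics estimated from several spellings per
# molecule cover far more contexts than canonical spellings alone.

bond_symbol <- function(order) c("", "=", "#")[order]

write_smiles_walk <- function(g, start) {
  heavy <- which(g$elements != "H")
  parent <- integer(g$n)
  children <- vector("list", g$n)
  ring_digit <- new.env(parent = emptyenv())  # "i-j" (i < j) -> digit
  ring_at <- vector("list", g$n)              # atom -> list(digit, order)
  next_digit <- 0L
  visited <- rep(FALSE, g$n)

  edge_key <- function(i, j) paste(min(i, j), max(i, j))
  shuffle <- function(v) v[sample.int(length(v))]
  dfs <- function(i, from) {
    visited[i] <<- TRUE
    parent[i] <<- from
    for (j in shuffle(setdiff(g$adj[[i]], from))) {
      if (g$elements[j] == "H") next
      if (!visited[j]) {
        children[[i]] <<- c(children[[i]], j)
        dfs(j, i)
      } else if (is.null(get0(edge_key(i, j), envir = ring_digit))) {
        if (j == from) next
        next_digit <<- next_digit + 1L
        if (next_digit > 9L) stop_domain("more than nine ring bonds")
        assign(edge_key(i, j), next_digit, envir = ring_digit)
        ord <- graph_order(g, i, j)
        ring_at[[i]] <<- c(ring_at[[i]], list(c(next_digit, ord)))
        ring_at[[j]] <<- c(ring_at[[j]], list(c(next_digit, ord)))
      }
    }
  }
  dfs(start, 0L)

  emit <- function(i) {
    out <- g$elements[i]
    for (rb in ring_at[[i]])
      out <- paste0(out, bond_symbol(rb[2]), rb[1])
    kids <- children[[i]]
    if (length(kids)) {
      for (k in seq_along(kids)) {
        j <- kids[k]
        part <- paste0(bond_symbol(graph_order(g, i, j)), emit(j))
        out <- if (k < length(kids)) paste0(out, "(", part, ")")
               else paste0(out, part)
      }
    }
    out
  }
  emit(start)
}

#' Random alternative spellings of a molecule
#'
#' Generates up to `n` distinct non-canonical SMILES spellings of the same
#' molecular graph by depth-first walks from random atoms with shuffled
#' branch order. Each candidate is verified to canonicalize back to the
#' input's canonical form; candidates that do not are discarded.
#'
#' @param smiles A valid SMILES string.
#' @param n Number of spellings to attempt.
#' @param seed Optional seed (caller RNG preserved if given).
#' @return Character vector of valid spellings (possibly fewer than `n`,
#'   possibly including the canonical spelling itself).
#' @export
random_smiles <- function(smiles, n = 3, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  canonical <- canonicalize_smiles(smiles)
  g <- mol_graph(canonical)
  heavy <- which(g$elements != "H")
  if (length(heavy) == 0L) return(character())
  out <- character()
  for (k in seq_len(n)) {
    start <- heavy[sample.int(length(heavy), 1)]
    cand <- tryCatch(write_smiles_walk(g, start), error = function(e) NULL)
    if (is.null(cand)) next
    back <- tryCatch(canonicalize_smiles(cand), error = function(e) NULL)
    if (identical(back, canonical)) out <- c(out, cand)
  }
  unique(out)
}

#' Augment a SMILES corpus with alternative spellings
#'
#' Appends up to `variants` random valid respellings of every corpus
#' molecule. Training a next-symbol policy on the augmented corpus covers
#' many more token contexts than canonical spellings alone, which improves
#' both rollout validity and the reachability of molecules whose canonical
#' spelling uses rare token patterns.
#'
#' @param corpus Character vector of SMILES (or a fixture corpus).
#' @param variants Spellings attempted per molecule.
#' @param seed Seed for the walk randomization.
#' @return Character vector: the original corpus followed by the variants.
#' @export
augment_corpus <- function(corpus, variants = 2, seed = 1) {
  if (is.list(corpus) && !is.null(corpus$smiles)) corpus <- corpus$smiles
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  extra <- unlist(lapply(corpus, function(s)
    tryCatch(random_smiles(s, n = variants), error = function(e) character())))
  c(corpus, extra)
}
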