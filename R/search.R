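# Monte Carlo tree search over SMILES prefixes.
#
# Nodes are R environments (reference semantics) carrying the statistics of
# the selection rule: total score s, visit count v, virtual visit count w
# (in-flight selections), prior p from the policy, and an ordered child
# list. Selection descends by the PUCT-style upper confidence bound
#     s_i/(v_i + w_i) + C * p_i * sqrt(v_p + w_p) / (1 + v_i + w_i)
# with the exploitation term defined as 0 for unvisited nodes, so selection
# among fresh children is driven by C * p_i. Virtual visits are incremented
# on the way down and removed at backpropagation, allowing several
# selections to be in flight before their evaluations return; the reference
# execution mode here is sequential.

new_search_node <- function(token, prior = 0) {
  node <- new.env(parent = emptyenv())
  node$token <- token
  node$score_sum <- 0
  node$visits <- 0L
  node$virtual_visits <- 0L
  node$prior <- prior
  node$children <- list()
  node$expanded <- FALSE
  node$exhausted <- FALSE
  class(node) <- "search_node"
  node
}

#' Search tree root
#'
#' @param vocab An `nmr_vocabulary`; the root carries the begin marker.
#' @return A `search_node` environment.
#' @export
new_search_tree <- function(vocab) new_search_node(vocab$bos)

#' Upper confidence bound of a child node
#'
#' `s/(v+w) + C * p * sqrt(v_p + w_p) / (1 + v + w)`, where `s`, `v`, `w`,
#' `p` are the child's score sum, visits, virtual visits and prior and
#' `v_p`, `w_p` the parent's counts. The exploitation term is 0 when
#' `v + w = 0`.
#'
#' @param node The child `search_node`.
#' @param parent_visits,parent_virtual The parent's (virtual) visit counts.
#' @param exploration_c Exploration constant C (>= 0).
#' @return The selection score.
#' @export
ucb_score <- function(node, parent_visits, parent_virtual, exploration_c) {
  if (parent_visits < 0 || parent_virtual < 0 ||
      node$visits < 0 || node$virtual_visits < 0)
    stop_domain("visit counts must be non-negative")
  n <- node$visits + node$virtual_visits
  exploit <- if (n > 0) node$score_sum / n else 0
  exploit + exploration_c * node$prior *
    sqrt(parent_visits + parent_virtual) / (1 + n)
}

# arg-max over children with deterministic tie-breaking:
# highest UCB, then highest prior, then lowest child index. Children whose
# complete subtree has already been evaluated (exhausted) are skipped, so
# the finite string space is not re-enumerated through selection.
select_child_index <- function(node, exploration_c) {
  kids <- node$children
  open <- which(!vapply(kids, function(k) k$exhausted, logical(1)))
  if (length(open) == 0L) return(NA_integer_)
  u <- vapply(kids[open], ucb_score, numeric(1),
              parent_visits = node$visits,
              parent_virtual = node$virtual_visits,
              exploration_c = exploration_c)
  best <- which(u >= max(u) - 1e-12)
  if (length(best) > 1L) {
    priors <- vapply(kids[open[best]], function(k) k$prior, numeric(1))
    best <- best[priors >= max(priors) - 1e-12]
  }
  open[best[1]]
}

# Fill priors (and add missing children) from the policy. Preloaded
# children keep their position; missing symbols are appended in policy
# order.
expand_node <- function(node, prefix, model) {
  dist <- next_symbol_distribution(model, prefix)
  for (sym in names(dist)) {
    kid <- node$children[[sym]]
    if (is.null(kid)) {
      node$children[[sym]] <- new_search_node(sym, dist[[sym]])
    } else {
      kid$prior <- dist[[sym]]
    }
  }
  node$expanded <- TRUE
  invisible(node)
}

#' Search settings
#'
#' @param exploration_c Exploration constant C of the selection rule.
#' @param alpha Atom-penalty strength of the evaluation score.
#' @param trie_size Number of top-ranked database molecules preloaded into
#'   the tree (0 = bare root).
#' @param evaluation_budget Maximum number of candidate evaluations.
#' @param time_budget_seconds Optional wall-clock cap.
#' @param seed Integer seed; the whole search is reproducible given it.
#' @param max_length Token cap for prefixes and rollouts.
#' @param early_stop Stop as soon as a score of 1.0 (exact identification)
#'   is found. On by default; disable to emulate fixed-budget exploration.
#' @return A list of class `search_config`.
#' @export
search_config <- function(exploration_c = 1, alpha = 0.1, trie_size = 0,
                          evaluation_budget = 1000,
                          time_budget_seconds = NULL, seed = 1,
                          max_length = 80, early_stop = TRUE) {
  if (evaluation_budget <= 0) stop_config("evaluation_budget must be positive")
  if (exploration_c < 0 || alpha < 0) stop_config("constants must be >= 0")
  structure(list(exploration_c = exploration_c, alpha = alpha,
                 trie_size = as.integer(trie_size),
                 evaluation_budget = as.integer(evaluation_budget),
                 time_budget_seconds = time_budget_seconds,
                 seed = as.integer(seed),
                 max_length = as.integer(max_length),
                 early_stop = isTRUE(early_stop)),
            class = "search_config")
}

# Selection phase: descend from the root by maximal UCB, expanding the
# first unexpanded node met, incrementing virtual visits along the path.
# Returns the path, the token prefix and whether the prefix is already a
# complete string (end marker reached or length cap hit).
mcts_select <- function(root, model, config) {
  eos <- model$vocab$eos
  root$virtual_visits <- root$virtual_visits + 1L
  path <- list(root)
  prefix <- character()
  node <- root
  repeat {
    if (node$token == eos)
      return(list(path = path, prefix = prefix, complete = TRUE))
    if (length(prefix) >= config$max_length)
      return(list(path = path, prefix = prefix, complete = TRUE))
    was_leaf <- !node$expanded
    if (was_leaf) expand_node(node, prefix, model)
    i <- select_child_index(node, config$exploration_c)
    if (is.na(i))  # every continuation already enumerated below this node
      return(list(path = path, prefix = prefix, complete = TRUE))
    child <- node$children[[i]]
    child$virtual_visits <- child$virtual_visits + 1L
    path <- c(path, child)
    if (child$token != eos) prefix <- c(prefix, child$token)
    node <- child
    if (was_leaf) {
      complete <- child$token == eos || length(prefix) >= config$max_length
      return(list(path = path, prefix = prefix, complete = complete))
    }
  }
}

# Backpropagation: add the score and one visit to every node on the path
# and release the virtual visits taken during selection.
mcts_backprop <- function(path, score) {
  for (node in path) {
    node$score_sum <- node$score_sum + score
    node$visits <- node$visits + 1L
    node$virtual_visits <- node$virtual_visits - 1L
  }
  invisible(NULL)
}

#' One search iteration
#'
#' Selection (UCB descent with virtual loss), expansion at the first leaf,
#' completion of the prefix by a policy rollout, evaluation of the
#' completed string, and backpropagation of the score. Evaluation failures
#' propagate score 0 and never raise.
#'
#' @param root The search tree root.
#' @param model A [fit_policy()] model.
#' @param evaluator Function mapping a SMILES string to a [score_result()].
#' @param config A [search_config()].
#' @return List with the generated `smiles` and its `result`.
#' @export
run_iteration <- function(root, model, evaluator, config) {
  sel <- mcts_select(root, model, config)
  smiles <- if (sel$complete) {
    detokenize(sel$prefix)
  } else {
    as.character(rollout(model, sel$prefix, max_length = config$max_length))
  }
  result <- evaluator(smiles)
  mcts_backprop(sel$path, result$score)
  if (sel$complete) mark_exhausted(sel$path)
  list(smiles = smiles, result = result)
}

# A selection that ended on a terminal (end marker or length cap) has fully
# enumerated that string; close the terminal and propagate exhaustion to
# ancestors whose expanded child sets are entirely closed.
mark_exhausted <- function(path) {
  n <- length(path)
  path[[n]]$exhausted <- TRUE
  for (i in rev(seq_len(n - 1))) {
    node <- path[[i]]
    if (!node$expanded || length(node$children) == 0L) break
    if (!all(vapply(node$children, function(k) k$exhausted, logical(1)))) break
    node$exhausted <- TRUE
  }
  invisible(NULL)
}

#' Precompute a spectral database
#'
#' Canonicalizes the database SMILES, counts their atoms and predicts each
#' spectrum once with the active predictor.
#'
#' @param smiles Character vector of database SMILES (or a fixture corpus).
#' @param predictor An `nmr_predictor`.
#' @return List of class `spectral_database` with `records` (data frame:
#'   smiles, carbon_count, hydrogen_count) and `spectra` (list).
#' @export
build_spectral_database <- function(smiles, predictor = surrogate_predictor()) {
  if (is.list(smiles) && !is.null(smiles$smiles)) smiles <- smiles$smiles
  if (length(smiles) == 0L) stop_empty_input("database")
  canonical <- vapply(smiles, canonicalize_smiles, character(1),
                      USE.NAMES = FALSE)
  counts <- t(vapply(canonical, count_atoms, integer(2), USE.NAMES = FALSE))
  spectra <- lapply(canonical, predictor$predict)
  structure(list(records = data.frame(smiles = canonical,
                                      carbon_count = counts[, 1],
                                      hydrogen_count = counts[, 2],
                                      stringsAsFactors = FALSE),
                 spectra = spectra),
            class = "spectral_database")
}

#' Rank a spectral database against a target spectrum
#'
#' Scores every database molecule with the Wasserstein-plus-penalty score
#' against the target and returns a stable descending sort. The top entry
#' is the database-search baseline: the best answer available without
#' generating any new molecule.
#'
#' @param db A [build_spectral_database()] object.
#' @param target Target line spectrum.
#' @param target_c,target_h Carbon/hydrogen counts of the target.
#' @param alpha Penalty strength.
#' @return Data frame (smiles, wd, penalty, score) sorted by score
#'   descending, ties kept in database order.
#' @export
rank_database <- function(db, target, target_c, target_h, alpha = 0.1) {
  stopifnot(inherits(db, "spectral_database"))
  if (nrow(db$records) == 0L) stop_empty_input("database")
  validate_spectrum(target, "target spectrum")
  wd <- vapply(db$spectra, wasserstein_distance, numeric(1), b = target)
  pen <- atom_penalty(db$records$carbon_count, db$records$hydrogen_count,
                      target_c, target_h)
  score <- evaluation_score(wd, pen, alpha)
  out <- data.frame(smiles = db$records$smiles, wd = wd, penalty = pen,
                    score = score, stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}

#' Preload the search tree with ranked database strings
#'
#' Inserts each string's token path (end marker included) into the tree and
#' applies, along the path, the same bookkeeping as a backpropagation of
#' that string's score: visits + 1 and score_sum + score on every node.
#' Priors of preloaded nodes are filled from the policy on first expansion
#' of their parent.
#'
#' @param root The search tree root.
#' @param ranked Data frame with columns `smiles` and `score` (typically
#'   the head of [rank_database()]).
#' @param vocab The search vocabulary.
#' @return The root, invisibly.
#' @export
preload_trie <- function(root, ranked, vocab) {
  for (i in seq_len(nrow(ranked))) {
    toks <- tokenize_smiles(ranked$smiles[i], vocab)
    score <- ranked$score[i]
    node <- root
    node$score_sum <- node$score_sum + score
    node$visits <- node$visits + 1L
    for (t in toks) {
      kid <- node$children[[t]]
      if (is.null(kid)) {
        kid <- new_search_node(t)
        node$children[[t]] <- kid
      }
      kid$score_sum <- kid$score_sum + score
      kid$visits <- kid$visits + 1L
      node <- kid
    }
  }
  invisible(root)
}

#' Identify candidate molecules for a target spectrum
#'
#' The full search: ranks the database against the target (the top entry
#' being the database-search baseline), preloads the tree with the
#' top-`trie_size` strings, then iterates selection / expansion / rollout /
#' evaluation / backpropagation until the evaluation budget (or time
#' budget) is exhausted, stopping early when an exact match (score 1.0) is
#' found unless disabled. Duplicate generations are re-scored from the
#' cache and backpropagated normally.
#'
#' @param target Target line spectrum (numeric, one shift per proton).
#' @param target_c,target_h Carbon/hydrogen counts of the target molecule.
#' @param model A [fit_policy()] model.
#' @param predictor An `nmr_predictor`.
#' @param db Optional [build_spectral_database()]; required if
#'   `config$trie_size > 0`.
#' @param config A [search_config()].
#' @return Object of class `nmr_search`: `candidates` (data frame sorted by
#'   score descending, deduplicated by canonical SMILES), `baseline` (top
#'   database entry or NULL), `trace` (best score per iteration),
#'   `n_iterations`, `cache`, `config`, and the search `root`.
#' @export
run_search <- function(target, target_c, target_h, model,
                       predictor = surrogate_predictor(), db = NULL,
                       config = search_config()) {
  validate_spectrum(target, "target spectrum")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  baseline <- NULL
  ranked <- NULL
  if (!is.null(db)) {
    ranked <- rank_database(db, target, target_c, target_h, config$alpha)
    baseline <- ranked[1, , drop = FALSE]
  }
  root <- new_search_tree(model$vocab)
  if (config$trie_size > 0) {
    if (is.null(ranked)) stop_config("trie preloading requires a database")
    if (config$trie_size > nrow(ranked))
      stop_config("trie_size exceeds database size")
    preload_trie(root, utils::head(ranked, config$trie_size), model$vocab)
  }
  cache <- spectrum_cache()
  evaluator <- function(s)
    evaluate_candidate(s, target, target_c, target_h, predictor, cache,
                       config$alpha)

  seen <- new.env(hash = TRUE, parent = emptyenv())
  cand <- list()
  trace_best <- numeric(0)
  best <- 0
  started <- Sys.time()
  n_done <- 0L
  for (i in seq_len(config$evaluation_budget)) {
    if (root$exhausted) break  # every reachable string has been evaluated
    if (!is.null(config$time_budget_seconds) &&
        as.numeric(Sys.time() - started, units = "secs") >
          config$time_budget_seconds) break
    it <- run_iteration(root, model, evaluator, config)
    n_done <- i
    res <- it$result
    if (is.na(res$reason) && is.null(get0(res$candidate_canonical,
                                          envir = seen, inherits = FALSE))) {
      assign(res$candidate_canonical, TRUE, envir = seen)
      cand[[length(cand) + 1L]] <-
        data.frame(smiles = res$candidate_canonical,
                   score = res$score, wd = res$wasserstein_distance,
                   penalty = res$atom_penalty, iteration = i,
                   stringsAsFactors = FALSE)
    }
    if (is.na(res$reason) && res$score > best) best <- res$score
    trace_best[i] <- best
    if (config$early_stop && best >= 1) break
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(smiles = character(), score = numeric(), wd = numeric(),
               penalty = numeric(), iteration = integer(),
               stringsAsFactors = FALSE)
  candidates <- candidates[order(-candidates$score, candidates$iteration), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  structure(list(candidates = candidates, baseline = baseline,
                 trace = data.frame(iteration = seq_len(n_done),
                                    best_score = trace_best[seq_len(n_done)]),
                 n_iterations = n_done, cache = cache_stats(cache),
                 config = config, root = root),
            class = "nmr_search")
}

#' @export
print.nmr_search <- function(x, ...) {
  cat(sprintf("<nmr_search> %d iterations, %d unique candidates\n",
              x$n_iterations, nrow(x$candidates)))
  if (!is.null(x$baseline))
    cat(sprintf("  database baseline: %s (score %.4f)\n",
                x$baseline$smiles, x$baseline$score))
  if (nrow(x$candidates)) {
    cat(sprintf("  best candidate:    %s (score %.4f, iteration %d)\n",
                x$candidates$smiles[1], x$candidates$score[1],
                x$candidates$iteration[1]))
  }
  invisible(x)
}
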