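# Next-symbol policy over SMILES tokens.
#
# Two interchangeable backends satisfy the same interface:
#   * "markov"  - exact order-k corpus statistics with additive smoothing
#                 and backoff to shorter contexts; fast and fully
#                 reproducible, the default for searches and tests.
#   * "rnn"     - a small Elman recurrent network trained by truncated
#                 gradient descent; closer to the original design, slower.
# Both emit, for any prefix, a probability vector over the emission
# alphabet (all vocabulary symbols except the begin marker) that sums to 1.

#' Policy training settings
#'
#' @param backend `"markov"` or `"rnn"`.
#' @param order Markov context length (tokens).
#' @param smoothing Additive smoothing mass per symbol (Markov backend).
#' @param interpolation Jelinek-Mercer weight in (0, 1] given to the
#'   longest-context estimate at each level; 1 means pure backoff (lower
#'   orders consulted only when a context is unseen), values below 1 blend
#'   lower-order statistics everywhere so that no continuation observed at
#'   any order has vanishing probability.
#' @param grammar_mask Zero out next symbols that are syntactically
#'   impossible for the prefix (closing an unopened branch, terminating
#'   with open branches or ring bonds, bonds in illegal positions) and
#'   renormalize. A finite-context model cannot track bracket balance the
#'   way a recurrent state can; the mask restores that.
#' @param hidden,epochs,learning_rate,clip RNN backend hyperparameters
#'   (hidden units, training epochs, step size, gradient-clipping norm).
#' @param max_length Rollout cap in tokens.
#' @return A list of settings for [fit_policy()].
#' @export
policy_config <- function(backend = c("markov", "rnn"), order = 3,
                          smoothing = 0.001, interpolation = 1,
                          grammar_mask = TRUE, hidden = 32, epochs = 30,
                          learning_rate = 0.1, clip = 5, max_length = 80) {
  if (interpolation <= 0 || interpolation > 1)
    stop_config("interpolation must be in (0, 1]")
  list(backend = match.arg(backend), order = as.integer(order),
       smoothing = smoothing, interpolation = interpolation,
       grammar_mask = isTRUE(grammar_mask),
       hidden = as.integer(hidden),
       epochs = as.integer(epochs), learning_rate = learning_rate,
       clip = clip, max_length = as.integer(max_length))
}

ctx_key <- function(tokens) {
  if (length(tokens) == 0L) return("<empty>")
  paste(tokens, collapse = "\x1f")
}

token_categories <- function(tokens) {
  cats <- rep("atom", length(tokens))
  cats[tokens %in% c("=", "#", "-", "/", "\\")] <- "bond"
  cats[tokens == "("] <- "open"
  cats[tokens == ")"] <- "close"
  cats[grepl("^[0-9]$|^%[0-9]{2}$", tokens)] <- "digit"
  cats[tokens %in% c(BOS_TOKEN, EOS_TOKEN)] <- "marker"
  cats
}

# SMILES syntax state of a token prefix: branch depth, open ring bonds and
# the category of the last token. A finite-order Markov model cannot see an
# unclosed parenthesis beyond its context window, so without a syntactic
# mask it assigns real mass to continuations no SMILES grammar allows
# (closing an unopened branch, ending with a dangling ring bond, ...).
prefix_syntax_state <- function(prefix) {
  if (length(prefix) == 0L)
    return(list(depth = 0L, n_open_rings = 0L, last = "none"))
  cats <- token_categories(prefix)
  depth <- sum(cats == "open") - sum(cats == "close")
  digits <- prefix[cats == "digit"]
  n_open <- if (length(digits)) sum(table(digits) %% 2L != 0L) else 0L
  list(depth = depth, n_open_rings = n_open, last = cats[length(cats)])
}

# TRUE for each emission symbol that can legally extend the prefix.
legal_next_tokens <- function(prefix, emission,
                              cats = token_categories(emission)) {
  st <- prefix_syntax_state(prefix)
  after_atomish <- st$last %in% c("atom", "close", "digit")
  allowed <- c(
    atom = TRUE,
    bond = after_atomish || st$last == "open",
    open = after_atomish,
    close = st$depth > 0L && after_atomish,
    digit = st$last %in% c("atom", "digit"),
    marker = st$depth == 0L && st$n_open_rings == 0L && after_atomish)
  legal <- unname(allowed[cats])
  legal[cats == "marker" & emission != EOS_TOKEN] <- FALSE
  legal
}

#' Train a next-symbol policy on a SMILES corpus
#'
#' Builds the vocabulary from the corpus, tokenizes every string and fits
#' the chosen backend. Training is reproducible given the seed.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @param config See [policy_config()].
#' @param seed Integer seed controlling any training randomness.
#' @return Object of class `policy_model`.
#' @export
fit_policy <- function(corpus, config = policy_config(), seed = 1) {
  if (is.list(corpus) && !is.null(corpus$smiles)) corpus <- corpus$smiles
  if (length(corpus) == 0L) stop_empty_input("corpus")
  vocab <- build_vocabulary(corpus)
  sequences <- lapply(corpus, tokenize_smiles, vocab = vocab)
  emission <- setdiff(vocab$symbols, vocab$bos)
  model <- list(vocab = vocab, emission = emission,
                emission_cats = token_categories(emission),
                backend = config$backend,
                config = config, max_length = config$max_length)
  if (config$backend == "markov") {
    k <- config$order
    tables <- lapply(0:k, function(i) new.env(hash = TRUE, parent = emptyenv()))
    zero <- stats::setNames(numeric(length(emission)), emission)
    for (toks in sequences) {
      padded <- c(rep(vocab$bos, k), toks)
      for (i in seq_along(toks)) {
        sym <- toks[i]
        for (len in 0:k) {
          ctx <- if (len == 0) character() else padded[(i + k - len):(i + k - 1)]
          key <- ctx_key(ctx)
          tab <- tables[[len + 1]]
          counts <- get0(key, envir = tab, inherits = FALSE)
          if (is.null(counts)) counts <- zero
          counts[sym] <- counts[sym] + 1
          assign(key, counts, envir = tab)
        }
      }
    }
    model$tables <- tables
  } else {
    ids <- lapply(sequences, function(t) match(t, vocab$symbols))
    old <- get0(".Random.seed", envir = globalenv())
    model$params <- rnn_fit(ids, vocab, config, seed)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(model, class = "policy_model")
}

#' @export
print.policy_model <- function(x, ...) {
  cat(sprintf("<policy_model> backend=%s vocab=%d symbols max_length=%d\n",
              x$backend, length(x$vocab$symbols), x$max_length))
  invisible(x)
}

validate_prefix <- function(model, prefix) {
  bad <- which(!(prefix %in% model$vocab$symbols))
  if (length(bad)) stop_vocabulary(prefix[bad[1]], bad[1])
  invisible(prefix)
}

#' Next-symbol probability distribution
#'
#' Probability of each emission symbol (including the end marker) following
#' the given token prefix. Deterministic for a fixed model and prefix. The
#' end marker is absorbing: any prefix already containing it yields
#' probability 1 on the end marker.
#'
#' @param model A [fit_policy()] model.
#' @param prefix Character vector of tokens (may be empty).
#' @return Named probability vector over the emission alphabet, summing to 1.
#' @export
next_symbol_distribution <- function(model, prefix = character()) {
  stopifnot(inherits(model, "policy_model"))
  validate_prefix(model, prefix)
  emission <- model$emission
  if (length(prefix) && model$vocab$eos %in% prefix) {
    p <- stats::setNames(numeric(length(emission)), emission)
    p[model$vocab$eos] <- 1
    return(p)
  }
  p <- next_symbol_unmasked(model, prefix, emission)
  if (isTRUE(model$config$grammar_mask)) {
    cats <- model$emission_cats
    if (is.null(cats)) cats <- token_categories(emission)
    legal <- legal_next_tokens(prefix, emission, cats)
    if (any(legal) && sum(p[legal]) > 0) {
      p[!legal] <- 0
      p <- p / sum(p)
    }
  }
  p
}

next_symbol_unmasked <- function(model, prefix, emission) {
  if (model$backend == "markov") {
    k <- model$config$order
    sm <- model$config$smoothing
    lambda <- model$config$interpolation
    padded <- c(rep(model$vocab$bos, k), prefix)
    n <- length(padded)
    level_est <- function(len) {
      ctx <- if (len == 0) character() else padded[(n - len + 1):n]
      counts <- get0(ctx_key(ctx), envir = model$tables[[len + 1]],
                     inherits = FALSE)
      if (is.null(counts)) return(NULL)
      (counts + sm) / (sum(counts) + sm * length(counts))
    }
    if (lambda == 1) {
      # pure backoff: exact statistics at the longest matched context
      for (len in k:0) {
        p <- level_est(len)
        if (!is.null(p)) return(p)
      }
    } else {
      # Jelinek-Mercer: blend matched levels bottom-up
      p <- stats::setNames(rep(1 / length(emission), length(emission)),
                           emission)
      for (len in 0:k) {
        ml <- level_est(len)
        if (!is.null(ml)) p <- (1 - lambda) * p + lambda * ml
      }
      return(p)
    }
    return(stats::setNames(rep(1 / length(emission), length(emission)), emission))
  }
  rnn_next_distribution(model$params, model$vocab, emission, prefix)
}

#' Complete a SMILES prefix by sampling the policy
#'
#' Samples symbols autoregressively from [next_symbol_distribution()] until
#' the end marker appears or `max_length` tokens are reached (in which case
#' the result carries attribute `truncated = TRUE`). The returned string may
#' be syntactically invalid SMILES; validity is judged downstream by the
#' evaluator.
#'
#' @param model A [fit_policy()] model.
#' @param prefix Character vector of tokens to extend (may be empty).
#' @param seed Optional integer seed; if given, the caller's RNG state is
#'   preserved and the rollout is reproducible.
#' @param max_length Token cap (defaults to the model's).
#' @return The completed SMILES string, with attribute `truncated`.
#' @export
rollout <- function(model, prefix = character(), seed = NULL,
                    max_length = model$max_length) {
  stopifnot(inherits(model, "policy_model"))
  validate_prefix(model, prefix)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  toks <- prefix
  truncated <- FALSE
  while (!(length(toks) && toks[length(toks)] == model$vocab$eos)) {
    if (length(toks) >= max_length) {
      truncated <- TRUE
      break
    }
    p <- next_symbol_distribution(model, toks)
    toks <- c(toks, sample(names(p), 1L, prob = p))
  }
  structure(detokenize(toks), truncated = truncated)
}
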