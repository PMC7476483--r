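# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small corpus used across unit tests (built lazily, then reused).
fixture_corpus_small <- function() {
  if (is.null(.fixture_env$small))
    .fixture_env$small <- generate_corpus(60, seed = 11)
  .fixture_env$small
}

fixture_predictor <- function() surrogate_predictor()

# A policy model whose rollouts always emit a fixed string (a one-string
# corpus with zero smoothing and a long context): used to wire oracle
# molecules into the search loop.
constant_policy <- function(smiles) {
  fit_policy(smiles, policy_config("markov", order = nchar(smiles) + 2,
                                   smoothing = 0))
}
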