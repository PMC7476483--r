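# Structured error conditions used across the package. Every error raised by
# nmrts carries a subclass so callers (notably the search loop, which must
# never die on a bad candidate) can discriminate failure modes.

stop_nmrts <- function(subclass, message, call = sys.call(-1), ...) {
  cnd <- structure(
    class = c(subclass, "nmrts_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}

stop_invalid_molecule <- function(smiles, detail = "not parseable as SMILES") {
  stop_nmrts("nmrts_invalid_molecule",
             sprintf("invalid molecule '%s': %s", smiles, detail),
             smiles = smiles)
}

stop_vocabulary <- function(token, position, smiles = NULL) {
  msg <- sprintf("token '%s' at position %d is not in the vocabulary", token, position)
  if (!is.null(smiles)) msg <- paste0(msg, sprintf(" (string '%s')", smiles))
  stop_nmrts("nmrts_vocabulary_error", msg, token = token, position = position)
}

stop_empty_input <- function(what) {
  stop_nmrts("nmrts_empty_input", sprintf("empty input: %s", what))
}

stop_domain <- function(message) stop_nmrts("nmrts_domain_error", message)

stop_config <- function(message) stop_nmrts("nmrts_config_error", message)
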