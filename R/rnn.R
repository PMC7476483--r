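# Minimal Elman recurrent network for next-symbol prediction, written in
# base R matrix algebra. One-hot inputs over the full vocabulary (begin
# marker included), softmax outputs over the emission alphabet, trained by
# per-sequence stochastic gradient descent with full backpropagation
# through time and global-norm gradient clipping. Deliberately small: the
# SMILES alphabets this package targets have ~15 symbols and the corpus
# strings are short, so a compact network suffices as the recurrent policy
# backend.

rnn_init <- function(V, E, H, seed) {
  set.seed(seed)
  sd <- 0.2
  list(Wxh = matrix(stats::rnorm(H * V, sd = sd), H, V),
       Whh = matrix(stats::rnorm(H * H, sd = sd / sqrt(H)), H, H),
       bh = numeric(H),
       Why = matrix(stats::rnorm(E * H, sd = sd), E, H),
       by = numeric(E))
}

rnn_softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# ids: list of integer vectors (vocabulary indices, EOS-terminated, no BOS)
rnn_fit <- function(ids, vocab, config, seed) {
  V <- length(vocab$symbols)
  emission_idx <- which(vocab$symbols != vocab$bos)
  E <- length(emission_idx)
  emission_map <- match(seq_len(V), emission_idx)  # vocab id -> emission row
  H <- config$hidden
  params <- rnn_init(V, E, H, seed)
  bos_id <- match(vocab$bos, vocab$symbols)
  n <- length(ids)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate / (1 + 0.05 * (epoch - 1))
    ord <- sample.int(n)
    for (s in ord) {
      targets <- emission_map[ids[[s]]]
      inputs <- c(bos_id, ids[[s]][-length(ids[[s]])])
      Tn <- length(inputs)
      hs <- matrix(0, H, Tn + 1)
      ps <- matrix(0, E, Tn)
      for (t in seq_len(Tn)) {
        h <- tanh(params$Wxh[, inputs[t]] + params$Whh %*% hs[, t] + params$bh)
        hs[, t + 1] <- h
        ps[, t] <- rnn_softmax(params$Why %*% h + params$by)
      }
      gWxh <- matrix(0, H, V); gWhh <- matrix(0, H, H); gbh <- numeric(H)
      gWhy <- matrix(0, E, H); gby <- numeric(E)
      carry <- numeric(H)
      for (t in rev(seq_len(Tn))) {
        dlog <- ps[, t]
        dlog[targets[t]] <- dlog[targets[t]] - 1
        gWhy <- gWhy + dlog %*% t(hs[, t + 1])
        gby <- gby + dlog
        dh <- drop(crossprod(params$Why, dlog)) + carry
        dz <- dh * (1 - hs[, t + 1]^2)
        gWxh[, inputs[t]] <- gWxh[, inputs[t]] + dz
        gWhh <- gWhh + dz %*% t(hs[, t])
        gbh <- gbh + dz
        carry <- drop(crossprod(params$Whh, dz))
      }
      nrm <- sqrt(sum(gWxh^2) + sum(gWhh^2) + sum(gbh^2) +
                  sum(gWhy^2) + sum(gby^2))
      if (nrm > config$clip) {
        scale <- config$clip / nrm
        gWxh <- gWxh * scale; gWhh <- gWhh * scale; gbh <- gbh * scale
        gWhy <- gWhy * scale; gby <- gby * scale
      }
      params$Wxh <- params$Wxh - lr * gWxh
      params$Whh <- params$Whh - lr * gWhh
      params$bh <- params$bh - lr * gbh
      params$Why <- params$Why - lr * gWhy
      params$by <- params$by - lr * gby
    }
  }
  params$emission_idx <- emission_idx
  params
}

rnn_next_distribution <- function(params, vocab, emission, prefix) {
  ids <- c(match(vocab$bos, vocab$symbols), match(prefix, vocab$symbols))
  H <- length(params$bh)
  h <- numeric(H)
  for (id in ids)
    h <- drop(tanh(params$Wxh[, id] + params$Whh %*% h + params$bh))
  p <- drop(rnn_softmax(params$Why %*% h + params$by))
  stats::setNames(as.numeric(p), vocab$symbols[params$emission_idx])
}
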