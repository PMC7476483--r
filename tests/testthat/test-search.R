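make_child <- function(token, s, v, w, p) {
  node <- nmrts:::new_search_node(token, prior = p)
  node$score_sum <- s
  node$visits <- as.integer(v)
  node$virtual_visits <- as.integer(w)
  node
}

test_that("upper confidence bound matches its closed form and conventions", {
  child <- make_child("C", s = 2.0, v = 4, w = 0, p = 0.25)
  expect_equal(ucb_score(child, 10, 0, 1), 0.5 + 0.25 * sqrt(10) / 5)
  expect_equal(ucb_score(child, 10, 0, 1), 0.6581, tolerance = 1e-4)
  # C = 0: exactly the mean score
  expect_equal(ucb_score(child, 10, 0, 0), 0.5)
  # unvisited node: exploitation term is zero, selection driven by C * p
  fresh <- make_child("O", 0, 0, 0, 0.3)
  expect_equal(ucb_score(fresh, 1, 0, 2), 0.6)
  expect_error(ucb_score(child, -1, 0, 1), class = "nmrts_domain_error")
})

test_that("selection picks the exhaustive arg-max over children", {
  set.seed(21)
  for (rep in 1:30) {
    parent <- nmrts:::new_search_node("<bos>")
    parent$visits <- sample(5:50, 1)
    parent$expanded <- TRUE
    n_kids <- sample(2:8, 1)
    for (i in seq_len(n_kids)) {
      v <- sample(0:6, 1)
      parent$children[[paste0("k", i)]] <-
        make_child(paste0("k", i), s = round(runif(1) * v, 3), v = v, w = 0,
                   p = round(runif(1), 3))
    }
    C <- runif(1, 0, 2)
    picked <- nmrts:::select_child_index(parent, C)
    scores <- vapply(parent$children, ucb_score, numeric(1),
                     parent_visits = parent$visits, parent_virtual = 0,
                     exploration_c = C)
    expect_equal(scores[[picked]], max(scores))
  }
})

test_that("virtual visits steer a second in-flight selection away from the first", {
  # two equally likely first symbols, so the first in-flight selection's
  # virtual visit flips the arg-max for the second
  corpus <- c("CC", "OO")
  model <- fit_policy(corpus, policy_config("markov", order = 2, smoothing = 0.01))
  config <- search_config(exploration_c = 1, evaluation_budget = 10, seed = 1)
  # two descents before any backpropagation: the second must diverge at the
  # point where the first's virtual visit changed the arg-max
  root <- new_search_tree(model$vocab)
  sel1 <- nmrts:::mcts_select(root, model, config)
  first_child <- sel1$path[[2]]$token
  expect_equal(root$virtual_visits, 1L)
  sel2 <- nmrts:::mcts_select(root, model, config)
  second_child <- sel2$path[[2]]$token
  expect_false(identical(first_child, second_child))
  expect_equal(root$virtual_visits, 2L)
  # backpropagation releases all virtual visits
  nmrts:::mcts_backprop(sel1$path, 0.5)
  nmrts:::mcts_backprop(sel2$path, 0.25)
  expect_equal(root$virtual_visits, 0L)
  expect_equal(root$visits, 2L)
  expect_equal(root$score_sum, 0.75)
})

test_that("iteration bookkeeping conserves visits and releases virtual visits", {
  model <- fit_policy(fixture_corpus_small()$smiles[1:20], policy_config("markov"))
  config <- search_config(evaluation_budget = 50, seed = 2)
  root <- new_search_tree(model$vocab)
  evaluator <- function(s) score_result(s, 0.5, 0L, 1.0)
  out1 <- run_iteration(root, model, evaluator, config)
  expect_equal(root$visits, 1L)
  expect_equal(root$virtual_visits, 0L)
  out2 <- run_iteration(root, model, evaluator, config)
  expect_equal(root$visits, 2L)
  expect_equal(root$score_sum, 2.0)  # constant evaluator at 1.0

  # deeper conservation: after n iterations all virtual visits are 0 and
  # the root holds every backpropagated score
  root <- new_search_tree(model$vocab)
  cache <- spectrum_cache()
  target <- surrogate_predict(fixture_corpus_small()$smiles[1])
  ev <- function(s) evaluate_candidate(s, target, 5, 10,
                                       fixture_predictor(), cache, 0.1)
  total <- 0
  for (i in 1:40) total <- total + run_iteration(root, model, ev, config)$result$score
  expect_equal(root$visits, 40L)
  expect_equal(root$score_sum, total)
  walk <- function(node) {
    expect_equal(node$virtual_visits, 0L)
    expect_lte(node$score_sum, node$visits + 1e-9)
    kid_visits <- sum(vapply(node$children, function(k) k$visits, integer(1)))
    expect_gte(node$visits, kid_visits)
    for (k in node$children) walk(k)
  }
  walk(root)
})

test_that("trie preloading applies backpropagation bookkeeping along shared prefixes", {
  vocab <- build_vocabulary(c("CC", "CO"))
  root <- new_search_tree(vocab)
  preload_trie(root, data.frame(smiles = c("CC", "CO"), score = c(0.6, 0.4)),
               vocab)
  expect_equal(root$visits, 2L)
  expect_equal(root$score_sum, 1.0)
  c_node <- root$children[["C"]]
  expect_equal(c_node$visits, 2L)
  expect_equal(c_node$score_sum, 1.0)
  expect_equal(c_node$children[["C"]]$visits, 1L)
  expect_equal(c_node$children[["C"]]$score_sum, 0.6)
  expect_equal(c_node$children[["O"]]$score_sum, 0.4)
  # end-marker leaves carry the insertion too
  expect_equal(c_node$children[["C"]]$children[["<eos>"]]$visits, 1L)
  err <- expect_error(
    preload_trie(root, data.frame(smiles = "CS", score = 0.5), vocab),
    class = "nmrts_vocabulary_error")
  expect_match(conditionMessage(err), "CS")
})

test_that("database ranking puts an exact member first and mirrors the evaluator", {
  pred <- fixture_predictor()
  corpus <- fixture_corpus_small()$smiles[1:25]
  db <- build_spectral_database(corpus, pred)
  target_smiles <- corpus[7]
  target <- pred$predict(target_smiles)
  counts <- count_atoms(target_smiles)
  ranked <- rank_database(db, target, counts[["carbon"]], counts[["hydrogen"]],
                          alpha = 0.1)
  expect_identical(ranked$smiles[1], target_smiles)
  expect_identical(ranked$score[1], 1.0)
  expect_true(all(diff(ranked$score) <= 0))
  # same code path as the per-candidate evaluator
  for (i in c(1, 5, 12)) {
    res <- evaluate_candidate(ranked$smiles[i], target, counts[["carbon"]],
                              counts[["hydrogen"]], pred, NULL, 0.1)
    expect_equal(res$score, ranked$score[i])
    expect_equal(res$wasserstein_distance, ranked$wd[i])
  }
  # a single-molecule database is the baseline regardless of score
  db1 <- build_spectral_database(corpus[12], pred)
  r1 <- rank_database(db1, target, 3, 8)
  expect_equal(nrow(r1), 1L)
  expect_error(rank_database(db, numeric(), 3, 8), class = "nmrts_empty_input")
})

test_that("full search conserves counts, respects budgets, and replays under a seed", {
  pred <- fixture_predictor()
  corp <- fixture_corpus_small()
  case <- make_identification_case(corp, 5, pred)
  db <- build_spectral_database(case$corpus, pred)
  model <- fit_policy(case$corpus, policy_config("markov"))
  cfg <- search_config(trie_size = 10, evaluation_budget = 60, seed = 31,
                       early_stop = FALSE)
  res <- run_search(case$spectrum, case$carbon_count, case$hydrogen_count,
                    model, pred, db, cfg)
  # root visits = iterations + preloaded strings; idle tree has no virtual visits
  expect_equal(res$root$visits, res$n_iterations + 10L)
  expect_equal(res$root$virtual_visits, 0L)
  expect_equal(res$n_iterations, 60L)
  # candidate list: sorted, deduplicated, consistent with the trace
  expect_true(all(diff(res$candidates$score) <= 0))
  expect_false(any(duplicated(res$candidates$smiles)))
  expect_equal(max(res$candidates$score), max(res$trace$best_score))
  expect_true(all(diff(res$trace$best_score) >= 0))
  # pinned seed replays the identical search
  res2 <- run_search(case$spectrum, case$carbon_count, case$hydrogen_count,
                     model, pred, db, cfg)
  expect_identical(res$candidates, res2$candidates)
  expect_identical(res$trace, res2$trace)
  # budget of one evaluation
  res1 <- run_search(case$spectrum, case$carbon_count, case$hydrogen_count,
                     model, pred, db,
                     search_config(evaluation_budget = 1, seed = 3))
  expect_equal(res1$n_iterations, 1L)
  expect_error(search_config(evaluation_budget = 0), class = "nmrts_config_error")
})

test_that("an injected oracle rollout closes the loop at score 1.0", {
  pred <- fixture_predictor()
  corp <- fixture_corpus_small()
  for (i in c(3, 9)) {
    case <- make_identification_case(corp, i, pred)
    model <- constant_policy(case$target_smiles)
    res <- run_search(case$spectrum, case$carbon_count, case$hydrogen_count,
                      model, pred, db = NULL,
                      search_config(evaluation_budget = 20, seed = 1))
    expect_identical(res$candidates$score[1], 1.0)
    expect_identical(res$candidates$smiles[1], case$target_smiles)
  }
})

test_that("seeding the trie with the true molecule accelerates identification", {
  pred <- fixture_predictor()
  corp <- fixture_corpus_small()
  for (idx in c(2, 36)) {
    case <- make_identification_case(corp, idx, pred)
    model <- fit_policy(case$corpus, policy_config("markov"))
    # put the target itself at the top of the database
    db <- build_spectral_database(c(case$target_smiles,
                                    case$corpus$smiles[1:20]), pred)
    seeded <- run_search(case$spectrum, case$carbon_count, case$hydrogen_count,
                         model, pred, db,
                         search_config(trie_size = 1, evaluation_budget = 600,
                                       seed = 2))
    expect_identical(seeded$candidates$smiles[1], case$target_smiles)
    expect_identical(seeded$candidates$score[1], 1.0)
    expect_lte(seeded$candidates$iteration[1], 50L)
    # without the preloaded path the same search finds it later or not at all
    bare <- run_search(case$spectrum, case$carbon_count, case$hydrogen_count,
                       model, pred, db,
                       search_config(trie_size = 0, evaluation_budget = 600,
                                     seed = 2))
    found_bare <- nrow(bare$candidates) > 0 && bare$candidates$score[1] >= 1
    expect_true(!found_bare ||
                  bare$candidates$iteration[1] > seeded$candidates$iteration[1])
  }
})
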