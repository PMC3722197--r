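test_that("examples are one per nonzero call with uniform weights", {
  calls <- tibble::tibble(gene = c("g1", "g2"),
                          c1 = c(1L, 1L), c2 = c(1L, 1L), c3 = c(1L, 1L))
  ex <- build_examples(calls)
  expect_equal(nrow(ex), 6)
  expect_equal(ex$weight, rep(1 / 6, 6))
  calls$c2 <- c(0L, -1L)
  ex2 <- build_examples(calls)
  expect_equal(nrow(ex2), 5)  # the zero call is absent
  expect_false(any(ex2$gene == "g1" & ex2$condition == "c2"))
  expect_equal(ex2$label[ex2$gene == "g2" & ex2$condition == "c2"], -1L)
  zero <- tibble::tibble(gene = "g", c1 = 0L)
  expect_error(build_examples(zero), "nothing to learn")
})

test_that("condition predicates follow their truth tables", {
  presence <- matrix(c(TRUE, FALSE), 2, 1,
                     dimnames = list(c("g1", "g2"), "AAACC"))
  feats <- make_features(presence)
  panel <- make_panel(matrix(c(1L, -1L), 1, 2,
                             dimnames = list("tf1", c("c1", "c2"))))
  mot <- list(kind = "motif", motif = "AAACC")
  expect_true(evaluate_condition(mot, "g1", "c1", feats, panel))
  expect_true(evaluate_condition(mot, "g1", "c2", feats, panel))
  expect_false(evaluate_condition(mot, "g2", "c1", feats, panel))
  reg <- list(kind = "regulator_state", tf = "tf1", state = 1L)
  expect_true(evaluate_condition(reg, "g2", "c1", feats, panel))
  expect_false(evaluate_condition(reg, "g2", "c2", feats, panel))
  conj <- list(kind = "conjunction", motif = "AAACC", tf = "tf1", state = 1L)
  expect_equal(
    evaluate_condition(conj, c("g1", "g1", "g2", "g2"),
                       c("c1", "c2", "c1", "c2"), feats, panel),
    c(TRUE, FALSE, FALSE, FALSE)
  )
  expect_error(evaluate_condition(list(kind = "regulator_state", tf = "nope",
                                       state = 1L), "g1", "c1", feats, panel),
               "unknown TF")
})

test_that("best_condition minimises Z over the candidate list", {
  # 6 examples; one motif separates the +1 examples exactly
  presence <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                     3, 2, dimnames = list(paste0("g", 1:3), c("GOODX", "OTHER")))
  presence[, "GOODX"] <- c(TRUE, TRUE, FALSE)
  presence[, "OTHER"] <- c(TRUE, FALSE, TRUE)
  feats <- make_features(presence)
  panel <- make_panel(matrix(c(1L, -1L), 1, 2,
                             dimnames = list("tf1", c("c1", "c2"))))
  calls <- tibble::tibble(gene = paste0("g", 1:3),
                          c1 = c(1L, 1L, -1L), c2 = c(1L, 1L, -1L))
  ex <- build_examples(calls)
  cands <- list(
    list(kind = "motif", motif = "GOODX"),
    list(kind = "motif", motif = "OTHER"),
    list(kind = "regulator_state", tf = "tf1", state = 1L)
  )
  out <- best_condition(cands, ex, feats, panel)
  # brute-force check that no candidate beats the winner
  eps <- 1 / (2 * nrow(ex))
  zs <- vapply(cands, function(cd) {
    sat <- evaluate_condition(cd, ex$gene, ex$condition, feats, panel)
    sp <- sum(ex$weight[sat & ex$label > 0]); sm <- sum(ex$weight[sat & ex$label < 0])
    up <- sum(ex$weight[ex$label > 0]) - sp; um <- sum(ex$weight[ex$label < 0]) - sm
    2 * (sqrt((sp + eps) * (sm + eps)) + sqrt((up + eps) * (um + eps)))
  }, numeric(1))
  expect_equal(out$z, min(zs))
  expect_equal(out$condition$motif, "GOODX")
  # duplicating the candidate list cannot change the selection
  out2 <- best_condition(c(cands, cands), ex, feats, panel)
  expect_equal(out2$condition, out$condition)
})

test_that("exact ties break by kind order then lexicographic form", {
  # all labels identical: every candidate has the same Z
  presence <- matrix(TRUE, 2, 2,
                     dimnames = list(c("g1", "g2"), c("AAAAA", "CCCCC")))
  feats <- make_features(presence)
  panel <- make_panel(matrix(1L, 1, 2, dimnames = list("atf", c("c1", "c2"))))
  calls <- tibble::tibble(gene = c("g1", "g2"), c1 = c(1L, 1L), c2 = c(1L, 1L))
  ex <- build_examples(calls)
  cands <- list(
    list(kind = "motif", motif = "CCCCC"),
    list(kind = "motif", motif = "AAAAA"),
    list(kind = "regulator_state", tf = "atf", state = 1L)
  )
  out <- best_condition(cands, ex, feats, panel)
  expect_equal(out$condition$kind, "regulator_state")  # kind wins first
  out_m <- best_condition(cands[1:2], ex, feats, panel)
  expect_equal(out_m$condition$motif, "AAAAA")          # then lexicographic
})

test_that("a separable toy is solved in one round", {
  toy <- separable_toy()
  m <- boost_train(toy$examples, toy$features, toy$panel, rounds = 1, seed = 1,
                   config = boost_config(subsample = 1))
  expect_equal(nrow(m$rules), 1)
  expect_equal(m$trace$train_error, 0)
  f <- predict_score(m, c("g1", "g3"), "c1", toy$features, toy$panel)
  expect_true(f[1] > 0 && f[2] < 0)
  expect_error(boost_train(toy$examples, toy$features, toy$panel, rounds = 0),
               "rounds")
})

test_that("training error never exceeds the product of round normalisers", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    eps <- 1 / (4 * nrow(inst$examples))  # small enough to guarantee Z <= 1
    m <- boost_train(inst$examples, inst$features, inst$panel,
                     rounds = 12, seed = seed,
                     config = boost_config(epsilon = eps))
    bound <- cumprod(m$trace$z)
    expect_true(all(m$trace$train_error <= bound + 1e-12),
                info = paste("seed", seed))
    # the selection Z carries the smoothing inflation: Z <= 1 + 4 eps by AM-GM
    expect_true(all(m$trace$z <= 1 + 4 * eps + 1e-12))
    # the true normaliser never exceeds 1, so exponential loss is non-increasing
    expect_true(all(m$trace$normalizer <= 1 + 1e-12))
  }
})

test_that("training is bit-reproducible for a fixed seed", {
  inst <- random_instance(99)
  m1 <- boost_train(inst$examples, inst$features, inst$panel, rounds = 8, seed = 5)
  m2 <- boost_train(inst$examples, inst$features, inst$panel, rounds = 8, seed = 5)
  expect_identical(m1, m2)
  m3 <- boost_train(inst$examples, inst$features, inst$panel, rounds = 8, seed = 6)
  expect_false(identical(m1$rules, m3$rules))
})

test_that("training restores the caller's RNG state", {
  inst <- random_instance(1)
  set.seed(123)
  before <- .Random.seed
  invisible(boost_train(inst$examples, inst$features, inst$panel,
                        rounds = 3, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("margin scores are empty-sum, per-rule and additive", {
  toy <- separable_toy()
  empty <- boost_train(toy$examples, toy$features, toy$panel, rounds = 1,
                       seed = 1, config = boost_config(subsample = 1))
  empty$rules <- empty$rules[0, ]
  expect_equal(predict_score(empty, "g1", "c1", toy$features, toy$panel), 0)
  one <- empty
  one$rules <- tibble::tibble(
    round = 1L, kind = "motif", motif = "AAAAA", tf = NA_character_,
    state = NA_integer_, alpha_sat = 0.7, alpha_unsat = -0.2, z = 0.9
  )
  expect_equal(predict_score(one, "g1", "c1", toy$features, toy$panel), 0.7)
  expect_equal(predict_score(one, "g3", "c1", toy$features, toy$panel), -0.2)
  two <- one
  two$rules <- dplyr::bind_rows(one$rules, one$rules)
  expect_equal(
    predict_score(two, c("g1", "g3"), "c1", toy$features, toy$panel),
    2 * predict_score(one, c("g1", "g3"), "c1", toy$features, toy$panel)
  )
  expect_error(predict_score(one, "missing_gene", "c1", toy$features, toy$panel),
               "unknown gene")
})
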