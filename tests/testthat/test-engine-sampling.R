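test_that("apply_constraints implements the three rule kinds", {
  vocab <- c("X", "Y", "Z", "W")
  p <- c(0.5, 0.6, 0.7, 0.2)
  # forbid-token zeroes its consequent regardless of the partial visit
  r1 <- constraint_rules(list(kind = "forbid-token", antecedent = character(0),
                              consequent = "Z"))
  out <- apply_constraints(p, c(0, 0, 0, 0), r1, vocab)
  expect_equal(out, c(0.5, 0.6, 0, 0.2))
  # forbid-co-occurrence masks either side once the other is active
  r2 <- constraint_rules(list(kind = "forbid-co-occurrence",
                              antecedent = "X", consequent = "Y"))
  expect_equal(apply_constraints(p, c(1, 0, 0, 0), r2, vocab)[2], 0)
  expect_equal(apply_constraints(p, c(0, 1, 0, 0), r2, vocab)[1], 0)
  # require-if forces the consequent once the antecedent is active
  r3 <- constraint_rules(list(kind = "require-if", antecedent = "X",
                              consequent = "W"))
  expect_equal(apply_constraints(p, c(1, 0, 0, 0), r3, vocab)[4], 1)
  expect_equal(apply_constraints(p, c(0, 1, 0, 0), r3, vocab), p)
  # no rules -> identity
  expect_equal(apply_constraints(p, c(1, 1, 1, 1), constraint_rules(), vocab),
               p)
  # contradictory rules are an error
  r4 <- constraint_rules(
    list(kind = "forbid-token", antecedent = character(0), consequent = "W"),
    list(kind = "require-if", antecedent = "X", consequent = "W"))
  expect_error(apply_constraints(p, c(1, 0, 0, 0), r4, vocab),
               "contradictory")
  # unknown tokens are rejected
  expect_error(apply_constraints(p, p * 0, constraint_rules(
    list(kind = "forbid-token", antecedent = character(0),
         consequent = "nope")), vocab), "absent from the vocabulary")
})

test_that("sampling is deterministic and respects the record invariants", {
  model <- ab_model()
  s1 <- sample_patients(model, 5, rng_seed = 99)
  s2 <- sample_patients(model, 5, rng_seed = 99)
  expect_identical(s1$records, s2$records)
  s3 <- sample_patients(model, 5, rng_seed = 100)
  expect_false(identical(s1$records, s3$records))
  # every record has between 1 and max_visits visits
  nv <- vapply(s1$records, function(r) length(r$visits), numeric(1))
  expect_true(all(nv >= 1 & nv <= model$schema$max_visits))
})

test_that("forbid-co-occurrence yields zero violations in generated data", {
  model <- ab_model()
  rules <- constraint_rules(list(kind = "forbid-co-occurrence",
                                 antecedent = "c:diagnosis:AAA",
                                 consequent = "c:diagnosis:CCC"))
  synth <- sample_patients(model, 400, rng_seed = 17, rules = rules)
  prov <- synth$provenance
  ia <- prov$index[prov$token == "c:diagnosis:AAA"]
  ic <- prov$index[prov$token == "c:diagnosis:CCC"]
  viol <- vapply(synth$records, function(r)
    any(vapply(r$visits, function(v) ia %in% v && ic %in% v, logical(1))),
    logical(1))
  expect_equal(sum(viol), 0)
  # the same model without rules does produce co-occurrences (the rule
  # actually bites: AAA and CCC co-occur in half the training visits)
  free <- sample_patients(model, 400, rng_seed = 17)
  viol_free <- vapply(free$records, function(r)
    any(vapply(r$visits, function(v) ia %in% v && ic %in% v, logical(1))),
    logical(1))
  expect_gt(sum(viol_free), 0)
})

test_that("require-if rules force their consequent in generated visits", {
  model <- ab_model()
  rules <- constraint_rules(list(kind = "require-if",
                                 antecedent = "c:diagnosis:AAA",
                                 consequent = "c:diagnosis:BBB"))
  synth <- sample_patients(model, 200, rng_seed = 23, rules = rules)
  prov <- synth$provenance
  ia <- prov$index[prov$token == "c:diagnosis:AAA"]
  ib <- prov$index[prov$token == "c:diagnosis:BBB"]
  for (r in synth$records) {
    for (v in r$visits) {
      if (ia %in% v) expect_true(ib %in% v)
    }
  }
})

test_that("conditioning clamps label tokens and validates them", {
  prep <- small_prepared()
  # a 2-epoch engine is enough to exercise the clamping mechanics
  model <- memo("tiny_sim_model", function()
    train_engine(prep$toks$train, prep$toks$validation,
                 engine_config(n_layers = 1, embedding_dim = 32, n_heads = 2,
                               epochs = 2, seed = 2)))
  synth <- sample_patients(model, 30, rng_seed = 3,
                           condition_labels = "l:diabetes")
  prov <- model$provenance
  lab <- prov$index[prov$token == "l:diabetes"]
  expect_true(all(vapply(synth$records, function(r) lab %in% r$static,
                         logical(1))))
  expect_error(sample_patients(model, 3, rng_seed = 1,
                               condition_labels = "l:unicorn"),
               "label tokens")
})
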