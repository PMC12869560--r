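mk_dx_cohort <- function(counts) {
  codes <- rep(names(counts), counts)
  n <- length(codes)
  patients <- tibble::tibble(patient_id = "p1", gender = "F", age = 50)
  visits <- tibble::tibble(
    patient_id = "p1", visit_id = paste0("v", seq_len(n)),
    start_time = as.POSIXct("2019-01-07", tz = "UTC") + seq_len(n) * 86400,
    event_type = "ED", los_total = 1, los_treatment = NA)
  schema <- toy_schema()
  schema$max_visits <- n
  schema$code_systems <- list(diagnosis = names(counts))
  ehr_cohort(patients, visits,
             tibble::tibble(patient_id = "p1",
                            visit_id = paste0("v", seq_len(n)),
                            code = codes), schema)
}

test_that("codes at or above the threshold are unchanged", {
  co <- mk_dx_cohort(c(I21.0 = 60))
  res <- aggregate_codes(co, min_count = 50, prefix_lengths = c(3, 2))
  expect_true(all(res$cohort$diagnoses$code == "I21.0"))
  expect_identical(unname(res$map$forward[["I21.0"]]), "I21.0")
})

test_that("rare codes pool to the longest prefix reaching the threshold", {
  co <- mk_dx_cohort(c(I21.0 = 30, I21.9 = 30))
  res <- aggregate_codes(co, min_count = 50, prefix_lengths = 3)
  expect_true(all(res$cohort$diagnoses$code == "I21"))
})

test_that("shortest candidate is the fallback when no prefix reaches it", {
  co <- mk_dx_cohort(c(Z99.1 = 5, Z98.0 = 7))
  res <- aggregate_codes(co, min_count = 50, prefix_lengths = c(3, 2))
  expect_identical(unname(res$map$forward[["Z99.1"]]), "Z9")
  expect_identical(unname(res$map$forward[["Z98.0"]]), "Z9")
})

test_that("aggregation matches a brute-force oracle on random vocabularies", {
  brute <- function(counts, min_count, lens) {
    rare <- names(counts)[counts < min_count]
    fwd <- stats::setNames(names(counts), names(counts))
    for (code in rare) {
      got <- substr(code, 1, min(lens))
      for (len in sort(lens, decreasing = TRUE)) {
        pooled <- sum(counts[rare][substr(rare, 1, len) ==
                                     substr(code, 1, len)])
        if (pooled >= min_count) { got <- substr(code, 1, len); break }
      }
      fwd[code] <- got
    }
    fwd
  }
  set.seed(7)
  for (i in 1:5) {
    roots <- c("A10", "A11", "B20", "C33", "Z99")
    vocab <- paste0(sample(roots, 12, replace = TRUE), ".",
                    sample(0:9, 12, replace = TRUE))
    vocab <- unique(vocab)
    counts <- stats::setNames(sample(1:40, length(vocab), replace = TRUE),
                              vocab)
    co <- mk_dx_cohort(counts)
    res <- aggregate_codes(co, min_count = 25, prefix_lengths = c(3, 2))
    want <- brute(counts, 25, c(3, 2))
    expect_identical(res$map$forward[sort(names(res$map$forward))],
                     want[sort(names(want))])
    # vocabulary never grows
    expect_lte(length(unique(res$cohort$diagnoses$code)), length(vocab))
    # every aggregated bucket meets the threshold or is the fallback
    newc <- table(res$cohort$diagnoses$code)
    for (code in names(newc)) {
      if (code %in% vocab) next
      expect_true(newc[[code]] >= 25 || nchar(code) == 2)
    }
  }
})

test_that("expansion reproduces the stored empirical distribution", {
  map <- structure(list(
    forward = c(I21.0 = "I21", I21.9 = "I21", J45.0 = "J45.0"),
    empirical = tibble::tibble(
      aggregated = rep("I21", 4),
      stratum = c("F", "F", "(pooled)", "(pooled)"),
      code = c("I21.0", "I21.9", "I21.0", "I21.9"),
      n = c(7, 3, 7, 3), prob = c(0.7, 0.3, 0.7, 0.3)),
    stratify_by = "gender"), class = "code_aggregation_map")
  set.seed(1)
  out <- expand_codes(rep("I21", 10000), "F", map)
  expect_true(all(out %in% c("I21.0", "I21.9")))
  expect_lt(abs(mean(out == "I21.0") - 0.7), 0.02)
  # unseen stratum falls back to the pooled table
  out2 <- expand_codes(rep("I21", 2000), "X", map)
  expect_lt(abs(mean(out2 == "I21.0") - 0.7), 0.05)
  # never-aggregated codes pass through unchanged
  expect_identical(expand_codes("J45.0", "F", map), "J45.0")
  # single-entry table expands deterministically
  map1 <- map
  map1$empirical <- map1$empirical[c(1, 3), ]
  map1$empirical$prob <- 1
  expect_true(all(expand_codes(rep("I21", 50), "F", map1) == "I21.0"))
  # unknown aggregated code warns and passes through
  expect_warning(out3 <- expand_codes("QQ", "F", map), "unknown")
  expect_identical(out3, "QQ")
})
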