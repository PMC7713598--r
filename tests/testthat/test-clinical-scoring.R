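# actions under toy_target (1, 2, 3): card 1 sorts by color, card 2 by
# shape, card 3 by number, card 4 matches nothing; rule starts at color

test_that("perseverative errors follow the perseverated-to principle", {
  # 10 correct by color completes the category; the rule becomes shape and
  # continuing to sort by color is perseverative
  acts <- c(rep(1, 10), 1, 1, 2)
  cls <- classify_errors(toy_session(acts))
  expect_equal(as.character(cls$response_type[11:12]),
               c("perseverative", "perseverative"))
  expect_equal(as.character(cls$response_type[13]), "correct")
  # an error by number after the change is non-perseverative
  cls <- classify_errors(toy_session(c(rep(1, 10), 3)))
  expect_equal(as.character(cls$response_type[11]), "other_error")
  # errors before the first change are never perseverative
  cls <- classify_errors(toy_session(c(2, 3, 1)))
  expect_equal(as.character(cls$response_type[1:2]),
               c("other_error", "other_error"))
})

test_that("scoring criteria differ only on ambiguous principle matches", {
  # after completing the color category the rule is shape; choosing card 1
  # on target (1, 3, 1) is an error matching the old principle ambiguously
  # (card 1 = one red triangle matches color AND number)
  base <- toy_session(rep(1, 10))
  amb_target <- c(1L, 3L, 1L)
  mv <- match_vector(amb_target, 1L)
  expect_equal(mv, c(1L, 0L, 1L))
  amb_row <- base[1, ]
  amb_row$trial <- 11L
  amb_row[c("target_color", "target_shape", "target_number")] <-
    as.list(as.integer(amb_target))
  amb_row$action <- 1L
  amb_row[c("match_color", "match_shape", "match_number")] <- as.list(mv)
  amb_row$true_rule <- 2L
  amb_row$feedback <- 0L
  amb_row$rule_change <- FALSE
  s <- dplyr::bind_rows(base, amb_row)
  expect_equal(as.character(classify_errors(s, "principle")$response_type[11]),
               "perseverative")
  expect_equal(as.character(classify_errors(s, "unambiguous")$response_type[11]),
               "other_error")
  # sandwich: the same ambiguous error flanked by two unambiguous PEs
  pe_row <- s[11, ]
  pe_row$target_color <- 1L; pe_row$target_shape <- 4L; pe_row$target_number <- 4L
  pe_row[c("match_color", "match_shape", "match_number")] <-
    as.list(match_vector(c(1, 4, 4), 1L))   # color only
  s3 <- dplyr::bind_rows(base, pe_row, s[11, ], pe_row)
  s3$trial <- seq_len(nrow(s3))
  cls <- classify_errors(s3, "sandwich")
  expect_equal(as.character(cls$response_type[11:13]),
               rep("perseverative", 3))
})

test_that("trials to first category counts to the end of the first run", {
  expect_equal(trials_to_first_category(toy_session(rep(1, 12)))$trials, 10)
  # six correct, one error, ten correct: category completes at trial 17
  tfc <- trials_to_first_category(toy_session(c(rep(1, 6), 2, rep(1, 10))))
  expect_equal(tfc$trials, 17)
  expect_false(tfc$censored)
  # never completed: censored at session length
  tfc <- trials_to_first_category(toy_session(rep(c(1, 1, 2), 10)))
  expect_equal(tfc$trials, 30)
  expect_true(tfc$censored)
})

test_that("failures to maintain set require five correct under the same rule", {
  # 6 correct, error, 10 correct: the set was acquired, one failure
  s <- toy_session(c(rep(1, 6), 2, rep(1, 10)))
  expect_equal(failures_to_maintain_set(s), 1)
  # 4 correct then an error: set not acquired
  expect_equal(failures_to_maintain_set(toy_session(c(rep(1, 4), 2))), 0)
  # a perfect agent never fails to maintain the set, and the error right
  # after a completed category is not a failure (the rule changed)
  expect_equal(failures_to_maintain_set(toy_session(rep(1, 20))), 0)
})

test_that("score_session aggregates consistently", {
  s <- toy_session(c(rep(1, 10), 1, 2, rep(2, 9), 3))
  rep <- score_session(s)
  expect_equal(rep$total_errors,
               rep$perseverative_errors + rep$other_errors)
  expect_equal(rep$trials_to_first_category, 10)
  expect_equal(rep$categories_completed, 2)
  # a perfect session on the default protocol
  perfect <- score_session(toy_session(rep(1, 10)))
  expect_equal(perfect$total_errors, 0)
  expect_equal(perfect$failures_to_maintain_set, 0)
  # determinism: identical sessions yield identical reports
  s2 <- run_agent(agent_params(0.3, 0.7), task_config(), seed = 55)
  expect_identical(score_session(s2), score_session(s2))
  expect_error(score_session(dplyr::select(tibble::as_tibble(s2), -"true_rule")),
               "true-rule")
})
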