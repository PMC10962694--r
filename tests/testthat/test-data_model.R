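test_that("delays are signed distances and translation-equivariant", {
  expect_equal(compute_delays(c(1, 4, 9), 10), c(9, 6, 1))
  expect_equal(compute_delays(c(12), 10), -2)
  expect_equal(compute_delays(c(10), 10), 0)
  expect_equal(compute_delays(numeric(0), 3), numeric(0))
  # shifting every timestamp by a constant leaves delays unchanged
  t <- c(0.3, 1.7, 2.2)
  expect_equal(compute_delays(t, 5), compute_delays(t + 1234.5, 5 + 1234.5),
               tolerance = 1e-10)
  # data.frame input goes through the time column
  expect_equal(compute_delays(data.frame(time = c(1, 2)), 4), c(3, 2))
})

test_that("sentence-cycled partition follows (e + u) mod 4", {
  expect_equal(assign_partition_sentence(0, 0), "train")
  expect_equal(assign_partition_sentence(1, 1), "exploratory")
  expect_equal(assign_partition_sentence(3, 0), "test")
  expect_error(assign_partition_sentence(-1, 0), "nonnegative")
  # complete cycle: exactly 2/4 train, 1/4 exploratory, 1/4 test
  grid <- expand.grid(e = 0:7, u = 0:3)
  lab <- assign_partition_sentence(grid$e, grid$u)
  expect_equal(unname(table(lab)["train"]) / nrow(grid), 0.5)
  expect_equal(unname(table(lab)["exploratory"]) / nrow(grid), 0.25)
  expect_equal(unname(table(lab)["test"]) / nrow(grid), 0.25)
})

test_that("chunk-cycled partition shares labels within chunks and halves train", {
  # all samples of one chunk share a label
  lab <- assign_partition_chunk(0:14, u = 0, chunk_len = 15)
  expect_length(unique(lab), 1L)
  # chunk_len = 1 reduces to per-sample cycling
  expect_equal(assign_partition_chunk(0:3, 0, 1),
               c("train", "train", "exploratory", "test"))
  # full enumeration over 4 * chunk_len samples: exactly half train
  for (cl in c(1L, 3L, 15L)) {
    lab <- assign_partition_chunk(seq_len(4 * cl) - 1L, u = 2, chunk_len = cl)
    expect_equal(sum(lab == "train"), 2 * cl)
    expect_equal(sum(lab == "exploratory"), cl)
    expect_equal(sum(lab == "test"), cl)
  }
  expect_error(assign_partition_chunk(0, 0, 0), "positive")
})

test_that("partition_responses labels by scheme and participant phase", {
  rs <- data.frame(participant = rep(c("a", "b"), each = 6),
                   sentence = rep(0:5, 2))
  out <- partition_responses(rs, "sentence")
  expect_equal(out$partition_label[1:4], c("train", "train", "exploratory",
                                           "test"))
  # participant b is phase-shifted by one
  expect_equal(out$partition_label[7], "train")
  expect_equal(out$partition_label[8], "exploratory")
  out2 <- partition_responses(rs, "chunk", chunk_len = 3)
  expect_equal(out2$partition_label[1:6],
               c(rep("train", 3), rep("train", 3)))
})

test_that("self-paced reading filter applies the printed rules in order", {
  tab <- data.frame(duration = c(50, 150, 200, 3500, 400, 600),
                    participant = "p1",
                    sentence_initial = FALSE, sentence_final = FALSE)
  res <- filter_spr(tab, question_misses = c(p1 = 0), min_responses = 1)
  expect_equal(nrow(res$data), 4L)  # 50 and 3500 removed
  expect_equal(unname(res$report["n_duration"]), 2)
  # strict bounds: exactly 100 and 3000 are retained
  tab2 <- data.frame(duration = c(100, 3000, 99.9, 3000.1),
                     participant = "p1",
                     sentence_initial = FALSE, sentence_final = FALSE)
  expect_equal(nrow(filter_spr(tab2, c(p1 = 0), min_responses = 1)$data), 2L)
  # participant with >= 4 missed questions loses every row
  res3 <- filter_spr(tab, question_misses = c(p1 = 5), min_responses = 1)
  expect_equal(nrow(res3$data), 0L)
  # no rule fires -> identity
  tab4 <- data.frame(duration = rep(500, 120), participant = "p1",
                     sentence_initial = FALSE, sentence_final = FALSE)
  res4 <- filter_spr(tab4, c(p1 = 0), min_responses = 100)
  expect_identical(res4$data, tab4)
  # idempotence and count bookkeeping
  res5 <- filter_spr(res$data, c(p1 = 0), min_responses = 1)
  expect_identical(res5$data, res$data)
  expect_equal(unname(res$report["n_input"] - res$report["n_output"]),
               unname(res$report["n_duration"] +
                        res$report["n_sentence_boundary"] +
                        res$report["n_missed_questions"] +
                        res$report["n_low_response"]))
  expect_error(filter_spr(tab[, -1], c(p1 = 0)), "duration")
})

test_that("eye-tracking filter is strict on saccade length and blinks", {
  base <- data.frame(fixated = TRUE, saccade_len = c(5, 4, 2, 2),
                     blink = c(FALSE, FALSE, TRUE, FALSE),
                     sentence_start = FALSE, sentence_end = FALSE)
  res <- filter_et(base)
  # saccade of 5 excluded, 4 retained; blink excluded; one clean row stays
  expect_equal(nrow(res$data), 2L)
  expect_equal(unname(res$report["n_long_saccade"]), 1)
  expect_equal(unname(res$report["n_blink"]), 1)
  # boundary flags drop rows
  base$sentence_end <- c(FALSE, TRUE, FALSE, FALSE)
  expect_equal(nrow(filter_et(base)$data), 1L)
  # unfixated rows removed first
  base2 <- data.frame(fixated = c(FALSE, TRUE), saccade_len = 0,
                      blink = FALSE)
  expect_equal(nrow(filter_et(base2)$data), 1L)
  expect_error(filter_et(base2[, -1]), "fixated")
  # idempotence
  expect_identical(filter_et(res$data)$data, res$data)
})

test_that("regression split partitions each predictor exactly", {
  tab <- data.frame(x = c(3, -1, 2), z = c(1, 1, 0),
                    in_regression = c(TRUE, FALSE, TRUE))
  out <- split_by_regression(tab, c("x", "z"))
  expect_equal(out$x_plusreg, c(3, 0, 2))
  expect_equal(out$x_minusreg, c(0, -1, 0))
  expect_equal(out$x_plusreg + out$x_minusreg, tab$x)
  expect_equal(sum(out$z_plusreg) + sum(out$z_minusreg), sum(tab$z))
  expect_false("x" %in% names(out))
  expect_error(split_by_regression(tab[, 1:2], "x"), "in_regression")
})
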