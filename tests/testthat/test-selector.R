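toy_events <- function(n, seed = 5) {
  set.seed(seed)
  ev <- data.frame(E1 = runif(n, 0.1, 4), E2 = runif(n, 0.1, 4))
  ev$label <- ifelse(ev$E1 + ev$E2 > 3, "signal", "background")
  ev
}

test_that("the network learns a separable energy rule", {
  ev <- toy_events(4000)
  model <- train_selector(ev, epochs = 60, seed = 1)
  pred <- predict(model, ev) > 0.5
  acc <- mean(pred == (ev$label == "signal"))
  expect_gte(acc, 0.99)
  expect_lt(tail(model$history$train_bce, 1), model$history$train_bce[1])
})

test_that("training is deterministic given the seed", {
  ev <- toy_events(800)
  m1 <- train_selector(ev, epochs = 5, seed = 3)
  m2 <- train_selector(ev, epochs = 5, seed = 3)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W3, m2$W3)
})

test_that("degenerate single-class training is refused", {
  ev <- toy_events(100)
  ev$label <- "background"
  expect_error(train_selector(ev), class = "pg_degenerate_training")
})

test_that("selection respects the strict 0.5 threshold", {
  ev <- toy_events(50)
  accept_all <- selector_model(matrix(0, 2, 1), 0, matrix(0, 1, 1), 0,
                               matrix(0, 1, 1), 50)
  expect_equal(nrow(select_events(accept_all, ev)), 50)
  # constant output exactly 0.5: boundary excluded
  boundary <- selector_model(matrix(0, 2, 1), 0, matrix(0, 1, 1), 0,
                             matrix(0, 1, 1), 0)
  expect_identical(predict(boundary, ev)[1], 0.5)
  expect_equal(nrow(select_events(boundary, ev)), 0)
  # idempotence
  once <- select_events(accept_all, ev)
  expect_equal(select_events(accept_all, once), once)
})

test_that("selection metrics reproduce the reference worked example", {
  m <- selection_metrics_counts(n_total = 6.1e5, n_signal = 4.7e4,
                                n_accepted = 3.8e5,
                                n_accepted_signal = 3.9e4)
  expect_equal(round(m$precision, 1), 10.3)
  expect_equal(m$signal_fraction_after, m$precision)
  expect_gt(m$relative_increase, 0)
})

test_that("selection metrics handle edge cases", {
  ev <- toy_events(200)
  # perfect classifier
  perfect <- ev[ev$label == "signal", ]
  m <- selection_metrics(ev, perfect)
  expect_equal(m$recall, 100)
  expect_equal(m$precision, 100)
  # accept-all: precision equals prevalence
  m2 <- selection_metrics(ev, ev)
  expect_equal(m2$precision, 100 * mean(ev$label == "signal"))
  expect_equal(m2$relative_increase, 0)
  # empty selection: undefined, signalled distinctly
  expect_error(selection_metrics(ev, ev[0, ]), class = "pg_undefined")
  # missing labels: refused cleanly
  ev_na <- ev; ev_na$label <- NA_character_
  expect_error(selection_metrics(ev_na, ev_na), class = "pg_schema_error")
})

test_that("saved models reproduce scores exactly", {
  ev <- toy_events(600)
  model <- train_selector(ev, epochs = 4, seed = 2)
  path <- tempfile(fileext = ".json")
  save_selector(model, path)
  reloaded <- load_selector(path)
  expect_identical(predict(model, ev), predict(reloaded, ev))
  expect_error(load_selector(tempfile()), "no such file")
})
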