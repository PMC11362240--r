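test_that("bell_design matches the stated trial structure", {
  d <- bell_design(138)
  expect_equal(d$n_participants, 138L)
  expect_equal(sum(d$design$items), 80)
  percond <- tapply(d$design$items,
                    sub("^.*_", "", d$design$tree), sum)
  expect_equal(as.vector(percond), c(40, 40))
  d1 <- bell_design(1)
  expect_equal(d1$n_participants, 1L)
  d2 <- bell_design(10, new_split = c(30L, 10L))
  expect_equal(sum(d2$design$items[grepl("^new_", d2$design$tree)]), 40)
})

test_that("generation is deterministic given the seed", {
  m <- build_2htsm()
  g1 <- generate_dataset(m, smoke_design(5), smoke_truth(), seed = 3)
  g2 <- generate_dataset(m, smoke_design(5), smoke_truth(), seed = 3)
  expect_equal(as.data.frame(g1$data), as.data.frame(g2$data))
  g3 <- generate_dataset(m, smoke_design(5), smoke_truth(), seed = 4)
  expect_false(identical(as.data.frame(g1$data), as.data.frame(g3$data)))
})

test_that("degenerate memory truth yields perfect source answers", {
  m <- build_2htsm()
  truth <- list(group_prob = c(D = 1, d = 1, b = 0.5, g = 0.5), sigma = 0)
  gen <- generate_dataset(m, smoke_design(8), truth, seed = 2)
  expect_true(all(gen$data[["sourceA:A"]] == 20))
  expect_true(all(gen$data[["sourceB:B"]] == 20))
  expect_true(all(gen$data[["new:New"]] == 40))
})

test_that("the guessing path is binomial with probability g", {
  m <- build_2htsm()
  truth <- list(group_prob = c(D = 0, d = 0.5, b = 1, g = 0.7), sigma = 0)
  gen <- generate_dataset(m, smoke_design(2000), truth, seed = 6)
  k <- sum(gen$data[["new:A"]])
  n <- 2000 * 40
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(k / n - 0.7), 3 * se)
})

test_that("empirical frequencies converge to category_probabilities (LLN)", {
  m <- build_2htsm()
  design <- study_design(c(sourceA = 1e5L, sourceB = 1e5L, new = 1e5L), 1)
  truth <- list(group_prob = c(D = 0.55, d = 0.35, b = 0.45, g = 0.6),
                sigma = 0)
  gen <- generate_dataset(m, design, truth, seed = 8)
  th <- matrix(truth$group_prob, 1,
               dimnames = list(NULL, names(truth$group_prob)))
  want <- category_probabilities(m, th)
  for (i in seq_len(nrow(want))) {
    cell <- paste0(want$tree[i], ":", want$category[i])
    p <- want$prob[i]
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(gen$data[[cell]][1] / 1e5 - p), 3 * se + 1e-9)
  }
})

test_that("truth can be drawn from a prior specification", {
  m <- build_2htsm()
  gen <- generate_dataset(m, smoke_design(3), informative_preset(m), seed = 9)
  expect_equal(nrow(gen$truth), 4)
  expect_true(all(is.finite(gen$truth$mu)))
  expect_true(all(gen$truth$sigma >= 0))
})

test_that("design/model tree mismatches error", {
  m <- build_2htsm()
  bad <- study_design(c(foo = 10L), 2)
  expect_error(generate_dataset(m, bad, smoke_truth(), seed = 1),
               class = "ordtree_value_error")
})

test_that("recovery summaries satisfy RMSE >= |bias|", {
  reports <- list(
    tibble::tibble(parameter = c("D", "d"), truth = c(0.5, 0.4),
                   estimate = c(0.52, 0.35), error = c(0.02, -0.05),
                   conf.low = c(0.4, 0.3), conf.high = c(0.6, 0.5),
                   covered = c(TRUE, TRUE)),
    tibble::tibble(parameter = c("D", "d"), truth = c(0.5, 0.4),
                   estimate = c(0.46, 0.44), error = c(-0.04, 0.04),
                   conf.low = c(0.4, 0.3), conf.high = c(0.6, 0.5),
                   covered = c(TRUE, FALSE))
  )
  s <- recovery_summary(reports)
  expect_true(all(s$rmse >= abs(s$bias) - 1e-12))
  expect_true(all(s$coverage >= 0 & s$coverage <= 1))
  expect_equal(s$coverage[s$parameter == "d"], 0.5)
})
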