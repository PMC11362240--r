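test_that("EQN parsing handles headers, comments, and branch terms", {
  txt <- c("2", "# a comment", "T x p", "T y (1-p)  # trailing comment")
  m <- parse_eqn(txt)
  expect_s3_class(m, "mpt_model")
  expect_equal(m$parameters, "p")
  expect_equal(vapply(m$trees, `[[`, character(1), "name"), "T")
  expect_setequal(m$trees[[1]]$categories, c("x", "y"))
})

test_that("EQN labels are case-sensitive", {
  m <- parse_eqn(c("T x p", "T y (1-p)", "t x q", "t y (1-q)"))
  expect_setequal(vapply(m$trees, `[[`, character(1), "name"), c("T", "t"))
  expect_setequal(m$parameters, c("p", "q"))
})

test_that("malformed EQN lines raise format errors naming the line", {
  expect_error(parse_eqn("T x"), class = "ordtree_format_error")
  expect_error(parse_eqn("T x p^2"), class = "ordtree_format_error")
  err <- tryCatch(parse_eqn(c("T x p", "T y 1-p+")), error = identity)
  expect_s3_class(err, "ordtree_format_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("structurally invalid models fail branch-sum validation", {
  expect_error(parse_eqn(c("T x p", "T y p")),
               class = "ordtree_structure_error")
  # validation can be disabled
  m <- parse_eqn(c("T x p", "T y p"), validate = FALSE)
  expect_s3_class(m, "mpt_model")
})

test_that("EQN round-trips through write_eqn", {
  m <- build_2htsm()
  path <- withr::local_tempfile(fileext = ".eqn")
  write_eqn(m, path)
  m2 <- read_eqn(path)
  th <- matrix(c(0.3, 0.6, 0.4, 0.7), 1,
               dimnames = list(NULL, c("D", "d", "b", "g")))
  p1 <- category_probabilities(m, th)
  p2 <- category_probabilities(m2, th)
  p2 <- p2[match(paste(p1$tree, p1$category), paste(p2$tree, p2$category)), ]
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
})

test_that("2HTSM category probabilities match hand computation", {
  m <- build_2htsm()
  D <- 0.6; d <- 0.3; b <- 0.4; g <- 0.55
  th <- matrix(c(D, d, b, g), 1, dimnames = list(NULL, c("D", "d", "b", "g")))
  probs <- ordtree:::compute_tree_probs(m, th)
  names(probs) <- vapply(m$trees, `[[`, character(1), "name")
  expect_equal(unname(probs$sourceA[1, "A"]),
               D * d + D * (1 - d) * g + (1 - D) * b * g, tolerance = 1e-12)
  expect_equal(unname(probs$sourceB[1, "B"]),
               D * d + D * (1 - d) * (1 - g) + (1 - D) * b * (1 - g),
               tolerance = 1e-12)
  expect_equal(unname(probs$new[1, "New"]),
               D + (1 - D) * (1 - b), tolerance = 1e-12)
})

test_that("tree probabilities sum to one at random parameter points", {
  for (m in list(build_2htsm(), build_2htsm_bell())) {
    set.seed(42)
    th <- matrix(runif(10 * length(m$parameters)), 10,
                 dimnames = list(NULL, m$parameters))
    for (pm in ordtree:::compute_tree_probs(m, th)) {
      expect_equal(unname(rowSums(pm)), rep(1, 10), tolerance = 1e-12)
    }
  }
})

test_that("the Bell variant computes D_New as the item-memory average", {
  m <- build_2htsm_bell()
  expect_length(m$parameters, 12)
  th <- matrix(0.5, 1, 12, dimnames = list(NULL, m$parameters))
  th[1, "D_A_pleasant"] <- 0.8
  th[1, "D_B_pleasant"] <- 0.2
  full <- ordtree:::full_theta(m, th)
  expect_equal(unname(full[1, "D_New_pleasant"]), 0.5)
  # new-item "New" rate = D_New + (1 - D_New) * (1 - b)
  probs <- ordtree:::compute_tree_probs(m, th)
  names(probs) <- vapply(m$trees, `[[`, character(1), "name")
  expect_equal(unname(probs$new_pleasant[1, "New"]),
               0.5 + 0.5 * 0.5, tolerance = 1e-12)
})

test_that("condition labels must be distinct", {
  expect_error(build_2htsm_bell(c("a", "a")), class = "ordtree_value_error")
})

test_that("category_probabilities returns a tidy tibble", {
  m <- build_2htsm()
  th <- matrix(runif(8), 2, dimnames = list(NULL, m$parameters))
  tb <- category_probabilities(m, th)
  expect_s3_class(tb, "tbl_df")
  expect_setequal(names(tb), c(".row", "tree", "category", "prob"))
  expect_equal(nrow(tb), 2 * 9)
  sums <- tapply(tb$prob, paste(tb$.row, tb$tree), sum)
  expect_equal(as.vector(sums), rep(1, 6), tolerance = 1e-12)
})

test_that("mpt_parameters reports free and derived roles", {
  pp <- mpt_parameters(build_2htsm_bell())
  expect_equal(sum(pp$role == "free"), 12)
  expect_equal(sum(pp$role == "derived"), 2)
})
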