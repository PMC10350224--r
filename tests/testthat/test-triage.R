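test_that("triage parameter invariants are enforced", {
  expect_error(triage_params(kernel_small = 40, kernel_large = 40), "smaller")
  expect_error(triage_params(informative_cutoff = 0), ">")
  expect_error(triage_params(informative_cutoff = 100), "< 100")
  expect_error(intensity_score(matrix(0, 30, 30)), "smaller than")
})

test_that("intensity score is bit-exact against the brute-force oracle", {
  params <- triage_params()
  set.seed(61)
  for (i in 1:50) {
    m <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
    # sprinkle structure into some tiles
    if (i %% 2 == 0)
      m[20:35, 20:35] <- m[20:35, 20:35] + 15
    expect_identical(intensity_score(m, params),
                     brute_intensity_score(m, params))
  }
})

test_that("constant tiles score zero and the score ignores constant offsets", {
  params <- triage_params()
  expect_identical(intensity_score(matrix(7, 64, 64), params), 0)
  set.seed(62)
  m <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
  m[10:40, 10:40] <- m[10:40, 10:40] + 20
  s0 <- intensity_score(m, params)
  expect_gt(s0, 0)
  expect_equal(intensity_score(m + 123.4, params), s0, tolerance = 1e-9)
  # but not scale-invariant: the 2.5 threshold is absolute
  expect_false(isTRUE(all.equal(intensity_score(m * 0.05, params), s0)))
})

test_that("the informative cutoff uses a >= comparison", {
  set.seed(63)
  m <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
  m[25:35, 25:35] <- m[25:35, 25:35] + 25
  s <- intensity_score(m, triage_params())
  at <- triage_params(informative_cutoff = s)
  above <- triage_params(informative_cutoff = s + 1e-9)
  expect_identical(classify_intensity(list(m), at)$label, "informative")
  expect_identical(classify_intensity(list(m), above)$label,
                   "non-informative")
})

test_that("intensity triage separates the synthetic classes", {
  ds <- make_tile_dataset(n_per_class = 40, seed = 8)
  res <- classify_intensity(ds)
  truth <- ifelse(ds$labels == 1, "informative", "non-informative")
  expect_gte(mean(res$label[ds$labels == 1] == "informative"), 0.975)
  expect_gte(mean(res$label[ds$labels == 0] == "non-informative"), 0.975)
  expect_identical(nrow(classify_intensity(list())), 0L)
})

test_that("ROC handles perfect, random and inverted scores", {
  perfect <- roc_curve(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_identical(perfect$auc, 1)
  # scores independent of labels: AUC ~ 0.5
  set.seed(64)
  lab <- rep(0:1, each = 1000)
  sc <- rnorm(2000)
  r <- roc_curve(lab, sc)
  expect_equal(r$auc, 0.5, tolerance = 0.05)
  # reversing the score direction mirrors the AUC
  expect_equal(roc_curve(lab, -sc)$auc, 1 - r$auc, tolerance = 1e-12)
  # curve is monotone in both coordinates
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_error(roc_curve(c(1, 1, 1), c(0.2, 0.5, 0.8)), "both classes")
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(65)
  lab <- rbinom(300, 1, 0.5)
  lab[1:2] <- 0:1
  sc <- rnorm(300) + lab
  ours <- roc_curve(lab, sc)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("coordinate map filters the grid to informative positions", {
  grid <- expand.grid(x = (0:3) * 800, y = (0:3) * 800)
  all_inf <- data.frame(label = rep("informative", 16))
  expect_identical(coordinate_map(grid, all_inf), grid)
  none <- data.frame(label = rep("non-informative", 16))
  expect_identical(nrow(coordinate_map(grid, none)), 0L)
  checker <- data.frame(label = ifelse((seq_len(16) %% 2) == 1,
                                       "informative", "non-informative"))
  got <- coordinate_map(grid, checker)
  ref <- grid[checker$label == "informative", ]
  rownames(ref) <- NULL
  expect_identical(got, ref)
  expect_identical(nrow(got), 8L)
  expect_error(coordinate_map(grid, checker[1:5, , drop = FALSE]),
               "16 positions")
  f <- tempfile(fileext = ".csv")
  coordinate_map(grid, checker, file = f)
  expect_identical(nrow(read.csv(f)), 8L)
})
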