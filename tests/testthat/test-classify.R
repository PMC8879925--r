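# Shared small planted-effect image set (two groups, clearly distinct
# kinematics), reused across the classifier tests to keep the suite fast.
planted_iset <- local({
  st <- planted_cohort(n_fish = 8, duration = 300, rate = 5, seed = 7)
  rasterize_cohort(st, size = 32)
})

test_that("experiment designs enumerate the canonical class sets", {
  e1 <- experiment_design("E1")
  expect_length(e1$train_classes, 6L)
  expect_identical(e1$train_classes, e1$test_classes)
  e2a <- experiment_design("E2A")
  expect_identical(e2a$train_classes, paste0("Day1-", c("control", "100ug", "200ug")))
  e3a <- experiment_design("E3A")
  expect_equal(e3a$split_mode, "cross-day")
  expect_true(all(grepl("^Day1", e3a$train_classes)))
  expect_true(all(grepl("^Day2", e3a$test_classes)))
  e3b <- experiment_design("E3B")
  expect_identical(e3b$train_classes, e3a$test_classes)
  expect_error(experiment_design("E9"))
})

test_that("holdout splits are by fish with no leakage, and deterministic", {
  des <- experiment_design("E2A", doses = c("control", "200ug"))
  sp <- assemble_dataset(planted_iset, des, holdout_frac = 0.25, seed = 3)
  expect_length(intersect(unique(sp$train$meta$fish_id),
                          unique(sp$validation$meta$fish_id)), 0L)
  # every class retains both sides
  expect_setequal(unique(sp$train$meta$class), des$train_classes)
  expect_setequal(unique(sp$validation$meta$class), des$test_classes)
  sp2 <- assemble_dataset(planted_iset, des, holdout_frac = 0.25, seed = 3)
  expect_identical(sp$train$meta, sp2$train$meta)
  # missing class errors
  expect_error(assemble_dataset(planted_iset, experiment_design("E1")),
               "invalid-design")
})

test_that("cross-day assembly puts whole days on each side", {
  st <- planted_cohort(n_fish = 3, duration = 90, rate = 5, seed = 11,
                       days = c("Day1", "Day2"))
  iset <- rasterize_cohort(st, size = 32)
  des <- experiment_design("E3A", doses = c("control", "200ug"))
  sp <- assemble_dataset(iset, des, seed = 1)
  expect_true(all(sp$train$meta$day == "Day1"))
  expect_true(all(sp$validation$meta$day == "Day2"))
  # 2 doses x 3 fish x 3 segments per side
  expect_equal(nrow(sp$train$meta), 18L)
  expect_equal(nrow(sp$validation$meta), 18L)
})

# helper: restrict an image set to its first class (invalid design)
subset_train_single <- function(iset) {
  keep <- iset$meta$class == iset$meta$class[1]
  structure(list(images = iset$images[, , keep, drop = FALSE],
                 meta = iset$meta[keep, , drop = FALSE]),
            class = "image_set")
}

test_that("training detects a gross planted kinematic difference", {
  des <- experiment_design("E2A", doses = c("control", "200ug"))
  sp <- assemble_dataset(planted_iset, des, holdout_frac = 0.25, seed = 3)
  model <- train_classifier(sp$train, epochs = 12, seed = 5)
  ev <- evaluate(model, sp$validation)
  pb <- permutation_baseline(ev$predictions, reps = 500, seed = 9)
  expect_gt(ev$accuracy, pb$threshold)
  expect_true(pb$significant)
  expect_equal(nrow(ev$predictions), nrow(sp$validation$meta))
  # determinism: same data/seed/config -> identical accuracy
  model2 <- train_classifier(sp$train, epochs = 12, seed = 5)
  ev2 <- evaluate(model2, sp$validation)
  expect_identical(ev$accuracy, ev2$accuracy)
  expect_identical(model$params$fc_w, model2$params$fc_w)
  expect_error(train_classifier(subset_train_single(sp$train)), "single-class")
})


test_that("label shuffling destroys the signal down to the permutation band", {
  des <- experiment_design("E2A", doses = c("control", "200ug"))
  sp <- assemble_dataset(planted_iset, des, holdout_frac = 0.25, seed = 3)
  shuffled <- sp$train
  shuffled$meta$class <- withr::with_seed(4, sample(shuffled$meta$class))
  model <- train_classifier(shuffled, epochs = 6, seed = 5)
  ev <- evaluate(model, sp$validation)
  pb <- permutation_baseline(ev$predictions, reps = 500, seed = 10)
  expect_lte(ev$accuracy, pb$threshold + 0.15)  # within the chance band
})

test_that("confusion matrices are column-normalized with hand-tallied cells", {
  # true -> predicted: (A->A), (B->A), (B->B), (B->B)
  preds <- data.frame(true_class = c("A", "B", "B", "B"),
                      predicted_class = c("A", "A", "B", "B"))
  cm <- confusion(preds)
  expect_equal(unname(cm[, "A"]), c(1, 0))
  expect_equal(unname(cm[, "B"]), c(1 / 3, 2 / 3))
  expect_equal(unname(colSums(cm)), c(1, 1), tolerance = 1e-12)
  # perfect predictions -> identity
  pp <- data.frame(true_class = c("A", "B", "C"),
                   predicted_class = c("A", "B", "C"))
  expect_equal(matrix(as.numeric(confusion(pp)), 3), diag(3))
  # absent true class yields a flagged empty column
  cm2 <- confusion(preds, true_levels = c("A", "B", "C"))
  expect_equal(attr(cm2, "empty_columns"), "C")
  expect_equal(unname(colSums(cm2)), c(1, 1, 0))
  expect_error(confusion(preds[0, ]), "empty")
})

test_that("accuracy equals the trace mass of unnormalized confusion counts", {
  withr::local_seed(31)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(20:60, 1)
    preds <- data.frame(true_class = sample(LETTERS[1:k], n, replace = TRUE),
                        predicted_class = sample(LETTERS[1:k], n, replace = TRUE))
    acc <- mean(preds$true_class == preds$predicted_class)
    counts <- attr(confusion(preds, pred_levels = LETTERS[1:k],
                             true_levels = LETTERS[1:k]), "counts")
    expect_equal(sum(diag(counts)) / sum(counts), acc)
  }
})

test_that("permutation baseline is deterministic with mean near 1/k", {
  withr::local_seed(17)
  preds <- data.frame(true_class = rep(c("A", "B", "C", "D"), each = 25),
                      predicted_class = sample(rep(c("A", "B", "C", "D"), 25)))
  p1 <- permutation_baseline(preds, reps = 1000, seed = 6)
  p2 <- permutation_baseline(preds, reps = 1000, seed = 6)
  expect_identical(p1$threshold, p2$threshold)
  expect_identical(p1$distribution, p2$distribution)
  expect_equal(mean(p1$distribution), 0.25, tolerance = 0.02)
  expect_true(p1$p_value > 0 && p1$p_value <= 1)
})
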