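#' In-silico experiment designs over day-by-dose classes
#'
#' Five canonical designs: `E1` trains and tests on all day-by-dose
#' classes (within-class holdout), `E2A`/`E2B` restrict to Day 1 / Day 2
#' only, `E3A` trains on all Day-1 classes and tests on all Day-2 classes,
#' `E3B` the reverse.
#'
#' @param id one of `"E1"`, `"E2A"`, `"E2B"`, `"E3A"`, `"E3B"`.
#' @param doses dose labels (default `c("control","100ug","200ug")`).
#' @param days the two day labels (default `c("Day1","Day2")`).
#' @return an object of class `experiment_design` with `train_classes`,
#'   `test_classes` and `split_mode` (`"holdout"` or `"cross-day"`).
#' @export
experiment_design <- function(id, doses = c("control", "100ug", "200ug"),
                              days = c("Day1", "Day2")) {
  id <- match.arg(id, c("E1", "E2A", "E2B", "E3A", "E3B"))
  stopifnot(length(days) == 2L)
  cls <- function(day) paste(day, doses, sep = "-")
  spec <- switch(id,
    E1  = list(train = c(cls(days[1]), cls(days[2])),
               test = c(cls(days[1]), cls(days[2])), mode = "holdout"),
    E2A = list(train = cls(days[1]), test = cls(days[1]), mode = "holdout"),
    E2B = list(train = cls(days[2]), test = cls(days[2]), mode = "holdout"),
    E3A = list(train = cls(days[1]), test = cls(days[2]), mode = "cross-day"),
    E3B = list(train = cls(days[2]), test = cls(days[1]), mode = "cross-day"))
  structure(list(id = id, train_classes = spec$train,
                 test_classes = spec$test, split_mode = spec$mode),
            class = "experiment_design")
}

#' Split a labeled image set into train and validation sets
#'
#' Under within-class holdout the split is by fish: all segments of one
#' fish (across both days, for designs spanning days) land on the same
#' side, guarding against segment-autocorrelation leakage. Under cross-day
#' designs, training takes every image of the train classes and validation
#' every image of the test classes.
#'
#' @param iset an `image_set` from [rasterize_cohort()].
#' @param design an [experiment_design()].
#' @param holdout_frac fraction of fish per class held out for validation
#'   (holdout mode; default 0.25).
#' @param seed integer seed for the fish-level split.
#' @return `list(train = image_set, validation = image_set)`.
#' @export
assemble_dataset <- function(iset, design, holdout_frac = 0.25, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  meta <- iset$meta
  present <- unique(meta$class)
  need <- unique(c(design$train_classes, design$test_classes))
  if (!all(need %in% present)) {
    stop_invalid("invalid-design: class(es) %s absent from the image set",
                 paste(setdiff(need, present), collapse = ", "))
  }
  if (design$split_mode == "cross-day") {
    tr_idx <- which(meta$class %in% design$train_classes)
    va_idx <- which(meta$class %in% design$test_classes)
  } else {
    sel <- meta$class %in% design$train_classes
    # fish-level split within each dose group
    fish_tab <- unique(meta[sel, c("fish_id", "dose")])
    picks <- with_seed(seed, {
      unlist(lapply(split(fish_tab$fish_id, fish_tab$dose), function(ids) {
        ids <- sort(unique(ids))
        if (length(ids) < 2) {
          stop_invalid("insufficient-subjects: a class has < 2 fish under holdout")
        }
        n_val <- max(1L, round(holdout_frac * length(ids)))
        sample(ids, n_val)
      }))
    })
    tr_idx <- which(sel & !(meta$fish_id %in% picks))
    va_idx <- which(sel & (meta$fish_id %in% picks))
  }
  list(train = subset_image_set(iset, tr_idx),
       validation = subset_image_set(iset, va_idx))
}

#' Train the reduced residual CNN on a labeled image set
#'
#' Optimizes a class-weighted softmax cross-entropy with Adam. Class
#' weights are inversely proportional to class frequency (unequal group
#' sizes are the norm in dose-response cohorts). Fully deterministic for a
#' fixed seed in single-threaded mode.
#'
#' @param train an `image_set` with >= 2 classes and >= 1 image per class.
#' @param channels feature channels of the residual trunk (default 8).
#' @param epochs training epochs (default 15).
#' @param batch_size minibatch size (default 16).
#' @param lr Adam learning rate (default 3e-3).
#' @param seed integer seed for init and shuffling.
#' @param verbose print per-epoch loss?
#' @return an object of class `track_cnn`: fitted weights, class labels,
#'   input size and the training configuration.
#' @export
train_classifier <- function(train, channels = 8, epochs = 15,
                             batch_size = 16, lr = 3e-3, seed = 1L,
                             verbose = FALSE) {
  classes <- sort(unique(train$meta$class))
  if (length(classes) < 2) stop_invalid("invalid-design: single-class training set")
  size <- dim(train$images)[1]
  if (size %% 8 != 0) stop_invalid("invalid-argument: image size must be divisible by 8")
  n <- dim(train$images)[3]
  y <- match(train$meta$class, classes)
  freq <- tabulate(y, nbins = length(classes))
  cw <- (n / (length(classes) * freq))
  with_seed(seed, {
    p <- cnn_init_params(channels, length(classes))
    state <- list(m = lapply(p, function(z) numeric(length(z))),
                  v = lapply(p, function(z) numeric(length(z))))
    t_step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(idx)
        xb <- array(train$images[, , idx], dim = c(size, size, 1L, B))
        yb <- y[idx]
        fwd <- cnn_forward(p, xb, train = TRUE)
        pr <- softmax_rows(fwd$logits)
        wv <- cw[yb]
        ep_loss <- ep_loss - sum(wv * log(pmax(pr[cbind(seq_len(B), yb)], 1e-12)))
        dlogits <- pr
        dlogits[cbind(seq_len(B), yb)] <- dlogits[cbind(seq_len(B), yb)] - 1
        dlogits <- dlogits * (wv / B)  # mean(cw[y]) == 1 by construction
        g <- cnn_backward(p, fwd$cache, dlogits)
        t_step <- t_step + 1L
        st <- adam_step(p, g, state, lr, t_step)
        p <- st$p; state <- st$state
      }
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, ep_loss / n))
    }
    structure(list(params = p, classes = classes, size = size,
                   channels = channels,
                   config = list(epochs = epochs, batch_size = batch_size,
                                 lr = lr, seed = seed)),
              class = "track_cnn")
  })
}

#' @export
print.track_cnn <- function(x, ...) {
  cat(sprintf("track_cnn: %d-channel residual CNN, %d classes, input %dx%d\n",
              x$channels, length(x$classes), x$size, x$size))
  invisible(x)
}

#' Predict class labels for an image set
#'
#' @param object a fitted `track_cnn`.
#' @param newdata an `image_set`.
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.track_cnn <- function(object, newdata, batch_size = 64, ...) {
  size <- object$size
  n <- dim(newdata$images)[3]
  preds <- character(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- array(newdata$images[, , idx], dim = c(size, size, 1L, length(idx)))
    lg <- cnn_forward(object$params, xb)$logits
    preds[idx] <- object$classes[max.col(lg, ties.method = "first")]
  }
  preds
}

#' Evaluate a model on a validation image set
#'
#' @param model a fitted `track_cnn`.
#' @param validation an `image_set`.
#' @return `list(predictions, accuracy)` where `predictions` is a
#'   data frame (`true_class`, `predicted_class`, `fish_id`, `window_idx`)
#'   with one row per validation image, and `accuracy = correct / total`.
#' @export
evaluate <- function(model, validation) {
  n <- dim(validation$images)[3]
  if (n == 0) stop_invalid("invalid-argument: empty validation set")
  pred <- predict(model, validation)
  preds <- data.frame(true_class = validation$meta$class,
                      predicted_class = pred,
                      fish_id = validation$meta$fish_id,
                      window_idx = validation$meta$window_idx)
  list(predictions = preds,
       accuracy = mean(preds$predicted_class == preds$true_class))
}

#' Column-normalized confusion matrix
#'
#' Cell `(i, j)` is the fraction of validation samples of true class `j`
#' (column) predicted as class `i` (row); every non-empty column sums
#' to 1. Rows span the model's (training) label set and columns the true
#' (validation) label set, so cross-day designs yield rectangular
#' matrices. Classes absent from the predictions yield flagged empty
#' columns.
#'
#' @param preds a predictions data frame from [evaluate()] (columns
#'   `true_class`, `predicted_class`).
#' @param pred_levels row label set; defaults to observed predicted classes.
#' @param true_levels column label set; defaults to observed true classes.
#' @return a matrix of class `confusion_matrix` with attributes `counts`
#'   (unnormalized) and `empty_columns`.
#' @export
confusion <- function(preds, pred_levels = NULL, true_levels = NULL) {
  if (nrow(preds) == 0) stop_invalid("invalid-argument: empty prediction set")
  pl <- pred_levels %||% sort(unique(preds$predicted_class))
  tl <- true_levels %||% sort(unique(preds$true_class))
  counts <- table(factor(preds$predicted_class, levels = pl),
                  factor(preds$true_class, levels = tl))
  counts <- matrix(as.numeric(counts), nrow = length(pl),
                   dimnames = list(predicted = pl, true = tl))
  tot <- colSums(counts)
  cm <- sweep(counts, 2, pmax(tot, 1), "/")
  structure(cm, class = c("confusion_matrix", class(cm)),
            counts = counts, empty_columns = tl[tot == 0])
}

#' Permutation baseline for classifier accuracy
#'
#' Shuffles the true labels against the fixed predictions `reps` times and
#' recomputes accuracy each time; the significance threshold is the
#' `(1 - alpha)` empirical quantile of the permuted accuracies. The
#' observed accuracy is significant iff it exceeds the threshold.
#'
#' @param preds a predictions data frame from [evaluate()].
#' @param reps number of permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return `list(threshold, observed, significant, p_value, distribution)`.
#' @export
permutation_baseline <- function(preds, reps = 1000, alpha = 0.05, seed = 1L) {
  if (reps < 1) stop_invalid("invalid-argument: reps must be >= 1")
  obs <- mean(preds$predicted_class == preds$true_class)
  truth <- preds$true_class
  pred <- preds$predicted_class
  perm <- with_seed(seed, {
    vapply(seq_len(reps), function(i) mean(pred == sample(truth)), numeric(1))
  })
  thr <- stats::quantile(perm, 1 - alpha, names = FALSE, type = 1)
  list(threshold = thr, observed = obs, significant = obs > thr,
       p_value = (1 + sum(perm >= obs)) / (reps + 1),
       distribution = perm)
}
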