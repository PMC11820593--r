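#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam, learning rate
#' 0.0007, batch size 256, 200 epochs, cross-entropy loss, no weight decay
#' or schedule. Early stopping is off by default (a fixed epoch budget);
#' `keep_best_val = TRUE` retains the parameters from the epoch with the
#' best validation overall accuracy.
#'
#' @param lr Learning rate. Default 0.0007.
#' @param batch_size Mini-batch size. Default 256.
#' @param epochs Training epochs. Default 200.
#' @param optimizer Only `"adam"` is provided.
#' @param loss Only `"cross_entropy"` is provided.
#' @param keep_best_val Keep the best-validation-accuracy checkpoint.
#' @param stop_loss Optional early stop: end training once the epoch mean
#'   training loss falls below this value (`NULL` = train the full budget).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 0.0007, batch_size = 256L, epochs = 200L,
                         optimizer = "adam", loss = "cross_entropy",
                         keep_best_val = TRUE, stop_loss = NULL, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1)
  if (optimizer != "adam") stop("only the adam optimizer is provided")
  if (loss != "cross_entropy") stop("only cross-entropy loss is provided")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 loss = loss, keep_best_val = keep_best_val,
                 stop_loss = stop_loss, seed = as.integer(seed)),
            class = "train_config")
}

# one Adam step over matched param/grad/moment trees
adam_step <- function(params, grads, m, v, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  m <- tree_map2(function(mi, g) beta1 * mi + (1 - beta1) * g, m, grads)
  v <- tree_map2(function(vi, g) beta2 * vi + (1 - beta2) * g^2, v, grads)
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  params <- tree_map2(function(p, mv) p - lr * mv, params,
                      tree_map2(function(mi, vi) (mi / bc1) / (sqrt(vi / bc2) + eps),
                                m, v))
  list(params = params, m = m, v = v)
}

#' Fit the dual-channel fusion classifier
#'
#' Minimizes cross-entropy with Adam over mini-batches of (slice, image)
#' pairs. Deterministic given `cfg$seed` (up to floating-point reduction
#' order). Returns a fitted-model object with the classic methods
#' ([predict.ecgfusion_fit()], `print`, `summary`, `plot`).
#'
#' @param segments Matrix `(n, input_len)` of 1-D slices.
#' @param images Array `(n, size, size, 3)` of encoded slices (see
#'   [encode_segments()]).
#' @param labels Factor (or character) of AAMI labels, length `n`.
#' @param model An `ecgfusion_model` to start from; default a fresh
#'   Kaiming-initialized one matching `cfg$seed`.
#' @param cfg A [train_config()].
#' @param val Optional list `list(segments, images, labels)` used to track
#'   validation accuracy (and select the checkpoint when
#'   `cfg$keep_best_val`).
#' @param verbose Print a line per epoch.
#' @return An object of class `ecgfusion_fit`: the trained model plus
#'   per-epoch `history` (loss, training accuracy, validation accuracy).
#' @export
fit_fusion <- function(segments, images, labels, model = NULL,
                       cfg = train_config(), val = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  labels <- factor(as.character(labels), levels = aami_levels())
  present <- levels(droplevels(labels))
  if (length(setdiff(aami_levels(), present)))
    warning("classes absent from training set: ",
            paste(setdiff(aami_levels(), present), collapse = " "))
  if (is.null(model)) model <- fusion_model(fusion_config(), seed = cfg$seed)
  net_cfg <- model$cfg
  x1 <- as_branch1_input(segments, net_cfg)
  x2 <- as_branch2_input(images, net_cfg)
  y <- as.integer(labels)
  n <- length(y)
  params <- model$params; state <- model$state
  m <- tree_map(function(p) p * 0, params)
  v <- m
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_acc = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, params = params, state = state)
  t_step <- 0L
  with_seed(derive_seed(cfg$seed, "train"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0
      for (lo in seq(1L, n, by = cfg$batch_size)) {
        bi <- ord[lo:min(lo + cfg$batch_size - 1L, n)]
        fw <- fusion_fwd(x1[bi, , , drop = FALSE], x2[bi, , , , drop = FALSE],
                         params, state, net_cfg, training = TRUE)
        state <- fw$state
        sm <- softmax_ce(fw$logits, y[bi])
        bw <- fusion_bwd(fw$cache, sm$dlogits, params, net_cfg)
        t_step <- t_step + 1L
        upd <- adam_step(params, bw$grads, m, v, t_step, cfg$lr)
        params <- upd$params; m <- upd$m; v <- upd$v
        ep_loss <- ep_loss + sm$loss * length(bi)
        ep_hits <- ep_hits + sum(max.col(sm$probs, "first") == y[bi])
      }
      val_acc <- NA_real_
      if (!is.null(val)) {
        vp <- predict_probs(params, state, net_cfg, val$segments, val$images)
        val_acc <- mean(aami_levels()[max.col(vp, "first")] ==
                          as.character(val$labels))
        if (cfg$keep_best_val && val_acc >= best$acc) {
          best <- list(acc = val_acc, params = params, state = state)
        }
      }
      history[ep, ] <- list(ep, ep_loss / n, ep_hits / n, val_acc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.4f  val %.4f",
                        ep, ep_loss / n, ep_hits / n, val_acc))
      if (!is.null(cfg$stop_loss) && ep_loss / n < cfg$stop_loss) break
    }
  })
  if (!is.null(val) && cfg$keep_best_val && is.finite(best$acc)) {
    params <- best$params; state <- best$state
  }
  structure(list(params = params, state = state, cfg = model$cfg,
                 train_cfg = cfg, history = history,
                 levels = aami_levels()),
            class = c("ecgfusion_fit", "ecgfusion_model"))
}

predict_probs <- function(params, state, net_cfg, segments, images,
                          batch = 256L) {
  x1 <- as_branch1_input(segments, net_cfg)
  x2 <- as_branch2_input(images, net_cfg)
  n <- dim(x1)[1]
  out <- matrix(0, n, net_cfg$n_classes)
  for (lo in seq(1L, n, by = batch)) {
    bi <- lo:min(lo + batch - 1L, n)
    fw <- fusion_fwd(x1[bi, , , drop = FALSE], x2[bi, , , , drop = FALSE],
                     params, state, net_cfg, training = FALSE)
    out[bi, ] <- softmax_probs(fw$logits)
  }
  out
}

#' Predict from a fitted fusion model
#'
#' @param object An `ecgfusion_fit`.
#' @param segments Matrix `(n, input_len)`.
#' @param images Array `(n, size, size, 3)`.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of AAMI labels, or a probability matrix.
#' @export
predict.ecgfusion_fit <- function(object, segments, images,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_probs(object$params, object$state, object$cfg,
                     segments, images)
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, "first")], levels = object$levels)
}

#' @export
print.ecgfusion_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<ecgfusion_fit> %d epochs, final loss %.4f, train acc %.4f",
              nrow(h), h$loss[nrow(h)], h$train_acc[nrow(h)]))
  if (!all(is.na(h$val_acc)))
    cat(sprintf(", val acc %.4f", max(h$val_acc, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
summary.ecgfusion_fit <- function(object, ...) {
  print(object)
  cat("architecture:\n")
  print.ecgfusion_model(object)
  cat("training: ", object$train_cfg$optimizer,
      " lr=", object$train_cfg$lr,
      " batch=", object$train_cfg$batch_size,
      " epochs=", object$train_cfg$epochs, "\n", sep = "")
  invisible(object)
}

#' @export
plot.ecgfusion_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", main = "training curve", ...)
  invisible(x)
}

# ---- evaluation --------------------------------------------------------

#' Evaluate predictions into a confusion matrix and metric suite
#'
#' Builds the 5x5 confusion matrix (rows = actual, columns = predicted)
#' and, per class under the one-vs-rest reduction, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, precision `PPV = TP/(TP+FP)`, sensitivity
#' `Sen = TP/(TP+FN)`, specificity `Spec = TN/(TN+FP)` and
#' `F1 = 2 PPV Sen/(PPV+Sen)`; overall accuracy `OA` is the matrix trace
#' over the total count. A class never predicted has undefined PPV,
#' reported as 0 and flagged.
#'
#' @param truth Factor/character of actual AAMI labels.
#' @param predicted Factor/character of predicted labels.
#' @return An object of class `eval_report`.
#' @export
evaluate_predictions <- function(truth, predicted) {
  truth <- factor(as.character(truth), levels = aami_levels())
  predicted <- factor(as.character(predicted), levels = aami_levels())
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  cm <- table(actual = truth, predicted = predicted)
  total <- sum(cm)
  per_class <- lapply(aami_levels(), function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    ppv_undef <- (tp + fp) == 0
    ppv <- if (ppv_undef) 0 else tp / (tp + fp)
    sen <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    acc <- (tp + tn) / total
    f1 <- if (is.na(sen) || ppv + sen == 0) 0 else 2 * ppv * sen / (ppv + sen)
    list(ppv = ppv, sen = sen, spec = spec, acc = acc, f1 = f1,
         support = tp + fn, ppv_undefined = ppv_undef)
  })
  names(per_class) <- aami_levels()
  structure(list(confusion = unclass(cm),
                 per_class = per_class,
                 oa = sum(diag(cm)) / total,
                 n = total),
            class = "eval_report")
}

#' Evaluate a fitted model on a test set
#'
#' @param fit An `ecgfusion_fit`.
#' @param segments,images,labels The test set.
#' @return An `eval_report` (see [evaluate_predictions()]).
#' @export
evaluate_model <- function(fit, segments, images, labels) {
  if (!length(labels)) stop("test set is empty")
  pred <- predict(fit, segments, images)
  evaluate_predictions(labels, pred)
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("confusion matrix (rows = actual, cols = predicted):\n")
  print(x$confusion)
  tab <- do.call(rbind, lapply(x$per_class, function(p) {
    c(PPV = p$ppv, Sen = p$sen, Spec = p$spec, F1 = p$f1, Acc = p$acc,
      n = p$support)
  }))
  print(round(tab, digits))
  cat(sprintf("overall accuracy (OA): %.4f on %d samples\n", x$oa, x$n))
  invisible(x)
}

#' Serialize an evaluation report to JSON / CSV
#'
#' @param report An `eval_report`.
#' @param json_path Path for the JSON report (metrics + confusion matrix).
#' @param csv_path Optional path for the confusion matrix as CSV.
#' @return Invisibly, `json_path`.
#' @export
write_eval_report <- function(report, json_path, csv_path = NULL) {
  obj <- list(oa = report$oa, n = report$n,
              per_class = report$per_class,
              confusion = as.data.frame.matrix(report$confusion))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame.matrix(report$confusion), csv_path)
  invisible(json_path)
}
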