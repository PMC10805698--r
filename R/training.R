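# MIL-specific training: instance (data) dropout, class weighting,
# stratified folds and batches, early stopping on validation weighted
# cross-entropy.

#' MIL instance dropout
#'
#' During training a random fraction of each bag's instances is sent into
#' the model at every gradient update, while evaluation always uses all
#' instances. The kept subset has size `ceiling((1 - rate) * n)`, never
#' below 1, drawn uniformly without replacement.
#'
#' @param bags A [mil_bags] object.
#' @param rate Fraction of instances to drop, in `[0, 1)`.
#' @param training If `FALSE`, identity (all instances kept).
#' @return A [mil_bags] object.
#' @export
instance_dropout <- function(bags, rate, training = TRUE) {
  stopifnot(rate >= 0, rate < 1)
  if (!training || rate == 0) return(bags)
  idx_by_bag <- split(seq_len(nrow(bags$x)), bags$bag)
  keep <- unlist(lapply(idx_by_bag, function(ix) {
    m <- max(1L, ceiling((1 - rate) * length(ix)))
    if (m >= length(ix)) ix else sample(ix, m)
  }), use.names = FALSE)
  keep <- sort(keep)
  mil_bags(
    x = bags$x[keep, , drop = FALSE],
    bag = bags$bag[keep],
    labels = bags$labels,
    sample_features = bags$sample_features,
    sample_ids = bags$sample_ids,
    n_bags = bags$n_bags
  )
}

#' Inverse-frequency class weights
#'
#' `w_c = n / (C * n_c)` for class `c`: proportional to inverse class
#' frequency and normalized so the sample-weighted mean weight is 1. With
#' these weights the cross-entropy of a perfectly calibrated uniform
#' predictor is `log(C)` regardless of imbalance.
#'
#' @param labels Factor (or coercible) of sample labels.
#' @return Named numeric vector, one weight per class level.
#' @export
class_weights <- function(labels) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab == 0)) {
    stop("empty class: ", paste(names(tab)[tab == 0], collapse = ", "))
  }
  if (length(tab) < 2L) stop("need at least two classes")
  w <- as.numeric(sum(tab) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

#' Stratified k-fold plan
#'
#' Assigns samples to `k` folds so that within every class the per-fold
#' counts differ by at most 1. Deterministic given `seed`.
#'
#' @param labels Factor (or coercible) of sample labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: list with `k`, `assignments`
#'   (integer fold index per sample) and `labels`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  if (k < 2L) stop("k must be >= 2")
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small)) {
    warning("classes with fewer than k members spread best-effort: ",
            paste(small, collapse = ", "))
  }
  set.seed(seed)
  assignments <- integer(length(labels))
  offset <- 0L
  for (cl in levels(labels)) {
    ix <- which(labels == cl)
    ix <- ix[sample.int(length(ix))]
    # rotate the fold sequence between classes so small classes do not all
    # land in fold 1
    folds <- ((seq_along(ix) - 1L + offset) %% k) + 1L
    assignments[ix] <- folds
    offset <- (offset + length(ix)) %% k
  }
  structure(list(k = as.integer(k), assignments = assignments,
                 labels = labels),
            class = "fold_plan")
}

# stratified batches: proportional class representation per batch,
# reshuffled every epoch (sampling without replacement within class)
stratified_batches <- function(labels, batch_size) {
  n <- length(labels)
  n_batches <- max(1L, ceiling(n / batch_size))
  batch_of <- integer(n)
  offset <- 0L
  for (cl in levels(labels)) {
    ix <- which(labels == cl)
    ix <- ix[sample.int(length(ix))]
    batch_of[ix] <- ((seq_along(ix) - 1L + offset) %% n_batches) + 1L
    offset <- (offset + length(ix)) %% n_batches
  }
  split(seq_len(n), batch_of)
}

# weighted cross-entropy + accuracy of a model on bags
mil_evaluate <- function(model, bags, weights = NULL) {
  pr <- predict(model, bags)
  y <- as.integer(bags$labels)
  if (is.null(weights)) weights <- rep(1, bags$n_bags)
  ce <- -log(pmax(pr[cbind(seq_len(bags$n_bags), y)], 1e-12))
  list(
    loss = sum(weights * ce) / sum(weights),
    acc = mean(max.col(pr) == y)
  )
}

#' Train an attention MIL model
#'
#' Minimizes class-weighted cross-entropy plus the attention L1 and weight
#' L2 penalties with Adam, using stratified mini-batches of bags and fresh
#' MIL instance dropout at every gradient update. Early stopping monitors
#' weighted cross-entropy on `val_bags` (when given) with the configured
#' patience; the best parameters seen are restored.
#'
#' @param model A `mil_model` from [mil_new()].
#' @param bags Labelled training [mil_bags].
#' @param val_bags Optional labelled validation [mil_bags].
#' @param weight_classes If `TRUE`, per-bag weights from [class_weights()].
#' @param verbose Print per-epoch progress.
#' @return The fitted model, with a `history` data frame (one row per
#'   epoch: training loss, validation loss/accuracy) attached.
#' @export
mil_train <- function(model, bags, val_bags = NULL, weight_classes = TRUE,
                      verbose = FALSE) {
  stopifnot(inherits(model, "mil_model"), inherits(bags, "mil_bags"))
  if (is.null(bags$labels)) stop("training bags must be labelled")
  cfg <- model$config
  set.seed(cfg$seed + 1L)

  y <- as.integer(bags$labels)
  cw <- if (weight_classes) class_weights(bags$labels) else
    rep(1, nlevels(bags$labels))
  wts <- cw[y]
  val_wts <- if (!is.null(val_bags)) cw[as.integer(val_bags$labels)]

  model$classes <- levels(bags$labels)
  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  best_loss <- Inf
  best_params <- model$params
  stale <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    batches <- stratified_batches(bags$labels, cfg$batch_size)
    ep_loss <- 0
    for (bt in batches) {
      sub <- subset_bags(bags, bt)
      sub <- instance_dropout(sub, cfg$instance_dropout, training = TRUE)
      lg <- mil_loss_grad(model, sub$x, sub$bag, sub$n_bags,
                          y = as.integer(sub$labels), weights = wts[bt],
                          sf = sub$sample_features, training = TRUE)
      if (!is.finite(lg$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      st <- adam_step(model$params, lg$grads, opt, lr = cfg$lr)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + lg$loss * length(bt)
    }
    ep_loss <- ep_loss / bags$n_bags

    if (!is.null(val_bags)) {
      ev <- mil_evaluate(model, val_bags, val_wts)
      monitor <- ev$loss
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss,
        val_loss = ev$loss, val_acc = ev$acc
      ))
      if (verbose) {
        message(sprintf("epoch %d loss %.4f val %.4f acc %.3f",
                        epoch, ep_loss, ev$loss, ev$acc))
      }
    } else {
      monitor <- ep_loss
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss,
        val_loss = NA_real_, val_acc = NA_real_
      ))
      if (verbose) message(sprintf("epoch %d loss %.4f", epoch, ep_loss))
    }

    if (monitor < best_loss - 1e-6) {
      best_loss <- monitor
      best_params <- model$params
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  model$params <- best_params
  model$history <- history
  model
}

#' Cross-validated training
#'
#' Trains one model per fold of a [stratified_kfold()] plan, evaluating on
#' the held-out fold each time.
#'
#' @param bags Labelled [mil_bags].
#' @param config A [mil_config()]; each fold gets `seed + fold` for its
#'   initialization seed.
#' @param fold_plan A `fold_plan` over the bags.
#' @param weight_classes Passed to [mil_train()].
#' @return List with `models` (per fold), `metrics` (data frame of held-out
#'   loss/accuracy) and the plan.
#' @export
mil_crossval <- function(bags, config, fold_plan, weight_classes = TRUE) {
  stopifnot(inherits(fold_plan, "fold_plan"),
            length(fold_plan$assignments) == bags$n_bags)
  models <- vector("list", fold_plan$k)
  metrics <- data.frame(fold = integer(0), loss = numeric(0),
                        acc = numeric(0))
  for (f in seq_len(fold_plan$k)) {
    test_ix <- which(fold_plan$assignments == f)
    train_ix <- setdiff(seq_len(bags$n_bags), test_ix)
    cfg <- config
    cfg$seed <- config$seed + f
    m <- mil_new(ncol(bags$x), cfg)
    m <- mil_train(m, subset_bags(bags, train_ix),
                   val_bags = subset_bags(bags, test_ix),
                   weight_classes = weight_classes)
    ev <- mil_evaluate(m, subset_bags(bags, test_ix))
    models[[f]] <- m
    metrics <- rbind(metrics,
                     data.frame(fold = f, loss = ev$loss, acc = ev$acc))
  }
  list(models = models, metrics = metrics, fold_plan = fold_plan)
}
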