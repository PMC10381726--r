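# Training protocol: per-epoch augmentation, the freezer schedule (extractor
# weights frozen for the first epochs), Adam with L2 weight decay, and
# stratified holdout / k-fold splitting. Classical-layer gradients come from
# reverse-mode differentiation, quantum-layer Jacobians from the
# parameter-shift rule, composed by chain rule.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param weight_decay L2 coefficient folded into the gradient (1e-4).
#' @param epochs Total training epochs (default 20).
#' @param freezer_epochs Initial epochs during which the extractor's
#'   (pretrained) parameters receive no updates; 0 disables the freezer.
#' @param batch_size Minibatch size (default 8).
#' @param seed Root seed: batch order, augmentation draws and (in shots
#'   mode) measurement noise all derive from it, so two runs differing
#'   only in the head see identical batch orders and augmentations.
#' @param measurement_mode `"exact"` or `"shots"` for the sampling head's
#'   forward pass (gradients always use the exact expectation path).
#' @param augment An `augmentation_spec`, or `NULL` to disable.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         epochs = 20L, freezer_epochs = 2L, batch_size = 8L,
                         seed = 1L, measurement_mode = c("exact", "shots"),
                         augment = augmentation_spec()) {
  stopifnot(freezer_epochs <= epochs)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 freezer_epochs = as.integer(freezer_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 measurement_mode = match.arg(measurement_mode),
                 augment = augment),
            class = "train_config")
}

#' Augmentation policy
#'
#' A reduced random-augmentation policy: `rand_n` operations are sampled
#' per image per epoch from `ops`, followed by autocontrast with
#' probability `autocontrast_prob`. Applied to the training split only.
#'
#' @param ops Available operations.
#' @param rand_n Operations sampled per image.
#' @param autocontrast_prob Probability of the final autocontrast.
#' @param magnitude Fixed op magnitudes: rotation limit (degrees),
#'   translation limit (fraction), brightness/contrast limits (fraction).
#' @return An `augmentation_spec`.
#' @export
augmentation_spec <- function(ops = c("rotate", "translate", "brightness",
                                      "contrast", "autocontrast"),
                              rand_n = 2L, autocontrast_prob = 0.5,
                              magnitude = list(rotate = 15, translate = 0.10,
                                               brightness = 0.20,
                                               contrast = 0.20)) {
  structure(list(ops = ops, rand_n = as.integer(rand_n),
                 autocontrast_prob = autocontrast_prob,
                 magnitude = magnitude),
            class = "augmentation_spec")
}

#' Apply the augmentation policy to one image
#'
#' @param image 2D grayscale matrix in `[0, 1]`.
#' @param spec An `augmentation_spec`.
#' @return The augmented image (same dimensions; values clamped to
#'   `[0, 1]`). Draws from R's global RNG.
#' @export
augment_image <- function(image, spec = augmentation_spec()) {
  mg <- spec$magnitude
  chosen <- sample(spec$ops, spec$rand_n, replace = FALSE)
  for (op in chosen) {
    image <- switch(op,
      rotate = {
        ang <- stats::runif(1, -mg$rotate, mg$rotate)
        EBImage::rotate(image, ang, output.dim = dim(image), bg.col = 0)
      },
      translate = {
        v <- round(stats::runif(2, -mg$translate, mg$translate) * dim(image))
        EBImage::translate(image, v, bg.col = 0)
      },
      brightness = image + stats::runif(1, -mg$brightness, mg$brightness),
      contrast = (image - 0.5) * (1 + stats::runif(1, -mg$contrast,
                                                   mg$contrast)) + 0.5,
      autocontrast = .autocontrast(image))
  }
  if (stats::runif(1) < spec$autocontrast_prob) image <- .autocontrast(image)
  pmin(pmax(image, 0), 1)
}

.autocontrast <- function(img) {
  r <- range(img)
  if (diff(r) < 1e-12) return(img)
  (img - r[1]) / diff(r)
}

#' Split specification
#'
#' @param mode `"holdout_70_30"` or `"kfold"`.
#' @param k Number of folds in kfold mode (default 10).
#' @param seed Shuffle seed.
#' @param stratified Preserve the class ratio within folds (default TRUE).
#' @return A `split_spec`.
#' @export
split_spec <- function(mode = c("holdout_70_30", "kfold"), k = 10L,
                       seed = 1L, stratified = TRUE) {
  structure(list(mode = match.arg(mode), k = as.integer(k),
                 seed = as.integer(seed), stratified = stratified),
            class = "split_spec")
}

#' Train/test splits
#'
#' Holdout mode returns one stratified 70/30 pair; kfold mode returns `k`
#' pairs whose test sets partition the dataset. Reproducible by seed.
#'
#' @param labels 0/1 label vector, or a manifest data frame with a
#'   `Cardiomegaly` column.
#' @param spec A `split_spec`.
#' @return List of `list(train, test)` index pairs.
#' @export
make_splits <- function(labels, spec = split_spec()) {
  if (is.data.frame(labels)) labels <- labels$Cardiomegaly
  labels <- as.integer(labels)
  n <- length(labels)
  idx_by_class <- if (spec$stratified) split(seq_len(n), labels)
                  else list(seq_len(n))
  if (spec$mode == "kfold" && spec$stratified &&
      any(vapply(idx_by_class, length, integer(1)) < spec$k))
    stop("stratified kfold requires at least k records per class")
  with_seed(spec$seed, {
    if (spec$mode == "holdout_70_30") {
      test <- unlist(lapply(idx_by_class, function(ix)
        sample(ix, round(0.3 * length(ix)))))
      list(list(train = sort(setdiff(seq_len(n), test)), test = sort(test)))
    } else {
      fold_of <- integer(n)
      for (ix in idx_by_class)
        fold_of[sample(ix)] <- rep_len(seq_len(spec$k), length(ix))
      lapply(seq_len(spec$k), function(f)
        list(train = which(fold_of != f), test = which(fold_of == f)))
    }
  })
}

# Adam with standard L2 decay folded into the gradient
.adam_init <- function(params)
  list(t = 0L, m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))

.adam_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.head_param_names <- function(head) {
  if (head$variant == "classical") c("W1", "b1", "W2", "b2")
  else c("W1", "b1", "theta", "W2", "b2")
}

# backprop dL/dfeatures into the toy extractor's filter bank
.extractor_backward <- function(extractor, fulls, dX) {
  dW <- extractor$W * 0
  db <- numeric(extractor$f)
  for (i in seq_along(fulls)) {
    fu <- fulls[[i]]
    npos <- nrow(fu$maps)
    dM <- matrix(dX[i, ] / npos, npos, extractor$f, byrow = TRUE)
    dM[fu$maps <= 0] <- 0
    dW <- dW + crossprod(fu$patches, dM)
    db <- db + colSums(dM)
  }
  list(W = dW, b = db)
}

#' Train a hybrid model
#'
#' Runs the full protocol: per-epoch augmentation of the training images,
#' minibatch Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) with L2 weight
#' decay, and the freezer schedule under which the extractor's parameters
#' are untouched during the first `freezer_epochs` epochs. The epoch loss
#' is the mean over batches of the mean cross-entropy.
#'
#' @param model A `hybrid_model`.
#' @param images List of raw 2D grayscale training images.
#' @param labels 0/1 vector matching `images`.
#' @param config A `train_config`.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained), `loss_history` (length `epochs`)
#'   and `config`.
#' @export
train <- function(model, images, labels, config = train_config(),
                  verbose = FALSE) {
  labels <- as.integer(labels)
  stopifnot(length(images) == length(labels))
  if (length(unique(labels)) < 2) stop("training set has a single class")
  extractor <- model$extractor
  head <- model$head
  pnames <- .head_param_names(head)
  head_state <- .adam_init(head[pnames])
  ext_trainable <- extractor$kind == "toy"
  ext_state <- if (ext_trainable) .adam_init(extractor[c("W", "b")])
  n <- length(images)
  loss_history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    frozen <- epoch <= config$freezer_epochs || !ext_trainable
    # augmentation and batch order are drawn from an epoch-derived seed so
    # that runs differing only in the head share them exactly
    epoch_prep <- with_seed(config$seed + 7919L * epoch, {
      imgs <- if (is.null(config$augment)) images
              else lapply(images, augment_image, spec = config$augment)
      list(imgs = imgs, order = sample.int(n))
    })
    batches <- split(epoch_prep$order,
                     ceiling(seq_len(n) / config$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      ids <- batches[[bi]]
      fulls <- lapply(epoch_prep$imgs[ids], function(im)
        .extract_one_full(preprocess_image(im, model$preprocess), extractor))
      X <- do.call(rbind, lapply(fulls, `[[`, "features"))
      fw <- .head_forward(head, X, mode = "exact", want_grad = TRUE)
      probs <- fw$probs
      if (config$measurement_mode == "shots" &&
          head$variant == "quantum_sampling") {
        probs <- with_seed(config$seed + 104729L * epoch + bi, {
          sfw <- .head_forward(head, X, mode = "shots", want_grad = FALSE)
          sfw$probs
        })
      }
      cl <- .ce_loss(probs, labels[ids])
      if (!is.finite(cl$loss))
        stop("non-finite loss at epoch ", epoch, ", batch ", bi,
             " (loss = ", cl$loss, ")")
      losses[bi] <- cl$loss
      # gradients always flow through the exact-expectation path
      grad_src <- .ce_loss(fw$probs, labels[ids])
      bk <- .head_backward(head, fw, grad_src$dlogits)
      upd <- .adam_step(head[pnames], bk$grads, head_state,
                        config$learning_rate, config$weight_decay)
      head[pnames] <- upd$params
      head_state <- upd$state
      if (!frozen) {
        eg <- .extractor_backward(extractor, fulls, bk$dX)
        updE <- .adam_step(extractor[c("W", "b")], eg, ext_state,
                           config$learning_rate, config$weight_decay)
        extractor[c("W", "b")] <- updE$params
        ext_state <- updE$state
      }
    }
    loss_history[epoch] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f%s", epoch, loss_history[epoch],
                      if (epoch <= config$freezer_epochs) "  [freezer]" else ""))
  }
  model$head <- head
  model$extractor <- extractor
  list(model = model, loss_history = loss_history, config = config)
}

#' Evaluate a model on a labelled image set
#'
#' @param model A `hybrid_model`.
#' @param images List of raw grayscale images.
#' @param labels 0/1 vector.
#' @param threshold Decision threshold on the class-1 probability.
#' @return A `metrics_report` (see [compute_metrics()]); the class-1
#'   scores are attached as attribute `scores`.
#' @export
evaluate_model <- function(model, images, labels, threshold = 0.5) {
  p <- model_forward(model, images)
  rep <- compute_metrics(labels, p[, 2], threshold)
  attr(rep, "scores") <- p[, 2]
  rep
}
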