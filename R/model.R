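# Image preprocessing, the pluggable feature extractor, and the three
# classifier heads (classical, quantum-expectation, quantum-sampling).
#
# The toy extractor is a fixed-seed random convolution bank with global
# average pooling: deterministic, desk-scale, and differentiable, standing
# behind the same interface an external pretrained CNN adapter would use.
# All gradients are computed manually: classical layers by reverse mode,
# the quantum layer by parameter-shift Jacobians composed via chain rule.

#' Preprocessing specification
#'
#' @param resize_to Side length after resizing (default 256).
#' @param crop_to Side length of the centered crop (default 224).
#' @param mean,sd Per-channel normalization constants (defaults are the
#'   ImageNet values customary with pretrained extractors).
#' @return A `preprocess_spec` list.
#' @export
preprocess_spec <- function(resize_to = 256L, crop_to = 224L,
                            mean = c(0.485, 0.456, 0.406),
                            sd = c(0.229, 0.224, 0.225)) {
  stopifnot(crop_to <= resize_to, length(mean) == 3, length(sd) == 3)
  structure(list(resize_to = as.integer(resize_to),
                 crop_to = as.integer(crop_to), mean = mean, sd = sd),
            class = "preprocess_spec")
}

#' Preprocess a grayscale radiograph
#'
#' Resizes to `resize_to` x `resize_to` (bilinear), center-crops to
#' `crop_to`, replicates the single channel three times, and normalizes
#' each channel as `(x - mean_c) / sd_c`.
#'
#' @param image 2D numeric matrix (grayscale, finite values).
#' @param spec A `preprocess_spec`.
#' @return Array of dim `c(3, crop_to, crop_to)`.
#' @export
preprocess_image <- function(image, spec = preprocess_spec()) {
  if (!is.matrix(image) || length(image) == 0) stop("image must be a matrix")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  r <- EBImage::resize(image, w = spec$resize_to, h = spec$resize_to,
                       filter = "bilinear")
  off <- (spec$resize_to - spec$crop_to) %/% 2
  crop <- r[off + seq_len(spec$crop_to), off + seq_len(spec$crop_to)]
  out <- array(0, c(3L, spec$crop_to, spec$crop_to))
  for (c in 1:3) out[c, , ] <- (crop - spec$mean[c]) / spec$sd[c]
  out
}

#' Toy feature extractor
#'
#' A bank of `f` random 5x5 convolution filters applied to a block-pooled
#' version of the preprocessed image, followed by ReLU and global spatial
#' average pooling. Filters are drawn once from a seeded N(0, 1/5^2)
#' distribution, so the extractor is deterministic given its seed and
#' plays the role of frozen pretrained weights.
#'
#' @param f Feature dimension (default 64; configurable to 1024/4096 to
#'   mirror full-scale CNN extractors).
#' @param seed Seed for the filter bank.
#' @param pool_to Side of the pooled grid the filters slide over.
#' @return A `feature_extractor` with trainable fields `W` (25 x f) and
#'   `b` (f).
#' @export
toy_extractor <- function(f = 64L, seed = 1L, pool_to = 28L) {
  patch <- 5L
  W <- with_seed(seed, matrix(stats::rnorm(patch^2 * f, 0, 1 / patch), patch^2, f))
  structure(list(kind = "toy", f = as.integer(f), seed = as.integer(seed),
                 pool_to = as.integer(pool_to), patch = patch,
                 W = W, b = numeric(f), frozen = FALSE),
            class = "feature_extractor")
}

#' Wrap an external CNN adapter as a feature extractor
#'
#' @param fn Function taking a preprocessed `c(3, H, W)` array and
#'   returning a length-`f` feature vector.
#' @param f Feature dimension of the adapter output.
#' @return A `feature_extractor` of kind `"external_cnn"`.
#' @export
external_extractor <- function(fn, f) {
  stopifnot(is.function(fn))
  structure(list(kind = "external_cnn", f = as.integer(f), fn = fn,
                 frozen = TRUE),
            class = "feature_extractor")
}

# 24x24 valid 5x5 im2col index matrix over a pool_to x pool_to grid, cached
.im2col_idx <- local({
  cache <- list()
  function(pool_to, patch) {
    key <- paste(pool_to, patch)
    if (is.null(cache[[key]])) {
      side <- pool_to - patch + 1L
      pos <- expand.grid(i = seq_len(side), j = seq_len(side))
      d <- expand.grid(di = 0:(patch - 1L), dj = 0:(patch - 1L))
      idx <- outer(seq_len(nrow(pos)), seq_len(nrow(d)), function(p, q)
        (pos$i[p] + d$di[q]) + (pos$j[p] + d$dj[q] - 1L) * pool_to)
      cache[[key]] <<- idx
    }
    cache[[key]]
  }
})

.block_pool_mat <- local({
  cache <- list()
  function(from, to) {
    key <- paste(from, to)
    if (is.null(cache[[key]])) {
      k <- from %/% to
      cache[[key]] <<- kronecker(diag(to), matrix(1 / k, 1, k))
    }
    cache[[key]]
  }
})

# Full toy-extractor forward for one preprocessed image: keeps the
# intermediates needed for backprop and for Grad-CAM++ (the post-ReLU
# feature maps are the saliency source layer).
.extract_one_full <- function(x3, extractor) {
  g <- (x3[1, , ] + x3[2, , ] + x3[3, , ]) / 3
  Pm <- .block_pool_mat(nrow(g), extractor$pool_to)
  pooled <- Pm %*% g %*% t(Pm)
  idx <- .im2col_idx(extractor$pool_to, extractor$patch)
  patches <- matrix(pooled[idx], nrow = nrow(idx))        # positions x 25
  pre <- sweep(patches %*% extractor$W, 2, extractor$b, `+`)
  maps <- pmax(pre, 0)                                    # positions x f
  feats <- colMeans(maps)
  list(features = feats, maps = maps, patches = patches,
       map_side = extractor$pool_to - extractor$patch + 1L)
}

#' Extract features from a batch of images
#'
#' @param images List of raw 2D grayscale matrices, or of preprocessed
#'   `c(3, H, W)` arrays (detected by dimensionality).
#' @param extractor A `feature_extractor`.
#' @param preprocess A `preprocess_spec` applied to raw 2D inputs.
#' @return B x f feature matrix.
#' @export
extract_features <- function(images, extractor,
                             preprocess = preprocess_spec()) {
  if (!is.list(images)) images <- list(images)
  out <- matrix(0, length(images), extractor$f)
  for (i in seq_along(images)) {
    x <- images[[i]]
    if (is.matrix(x)) x <- preprocess_image(x, preprocess)
    if (extractor$kind == "external_cnn") {
      out[i, ] <- extractor$fn(x)
    } else {
      out[i, ] <- .extract_one_full(x, extractor)$features
    }
  }
  out
}

.init_linear <- function(fan_in, fan_out) {
  lim <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
       b = numeric(fan_out))
}

#' Construct a classifier head
#'
#' Three variants mirror the trainable classifier designs:
#' * `classical`: linear(f, 512) -> ReLU -> linear(512, 2)
#' * `quantum_expectation`: linear(f, n) -> tanh -> n-qubit PQC ->
#'   per-qubit Z expectations -> linear(n, 2)
#' * `quantum_sampling`: linear(f, n) -> tanh -> PQC -> class
#'   probabilities over D basis classes -> linear(D, 2)
#'
#' tanh outputs in (-1, 1) are scaled by pi/2 before use as RY encoding
#' angles. Trainable circuit angles initialize uniformly in [0, 2 pi).
#'
#' @param variant One of `"classical"`, `"quantum_expectation"`,
#'   `"quantum_sampling"`.
#' @param f Input feature dimension.
#' @param n_qubits Qubit count for quantum variants.
#' @param depth PQC entanglement-block count.
#' @param D Output dimension of the sampling head (must divide into
#'   `2^n_qubits`).
#' @param shots Default measurement shots for the sampling head forward
#'   pass (`NULL` = exact probabilities).
#' @param hidden Hidden width of the classical head.
#' @param seed Seed for weight initialization.
#' @return A `classifier_head`.
#' @export
classifier_head <- function(variant = c("classical", "quantum_expectation",
                                        "quantum_sampling"),
                            f = 64L, n_qubits = 4L, depth = 4L, D = 2L,
                            shots = 10L, hidden = 512L, seed = 1L) {
  variant <- match.arg(variant)
  with_seed(seed, {
    if (variant == "classical") {
      l1 <- .init_linear(f, hidden); l2 <- .init_linear(hidden, 2L)
      head <- list(variant = variant, f = f, hidden = hidden,
                   W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b)
    } else {
      spec <- build_pqc(n_qubits, depth)
      out_dim <- if (variant == "quantum_expectation") n_qubits else D
      if (variant == "quantum_sampling" && D > 2^n_qubits)
        stop("D must not exceed 2^n_qubits")
      l1 <- .init_linear(f, n_qubits); l2 <- .init_linear(out_dim, 2L)
      head <- list(variant = variant, f = f, n_qubits = as.integer(n_qubits),
                   depth = as.integer(depth), D = as.integer(D),
                   shots = if (variant == "quantum_sampling") shots else NULL,
                   spec = spec,
                   W1 = l1$W, b1 = l1$b,
                   theta = stats::runif(spec$n_params, 0, 2 * pi),
                   W2 = l2$W, b2 = l2$b)
    }
    structure(head, class = "classifier_head")
  })
}

#' Assemble a hybrid model
#'
#' @param extractor A `feature_extractor`.
#' @param head A `classifier_head` with matching input dimension `f`.
#' @param preprocess A `preprocess_spec`.
#' @return A `hybrid_model`.
#' @export
hybrid_model <- function(extractor, head, preprocess = preprocess_spec()) {
  stopifnot(inherits(extractor, "feature_extractor"),
            inherits(head, "classifier_head"))
  if (extractor$f != head$f)
    stop("extractor feature dimension does not match head input dimension")
  structure(list(extractor = extractor, head = head, preprocess = preprocess),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("<hybrid_model>", x$extractor$kind, "extractor (f =", x$extractor$f,
      ") +", x$head$variant, "head")
  if (x$head$variant != "classical")
    cat(" (", x$head$n_qubits, "qubits, depth", x$head$depth,
        if (x$head$variant == "quantum_sampling") paste(", D =", x$head$D),
        ")")
  cat("\n")
  invisible(x)
}

.softmax2 <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# Head forward from a feature matrix X (B x f). mode = "exact" computes
# exact measurement statistics; "shots" draws empirical frequencies for the
# sampling head (forward only; gradients always follow the exact path).
# Returns probs plus the cache used by .head_backward.
.head_forward <- function(head, X, mode = c("exact", "shots"),
                          want_grad = FALSE) {
  mode <- match.arg(mode)
  B <- nrow(X)
  if (head$variant == "classical") {
    pre <- sweep(X %*% head$W1, 2, head$b1, `+`)
    h <- pmax(pre, 0)
    logits <- sweep(h %*% head$W2, 2, head$b2, `+`)
    return(list(probs = .softmax2(logits), logits = logits,
                cache = list(X = X, h = h, pre = pre)))
  }
  u <- sweep(X %*% head$W1, 2, head$b1, `+`)      # B x n
  tnh <- tanh(u)
  enc <- t(tnh) * (pi / 2)                         # n x B encoding angles
  out_kind <- if (head$variant == "quantum_expectation") "z" else "class"
  if (want_grad) {
    jac <- pqc_jacobians(head$spec, enc, head$theta, output = out_kind,
                         D = if (out_kind == "class") head$D else 2L)
    q_exact <- t(jac$value)                        # B x out_dim
  } else {
    A <- run_circuit_batch(head$spec, enc,
                           matrix(head$theta, head$spec$n_params, B))
    q_exact <- if (out_kind == "z") t(.z_expectations_batch(A, head$n_qubits))
               else t(.class_probs_batch(A, head$n_qubits, head$D))
    jac <- NULL
  }
  q <- q_exact
  if (head$variant == "quantum_sampling" && mode == "shots" &&
      !is.null(head$shots)) {
    A <- run_circuit_batch(head$spec, enc,
                           matrix(head$theta, head$spec$n_params, B))
    for (b in seq_len(B)) {
      st <- quantum_state(head$n_qubits, A[, b])
      q[b, ] <- sample_class_probabilities(st, head$D, shots = head$shots)
    }
  }
  logits <- sweep(q %*% head$W2, 2, head$b2, `+`)
  list(probs = .softmax2(logits), logits = logits,
       cache = list(X = X, u = u, tnh = tnh, q_exact = q_exact, jac = jac))
}

# Backward through a head given d(loss)/d(logits) (B x 2); the quantum
# layer contributes parameter-shift Jacobians, composed by chain rule.
# Returns gradients for the head weights and dX (B x f).
.head_backward <- function(head, fw, dlogits) {
  cache <- fw$cache
  X <- cache$X
  if (head$variant == "classical") {
    dW2 <- t(cache$h) %*% dlogits
    db2 <- colSums(dlogits)
    dh <- dlogits %*% t(head$W2)
    dh[cache$pre <= 0] <- 0
    dW1 <- t(X) %*% dh
    db1 <- colSums(dh)
    dX <- dh %*% t(head$W1)
    return(list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
                dX = dX))
  }
  B <- nrow(X)
  q <- cache$q_exact                     # exact path (B x out_dim)
  dW2 <- t(q) %*% dlogits
  db2 <- colSums(dlogits)
  dq <- dlogits %*% t(head$W2)           # B x out_dim
  jac <- cache$jac
  if (is.null(jac)) stop("forward pass was run without want_grad")
  P <- head$spec$n_params; n <- head$n_qubits
  dtheta <- numeric(P)
  denc <- matrix(0, B, n)
  for (b in seq_len(B)) {
    dtheta <- dtheta + as.numeric(crossprod(jac$d_params[, , b], dq[b, ]))
    denc[b, ] <- as.numeric(crossprod(jac$d_encoding[, , b], dq[b, ]))
  }
  du <- denc * (pi / 2) * (1 - cache$tnh^2)
  dW1 <- t(X) %*% du
  db1 <- colSums(du)
  dX <- du %*% t(head$W1)
  list(grads = list(W1 = dW1, b1 = db1, theta = dtheta, W2 = dW2, b2 = db2),
       dX = dX)
}

#' Model forward pass
#'
#' Runs preprocessing, feature extraction and the classifier head,
#' returning per-class probabilities (softmax over the two output
#' logits). Deterministic in exact-measurement mode.
#'
#' @param model A `hybrid_model`.
#' @param images List of raw grayscale matrices or preprocessed arrays.
#' @param mode `"exact"` for exact measurement statistics, `"shots"` for
#'   a finite-shot forward pass of the sampling head.
#' @return B x 2 matrix of class probabilities (rows sum to 1).
#' @export
model_forward <- function(model, images, mode = c("exact", "shots")) {
  mode <- match.arg(mode)
  X <- extract_features(images, model$extractor, model$preprocess)
  .head_forward(model$head, X, mode = mode)$probs
}

#' @export
predict.hybrid_model <- function(object, images,
                                 type = c("prob", "class"), ...) {
  p <- model_forward(object, images)
  if (match.arg(type) == "class") as.integer(p[, 2] >= 0.5) else p
}

# mean cross-entropy of softmax probs against 0/1 labels, with the
# gradient w.r.t. logits
.ce_loss <- function(probs, labels) {
  B <- nrow(probs)
  p_true <- probs[cbind(seq_len(B), labels + 1L)]
  loss <- -mean(log(pmax(p_true, 1e-300)))
  dlogits <- probs
  dlogits[cbind(seq_len(B), labels + 1L)] <-
    dlogits[cbind(seq_len(B), labels + 1L)] - 1
  list(loss = loss, dlogits = dlogits / B)
}
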