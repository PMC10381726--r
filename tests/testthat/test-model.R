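test_that("preprocessing yields normalized three-channel crops", {
  img <- matrix(runif(300 * 400), 300, 400)
  out <- preprocess_image(img)
  expect_equal(dim(out), c(3, 224, 224))
  # channels identical before normalization: undo the affine map
  sp <- preprocess_spec()
  ch <- lapply(1:3, function(c) out[c, , ] * sp$sd[c] + sp$mean[c])
  expect_equal(ch[[1]], ch[[2]], tolerance = 1e-12)
  expect_equal(ch[[2]], ch[[3]], tolerance = 1e-12)
  # constant image equal to the channel means with unit sds -> all zeros
  sp2 <- preprocess_spec(mean = c(0.3, 0.3, 0.3), sd = c(1, 1, 1))
  z <- preprocess_image(matrix(0.3, 250, 250), sp2)
  expect_equal(max(abs(z)), 0, tolerance = 1e-12)
  expect_error(preprocess_image(matrix(NaN, 240, 240)), "finite")
  expect_error(preprocess_image(numeric(0)), "matrix")
})

test_that("toy extractor is deterministic and shape-correct", {
  ex <- toy_extractor(f = 32, seed = 9)
  imgs <- lapply(1:3, function(i) matrix(runif(240 * 240, 0, 1), 240, 240))
  F1 <- extract_features(imgs, ex)
  F2 <- extract_features(imgs, ex)
  expect_identical(F1, F2)
  expect_equal(dim(F1), c(3, 32))
  ex2 <- toy_extractor(f = 32, seed = 10)
  expect_false(identical(extract_features(imgs, ex2), F1))
})

test_that("features separate images differing only inside the heart region", {
  cfg <- synthetic_config(seed = 6, noise_sd = 0)
  small <- generate_cxr(0.38, cfg, seed = 1, confounder = FALSE)
  big <- generate_cxr(0.68, cfg, seed = 1, confounder = FALSE)
  ex <- toy_extractor(f = 64, seed = 1)
  Fm <- extract_features(list(small$image, big$image), ex)
  expect_gt(sqrt(sum((Fm[1, ] - Fm[2, ])^2)), 0)
})

test_that("forward pass produces valid class probabilities for all heads", {
  cfg <- synthetic_config(seed = 12, image_size = 128)
  imgs <- lapply(c(0.4, 0.6), function(ctr) generate_cxr(ctr, cfg, seed = 3)$image)
  ex <- toy_extractor(f = 16, seed = 2)
  for (variant in c("classical", "quantum_expectation", "quantum_sampling")) {
    head <- classifier_head(variant, f = 16, n_qubits = 3, depth = 2, D = 2,
                            seed = 4)
    m <- hybrid_model(ex, head)
    p <- model_forward(m, imgs)
    expect_equal(dim(p), c(2, 2))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-9)
  }
})

test_that("classical head with zero weights outputs (0.5, 0.5)", {
  head <- classifier_head("classical", f = 8, seed = 1)
  head$W1[] <- 0; head$b1[] <- 0; head$W2[] <- 0; head$b2[] <- 0
  p <- qcxr:::.head_forward(head, matrix(rnorm(16), 2, 8))$probs
  expect_equal(p, matrix(0.5, 2, 2), tolerance = 1e-12)
})

test_that("quantum head forward equals a hand-composed pipeline", {
  set.seed(20)
  ex <- toy_extractor(f = 12, seed = 5)
  head <- classifier_head("quantum_expectation", f = 12, n_qubits = 3,
                          depth = 2, seed = 6)
  m <- hybrid_model(ex, head)
  img <- generate_cxr(0.62, synthetic_config(seed = 1, image_size = 128),
                      seed = 2)$image
  got <- model_forward(m, list(img))

  # manual composition: extract -> linear -> tanh -> circuit -> Z -> linear
  x <- extract_features(list(img), ex)[1, ]
  u <- as.numeric(x %*% head$W1) + head$b1
  enc <- (pi / 2) * tanh(u)
  st <- run_circuit(head$spec, enc, head$theta)
  z <- measure_z_expectations(st)
  logits <- as.numeric(z %*% head$W2) + head$b2
  want <- exp(logits - max(logits)); want <- want / sum(want)
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
})

test_that("analytic head gradients match finite differences", {
  set.seed(33)
  f <- 6; B <- 2
  X <- matrix(rnorm(B * f), B, f)
  labels <- c(0L, 1L)
  loss_at <- function(head) {
    fw <- qcxr:::.head_forward(head, X, want_grad = FALSE)
    qcxr:::.ce_loss(fw$probs, labels)$loss
  }
  h <- 1e-5
  for (variant in c("classical", "quantum_expectation", "quantum_sampling")) {
    head <- classifier_head(variant, f = f, n_qubits = 3, depth = 1, D = 2,
                            hidden = 7, seed = 3)
    fw <- qcxr:::.head_forward(head, X, want_grad = TRUE)
    cl <- qcxr:::.ce_loss(fw$probs, labels)
    bk <- qcxr:::.head_backward(head, fw, cl$dlogits)
    for (nm in names(bk$grads)) {
      g <- bk$grads[[nm]]
      w <- head[[nm]]
      for (j in sample(length(w), min(5, length(w)))) {
        hp <- head; hm <- head
        hp[[nm]][j] <- hp[[nm]][j] + h
        hm[[nm]][j] <- hm[[nm]][j] - h
        fd <- (loss_at(hp) - loss_at(hm)) / (2 * h)
        expect_equal(as.numeric(g)[j], fd, tolerance = 1e-4,
                     label = paste(variant, nm, j))
      }
    }
    # gradient w.r.t. the input features (chain into the extractor)
    for (j in 1:3) {
      Xp <- X; Xm <- X
      Xp[1, j] <- Xp[1, j] + h; Xm[1, j] <- Xm[1, j] - h
      fwp <- qcxr:::.head_forward(head, Xp)
      fwm <- qcxr:::.head_forward(head, Xm)
      fd <- (qcxr:::.ce_loss(fwp$probs, labels)$loss -
             qcxr:::.ce_loss(fwm$probs, labels)$loss) / (2 * h)
      expect_equal(bk$dX[1, j], fd, tolerance = 1e-4)
    }
  }
})

test_that("permuting batch order permutes outputs identically", {
  set.seed(50)
  cfg <- synthetic_config(seed = 14, image_size = 128)
  imgs <- lapply(c(0.38, 0.42, 0.6, 0.66), function(ctr)
    generate_cxr(ctr, cfg, seed = round(ctr * 100))$image)
  ex <- toy_extractor(f = 16, seed = 2)
  m <- hybrid_model(ex, classifier_head("quantum_expectation", f = 16,
                                        n_qubits = 3, depth = 1, seed = 8))
  p <- model_forward(m, imgs)
  perm <- c(3, 1, 4, 2)
  p_perm <- model_forward(m, imgs[perm])
  expect_equal(p_perm, p[perm, ], tolerance = 1e-12)
})

test_that("mismatched extractor and head dimensions are rejected", {
  expect_error(hybrid_model(toy_extractor(f = 8),
                            classifier_head("classical", f = 16)),
               "dimension")
})
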