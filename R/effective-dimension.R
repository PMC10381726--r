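# Empirical Fisher information of the quantum layer and the normalized
# global effective dimension (NGED): a Fisher-based capacity measure
# averaged over a uniform prior on the trainable circuit angles, divided
# by the parameter count. "Global" means averaged over the parameter
# prior, not evaluated at a trained point.

# F = (1/M) sum_m sum_y p_ym grad log p_ym grad log p_ym^T
# probs: D x M, grads: D x P x M
fisher_from_gradients <- function(probs, grads, clamp = 1e-12) {
  D <- nrow(probs); M <- ncol(probs); P <- dim(grads)[2]
  clamped <- sum(probs < clamp)
  probs <- pmax(probs, clamp)
  F <- matrix(0, P, P)
  for (m in seq_len(M)) {
    for (y in seq_len(D)) {
      s <- grads[y, , m] / probs[y, m]         # score vector
      F <- F + probs[y, m] * tcrossprod(s)
    }
  }
  attr(F, "clamped") <- clamped
  F / M
}

#' Empirical Fisher information of the quantum layer
#'
#' Treats the circuit plus its class-probability readout as a conditional
#' model \eqn{p(y | x; \theta)} (basis outcome mod D), with the encoding
#' angles x as inputs. For every sampled \eqn{\theta}, the Fisher matrix
#' is the average over inputs and classes of the outer product of the
#' score \eqn{\nabla_\theta \log p}, class-weighted by p. Gradients come
#' from the parameter-shift rule.
#'
#' @param spec A `circuit_spec`.
#' @param theta_samples P x S matrix of trainable-angle samples.
#' @param input_samples n x M matrix of encoding-angle samples.
#' @param D Number of output classes (basis index mod D).
#' @param clamp Probabilities below this are clamped (and counted in the
#'   `clamped` field) before taking logs.
#' @return A `fisher_estimate`: list with `matrices` (S symmetric PSD
#'   P x P matrices), `P`, `n_theta_samples`, `n_input_samples`,
#'   `clamped`.
#' @export
empirical_fisher <- function(spec, theta_samples, input_samples, D = 2L,
                             clamp = 1e-12) {
  stopifnot(inherits(spec, "circuit_spec"))
  theta_samples <- matrix(theta_samples, nrow = spec$n_params)
  input_samples <- matrix(input_samples, nrow = spec$n_encoding)
  S <- ncol(theta_samples)
  clamped <- 0L
  mats <- vector("list", S)
  for (s in seq_len(S)) {
    jac <- pqc_jacobians(spec, input_samples, theta_samples[, s],
                         output = "class", D = D)
    F <- fisher_from_gradients(jac$value, jac$d_params, clamp)
    clamped <- clamped + attr(F, "clamped")
    attr(F, "clamped") <- NULL
    mats[[s]] <- (F + t(F)) / 2
  }
  structure(list(matrices = mats, P = spec$n_params,
                 n_theta_samples = S, n_input_samples = ncol(input_samples),
                 clamped = clamped),
            class = "fisher_estimate")
}

#' Normalize a Fisher estimate
#'
#' \eqn{\hat F(\theta) = P \, F(\theta) / \overline{tr F}}, where the
#' trace is averaged over the theta samples; after normalization the mean
#' trace equals P.
#'
#' @param estimate A `fisher_estimate` (or plain list of matrices).
#' @return The estimate with normalized matrices.
#' @export
normalize_fisher <- function(estimate) {
  mats <- if (inherits(estimate, "fisher_estimate")) estimate$matrices
          else estimate
  trs <- vapply(mats, function(m) sum(diag(m)), numeric(1))
  if (mean(trs) <= 0) stop("all-zero Fisher: normalization undefined")
  P <- nrow(mats[[1]])
  scaled <- lapply(mats, function(m) P * m / mean(trs))
  if (inherits(estimate, "fisher_estimate")) {
    estimate$matrices <- scaled
    estimate
  } else scaled
}

.logmeanexp <- function(v) {
  m <- max(v)
  m + log(mean(exp(v - m)))
}

# eigenvalues of each matrix, floored at 0 (numerical PSD jitter)
.fisher_eigs <- function(mats)
  lapply(mats, function(m) pmax(eigen(m, symmetric = TRUE,
                                      only.values = TRUE)$values, 0))

.nged_from_eigs <- function(eigs, P, n, gamma = 1) {
  c_n <- gamma * n / (2 * pi * log(n))
  if (!(c_n > 0) || abs(c_n - 1) < 1e-12)
    stop("c_n = gamma n / (2 pi log n) must be positive and != 1")
  # log sqrt(det(I + c_n F)) = 0.5 sum log1p(c_n lambda): stable at large n
  half_logdets <- vapply(eigs, function(l) 0.5 * sum(log1p(c_n * l)),
                         numeric(1))
  d_eff <- 2 * .logmeanexp(half_logdets) / log(c_n)
  d_eff / P
}

#' Normalized global effective dimension
#'
#' \eqn{d_{eff} = 2 \log( E_\theta \sqrt{\det(I + c_n \hat F(\theta))} ) /
#' \log c_n} with \eqn{c_n = \gamma n / (2\pi \log n)}; the returned value
#' is \eqn{d_{eff} / P}. Square-root determinants are evaluated through
#' eigenvalue log-sums to avoid overflow at large n.
#'
#' @param fhat Normalized `fisher_estimate` (or list of matrices).
#' @param n Dataset size (>= 2, with `c_n != 1`).
#' @param gamma Scale constant (default 1).
#' @return The NGED (scalar > 0 for nonzero Fisher, 0 for zero Fisher).
#' @export
nged <- function(fhat, n, gamma = 1) {
  mats <- if (inherits(fhat, "fisher_estimate")) fhat$matrices else fhat
  stopifnot(n >= 2)
  .nged_from_eigs(.fisher_eigs(mats), nrow(mats[[1]]), n, gamma)
}

#' NGED as a function of dataset size
#'
#' Samples trainable angles uniformly on \eqn{[0, 2\pi)^P} and encoding
#' angles uniformly on \eqn{(-\pi/2, \pi/2)^n} (the image of the tanh
#' encoding layer), estimates and normalizes the Fisher information once,
#' and evaluates the NGED on the dataset-size grid with those shared
#' samples.
#'
#' @param spec A `circuit_spec` (e.g. `build_pqc(4, 4)`).
#' @param n_grid Integer vector of dataset sizes.
#' @param D Output dimension of the class readout.
#' @param n_theta,n_input Numbers of theta / input samples (default 30
#'   each).
#' @param gamma Scale constant.
#' @param seed Seed for both sample draws.
#' @return An `nged_curve`: data frame with columns `n` and `nged`, with
#'   the normalized estimate attached as attribute `fisher`.
#' @export
nged_curve <- function(spec, n_grid, D = 2L, n_theta = 30L, n_input = 30L,
                       gamma = 1, seed = 1L) {
  stopifnot(all(n_grid >= 2))
  samples <- with_seed(seed, list(
    theta = matrix(stats::runif(spec$n_params * n_theta, 0, 2 * pi),
                   spec$n_params, n_theta),
    inputs = matrix(stats::runif(spec$n_encoding * n_input,
                                 -pi / 2, pi / 2),
                    spec$n_encoding, n_input)))
  est <- empirical_fisher(spec, samples$theta, samples$inputs, D = D)
  est <- normalize_fisher(est)
  eigs <- .fisher_eigs(est$matrices)
  vals <- vapply(n_grid, function(n)
    .nged_from_eigs(eigs, est$P, n, gamma), numeric(1))
  out <- data.frame(n = n_grid, nged = vals)
  attr(out, "fisher") <- est
  class(out) <- c("nged_curve", "data.frame")
  out
}
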