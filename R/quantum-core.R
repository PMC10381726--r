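# Dense statevector simulation of the parameterized quantum circuit used in
# the classifier heads, plus analytic parameter-shift gradients.
#
# Bit-ordering convention (pinned by tests): qubit 0 is the MOST significant
# bit of the computational-basis index, so for n = 2 the amplitude vector is
# ordered |00>, |01>, |10>, |11> with qubit 0 being the left bit.

#' Construct an n-qubit quantum state
#'
#' Creates a valid computational-basis state (default the ground state
#' \eqn{|0...0\rangle}) as used by the circuit simulator.
#'
#' @param n_qubits Number of qubits (>= 1).
#' @param amplitudes Optional complex amplitude vector of length
#'   `2^n_qubits`; must have unit L2 norm (checked to 1e-6).
#' @return An object of class `quantum_state` with fields `n_qubits` and
#'   `amplitudes`.
#' @export
quantum_state <- function(n_qubits, amplitudes = NULL) {
  stopifnot(n_qubits >= 1)
  N <- 2L^n_qubits
  if (is.null(amplitudes)) {
    amplitudes <- complex(N)
    amplitudes[1] <- 1 + 0i
  } else {
    amplitudes <- as.complex(amplitudes)
    if (length(amplitudes) != N)
      stop("amplitude vector must have length 2^n_qubits")
    nrm <- sqrt(sum(Mod(amplitudes)^2))
    if (abs(nrm - 1) > 1e-6)
      stop("state is not normalized (||a|| = ", format(nrm), ")")
  }
  structure(list(n_qubits = as.integer(n_qubits), amplitudes = amplitudes),
            class = "quantum_state")
}

#' @export
print.quantum_state <- function(x, ...) {
  cat("<quantum_state>", x$n_qubits, "qubits,", length(x$amplitudes),
      "amplitudes, norm", format(sqrt(sum(Mod(x$amplitudes)^2))), "\n")
  invisible(x)
}

# single-qubit gate matrices ------------------------------------------------

.gate_h_mat <- matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2)

.ry_mat <- function(theta) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  matrix(c(c2, s2, -s2, c2), 2, 2)   # [[c,-s],[s,c]]
}

#' Describe one gate of a circuit
#'
#' @param kind One of `"H"`, `"RY"`, `"CNOT"`.
#' @param target Target qubit index (0-based).
#' @param control Control qubit index for CNOT, otherwise `NA`.
#' @param angle_source For RY gates: a list with `kind` in
#'   `{"encoding","param","const"}` and `index` (1-based position in the
#'   encoding/parameter vector) or `value` (radians) for constants.
#' @return A `gate_op` list.
#' @export
gate_op <- function(kind, target, control = NA_integer_, angle_source = NULL) {
  kind <- match.arg(kind, c("H", "RY", "CNOT"))
  if (kind == "CNOT") {
    if (is.na(control)) stop("CNOT requires a control qubit")
    if (control == target) stop("CNOT control and target must differ")
  }
  if (kind == "RY" && is.null(angle_source))
    stop("RY requires an angle_source")
  structure(list(kind = kind, target = as.integer(target),
                 control = as.integer(control), angle_source = angle_source),
            class = "gate_op")
}

angle_const    <- function(value) list(kind = "const", value = value)
angle_encoding <- function(i)     list(kind = "encoding", index = as.integer(i))
angle_param    <- function(k)     list(kind = "param", index = as.integer(k))

#' Build the default parameterized quantum circuit
#'
#' Constructs the circuit used by the quantum classifier heads: a Hadamard
#' layer placing all qubits in superposition, an RY encoding layer (one
#' angle \eqn{\phi_i} per qubit), a trainable RY layer, then `depth` blocks
#' each consisting of a linear CNOT entanglement chain
#' (control i -> target i+1) followed by a trainable RY layer, and a final
#' trainable RY layer. The trainable parameter count is
#' \eqn{P = n (depth + 2)}; the default 4-qubit, depth-4 circuit therefore
#' has 24 trainable parameters.
#'
#' @param n_qubits Number of qubits (>= 2; below 2 no entanglement is
#'   possible).
#' @param depth Number of entanglement blocks (>= 1).
#' @return A `circuit_spec` with fields `n_qubits`, `depth`, `gates`,
#'   `n_encoding` and `n_params`.
#' @examples
#' spec <- build_pqc(4, 4)
#' spec$n_params  # 24
#' @export
build_pqc <- function(n_qubits, depth) {
  if (n_qubits < 2) stop("n_qubits must be >= 2 (no entanglement possible)")
  if (depth < 1) stop("depth must be >= 1")
  n <- as.integer(n_qubits); d <- as.integer(depth)
  gates <- list()
  add <- function(g) gates[[length(gates) + 1L]] <<- g
  for (q in 0:(n - 1)) add(gate_op("H", q))
  for (q in 0:(n - 1)) add(gate_op("RY", q, angle_source = angle_encoding(q + 1L)))
  k <- 0L
  ry_layer <- function() {
    for (q in 0:(n - 1)) {
      k <<- k + 1L
      add(gate_op("RY", q, angle_source = angle_param(k)))
    }
  }
  ry_layer()                                   # pre-rotation layer
  for (b in seq_len(d)) {
    for (q in 0:(n - 2)) add(gate_op("CNOT", target = q + 1L, control = q))
    ry_layer()                                 # per-block rotation layer
  }
  ry_layer()                                   # post-rotation layer
  structure(list(n_qubits = n, depth = d, gates = gates,
                 n_encoding = n, n_params = k),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  kinds <- vapply(x$gates, function(g) g$kind, character(1))
  cat("<circuit_spec>", x$n_qubits, "qubits, depth", x$depth, "-",
      length(x$gates), "gates (", sum(kinds == "H"), "H,",
      sum(kinds == "RY"), "RY,", sum(kinds == "CNOT"), "CNOT ),",
      x$n_params, "trainable parameters\n")
  invisible(x)
}

# batched amplitude-matrix kernels ------------------------------------------
# A is a 2^n x B complex matrix (one state per column). Angles for RY may be
# a length-B vector (per-column angle).

.apply_1q <- function(A, n, q, c2, s2, hadamard = FALSE) {
  N <- nrow(A)
  stepb <- bitwShiftL(1L, n - 1L - q)
  i0 <- which(bitwAnd(0:(N - 1L), stepb) == 0L)
  i1 <- i0 + stepb
  a0 <- A[i0, , drop = FALSE]; a1 <- A[i1, , drop = FALSE]
  if (hadamard) {
    r <- 1 / sqrt(2)
    A[i0, ] <- r * (a0 + a1)
    A[i1, ] <- r * (a0 - a1)
  } else {
    # RY: per-column cos/sin recycled down each column
    cc <- rep(c2, each = nrow(a0)); ss <- rep(s2, each = nrow(a0))
    A[i0, ] <- cc * a0 - ss * a1
    A[i1, ] <- ss * a0 + cc * a1
  }
  A
}

.apply_cnot <- function(A, n, control, target) {
  N <- nrow(A)
  pc <- bitwShiftL(1L, n - 1L - control)
  pt <- bitwShiftL(1L, n - 1L - target)
  b <- 0:(N - 1L)
  i0 <- which(bitwAnd(b, pc) != 0L & bitwAnd(b, pt) == 0L)
  i1 <- i0 + pt
  tmp <- A[i0, , drop = FALSE]
  A[i0, ] <- A[i1, , drop = FALSE]
  A[i1, ] <- tmp
  A
}

# Run a circuit on B states at once. encoding: n x B, params: P x B.
run_circuit_batch <- function(spec, encoding, params) {
  n <- spec$n_qubits
  encoding <- matrix(encoding, nrow = spec$n_encoding)
  params <- matrix(params, nrow = max(spec$n_params, 1L))
  B <- ncol(encoding)
  if (spec$n_params > 0 && ncol(params) != B)
    stop("encoding and params batches differ in size")
  N <- 2L^n
  A <- matrix(0 + 0i, N, B)
  A[1, ] <- 1 + 0i
  for (g in spec$gates) {
    if (g$kind == "H") {
      A <- .apply_1q(A, n, g$target, hadamard = TRUE)
    } else if (g$kind == "CNOT") {
      A <- .apply_cnot(A, n, g$control, g$target)
    } else {
      src <- g$angle_source
      th <- switch(src$kind,
                   const    = rep(src$value, B),
                   encoding = encoding[src$index, ],
                   param    = params[src$index, ])
      A <- .apply_1q(A, n, g$target, cos(th / 2), sin(th / 2))
    }
  }
  A
}

#' Apply a single gate to a state
#'
#' Applies the 2x2 (H, RY) or controlled-X unitary of `gate` to `state`.
#' RY angles referring to the encoding or parameter vectors are resolved
#' against `encoding` / `params`.
#'
#' @param state A `quantum_state`.
#' @param gate A `gate_op`.
#' @param encoding,params Angle vectors used to resolve `angle_source`
#'   references (only needed for RY gates that reference them).
#' @return The transformed `quantum_state` (unit norm preserved).
#' @export
apply_gate <- function(state, gate, encoding = NULL, params = NULL) {
  stopifnot(inherits(state, "quantum_state"), inherits(gate, "gate_op"))
  n <- state$n_qubits
  if (gate$target >= n || gate$target < 0) stop("target qubit out of range")
  if (gate$kind == "CNOT" && (gate$control >= n || gate$control < 0))
    stop("control qubit out of range")
  nrm <- sqrt(sum(Mod(state$amplitudes)^2))
  if (abs(nrm - 1) > 1e-6) stop("input state is not normalized")
  A <- matrix(state$amplitudes, ncol = 1)
  if (gate$kind == "H") {
    A <- .apply_1q(A, n, gate$target, hadamard = TRUE)
  } else if (gate$kind == "CNOT") {
    A <- .apply_cnot(A, n, gate$control, gate$target)
  } else {
    src <- gate$angle_source
    th <- switch(src$kind,
                 const = src$value,
                 encoding = encoding[src$index],
                 param = params[src$index])
    if (is.null(th) || is.na(th)) stop("could not resolve RY angle")
    A <- .apply_1q(A, n, gate$target, cos(th / 2), sin(th / 2))
  }
  quantum_state(n, A[, 1])
}

#' Run a circuit on the ground state
#'
#' Sequentially applies every gate of `spec` to \eqn{|0...0\rangle}.
#' Deterministic: identical inputs give identical output amplitudes.
#'
#' @param spec A `circuit_spec`.
#' @param encoding Numeric vector of encoding angles (length `n_encoding`).
#' @param params Numeric vector of trainable angles (length `n_params`).
#' @return The final `quantum_state`.
#' @export
run_circuit <- function(spec, encoding, params) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (length(encoding) != spec$n_encoding)
    stop("encoding must have length ", spec$n_encoding)
  if (length(params) != spec$n_params)
    stop("params must have length ", spec$n_params)
  A <- run_circuit_batch(spec, matrix(encoding, ncol = 1),
                         matrix(params, ncol = 1))
  quantum_state(spec$n_qubits, A[, 1])
}

# n x N matrix of +/-1 signs: row q holds (-1)^bit_q(b) over basis states b
.z_sign_matrix <- function(n) {
  N <- 2L^n
  b <- 0:(N - 1L)
  t(vapply(0:(n - 1L), function(q) {
    ifelse(bitwAnd(b, bitwShiftL(1L, n - 1L - q)) == 0L, 1, -1)
  }, numeric(N)))
}

#' Pauli-Z expectation values per qubit
#'
#' Component i is \eqn{\langle Z_i\rangle = \sum_b s_i(b) |a_b|^2} with
#' \eqn{s_i(b) = +1} when bit i of the basis index is 0 and \eqn{-1}
#' otherwise; every value lies in \eqn{[-1, 1]}.
#'
#' @param state A `quantum_state`.
#' @return Numeric vector of length `n_qubits`.
#' @export
measure_z_expectations <- function(state) {
  stopifnot(inherits(state, "quantum_state"))
  probs <- Mod(state$amplitudes)^2
  as.numeric(.z_sign_matrix(state$n_qubits) %*% probs)
}

.z_expectations_batch <- function(A, n) .z_sign_matrix(n) %*% (Mod(A)^2)

# D x N indicator matrix mapping basis index b to class b mod D
.class_map_matrix <- function(n, D) {
  N <- 2L^n
  cls <- (0:(N - 1L)) %% D
  M <- matrix(0, D, N)
  M[cbind(cls + 1L, 1:N)] <- 1
  M
}

.class_probs_batch <- function(A, n, D) .class_map_matrix(n, D) %*% (Mod(A)^2)

#' Class probabilities from basis-state measurement
#'
#' Basis outcome `b` is mapped to class `b mod D`. In exact mode the class
#' probabilities are the summed basis probabilities; in shots mode they are
#' the empirical frequencies of `shots` simulated measurements (draws use
#' R's global RNG, so results are reproducible after `set.seed()`).
#'
#' @param state A `quantum_state`.
#' @param D Output dimension (>= 2, <= `2^n_qubits`).
#' @param shots Number of measurement repetitions; `NULL` (default) for
#'   exact probabilities.
#' @return Numeric probability vector of length `D` summing to 1.
#' @export
sample_class_probabilities <- function(state, D, shots = NULL) {
  stopifnot(inherits(state, "quantum_state"))
  n <- state$n_qubits
  if (D > 2^n) stop("D must not exceed 2^n_qubits")
  if (D < 2) stop("D must be >= 2")
  probs <- Mod(state$amplitudes)^2
  exact <- as.numeric(.class_map_matrix(n, D) %*% probs)
  if (is.null(shots)) return(exact / sum(exact))
  if (shots < 1) stop("shots must be >= 1")
  draws <- sample.int(length(probs), size = shots, replace = TRUE,
                      prob = probs) - 1L
  tabulate((draws %% D) + 1L, nbins = D) / shots
}

#' Parameter-shift gradient of a circuit observable
#'
#' For every RY rotation angle `a` (trainable parameters and encoding
#' angles alike), the exact derivative of an expectation-valued observable
#' is \eqn{[E(a + \pi/2) - E(a - \pi/2)] / 2} with all other angles fixed.
#' Encoding-angle gradients are returned too, so the loss can be
#' backpropagated into the classical layer that produced the encoding.
#'
#' @param spec A `circuit_spec`.
#' @param encoding,params Angle vectors at the evaluation point.
#' @param observable_fn Function mapping a `quantum_state` to a real
#'   scalar that is linear in the density matrix (each Z expectation or an
#'   exact class probability qualifies).
#' @return List with `d_params` (length `n_params`) and `d_encoding`
#'   (length `n_encoding`).
#' @export
parameter_shift_gradient <- function(spec, encoding, params, observable_fn) {
  stopifnot(inherits(spec, "circuit_spec"))
  P <- spec$n_params; n <- spec$n_encoding
  eval_at <- function(enc, par) {
    v <- observable_fn(quantum_state(spec$n_qubits,
                                     run_circuit_batch(spec, enc, par)[, 1]))
    if (length(v) != 1 || !is.numeric(v))
      stop("observable_fn must return a real scalar")
    v
  }
  d_params <- numeric(P)
  for (k in seq_len(P)) {
    pp <- params; pm <- params
    pp[k] <- pp[k] + pi / 2; pm[k] <- pm[k] - pi / 2
    d_params[k] <- (eval_at(encoding, pp) - eval_at(encoding, pm)) / 2
  }
  d_encoding <- numeric(n)
  for (i in seq_len(n)) {
    ep <- encoding; em <- encoding
    ep[i] <- ep[i] + pi / 2; em[i] <- em[i] - pi / 2
    d_encoding[i] <- (eval_at(ep, params) - eval_at(em, params)) / 2
  }
  list(d_params = d_params, d_encoding = d_encoding)
}

# Batched parameter-shift Jacobians of the measurement-layer outputs.
#
# For a batch of B encoding columns (n x B) and shared trainable params
# (length P), returns for output = "z" (n outputs) or "class" (D outputs):
#   value:  out_dim x B matrix of exact outputs
#   d_params: array out_dim x P x B
#   d_encoding: array out_dim x n x B
# One statevector pass evaluates all shifted circuits as extra columns.
pqc_jacobians <- function(spec, encoding, params, output = c("z", "class"),
                          D = 2L) {
  output <- match.arg(output)
  n <- spec$n_qubits; P <- spec$n_params
  encoding <- matrix(encoding, nrow = spec$n_encoding)
  B <- ncol(encoding)
  n_shift <- P + spec$n_encoding
  # columns: B unshifted, then for each shift s: B cols at +pi/2, B at -pi/2
  enc_big <- matrix(encoding, spec$n_encoding, B * (1 + 2 * n_shift))
  par_big <- matrix(params, P, B * (1 + 2 * n_shift))
  col0 <- function(s, sign) B * (1 + 2 * (s - 1) + (sign < 0)) + seq_len(B)
  for (s in seq_len(n_shift)) {
    for (sgn in c(1, -1)) {
      cols <- col0(s, sgn)
      if (s <= P) par_big[s, cols] <- par_big[s, cols] + sgn * pi / 2
      else enc_big[s - P, cols] <- enc_big[s - P, cols] + sgn * pi / 2
    }
  }
  A <- run_circuit_batch(spec, enc_big, par_big)
  out <- if (output == "z") .z_expectations_batch(A, n)
         else .class_probs_batch(A, n, D)
  m <- nrow(out)
  value <- out[, seq_len(B), drop = FALSE]
  d_params <- array(0, c(m, P, B))
  d_encoding <- array(0, c(m, spec$n_encoding, B))
  for (s in seq_len(n_shift)) {
    g <- (out[, col0(s, 1), drop = FALSE] -
          out[, col0(s, -1), drop = FALSE]) / 2
    if (s <= P) d_params[, s, ] <- g else d_encoding[, s - P, ] <- g
  }
  list(value = value, d_params = d_params, d_encoding = d_encoding)
}
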