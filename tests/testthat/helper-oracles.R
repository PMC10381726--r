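# Independent dense-matrix oracle for the statevector simulator: every gate
# is expanded to its full 2^n x 2^n unitary with kronecker products (qubit 0
# = most significant bit, so qubit q occupies factor q+1 of the product).

oracle_gate_matrix <- function(gate, n, encoding = NULL, params = NULL) {
  I2 <- diag(2)
  if (gate$kind == "CNOT") {
    P0 <- matrix(c(1, 0, 0, 0), 2, 2)  # |0><0|
    P1 <- matrix(c(0, 0, 0, 1), 2, 2)  # |1><1|
    X <- matrix(c(0, 1, 1, 0), 2, 2)
    term <- function(ctrl_proj, tgt_op) {
      out <- 1
      for (q in 0:(n - 1)) {
        f <- if (q == gate$control) ctrl_proj
             else if (q == gate$target) tgt_op
             else I2
        out <- kronecker(out, f)
      }
      out
    }
    return(term(P0, I2) + term(P1, X))
  }
  U <- if (gate$kind == "H") {
    matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2)
  } else {
    src <- gate$angle_source
    th <- switch(src$kind,
                 const = src$value,
                 encoding = encoding[src$index],
                 param = params[src$index])
    matrix(c(cos(th / 2), sin(th / 2), -sin(th / 2), cos(th / 2)), 2, 2)
  }
  out <- 1
  for (q in 0:(n - 1)) out <- kronecker(out, if (q == gate$target) U else I2)
  out
}

oracle_run_circuit <- function(spec, encoding, params) {
  n <- spec$n_qubits
  psi <- complex(2^n); psi[1] <- 1 + 0i
  for (g in spec$gates)
    psi <- oracle_gate_matrix(g, n, encoding, params) %*% psi
  as.complex(psi)
}

# <psi| Z_q |psi> via the explicit observable matrix
oracle_z_expectation <- function(amps, n, q) {
  Z <- matrix(c(1, 0, 0, -1), 2, 2)
  O <- 1
  for (p in 0:(n - 1)) O <- kronecker(O, if (p == q) Z else diag(2))
  Re(Conj(amps) %*% O %*% amps)[1]
}

# random circuit over {H, RY(const), CNOT} for property tests
random_circuit <- function(n, n_gates) {
  gates <- lapply(seq_len(n_gates), function(i) {
    kind <- sample(c("H", "RY", "CNOT"), 1)
    if (kind == "CNOT" && n >= 2) {
      qs <- sample(0:(n - 1), 2)
      gate_op("CNOT", target = qs[1], control = qs[2])
    } else if (kind == "H") {
      gate_op("H", sample(0:(n - 1), 1))
    } else {
      gate_op("RY", sample(0:(n - 1), 1),
              angle_source = qcxr:::angle_const(runif(1, 0, 2 * pi)))
    }
  })
  structure(list(n_qubits = as.integer(n), depth = 0L, gates = gates,
                 n_encoding = as.integer(n), n_params = 0L),
            class = "circuit_spec")
}
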