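test_that("default circuit layout has the expected structure", {
  spec <- build_pqc(4, 4)
  expect_s3_class(spec, "circuit_spec")
  expect_identical(spec$n_params, 24L)          # n * (depth + 2)
  kinds <- vapply(spec$gates, function(g) g$kind, character(1))
  expect_identical(sum(kinds == "CNOT"), 12L)   # 3 per block x 4 blocks
  expect_identical(sum(kinds == "H"), 4L)
  # n encoding RYs + P trainable RYs
  expect_identical(sum(kinds == "RY"), 4L + 24L)

  spec2 <- build_pqc(2, 1)
  expect_identical(spec2$n_params, 6L)
  kinds2 <- vapply(spec2$gates, function(g) g$kind, character(1))
  expect_identical(sum(kinds2 == "CNOT"), 1L)

  expect_error(build_pqc(1, 4), "n_qubits")
  expect_error(build_pqc(4, 0), "depth")
})

test_that("single-gate semantics match textbook definitions", {
  s <- quantum_state(1)
  h <- apply_gate(s, gate_op("H", 0))
  expect_equal(h$amplitudes, complex(real = c(1, 1) / sqrt(2)), tolerance = 1e-12)

  # CNOT on |10> -> |11> (qubit 0 = MSB)
  s10 <- quantum_state(2, c(0, 0, 1, 0))
  out <- apply_gate(s10, gate_op("CNOT", target = 1, control = 0))
  expect_equal(Mod(out$amplitudes), c(0, 0, 0, 1), tolerance = 1e-12)

  # RY(pi)|0> = |1> up to global sign
  r <- apply_gate(quantum_state(1), gate_op("RY", 0, angle_source = qcxr:::angle_const(pi)))
  expect_equal(Mod(r$amplitudes), c(0, 1), tolerance = 1e-12)

  expect_error(apply_gate(quantum_state(1), gate_op("H", 3)), "range")
  expect_error(apply_gate(quantum_state(1, c(1, 0)) |>
                            (\(x) { x$amplitudes <- c(2, 0); x })(),
                          gate_op("H", 0)), "normalized")
})

test_that("run_circuit matches the dense-matrix oracle on random circuits", {
  set.seed(42)
  for (n in 2:4) {
    for (rep in 1:5) {
      spec <- random_circuit(n, n_gates = 12)
      got <- run_circuit(spec, numeric(n), numeric(0))
      want <- oracle_run_circuit(spec, numeric(n), numeric(0))
      expect_lt(max(Mod(got$amplitudes - want)), 1e-10)
    }
  }
  # the full default PQC against the oracle
  spec <- build_pqc(3, 2)
  enc <- runif(3, -pi, pi); th <- runif(spec$n_params, 0, 2 * pi)
  got <- run_circuit(spec, enc, th)
  want <- oracle_run_circuit(spec, enc, th)
  expect_lt(max(Mod(got$amplitudes - want)), 1e-10)
})

test_that("norm is preserved through arbitrary random gate sequences", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    spec <- random_circuit(n, n_gates = 30)
    st <- run_circuit(spec, numeric(n), numeric(0))
    expect_lt(abs(sqrt(sum(Mod(st$amplitudes)^2)) - 1), 1e-9)
  }
})

test_that("Z expectations follow the spectral definition", {
  # |0...0> -> all +1 ; |+>^n -> all 0
  expect_equal(measure_z_expectations(quantum_state(3)), rep(1, 3))
  spec <- build_pqc(3, 1)
  plus <- run_circuit(spec, numeric(3), numeric(spec$n_params))
  # all angles zero: H layer only
  expect_equal(measure_z_expectations(plus), rep(0, 3), tolerance = 1e-12)

  set.seed(11)
  circ <- random_circuit(3, 15)
  st <- run_circuit(circ, numeric(3), numeric(0))
  z <- measure_z_expectations(st)
  for (q in 0:2)
    expect_equal(z[q + 1], oracle_z_expectation(st$amplitudes, 3, q),
                 tolerance = 1e-10)
  expect_true(all(z >= -1 - 1e-12 & z <= 1 + 1e-12))
})

test_that("1-qubit H,RY circuit has <Z> = -sin(theta)", {
  # closed form checked against a brute-force 2x2 matrix product
  spec <- structure(list(
    n_qubits = 1L, depth = 0L,
    gates = list(gate_op("H", 0),
                 gate_op("RY", 0, angle_source = qcxr:::angle_encoding(1))),
    n_encoding = 1L, n_params = 0L), class = "circuit_spec")
  for (th in c(0, 0.3, -1.2, pi / 2, 2.5)) {
    st <- run_circuit(spec, th, numeric(0))
    expect_equal(measure_z_expectations(st), -sin(th), tolerance = 1e-12)
    want <- oracle_run_circuit(spec, th, numeric(0))
    expect_lt(max(Mod(st$amplitudes - want)), 1e-12)
  }
})

test_that("class probabilities: exact mode, shots mode, determinism", {
  expect_equal(sample_class_probabilities(quantum_state(2), D = 2), c(1, 0))
  plus2 <- run_circuit(build_pqc(2, 1), numeric(2), numeric(6))
  expect_equal(sample_class_probabilities(plus2, D = 4), rep(0.25, 4),
               tolerance = 1e-9)
  expect_error(sample_class_probabilities(quantum_state(2), D = 8), "exceed")
  expect_error(sample_class_probabilities(quantum_state(2), D = 2, shots = 0),
               "shots")

  set.seed(123)
  a <- sample_class_probabilities(plus2, D = 2, shots = 10)
  set.seed(123)
  b <- sample_class_probabilities(plus2, D = 2, shots = 10)
  expect_identical(a, b)
  expect_equal(sum(a), 1)
})

test_that("shots mode converges to exact class probabilities", {
  set.seed(99)
  spec <- build_pqc(3, 2)
  enc <- runif(3, -pi / 2, pi / 2); th <- runif(spec$n_params, 0, 2 * pi)
  st <- run_circuit(spec, enc, th)
  exact <- sample_class_probabilities(st, D = 4)
  emp <- sample_class_probabilities(st, D = 4, shots = 1e5)
  expect_lt(max(abs(emp - exact)), 0.01)
})

test_that("parameter-shift gradients equal finite differences", {
  set.seed(5)
  z_first <- function(st) measure_z_expectations(st)[1]
  # closed-form check: 1-qubit [H, RY(theta)], O = Z, theta = 0 -> grad -1
  spec1 <- structure(list(
    n_qubits = 1L, depth = 0L,
    gates = list(gate_op("H", 0),
                 gate_op("RY", 0, angle_source = qcxr:::angle_param(1))),
    n_encoding = 1L, n_params = 1L), class = "circuit_spec")
  g <- parameter_shift_gradient(spec1, 0, 0, z_first)
  expect_equal(g$d_params, -1, tolerance = 1e-12)

  # 100 random (circuit, angle) cases against central finite differences
  h <- 1e-6
  n_checked <- 0
  for (rep in 1:10) {
    n <- sample(2:3, 1)
    spec <- build_pqc(n, sample(1:2, 1))
    enc <- runif(n, -pi, pi); th <- runif(spec$n_params, 0, 2 * pi)
    obs <- function(st) measure_z_expectations(st)[1]
    g <- parameter_shift_gradient(spec, enc, th, obs)
    ks <- sample(spec$n_params, min(8, spec$n_params))
    for (k in ks) {
      tp <- th; tm <- th; tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      fd <- (obs(run_circuit(spec, enc, tp)) -
             obs(run_circuit(spec, enc, tm))) / (2 * h)
      expect_equal(g$d_params[k], fd, tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
    for (i in seq_len(n)) {
      ep <- enc; em <- enc; ep[i] <- ep[i] + h; em[i] <- em[i] - h
      fd <- (obs(run_circuit(spec, ep, th)) -
             obs(run_circuit(spec, em, th))) / (2 * h)
      expect_equal(g$d_encoding[i], fd, tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("batched Jacobians agree with per-sample parameter-shift calls", {
  set.seed(17)
  spec <- build_pqc(3, 1)
  B <- 3
  enc <- matrix(runif(3 * B, -pi, pi), 3, B)
  th <- runif(spec$n_params, 0, 2 * pi)
  jac <- qcxr:::pqc_jacobians(spec, enc, th, output = "z")
  for (b in seq_len(B)) {
    st <- run_circuit(spec, enc[, b], th)
    expect_equal(jac$value[, b], measure_z_expectations(st), tolerance = 1e-12)
    for (q in 1:3) {
      g <- parameter_shift_gradient(spec, enc[, b], th,
                                    function(s) measure_z_expectations(s)[q])
      expect_equal(jac$d_params[q, , b], g$d_params, tolerance = 1e-12)
      expect_equal(jac$d_encoding[q, , b], g$d_encoding, tolerance = 1e-12)
    }
  }
  # class-probability output path
  jac_c <- qcxr:::pqc_jacobians(spec, enc, th, output = "class", D = 4)
  for (b in seq_len(B)) {
    st <- run_circuit(spec, enc[, b], th)
    expect_equal(jac_c$value[, b], sample_class_probabilities(st, 4),
                 tolerance = 1e-12)
  }
})
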