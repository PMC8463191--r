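# Shared fixtures and independent oracles.

# Independent single-module (Taylor-type) right-hand side, written directly
# from the printed four-population equations; used as the oracle for the
# uncoupled-topology equivalence property.
taylor_rhs <- function(state, h7, h8,
                       h = c(1.8, 1.5, 1, 4, 3, 0.6, h7, h8, 0.2),
                       eps = c(-0.35, -3.4, -2, -5),
                       tau = c(26, 32.5, 2.6, 2.6),
                       a = 2.8, b = 0.5, base = 250000) {
  Q <- function(x) 1 / (1 + base^(-x))
  K <- function(y) a * y + b
  py <- state[1]; inn <- state[2]; srn <- state[3]; trn <- state[4]
  c((eps[1] - py + h[1] * Q(py) - h[2] * Q(inn) + h[3] * Q(srn)) * tau[1],
    (eps[2] - inn + h[4] * Q(py)) * tau[2],
    (eps[3] - srn + h[5] * Q(py) - h[6] * K(trn)) * tau[3],
    (eps[4] - trn + h[7] * Q(py) + h[8] * K(srn) - h[9] * K(trn)) * tau[4])
}

# short simulation config for tests that only need qualitative dynamics
fast_config <- function(...) {
  sim_config(duration = 15, transient = 5, n_repeats = 2, seed = 42,
             record_every = 8L, ...)
}

# module-swapped copy of a state vector
swap_modules <- function(state) state[c(5:8, 1:4)]
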