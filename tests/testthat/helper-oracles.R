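# Independent oracles for the numerical propagators.

# Carver-Richards closed form for two-site SQ CPMG (literature expression,
# no fast-exchange approximation)
carver_richards <- function(p_GS, k_ex, dw, R2_G, R2_E, nu_cpmg) {
  p_E <- 1 - p_GS
  k_GE <- p_E * k_ex
  k_EG <- p_GS * k_ex
  d <- R2_G - R2_E - k_GE + k_EG
  psi <- d^2 - dw^2 + 4 * p_GS * p_E * k_ex^2
  zeta <- 2 * dw * d
  root <- sqrt(psi^2 + zeta^2)
  Dp <- 0.5 * (1 + (psi + 2 * dw^2) / root)
  Dm <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  eta_p <- sqrt(pmax(psi + root, 0)) / (2 * sqrt(2) * nu_cpmg)
  eta_m <- sqrt(pmax(-psi + root, 0)) / (2 * sqrt(2) * nu_cpmg)
  0.5 * (R2_G + R2_E + k_ex) -
    nu_cpmg * acosh(Dp * cosh(eta_p) - Dm * cos(eta_m))
}

# RK4 integration of dv/dt = L v over duration 'dur' with step <= dt_max
rk4_prop <- function(L, v, dur, dt_max = 1e-6) {
  n <- max(1L, ceiling(dur / dt_max))
  dt <- dur / n
  for (i in seq_len(n)) {
    k1 <- L %*% v
    k2 <- L %*% (v + dt / 2 * k1)
    k3 <- L %*% (v + dt / 2 * k2)
    k4 <- L %*% (v + dt * k3)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  v
}

sq_evolution_matrix <- function(p_GS, k_ex, dw, R2_G, R2_E) {
  k_GE <- (1 - p_GS) * k_ex
  k_EG <- p_GS * k_ex
  matrix(c(-R2_G - k_GE, k_EG,
           k_GE, -R2_E - k_EG + 1i * dw), 2, 2, byrow = TRUE)
}

# brute-force MQ CPMG by small-time-step propagation of the ZQ/DQ
# amplitude vectors through the full pulse train (proton pulse at the
# midpoint), signal = |sum(ZQ) + sum(DQ)| / 2
brute_mq_signal <- function(p_GS, k_ex, dwH, dwC, R2, Tcp, nu,
                            dt_max = 1e-6) {
  LZ <- sq_evolution_matrix(p_GS, k_ex, dwH - dwC, R2, R2)
  LD <- sq_evolution_matrix(p_GS, k_ex, dwH + dwC, R2, R2)
  N <- round(2 * Tcp * nu)
  stopifnot(N %% 2 == 0)
  tau <- Tcp / N
  z <- c(p_GS, 1 - p_GS) + 0i
  d <- z
  for (half in 1:2) {
    for (j in seq_len(N / 2)) {
      z1 <- rk4_prop(LZ, z, tau / 2, dt_max)
      d1 <- rk4_prop(LD, d, tau / 2, dt_max)
      z <- rk4_prop(LZ, d1, tau / 2, dt_max)
      d <- rk4_prop(LD, z1, tau / 2, dt_max)
    }
    if (half == 1) {
      tmp <- z
      z <- Conj(d)
      d <- Conj(tmp)
    }
  }
  s <- 0.5 * Mod(sum(z) + sum(d))
  -log(s) / Tcp
}

# brute-force dominant-mode rate: the two-echo cycle operator in the ZQ
# channel assembled by RK4 integration of basis vectors, eigenvalues by
# base R
brute_mq_cycle_rate <- function(p_GS, k_ex, dwH, dwC, R2, Tcp, nu,
                                dt_max = 1e-6) {
  LZ <- sq_evolution_matrix(p_GS, k_ex, dwH - dwC, R2, R2)
  LD <- sq_evolution_matrix(p_GS, k_ex, dwH + dwC, R2, R2)
  N <- round(2 * Tcp * nu)
  tau <- Tcp / N
  cyc <- function(v) {
    v <- rk4_prop(LZ, v, tau / 2, dt_max)
    v <- rk4_prop(LD, v, tau, dt_max)
    rk4_prop(LZ, v, tau / 2, dt_max)
  }
  A <- cbind(cyc(c(1, 0) + 0i), cyc(c(0, 1) + 0i))
  lam <- eigen(A, only.values = TRUE)$values
  -(N / (2 * Tcp)) * log(max(Mod(lam)))
}
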