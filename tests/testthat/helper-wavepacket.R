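# Independent quantum oracle: split-operator wavepacket propagation on the
# two-state avoided-crossing model, diabatic representation, FFT grid.
# Used to benchmark surface-hopping transmission probabilities; kept fully
# independent of the package's propagation code.

wavepacket_transmission <- function(A, B, C, D, mass, k0,
                                    x0 = -10 * 0.529177211,
                                    sigx = 0.529177211,
                                    L = 45, N = 2048, dt = 0.01, tmax = 70) {
  hbar <- 0.6582119569
  Cm <- 103.642697
  x <- seq(-L / 2, L / 2, length.out = N + 1)[1:N]
  dx <- x[2] - x[1]
  k <- 2 * pi / (N * dx) * c(0:(N / 2 - 1), -(N / 2):-1)
  v11 <- ifelse(x >= 0, A * (1 - exp(-B * x)), -A * (1 - exp(B * x)))
  v12 <- C * exp(-D * x^2)
  # half-step potential propagator (2x2 closed form per grid point)
  hz <- v11
  hx <- v12
  w <- sqrt(hz^2 + hx^2)
  phi <- (dt / 2) / hbar
  cw <- cos(w * phi)
  sw <- ifelse(w > 0, sin(w * phi) / w, phi)
  P11 <- complex(real = cw, imaginary = -sw * hz)
  P22 <- complex(real = cw, imaginary = sw * hz)
  P12 <- complex(real = 0, imaginary = -sw * hx)
  Tk <- exp(-1i * (hbar * k^2 / (2 * mass * Cm)) * dt)
  psi1 <- exp(-(x - x0)^2 / (4 * sigx^2)) * exp(1i * k0 * x)
  psi1 <- psi1 / sqrt(sum(Mod(psi1)^2) * dx)
  psi2 <- complex(real = numeric(N))
  for (s in seq_len(ceiling(tmax / dt))) {
    a <- P11 * psi1 + P12 * psi2
    b <- P12 * psi1 + P22 * psi2
    a <- fft(Tk * fft(a), inverse = TRUE) / N
    b <- fft(Tk * fft(b), inverse = TRUE) / N
    psi1 <- P11 * a + P12 * b
    psi2 <- P12 * a + P22 * b
  }
  right <- x > 2
  # asymptotically (x >> 0) diabatic state 2 is the lower adiabat
  c(T_lower = sum(Mod(psi2[right])^2) * dx,
    T_upper = sum(Mod(psi1[right])^2) * dx,
    norm = sum(Mod(psi1)^2 + Mod(psi2)^2) * dx)
}
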