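# shared small fixtures built in code

# planar all-trans polyene with given single/double bond lengths
make_polyene <- function(single = 1.45, double = 1.35, angle = 120,
                         dihedrals = rep(180, 19)) {
  lens <- rep(c(double, single), length.out = 21)  # bond i: odd = double
  build_chain_geometry(lens, rep(angle, 20), dihedrals)
}

# random rigid transform applied to a geometry
rigid_transform <- function(X, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(X %*% Q, 2, rnorm(3, sd = 5), `+`)
}

# incoming velocity (A/fs) for momentum p in hbar/bohr units on a model
incoming_velocity <- function(model, p_au) {
  p_au * 0.6582119569 / (model$masses * 0.529177211) / 103.642697
}
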