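#' Analytic multi-state model Hamiltonians
#'
#' A `model_hamiltonian` bundles a diabatic potential-energy matrix (a named
#' functional form evaluated in compiled code, or user-supplied R functions),
#' per-degree-of-freedom masses and state labels. Adiabatic surfaces are the
#' eigenvalues of the diabatic matrix; eigenvector phases follow the
#' deterministic largest-magnitude-component-positive convention so that
#' repeated evaluation is bitwise reproducible.
#'
#' Units throughout: energies eV, coordinates Angstrom (torsions in radians),
#' masses amu, time fs.
#'
#' @param form name of the functional form: one of `"avoided_crossing"`,
#'   `"harmonic"`, `"coupled_harmonics"`, `"carotenoid"`, or `"custom"`.
#' @param params numeric parameter vector in the layout documented for each
#'   form (see the constructors below).
#' @param n_states,n_dof number of electronic states / nuclear coordinates.
#' @param masses per-dof masses in amu.
#' @param labels state labels, default `S0, S1, ...`.
#' @param dipole optional symmetric `n_states x n_states` matrix of diabatic
#'   transition-dipole magnitudes (arbitrary units); used for initial-state
#'   sampling and excited-state absorption weights.
#' @param potential,gradient for `form = "custom"`: an R function
#'   `coords -> symmetric matrix` and (optionally) `coords -> array
#'   (n_states, n_states, n_dof)`. When `gradient` is `NULL` it is obtained
#'   by central finite differences of `potential`.
#' @param id short model identifier stored in trajectory metadata.
#' @return an object of class `model_hamiltonian`.
#' @export
model_hamiltonian <- function(form, params = numeric(), n_states, n_dof,
                              masses, labels = paste0("S", seq_len(n_states) - 1L),
                              dipole = NULL, potential = NULL, gradient = NULL,
                              id = form) {
  forms <- c(custom = 0L, avoided_crossing = 1L, harmonic = 2L,
             coupled_harmonics = 3L, carotenoid = 4L)
  if (!form %in% names(forms))
    stop("unknown model form '", form, "'")
  if (form == "custom" && !is.function(potential))
    stop("form 'custom' requires a potential function")
  if (length(masses) != n_dof)
    stop("masses must have length n_dof")
  if (!is.null(dipole)) {
    dipole <- as.matrix(dipole)
    stopifnot(nrow(dipole) == n_states, ncol(dipole) == n_states)
    if (max(abs(dipole - t(dipole))) > 1e-12)
      stop("dipole matrix must be symmetric")
  }
  structure(list(form = form, form_code = forms[[form]],
                 params = as.numeric(params), n_states = as.integer(n_states),
                 n_dof = as.integer(n_dof), masses = as.numeric(masses),
                 labels = labels, dipole = dipole,
                 potential = potential, gradient = gradient, id = id),
            class = "model_hamiltonian")
}

#' @export
print.model_hamiltonian <- function(x, ...) {
  cat("model_hamiltonian '", x$id, "' (form: ", x$form, ")\n", sep = "")
  cat("  states:", x$n_states, paste0("(", paste(x$labels, collapse = ", "), ")"),
      "\n  dof:   ", x$n_dof, " masses [amu]:", paste(signif(x$masses, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' One-dimensional two-state single avoided crossing
#'
#' The classic scattering benchmark: `V11 = A(1 - exp(-B x))` for `x >= 0`,
#' `-A(1 - exp(B x))` for `x < 0`, `V22 = -V11`, `V12 = C exp(-D x^2)`.
#' Defaults are the standard parameterization (A = 0.01 Ha, B = 1.6 / bohr,
#' C = 0.005 Ha, D = 1 / bohr^2, mass 2000 electron masses) converted to
#' eV / Angstrom / amu.
#'
#' @param A,C energies (eV); @param B inverse length (1/A); @param D inverse
#'   squared length (1/A^2); @param mass amu.
#' @return a `model_hamiltonian`.
#' @export
model_avoided_crossing <- function(A = 0.01 * .const$hartree_ev,
                                   B = 1.6 / .const$bohr_A,
                                   C = 0.005 * .const$hartree_ev,
                                   D = 1.0 / .const$bohr_A^2,
                                   mass = 2000 / 1822.888486) {
  model_hamiltonian("avoided_crossing", params = c(A, B, C, D),
                    n_states = 2L, n_dof = 1L, masses = mass,
                    id = "avoided_crossing_1d")
}

#' Uncoupled harmonic surface(s)
#'
#' Single-state separable harmonic oscillator, `V = sum_i k_i (x_i - x0_i)^2 / 2`.
#'
#' @param k force constants (eV/A^2); @param x0 minima (A); @param mass amu.
#' @return a `model_hamiltonian`.
#' @export
model_harmonic <- function(k, x0 = rep(0, length(k)), mass = rep(10, length(k))) {
  stopifnot(length(k) == length(x0))
  model_hamiltonian("harmonic", params = c(k, x0), n_states = 1L,
                    n_dof = length(k), masses = mass, id = "harmonic")
}

#' Displaced harmonic surfaces with constant couplings (1 dof)
#'
#' `V_ii = k_i (x - a_i)^2 / 2 + e_i`, constant off-diagonal couplings.
#'
#' @param k,a,e per-state curvature (eV/A^2), minimum (A), energy offset (eV).
#' @param coupling symmetric coupling matrix (eV) or a single scalar applied
#'   to every off-diagonal element.
#' @param mass amu.
#' @return a `model_hamiltonian`.
#' @export
model_coupled_harmonics <- function(k, a, e, coupling = 0, mass = 10) {
  ns <- length(k)
  stopifnot(length(a) == ns, length(e) == ns)
  if (is.matrix(coupling)) {
    cu <- coupling[upper.tri(coupling)]
  } else {
    cu <- rep(coupling, ns * (ns - 1) / 2)
  }
  model_hamiltonian("coupled_harmonics", params = c(k, a, e, cu),
                    n_states = ns, n_dof = 1L, masses = mass,
                    id = "coupled_harmonics")
}

#' Three-state carotenoid surrogate along BLA and a lumenal torsion
#'
#' A minimal model of a carotenoid's low-lying singlet manifold with two
#' reduced nuclear coordinates: the bond-length-alternation coordinate `b`
#' (Angstrom; positive in the ground state) and one lumenal C=C torsion
#' `theta` (radians; planar at 0 and pi). The ground state has its BLA
#' minimum at `b0 > 0`, the dark S1 state near `b = 0`, and the bright S2
#' above it. The diabatic S0-S1 coupling switches on as `b` drops below zero
#' (a sigmoid of width `wb`) and grows with out-of-plane distortion
#' (`1 + ctheta sin^2 theta`), encoding the two internal-conversion channels:
#' inverted bond-length alternation and backbone twisting.
#'
#' Parameter vector layout:
#' `(k0, b0, k1, e1, k2, b2, e2, ktheta0, ktheta1, ktheta2, c01, wb, ctheta,
#'  c12, c02)`.
#'
#' @param k0,b0 ground-state BLA curvature (eV/A^2) and minimum (A).
#' @param k1,e1 S1 BLA curvature and vertical offset (minimum at b = 0).
#' @param k2,b2,e2 S2 curvature, BLA minimum and offset.
#' @param ktheta0,ktheta1,ktheta2 torsional barrier scales per state (eV);
#'   the S1 value is smallest so the chain is floppier on S1.
#' @param c01 maximal S0-S1 diabatic coupling (eV); @param wb sigmoid width
#'   (A); @param ctheta distortion enhancement factor.
#' @param c12,c02 constant S1-S2 and S0-S2 couplings (eV).
#' @param masses amu for (BLA, torsion)-like coordinates.
#' @param conformer_offset label recorded in the id ("s-trans" or "s-cis");
#'   the torsional potential is identical, the offset distinguishes the
#'   parameterization used for ensemble setup.
#' @param dipole diabatic transition-dipole magnitudes; default makes S0-S2
#'   bright, S0-S1 nearly dark and gives S1 -> Sn intensity.
#' @return a `model_hamiltonian`.
#' @export
model_carotenoid <- function(k0 = 30, b0 = 0.10, k1 = 15, e1 = 1.90,
                             k2 = 25, b2 = 0.20, e2 = 2.30,
                             ktheta0 = 2.0, ktheta1 = 0.8, ktheta2 = 1.5,
                             c01 = 0.20, wb = 0.02, ctheta = 1.0,
                             c12 = 0.05, c02 = 0.01,
                             masses = c(10, 50),
                             conformer_offset = "s-trans",
                             dipole = NULL) {
  if (is.null(dipole)) {
    dipole <- matrix(c(0, 0.05, 1.0,
                       0.05, 0, 0.6,
                       1.0, 0.6, 0), 3, 3, byrow = TRUE)
  }
  model_hamiltonian("carotenoid",
                    params = c(k0, b0, k1, e1, k2, b2, e2,
                               ktheta0, ktheta1, ktheta2,
                               c01, wb, ctheta, c12, c02),
                    n_states = 3L, n_dof = 2L, masses = masses,
                    dipole = dipole,
                    id = paste0("carotenoid_", conformer_offset))
}

# diabatic matrix at coords, dispatching to compiled forms or R callbacks
diabatic_matrix <- function(model, coords) {
  coords <- as.numeric(coords)
  if (length(coords) != model$n_dof)
    stop("coords must have length n_dof (", model$n_dof, ")")
  V <- if (model$form_code == 0L) {
    v <- model$potential(coords)
    if (all(is.finite(v)) && max(abs(v - t(v))) > 1e-10)
      stop("custom potential matrix not symmetric")
    v
  } else {
    cpp_diabatic(model$form_code, model$params, coords, model$n_states)
  }
  if (any(!is.finite(V)))
    stop("non-finite potential at coords (",
         paste(signif(coords, 6), collapse = ", "), ")")
  V
}

# gradient of the diabatic matrix: array (n_states, n_states, n_dof)
diabatic_gradient <- function(model, coords, h = 1e-5) {
  coords <- as.numeric(coords)
  if (model$form_code != 0L)
    return(cpp_diabatic_grad(model$form_code, model$params, coords, model$n_states))
  if (is.function(model$gradient))
    return(model$gradient(coords))
  ns <- model$n_states
  G <- array(0, c(ns, ns, model$n_dof))
  for (i in seq_len(model$n_dof)) {
    xp <- coords; xp[i] <- xp[i] + h
    xm <- coords; xm[i] <- xm[i] - h
    G[, , i] <- (model$potential(xp) - model$potential(xm)) / (2 * h)
  }
  G
}

# fix eigenvector phases: largest-|component| entry positive
fix_eigvec_phase <- function(U) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  U
}

#' Adiabatic energies, gradients and eigenvectors
#'
#' Diagonalizes the diabatic potential matrix at `coords`. Energies are
#' sorted ascending; adiabatic gradients follow from the Hellmann-Feynman
#' expression `g_k = v_k' (dV/dx) v_k`; eigenvector phases are fixed by the
#' largest-magnitude-component-positive convention.
#'
#' @param coords numeric vector of length `n_dof`.
#' @param model a [model_hamiltonian()].
#' @return list with `energies` (ascending, eV), `gradients`
#'   (`n_states x n_dof` matrix, eV/A) and `vectors` (orthonormal columns).
#' @export
evaluate_surfaces <- function(coords, model) {
  V <- diabatic_matrix(model, coords)
  es <- eigen(V, symmetric = TRUE)
  ord <- order(es$values)
  E <- es$values[ord]
  U <- fix_eigvec_phase(es$vectors[, ord, drop = FALSE])
  G <- diabatic_gradient(model, coords)
  grads <- matrix(0, model$n_states, model$n_dof)
  for (k in seq_len(model$n_states))
    for (i in seq_len(model$n_dof))
      grads[k, i] <- drop(crossprod(U[, k], G[, , i] %*% U[, k]))
  rownames(grads) <- model$labels
  list(energies = setNames(E, model$labels), gradients = grads, vectors = U)
}

#' Overlap matrix between adiabatic states at successive geometries
#'
#' `S[j, k] = <psi_j(coords_t) | psi_k(coords_tdt)>` in the diabatic basis.
#' Column signs are corrected so the diagonal is non-negative
#' (diagonal-dominant phase convention). If the step is so large that the
#' matrix is near-singular, a warning is raised and the Loewdin-orthonormalized
#' matrix is returned instead.
#'
#' @param coords_t,coords_tdt coordinates at the two geometries.
#' @param model a [model_hamiltonian()].
#' @param orthonormalize return the Loewdin-orthonormalized overlap.
#' @return `n_states x n_states` overlap matrix.
#' @export
state_overlap_matrix <- function(coords_t, coords_tdt, model,
                                 orthonormalize = FALSE) {
  U1 <- evaluate_surfaces(coords_t, model)$vectors
  U2 <- evaluate_surfaces(coords_tdt, model)$vectors
  S <- crossprod(U1, U2)
  for (k in seq_len(ncol(S))) if (S[k, k] < 0) S[, k] <- -S[, k]
  sv <- svd(S)
  if (min(sv$d) < 1e-8) {
    warning("overlap matrix near-singular (step too large); ",
            "returning renormalized overlap")
    orthonormalize <- TRUE
  }
  if (orthonormalize) S <- sv$u %*% t(sv$v)
  S
}

#' Sample a classical thermal ensemble on one adiabatic surface
#'
#' Locates the minimum of the requested adiabatic surface, builds the
#' mass-weighted Hessian by finite differences, and draws uncorrelated
#' classical Boltzmann samples of positions and velocities from the
#' normal-mode harmonic approximation at the given temperature.
#'
#' @param model a [model_hamiltonian()].
#' @param n number of samples.
#' @param temperature K.
#' @param state surface index (1 = ground state).
#' @param x0 starting guess for the minimum search.
#' @param seed integer RNG seed.
#' @return list with `coords` and `velocities` (`n x n_dof` matrices) and the
#'   located `minimum`.
#' @export
sample_ground_ensemble <- function(model, n, temperature = 300, state = 1L,
                                   x0 = rep(0, model$n_dof), seed = 1L) {
  efun <- function(x) evaluate_surfaces(x, model)$energies[state]
  opt <- if (model$n_dof == 1L) {
    o <- optim(x0, efun, method = "Brent", lower = x0 - 5, upper = x0 + 5)
  } else {
    optim(x0, efun, method = "BFGS")
  }
  xmin <- opt$par
  h <- 1e-4
  nd <- model$n_dof
  H <- matrix(0, nd, nd)
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    pp <- pm <- mp <- mm <- xmin
    pp[i] <- pp[i] + h; pp[j] <- pp[j] + h
    pm[i] <- pm[i] + h; pm[j] <- pm[j] - h
    mp[i] <- mp[i] - h; mp[j] <- mp[j] + h
    mm[i] <- mm[i] - h; mm[j] <- mm[j] - h
    H[i, j] <- (efun(pp) - efun(pm) - efun(mp) + efun(mm)) / (4 * h^2)
  }
  Minv <- 1 / sqrt(model$masses)
  Hmw <- H * tcrossprod(Minv)          # eV / (amu A^2)
  ev <- eigen(Hmw, symmetric = TRUE)
  if (any(ev$values <= 0))
    stop("non-positive curvature at the located minimum; not a bound well")
  kT <- .const$kB_ev * temperature
  set.seed(seed)
  q  <- sweep(matrix(rnorm(n * nd), n, nd), 2, sqrt(kT / ev$values), `*`)
  qd <- matrix(rnorm(n * nd, sd = sqrt(kT / .const$amu_a2fs2_ev)), n, nd)
  coords <- sweep(q %*% t(ev$vectors), 2, Minv, `*`)
  coords <- sweep(coords, 2, xmin, `+`)
  vels <- sweep(qd %*% t(ev$vectors), 2, Minv, `*`)
  list(coords = coords, velocities = vels, minimum = xmin)
}

#' Read / write model definitions as structured config files
#'
#' YAML schema (format id `carotdyn-model/1`): keys `format`, `id`, `form`,
#' `states`, `dof`, `labels`, `masses`, `params`, optional `dipole`
#' (row-major flattened symmetric matrix).
#'
#' @param path file path.
#' @return `read_model_config` returns a [model_hamiltonian()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$format) || !identical(cfg$format, "carotdyn-model/1"))
    stop("unrecognized model config format: ", cfg$format)
  dip <- if (!is.null(cfg$dipole))
    matrix(as.numeric(cfg$dipole), cfg$states, cfg$states, byrow = TRUE)
  model_hamiltonian(cfg$form, params = as.numeric(cfg$params),
                    n_states = cfg$states, n_dof = cfg$dof,
                    masses = as.numeric(cfg$masses),
                    labels = if (!is.null(cfg$labels)) cfg$labels else
                      paste0("S", seq_len(cfg$states) - 1L),
                    dipole = dip,
                    id = if (!is.null(cfg$id)) cfg$id else cfg$form)
}

#' @rdname read_model_config
#' @param model a [model_hamiltonian()] (non-custom form).
#' @export
write_model_config <- function(model, path) {
  if (model$form == "custom")
    stop("custom-form models cannot be serialized to config files")
  cfg <- list(format = "carotdyn-model/1", id = model$id, form = model$form,
              states = model$n_states, dof = model$n_dof,
              labels = model$labels, masses = model$masses,
              params = model$params)
  if (!is.null(model$dipole)) cfg$dipole <- as.numeric(t(model$dipole))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
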