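#' Surface-hopping run settings
#'
#' @param timestep nuclear timestep in fs.
#' @param substeps electronic substeps per nuclear step (locally diabatic
#'   propagation with linearly interpolated Hamiltonian).
#' @param total_time total propagation time in fs; must be an integer
#'   multiple of `timestep`.
#' @param decoherence one of `"overlap"` (frozen-Gaussian collapse),
#'   `"energy_based"` (gap/kinetic-energy damping) or `"none"`.
#' @param decoherence_width Gaussian width for the overlap scheme, in
#'   mass-weighted amu^(1/2) Angstrom.
#' @param decoherence_threshold overlap below which the electronic wave
#'   function collapses onto the active state.
#' @param decoherence_const energy constant C of the energy-based scheme, eV
#'   (default 0.1 Hartree).
#' @param frustrated `"ignore"` (keep velocities) or `"reverse"` (invert
#'   them) after a rejected upward hop.
#' @param energy_tol allowed total-energy drift between hops, eV per ps.
#' @param seed integer RNG seed for the hop random numbers.
#' @param temperature K, used by initial-condition sampling helpers.
#' @param record_stride store every `record_stride`-th frame.
#' @param exit_coord if positive, stop a trajectory once `|x_1|` exceeds this
#'   value (scattering runs).
#' @return an `sh_settings` object.
#' @export
sh_settings <- function(timestep = 0.1, substeps = 100L, total_time = 1000,
                        decoherence = c("overlap", "energy_based", "none"),
                        decoherence_width = 6, decoherence_threshold = 1e-3,
                        decoherence_const = 0.1 * .const$hartree_ev,
                        frustrated = c("ignore", "reverse"),
                        energy_tol = 0.02, seed = 1L, temperature = 300,
                        record_stride = 1L, exit_coord = 0) {
  decoherence <- match.arg(decoherence)
  frustrated <- match.arg(frustrated)
  stopifnot(timestep > 0, substeps >= 1)
  nsteps <- total_time / timestep
  if (abs(nsteps - round(nsteps)) > 1e-8)
    stop("total_time must be a multiple of timestep")
  structure(list(timestep = timestep, substeps = as.integer(substeps),
                 total_time = total_time, nsteps = as.integer(round(nsteps)),
                 decoherence = decoherence,
                 decoherence_width = decoherence_width,
                 decoherence_threshold = decoherence_threshold,
                 decoherence_const = decoherence_const,
                 frustrated = frustrated, energy_tol = energy_tol,
                 seed = as.integer(seed), temperature = temperature,
                 record_stride = as.integer(record_stride),
                 exit_coord = exit_coord),
            class = "sh_settings")
}

.deco_code <- c(none = 0L, overlap = 1L, energy_based = 2L)
.frus_code <- c(ignore = 0L, reverse = 1L)

#' Propagate one fewest-switches surface-hopping trajectory
#'
#' Classical nuclei move on the active adiabatic surface (velocity Verlet);
#' the electronic amplitudes are integrated in the locally diabatic
#' representation built from Loewdin-orthonormalized overlaps between
#' adiabatic eigenvectors at successive geometries. Hops are drawn from the
#' fewest-switches probabilities computed from the net population flux out
#' of the active state; accepted hops rescale the velocities isotropically
#' so total energy is conserved, energetically forbidden hops are frustrated.
#'
#' @param initial list with `coords`, `velocities` (length `n_dof`), `state`
#'   (1-based surface index) and optionally `coefficients` (complex, defaults
#'   to the pure active state).
#' @param model a [model_hamiltonian()].
#' @param settings an [sh_settings()].
#' @param metadata optional named list merged into the trajectory metadata
#'   (e.g. `conformer`, `set`).
#' @return list with `record` (class `sh_trajectory`: `time`, `coords`,
#'   `velocities`, `energies`, `coeffs`, `active`, `dipoles`, `metadata`) and
#'   `hops` (data frame: `time_fs`, `from`, `to`, `energy_gap_ev` and hop-frame
#'   coordinates).
#' @export
propagate_trajectory <- function(initial, model, settings,
                                 metadata = list()) {
  stopifnot(inherits(model, "model_hamiltonian"),
            inherits(settings, "sh_settings"))
  st <- as.integer(initial$state)
  if (st < 1L || st > model$n_states)
    stop("initial state out of range")
  coeffs <- initial$coefficients
  if (is.null(coeffs)) {
    coeffs <- complex(real = rep(0, model$n_states))
    coeffs[st] <- 1 + 0i
  }
  if (abs(sum(Mod(coeffs)^2) - 1) > 1e-8)
    stop("initial coefficients not normalized")
  if (model$form_code == 0L)
    stop("the compiled propagator requires a named model form; ",
         "evaluate custom models through evaluate_surfaces/electronic_step")
  dip <- model$dipole
  if (is.null(dip)) dip <- matrix(0, 1, 1)  # sentinel: no dipoles
  res <- cpp_propagate(model$form_code, model$params, model$n_states,
                       model$masses, as.numeric(initial$coords),
                       as.numeric(initial$velocities), st - 1L,
                       Re(coeffs), Im(coeffs),
                       dip, settings$timestep, settings$substeps,
                       settings$nsteps, .deco_code[[settings$decoherence]],
                       settings$decoherence_width,
                       settings$decoherence_threshold,
                       settings$decoherence_const,
                       .frus_code[[settings$frustrated]],
                       settings$energy_tol, settings$seed,
                       settings$record_stride, settings$exit_coord)
  hops <- data.frame(time_fs = as.numeric(res$hop_time),
                     from = as.integer(res$hop_from) + 1L,
                     to = as.integer(res$hop_to) + 1L,
                     energy_gap_ev = as.numeric(res$hop_gap))
  hc <- res$hop_coords
  if (nrow(hops) > 0) {
    colnames(hc) <- paste0("x", seq_len(model$n_dof))
    hops <- cbind(hops, as.data.frame(hc))
  }
  record <- structure(list(
    time = as.numeric(res$time), coords = res$coords,
    velocities = res$velocities, energies = res$energies,
    coeffs = matrix(complex(real = res$coeffs_re, imaginary = res$coeffs_im),
                    nrow = nrow(res$coeffs_re)),
    active = as.integer(res$active) + 1L,
    dipoles = res$dipoles,
    final_state = as.integer(res$final_state) + 1L,
    final_coords = as.numeric(res$final_coords),
    final_velocities = as.numeric(res$final_velocities),
    exited = isTRUE(res$exited),
    metadata = c(list(model = model$id, seed = settings$seed,
                      timestep = settings$timestep,
                      labels = model$labels), metadata)),
    class = "sh_trajectory")
  list(record = record, hops = hops)
}

#' @export
print.sh_trajectory <- function(x, ...) {
  cat("sh_trajectory:", length(x$time), "frames,",
      ncol(x$coords), "dof,", ncol(x$energies), "states; model",
      x$metadata$model, "\n")
  invisible(x)
}

#' Propagate an ensemble of surface-hopping trajectories
#'
#' Each trajectory uses an independent RNG stream seeded
#' `base_seed + trajectory index`.
#'
#' @param model a [model_hamiltonian()].
#' @param inits either a list of initial-condition lists (see
#'   [propagate_trajectory()]) or a function `i -> initial`.
#' @param settings an [sh_settings()]; its `seed` is used as the base seed.
#' @param n number of trajectories (defaults to `length(inits)`).
#' @param keep_frames store full frame records (memory-heavy); otherwise only
#'   final states, hop tables and per-frame active-state series are kept.
#' @return list with `trajectories` (if `keep_frames`), `final_state`
#'   (integer vector), `final_coords`, `hops` (row-bound hop table with
#'   trajectory ids), `active` (list of active-state series) and `time`.
#' @export
propagate_ensemble <- function(model, inits, settings, n = NULL,
                               keep_frames = FALSE) {
  if (is.function(inits)) {
    stopifnot(!is.null(n))
    getinit <- inits
  } else {
    if (is.null(n)) n <- length(inits)
    getinit <- function(i) inits[[i]]
  }
  final_state <- integer(n)
  final_coords <- matrix(NA_real_, n, model$n_dof)
  actives <- vector("list", n)
  trajs <- if (keep_frames) vector("list", n) else NULL
  hop_list <- vector("list", n)
  tgrid <- NULL
  for (i in seq_len(n)) {
    s <- settings
    s$seed <- settings$seed + i
    out <- propagate_trajectory(getinit(i), model, s,
                                metadata = list(index = i))
    final_state[i] <- out$record$final_state
    final_coords[i, ] <- out$record$final_coords
    actives[[i]] <- out$record$active
    if (is.null(tgrid) || length(out$record$time) > length(tgrid))
      tgrid <- out$record$time
    if (nrow(out$hops) > 0) {
      out$hops$trajectory <- i
      hop_list[[i]] <- out$hops
    }
    if (keep_frames) trajs[[i]] <- out$record
  }
  hops <- do.call(rbind, hop_list[!vapply(hop_list, is.null, TRUE)])
  if (is.null(hops)) hops <- data.frame(time_fs = numeric(), from = integer(),
                                        to = integer(),
                                        energy_gap_ev = numeric(),
                                        trajectory = integer())
  list(trajectories = trajs, final_state = final_state,
       final_coords = final_coords, hops = hops, active = actives,
       time = tgrid)
}

#' One locally diabatic electronic propagation step
#'
#' Integrates the electronic amplitudes over one nuclear step of length `dt`
#' given the overlap matrix between adiabatic eigenvectors at the two ends.
#' The Hamiltonian is linearly interpolated between `diag(energies)` and
#' `T diag(energies_next) T'` (with `T` the Loewdin-orthonormalized overlap)
#' and applied over `substeps` midpoint sub-intervals; the result is rotated
#' into the adiabatic basis at the end of the step.
#'
#' @param coeffs complex amplitudes (normalized).
#' @param overlap overlap matrix `<psi(t)|psi(t+dt)>`.
#' @param energies adiabatic energies at the start of the step (eV).
#' @param dt step length (fs).
#' @param energies_next energies at the end of the step (default `energies`).
#' @param substeps number of electronic sub-intervals.
#' @return list with `coeffs` (amplitudes at `t + dt`), `flux` (net
#'   population-flux matrix `N`, see [hop_probabilities()]) and `propagator`.
#' @export
electronic_step <- function(coeffs, overlap, energies, dt,
                            energies_next = energies, substeps = 100L) {
  nrm <- sum(Mod(coeffs)^2)
  if (abs(nrm - 1) > 1e-6) stop("coefficients not normalized")
  n <- length(coeffs)
  sv <- svd(overlap)
  T_ <- sv$u %*% t(sv$v)
  H0 <- diag(energies, n)
  H1 <- T_ %*% diag(energies_next, n) %*% t(T_)
  P <- diag(1 + 0i, n)
  dtau <- dt / substeps
  for (s in seq_len(substeps)) {
    frac <- (s - 0.5) / substeps
    H <- (1 - frac) * H0 + frac * H1
    es <- eigen(H, symmetric = TRUE)
    Uh <- es$vectors
    ph <- exp(-1i * es$values * dtau / .const$hbar_evfs)
    P <- (Uh %*% (ph * t(Uh))) %*% P
  }
  P <- t(T_) %*% P
  cnew <- drop(P %*% coeffs)
  if (abs(sum(Mod(cnew)^2) - nrm) > 1e-8)
    stop("non-unitary electronic propagator in step")
  M <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n))
    M[j, k] <- Re(Conj(cnew[k]) * P[k, j] * coeffs[j])
  list(coeffs = cnew, flux = M - t(M), propagator = P)
}

#' Fewest-switches hop probabilities
#'
#' Converts the net population-flux matrix of an electronic step into
#' per-state hop probabilities out of the active state:
#' `g_k = max(0, N[active, k]) / |c_active|^2`, clipped so the total never
#' exceeds one. With two states this is exactly the fractional population
#' loss of the active state, the minimal-switch prescription.
#'
#' @param active 1-based active-state index.
#' @param coeffs complex amplitudes at the start of the step.
#' @param flux net population-flux matrix from [electronic_step()].
#' @param dt step length (fs); kept for interface completeness, the flux is
#'   already integrated over the step.
#' @return numeric vector of probabilities (zero at the active position).
#' @export
hop_probabilities <- function(active, coeffs, flux, dt = NULL) {
  n <- length(coeffs)
  pop <- Mod(coeffs[active])^2
  g <- numeric(n)
  if (pop <= .Machine$double.eps) {
    warning("active-state population at machine epsilon; no hops possible")
    return(g)
  }
  for (k in seq_len(n)) if (k != active) g[k] <- max(0, flux[active, k]) / pop
  tot <- sum(g)
  if (tot > 1) g <- g / tot
  g
}

#' Apply (or frustrate) a surface hop
#'
#' Rescales all velocities isotropically so total energy is conserved across
#' the surface switch. If the kinetic energy cannot pay for an upward gap the
#' hop is frustrated: the state is kept and the velocities are either left
#' unchanged (`"ignore"`) or reversed (`"reverse"`).
#'
#' @param frame list with `velocities`, `masses` (amu), `energies` (adiabatic,
#'   eV) and `active` (1-based index).
#' @param target 1-based target surface.
#' @param policy frustrated-hop policy.
#' @return the updated frame list, with `hopped` (logical) and `scale` (the
#'   velocity rescale factor, `NA` if frustrated) added.
#' @export
apply_hop <- function(frame, target, policy = c("ignore", "reverse")) {
  policy <- match.arg(policy)
  if (target == frame$active) stop("target equals active state")
  ke <- 0.5 * .const$amu_a2fs2_ev * sum(frame$masses * frame$velocities^2)
  gap <- frame$energies[target] - frame$energies[frame$active]
  if (ke > gap) {
    fac <- sqrt(1 - gap / ke)
    frame$velocities <- frame$velocities * fac
    frame$active <- target
    frame$hopped <- TRUE
    frame$scale <- fac
  } else {
    frame$hopped <- FALSE
    frame$scale <- NA_real_
    if (policy == "reverse") frame$velocities <- -frame$velocities
  }
  frame
}

#' Decoherence correction of the electronic amplitudes
#'
#' `"overlap"`: full collapse onto the active state once the frozen-Gaussian
#' overlap between the nuclear wavepackets on different surfaces (supplied in
#' `context$overlap`) falls below `params$threshold`. `"energy_based"`: damps
#' each non-active amplitude by `exp(-dt / tau_k)` with
#' `tau_k = hbar/|E_k - E_a| (1 + C/E_kin)` and restores the norm onto the
#' active state. `"none"`: identity.
#'
#' @param coeffs complex amplitudes.
#' @param active 1-based active index.
#' @param scheme `"overlap"`, `"energy_based"` or `"none"`.
#' @param params list: `threshold` (overlap) or `C` (eV, energy-based).
#' @param context list: `overlap` (overlap scheme) or `energies`,
#'   `kinetic_energy` (eV) and `dt` (fs) for the energy-based scheme.
#' @return corrected, renormalized amplitudes.
#' @export
decoherence_correct <- function(coeffs, active, scheme, params = list(),
                                context = list()) {
  if (scheme == "none") return(coeffs)
  if (scheme == "overlap") {
    thr <- if (!is.null(params$threshold)) params$threshold else 1e-3
    if (!is.null(context$overlap) && context$overlap < thr) {
      ph <- coeffs[active]
      ph <- if (Mod(ph) > 0) ph / Mod(ph) else 1 + 0i
      coeffs[] <- 0 + 0i
      coeffs[active] <- ph
    }
    return(coeffs)
  }
  if (scheme == "energy_based") {
    C <- if (!is.null(params$C)) params$C else 0.1 * .const$hartree_ev
    E <- context$energies
    ke <- max(context$kinetic_energy, 1e-8)
    dt <- context$dt
    for (k in seq_along(coeffs)) {
      if (k == active) next
      gap <- abs(E[k] - E[active])
      if (gap < 1e-12) next
      tau <- .const$hbar_evfs / gap * (1 + C / ke)
      coeffs[k] <- coeffs[k] * exp(-dt / tau)
    }
    pna <- sum(Mod(coeffs[-active])^2)
    if (Mod(coeffs[active]) > 1e-14 && pna < 1)
      coeffs[active] <- coeffs[active] * sqrt(1 - pna) / Mod(coeffs[active])
    return(coeffs / sqrt(sum(Mod(coeffs)^2)))
  }
  stop("unknown decoherence scheme '", scheme, "'")
}

#' Sample initial excited states according to transition dipole moments
#'
#' Draws `n` phase-space points uniformly from a ground-state ensemble and,
#' for each, an initial excited state with probability proportional to
#' `|mu_0k|^2`, optionally restricted to an excitation-energy window.
#'
#' @param ensemble list with `coords` and `velocities` matrices (rows =
#'   samples), e.g. from [sample_ground_ensemble()].
#' @param dipoles matrix (`n_samples x n_states`) of ground-to-state
#'   transition-dipole magnitudes, or a single vector reused for every
#'   sample. Column 1 (the ground state) is ignored.
#' @param n number of initial conditions to draw.
#' @param seed integer RNG seed.
#' @param energies optional matrix of excitation energies (eV) matching
#'   `dipoles`; required when `window` is given.
#' @param window optional `c(min, max)` excitation-energy window in eV.
#' @return list of initial-condition lists (`coords`, `velocities`, `state`).
#' @export
sample_initial_conditions <- function(ensemble, dipoles, n, seed = 1L,
                                      energies = NULL, window = NULL) {
  nf <- nrow(ensemble$coords)
  if (is.null(dim(dipoles)))
    dipoles <- matrix(dipoles, nf, length(dipoles), byrow = TRUE)
  ns <- ncol(dipoles)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- sample.int(nf, 1L)
    w <- dipoles[f, ]^2
    w[1] <- 0
    if (!is.null(window)) {
      if (is.null(energies)) stop("window requires excitation energies")
      w[energies[f, ] < window[1] | energies[f, ] > window[2]] <- 0
    }
    if (sum(w) <= 0)
      stop("all candidate transition dipoles are zero for frame ", f)
    st <- sample.int(ns, 1L, prob = w)
    out[[i]] <- list(coords = ensemble$coords[f, ],
                     velocities = ensemble$velocities[f, ], state = st)
  }
  out
}
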