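#' Chromophore transition density as atomic transition charges
#'
#' @param positions `n x 3` matrix of atom coordinates (Angstrom).
#' @param charges per-atom transition charges (e).
#' @param label chromophore label, e.g. `"Lut-S1"` or `"Chl-a612-Qy"`.
#' @return a `chromophore_transition` with the derived transition dipole
#'   `sum_i q_i r_i` (e Angstrom).
#' @export
chromophore_transition <- function(positions, charges, label = "chromophore") {
  positions <- as.matrix(positions)
  if (nrow(positions) != length(charges))
    stop("charge list length must match positions")
  structure(list(positions = positions, charges = as.numeric(charges),
                 label = label,
                 dipole = drop(crossprod(positions, charges))),
            class = "chromophore_transition")
}

#' @export
print.chromophore_transition <- function(x, ...) {
  cat("chromophore_transition '", x$label, "': ", nrow(x$positions),
      " atoms, |mu| = ", signif(sqrt(sum(x$dipole^2)), 4), " e A\n", sep = "")
  invisible(x)
}

#' Read / write transition-charge files
#'
#' CSV with columns `atom`, `x`, `y`, `z` (Angstrom), `q` (e).
#'
#' @param path file path; @param label chromophore label.
#' @return a [chromophore_transition()].
#' @export
read_chromophore <- function(path, label = basename(path)) {
  d <- read.csv(path)
  need <- c("x", "y", "z", "q")
  if (!all(need %in% names(d)))
    stop("chromophore file must have columns atom, x, y, z, q")
  chromophore_transition(as.matrix(d[, c("x", "y", "z")]), d$q, label)
}

#' @rdname read_chromophore
#' @param chrom a [chromophore_transition()].
#' @export
write_chromophore <- function(chrom, path) {
  d <- data.frame(atom = seq_len(nrow(chrom$positions)),
                  x = chrom$positions[, 1], y = chrom$positions[, 2],
                  z = chrom$positions[, 3], q = chrom$charges)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Coulomb coupling between two transition-charge distributions
#'
#' `V = s * sum_ij q_i q_j / r_ij` evaluated in atomic units (charges in e,
#' distances converted at 1 bohr = 0.529177211 Angstrom) and reported in
#' cm^-1 (1 Hartree = 219474.6314 cm^-1). Symmetric under argument swap and
#' bilinear in each charge set.
#'
#' @param a,b [chromophore_transition()] objects.
#' @param screening optional scalar screening factor multiplying V
#'   (default 1: no dielectric screening).
#' @return coupling in cm^-1.
#' @export
coulomb_coupling <- function(a, b, screening = 1) {
  ra <- a$positions / .const$bohr_A
  rb <- b$positions / .const$bohr_A
  d2 <- outer(rowSums(ra^2), rowSums(rb^2), `+`) - 2 * tcrossprod(ra, rb)
  d <- sqrt(pmax(d2, 0))
  tooclose <- which(d * .const$bohr_A < 0.1, arr.ind = TRUE)
  if (nrow(tooclose) > 0)
    stop("coincident atoms across chromophores: pair (",
         tooclose[1, 1], ", ", tooclose[1, 2], ") at ",
         signif(d[tooclose[1, 1], tooclose[1, 2]] * .const$bohr_A, 3), " A")
  v_au <- sum(outer(a$charges, b$charges) / d)
  screening * v_au * .const$hartree_cm1
}

#' Ideal point-dipole coupling
#'
#' `V = s * (mu_a . mu_b - 3 (mu_a . n)(mu_b . n)) / R^3` from the derived
#' transition dipoles and the |q|-weighted charge centers; refuses geometries
#' whose centers are closer than three times either charge-cloud radius,
#' where the ideal-dipole limit does not apply.
#'
#' @param a,b [chromophore_transition()] objects.
#' @param screening optional scalar screening factor.
#' @return coupling in cm^-1.
#' @export
point_dipole_coupling <- function(a, b, screening = 1) {
  center <- function(ch) {
    w <- abs(ch$charges)
    if (sum(w) == 0) w <- rep(1, length(ch$charges))
    drop(crossprod(ch$positions, w)) / sum(w)
  }
  radius <- function(ch, cen) max(sqrt(rowSums(
    sweep(ch$positions, 2, cen)^2)))
  ca <- center(a); cb <- center(b)
  R <- cb - ca
  Rlen <- sqrt(sum(R^2))
  if (Rlen < 3 * max(radius(a, ca), radius(b, cb)))
    stop("charge clouds overlap: center separation ", signif(Rlen, 3),
         " A is below 3x the cloud radius; use coulomb_coupling() instead")
  n <- R / Rlen
  mua <- a$dipole / .const$bohr_A  # e bohr
  mub <- b$dipole / .const$bohr_A
  Rb <- Rlen / .const$bohr_A
  v_au <- (sum(mua * mub) - 3 * sum(mua * n) * sum(mub * n)) / Rb^3
  screening * v_au * .const$hartree_cm1
}

#' Energy-transfer favorability from paired vertical energies
#'
#' Fraction of frames in which the acceptor excitation (carotenoid S1) lies
#' below the donor excitation (chlorophyll Qy), i.e. downhill
#' excitation-energy transfer is energetically favorable.
#'
#' @param samples data frame with columns `donor_ev` and `acceptor_ev`
#'   (paired per frame) and optionally `donor` (label) for per-donor
#'   splits.
#' @param breaks histogram breaks (eV) for the emitted summaries.
#' @return list with `fraction`, `n`, `by_donor` (data frame, when donor
#'   labels are present) and `histograms` (donor/acceptor energy counts).
#' @export
eet_favorability <- function(samples, breaks = seq(0, 5, by = 0.05)) {
  if (nrow(samples) == 0) stop("empty sample")
  fav <- samples$acceptor_ev < samples$donor_ev
  by_donor <- NULL
  if (!is.null(samples$donor)) {
    by_donor <- do.call(rbind, lapply(split(fav, samples$donor), function(f)
      data.frame(fraction = mean(f), n = length(f))))
    by_donor$donor <- rownames(by_donor)
    rownames(by_donor) <- NULL
  }
  rng <- range(samples$donor_ev, samples$acceptor_ev)
  if (rng[1] < min(breaks) || rng[2] > max(breaks))
    breaks <- seq(floor(rng[1]), ceiling(rng[2]), by = 0.05)
  list(fraction = mean(fav), n = nrow(samples), by_donor = by_donor,
       histograms = list(
         donor = graphics::hist(samples$donor_ev, breaks = breaks,
                                plot = FALSE),
         acceptor = graphics::hist(samples$acceptor_ev, breaks = breaks,
                                   plot = FALSE)))
}
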