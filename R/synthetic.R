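#' Specification of a synthetic surface-hopping ensemble
#'
#' Defines the statistical structure of a mock trajectory ensemble: group
#' sizes and conformer fractions per conformational set, the sequential
#' kinetic parameters per (set, conformer) group, the production window, and
#' the descriptor/energy distributions. The defaults reproduce the study
#' conditions this package models: two conformational sets with 396 and 386
#' trajectories (782 total) propagated for 15 ps; set A purely s-cis, set B
#' an equal s-cis/s-trans mixture; kinetic parameters per group equal to the
#' fitted decay constants of those ensembles; ds2 centered at 180 (s-trans)
#' versus 0 degrees (s-cis), ds1 at 80 versus -50; ground-state BLA near
#' +0.10 Angstrom (broader for s-trans) shifting to zero on S1; chlorophyll
#' Qy energies narrowly distributed near 2 eV against a wide s-trans / narrow
#' s-cis S1 energy distribution.
#'
#' @param groups data frame with one row per (set, conformer) group:
#'   columns `set`, `conformer`, `n`, `tau2_fs`, `tau1_ps`, `w_fast`,
#'   `tau1p_ps`.
#' @param total_time_ps production window (ps).
#' @param frame_dt_fs frame spacing used when descriptor series are
#'   generated.
#' @param bla_channel_fraction fraction of fast-channel S1 -> S0 hops
#'   assigned to the negative-BLA channel (the remainder go to the
#'   lumenal-distortion channel). A free parameter of the generator.
#' @param descriptors named list of distribution parameters (means/sds for
#'   `ds1`, `ds2`, `bla` per state, `d_lum` baselines, hop-channel
#'   distributions); see defaults in the function body.
#' @param energies named list: `qy_mean`, `qy_sd`, and per-conformer S1
#'   `mean`/`sd`.
#' @return an `ensemble_spec` object.
#' @export
ensemble_spec <- function(groups = NULL, total_time_ps = 15, frame_dt_fs = 50,
                          bla_channel_fraction = 33 / 49,
                          descriptors = list(), energies = list()) {
  if (is.null(groups)) {
    groups <- data.frame(
      set = c("A", "B", "B"),
      conformer = c("s-cis", "s-cis", "s-trans"),
      n = c(396L, 193L, 193L),
      tau2_fs = c(135, 162, 141),
      tau1_ps = c(1.0, 1.2, 1.1),
      w_fast = c(0.201, 0.222, 0.590),
      tau1p_ps = c(21.2, 25.0, 16.7))
  }
  need <- c("set", "conformer", "n", "tau2_fs", "tau1_ps", "w_fast", "tau1p_ps")
  missing_cols <- setdiff(need, names(groups))
  if (length(missing_cols) > 0)
    stop("invalid spec: groups lacks columns ",
         paste(missing_cols, collapse = ", "))
  if (any(groups$w_fast < 0 | groups$w_fast > 1))
    stop("invalid spec: w_fast outside [0, 1]")
  if (any(groups$tau2_fs <= 0 | groups$tau1_ps <= 0 | groups$tau1p_ps <= 0))
    stop("invalid spec: non-positive time constants")
  desc <- list(
    ds2 = list(`s-trans` = c(mean = 180, sd = 8),
               `s-cis` = c(mean = 0, sd = 8)),
    ds1 = list(`s-trans` = c(mean = 80, sd = 10),
               `s-cis` = c(mean = -50, sd = 10)),
    bla_s0 = list(`s-trans` = c(mean = 0.10, sd = 0.020),
                  `s-cis` = c(mean = 0.10, sd = 0.012)),
    bla_s1 = list(`s-trans` = c(mean = 0.00, sd = 0.020),
                  `s-cis` = c(mean = 0.00, sd = 0.012)),
    d_lum = list(`s-trans` = c(mean = 0.05, sd = 0.025),
                 `s-cis` = c(mean = 0.03, sd = 0.015)),
    hop_bla_channel = c(mean = -0.035, sd = 0.008),
    hop_dlum_channel = c(mean = 0.14, sd = 0.03))
  desc[names(descriptors)] <- descriptors
  ener <- list(qy_mean = 2.00, qy_sd = 0.04,
               s1 = list(`s-trans` = c(mean = 1.95, sd = 0.45),
                         `s-cis` = c(mean = 2.10, sd = 0.12)))
  ener[names(energies)] <- energies
  if (any(vapply(desc$ds2, function(p) p["sd"], numeric(1)) <= 0))
    stop("invalid spec: non-positive width")
  structure(list(groups = groups, total_time_ps = total_time_ps,
                 frame_dt_fs = frame_dt_fs,
                 bla_channel_fraction = bla_channel_fraction,
                 descriptors = desc, energies = ener),
            class = "ensemble_spec")
}

# draw from a truncated normal by rejection (vectorized, modest tails)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Generate a synthetic trajectory ensemble
#'
#' Per trajectory: the S2 -> S1 hop time is exponential with the group's
#' tau2; the S1 -> S0 hop time adds a draw from the bi-exponential mixture
#' `w Exp(tau1) + (1 - w) Exp(tau1')`, truncated at the production window
#' (survivors end on S1 and carry `NA` hop descriptors). S1 -> S0 hops drawn
#' from the fast mixture component are assigned hop-frame descriptors in one
#' of the two decay channels (negative BLA, or lumenal distortion with
#' near-zero BLA) according to `bla_channel_fraction`; slow-component hops
#' get unremarkable hop geometries. All draws are reproducible under the
#' seed.
#'
#' @param spec an [ensemble_spec()].
#' @param seed integer RNG seed.
#' @return a `synthetic_ensemble`: list with `trajectories` (data frame:
#'   `id`, `set`, `conformer`, `t21_fs`, `t10_fs`, `channel`, `hop_time_fs`,
#'   `hop_bla`, `hop_d_lum`, `hop_ds2`, `survivor`), `total_time_fs`,
#'   `spec`, `seed`.
#' @export
generate_ensemble <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(seed)
  total_fs <- spec$total_time_ps * 1000
  rows <- vector("list", nrow(spec$groups))
  id0 <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    gr <- spec$groups[g, ]
    n <- gr$n
    conf <- gr$conformer
    t21 <- rexp(n, rate = 1 / gr$tau2_fs)
    fast <- runif(n) < gr$w_fast
    dwell <- ifelse(fast, rexp(n, rate = 1 / (gr$tau1_ps * 1000)),
                    rexp(n, rate = 1 / (gr$tau1p_ps * 1000)))
    t10 <- t21 + dwell
    survivor <- t10 > total_fs | t21 > total_fs
    t10[survivor] <- NA_real_
    channel <- rep("none", n)
    isfast <- fast & !survivor
    channel[isfast] <- ifelse(runif(sum(isfast)) < spec$bla_channel_fraction,
                              "bla", "distortion")
    channel[survivor] <- NA_character_
    dpar <- spec$descriptors
    hop_bla <- hop_dlum <- rep(NA_real_, n)
    hopped <- !survivor
    # slow-channel hops: unremarkable geometries (outside both channels)
    slow <- hopped & channel == "none"
    hop_bla[slow] <- rnorm_trunc(sum(slow), -0.005, 0.008, lower = -0.02)
    hop_dlum[slow] <- rnorm_trunc(sum(slow),
                                  dpar$d_lum[[conf]]["mean"] + 0.02,
                                  dpar$d_lum[[conf]]["sd"],
                                  lower = 0, upper = 0.10)
    isb <- hopped & channel == "bla"
    hop_bla[isb] <- rnorm_trunc(sum(isb), dpar$hop_bla_channel["mean"],
                                dpar$hop_bla_channel["sd"], upper = -0.0201)
    hop_dlum[isb] <- rnorm_trunc(sum(isb), dpar$d_lum[[conf]]["mean"] + 0.02,
                                 dpar$d_lum[[conf]]["sd"],
                                 lower = 0, upper = 0.10)
    isd <- hopped & channel == "distortion"
    hop_bla[isd] <- rnorm_trunc(sum(isd), -0.005, 0.008, lower = -0.02)
    hop_dlum[isd] <- rnorm_trunc(sum(isd), dpar$hop_dlum_channel["mean"],
                                 dpar$hop_dlum_channel["sd"], lower = 0.101)
    ds2p <- dpar$ds2[[conf]]
    hop_ds2 <- rep(NA_real_, n)
    hop_ds2[hopped] <- rnorm(sum(hopped), ds2p["mean"], ds2p["sd"])
    hop_ds2 <- ((hop_ds2 + 180) %% 360) - 180
    hop_ds2[!is.na(hop_ds2) & hop_ds2 <= -180] <- 180
    rows[[g]] <- data.frame(
      id = id0 + seq_len(n), set = gr$set, conformer = conf,
      t21_fs = t21, t10_fs = t10, survivor = survivor,
      channel = channel, hop_time_fs = t10,
      hop_bla = hop_bla, hop_d_lum = hop_dlum, hop_ds2 = hop_ds2)
    id0 <- id0 + n
  }
  structure(list(trajectories = do.call(rbind, rows),
                 total_time_fs = total_fs, spec = spec, seed = seed),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  tr <- x$trajectories
  cat("synthetic_ensemble:", nrow(tr), "trajectories,",
      sum(tr$survivor), "S1 survivors at", x$total_time_fs / 1000, "ps\n")
  print(table(tr$set, tr$conformer))
  invisible(x)
}

#' Hop table of a synthetic ensemble in analysis format
#'
#' @param ensemble a `synthetic_ensemble`.
#' @return data frame with `time_fs`, `from`, `to`, `bla`, `d_lum`, `ds2`,
#'   `conformer`, `set` for every S1 -> S0 hop.
#' @export
synthetic_hop_table <- function(ensemble) {
  tr <- ensemble$trajectories
  h <- tr[!tr$survivor, ]
  data.frame(trajectory = h$id, time_fs = h$hop_time_fs,
             from = 2L, to = 1L, bla = h$hop_bla, d_lum = h$hop_d_lum,
             ds2 = h$hop_ds2, conformer = h$conformer, set = h$set,
             channel = h$channel)
}

#' Mean-reverting descriptor series for one trajectory
#'
#' Generates per-frame geometry-descriptor series (ds1, ds2, BLA, D_Lum) as
#' stationary Ornstein-Uhlenbeck processes whose means switch with the
#' active electronic state (BLA relaxes from its ground-state mean toward
#' zero once S1 is populated).
#'
#' @param spec an [ensemble_spec()].
#' @param conformer `"s-trans"` or `"s-cis"`.
#' @param t21_fs,t10_fs hop times (fs); `t10_fs` may be `NA` (survivor).
#' @param seed integer RNG seed.
#' @param corr_time_fs mean-reversion time of the processes (fs).
#' @return data frame with `time_fs`, `active` (3/2/1 before first hop,
#'   between hops, after), `ds1`, `ds2`, `bla`, `d_lum`.
#' @export
generate_descriptor_series <- function(spec, conformer, t21_fs, t10_fs,
                                       seed = 1L, corr_time_fs = 200) {
  set.seed(seed)
  dt <- spec$frame_dt_fs
  tgrid <- seq(0, spec$total_time_ps * 1000, by = dt)
  n <- length(tgrid)
  active <- ifelse(tgrid < t21_fs, 3L,
                   ifelse(is.na(t10_fs) | tgrid < t10_fs, 2L, 1L))
  phi <- exp(-dt / corr_time_fs)
  ou <- function(mu, sd) {
    x <- numeric(n)
    x[1] <- rnorm(1, mu[1], sd)
    for (i in 2:n)
      x[i] <- mu[i] + phi * (x[i - 1] - mu[i]) +
        sd * sqrt(1 - phi^2) * rnorm(1)
    x
  }
  d <- spec$descriptors
  on_s1 <- active == 2L
  bla_mu <- ifelse(on_s1, d$bla_s1[[conformer]]["mean"],
                   d$bla_s0[[conformer]]["mean"])
  bla_sd <- d$bla_s0[[conformer]]["sd"]
  dl_mu <- ifelse(on_s1, d$d_lum[[conformer]]["mean"] + 0.03,
                  d$d_lum[[conformer]]["mean"])
  ds2 <- ou(rep(d$ds2[[conformer]]["mean"], n), d$ds2[[conformer]]["sd"])
  ds2 <- ((ds2 + 180) %% 360) - 180
  ds2[ds2 <= -180] <- 180
  data.frame(time_fs = tgrid, active = active,
             ds1 = ou(rep(d$ds1[[conformer]]["mean"], n),
                      d$ds1[[conformer]]["sd"]),
             ds2 = ds2,
             bla = ou(bla_mu, bla_sd),
             d_lum = pmax(0, ou(dl_mu, d$d_lum[[conformer]]["sd"])))
}

#' Paired donor/acceptor vertical-energy samples
#'
#' Draws chlorophyll Qy energies from the narrow distribution near 2 eV and
#' carotenoid S1 energies from the conformer-dependent distribution (wide
#' for s-trans, narrow for s-cis).
#'
#' @param spec an [ensemble_spec()].
#' @param n_per_group samples per (set, conformer) group.
#' @param seed integer RNG seed.
#' @return data frame with `set`, `conformer`, `donor`, `donor_ev`,
#'   `acceptor_ev`.
#' @export
generate_gap_samples <- function(spec, n_per_group = 500, seed = 1L) {
  set.seed(seed)
  en <- spec$energies
  donors <- c("a610", "a612", "a613")
  out <- lapply(seq_len(nrow(spec$groups)), function(g) {
    gr <- spec$groups[g, ]
    s1p <- en$s1[[gr$conformer]]
    dn <- sample(donors, n_per_group, replace = TRUE)
    data.frame(set = gr$set, conformer = gr$conformer, donor = dn,
               donor_ev = rnorm_trunc(n_per_group, en$qy_mean, en$qy_sd,
                                      lower = 0.1),
               acceptor_ev = rnorm_trunc(n_per_group, s1p["mean"], s1p["sd"],
                                         lower = 0.1))
  })
  do.call(rbind, out)
}

#' Generate a transition-charge set with a prescribed dipole
#'
#' Places `n_atoms` atoms (random positions in a 10 Angstrom box unless
#' given) and solves the minimum-norm charge problem subject to zero net
#' charge and `sum q_i r_i` equal to the target dipole.
#'
#' @param n_atoms at least 2.
#' @param dipole_target length-3 target dipole (e Angstrom).
#' @param seed integer RNG seed (positions).
#' @param positions optional `n_atoms x 3` coordinates.
#' @param label chromophore label.
#' @return a [chromophore_transition()].
#' @export
generate_transition_charges <- function(n_atoms, dipole_target, seed = 1L,
                                        positions = NULL,
                                        label = "synthetic") {
  if (n_atoms < 2) stop("need at least 2 atoms")
  dipole_target <- as.numeric(dipole_target)
  if (is.null(positions)) {
    set.seed(seed)
    positions <- matrix(runif(3 * n_atoms, -5, 5), n_atoms, 3)
  }
  A <- rbind(rep(1, n_atoms), t(positions))  # constraints: sum q, sum q r
  b <- c(0, dipole_target)
  AAt <- A %*% t(A)
  sol <- tryCatch(solve(AAt, b), error = function(e) NULL)
  if (is.null(sol)) {
    # degenerate geometry: the target may still be reachable along the span
    sv <- svd(AAt)
    keep <- sv$d > 1e-10 * sv$d[1]
    proj <- sv$u[, keep, drop = FALSE]
    b_in <- proj %*% crossprod(proj, b)
    if (max(abs(b_in - b)) > 1e-8)
      stop("dipole target unreachable for the given geometry ",
           "(collinear/degenerate atom positions)")
    sol <- sv$v[, keep, drop = FALSE] %*%
      ((1 / sv$d[keep]) * crossprod(sv$u[, keep, drop = FALSE], b))
  }
  q <- drop(t(A) %*% sol)
  chromophore_transition(positions, q, label)
}
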