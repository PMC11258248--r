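#' Conjugation topology of a polyene chain
#'
#' Explicit bond lists and named dihedrals of the conjugated backbone:
#' ordered single/double bond pairs, the C-C dihedrals `ds1..ds9` and the
#' C=C dihedrals `dd1..dd9`, split into a lumenal (`dd1-dd4`) and a stromal
#' (`dd5-dd9`) set. Atom indices are 1-based.
#'
#' @param single_bonds,double_bonds 2-column integer matrices of atom pairs.
#' @param dihedrals_s,dihedrals_d named lists of length-4 integer vectors
#'   (the C-C and C=C dihedrals).
#' @param lumenal,stromal names of the C=C dihedrals on each side; must be
#'   disjoint and together exhaust `names(dihedrals_d)`.
#' @param n_atoms total number of atoms indices may refer to.
#' @return a `conjugation_topology` object.
#' @export
conjugation_topology <- function(single_bonds, double_bonds,
                                 dihedrals_s, dihedrals_d,
                                 lumenal = paste0("dd", 1:4),
                                 stromal = paste0("dd", 5:9),
                                 n_atoms = max(single_bonds, double_bonds,
                                               unlist(dihedrals_s),
                                               unlist(dihedrals_d))) {
  single_bonds <- matrix(as.integer(single_bonds), ncol = 2)
  double_bonds <- matrix(as.integer(double_bonds), ncol = 2)
  idx <- c(single_bonds, double_bonds, unlist(dihedrals_s), unlist(dihedrals_d))
  if (any(idx < 1L) || any(idx > n_atoms))
    stop("atom index out of range 1..", n_atoms)
  dd_names <- names(dihedrals_d)
  if (length(intersect(lumenal, stromal)) > 0)
    stop("lumenal and stromal sets must be disjoint")
  if (!setequal(c(lumenal, stromal), dd_names))
    stop("lumenal + stromal must exhaust the named C=C dihedrals")
  structure(list(single_bonds = single_bonds, double_bonds = double_bonds,
                 dihedrals_s = dihedrals_s, dihedrals_d = dihedrals_d,
                 lumenal = lumenal, stromal = stromal, n_atoms = n_atoms),
            class = "conjugation_topology")
}

#' Standard 22-atom polyene backbone topology
#'
#' A linear conjugated chain of 22 carbons with alternating bonds starting
#' on a double bond: doubles at positions (1,2), (3,4), ..., singles in
#' between. The nine interior C=C dihedrals are named `dd1..dd9`
#' (lumenal = `dd1-dd4`, stromal = `dd5-dd9`) and the first nine interior
#' C-C dihedrals `ds1..ds9`, numbered from the lumenal end, mirroring the
#' conjugated chain of lutein.
#'
#' @return a [conjugation_topology()].
#' @export
polyene_topology <- function() {
  bonds <- cbind(1:21, 2:22)
  dbl <- bonds[seq(1, 21, by = 2), ]
  sgl <- bonds[seq(2, 20, by = 2), ]
  dd <- lapply(1:9, function(k) c(2 * k, 2 * k + 1, 2 * k + 2, 2 * k + 3))
  names(dd) <- paste0("dd", 1:9)
  ds <- lapply(1:9, function(k) c(2 * k - 1, 2 * k, 2 * k + 1, 2 * k + 2))
  names(ds) <- paste0("ds", 1:9)
  conjugation_topology(sgl, dbl, ds, dd, n_atoms = 22)
}

#' Read / write a topology config file
#'
#' YAML schema (`carotdyn-topology/1`): `single_bonds`, `double_bonds` as
#' flat integer lists (pairs, 1-based), `dihedrals_s`/`dihedrals_d` as named
#' 4-index lists, `lumenal`, `stromal`.
#'
#' @param path file path.
#' @return a [conjugation_topology()].
#' @export
read_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$format, "carotdyn-topology/1"))
    stop("unrecognized topology format: ", cfg$format)
  conjugation_topology(
    matrix(as.integer(cfg$single_bonds), ncol = 2, byrow = TRUE),
    matrix(as.integer(cfg$double_bonds), ncol = 2, byrow = TRUE),
    lapply(cfg$dihedrals_s, as.integer),
    lapply(cfg$dihedrals_d, as.integer),
    lumenal = cfg$lumenal, stromal = cfg$stromal)
}

#' @rdname read_topology
#' @param topology a [conjugation_topology()].
#' @export
write_topology <- function(topology, path) {
  yaml::write_yaml(list(
    format = "carotdyn-topology/1",
    single_bonds = as.integer(t(topology$single_bonds)),
    double_bonds = as.integer(t(topology$double_bonds)),
    dihedrals_s = topology$dihedrals_s,
    dihedrals_d = topology$dihedrals_d,
    lumenal = topology$lumenal, stromal = topology$stromal), path)
  invisible(path)
}

#' Bond-length alternation
#'
#' BLA = mean(single-bond lengths) - mean(double-bond lengths) over the
#' conjugated backbone, in Angstrom. Positive in the ground state; collapses
#' toward (and below) zero on the S1 surface.
#'
#' @param geometry `n_atoms x 3` coordinate matrix (Angstrom).
#' @param topology a [conjugation_topology()].
#' @return BLA in Angstrom.
#' @export
compute_bla <- function(geometry, topology) {
  if (nrow(topology$single_bonds) == 0 || nrow(topology$double_bonds) == 0)
    stop("empty bond list")
  blen <- function(b) sqrt(rowSums(
    (geometry[b[, 1], , drop = FALSE] - geometry[b[, 2], , drop = FALSE])^2))
  mean(blen(topology$single_bonds)) - mean(blen(topology$double_bonds))
}

#' Signed dihedral angle
#'
#' Standard IUPAC right-handed torsion in degrees, reported in (-180, 180]:
#' planar-trans fragments give 180, planar-cis 0.
#'
#' @param geometry `n_atoms x 3` coordinate matrix.
#' @param atoms four distinct atom indices.
#' @return angle in degrees.
#' @export
compute_dihedral <- function(geometry, atoms) {
  if (length(unique(atoms)) != 4) stop("four distinct atom indices required")
  p <- geometry[atoms, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("undefined torsion: collinear atom triple")
  m1 <- n1 / sqrt(sum(n1^2))
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(m1 * n2) / sqrt(sum(n2^2))
  y <- -sum((c(m1[2] * b2u[3] - m1[3] * b2u[2],
               m1[3] * b2u[1] - m1[1] * b2u[3],
               m1[1] * b2u[2] - m1[2] * b2u[1])) * n2 / sqrt(sum(n2^2)))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Distortion index over a dihedral set
#'
#' `D = mean(1 - |cos(theta_i)|)`: zero iff every dihedral is planar (0 or
#' 180 degrees), maximal (1) when all are twisted to 90 degrees, bounded in
#' `[0, 1]` and symmetric about planarity in both the cis and trans basins.
#' The threshold `D_Lum > 0.10` used in hop-channel analysis corresponds to
#' a ~26-degree mean twist under this form.
#'
#' @param geometry coordinate matrix, or `NULL` if `angles` given.
#' @param topology a [conjugation_topology()], or `NULL` if `angles` given.
#' @param set dihedral names over which to average (default all C=C),
#'   e.g. `topology$lumenal`.
#' @param angles alternatively, dihedral angles in degrees.
#' @return D in `[0, 1]`.
#' @export
distortion_index <- function(geometry = NULL, topology = NULL,
                             set = NULL, angles = NULL) {
  if (is.null(angles)) {
    if (is.null(set)) set <- names(topology$dihedrals_d)
    if (length(set) == 0) stop("empty dihedral set")
    angles <- vapply(set, function(nm)
      compute_dihedral(geometry, topology$dihedrals_d[[nm]]), numeric(1))
  }
  if (length(angles) == 0) stop("empty dihedral set")
  mean(1 - abs(cos(angles * pi / 180)))
}

#' Classify the conformer from ds2
#'
#' `|ds2| > 90` degrees is s-trans (around 180), `|ds2| < 90` s-cis (around
#' 0); exactly 90 classifies as s-trans by the documented tie-break.
#' Vectorized.
#'
#' @param ds2 dihedral(s) in degrees, in (-180, 180].
#' @return character vector, `"s-trans"` or `"s-cis"`.
#' @export
classify_conformer <- function(ds2) {
  ifelse(abs(ds2) >= 90, "s-trans", "s-cis")
}

#' Per-frame geometry descriptors
#'
#' @param geometry `n_atoms x 3` coordinate matrix.
#' @param topology a [conjugation_topology()].
#' @return list with `bla`, named `ds` and `dd` angle vectors, `D`,
#'   `D_Lum`, `D_Strom` and the `conformer` label from ds2.
#' @export
geometry_descriptors <- function(geometry, topology) {
  ds <- vapply(topology$dihedrals_s, function(a)
    compute_dihedral(geometry, a), numeric(1))
  dd <- vapply(topology$dihedrals_d, function(a)
    compute_dihedral(geometry, a), numeric(1))
  list(bla = compute_bla(geometry, topology), ds = ds, dd = dd,
       D = distortion_index(angles = dd),
       D_Lum = distortion_index(angles = dd[topology$lumenal]),
       D_Strom = distortion_index(angles = dd[topology$stromal]),
       conformer = classify_conformer(ds[["ds2"]]))
}

#' Characterize S1 -> S0 hop geometries and decay channels
#'
#' Annotates each hop with its decay channel: the BLA channel
#' (`bla < -0.02` Angstrom) and the distortion channel (`D_Lum > 0.10` with
#' `bla >= -0.02`), and summarizes counts within a time cutoff per conformer.
#' The reported percentage is the fraction of channel hops occurring before
#' the cutoff, rounded to the nearest percent.
#'
#' @param hops data frame with columns `time_fs`, `bla`, `d_lum` and
#'   optionally `conformer`, `from`, `to` (rows with `from`/`to` present are
#'   filtered to S1 -> S0, i.e. `from == 2 & to == 1`).
#' @param bla_threshold Angstrom (default -0.02).
#' @param dlum_threshold unitless (default 0.10).
#' @param time_cutoff_fs fs (default 2000, i.e. 2 ps).
#' @return list with `table` (the annotated hop table with logical
#'   `bla_channel` / `distortion_channel` columns) and `summary` (one row per
#'   conformer: totals, per-channel counts, counts within the cutoff, and
#'   `pct_bla_within` / `pct_distortion_within`).
#' @export
characterize_hops <- function(hops, bla_threshold = -0.02,
                              dlum_threshold = 0.10, time_cutoff_fs = 2000) {
  if (!is.null(hops$from) && !is.null(hops$to))
    hops <- hops[hops$from == 2L & hops$to == 1L, , drop = FALSE]
  if (nrow(hops) == 0) {
    return(list(table = cbind(hops, bla_channel = logical(0),
                              distortion_channel = logical(0)),
                summary = data.frame(conformer = character(),
                                     n_hops = integer())))
  }
  if (is.null(hops$conformer)) hops$conformer <- "all"
  hops$bla_channel <- hops$bla < bla_threshold
  hops$distortion_channel <- hops$d_lum > dlum_threshold &
    hops$bla >= bla_threshold
  summ <- do.call(rbind, lapply(split(hops, hops$conformer), function(h) {
    nb <- sum(h$bla_channel)
    nbw <- sum(h$bla_channel & h$time_fs <= time_cutoff_fs)
    ndc <- sum(h$distortion_channel)
    ndw <- sum(h$distortion_channel & h$time_fs <= time_cutoff_fs)
    data.frame(conformer = h$conformer[1], n_hops = nrow(h),
               n_bla = nb, n_bla_within = nbw,
               pct_bla_within = if (nb > 0) round(100 * nbw / nb) else NA_real_,
               n_distortion = ndc, n_distortion_within = ndw,
               pct_distortion_within = if (ndc > 0) round(100 * ndw / ndc)
                                       else NA_real_)
  }))
  rownames(summ) <- NULL
  list(table = hops, summary = summ)
}

#' Detect photoisomerization events around C=C bonds
#'
#' A dihedral series produces an event when it crosses 90 degrees from one
#' planar basin (|theta| > 90: trans; |theta| < 90: cis) and dwells in the
#' opposite basin for at least `dwell` consecutive frames.
#'
#' @param dd_series numeric matrix (frames x dihedrals, degrees) or a single
#'   numeric vector; column names label the dihedrals.
#' @param dwell minimum number of frames in the new basin.
#' @return data frame with `dihedral`, `frame` (first frame of the settled
#'   basin), `from`, `to` (`"trans"`/`"cis"`); zero rows when no event.
#' @export
detect_photoisomerization <- function(dd_series, dwell = 10L) {
  if (is.null(dim(dd_series)))
    dd_series <- matrix(dd_series, ncol = 1,
                        dimnames = list(NULL, "dd"))
  if (is.null(colnames(dd_series)))
    colnames(dd_series) <- paste0("dd", seq_len(ncol(dd_series)))
  events <- list()
  for (j in seq_len(ncol(dd_series))) {
    basin <- ifelse(abs(dd_series[, j]) > 90, "trans", "cis")
    cur <- basin[1]
    i <- 2L
    while (i <= length(basin)) {
      if (basin[i] != cur) {
        run_end <- i
        while (run_end < length(basin) && basin[run_end + 1L] == basin[i])
          run_end <- run_end + 1L
        if (run_end - i + 1L >= dwell) {
          events[[length(events) + 1L]] <-
            data.frame(dihedral = colnames(dd_series)[j], frame = i,
                       from = cur, to = basin[i])
          cur <- basin[i]
        }
        i <- run_end + 1L
      } else i <- i + 1L
    }
  }
  if (length(events) == 0)
    return(data.frame(dihedral = character(), frame = integer(),
                      from = character(), to = character()))
  do.call(rbind, events)
}

#' Build a 3-D chain geometry from internal coordinates
#'
#' Places atoms sequentially (natural extension reference frame): atom 1 at
#' the origin, atom 2 along x, atom 3 in the xy-plane; atom `i >= 4` from its
#' bond length, bond angle and dihedral relative to the three preceding atoms.
#'
#' @param bond_lengths length `n - 1` (Angstrom).
#' @param bond_angles length `n - 2` (degrees).
#' @param dihedrals length `n - 3` (degrees, IUPAC signed convention).
#' @return `n x 3` coordinate matrix.
#' @export
build_chain_geometry <- function(bond_lengths, bond_angles, dihedrals) {
  n <- length(bond_lengths) + 1L
  stopifnot(length(bond_angles) == n - 2L, length(dihedrals) == n - 3L)
  X <- matrix(0, n, 3)
  X[2, ] <- c(bond_lengths[1], 0, 0)
  if (n >= 3) {
    a <- bond_angles[1] * pi / 180
    X[3, ] <- X[2, ] + bond_lengths[2] * c(-cos(a), sin(a), 0)
  }
  if (n >= 4) for (i in 4:n) {
    r <- bond_lengths[i - 1]
    theta <- bond_angles[i - 2] * pi / 180
    phi <- dihedrals[i - 3] * pi / 180
    A <- X[i - 3, ]; B <- X[i - 2, ]; C <- X[i - 1, ]
    bc <- C - B
    bc <- bc / sqrt(sum(bc^2))
    ab <- B - A
    nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
             ab[3] * bc[1] - ab[1] * bc[3],
             ab[1] * bc[2] - ab[2] * bc[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
           nrm[3] * bc[1] - nrm[1] * bc[3],
           nrm[1] * bc[2] - nrm[2] * bc[1])
    d <- c(-r * cos(theta), r * sin(theta) * cos(phi),
           r * sin(theta) * sin(phi))
    X[i, ] <- C + d[1] * bc + d[2] * m + d[3] * nrm
  }
  X
}
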