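#' Write / read an XYZ multi-frame geometry file
#'
#' Standard XYZ dialect: atom-count line, comment line carrying `t= <fs>`,
#' then `element x y z` rows per atom.
#'
#' @param frames list of `n_atoms x 3` coordinate matrices.
#' @param path file path.
#' @param elements per-atom element symbols (recycled).
#' @param times per-frame times in fs.
#' @return `read_xyz` returns `list(frames =, times =, elements =)`.
#' @export
write_xyz <- function(frames, path, elements = "C",
                      times = seq_along(frames) - 1) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    X <- frames[[i]]
    el <- rep_len(elements, nrow(X))
    writeLines(c(as.character(nrow(X)),
                 sprintf("t= %.6f", times[i]),
                 sprintf("%s %.10g %.10g %.10g", el,
                         X[, 1], X[, 2], X[, 3])), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("malformed frame header at line ", i, ": expected atom count")
    na <- as.integer(lines[i])
    tm <- suppressWarnings(as.numeric(sub("^.*t=\\s*", "", lines[i + 1L])))
    if (i + 1L + na > length(lines))
      stop("truncated frame starting at line ", i)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + na)]), "\\s+")
    if (any(lengths(rows) < 4))
      stop("malformed atom row at line ",
           i + 1L + which(lengths(rows) < 4)[1])
    elements <- vapply(rows, `[`, character(1), 1)
    X <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- X
    times <- c(times, tm)
    i <- i + 2L + na
  }
  list(frames = frames, times = times, elements = elements)
}

#' Write a surface-hopping trajectory to XYZ + CSV sidecar
#'
#' Geometries go to an XYZ file (model coordinates are written as one
#' pseudo-atom per degree of freedom, element `X`, with the coordinate in
#' the x column); the per-frame electronic record goes to a versioned CSV
#' sidecar with time, active state, adiabatic energies, coefficient
#' magnitude/phase pairs and transition dipoles.
#'
#' @param traj an `sh_trajectory`.
#' @param xyz_path,sidecar_path output paths.
#' @return invisibly, the sidecar path.
#' @export
write_trajectory <- function(traj, xyz_path, sidecar_path) {
  nd <- ncol(traj$coords)
  frames <- lapply(seq_along(traj$time), function(i)
    cbind(traj$coords[i, ], 0, 0))
  write_xyz(frames, xyz_path, elements = "X", times = traj$time)
  ns <- ncol(traj$energies)
  d <- data.frame(frame = seq_along(traj$time), time_fs = traj$time,
                  active = traj$active)
  for (k in seq_len(ns)) d[[paste0("E", k - 1L)]] <- traj$energies[, k]
  for (k in seq_len(ns)) {
    d[[paste0("c", k - 1L, "_mag")]] <- Mod(traj$coeffs[, k])
    d[[paste0("c", k - 1L, "_phase")]] <- Arg(traj$coeffs[, k])
  }
  for (k in seq_len(ns)) d[[paste0("mu", k - 1L)]] <- traj$dipoles[, k]
  for (j in seq_len(nd)) d[[paste0("v", j)]] <- traj$velocities[, j]
  attr_line <- paste0("# carotdyn-sidecar/1 model=", traj$metadata$model,
                      " seed=", traj$metadata$seed)
  con <- file(sidecar_path, "w")
  writeLines(attr_line, con)
  close(con)
  suppressWarnings(write.table(d, sidecar_path, sep = ",", row.names = FALSE,
                               append = TRUE, qmethod = "double"))
  invisible(sidecar_path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param xyz_path,sidecar_path input paths.
#' @return an `sh_trajectory`.
#' @export
read_trajectory <- function(xyz_path, sidecar_path) {
  xyz <- read_xyz(xyz_path)
  hdr <- readLines(sidecar_path, n = 1L)
  if (!grepl("^# carotdyn-sidecar/1", hdr))
    stop("unrecognized sidecar format (line 1)")
  d <- read.csv(sidecar_path, skip = 1L)
  if (length(xyz$frames) != nrow(d))
    stop("frame count mismatch: ", length(xyz$frames), " XYZ frames vs ",
         nrow(d), " sidecar rows")
  ns <- sum(grepl("^E\\d+$", names(d)))
  nd <- sum(grepl("^v\\d+$", names(d)))
  coords <- t(vapply(xyz$frames, function(X) X[, 1], numeric(nd)))
  if (nd == 1) coords <- matrix(unlist(lapply(xyz$frames, function(X) X[, 1])),
                                ncol = 1)
  en <- as.matrix(d[, paste0("E", seq_len(ns) - 1L), drop = FALSE])
  co <- sapply(seq_len(ns) - 1L, function(k)
    complex(modulus = d[[paste0("c", k, "_mag")]],
            argument = d[[paste0("c", k, "_phase")]]))
  dip <- as.matrix(d[, paste0("mu", seq_len(ns) - 1L), drop = FALSE])
  vel <- as.matrix(d[, paste0("v", seq_len(nd)), drop = FALSE])
  model_id <- sub(".*model=(\\S+).*", "\\1", hdr)
  seed <- suppressWarnings(as.integer(sub(".*seed=(\\S+).*", "\\1", hdr)))
  structure(list(time = d$time_fs, coords = coords, velocities = vel,
                 energies = en, coeffs = co, active = d$active,
                 dipoles = dip,
                 final_state = d$active[nrow(d)], exited = FALSE,
                 metadata = list(model = model_id, seed = seed)),
            class = "sh_trajectory")
}

#' Write a run manifest
#'
#' Every artifact directory gets a manifest echoing the configuration,
#' seeds and package version, sufficient to regenerate the outputs.
#'
#' @param dir output directory.
#' @param config named list echoed verbatim.
#' @return invisibly, the manifest path.
#' @export
write_manifest <- function(dir, config) {
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(c(list(
    format = "carotdyn-manifest/1",
    package_version = as.character(utils::packageVersion("carotdyn")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), config), path)
  invisible(path)
}
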