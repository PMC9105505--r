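#' Van der Waals radii by element
#'
#' Bondi-type radii (Angstrom) for the elements that occur in protein
#' structures. Unknown elements fall back to `default` with a warning.
#'
#' @param element character vector of element symbols (e.g. `"C"`, `"N"`).
#' @param default radius used for elements missing from the table, Angstrom.
#' @return numeric vector of radii, Angstrom.
#' @export
vdw_radius <- function(element, default = 1.70) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
           FE = 1.40, ZN = 1.39, MG = 1.73, "NA" = 2.27, K = 2.75, CA = 2.31)
  key <- toupper(trimws(element))
  r <- unname(tab[key])
  unknown <- is.na(r) & !is.na(key) & nzchar(key)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using default vdW radius %.2f A",
                    paste(unique(key[unknown]), collapse = ", "), default))
  }
  r[is.na(r)] <- default
  r
}

# Derive an element symbol from a PDB atom name when the element column is
# empty. Protein atom names start with the element letter (NZ -> N, CD1 -> C);
# "CA" within a standard residue is carbon-alpha, never calcium.
element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- c("CL", "BR", "SE", "FE", "ZN", "MG", "NA")
  el <- substr(nm, 1, 1)
  el[nm %in% two] <- nm[nm %in% two]
  el
}

new_structure <- function(atoms, label = "structure") {
  structure(list(atoms = atoms, label = label), class = "md_structure")
}

new_trajectory <- function(atoms, xyz, times, label = "trajectory") {
  structure(list(atoms = atoms, xyz = xyz, times = times, label = label),
            class = "md_trajectory")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("<md_structure> %s: %d atoms, %d residues\n", x$label,
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %s: %d frames x %d atoms, t = %.3f..%.3f ns\n",
              x$label, n_frames(x), nrow(x$atoms),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' Extract one frame of a trajectory as a structure
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return an `md_structure` carrying the frame's coordinates.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  at <- traj$atoms
  at$x <- traj$xyz[i, , 1]; at$y <- traj$xyz[i, , 2]; at$z <- traj$xyz[i, , 3]
  new_structure(at, label = sprintf("%s[frame %d]", traj$label, i))
}

#' Coordinate matrix of a structure
#' @param x an `md_structure`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(x) cbind(x = x$atoms$x, y = x$atoms$y, z = x$atoms$z)

#' Assemble a trajectory from structures with identical topology
#' @param frames list of `md_structure` sharing the same atom identity list.
#' @param times per-frame times in ns; defaults to `(i-1) * 0.005` (a 5 ps
#'   recording interval).
#' @param label trajectory label.
#' @return an `md_trajectory`.
#' @export
traj_from_frames <- function(frames, times = NULL, label = "trajectory") {
  stopifnot(length(frames) >= 1)
  id0 <- atom_identity(frames[[1]]$atoms)
  for (k in seq_along(frames)) {
    if (!identical(atom_identity(frames[[k]]$atoms), id0))
      stopf("topology error: frame %d differs in atom identity from frame 1", k)
  }
  nf <- length(frames); na <- nrow(frames[[1]]$atoms)
  xyz <- array(NA_real_, c(nf, na, 3))
  for (k in seq_len(nf)) xyz[k, , ] <- coords(frames[[k]])
  times <- times %||% ((seq_len(nf) - 1) * 0.005)
  stopifnot(length(times) == nf, !is.unsorted(times, strictly = TRUE))
  at <- frames[[1]]$atoms
  new_trajectory(at, xyz, times, label)
}

#' Treat a single structure as a one-frame trajectory
#' @param x an `md_structure`.
#' @return an `md_trajectory` with one frame at t = 0.
#' @export
as_trajectory <- function(x) {
  if (inherits(x, "md_trajectory")) return(x)
  stopifnot(inherits(x, "md_structure"))
  traj_from_frames(list(x), times = 0, label = x$label)
}

atom_identity <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
}

validate_structure <- function(x) {
  at <- x$atoms
  if (nrow(at) == 0) stopf("structure '%s' is empty", x$label)
  dup <- duplicated(atom_identity(at))
  if (any(dup))
    stopf("duplicate atom identity: %s", atom_identity(at)[which(dup)[1]])
  if (!all(is.finite(coords(x)))) stopf("non-finite coordinates")
  if (!all(at$vdw > 0)) stopf("non-positive vdW radius")
  invisible(x)
}

#' Read a PDB file as a trajectory
#'
#' Single-model files yield a one-frame trajectory; `MODEL`/`ENDMDL` blocks
#' yield one frame each and must agree atom-for-atom in identity. Alternate
#' locations are reduced to the highest-occupancy conformer; insertion codes
#' are rejected; hydrogens are retained but flagged (`is_heavy = FALSE`).
#' Van der Waals radii are assigned from [vdw_radius()]. Frame times default
#' to `(frame - 1) * 0.005` ns, the 5 ps recording interval of the study
#' design this package targets.
#'
#' @param path PDB file path.
#' @param dt frame spacing in ns used to synthesise time stamps.
#' @return an `md_trajectory`.
#' @export
read_pdb <- function(path, dt = 0.005) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")

  # malformed-record scan: coordinate fields must parse as numbers
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stopf("parse error at line %d: ATOM record too short", i)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stopf("parse error at line %d: unreadable coordinates", i)
  }
  if (!any(is_atom)) stopf("no ATOM/HETATM records in %s", path)

  # per-MODEL topology check on raw identity fields (cols 13-27)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1) {
    model_id <- cumsum(rec == "MODEL ")
    ids <- split(substr(lines[is_atom], 13, 27), model_id[is_atom])
    for (k in seq_along(ids)) {
      if (!identical(ids[[k]], ids[[1]]))
        stopf("topology error: MODEL %d atom list differs from MODEL 1", k)
    }
  }

  multi <- length(model_starts) > 1
  p <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, rm.insert = FALSE,
                       verbose = FALSE)
  at <- p$atom
  if (any(!is.na(at$insert)))
    stopf("insertion codes present (e.g. residue %s%s%s): renumber first",
          at$chain[!is.na(at$insert)][1], at$resno[!is.na(at$insert)][1],
          at$insert[!is.na(at$insert)][1])

  # alternate locations: keep highest-occupancy conformer per atom identity
  keep <- seq_len(nrow(at))
  if (any(!is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ)
    keep <- sort(ord[!duplicated(key[ord])])
  }
  at <- at[keep, , drop = FALSE]

  elesy <- trimws(at$elesy %||% "")
  miss <- is.na(elesy) | !nzchar(elesy)
  elesy[miss] <- element_from_name(at$elety[miss])
  elesy <- toupper(elesy)

  nf <- if (multi) nrow(p$xyz) else 1
  xyzm <- matrix(as.numeric(p$xyz), nrow = nf)
  na_all <- ncol(xyzm) / 3
  cols <- as.vector(rbind(3 * (keep - 1) + 1, 3 * (keep - 1) + 2, 3 * keep))
  xyzm <- xyzm[, cols, drop = FALSE]

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    resname = trimws(at$resid),
    resno = at$resno,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    element = elesy,
    x = xyzm[1, seq(1, ncol(xyzm), 3)],
    y = xyzm[1, seq(2, ncol(xyzm), 3)],
    z = xyzm[1, seq(3, ncol(xyzm), 3)],
    occ = ifelse(is.na(at$o), 1, at$o),
    bfac = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
  atoms$vdw <- vdw_radius(atoms$element)
  atoms$is_heavy <- atoms$element != "H"

  nat <- nrow(atoms)
  xyz <- array(NA_real_, c(nf, nat, 3))
  for (k in seq_len(nf)) {
    m <- matrix(xyzm[k, ], ncol = 3, byrow = TRUE)
    xyz[k, , ] <- m
  }
  traj <- new_trajectory(atoms, xyz, times = (seq_len(nf) - 1) * dt,
                         label = basename(path))
  validate_structure(get_frame(traj, 1))
  traj
}

#' Write a trajectory (or structure) as a PDB file
#'
#' Multi-frame trajectories are written as `MODEL`/`ENDMDL` blocks.
#' Coordinates round-trip through [read_pdb()] to 1e-3 Angstrom; identity
#' fields round-trip exactly.
#'
#' @param x an `md_trajectory` or `md_structure`.
#' @param path output file path.
#' @param bfac optional per-atom B-factor override (recycled over frames).
#' @return invisibly, `path`.
#' @export
write_pdb <- function(x, path, bfac = NULL) {
  traj <- as_trajectory(x)
  if (n_frames(traj) < 1 || nrow(traj$atoms) == 0)
    stopf("refusing to write an empty trajectory")
  at <- traj$atoms
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nf, 3 * nrow(at))
  for (k in seq_len(nf)) xyz[k, ] <- as.vector(t(traj$xyz[k, , ]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resname,
                   eleno = at$serial, elety = at$name,
                   chain = at$chain, o = at$occ,
                   b = bfac %||% at$bfac, elesy = at$element)
  invisible(path)
}

#' Fetch a PDB entry from the RCSB archive
#'
#' Downloads `https://files.rcsb.org/download/<id>.pdb` into `dir` (skipped
#' when a cached copy exists) and returns the local path. Requires network
#' access; intended for pulling the reference crystal structures (e.g. the
#' self-inhibited phosphatase 2SHP and the isolated open N-SH2 domain 1AYA).
#'
#' @param id 4-character PDB accession.
#' @param dir cache directory.
#' @param quiet passed to [utils::download.file()].
#' @return local file path.
#' @export
fetch_pdb <- function(id, dir = tempdir(), quiet = TRUE) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", id))
  dest <- file.path(dir, paste0(toupper(id), ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  ok <- tryCatch(utils::download.file(url, dest, quiet = quiet, mode = "wb"),
                 error = function(e) -1L, warning = function(w) -1L)
  if (!identical(ok, 0L) || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stopf("could not fetch PDB entry %s (no network access to RCSB?)", id)
  }
  dest
}
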