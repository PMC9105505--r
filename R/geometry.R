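#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid motion mapping the selected atoms of `mobile` onto
#' the corresponding atoms of `reference`, computed by SVD of the
#' cross-covariance with the usual sign correction so that a proper
#' rotation (det = +1, never a reflection) is returned.
#'
#' @param mobile,reference `md_structure`s.
#' @param sel_mobile logical or integer selection over `mobile`'s atoms.
#' @param sel_reference selection over `reference`'s atoms; defaults to
#'   `sel_mobile`. The two selections must list the same atom identities in
#'   the same order.
#' @return list with `rotation` (3x3), `translation` (length 3, so that
#'   `x %*% t(rotation) + translation` maps mobile coordinates), and `rmsd`
#'   over the selection after superposition (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, sel_mobile,
                             sel_reference = sel_mobile) {
  P <- coords(mobile)[sel_mobile, , drop = FALSE]
  Q <- coords(reference)[sel_reference, , drop = FALSE]
  idm <- atom_identity(mobile$atoms[sel_mobile, , drop = FALSE])
  idr <- atom_identity(reference$atoms[sel_reference, , drop = FALSE])
  if (!identical(idm, idr))
    stopf("mismatched selections: %d mobile vs %d reference atoms%s",
          length(idm), length(idr),
          if (length(idm) == length(idr))
            paste0(" (first mismatch: ", idm[which(idm != idr)[1]], ")")
          else "")
  if (nrow(P) < 3) stopf("need >= 3 paired atoms for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  moved <- P %*% t(R) + matrix(tr, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

# Apply a rigid transform to an n x 3 coordinate matrix.
apply_rigid <- function(xyz, rotation, translation) {
  xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
}

# Match each selected trajectory atom to a reference atom by
# (chain, resno, name); errors listing unmatched identities.
match_to_reference <- function(traj_atoms, ref_atoms, sel) {
  idx <- which(sel)
  key_t <- atom_identity(traj_atoms)[idx]
  key_r <- atom_identity(ref_atoms)
  pos <- match(key_t, key_r)
  if (anyNA(pos))
    stopf("atoms not found in reference: %s",
          paste(utils::head(key_t[is.na(pos)], 5), collapse = ", "))
  list(traj = idx, ref = pos)
}

#' RMSD time series against an arbitrary reference
#'
#' Per frame: superpose onto the reference over `align_sel` (matched by
#' chain/residue/atom name), then report the RMSD over `sel`. Supports an
#' overall RMSD or a per-residue breakdown (the mode used to thicken
#' ribbons by local mobility).
#'
#' @param traj an `md_trajectory`.
#' @param reference an `md_structure` (any topology containing the selected
#'   identities).
#' @param sel logical selection (over `traj`'s atoms) whose RMSD is reported;
#'   default backbone N, CA, C, O.
#' @param align_sel selection used for the superposition; defaults to `sel`.
#' @param per_residue if `TRUE`, return a frames x residues matrix of
#'   per-residue RMSDs instead of one value per frame.
#' @return data.frame `time_ns`, `rmsd` (class `rmsd_series`), or a matrix
#'   in per-residue mode (rownames = times, colnames = chain:resno).
#' @export
rmsd_series <- function(traj, reference,
                        sel = atom_sel(traj, name = c("N", "CA", "C", "O")),
                        align_sel = sel, per_residue = FALSE) {
  ma <- match_to_reference(traj$atoms, reference$atoms, align_sel)
  ms <- match_to_reference(traj$atoms, reference$atoms, sel)
  Qa <- coords(reference)[ma$ref, , drop = FALSE]
  Qs <- coords(reference)[ms$ref, , drop = FALSE]
  nf <- n_frames(traj)
  res_key <- paste(traj$atoms$chain, traj$atoms$resno, sep = ":")[ms$traj]
  if (per_residue) {
    out <- matrix(NA_real_, nf, length(unique(res_key)),
                  dimnames = list(format(traj$times), unique(res_key)))
  } else {
    vals <- numeric(nf)
  }
  for (k in seq_len(nf)) {
    Pa <- traj$xyz[k, ma$traj, , drop = TRUE]
    Ps <- traj$xyz[k, ms$traj, , drop = TRUE]
    if (is.null(dim(Pa))) Pa <- matrix(Pa, ncol = 3)
    if (is.null(dim(Ps))) Ps <- matrix(Ps, ncol = 3)
    fit <- kabsch_xyz(Pa, Qa)
    moved <- apply_rigid(Ps, fit$rotation, fit$translation)
    d2 <- rowSums((moved - Qs)^2)
    if (per_residue) {
      out[k, ] <- sqrt(tapply(d2, factor(res_key, levels = unique(res_key)),
                              mean))
    } else {
      vals[k] <- sqrt(mean(d2))
    }
  }
  if (per_residue) return(out)
  structure(data.frame(time_ns = traj$times, rmsd = vals),
            class = c("rmsd_series", "data.frame"),
            reference = reference$label)
}

# Kabsch on bare coordinate matrices (no identity checks).
kabsch_xyz <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(cq - R %*% cp))
}

#' Interatomic distance time series
#'
#' Euclidean distance between two atoms, per frame. This is the observable
#' behind the loop-separation coordinates (e.g. Gly67 CA - Asn92 CA for the
#' EF/BG loop gate of the pY peptide cleft).
#'
#' @param traj an `md_trajectory`.
#' @param a,b atom identities, each `c(chain, resno, name)` (resno coerced
#'   to integer).
#' @param name observable label.
#' @return data.frame `time_ns`, `value` (Angstrom), class
#'   `distance_series`, with the atom pair in attributes.
#' @export
distance_series <- function(traj, a, b, name = NULL) {
  ia <- atom_index(traj$atoms, a[1], as.integer(a[2]), a[3])
  ib <- atom_index(traj$atoms, b[1], as.integer(b[2]), b[3])
  dv <- sqrt(rowSums((traj$xyz[, ia, , drop = FALSE] -
                        traj$xyz[, ib, , drop = FALSE])^2, dims = 1))
  name <- name %||% sprintf("%s%s(%s)-%s%s(%s)", a[1], a[2], a[3],
                            b[1], b[2], b[3])
  structure(data.frame(time_ns = traj$times, value = as.numeric(dv)),
            class = c("distance_series", "data.frame"),
            observable = name, atom_pair = list(a = a, b = b))
}

#' Restrict a time series to an analysis window
#' @param series data.frame with a `time_ns` column.
#' @param window `c(from, to)` in ns, inclusive.
#' @return the series restricted to the window (attributes kept).
#' @export
clip_window <- function(series, window = c(3, 30)) {
  keep <- series$time_ns >= window[1] & series$time_ns <= window[2]
  if (!any(keep)) stopf("analysis window [%g, %g] ns selects no frames",
                        window[1], window[2])
  out <- series[keep, , drop = FALSE]
  attributes(out)[setdiff(names(attributes(series)),
                          c("row.names", "names"))] <-
    attributes(series)[setdiff(names(attributes(series)),
                               c("row.names", "names"))]
  rownames(out) <- NULL
  out
}

#' Write a time series as tab-separated text
#' @param series data.frame (first column time, second the observable).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
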