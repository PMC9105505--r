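# Interface mapping between two regions at a heavy-atom distance threshold.

# Per-residue minimum heavy-atom distance from each residue of `sel_a` to any
# heavy atom of `sel_b`. Exact (block-vectorised all-pairs per residue).
min_dist_per_residue <- function(frame, sel_a, sel_b) {
  at <- frame$atoms
  ia <- which(sel_a & at$is_heavy)
  ib <- which(sel_b & at$is_heavy)
  if (!length(ia) || !length(ib)) stopf("empty region after exclusions")
  xb <- coords(frame)[ib, , drop = FALSE]
  key <- paste(at$chain[ia], at$resno[ia], sep = ":")
  res <- unique(key)
  out <- vapply(res, function(r) {
    xa <- coords(frame)[ia[key == r], , drop = FALSE]
    sqrt(min(cross_dist2(xa, xb)))
  }, numeric(1))
  names(out) <- res
  out
}

#' Interfacial residues of one region with respect to another
#'
#' A residue of `region_a` is interfacial when its closest heavy atom lies
#' within `threshold` of any heavy atom of `region_b`. Inter-domain linker
#' residues are excluded before the scan (they belong to neither region's
#' interface by construction).
#'
#' @param frame an `md_structure`.
#' @param region_map a `region_map`.
#' @param region_a,region_b region names.
#' @param threshold distance cutoff, Angstrom (default 5).
#' @param exclude optional data.frame `chain`,`resno` of residues to drop
#'   from both regions (e.g. the SH2-SH2 linker 104-110, Gln214, Thr253).
#' @return named numeric vector: minimum heavy-atom distance (Angstrom) per
#'   interfacial residue of `region_a`, names `chain:resno`.
#' @export
interfacial_residues <- function(frame, region_map, region_a, region_b,
                                 threshold = 5.0, exclude = NULL) {
  sel_a <- region_mask(frame$atoms, region_map, region_a)
  sel_b <- region_mask(frame$atoms, region_map, region_b)
  if (any(sel_a & sel_b)) stopf("regions %s and %s overlap", region_a, region_b)
  if (!is.null(exclude)) {
    ex <- paste(frame$atoms$chain, frame$atoms$resno, sep = ":") %in%
      paste(exclude$chain, exclude$resno, sep = ":")
    sel_a <- sel_a & !ex
    sel_b <- sel_b & !ex
  }
  d <- min_dist_per_residue(frame, sel_a, sel_b)
  d[d <= threshold]
}

#' Interface heat map over a trajectory
#'
#' Rows are the residues of `region_a` found interfacial with `region_b`
#' (at `threshold`) in at least one analysed column; columns are frame
#' times, optionally preceded by a reference crystal structure at column
#' `t = 0`. Cells hold the per-frame minimum heavy-atom distance, `NA`
#' beyond `cap` (the "absent" colour of a rendered map).
#'
#' @inheritParams interfacial_residues
#' @param traj an `md_trajectory`.
#' @param reference optional `md_structure` occupying column 0.
#' @param cap distance cap, Angstrom (default 10).
#' @param window analysis window in ns (`NULL` = all frames).
#' @return an `interface_map`: numeric matrix residues x columns with
#'   attributes `times`, `threshold`, `cap`, `regions`.
#' @export
interface_heatmap <- function(traj, region_map, region_a, region_b,
                              threshold = 5.0, cap = 10.0, reference = NULL,
                              exclude = NULL, window = NULL) {
  frames <- seq_len(n_frames(traj))
  times <- traj$times
  if (!is.null(window)) {
    keep <- times >= window[1] & times <= window[2]
    if (!any(keep)) stopf("window selects no frames")
    frames <- frames[keep]; times <- times[keep]
  }
  cols <- list()
  if (!is.null(reference)) {
    sel_a <- region_mask(reference$atoms, region_map, region_a)
    sel_b <- region_mask(reference$atoms, region_map, region_b)
    cols[["ref"]] <- min_dist_per_residue_excl(reference, sel_a, sel_b, exclude)
  }
  for (k in frames) {
    fr <- get_frame(traj, k)
    sel_a <- region_mask(fr$atoms, region_map, region_a)
    sel_b <- region_mask(fr$atoms, region_map, region_b)
    cols[[sprintf("t%g", traj$times[k])]] <-
      min_dist_per_residue_excl(fr, sel_a, sel_b, exclude)
  }
  rows <- Reduce(union, lapply(cols, names))
  m <- sapply(cols, function(co) unname(co[rows]))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(rows))
  rownames(m) <- rows
  keep_rows <- apply(m, 1, function(v) any(v <= threshold, na.rm = TRUE))
  m <- m[keep_rows, , drop = FALSE]
  m[m > cap] <- NA_real_
  structure(m,
            times = c(if (!is.null(reference)) 0, traj$times[frames]),
            threshold = threshold, cap = cap,
            regions = c(region_a, region_b), class = "interface_map")
}

min_dist_per_residue_excl <- function(frame, sel_a, sel_b, exclude) {
  if (!is.null(exclude)) {
    ex <- paste(frame$atoms$chain, frame$atoms$resno, sep = ":") %in%
      paste(exclude$chain, exclude$resno, sep = ":")
    sel_a <- sel_a & !ex
    sel_b <- sel_b & !ex
  }
  min_dist_per_residue(frame, sel_a, sel_b)
}

#' Classify interfacial residues as stable or transient
#'
#' Operational reading of "stable" vs "transient" interface membership:
#' a residue interfacial in at least `stable_frac` of the analysed columns
#' is stable, in at least one but fewer is transient.
#'
#' @param map an `interface_map`.
#' @param stable_frac fraction of columns (default 0.5).
#' @return data.frame `residue`, `occupancy`, `class`.
#' @export
interface_residence <- function(map, stable_frac = 0.5) {
  thr <- attr(map, "threshold")
  occ <- apply(map, 1, function(v) mean(!is.na(v) & v <= thr))
  data.frame(residue = rownames(map), occupancy = occ,
             class = ifelse(occ >= stable_frac, "stable", "transient"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate a region's atoms with distance to a partner region
#'
#' Each atom of `region` gets its minimum distance to any heavy atom of
#' `partner`, clipped at `cap`, stored in the B-factor field so external
#' renderers can colour molecular surfaces by partner proximity.
#'
#' @inheritParams interfacial_residues
#' @param region,partner region names.
#' @param cap clip distance, Angstrom.
#' @return the selected region as an `md_structure` with annotated `bfac`.
#' @export
surface_distance_coloring <- function(frame, region_map, region, partner,
                                      cap = 10.0) {
  sel_r <- region_mask(frame$atoms, region_map, region)
  sel_p <- region_mask(frame$atoms, region_map, partner) & frame$atoms$is_heavy
  if (!any(sel_r) || !any(sel_p)) stopf("empty region selection")
  xr <- coords(frame)[sel_r, , drop = FALSE]
  xp <- coords(frame)[sel_p, , drop = FALSE]
  d <- sqrt(apply(cross_dist2(xr, xp), 1, min))
  out <- new_structure(frame$atoms[sel_r, , drop = FALSE],
                       label = sprintf("%s[%s~%s]", frame$label, region, partner))
  out$atoms$bfac <- pmin(d, cap)
  out
}

#' Write an interface map as tab-separated text
#' @param map an `interface_map`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_interface_map <- function(map, path) {
  df <- data.frame(residue = rownames(map), as.data.frame(unclass(map)[, ,
                   drop = FALSE]), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
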