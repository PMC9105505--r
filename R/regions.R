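#' Default SHP2 region map
#'
#' Named residue ranges (author numbering, 1-based inclusive) for the SHP2
#' phosphatase architecture: the two tandem SH2 domains, the catalytic PTP
#' domain, the exon 6-encoded E6 region bridging them in the self-inhibited
#' enzyme, the inter-SH2 linker, and the N-SH2 functional loops (the D'E
#' loop that plugs the catalytic pocket, the EF and BG loops gating the pY
#' peptide cleft, and the 34-40 loop that contacts E6).
#'
#' @param chain chain identifier the ranges refer to.
#' @return a `region_map`: named list of data.frames with columns
#'   `chain`, `start`, `end`.
#' @export
default_region_map <- function(chain = "A") {
  rng <- list(
    "N-SH2"      = c(1, 103),
    "C-SH2"      = c(111, 213),
    "PTP"        = c(253, 529),
    "E6"         = c(215, 252),
    "DE_loop"    = c(58, 62),
    "EF_loop"    = c(66, 68),
    "BG_loop"    = c(89, 92),
    "loop_34_40" = c(34, 40),
    "linker"     = c(104, 110)
  )
  rm <- lapply(rng, function(r)
    data.frame(chain = chain, start = r[1], end = r[2],
               stringsAsFactors = FALSE))
  structure(rm, class = "region_map")
}

#' Read a region map from a key-value text config
#'
#' Each line has the form `name: chain:start-end[, chain:start-end...]`.
#' Blank lines and `#` comments are ignored.
#'
#' @param path config file path.
#' @return a `region_map`.
#' @export
read_region_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("bad region line: '%s' (want name: chain:start-end)", ln)
    name <- trimws(parts[1])
    spec <- trimws(paste(parts[-1], collapse = ":"))
    pieces <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
    df <- do.call(rbind, lapply(pieces, function(p) {
      m <- regmatches(p, regexec("^(.):([0-9]+)-([0-9]+)$", p))[[1]]
      if (length(m) == 0) stopf("bad range '%s' in region '%s'", p, name)
      data.frame(chain = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
                 stringsAsFactors = FALSE)
    }))
    if (any(df$start > df$end))
      stopf("region '%s': start > end", name)
    out[[name]] <- df
  }
  structure(out, class = "region_map")
}

region_mask <- function(atoms, region_map, names) {
  unknown <- setdiff(names, names(region_map))
  if (length(unknown))
    stopf("unknown region name(s): %s", paste(unknown, collapse = ", "))
  mask <- rep(FALSE, nrow(atoms))
  for (nm in names) {
    for (i in seq_len(nrow(region_map[[nm]]))) {
      r <- region_map[[nm]][i, ]
      mask <- mask | (atoms$chain == r$chain &
                        atoms$resno >= r$start & atoms$resno <= r$end)
    }
  }
  mask
}

#' Select the atoms of named regions
#'
#' @param x an `md_structure`.
#' @param region_map a `region_map` (see [default_region_map()]).
#' @param names character vector of region names to keep.
#' @return an `md_structure` restricted to the selected atoms, original
#'   order preserved.
#' @export
select_region <- function(x, region_map, names) {
  stopifnot(inherits(x, "md_structure"))
  mask <- region_mask(x$atoms, region_map, names)
  if (!any(mask))
    stopf("empty selection: regions %s match no atoms",
          paste(names, collapse = ", "))
  new_structure(x$atoms[mask, , drop = FALSE],
                label = sprintf("%s[%s]", x$label, paste(names, collapse = "+")))
}

#' Logical atom selection by identity fields
#'
#' @param x an `md_structure` or `md_trajectory` (its topology is used).
#' @param chain,resno,name optional filters; `resno` may be any integer
#'   vector (e.g. `3:103`).
#' @param heavy if `TRUE`, restrict to heavy atoms.
#' @return logical vector over the atom table.
#' @export
atom_sel <- function(x, chain = NULL, resno = NULL, name = NULL, heavy = FALSE) {
  at <- x$atoms
  m <- rep(TRUE, nrow(at))
  if (!is.null(chain)) m <- m & at$chain %in% chain
  if (!is.null(resno)) m <- m & at$resno %in% resno
  if (!is.null(name)) m <- m & at$name %in% name
  if (heavy) m <- m & at$is_heavy
  m
}

# Index of a single atom identified by (chain, resno, name); errors if absent.
atom_index <- function(atoms, chain, resno, name) {
  i <- which(atoms$chain == chain & atoms$resno == resno & atoms$name == name)
  if (length(i) != 1)
    stopf("atom %s/%s/%s: %s", chain, resno, name,
          if (length(i) == 0) "not found in topology" else "ambiguous")
  i
}
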