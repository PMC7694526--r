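#' Write configurations as extended-XYZ
#'
#' One frame per snapshot: bead count, a comment line carrying the lattice
#' (Angstrom), the column layout, the frame time and the length scale, then
#' one line per bead with species, position (Angstrom), velocity (reduced)
#' and molecule id.  The bond list travels in a sidecar CSV
#' (\code{\link{write_bonds}}) because XYZ has no bond notion.
#'
#' @param x A \code{dpd_config} or \code{dpd_trajectory}.
#' @param path Output file.
#' @param append Append frames instead of truncating.
#' @return The path, invisibly.
#' @export
write_snapshot <- function(x, path, append = FALSE) {
  if (inherits(x, "dpd_trajectory")) {
    con <- file(path, if (append) "a" else "w")
    on.exit(close(con))
    for (i in seq_along(x$snapshots)) {
      write_xyz_frame(x$snapshots[[i]], con,
                      time_ps = x$scalars$time_ps[i])
    }
    return(invisible(path))
  }
  stopifnot(inherits(x, "dpd_config"))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  write_xyz_frame(x, con, time_ps = 0)
  invisible(path)
}

write_xyz_frame <- function(cfg, con, time_ps = 0) {
  rc <- cfg$units$r_c
  box_A <- cfg$box * rc
  n <- n_beads(cfg)
  writeLines(as.character(n), con)
  writeLines(sprintf(
    paste0('Lattice="%.6f 0 0 0 %.6f 0 0 0 %.6f" ',
           'Properties=species:S:1:pos:R:3:vel:R:3:mol:I:1 ',
           "Time=%.6f r_c=%.6f"),
    box_A[1], box_A[2], box_A[3], time_ps, rc), con)
  if (n) {
    lines <- sprintf("%s %.8f %.8f %.8f %.8f %.8f %.8f %d",
                     cfg$species,
                     cfg$pos[, 1] * rc, cfg$pos[, 2] * rc, cfg$pos[, 3] * rc,
                     cfg$vel[, 1], cfg$vel[, 2], cfg$vel[, 3], cfg$mol_id)
    writeLines(lines, con)
  }
  invisible(NULL)
}

#' Read an extended-XYZ snapshot file
#'
#' Inverse of \code{\link{write_snapshot}}.  Multi-frame files return a list
#' of configurations unless \code{frame} selects one.  Molecule names are
#' not stored in the XYZ dialect; beads of one molecule id are labelled by
#' their species content against the default templates when possible,
#' otherwise \code{"custom"}.
#'
#' @param path File in the dialect written by \code{\link{write_snapshot}}.
#' @param bonds_path Optional sidecar CSV restoring the bond list.
#' @param frame Optional 1-based frame index.
#' @param units A \code{dpd_units} (r_c is cross-checked against the file).
#' @return A \code{dpd_config}, or a list of them.
#' @export
read_snapshot <- function(path, bonds_path = NULL, frame = NULL,
                          units = sim_units()) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed header at line ", i, ": expected bead count")
    if (i + 1L > length(lines)) stop("missing comment line at line ", i + 1L)
    hdr <- lines[i + 1L]
    lat <- regmatches(hdr, regexec('Lattice="([^"]*)"', hdr))[[1]][2]
    if (is.na(lat)) stop("malformed header at line ", i + 1L, ": no Lattice")
    lat <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    box_A <- lat[c(1, 5, 9)]
    rc <- regmatches(hdr, regexec("r_c=([0-9.eE+-]+)", hdr))[[1]][2]
    rc <- if (is.na(rc)) units$r_c else as.numeric(rc)
    body <- if (n > 0) lines[(i + 2L):(i + 1L + n)] else character(0)
    if (n > 0 && length(body) < n) stop("truncated frame at line ", i)
    tok <- strsplit(body, "\\s+")
    bad <- which(lengths(tok) != 8)
    if (length(bad)) stop("malformed atom line ", i + 1L + bad[1])
    species <- vapply(tok, `[[`, "", 1)
    num <- matrix(as.numeric(unlist(lapply(tok, `[`, 2:8))),
                  ncol = 7, byrow = TRUE)
    u <- sim_units(r_c = rc, mass_da = units$mass_da,
                   ps_per_step = units$ps_per_step, kT = units$kT)
    pos <- if (n > 0) num[, 1:3, drop = FALSE] / rc else matrix(0, 0, 3)
    vel <- if (n > 0) num[, 4:6, drop = FALSE] else matrix(0, 0, 3)
    mol_id <- if (n > 0) as.integer(num[, 7]) else integer(0)
    cfg <- new_config(box_A / rc, pos, vel, species, mol_id,
                      infer_mol_names(species, mol_id),
                      matrix(integer(0), ncol = 2), u, NA_integer_)
    frames[[length(frames) + 1L]] <- cfg
    i <- i + 2L + n
  }
  if (!is.null(bonds_path)) {
    b <- utils::read.csv(bonds_path)
    bm <- cbind(as.integer(b$bead_i), as.integer(b$bead_j))
    for (k in seq_along(frames)) frames[[k]]$bonds <- bm
  }
  frames <- lapply(frames, validate_config)
  if (!is.null(frame)) return(frames[[frame]])
  if (length(frames) == 1) frames[[1]] else frames
}

# label molecules by species content against the default templates
infer_mol_names <- function(species, mol_id) {
  if (!length(species)) return(character(0))
  sig <- function(sp) paste(sort(table(sp)), sort(unique(sp)), collapse = "|")
  ref <- vapply(default_templates(), function(t) sig(t$beads), "")
  grp <- split(seq_along(mol_id), mol_id)
  nm <- character(length(species))
  for (g in grp) {
    s <- sig(species[g])
    hit <- names(ref)[match(s, ref)]
    nm[g] <- if (is.na(hit)) "custom" else hit
  }
  nm
}

#' Write / read the bond sidecar table
#'
#' @param config A \code{dpd_config}.
#' @param path CSV path (columns \code{bead_i}, \code{bead_j}).
#' @export
write_bonds <- function(config, path) {
  utils::write.csv(data.frame(bead_i = config$bonds[, 1],
                              bead_j = config$bonds[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to regenerate an output: scenario, units,
#' builder and engine parameters, seeds, output paths and the package
#' version.
#'
#' @param path JSON output path.
#' @param scenario Scenario name or description.
#' @param units A \code{dpd_units}.
#' @param builder Named list of builder arguments.
#' @param params A \code{dpd_params} (or NULL).
#' @param matrix_source Matrix identifier or path.
#' @param seed Integer seed.
#' @param outputs Character vector of produced files.
#' @export
write_manifest <- function(path, scenario, units, builder = list(),
                           params = NULL, matrix_source = NULL, seed = NA,
                           outputs = character(0)) {
  doc <- list(scenario = scenario,
              package = "dpdnano",
              version = as.character(utils::packageVersion("dpdnano")),
              units = unclass(units),
              builder = builder,
              engine = if (!is.null(params)) unclass(params),
              matrix = matrix_source,
              seed = seed,
              outputs = as.list(outputs))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
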