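#' Write frames as extended XYZ
#'
#' One block per frame: particle count, a comment line carrying the lattice,
#' per-column properties, hydration level and periodicity, then one row per
#' particle (`species x y z is_water residue chain`). Coordinates are
#' printed with 17 significant digits so a write/read round trip is
#' bit-exact. The bonded topology, species table and model parameters go to
#' a JSON sidecar (`<path>.json`) unless suppressed.
#'
#' @param frames an `hs_config` or a list of them (sharing one topology).
#' @param path output file.
#' @param sidecar write the topology sidecar next to `path`.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, sidecar = TRUE) {
  if (inherits(frames, "hs_config")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in frames) {
    n <- nrow(cfg$positions)
    L <- cfg$box$lengths
    comment <- sprintf(
      paste0('Lattice="%.17g 0 0 0 %.17g 0 0 0 %.17g" ',
             'Properties=species:S:1:pos:R:3:is_water:I:1:residue:I:1:chain:I:1 ',
             'periodic="%d %d %d" h=%.10g'),
      L[1], L[2], L[3], cfg$box$periodic[1], cfg$box$periodic[2],
      cfg$box$periodic[3],
      if (any(!cfg$is_water)) hydration_level(cfg) else 0)
    writeLines(c(as.character(n), comment), con)
    sp <- cfg$species$name[cfg$species_ids]
    rows <- sprintf("%s %.17g %.17g %.17g %d %d %d", sp,
                    cfg$positions[, 1], cfg$positions[, 2], cfg$positions[, 3],
                    as.integer(cfg$is_water), cfg$residue_ids, cfg$chain_ids)
    writeLines(rows, con)
  }
  if (sidecar) {
    cfg <- frames[[1]]
    meta <- list(species = cfg$species,
                 topology = list(chain_bonds = cfg$topology$chain_bonds,
                                 crosslinks = cfg$topology$crosslinks,
                                 tethers = cfg$topology$tethers),
                 cutoff = cfg$cutoff, softcore_alpha = cfg$softcore_alpha)
    jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                         matrix = "rowmajor")
  }
  invisible(path)
}

.parse_xyz_comment <- function(line, lineno) {
  lat <- regmatches(line, regexec('Lattice="([^"]+)"', line))[[1]]
  if (length(lat) < 2) stop("malformed XYZ comment (no Lattice) at line ", lineno)
  v <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
  per <- regmatches(line, regexec('periodic="([^"]+)"', line))[[1]]
  periodic <- if (length(per) >= 2) {
    as.integer(strsplit(trimws(per[2]), "\\s+")[[1]]) == 1L
  } else c(TRUE, TRUE, TRUE)
  hs_box(c(v[1], v[5], v[9]), periodic)
}

#' Read extended-XYZ frames
#'
#' Inverse of [write_xyz()]. Topology and model parameters are restored from
#' the JSON sidecar when present (or a `topology` argument).
#'
#' @param path input file.
#' @param species species table used to map names to ids (defaults to the
#'   sidecar's table, else [hs_species_table()]).
#' @param topology optional `hs_topology` overriding the sidecar.
#' @return list of `hs_config` frames.
#' @export
read_xyz <- function(path, species = NULL, topology = NULL) {
  lines <- readLines(path)
  side <- paste0(path, ".json")
  cutoff <- 3.0
  alpha <- 0.5
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(species)) species <- as.data.frame(meta$species)
    if (is.null(topology)) {
      as_m <- function(m, ncol) {
        if (is.null(m) || length(m) == 0) NULL else matrix(unlist(m),
                                                           ncol = ncol,
                                                           byrow = FALSE)
      }
      tb <- function(x, nc) {
        if (is.null(x) || length(x) == 0) return(NULL)
        if (is.matrix(x)) x else matrix(unlist(x), ncol = nc, byrow = TRUE)
      }
      topology <- hs_topology(tb(meta$topology$chain_bonds, 4),
                              tb(meta$topology$crosslinks, 4))
      tet <- tb(meta$topology$tethers, 5)
      if (!is.null(tet)) topology$tethers <- tet
    }
    cutoff <- meta$cutoff %||% cutoff
    alpha <- meta$softcore_alpha %||% alpha
  }
  species <- species %||% hs_species_table()
  topology <- topology %||% hs_topology()
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed XYZ particle count at line ", i)
    box <- .parse_xyz_comment(lines[i + 1L], i + 1L)
    rows <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(tok, length, integer(1)) < 7)
    if (length(bad) > 0) stop("malformed XYZ record at line ", i + 1L + bad[1])
    m <- do.call(rbind, tok)
    sid <- match(m[, 1], species$name)
    if (anyNA(sid)) stop("unknown species name at line ",
                         i + 1L + which(is.na(sid))[1])
    frames[[length(frames) + 1L]] <- hs_configuration(
      positions = cbind(as.numeric(m[, 2]), as.numeric(m[, 3]),
                        as.numeric(m[, 4])),
      species_ids = sid, is_water = as.integer(m[, 5]) == 1L, box = box,
      topology = topology, species = species,
      residue_ids = as.integer(m[, 6]), chain_ids = as.integer(m[, 7]),
      cutoff = cutoff, softcore_alpha = alpha, validate = FALSE)
    i <- i + 2L + n
  }
  frames
}

#' Read a minimal PDB subset
#'
#' Handles `ATOM`/`HETATM`, `CRYST1` and `END` records (fixed wwPDB
#' columns). Residues are numbered from the file's 1-based `resSeq`; waters
#' are recognized by residue names HOH/WAT/SOL/TIP3 and mapped to the
#' reserved residue label 0. Intended for Angstrom-unit real trajectories
#' feeding the analysis module.
#'
#' @param path PDB file.
#' @param species species table used for the two classes (`philic` for
#'   non-water atoms, `water` for waters); pass an Angstrom-parameterized
#'   table for physical SASA values.
#' @param cutoff pair cutoff stored on the configuration (Angstrom).
#' @return an `hs_config`.
#' @export
read_pdb <- function(path, species = NULL, cutoff = 10) {
  if (is.null(species)) {
    species <- hs_species_table(bead_sigma = 4.0, water_sigma = 2.8)
    species$sasa_radius <- c(1.9, 1.9, 1.4)
  }
  lines <- readLines(path)
  box <- NULL
  rec <- list()
  for (k in seq_along(lines)) {
    ln <- lines[k]
    tag <- substr(ln, 1, 6)
    if (tag == "CRYST1") {
      abc <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                          substr(ln, 25, 33)))
      if (anyNA(abc)) stop("malformed CRYST1 record at line ", k)
      box <- hs_box(abc)
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      if (anyNA(xyz)) stop("malformed ATOM coordinates at line ", k)
      resseq <- suppressWarnings(as.integer(substr(ln, 23, 26)))
      if (is.na(resseq)) stop("malformed ATOM resSeq at line ", k)
      rec[[length(rec) + 1L]] <- list(
        xyz = xyz, resname = trimws(substr(ln, 18, 20)), resseq = resseq)
    } else if (trimws(tag) == "END") {
      break
    }
  }
  if (length(rec) == 0) stop("no ATOM records found in ", path)
  pos <- do.call(rbind, lapply(rec, `[[`, "xyz"))
  resname <- vapply(rec, `[[`, character(1), "resname")
  resseq <- vapply(rec, `[[`, integer(1), "resseq")
  isw <- resname %in% c("HOH", "WAT", "SOL", "TIP", "TIP3")
  ord <- order(isw)  # beads before waters
  pos <- pos[ord, , drop = FALSE]
  isw <- isw[ord]; resseq <- resseq[ord]
  if (is.null(box)) {
    span <- apply(pos, 2, function(x) diff(range(x))) + 2 * cutoff
    box <- hs_box(span, periodic = c(FALSE, FALSE, FALSE))
  }
  sid <- ifelse(isw, which(species$name == "water")[1],
                which(species$name == "philic")[1])
  res <- ifelse(isw, 0L, resseq)
  hs_configuration(pos, sid, isw, box, species = species,
                   residue_ids = res, chain_ids = ifelse(isw, 0L, 1L),
                   cutoff = cutoff, validate = FALSE)
}

#' Write an isotherm to CSV
#'
#' Columns `branch,h,n_waters,mu_w,mu_stderr,rh` with fixed 12-significant-
#' digit formatting, so identical runs produce byte-identical files.
#'
#' @param isotherm an `hs_isotherm` or its `records` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(isotherm, path) {
  df <- if (inherits(isotherm, "hs_isotherm")) isotherm$records else isotherm
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("branch,h,n_waters,mu_w,mu_stderr,rh", con)
  writeLines(sprintf("%s,%.12g,%d,%.12g,%.12g,%.12g", df$branch, df$h,
                     as.integer(df$n_waters), df$mu_w, df$mu_stderr, df$rh),
             con)
  invisible(path)
}

#' Read an isotherm CSV written by [write_isotherm_csv()]
#'
#' @param path input file.
#' @return data.frame with the isotherm records.
#' @export
read_isotherm_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
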