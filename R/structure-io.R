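#' Read a PDB file as a conformer ensemble
#'
#' Parses fixed-format PDB text into a tidy atom table. Multi-model files
#' (MODEL/ENDMDL blocks) are treated as frames of one conformer ensemble: all
#' models must contain the same atoms in the same order. Alternate locations
#' are resolved per atom by highest occupancy, ties broken by alphabetical
#' altloc code. Hydrogens are retained; downstream radius computations drop
#' them by default.
#'
#' @param path Path to a PDB file.
#' @param model_policy `"all"` keeps every MODEL as a frame; `"first"` keeps
#'   only the first.
#' @return A tibble with one row per atom per frame and columns `frame`,
#'   `serial`, `atom`, `altloc`, `resname`, `chain`, `resno`, `x`, `y`, `z`,
#'   `occupancy`, `element`. Residue numbers are the author numbering of the
#'   source file; no renumbering is performed.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "END"), pdb)
#' read_pdb(pdb)
#' @export
read_pdb <- function(path, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")

  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L

  keep <- which(is_atom)
  if (length(keep) == 0) abort(paste0("no ATOM/HETATM records in ", path))

  parse_num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & !grepl("^\\s*$", s))
    if (length(bad) > 0) {
      abort(paste0("malformed ATOM line ", ln[bad[1]], " in ", path,
                   ": cannot parse ", what, " from '", s[bad[1]], "'"))
    }
    v
  }

  al <- lines[keep]
  if (any(nchar(al) < 54)) {
    short <- keep[which(nchar(al) < 54)[1]]
    abort(paste0("malformed ATOM line ", short, " in ", path,
                 ": line shorter than coordinate fields"))
  }
  x <- parse_num(substr(al, 31, 38), "x", keep)
  y <- parse_num(substr(al, 39, 46), "y", keep)
  z <- parse_num(substr(al, 47, 54), "z", keep)
  if (any(!is.finite(x) | !is.finite(y) | !is.finite(z))) {
    bad <- keep[which(!is.finite(x) | !is.finite(y) | !is.finite(z))[1]]
    abort(paste0("malformed ATOM line ", bad, " in ", path,
                 ": non-finite coordinates"))
  }
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[is.na(occ)] <- 1
  resno <- parse_num(substr(al, 23, 26), "residue number", keep)

  element <- trimws(substr(al, 77, 78))
  name <- trimws(substr(al, 13, 16))
  guess <- sub("^[0-9']+", "", name)
  element <- ifelse(element == "", toupper(substr(guess, 1, 1)), toupper(element))

  atoms <- tibble(
    frame = model_id[keep],
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    atom = name,
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = as.integer(resno),
    x = x, y = y, z = z,
    occupancy = occ,
    element = element
  )
  atoms$frame <- match(atoms$frame, sort(unique(atoms$frame)))

  # altloc resolution: highest occupancy, then alphabetical altloc
  atoms <- atoms %>%
    arrange(.data$frame, .data$serial) %>%
    group_by(.data$frame, .data$chain, .data$resno, .data$resname, .data$atom) %>%
    arrange(dplyr::desc(.data$occupancy), .data$altloc, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$frame, .data$serial) %>%
    mutate(altloc = ifelse(.data$altloc == " ", "", .data$altloc))

  if (model_policy == "first") {
    atoms <- filter(atoms, .data$frame == 1L)
  } else {
    check_ensemble(atoms, where = path)
  }
  atoms
}

# Shared-atom-table invariant: every frame must list the same atoms in the
# same order. Errors name the first offending model.
check_ensemble <- function(atoms, where = "ensemble") {
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$atom)
  ref <- key[atoms$frame == 1L]
  for (f in unique(atoms$frame)) {
    k <- key[atoms$frame == f]
    if (length(k) != length(ref) || any(k != ref)) {
      abort(paste0("frame/model ", f, " of ", where,
                   " does not share the atom table of model 1 (",
                   length(k), " vs ", length(ref), " atoms)"))
    }
  }
  invisible(atoms)
}

#' Number of frames in an ensemble
#' @param ensemble An atom tibble as returned by [read_pdb()].
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) length(unique(ensemble$frame))

#' Extract one frame of an ensemble
#' @param ensemble An atom tibble.
#' @param frame Frame index.
#' @return The atom tibble restricted to that frame.
#' @export
get_frame <- function(ensemble, frame) {
  out <- ensemble[ensemble$frame == frame, , drop = FALSE]
  if (nrow(out) == 0) abort(paste0("frame ", frame, " not present"))
  out
}

coords_mat <- function(df) cbind(df$x, df$y, df$z)

#' Write an ensemble back to PDB
#'
#' Writes fixed-format PDB; ensembles with more than one frame are written as
#' MODEL/ENDMDL blocks. Coordinates keep the format's 3-decimal precision.
#'
#' @param ensemble Atom tibble (see [read_pdb()]).
#' @param path Output file path.
#' @param remarks Optional character vector written as REMARK lines.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ensemble, path, remarks = NULL) {
  frames <- sort(unique(ensemble$frame))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(remarks)) {
    writeLines(sprintf("REMARK   3 %s", remarks), con)
  }
  fmt_atom <- function(df) {
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            df$serial %% 100000L,
            ifelse(nchar(df$atom) >= 4, df$atom, paste0(" ", df$atom)),
            ifelse(df$altloc == "", " ", df$altloc),
            df$resname, df$chain, df$resno,
            df$x, df$y, df$z, df$occupancy, 0, df$element)
  }
  multi <- length(frames) > 1
  for (f in frames) {
    df <- ensemble[ensemble$frame == f, , drop = FALSE]
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(fmt_atom(df), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' C-beta reference points for every residue of every frame
#'
#' Cross-linking geometry is referenced to the side-chain take-off, so the
#' analysis uses C-beta atoms throughout. Glycine has no C-beta; a virtual one
#' is constructed deterministically from N, C-alpha and C with ideal
#' tetrahedral geometry and a 1.53 Angstrom C-alpha--C-beta bond (the same
#' construction is applied to any residue whose C-beta is missing but whose
#' backbone is complete). If the backbone is incomplete, the C-alpha position
#' is returned and flagged as a fallback.
#'
#' @param ensemble Atom tibble (see [read_pdb()]).
#' @param residues Optional tibble with columns `chain` and `resno` selecting
#'   residues; default all residues.
#' @return Tibble with columns `frame`, `chain`, `resno`, `resname`, `x`, `y`,
#'   `z`, `source` (`"CB"`, `"virtual"` or `"CA-fallback"`).
#' @export
cbeta_points <- function(ensemble, residues = NULL) {
  df <- ensemble
  if (!is.null(residues)) {
    sel <- distinct(as_tibble(residues)[, c("chain", "resno")])
    df <- semi_join(df, sel, by = c("chain", "resno"))
    found <- distinct(df[, c("chain", "resno")])
    missing <- anti_join(sel, found, by = c("chain", "resno"))
    if (nrow(missing) > 0) {
      abort(paste0("residue ", missing$chain[1], "/", missing$resno[1],
                   " not found in ensemble"))
    }
  }
  df <- filter(df, .data$atom %in% c("N", "CA", "C", "CB"))
  wide <- df %>%
    select("frame", "chain", "resno", "resname", "atom", "x", "y", "z") %>%
    tidyr::pivot_wider(names_from = "atom",
                       values_from = c("x", "y", "z"))
  need <- function(col) if (col %in% names(wide)) wide[[col]] else rep(NA_real_, nrow(wide))
  has_cb <- !is.na(need("x_CB"))
  has_bb <- !is.na(need("x_N")) & !is.na(need("x_CA")) & !is.na(need("x_C"))
  has_ca <- !is.na(need("x_CA"))
  if (any(!has_ca & !has_cb)) {
    bad <- wide[!has_ca & !has_cb, ]
    abort(paste0("residue ", bad$chain[1], "/", bad$resno[1],
                 " has neither CB nor CA; cannot build a C-beta reference point"))
  }

  n <- nrow(wide)
  out_x <- out_y <- out_z <- numeric(n)
  src <- character(n)
  for (i in seq_len(n)) {
    if (has_cb[i]) {
      out_x[i] <- need("x_CB")[i]; out_y[i] <- need("y_CB")[i]; out_z[i] <- need("z_CB")[i]
      src[i] <- "CB"
    } else if (has_bb[i]) {
      ca <- c(need("x_CA")[i], need("y_CA")[i], need("z_CA")[i])
      nn <- c(need("x_N")[i], need("y_N")[i], need("z_N")[i])
      cc <- c(need("x_C")[i], need("y_C")[i], need("z_C")[i])
      p <- virtual_cbeta(nn, ca, cc)
      out_x[i] <- p[1]; out_y[i] <- p[2]; out_z[i] <- p[3]
      src[i] <- "virtual"
    } else {
      out_x[i] <- need("x_CA")[i]; out_y[i] <- need("y_CA")[i]; out_z[i] <- need("z_CA")[i]
      src[i] <- "CA-fallback"
    }
  }
  tibble(frame = wide$frame, chain = wide$chain, resno = wide$resno,
         resname = wide$resname, x = out_x, y = out_y, z = out_z,
         source = src) %>%
    arrange(.data$frame, .data$chain, .data$resno)
}

# Virtual C-beta from backbone N, CA, C: ideal tetrahedral branch direction
# with L-amino-acid chirality, rescaled to the 1.53 A CA-CB bond.
virtual_cbeta <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  dir <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
  ca + 1.53 * unit(dir)
}

#' Define named structural segments
#'
#' A segment map names residue ranges (transmembrane helices, nucleotide
#' binding domains, ...) plus an axial membrane window used by the pore
#' profiler. Ranges are inclusive author residue numbers.
#'
#' @param ... Named segments. Each is either a numeric `c(start, end)`
#'   (applies to any chain) or a data frame with columns `chain`, `start`,
#'   `end` (one row per range).
#' @param membrane_z Optional length-2 numeric: axial bounds of the membrane
#'   window in Angstrom (in the profiler's axis frame).
#' @return An object of class `plx_segment_map`.
#' @examples
#' segment_map(TMH6 = c(330, 360), TMH12 = c(1118, 1155),
#'             membrane_z = c(-15, 15))
#' @export
segment_map <- function(..., membrane_z = NULL) {
  entries <- list(...)
  if (length(entries) > 0 && (is.null(names(entries)) || any(names(entries) == ""))) {
    abort("every segment must be named")
  }
  segs <- lapply(entries, function(e) {
    if (is.numeric(e) && length(e) == 2) {
      tibble(chain = NA_character_, start = as.integer(min(e)), end = as.integer(max(e)))
    } else if (is.data.frame(e)) {
      e <- as_tibble(e)
      if (!all(c("start", "end") %in% names(e))) {
        abort("segment data frames need 'start' and 'end' columns")
      }
      if (!"chain" %in% names(e)) e$chain <- NA_character_
      e[, c("chain", "start", "end")]
    } else {
      abort("segments must be c(start, end) or a data frame")
    }
  })
  for (nm in names(segs)) {
    s <- segs[[nm]]
    if (any(s$end < s$start)) abort(paste0("segment ", nm, " has an empty range"))
  }
  structure(list(segments = segs, membrane_z = membrane_z),
            class = "plx_segment_map")
}

#' @export
print.plx_segment_map <- function(x, ...) {
  cat("<segment map>", length(x$segments), "segments\n")
  for (nm in names(x$segments)) {
    s <- x$segments[[nm]]
    cat(" ", nm, ": ",
        paste(sprintf("%s%d-%d", ifelse(is.na(s$chain), "", paste0(s$chain, ":")),
                      s$start, s$end), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$membrane_z)) {
    cat("  membrane z-window: [", x$membrane_z[1], ",", x$membrane_z[2], "] A\n")
  }
  invisible(x)
}

#' Read a segment map from a YAML file
#'
#' Expected layout: a top-level `segments` mapping of name to `[start, end]`
#' (or a list of `{chain, start, end}` entries) and an optional `membrane_z`
#' pair.
#'
#' @param path YAML file path.
#' @return A `plx_segment_map`.
#' @export
read_segment_map <- function(path) {
  doc <- yaml::read_yaml(path)
  segs <- doc$segments %||% doc
  args <- lapply(segs, function(e) {
    if (is.list(e) && !is.null(e[[1]]$start %||% NULL)) {
      dplyr::bind_rows(lapply(e, function(r) {
        tibble(chain = r$chain %||% NA_character_,
               start = as.integer(r$start), end = as.integer(r$end))
      }))
    } else {
      as.numeric(unlist(e))
    }
  })
  args$membrane_z <- if (!is.null(doc$membrane_z)) as.numeric(doc$membrane_z) else NULL
  do.call(segment_map, args)
}

#' Select a named segment from an ensemble
#'
#' @param ensemble Atom tibble.
#' @param map A [segment_map()].
#' @param name Segment name present in `map`.
#' @param atoms Atom filter: `"CA"`, `"backbone"` (N, CA, C, O), `"heavy"`
#'   (no hydrogens) or `"all"`.
#' @return The sub-ensemble tibble (same frame count, same atom order).
#' @export
select_segment <- function(ensemble, map, name,
                           atoms = c("all", "CA", "backbone", "heavy")) {
  atoms <- match.arg(atoms)
  if (!inherits(map, "plx_segment_map")) abort("map must be a segment_map()")
  if (!name %in% names(map$segments)) {
    abort(paste0("unknown segment '", name, "'; available: ",
                 paste(names(map$segments), collapse = ", ")))
  }
  ranges <- map$segments[[name]]
  hit <- rep(FALSE, nrow(ensemble))
  for (i in seq_len(nrow(ranges))) {
    m <- ensemble$resno >= ranges$start[i] & ensemble$resno <= ranges$end[i]
    if (!is.na(ranges$chain[i])) m <- m & ensemble$chain == ranges$chain[i]
    hit <- hit | m
  }
  out <- ensemble[hit, , drop = FALSE]
  out <- filter_atoms(out, atoms)
  if (nrow(out) == 0) {
    abort(paste0("segment '", name, "' selects no atoms"))
  }
  out
}

filter_atoms <- function(df, atoms) {
  switch(atoms,
    all = df,
    CA = filter(df, .data$atom == "CA"),
    backbone = filter(df, .data$atom %in% c("N", "CA", "C", "O")),
    heavy = filter(df, .data$element != "H")
  )
}

#' Van der Waals radius table
#'
#' United-atom style radii used by the pore profiler (hydrogens are dropped by
#' default and their bulk absorbed into the heavy-atom radii). Values are
#' overridable and unknown elements fall back to the carbon radius.
#'
#' @return Tibble with columns `element` and `radius` (Angstrom).
#' @export
default_radius_table <- function() {
  tibble(element = c("C", "N", "O", "S", "P", "H"),
         radius = c(1.85, 1.75, 1.65, 2.00, 1.90, 1.00))
}

#' Read a radius table from a key-value YAML/TSV file
#' @param path File path; YAML mapping element to radius, or TSV with columns
#'   `element`, `radius`.
#' @return Tibble with columns `element`, `radius`.
#' @export
read_radius_table <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    doc <- yaml::read_yaml(path)
    tab <- tibble(element = names(doc), radius = as.numeric(unlist(doc)))
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
  }
  if (any(tab$radius <= 0.5 | tab$radius >= 3.0)) {
    abort("van der Waals radii must lie in (0.5, 3.0) Angstrom")
  }
  tab
}

# Attach a vdW radius to every atom row.
atom_radii <- function(df, radius_table = default_radius_table()) {
  r <- radius_table$radius[match(df$element, radius_table$element)]
  fallback <- radius_table$radius[match("C", radius_table$element)]
  r[is.na(r)] <- if (is.na(fallback)) 1.85 else fallback
  r
}
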