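#' Structure container and coordinate-file input/output
#'
#' A `StructureModel` holds the atoms of one coordinate model together with
#' protomer labels for the receptor chains of a homodimer. Atoms live in a
#' data frame with columns `chain`, `resno` (1-based author numbering),
#' `icode`, `resname`, `atom`, `element`, `x`, `y`, `z` (Angstrom), `occ`,
#' `b`, and `het` (logical flag for HETATM records: waters, ligands,
#' sterols). `protomer_map` is a named character vector mapping receptor
#' chain ids to protomer labels `"A"`/`"B"`.
#'
#' @param atoms data frame as described above
#' @param protomer_map named character vector, chain id -> protomer label
#' @param source_id free-text provenance tag (for example a PDB accession)
#' @return an object of class `StructureModel`
#' @export
StructureModel <- function(atoms, protomer_map = character(), source_id = "") {
  required <- c("chain", "resno", "icode", "resname", "atom", "element",
                "x", "y", "z", "occ", "b", "het")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    abort(paste("atoms lacks columns:", paste(missing_cols, collapse = ", ")),
          "format_error")
  if (nrow(atoms) == 0L) abort("empty structure: no atoms", "empty_structure")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("non-finite atom coordinates", "format_error")
  structure(list(atoms = atoms, protomer_map = protomer_map,
                 source_id = source_id),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s': %d atoms, chains %s\n", x$source_id,
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = ",")))
  if (length(x$protomer_map))
    cat("  protomers:", paste(names(x$protomer_map), x$protomer_map,
                              sep = "->", collapse = " "), "\n")
  invisible(x)
}

empty_atoms <- function(n = 0L) {
  data.frame(chain = character(n), resno = integer(n), icode = character(n),
             resname = character(n), atom = character(n),
             element = character(n), x = numeric(n), y = numeric(n),
             z = numeric(n), occ = numeric(n), b = numeric(n),
             het = logical(n), stringsAsFactors = FALSE)
}

guess_element <- function(atom_name, resname) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  if (!nzchar(nm)) return("C")
  first <- toupper(substr(nm, 1, 1))
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("CL", "BR", "SE") && nchar(nm) == 2) return(two)
  first
}

parse_pdb_atom_lines <- function(lines, lineno) {
  rec <- substr(lines, 1, 6)
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(lines, 31, 38)); y <- num(substr(lines, 39, 46))
  z <- num(substr(lines, 47, 54))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    abort(sprintf("unparsable PDB coordinate field at line %d: '%s'",
                  lineno[bad[1]], lines[bad[1]]), "format_error")
  resno <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  if (anyNA(resno))
    abort(sprintf("unparsable PDB residue number at line %d",
                  lineno[which(is.na(resno))[1]]), "format_error")
  occ <- num(substr(lines, 55, 60)); occ[is.na(occ)] <- 1
  b <- num(substr(lines, 61, 66)); b[is.na(b)] <- 0
  element <- trimws(substr(lines, 77, 78))
  atom <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  noel <- !nzchar(element)
  if (any(noel))
    element[noel] <- mapply(guess_element, atom[noel], resname[noel])
  data.frame(chain = substr(lines, 22, 22), resno = resno,
             icode = trimws(substr(lines, 27, 27)), resname = resname,
             atom = atom, element = element, x = x, y = y, z = z,
             occ = occ, b = b,
             het = trimws(rec) == "HETATM",
             altloc = substr(lines, 17, 17),
             stringsAsFactors = FALSE)
}

## keep one altloc per (chain,resno,icode,atom): highest occupancy, then
## alphabetical altloc id
resolve_altlocs <- function(atoms) {
  if (!"altloc" %in% names(atoms)) return(atoms)
  alt <- atoms$altloc
  alt[is.na(alt)] <- " "
  if (all(alt %in% c(" ", ""))) { atoms$altloc <- NULL; return(atoms) }
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occ, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                   atoms$atom, sep = "|")), , drop = FALSE]
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  atoms
}

read_pdb_atoms <- function(path, model = 1L) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) >= 1L) {
    ends <- c(model_starts[-1] - 1L, length(lines))
    if (model > length(model_starts))
      abort(sprintf("model %d requested but file has %d models", model,
                    length(model_starts)), "format_error")
    keep <- seq(model_starts[model], ends[model])
    lines <- lines[keep]
    rec <- rec[keep]
    lineno <- keep
  } else lineno <- seq_along(lines)
  sel <- trimws(rec) %in% c("ATOM", "HETATM")
  if (!any(sel)) abort(sprintf("empty structure: no ATOM/HETATM records in %s",
                               path), "empty_structure")
  resolve_altlocs(parse_pdb_atom_lines(lines[sel], lineno[sel]))
}

## minimal mmCIF tokenizer for one line (handles '...' and "..." quoting)
cif_tokens <- function(line) {
  out <- character(); i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && !(substr(line, j, j) == ch &&
                         (j == n || substr(line, j + 1, j + 1) %in% c(" ", "\t"))))
        j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L)); i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L)); i <- j
    }
  }
  out
}

read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx))
    abort(sprintf("no _atom_site loop found in %s", path), "format_error")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  start <- max(hdr_idx) + 1L
  rows <- list(); i <- start
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    rows[[length(rows) + 1L]] <- cif_tokens(lines[i])
    i <- i + 1L
  }
  if (!length(rows))
    abort(sprintf("empty structure: _atom_site loop has no rows in %s", path),
          "empty_structure")
  nf <- length(fields)
  badrow <- which(vapply(rows, length, 1L) != nf)
  if (length(badrow))
    abort(sprintf("mmCIF _atom_site row %d has %d fields, expected %d",
                  badrow[1], length(rows[[badrow[1]]]), nf), "format_error")
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- fields
  get <- function(nm, default = NA_character_)
    if (nm %in% fields) tab[[nm]] else rep(default, nrow(tab))
  ## restrict to first model when _atom_site.pdbx_PDB_model_num present
  mdl <- get("pdbx_PDB_model_num")
  if (!all(is.na(mdl))) tabsel <- mdl == mdl[1] else tabsel <- rep(TRUE, nrow(tab))
  tab <- tab[tabsel, , drop = FALSE]
  get <- function(nm, default = NA_character_)
    if (nm %in% fields) tab[[nm]] else rep(default, nrow(tab))
  dot_na <- function(v) { v[v %in% c(".", "?")] <- NA_character_; v }
  num <- function(v) suppressWarnings(as.numeric(v))
  x <- num(get("Cartn_x")); y <- num(get("Cartn_y")); z <- num(get("Cartn_z"))
  if (!all(is.finite(c(x, y, z))))
    abort("unparsable coordinates in mmCIF _atom_site block", "format_error")
  chain <- dot_na(get("auth_asym_id"))
  chain[is.na(chain)] <- dot_na(get("label_asym_id"))[is.na(chain)]
  resno <- suppressWarnings(as.integer(dot_na(get("auth_seq_id"))))
  if (anyNA(resno))
    resno[is.na(resno)] <-
      suppressWarnings(as.integer(dot_na(get("label_seq_id"))))[is.na(resno)]
  icode <- dot_na(get("pdbx_PDB_ins_code")); icode[is.na(icode)] <- ""
  occ <- num(dot_na(get("occupancy"))); occ[is.na(occ)] <- 1
  b <- num(dot_na(get("B_iso_or_equiv"))); b[is.na(b)] <- 0
  atoms <- data.frame(chain = chain, resno = resno, icode = icode,
                      resname = dot_na(get("label_comp_id")),
                      atom = dot_na(get("label_atom_id")),
                      element = toupper(dot_na(get("type_symbol"))),
                      x = x, y = y, z = z, occ = occ, b = b,
                      het = get("group_PDB", "ATOM") == "HETATM",
                      altloc = {
                        a <- dot_na(get("label_alt_id")); a[is.na(a)] <- " "; a
                      },
                      stringsAsFactors = FALSE)
  noel <- is.na(atoms$element) | !nzchar(atoms$element)
  if (any(noel))
    atoms$element[noel] <- mapply(guess_element, atoms$atom[noel],
                                  atoms$resname[noel])
  resolve_altlocs(atoms)
}

#' Read a structure from PDB or mmCIF
#'
#' ATOM and HETATM records are both retained; heteroatoms (waters, ligands,
#' sterols) are flagged in the `het` column. Alternative locations are
#' resolved by highest occupancy, then alphabetical altloc id. For
#' multi-model PDB files the first model is returned (use
#' [load_trajectory()] to read all models as frames).
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`
#' @param source_id provenance tag stored on the model; defaults to the
#'   file base name
#' @return a [StructureModel]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("file not found:", path), "format_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  atoms <- switch(format, pdb = read_pdb_atoms(path),
                  mmcif = read_mmcif_atoms(path))
  StructureModel(atoms, source_id = source_id %||%
                   tools::file_path_sans_ext(basename(path)))
}

format_pdb_line <- function(a, serial) {
  nm <- a$atom
  ## PDB atom-name column convention: element-start at col 14 for 1-2 char
  ## element names unless the name is 4 characters long
  nm_fmt <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
                   ifelse(nchar(a$element) == 2, sprintf("%-4s", nm),
                          sprintf(" %-3s", nm)))
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$het, "HETATM", "ATOM"), serial %% 100000, nm_fmt, " ",
          a$resname, a$chain, a$resno,
          ifelse(nzchar(a$icode), a$icode, " "),
          a$x, a$y, a$z, a$occ, a$b, a$element)
}

#' Write a structure to PDB or mmCIF
#'
#' Coordinates are written at 3-decimal precision (the PDB fixed-column
#' limit) in both formats so the two renderings round-trip identically.
#'
#' @param model a [StructureModel]
#' @param path output file path
#' @param format `"pdb"` or `"mmcif"`
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- model$atoms
  if (format == "pdb") {
    lines <- vapply(seq_len(nrow(a)), function(i)
      format_pdb_line(a[i, ], i), character(1))
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c(sprintf("data_%s", ifelse(nzchar(model$source_id),
                                       gsub("[^A-Za-z0-9_]", "_", model$source_id),
                                       "model")),
             "loop_", "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.label_atom_id", "_atom_site.label_comp_id",
             "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
             "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
             "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.type_symbol")
    rows <- sprintf("%s %d %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f %s",
                    ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)),
                    a$atom, a$resname, a$chain, a$resno,
                    ifelse(nzchar(a$icode), a$icode, "?"),
                    a$x, a$y, a$z, a$occ, a$b, a$element)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Assign protomer labels to receptor chains
#'
#' The first listed chain becomes protomer `"A"`, the second `"B"`.
#' Non-receptor chains (ligand peptides, G-protein subunits) are excluded
#' from the protomer map and thereby from all receptor-only analyses.
#' Assignment is a pure relabelling: coordinates are untouched.
#'
#' @param model a [StructureModel]
#' @param receptor_chains character vector of chain ids, length >= 1
#' @return the model with `protomer_map` set
#' @export
assign_protomers <- function(model, receptor_chains) {
  present <- unique(model$atoms$chain)
  missing_ch <- setdiff(receptor_chains, present)
  if (length(missing_ch))
    abort(paste("receptor chain(s) not in model:",
                paste(missing_ch, collapse = ", ")), "format_error")
  labels <- c("A", "B")[seq_along(receptor_chains)]
  if (length(receptor_chains) > 2)
    abort("at most two receptor chains (protomers A and B) supported",
          "format_error")
  model$protomer_map <- stats::setNames(labels, receptor_chains)
  model
}

protomer_chain <- function(model, protomer, required = TRUE) {
  ch <- names(model$protomer_map)[model$protomer_map == protomer]
  if (!length(ch)) {
    if (required)
      abort(sprintf("model has no protomer '%s' (dimer required)", protomer),
            "dimer_required")
    return(NA_character_)
  }
  ch[1]
}

#' Read a segment table (helix/loop residue ranges and anchors)
#'
#' JSON schema: `{"segments": {"H6": [250, 270], "ECL3": [271, 276], ...},
#' "anchors": {"267": "6x59", ...}}`. Ranges are inclusive author residue
#' numbers and must not overlap; each helix needs one anchor residue whose
#' generic number fixes the offset of the whole range.
#'
#' @param path JSON file path
#' @return a `SegmentTable` list with elements `segments` and `anchors`
#' @export
read_segment_table <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  segment_table(cfg$segments, cfg$anchors %||% list())
}

#' Construct a segment table from R lists
#'
#' @param segments named list, segment name -> `c(start, end)`
#' @param anchors named list/vector, residue number (as name) -> generic
#'   number string such as `"6x59"`
#' @return a `SegmentTable`
#' @export
segment_table <- function(segments, anchors = list()) {
  segs <- lapply(segments, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || anyNA(r) || r[2] < r[1])
      abort("segment ranges must be [start, end] with end >= start",
            "configuration_error")
    r
  })
  ## overlap check
  if (length(segs) > 1) {
    m <- do.call(rbind, segs)
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2]))
      abort("segment ranges overlap", "configuration_error")
  }
  structure(list(segments = segs,
                 anchors = unlist(anchors) %||% character()),
            class = "SegmentTable")
}

#' Map author residue numbers to generic numbers
#'
#' Residues inside a helix range `HN = [start, end]` receive generic number
#' `"Nx(M)"` where `M` counts from the range start, offset so the anchor
#' residue carries its configured generic number (for example anchoring
#' `267 -> "6x59"` in `H6 = [250, 270]` labels residue 250 as `"6x42"`).
#' Loop residues receive their region label (`ECL1`-`ECL3`, `ICL1`-`ICL3`,
#' `N-term`, ...). Residues outside all ranges are unlabelled (`NA`).
#' Author numbering remains the internal key; generic numbers are report
#' metadata.
#'
#' @param model a [StructureModel] with protomers assigned
#' @param table a `SegmentTable`
#' @return data frame of `ResidueRef`s: protomer, chain, resno, resname,
#'   generic
#' @export
map_generic_numbers <- function(model, table) {
  stopifnot(inherits(table, "SegmentTable"))
  chains <- names(model$protomer_map)
  a <- model$atoms[model$atoms$chain %in% chains & !model$atoms$het, ,
                   drop = FALSE]
  res <- unique(a[, c("chain", "resno", "resname")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  res$protomer <- unname(model$protomer_map[res$chain])
  res$generic <- NA_character_
  for (seg in names(table$segments)) {
    rng <- table$segments[[seg]]
    inside <- res$resno >= rng[1] & res$resno <= rng[2]
    if (!any(inside)) next
    if (grepl("^H[1-7]$", seg)) {
      hel <- substr(seg, 2, 2)
      base <- 1L  # default: first residue of range is Nx01
      anchor_in <- names(table$anchors)[as.integer(names(table$anchors)) >= rng[1] &
                                        as.integer(names(table$anchors)) <= rng[2]]
      if (length(anchor_in)) {
        anc_res <- as.integer(anchor_in[1])
        anc_gen <- table$anchors[[anchor_in[1]]]
        if (!grepl("^[1-7]x[0-9]{2}$", anc_gen))
          abort(sprintf("anchor generic number '%s' malformed", anc_gen),
                "configuration_error")
        anc_off <- as.integer(sub("^[1-7]x", "", anc_gen))
        base <- anc_off - (anc_res - rng[1])
      }
      res$generic[inside] <- sprintf("%sx%02d", hel,
                                     base + (res$resno[inside] - rng[1]))
    } else {
      res$generic[inside] <- seg
    }
  }
  rownames(res) <- NULL
  res[, c("protomer", "chain", "resno", "resname", "generic")]
}

#' Default Ste2 segment table
#'
#' Transmembrane-helix boundaries for the yeast pheromone receptor Ste2,
#' anchored so that the printed residue/generic-number pairs hold:
#' Ser267 -> 6x59, Ser243 -> 6x35, Asn301 -> 7x61, Pro290 -> 7x50, and
#' Gly273 in ECL3. Boundaries between anchors are interpolated from the
#' anchor arithmetic (contiguous helix numbering within each range) and
#' ship as package defaults that a user can override with their own table.
#'
#' @return a `SegmentTable`
#' @export
ste2_default_segments <- function() {
  segment_table(
    segments = list(
      H1 = c(49, 72), ICL1 = c(73, 77), H2 = c(78, 104), ECL1 = c(105, 112),
      H3 = c(113, 152), ICL2 = c(153, 159), H4 = c(160, 185),
      ECL2 = c(186, 200), H5 = c(201, 238), ICL3 = c(239, 241),
      H6 = c(242, 268), ECL3 = c(269, 280), H7 = c(281, 303)),
    anchors = c(`53` = "1x43", `95` = "2x57", `132` = "3x33", `184` = "4x64",
                `234` = "5x58", `267` = "6x59", `301` = "7x61"))
}
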