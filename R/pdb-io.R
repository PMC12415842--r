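# Multi-model PDB read/write and trajectory attachment (PDB, DCD, XTC).
#
# PDB is the package's canonical text interchange format. DCD is parsed
# natively (CHARMM/NAMD layout). XTC is bridged through the MDAnalysis
# Python library when a `python` interpreter with MDAnalysis is on PATH,
# since no R-native XTC reader exists in this stack.

#' Read a (multi-model) PDB file into a SystemModel
#'
#' One trajectory frame per MODEL record (a file without MODEL records is a
#' single frame). Elements are taken from the element column when present
#' and inferred from atom names otherwise. Residues whose type is not a
#' standard amino acid, water or Na/Cl are labelled component "other" with
#' a warning.
#'
#' @param path PDB file path
#' @param format only "pdb" is supported
#' @param domain_map optional \code{domain_map} to attach
#' @return a \code{SystemModel}
#' @export
read_structure <- function(path, format = "pdb", domain_map = NULL) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  box <- NULL
  cryst <- lines[rec == "CRYST1"]
  if (length(cryst) >= 1) {
    box <- c(as.numeric(substr(cryst[1], 7, 15)),
             as.numeric(substr(cryst[1], 16, 24)),
             as.numeric(substr(cryst[1], 25, 33)))
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0L) {
    frames_idx <- list(which(is_atom))
  } else {
    model_ends <- which(rec == "ENDMDL")
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    frames_idx <- mapply(function(s, e) {
      w <- s:e
      w[is_atom[w]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  nat <- vapply(frames_idx, length, integer(1))
  if (any(nat == 0L)) stop("PDB contains a model with no atoms")
  if (length(unique(nat)) != 1L)
    stop("inconsistent atom counts across models: ",
         paste(unique(nat), collapse = ", "))

  first <- lines[frames_idx[[1]]]
  name <- trimws(substr(first, 13, 16))
  res_type <- trimws(substr(first, 18, 20))
  chain_id <- substr(first, 22, 22)
  chain_id[chain_id == " "] <- "A"
  res_seq <- as.integer(substr(first, 23, 26))
  element <- trimws(substr(first, 77, 78))
  blank <- is.na(element) | element == ""
  if (any(blank))
    element[blank] <- mapply(infer_element, name[blank], res_type[blank])
  element <- toupper(element)

  n_frames <- length(frames_idx)
  coords <- array(NA_real_, c(nat[1], 3, n_frames))
  for (f in seq_len(n_frames)) {
    fl <- lines[frames_idx[[f]]]
    coords[, 1, f] <- as.numeric(substr(fl, 31, 38))
    coords[, 2, f] <- as.numeric(substr(fl, 39, 46))
    coords[, 3, f] <- as.numeric(substr(fl, 47, 54))
  }
  if (!all(is.finite(coords))) stop("unreadable coordinates in ", path)

  build_system(name, element, res_type, chain_id, res_seq, coords,
               box = box, domain_map = domain_map)
}

#' Assemble a SystemModel from per-atom vectors
#' @keywords internal
build_system <- function(name, element, res_type, chain_id, res_seq,
                         coords, box = NULL, times = NULL,
                         domain_map = NULL) {
  n <- length(name)
  # residue boundaries where (chain, resSeq, resName) changes
  key <- paste(chain_id, res_seq, res_type, sep = "|")
  newres <- c(TRUE, key[-1] != key[-n])
  res_id <- cumsum(newres)
  first_atom <- which(newres)
  last_atom <- c(first_atom[-1] - 1L, n)
  comp <- component_for_restype(res_type[first_atom])
  unknown <- comp == "other" &
    !(toupper(res_type[first_atom]) %in% c("ZN", "ZN2"))
  if (any(unknown))
    warning("residue type(s) not recognised, labelled 'other': ",
            paste(unique(res_type[first_atom][unknown]), collapse = ", "))
  atoms <- data.frame(
    name = name, element = element,
    mass = ifelse(toupper(res_type) %in% c("HOH", "WAT", "SOL", "TIP3"),
                  .WATER_MASS, element_mass(element, strict = FALSE)),
    is_heavy = toupper(element) != "H",
    res_id = res_id, stringsAsFactors = FALSE)
  residues <- data.frame(
    res_id = seq_along(first_atom),
    seq_index = res_seq[first_atom],
    res_type = toupper(res_type[first_atom]),
    chain_id = chain_id[first_atom],
    first_atom = first_atom, last_atom = last_atom,
    component = comp, stringsAsFactors = FALSE)
  system_model(atoms, residues, coords, box = box, times = times,
               domain_map = domain_map)
}

#' Write a SystemModel as a multi-model PDB file
#'
#' Coordinates are written at the format's %8.3f precision; an orthorhombic
#' CRYST1 record is emitted when the model carries a box.
#'
#' @param model a SystemModel
#' @param path output path
#' @param frames frame indices to write (default: all)
#' @return \code{path}, invisibly
#' @export
write_structure <- function(model, path, frames = seq_len(n_frames(model))) {
  at <- model$atoms
  res <- model$residues
  rid <- at$res_id
  res_seq <- res$seq_index[rid] %% 10000L
  res_type <- substr(res$res_type[rid], 1, 3)
  chain <- substr(res$chain_id[rid], 1, 1)
  het <- res$component[rid] != "protein"
  # PDB atom-name column convention: 1-letter elements start in column 14
  nm <- at$name
  nm4 <- ifelse(nchar(at$element) == 1 & nchar(nm) <= 3,
                sprintf(" %-3s", nm), sprintf("%-4s", nm))
  serial <- (seq_len(nrow(at)) - 1L) %% 99999L + 1L
  head_fmt <- sprintf("%s%5d %s %-3s %s%4d    ",
                      ifelse(het, "HETATM", "ATOM  "), serial, nm4,
                      res_type, chain, res_seq)
  tail_fmt <- sprintf("  1.00  0.00          %2s", toupper(at$element))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model$box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      model$box[1, 1], model$box[1, 2], model$box[1, 3], 90, 90, 90), con)
  multi <- length(frames) > 1L
  for (f in frames) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- model$coords[, , f]
    writeLines(paste0(head_fmt,
                      sprintf("%8.3f%8.3f%8.3f", xyz[, 1], xyz[, 2],
                              xyz[, 3]),
                      tail_fmt), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Append trajectory frames to a SystemModel
#'
#' Frames are appended in file order and converted to Angstrom internally
#' (XTC sources are in nm and are multiplied by 10).
#'
#' @param model a SystemModel whose topology matches the trajectory
#' @param path trajectory file
#' @param format "pdb" (multi-model), "dcd", or "xtc"
#' @param replace drop the model's existing frames first (default TRUE,
#'   since a structure file's frame is usually just a topology template)
#' @return the SystemModel with the new frames
#' @export
attach_trajectory <- function(model, path, format = c("pdb", "dcd", "xtc"),
                              replace = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  traj <- switch(format,
    pdb = {
      m <- read_structure(path)
      list(coords = m$coords, box = m$box)
    },
    dcd = read_dcd(path),
    xtc = read_xtc_via_python(model, path))
  nf <- dim(traj$coords)[3]
  if (is.null(nf) || nf == 0L) stop("trajectory file contains no frames")
  if (dim(traj$coords)[1] != nrow(model$atoms))
    stop("trajectory atom count (", dim(traj$coords)[1],
         ") does not match topology (", nrow(model$atoms), ")")
  if (replace) {
    model$coords <- traj$coords
    model$box <- traj$box
    model$times <- NULL
  } else {
    model$coords <- array(c(model$coords, traj$coords),
                          c(nrow(model$atoms), 3,
                            n_frames(model) + nf))
    if (!is.null(model$box) && !is.null(traj$box))
      model$box <- rbind(model$box, traj$box)
  }
  model
}

#' Read a CHARMM/NAMD DCD trajectory
#' @param path DCD file
#' @return list(coords = n_atoms x 3 x n_frames array in Angstrom,
#'   box = n_frames x 3 matrix or NULL)
#' @keywords internal
read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rec_len <- readBin(con, "integer", 1, size = 4)
  if (rec_len != 84) stop("not a DCD file (unexpected header length)")
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a coordinate DCD file")
  icntrl <- readBin(con, "integer", 20, size = 4)
  readBin(con, "integer", 1, size = 4)  # trailing record marker
  n_frames <- icntrl[1]
  has_box <- icntrl[11] == 1L
  # title block
  tlen <- readBin(con, "integer", 1, size = 4)
  readBin(con, "raw", tlen)
  readBin(con, "integer", 1, size = 4)
  # natom block
  readBin(con, "integer", 1, size = 4)
  natom <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)
  coords <- array(NA_real_, c(natom, 3, n_frames))
  box <- if (has_box) matrix(NA_real_, n_frames, 3) else NULL
  for (f in seq_len(n_frames)) {
    if (has_box) {
      readBin(con, "integer", 1, size = 4)
      cell <- readBin(con, "double", 6, size = 8)  # A,gamma,B,beta,alpha,C
      readBin(con, "integer", 1, size = 4)
      box[f, ] <- cell[c(1, 3, 6)]
    }
    for (k in 1:3) {
      readBin(con, "integer", 1, size = 4)
      coords[, k, f] <- readBin(con, "double", natom, size = 4)
      readBin(con, "integer", 1, size = 4)
    }
  }
  list(coords = coords, box = box)
}

#' Read an XTC trajectory through MDAnalysis
#'
#' Writes the model's first frame as a temporary PDB topology, loads the
#' XTC with MDAnalysis (which converts nm to Angstrom), and returns the
#' frames as plain text. Requires `python` with MDAnalysis on PATH.
#' @keywords internal
read_xtc_via_python <- function(model, path) {
  py <- Sys.which("python")
  if (py == "") stop("XTC reading requires a python interpreter with ",
                     "MDAnalysis on PATH")
  top <- tempfile(fileext = ".pdb")
  out <- tempfile(fileext = ".txt")
  write_structure(slice_frames(model, 1L), top)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import MDAnalysis as mda",
    "import numpy as np",
    "u = mda.Universe(sys.argv[1], sys.argv[2])",
    "rows = []",
    "boxes = []",
    "for ts in u.trajectory:",
    "    rows.append(ts.positions.copy())",
    "    dims = ts.dimensions",
    "    boxes.append(dims[:3].copy() if dims is not None else np.zeros(3))",
    "arr = np.concatenate(rows, axis=0)",
    "hdr = '%d %d' % (len(rows), u.atoms.n_atoms)",
    "np.savetxt(sys.argv[3], arr, fmt='%.6f', header=hdr, comments='')",
    "np.savetxt(sys.argv[3] + '.box', np.array(boxes), fmt='%.6f')"
  ), script)
  status <- system2(py, c(script, top, path, out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("MDAnalysis failed to read ", path)
  hdr <- scan(out, what = integer(), nmax = 2, quiet = TRUE)
  dat <- as.matrix(utils::read.table(out, skip = 1))
  nf <- hdr[1]; na <- hdr[2]
  coords <- aperm(array(t(dat), c(3, na, nf)), c(2, 1, 3))
  box <- as.matrix(utils::read.table(paste0(out, ".box")))
  if (all(box == 0)) box <- NULL else dimnames(box) <- NULL
  list(coords = coords, box = box)
}
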