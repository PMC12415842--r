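# Core data model: topology + trajectory container and domain maps.
#
# A SystemModel bundles a topology (atoms, residues, chains), an ordered set
# of coordinate frames (internally always in Angstrom), optional per-frame
# orthorhombic box lengths, and a domain map. All analysis stages consume
# this one container.

#' Construct a SystemModel
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{mass} (amu), \code{is_heavy} (logical), \code{res_id}
#'   (1-based index into \code{residues}).
#' @param residues data.frame with columns \code{res_id}, \code{seq_index}
#'   (1-based within chain), \code{res_type}, \code{chain_id},
#'   \code{first_atom}, \code{last_atom}, \code{component}
#'   (one of protein/water/Na/Cl/other).
#' @param coords numeric array \code{n_atoms x 3 x n_frames} in Angstrom.
#' @param box optional \code{n_frames x 3} matrix of orthorhombic box
#'   lengths (Angstrom), or NULL for non-periodic systems.
#' @param times optional per-frame time stamps (ps).
#' @param domain_map optional domain map (see \code{\link{domain_map}}).
#' @return an object of class \code{SystemModel}
#' @export
system_model <- function(atoms, residues, coords, box = NULL, times = NULL,
                         domain_map = NULL) {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(atoms))
    stop("coordinate rows (", dim(coords)[1], ") != atom count (",
         nrow(atoms), ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  bad <- atoms$is_heavy != (toupper(atoms$element) != "H")
  if (any(bad)) stop("is_heavy inconsistent with element for ",
                     sum(bad), " atom(s)")
  if (!is.null(box)) {
    box <- matrix(as.numeric(box), ncol = 3)
    if (nrow(box) == 1L) box <- box[rep(1L, dim(coords)[3]), , drop = FALSE]
    stopifnot(nrow(box) == dim(coords)[3])
  }
  comp_ok <- residues$component %in% c("protein", "water", "Na", "Cl", "other")
  if (!all(comp_ok)) stop("unknown component label(s): ",
                          paste(unique(residues$component[!comp_ok]),
                                collapse = ", "))
  # atom spans must tile the atom table
  spans <- unlist(mapply(seq, residues$first_atom, residues$last_atom,
                         SIMPLIFY = FALSE))
  if (length(spans) != nrow(atoms) || anyDuplicated(spans))
    stop("residue atom spans must partition the atom table")
  for (ch in unique(residues$chain_id)) {
    si <- residues$seq_index[residues$chain_id == ch]
    if (any(diff(si) <= 0))
      stop("seq_index not strictly increasing in chain ", ch)
  }
  structure(list(atoms = atoms, residues = residues, coords = coords,
                 box = box, times = times, domain_map = domain_map),
            class = "SystemModel")
}

#' @export
print.SystemModel <- function(x, ...) {
  comp <- table(x$residues$component)
  cat("SystemModel:", nrow(x$atoms), "atoms,", nrow(x$residues),
      "residues,", length(unique(x$residues$chain_id)), "chain(s),",
      n_frames(x), "frame(s)\n")
  cat("  components:",
      paste(sprintf("%s=%d", names(comp), comp), collapse = ", "), "\n")
  if (!is.null(x$box))
    cat("  box (frame 1):",
        paste(sprintf("%.1f", x$box[1, ]), collapse = " x "), "A\n")
  invisible(x)
}

#' Number of trajectory frames
#' @param model a SystemModel
#' @return integer frame count
#' @export
n_frames <- function(model) dim(model$coords)[3]

#' Extract one coordinate frame
#' @param model a SystemModel
#' @param frame 1-based frame index
#' @return \code{n_atoms x 3} matrix (Angstrom)
#' @export
get_frame <- function(model, frame) {
  stopifnot(frame >= 1L, frame <= n_frames(model))
  model$coords[, , frame, drop = TRUE]
}

#' Component partition of a model's residues
#'
#' Every residue belongs to exactly one of protein, water, Na, Cl, other.
#' @param model a SystemModel
#' @return named integer vector of residue counts per component
#' @export
component_sizes <- function(model) {
  tab <- table(factor(model$residues$component,
                      levels = c("protein", "water", "Na", "Cl", "other")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Assign a component label from a residue type
#' @keywords internal
component_for_restype <- function(res_type) {
  rt <- toupper(res_type)
  ifelse(rt %in% .AA3, "protein",
  ifelse(rt %in% c("HOH", "WAT", "SOL", "TIP3"), "water",
  ifelse(rt %in% c("NA", "SOD"), "Na",
  ifelse(rt %in% c("CL", "CLA"), "Cl", "other"))))
}

# ---- Domain maps ------------------------------------------------------

#' Construct a domain map
#'
#' A table of named, 1-based residue ranges (first <= last). Ranges may be
#' listed in any order and are allowed to share a boundary residue, as
#' printed domain annotations sometimes do.
#'
#' @param domain character vector of domain names
#' @param first,last 1-based residue bounds, inclusive
#' @return data.frame of class \code{domain_map}
#' @export
domain_map <- function(domain, first, last) {
  first <- as.integer(first); last <- as.integer(last)
  stopifnot(length(domain) == length(first), length(first) == length(last))
  if (any(first > last)) stop("domain ranges must satisfy first <= last")
  if (any(first < 1L)) stop("residue numbering is 1-based")
  if (anyDuplicated(domain)) stop("duplicate domain names")
  structure(data.frame(domain = as.character(domain), first = first,
                       last = last, stringsAsFactors = FALSE),
            class = c("domain_map", "data.frame"))
}

#' Total chain length implied by a domain map
#' @param map a domain_map
#' @return max(last) over all entries
#' @export
domain_map_length <- function(map) max(map$last)

#' Read a domain map from a 3-column TSV (name, first, last)
#' @param path file path; a header line is optional
#' @return a \code{domain_map}
#' @export
read_domain_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.numeric(df[[2]])) {  # header present
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  }
  domain_map(df[[1]], df[[2]], df[[3]])
}

#' Write a domain map as TSV
#' @param map a domain_map
#' @param path output file
#' @export
write_domain_map <- function(map, path) {
  utils::write.table(data.frame(domain = map$domain, first = map$first,
                                last = map$last),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The FUS full-length domain map
#'
#' Residue ranges of the seven annotated regions of human full-length FUS
#' (526 aa): the prion-like low-complexity domain, three RGG regions, the
#' RNA-recognition motif, the RanBP2-type zinc finger, and the nuclear
#' localization sequence. ZnF and RGG3 share boundary residue 453 as
#' annotated.
#' @return a \code{domain_map}
#' @export
fus_domain_map <- function() {
  path <- system.file("extdata", "fus_domains.tsv", package = "condensekit",
                      mustWork = TRUE)
  read_domain_map(path)
}

#' Map residues to domains
#' @param map a domain_map
#' @param seq_index vector of 1-based residue positions
#' @return character vector of domain names ("unassigned" where no range
#'   covers the residue; the first listed matching range wins on overlap)
#' @export
domain_of <- function(map, seq_index) {
  out <- rep("unassigned", length(seq_index))
  for (k in rev(seq_len(nrow(map)))) {
    hit <- seq_index >= map$first[k] & seq_index <= map$last[k]
    out[hit] <- map$domain[k]
  }
  out
}

# ---- Selections -------------------------------------------------------

#' Select atoms by topology attributes
#'
#' Filters combine with AND. Empty selections warn (they are legal).
#' Selection is deterministic and order-preserving, and commutes with
#' frame slicing since it only touches the topology.
#'
#' @param model a SystemModel
#' @param chain chain id(s), or NULL for all
#' @param res_type residue type(s) (e.g. "ARG"), or NULL
#' @param res_range 1-based \code{c(first, last)} seq_index window, or NULL
#' @param domain domain name(s) resolved through the model's domain map
#' @param component component label(s) (protein/water/Na/Cl/other)
#' @param atom_name atom name(s) (e.g. "CA"), or NULL
#' @param heavy_only drop hydrogens (default FALSE)
#' @return increasing integer vector of atom indices
#' @export
select_atoms <- function(model, chain = NULL, res_type = NULL,
                         res_range = NULL, domain = NULL, component = NULL,
                         atom_name = NULL, heavy_only = FALSE) {
  res <- model$residues
  keep <- rep(TRUE, nrow(res))
  if (!is.null(chain)) {
    if (!all(chain %in% res$chain_id)) stop("unknown chain id")
    keep <- keep & res$chain_id %in% chain
  }
  if (!is.null(res_type)) keep <- keep & toupper(res$res_type) %in%
      toupper(res_type)
  if (!is.null(res_range)) {
    stopifnot(length(res_range) == 2L)
    keep <- keep & res$seq_index >= res_range[1] &
      res$seq_index <= res_range[2]
  }
  if (!is.null(domain)) {
    if (is.null(model$domain_map)) stop("model has no domain map")
    if (!all(domain %in% model$domain_map$domain))
      stop("unknown domain name")
    dom <- domain_of(model$domain_map, res$seq_index)
    keep <- keep & dom %in% domain & res$component == "protein"
  }
  if (!is.null(component)) keep <- keep & res$component %in% component
  rid <- res$res_id[keep]
  idx <- which(model$atoms$res_id %in% rid)
  if (!is.null(atom_name))
    idx <- idx[model$atoms$name[idx] %in% atom_name]
  if (heavy_only) idx <- idx[model$atoms$is_heavy[idx]]
  if (length(idx) == 0L) warning("empty selection")
  idx
}

#' Restrict a model to a frame subset
#' @param model a SystemModel
#' @param frames integer frame indices to keep (in the given order)
#' @return a SystemModel with the sliced trajectory
#' @export
slice_frames <- function(model, frames) {
  stopifnot(all(frames >= 1L), all(frames <= n_frames(model)))
  model$coords <- model$coords[, , frames, drop = FALSE]
  if (!is.null(model$box)) model$box <- model$box[frames, , drop = FALSE]
  if (!is.null(model$times)) model$times <- model$times[frames]
  model
}

# ---- Geometry helpers -------------------------------------------------

#' Minimum-image displacement vectors (orthorhombic box)
#' @param d displacement matrix (n x 3) or vector of length 3
#' @param box box lengths (length 3) or NULL
#' @return wrapped displacements
#' @keywords internal
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  if (is.null(dim(d))) d <- matrix(d, ncol = 3)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Pairwise minimum-image distance between two coordinate sets
#' @keywords internal
pair_dist <- function(a, b, box = NULL) {
  d <- min_image(b - a, box)
  sqrt(rowSums(d * d))
}
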