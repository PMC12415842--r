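# Flat-bottom distance restraints for maintaining native folded domains:
# potential/force evaluation, hydrogen-bond pair derivation from a native
# structure, and a generic tabular export.
#
# The potential is zero on the flat region [r0, r1], harmonic just outside
# it, and linear (bounded force) beyond r2:
#   V(r) = 1/2 k (r - r0)^2                      r <  r0
#        = 0                                     r0 <= r <= r1
#        = 1/2 k (r - r1)^2                      r1 <  r <= r2
#        = 1/2 k (r2 - r1) (2 r - r2 - r1)       r >  r2
# which is the unique C1-continuous completion of the piecewise form; the
# two expressions agree (value and slope) at every knot.

#' Flat-bottom restraint parameters
#'
#' Defaults are the published hydrogen-bond restraint values:
#' k = 20 kcal mol^-1 nm^-2, r0 = 0.27 nm, r1 = 0.3 nm, r2 = 0.35 nm.
#' All lengths in nm; energies in kcal/mol.
#'
#' @param k force constant (kcal mol^-1 nm^-2)
#' @param r0,r1,r2 knot distances in nm, 0 < r0 < r1 < r2
#' @return list of class \code{restraint_params}
#' @export
restraint_params <- function(k = 20, r0 = 0.27, r1 = 0.30, r2 = 0.35) {
  if (!(k > 0 && 0 < r0 && r0 < r1 && r1 < r2))
    stop("require k > 0 and 0 < r0 < r1 < r2")
  structure(list(k = k, r0 = r0, r1 = r1, r2 = r2),
            class = "restraint_params")
}

#' Flat-bottom restraint potential
#' @param r distance(s) in nm, >= 0
#' @param params a \code{\link{restraint_params}}
#' @return energy in kcal/mol (vectorised)
#' @export
flat_bottom_potential <- function(r, params = restraint_params()) {
  stopifnot(all(r >= 0))
  with(params,
    ifelse(r < r0, 0.5 * k * (r - r0)^2,
    ifelse(r <= r1, 0,
    ifelse(r <= r2, 0.5 * k * (r - r1)^2,
           0.5 * k * (r2 - r1) * (2 * r - r2 - r1)))))
}

#' Flat-bottom restraint force magnitude (dV/dr)
#' @param r distance(s) in nm
#' @param params a \code{\link{restraint_params}}
#' @return dV/dr in kcal mol^-1 nm^-1; constant \code{k (r2 - r1)} beyond
#'   r2 (bounded force)
#' @export
flat_bottom_force <- function(r, params = restraint_params()) {
  stopifnot(all(r >= 0))
  with(params,
    ifelse(r < r0, k * (r - r0),
    ifelse(r <= r1, 0,
    ifelse(r <= r2, k * (r - r1), k * (r2 - r1)))))
}

#' Derive hydrogen-bond donor-acceptor restraint pairs from a structure
#'
#' Geometric criterion over N (donor) and O (acceptor) heavy atoms:
#' d(N, O) <= cutoff, donor and acceptor at least two residues apart in
#' sequence (same chain). When hydrogens are present the D-H...A angle
#' must exceed \code{angle_cutoff}; without hydrogens a heavy-atom
#' directionality filter (carbonyl C-O...N angle >= 90 deg) substitutes.
#' Multi-model input keeps pairs present in at least half the models.
#'
#' @param model a SystemModel (all frames are treated as models)
#' @param cutoff donor-acceptor distance cutoff in Angstrom (default 3.5)
#' @param angle_cutoff D-H...A angle cutoff in degrees (default 120)
#' @param scope "backbone" (N and O backbone atoms only) or "all"
#' @param params restraint parameters attached to every pair
#' @return object of class \code{RestraintSet}: data.frame \code{pairs}
#'   (donor, acceptor atom indices, k, r0, r1, r2) plus provenance
#' @export
derive_hbond_pairs <- function(model, cutoff = 3.5, angle_cutoff = 120,
                               scope = c("backbone", "all"),
                               params = restraint_params()) {
  scope <- match.arg(scope)
  at <- model$atoms
  res <- model$residues
  prot_res <- res$res_id[res$component == "protein"]
  in_prot <- at$res_id %in% prot_res
  don <- which(in_prot & toupper(at$element) == "N" &
                 (scope == "all" | at$name == "N"))
  acc <- which(in_prot & toupper(at$element) == "O" &
                 (scope == "all" | at$name == "O"))
  if (length(don) == 0L || length(acc) == 0L) {
    warning("no donor/acceptor candidates")
    return(empty_restraint_set(params))
  }
  hydro <- which(!at$is_heavy)
  has_h <- length(hydro) > 0L
  nf <- n_frames(model)
  tally <- new.env(hash = TRUE)
  for (f in seq_len(nf)) {
    xyz <- model$coords[, , f]
    for (d in don) {
      dd <- pair_dist(matrix(xyz[d, ], length(acc), 3, byrow = TRUE),
                      xyz[acc, , drop = FALSE])
      for (ai in which(dd <= cutoff)) {
        a <- acc[ai]
        rd <- at$res_id[d]; ra <- at$res_id[a]
        if (res$chain_id[rd] == res$chain_id[ra] &&
            abs(res$seq_index[rd] - res$seq_index[ra]) < 2) next
        ok <- TRUE
        if (has_h) {
          # hydrogens bonded to the donor: same residue, within 1.2 A
          hs <- hydro[at$res_id[hydro] == rd]
          hs <- hs[pair_dist(matrix(xyz[d, ], length(hs), 3, byrow = TRUE),
                             xyz[hs, , drop = FALSE]) < 1.2]
          ok <- FALSE
          for (h in hs) {
            v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
            ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
            ang <- acos(max(-1, min(1, ct))) * 180 / pi
            if (ang >= angle_cutoff) { ok <- TRUE; break }
          }
        } else {
          # heavy-atom directionality: carbonyl C of the acceptor
          span <- res$first_atom[ra]:res$last_atom[ra]
          cidx <- span[match("C", at$name[span])]
          if (!is.na(cidx)) {
            v1 <- xyz[cidx, ] - xyz[a, ]; v2 <- xyz[d, ] - xyz[a, ]
            ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
            ok <- acos(max(-1, min(1, ct))) * 180 / pi >= 90
          }
        }
        if (ok) {
          key <- paste(d, a)
          tally[[key]] <- if (is.null(tally[[key]])) 1L else tally[[key]] + 1L
        }
      }
    }
  }
  keys <- ls(tally)
  keep <- keys[vapply(keys, function(k) tally[[k]] >= nf / 2, logical(1))]
  if (length(keep) == 0L) {
    warning("no hydrogen-bond pairs found")
    return(empty_restraint_set(params))
  }
  ij <- do.call(rbind, lapply(strsplit(keep, " "), as.integer))
  ord <- order(ij[, 1], ij[, 2])
  pairs <- data.frame(donor = ij[ord, 1], acceptor = ij[ord, 2],
                      k = params$k, r0 = params$r0, r1 = params$r1,
                      r2 = params$r2)
  structure(list(pairs = pairs,
                 provenance = list(cutoff = cutoff,
                                   angle_cutoff = angle_cutoff,
                                   scope = scope, n_models = nf,
                                   hydrogens_present = has_h)),
            class = "RestraintSet")
}

#' @keywords internal
empty_restraint_set <- function(params) {
  structure(list(pairs = data.frame(donor = integer(0),
                                    acceptor = integer(0),
                                    k = numeric(0), r0 = numeric(0),
                                    r1 = numeric(0), r2 = numeric(0)),
                 provenance = list()),
            class = "RestraintSet")
}

#' @export
print.RestraintSet <- function(x, ...) {
  cat("RestraintSet:", nrow(x$pairs), "donor-acceptor pair(s)\n")
  invisible(x)
}

#' Export a restraint set
#'
#' \code{generic-tsv}: header + one line per pair (donor, acceptor, k, r0,
#' r1, r2; nm and kcal/mol). \code{engine-table}: the same columns without
#' a header, space-separated, for engines that read bare tables. Ordering
#' is deterministic (by donor, then acceptor).
#'
#' @param rset a RestraintSet
#' @param path output file
#' @param dialect "generic-tsv" or "engine-table"
#' @export
export_restraints <- function(rset, path,
                              dialect = c("generic-tsv", "engine-table")) {
  dialect <- match.arg(dialect)
  if (nrow(rset$pairs) == 0L) stop("refusing to export an empty set")
  p <- rset$pairs[order(rset$pairs$donor, rset$pairs$acceptor), ]
  if (dialect == "generic-tsv") {
    utils::write.table(p, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(p, path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a generic-tsv restraint table back into a RestraintSet
#' @param path file written by \code{\link{export_restraints}}
#' @return a RestraintSet
#' @export
read_restraints <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(pairs = p, provenance = list(source = path)),
            class = "RestraintSet")
}
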