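# sp2-plane stacking geometry: the angle-distance pair correlation between
# phenylalanine rings and arginine guanidinium groups, plus zinc
# coordination geometry.
#
# For each F-R pair, r is the distance between the mass-weighted centers of
# the two side-chain heavy-atom groups and theta the angle between the two
# plane normals, folded into [0, 90] degrees. The histogram over (r, theta)
# is corrected by the volume element r^2 sin(theta): each bin is divided by
# the EXACT integral of r^2 sin(theta) over the bin, so bins touching
# theta = 0 stay finite.

.PHE_RING <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
.ARG_GUA <- c("CZ", "NE", "NH1", "NH2")

#' Unit normal of the best-fit plane of a group of atoms
#'
#' The smallest principal axis of the centred coordinates (eigenvector of
#' the covariance with least variance). Sign is arbitrary.
#'
#' @param xyz n x 3 coordinate matrix, n >= 3
#' @return unit 3-vector
#' @export
plane_normal <- function(xyz) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) >= 3)
  cen <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  if (ev$values[2] < 1e-10 * max(ev$values[1], 1e-300))
    stop("collinear atoms: plane undefined")
  ev$vectors[, 3]
}

#' Distance and plane angle of a phenyl/guanidinium pair
#'
#' @param f_xyz phenyl-ring heavy atoms (n x 3)
#' @param r_xyz guanidinium heavy atoms (n x 3)
#' @param f_mass,r_mass atom masses for the centers of mass (default equal)
#' @param box orthorhombic box lengths for minimum image, or NULL
#' @return c(r = Angstrom, theta = degrees in [0, 90])
#' @export
pair_geometry <- function(f_xyz, r_xyz, f_mass = NULL, r_mass = NULL,
                          box = NULL) {
  com <- function(x, m) {
    if (is.null(m)) colMeans(x) else colSums(x * m) / sum(m)
  }
  d <- min_image(com(r_xyz, r_mass) - com(f_xyz, f_mass), box)
  r <- sqrt(sum(d * d))
  n1 <- plane_normal(f_xyz)
  n2 <- plane_normal(r_xyz)
  ct <- abs(sum(n1 * n2))  # fold into [0, 90] (normal sign is arbitrary)
  theta <- acos(min(1, ct)) * 180 / pi
  c(r = r, theta = theta)
}

#' Bin (r, theta) samples into a corrected stacking histogram
#'
#' Lower-level workhorse behind \code{\link{accumulate_g}}; also usable on
#' externally computed pair samples (e.g. for null-model simulations).
#'
#' @param r,theta equal-length samples (Angstrom, degrees)
#' @param r_max histogram range (default 12 A)
#' @param r_bin,theta_bin bin widths (defaults 0.6 A and 2.5 deg)
#' @param n_frames frame count used for normalisation
#' @param rescale scale g so its mean over sampled bins is 1 (default TRUE)
#' @return object of class \code{StackingHistogram}: r_edges, theta_edges,
#'   counts, g (both n_r x n_theta), bin_volume, n_pairs, n_frames
#' @export
stacking_histogram <- function(r, theta, r_max = 12, r_bin = 0.6,
                               theta_bin = 2.5, n_frames = 1L,
                               rescale = TRUE) {
  stopifnot(length(r) == length(theta))
  r_edges <- seq(0, r_max, by = r_bin)
  theta_edges <- seq(0, 90, by = theta_bin)
  keep <- r < r_max & theta <= 90
  ri <- findInterval(r[keep], r_edges, rightmost.closed = TRUE)
  ti <- findInterval(theta[keep], theta_edges, rightmost.closed = TRUE)
  nr <- length(r_edges) - 1L
  nt <- length(theta_edges) - 1L
  counts <- matrix(0, nr, nt)
  if (any(keep)) {
    tab <- table(factor(ri, levels = seq_len(nr)),
                 factor(ti, levels = seq_len(nt)))
    counts <- matrix(as.numeric(tab), nr, nt)
  }
  # exact integral of r^2 sin(theta) dr dtheta over each bin:
  # [ (r2^3 - r1^3)/3 ] * [ cos(t1) - cos(t2) ]
  dr3 <- diff(r_edges^3) / 3
  dcos <- -diff(cos(theta_edges * pi / 180))
  bin_volume <- outer(dr3, dcos)
  g <- counts / (n_frames * bin_volume)
  if (rescale && any(counts > 0)) g <- g / mean(g[counts > 0])
  structure(list(r_edges = r_edges, theta_edges = theta_edges,
                 counts = counts, g = g, bin_volume = bin_volume,
                 n_pairs = sum(counts), n_frames = n_frames),
            class = "StackingHistogram")
}

#' @export
print.StackingHistogram <- function(x, ...) {
  cat("StackingHistogram:", nrow(x$counts), "x", ncol(x$counts),
      "bins,", x$n_pairs, "pairs over", x$n_frames, "frame(s)\n")
  if (x$n_pairs > 0) {
    mx <- which(x$g == max(x$g), arr.ind = TRUE)[1, ]
    cat(sprintf("  g mode at r = %.2f A, theta = %.2f deg\n",
                mean(x$r_edges[mx[1] + 0:1]),
                mean(x$theta_edges[mx[2] + 0:1])))
  }
  invisible(x)
}

#' Locate phenyl-ring and guanidinium groups in a topology
#' @keywords internal
find_sp2_groups <- function(model) {
  res <- model$residues
  grab <- function(rtype, names_wanted) {
    rid <- res$res_id[res$res_type == rtype & res$component == "protein"]
    out <- list()
    for (id in rid) {
      span <- res$first_atom[res$res_id == id]:res$last_atom[res$res_id == id]
      idx <- span[match(names_wanted, model$atoms$name[span])]
      if (anyNA(idx)) next
      out[[length(out) + 1L]] <- list(res_id = id, atoms = idx,
                                      mass = model$atoms$mass[idx],
                                      chain = res$chain_id[res$res_id == id])
    }
    out
  }
  list(F = grab("PHE", .PHE_RING), R = grab("ARG", .ARG_GUA))
}

#' Accumulate the F-R angle-distance pair correlation over a trajectory
#'
#' All phenylalanine-arginine group pairs within \code{r_max} contribute,
#' over all requested frames. See \code{\link{stacking_histogram}} for the
#' geometric correction.
#'
#' @param model a SystemModel
#' @param frames frame indices (default all)
#' @param r_max,r_bin,theta_bin histogram geometry
#' @param intermolecular_only drop same-chain F-R pairs (default FALSE)
#' @param rescale normalise mean g over sampled bins to 1
#' @return a \code{StackingHistogram}
#' @export
accumulate_g <- function(model, frames = seq_len(n_frames(model)),
                         r_max = 12, r_bin = 0.6, theta_bin = 2.5,
                         intermolecular_only = FALSE, rescale = TRUE) {
  grp <- find_sp2_groups(model)
  if (length(grp$F) == 0L || length(grp$R) == 0L) {
    warning("no resolvable PHE ring / ARG guanidinium groups")
    return(stacking_histogram(numeric(0), numeric(0), r_max, r_bin,
                              theta_bin, n_frames = length(frames)))
  }
  rs <- numeric(0); ts <- numeric(0)
  for (f in frames) {
    xyz <- model$coords[, , f]
    box <- if (is.null(model$box)) NULL else model$box[f, ]
    for (gf in grp$F) for (gr in grp$R) {
      if (intermolecular_only && gf$chain == gr$chain) next
      gt <- pair_geometry(xyz[gf$atoms, , drop = FALSE],
                          xyz[gr$atoms, , drop = FALSE],
                          gf$mass, gr$mass, box)
      rs <- c(rs, gt["r"]); ts <- c(ts, gt["theta"])
    }
  }
  stacking_histogram(rs, ts, r_max, r_bin, theta_bin,
                     n_frames = length(frames), rescale = rescale)
}

#' Write a stacking histogram as TSV (r_center, theta_center, count, g)
#' @param h a StackingHistogram
#' @param path output file
#' @export
write_stacking_histogram <- function(h, path) {
  rc <- (h$r_edges[-1] + h$r_edges[-length(h$r_edges)]) / 2
  tc <- (h$theta_edges[-1] + h$theta_edges[-length(h$theta_edges)]) / 2
  df <- expand.grid(r_center = rc, theta_center = tc)
  df$count <- as.vector(h$counts)
  df$g <- as.vector(h$g)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- Zinc coordination ------------------------------------------------

#' Zinc-sulfur coordination geometry
#'
#' Per-frame Zn-SG distances and Zn-SG-CB angles for each cysteine, for
#' monitoring whether a zinc ion stays bound to its cysteine tetrad.
#'
#' @param model a SystemModel
#' @param zn_atom atom index of the zinc (default: the single ZN atom)
#' @param cys_res_ids residue ids of the cysteines (default: all CYS)
#' @return object of class \code{CoordinationReport}: \code{distances} and
#'   \code{angles} matrices (frame x cysteine) plus a \code{summary}
#'   data.frame (min/mean/max per cysteine)
#' @export
coordination_geometry <- function(model, zn_atom = NULL,
                                  cys_res_ids = NULL) {
  if (is.null(zn_atom)) {
    zn_atom <- which(toupper(model$atoms$element) == "ZN")
    if (length(zn_atom) != 1L)
      stop("expected exactly one Zn atom, found ", length(zn_atom))
  }
  res <- model$residues
  if (is.null(cys_res_ids))
    cys_res_ids <- res$res_id[res$res_type == "CYS"]
  if (length(cys_res_ids) == 0L) stop("no cysteine residues")
  sg <- cb <- integer(0); keep <- integer(0)
  for (id in cys_res_ids) {
    span <- res$first_atom[res$res_id == id]:res$last_atom[res$res_id == id]
    s <- span[match("SG", model$atoms$name[span])]
    b <- span[match("CB", model$atoms$name[span])]
    if (is.na(s) || is.na(b)) {
      warning("cysteine res_id ", id, " lacks SG/CB; skipped")
      next
    }
    sg <- c(sg, s); cb <- c(cb, b); keep <- c(keep, id)
  }
  if (length(keep) == 0L) stop("no usable cysteines")
  nf <- n_frames(model)
  distances <- matrix(NA_real_, nf, length(keep))
  angles <- matrix(NA_real_, nf, length(keep))
  for (f in seq_len(nf)) {
    xyz <- model$coords[, , f]
    box <- if (is.null(model$box)) NULL else model$box[f, ]
    for (k in seq_along(keep)) {
      v1 <- as.numeric(min_image(xyz[zn_atom, ] - xyz[sg[k], ], box))
      v2 <- as.numeric(min_image(xyz[cb[k], ] - xyz[sg[k], ], box))
      distances[f, k] <- sqrt(sum(v1^2))
      ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      angles[f, k] <- acos(max(-1, min(1, ct))) * 180 / pi
    }
  }
  colnames(distances) <- colnames(angles) <- paste0("CYS", keep)
  summary <- data.frame(
    res_id = keep,
    d_min = apply(distances, 2, min), d_mean = colMeans(distances),
    d_max = apply(distances, 2, max),
    ang_min = apply(angles, 2, min), ang_mean = colMeans(angles),
    ang_max = apply(angles, 2, max))
  structure(list(distances = distances, angles = angles,
                 summary = summary),
            class = "CoordinationReport")
}
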