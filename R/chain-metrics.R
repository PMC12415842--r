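# Chain-dimension and stability metrics: Rg, end-to-end distance,
# autocorrelation / equilibration, Kabsch RMSD, RMSF.

#' Radius of gyration of a selection in one frame
#'
#' \code{Rg = sqrt( sum m_i |x_i - x_com|^2 / sum m_i )}. Mass-weighted by
#' default, matching standard polymer-statistics tools.
#'
#' @param model a SystemModel
#' @param frame frame index
#' @param selection atom indices (default: all atoms)
#' @param mass_weighted use atomic masses (default TRUE)
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(model, frame,
                               selection = seq_len(nrow(model$atoms)),
                               mass_weighted = TRUE) {
  stopifnot(length(selection) >= 2L)
  xyz <- model$coords[selection, , frame, drop = FALSE]
  m <- if (mass_weighted) model$atoms$mass[selection]
       else rep(1, length(selection))
  com <- colSums(xyz * m) / sum(m)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' End-to-end distance of a chain in one frame
#'
#' Distance between the CA atoms of the chain's first and last residues.
#'
#' @param model a SystemModel
#' @param frame frame index
#' @param chain chain id (default: first protein chain)
#' @return distance in Angstrom
#' @export
end_to_end <- function(model, frame, chain = NULL) {
  res <- model$residues
  prot <- res[res$component == "protein", ]
  if (is.null(chain)) chain <- prot$chain_id[1]
  rc <- prot[prot$chain_id == chain, ]
  if (nrow(rc) < 2L) stop("chain has fewer than 2 residues")
  ca_of <- function(row) {
    span <- row$first_atom:row$last_atom
    i <- span[match("CA", model$atoms$name[span])]
    if (is.na(i)) stop("terminal residue lacks a CA atom")
    i
  }
  a <- ca_of(rc[1, ]); b <- ca_of(rc[nrow(rc), ])
  sqrt(sum((model$coords[b, , frame] - model$coords[a, , frame])^2))
}

#' Normalised autocorrelation function and integrated autocorrelation time
#'
#' Mean-removed, variance-normalised ACF. The integrated autocorrelation
#' time uses the self-consistent window of Sokal: the smallest W with
#' \code{W >= c * tau(W)} where \code{tau(W) = 1 + 2 sum_{k<=W} acf(k)}
#' (default c = 5). Also suggests an equilibration cut: the smallest
#' prefix (on a 5\% grid) whose removal brings the running mean within one
#' standard deviation of the second-half mean.
#'
#' @param series numeric vector
#' @param max_lag largest lag (default \code{length(series) - 1},
#'   capped at 10000)
#' @param c_sokal window constant (default 5)
#' @return list(acf, act, window, equilibration_frames)
#' @export
autocorrelation <- function(series, max_lag = NULL, c_sokal = 5) {
  n <- length(series)
  if (is.null(max_lag)) max_lag <- min(n - 1L, 10000L)
  stopifnot(n > max_lag)
  v <- stats::var(series) * (n - 1) / n
  if (v < .Machine$double.eps * max(1, mean(series)^2)) {
    warning("constant series: ACF defined as 1 at lag 0, 0 elsewhere")
    return(list(acf = c(1, rep(0, max_lag)), act = 1, window = 0L,
                equilibration_frames = 0L))
  }
  rho <- as.numeric(stats::acf(series, lag.max = max_lag,
                               plot = FALSE, demean = TRUE)$acf)
  tau <- 1 + 2 * cumsum(rho[-1])
  W <- which(seq_along(tau) >= c_sokal * tau)[1]
  if (is.na(W)) W <- length(tau)
  act <- max(tau[W], 1)
  half <- series[seq(floor(n / 2), n)]
  mu2 <- mean(half); sd2 <- stats::sd(half)
  eq <- 0L
  for (fr in seq(0, 0.5, by = 0.05)) {
    k <- floor(fr * n)
    if (abs(mean(series[(k + 1):n]) - mu2) <= sd2) { eq <- k; break }
  }
  list(acf = rho, act = act, window = W, equilibration_frames = eq)
}

#' Per-frame Rg and end-to-end series with equilibration diagnostics
#'
#' Chains are made whole across periodic boundaries before measuring.
#'
#' @param model a SystemModel
#' @param chain chain id (default first protein chain)
#' @param mass_weighted for Rg
#' @return object of class \code{DimensionSeries}: data.frame
#'   \code{series} (frame, rg, dee), summary means/sds, and (when the
#'   trajectory is long enough) ACF and ACT for both observables
#' @export
dimension_series <- function(model, chain = NULL, mass_weighted = TRUE) {
  res <- model$residues
  prot <- res[res$component == "protein", ]
  if (is.null(chain)) chain <- prot$chain_id[1]
  sel <- select_atoms(model, chain = chain, component = "protein")
  nf <- n_frames(model)
  rg <- dee <- numeric(nf)
  m2 <- model
  for (f in seq_len(nf)) {
    if (!is.null(model$box))
      m2$coords[, , f] <- unwrap_chains(model, f)
    rg[f] <- radius_of_gyration(m2, f, sel, mass_weighted)
    dee[f] <- end_to_end(m2, f, chain)
  }
  out <- list(series = data.frame(frame = seq_len(nf), rg = rg, dee = dee),
              rg_mean = mean(rg), rg_sd = stats::sd(rg),
              dee_mean = mean(dee), dee_sd = stats::sd(dee))
  if (nf >= 10L) {
    out$rg_acf <- autocorrelation(rg)
    out$dee_acf <- autocorrelation(dee)
  }
  structure(out, class = "DimensionSeries")
}

#' Make chains whole across periodic boundaries
#'
#' Bonded-neighbour walk along each chain: every residue is shifted by box
#' vectors so its CA (or first atom) lies within half a box of the
#' previous residue's, and atoms are kept whole about their residue
#' anchor. No-op without a box.
#'
#' @param model a SystemModel
#' @param frame frame index
#' @return n_atoms x 3 unwrapped coordinate matrix
#' @export
unwrap_chains <- function(model, frame) {
  xyz <- model$coords[, , frame]
  if (is.null(model$box)) return(xyz)
  box <- model$box[frame, ]
  res <- model$residues
  for (ch in unique(res$chain_id[res$component == "protein"])) {
    rc <- res[res$chain_id == ch & res$component == "protein", ]
    anchor_prev <- NULL
    for (k in seq_len(nrow(rc))) {
      span <- rc$first_atom[k]:rc$last_atom[k]
      ca <- span[match("CA", model$atoms$name[span])]
      if (is.na(ca)) ca <- span[1]
      # keep atoms whole about the residue anchor
      d <- sweep(xyz[span, , drop = FALSE], 2, xyz[ca, ])
      shift <- -round(sweep(d, 2, box, "/")) %*% diag(box)
      xyz[span, ] <- xyz[span, , drop = FALSE] + shift
      if (!is.null(anchor_prev)) {
        dv <- xyz[ca, ] - anchor_prev
        sh <- -round(dv / box) * box
        if (any(sh != 0))
          xyz[span, ] <- sweep(xyz[span, , drop = FALSE], 2, sh, "+")
      }
      anchor_prev <- xyz[ca, ]
    }
  }
  xyz
}

# ---- Kabsch superposition, RMSD, RMSF ---------------------------------

#' Optimal (proper) rotation superposing x onto y
#' @param x,y n x 3 matrices (n >= 3), already centred
#' @return 3 x 3 rotation matrix R such that x %*% R approximates y
#' @keywords internal
kabsch_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' RMSD after least-squares superposition
#'
#' The frame is superposed on the reference using the fit selection
#' (proper rotations only; mirror images are not matched), then RMSD is
#' measured over the measure selection.
#'
#' @param frame_xyz,ref_xyz full coordinate matrices with matching rows
#' @param fit atom indices used for the superposition (>= 3)
#' @param measure atom indices for the RMSD (default: the fit set)
#' @return RMSD in Angstrom
#' @export
kabsch_rmsd <- function(frame_xyz, ref_xyz, fit, measure = fit) {
  stopifnot(length(fit) >= 3L, nrow(frame_xyz) == nrow(ref_xyz))
  cx <- colMeans(frame_xyz[fit, , drop = FALSE])
  cy <- colMeans(ref_xyz[fit, , drop = FALSE])
  R <- kabsch_rotation(sweep(frame_xyz[fit, , drop = FALSE], 2, cx),
                       sweep(ref_xyz[fit, , drop = FALSE], 2, cy))
  moved <- sweep(sweep(frame_xyz, 2, cx) %*% R, 2, cy, "+")
  d <- moved[measure, , drop = FALSE] - ref_xyz[measure, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}

#' Per-frame RMSD of a selection against a reference structure
#'
#' @param model a SystemModel
#' @param ref_xyz reference coordinates (n_atoms x 3, same topology) or a
#'   frame index into the model
#' @param fit fit selection (e.g. domain CA atoms)
#' @param measure measure selection (default: fit)
#' @return numeric vector, one RMSD per frame
#' @export
rmsd_series <- function(model, ref_xyz, fit, measure = fit) {
  if (length(ref_xyz) == 1L) ref_xyz <- model$coords[, , ref_xyz]
  vapply(seq_len(n_frames(model)), function(f)
    kabsch_rmsd(model$coords[, , f], ref_xyz, fit, measure), numeric(1))
}

#' Root-mean-square fluctuation about the mean structure
#'
#' All frames are superposed on their mean structure (the mean is refined
#' by a second superposition pass), then
#' \code{RMSF_i = sqrt(mean_f |x_i(f) - <x_i>|^2)} per selected atom.
#'
#' @param model a SystemModel (>= 2 frames)
#' @param selection atom indices to measure (typically domain CA atoms)
#' @param fit atom indices (relative to \code{selection}) used for the
#'   superposition; default all of them
#' @return named numeric vector of per-atom RMSF (Angstrom)
#' @export
rmsf <- function(model, selection, fit = seq_along(selection)) {
  nf <- n_frames(model)
  stopifnot(nf >= 2L, length(fit) >= 3L)
  sub <- model$coords[selection, , , drop = FALSE]
  aligned <- sub
  ref <- sub[, , 1]
  for (pass in 1:2) {
    refc <- sweep(ref, 2, colMeans(ref[fit, , drop = FALSE]))
    for (f in seq_len(nf)) {
      x <- sub[, , f]
      xc <- sweep(x, 2, colMeans(x[fit, , drop = FALSE]))
      R <- kabsch_rotation(xc[fit, , drop = FALSE],
                           refc[fit, , drop = FALSE])
      aligned[, , f] <- xc %*% R
    }
    ref <- apply(aligned, c(1, 2), mean)
  }
  mean_xyz <- apply(aligned, c(1, 2), mean)
  dev2 <- apply((aligned - array(mean_xyz, dim(aligned)))^2, c(1, 3), sum)
  out <- sqrt(rowMeans(dev2))
  names(out) <- model$atoms$name[selection]
  out
}
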