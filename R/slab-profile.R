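# Slab-geometry condensed-phase analysis: per-component density and molar
# concentration profiles along z, dense/dilute phase assignment, and the
# electroneutrality-based prediction of small-ion partitioning.

# amu / A^3  ->  mg/mL (= g/L = kg/m^3): 1 amu/A^3 = 1.66053907e3 kg/m^3
.AMU_PER_A3_TO_MG_ML <- 1.66053907e3
# count / A^3 -> mM: (n / (N_A * V_L)) * 1e3 with V_L = V_A3 * 1e-27
.COUNT_PER_A3_TO_MM <- 1e30 / 6.02214076e23  # = 1.66054e6 mM per (1/A^3)

#' Per-component density and concentration profiles along z
#'
#' Each frame is recentred so the protein centre of mass sits at the box
#' z-midpoint (removes slab drift), coordinates are wrapped into the box,
#' and atom masses are binned. Mass densities are in mg/mL; ion and water
#' number concentrations in mM.
#'
#' @param model a SystemModel with a box
#' @param frames frame indices (default all)
#' @param bin_width z bin width in Angstrom (default 2.5)
#' @param recenter recentre on the protein COM each frame (default TRUE)
#' @param his_charged count histidine as cationic (default FALSE)
#' @return object of class \code{DensityProfile}: \code{z_centers},
#'   \code{mass} (bins x components, mg/mL), \code{molar} (bins x species,
#'   mM: water, Na, Cl, cationic, anionic), bin volume and frame range
#' @export
density_profile <- function(model, frames = seq_len(n_frames(model)),
                            bin_width = 2.5, recenter = TRUE,
                            his_charged = FALSE) {
  if (is.null(model$box)) stop("density profile requires a periodic box")
  box <- model$box[frames[1], ]
  lz <- box[3]
  edges <- seq(0, lz, by = bin_width)
  if (abs(edges[length(edges)] - lz) > 1e-9) edges <- c(edges, lz)
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin_vol <- box[1] * box[2] * diff(edges)

  res <- model$residues
  comp_atom <- res$component[model$atoms$res_id]
  mass <- model$atoms$mass
  prot <- comp_atom == "protein"
  rtype_atom <- res$res_type[model$atoms$res_id]
  is_ca <- model$atoms$name == "CA"
  cat_atoms <- which(prot & is_ca &
                       residue_charge(rtype_atom, his_charged) > 0)
  an_atoms <- which(prot & is_ca & residue_charge(rtype_atom) < 0)

  comps <- c("protein", "water", "Na", "Cl", "other")
  mass_acc <- matrix(0, nb, length(comps), dimnames = list(NULL, comps))
  species <- c("water", "Na", "Cl", "cationic", "anionic")
  count_acc <- matrix(0, nb, length(species),
                      dimnames = list(NULL, species))

  for (f in frames) {
    z <- model$coords[, 3, f]
    if (recenter) {
      com_z <- sum(z[prot] * mass[prot]) / sum(mass[prot])
      z <- z - com_z + lz / 2
    }
    z <- z - lz * floor(z / lz)  # wrap into [0, lz)
    bi <- pmin(findInterval(z, edges, rightmost.closed = TRUE), nb)
    for (cc in comps) {
      sel <- comp_atom == cc
      if (!any(sel)) next
      mass_acc[, cc] <- mass_acc[, cc] +
        as.numeric(tapply(mass[sel], factor(bi[sel], levels = 1:nb), sum,
                          default = 0))
    }
    cnt <- function(sel) as.numeric(table(factor(bi[sel], levels = 1:nb)))
    count_acc[, "water"] <- count_acc[, "water"] + cnt(comp_atom == "water")
    count_acc[, "Na"] <- count_acc[, "Na"] + cnt(comp_atom == "Na")
    count_acc[, "Cl"] <- count_acc[, "Cl"] + cnt(comp_atom == "Cl")
    count_acc[, "cationic"] <- count_acc[, "cationic"] +
      cnt(seq_along(z) %in% cat_atoms)
    count_acc[, "anionic"] <- count_acc[, "anionic"] +
      cnt(seq_along(z) %in% an_atoms)
  }
  nf <- length(frames)
  mass_dens <- mass_acc / nf / bin_vol * .AMU_PER_A3_TO_MG_ML
  molar <- count_acc / nf / bin_vol * .COUNT_PER_A3_TO_MM
  structure(list(z_centers = centers, z_edges = edges,
                 mass = mass_dens, molar = molar,
                 bin_volume = bin_vol, box = box, n_frames = nf,
                 frames = frames),
            class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat("DensityProfile:", length(x$z_centers), "bins of",
      format(diff(x$z_edges[1:2]), digits = 3), "A over",
      x$n_frames, "frame(s)\n")
  cat("  peak protein density:",
      format(max(x$mass[, "protein"]), digits = 4), "mg/mL\n")
  invisible(x)
}

#' Assign dense and dilute phases from a protein density profile
#'
#' The dense phase is the largest contiguous run of bins (with periodic
#' wrap) whose protein density is at least \code{threshold} times the
#' plateau (the mean of the top decile of smoothed bins).
#'
#' @param profile a \code{\link{density_profile}} result
#' @param threshold fraction of the plateau (default 0.5)
#' @return list(dense_z = c(lo, hi) interval in Angstrom or NULL,
#'   dense_bins, protein_mg_ml, water_mg_ml, na_mM, cl_mM) — dense-phase
#'   means; NULL interval means no dense phase
#' @export
assign_phases <- function(profile, threshold = 0.5) {
  p <- profile$mass[, "protein"]
  nb <- length(p)
  sm <- as.numeric(stats::filter(c(p[nb], p, p[1]), rep(1 / 3, 3)))[2:(nb + 1)]
  plateau <- mean(sort(sm, decreasing = TRUE)[seq_len(max(1, nb %/% 10))])
  if (plateau <= 0) return(list(dense_z = NULL, dense_bins = integer(0)))
  above <- sm >= threshold * plateau
  if (!any(above)) return(list(dense_z = NULL, dense_bins = integer(0)))
  if (all(above)) {
    runs <- list(seq_len(nb))
  } else {
    # longest circular run of TRUE
    idx <- rep(above, 2)
    best <- integer(0); cur <- integer(0)
    for (k in seq_len(2 * nb)) {
      if (idx[k]) cur <- c(cur, k) else cur <- integer(0)
      if (length(cur) > length(best) && length(cur) <= nb) best <- cur
    }
    runs <- list((best - 1L) %% nb + 1L)
  }
  dense <- runs[[1]]
  list(dense_z = range(profile$z_centers[dense]),
       dense_bins = dense,
       protein_mg_ml = mean(profile$mass[dense, "protein"]),
       water_mg_ml = mean(profile$mass[dense, "water"]),
       na_mM = mean(profile$molar[dense, "Na"]),
       cl_mM = mean(profile$molar[dense, "Cl"]))
}

#' Predict local ion concentrations from electroneutrality
#'
#' Donnan-style closure: fixed protein charges inside the condensate must
#' be neutralised by the mobile ions, so
#' \code{Na(z) = bulk + c_anionic(z)} and
#' \code{Cl(z) = bulk + c_cationic(z)}; the difference Cl - Na equals the
#' local fixed-charge concentration identically.
#'
#' @param profile a \code{\link{density_profile}} result (its
#'   cationic/anionic residue concentrations are the inputs)
#' @param bulk_salt_mM bulk salt concentration
#' @return object of class \code{IonPartitionPrediction}: data.frame
#'   (z_center, cationic_mM, anionic_mM, predicted_Na, predicted_Cl)
#' @export
predict_ion_partition <- function(profile, bulk_salt_mM) {
  c_cat <- profile$molar[, "cationic"]
  c_an <- profile$molar[, "anionic"]
  out <- data.frame(z_center = profile$z_centers,
                    cationic_mM = c_cat, anionic_mM = c_an,
                    predicted_Na = bulk_salt_mM + c_an,
                    predicted_Cl = bulk_salt_mM + c_cat)
  structure(out, class = c("IonPartitionPrediction", "data.frame"))
}

#' Write a density profile (+ optional ion prediction) as TSV
#' @param profile a DensityProfile
#' @param path output file
#' @param prediction optional \code{\link{predict_ion_partition}} result
#' @export
write_density_profile <- function(profile, path, prediction = NULL) {
  df <- data.frame(z_center = profile$z_centers)
  for (cc in colnames(profile$mass))
    df[[paste0(cc, "_mg_ml")]] <- profile$mass[, cc]
  for (sp in colnames(profile$molar))
    df[[paste0(sp, "_mM")]] <- profile$molar[, sp]
  if (!is.null(prediction)) {
    df$predicted_Na_mM <- prediction$predicted_Na
    df$predicted_Cl_mM <- prediction$predicted_Cl
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
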