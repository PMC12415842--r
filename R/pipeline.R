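# Orchestration: the two standard report bundles (single-chain ensemble,
# slab condensate) with JSON manifests, plus a small subcommand CLI.

#' Run configuration for the report pipelines
#'
#' Defaults are the analysis parameters used throughout: 4.5 A contact
#' cutoff with a 4-residue exclusion window, 0.6 A / 2.5 deg stacking
#' bins, 2.5 A slab bins, and an equilibration policy of dropping the
#' first 20\% of frames unless an explicit frame count is given.
#'
#' @param contact_cutoff,contact_exclusion contact stage parameters
#' @param r_max,r_bin,theta_bin stacking histogram geometry
#' @param slab_bin slab profile bin width (Angstrom)
#' @param phase_threshold dense-phase threshold fraction
#' @param bulk_salt_mM bulk salt concentration for ion prediction
#' @param equilibration_frames frames to drop, or NULL for the 20\% rule
#' @param stages character vector of stage names to run (default all)
#' @param seed integer recorded in the manifest
#' @return list of class \code{run_config}
#' @export
run_config <- function(contact_cutoff = 4.5, contact_exclusion = 4L,
                       r_max = 12, r_bin = 0.6, theta_bin = 2.5,
                       slab_bin = 2.5, phase_threshold = 0.5,
                       bulk_salt_mM = 150,
                       equilibration_frames = NULL,
                       stages = c("dimensions", "contacts", "ratios",
                                  "stacking", "slab", "zinc"),
                       seed = 1L) {
  structure(list(contact_cutoff = contact_cutoff,
                 contact_exclusion = as.integer(contact_exclusion),
                 r_max = r_max, r_bin = r_bin, theta_bin = theta_bin,
                 slab_bin = slab_bin, phase_threshold = phase_threshold,
                 bulk_salt_mM = bulk_salt_mM,
                 equilibration_frames = equilibration_frames,
                 stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

#' @keywords internal
production_frames <- function(model, config) {
  nf <- n_frames(model)
  drop <- config$equilibration_frames %||% floor(0.2 * nf)
  if (drop >= nf) stop("equilibration cut leaves no frames")
  (drop + 1L):nf
}

#' @keywords internal
write_manifest <- function(out_dir, config, extra = list()) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  checksums <- vapply(files, function(f)
    unname(tools::md5sum(file.path(out_dir, f))), character(1))
  manifest <- c(list(
    package = "condensekit",
    version = as.character(utils::packageVersion("condensekit")),
    config = unclass(config),
    outputs = as.list(checksums)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Single-chain ensemble report
#'
#' For one or more replicas of the same topology: per-replica and pooled
#' Rg/end-to-end/Rh statistics with ACF-based equilibration diagnostics,
#' contact map + per-position profile + domain blocks, residue-type
#' contact ratio table, per-folded-domain RMSD/RMSF, and zinc geometry
#' when a Zn atom is present. TSV/JSON outputs plus a manifest land in
#' \code{out_dir}.
#'
#' @param models a SystemModel or list of replicas (matching topologies)
#' @param out_dir output directory (created)
#' @param config a \code{\link{run_config}}
#' @param rigid_domains domain names for RMSD/RMSF (default: none)
#' @return list with all computed objects, invisibly
#' @export
run_single_chain_report <- function(models, out_dir,
                                    config = run_config(),
                                    rigid_domains = character(0)) {
  if (inherits(models, "SystemModel")) models <- list(models)
  sig <- lapply(models, function(m)
    paste(m$atoms$name, m$atoms$res_id, collapse = " "))
  if (length(unique(unlist(sig))) != 1L)
    stop("replicas have mismatched topologies")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- contact_params(config$contact_cutoff, config$contact_exclusion)
  out <- list(replicas = list())
  pooled_cm <- NULL
  for (ri in seq_along(models)) {
    model <- models[[ri]]
    frames <- production_frames(model, config)
    rep_out <- list(frames = frames)
    if ("dimensions" %in% config$stages) {
      dims <- dimension_series(slice_frames(model, frames))
      rh <- hullrad_series(slice_frames(model, frames))
      rep_out$dimensions <- dims
      rep_out$rh_mean <- mean(rh$rh)
      utils::write.table(cbind(dims$series, rh = rh$rh),
                         file.path(out_dir, sprintf("dimensions_rep%d.tsv",
                                                    ri)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("contacts" %in% config$stages) {
      cm <- ensemble_contact_map(model, frames, params)
      rep_out$contact_map <- cm
      pooled_cm <- if (is.null(pooled_cm)) cm$total * length(frames)
                   else pooled_cm + cm$total * length(frames)
    }
    if (length(rigid_domains) > 0 && !is.null(model$domain_map)) {
      stab <- list()
      for (dn in rigid_domains) {
        ca <- select_atoms(model, domain = dn, atom_name = "CA")
        if (length(ca) < 3L) next
        stab[[dn]] <- list(
          rmsd = rmsd_series(slice_frames(model, frames),
                             model$coords[, , frames[1]], ca),
          rmsf = rmsf(slice_frames(model, frames), ca))
      }
      rep_out$stability <- stab
    }
    if ("zinc" %in% config$stages &&
        any(toupper(model$atoms$element) == "ZN"))
      rep_out$zinc <- coordination_geometry(slice_frames(model, frames))
    out$replicas[[ri]] <- rep_out
  }
  if ("contacts" %in% config$stages) {
    n_tot <- sum(vapply(out$replicas, function(r) length(r$frames),
                        numeric(1)))
    pooled <- pooled_cm / n_tot
    out$pooled_contact_profile <- position_profile(pooled)
    cm1 <- out$replicas[[1]]$contact_map
    pooled_cm_obj <- cm1
    pooled_cm_obj$total <- pooled
    out$pooled_contact_map <- pooled_cm_obj
    write_contact_map(pooled_cm_obj, file.path(out_dir,
                                               "contact_map_pooled.tsv"))
    if ("ratios" %in% config$stages) {
      out$ratio_table <- pair_ratio_table(pooled_cm_obj)
      utils::write.table(out$ratio_table$pairs,
                         file.path(out_dir, "pair_ratios.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(models[[1]]$domain_map))
      out$domain_blocks <- domain_block_map(pooled_cm_obj,
                                            models[[1]]$domain_map)
  }
  write_manifest(out_dir, config,
                 list(kind = "single_chain",
                      n_replicas = length(models)))
  invisible(out)
}

#' Slab condensate report
#'
#' Density profiles with phase assignment and ion-partition prediction,
#' intra/intermolecular contact maps averaged over chains, the F-R
#' stacking pair correlation, per-chain Rg/end-to-end series, and (when a
#' single-chain ratio table is supplied) the dilute-vs-dense contact
#' correlation.
#'
#' @param model a slab SystemModel with a box
#' @param out_dir output directory
#' @param config a \code{\link{run_config}}
#' @param single_chain_ratios optional PairRatioTable from
#'   \code{\link{run_single_chain_report}}
#' @return list with all computed objects, invisibly
#' @export
run_slab_report <- function(model, out_dir, config = run_config(),
                            single_chain_ratios = NULL) {
  if (is.null(model$box)) stop("slab report requires a periodic box")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  frames <- production_frames(model, config)
  params <- contact_params(config$contact_cutoff, config$contact_exclusion)
  out <- list(frames = frames)
  if ("slab" %in% config$stages) {
    prof <- density_profile(model, frames, bin_width = config$slab_bin)
    out$profile <- prof
    out$phases <- assign_phases(prof, config$phase_threshold)
    out$ion_prediction <- predict_ion_partition(prof, config$bulk_salt_mM)
    write_density_profile(prof, file.path(out_dir, "density_profile.tsv"),
                          out$ion_prediction)
  }
  if ("contacts" %in% config$stages) {
    cm <- ensemble_contact_map(model, frames, params)
    out$contact_map <- cm
    write_contact_map(cm, file.path(out_dir, "contact_map_total.tsv"))
    write_contact_map(cm, file.path(out_dir, "contact_map_inter.tsv"),
                      channel = "inter")
    if ("ratios" %in% config$stages) {
      out$ratio_table <- pair_ratio_table(cm)
      utils::write.table(out$ratio_table$pairs,
                         file.path(out_dir, "pair_ratios.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(single_chain_ratios))
        out$dilute_dense_correlation <-
          contact_correlation(single_chain_ratios, out$ratio_table)
    }
  }
  if ("stacking" %in% config$stages) {
    out$stacking <- accumulate_g(model, frames, r_max = config$r_max,
                                 r_bin = config$r_bin,
                                 theta_bin = config$theta_bin)
    write_stacking_histogram(out$stacking,
                             file.path(out_dir, "stacking_g.tsv"))
  }
  if ("dimensions" %in% config$stages) {
    prot <- model$residues[model$residues$component == "protein", ]
    for (ch in unique(prot$chain_id)) {
      ds <- dimension_series(slice_frames(model, frames), chain = ch)
      utils::write.table(ds$series,
                         file.path(out_dir,
                                   sprintf("dimensions_chain_%s.tsv", ch)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_manifest(out_dir, config, list(kind = "slab"))
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: \code{synth} (write a synthetic single-chain PDB),
#' \code{contacts}, \code{dimensions}, \code{stacking}, \code{slab},
#' \code{restraints}, \code{report}. Run with no arguments for usage.
#' An executable wrapper is installed at
#' \code{system.file("cli", "condensekit", package = "condensekit")}.
#'
#' @param args character vector (default: \code{commandArgs(TRUE)})
#' @return exit status, invisibly
#' @export
condensekit_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: condensekit <subcommand> [options]",
    "  synth      --out FILE [--seed N] [--length N] [--frames N]",
    "  contacts   --in FILE --out DIR [--cutoff X] [--exclusion N]",
    "  dimensions --in FILE --out DIR",
    "  stacking   --in FILE --out DIR [--rmax X] [--rbin X] [--abin X]",
    "  slab       --in FILE --out DIR [--bin X] [--threshold X]",
    "  restraints --in FILE --out FILE [--cutoff X] [--angle X]",
    "  report     --in FILE --out DIR [--kind single|slab]",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  sub <- args[1]
  opt <- parse_cli_options(args[-1])
  get <- function(key, default = NULL, num = FALSE) {
    v <- opt[[key]] %||% default
    if (num && !is.null(v)) as.numeric(v) else v
  }
  status <- 0L
  switch(sub,
    synth = {
      spec <- synthetic_spec(seed = get("seed", 1, num = TRUE),
                             chain_length = get("length", 50, num = TRUE),
                             frames = get("frames", 5, num = TRUE))
      write_structure(generate_chain(spec), get("out"))
    },
    contacts = {
      model <- read_structure(get("in"))
      dir.create(get("out"), showWarnings = FALSE, recursive = TRUE)
      cm <- ensemble_contact_map(model, params = contact_params(
        get("cutoff", 4.5, num = TRUE), get("exclusion", 4, num = TRUE)))
      write_contact_map(cm, file.path(get("out"), "contact_map.tsv"))
    },
    dimensions = {
      model <- read_structure(get("in"))
      dir.create(get("out"), showWarnings = FALSE, recursive = TRUE)
      ds <- dimension_series(model)
      utils::write.table(ds$series,
                         file.path(get("out"), "dimensions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    stacking = {
      model <- read_structure(get("in"))
      dir.create(get("out"), showWarnings = FALSE, recursive = TRUE)
      h <- accumulate_g(model, r_max = get("rmax", 12, num = TRUE),
                        r_bin = get("rbin", 0.6, num = TRUE),
                        theta_bin = get("abin", 2.5, num = TRUE))
      write_stacking_histogram(h, file.path(get("out"), "stacking_g.tsv"))
    },
    slab = {
      model <- read_structure(get("in"))
      dir.create(get("out"), showWarnings = FALSE, recursive = TRUE)
      prof <- density_profile(model, bin_width = get("bin", 2.5, num = TRUE))
      write_density_profile(prof,
                            file.path(get("out"), "density_profile.tsv"),
                            predict_ion_partition(prof, 150))
    },
    restraints = {
      model <- read_structure(get("in"))
      rs <- derive_hbond_pairs(model,
                               cutoff = get("cutoff", 3.5, num = TRUE),
                               angle_cutoff = get("angle", 120, num = TRUE))
      export_restraints(rs, get("out"))
    },
    report = {
      model <- read_structure(get("in"))
      if (identical(get("kind", "single"), "slab"))
        run_slab_report(model, get("out"))
      else run_single_chain_report(model, get("out"))
    },
    { message("unknown subcommand: ", sub, "\n", usage); status <- 1L })
  invisible(status)
}

#' @keywords internal
parse_cli_options <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      out[[substring(args[i], 3)]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  out
}
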