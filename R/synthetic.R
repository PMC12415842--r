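# Seed-reproducible synthetic systems with planted structure.
#
# The generator is a stated world for testing the analysis stages, not a
# physical sampler: backbones are freely-jointed CA walks at a fixed bond
# length, side chains are pseudo heavy atoms on a deterministic local
# frame (only heavy-atom COUNTS per residue type are faithful, plus exact
# planar geometry for PHE rings and ARG guanidinium groups), folded
# domains are rigid compact clusters re-used identically across frames,
# and slab systems carry single-bead pseudo-water and Na/Cl particles.
# Planted residue contacts, planted F-R stack geometries, and planted
# dense-phase ion excesses give every analysis stage a known ground truth.

#' Specification for a synthetic system
#'
#' @param seed integer RNG seed; all generator output is a pure function
#'   of the spec (seed included)
#' @param n_chains number of protein chains (slab systems)
#' @param chain_length residues per chain
#' @param sequence residue types (3-letter codes) per position; NULL for
#'   a seed-determined random sequence
#' @param domain_map optional \code{\link{domain_map}}
#' @param rigid_domains names of domain-map entries built as rigid bodies
#' @param bond_length CA-CA bond length in Angstrom (default 3.8)
#' @param planted_contacts data.frame (res_i, res_j, distance) of CA-level
#'   contacts planted in every frame
#' @param planted_stacks data.frame (phe, arg, distance, angle) of F-R
#'   stack geometries planted in every frame (forces those positions to
#'   PHE/ARG); \code{jitter} column optional (Angstrom, default 0)
#' @param frames number of frames (default 1)
#' @param slab list(box = c(Lx, Ly, Lz) Angstrom, dense_z = c(lo, hi),
#'   n_water, n_na, n_cl, excess_na_mM = 0, excess_cl_mM = 0,
#'   neutralize = TRUE) for slab systems
#' @return list of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(seed = 1L, n_chains = 1L, chain_length = 50L,
                           sequence = NULL, domain_map = NULL,
                           rigid_domains = character(0), bond_length = 3.8,
                           planted_contacts = NULL, planted_stacks = NULL,
                           frames = 1L, slab = NULL) {
  stopifnot(bond_length > 0, frames >= 1L, chain_length >= 2L)
  if (!is.null(sequence)) {
    stopifnot(length(sequence) == chain_length,
              all(toupper(sequence) %in% .AA3))
    sequence <- toupper(sequence)
  }
  if (!is.null(planted_contacts))
    stopifnot(all(planted_contacts$distance > 0),
              all(planted_contacts$res_i < planted_contacts$res_j),
              all(planted_contacts$res_j <= chain_length))
  if (!is.null(planted_stacks))
    stopifnot(all(planted_stacks$distance > 0),
              all(planted_stacks$angle >= 0), all(planted_stacks$angle <= 90))
  if (!is.null(slab)) {
    stopifnot(length(slab$box) == 3, all(slab$box > 0),
              slab$dense_z[1] >= 0, slab$dense_z[2] <= slab$box[3],
              diff(slab$dense_z) > 0)
    slab$excess_na_mM <- slab$excess_na_mM %||% 0
    slab$excess_cl_mM <- slab$excess_cl_mM %||% 0
    slab$neutralize <- slab$neutralize %||% TRUE
  }
  structure(list(seed = as.integer(seed), n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 sequence = sequence, domain_map = domain_map,
                 rigid_domains = rigid_domains, bond_length = bond_length,
                 planted_contacts = planted_contacts,
                 planted_stacks = planted_stacks,
                 frames = as.integer(frames), slab = slab),
            class = "synthetic_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
runit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' @keywords internal
random_rotation <- function(angle = NULL) {
  ax <- runit()
  th <- if (is.null(angle)) stats::runif(1, 0, 2 * pi) else angle
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @keywords internal
orthobasis_perp <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(n, a); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

# ---- Per-residue pseudo heavy-atom offsets ----------------------------

# Offsets are relative to CA. Backbone N/C/O are fixed; side-chain atoms
# are drawn once per residue (deterministic in the generator's RNG
# stream). PHE rings and ARG guanidinium groups get exact planar geometry
# (C-C 1.39 A, C-N 1.33 A); CYS gets named CB/SG for zinc analysis.
#' @keywords internal
residue_offsets <- function(res_type) {
  nm <- aa_heavy_atoms(res_type)
  off <- matrix(0, length(nm), 3, dimnames = list(nm, NULL))
  off["N", ] <- c(-1.46, 0, 0)
  off["C", ] <- c(1.52, 0, 0)
  off["O", ] <- c(2.10, 1.05, 0)
  side <- setdiff(nm, c("N", "CA", "C", "O"))
  if (res_type == "PHE") {
    off["CB", ] <- c(0.0, 1.53, 0.0)
    cen <- 1.1 * runit()
    b <- orthobasis_perp(runit())
    ring <- .PHE_RING
    for (k in seq_along(ring)) {
      a <- (k - 1) * pi / 3
      off[ring[k], ] <- cen + 1.39 * (cos(a) * b$e1 + sin(a) * b$e2)
    }
  } else if (res_type == "ARG") {
    for (x in c("CB", "CG", "CD"))
      off[x, ] <- stats::runif(1, 1.2, 2.2) * runit()
    cen <- 1.1 * runit()
    b <- orthobasis_perp(runit())
    off["CZ", ] <- cen
    gua <- c("NE", "NH1", "NH2")
    for (k in 1:3) {
      a <- (k - 1) * 2 * pi / 3
      off[gua[k], ] <- cen + 1.33 * (cos(a) * b$e1 + sin(a) * b$e2)
    }
  } else if (res_type == "CYS") {
    off["CB", ] <- c(0.5, 1.4, 0.0)
    off["SG", ] <- c(1.2, 2.1, 0.4)
  } else {
    for (x in side) off[x, ] <- stats::runif(1, 1.2, 2.4) * runit()
  }
  off
}

# ---- Backbone walks ---------------------------------------------------

# Freely-jointed CA walk with planted-contact bridging: while a contact
# (i, j, d) is pending, steps are rejection-biased to keep residue j
# reachable at distance d from residue i, and residue j is placed exactly
# on the sphere-sphere intersection circle.
#' @keywords internal
fjc_walk <- function(n, b, contacts = NULL, rigid = NULL) {
  x <- matrix(NA_real_, n, 3)
  x[1, ] <- 0
  if (!is.null(contacts) && nrow(contacts) > 0)
    contacts <- contacts[order(contacts$res_j), , drop = FALSE]
  pend <- function(k) {
    if (is.null(contacts)) return(NULL)
    w <- which(contacts$res_i < k & contacts$res_j >= k)
    if (length(w) == 0) NULL else contacts[w[1], ]
  }
  in_rigid <- function(k) {
    if (is.null(rigid)) return(0L)
    for (rk in seq_along(rigid))
      if (k >= rigid[[rk]]$first && k <= rigid[[rk]]$last) return(rk)
    0L
  }
  k <- 2L
  while (k <= n) {
    rk <- in_rigid(k)
    if (rk > 0L && k == rigid[[rk]]$first) {
      # drop the whole rigid cluster anchored one bond from the previous CA
      tm <- rigid[[rk]]$template           # m x 3, first row at origin
      R <- random_rotation()
      anchor <- x[k - 1L, ] + b * runit()
      m <- nrow(tm)
      x[k:(k + m - 1L), ] <- sweep(tm %*% t(R), 2, anchor, "+")
      k <- k + m
      next
    }
    cst <- pend(k)
    if (!is.null(cst) && k == cst$res_j) {
      # place exactly at distance d from res_i and b from k-1
      w <- x[cst$res_i, ] - x[k - 1L, ]
      L <- sqrt(sum(w^2)); d <- cst$distance
      if (L > 1e-9 && abs(L - d) <= b && b <= L + d) {
        a <- (L^2 + b^2 - d^2) / (2 * L)
        rho <- sqrt(max(0, b^2 - a^2))
        wn <- w / L
        bb <- orthobasis_perp(wn)
        phi <- stats::runif(1, 0, 2 * pi)
        x[k, ] <- x[k - 1L, ] + a * wn +
          rho * (cos(phi) * bb$e1 + sin(phi) * bb$e2)
      } else {
        # infeasible corner: step straight toward the target sphere
        tgt <- x[cst$res_i, ] + d * (if (L > 1e-9) -w / L else runit())
        dirv <- tgt - x[k - 1L, ]
        nd <- sqrt(sum(dirv^2))
        x[k, ] <- x[k - 1L, ] + b * (if (nd > 1e-9) dirv / nd else runit())
      }
    } else {
      ok <- FALSE
      for (try in 1:100) {
        cand <- x[k - 1L, ] + b * runit()
        if (is.null(cst)) { ok <- TRUE; break }
        m <- cst$res_j - k          # steps remaining after this one
        L <- sqrt(sum((cand - x[cst$res_i, ])^2))
        if (L <= cst$distance + (m - 0.5) * b &&
            L >= cst$distance - (m - 0.5) * b) { ok <- TRUE; break }
      }
      if (!ok) {
        # deterministic fallback: walk toward the anchor residue
        dirv <- x[cst$res_i, ] - x[k - 1L, ]
        nd <- sqrt(sum(dirv^2))
        cand <- x[k - 1L, ] + b * (if (nd > 1e-9) dirv / nd else runit())
      }
      x[k, ] <- cand
    }
    k <- k + 1L
  }
  x
}

# Compact rigid CA cluster: biased self-returning walk confined to a
# sphere of radius ~ b * m^(1/3), first residue at the origin.
#' @keywords internal
compact_cluster <- function(m, b) {
  r0 <- b * max(1, m)^(1 / 3)
  x <- matrix(NA_real_, m, 3)
  x[1, ] <- 0
  for (k in 2:m) {
    repeat {
      cand <- x[k - 1, ] + b * runit()
      if (sqrt(sum(cand^2)) <= r0) break
    }
    x[k, ] <- cand
  }
  sweep(x, 2, x[1, ])
}

# ---- Stacked pair geometry --------------------------------------------

#' Generate a phenyl-ring / guanidinium pair at a chosen geometry
#'
#' The ring is a regular planar hexagon (C-C 1.39 A) centred at the
#' origin in the xy-plane; the guanidinium (CZ + NE/NH1/NH2, C-N 1.33 A)
#' is centred at distance \code{center_distance} along +z with its plane
#' normal at \code{plane_angle} degrees from the ring normal. Optional
#' isotropic Gaussian jitter is added per coordinate.
#'
#' @param center_distance COM separation in Angstrom (> 0)
#' @param plane_angle angle between plane normals, degrees in [0, 90]
#' @param jitter_sd per-coordinate Gaussian noise sd in Angstrom
#' @return list(phe = 6 x 3, arg = 4 x 3, phe_names, arg_names)
#' @export
generate_stacked_pair <- function(center_distance, plane_angle,
                                  jitter_sd = 0) {
  stopifnot(center_distance > 0, plane_angle >= 0, plane_angle <= 90)
  phe <- t(vapply(0:5, function(k) {
    a <- k * pi / 3
    c(1.39 * cos(a), 1.39 * sin(a), 0)
  }, numeric(3)))
  th <- plane_angle * pi / 180
  nrm <- c(sin(th), 0, cos(th))
  e1 <- c(cos(th), 0, -sin(th)); e2 <- c(0, 1, 0)
  cen <- c(0, 0, center_distance)
  arg <- rbind(cen,
               t(vapply(0:2, function(k) {
                 a <- k * 2 * pi / 3
                 cen + 1.33 * (cos(a) * e1 + sin(a) * e2)
               }, numeric(3))))
  if (jitter_sd > 0) {
    phe <- phe + matrix(stats::rnorm(18, 0, jitter_sd), 6, 3)
    arg <- arg + matrix(stats::rnorm(12, 0, jitter_sd), 4, 3)
  }
  dimnames(phe) <- list(.PHE_RING, NULL)
  dimnames(arg) <- list(.ARG_GUA, NULL)
  list(phe = phe, arg = arg, phe_names = .PHE_RING, arg_names = .ARG_GUA)
}

# ---- Single-chain generator -------------------------------------------

#' Generate a synthetic single- or multi-frame protein chain
#'
#' See the module description at the top of this file for the stated
#' world. Identical spec (including seed) gives bitwise-identical output.
#'
#' @param spec a \code{\link{synthetic_spec}}
#' @return a \code{SystemModel} (no box)
#' @export
generate_chain <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  built <- build_chain_internal(spec, chain_id = "A")
  system_model(built$atoms, built$residues, built$coords,
               domain_map = spec$domain_map)
}

# Shared chain builder: consumes the current RNG stream.
#' @keywords internal
build_chain_internal <- function(spec, chain_id = "A") {
  n <- spec$chain_length
  b <- spec$bond_length
  sequence <- spec$sequence %||% sample(.AA3, n, replace = TRUE)
  stacks <- spec$planted_stacks
  if (!is.null(stacks) && nrow(stacks) > 0) {
    sequence[stacks$phe] <- "PHE"
    sequence[stacks$arg] <- "ARG"
    if (is.null(stacks$jitter)) stacks$jitter <- 0
  }
  contacts <- spec$planted_contacts
  if (!is.null(stacks) && nrow(stacks) > 0) {
    # bring each planted stack's residues together at the CA level
    add <- data.frame(res_i = pmin(stacks$phe, stacks$arg),
                      res_j = pmax(stacks$phe, stacks$arg),
                      distance = stacks$distance)
    contacts <- rbind(contacts, add)
  }
  if (!is.null(contacts) && nrow(contacts) > 0 &&
      any(contacts$res_j - contacts$res_i <= 4))
    warning("planted contact within the proximity-exclusion window ",
            "will be invisible to the contact stage")

  # rigid domain blocks
  rigid <- NULL
  if (length(spec$rigid_domains) > 0) {
    dm <- spec$domain_map
    rigid <- lapply(spec$rigid_domains, function(dn) {
      k <- which(dm$domain == dn)
      if (length(k) != 1L) stop("rigid domain not in domain map: ", dn)
      first <- dm$first[k]; last <- min(dm$last[k], n)
      if (first < 2L) stop("rigid domains must start at residue 2 or later")
      list(first = first, last = last,
           template = compact_cluster(last - first + 1L, b))
    })
    if (!is.null(contacts) && nrow(contacts) > 0) {
      inr <- function(k) any(vapply(rigid, function(r)
        k >= r$first && k <= r$last, logical(1)))
      bad <- vapply(contacts$res_i, inr, logical(1)) |
        vapply(contacts$res_j, inr, logical(1))
      if (any(bad)) {
        warning("planted contact inside a rigid domain dropped")
        contacts <- contacts[!bad, , drop = FALSE]
      }
    }
  }

  offsets <- lapply(sequence, residue_offsets)
  n_at <- vapply(offsets, nrow, integer(1))
  atom_res <- rep(seq_len(n), n_at)
  atom_name <- unlist(lapply(offsets, rownames))
  element <- substr(atom_name, 1, 1)
  first_atom <- cumsum(c(1L, n_at[-n]))
  last_atom <- cumsum(n_at)

  coords <- array(NA_real_, c(sum(n_at), 3, spec$frames))
  for (f in seq_len(spec$frames)) {
    ca <- fjc_walk(n, b, contacts, rigid)
    xyz <- matrix(NA_real_, sum(n_at), 3)
    for (r in seq_len(n)) {
      rows <- first_atom[r]:last_atom[r]
      xyz[rows, ] <- sweep(offsets[[r]], 2, ca[r, ], "+")
    }
    # planted contacts: engage the side chains across the interface, as
    # a genuinely bound residue pair would (backbone proximity alone is
    # indistinguishable from a transient random-walk collision)
    if (!is.null(contacts) && nrow(contacts) > 0)
      for (ci in seq_len(nrow(contacts))) {
        ri <- contacts$res_i[ci]; rj <- contacts$res_j[ci]
        u <- ca[rj, ] - ca[ri, ]
        nu <- sqrt(sum(u * u))
        if (nu < 1e-9) next
        u <- u / nu
        bb <- orthobasis_perp(u)
        engage <- function(r, dirv) {
          rows <- first_atom[r]:last_atom[r]
          side <- rows[-(1:4)]            # beyond backbone N, CA, C, O
          for (s in seq_along(side)) {
            a <- s * 2.3
            xyz[side[s], ] <<- ca[r, ] +
              (0.8 + 0.4 * ((s - 1) %% 5)) * dirv +
              0.5 * (cos(a) * bb$e1 + sin(a) * bb$e2)
          }
        }
        engage(ri, u)
        engage(rj, -u)
      }
    # rigid domains: side chains must rotate with the body. Re-place all
    # domain atoms from the template-frame offsets using the realised
    # CA positions (template CAs are rigid, so solve the transform).
    if (!is.null(rigid)) for (rg in rigid) {
      rr <- rg$first:rg$last
      tpl_ca <- rg$template
      real_ca <- ca[rr, , drop = FALSE]
      R <- kabsch_rotation(sweep(tpl_ca, 2, colMeans(tpl_ca)),
                           sweep(real_ca, 2, colMeans(real_ca)))
      for (ii in seq_along(rr)) {
        r <- rr[ii]
        rows <- first_atom[r]:last_atom[r]
        xyz[rows, ] <- sweep(offsets[[r]] %*% R, 2, ca[r, ], "+")
      }
    }
    # planted stacks: overwrite the sp2 group geometry
    if (!is.null(stacks) && nrow(stacks) > 0) for (s in seq_len(nrow(stacks))) {
      geo <- generate_stacked_pair(stacks$distance[s], stacks$angle[s],
                                   stacks$jitter[s])
      Rr <- random_rotation()
      mid <- (ca[stacks$phe[s], ] + ca[stacks$arg[s], ]) / 2
      # rotate the canonical pair about its midpoint, then translate
      pair_mid <- c(0, 0, stacks$distance[s] / 2)
      place <- function(g) sweep(sweep(g, 2, pair_mid) %*% t(Rr), 2, mid, "+")
      phe_rows <- first_atom[stacks$phe[s]] - 1L +
        match(.PHE_RING, rownames(offsets[[stacks$phe[s]]]))
      arg_rows <- first_atom[stacks$arg[s]] - 1L +
        match(.ARG_GUA, rownames(offsets[[stacks$arg[s]]]))
      xyz[phe_rows, ] <- place(geo$phe)
      xyz[arg_rows, ] <- place(geo$arg)
    }
    coords[, , f] <- xyz
  }

  atoms <- data.frame(name = atom_name, element = element,
                      mass = element_mass(element),
                      is_heavy = TRUE, res_id = atom_res,
                      stringsAsFactors = FALSE)
  residues <- data.frame(res_id = seq_len(n), seq_index = seq_len(n),
                         res_type = sequence, chain_id = chain_id,
                         first_atom = first_atom, last_atom = last_atom,
                         component = "protein", stringsAsFactors = FALSE)
  list(atoms = atoms, residues = residues, coords = coords,
       sequence = sequence)
}

# ---- Slab generator ---------------------------------------------------

#' Generate a synthetic multi-chain slab with solvent and ions
#'
#' Protein chains are placed with their centres inside the dense
#' z-extent and rigidly jittered per frame (planted intra-chain structure
#' is preserved exactly). Pseudo-water is uniform over the box. Na/Cl
#' are uniform plus a planted dense-region excess; when
#' \code{slab$neutralize} is TRUE the protein's net formal charge is
#' compensated by extra counterions placed in the dense region
#' (Donnan-style), so a net-positive protein yields a dense-phase Cl
#' excess.
#'
#' @param spec a \code{\link{synthetic_spec}} with a \code{slab} block
#' @return a \code{SystemModel} with a periodic box
#' @export
generate_slab <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), !is.null(spec$slab))
  set.seed(spec$seed)
  sl <- spec$slab
  box <- sl$box
  v_box <- prod(box)
  n_sol <- sl$n_water + sl$n_na + sl$n_cl
  if (n_sol > v_box / 8)
    stop("requested particle counts exceed box capacity at 2.0 A spacing")
  v_dense <- box[1] * box[2] * diff(sl$dense_z)

  chains <- lapply(seq_len(spec$n_chains), function(cix)
    build_chain_internal(spec, chain_id = LETTERS[cix]))
  # centre each base conformation and give it a home position
  homes <- matrix(NA_real_, spec$n_chains, 3)
  margin <- 0.15 * diff(sl$dense_z)
  for (cix in seq_len(spec$n_chains)) {
    base <- chains[[cix]]$coords[, , 1]
    chains[[cix]]$base <- sweep(base, 2, colMeans(base))
    homes[cix, ] <- c(stats::runif(1, 0, box[1]),
                      stats::runif(1, 0, box[2]),
                      stats::runif(1, sl$dense_z[1] + margin,
                                   sl$dense_z[2] - margin))
  }

  # dense-region ion extras: planted excesses plus charge compensation
  mM_to_count <- function(mM, vol) round(mM * vol / .COUNT_PER_A3_TO_MM)
  extra_na <- mM_to_count(sl$excess_na_mM, v_dense)
  extra_cl <- mM_to_count(sl$excess_cl_mM, v_dense)
  q_total <- sum(vapply(chains, function(ch)
    sum(residue_charge(ch$sequence)), numeric(1)))
  if (isTRUE(sl$neutralize) && q_total != 0) {
    if (q_total > 0) extra_cl <- extra_cl + q_total
    else extra_na <- extra_na - q_total
  }
  n_na_tot <- sl$n_na + extra_na
  n_cl_tot <- sl$n_cl + extra_cl

  # topology: protein chains, then water, Na, Cl
  atoms_list <- lapply(chains, function(ch) ch$atoms)
  res_list <- lapply(chains, function(ch) ch$residues)
  mk_part <- function(nrep, rtype, aname, elem, mass, chain_id) {
    if (nrep == 0) return(NULL)
    list(atoms = data.frame(name = aname, element = elem, mass = mass,
                            is_heavy = TRUE, res_id = seq_len(nrep),
                            stringsAsFactors = FALSE),
         residues = data.frame(res_id = seq_len(nrep),
                               seq_index = seq_len(nrep),
                               res_type = rtype, chain_id = chain_id,
                               first_atom = seq_len(nrep),
                               last_atom = seq_len(nrep),
                               component = component_for_restype(rtype),
                               stringsAsFactors = FALSE))
  }
  parts <- Filter(Negate(is.null), list(
    mk_part(sl$n_water, "HOH", "O", "O", .WATER_MASS, "w"),
    mk_part(n_na_tot, "NA", "NA", "NA", element_mass("NA"), "x"),
    mk_part(n_cl_tot, "CL", "CL", "CL", element_mass("CL"), "y")))

  # merge with global res_id / atom offsets
  atoms <- NULL; residues <- NULL
  res_off <- 0L; atom_off <- 0L
  add_block <- function(a, r) {
    a$res_id <- a$res_id + res_off
    r$res_id <- r$res_id + res_off
    r$first_atom <- r$first_atom + atom_off
    r$last_atom <- r$last_atom + atom_off
    atoms <<- rbind(atoms, a)
    residues <<- rbind(residues, r)
    res_off <<- res_off + nrow(r)
    atom_off <<- atom_off + nrow(a)
  }
  for (cix in seq_len(spec$n_chains))
    add_block(atoms_list[[cix]], res_list[[cix]])
  prot_atoms <- atom_off
  for (p in parts) add_block(p$atoms, p$residues)

  uniform_z <- function(k) stats::runif(k, 0, box[3])
  dense_zs <- function(k) stats::runif(k, sl$dense_z[1], sl$dense_z[2])
  coords <- array(NA_real_, c(nrow(atoms), 3, spec$frames))
  for (f in seq_len(spec$frames)) {
    ofs <- 0L
    for (cix in seq_len(spec$n_chains)) {
      R <- random_rotation(stats::rnorm(1, 0, 0.1))
      jit <- stats::rnorm(3, 0, 0.5)
      xyz <- sweep(chains[[cix]]$base %*% t(R), 2, homes[cix, ] + jit, "+")
      na_c <- nrow(chains[[cix]]$atoms)
      coords[(ofs + 1):(ofs + na_c), , f] <- xyz
      ofs <- ofs + na_c
    }
    place <- function(k, zfun)
      cbind(stats::runif(k, 0, box[1]), stats::runif(k, 0, box[2]), zfun(k))
    sol <- rbind(
      if (sl$n_water > 0) place(sl$n_water, uniform_z),
      if (n_na_tot > 0) rbind(
        if (sl$n_na > 0) place(sl$n_na, uniform_z),
        if (extra_na > 0) place(extra_na, dense_zs)),
      if (n_cl_tot > 0) rbind(
        if (sl$n_cl > 0) place(sl$n_cl, uniform_z),
        if (extra_cl > 0) place(extra_cl, dense_zs)))
    if (!is.null(sol))
      coords[(prot_atoms + 1):nrow(atoms), , f] <- sol
  }
  system_model(atoms, residues, coords,
               box = matrix(box, spec$frames, 3, byrow = TRUE),
               domain_map = spec$domain_map)
}
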