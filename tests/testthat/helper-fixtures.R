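# Shared fixtures and independent oracles. Everything is generated in
# code; no binary fixtures.

# Pure-R exhaustive contact oracle: double loop over residue pairs and
# heavy-atom pairs, independent of the C++ kernel.
oracle_contact_matrix <- function(model, frame, params = contact_params()) {
  res <- model$residues
  prot <- res[res$component == "protein", ]
  n <- nrow(prot)
  out <- matrix(0, n, n, dimnames = list(prot$res_id, prot$res_id))
  xyz <- model$coords[, , frame]
  box <- if (is.null(model$box)) NULL else model$box[frame, ]
  heavy <- model$atoms$is_heavy
  for (a in seq_len(n - 1)) {
    ra <- prot[a, ]
    ia <- ra$first_atom:ra$last_atom
    if (params$heavy_only) ia <- ia[heavy[ia]]
    for (b in (a + 1):n) {
      rb <- prot[b, ]
      if (ra$chain_id == rb$chain_id &&
          abs(ra$seq_index - rb$seq_index) <= params$exclusion) next
      ib <- rb$first_atom:rb$last_atom
      if (params$heavy_only) ib <- ib[heavy[ib]]
      cnt <- 0L
      for (p in ia) {
        d <- xyz[ib, , drop = FALSE] -
          matrix(xyz[p, ], length(ib), 3, byrow = TRUE)
        if (!is.null(box))
          for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
        cnt <- cnt + sum(sqrt(rowSums(d * d)) < params$cutoff)
      }
      out[a, b] <- cnt
    }
  }
  out
}

# frame_contacts result as a dense matrix for comparison with the oracle
sparse_to_matrix <- function(fc, model) {
  prot <- model$residues[model$residues$component == "protein", ]
  n <- nrow(prot)
  out <- matrix(0, n, n, dimnames = list(prot$res_id, prot$res_id))
  if (nrow(fc) > 0) {
    ia <- match(fc$res_i, prot$res_id)
    ib <- match(fc$res_j, prot$res_id)
    for (k in seq_len(nrow(fc))) out[ia[k], ib[k]] <- fc$count[k]
  }
  out
}

# Minimal hand-built model: residues given as a list of per-residue atom
# tables (name, element, x, y, z); one frame unless coords given.
toy_model <- function(res_specs, chain_ids = NULL, res_types = NULL,
                      box = NULL) {
  n_res <- length(res_specs)
  if (is.null(chain_ids)) chain_ids <- rep("A", n_res)
  if (is.null(res_types)) res_types <- rep("GLY", n_res)
  name <- unlist(lapply(res_specs, function(r) r$name))
  element <- unlist(lapply(res_specs, function(r) r$element))
  n_at <- vapply(res_specs, function(r) length(r$name), integer(1))
  xyz <- do.call(rbind, lapply(res_specs, function(r)
    cbind(r$x, r$y, r$z)))
  first <- cumsum(c(1L, n_at[-n_res]))
  atoms <- data.frame(name = name, element = element,
                      mass = condensekit:::element_mass(element),
                      is_heavy = toupper(element) != "H",
                      res_id = rep(seq_len(n_res), n_at),
                      stringsAsFactors = FALSE)
  seq_index <- stats::ave(seq_len(n_res), chain_ids, FUN = seq_along)
  residues <- data.frame(res_id = seq_len(n_res), seq_index = seq_index,
                         res_type = res_types, chain_id = chain_ids,
                         first_atom = first,
                         last_atom = first + n_at - 1L,
                         component = condensekit:::component_for_restype(
                           res_types),
                         stringsAsFactors = FALSE)
  system_model(atoms, residues, array(xyz, c(nrow(xyz), 3, 1)), box = box)
}

# single-heavy-atom residue at a point
point_res <- function(x, y, z, name = "CA", element = "C")
  list(name = name, element = element, x = x, y = y, z = z)

# random rotation matrix (proper)
random_proper_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

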