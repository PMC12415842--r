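# Summed heavy-atom residue-pair contact statistics.
#
# A contact exists between two residues whenever any pair of their heavy
# atoms is closer than the cutoff (default 4.5 A); the residue-pair count
# is the NUMBER of such heavy-atom pairs, not a 0/1 occupancy. Same-chain
# pairs within the proximity-exclusion window contribute nothing. Counts
# are averaged over frames and split into intra- and intermolecular
# channels.

#' Contact-counting parameters
#'
#' @param cutoff heavy-atom distance cutoff in Angstrom; strict inequality
#'   d < cutoff (default 4.5)
#' @param exclusion same-chain sequence-separation window: pairs with
#'   |seq_i - seq_j| <= exclusion are excluded. The default 4 makes
#'   separation 5 the first included one ("five-residue proximity").
#' @param heavy_only count only non-hydrogen atoms (default TRUE)
#' @return list of class \code{contact_params}
#' @export
contact_params <- function(cutoff = 4.5, exclusion = 4L, heavy_only = TRUE) {
  stopifnot(cutoff > 0, exclusion >= 0)
  structure(list(cutoff = cutoff, exclusion = as.integer(exclusion),
                 heavy_only = isTRUE(heavy_only)),
            class = "contact_params")
}

#' Residue-pair contact counts for a single frame
#'
#' @param model a SystemModel
#' @param frame 1-based frame index
#' @param params a \code{\link{contact_params}}
#' @return data.frame (res_i, res_j, count, same_chain) over protein
#'   residue ids with res_i < res_j; integer counts; excluded and distant
#'   pairs are absent (zero).
#' @export
frame_contacts <- function(model, frame, params = contact_params()) {
  idx <- which(model$atoms$res_id %in%
                 model$residues$res_id[model$residues$component == "protein"])
  if (params$heavy_only) idx <- idx[model$atoms$is_heavy[idx]]
  if (length(idx) == 0L) stop("no protein atoms to analyse")
  xyz <- model$coords[idx, , frame, drop = FALSE]
  dim(xyz) <- dim(xyz)[1:2]
  box <- if (is.null(model$box)) numeric(0) else model$box[frame, ]
  tri <- .contact_counts_cpp(xyz, model$atoms$res_id[idx], box,
                             params$cutoff)
  if (nrow(tri) == 0L)
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      count = integer(0), same_chain = logical(0)))
  res <- model$residues
  ch_i <- res$chain_id[tri$res_i]; ch_j <- res$chain_id[tri$res_j]
  sq_i <- res$seq_index[tri$res_i]; sq_j <- res$seq_index[tri$res_j]
  same <- ch_i == ch_j
  keep <- !(same & abs(sq_i - sq_j) <= params$exclusion)
  out <- tri[keep, , drop = FALSE]
  out$same_chain <- same[keep]
  rownames(out) <- NULL
  out
}

#' Ensemble-averaged contact map
#'
#' Mean summed heavy-atom contacts per residue pair over a frame range,
#' indexed by within-chain sequence position so chains of a multi-chain
#' system are pooled. The intra channel holds same-chain contacts, inter
#' holds cross-chain contacts; intra + inter = total elementwise. For
#' multi-chain systems \code{per_chain} holds the per-chain average
#' (channel totals divided by the chain count).
#'
#' @param model a SystemModel
#' @param frames frame indices (default all)
#' @param params a \code{\link{contact_params}}
#' @return object of class \code{ContactMatrix}: upper-triangular matrices
#'   \code{intra}, \code{inter}, \code{total} (L x L, L = max protein
#'   seq_index), plus metadata.
#' @export
ensemble_contact_map <- function(model, frames = seq_len(n_frames(model)),
                                 params = contact_params()) {
  if (length(frames) == 0L) stop("empty frame range")
  prot <- model$residues[model$residues$component == "protein", ]
  L <- max(prot$seq_index)
  intra <- matrix(0, L, L)
  inter <- matrix(0, L, L)
  seq_of <- model$residues$seq_index
  for (f in frames) {
    fc <- frame_contacts(model, f, params)
    if (nrow(fc) == 0L) next
    si <- seq_of[fc$res_i]; sj <- seq_of[fc$res_j]
    lo <- pmin(si, sj); hi <- pmax(si, sj)
    for (k in seq_len(nrow(fc))) {
      if (fc$same_chain[k])
        intra[lo[k], hi[k]] <- intra[lo[k], hi[k]] + fc$count[k]
      else
        inter[lo[k], hi[k]] <- inter[lo[k], hi[k]] + fc$count[k]
    }
  }
  nf <- length(frames)
  intra <- intra / nf
  inter <- inter / nf
  n_chains <- length(unique(prot$chain_id))
  structure(list(intra = intra, inter = inter, total = intra + inter,
                 per_chain = (intra + inter) / n_chains,
                 n_frames = nf, n_chains = n_chains, params = params,
                 sequence = chain_sequence(model)),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat("ContactMatrix:", nrow(x$total), "positions,", x$n_frames,
      "frame(s),", x$n_chains, "chain(s); mean total contacts/frame =",
      format(sum(x$total), digits = 5), "\n")
  invisible(x)
}

#' Residue types per sequence position (first protein chain)
#' @keywords internal
chain_sequence <- function(model) {
  prot <- model$residues[model$residues$component == "protein", ]
  ch1 <- prot[prot$chain_id == prot$chain_id[1], ]
  sq <- character(max(prot$seq_index))
  sq[ch1$seq_index] <- ch1$res_type
  sq
}

#' One-dimensional per-position contact profile
#'
#' \code{profile(i) = sum_j counts(i, j)}; both endpoints of every pair
#' are credited, so the profile sums to twice the matrix total.
#'
#' @param cm a ContactMatrix (or a plain upper-triangular matrix)
#' @param channel "total", "intra", "inter", or "per_chain"
#' @return numeric vector of length L
#' @export
position_profile <- function(cm, channel = "total") {
  m <- if (inherits(cm, "ContactMatrix")) cm[[channel]] else cm
  rowSums(m) + colSums(m)
}

#' Aggregate a contact map into domain-by-domain blocks
#'
#' @param cm a ContactMatrix
#' @param map a \code{\link{domain_map}}; positions outside every range go
#'   to an implicit "unassigned" block with a warning
#' @param channel which channel to aggregate
#' @return symmetric domain x domain matrix of summed contacts (each
#'   unordered residue pair counted once; grand total conserved)
#' @export
domain_block_map <- function(cm, map, channel = "total") {
  m <- cm[[channel]]
  L <- nrow(m)
  dom <- domain_of(map, seq_len(L))
  if (any(dom == "unassigned"))
    warning(sum(dom == "unassigned"),
            " position(s) outside all domains -> 'unassigned' block")
  doms <- unique(c(map$domain, if (any(dom == "unassigned")) "unassigned"))
  dfac <- factor(dom, levels = doms)
  nd <- length(doms)
  block <- matrix(0, nd, nd, dimnames = list(doms, doms))
  nz <- which(m != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    a <- as.integer(dfac[nz[k, 1]]); b <- as.integer(dfac[nz[k, 2]])
    lo <- min(a, b); hi <- max(a, b)
    block[lo, hi] <- block[lo, hi] + m[nz[k, 1], nz[k, 2]]
  }
  block[lower.tri(block)] <- t(block)[lower.tri(block)]
  block
}

#' Residue-type pair contact ratios and per-type normalised contacts
#'
#' Contacts are tallied into the 210 unordered amino-acid type pairs; the
#' contact ratio of a pair is its share of the total (ratios sum to 1).
#' Per-type contacts are additionally normalised by the type's abundance
#' in the sequence.
#'
#' @param cm a ContactMatrix
#' @param sequence residue types per position (default: taken from the map)
#' @param channel which channel to tally
#' @return object of class \code{PairRatioTable}: \code{pairs} data.frame
#'   (type_i, type_j, contacts, ratio, rank; sorted descending) and
#'   \code{per_type} data.frame (res_type, contacts, aa_count, normalized)
#' @export
pair_ratio_table <- function(cm, sequence = cm$sequence,
                             channel = "total") {
  m <- cm[[channel]]
  L <- nrow(m)
  stopifnot(length(sequence) == L)
  types <- .AA3
  ti <- match(toupper(sequence), types)
  pair_counts <- matrix(0, 20, 20, dimnames = list(types, types))
  nz <- which(m != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    a <- ti[nz[k, 1]]; b <- ti[nz[k, 2]]
    if (is.na(a) || is.na(b)) next
    lo <- min(a, b); hi <- max(a, b)
    pair_counts[lo, hi] <- pair_counts[lo, hi] + m[nz[k, 1], nz[k, 2]]
  }
  ut <- which(upper.tri(pair_counts, diag = TRUE), arr.ind = TRUE)
  pairs <- data.frame(
    type_i = types[ut[, 1]], type_j = types[ut[, 2]],
    contacts = pair_counts[ut], stringsAsFactors = FALSE)
  tot <- sum(pairs$contacts)
  pairs$ratio <- if (tot > 0) pairs$contacts / tot else 0
  pairs <- pairs[order(-pairs$ratio, pairs$type_i, pairs$type_j), ]
  pairs$rank <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  # per-type: credit both endpoints of each pair; the diagonal appears in
  # both row and column sums, so homotypic pairs credit the type twice
  per_type_contacts <- rowSums(pair_counts) + colSums(pair_counts)
  aa_count <- as.integer(table(factor(toupper(sequence), levels = types)))
  per_type <- data.frame(
    res_type = types, contacts = unname(per_type_contacts),
    aa_count = aa_count,
    normalized = ifelse(aa_count > 0, per_type_contacts / aa_count, 0),
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, per_type = per_type, total = tot),
            class = "PairRatioTable")
}

#' @export
print.PairRatioTable <- function(x, n = 10, ...) {
  cat("PairRatioTable: total contacts/frame =",
      format(x$total, digits = 5), "\n")
  print(utils::head(x$pairs, n))
  invisible(x)
}

#' Correlation between two contact-ratio tables or profiles
#'
#' Pearson correlation (and least-squares slope) over paired bins.
#' Bins that are zero in BOTH inputs are structural zeros and are dropped
#' so they cannot inflate the correlation.
#'
#' @param a,b two \code{PairRatioTable}s or two equal-length numeric
#'   vectors (e.g. per-position profiles)
#' @return list(r, slope, n_used)
#' @export
contact_correlation <- function(a, b) {
  if (inherits(a, "PairRatioTable")) {
    key <- paste(a$pairs$type_i, a$pairs$type_j)
    va <- a$pairs$ratio[order(key)]
    keyb <- paste(b$pairs$type_i, b$pairs$type_j)
    vb <- b$pairs$ratio[order(keyb)]
  } else {
    va <- as.numeric(a); vb <- as.numeric(b)
  }
  stopifnot(length(va) == length(vb))
  keep <- !(va == 0 & vb == 0)
  va <- va[keep]; vb <- vb[keep]
  if (length(va) < 3L) stop("fewer than 3 non-zero pairs")
  r <- stats::cor(va, vb)
  slope <- stats::cov(va, vb) / stats::var(va)
  list(r = r, slope = slope, n_used = length(va))
}

#' Per-frame total contact counts
#'
#' Convergence/equilibration diagnostic: the summed contact count of each
#' frame plus a centred running mean.
#'
#' @param model a SystemModel
#' @param params a \code{\link{contact_params}}
#' @param window running-mean window in frames (odd; default 1 = none)
#' @return data.frame (frame, total, running_mean)
#' @export
contact_timeseries <- function(model, params = contact_params(),
                               window = 1L) {
  nf <- n_frames(model)
  stopifnot(nf >= 1L)
  tot <- vapply(seq_len(nf), function(f)
    sum(frame_contacts(model, f, params)$count), numeric(1))
  rm <- stats::filter(tot, rep(1 / window, window), sides = 2)
  data.frame(frame = seq_len(nf), total = tot,
             running_mean = as.numeric(rm))
}

#' Export a contact map channel as residue-labelled TSV
#' @param cm a ContactMatrix
#' @param path output file
#' @param channel which channel
#' @export
write_contact_map <- function(cm, path, channel = "total") {
  m <- cm[[channel]]
  dimnames(m) <- list(seq_len(nrow(m)), seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
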