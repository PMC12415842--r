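# Contact statistics vs the exhaustive pure-R oracle, plus the derived
# tables and their invariants.

test_that("cutoff boundary: strict inequality, summed heavy-atom pairs", {
  # two 1-atom residues at 5.0 A: no contact
  m <- toy_model(list(point_res(0, 0, 0), point_res(5, 0, 0)))
  expect_identical(nrow(frame_contacts(m, 1, contact_params(exclusion = 0))),
                   0L)
  # exactly one heavy-atom pair at 4.4 A: count 1
  m2 <- toy_model(list(point_res(0, 0, 0), point_res(4.4, 0, 0)))
  fc <- frame_contacts(m2, 1, contact_params(exclusion = 0))
  expect_identical(fc$count, 1L)
  # a pair at exactly the cutoff is excluded (d < cutoff)
  m3 <- toy_model(list(point_res(0, 0, 0), point_res(4.5, 0, 0)))
  expect_identical(nrow(frame_contacts(m3, 1, contact_params(exclusion = 0))),
                   0L)
  # hydrogens never count
  m4 <- toy_model(list(
    list(name = c("CA", "HA"), element = c("C", "H"),
         x = c(0, 4), y = c(0, 0), z = c(0, 0)),
    point_res(8, 0, 0)))
  expect_identical(nrow(frame_contacts(m4, 1, contact_params(exclusion = 0))),
                   0L)
})

test_that("C++ kernel equals the exhaustive oracle on random frames", {
  for (seed in c(101, 202)) {
    spec <- synthetic_spec(seed = seed, chain_length = 30, frames = 2)
    m <- generate_chain(spec)
    for (f in 1:2) {
      got <- sparse_to_matrix(frame_contacts(m, f), m)
      want <- oracle_contact_matrix(m, f)
      expect_identical(got, want)
    }
  }
  # with a periodic box and multiple chains (minimum image, channels)
  sl <- synthetic_spec(seed = 77, n_chains = 2, chain_length = 10,
                       frames = 2,
                       slab = list(box = c(30, 30, 60),
                                   dense_z = c(15, 45), n_water = 50,
                                   n_na = 5, n_cl = 5))
  ms <- generate_slab(sl)
  for (f in 1:2)
    expect_identical(sparse_to_matrix(frame_contacts(ms, f), ms),
                     oracle_contact_matrix(ms, f))
})

test_that("proximity exclusion and cutoff monotonicity", {
  spec <- synthetic_spec(seed = 5, chain_length = 25, frames = 1)
  m <- generate_chain(spec)
  fc4 <- frame_contacts(m, 1, contact_params(exclusion = 4))
  sq <- m$residues$seq_index
  expect_true(all(abs(sq[fc4$res_i] - sq[fc4$res_j]) >= 5 |
                    !fc4$same_chain))
  # first included separation is 5
  fc0 <- frame_contacts(m, 1, contact_params(exclusion = 0))
  expect_gt(nrow(fc0), nrow(fc4))
  # monotone in cutoff
  m_lo <- sparse_to_matrix(frame_contacts(m, 1, contact_params(cutoff = 4)),
                           m)
  m_hi <- sparse_to_matrix(frame_contacts(m, 1, contact_params(cutoff = 6)),
                           m)
  expect_true(all(m_hi >= m_lo))
  # intermolecular channel ignores the exclusion window entirely
  sl <- synthetic_spec(seed = 7, n_chains = 2, chain_length = 8, frames = 1,
                       slab = list(box = c(25, 25, 50), dense_z = c(15, 35),
                                   n_water = 0, n_na = 0, n_cl = 0))
  ms <- generate_slab(sl)
  inter0 <- ensemble_contact_map(ms, 1, contact_params(exclusion = 0))$inter
  inter7 <- ensemble_contact_map(ms, 1, contact_params(exclusion = 7))$inter
  expect_identical(inter0, inter7)
})

test_that("atom order within residues does not change the result", {
  spec <- synthetic_spec(seed = 15, chain_length = 15, frames = 1)
  m <- generate_chain(spec)
  base <- sparse_to_matrix(frame_contacts(m, 1), m)
  set.seed(1)
  m2 <- m
  for (r in seq_len(nrow(m2$residues))) {
    span <- m2$residues$first_atom[r]:m2$residues$last_atom[r]
    perm <- sample(span)
    m2$coords[span, , 1] <- m$coords[perm, , 1]
    m2$atoms[span, ] <- m$atoms[perm, ]
    m2$atoms$res_id[span] <- r
  }
  expect_identical(sparse_to_matrix(frame_contacts(m2, 1), m2), base)
})

test_that("ensemble map averages frames and recovers planted contacts", {
  spec <- synthetic_spec(seed = 3, chain_length = 30, frames = 1)
  m <- generate_chain(spec)
  cm1 <- ensemble_contact_map(m, 1)
  # duplicated frame: same map
  m2 <- m
  m2$coords <- array(m$coords[, , c(1, 1)], c(dim(m$coords)[1], 3, 2))
  cm2 <- ensemble_contact_map(m2)
  expect_equal(cm2$total, cm1$total)
  expect_identical(cm2$intra + cm2$inter, cm2$total)
  expect_error(ensemble_contact_map(m, integer(0)), "empty")
  # planted distal contact outranks every unplanted distal pair
  spec3 <- synthetic_spec(seed = 41, chain_length = 60, frames = 8,
                          planted_contacts = data.frame(
                            res_i = 10, res_j = 50, distance = 4.0))
  m3 <- generate_chain(spec3)
  cm3 <- ensemble_contact_map(m3)
  expect_gt(cm3$total[10, 50], 0)
})

test_that("position profile sums both endpoints", {
  z <- matrix(0, 5, 5)
  expect_identical(position_profile(z), rep(0, 5))
  one <- matrix(0, 5, 5); one[2, 4] <- 3
  expect_identical(position_profile(one), c(0, 3, 0, 3, 0))
  set.seed(9)
  rnd <- matrix(0, 8, 8)
  rnd[upper.tri(rnd)] <- rpois(28, 2)
  prof <- position_profile(rnd)
  manual <- vapply(1:8, function(i) sum(rnd[i, ]) + sum(rnd[, i]),
                   numeric(1))
  expect_equal(prof, manual)
  expect_equal(sum(prof), 2 * sum(rnd))
})

test_that("domain blocks conserve totals and reduce correctly", {
  spec <- synthetic_spec(seed = 19, chain_length = 21, frames = 2)
  m <- generate_chain(spec)
  cm <- ensemble_contact_map(m)
  # identity partition returns the original matrix (plus symmetry)
  idmap <- domain_map(paste0("r", 1:21), 1:21, 1:21)
  blocks <- domain_block_map(cm, idmap)
  expect_equal(blocks[upper.tri(blocks)], cm$total[upper.tri(cm$total)])
  # single domain -> scalar total
  one <- domain_block_map(cm, domain_map("all", 1, 21))
  expect_equal(one[1, 1], sum(cm$total))
  # 3-block map sums match brute force
  dm <- domain_map(c("N", "M", "C"), c(1, 8, 15), c(7, 14, 21))
  b3 <- domain_block_map(cm, dm)
  expect_equal(sum(b3[upper.tri(b3, diag = TRUE)]), sum(cm$total))
  manual_nm <- sum(cm$total[1:7, 8:14])
  expect_equal(b3["N", "M"], manual_nm)
  # uncovered residues go to an 'unassigned' block with warning
  expect_warning(
    b4 <- domain_block_map(cm, domain_map("N", 1, 7)), "unassigned")
  expect_equal(sum(b4[upper.tri(b4, diag = TRUE)]), sum(cm$total))
})

test_that("pair ratio table: 210 bins, normalisation, rankings", {
  # contacts only between an ARG and a TYR -> RY ratio 1
  m <- toy_model(list(point_res(0, 0, 0), point_res(30, 0, 0),
                      point_res(4, 0, 0)),
                 res_types = c("ARG", "GLY", "TYR"))
  cm <- ensemble_contact_map(m, 1, contact_params(exclusion = 0))
  rt <- pair_ratio_table(cm, sequence = c("ARG", "GLY", "TYR"))
  expect_identical(nrow(rt$pairs), 210L)
  ry <- rt$pairs[rt$pairs$type_i == "ARG" & rt$pairs$type_j == "TYR", ]
  expect_equal(ry$ratio, 1)
  expect_identical(ry$rank, 1L)
  expect_equal(sum(rt$pairs$ratio), 1, tolerance = 1e-12)
  # glycine-only chain populates only GG
  mg <- generate_chain(synthetic_spec(seed = 8, chain_length = 20,
                                      sequence = rep("GLY", 20)))
  rtg <- pair_ratio_table(ensemble_contact_map(mg))
  nz <- rtg$pairs[rtg$pairs$ratio > 0, ]
  expect_identical(paste(nz$type_i, nz$type_j), "GLY GLY")
  # mixed chain matches a brute-force tally; rankings invariant to scale
  spec <- synthetic_spec(seed = 57, chain_length = 40, frames = 2)
  mm <- generate_chain(spec)
  cmm <- ensemble_contact_map(mm)
  rtm <- pair_ratio_table(cmm)
  seqs <- cmm$sequence
  manual <- 0
  nzc <- which(cmm$total != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nzc))) {
    a <- seqs[nzc[k, 1]]; b <- seqs[nzc[k, 2]]
    if (a == "SER" && b == "GLY" || a == "GLY" && b == "SER")
      manual <- manual + cmm$total[nzc[k, 1], nzc[k, 2]]
  }
  sg <- rtm$pairs[rtm$pairs$type_i == "GLY" & rtm$pairs$type_j == "SER", ]
  expect_equal(sg$contacts, manual)
  cm_scaled <- cmm; cm_scaled$total <- cmm$total * 7.5
  expect_identical(pair_ratio_table(cm_scaled)$pairs$rank, rtm$pairs$rank)
  expect_equal(pair_ratio_table(cm_scaled)$pairs$ratio, rtm$pairs$ratio)
  # per-type normalisation divides by abundance
  pt <- rtm$per_type
  expect_equal(pt$normalized[pt$aa_count > 0],
               (pt$contacts / pt$aa_count)[pt$aa_count > 0])
})

test_that("contact correlation: self, negation, degenerate input", {
  spec <- synthetic_spec(seed = 33, chain_length = 30, frames = 2)
  m <- generate_chain(spec)
  rt <- pair_ratio_table(ensemble_contact_map(m))
  self <- contact_correlation(rt, rt)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$slope, 1, tolerance = 1e-12)
  prof <- position_profile(ensemble_contact_map(m))
  expect_equal(contact_correlation(prof, -prof)$r, -1, tolerance = 1e-12)
  expect_error(contact_correlation(c(0, 0, 1), c(0, 0, 2)),
               "fewer than 3")
})

test_that("contact timeseries matches the frame-by-frame oracle", {
  spec <- synthetic_spec(seed = 12, chain_length = 20, frames = 4)
  m <- generate_chain(spec)
  ts <- contact_timeseries(m)
  manual <- vapply(1:4, function(f) sum(frame_contacts(m, f)$count),
                   numeric(1))
  expect_equal(ts$total, manual)
  # static trajectory -> constant series
  m2 <- m
  for (f in 2:4) m2$coords[, , f] <- m2$coords[, , 1]
  expect_identical(length(unique(contact_timeseries(m2)$total)), 1L)
})
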