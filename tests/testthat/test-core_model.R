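# Topology/trajectory container, PDB round trips, selections, domain maps.

test_that("multi-model PDB round trip preserves coordinates and identity", {
  spec <- synthetic_spec(seed = 11, chain_length = 25, frames = 3)
  m <- generate_chain(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  m2 <- read_structure(path)
  expect_equal(n_frames(m2), 3)
  expect_lt(max(abs(m2$coords - m$coords)), 5.1e-4)  # %8.3f precision
  expect_identical(m2$residues$res_type, m$residues$res_type)
  expect_identical(m2$residues$chain_id, m$residues$chain_id)
  expect_identical(m2$residues$seq_index, m$residues$seq_index)
  expect_identical(m2$atoms$name, m$atoms$name)
  # second round trip is exact (coordinates already quantised)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, path2)
  m3 <- read_structure(path2)
  expect_identical(m3$coords, m2$coords)
})

test_that("component labelling assigns water, ions, and unknowns", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000           C",
    "HETATM    2  O   HOH W   1       5.000   0.000   0.000           O",
    "HETATM    3 CL   CL  Y   1       9.000   0.000   0.000          CL",
    "HETATM    4 NA   NA  X   1      12.000   0.000   0.000          NA",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  m <- read_structure(path)
  expect_identical(m$residues$component, c("protein", "water", "Cl", "Na"))
  expect_identical(sum(component_sizes(m)), nrow(m$residues))
  expect_equal(m$atoms$mass[2], 18.0153)  # pseudo-water carries full mass
  # unknown residue type -> 'other' with a warning
  writeLines(c(lines[1],
    "HETATM    2  X1  XYZ B   1       3.000   0.000   0.000           C",
    "END"), path)
  expect_warning(expect_warning(m2 <- read_structure(path), "other"),
                 "carbon mass")
  expect_identical(m2$residues$component, c("protein", "other"))
})

test_that("inconsistent atom counts across models is a format error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000           C",
    "ENDMDL", "END"), path)
  expect_error(read_structure(path), "inconsistent atom counts")
})

test_that("elements are inferred from atom names when column is blank", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000",
    "ATOM      3  SG  CYS A   2       4.000   0.000   0.000",
    "END"), path)
  m <- read_structure(path)
  expect_identical(m$atoms$element, c("N", "C", "S"))
})

test_that("attach_trajectory replaces frames and validates atom counts", {
  spec <- synthetic_spec(seed = 4, chain_length = 10, frames = 4)
  m <- generate_chain(spec)
  tp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, tp)
  m1 <- slice_frames(m, 1)
  m2 <- attach_trajectory(m1, tp, "pdb")
  expect_equal(n_frames(m2), 4)
  # mismatched topology
  other <- generate_chain(synthetic_spec(seed = 4, chain_length = 11))
  expect_error(attach_trajectory(other, tp, "pdb"), "atom count")
  # empty trajectory file errors rather than succeeding
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(attach_trajectory(m1, empty, "pdb"))
})

test_that("DCD attachment reproduces coordinates (binary route)", {
  spec <- synthetic_spec(seed = 7, chain_length = 12, frames = 5)
  m <- generate_chain(spec)
  dir <- withr::local_tempdir()
  pdb <- file.path(dir, "t.pdb"); dcd <- file.path(dir, "t.dcd")
  write_structure(m, pdb)
  script <- file.path(dir, "conv.py")
  writeLines(c(
    "import MDAnalysis as mda, sys",
    "u = mda.Universe(sys.argv[1])",
    "with mda.Writer(sys.argv[2], u.atoms.n_atoms) as w:",
    "    for ts in u.trajectory: w.write(u.atoms)"), script)
  expect_identical(system2("python", c(script, pdb, dcd),
                           stdout = FALSE, stderr = FALSE), 0L)
  md <- attach_trajectory(slice_frames(m, 1), dcd, "dcd")
  expect_equal(n_frames(md), 5)
  expect_lt(max(abs(md$coords - round(m$coords, 3))), 1e-5)
})

test_that("XTC attachment converts nm to Angstrom", {
  spec <- synthetic_spec(seed = 7, chain_length = 12, frames = 3)
  m <- generate_chain(spec)
  dir <- withr::local_tempdir()
  pdb <- file.path(dir, "t.pdb"); xtc <- file.path(dir, "t.xtc")
  write_structure(m, pdb)
  script <- file.path(dir, "conv.py")
  writeLines(c(
    "import MDAnalysis as mda, sys",
    "u = mda.Universe(sys.argv[1])",
    "with mda.Writer(sys.argv[2], u.atoms.n_atoms) as w:",
    "    for ts in u.trajectory: w.write(u.atoms)"), script)
  expect_identical(system2("python", c(script, pdb, xtc),
                           stdout = FALSE, stderr = FALSE), 0L)
  mx <- attach_trajectory(slice_frames(m, 1), xtc, "xtc")
  expect_equal(n_frames(mx), 3)
  # XTC stores nm at 1e-3 nm precision = 0.01 A; values must come back
  # on the Angstrom scale (x10 the raw nm payload)
  expect_lt(max(abs(mx$coords - m$coords)), 0.02)
  expect_gt(max(abs(mx$coords)), 10)  # would be ~x10 smaller if left in nm
})

test_that("selections filter by domain, type, heaviness and compose", {
  dm <- fus_domain_map()
  expect_equal(domain_map_length(dm), 526)
  spec <- synthetic_spec(seed = 2, chain_length = 526, domain_map = dm)
  m <- generate_chain(spec)
  rrm <- select_atoms(m, domain = "RRM")
  rr <- range(m$residues$seq_index[m$atoms$res_id[rrm]])
  expect_identical(rr, c(285L, 371L))
  # res_type on a glycine-only chain -> empty with warning
  gly <- generate_chain(synthetic_spec(seed = 1, chain_length = 5,
                                       sequence = rep("GLY", 5)))
  expect_warning(idx <- select_atoms(gly, res_type = "ARG"), "empty")
  expect_length(idx, 0)
  # union of all domain selections covers every protein residue once
  # (overlap residue 453 appears in ZnF and RGG3; count unique residues)
  all_idx <- sort(unique(unlist(lapply(dm$domain, function(d)
    select_atoms(m, domain = d)))))
  expect_identical(all_idx, select_atoms(m, component = "protein"))
  # selection commutes with frame slicing (topology-only operation)
  expect_identical(select_atoms(slice_frames(m, 1), domain = "RRM"), rrm)
  # idempotence: selecting from the selection changes nothing
  expect_identical(select_atoms(m, domain = "RRM", heavy_only = TRUE), rrm)
})

test_that("domain map I/O and validation", {
  dm <- domain_map(c("A", "B"), c(1, 11), c(10, 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_domain_map(dm, path)
  dm2 <- read_domain_map(path)
  expect_equal(dm2$domain, dm$domain)
  expect_equal(dm2$first, dm$first)
  expect_equal(dm2$last, dm$last)
  expect_error(domain_map("X", 5, 3), "first <= last")
  expect_error(domain_map(c("X", "X"), c(1, 2), c(3, 4)), "duplicate")
  expect_identical(domain_of(dm, c(1, 10, 11, 25)),
                   c("A", "A", "B", "unassigned"))
})
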