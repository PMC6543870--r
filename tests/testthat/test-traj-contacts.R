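# Trajectory reading, center-of-mass tracking, geometric interaction typing
# and the dissociation-event criterion.

test_that("read_trajectory computes the mass-weighted ligand COM per frame", {
  toy <- gen_toy_complex(recipe = c(HB = 4), egress_frame = 2, n_frames = 3)
  fs <- read_trajectory(toy$topology, toy$frames,
                        ligand_types = toy$ligand_types)
  expect_s3_class(fs, "frame_series")
  expect_equal(nrow(fs$xyz), 3)
  # oracle: explicit weighted mean over the ligand atoms of frame 0
  lig <- fs$atoms$role == "ligand"
  m0 <- matrix(fs$xyz[1, ], nrow(fs$atoms), 3, byrow = TRUE)
  w <- fs$atoms$mass[lig] / sum(fs$atoms$mass[lig])
  expect_equal(unname(fs$ligand_com[1, ]),
               unname(colSums(m0[lig, , drop = FALSE] * w)))
  expect_equal(fs$initial_com, fs$ligand_com[1, ])
})

test_that("single-frame trajectories load and are censored", {
  toy <- gen_toy_complex(recipe = c(APO = NA), egress_frame = 4, n_frames = 5)
  fs <- read_trajectory(toy$topology, ligand_types = toy$ligand_types)
  expect_equal(nrow(fs$xyz), 1)  # topology alone = one model
  expect_true(is.na(detect_dissociation(fs)))
})

test_that("atom-count mismatches between topology and frames are rejected", {
  toy_a <- gen_toy_complex(recipe = c(HB = 1), egress_frame = 2, n_frames = 3)
  toy_b <- gen_toy_complex(recipe = c(HB = 1, APO = 2), egress_frame = 2,
                           n_frames = 3)
  expect_error(read_trajectory(toy_a$topology, toy_b$frames,
                               ligand_types = toy_b$ligand_types),
               "atom-count mismatch")
  expect_error(read_trajectory(toy_a$topology, toy_a$frames,
                               ligand_selection = "XYZ"),
               "empty ligand selection")
})

test_that("detect_dissociation finds the first frame past the threshold", {
  # ligand moving +1 A per frame along z from the contact position
  fs <- make_linear_series(z_lig = 0:40)
  expect_identical(detect_dissociation(fs, 30), 30L)
  expect_identical(detect_dissociation(fs, 0), 0L)   # degenerate threshold
  still <- make_linear_series(z_lig = rep(2, 10))
  expect_true(is.na(detect_dissociation(still, 30)))
  # non-decreasing in the threshold
  idx <- vapply(c(1, 5, 10, 20, 30, 40), function(th)
    detect_dissociation(fs, th), 0L)
  expect_true(all(diff(idx) >= 0))
})

test_that("hydrogen bonds are typed by distance and donor angle", {
  toy <- gen_toy_complex(recipe = c(HB = NA), egress_frame = 2, n_frames = 3)
  fs <- read_trajectory(toy$topology, toy$frames,
                        ligand_types = toy$ligand_types)
  ti <- type_interactions(fs, 0)
  expect_equal(nrow(ti), 1)
  expect_equal(ti$hb_donor, 1L)
  expect_equal(sum(ti[, c("hydrophobic", "aro_face", "aro_edge",
                          "hb_acceptor", "cationic", "anionic")]), 0)
  # a 12 A gap emits nothing
  far <- make_linear_series(z_lig = rep(12, 2))
  expect_equal(nrow(type_interactions(far, 0)), 0)
})

test_that("parallel rings at 3.8 A / 5 deg are face-to-face stacked", {
  # oracle geometry built directly: two hexagons, centroid distance 3.8,
  # plane angle 5 degrees
  ring_at <- function(center, tilt = 0) {
    th <- seq(0, 2 * pi, length.out = 7)[-7]
    t(vapply(th, function(a) {
      p <- c(1.39 * cos(a), 1.39 * sin(a), 0)
      R <- matrix(c(1, 0, 0, 0, cos(tilt), -sin(tilt),
                    0, sin(tilt), cos(tilt)), 3, byrow = TRUE)
      center + drop(R %*% p)
    }, numeric(3)))
  }
  prot_ring <- ring_at(c(0, 0, 0))
  lig_ring <- ring_at(c(0, 0, 3.8), tilt = 5 * pi / 180)
  nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  atoms <- data.frame(
    atom = c(nm, paste0("C", 1:6)), resno = c(rep(40L, 6), rep(1L, 6)),
    resid = c(rep("PHE", 6), rep("LIG", 6)),
    role = rep(c("protein", "ligand"), each = 6), element = "C",
    mass = 12.011, charge = 0,
    aromatic = TRUE, donor = FALSE, acceptor = FALSE, apolar = FALSE,
    ring_id = c(rep("P40.1", 6), rep("L1", 6)), stringsAsFactors = FALSE)
  fs <- frame_series(atoms, matrix(as.vector(t(rbind(prot_ring, lig_ring))),
                                   nrow = 1))
  ti <- type_interactions(fs, 0)
  expect_equal(ti$aro_face, 1L)
  expect_equal(ti$aro_edge, 0L)
})

test_that("missing atom typing raises a classed error", {
  fs <- make_linear_series(z_lig = c(3, 4))
  fs$atoms$donor <- NULL
  expect_error(type_interactions(fs, 0), class = "tauramd_typing_error")
})

test_that("category grouping is the OR of the constituent flags", {
  # exhaustive over all 2^7 input patterns against a brute-force oracle
  for (i in 0:127) {
    bits <- as.integer(intToBits(i)[1:7])
    got <- group_to_categories(bits)
    expect_identical(got, c(HB = as.integer(bits[4] || bits[5]),
                            ARO = as.integer(bits[2] || bits[3]),
                            IP = as.integer(bits[6] || bits[7]),
                            APO = bits[1]))
  }
  expect_identical(group_to_categories(c(1, 0, 0, 0, 0, 0, 0)),
                   c(HB = 0L, ARO = 0L, IP = 0L, APO = 1L))
  expect_identical(unname(group_to_categories(c(0, 0, 0, 1, 1, 0, 0))),
                   c(1L, 0L, 0L, 0L))
})

test_that("interaction typing is invariant under rigid motion", {
  toy <- gen_toy_complex()
  fs <- read_trajectory(toy$topology, toy$frames,
                        ligand_types = toy$ligand_types)
  fs2 <- transform_series(fs)
  for (f in c(0L, 3L, 6L))
    expect_equal(type_interactions(fs, f), type_interactions(fs2, f))
  expect_identical(fingerprint_trajectory(fs)$frames,
                   fingerprint_trajectory(fs2)$frames)
})

test_that("fingerprinting a reversed trajectory reverses the rows", {
  toy <- gen_toy_complex()
  fs <- read_trajectory(toy$topology, toy$frames,
                        ligand_types = toy$ligand_types)
  ifs <- fingerprint_trajectory(fs)
  rev_fs <- frame_series(fs$atoms, fs$xyz[rev(seq_len(nrow(fs$xyz))), ],
                         fs$frame_times)
  rev_ifs <- fingerprint_trajectory(rev_fs)
  expect_identical(unname(rev_ifs$frames[, colnames(ifs$frames)]),
                   unname(ifs$frames[rev(seq_len(nrow(ifs$frames))), ]))
})

test_that("fingerprint series round-trip through CSV + sidecar", {
  toy <- gen_toy_complex(recipe = c(HB = 2, IP = 3), egress_frame = 5,
                         n_frames = 6)
  fs <- read_trajectory(toy$topology, toy$frames,
                        ligand_types = toy$ligand_types,
                        compound_id = "cmpdX", replica_id = "r2",
                        trajectory_id = "t7")
  ifs <- fingerprint_trajectory(fs)
  path <- file.path(tempdir(), "ifs_roundtrip.csv")
  write_if_series(ifs, path)
  back <- read_if_series(path)
  expect_identical(back$frames, ifs$frames)
  expect_identical(back$dissociation_frame, ifs$dissociation_frame)
  expect_identical(back$compound_id, "cmpdX")
  expect_identical(back$replica_id, "r2")
})
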