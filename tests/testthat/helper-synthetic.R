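# Shared fixture builders (all generated in code; no stored data).

# if_series from a 0/1 matrix given as rows = frames
make_ifs <- function(mat, dis = nrow(mat) - 1L, cmpd = "cmpd", traj = "t1") {
  if (is.null(colnames(mat)))
    colnames(mat) <- letters[seq_len(ncol(mat))]
  if_series(mat, dissociation_frame = dis, compound_id = cmpd,
            trajectory_id = traj)
}

# three well-separated Gaussian blobs in [0,1]^d with labels by blob
make_blobs <- function(n_per = 30, d = 5, sd = 0.04, seed = 42,
                       label_means = c(-1, 0.5, 2)) {
  set.seed(seed)
  ctr <- matrix(runif(3 * d, 0.15, 0.85), 3)
  x <- do.call(rbind, lapply(1:3, function(i)
    matrix(rnorm(n_per * d, rep(ctr[i, ], each = n_per), sd), n_per)))
  colnames(x) <- paste0("f", seq_len(d))
  rownames(x) <- paste0("c", seq_len(3 * n_per))
  list(x = x, labels = rep(label_means, each = n_per),
       truth = rep(1:3, each = n_per))
}

# minimal two-atom frame series: one ligand carbon approaching/leaving one
# leucine CD1 along z; useful for COM and dissociation checks
make_linear_series <- function(z_lig, cmpd = "cmpd") {
  atoms <- data.frame(
    atom = c("CD1", "C1"), resno = c(10L, 1L), resid = c("LEU", "LIG"),
    role = c("protein", "ligand"), element = "C", mass = 12.011,
    charge = 0, aromatic = FALSE, donor = FALSE, acceptor = FALSE,
    apolar = TRUE, ring_id = NA_character_, stringsAsFactors = FALSE)
  xyz <- t(vapply(z_lig, function(z) c(0, 0, 0, 0, 0, z), numeric(6)))
  frame_series(atoms, xyz, compound_id = cmpd)
}

# apply a rigid rotation + translation to every frame of a frame_series
transform_series <- function(fs, angle = 0.7, axis = c(1, 2, 2) / 3,
                             shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  n <- nrow(fs$atoms)
  xyz2 <- fs$xyz
  for (f in seq_len(nrow(fs$xyz))) {
    m <- matrix(fs$xyz[f, ], n, 3, byrow = TRUE)
    m <- sweep(m %*% t(R), 2, shift, "+")
    xyz2[f, ] <- as.vector(t(m))
  }
  frame_series(fs$atoms, xyz2, fs$frame_times, fs$compound_id,
               fs$replica_id, fs$trajectory_id)
}
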