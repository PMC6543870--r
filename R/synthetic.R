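# Synthetic inputs for building and testing the pipeline without downloads:
# programmable contact-loss fingerprint streams, planted-law compound sets,
# replica egress-time samples, and toy coordinate fixtures in which every
# contact archetype satisfies the geometric cutoffs by construction.

#' Contact-loss schedule for a synthetic fingerprint stream
#'
#' @param features character feature names.
#' @param bound subset of `features` present in the bound state (frame 0).
#' @param loss_frame named integer vector: frame at which each feature is
#'   lost (`NA` = never lost before egress). Non-bound features behave as
#'   lost at frame 0. Loss frames must not exceed the egress frame.
#' @param reform_prob per-frame probability that a lost contact transiently
#'   re-forms (scalar or named vector, default 0).
#' @param n_frames trajectory length in frames.
#' @param egress_frame 0-based dissociation frame (default last frame).
#' @return an object of class `contact_schedule`.
#' @export
contact_schedule <- function(features, bound = features,
                             loss_frame = NULL, reform_prob = 0,
                             n_frames = 20,
                             egress_frame = n_frames - 1L) {
  if (length(bound) == 0) stopf("bound set must be non-empty")
  if (!all(bound %in% features)) stopf("bound set outside feature list")
  lf <- stats::setNames(rep(NA_real_, length(features)), features)
  if (!is.null(loss_frame)) lf[names(loss_frame)] <- loss_frame
  lf[!(features %in% bound) & is.na(lf)] <- 0
  if (any(lf > egress_frame, na.rm = TRUE))
    stopf("loss frames must not exceed the egress frame")
  rp <- stats::setNames(rep_len(reform_prob, length(features)), features)
  if (egress_frame >= n_frames) stopf("egress frame beyond trajectory")
  structure(list(features = features, bound = bound, loss_frame = lf,
                 reform_prob = rp, n_frames = n_frames,
                 egress_frame = as.integer(egress_frame)),
            class = "contact_schedule")
}

#' Generate a fingerprint series from a contact schedule
#'
#' A feature is present while its loss frame has not been reached; after
#' loss it re-forms independently per frame with its re-formation
#' probability. Deterministic under the seed.
#'
#' @param schedule a [contact_schedule()].
#' @param seed integer seed.
#' @param compound_id,replica_id,trajectory_id identifiers.
#' @return an [if_series()].
#' @export
gen_if_series <- function(schedule, seed = 1L, compound_id = "cmpd",
                          replica_id = "r1", trajectory_id = "t1") {
  stopifnot(inherits(schedule, "contact_schedule"))
  nf <- schedule$n_frames
  feats <- schedule$features
  mat <- matrix(0L, nf, length(feats), dimnames = list(NULL, feats))
  with_seed(seed, {
    for (j in seq_along(feats)) {
      lf <- schedule$loss_frame[j]
      held <- if (is.na(lf)) rep(TRUE, nf) else (seq_len(nf) - 1) < lf
      reformed <- !held & stats::runif(nf) < schedule$reform_prob[j]
      mat[, j] <- as.integer(held | reformed)
    }
  })
  if_series(mat, dissociation_frame = schedule$egress_frame,
            compound_id = compound_id, replica_id = replica_id,
            trajectory_id = trajectory_id)
}

#' Planted linear feature-to-residence-time law
#'
#' @param n_features number of features (ignored when `weights` given).
#' @param weights per-feature weights in log10(s) per unit occurrence
#'   (default drawn N(0,1) under `seed`).
#' @param intercept label intercept, log10(s) (default -1, centering labels
#'   in the observed experimental range of roughly -4..2).
#' @param noise_sd label noise SD in log10(s) (default 0.3).
#' @param occupancy_shape Beta distribution shape parameters for feature
#'   occurrences.
#' @param seed seed for the default weight draw.
#' @return an object of class `planted_model`.
#' @export
planted_model <- function(n_features = 47, weights = NULL, intercept = -1,
                          noise_sd = 0.3, occupancy_shape = c(2, 2),
                          seed = 1L) {
  if (noise_sd < 0) stopf("noise SD must be >= 0")
  if (is.null(weights))
    weights <- with_seed(substream_seed(seed, "weights"),
                         stats::rnorm(n_features))
  structure(list(weights = weights, intercept = intercept,
                 noise_sd = noise_sd, occupancy_shape = occupancy_shape),
            class = "planted_model")
}

#' Generate a compound set with a planted linear law
#'
#' Feature occurrences are iid Beta draws in \[0,1\]; labels are
#' `intercept + occurrences %*% weights + N(0, noise_sd)`. Annotations mimic
#' the composition of the study set: an `indazole` pool (45 of 94 by
#' default), an `outlier` pool of 14 (8 flagged `quinazoline` plus 6 others)
#' and a residual class.
#'
#' @param n_compounds number of compounds (>= 10; default 94).
#' @param n_features number of features (default 47).
#' @param model a [planted_model()].
#' @param seed integer seed.
#' @param n_indazole,n_quinazoline,n_other_outlier annotation pool sizes,
#'   scaled down proportionally for small sets.
#' @return a [feature_matrix()]; the ground truth (weights, intercept,
#'   noise SD, seed) is attached as attribute `"manifest"`.
#' @export
gen_compound_set <- function(n_compounds = 94, n_features = 47,
                             model = planted_model(n_features, seed = seed),
                             seed = 1L,
                             n_indazole = round(45 / 94 * n_compounds),
                             n_quinazoline = max(2, round(8 / 94 * n_compounds)),
                             n_other_outlier = max(1, round(6 / 94 * n_compounds))) {
  if (n_compounds < 10) stopf("need at least 10 compounds")
  if (length(model$weights) != n_features)
    stopf("planted model has %d weights for %d features",
          length(model$weights), n_features)
  ids <- sprintf("c%03d", seq_len(n_compounds))
  x <- with_seed(substream_seed(seed, "occurrence"),
                 matrix(stats::rbeta(n_compounds * n_features,
                                     model$occupancy_shape[1],
                                     model$occupancy_shape[2]),
                        n_compounds, n_features,
                        dimnames = list(ids, sprintf("f%02d", seq_len(n_features)))))
  noise <- with_seed(substream_seed(seed, "noise"),
                     stats::rnorm(n_compounds, 0, model$noise_sd))
  labels <- model$intercept + drop(x %*% model$weights) + noise
  scaffold <- rep("other", n_compounds)
  scaffold[seq_len(n_quinazoline)] <- "quinazoline"
  scaffold[n_quinazoline + seq_len(n_indazole)] <- "indazole"
  outlier <- logical(n_compounds)
  outlier[seq_len(n_quinazoline)] <- TRUE
  other_pool <- which(scaffold == "other")
  outlier[utils::tail(other_pool, n_other_outlier)] <- TRUE
  ann <- data.frame(scaffold = scaffold, outlier = outlier,
                    indazole = scaffold == "indazole")
  fm <- feature_matrix(x, labels, ann)
  attr(fm, "manifest") <- list(weights = model$weights,
                               intercept = model$intercept,
                               noise_sd = model$noise_sd, seed = seed)
  fm
}

#' Generate replica-structured egress times
#'
#' @param n_replicas number of equilibration replicas (default 4).
#' @param n_traj dissociation trajectories per replica (default 15).
#' @param distribution "lognormal", "exponential" or "point".
#' @param params distribution parameters: `meanlog`/`sdlog` (lognormal, ns),
#'   `mean` (exponential, ns) or `value` (point, ns).
#' @param seed integer seed.
#' @param compound_id identifier.
#' @param censor_above trajectories exceeding this time (ns) are censored at
#'   it (default `Inf`, no censoring).
#' @return an [egress_times()] object.
#' @export
gen_egress_times <- function(n_replicas = 4, n_traj = 15,
                             distribution = c("lognormal", "exponential",
                                              "point"),
                             params = list(meanlog = log(2), sdlog = 0.5),
                             seed = 1L, compound_id = "cmpd",
                             censor_above = Inf) {
  distribution <- match.arg(distribution)
  reps <- with_seed(substream_seed(seed, paste0("egress.", compound_id)), {
    lapply(seq_len(n_replicas), function(r) {
      t <- switch(distribution,
        lognormal = stats::rlnorm(n_traj, params$meanlog, params$sdlog),
        exponential = stats::rexp(n_traj, rate = 1 / params$mean),
        point = rep(params$value, n_traj))
      cens <- t > censor_above
      t[cens] <- censor_above
      list(times = t, censored = cens)
    })
  })
  names(reps) <- paste0("r", seq_len(n_replicas))
  egress_times(compound_id, reps)
}

# ---- toy coordinate fixtures ---------------------------------------------

TOY_ARCHETYPES <- c("HB", "APO", "IP", "ARO_FACE", "ARO_EDGE")

hexagon <- function(center, radius = 1.39, normal = c(0, 0, 1)) {
  # orthonormal basis of the ring plane
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal; u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  t(vapply(th, function(a) center + radius * (cos(a) * u + sin(a) * v),
           numeric(3)))
}

#' Generate a toy protein-ligand complex fixture
#'
#' Writes a small complex in which each requested contact archetype satisfies
#' the default geometric cutoffs in frame 0 and is broken (the ligand
#' fragment is displaced) at a scripted frame; at the egress frame the whole
#' ligand is translated so that its center of mass crosses the 30 Angstrom
#' dissociation threshold. Files written: `topology.pdb` (frame 0),
#' `frames.pdb` (multi-model), `ligand_types.csv`, `manifest.json` (the
#' scheduled per-frame contact pattern). All coordinates are synthetic.
#'
#' @param recipe named numeric vector of break frames per archetype, names
#'   from `HB`, `APO`, `IP`, `ARO_FACE`, `ARO_EDGE` (value `NA` = broken only
#'   by egress). An empty recipe writes a complex with no contacts.
#' @param egress_frame 0-based dissociation frame (default 12).
#' @param n_frames trajectory length (default `egress_frame + 1`).
#' @param dir output directory.
#' @return list with file paths, the expected feature names and the expected
#'   per-frame presence matrix (`expected`).
#' @export
gen_toy_complex <- function(recipe = c(HB = 4, APO = 6, IP = 8,
                                       ARO_FACE = 5, ARO_EDGE = 7),
                            egress_frame = 12, n_frames = egress_frame + 1,
                            dir = tempfile("toycomplex")) {
  if (length(recipe) && is.null(names(recipe)))
    stopf("recipe must be named by archetype")
  bad <- setdiff(names(recipe), TOY_ARCHETYPES)
  if (length(bad)) stopf("unsupported archetype(s): %s",
                         paste(bad, collapse = ", "))
  if (egress_frame >= n_frames) stopf("egress frame beyond trajectory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  arche <- names(recipe)
  slot <- function(a) 20 * (match(a, TOY_ARCHETYPES) - 1)
  atoms <- list()  # each: name, resno, resid, xyz, group ("prot"/archetype)
  add <- function(name, resno, resid, xyz, group)
    atoms[[length(atoms) + 1L]] <<- list(name = name, resno = resno,
                                         resid = resid, xyz = xyz,
                                         group = group)
  # protein side (always below the interface plane except the contact atoms)
  if ("HB" %in% arche) {
    x0 <- slot("HB")
    add("N", 10L, "GLY", c(x0, 0, -7), "prot")
    add("CA", 10L, "GLY", c(x0 + 1.5, 0, -7), "prot")
    add("C", 10L, "GLY", c(x0 + 3, 0, -7), "prot")
    add("O", 10L, "GLY", c(x0, 0, 0), "prot")       # acceptor at interface
  }
  if ("APO" %in% arche) {
    x0 <- slot("APO")
    add("N", 20L, "LEU", c(x0, 0, -7), "prot")
    add("CA", 20L, "LEU", c(x0 + 1.5, 0, -7), "prot")
    add("C", 20L, "LEU", c(x0 + 3, 0, -7), "prot")
    add("O", 20L, "LEU", c(x0 + 3, 1.2, -7), "prot")
    add("CB", 20L, "LEU", c(x0, 0, -5), "prot")
    add("CG", 20L, "LEU", c(x0, 1.5, -5), "prot")
    add("CD2", 20L, "LEU", c(x0, 3, -5), "prot")
    add("CD1", 20L, "LEU", c(x0, 0, 0), "prot")     # apolar at interface
  }
  if ("IP" %in% arche) {
    x0 <- slot("IP")
    add("CB", 30L, "ASP", c(x0, 0, -5), "prot")
    add("CG", 30L, "ASP", c(x0, 0, -2.5), "prot")
    add("OD1", 30L, "ASP", c(x0, 0, 0), "prot")     # anion at interface
    add("OD2", 30L, "ASP", c(x0 + 1.2, 0, -1), "prot")
  }
  if ("ARO_FACE" %in% arche) {
    x0 <- slot("ARO_FACE")
    ring <- hexagon(c(x0, 0, 0))
    nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    for (i in 1:6) add(nm[i], 40L, "PHE", ring[i, ], "prot")
    add("CB", 40L, "PHE", c(x0, -3, -2), "prot")
  }
  if ("ARO_EDGE" %in% arche) {
    x0 <- slot("ARO_EDGE")
    ring <- hexagon(c(x0, 0, 0))
    nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    for (i in 1:6) add(nm[i], 50L, "TYR", ring[i, ], "prot")
    add("CB", 50L, "TYR", c(x0, -3, -2), "prot")
  }
  # ligand side: one fragment per archetype, typed explicitly
  lig <- list()  # name, xyz, typing row, group
  ligadd <- function(name, xyz, group, element, charge = 0, aromatic = FALSE,
                     donor = FALSE, acceptor = FALSE, apolar = FALSE,
                     ring_id = NA) {
    lig[[length(lig) + 1L]] <<- list(name = name, xyz = xyz, group = group,
                                     element = element, charge = charge,
                                     aromatic = aromatic, donor = donor,
                                     acceptor = acceptor, apolar = apolar,
                                     ring_id = ring_id)
  }
  if ("HB" %in% arche) {
    x0 <- slot("HB")
    ligadd("N1", c(x0, 0, 2.9), "HB", "N", donor = TRUE)
    ligadd("H1", c(x0, 0, 1.9), "HB", "H")
  }
  if ("APO" %in% arche)
    ligadd("C2", c(slot("APO"), 0, 3.8), "APO", "C", apolar = TRUE)
  if ("IP" %in% arche)
    ligadd("N2", c(slot("IP"), 0, 3.5), "IP", "N", charge = 1)
  if ("ARO_FACE" %in% arche) {
    ring <- hexagon(c(slot("ARO_FACE"), 0, 3.6))
    for (i in 1:6) ligadd(paste0("C", i + 2), ring[i, ], "ARO_FACE", "C",
                          aromatic = TRUE, ring_id = 1)
  }
  if ("ARO_EDGE" %in% arche) {
    ring <- hexagon(c(slot("ARO_EDGE"), 0, 5.0), normal = c(1, 0, 0))
    for (i in 1:6) ligadd(paste0("C", i + 8), ring[i, ], "ARO_EDGE", "C",
                          aromatic = TRUE, ring_id = 2)
  }
  if (length(lig) == 0)  # empty recipe: a bare ligand atom far from protein
    ligadd("C1", c(0, 50, 50), "none", "C", apolar = TRUE)

  # assemble per-frame coordinates
  n_prot <- length(atoms); n_lig <- length(lig)
  base <- rbind(do.call(rbind, lapply(atoms, `[[`, "xyz")),
                do.call(rbind, lapply(lig, `[[`, "xyz")))
  lig_group <- vapply(lig, `[[`, "", "group")
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    xyz <- base
    for (a in arche) {
      brk <- recipe[[a]]
      if (!is.na(brk) && f >= brk)
        xyz[n_prot + which(lig_group == a), 3] <-
          xyz[n_prot + which(lig_group == a), 3] + 25
    }
    if (f >= egress_frame) xyz[n_prot + seq_len(n_lig), 3] <-
      xyz[n_prot + seq_len(n_lig), 3] + 40
    frames[[f + 1L]] <- xyz
  }

  # PDB records
  rec <- function(i, name, resid, resno, xyz, element) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, name, resid, resno, xyz[1], xyz[2], xyz[3], element)
  }
  prot_el <- vapply(atoms, function(a) substr(a$name, 1, 1), "")
  all_names <- c(vapply(atoms, `[[`, "", "name"), vapply(lig, `[[`, "", "name"))
  all_resid <- c(vapply(atoms, `[[`, "", "resid"), rep("LIG", n_lig))
  all_resno <- c(vapply(atoms, function(a) a$resno, 0L), rep(1L, n_lig))
  all_el <- c(prot_el, vapply(lig, `[[`, "", "element"))
  pdb_lines <- function(xyz) c(
    vapply(seq_len(nrow(xyz)), function(i)
      rec(i, all_names[i], all_resid[i], all_resno[i], xyz[i, ], all_el[i]),
      ""), "TER", "END")
  topology <- file.path(dir, "topology.pdb")
  writeLines(pdb_lines(frames[[1]]), topology)
  frames_path <- file.path(dir, "frames.pdb")
  con <- file(frames_path, "w")
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(utils::head(pdb_lines(frames[[f]]), -1), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)

  types <- data.frame(atom = vapply(lig, `[[`, "", "name"),
                      element = vapply(lig, `[[`, "", "element"),
                      charge = vapply(lig, `[[`, 0, "charge"),
                      aromatic = vapply(lig, `[[`, FALSE, "aromatic"),
                      donor = vapply(lig, `[[`, FALSE, "donor"),
                      acceptor = vapply(lig, `[[`, FALSE, "acceptor"),
                      apolar = vapply(lig, `[[`, FALSE, "apolar"),
                      ring_id = vapply(lig, function(l)
                        if (is.na(l$ring_id)) NA_character_
                        else as.character(l$ring_id), ""))
  types_path <- file.path(dir, "ligand_types.csv")
  utils::write.csv(types, types_path, row.names = FALSE)

  feat_name <- c(HB = "G10-HB", APO = "L20-APO", IP = "D30-IP",
                 ARO_FACE = "F40-ARO", ARO_EDGE = "Y50-ARO")
  feats <- unname(feat_name[arche])
  expected <- matrix(0L, n_frames, length(feats),
                     dimnames = list(NULL, feats))
  for (i in seq_along(arche)) {
    brk <- recipe[[arche[i]]]
    last <- min(if (is.na(brk)) Inf else brk, egress_frame)
    if (last > 0) expected[seq_len(last), i] <- 1L
  }
  if (length(feats)) {
    ord <- order_features(feats)
    feats <- feats[ord]; expected <- expected[, ord, drop = FALSE]
  }
  manifest <- list(archetypes = as.list(recipe), egress_frame = egress_frame,
                   n_frames = n_frames, features = feats,
                   expected = expected)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  list(dir = dir, topology = topology, frames = frames_path,
       ligand_types = types_path,
       manifest = file.path(dir, "manifest.json"),
       features = feats, expected = expected)
}
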