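#' Build a rigid pseudo-protein for docking simulations
#'
#' A coarse stand-in (synthetic, not derived from any deposited structure)
#' for an ORD-fold lipid-transfer protein, carrying exactly the features
#' the geometry analyses reference:
#' * an orientation segment, residues 346-356, whose CA pseudo-atoms are
#'   collinear along the body x axis (so its principal axis is exact);
#' * three pocket-entry residues 129, 185 and 190 clustered below the
#'   center of mass;
#' * a ring of body residues giving the molecule bulk.
#'
#' Each residue is a cluster of `atoms_per_residue` points whose mean is
#' exactly the residue center, so unit-mass residue centers of mass are
#' known in closed form. The whole-protein unit-mass center of mass is
#' translated to the origin.
#'
#' @param n_body number of body residues (ids 1..n_body).
#' @param atoms_per_residue atoms per residue cluster (>= 1).
#' @param cluster_radius radius of each residue's atom cluster, Angstrom.
#' @param body_radius radius of the body residue ring, Angstrom.
#' @param entry_drop z offset of the entry residues below the protein
#'   center of mass, Angstrom (positive = below).
#' @param seed integer seed for the (deterministic per seed) cluster
#'   offsets.
#' @return data.frame of atom records (columns `atom_id`, `atom_name`,
#'   `residue_id`, `residue_name`, `chain_tag`, `leaflet`, `x`, `y`, `z`)
#'   with attribute `residue_centers` (data.frame residue_id, x, y, z).
#' @export
pseudo_protein <- function(n_body = 24, atoms_per_residue = 1,
                           cluster_radius = 0.5, body_radius = 12,
                           entry_drop = 6, seed = 7) {
  segment_ids <- 346:356
  entry_ids <- c(129L, 185L, 190L)
  body_ids <- seq_len(n_body)

  ang <- 2 * pi * (seq_along(body_ids) - 1) / length(body_ids)
  centers <- rbind(
    data.frame(residue_id = body_ids,
               x = body_radius * cos(ang), y = body_radius * sin(ang),
               z = 3 * sin(2 * ang)),
    data.frame(residue_id = entry_ids,
               x = c(-3, 3, 0), y = c(0, 0, 3), z = -entry_drop),
    data.frame(residue_id = segment_ids,
               x = seq(-7.5, 7.5, length.out = length(segment_ids)),
               y = 3, z = 4)
  )

  atoms <- with_seed(seed, {
    rows <- lapply(seq_len(nrow(centers)), function(i) {
      nc <- atoms_per_residue
      if (nc == 1L) {
        off <- matrix(0, 1, 3)
      } else {
        off <- matrix(stats::rnorm(3 * nc, 0, cluster_radius), nc, 3)
        off <- sweep(off, 2, colMeans(off))  # cluster mean exactly at center
      }
      data.frame(
        atom_name = if (nc == 1L) "CA" else c("CA", paste0("C", seq_len(nc - 1L))),
        residue_id = centers$residue_id[i],
        x = centers$x[i] + off[, 1],
        y = centers$y[i] + off[, 2],
        z = centers$z[i] + off[, 3],
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  com <- colMeans(atoms[, c("x", "y", "z")])
  atoms$x <- atoms$x - com[1]
  atoms$y <- atoms$y - com[2]
  atoms$z <- atoms$z - com[3]
  centers$x <- centers$x - com[1]
  centers$y <- centers$y - com[2]
  centers$z <- centers$z - com[3]

  out <- data.frame(
    atom_id = seq_len(nrow(atoms)),
    atom_name = atoms$atom_name,
    residue_id = atoms$residue_id,
    residue_name = "ALA",
    chain_tag = "PROT",
    leaflet = "none",
    x = atoms$x, y = atoms$y, z = atoms$z,
    stringsAsFactors = FALSE)
  attr(out, "residue_centers") <- centers
  out
}

#' Define a scripted docking schedule
#'
#' Piecewise-linear targets for the protein's center-of-mass height above
#' the membrane plane and its segment orientation angle, plus the
#' positional noise added to every atom coordinate. The simulator follows
#' the schedule exactly before noise, so the schedule is the ground truth
#' for parameter-recovery tests.
#'
#' @param time_ns strictly increasing breakpoint times, ns, covering the
#'   simulated duration from 0.
#' @param height_A target center-of-mass heights at the breakpoints,
#'   Angstrom above the upper-leaflet headgroup plane.
#' @param angle_deg target segment angles at the breakpoints, degrees in
#'   `[0, 90]` relative to the membrane plane.
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise added
#'   to every atom coordinate, Angstrom.
#' @param seed integer seed for the noise.
#' @return an object of class `lip_schedule`.
#' @export
docking_schedule <- function(time_ns, height_A, angle_deg, noise_sd = 0,
                             seed = 1) {
  if (length(time_ns) < 2L || any(diff(time_ns) <= 0)) {
    stop("time_ns must be strictly increasing with >= 2 breakpoints")
  }
  if (length(height_A) != length(time_ns) ||
      length(angle_deg) != length(time_ns)) {
    stop("height_A and angle_deg must match time_ns in length")
  }
  if (any(angle_deg < 0 | angle_deg > 90)) {
    stop("angle_deg must lie in [0, 90]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(time_ns = time_ns, height_A = height_A,
                 angle_deg = angle_deg, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "lip_schedule")
}

#' A distant-approach schedule preset
#'
#' Starts the protein about 54 A above the headgroup plane (a solvated
#' starting pose well clear of the membrane), approaches, docks and
#' reorients to a shallow membrane-bound angle. The approach kinetics are
#' a scripted stand-in, not a physical model.
#'
#' @param duration_ns total schedule duration, ns.
#' @param noise_sd,seed passed to [docking_schedule()].
#' @return a `lip_schedule`.
#' @export
approach_schedule <- function(duration_ns = 500, noise_sd = 0.5, seed = 1) {
  docking_schedule(
    time_ns = c(0, 0.2, 0.5, 1) * duration_ns,
    height_A = c(54, 30, 16, 16),
    angle_deg = c(60, 45, 10, 10),
    noise_sd = noise_sd, seed = seed)
}

# linear interpolation of the schedule at arbitrary times (ns)
schedule_at <- function(schedule, t_ns) {
  if (min(t_ns) < min(schedule$time_ns) - 1e-9 ||
      max(t_ns) > max(schedule$time_ns) + 1e-9) {
    stop("schedule does not cover requested times [",
         format(min(t_ns)), ", ", format(max(t_ns)), "] ns")
  }
  list(h = stats::approx(schedule$time_ns, schedule$height_A, t_ns,
                         rule = 2)$y,
       theta = stats::approx(schedule$time_ns, schedule$angle_deg, t_ns,
                             rule = 2)$y)
}

#' Simulate a rigid-body docking trajectory with known ground truth
#'
#' The protein is translated and rotated rigidly so that, frame by frame,
#' its unit-mass center-of-mass height above the (static) upper-leaflet
#' headgroup plane and its segment angle follow the schedule exactly;
#' i.i.d. Gaussian noise (`schedule$noise_sd`) is then added to every atom
#' coordinate of protein and membrane alike. Frames are emitted at
#' `t = k * frame_interval` for `k = 1..duration/frame_interval`, so a
#' 500 ns run sampled every 100 ps yields 5000 frames.
#'
#' @param protein atom records from [pseudo_protein()] (or any rigid
#'   PROT-chain atom set whose unit-mass center of mass is at the origin
#'   and whose 346-356 CA atoms are collinear along x).
#' @param bilayer a [build_bilayer()] result.
#' @param schedule a [docking_schedule()].
#' @param frame_interval frame spacing, ps.
#' @param duration_ns simulated duration, ns.
#' @param contact_threshold threshold used for the ground-truth contact
#'   indicator, Angstrom (default 5).
#' @return list with `trajectory` (a [trajectory()]) and `truth`, a list:
#'   `time_ns`, `h` (true COM heights), `theta` (true angles), `h_entry`
#'   (true pocket-entry heights), `plane_z` (static noiseless plane),
#'   `contact` (residues x frames logical matrix of the noiseless contact
#'   indicator) and `contact_fraction` (per-residue percentage).
#' @export
simulate_docking_trajectory <- function(protein, bilayer, schedule,
                                        frame_interval = 100,
                                        duration_ns = 1,
                                        contact_threshold = 5) {
  stopifnot(inherits(bilayer, "lip_bilayer"),
            inherits(schedule, "lip_schedule"))
  n_fr <- duration_ns * 1000 / frame_interval
  if (abs(n_fr - round(n_fr)) > 1e-9) {
    stop("duration_ns must be a multiple of frame_interval")
  }
  n_fr <- as.integer(round(n_fr))
  t_ns <- seq_len(n_fr) * frame_interval / 1000
  targ <- schedule_at(schedule, t_ns)

  mem <- bilayer$atoms
  plane_z <- mean(mem$z[mem$leaflet == "upper"])
  prot_xyz <- as.matrix(protein[, c("x", "y", "z")])
  mem_xyz <- as.matrix(mem[, c("x", "y", "z")])
  n_p <- nrow(prot_xyz); n_m <- nrow(mem_xyz)

  top <- rbind(
    data.frame(atom_id = seq_len(n_p),
               atom_name = protein$atom_name,
               residue_id = protein$residue_id,
               residue_name = protein$residue_name,
               chain_tag = "PROT", leaflet = "none",
               stringsAsFactors = FALSE),
    data.frame(atom_id = n_p + seq_len(n_m),
               atom_name = mem$atom_name,
               residue_id = mem$residue_id,
               residue_name = mem$residue_name,
               chain_tag = "MEMB", leaflet = mem$leaflet,
               stringsAsFactors = FALSE))

  res_ids <- unique(protein$residue_id)
  res_index <- split(seq_len(n_p), protein$residue_id)[as.character(res_ids)]

  coords <- array(NA_real_, c(n_p + n_m, 3L, n_fr))
  truth_h_entry <- numeric(n_fr)
  contact <- matrix(NA, length(res_ids), n_fr,
                    dimnames = list(res_ids, NULL))
  entry_rows <- which(protein$residue_id %in% c(129L, 185L, 190L))

  for (k in seq_len(n_fr)) {
    rot <- prot_xyz %*% t(rot_y(targ$theta[k]))
    rot[, 3] <- rot[, 3] + plane_z + targ$h[k]
    coords[seq_len(n_p), , k] <- rot
    coords[n_p + seq_len(n_m), , k] <- mem_xyz
    truth_h_entry[k] <- mean(rot[entry_rows, 3]) - plane_z
    res_z <- vapply(res_index, function(idx) mean(rot[idx, 3]), numeric(1))
    contact[, k] <- (res_z - plane_z) < contact_threshold
  }
  if (schedule$noise_sd > 0) {
    coords <- coords + with_seed(schedule$seed,
      array(stats::rnorm(length(coords), 0, schedule$noise_sd), dim(coords)))
  }
  trj <- trajectory(top, coords, frame_interval = frame_interval)
  truth <- list(time_ns = t_ns, h = targ$h, theta = targ$theta,
                h_entry = truth_h_entry, plane_z = plane_z,
                contact = contact,
                contact_fraction = 100 * rowMeans(contact),
                contact_threshold = contact_threshold)
  list(trajectory = trj, truth = truth)
}
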