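#' Membrane reference plane (z of the headgroup nitrogens)
#'
#' The membrane reference plane is the arithmetic mean z of the headgroup
#' nitrogen atoms (atom name "N") of the chosen leaflet; all heights in
#' this package are measured against it.
#'
#' @param traj a [trajectory()].
#' @param frame 1-based frame index.
#' @param leaflet "upper" (default) or "lower".
#' @return plane z coordinate, Angstrom.
#' @export
membrane_plane_z <- function(traj, frame, leaflet = "upper") {
  idx <- select_atoms(traj$topology, chain_tag = "MEMB", leaflet = leaflet,
                      atom_name = "N")
  if (length(idx) == 0L) {
    stop("no \"N\" atoms in the ", leaflet, " leaflet")
  }
  mean(frame_coords(traj, frame)[idx, 3])
}

#' Center of mass of an atom subset
#'
#' @param coords `n x 3` coordinate matrix.
#' @param idx row indices of the subset (default: all rows).
#' @param masses numeric masses matching `idx`, or NULL for unit masses
#'   (the package default; exact for single-atom pseudo-residues).
#' @return length-3 numeric vector (x, y, z).
#' @export
com <- function(coords, idx = seq_len(nrow(coords)), masses = NULL) {
  if (length(idx) == 0L) stop("empty atom subset")
  m <- coords[idx, , drop = FALSE]
  if (is.null(masses)) return(colMeans(m))
  if (length(masses) != length(idx)) stop("masses must match subset length")
  if (any(masses <= 0)) stop("masses must be positive")
  colSums(m * masses) / sum(masses)
}

#' Protein center-of-mass height above the membrane plane
#'
#' `h = z(COM of the protein) - membrane_plane_z`, signed: negative when
#' the center of mass lies below the upper-leaflet headgroup plane. The
#' height is invariant under rigid in-plane translations of the whole
#' system.
#'
#' @inheritParams membrane_plane_z
#' @param masses optional per-atom masses for the protein selection;
#'   `NULL` = unit masses, `"physical"` = standard masses inferred from
#'   atom names via [atomic_masses()].
#' @return height h, Angstrom.
#' @export
protein_height <- function(traj, frame, leaflet = "upper", masses = NULL) {
  idx <- select_atoms(traj$topology, chain_tag = "PROT")
  if (length(idx) == 0L) stop("trajectory has no protein atoms")
  mm <- resolve_masses(masses, traj$topology$atom_name[idx])
  cz <- unname(com(frame_coords(traj, frame), idx, mm)[3])
  cz - membrane_plane_z(traj, frame, leaflet)
}

resolve_masses <- function(masses, atom_names) {
  if (is.null(masses)) return(NULL)
  if (identical(masses, "physical")) return(atomic_masses(atom_names))
  masses
}

#' Specification of the orientation segment and pocket-entry residues
#'
#' @param segment residue-id range whose CA atoms define the orientation
#'   axis (default 346:356, the alpha-7 helix segment).
#' @param entry residue ids whose joint mass center defines the
#'   lipid-pocket entry (default 129, 185, 190).
#' @return an object of class `lip_segment_spec`.
#' @export
segment_spec <- function(segment = 346:356, entry = c(129L, 185L, 190L)) {
  if (length(segment) == 0L || length(entry) == 0L) {
    stop("segment and entry must be non-empty")
  }
  structure(list(segment = as.integer(segment), entry = as.integer(entry)),
            class = "lip_segment_spec")
}

#' Pocket-entry height above the membrane plane
#'
#' z of the joint (unit-mass by default) mass center of all atoms of the
#' pocket-entry residues, minus the membrane plane. Signed: values near
#' zero or slightly negative indicate an entry sitting in the headgroup
#' plane.
#'
#' @inheritParams protein_height
#' @param spec a [segment_spec()].
#' @return h_entry, Angstrom.
#' @export
entry_height <- function(traj, frame, spec = segment_spec(),
                         leaflet = "upper", masses = NULL) {
  top <- traj$topology
  present <- spec$entry %in% top$residue_id[top$chain_tag == "PROT"]
  if (!all(present)) {
    stop("entry residue(s) missing from protein: ",
         paste(spec$entry[!present], collapse = ", "))
  }
  idx <- select_atoms(top, chain_tag = "PROT", residue_id = spec$entry)
  mm <- resolve_masses(masses, top$atom_name[idx])
  cz <- unname(com(frame_coords(traj, frame), idx, mm)[3])
  cz - membrane_plane_z(traj, frame, leaflet)
}

#' Orientation angle of the helix segment
#'
#' The segment axis is the first principal component of the segment's CA
#' coordinates (all segment atoms if none is named CA), with its sign
#' fixed toward increasing residue number. The reported angle is measured
#' against the membrane plane (`angle_ref = "plane"`, the default):
#' 0 degrees = axis lying in the plane, 90 = perpendicular to it.
#' `angle_ref = "normal"` reports the complement (angle to the z axis).
#'
#' @inheritParams entry_height
#' @param angle_ref "plane" (default) or "normal".
#' @param axis_method "pca" (default) or "endpoints" (vector from the
#'   first to the last segment residue center; cross-check alternative).
#' @return angle in degrees, folded into `[0, 90]`.
#' @export
segment_angle <- function(traj, frame, spec = segment_spec(),
                          angle_ref = c("plane", "normal"),
                          axis_method = c("pca", "endpoints")) {
  angle_ref <- match.arg(angle_ref)
  axis_method <- match.arg(axis_method)
  top <- traj$topology
  idx <- select_atoms(top, chain_tag = "PROT", residue_id = spec$segment,
                      atom_name = "CA")
  if (length(idx) < 3L) {
    idx <- select_atoms(top, chain_tag = "PROT", residue_id = spec$segment)
  }
  if (length(idx) < 3L) stop("need >= 3 reference atoms in the segment")
  pts <- frame_coords(traj, frame)[idx, , drop = FALSE]
  if (axis_method == "pca") {
    centered <- sweep(pts, 2, colMeans(pts))
    if (max(abs(centered)) < 1e-12) stop("degenerate segment: atoms coincide")
    axis <- svd(centered, nu = 0, nv = 1)$v[, 1]
  } else {
    rid <- top$residue_id[idx]
    p1 <- colMeans(pts[rid == min(rid), , drop = FALSE])
    p2 <- colMeans(pts[rid == max(rid), , drop = FALSE])
    axis <- p2 - p1
    if (sqrt(sum(axis^2)) < 1e-12) stop("degenerate segment: endpoints coincide")
  }
  # sign toward increasing residue number (irrelevant after folding, but
  # keeps the axis itself interpretable)
  rid <- top$residue_id[idx]
  direction <- colMeans(pts[rid >= stats::median(rid), , drop = FALSE]) -
    colMeans(pts[rid <= stats::median(rid), , drop = FALSE])
  if (sum(axis * direction) < 0) axis <- -axis
  axis <- axis / sqrt(sum(axis^2))
  to_normal <- acos(min(1, abs(axis[3]))) * 180 / pi  # in [0, 90]
  if (angle_ref == "plane") 90 - to_normal else to_normal
}

#' Per-residue membrane contact fractions
#'
#' A protein residue is in contact in a frame when the signed z distance
#' between its center of mass and the membrane plane is strictly less
#' than the threshold; residues below the plane therefore always count as
#' contacts (inserted loops are membrane contacts). The contact fraction
#' f is the percentage of analyzed frames in contact.
#'
#' @param traj a [trajectory()].
#' @param threshold contact threshold, Angstrom (default 5).
#' @param window 1-based inclusive frame window `c(start, end)`; default
#'   the full trajectory.
#' @param leaflet reference leaflet for the plane.
#' @param masses optional residue masses policy as in [protein_height()].
#' @return data.frame with columns `residue_id` and `f` (percent), plus
#'   attribute `threshold`.
#' @export
contact_fractions <- function(traj, threshold = 5, window = NULL,
                              leaflet = "upper", masses = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.null(window)) window <- c(1L, traj$n_frames)
  if (window[1] < 1L || window[2] > traj$n_frames || window[1] > window[2]) {
    stop("empty or out-of-range frame window")
  }
  frames <- seq.int(window[1], window[2])
  top <- traj$topology
  pidx <- select_atoms(top, chain_tag = "PROT")
  if (length(pidx) == 0L) stop("trajectory has no protein atoms")
  res_ids <- unique(top$residue_id[pidx])
  groups <- split(pidx, top$residue_id[pidx])[as.character(res_ids)]
  counts <- stats::setNames(numeric(length(res_ids)), res_ids)
  for (fr in frames) {
    m <- frame_coords(traj, fr)
    plane <- membrane_plane_z(traj, fr, leaflet)
    for (i in seq_along(groups)) {
      idx <- groups[[i]]
      mm <- resolve_masses(masses, top$atom_name[idx])
      dz <- unname(com(m, idx, mm)[3]) - plane
      if (dz < threshold) counts[i] <- counts[i] + 1
    }
  }
  out <- data.frame(residue_id = res_ids,
                    f = 100 * unname(counts) / length(frames))
  attr(out, "threshold") <- threshold
  out
}

#' Sample the docking-geometry series from a trajectory
#'
#' One (h, h_entry, theta) sample every `every` picoseconds; a 500 ns
#' trajectory sampled every 100 ps yields 5000 samples.
#'
#' @inheritParams contact_fractions
#' @param every sampling stride, ps; must be a multiple of the
#'   trajectory's frame interval.
#' @param spec a [segment_spec()].
#' @param angle_ref passed to [segment_angle()].
#' @return data.frame (class `lip_geometry_series`) with columns
#'   `time_ns`, `h`, `h_entry`, `theta_deg`.
#' @export
sample_series <- function(traj, every = NULL, spec = segment_spec(),
                          leaflet = "upper", angle_ref = "plane",
                          masses = NULL) {
  if (is.null(every)) every <- traj$frame_interval
  stride <- every / traj$frame_interval
  if (abs(stride - round(stride)) > 1e-9 || stride < 1) {
    stop("'every' (", every, " ps) must be a positive multiple of the ",
         "frame interval (", traj$frame_interval, " ps)")
  }
  stride <- as.integer(round(stride))
  frames <- seq.int(stride, traj$n_frames, by = stride)
  out <- data.frame(
    time_ns = frames * traj$frame_interval / 1000,
    h = vapply(frames, function(fr)
      protein_height(traj, fr, leaflet, masses), numeric(1)),
    h_entry = vapply(frames, function(fr)
      entry_height(traj, fr, spec, leaflet, masses), numeric(1)),
    theta_deg = vapply(frames, function(fr)
      segment_angle(traj, fr, spec, angle_ref), numeric(1)))
  class(out) <- c("lip_geometry_series", "data.frame")
  out
}
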