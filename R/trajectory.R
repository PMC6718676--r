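#' Construct a trajectory object
#'
#' A trajectory couples a fixed atom topology with an ordered stack of
#' coordinate frames. All docking-geometry and interaction-energy analyses
#' in this package operate on this container.
#'
#' @param topology data.frame with one row per atom and columns `atom_id`
#'   (integer), `atom_name` (e.g. "N", "CA"), `residue_id` (integer, 1-based
#'   PDB-style numbering), `residue_name` (3-letter code), `chain_tag`
#'   ("PROT" or "MEMB") and `leaflet` ("upper", "lower" or "none").
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`, in
#'   Angstrom. A single `n_atoms x 3` matrix is promoted to one frame.
#' @param frame_interval time between consecutive frames, in picoseconds.
#' @return An object of class `lip_trajectory`: a list with elements
#'   `topology`, `coords`, `frame_interval` (ps) and `n_frames`.
#' @examples
#' top <- data.frame(atom_id = 1:2, atom_name = "N", residue_id = 1:2,
#'                   residue_name = "DOP", chain_tag = "MEMB",
#'                   leaflet = "upper")
#' xyz <- array(0, c(2, 3, 5))
#' trj <- trajectory(top, xyz, frame_interval = 100)
#' n_frames(trj)
#' @export
trajectory <- function(topology, coords, frame_interval = 100) {
  required <- c("atom_id", "atom_name", "residue_id", "residue_name",
                "chain_tag", "leaflet")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols) > 0L) {
    stop("topology is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.matrix(coords)) {
    coords <- array(coords, c(nrow(coords), ncol(coords), 1L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(topology)) {
    stop("coords has ", dim(coords)[1], " atoms but topology has ",
         nrow(topology), " rows")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!all(topology$chain_tag %in% c("PROT", "MEMB"))) {
    stop("chain_tag must be \"PROT\" or \"MEMB\"")
  }
  if (!all(topology$leaflet %in% c("upper", "lower", "none"))) {
    stop("leaflet must be \"upper\", \"lower\" or \"none\"")
  }
  if (any(topology$leaflet != "none" & topology$chain_tag == "PROT")) {
    stop("protein atoms must have leaflet = \"none\"")
  }
  if (anyNA(topology$residue_id)) stop("residue_id contains NA")
  if (anyDuplicated(topology$atom_id)) stop("atom_id must be unique")
  if (frame_interval <= 0) stop("frame_interval must be positive (ps)")
  structure(
    list(topology = as.data.frame(topology), coords = coords,
         frame_interval = frame_interval, n_frames = dim(coords)[3]),
    class = "lip_trajectory"
  )
}

#' @export
print.lip_trajectory <- function(x, ...) {
  cat("<lip_trajectory> ", x$n_frames, " frame(s), ",
      nrow(x$topology), " atoms, dt = ", x$frame_interval, " ps (",
      format(duration_ns(x), digits = 4), " ns)\n", sep = "")
  cat("  chains: ",
      paste(sprintf("%s=%d", names(table(x$topology$chain_tag)),
                    as.integer(table(x$topology$chain_tag))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `lip_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "lip_trajectory"))
  traj$n_frames
}

#' Trajectory duration in nanoseconds
#'
#' Defined as `(n_frames - 1) * frame_interval`, i.e. the time spanned from
#' the first to the last stored frame.
#' @param traj a `lip_trajectory`.
#' @return duration in ns.
#' @export
duration_ns <- function(traj) {
  stopifnot(inherits(traj, "lip_trajectory"))
  (traj$n_frames - 1L) * traj$frame_interval / 1000
}

#' Extract the coordinates of one frame
#' @param traj a `lip_trajectory`.
#' @param frame 1-based frame index.
#' @return `n_atoms x 3` numeric matrix (Angstrom).
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(inherits(traj, "lip_trajectory"))
  if (frame < 1L || frame > traj$n_frames) {
    stop("frame ", frame, " out of range [1, ", traj$n_frames, "]")
  }
  m <- traj$coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Row indices of atoms matching a selection
#'
#' @param topology a trajectory topology data.frame.
#' @param chain_tag optional "PROT"/"MEMB" filter.
#' @param leaflet optional "upper"/"lower"/"none" filter.
#' @param atom_name optional atom-name filter (exact match, vectorised).
#' @param residue_id optional residue-id filter.
#' @return integer vector of topology row indices.
#' @export
select_atoms <- function(topology, chain_tag = NULL, leaflet = NULL,
                         atom_name = NULL, residue_id = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(chain_tag))  keep <- keep & topology$chain_tag %in% chain_tag
  if (!is.null(leaflet))    keep <- keep & topology$leaflet %in% leaflet
  if (!is.null(atom_name))  keep <- keep & topology$atom_name %in% atom_name
  if (!is.null(residue_id)) keep <- keep & topology$residue_id %in% residue_id
  which(keep)
}

#' Standard atomic masses inferred from atom names
#'
#' Element is taken as the first alphabetic character of the atom name
#' (PDB convention for the fixtures used here); unknown elements fall back
#' to 12.011. Used only when `masses = "physical"` is requested; residue
#' and protein centers of mass default to unit masses, which is exact for
#' single-atom pseudo-residues and a documented approximation otherwise.
#'
#' @param atom_names character vector of atom names.
#' @return numeric vector of masses (Da).
#' @export
atomic_masses <- function(atom_names) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
           P = 30.974, S = 32.06)
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", atom_names), 1, 1))
  m <- unname(tab[el])
  m[is.na(m)] <- 12.011
  m
}
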