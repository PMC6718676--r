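COULOMB_K <- 332.0636  # kcal * Angstrom / (mol * e^2), CHARMM convention

#' Switching-window specification for nonbonded interactions
#'
#' Both Coulomb and Lennard-Jones protein-membrane terms are multiplied
#' by a C1-continuous potential switch taking them from full strength at
#' `r_on` to zero at `r_off` (defaults 10 and 12 Angstrom).
#'
#' @param r_on switch-on radius, Angstrom.
#' @param r_off cutoff radius, Angstrom (> r_on).
#' @return an object of class `lip_switch_spec`.
#' @export
switch_spec <- function(r_on = 10, r_off = 12) {
  if (r_on <= 0 || r_off <= r_on) stop("need 0 < r_on < r_off")
  structure(list(r_on = r_on, r_off = r_off), class = "lip_switch_spec")
}

#' Potential-switching factor
#'
#' `S = 1` for `r <= r_on`, `S = 0` for `r >= r_off`, and the cubic
#' `S(x) = 1 - 3 x^2 + 2 x^3` with `x = (r - r_on)/(r_off - r_on)` in
#' between; S and dS/dr are continuous at both ends. Vectorised in `r`.
#'
#' @param r distance(s), Angstrom, >= 0.
#' @param spec a [switch_spec()].
#' @return dimensionless factor(s) in `[0, 1]`.
#' @export
switch_factor <- function(r, spec = switch_spec()) {
  if (any(r < 0)) stop("r must be >= 0")
  x <- pmin(1, pmax(0, (r - spec$r_on) / (spec$r_off - spec$r_on)))
  1 - 3 * x^2 + 2 * x^3
}

#' Switched Coulomb and Lennard-Jones energy of one atom pair
#'
#' Coulomb: `332.0636 q_i q_j / r * S(r)` kcal/mol. Lennard-Jones:
#' `4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6) * S(r)` with Lorentz-Berthelot
#' combining (arithmetic sigma, geometric epsilon). Both vanish at and
#' beyond `r_off`.
#'
#' @param r pair distance, Angstrom (> 0).
#' @param qi,qj partial charges, elementary charges.
#' @param sigi,sigj LJ sigma parameters, Angstrom.
#' @param epsi,epsj LJ epsilon parameters, kcal/mol.
#' @param spec a [switch_spec()].
#' @return named numeric vector `c(coul = , vdw = )`, kcal/mol.
#' @export
pair_energy <- function(r, qi, qj, sigi, sigj, epsi, epsj,
                        spec = switch_spec()) {
  if (r <= 0) stop("overlapping atoms: r must be > 0")
  s <- switch_factor(r, spec)
  coul <- COULOMB_K * qi * qj / r * s
  sij <- (sigi + sigj) / 2
  eij <- sqrt(epsi * epsj)
  sr6 <- (sij / r)^6
  vdw <- 4 * eij * (sr6^2 - sr6) * s
  c(coul = coul, vdw = vdw)
}

#' Protein-membrane interaction energy of one frame
#'
#' Sum of [pair_energy()] over every protein-membrane atom pair (the
#' evaluation is vectorised but numerically identical to the brute-force
#' double loop). Pairs beyond `r_off` contribute exactly zero.
#'
#' @param traj a [trajectory()].
#' @param frame 1-based frame index.
#' @param params parameter table (data.frame `atom_id`, `charge`, `sigma`,
#'   `epsilon`) covering every atom of both selections.
#' @param spec a [switch_spec()].
#' @param protein_idx,membrane_idx topology row indices of the two
#'   (disjoint) selections; defaults: chain_tag "PROT" and "MEMB".
#' @return named numeric vector `c(coul = , vdw = )`, kcal/mol.
#' @export
frame_interaction_energy <- function(traj, frame, params,
                                     spec = switch_spec(),
                                     protein_idx = NULL,
                                     membrane_idx = NULL) {
  top <- traj$topology
  if (is.null(protein_idx)) protein_idx <- select_atoms(top, chain_tag = "PROT")
  if (is.null(membrane_idx)) membrane_idx <- select_atoms(top, chain_tag = "MEMB")
  if (length(intersect(protein_idx, membrane_idx)) > 0L) {
    stop("selections must be disjoint")
  }
  validate_param_table(params)
  pid <- match(top$atom_id[protein_idx], params$atom_id)
  mid <- match(top$atom_id[membrane_idx], params$atom_id)
  if (anyNA(pid) || anyNA(mid)) {
    missing_ids <- c(top$atom_id[protein_idx][is.na(pid)],
                     top$atom_id[membrane_idx][is.na(mid)])
    stop("missing parameters for atom_id(s): ",
         paste(missing_ids, collapse = ", "))
  }
  m <- frame_coords(traj, frame)
  pp <- m[protein_idx, , drop = FALSE]
  mm <- m[membrane_idx, , drop = FALSE]
  # pairwise distances, protein x membrane
  d2 <- outer(rowSums(pp^2), rowSums(mm^2), "+") - 2 * tcrossprod(pp, mm)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 1e-9)) stop("overlapping atoms between the two selections")
  live <- r < spec$r_off
  if (!any(live)) return(c(coul = 0, vdw = 0))
  s <- matrix(0, nrow(r), ncol(r))
  s[live] <- switch_factor(r[live], spec)
  qq <- outer(params$charge[pid], params$charge[mid])
  coul <- COULOMB_K * sum((qq / r * s)[live])
  sij <- outer(params$sigma[pid], params$sigma[mid], function(a, b) (a + b) / 2)
  eij <- sqrt(outer(params$epsilon[pid], params$epsilon[mid]))
  sr6 <- (sij / r)^6
  vdw <- 4 * sum((eij * (sr6^2 - sr6) * s)[live])
  c(coul = coul, vdw = vdw)
}

#' Interaction-energy series over a trajectory
#'
#' @inheritParams frame_interaction_energy
#' @param every sampling stride, ps (default: every frame).
#' @return data.frame (class `lip_energy_series`) with columns `time_ns`,
#'   `e_coul_kcal`, `e_vdw_kcal`.
#' @export
energy_series <- function(traj, params, spec = switch_spec(), every = NULL) {
  if (is.null(every)) every <- traj$frame_interval
  stride <- every / traj$frame_interval
  if (abs(stride - round(stride)) > 1e-9 || stride < 1) {
    stop("'every' must be a positive multiple of the frame interval")
  }
  frames <- seq.int(as.integer(round(stride)), traj$n_frames,
                    by = as.integer(round(stride)))
  e <- vapply(frames, function(fr)
    frame_interaction_energy(traj, fr, params, spec), numeric(2))
  out <- data.frame(time_ns = frames * traj$frame_interval / 1000,
                    e_coul_kcal = e[1, ], e_vdw_kcal = e[2, ])
  class(out) <- c("lip_energy_series", "data.frame")
  out
}
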