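#' Van der Waals radius set for accessible-surface-area computation
#'
#' Radii are keyed by element (first alphabetic character of the atom
#' name); the defaults are a standard set (Bondi-style) and are
#' configurable because published ASA programs differ slightly in their
#' radii. The probe defaults to 1.5 Angstrom.
#'
#' @param radii named numeric vector of VDW radii per element, Angstrom.
#' @param probe_radius solvent probe radius, Angstrom.
#' @param n_sphere_points surface sample points per atom (default 960).
#' @return an object of class `lip_radius_set`.
#' @export
radius_set <- function(radii = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                                 P = 1.80, S = 1.80),
                       probe_radius = 1.5, n_sphere_points = 960) {
  if (any(radii <= 0)) stop("radii must be > 0")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 12) stop("n_sphere_points too small")
  structure(list(radii = radii, probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "lip_radius_set")
}

# deterministic golden-spiral unit-sphere points (no RNG: ASA values are
# exactly reproducible)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(atom_names, rset) {
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", atom_names), 1, 1))
  r <- unname(rset$radii[el])
  if (anyNA(r)) {
    stop("no VDW radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  }
  r
}

#' Shrake-Rupley accessible surface area
#'
#' Each atom's expanded sphere (VDW radius + probe) is sampled with a
#' deterministic golden-spiral point set; a point is accessible when it
#' lies outside every other atom's expanded sphere, and the atom's ASA is
#' the accessible fraction times the expanded-sphere area.
#'
#' @param coords `n x 3` coordinate matrix, Angstrom.
#' @param atom_names atom names (element inferred from the first letter).
#' @param rset a [radius_set()].
#' @return list with `per_atom` (numeric vector, Angstrom^2) and `total`.
#' @export
shrake_rupley_asa <- function(coords, atom_names, rset = radius_set()) {
  n <- nrow(coords)
  if (length(atom_names) != n) stop("atom_names must match coords rows")
  rad <- atom_radii(atom_names, rset) + rset$probe_radius
  pts <- golden_spiral_points(rset$n_sphere_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    ci <- coords[i, ]
    # neighbors whose expanded sphere can bury points of sphere i
    dc <- sqrt(colSums((t(coords) - ci)^2))
    nb <- which(dc < rad[i] + rad & seq_len(n) != i)
    sp <- sweep(pts * rad[i], 2, ci, "+")
    accessible <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(accessible)) break
      d2 <- colSums((t(sp[accessible, , drop = FALSE]) - coords[j, ])^2)
      accessible[accessible] <- d2 >= rad[j]^2
    }
    per_atom[i] <- mean(accessible) * 4 * pi * rad[i]^2
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

#' ASA difference between a full and a truncated structure
#'
#' Quantifies occlusion by a deleted segment (e.g. an N-terminal lid):
#' for every residue shared by both structures,
#' `delta = ASA(truncated) - ASA(full)`; positive values mark surface
#' that the deleted part was covering. The truncated structure must be a
#' residue-wise subset of the full one.
#'
#' @param coords_full,coords_trunc coordinate matrices.
#' @param topo_full,topo_trunc data.frames with at least `atom_name` and
#'   `residue_id` columns, matching the coordinate rows.
#' @param rset a [radius_set()].
#' @return data.frame with columns `residue_id`, `asa_full`, `asa_trunc`,
#'   `delta_asa` (Angstrom^2), one row per shared residue.
#' @export
delta_asa <- function(coords_full, topo_full, coords_trunc, topo_trunc,
                      rset = radius_set()) {
  shared <- unique(topo_trunc$residue_id)
  if (!all(shared %in% topo_full$residue_id)) {
    stop("truncated structure contains residues absent from the full one")
  }
  asa_f <- shrake_rupley_asa(coords_full, topo_full$atom_name, rset)$per_atom
  asa_t <- shrake_rupley_asa(coords_trunc, topo_trunc$atom_name, rset)$per_atom
  agg_f <- tapply(asa_f, topo_full$residue_id, sum)
  agg_t <- tapply(asa_t, topo_trunc$residue_id, sum)
  shared <- sort(shared)
  data.frame(residue_id = shared,
             asa_full = unname(agg_f[as.character(shared)]),
             asa_trunc = unname(agg_t[as.character(shared)]),
             delta_asa = unname(agg_t[as.character(shared)] -
                                agg_f[as.character(shared)]))
}
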