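#' Specify a planar two-leaflet bilayer patch
#'
#' The synthetic membrane is headgroup-only: each lipid is a single
#' pseudo-atom named "N" sitting near one of two parallel headgroup
#' planes. That is sufficient because every docking metric in this
#' package references only the headgroup-nitrogen plane. Defaults emulate
#' a 1000-lipid patch with a 70/30 neutral/anionic (PC/PS-like) mix.
#'
#' @param n_lipids total lipid count, even (split equally across leaflets).
#' @param anionic_fraction fraction of anionic lipids in `[0, 1]`.
#' @param lipid_charge formal charge of the anionic species (default -1).
#' @param leaflet_separation distance between the two headgroup planes, in
#'   Angstrom. Default 38, a typical fluid PC bilayer phosphate-phosphate
#'   distance; no metric depends on it beyond sign conventions.
#' @param patch_side side length of the square patch, Angstrom.
#' @param z_jitter_sd Gaussian jitter of headgroup z positions, Angstrom.
#' @return an object of class `lip_bilayer_spec` (a validated list).
#' @export
bilayer_spec <- function(n_lipids = 1000, anionic_fraction = 0.30,
                         lipid_charge = -1, leaflet_separation = 38,
                         patch_side = 181, z_jitter_sd = 1) {
  if (n_lipids %% 2 != 0) stop("n_lipids must be even")
  if (anionic_fraction < 0 || anionic_fraction > 1) {
    stop("anionic_fraction must be in [0, 1]")
  }
  if (leaflet_separation <= 0 || patch_side <= 0 || z_jitter_sd < 0) {
    stop("leaflet_separation and patch_side must be positive, z_jitter_sd >= 0")
  }
  structure(list(n_lipids = as.integer(n_lipids),
                 anionic_fraction = anionic_fraction,
                 lipid_charge = lipid_charge,
                 leaflet_separation = leaflet_separation,
                 patch_side = patch_side,
                 z_jitter_sd = z_jitter_sd),
            class = "lip_bilayer_spec")
}

# Largest-remainder (Hamilton) apportionment of `seats` among quotas,
# deterministic tie-break toward the earliest entry.
largest_remainder <- function(quotas, seats) {
  fl <- floor(quotas)
  left <- seats - sum(fl)
  if (left > 0) {
    rem <- quotas - fl
    ord <- order(-rem, seq_along(rem))  # ties -> earlier index
    fl[ord[seq_len(left)]] <- fl[ord[seq_len(left)]] + 1
  }
  as.integer(fl)
}

#' Build a synthetic bilayer patch
#'
#' Places `n_lipids/2` headgroup pseudo-atoms per leaflet on a jittered
#' square lattice at z = +/- `leaflet_separation / 2`. Species counts use
#' largest-remainder rounding with the anionic species (then the upper
#' leaflet) winning deterministic ties; anionic sites are then assigned at
#' random among lattice positions. The implied sodium counterion count is
#' the magnitude of the total anionic charge.
#'
#' @param spec a [bilayer_spec()].
#' @param seed integer seed (placement jitter and species assignment).
#' @return an object of class `lip_bilayer`: list with `atoms` (data.frame
#'   of atom records with coordinates; anionic lipids are residue "POS",
#'   neutral "DOP"), `counterion_count` (integer) and `spec`.
#' @examples
#' b <- build_bilayer(bilayer_spec(n_lipids = 1000, anionic_fraction = 0.30),
#'                    seed = 1)
#' b$counterion_count  # 300
#' @export
build_bilayer <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "lip_bilayer_spec"))
  n_leaf <- spec$n_lipids %/% 2L

  # species apportionment: anionic total first (tie -> anionic), then the
  # anionic total across leaflets (tie -> upper)
  tot <- largest_remainder(
    c(spec$n_lipids * spec$anionic_fraction,
      spec$n_lipids * (1 - spec$anionic_fraction)), spec$n_lipids)
  n_anion <- tot[1]
  per_leaf_anion <- largest_remainder(c(n_anion / 2, n_anion / 2), n_anion)
  if (any(per_leaf_anion > n_leaf)) stop("anionic count exceeds leaflet size")
  counterions <- as.integer(round(n_anion * abs(spec$lipid_charge)))

  side_n <- ceiling(sqrt(n_leaf))
  spacing <- spec$patch_side / side_n
  if (spacing < 5) {
    stop("patch too small: lattice spacing ", format(spacing, digits = 3),
         " A < 5 A minimum headgroup spacing")
  }

  atoms <- with_seed(seed, {
    out <- vector("list", 2L)
    for (li in 1:2) {
      leaf <- c("upper", "lower")[li]
      zc <- c(1, -1)[li] * spec$leaflet_separation / 2
      g <- expand.grid(ix = seq_len(side_n), iy = seq_len(side_n))[seq_len(n_leaf), ]
      x <- (g$ix - (side_n + 1) / 2) * spacing +
        stats::runif(n_leaf, -0.2, 0.2) * spacing
      y <- (g$iy - (side_n + 1) / 2) * spacing +
        stats::runif(n_leaf, -0.2, 0.2) * spacing
      z <- zc + stats::rnorm(n_leaf, 0, spec$z_jitter_sd)
      species <- rep("DOP", n_leaf)
      species[sample.int(n_leaf, per_leaf_anion[li])] <- "POS"
      out[[li]] <- data.frame(
        atom_name = "N", residue_name = species, leaflet = leaf,
        x = x, y = y, z = z, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  atoms <- data.frame(
    atom_id = seq_len(nrow(atoms)),
    atom_name = atoms$atom_name,
    residue_id = seq_len(nrow(atoms)),
    residue_name = atoms$residue_name,
    chain_tag = "MEMB",
    leaflet = atoms$leaflet,
    x = atoms$x, y = atoms$y, z = atoms$z,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, counterion_count = counterions, spec = spec),
            class = "lip_bilayer")
}

#' @export
print.lip_bilayer <- function(x, ...) {
  cat("<lip_bilayer> ", nrow(x$atoms), " headgroup atoms (",
      sum(x$atoms$residue_name == "POS"), " anionic), ",
      x$counterion_count, " implied counterions\n", sep = "")
  invisible(x)
}
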