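#' Kabsch least-squares superposition
#'
#' Optimal rigid-body (rotation + translation, no reflection)
#' superposition of `mobile` onto `target`, via the SVD of the
#' cross-covariance matrix.
#'
#' @param mobile,target `n x 3` coordinate matrices with matched rows.
#' @return list with `coords` (superposed mobile), `rotation` (3x3) and
#'   `rmsd` (Angstrom).
#' @export
kabsch <- function(mobile, target) {
  if (!all(dim(mobile) == dim(target))) stop("atom-count mismatch")
  if (nrow(mobile) < 1L) stop("empty coordinate sets")
  cm <- colMeans(mobile); ct <- colMeans(target)
  a <- sweep(mobile, 2, cm); b <- sweep(target, 2, ct)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(a %*% rot, 2, ct, "+")
  list(coords = fitted, rotation = rot,
       rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

#' Root-mean-square deviation between two frames
#'
#' @param frame_a,frame_b `n x 3` coordinate matrices with matched atom
#'   order.
#' @param superpose if TRUE (default), remove the optimal rigid-body
#'   transform (Kabsch) before measuring; the superposed RMSD is never
#'   larger than the raw one.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame_a, frame_b, superpose = TRUE) {
  if (!all(dim(frame_a) == dim(frame_b))) stop("atom-count mismatch")
  if (superpose) {
    kabsch(frame_b, frame_a)$rmsd
  } else {
    sqrt(mean(rowSums((frame_a - frame_b)^2)))
  }
}

#' Per-residue root-mean-square fluctuation
#'
#' Each frame is superposed (Kabsch) onto the time-averaged structure,
#' the average is recomputed from the superposed frames, and the per-atom
#' RMSF is the root-mean-square displacement from that average over
#' frames. Per-residue values are the RMS over the residue's atoms.
#'
#' @param traj a [trajectory()].
#' @param chain_tag selection, default "PROT".
#' @param n_iter average/superpose refinement sweeps (default 2).
#' @return data.frame with columns `residue_id` and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, chain_tag = "PROT", n_iter = 2) {
  idx <- select_atoms(traj$topology, chain_tag = chain_tag)
  if (length(idx) == 0L) stop("empty selection")
  nf <- traj$n_frames
  stack <- lapply(seq_len(nf), function(fr)
    frame_coords(traj, fr)[idx, , drop = FALSE])
  ref <- stack[[1]]
  for (it in seq_len(n_iter)) {
    stack <- lapply(stack, function(m) kabsch(m, ref)$coords)
    ref <- Reduce(`+`, stack) / nf
  }
  msf <- Reduce(`+`, lapply(stack, function(m) rowSums((m - ref)^2))) / nf
  rid <- traj$topology$residue_id[idx]
  agg <- tapply(msf, rid, mean)
  data.frame(residue_id = as.integer(names(agg)),
             rmsf = sqrt(unname(agg)))
}
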