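#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block is one frame; the topology (atom names,
#' residue numbering, chains, leaflet flags) is taken from the first model.
#' Chain `P` maps to `chain_tag = "PROT"` and chain `M` to `"MEMB"`.
#' Leaflet membership is read from the B-factor column (1 = upper,
#' 2 = lower, 0 = none) unless a sidecar TSV is given, in which case the
#' sidecar wins. Parsing itself is delegated to [bio3d::read.pdb()]; a
#' pre-scan validates that every model carries the same atom count so a
#' malformed file fails with the offending model named.
#'
#' @param path path to a PDB file with MODEL/ENDMDL records (a single
#'   model without MODEL records is accepted as a 1-frame trajectory).
#' @param frame_interval time between models, ps (not stored in PDB).
#' @param leaflet_tsv optional sidecar TSV with columns `atom_id`,
#'   `leaflet`; overrides the B-factor flags.
#' @return a [trajectory()] object.
#' @seealso [write_multimodel_pdb()]
#' @export
read_multimodel_pdb <- function(path, frame_interval = 100,
                                leaflet_tsv = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("format error: ", length(model_starts), " MODEL but ",
           length(model_ends), " ENDMDL records")
    }
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1])[1]
      stop("format error: model ", bad, " has ", counts[bad],
           " atoms, expected ", counts[1])
    }
  }
  # coordinate sanity: every atom line must carry three parseable reals
  coord_txt <- substr(lines[is_atom], 31, 54)
  xyz_ok <- !is.na(suppressWarnings(as.numeric(substr(coord_txt, 1, 8)))) &
            !is.na(suppressWarnings(as.numeric(substr(coord_txt, 9, 16)))) &
            !is.na(suppressWarnings(as.numeric(substr(coord_txt, 17, 24))))
  if (!all(xyz_ok)) {
    bad_line <- which(is_atom)[which(!xyz_ok)[1]]
    stop("format error: unparseable coordinate at line ", bad_line)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  nat <- nrow(atom)
  xyz <- pdb$xyz
  nfr <- nrow(xyz)
  coords <- aperm(array(t(xyz), c(3L, nat, nfr)), c(2L, 1L, 3L))

  chain_tag <- ifelse(atom$chain == "M", "MEMB", "PROT")
  leaflet <- rep("none", nat)
  bflag <- round(atom$b)
  leaflet[chain_tag == "MEMB" & bflag == 1] <- "upper"
  leaflet[chain_tag == "MEMB" & bflag == 2] <- "lower"
  top <- data.frame(
    atom_id = atom$eleno,
    atom_name = atom$elety,
    residue_id = atom$resno,
    residue_name = atom$resid,
    chain_tag = chain_tag,
    leaflet = leaflet,
    stringsAsFactors = FALSE
  )
  if (!is.null(leaflet_tsv)) {
    side <- utils::read.table(leaflet_tsv, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    idx <- match(top$atom_id, side$atom_id)
    hit <- !is.na(idx)
    top$leaflet[hit] <- side$leaflet[idx[hit]]
  }
  trajectory(top, coords, frame_interval = frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Inverse of [read_multimodel_pdb()]: chain_tag is encoded as chain
#' `P`/`M` and the leaflet flag in the B-factor column (1 upper, 2 lower,
#' 0 none). Coordinates are written at the format's fixed 3-decimal
#' precision, so a round trip reproduces them to 1e-3 Angstrom.
#'
#' @param traj a [trajectory()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "lip_trajectory"))
  top <- traj$topology
  nat <- nrow(top)
  xyz <- t(vapply(seq_len(traj$n_frames),
                  function(i) as.vector(t(frame_coords(traj, i))),
                  numeric(3L * nat)))
  b <- ifelse(top$leaflet == "upper", 1, ifelse(top$leaflet == "lower", 2, 0))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = top$residue_id, resid = top$residue_name,
    eleno = top$atom_id, elety = top$atom_name,
    chain = ifelse(top$chain_tag == "MEMB", "M", "P"),
    o = rep(1, nat), b = b
  )
  invisible(path)
}

#' Read a per-atom nonbonded parameter table
#'
#' TSV with columns `atom_id`, `charge` (elementary charges), `sigma`
#' (Angstrom) and `epsilon` (kcal/mol), as consumed by
#' [frame_interaction_energy()].
#'
#' @param path path to the TSV file.
#' @return data.frame with the four columns, validated.
#' @export
read_param_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("atom_id", "charge", "sigma", "epsilon")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("parameter table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_param_table(tab)
  tab[required]
}

#' Validate a nonbonded parameter table
#' @param params data.frame with `atom_id`, `charge`, `sigma`, `epsilon`.
#' @return `params`, invisibly; errors on violated invariants.
#' @keywords internal
validate_param_table <- function(params) {
  if (any(params$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(params$sigma <= 0)) stop("sigma must be > 0")
  if (anyDuplicated(params$atom_id)) stop("duplicate atom_id in parameter table")
  invisible(params)
}

#' Write a nonbonded parameter table as TSV
#' @param params data.frame with `atom_id`, `charge`, `sigma`, `epsilon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(params, path) {
  validate_param_table(params)
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
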