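AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# internal scanner on a bare string; 'x' in the motif is a one-letter
# wildcard. Overlapping matches are all reported (lookahead).
scan_motif_string <- function(sequence, motif) {
  pat <- paste0("(?=", gsub("x", ".", motif, fixed = TRUE), ")")
  hits <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Scan a sequence for a literal motif
#'
#' Exact-substring semantics (the ORP/Osh signature EQTSHHPP and the
#' PS-recognition motif LPTFILE are literal patterns); a lone `x` in the
#' motif acts as a single-position wildcard. Overlapping occurrences are
#' all reported.
#'
#' @param record a single-row data.frame with `id` and `sequence`, or a
#'   bare sequence string.
#' @param motif motif string over the 20-letter alphabet (plus `x`).
#' @return integer vector of 1-based match start positions.
#' @examples
#' scan_motif("AAEQTSHHPPAA", "EQTSHHPP")  # 3
#' @export
scan_motif <- function(record, motif) {
  sequence <- if (is.data.frame(record)) record$sequence[1] else record
  check_aa(sequence, "sequence")
  if (nchar(motif) == 0L) stop("motif must be non-empty")
  check_aa(gsub("x", "", motif, fixed = TRUE), "motif")
  scan_motif_string(sequence, motif)
}

check_aa <- function(s, what) {
  bad <- setdiff(strsplit(s, "")[[1]], AA20)
  if (length(bad) > 0L) {
    stop(what, " contains invalid character(s): ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(s)
}

#' Motif-based filtering of a sequence set
#'
#' Retains the records that contain every motif in `require` (e.g. first
#' the family signature EQTSHHPP, then the PS-motif LPTFILE), and reports
#' per-motif retention counts. An empty `require` retains everything.
#'
#' @param records data.frame with columns `id` and `sequence`.
#' @param require character vector of motifs that must all be present.
#' @return list with `retained` (subset of `records`), `rejected`
#'   (subset with a `missing_motif` column naming the first absent
#'   motif) and `report` (data.frame `motif`, `n_with`, `n_without`).
#' @export
filter_by_motifs <- function(records, require = character(0)) {
  has <- vapply(require, function(m)
    vapply(records$sequence, function(s)
      length(scan_motif_string(s, m)) > 0L, logical(1), USE.NAMES = FALSE),
    logical(nrow(records)))
  if (length(require) == 0L) {
    keep <- rep(TRUE, nrow(records))
    report <- data.frame(motif = character(0), n_with = integer(0),
                         n_without = integer(0))
  } else {
    has <- matrix(has, nrow = nrow(records))
    keep <- rowSums(has) == length(require)
    report <- data.frame(motif = require,
                         n_with = colSums(has),
                         n_without = nrow(records) - colSums(has),
                         row.names = NULL)
  }
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    first_missing <- apply(!matrix(has, nrow = nrow(records))[!keep, ,
                                                              drop = FALSE],
                           1, function(miss) require[which(miss)[1]])
    rejected$missing_motif <- first_missing
  } else if (length(require) > 0L) {
    rejected$missing_motif <- character(0)
  }
  list(retained = records[keep, , drop = FALSE],
       rejected = rejected, report = report)
}

#' Net charge of a peptide sequence or subrange
#'
#' `(#K + #R) - (#D + #E)`, with histidine neutral at pH ~7 by default
#' and termini ignored — the convention under which an N-terminal 1-35
#' region rich in lysines scores +4.
#'
#' @param sequence amino-acid string.
#' @param range optional 1-based inclusive `c(start, end)` subrange.
#' @param his_charge charge assigned to histidine (default 0).
#' @return integer (numeric if `his_charge` is fractional).
#' @export
net_charge <- function(sequence, range = NULL, his_charge = 0) {
  check_aa(sequence, "sequence")
  if (!is.null(range)) {
    if (range[1] < 1L || range[2] > nchar(sequence) || range[1] > range[2]) {
      stop("range [", range[1], ", ", range[2], "] out of bounds for a ",
           nchar(sequence), "-residue sequence")
    }
    sequence <- substr(sequence, range[1], range[2])
  }
  ch <- strsplit(sequence, "")[[1]]
  q <- sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E")) +
    his_charge * sum(ch == "H")
  if (his_charge == round(his_charge)) as.integer(q) else q
}

#' Define a set of point mutations
#'
#' Each mutation is checked against the sequence it is applied to
#' (`from` must match at `position`), guarding against numbering drift.
#' Presets follow the lid charge-neutralization series: `"L69D"`;
#' `"4A"` = D38A, D39A, D41A, E42A; `"5A2G"` = 4A plus D43G, D44G, E45A.
#'
#' @param position 1-based positions, or a preset name.
#' @param from,to single-letter residues (vectorised with `position`).
#' @return an object of class `lip_mutation_spec` (data.frame
#'   `position`, `from`, `to`).
#' @export
mutation_spec <- function(position, from = NULL, to = NULL) {
  presets <- list(
    L69D = data.frame(position = 69L, from = "L", to = "D"),
    `4A` = data.frame(position = c(38L, 39L, 41L, 42L),
                      from = c("D", "D", "D", "E"), to = "A"),
    `5A2G` = data.frame(position = c(38L, 39L, 41L, 42L, 43L, 44L, 45L),
                        from = c("D", "D", "D", "E", "D", "D", "E"),
                        to = c("A", "A", "A", "A", "G", "G", "A")))
  if (is.character(position) && length(position) == 1L &&
      position %in% names(presets)) {
    spec <- presets[[position]]
  } else {
    if (is.null(from) || is.null(to)) stop("from and to are required")
    spec <- data.frame(position = as.integer(position), from = from, to = to)
  }
  if (anyDuplicated(spec$position)) stop("duplicate mutation positions")
  structure(spec, class = c("lip_mutation_spec", "data.frame"))
}

#' Apply point mutations to a sequence record
#'
#' @param record data.frame row with `id` and `sequence`, or a bare
#'   sequence string.
#' @param spec a [mutation_spec()].
#' @param his_charge passed to [net_charge()].
#' @return list with `record` (mutated), `delta_charge`
#'   (`net_charge(after) - net_charge(before)`).
#' @export
apply_mutations <- function(record, spec, his_charge = 0) {
  is_df <- is.data.frame(record)
  sequence <- if (is_df) record$sequence[1] else record
  check_aa(sequence, "sequence")
  ch <- strsplit(sequence, "")[[1]]
  for (i in seq_len(nrow(spec))) {
    pos <- spec$position[i]
    if (pos < 1L || pos > length(ch)) {
      stop("mutation position ", pos, " outside the sequence (length ",
           length(ch), ")")
    }
    if (ch[pos] != spec$from[i]) {
      stop("residue mismatch at position ", pos, ": found ", ch[pos],
           ", expected ", spec$from[i])
    }
    ch[pos] <- spec$to[i]
  }
  mutated <- paste(ch, collapse = "")
  dq <- net_charge(mutated, his_charge = his_charge) -
    net_charge(sequence, his_charge = his_charge)
  out <- if (is_df) {
    r <- record
    r$sequence[1] <- mutated
    r
  } else {
    mutated
  }
  list(record = out, delta_charge = dq)
}
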