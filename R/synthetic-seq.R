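#' Generate a sequence set with planted signature motifs
#'
#' Random amino-acid sequences over the 20-letter alphabet, a fixed
#' fraction of which carry one literal copy of `motif` at a recorded
#' position. Background sequences are rejection-sampled to be motif-free,
#' and planted sequences are re-drawn until the motif occurs exactly once,
#' so the planted positions are exactly what a motif scanner must report.
#'
#' @param n number of sequences.
#' @param motif literal amino-acid motif to plant (e.g. "LPTFILE").
#' @param plant_fraction fraction of sequences that receive the motif;
#'   the planted count is `round(plant_fraction * n)`.
#' @param length sequence length (> motif length).
#' @param seed integer seed.
#' @return list with `records` (data.frame `id`, `sequence`) and `planted`
#'   (data.frame `id`, `position` with 1-based motif start positions; zero
#'   rows when nothing is planted).
#' @export
generate_sequences <- function(n, motif, plant_fraction = 0.5, length = 120,
                               seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  motif_chars <- strsplit(motif, "")[[1]]
  if (!all(motif_chars %in% c(aa, "x"))) {
    stop("motif contains characters outside the amino-acid alphabet")
  }
  if (nchar(motif) >= length) stop("motif must be shorter than length")
  n_plant <- round(plant_fraction * n)

  with_seed(seed, {
    draw_background <- function() {
      repeat {
        s <- paste(sample(aa, length, replace = TRUE), collapse = "")
        if (base::length(scan_motif_string(s, motif)) == 0L) return(s)
      }
    }
    seqs <- character(n)
    planted <- data.frame(id = character(0), position = integer(0),
                          stringsAsFactors = FALSE)
    plant_idx <- if (n_plant > 0) seq_len(n_plant) else integer(0)
    for (i in seq_len(n)) {
      if (i %in% plant_idx) {
        repeat {
          s <- draw_background()
          pos <- sample.int(length - nchar(motif) + 1L, 1L)
          # plant by substitution; 'x' wildcard keeps the background letter
          sub_chars <- strsplit(s, "")[[1]]
          keep <- motif_chars == "x"
          repl <- motif_chars
          repl[keep] <- sub_chars[pos + which(keep) - 1L]
          sub_chars[pos:(pos + nchar(motif) - 1L)] <- repl
          s2 <- paste(sub_chars, collapse = "")
          hits <- scan_motif_string(s2, motif)
          if (identical(hits, as.integer(pos))) {
            seqs[i] <- s2
            planted <- rbind(planted,
                             data.frame(id = sprintf("seq%03d", i),
                                        position = as.integer(pos)))
            break
          }
        }
      } else {
        seqs[i] <- draw_background()
      }
    }
    list(records = data.frame(id = sprintf("seq%03d", seq_len(n)),
                              sequence = seqs, stringsAsFactors = FALSE),
         planted = planted)
  })
}
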