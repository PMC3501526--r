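# Peptide/protein mass arithmetic used for adduct annotation and fragment
# bookkeeping. Residue masses are the standard monoisotopic and average
# tables for the 20 canonical amino acids; coordinates are 1-based inclusive.

# Monoisotopic residue (i.e. dehydrated) masses, Da.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00918, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04048,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average residue masses, Da.
.AA_AVG <- c(
  G = 57.0514, A = 71.0780, S = 87.0774, P = 97.1154, V = 99.1313,
  T = 101.1040, C = 103.1428, L = 113.1579, I = 113.1579, N = 114.1028,
  D = 115.0876, Q = 128.1294, K = 128.1725, E = 129.1142, M = 131.1960,
  H = 137.1395, F = 147.1742, R = 156.1859, Y = 163.1736, W = 186.2103
)

.MASS_WATER_MONO <- 18.010565
.MASS_WATER_AVG <- 18.01529
.MASS_PROTON <- 1.007276

#' Fixed table of cysteine-thiol adduct mass shifts
#'
#' Monoisotopic mass deltas (Da) for the covalent proteoform adducts handled
#' by the pipeline: cysteinylation, cysteinyl-glycine, glutathionylation and
#' sulfonation. These shift a protein's m/z without changing its identity, so
#' peak annotation matches observed peaks against `base + delta`.
#'
#' @return Named numeric vector of positive mass deltas in Daltons.
#' @examples
#' adduct_table()
#' @export
adduct_table <- function() {
  c(
    cysteinyl = 119.004,
    cys_gly = 176.026,
    glutathionyl = 305.068,
    sulfonation = 79.957
  )
}

#' Peptide mass from sequence
#'
#' Sums standard residue masses over a one-letter amino-acid sequence and adds
#' one water (condensation termini). `ion = "mh"` adds one proton, giving the
#' singly-protonated m/z convention usual for linear-TOF spectra.
#'
#' @param seq Character scalar; one-letter codes for the 20 standard residues.
#' @param kind `"monoisotopic"` (default) or `"average"` residue masses.
#' @param ion `"neutral"` (default) for the neutral molecular mass M, or
#'   `"mh"` for the \[M+H\]+ ion m/z.
#' @return Mass in Daltons (numeric scalar).
#' @examples
#' peptide_mass("G", ion = "mh") # 76.04
#' @export
peptide_mass <- function(seq, kind = c("monoisotopic", "average"),
                         ion = c("neutral", "mh")) {
  kind <- match.arg(kind)
  ion <- match.arg(ion)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("'seq' must be a non-empty character scalar")
  residues <- strsplit(toupper(seq), "")[[1L]]
  tab <- if (kind == "monoisotopic") .AA_MONO else .AA_AVG
  bad <- which(!residues %in% names(tab))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", residues[bad[1L]], bad[1L]))
  water <- if (kind == "monoisotopic") .MASS_WATER_MONO else .MASS_WATER_AVG
  m <- sum(tab[residues]) + water
  if (ion == "mh") m <- m + .MASS_PROTON
  unname(m)
}

#' Locate a fragment within a parent protein
#'
#' Describes a contiguous fragment of a parent chain in 1-based inclusive
#' coordinates, and flags whether the fragment stops exactly one residue short
#' of a declared downstream subunit start (the single missing residue is then
#' named when the parent sequence is supplied). This is the bookkeeping used
#' to recognise protease-trimmed fragments such as a C-terminally clipped
#' heavy-chain peptide.
#'
#' @param parent_length Length of the parent chain (residues).
#' @param start,end 1-based inclusive fragment coordinates.
#' @param subunit_starts Integer vector of known subunit start positions in
#'   the parent (may be empty).
#' @param parent_seq Optional full parent sequence (one-letter codes); used
#'   only to name the missing residue.
#' @return A list with `start`, `end`, `length`, `abuts_known_subunit`
#'   (logical), `missing_position` (the skipped residue index, or `NA`) and
#'   `missing_residue` (its one-letter code if `parent_seq` given, else `NA`).
#' @examples
#' map_fragment(1500, 1212, 1243, subunit_starts = 1245)
#' @export
map_fragment <- function(parent_length, start, end, subunit_starts = integer(),
                         parent_seq = NULL) {
  parent_length <- as.integer(parent_length)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(parent_length) || parent_length < 1L)
    stop("'parent_length' must be a positive integer")
  if (is.na(start) || is.na(end) || start < 1L || end < start || end > parent_length)
    stop("require 1 <= start <= end <= parent_length")
  abuts <- any(!is.na(subunit_starts) & (end + 2L) == as.integer(subunit_starts))
  missing_pos <- if (abuts) end + 1L else NA_integer_
  missing_res <- NA_character_
  if (abuts && !is.null(parent_seq)) {
    res <- strsplit(toupper(parent_seq), "")[[1L]]
    if (length(res) != parent_length)
      stop("'parent_seq' length does not match 'parent_length'")
    missing_res <- res[missing_pos]
  }
  list(
    start = start, end = end, length = end - start + 1L,
    abuts_known_subunit = abuts,
    missing_position = missing_pos,
    missing_residue = missing_res
  )
}

#' Annotate adduct relationships within a set of m/z values
#'
#' Given a base (unmodified) m/z and candidate peak m/z values, labels every
#' candidate lying within a relative tolerance of `base + delta` for the
#' deltas in [adduct_table()]. A candidate matching two deltas is reported
#' twice and flagged ambiguous.
#'
#' @param base_mz Base peak m/z (Da).
#' @param candidate_mz Numeric vector of observed peak m/z values.
#' @param rel_tol Relative tolerance on the summed mass (default 0.001).
#' @param adducts Named numeric vector of mass deltas; default [adduct_table()].
#' @return Data frame with columns `mz`, `adduct`, `expected_mz`,
#'   `deviation_rel` and `ambiguous`; zero rows when nothing matches.
#' @examples
#' match_adducts(13601, c(13725, 13788, 13913))
#' @export
match_adducts <- function(base_mz, candidate_mz, rel_tol = 0.001,
                          adducts = adduct_table()) {
  stopifnot(is.numeric(base_mz), length(base_mz) == 1L, base_mz > 0,
            rel_tol > 0)
  out <- list()
  for (i in seq_along(adducts)) {
    expected <- base_mz + adducts[[i]]
    dev <- abs(candidate_mz - expected) / expected
    hit <- which(dev <= rel_tol)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        mz = candidate_mz[hit],
        adduct = names(adducts)[i],
        expected_mz = expected,
        deviation_rel = dev[hit],
        stringsAsFactors = FALSE
      )
  }
  if (!length(out))
    return(data.frame(mz = numeric(), adduct = character(),
                      expected_mz = numeric(), deviation_rel = numeric(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$ambiguous <- duplicated(res$mz) | duplicated(res$mz, fromLast = TRUE)
  rownames(res) <- NULL
  res[order(res$mz), , drop = FALSE]
}
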