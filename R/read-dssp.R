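#' Read classic DSSP output
#'
#' Parses the fixed-column text emitted by DSSP. Data begin on the line after
#' the header sentinel starting with `"  #  RESIDUE"`; the residue letter is
#' taken from column 14, the 8-state secondary structure symbol from column
#' 17 (blank meaning loop) and the absolute solvent accessibility (A^2) from
#' columns 35-38. Chain-break lines (residue letter `!`) are skipped.
#'
#' @param path Path to a DSSP output file.
#' @return A tibble with one row per residue: `residue_index` (1-based
#'   sequence position), `chain`, `aa`, `ss8`, `acc`.
#' @seealso [dssp_ss3()] and [dssp_sa2()] to collapse the records to 3-state
#'   secondary structure and 2-state solvent accessibility.
#' @export
read_dssp <- function(path) {
  lines <- read_file_lines(path, "DSSP")
  sentinel <- which(startsWith(lines, "  #  RESIDUE"))
  if (length(sentinel) == 0) {
    abort_format("not DSSP output: missing '  #  RESIDUE' header line")
  }
  data_lines <- lines[seq.int(sentinel[[1]] + 1, length.out = length(lines) - sentinel[[1]])]
  out <- list()
  idx <- 0L
  for (i in seq_along(data_lines)) {
    line <- data_lines[[i]]
    if (!nzchar(trimws(line))) next
    aa <- substr(line, 14, 14)
    if (aa == "!") next # chain break
    ss8 <- substr(line, 17, 17)
    if (!ss8 %in% DSSP8) {
      abort_format(paste0(
        "DSSP line ", sentinel[[1]] + i, ": unknown secondary structure symbol '",
        ss8, "'"
      ))
    }
    acc_field <- trimws(substr(line, 35, 38))
    if (!grepl("^[0-9]+$", acc_field)) {
      abort_format(paste0(
        "DSSP line ", sentinel[[1]] + i, ": unparsable ACC field '", acc_field, "'"
      ))
    }
    idx <- idx + 1L
    out[[idx]] <- tibble(
      residue_index = idx,
      chain = substr(line, 12, 12),
      aa = normalize_sequence(toupper(aa), record = "DSSP residue"),
      ss8 = ss8,
      acc = as.integer(acc_field)
    )
  }
  if (idx == 0L) abort_format("DSSP file contains no residue records")
  dplyr::bind_rows(out)
}

# EVA/CASP-style 8->3 collapse: H,G,I -> H; E,B -> E; T,S,loop -> C.
DSSP_TO_SS3 <- c(
  H = "H", G = "H", I = "H",
  E = "E", B = "E",
  T = "C", S = "C", " " = "C"
)

# Maximum accessible surface areas (A^2) per residue (Rost & Sander 1994
# normalization), used for the relative-accessibility threshold.
MAX_ACC <- c(
  A = 106, C = 135, D = 163, E = 194, F = 197, G = 84, H = 184, I = 169,
  K = 205, L = 164, M = 188, N = 157, P = 136, Q = 198, R = 248, S = 130,
  T = 142, V = 142, W = 227, Y = 222
)

#' Collapse DSSP records to 3-state secondary structure
#'
#' Applies the conventional 8-to-3 state mapping (H, G, I to helix; E, B to
#' strand; T, S and loop to coil).
#'
#' @param records A tibble as returned by [read_dssp()].
#' @return A single SS3 string over \{H, E, C\}, one symbol per residue.
#' @export
dssp_ss3 <- function(records) {
  paste(unname(DSSP_TO_SS3[records$ss8]), collapse = "")
}

#' Collapse DSSP records to buried/exposed solvent accessibility
#'
#' A residue is called exposed (`e`) when its relative accessibility —
#' absolute accessibility divided by the residue's maximum accessible
#' surface area — is at least `threshold`, else buried (`b`). The default
#' threshold of 0.25 is the convention of the ACCpro/SSpro family of
#' accessibility predictors. Unknown residues (`X`) are normalized by the
#' mean maximum accessibility of the 20 residues.
#'
#' @inheritParams dssp_ss3
#' @param threshold Relative accessibility at or above which a residue is
#'   exposed (default 0.25).
#' @return A single SA2 string over \{b, e\}, one symbol per residue.
#' @export
dssp_sa2 <- function(records, threshold = 0.25) {
  max_acc <- unname(MAX_ACC[records$aa])
  max_acc[is.na(max_acc)] <- mean(MAX_ACC)
  rel <- records$acc / max_acc
  paste(ifelse(rel >= threshold, "e", "b"), collapse = "")
}
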