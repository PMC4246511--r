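# Deterministic synthetic input files for every supported format, returned
# together with the generator's in-memory ground truth, so parsers and the
# CLI are testable without external data. Not a biophysical simulator: the
# only statistical realism promised is that the PSSM is consistent with the
# MSA it accompanies.

# Rates of the MSA mutation model (per position, per non-query row).
FIXTURE_RATES <- list(substitution = 0.2, gap = 0.05)

#' Generate a coherent bundle of synthetic input files
#'
#' Draws a random protein, then fabricates mutually consistent files in all
#' six supported dialects: FASTA; an anchored MSA obtained by mutating the
#' query (substitution rate 0.2, gap rate 0.05 per position in non-query
#' rows); a PSI-BLAST-style ASCII PSSM whose percentage rows are the MSA
#' column frequencies apportioned to integers summing to 100, log-odds
#' `round(log2(freq/0.05))` (floored at -9 where the frequency is 0) and
#' information `log2(20) - H(column)` rounded to the file's 2-decimal
#' precision; a DSSP file with helix/strand/loop segments of length 5 and
#' accessibilities drawn uniformly in `[0, max_acc(aa)]` (plus one
#' chain-break line to exercise parsers); a PSIPRED `.ss2` and an SSpro flat
#' file consistent with the DSSP-derived 3-state string (true class
#' probability 0.8, others 0.1).
#'
#' All randomness derives from `seed`; regenerating with the same arguments
#' yields byte-identical files. Ground-truth components are stored at file
#' precision, so parsing any written file reproduces them exactly.
#'
#' @param seed Integer seed controlling all randomness.
#' @param length Number of residues (>= 1).
#' @param msa_rows Number of alignment rows including the query (>= 1).
#' @param dir Directory to write into (created if needed).
#' @return A list with `seed`, `protein` (tibble: `id`, `sequence`), `msa`
#'   (`anchored_msa`), `pssm` (`pssm_profile`), `dssp` (tibble of DSSP
#'   records), `ss_pred` (`ss_prediction` with probabilities), `sspro`
#'   (`ss_prediction`), and `file_paths` (named character vector: `fasta`,
#'   `msa`, `pssm`, `dssp`, `ss2`, `sspro`).
#' @export
#' @examples
#' fx <- make_fixture(seed = 1, length = 12, msa_rows = 4, dir = tempfile())
#' read_fasta(fx$file_paths[["fasta"]])
make_fixture <- function(seed, length = 60, msa_rows = 10,
                         dir = tempfile("protchar-fixture-")) {
  if (length < 1 || msa_rows < 1) {
    abort_domain("make_fixture needs length >= 1 and msa_rows >= 1")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  id <- sprintf("synthetic_%d", seed)
  query <- paste(sample(AA20, length, replace = TRUE), collapse = "")

  rows <- c(query, vapply(seq_len(max(msa_rows - 1, 0)), function(k) {
    chars <- seq_chars(query)
    mutate <- stats::runif(length) < FIXTURE_RATES$substitution
    chars[mutate] <- sample(AA20, sum(mutate), replace = TRUE)
    gap <- stats::runif(length) < FIXTURE_RATES$gap
    chars[gap] <- "-"
    paste(chars, collapse = "")
  }, character(1)))

  msa <- new_anchored_msa(id, rows)
  profiles <- column_profiles(msa)
  freq <- profile_freq_matrix(profiles)

  # percentages by largest-remainder apportionment so every row sums to 100
  percentages <- t(apply(freq, 1, apportion_100))
  log_odds <- round(log2(pmax(freq, 2^-9 * 0.05) / 0.05))
  information <- round(
    vapply(seq_len(length), function(j) log2(20) - calculate_entropy(freq[j, ]), numeric(1)),
    2
  )
  # remap ground truth to PSI-BLAST file column order, as the parser keeps it
  lo <- log_odds[, PSIBLAST_ORDER, drop = FALSE]
  pc <- percentages[, PSIBLAST_ORDER, drop = FALSE]
  pssm <- new_pssm_profile(seq_chars(query), lo, pc, information)

  ss8 <- fixture_ss8(length)
  aa_chars <- seq_chars(query)
  acc <- vapply(aa_chars, function(a) sample.int(MAX_ACC[[a]] + 1L, 1L) - 1L, integer(1))
  dssp <- tibble(
    residue_index = seq_len(length), chain = "A",
    aa = aa_chars, ss8 = ss8, acc = as.integer(acc)
  )

  ss3 <- dssp_ss3(dssp)
  probs <- t(vapply(seq_chars(ss3), function(s) {
    p <- c(coil = 0.1, helix = 0.1, strand = 0.1)
    p[[c(H = "helix", E = "strand", C = "coil")[[s]]]] <- 0.8
    p
  }, numeric(3)))
  rownames(probs) <- NULL
  ss_pred <- new_ss_prediction(query, "SS3", ss3, probs, source = "psipred")
  sspro <- new_ss_prediction(query, "SS3", ss3, NULL, source = "sspro")

  paths <- c(
    fasta = file.path(dir, "query.fasta"),
    msa = file.path(dir, "query.msa"),
    pssm = file.path(dir, "query.pssm"),
    dssp = file.path(dir, "query.dssp"),
    ss2 = file.path(dir, "query.ss2"),
    sspro = file.path(dir, "query.sspro")
  )
  write_lf(c(paste0(">", id, " synthetic fixture"), fold_sequence(query)), paths[["fasta"]])
  write_lf(rows, paths[["msa"]])
  write_lf(render_pssm(pssm), paths[["pssm"]])
  write_lf(render_dssp(dssp), paths[["dssp"]])
  write_lf(render_ss2(query, ss3, probs), paths[["ss2"]])
  write_lf(
    c("# SSpro synthetic fixture", "# three-state secondary structure", query, ss3),
    paths[["sspro"]]
  )

  list(
    seed = seed,
    protein = tibble(id = id, sequence = query),
    msa = msa, pssm = pssm, dssp = dssp,
    ss_pred = ss_pred, sspro = sspro,
    file_paths = paths
  )
}

write_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

fold_sequence <- function(seq, width = 60) {
  starts <- seq(1, nchar(seq), by = width)
  vapply(starts, function(s) substr(seq, s, min(s + width - 1, nchar(seq))), character(1))
}

# integer percentages summing to exactly 100 (largest-remainder method)
apportion_100 <- function(f) {
  raw <- f * 100
  base <- floor(raw)
  short <- 100L - as.integer(sum(base))
  if (short > 0) {
    give <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  base
}

# alternating helix/strand/loop segments of length 5
fixture_ss8 <- function(n) {
  pattern <- rep(c("H", "E", " "), each = 5)
  rep_len(pattern, n)
}

render_pssm <- function(pssm) {
  header <- c(
    "",
    paste(
      "Last position-specific scoring matrix computed, weighted observed percentages rounded down,",
      "information per position, and relative weight of gapless real matches to pseudocounts"
    ),
    paste0("           ", paste(sprintf("%3s", c(PSIBLAST_ORDER, PSIBLAST_ORDER)), collapse = " "))
  )
  body <- vapply(seq_along(pssm$residues), function(i) {
    paste0(
      sprintf("%5d %s ", i, pssm$residues[[i]]),
      paste(sprintf("%3d", pssm$log_odds[i, ]), collapse = " "), " ",
      paste(sprintf("%3d", pssm$percentages[i, ]), collapse = " "),
      sprintf("  %4.2f %8.2f", pssm$information[[i]], 1.0)
    )
  }, character(1))
  footer <- c(
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1343     0.3176",
    "Standard Gapped      0.0410     0.2670"
  )
  c(header, body, footer)
}

render_dssp <- function(records) {
  header <- c(
    "==== Secondary Structure Definition; synthetic fixture ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  )
  half <- nrow(records) %/% 2
  body <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(records))) {
    serial <- serial + 1L
    body <- c(body, dssp_line(serial, records$residue_index[[i]], records$chain[[i]],
      records$aa[[i]], records$ss8[[i]], records$acc[[i]]))
    if (i == half && nrow(records) >= 4) {
      # a chain-break line, to be skipped by parsers
      serial <- serial + 1L
      body <- c(body, sprintf("%5d        !              0", serial))
    }
  }
  c(header, body)
}

dssp_line <- function(serial, resnum, chain, aa, ss8, acc) {
  # fixed columns: serial 1-5, resnum 6-10, chain 12, AA 14, SS 17, ACC 35-38
  paste0(
    sprintf("%5d%5d %s %s  %s", serial, resnum, chain, aa, ss8),
    strrep(" ", 17),
    sprintf("%4d", acc)
  )
}

render_ss2 <- function(query, ss3, probs) {
  c(
    "# PSIPRED VFORMAT (synthetic fixture)",
    "",
    vapply(seq_len(nchar(query)), function(i) {
      sprintf(
        "%4d %s %s  %5.3f %5.3f %5.3f",
        i, substr(query, i, i), substr(ss3, i, i),
        probs[i, "coil"], probs[i, "helix"], probs[i, "strand"]
      )
    }, character(1))
  )
}
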