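# Independent oracles and small utilities shared across tests. These stay
# deliberately naive and separate from the implementation paths they check.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  path
}

# Reference FASTA parser: state machine over raw lines, no shared code with
# read_fasta (no regex grouping, no tibble plumbing).
reference_fasta <- function(lines) {
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (line in lines) {
    line <- trimws(line)
    if (line == "") next
    if (substr(line, 1, 1) == ">") {
      if (!is.null(cur)) seqs <- c(seqs, cur)
      ids <- c(ids, strsplit(substr(line, 2, nchar(line)), " +")[[1]][1])
      cur <- ""
    } else {
      cur <- paste0(cur, toupper(gsub(" ", "", line, fixed = TRUE)))
    }
  }
  if (!is.null(cur)) seqs <- c(seqs, cur)
  data.frame(id = ids, sequence = seqs)
}

# Textbook sum-formula Pearson correlation.
reference_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Element-by-element cosine.
reference_cosine <- function(x, y) {
  dot <- 0
  nx <- 0
  ny <- 0
  for (i in seq_along(x)) {
    dot <- dot + x[i] * y[i]
    nx <- nx + x[i]^2
    ny <- ny + y[i]^2
  }
  dot / sqrt(nx) / sqrt(ny)
}

# Direct entropy evaluation (loop form).
reference_entropy <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log(v) / log(2)
  h
}

# Brute-force power mean on raw values.
reference_power_mean <- function(v, n) {
  acc <- 0
  for (x in v) acc <- acc + x^n
  (acc / length(v))^(1 / n)
}

random_aa_string <- function(len) {
  paste(sample(protchar::aa_alphabet(), len, replace = TRUE), collapse = "")
}

# A tiny handcrafted PSI-BLAST-style PSSM with known values in row 1.
handcrafted_pssm_lines <- function(footer = TRUE) {
  order <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  label <- paste0("           ", paste(sprintf("%3s", c(order, order)), collapse = " "))
  lo1 <- c(-2, rep(0, 18), 3)
  pc1 <- c(rep(0, 12), 100, rep(0, 7)) # all mass on M (file column 13)
  row <- function(i, aa, lo, pc, info) {
    paste0(
      sprintf("%5d %s ", i, aa),
      paste(sprintf("%3d", lo), collapse = " "), " ",
      paste(sprintf("%3d", pc), collapse = " "),
      sprintf("  %4.2f %8.2f", info, 0.30)
    )
  }
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    label,
    row(1, "M", lo1, pc1, 0.95),
    row(2, "A", rep(1, 20), rep(5, 20), 0.10),
    row(3, "C", rep(-1, 20), rep(5, 20), 0.20),
    row(4, "D", rep(2, 20), rep(5, 20), 0.30)
  )
  if (footer) {
    lines <- c(
      lines, "",
      "                      K         Lambda",
      "Standard Ungapped    0.1343     0.3176"
    )
  }
  lines
}

# A tiny handcrafted DSSP file: H/H/E with ACC 10/20/120, fixed columns.
handcrafted_dssp_lines <- function(ss = c("H", "H", "E"), acc = c(10, 20, 120),
                                   aa = c("A", "A", "V"), chain_break = FALSE) {
  line <- function(serial, resnum, a, s, ac) {
    paste0(
      sprintf("%5d%5d %s %s  %s", serial, resnum, "A", a, s),
      strrep(" ", 17), sprintf("%4d", ac)
    )
  }
  body <- character(0)
  serial <- 0
  for (i in seq_along(ss)) {
    serial <- serial + 1
    body <- c(body, line(serial, i, aa[i], ss[i], acc[i]))
    if (chain_break && i == 1) {
      serial <- serial + 1
      body <- c(body, sprintf("%5d        !              0", serial))
    }
  }
  c(
    "==== Secondary Structure Definition ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    TCO",
    body
  )
}
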