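# Numeric lookup tables are shipped as tab-separated files under
# inst/extdata/lookup/, each with a '#' header carrying its citation (or
# synthetic provenance) and a checksum (sum of all values). They are loaded
# once per session into this cache.
.table_cache <- new.env(parent = emptyenv())

lookup_path <- function(name) {
  file <- switch(name,
    atchley = "atchley.tsv",
    hydrophobicity = "hydrophobicity.tsv",
    interface_contact = "interface_contact_synthetic.tsv",
    beta_contact = "beta_contact_synthetic.tsv",
    abort_domain(paste0("unknown lookup table '", name, "'"))
  )
  system.file("extdata", "lookup", file, package = "protchar", mustWork = TRUE)
}

#' Inspect an embedded lookup table
#'
#' Returns one of the package's numeric lookup tables as a tibble, exactly
#' as shipped (residue tables long by residue, pair tables one row per
#' unordered pair). The `atchley` and `hydrophobicity` tables are verbatim
#' transcriptions of published scales (citation in the file header and in
#' the table attribute); the two contact-potential tables are synthetic
#' stand-ins constructed for this package, flagged as such in their headers.
#'
#' @param name One of `"atchley"`, `"hydrophobicity"`,
#'   `"interface_contact"`, `"beta_contact"`.
#' @return A tibble; attribute `header` holds the file's comment header
#'   lines (citation and checksum).
#' @export
lookup_table <- function(name = c("atchley", "hydrophobicity",
                                  "interface_contact", "beta_contact")) {
  name <- match.arg(name)
  if (!is.null(.table_cache[[name]])) return(.table_cache[[name]])
  path <- lookup_path(name)
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  d <- as_tibble(read.table(path,
    sep = "\t", header = TRUE,
    comment.char = "#", stringsAsFactors = FALSE
  ))
  values <- unlist(d[vapply(d, is.numeric, logical(1))], use.names = FALSE)
  declared <- as.numeric(sub(".*checksum: ", "", header[grepl("checksum:", header)]))
  if (abs(sum(values) - declared) > 1e-6) {
    abort_format(paste0("lookup table '", name, "' fails its checksum"))
  }
  attr(d, "header") <- header
  .table_cache[[name]] <- d
  d
}

# Residue-keyed numeric matrix/vector accessors (canonical AA order).
atchley_matrix <- function() {
  d <- lookup_table("atchley")
  m <- as.matrix(d[, c("f1", "f2", "f3", "f4", "f5")])
  rownames(m) <- d$aa
  m[AA20, , drop = FALSE]
}

hydrophobicity_vector <- function() {
  d <- lookup_table("hydrophobicity")
  stats::setNames(d$value, d$aa)[AA20]
}

pair_matrix <- function(name) {
  key <- paste0(".m_", name)
  if (!is.null(.table_cache[[key]])) return(.table_cache[[key]])
  d <- lookup_table(name)
  m <- matrix(NA_real_, 20, 20, dimnames = list(AA20, AA20))
  for (i in seq_len(nrow(d))) {
    m[d$a[[i]], d$b[[i]]] <- d$value[[i]]
    m[d$b[[i]], d$a[[i]]] <- d$value[[i]]
  }
  stopifnot(!anyNA(m))
  .table_cache[[key]] <- m
  m
}

minmax <- function(x, lo, hi) (x - lo) / (hi - lo)

check_residue <- function(aa, context) {
  if (!is.character(aa) || length(aa) != 1 || nchar(aa) != 1) {
    abort_domain(paste0(context, " expects a single residue symbol"))
  }
  aa <- toupper(aa)
  if (!aa %in% c(AA20, "X")) abort_alphabet(aa, context)
  aa
}

#' Atchley physicochemical factors of a residue
#'
#' Returns the five published factor scores characterizing a residue's
#' polarity/accessibility, secondary-structure propensity, molecular size,
#' codon composition and electrostatic charge (Atchley et al. 2005).
#' Residues close in this 5-D space are biochemically similar. The unknown
#' residue `X` maps to five zeros.
#'
#' @param aa A single residue symbol (20 standard letters or `X`).
#' @param scaled If `TRUE`, each factor dimension is min-max rescaled to
#'   \[0, 1\] over the 20 residues (the per-dimension extreme residues map
#'   to exactly 0 and 1).
#' @return A named numeric vector of length 5 (`f1` ... `f5`).
#' @export
#' @examples
#' atchley_factors("A")
atchley_factors <- function(aa, scaled = FALSE) {
  aa <- check_residue(aa, "atchley_factors")
  m <- atchley_matrix()
  if (aa == "X") return(stats::setNames(numeric(5), colnames(m)))
  v <- m[aa, ]
  if (scaled) {
    v <- minmax(v, apply(m, 2, min), apply(m, 2, max))
  }
  v
}

#' Residue hydrophobicity
#'
#' Scalar lookup in the embedded side-chain hydrophobicity scale (Monera et
#' al. 1995, pH 7; glycine = 0, more positive = more hydrophobic). `X`
#' returns the scale mean.
#'
#' @inheritParams atchley_factors
#' @param scaled If `TRUE`, min-max rescale over the 20 scale values.
#' @return A single numeric value.
#' @export
hydrophobicity <- function(aa, scaled = FALSE) {
  aa <- check_residue(aa, "hydrophobicity")
  h <- hydrophobicity_vector()
  v <- if (aa == "X") mean(h) else h[[aa]]
  if (scaled) v <- minmax(v, min(h), max(h))
  unname(v)
}

pair_potential <- function(a, b, scaled, name, context) {
  a <- check_residue(a, context)
  b <- check_residue(b, context)
  m <- pair_matrix(name)
  v <- if (a == "X" || b == "X") mean(m[upper.tri(m, diag = TRUE)]) else m[a, b]
  if (scaled) v <- minmax(v, min(m), max(m))
  unname(v)
}

#' Pairwise statistical contact potentials
#'
#' `interface_contact_potential()` scores a residue pair by a
#' protein-protein interface contact potential;
#' `beta_contact_potential()` scores the pair for cross-strand pairing in a
#' beta sheet. Both lookups are symmetric (contacts are unordered) and any
#' pair involving the unknown residue `X` returns the table mean. The tables
#' shipped with this package are synthetic stand-ins with the documented
#' statistical shape (see [lookup_table()]); the file format allows dropping
#' in a transcribed published table.
#'
#' @param a,b Single residue symbols (20 standard letters or `X`).
#' @param scaled If `TRUE`, min-max rescale over the table's value range, so
#'   the extreme pairs map to exactly 0 and 1.
#' @return A single numeric value.
#' @export
interface_contact_potential <- function(a, b, scaled = FALSE) {
  pair_potential(a, b, scaled, "interface_contact", "interface_contact_potential")
}

#' @rdname interface_contact_potential
#' @export
beta_contact_potential <- function(a, b, scaled = FALSE) {
  pair_potential(a, b, scaled, "beta_contact", "beta_contact_potential")
}
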