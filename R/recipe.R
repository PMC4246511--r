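# Feature recipes: which characterizer/encoder blocks to evaluate and how to
# window them. Per-residue blocks are evaluated at every position of an odd
# window centred on the target residue; window slots falling outside the
# sequence contribute zeros plus a boundary indicator bit (1 = outside), so
# feature length is constant at window * sum(block width + 1).

PER_RESIDUE_BLOCKS <- c(
  hot_aa = 20, hot_ss = 3, hot_sa = 2, atchley = 5, hydrophobicity = 1,
  pssm_logodds = 20, pssm_freq = 20, msa_freq = 20, information = 1
)
GLOBAL_BLOCKS <- c(
  aa_composition = 20, ss_composition = 3, sa_composition = 2,
  ordered_mean = 1, entropy = 1
)

#' Define a feature recipe
#'
#' A recipe names the feature blocks to evaluate, either per residue (one
#' example per sequence position, each block evaluated over a sliding window)
#' or globally (one example per protein). Per-residue blocks: `hot_aa`,
#' `hot_ss`, `hot_sa`, `atchley`, `hydrophobicity`, `pssm_logodds`,
#' `pssm_freq`, `msa_freq`, `information`. Global blocks: `aa_composition`,
#' `ss_composition`, `sa_composition`, `ordered_mean` (parameterized as
#' `"ordered_mean:<n>:<scale>"`, e.g. `"ordered_mean:2:hydrophobicity"`) and
#' `entropy` (Shannon entropy of the residue composition). A recipe may not
#' mix the two kinds.
#'
#' @param blocks Character vector (or single comma-separated string) of block
#'   names in the order their features are concatenated.
#' @param window Odd positive window width for per-residue recipes (1 =
#'   target residue only; ignored for global recipes).
#' @param scaled If `TRUE`, blocks emit \[0, 1\]-scaled values: min-max for
#'   lookup tables, logistic `1/(1 + exp(-x))` for the unbounded PSSM
#'   log-odds, and information divided by its `log2(20)` maximum.
#' @return A `feature_recipe` list with fields `blocks`, `kind`
#'   (`"per_residue"` or `"global"`), `window`, `scaled`, and `width`
#'   (feature vector length, `NA` until input-independent).
#' @export
#' @examples
#' feature_recipe("hot_aa,pssm_logodds", window = 15)
feature_recipe <- function(blocks, window = 1L, scaled = FALSE) {
  if (length(blocks) == 1 && grepl(",", blocks)) {
    blocks <- strsplit(blocks, ",")[[1]]
  }
  blocks <- trimws(blocks)
  if (length(blocks) == 0 || !all(nzchar(blocks))) {
    abort_domain("recipe must name at least one block")
  }
  base <- sub(":.*$", "", blocks)
  per_res <- base %in% names(PER_RESIDUE_BLOCKS)
  glob <- base %in% names(GLOBAL_BLOCKS)
  if (any(!per_res & !glob)) {
    abort(
      paste0("unknown feature block(s): ", paste(blocks[!per_res & !glob], collapse = ", ")),
      class = "protchar_error_config"
    )
  }
  if (any(per_res) && any(glob & !per_res)) {
    abort("a recipe may not mix per-residue and global blocks",
      class = "protchar_error_config"
    )
  }
  kind <- if (all(per_res)) "per_residue" else "global"
  if (kind == "per_residue") {
    if (window < 1 || window %% 2 == 0) {
      abort_domain("window must be an odd positive integer")
    }
    width <- window * sum(PER_RESIDUE_BLOCKS[base] + 1)
  } else {
    window <- 1L
    width <- sum(GLOBAL_BLOCKS[base])
  }
  for (b in blocks[base == "ordered_mean"]) parse_ordered_mean_block(b)
  structure(
    list(
      blocks = blocks, kind = kind, window = as.integer(window),
      scaled = isTRUE(scaled), width = width
    ),
    class = "feature_recipe"
  )
}

parse_ordered_mean_block <- function(block) {
  parts <- strsplit(block, ":")[[1]]
  n <- if (length(parts) >= 2) suppressWarnings(as.integer(parts[[2]])) else 1L
  scale <- if (length(parts) >= 3) parts[[3]] else "hydrophobicity"
  if (is.na(n) || n < 1) {
    abort("ordered_mean block needs a positive integer order, e.g. ordered_mean:2:hydrophobicity",
      class = "protchar_error_config"
    )
  }
  list(n = n, scale = scale)
}

# Resolve the inputs a block needs; `inputs` is a named list with any of
# sequence (string), pssm (pssm_profile), msa (anchored_msa), ss (SS3
# string), sa (SA2 string).
required_input <- function(block) {
  switch(block,
    hot_aa = , atchley = , hydrophobicity = , aa_composition = ,
    ordered_mean = , entropy = "sequence",
    hot_ss = , ss_composition = "ss",
    hot_sa = , sa_composition = "sa",
    pssm_logodds = , pssm_freq = "pssm",
    msa_freq = "msa",
    information = "pssm_or_msa"
  )
}

check_recipe_inputs <- function(recipe, inputs) {
  base <- sub(":.*$", "", recipe$blocks)
  need <- unique(vapply(base, required_input, character(1)))
  missing <- character(0)
  for (n in need) {
    ok <- if (n == "pssm_or_msa") {
      !is.null(inputs$pssm) || !is.null(inputs$msa)
    } else {
      !is.null(inputs[[n]])
    }
    if (!ok) missing <- c(missing, if (n == "pssm_or_msa") "pssm or msa" else n)
  }
  if (length(missing) > 0) {
    abort(paste0("recipe requires missing input(s): ", paste(missing, collapse = ", ")),
      class = "protchar_error_config"
    )
  }
  invisible(TRUE)
}

logistic <- function(x) 1 / (1 + exp(-x))

# Precompute per-position block matrices once per protein.
block_values <- function(inputs, recipe) {
  L <- nchar(inputs$sequence)
  scaled <- recipe$scaled
  base <- unique(sub(":.*$", "", recipe$blocks))
  vals <- list()
  for (b in base) {
    vals[[b]] <- switch(b,
      hot_aa = encode_string(inputs$sequence, "AA20"),
      hot_ss = encode_string(inputs$ss, "SS3"),
      hot_sa = encode_string(inputs$sa, "SA2"),
      atchley = t(vapply(seq_chars(inputs$sequence), atchley_factors,
        numeric(5), scaled = scaled, USE.NAMES = FALSE
      )),
      hydrophobicity = matrix(vapply(seq_chars(inputs$sequence), hydrophobicity,
        numeric(1), scaled = scaled, USE.NAMES = FALSE
      ), ncol = 1),
      pssm_logodds = {
        m <- inputs$pssm$log_odds[, AA20, drop = FALSE]
        if (scaled) logistic(m) else m
      },
      pssm_freq = profile_freq_matrix(pssm_column_profiles(inputs$pssm)),
      msa_freq = profile_freq_matrix(msa_profiles_cached(inputs)),
      information = {
        info <- if (!is.null(inputs$pssm)) {
          inputs$pssm$information
        } else {
          msa_profiles_cached(inputs)$information
        }
        matrix(if (scaled) info / log2(20) else info, ncol = 1)
      }
    )
    if (nrow(vals[[b]]) != L) {
      abort(paste0("input for block '", b, "' has ", nrow(vals[[b]]),
        " positions but the sequence has ", L),
        class = "protchar_error_config"
      )
    }
  }
  vals
}

msa_profiles_cached <- function(inputs) {
  env <- attr(inputs, "cache")
  if (is.null(env)) return(column_profiles(inputs$msa))
  if (is.null(env$msa_profiles)) env$msa_profiles <- column_profiles(inputs$msa)
  env$msa_profiles
}

#' Assemble the windowed feature vector of one residue
#'
#' Concatenates, in recipe order, each per-residue block evaluated at every
#' position of the window centred on `position`. A window slot outside the
#' sequence contributes a zero vector for the block; each (block, slot) pair
#' ends with a boundary indicator bit, 1 when the slot falls outside the
#' sequence and 0 otherwise, so feature length is constant across positions.
#'
#' @param inputs Named list of parsed inputs: `sequence` (string) and, as
#'   the recipe requires, `pssm` (`pssm_profile`), `msa` (`anchored_msa`),
#'   `ss` / `sa` (annotation strings).
#' @param recipe A per-residue [feature_recipe()].
#' @param position 1-based residue position.
#' @return A numeric vector of length `recipe$width`.
#' @export
build_residue_features <- function(inputs, recipe, position) {
  if (recipe$kind != "per_residue") {
    abort_domain("build_residue_features needs a per-residue recipe")
  }
  check_recipe_inputs(recipe, inputs)
  L <- nchar(inputs$sequence)
  if (position < 1 || position > L) {
    abort_domain(paste0("position ", position, " outside sequence of length ", L))
  }
  vals <- block_values(inputs, recipe)
  residue_features_from(vals, recipe, position, L)
}

residue_features_from <- function(vals, recipe, position, L) {
  half <- (recipe$window - 1) %/% 2
  slots <- (position - half):(position + half)
  base <- sub(":.*$", "", recipe$blocks)
  out <- numeric(0)
  for (b in base) {
    m <- vals[[b]]
    w <- ncol(m)
    for (s in slots) {
      if (s >= 1 && s <= L) {
        out <- c(out, m[s, ], 0)
      } else {
        out <- c(out, numeric(w), 1)
      }
    }
  }
  unname(out)
}

global_features <- function(inputs, recipe) {
  check_recipe_inputs(recipe, inputs)
  out <- numeric(0)
  for (b in recipe$blocks) {
    base <- sub(":.*$", "", b)
    out <- c(out, switch(base,
      aa_composition = aa_composition(inputs$sequence)$fraction,
      ss_composition = ss_composition(inputs$ss)$fraction,
      sa_composition = sa_composition(inputs$sa)$fraction,
      ordered_mean = {
        p <- parse_ordered_mean_block(b)
        scaled_ordered_mean(inputs$sequence, p$n, p$scale)
      },
      entropy = calculate_entropy(aa_composition(inputs$sequence)$fraction)
    ))
  }
  unname(out)
}

#' Build a feature table for a whole protein
#'
#' Evaluates a recipe over parsed inputs. A per-residue recipe yields one
#' example per sequence position (windowed, see
#' [build_residue_features()]); a global recipe yields a single example.
#' Labels default to 0; supply `labels` (a numeric vector, one per example)
#' to override — e.g. 3-state secondary structure classes mapped H = 1,
#' E = 2, C = 3 via [ss3_labels()].
#'
#' @inheritParams build_residue_features
#' @param labels Optional numeric label vector (length = number of examples).
#' @return A tibble with columns `label` and `features` (list-column),
#'   ready for [write_features()].
#' @export
build_feature_table <- function(inputs, recipe, labels = NULL) {
  attr(inputs, "cache") <- new.env(parent = emptyenv())
  check_recipe_inputs(recipe, inputs)
  if (recipe$kind == "global") {
    feats <- list(global_features(inputs, recipe))
  } else {
    L <- nchar(inputs$sequence)
    vals <- block_values(inputs, recipe)
    feats <- lapply(seq_len(L), function(p) residue_features_from(vals, recipe, p, L))
  }
  if (is.null(labels)) labels <- rep(0, length(feats))
  if (length(labels) != length(feats)) {
    abort_domain(paste0(
      "got ", length(labels), " labels for ", length(feats), " examples"
    ))
  }
  tibble(label = as.numeric(labels), features = feats)
}

#' Numeric labels from a 3-state secondary structure string
#'
#' Maps H to 1, E to 2 and C to 3, the package's multiclass label
#' convention for secondary-structure training files.
#'
#' @param ss3 An SS3 annotation string.
#' @return An integer vector, one label per residue.
#' @export
ss3_labels <- function(ss3) {
  check_annotation(ss3, "SS3")
  unname(c(H = 1L, E = 2L, C = 3L)[seq_chars(ss3)])
}
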