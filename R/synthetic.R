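# Synthetic carbonyl datasets.
#
# The generator emits acyclic aldehyde/ketone-like molecules (a carbon
# chain with optional methyl branches and exactly one C=O) together with a
# property built from a known linear structure-property relationship, so
# the whole pipeline can be exercised against controlled ground truth.
# Property coefficients default to a retention-index-like scale
# (roughly 700-1400 over chain lengths 3-9).

#' Configuration for the synthetic dataset generator
#'
#' @param n_compounds number of molecules (>= 4; default 24).
#' @param max_chain_length longest backbone drawn (default 9 carbons;
#'   minimum backbone is 3).
#' @param branch_probability probability that an eligible interior carbon
#'   carries a methyl branch (default 0.3).
#' @param intercept,per_atom,per_branch,per_position coefficients of the
#'   property model: `property = intercept + per_atom * heavy_atoms +
#'   per_branch * branches + per_position * carbonyl_position + noise`,
#'   where `carbonyl_position` is the distance of the carbonyl carbon from
#'   the nearer chain end (0 for an aldehyde).  Defaults 350, 100, -25, 12.
#' @param noise_sd standard deviation of the Gaussian noise (default 0).
#' @param seed integer seed fixing all randomness (default 1).
#' @return an object of class `hq_synth_config`.
#' @export
synthetic_config <- function(n_compounds = 24L, max_chain_length = 9L,
                             branch_probability = 0.3, intercept = 350,
                             per_atom = 100, per_branch = -25,
                             per_position = 12, noise_sd = 0, seed = 1L) {
  n_compounds <- as.integer(n_compounds)
  if (is.na(n_compounds) || n_compounds < 4L) {
    stop_config("'n_compounds' must be >= 4")
  }
  if (max_chain_length < 3L) stop_config("'max_chain_length' must be >= 3")
  if (branch_probability < 0 || branch_probability > 1) {
    stop_config("'branch_probability' must be in [0, 1]")
  }
  if (noise_sd < 0) stop_config("'noise_sd' must be >= 0")
  structure(list(n_compounds = n_compounds,
                 max_chain_length = as.integer(max_chain_length),
                 branch_probability = branch_probability,
                 intercept = intercept, per_atom = per_atom,
                 per_branch = per_branch, per_position = per_position,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "hq_synth_config")
}

#' Generate a synthetic carbonyl dataset
#'
#' Draws molecules under the configuration, computes the property from the
#' known linear relationship plus Gaussian noise, and splits the compounds
#' 3:1 into training group I and external group II.  Deterministic under
#' the configuration seed.  Molecule SMILES are unique within a dataset
#' (duplicates are redrawn; if the structural space is too small to supply
#' enough distinct molecules, generation fails).
#'
#' @param config an [synthetic_config()].
#' @return an `hq_dataset` with a single phase `"synthetic"`.  The true
#'   (noise-free) property and the structural features are attached as the
#'   `truth` element.
#' @examples
#' generate_synthetic(synthetic_config(n_compounds = 8, seed = 42))
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "hq_synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  n <- config$n_compounds
  smiles <- character(0)
  feats <- list()
  tries <- 0L
  while (length(smiles) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) {
      stop_config("cannot draw ", n, " distinct molecules; ",
                  "increase 'max_chain_length'")
    }
    m <- .draw_molecule(config)
    if (m$smiles %in% smiles) next
    smiles <- c(smiles, m$smiles)
    feats[[length(smiles)]] <- m
  }
  heavy <- vapply(feats, `[[`, numeric(1), "heavy")
  branches <- vapply(feats, `[[`, numeric(1), "branches")
  position <- vapply(feats, `[[`, numeric(1), "position")
  truth <- config$intercept + config$per_atom * heavy +
    config$per_branch * branches + config$per_position * position
  prop <- truth + rnorm(n, 0, config$noise_sd)

  group <- rep("II", n)
  group[sample.int(n, round(0.75 * n))] <- "I"
  comp <- data.frame(name = sprintf("synth-%03d", seq_len(n)),
                     smiles = smiles, group = group)
  ri <- matrix(prop, ncol = 1, dimnames = list(comp$name, "synthetic"))
  ds <- hq_dataset(comp, ri, check_smiles = FALSE)
  ds$truth <- data.frame(name = comp$name, truth = truth, heavy = heavy,
                         branches = branches, position = position)
  ds
}

# one random molecule: backbone of `len` carbons, carbonyl at `pos`,
# optional methyl branches on interior non-carbonyl carbons
.draw_molecule <- function(config) {
  lens <- 3:config$max_chain_length
  len <- lens[sample.int(length(lens), 1L)]
  pos <- sample.int(len - 1L, 1L)
  eligible <- setdiff(seq(2L, len - 1L), pos)
  branch_at <- eligible[stats::runif(length(eligible)) < config$branch_probability]
  parts <- vapply(seq_len(len), function(i) {
    paste0("C",
           if (i == pos) "(=O)" else "",
           if (i %in% branch_at) "(C)" else "")
  }, character(1))
  list(smiles = paste0(parts, collapse = ""),
       heavy = len + length(branch_at) + 1L,
       branches = length(branch_at),
       position = min(pos, len + 1L - pos) - 1L)
}
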