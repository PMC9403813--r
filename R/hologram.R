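# Molecular holograms.
#
# A hologram is a fixed-length vector of fragment-occurrence counts: each
# canonical fragment key is mapped to a pseudo-random integer in [0, 2^31)
# by a CRC-32 hash and folded into one of L bins by reduction modulo the
# hologram length.  The shipped default lengths are the six primes
# 97, 151, 199, 257, 307 and 353; prime lengths spread systematic collision
# patterns.

#' Default hologram lengths
#' @export
HL_DEFAULT <- c(97L, 151L, 199L, 257L, 307L, 353L)

# CRC-32 (IEEE 802.3 polynomial, reflected), table-driven, pure R.
# Bit operations on R integers act on the 32-bit two's-complement pattern
# and bitwShiftR shifts logically, which is exactly what the algorithm
# needs; the result is returned as the unsigned value in a double.
.crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L) {
        bitwXor(bitwShiftR(crc, 1L), poly)
      } else {
        bitwShiftR(crc, 1L)
      }
    }
    tab[i + 1L] <- crc
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in bytes) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), .crc32_table[idx + 1L])
  }
  bitwXor(crc, -1L)
}

# cache of already-hashed keys; fragment keys repeat heavily across
# molecules, size windows and hologram lengths
.hash_cache <- new.env(parent = emptyenv())

#' Hash a fragment key to a pseudo-random integer
#'
#' Deterministically maps a canonical fragment key to an integer in
#' `[0, 2^31)`: the CRC-32 checksum of the key's UTF-8 bytes, masked to 31
#' bits.  Identical keys always map to identical integers; distinct keys
#' collide only on genuine CRC collisions.
#'
#' @param key a single non-empty string.
#' @return a double holding an integer in `[0, 2^31)`.
#' @examples
#' hash_fragment("(C)")
#' @export
hash_fragment <- function(key) {
  if (!is.character(key) || length(key) != 1L || !nzchar(key)) {
    stop_config("'key' must be a single non-empty string")
  }
  hit <- .hash_cache[[key]]
  if (!is.null(hit)) return(hit)
  crc <- .crc32(as.integer(charToRaw(enc2utf8(key))))
  val <- bitwAnd(crc, 2147483647L)  # mask to 31 bits
  val <- as.double(val)
  assign(key, val, envir = .hash_cache)
  val
}

#' Fold a fragment multiset into a hologram
#'
#' Each fragment key is hashed ([hash_fragment()]) and its occurrence count
#' accumulated in bin `hash mod L` (zero-based).  The bin sum therefore
#' always equals the total occurrence count of the multiset.
#'
#' @param fragments an `hq_fragments` object (or any named integer vector of
#'   counts keyed by fragment key).
#' @param hl hologram length.  The shipped defaults are
#'   `c(97, 151, 199, 257, 307, 353)`; any positive length is accepted.
#' @return an object of class `hq_hologram`: an integer vector of `hl`
#'   non-negative bin counts.
#' @examples
#' fr <- enumerate_fragments(parse_smiles("CCCCC"), fragment_params("A", 1, 5))
#' sum(build_hologram(fr, 97))
#' @export
build_hologram <- function(fragments, hl) {
  hl <- as.integer(hl)
  if (is.na(hl) || hl <= 0L) stop_config("'hl' must be a positive integer")
  bins <- integer(hl)
  if (length(fragments)) {
    keys <- names(fragments)
    if (is.null(keys)) stop_config("'fragments' must be named by key")
    idx <- vapply(keys, function(k) hash_fragment(k) %% hl, numeric(1)) + 1
    for (i in seq_along(idx)) {
      bins[idx[i]] <- bins[idx[i]] + as.integer(fragments[[i]])
    }
  }
  structure(bins, class = "hq_hologram", hl = hl)
}

#' @export
print.hq_hologram <- function(x, ...) {
  cat("<hq_hologram> length ", attr(x, "hl"), ", total count ",
      sum(unclass(x)), ", occupied bins ", sum(unclass(x) > 0L), "\n",
      sep = "")
  invisible(x)
}

#' Hologram matrix of a dataset
#'
#' Parses every compound of a dataset, enumerates fragments under one
#' parameter set, and stacks the holograms into a compounds-by-bins matrix
#' in dataset order.
#'
#' @param dataset an `hq_dataset` (see [read_dataset()]), or a character
#'   vector of SMILES.
#' @param params an [fragment_params()] object.
#' @param hl hologram length.
#' @return integer matrix with one row per compound (rownames = compound
#'   names) and `hl` columns.
#' @export
build_matrix <- function(dataset, params, hl) {
  if (inherits(dataset, "hq_dataset")) {
    smiles <- setNames(dataset$compounds$smiles, dataset$compounds$name)
  } else {
    smiles <- dataset
    if (is.null(names(smiles))) names(smiles) <- smiles
  }
  mols <- parse_smiles_all(smiles)
  frags <- lapply(mols, enumerate_fragments, params = params)
  fold_rows(frags, hl)
}

# stack per-compound fragment multisets into a matrix at one hologram length
fold_rows <- function(frags, hl) {
  hl <- as.integer(hl)
  mat <- matrix(0L, nrow = length(frags), ncol = hl,
                dimnames = list(names(frags), NULL))
  for (i in seq_along(frags)) {
    mat[i, ] <- as.integer(build_hologram(frags[[i]], hl))
  }
  mat
}

# parse a named vector of SMILES, collecting per-compound failures into a
# single data error that names the offending compounds
parse_smiles_all <- function(smiles) {
  mols <- vector("list", length(smiles))
  names(mols) <- names(smiles)
  bad <- character(0)
  for (i in seq_along(smiles)) {
    mols[i] <- list(tryCatch(parse_smiles(smiles[[i]]),
                             error = function(e) NULL))
    if (is.null(mols[[i]])) bad <- c(bad, names(smiles)[i])
  }
  if (length(bad)) {
    stop_data("cannot parse SMILES for: ", paste(bad, collapse = ", "))
  }
  mols
}
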