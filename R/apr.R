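#' Sliding-window aggregation-propensity profile
#'
#' Computes, for every position of `sequence` that admits a full window, the
#' arithmetic mean of the raw per-residue propensity over a window centred on
#' that position (the windowed profile is conventionally called "a4v").
#' Positions closer than `(window - 1) / 2` residues to either terminus get
#' `NA` unless `truncated = TRUE`, in which case the mean is taken over the
#' partial window clipped to the sequence.
#'
#' @param sequence Character scalar of one-letter residue codes, or an
#'   `AAString`/`AAStringSet` (first sequence used).
#' @param scale A `propensity_scale` from [load_propensity_scale()].
#' @param window Odd integer window size, or `"auto"` for the
#'   length-dependent schedule: 5 for sequences of at most 75 residues, 7 up
#'   to 175, 9 up to 300 and 11 beyond.
#' @param truncated If `TRUE`, edge positions are averaged over the clipped
#'   window instead of being left undefined. Default `FALSE`.
#' @return An object of class `"propensity_profile"`: a list with elements
#'   `sequence`, `window`, `raw` (per-residue scale values) and `a4v`
#'   (windowed means, `NA` at undefined edge positions).
#' @export
#' @examples
#' sc <- load_propensity_scale()
#' pr <- compute_profile("MKVLILACLVALALARE", sc, window = 5)
#' pr$a4v
compute_profile <- function(sequence, scale = load_propensity_scale(),
                            window = "auto", truncated = FALSE) {
  sequence <- as_sequence_string(sequence)
  n <- nchar(sequence)
  if (identical(window, "auto")) window <- auto_window(n)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer")
  }
  if (n < window) {
    stop("sequence length (", n, ") is smaller than window (", window, ")")
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!(res %in% names(scale)))
  if (length(bad)) {
    stop("unknown residue code '", res[bad[1]], "' at position ", bad[1])
  }
  raw <- as.numeric(scale[res])
  half <- (window - 1L) %/% 2L
  csum <- cumsum(c(0, raw))
  a4v <- rep(NA_real_, n)
  idx <- seq.int(half + 1L, n - half)
  a4v[idx] <- (csum[idx + half + 1L] - csum[idx - half]) / window
  if (truncated && half > 0L) {
    for (i in c(seq_len(half), seq.int(n - half + 1L, n))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      a4v[i] <- mean(raw[lo:hi])
    }
  }
  structure(list(sequence = sequence, window = window, raw = raw, a4v = a4v,
                 truncated = truncated),
            class = "propensity_profile")
}

#' @export
print.propensity_profile <- function(x, ...) {
  cat(sprintf("Propensity profile: %d residues, window %d (%s edges)\n",
              nchar(x$sequence), x$window,
              if (x$truncated) "truncated" else "undefined"))
  cat(sprintf("a4v range: [%.3f, %.3f] over %d defined positions\n",
              min(x$a4v, na.rm = TRUE), max(x$a4v, na.rm = TRUE),
              sum(!is.na(x$a4v))))
  invisible(x)
}

# Length-dependent window schedule used by the reference web method.
auto_window <- function(n) {
  if (n <= 75L) 5L else if (n <= 175L) 7L else if (n <= 300L) 9L else 11L
}

#' Detect aggregation-prone regions from a windowed profile
#'
#' A hot spot (APR patch) is a maximal run of at least `min_patch_length`
#' consecutive positions whose windowed propensity exceeds
#' `hotspot_threshold`. With `exclude_proline = TRUE` (the published rule),
#' proline positions are ineligible, so runs break at prolines. Edge
#' positions without a defined windowed value can never belong to a patch.
#'
#' @param profile A `propensity_profile` from [compute_profile()].
#' @param hotspot_threshold Dimensionless hot-spot threshold; default -0.02.
#' @param min_patch_length Minimum run length; default 5.
#' @param exclude_proline Break runs at proline; default `TRUE`.
#' @return An object of class `"apr_set"`: list with `patches` (two-column
#'   matrix of 1-based inclusive `start`,`end`), `n_patches`,
#'   `coverage_fraction` (patch residues / sequence length), and the
#'   parameters used.
#' @export
detect_aprs <- function(profile, hotspot_threshold = -0.02,
                        min_patch_length = 5L, exclude_proline = TRUE) {
  stopifnot(inherits(profile, "propensity_profile"))
  min_patch_length <- as.integer(min_patch_length)
  if (min_patch_length < 1L) stop("min_patch_length must be >= 1")
  n <- nchar(profile$sequence)
  hot <- !is.na(profile$a4v) & profile$a4v > hotspot_threshold
  if (exclude_proline) {
    hot <- hot & strsplit(profile$sequence, "")[[1]] != "P"
  }
  patches <- runs_at_least(hot, min_patch_length)
  covered <- if (nrow(patches)) sum(patches[, 2] - patches[, 1] + 1L) else 0L
  structure(list(patches = patches,
                 n_patches = nrow(patches),
                 coverage_fraction = covered / n,
                 sequence_length = n,
                 parameters = list(hotspot_threshold = hotspot_threshold,
                                   min_patch_length = min_patch_length,
                                   exclude_proline = exclude_proline,
                                   window = profile$window)),
            class = "apr_set")
}

# Maximal runs of TRUE of length >= k, as a start/end integer matrix.
runs_at_least <- function(flag, k) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k
  out <- cbind(start = starts[keep], end = ends[keep])
  storage.mode(out) <- "integer"
  out
}

#' @export
print.apr_set <- function(x, ...) {
  cat(sprintf("APR set: %d patch(es), coverage %.1f%% of %d residues\n",
              x$n_patches, 100 * x$coverage_fraction, x$sequence_length))
  if (x$n_patches) {
    apply(x$patches, 1, function(p)
      cat(sprintf("  %d-%d (%d residues)\n", p[1], p[2], p[2] - p[1] + 1L)))
  }
  invisible(x)
}

#' Map sequence-space APR patches onto trajectory beads
#'
#' @param aprs An `apr_set`.
#' @param residue_index_of_bead Integer vector giving, for each bead, the
#'   1-based residue it represents.
#' @return Logical mask over beads: `TRUE` iff the bead's residue lies inside
#'   any APR patch.
#' @export
map_aprs_to_beads <- function(aprs, residue_index_of_bead) {
  stopifnot(inherits(aprs, "apr_set"))
  ri <- as.integer(residue_index_of_bead)
  if (any(is.na(ri)) || any(ri < 1L) || any(ri > aprs$sequence_length)) {
    stop("bead residue indices must lie in 1..", aprs$sequence_length)
  }
  in_apr <- rep(FALSE, aprs$sequence_length)
  if (aprs$n_patches) {
    for (i in seq_len(nrow(aprs$patches))) {
      in_apr[aprs$patches[i, 1]:aprs$patches[i, 2]] <- TRUE
    }
  }
  in_apr[ri]
}

#' Serialize an APR set to JSON
#'
#' @param aprs An `apr_set`.
#' @param path Output file path.
#' @param scale Optional `propensity_scale` whose checksum is recorded.
#' @export
write_aprs_json <- function(aprs, path, scale = NULL) {
  obj <- list(
    patches = if (aprs$n_patches) {
      data.frame(start = unname(aprs$patches[, 1]),
                 end = unname(aprs$patches[, 2]), row.names = NULL)
    } else data.frame(start = integer(), end = integer()),
    n_patches = aprs$n_patches,
    coverage_fraction = aprs$coverage_fraction,
    sequence_length = aprs$sequence_length,
    parameters = aprs$parameters
  )
  if (!is.null(scale)) obj$scale_checksum <- scale_checksum(scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an APR set back from JSON
#' @param path File written by [write_aprs_json()].
#' @return An `apr_set`.
#' @export
read_aprs_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  patches <- cbind(start = as.integer(obj$patches$start),
                   end = as.integer(obj$patches$end))
  structure(list(patches = patches, n_patches = obj$n_patches,
                 coverage_fraction = obj$coverage_fraction,
                 sequence_length = obj$sequence_length,
                 parameters = obj$parameters),
            class = "apr_set")
}

#' Read a protein sequence from a FASTA file
#'
#' @param path FASTA file (single or multi record).
#' @param id Optional record identifier; by default the first record is used.
#' @return Character scalar sequence.
#' @export
read_fasta_sequence <- function(path, id = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  if (!is.null(id)) {
    hit <- which(vapply(names(set), function(nm)
      identical(strsplit(nm, "\\s+")[[1]][1], id), logical(1)))
    if (!length(hit)) stop("no FASTA record with id '", id, "'")
    set <- set[hit[1]]
  }
  as.character(set[[1]])
}

as_sequence_string <- function(x) {
  if (inherits(x, "AAStringSet")) x <- x[[1]]
  if (inherits(x, "AAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L) {
    stop("sequence must be a single character string")
  }
  toupper(x)
}
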