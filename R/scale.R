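#' Load a per-residue aggregation-propensity scale
#'
#' Reads a two-column table (`residue`, `value`) mapping each of the 20
#' canonical one-letter amino acid codes to a dimensionless aggregation
#' propensity. The scale shipped with the package
#' (`system.file("extdata", "a3v_scale.tsv", package = "aprshield")`) is the
#' experimentally derived in-vivo aggregation propensity scale ("a3v")
#' commonly used for hot-spot detection; it is treated as data, so users can
#' supply their own table in the same format.
#'
#' @param path Path to a tab-separated file with columns `residue` and
#'   `value`. Defaults to the scale bundled with the package.
#' @return A named numeric vector of length 20 with class
#'   `"propensity_scale"`; names are one-letter residue codes.
#' @export
#' @examples
#' sc <- load_propensity_scale()
#' sc["I"]  # most aggregation-prone residue
load_propensity_scale <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "a3v_scale.tsv", package = "aprshield")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(tab))) {
    stop("propensity scale file must have columns 'residue' and 'value'")
  }
  res <- toupper(trimws(tab$residue))
  val <- as.numeric(tab$value)
  if (anyDuplicated(res)) {
    stop("duplicate residue codes in scale: ",
         paste(unique(res[duplicated(res)]), collapse = ", "))
  }
  canonical <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  unknown <- setdiff(res, canonical)
  if (length(unknown)) {
    stop("unknown residue codes in scale: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(canonical, res)
  if (length(missing)) {
    stop("scale is missing residues: ", paste(missing, collapse = ", "))
  }
  if (!all(is.finite(val))) stop("scale values must be finite")
  out <- stats::setNames(val, res)[canonical]
  class(out) <- c("propensity_scale", "numeric")
  out
}

#' @export
print.propensity_scale <- function(x, ...) {
  cat("Per-residue aggregation-propensity scale (20 residues)\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' MD5 checksum of a scale (recorded in serialized APR reports)
#' @param scale A `propensity_scale`.
#' @return Character scalar.
#' @keywords internal
scale_checksum <- function(scale) {
  txt <- paste(names(scale), format(as.numeric(scale), digits = 15),
               sep = ":", collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}
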