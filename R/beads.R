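#' Construct a single coarse-grained bead frame
#'
#' A bead frame holds one configuration of a coarse-grained system: bead
#' centres in nm, per-bead van der Waals radii in nm, the 1-based residue
#' each bead belongs to, and a molecule tag classifying each bead as
#' `"protein"`, `"excipient"`, `"solvent"` or `"ion"`.
#'
#' The default bead radius, 0.235 nm, is half the standard coarse-grained
#' bead diameter of 0.47 nm used by 4-to-1 mapped force fields.
#'
#' @param coordinates N x 3 numeric matrix (nm).
#' @param radii Per-bead radius (nm); recycled if scalar.
#' @param residue_index Per-bead 1-based residue index; recycled if scalar.
#' @param molecule_tag Per-bead tag; recycled if scalar.
#' @return Object of class `"bead_frame"`.
#' @export
bead_frame <- function(coordinates, radii = 0.235, residue_index = 1L,
                       molecule_tag = "protein") {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L || nrow(coordinates) < 1L) {
    stop("coordinates must be an N x 3 matrix with N >= 1")
  }
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  n <- nrow(coordinates)
  radii <- rep_len(as.numeric(radii), n)
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("all bead radii must be positive and finite")
  }
  residue_index <- rep_len(as.integer(residue_index), n)
  molecule_tag <- rep_len(as.character(molecule_tag), n)
  bad <- setdiff(unique(molecule_tag),
                 c("protein", "excipient", "solvent", "ion"))
  if (length(bad)) stop("unknown molecule tag(s): ", paste(bad, collapse = ", "))
  structure(list(coordinates = coordinates, radii = radii,
                 residue_index = residue_index, molecule_tag = molecule_tag),
            class = "bead_frame")
}

#' @export
print.bead_frame <- function(x, ...) {
  tb <- table(x$molecule_tag)
  cat(sprintf("Bead frame: %d beads (%s)\n", nrow(x$coordinates),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

n_beads <- function(frame) nrow(frame$coordinates)

#' Construct a bead trajectory
#'
#' All frames must share the topology of the first frame (bead count, radii,
#' residue indices and molecule tags); only coordinates vary.
#'
#' @param frames List of `bead_frame` objects.
#' @param frame_times Numeric times in ps; defaults to `0, 1, 2, ...`.
#' @return Object of class `"bead_trajectory"`.
#' @export
bead_trajectory <- function(frames, frame_times = NULL) {
  if (!length(frames)) stop("trajectory must contain at least one frame")
  lapply(frames, function(f) stopifnot(inherits(f, "bead_frame")))
  ref <- frames[[1]]
  for (f in frames[-1]) {
    if (n_beads(f) != n_beads(ref) ||
        !isTRUE(all.equal(f$radii, ref$radii)) ||
        !identical(f$residue_index, ref$residue_index) ||
        !identical(f$molecule_tag, ref$molecule_tag)) {
      stop("all frames must share the topology of the first frame")
    }
  }
  if (is.null(frame_times)) frame_times <- seq_along(frames) - 1
  if (length(frame_times) != length(frames)) {
    stop("frame_times length must equal number of frames")
  }
  structure(list(frames = frames, frame_times = as.numeric(frame_times)),
            class = "bead_trajectory")
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat(sprintf("Bead trajectory: %d frames x %d beads, t = %g..%g ps\n",
              length(x$frames), n_beads(x$frames[[1]]),
              min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' @export
length.bead_trajectory <- function(x) length(x$frames)

#' Warn when a frame looks periodic-image broken
#'
#' SASA here assumes whole (unwrapped, clustered) molecules. A molecule
#' whose bounding box spans more than half the overall bounding box in any
#' dimension is a common symptom of an un-imaged periodic trajectory; this
#' heuristic flags protein beads only.
#'
#' @param frame A `bead_frame`.
#' @return Invisibly, `TRUE` if the frame looks whole.
#' @export
check_whole_molecule <- function(frame) {
  p <- frame$coordinates[frame$molecule_tag == "protein", , drop = FALSE]
  if (nrow(p) < 2L) return(invisible(TRUE))
  span <- apply(p, 2, function(v) diff(range(v)))
  all_span <- apply(frame$coordinates, 2, function(v) diff(range(v)))
  if (any(all_span > 0 & span > 0.9 * all_span & span > 5)) {
    warning("protein spans most of the box in at least one dimension; ",
            "the frame may need periodic-image unwrapping before SASA")
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
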