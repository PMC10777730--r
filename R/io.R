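# Frame readers for the two plain-text coordinate formats coarse-grained
# workflows actually exchange: GRO (fixed width, nm) and PDB (Angstrom).
# Multi-frame trajectories are read as concatenated GRO frames or supplied
# as a list of files; binary trajectory formats are out of scope.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
SOLVENT_NAMES <- c("W", "PW", "WN", "WF", "SOL", "HOH", "WAT", "TIP", "TIP3")
ION_NAMES <- c("ION", "NA", "CL", "NA+", "CL-", "K", "K+", "CA", "CA2+",
               "MG", "MG2+")

#' Classify residue names into bead molecule tags
#'
#' Standard three-letter amino acid names map to `"protein"`, common
#' coarse-grained/atomistic water names to `"solvent"`, common ion names to
#' `"ion"`, and everything else to `"excipient"`. Entries of `tag_map`
#' (named character vector, `resname = tag`) override the defaults.
#'
#' @param resnames Character vector of residue names.
#' @param tag_map Optional named character overrides.
#' @return Character vector of tags.
#' @export
tag_from_resname <- function(resnames, tag_map = NULL) {
  rn <- toupper(trimws(resnames))
  tag <- rep("excipient", length(rn))
  tag[rn %in% c(AA3, "BEA")] <- "protein"
  tag[rn %in% SOLVENT_NAMES] <- "solvent"
  tag[rn %in% ION_NAMES] <- "ion"
  if (!is.null(tag_map)) {
    hit <- rn %in% toupper(names(tag_map))
    tag[hit] <- as.character(tag_map[match(rn[hit], toupper(names(tag_map)))])
  }
  tag
}

parse_gro_block <- function(lines, radii, tag_map) {
  natoms <- as.integer(trimws(lines[2]))
  if (is.na(natoms) || length(lines) < natoms + 3L) {
    stop("malformed GRO frame: bad atom count")
  }
  at <- lines[3:(2 + natoms)]
  resnum <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  if (anyNA(c(x, y, z))) stop("malformed GRO frame: bad coordinates")
  bead_frame(cbind(x, y, z), radii = radii,
             residue_index = resnum,
             molecule_tag = tag_from_resname(resname, tag_map))
}

#' Read a GRO file as one frame or a trajectory
#'
#' @param path GRO file; concatenated frames are read as a trajectory.
#' @param radii Bead radius in nm (scalar, or named by residue name via
#'   `radii_table`); default 0.235.
#' @param radii_table Optional data frame with columns `resname`, `radius`
#'   overriding `radii` per residue name.
#' @param tag_map Optional residue-name to molecule-tag overrides, see
#'   [tag_from_resname()].
#' @return A [bead_frame()] if the file holds one frame, otherwise a
#'   [bead_trajectory()].
#' @export
read_gro <- function(path, radii = 0.235, radii_table = NULL,
                     tag_map = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    natoms <- as.integer(trimws(lines[i + 1L]))
    if (is.na(natoms)) stop("malformed GRO file at line ", i + 1L)
    block <- lines[i:(i + natoms + 2L)]
    fr <- parse_gro_block(block, radii = radii, tag_map = tag_map)
    if (!is.null(radii_table)) {
      resname <- trimws(substr(block[3:(2 + natoms)], 6, 10))
      m <- match(toupper(resname), toupper(radii_table$resname))
      fr$radii[!is.na(m)] <- radii_table$radius[m[!is.na(m)]]
    }
    frames[[length(frames) + 1L]] <- fr
    i <- i + natoms + 3L
  }
  if (!length(frames)) stop("no frames in ", path)
  if (length(frames) == 1L) frames[[1]] else bead_trajectory(frames)
}

#' Read a single-frame PDB file as a bead frame
#'
#' ATOM and HETATM records are used; coordinates are converted from
#' Angstrom to nm.
#'
#' @inheritParams read_gro
#' @return A [bead_frame()].
#' @export
read_pdb_frame <- function(path, radii = 0.235, radii_table = NULL,
                           tag_map = NULL) {
  lines <- readLines(path)
  at <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(at)) stop("no ATOM/HETATM records in ", path)
  resname <- trimws(substr(at, 18, 20))
  resnum <- as.integer(substr(at, 23, 26))
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54))) / 10
  fr <- bead_frame(xyz, radii = radii, residue_index = resnum,
                   molecule_tag = tag_from_resname(resname, tag_map))
  if (!is.null(radii_table)) {
    m <- match(toupper(resname), toupper(radii_table$resname))
    fr$radii[!is.na(m)] <- radii_table$radius[m[!is.na(m)]]
  }
  fr
}

#' Write a bead frame as a GRO file
#'
#' Residue names encode the molecule tag (`BEA` protein, `EXC` excipient,
#' `W` solvent, `ION` ion) so a round trip through [read_gro()] preserves
#' the classification.
#'
#' @param frame A [bead_frame()].
#' @param path Output path.
#' @param title Title line.
#' @param append Append as an extra trajectory frame.
#' @export
write_gro <- function(frame, path, title = "aprshield frame",
                      append = FALSE) {
  n <- n_beads(frame)
  resname <- c(protein = "BEA", excipient = "EXC", solvent = "W",
               ion = "ION")[frame$molecule_tag]
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     frame$residue_index %% 100000L, resname, "CG",
                     seq_len(n) %% 100000L,
                     frame$coordinates[, 1], frame$coordinates[, 2],
                     frame$coordinates[, 3]),
             sprintf("%10.5f%10.5f%10.5f", max(frame$coordinates[, 1]) + 1,
                     max(frame$coordinates[, 2]) + 1,
                     max(frame$coordinates[, 3]) + 1))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
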