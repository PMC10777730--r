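#' Shrake-Rupley exposed area of coarse-grained beads
#'
#' Dot-sampling solvent-accessible surface area. Each surface bead's sphere
#' is expanded by the probe radius and covered with a deterministic
#' quasi-uniform dot lattice; a dot is exposed iff it lies strictly outside
#' every other occluding bead's expanded sphere (a dot exactly on a boundary
#' counts as exposed). The exposed area of bead i is
#' \deqn{A_i = 4\pi (r_i + r_p)^2 \; n_{exposed} / n_{dots}.}
#'
#' By default the surface set is the protein beads (optionally restricted by
#' `subset`), and the occluder set is protein plus excipient beads: excipient
#' beads occlude protein surface but contribute no area of their own, which
#' is what makes the APR-SASA difference against an excipient-free control a
#' shielding measure. Solvent and ion beads are ignored on both sides, since
#' SASA is defined against the probe sphere rather than explicit solvent;
#' set `include_solvent = TRUE` to let them occlude too.
#'
#' @param frame A [bead_frame()].
#' @param probe_radius Probe radius in nm; default 0.14.
#' @param n_dots Number of surface dots per bead (>= 32); default 960.
#' @param subset Optional logical mask over beads restricting the surface
#'   set (applied on top of the protein-tag restriction unless
#'   `protein_only = FALSE`).
#' @param protein_only If `TRUE` (default) only protein beads can carry
#'   area; `subset` then selects within the protein.
#' @param occluders One of `"protein+excipient"` (default) or `"protein"`.
#' @param include_solvent Also let solvent/ion beads occlude; default FALSE.
#' @return Numeric vector of exposed areas (nm^2), one per surface bead, with
#'   attribute `"bead_index"` giving their indices in the frame.
#' @export
shrake_rupley <- function(frame, probe_radius = 0.14, n_dots = 960L,
                          subset = NULL, protein_only = TRUE,
                          occluders = c("protein+excipient", "protein"),
                          include_solvent = FALSE) {
  stopifnot(inherits(frame, "bead_frame"))
  occluders <- match.arg(occluders)
  n <- n_beads(frame)
  surf <- if (protein_only) frame$molecule_tag == "protein" else rep(TRUE, n)
  if (!is.null(subset)) {
    subset <- as.logical(subset)
    if (length(subset) != n) stop("subset mask length must equal bead count")
    surf <- surf & subset
  }
  occ <- frame$molecule_tag == "protein"
  if (occluders == "protein+excipient") {
    occ <- occ | frame$molecule_tag == "excipient"
  }
  if (include_solvent) occ <- rep(TRUE, n)
  if (!any(surf)) {
    out <- numeric(0)
    attr(out, "bead_index") <- integer(0)
    return(out)
  }
  area <- .sr_area(frame$coordinates, frame$radii, probe_radius,
                   as.integer(n_dots), which(surf) - 1L, which(occ) - 1L)
  attr(area, "bead_index") <- which(surf)
  area
}

#' Total and APR-restricted SASA of one frame
#'
#' @param frame A [bead_frame()].
#' @param apr_mask Logical mask over beads (from [map_aprs_to_beads()]).
#' @param probe_radius,n_dots,... Passed to [shrake_rupley()].
#' @return Named numeric vector `c(total =, apr =)` in nm^2.
#' @export
apr_sasa <- function(frame, apr_mask, probe_radius = 0.14, n_dots = 960L,
                     ...) {
  stopifnot(inherits(frame, "bead_frame"))
  apr_mask <- as.logical(apr_mask)
  prot <- frame$molecule_tag == "protein"
  if (length(apr_mask) == sum(prot) && length(apr_mask) != n_beads(frame)) {
    # mask given over protein beads only: pad with FALSE elsewhere
    full <- rep(FALSE, n_beads(frame))
    full[prot] <- apr_mask
    apr_mask <- full
  }
  if (length(apr_mask) != n_beads(frame)) {
    stop("apr_mask length (", length(apr_mask),
         ") must equal bead count (", n_beads(frame),
         ") or protein bead count (", sum(prot), ")")
  }
  area <- shrake_rupley(frame, probe_radius = probe_radius, n_dots = n_dots,
                        ...)
  idx <- attr(area, "bead_index")
  c(total = sum(area), apr = sum(area[apr_mask[idx]]))
}

#' Per-frame SASA series over a trajectory
#'
#' @param traj A [bead_trajectory()].
#' @param apr_mask Logical APR bead mask.
#' @param probe_radius,n_dots Passed to the SASA engine.
#' @param stride Keep every `stride`-th frame, starting at the first.
#' @param system_id,replicate_id Metadata labels carried into the series.
#' @param ... Further arguments for [shrake_rupley()].
#' @return Object of class `"sasa_series"`: data frame of
#'   (`frame`, `time_ps`, `total`, `apr`) plus attributes `mean_total`,
#'   `mean_apr`, `system_id`, `replicate_id`, `parameters`.
#' @export
trajectory_sasa <- function(traj, apr_mask, probe_radius = 0.14,
                            n_dots = 960L, stride = 1L,
                            system_id = "system", replicate_id = 1L, ...) {
  stopifnot(inherits(traj, "bead_trajectory"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  keep <- seq.int(1L, length(traj$frames), by = stride)
  vals <- vapply(keep, function(i)
    apr_sasa(traj$frames[[i]], apr_mask, probe_radius, n_dots, ...),
    numeric(2))
  out <- data.frame(frame = keep, time_ps = traj$frame_times[keep],
                    total = vals["total", ], apr = vals["apr", ])
  structure(out,
            class = c("sasa_series", "data.frame"),
            mean_total = mean(out$total), mean_apr = mean(out$apr),
            system_id = system_id, replicate_id = replicate_id,
            parameters = list(probe_radius = probe_radius, n_dots = n_dots,
                              stride = stride))
}

#' @export
print.sasa_series <- function(x, ...) {
  cat(sprintf(
    "SASA series [%s, replicate %s]: %d frames, mean total %.2f nm^2, mean APR %.2f nm^2\n",
    attr(x, "system_id"), attr(x, "replicate_id"), nrow(x),
    attr(x, "mean_total"), attr(x, "mean_apr")))
  invisible(x)
}

#' Build a sasa_series from precomputed per-frame values
#'
#' Lets deposited or externally computed per-frame SASA tables enter the
#' shielding/statistics stages without trajectories.
#'
#' @param total,apr Per-frame values (nm^2); `apr` must not exceed `total`.
#' @param time_ps Optional frame times.
#' @param system_id,replicate_id Metadata labels.
#' @return A `"sasa_series"`.
#' @export
sasa_series <- function(total, apr, time_ps = NULL, system_id = "system",
                        replicate_id = 1L) {
  total <- as.numeric(total); apr <- as.numeric(apr)
  if (length(total) != length(apr) || !length(total)) {
    stop("total and apr must be non-empty vectors of equal length")
  }
  if (any(apr > total + 1e-9) || any(apr < 0)) {
    stop("need 0 <= apr <= total at every frame")
  }
  if (is.null(time_ps)) time_ps <- seq_along(total) - 1
  out <- data.frame(frame = seq_along(total), time_ps = time_ps,
                    total = total, apr = apr)
  structure(out, class = c("sasa_series", "data.frame"),
            mean_total = mean(total), mean_apr = mean(apr),
            system_id = system_id, replicate_id = replicate_id,
            parameters = list())
}

#' Write / read SASA series as tidy CSV
#'
#' Columns: `system`, `replicate`, `frame`, `time_ps`, `total`, `apr`.
#'
#' @param series A `sasa_series` or list of them.
#' @param path CSV path.
#' @export
write_sasa_csv <- function(series, path) {
  if (inherits(series, "sasa_series")) series <- list(series)
  rows <- lapply(series, function(s)
    data.frame(system = attr(s, "system_id"),
               replicate = attr(s, "replicate_id"),
               frame = s$frame, time_ps = s$time_ps,
               total = s$total, apr = s$apr))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sasa_csv
#' @return `read_sasa_csv()`: named list of `sasa_series`, one per
#'   (system, replicate) pair.
#' @export
read_sasa_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("system", "replicate", "total", "apr")
  if (!all(need %in% names(df))) {
    stop("SASA CSV must contain columns: ", paste(need, collapse = ", "))
  }
  keys <- interaction(df$system, df$replicate, drop = TRUE, sep = "#")
  out <- lapply(split(df, keys), function(d)
    sasa_series(d$total, d$apr,
                time_ps = if ("time_ps" %in% names(d)) d$time_ps else NULL,
                system_id = d$system[1], replicate_id = d$replicate[1]))
  out
}

#' Shielding of APR SASA relative to an excipient-free control
#'
#' Aggregates replicate trajectories by their per-replicate mean APR SASA
#' (one value per trajectory, avoiding frame-level pseudoreplication), then
#' reports the control-minus-treated difference and its percentage of the
#' control mean. Positive values mean the excipient shields APRs.
#'
#' @param control,treated Lists of `sasa_series` (>= 1 replicate each).
#' @param pooled If `TRUE`, pool frames across replicates instead of using
#'   per-replicate means. Default `FALSE`.
#' @return Object of class `"shielding_result"`: list with
#'   `delta_apr_sasa` (nm^2), `percent_reduction`, `control_mean`,
#'   `treated_mean`, and per-replicate means for both systems.
#' @export
shielding <- function(control, treated, pooled = FALSE) {
  rep_means <- function(x, what) {
    if (inherits(x, "sasa_series")) x <- list(x)
    if (!length(x)) stop("empty ", what, " collection")
    if (pooled) {
      return(mean(unlist(lapply(x, function(s) s$apr))))
    }
    vapply(x, function(s) attr(s, "mean_apr"), numeric(1))
  }
  cm <- rep_means(control, "control")
  tm <- rep_means(treated, "treated")
  delta <- mean(cm) - mean(tm)
  structure(list(delta_apr_sasa = delta,
                 percent_reduction = 100 * delta / mean(cm),
                 control_mean = mean(cm), treated_mean = mean(tm),
                 control_replicate_means = cm,
                 treated_replicate_means = tm,
                 pooled = pooled),
            class = "shielding_result")
}

#' @export
print.shielding_result <- function(x, ...) {
  cat(sprintf(
    "APR shielding: %.2f nm^2 (%.1f%% of control %.2f nm^2)\n",
    x$delta_apr_sasa, x$percent_reduction, x$control_mean))
  invisible(x)
}

#' Molar concentration of n molecules in a simulation box
#'
#' @param n_molecules Molecule count.
#' @param box_volume Box volume in nm^3.
#' @return Concentration in mM.
#' @export
#' @examples
#' concentration(1, 30841.5)  # ~0.0538 mM
concentration <- function(n_molecules, box_volume) {
  if (!is.finite(box_volume) || box_volume <= 0) {
    stop("box volume must be positive")
  }
  avogadro <- 6.02214076e23
  n_molecules / (avogadro * box_volume * 1e-24) * 1e3
}

#' Number of excipient molecules for a target mass fraction
#'
#' @param target_w_w Target excipient mass fraction (e.g. 0.001 for
#'   0.1 % w/w).
#' @param excipient_mw Excipient molecular weight (g/mol).
#' @param system_mass Reference system mass in g per mole of boxes (e.g.
#'   water mass for a water-basis fraction).
#' @param rounding `"nearest"` (default), `"floor"` or `"ceiling"`.
#' @return Integer count with attribute `"rounding"`.
#' @export
excipient_count <- function(target_w_w, excipient_mw, system_mass,
                            rounding = c("nearest", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!is.finite(excipient_mw) || excipient_mw <= 0) {
    stop("excipient molecular weight must be positive")
  }
  if (target_w_w < 0 || system_mass <= 0) {
    stop("target_w_w must be >= 0 and system_mass > 0")
  }
  x <- target_w_w * system_mass / excipient_mw
  k <- switch(rounding, nearest = round(x), floor = floor(x),
              ceiling = ceiling(x))
  structure(as.integer(k), rounding = rounding)
}
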