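# Synthetic stand-ins for the molecular-dynamics stage: a rigid
# quasi-spherical protein bead cloud with labelled APR patches, mobile
# excipient molecules with tunable surface/APR affinity, and
# descriptor-response tables with known low-rank latent structure.
#
# Frames are independent equilibrium-ensemble draws, not dynamics: the
# downstream analysis consumes only per-frame SASA statistics, so temporal
# correlation is deliberately out of scope.

#' Specification of a synthetic protein-excipient system
#'
#' Defaults mirror the scale of a coarse-grained excipient screen: five
#' replicate trajectories per system, a protein of 60 one-bead residues
#' with about a quarter of the sequence in APR patches, and a handful of
#' short-chain excipient molecules in a 12 nm box.
#'
#' @param n_protein_residues Number of protein residues; default 60.
#' @param beads_per_residue Beads per residue; default 1.
#' @param apr_fraction Fraction of residues inside APR patches; default 0.25.
#' @param n_excipient_molecules Excipient molecules per frame; default 20.
#' @param beads_per_excipient Beads per excipient chain; default 3.
#' @param adsorption_strength Dimensionless surface/APR affinity, >= 0.
#'   0 means no interaction (uniform placement); larger values put more
#'   molecules on the surface and bias them toward APR beads.
#' @param box_edge Cubic box edge in nm; default 12.
#' @param n_frames Frames per replicate; default 20.
#' @param n_replicates Replicates per system; default 5.
#' @param bead_radius Bead radius in nm; default 0.235.
#' @param thermal_jitter Per-frame Gaussian jitter (nm) applied to protein
#'   bead positions; default 0.01. The protein is rigid in the sense of no
#'   conformational change, but a small thermal vibration keeps per-frame
#'   and per-replicate SASA variances non-degenerate, as in a real
#'   trajectory.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return Object of class `"synthetic_system_spec"`.
#' @export
synthetic_system_spec <- function(n_protein_residues = 60L,
                                  beads_per_residue = 1L,
                                  apr_fraction = 0.25,
                                  n_excipient_molecules = 20L,
                                  beads_per_excipient = 3L,
                                  adsorption_strength = 0,
                                  box_edge = 12,
                                  n_frames = 20L,
                                  n_replicates = 5L,
                                  bead_radius = 0.235,
                                  thermal_jitter = 0.01,
                                  seed = 1L) {
  stopifnot(n_protein_residues >= 1, beads_per_residue >= 1,
            apr_fraction >= 0, apr_fraction <= 1,
            n_excipient_molecules >= 0, beads_per_excipient >= 1,
            adsorption_strength >= 0, box_edge > 0,
            n_frames >= 1, n_replicates >= 1, bead_radius > 0,
            thermal_jitter >= 0)
  structure(as.list(environment()), class = "synthetic_system_spec")
}

# Deterministic quasi-uniform directions on the unit sphere.
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

#' Generate the rigid synthetic protein
#'
#' Beads sit on a jittered sphere lattice sized so neighbouring beads
#' touch; consecutive residues are lattice neighbours, so contiguous APR
#' patches form spatial patches on the surface. APR patches of about six
#' residues are spread evenly over the sequence to cover `apr_fraction` of
#' residues.
#'
#' @param spec A [synthetic_system_spec()].
#' @return List with `frame` ([bead_frame()], centred in the box), `aprs`
#'   (an `apr_set`) and `apr_mask` (per-bead logical).
#' @export
make_protein <- function(spec) {
  stopifnot(inherits(spec, "synthetic_system_spec"))
  set.seed(substream_seed(spec$seed, 0L))
  n_res <- as.integer(spec$n_protein_residues)
  bpr <- as.integer(spec$beads_per_residue)
  n <- n_res * bpr
  radius <- 2 * spec$bead_radius * sqrt(n / (4 * pi))
  if (radius <= spec$bead_radius) radius <- 2 * spec$bead_radius
  dirs <- fibonacci_directions(n)
  rr <- radius * (1 + stats::rnorm(n, 0, 0.02))
  centre <- rep(spec$box_edge / 2, 3)
  coords <- sweep(dirs * rr, 2, centre, "+")
  residue_index <- rep(seq_len(n_res), each = bpr)
  frame <- bead_frame(coords, radii = spec$bead_radius,
                      residue_index = residue_index,
                      molecule_tag = "protein")
  patches <- plan_patches(n_res, spec$apr_fraction)
  aprs <- structure(list(patches = patches, n_patches = nrow(patches),
                         coverage_fraction = if (nrow(patches))
                           sum(patches[, 2] - patches[, 1] + 1L) / n_res
                         else 0,
                         sequence_length = n_res,
                         parameters = list(synthetic = TRUE,
                                           apr_fraction = spec$apr_fraction)),
                    class = "apr_set")
  mask <- map_aprs_to_beads(aprs, residue_index)
  list(frame = frame, aprs = aprs, apr_mask = mask)
}

# Evenly spaced contiguous patches covering round(f * n) residues.
plan_patches <- function(n_res, fraction) {
  total <- round(fraction * n_res)
  if (total == 0) {
    return(cbind(start = integer(), end = integer()))
  }
  if (total >= n_res) {
    return(cbind(start = 1L, end = as.integer(n_res)))
  }
  n_p <- max(1L, as.integer(round(total / 6)))
  n_p <- min(n_p, total)
  len <- rep(total %/% n_p, n_p)
  extra <- total %% n_p
  if (extra) len[seq_len(extra)] <- len[seq_len(extra)] + 1L
  gap_total <- n_res - total
  gaps <- rep(gap_total %/% (n_p + 1L), n_p + 1L)
  g_extra <- gap_total %% (n_p + 1L)
  if (g_extra) gaps[seq_len(g_extra)] <- gaps[seq_len(g_extra)] + 1L
  start <- integer(n_p); pos <- 1L
  for (i in seq_len(n_p)) {
    pos <- pos + gaps[i]
    start[i] <- pos
    pos <- pos + len[i]
  }
  out <- cbind(start = start, end = start + len - 1L)
  storage.mode(out) <- "integer"
  out
}

#' Simulate excipient adsorption around the synthetic protein
#'
#' Per frame, each excipient molecule is drawn from a two-component
#' mixture: a uniform bulk component and a protein-surface component whose
#' weight `s / (s + 2)` grows with the adsorption strength `s`. A surface
#' molecule anchors on a protein bead chosen with weight `1 + s` for APR
#' beads versus 1 otherwise, and lays its remaining beads along
#' neighbouring surface beads (chains wrap; short molecules cluster).
#' Frames are independent ensemble draws; the protein is rigid.
#'
#' @param spec A [synthetic_system_spec()].
#' @param protein Output of [make_protein()] (regenerated from `spec` when
#'   omitted).
#' @return List of `n_replicates` [bead_trajectory()] objects.
#' @export
simulate_adsorption <- function(spec, protein = make_protein(spec)) {
  stopifnot(inherits(spec, "synthetic_system_spec"))
  pf <- protein$frame
  np <- n_beads(pf)
  centre <- colMeans(pf$coordinates)
  outward <- sweep(pf$coordinates, 2, centre)
  outward <- outward / sqrt(rowSums(outward^2))
  # 6 nearest lattice neighbours of each protein bead, for chain walking
  nn <- t(apply(as.matrix(stats::dist(pf$coordinates)), 1, function(d)
    order(d)[2:7]))
  anchor_w <- 1 + spec$adsorption_strength * protein$apr_mask
  p_surface <- spec$adsorption_strength / (spec$adsorption_strength + 2)
  offset <- 2 * spec$bead_radius
  n_exc_beads <- spec$n_excipient_molecules * spec$beads_per_excipient

  lapply(seq_len(spec$n_replicates), function(rep_i) {
    set.seed(substream_seed(spec$seed, rep_i))
    frames <- lapply(seq_len(spec$n_frames), function(fr) {
      pcoord <- pf$coordinates +
        matrix(stats::rnorm(3 * np, 0, spec$thermal_jitter), np, 3)
      if (n_exc_beads == 0) {
        return(bead_frame(pcoord, radii = spec$bead_radius,
                          residue_index = pf$residue_index,
                          molecule_tag = pf$molecule_tag))
      }
      ex <- matrix(0, n_exc_beads, 3)
      row <- 1L
      for (m in seq_len(spec$n_excipient_molecules)) {
        if (stats::runif(1) < p_surface) {
          b <- sample.int(np, 1, prob = anchor_w)
          for (k in seq_len(spec$beads_per_excipient)) {
            ex[row, ] <- pf$coordinates[b, ] + outward[b, ] * offset +
              stats::rnorm(3, 0, 0.03)
            row <- row + 1L
            b <- nn[b, sample.int(6, 1)]
          }
        } else {
          pos <- stats::runif(3, 0, spec$box_edge)
          for (k in seq_len(spec$beads_per_excipient)) {
            ex[row, ] <- pos
            row <- row + 1L
            step <- stats::rnorm(3)
            pos <- pos + step / sqrt(sum(step^2)) * 2 * spec$bead_radius
            pos <- pmin(pmax(pos, 0), spec$box_edge)
          }
        }
      }
      bead_frame(rbind(pcoord, ex),
                 radii = spec$bead_radius,
                 residue_index = c(pf$residue_index,
                                   rep(seq_len(spec$n_excipient_molecules),
                                       each = spec$beads_per_excipient)),
                 molecule_tag = c(pf$molecule_tag,
                                  rep("excipient", n_exc_beads)))
    })
    bead_trajectory(frames)
  })
}

#' Specification of a synthetic descriptor-response table
#'
#' Defaults mirror a 41-compound, 106-descriptor screen with two latent
#' factors driving the response.
#'
#' @param n_compounds Number of compounds; default 41.
#' @param n_descriptors Number of descriptors; default 106.
#' @param n_latent Number of latent factors; default 2.
#' @param n_informative Number of descriptors loading on the factors;
#'   default 10 (the rest are pure noise).
#' @param signal_coefficients Response coefficient per factor; default
#'   `c(2, 3)` (recycled/truncated to `n_latent`): the bulk factor (first)
#'   matters somewhat less for the response than the specific factor(s)
#'   tracked by the informative descriptors.
#' @param noise_sd Noise standard deviation as a fraction of the signal
#'   standard deviation, applied to the informative descriptors and the
#'   response; default 0.1.
#' @param background_noise Idiosyncratic noise multiplier for background
#'   descriptors (fraction of their signal sd); default `3.5 * noise_sd`
#'   (0.35 at the default noise level, 0 in the noiseless limit).
#' @param response_offset Constant added to the response so it is positive
#'   on the scale of a mean APR SASA (nm^2); default 50.
#' @param seed RNG seed.
#' @return Object of class `"synthetic_qspr_spec"`.
#' @export
synthetic_qspr_spec <- function(n_compounds = 41L, n_descriptors = 106L,
                                n_latent = 2L, n_informative = 10L,
                                signal_coefficients = c(2, 3),
                                noise_sd = 0.1,
                                background_noise = 3.5 * noise_sd,
                                response_offset = 50, seed = 1L) {
  stopifnot(n_latent >= 1, n_latent < min(n_compounds, n_descriptors),
            n_informative >= n_latent, n_informative <= n_descriptors,
            noise_sd >= 0, background_noise >= 0)
  signal_coefficients <- rep_len(as.numeric(signal_coefficients), n_latent)
  structure(as.list(environment()), class = "synthetic_qspr_spec")
}

#' Generate a descriptor-response table with known latent structure
#'
#' `X = T P' + E` with `n_latent` orthonormal score columns `T` and a
#' two-tier loading matrix. Factor 1 is a "bulk" factor tracked by all
#' background descriptors (think molecular size, which most
#' physicochemical descriptors correlate with); the remaining factor(s)
#' are "specific" and tracked only by the `n_informative` first
#' descriptors (think PEG content). Informative descriptors are clean
#' trackers (idiosyncratic noise `noise_sd` times their signal sd);
#' background descriptors get `background_noise` times theirs. The
#' response is `y = offset + T c + e` with `e` at `noise_sd` times the
#' signal sd, and the specific factor(s) weighted more heavily than the
#' bulk factor by default, so recovering them is what makes a model
#' predictive. Because PLS autoscales every column, a background of
#' literally pure-noise columns would be inflated to unit variance and
#' drown the latent structure at realistic n, which is why the background
#' carries (bulk) signal too.
#'
#' @param spec A [synthetic_qspr_spec()].
#' @return List with `X` (named matrix), `y`, `truth` (list: `T`, `P`,
#'   `coefficients`, `informative` descriptor indices).
#' @export
make_qspr <- function(spec) {
  stopifnot(inherits(spec, "synthetic_qspr_spec"))
  set.seed(substream_seed(spec$seed, 0L))
  n <- spec$n_compounds; p <- spec$n_descriptors; L <- spec$n_latent
  Tm <- qr.Q(qr(matrix(stats::rnorm(n * L), n, L))) * sqrt(n)
  inf <- seq_len(spec$n_informative)
  P <- matrix(0, p, L)
  for (j in inf) {
    # informative descriptors track the specific factors (2..L), or
    # factor 1 when there is only one factor
    l <- if (L == 1L) 1L else 2L + ((j - 1L) %% (L - 1L))
    P[j, l] <- sample(c(-1, 1), 1) * stats::runif(1, 1.5, 2.5)
  }
  for (j in setdiff(seq_len(p), inf)) {
    P[j, 1] <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
  }
  S <- Tm %*% t(P)
  col_sd <- apply(S, 2, stats::sd)
  noise_mult <- rep(spec$background_noise, p)
  noise_mult[inf] <- spec$noise_sd
  E <- sapply(seq_len(p), function(j)
    stats::rnorm(n, 0, noise_mult[j] * col_sd[j]))
  X <- S + E
  ysig <- drop(Tm %*% spec$signal_coefficients)
  y <- spec$response_offset + ysig +
    stats::rnorm(n, 0, spec$noise_sd * stats::sd(ysig))
  colnames(X) <- sprintf("d%03d", seq_len(p))
  rownames(X) <- sprintf("cmpd%02d", seq_len(n))
  list(X = X, y = y,
       truth = list(T = Tm, P = P, coefficients = spec$signal_coefficients,
                    informative = inf))
}

#' Run the full shielding pipeline on a synthetic excipient panel
#'
#' Generates one control (no excipient) and one system per adsorption
#' strength, computes per-replicate mean APR SASA by Shrake-Rupley, and
#' returns shielding results per system plus the grouped samples for the
#' statistics stage.
#'
#' @param strengths Named or unnamed numeric vector of adsorption
#'   strengths (one synthetic excipient per entry).
#' @param spec Base [synthetic_system_spec()] (its `adsorption_strength`
#'   is overridden per system).
#' @param n_dots,probe_radius SASA parameters (reduced dot counts keep the
#'   panel fast).
#' @return List with `control_means`, `treated_means` (list per system),
#'   `shielding` (list of `shielding_result`), `delta` (named vector).
#' @export
synthetic_panel <- function(strengths,
                            spec = synthetic_system_spec(),
                            n_dots = 240L, probe_radius = 0.14) {
  if (is.null(names(strengths))) {
    names(strengths) <- sprintf("exc%02d", seq_along(strengths))
  }
  protein <- make_protein(spec)
  series_for <- function(sp, tag) {
    sp$seed <- substream_seed(spec$seed,
                              match(tag, c("control", names(strengths))))
    trajs <- simulate_adsorption(sp, protein)
    lapply(seq_along(trajs), function(i)
      trajectory_sasa(trajs[[i]], protein$apr_mask,
                      probe_radius = probe_radius, n_dots = n_dots,
                      system_id = tag, replicate_id = i))
  }
  ctrl_spec <- spec
  ctrl_spec$n_excipient_molecules <- 0L
  ctrl_spec$adsorption_strength <- 0
  ctrl <- series_for(ctrl_spec, "control")
  ctrl_means <- vapply(ctrl, attr, numeric(1), "mean_apr")
  out <- lapply(names(strengths), function(nm) {
    sp <- spec
    sp$adsorption_strength <- strengths[[nm]]
    series_for(sp, nm)
  })
  names(out) <- names(strengths)
  sh <- lapply(out, function(s) shielding(ctrl, s))
  list(control_means = ctrl_means,
       treated_means = lapply(out, function(s)
         vapply(s, attr, numeric(1), "mean_apr")),
       shielding = sh,
       delta = vapply(sh, `[[`, numeric(1), "delta_apr_sasa"))
}
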