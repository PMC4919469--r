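# Seeded generators for every input class the pipeline consumes, each
# returning its data together with a ground-truth record.  All generators
# are pure functions of (parameters, seed): the RNG state is saved and
# restored around each call, and the same seed reproduces the output
# byte-for-byte.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Write a ground-truth record as JSON
#'
#' Every generator returns a \code{truth} list; serializing it alongside
#' the generated files lets end-to-end tests read planted parameters from
#' the record rather than from constants.
#'
#' @param truth a generator's \code{truth} list.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic SPA titration
#'
#' Forward-models a direct or competition titration at the standard
#' reporter design (30 nM immobilized receptor, 30 nM radiolabelled
#' ligand, reporter Kd 32 nM for competition), then applies
#' multiplicative Gaussian noise (scintillation counts are large) and a
#' paired no-fusion-protein control series carrying the same background.
#'
#' @param mode \code{"direct"} or \code{"competition"}.
#' @param kd_truth planted Kd of the varied interaction (molar).
#' @param grid varied-species concentrations (molar), strictly
#'   increasing.
#' @param reporter_concs named vector/list with \code{receptor} (and, in
#'   competition mode, \code{ligand}) totals; defaults 30 nM each.
#' @param kd_reporter reporter-pair Kd (competition mode; default 32 nM).
#' @param s_max,background signal parameters (counts).
#' @param noise_cv multiplicative noise coefficient of variation
#'   (default 0.05).
#' @param seed RNG seed.
#' @return list with \code{series} (a \code{\link{titration_series}})
#'   and \code{truth}.
#' @export
gen_spa_series <- function(mode = c("direct", "competition"),
                           kd_truth = 5e-6,
                           grid = NULL,
                           reporter_concs = c(receptor = 30e-9, ligand = 30e-9),
                           kd_reporter = 32e-9,
                           s_max = 1000, background = 100,
                           noise_cv = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  kd_truth <- parse_conc(kd_truth)
  kd_reporter <- parse_conc(kd_reporter)
  fixed <- as.list(vapply(reporter_concs, parse_conc, numeric(1)))
  if (is.null(grid)) {
    grid <- if (mode == "direct")
      kd_truth * 10^seq(-1.5, 1.5, length.out = 12)
    else kd_truth * 10^seq(-1.7, 1.3, length.out = 12)
  }
  clean <- simulate_signal(mode, grid, kd_truth, fixed,
                           s_max = s_max, background = background,
                           kd_reporter = if (mode == "competition") kd_reporter else NULL)
  .with_seed(seed, {
    noisy <- clean * (1 + noise_cv * stats::rnorm(length(clean)))
    control <- background * (1 + noise_cv * stats::rnorm(length(clean)))
  })
  series <- titration_series(mode = mode, varied_conc = grid,
                             signal = noisy, control_signal = control,
                             fixed = fixed,
                             known_kd_reporter = if (mode == "competition") kd_reporter else NULL)
  truth <- list(kind = "spa_series", mode = mode, kd = kd_truth,
                kd_reporter = if (mode == "competition") kd_reporter else NULL,
                s_max = s_max, background = background,
                noise_cv = noise_cv, fixed = fixed, seed = seed)
  list(series = series, truth = truth)
}

#' Generate paired HSQC peak lists for a binding titration
#'
#' Emulates an interface-mapping titration: a free 15N HSQC peak list
#' plus one bound list per titration ratio.  Planted fast-exchange
#' residues move along fixed shift vectors scaled by the exactly solved
#' bound fraction at each ratio; planted intermediate-exchange residues
#' are removed from lists once the ratio reaches
#' \code{disappear_ratio} (exchange broadening beyond detection);
#' overlapped residues are flagged; everything in a bound list jitters
#' with additive Gaussian noise (SD \code{noise_sd} ppm in 1H and
#' \code{5 * noise_sd} in 15N, so the weighted CSP contribution is
#' isotropic).
#'
#' @param n_residues number of residues (default 60).
#' @param fast data.frame \code{residue}, \code{d_H}, \code{d_X}: the
#'   fast-exchange residues and their full-saturation shift vectors
#'   (ppm).  Default: 8 residues with combined weighted shifts of
#'   0.12-0.30 ppm.
#' @param intermediate residue numbers that broaden away (default 6).
#' @param overlapped residue numbers flagged as overlapped (default 2).
#' @param ratio_series ligand:protein ratios (default 0, 0.25, 0.5, 1, 4).
#' @param protein_conc labelled-protein concentration (default 200 uM).
#' @param kd planted Kd governing the bound fraction (default 5 uM).
#' @param disappear_ratio ratio at or above which intermediate-exchange
#'   peaks vanish (default 0.5).
#' @param noise_sd 1H peak-position noise SD in ppm (default 0).
#' @param seed RNG seed.
#' @return list with \code{free} (a \code{\link{peak_list}}),
#'   \code{bound} (named list of peak lists, one per ratio) and
#'   \code{truth} (planted classes, shift vectors, per-ratio bound
#'   fractions, seed).
#' @export
gen_titration_peaklists <- function(n_residues = 60,
                                    fast = NULL, intermediate = NULL,
                                    overlapped = NULL,
                                    ratio_series = c(0, 0.25, 0.5, 1, 4),
                                    protein_conc = 200e-6, kd = 5e-6,
                                    disappear_ratio = 0.5,
                                    noise_sd = 0, seed = 1L) {
  if (is.null(fast))
    fast <- data.frame(residue = c(8, 12, 15, 22, 27, 33, 41, 48),
                       d_H = c(0.10, -0.12, 0.08, 0.06, -0.10, 0.15, 0.07, -0.11),
                       d_X = c(0.40, 0.35, -0.60, 0.30, 0.50, -0.45, -0.35, 0.55))
  if (is.null(intermediate)) intermediate <- c(10, 18, 25, 36, 44, 52)
  if (is.null(overlapped)) overlapped <- c(5, 55)
  fast$residue <- as.integer(fast$residue)
  classes <- list(fast = fast$residue, intermediate = as.integer(intermediate),
                  overlapped = as.integer(overlapped))
  if (anyDuplicated(unlist(classes)))
    stop("gen_titration_peaklists: residue classes must be disjoint")
  if (max(unlist(classes)) > n_residues)
    stop("gen_titration_peaklists: class residue number exceeds n_residues")

  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  out <- .with_seed(seed, {
    res <- seq_len(n_residues)
    base <- data.frame(residue_number = res,
                       residue_type = sample(aa, n_residues, replace = TRUE),
                       atom_group = "backbone-NH",
                       w_H = stats::runif(n_residues, 7.5, 9.5),
                       w_X = stats::runif(n_residues, 105, 130),
                       status = ifelse(res %in% classes$overlapped,
                                       "overlapped", "observed"),
                       stringsAsFactors = FALSE)
    free <- peak_list(base, spectrum_id = "free")
    bound <- lapply(ratio_series, function(ratio) {
      f <- if (ratio == 0) 0 else
        fraction_bound(solve_binary(protein_conc, ratio * protein_conc, kd),
                       "receptor")
      b <- base
      idx <- match(fast$residue, b$residue_number)
      b$w_H[idx] <- b$w_H[idx] + f * fast$d_H
      b$w_X[idx] <- b$w_X[idx] + f * fast$d_X
      if (noise_sd > 0) {
        b$w_H <- b$w_H + stats::rnorm(nrow(b), 0, noise_sd)
        b$w_X <- b$w_X + stats::rnorm(nrow(b), 0, 5 * noise_sd)
      }
      if (ratio >= disappear_ratio)
        b <- b[!b$residue_number %in% classes$intermediate, , drop = FALSE]
      peak_list(b, spectrum_id = sprintf("bound_1to%g", ratio))
    })
    names(bound) <- sprintf("1:%g", ratio_series)
    list(free = free, bound = bound)
  })
  fb <- vapply(ratio_series, function(ratio) {
    if (ratio == 0) 0 else
      fraction_bound(solve_binary(protein_conc, ratio * protein_conc, kd),
                     "receptor")
  }, numeric(1))
  truth <- list(kind = "titration_peaklists",
                fast = fast, intermediate = classes$intermediate,
                overlapped = classes$overlapped,
                interface = sort(c(fast$residue, classes$intermediate)),
                ratio_series = ratio_series, bound_fraction = fb,
                protein_conc = protein_conc, kd = kd,
                disappear_ratio = disappear_ratio,
                noise_sd = noise_sd, seed = seed)
  c(out, list(truth = truth))
}

# ideal-helix atom placement: each backbone atom type lives on a helix of
# the same pitch with its own radius, phase and axial offset (approximate
# canonical alpha-helix values; adequate for packing/SASA fixtures).
.HELIX_ATOMS <- data.frame(
  atom_name = c("N", "CA", "C", "O", "CB"),
  element   = c("N", "C", "C", "O", "C"),
  radius    = c(1.55, 2.28, 1.68, 2.00, 3.30),
  phase_deg = c(-26, 0, 26, 44, -8),
  dz        = c(-0.90, 0.00, 1.05, 1.25, -0.45),
  stringsAsFactors = FALSE)

#' Generate an ideal anti-parallel helical-hairpin structure
#'
#' Two ideal poly-alanine alpha-helices (3.6 residues/turn, 1.5 Angstrom
#' rise) packed anti-parallel at a given axis separation, with
#' C-beta-bearing pseudo-side-chains, numbered sequentially through the
#' hairpin.  Fully deterministic (no RNG).  The ground truth records
#' which residues face the partner helix (their C-beta points toward the
#' other axis) and the heavy-atom contact map at 6.5 Angstrom.
#'
#' @param n_res_per_helix residues per helix (default 15).
#' @param rise axial rise per residue (Angstrom, default 1.5).
#' @param radius C-alpha helix radius (Angstrom, default 2.28).
#' @param inter_helix_distance axis separation (Angstrom, default 10).
#' @return list with \code{structure} (a
#'   \code{\link{protein_structure}}) and \code{truth} (facing /
#'   outward residues per helix, contact map, parameters).
#' @export
gen_hairpin_structure <- function(n_res_per_helix = 15, rise = 1.5,
                                  radius = 2.28,
                                  inter_helix_distance = 10) {
  if (n_res_per_helix < 3 || rise <= 0 || radius <= 0 ||
      inter_helix_distance <= 0)
    stop("gen_hairpin_structure: geometric parameters must be positive")
  if (inter_helix_distance < 2 * max(.HELIX_ATOMS$radius) * 0.75 + 2)
    stop("gen_hairpin_structure: helices overlap at this separation")
  turn <- 100 * pi / 180   # 3.6 residues per turn
  helix_atoms <- function(resnos, axis_x, direction, phase0) {
    do.call(rbind, lapply(seq_along(resnos), function(i) {
      th <- phase0 + direction * (i - 1) * turn
      z0 <- direction * (i - 1) * rise
      r <- .HELIX_ATOMS$radius * radius / 2.28
      ang <- th + .HELIX_ATOMS$phase_deg * pi / 180 * direction
      data.frame(chain = "A", residue_number = resnos[i],
                 residue_type = "ALA",
                 atom_name = .HELIX_ATOMS$atom_name,
                 element = .HELIX_ATOMS$element,
                 x = axis_x + r * cos(ang),
                 y = r * sin(ang),
                 z = z0 + .HELIX_ATOMS$dz * direction,
                 stringsAsFactors = FALSE)
    }))
  }
  n <- n_res_per_helix
  # helix 1 runs +z with its facing side toward +x; helix 2 runs -z,
  # offset along x, facing back toward helix 1
  a1 <- helix_atoms(1:n, 0, +1, 0)
  a2 <- helix_atoms((n + 1):(2 * n), inter_helix_distance, -1, pi)
  a2$z <- a2$z + (n - 1) * rise   # align the spans
  atoms <- rbind(a1, a2)
  struct <- protein_structure(atoms)

  # facing classification: CB azimuth relative to the direction of the
  # partner axis
  cb <- atoms[atoms$atom_name == "CB", ]
  toward <- ifelse(cb$residue_number <= n, 0, pi)   # partner direction
  az <- atan2(cb$y, ifelse(cb$residue_number <= n, cb$x,
                           cb$x - inter_helix_distance))
  facing <- cos(az - toward) > 0.5
  # helix termini are dominated by end exposure, not packing: keep them
  # out of the facing/outward comparison sets
  termini <- c(1L, n, n + 1L, 2L * n)
  interior <- !cb$residue_number %in% termini
  facing_res <- cb$residue_number[facing & interior]
  outward_res <- cb$residue_number[!facing & interior]

  # ground-truth inter-helix contact map at 6.5 A (heavy atoms)
  h1 <- atoms[atoms$residue_number <= n, ]
  h2 <- atoms[atoms$residue_number > n, ]
  contacts <- do.call(rbind, lapply(unique(h1$residue_number), function(r1) {
    p1 <- as.matrix(h1[h1$residue_number == r1, c("x", "y", "z")])
    hits <- vapply(unique(h2$residue_number), function(r2) {
      p2 <- as.matrix(h2[h2$residue_number == r2, c("x", "y", "z")])
      d2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
      any(d2 <= 6.5^2)
    }, logical(1))
    if (any(hits)) data.frame(res_i = r1,
                              res_j = unique(h2$residue_number)[hits])
    else NULL
  }))
  truth <- list(kind = "hairpin_structure",
                n_res_per_helix = n, rise = rise, radius = radius,
                inter_helix_distance = inter_helix_distance,
                facing = sort(facing_res), outward = sort(outward_res),
                termini = termini, contacts = contacts)
  list(structure = struct, truth = truth)
}

#' Generate a pyrene-actin fluorescence trace
#'
#' Piecewise lag -> linear -> plateau curve: zero until \code{lag_s},
#' then linear growth at \code{rate_AU_per_s} until \code{plateau_AU},
#' then flat, plus additive Gaussian noise.  The planted maximal slope is
#' exactly \code{rate_AU_per_s}.
#'
#' @param lag_s lag-phase duration (s).
#' @param rate_AU_per_s linear-region polymerization rate (AU/s).
#' @param plateau_AU final fluorescence (AU).
#' @param noise_sd additive noise SD (AU, default 0).
#' @param time time grid (s; default 0-1200 s every 2 s).
#' @param condition,additive_conc trace metadata.
#' @param seed RNG seed.
#' @return list with \code{trace} (a \code{\link{fluorescence_trace}})
#'   and \code{truth}.
#' @export
gen_actin_trace <- function(lag_s = 120, rate_AU_per_s = 0.25,
                            plateau_AU = 100, noise_sd = 0,
                            time = seq(0, 1200, by = 2),
                            condition = "control", additive_conc = 0,
                            seed = 1L) {
  if (lag_s < 0 || rate_AU_per_s < 0 || plateau_AU < 0 || noise_sd < 0)
    stop("gen_actin_trace: parameters must be >= 0")
  f <- pmin(pmax(rate_AU_per_s * (time - lag_s), 0), plateau_AU)
  if (noise_sd > 0)
    f <- .with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  trace <- fluorescence_trace(time, f, condition = condition,
                              additive_conc = additive_conc)
  truth <- list(kind = "actin_trace", lag_s = lag_s,
                rate = rate_AU_per_s, plateau = plateau_AU,
                noise_sd = noise_sd, seed = seed)
  list(trace = trace, truth = truth)
}
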