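# Kd values below this floor are clamped: a numerically safe proxy for
# infinitely tight binding (division by free-receptor terms stays finite).
.KD_FLOOR <- 1e-15

#' Describe a binary or competitive binding system
#'
#' Bundles the total concentrations and dissociation constants of a
#' receptor R binding a ligand L (complex RL, \code{kd_ligand}) and,
#' optionally, a competitor C for the same site (complex RC,
#' \code{kd_competitor}).  A ternary RLC species is deliberately absent
#' from the model: the two effectors compete for one surface and do not
#' co-occupy it.
#'
#' @param receptor_total,ligand_total,competitor_total total species
#'   concentrations (molar, or strings like \code{"30nM"}); the competitor
#'   defaults to 0 (binary system).
#' @param kd_ligand,kd_competitor dissociation constants (molar or unit
#'   strings). \code{kd_competitor} is ignored when \code{competitor_total
#'   = 0}. Values below 1e-15 M are clamped to that floor.
#' @return an object of class \code{"binding_system"}.
#' @examples
#' binding_system("30nM", "30nM", kd_ligand = "32nM",
#'                competitor_total = "6.05uM", kd_competitor = "6.05uM")
#' @export
binding_system <- function(receptor_total, ligand_total,
                           kd_ligand,
                           competitor_total = 0,
                           kd_competitor = 1) {
  rt <- parse_conc(receptor_total)
  lt <- parse_conc(ligand_total)
  ct <- parse_conc(competitor_total)
  kl <- parse_conc(kd_ligand)
  kc <- parse_conc(kd_competitor)
  if (any(!is.finite(c(rt, lt, ct, kl, kc))))
    stop("binding_system: all inputs must be finite")
  if (rt < 0 || lt < 0 || ct < 0)
    stop("binding_system: total concentrations must be >= 0")
  if (kl <= 0 || kc <= 0)
    stop("binding_system: dissociation constants must be > 0")
  structure(list(receptor_total = rt, ligand_total = lt,
                 competitor_total = ct,
                 kd_ligand = max(kl, .KD_FLOOR),
                 kd_competitor = max(kc, .KD_FLOOR)),
            class = "binding_system")
}

#' @export
print.binding_system <- function(x, ...) {
  cat("Binding system (concentrations in M):\n")
  cat(sprintf("  receptor_total   %.6g\n", x$receptor_total))
  cat(sprintf("  ligand_total     %.6g  (Kd %.6g)\n", x$ligand_total, x$kd_ligand))
  if (x$competitor_total > 0)
    cat(sprintf("  competitor_total %.6g  (Kd %.6g)\n",
                x$competitor_total, x$kd_competitor))
  invisible(x)
}

# Build the solved-state object from free receptor; shared by both solvers
# so binary and competition paths derive complexes identically.
.state_from_free_receptor <- function(sys, r_free) {
  rl <- r_free * sys$ligand_total / (sys$kd_ligand + r_free)
  rc <- if (sys$competitor_total > 0)
    r_free * sys$competitor_total / (sys$kd_competitor + r_free) else 0
  structure(list(
    free_receptor   = r_free,
    free_ligand     = sys$ligand_total - rl,
    free_competitor = sys$competitor_total - rc,
    complex_RL      = rl,
    complex_RC      = rc,
    system          = sys
  ), class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Equilibrium state (M):\n")
  for (f in c("free_receptor", "free_ligand", "free_competitor",
              "complex_RL", "complex_RC"))
    cat(sprintf("  %-15s %.9g\n", f, x[[f]]))
  invisible(x)
}

# Receptor mass-balance residual as a function of free receptor r:
#   g(r) = r * (1 + Lt/(KdL + r) + Ct/(KdC + r)) - Rt
# g is strictly increasing on [0, Rt], g(0) = -Rt <= 0, g(Rt) >= 0, so the
# root is unique and bracketed.  Bisection to near machine precision, then
# Newton polish with the analytic derivative.
.solve_free_receptor <- function(sys) {
  rt <- sys$receptor_total
  if (rt == 0) return(0)
  lt <- sys$ligand_total; ct <- sys$competitor_total
  kl <- sys$kd_ligand;    kc <- sys$kd_competitor
  g <- function(r) r * (1 + lt / (kl + r) + ct / (kc + r)) - rt
  lo <- 0; hi <- rt
  for (i in seq_len(200)) {
    mid <- 0.5 * (lo + hi)
    if (mid == lo || mid == hi) break
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  r <- 0.5 * (lo + hi)
  # Newton polish: derivative is strictly positive
  for (i in seq_len(4)) {
    dg <- 1 + lt * kl / (kl + r)^2 + ct * kc / (kc + r)^2
    step <- g(r) / dg
    r2 <- r - step
    if (!is.finite(r2) || r2 < 0 || r2 > rt) break
    r <- r2
    if (abs(step) <= .Machine$double.eps * max(r, rt * 1e-12)) break
  }
  r
}

#' Solve a binary binding equilibrium exactly
#'
#' Finds the unique physical root x of (R_t - x)(L_t - x) = Kd x with
#' 0 <= x <= min(R_t, L_t).  Ligand depletion is not neglected: at
#' reporter concentrations near Kd (the 30 nM SPA regime) the free ligand
#' differs substantially from the total, and the approximate hyperbolic
#' isotherm would bias the fit.
#'
#' The quadratic is evaluated in the numerically stable form
#' x = 2ac / (b + sqrt(b^2 - 4ac)) to avoid cancellation when binding is
#' tight.
#'
#' @param receptor_total,ligand_total totals (molar or unit strings).
#' @param kd dissociation constant (molar or unit string), > 0.
#' @return an \code{equilibrium_state} with fields \code{free_receptor},
#'   \code{free_ligand}, \code{free_competitor} (0), \code{complex_RL},
#'   \code{complex_RC} (0).
#' @examples
#' st <- solve_binary("30nM", "30nM", "30nM")
#' st$complex_RL * 1e9   # ~ 11.459 nM
#' @export
solve_binary <- function(receptor_total, ligand_total, kd) {
  sys <- binding_system(receptor_total, ligand_total, kd_ligand = kd)
  rt <- sys$receptor_total; lt <- sys$ligand_total; k <- sys$kd_ligand
  b <- rt + lt + k
  disc <- b * b - 4 * rt * lt
  disc <- max(disc, 0)
  x <- if (b > 0) 2 * rt * lt / (b + sqrt(disc)) else 0
  x <- min(x, rt, lt)
  .state_from_free_receptor(sys, rt - x)
}

#' Solve a competitive binding equilibrium exactly
#'
#' Simultaneous solution of the two binding equilibria
#' R + L <-> RL (Kd_L) and R + C <-> RC (Kd_C) under the three mass
#' balances, by bracketed root-finding on the free receptor concentration
#' (the residual is strictly monotone on [0, R_t]).  No Cheng-Prusoff
#' approximation is used; the solution is exact under depletion, which is
#' the regime of the competition SPA (30 nM reporter pair) and of the NMR
#' displacement experiments (hundreds of micromolar of every species).
#'
#' Reduces exactly to \code{\link{solve_binary}} when
#' \code{competitor_total = 0}.
#'
#' @param system a \code{\link{binding_system}}.
#' @return an \code{equilibrium_state}.
#' @examples
#' sys <- binding_system("600uM", "600uM", kd_ligand = "0.037uM",
#'                       competitor_total = "600uM", kd_competitor = "5uM")
#' st <- solve_competition(sys)
#' fraction_bound(st, "competitor")   # weak effector almost fully displaced
#' @export
solve_competition <- function(system) {
  if (!inherits(system, "binding_system"))
    stop("solve_competition: 'system' must be a binding_system")
  if (system$competitor_total == 0)
    return(solve_binary(system$receptor_total, system$ligand_total,
                        system$kd_ligand))
  r <- .solve_free_receptor(system)
  st <- .state_from_free_receptor(system, r)
  # sanity: residual must have been bracketed and solved
  resid <- st$free_receptor + st$complex_RL + st$complex_RC -
    system$receptor_total
  if (abs(resid) > 1e-6 * max(system$receptor_total, 1e-30))
    stop("solve_competition: internal error, receptor mass balance residual = ",
         format(resid), " for R_t = ", format(system$receptor_total))
  st
}

#' Fraction of a species that is bound at equilibrium
#'
#' @param state an \code{equilibrium_state}.
#' @param species one of \code{"ligand"}, \code{"competitor"},
#'   \code{"receptor"}.
#' @return bound fraction in [0, 1]: the relevant complex concentration
#'   divided by that species' total (for the receptor, both complexes
#'   count).
#' @export
fraction_bound <- function(state, species = c("ligand", "competitor", "receptor")) {
  species <- match.arg(species)
  sys <- state$system
  tot <- switch(species,
                ligand = sys$ligand_total,
                competitor = sys$competitor_total,
                receptor = sys$receptor_total)
  if (tot <= 0)
    stop("fraction_bound: total ", species, " concentration is zero; fraction undefined")
  bound <- switch(species,
                  ligand = state$complex_RL,
                  competitor = state$complex_RC,
                  receptor = state$complex_RL + state$complex_RC)
  bound / tot
}

#' Ligand displacement curve over a competitor concentration grid
#'
#' One exact competition solution per grid point; the reporter-ligand bound
#' fraction is strictly non-increasing in competitor concentration.  This
#' is the forward model behind competition SPA titrations.
#'
#' @param system a \code{\link{binding_system}}; its
#'   \code{competitor_total} is overridden point-wise by \code{competitor_grid}.
#' @param competitor_grid sorted ascending competitor concentrations
#'   (molar), length >= 2 (a single point of 0 is also accepted and equals
#'   the binary solution).
#' @return data.frame with columns \code{competitor_total},
#'   \code{fraction_ligand_bound}, \code{complex_RL}.
#' @export
displacement_curve <- function(system, competitor_grid) {
  grid <- parse_conc(competitor_grid)
  if (is.unsorted(grid, strictly = FALSE))
    stop("displacement_curve: competitor_grid must be sorted ascending")
  if (any(grid < 0)) stop("displacement_curve: concentrations must be >= 0")
  frac <- vapply(grid, function(ct) {
    s <- system
    s$competitor_total <- ct
    st <- solve_competition(s)
    fraction_bound(st, "ligand")
  }, numeric(1))
  rl <- frac * system$ligand_total
  data.frame(competitor_total = grid,
             fraction_ligand_bound = frac,
             complex_RL = rl)
}

#' Population-weighted fast-exchange chemical shift
#'
#' In the fast-exchange NMR regime a resonance appears at the
#' population-weighted average of its free and bound positions:
#' \eqn{(1 - f)\,\delta_{free} + f\,\delta_{bound}}, applied per
#' dimension.  With the exact competition solver this predicts where a
#' labelled effector's peaks sit during a displacement titration - the
#' observable behind the effector-handover experiment.
#'
#' @param shift_free,shift_bound chemical shifts (ppm); vectors are
#'   treated per-dimension and recycled per R rules.
#' @param bound_fraction fraction bound in [0, 1].
#' @return observed shift(s), ppm.
#' @examples
#' fast_exchange_shift(8.00, 8.20, 0.5)  # 8.10
#' @export
fast_exchange_shift <- function(shift_free, shift_bound, bound_fraction) {
  if (any(bound_fraction < 0 | bound_fraction > 1))
    stop("fast_exchange_shift: bound_fraction must lie in [0, 1]")
  (1 - bound_fraction) * shift_free + bound_fraction * shift_bound
}
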