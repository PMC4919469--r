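# Shrake-Rupley solvent-accessible surface area and the derived
# per-residue relative accessibility (the NACCESS role in the interface
# mapping pipeline), plus heavy-atom neighbor queries used to define
# passive docking residues.

# Heavy-atom van der Waals radii (Angstrom).  Protein heavy atoms only;
# hydrogens are ignored throughout.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90)
.VDW_FALLBACK <- 1.70

# Theoretical maximum accessible surface areas (A^2) in an extended
# Gly-X-Gly tripeptide (Tien et al. 2013, theoretical values); the
# denominator for relative accessibility.
.MAX_ASA_GXG <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Deterministic quasi-uniform unit-sphere points: an antipodally
# symmetrized golden spiral (half the points plus their antipodes).  The
# symmetry cancels odd-order quadrature error in the cap-boundary
# counting; no RNG, so areas are bit-stable across runs and platforms.
.sphere_points <- function(n) {
  m <- n %/% 2L
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  p <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  p <- rbind(p, -p)
  if (n %% 2L == 1L) p <- rbind(p, c(0, 0, 1))
  p
}

.atom_radii <- function(elements, warn = TRUE) {
  r <- .VDW_RADII[elements]
  unknown <- is.na(r)
  if (any(unknown)) {
    if (warn)
      warning("unknown element(s) ", paste(unique(elements[unknown]), collapse = ", "),
              "; using fallback radius ", .VDW_FALLBACK, " A")
    r[unknown] <- .VDW_FALLBACK
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the heavy atoms: each atom carries a
#' deterministic quasi-uniform point set on its solvent-exposed sphere of
#' radius r + probe; points falling inside any neighboring atom's expanded
#' sphere are occluded, and the atom's area is the exposed fraction times
#' 4 pi (r + probe)^2.  Hydrogens are excluded.
#'
#' @param struct a \code{\link{protein_structure}}.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param n_points sphere sample points per atom (default 960; doubling
#'   changes residue areas by well under 2 percent on typical folds).
#' @return list with \code{atom_sasa} (per-atom areas, A^2, aligned to
#'   \code{struct$atoms}) and \code{residue_sasa} (data.frame
#'   \code{chain}, \code{residue_number}, \code{residue_type},
#'   \code{sasa}).
#' @examples
#' # isolated carbon: area = 4*pi*(1.7+1.4)^2 ~ 120.8 A^2
#' s <- protein_structure(data.frame(chain = "A", residue_number = 1,
#'   residue_type = "ALA", atom_name = "C", element = "C",
#'   x = 0, y = 0, z = 0))
#' shrake_rupley(s)$atom_sasa
#' @export
shrake_rupley <- function(struct, probe_radius = 1.4, n_points = 960L) {
  if (!inherits(struct, "protein_structure"))
    stop("shrake_rupley: need a protein_structure")
  a <- struct$atoms[struct$atoms$element != "H", , drop = FALSE]
  if (nrow(a) == 0) stop("shrake_rupley: no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- .atom_radii(a$element) + probe_radius
  n <- nrow(a)
  pts <- .sphere_points(n_points)
  # neighbor lists via a coarse distance cut: two expanded spheres can
  # only occlude each other within the sum of their radii
  area <- numeric(n)
  # decorrelate quadrature error between atoms: each atom gets a
  # deterministic rotation of the point set (golden-angle increments),
  # so per-atom quantization errors cancel rather than add in residue
  # sums; still RNG-free and bit-stable
  ga <- pi * (3 - sqrt(5))
  rotz <- function(p, th) {
    cbind(cos(th) * p[, 1] - sin(th) * p[, 2],
          sin(th) * p[, 1] + cos(th) * p[, 2], p[, 3])
  }
  rotx <- function(p, th) {
    cbind(p[, 1], cos(th) * p[, 2] - sin(th) * p[, 3],
          sin(th) * p[, 2] + cos(th) * p[, 3])
  }
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    sp <- rotz(rotx(pts, (i - 1) * ga * 0.5), (i - 1) * ga) * rad[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    if (length(nb)) {
      exposed <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(exposed)) break
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        exposed <- exposed & (dj2 >= rad[j]^2)
      }
      frac <- sum(exposed) / n_points
    } else frac <- 1
    area[i] <- frac * 4 * pi * rad[i]^2
  }
  key <- paste(a$chain, a$residue_number, sep = "|")
  res_area <- tapply(area, key, sum)
  first <- !duplicated(key)
  residue_sasa <- data.frame(chain = a$chain[first],
                             residue_number = a$residue_number[first],
                             residue_type = a$residue_type[first],
                             sasa = as.numeric(res_area[key[first]]),
                             stringsAsFactors = FALSE)
  residue_sasa <- residue_sasa[order(residue_sasa$chain,
                                     residue_sasa$residue_number), ]
  rownames(residue_sasa) <- NULL
  list(atom_sasa = area, residue_sasa = residue_sasa)
}

#' Relative solvent accessibility per residue
#'
#' Absolute residue SASA expressed as a percentage of the residue type's
#' maximum accessibility in an extended Gly-X-Gly reference tripeptide.
#' Values can exceed 100 for termini or isolated residues.
#'
#' @param residue_sasa the \code{residue_sasa} data.frame from
#'   \code{\link{shrake_rupley}}.
#' @param reference named vector of maximum ASA per 3-letter residue type
#'   (default: theoretical Gly-X-Gly maxima).
#' @return the input data.frame with an added \code{rsa_percent} column.
#' @export
relative_sasa <- function(residue_sasa, reference = NULL) {
  if (is.null(reference)) reference <- .MAX_ASA_GXG
  ref <- reference[residue_sasa$residue_type]
  if (any(is.na(ref))) {
    bad <- unique(residue_sasa$residue_type[is.na(ref)])
    stop("relative_sasa: no reference maximum for residue type(s): ",
         paste(bad, collapse = ", "))
  }
  residue_sasa$rsa_percent <- 100 * residue_sasa$sasa / as.numeric(ref)
  residue_sasa
}

#' Per-residue relative accessibility from coordinates
#'
#' Convenience wrapper: Shrake-Rupley areas followed by normalization to
#' the reference maxima.  The resulting table is what the CSP pipeline's
#' accessibility filter consumes.
#'
#' @inheritParams shrake_rupley
#' @inheritParams relative_sasa
#' @return data.frame with \code{chain}, \code{residue_number},
#'   \code{residue_type}, \code{sasa}, \code{rsa_percent}.
#' @export
rsa_table <- function(struct, probe_radius = 1.4, n_points = 960L,
                      reference = NULL) {
  relative_sasa(shrake_rupley(struct, probe_radius, n_points)$residue_sasa,
                reference = reference)
}

#' Residues with any heavy atom near a seed set
#'
#' Returns the residues (excluding the seeds themselves) having at least
#' one heavy atom within \code{cutoff} of any heavy atom of a seed
#' residue; distances exactly at the cutoff count as neighbors.  This is
#' the geometric half of the passive-residue definition for docking
#' restraints.
#'
#' @param struct a \code{\link{protein_structure}}.
#' @param seed_residues integer residue numbers (author numbering).
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return sorted integer vector of neighbor residue numbers.
#' @export
residue_neighbors <- function(struct, seed_residues, cutoff = 6.5) {
  if (cutoff <= 0) stop("residue_neighbors: cutoff must be > 0")
  a <- struct$atoms[struct$atoms$element != "H", , drop = FALSE]
  seed_residues <- as.integer(seed_residues)
  missing <- setdiff(seed_residues, a$residue_number)
  if (length(missing))
    stop("residue_neighbors: seed residue(s) absent from structure: ",
         paste(missing, collapse = ", "))
  seed <- a$residue_number %in% seed_residues
  if (!any(seed)) return(integer(0))
  sx <- as.matrix(a[seed, c("x", "y", "z")])
  ox <- as.matrix(a[!seed, c("x", "y", "z")])
  if (nrow(ox) == 0) return(integer(0))
  near <- logical(nrow(ox))
  c2 <- cutoff^2
  for (i in seq_len(nrow(sx))) {
    d2 <- (ox[, 1] - sx[i, 1])^2 + (ox[, 2] - sx[i, 2])^2 +
      (ox[, 3] - sx[i, 3])^2
    near <- near | (d2 <= c2)
  }
  sort(unique(a$residue_number[!seed][near]))
}
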