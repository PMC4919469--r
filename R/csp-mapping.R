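# Chemical-shift-perturbation interface mapping: match free/bound HSQC
# peak lists, compute combined 1H/15N shift changes, handle
# exchange-broadened (disappeared) and overlapped peaks with sentinel
# values, call significance against a spectrum-wide threshold, filter by
# solvent accessibility, and derive active/passive docking restraints.

#' Construct an assigned peak list
#'
#' @param entries data.frame with columns \code{residue_number} (integer,
#'   author numbering), \code{residue_type} (1-letter code),
#'   \code{atom_group} (\code{"backbone-NH"}, \code{"sidechain-NH"} or
#'   \code{"sidechain-CH"}), \code{w_H} (1H ppm), \code{w_X} (15N or 13C
#'   ppm), \code{status} (\code{"observed"} or \code{"overlapped"}).
#' @param spectrum_id label for the spectrum.
#' @return object of class \code{"peak_list"}.
#' @export
peak_list <- function(entries, spectrum_id = "spectrum") {
  need <- c("residue_number", "residue_type", "atom_group", "w_H", "w_X",
            "status")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("peak_list: missing columns: ", paste(miss, collapse = ", "))
  entries$residue_number <- as.integer(entries$residue_number)
  key <- paste(entries$residue_number, entries$atom_group)
  if (anyDuplicated(key))
    stop("peak_list: duplicate (residue_number, atom_group) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!all(is.finite(entries$w_H) & is.finite(entries$w_X)))
    stop("peak_list: chemical shifts must be finite")
  bad <- setdiff(unique(entries$status), c("observed", "overlapped"))
  if (length(bad)) stop("peak_list: unknown status: ", paste(bad, collapse = ", "))
  structure(list(spectrum_id = spectrum_id,
                 entries = entries[, need]), class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("Peak list '%s': %d peaks (%d overlapped)\n", x$spectrum_id,
              nrow(x$entries), sum(x$entries$status == "overlapped")))
  invisible(x)
}

#' Read a peak list from a tab-separated file
#'
#' Columns: \code{residue restype atom_group wH wX status}.
#'
#' @param path TSV file.
#' @param spectrum_id label (default: file name).
#' @return a \code{\link{peak_list}}.
#' @export
read_peak_list <- function(path, spectrum_id = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  map <- c(residue = "residue_number", restype = "residue_type",
           atom_group = "atom_group", wh = "w_H", wx = "w_X",
           status = "status")
  miss <- setdiff(names(map), names(df))
  if (length(miss))
    stop("read_peak_list: missing columns: ", paste(miss, collapse = ", "))
  out <- df[, names(map)]
  names(out) <- unname(map)
  peak_list(out, spectrum_id = spectrum_id)
}

#' Write a peak list to a tab-separated file
#' @param pl a \code{\link{peak_list}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_peak_list <- function(pl, path) {
  df <- pl$entries
  names(df) <- c("residue", "restype", "atom_group", "wH", "wX", "status")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' CSP configuration
#'
#' @param x_weight scaling applied to the X-dimension (15N/13C) shift in
#'   the combined CSP; default 0.2 (the 1/5 weighting that puts nitrogen
#'   shift ranges on the proton scale).
#' @param sentinel CSP value (ppm) assigned to disappeared residues; must
#'   exceed every observed CSP in the data set.  \code{NULL} means
#'   auto-select just above the maximum observed CSP.
#' @param threshold_mode \code{"mean"} (significant if CSP > spectrum
#'   mean) or \code{"mean_plus_sd"} (> mean + 1 SD; used when widespread
#'   disappearance leaves a low mean).
#' @param rsa_cutoff relative-accessibility cutoff in percent (default
#'   50): residues below it are buried and unavailable for binding.
#' @return object of class \code{"csp_config"}.
#' @export
csp_config <- function(x_weight = 0.2, sentinel = NULL,
                       threshold_mode = c("mean", "mean_plus_sd"),
                       rsa_cutoff = 50) {
  threshold_mode <- match.arg(threshold_mode)
  if (x_weight <= 0 || x_weight > 1)
    stop("csp_config: x_weight must be in (0, 1]")
  if (!is.null(sentinel) && sentinel <= 0)
    stop("csp_config: sentinel must be > 0")
  structure(list(x_weight = x_weight, sentinel = sentinel,
                 threshold_mode = threshold_mode, rsa_cutoff = rsa_cutoff),
            class = "csp_config")
}

#' Named CSP presets
#'
#' \code{"fig4"}: effector (HR1-domain) side of the titration - sentinel
#' 0.2 ppm, mean threshold.  \code{"fig5"}: G-protein side - sentinel 0.1
#' ppm, mean + 1 SD threshold (many peaks disappear, so the spectrum mean
#' alone is low).
#'
#' @param name \code{"fig4"} or \code{"fig5"}.
#' @return a \code{\link{csp_config}}.
#' @export
csp_preset <- function(name = c("fig4", "fig5")) {
  name <- match.arg(name)
  switch(name,
         fig4 = csp_config(sentinel = 0.2, threshold_mode = "mean"),
         fig5 = csp_config(sentinel = 0.1, threshold_mode = "mean_plus_sd"))
}

#' Match free and bound peak lists
#'
#' Pairing is strictly by (residue_number, atom_group).  A free-list entry
#' with no bound counterpart is classed \code{disappeared}
#' (intermediate-exchange broadening); a pair in which either member is
#' flagged overlapped is classed \code{overlapped}.
#'
#' @param free,bound \code{\link{peak_list}} objects sharing a numbering
#'   convention.
#' @return list with data.frame \code{pairs} (residue_number, atom_group,
#'   residue_type, w_H_free, w_X_free, w_H_bound, w_X_bound, category) and
#'   integer vectors \code{disappeared}, \code{overlapped} (residue
#'   numbers, backbone groups).
#' @export
match_peaks <- function(free, bound) {
  fe <- free$entries; be <- bound$entries
  fk <- paste(fe$residue_number, fe$atom_group)
  bk <- paste(be$residue_number, be$atom_group)
  idx <- match(fk, bk)
  category <- ifelse(is.na(idx), "disappeared",
                     ifelse(fe$status == "overlapped" |
                              be$status[pmax(idx, 1L)] == "overlapped",
                            "overlapped", "shifted"))
  pairs <- data.frame(residue_number = fe$residue_number,
                      atom_group = fe$atom_group,
                      residue_type = fe$residue_type,
                      w_H_free = fe$w_H, w_X_free = fe$w_X,
                      w_H_bound = be$w_H[idx], w_X_bound = be$w_X[idx],
                      category = category,
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       disappeared = sort(fe$residue_number[category == "disappeared"]),
       overlapped = sort(fe$residue_number[category == "overlapped"]))
}

#' Combined chemical shift perturbation
#'
#' delta = sqrt(dH^2 + (x_weight * dX)^2), with dH and dX the bound-minus-
#' free shift changes in the 1H and X (15N/13C) dimensions.
#'
#' @param d_H,d_X shift changes (ppm); vectorized.
#' @param config a \code{\link{csp_config}} (supplies \code{x_weight}).
#' @return combined CSP (ppm), >= 0.
#' @examples
#' compute_csp(0.1, 0.5)  # sqrt(0.1^2 + 0.1^2) = 0.1414
#' @export
compute_csp <- function(d_H, d_X, config = csp_config()) {
  sqrt(d_H^2 + (config$x_weight * d_X)^2)
}

#' Per-residue CSP records from matched peaks
#'
#' Computes the combined CSP for every shifted pair; overlapped pairs are
#' assigned delta = 0 (not reliably assignable in the complex spectrum),
#' disappeared ones delta = NA until \code{\link{apply_sentinels}} fills
#' in the sentinel.
#'
#' @param matched output of \code{\link{match_peaks}}.
#' @param config a \code{\link{csp_config}}.
#' @return data.frame of class \code{"csp_records"}: \code{residue_number},
#'   \code{atom_group}, \code{delta}, \code{category}, \code{significant}
#'   (NA until thresholded), \code{sidechain_evidence}.
#' @export
csp_records <- function(matched, config = csp_config()) {
  p <- matched$pairs
  delta <- ifelse(p$category == "shifted",
                  compute_csp(p$w_H_bound - p$w_H_free,
                              p$w_X_bound - p$w_X_free, config),
                  ifelse(p$category == "overlapped", 0, NA_real_))
  out <- data.frame(residue_number = p$residue_number,
                    atom_group = p$atom_group,
                    delta = delta, category = p$category,
                    significant = NA, sidechain_evidence = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$residue_number), ]
  rownames(out) <- NULL
  class(out) <- c("csp_records", "data.frame")
  out
}

#' Assign sentinel CSPs to disappeared residues
#'
#' Residues whose peaks disappear in the complex are assigned a fixed CSP
#' larger than the maximum observed CSP in the data set (0.2 and 0.1 ppm
#' in the shipped presets); they are excluded from the spectrum mean/SD
#' downstream.  A configured sentinel not exceeding the maximum observed
#' CSP is a configuration error.
#'
#' @param records output of \code{\link{csp_records}}.
#' @param config a \code{\link{csp_config}}; \code{sentinel = NULL}
#'   auto-selects 105 percent of the maximum observed CSP.
#' @return records with sentinel deltas filled in and an attribute
#'   \code{"sentinel"} recording the value used.
#' @export
apply_sentinels <- function(records, config = csp_config()) {
  obs <- records$category == "shifted"
  max_obs <- if (any(obs)) max(records$delta[obs]) else 0
  sentinel <- config$sentinel
  if (is.null(sentinel)) sentinel <- max(max_obs * 1.05, 0.05)
  if (any(obs) && sentinel <= max_obs) {
    worst <- records$residue_number[obs][which.max(records$delta[obs])]
    stop("apply_sentinels: sentinel (", sentinel,
         ") must exceed the maximum observed CSP (", signif(max_obs, 4),
         " at residue ", worst, ")")
  }
  records$delta[records$category == "disappeared"] <- sentinel
  attr(records, "sentinel") <- sentinel
  records
}

#' Flag significant chemical shift perturbations
#'
#' The threshold is the mean (or mean + 1 SD) of the CSPs of observed,
#' non-overlapped, non-sentinel residues; comparison is strict (ties are
#' not significant).  Disappeared residues are always significant;
#' overlapped residues never are.
#'
#' @param records sentinel-applied records (see
#'   \code{\link{apply_sentinels}}).
#' @param config a \code{\link{csp_config}}.
#' @return records with \code{significant} set; attributes
#'   \code{"threshold"}, \code{"spectrum_mean"}, \code{"spectrum_sd"}.
#' @export
threshold_significant <- function(records, config = csp_config()) {
  if (any(is.na(records$delta)))
    stop("threshold_significant: apply_sentinels first")
  obs <- records$category == "shifted"
  if (sum(obs) < 3)
    stop("threshold_significant: need at least 3 observed records for spectrum statistics")
  mu <- mean(records$delta[obs])
  sdv <- stats::sd(records$delta[obs])
  thr <- if (config$threshold_mode == "mean") mu else mu + sdv
  records$significant <- (obs & records$delta > thr) |
    records$category == "disappeared"
  records$significant[records$category == "overlapped"] <- FALSE
  attr(records, "threshold") <- thr
  attr(records, "spectrum_mean") <- mu
  attr(records, "spectrum_sd") <- sdv
  records
}

#' Fold side-chain (13C) evidence into backbone records
#'
#' A residue whose side-chain CH peaks disappeared or shifted
#' significantly in a 13C HSQC gains \code{sidechain_evidence} and joins
#' the significant set (logical OR with the backbone call).  Missing
#' carbon data is a no-op.  Idempotent.
#'
#' @param records thresholded backbone records.
#' @param carbon_free,carbon_bound optional 13C \code{\link{peak_list}}
#'   pair (side-chain CH groups).
#' @param config a \code{\link{csp_config}}.
#' @return updated records.
#' @export
merge_sidechain_evidence <- function(records, carbon_free = NULL,
                                     carbon_bound = NULL,
                                     config = csp_config()) {
  if (is.null(carbon_free) || is.null(carbon_bound) ||
      nrow(carbon_free$entries) == 0) return(records)
  m <- match_peaks(carbon_free, carbon_bound)
  rec <- csp_records(m, config)
  rec <- apply_sentinels(rec, csp_config(x_weight = config$x_weight,
                                         sentinel = NULL,
                                         threshold_mode = config$threshold_mode,
                                         rsa_cutoff = config$rsa_cutoff))
  obs <- rec$category == "shifted"
  hit <- if (sum(obs) >= 3) {
    rec <- threshold_significant(rec, config)
    rec$residue_number[rec$significant]
  } else rec$residue_number[rec$category == "disappeared"]
  affected <- records$residue_number %in% hit
  records$sidechain_evidence <- records$sidechain_evidence | affected
  records$significant <- records$significant | affected
  records$significant[records$category == "overlapped" & !affected] <- FALSE
  records
}

#' Partition significant residues by solvent accessibility
#'
#' Significant residues with relative accessibility below the cutoff
#' (strictly) are buried and unavailable for binding; those at or above
#' it are surface residues and candidate interface members.
#'
#' @param records thresholded records.
#' @param rsa data.frame with \code{residue_number} and
#'   \code{rsa_percent} (from \code{\link{rsa_table}} or an external
#'   accessibility calculation).
#' @param config a \code{\link{csp_config}} (supplies
#'   \code{rsa_cutoff}).
#' @return records with added \code{rsa_percent} and
#'   \code{accessibility} (\code{"surface"}, \code{"buried"} or NA for
#'   non-significant residues).
#' @export
filter_by_accessibility <- function(records, rsa, config = csp_config()) {
  idx <- match(records$residue_number, rsa$residue_number)
  sig <- which(records$significant)
  missing <- records$residue_number[sig][is.na(idx[sig])]
  if (length(missing))
    stop("filter_by_accessibility: no RSA for significant residue(s): ",
         paste(unique(missing), collapse = ", "))
  records$rsa_percent <- rsa$rsa_percent[idx]
  records$accessibility <- NA_character_
  records$accessibility[sig] <-
    ifelse(records$rsa_percent[sig] < config$rsa_cutoff, "buried", "surface")
  records
}

#' Define active and passive residues for docking restraints
#'
#' Active: significantly perturbed, surface-accessible residues.
#' Passive: surface-accessible residues, not active, with any heavy atom
#' within \code{neighbor_cutoff} of any active residue's heavy atom (the
#' automatic neighboring-residue definition of ambiguous-restraint
#' docking).
#'
#' @param records accessibility-filtered records.
#' @param struct a \code{\link{protein_structure}} covering the residue
#'   range.
#' @param rsa accessibility table as in
#'   \code{\link{filter_by_accessibility}}.
#' @param config a \code{\link{csp_config}}.
#' @param neighbor_cutoff heavy-atom distance cutoff in Angstrom
#'   (default 6.5).
#' @return list of class \code{"interface_set"} with sorted integer
#'   vectors \code{active} and \code{passive} (disjoint).
#' @export
define_active_passive <- function(records, struct, rsa,
                                  config = csp_config(),
                                  neighbor_cutoff = 6.5) {
  if (is.null(records$accessibility))
    stop("define_active_passive: run filter_by_accessibility first")
  active <- sort(unique(records$residue_number[
    records$significant & records$accessibility == "surface" &
      !is.na(records$accessibility)]))
  if (length(active) == 0)
    stop("define_active_passive: empty active set (no significant surface residues)")
  nb <- residue_neighbors(struct, active, cutoff = neighbor_cutoff)
  surf <- rsa$residue_number[rsa$rsa_percent >= config$rsa_cutoff]
  passive <- sort(setdiff(intersect(nb, surf), active))
  structure(list(active = active, passive = passive),
            class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  cat("Interface set:\n  active:  ",
      paste(x$active, collapse = " "), "\n  passive: ",
      paste(x$passive, collapse = " "), "\n")
  invisible(x)
}

#' Write active/passive listings and ambiguous restraints
#'
#' Emits (a) a plain active/passive listing per molecule and (b) an
#' ambiguous distance-restraint block in the CNS \code{assign} dialect:
#' each active residue of one molecule is restrained to the union of
#' active and passive residues of the partner at a 2.0 Angstrom
#' effective distance.  Output ordering is deterministic (by residue
#' number), so identical inputs give byte-identical files.
#'
#' @param interface_a,interface_b \code{interface_set}s for the two
#'   molecules (at least one active set non-empty).
#' @param name_a,name_b molecule labels (also used as segids).
#' @param path optional output file; when NULL the text is returned only.
#' @param effective_distance restraint distance in Angstrom (default 2.0).
#' @return character vector of output lines, invisibly if \code{path}
#'   is given.
#' @export
write_restraints <- function(interface_a, interface_b,
                             name_a = "A", name_b = "B",
                             path = NULL, effective_distance = 2.0) {
  if (length(interface_a$active) == 0 && length(interface_b$active) == 0)
    stop("write_restraints: both interfaces are empty")
  listing <- function(name, iface) {
    c(sprintf("molecule %s", name),
      sprintf("  active:  %s", paste(sort(iface$active), collapse = " ")),
      sprintf("  passive: %s", paste(sort(iface$passive), collapse = " ")))
  }
  ambig <- function(from_name, from, to_name, to) {
    targets <- sort(unique(c(to$active, to$passive)))
    if (length(from$active) == 0 || length(targets) == 0) return(character(0))
    unlist(lapply(sort(from$active), function(r) {
      head_line <- sprintf(
        "assign ( resid %d and segid %s ) (", r, from_name)
      tlines <- sprintf("        ( resid %d and segid %s )%s",
                        targets, to_name,
                        c(rep(" or", length(targets) - 1), ""))
      c(head_line, tlines,
        sprintf(") %.1f %.1f 0.0", effective_distance, effective_distance))
    }))
  }
  lines <- c("! active/passive residue listing",
             listing(name_a, interface_a),
             listing(name_b, interface_b),
             "",
             "! ambiguous interaction restraints",
             ambig(name_a, interface_a, name_b, interface_b),
             ambig(name_b, interface_b, name_a, interface_a))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Run the full CSP interface-mapping pipeline
#'
#' match -> CSP -> sentinels -> significance -> side-chain merge ->
#' accessibility filter (and optionally active/passive definition when a
#' structure is supplied).  Output is invariant to input row order.
#'
#' @param free,bound backbone \code{\link{peak_list}} pair.
#' @param config a \code{\link{csp_config}} or preset.
#' @param carbon_free,carbon_bound optional side-chain 13C pair.
#' @param struct optional \code{\link{protein_structure}} for the
#'   accessibility filter; when absent, \code{rsa} must be given.
#' @param rsa optional precomputed accessibility table.
#' @return list with \code{records}, \code{threshold},
#'   \code{sentinel}, and (when a structure or rsa was given)
#'   \code{interface}.
#' @export
csp_pipeline <- function(free, bound, config = csp_config(),
                         carbon_free = NULL, carbon_bound = NULL,
                         struct = NULL, rsa = NULL) {
  m <- match_peaks(free, bound)
  rec <- csp_records(m, config)
  rec <- apply_sentinels(rec, config)
  rec <- threshold_significant(rec, config)
  rec <- merge_sidechain_evidence(rec, carbon_free, carbon_bound, config)
  out <- list(records = rec,
              threshold = attr(rec, "threshold"),
              sentinel = attr(rec, "sentinel"))
  if (is.null(rsa) && !is.null(struct)) rsa <- rsa_table(struct)
  if (!is.null(rsa)) {
    rec <- filter_by_accessibility(rec, rsa, config)
    out$records <- rec
    if (!is.null(struct) && any(rec$significant &
                                rec$accessibility == "surface",
                                na.rm = TRUE))
      out$interface <- define_active_passive(rec, struct, rsa, config)
  }
  out
}
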