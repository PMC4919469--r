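# Maximal polymerization-rate extraction from pyrene-actin fluorescence
# time courses, and per-condition summaries (mean +/- SE bar-chart data).

#' Construct a fluorescence trace
#'
#' @param time time points (s), strictly increasing, length >= 10.
#' @param fluorescence fluorescence (AU), same length.
#' @param condition condition label (e.g. additive and concentration).
#' @param additive_conc additive concentration (molar; 0 for none).
#' @return object of class \code{"fluorescence_trace"}.
#' @export
fluorescence_trace <- function(time, fluorescence, condition = "control",
                               additive_conc = 0) {
  time <- as.numeric(time); fluorescence <- as.numeric(fluorescence)
  if (length(time) < 10L)
    stop("fluorescence_trace: need at least 10 points")
  if (length(fluorescence) != length(time))
    stop("fluorescence_trace: time and fluorescence lengths differ")
  if (is.unsorted(time, strictly = TRUE))
    stop("fluorescence_trace: time must be strictly increasing")
  structure(list(time = time, fluorescence = fluorescence,
                 condition = condition,
                 additive_conc = parse_conc(additive_conc)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace '%s': %d points, %.0f-%.0f s\n",
              x$condition, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Maximal polymerization rate from the linear region
#'
#' Slides an ordinary-least-squares window along the trace and returns
#' the maximum slope - the operational definition of the "maximal rate
#' derived from the linear region" of a polymerization curve.  Ties break
#' to the earliest window.
#'
#' @param trace a \code{\link{fluorescence_trace}}.
#' @param window_points window width in points; default 10 percent of the
#'   trace length (minimum 3).
#' @return list with \code{rate} (AU/s), \code{t_mid} (window midpoint,
#'   s), \code{window} (index range).
#' @export
max_rate <- function(trace, window_points = NULL) {
  t <- trace$time; y <- trace$fluorescence
  n <- length(t)
  if (is.null(window_points)) window_points <- max(3L, round(0.1 * n))
  window_points <- as.integer(window_points)
  if (window_points < 3L || window_points > n)
    stop("max_rate: window_points must be in [3, length(trace)]")
  nw <- n - window_points + 1L
  # OLS slope per window via rolling sums
  cs_t  <- c(0, cumsum(t));     cs_y  <- c(0, cumsum(y))
  cs_tt <- c(0, cumsum(t * t)); cs_ty <- c(0, cumsum(t * y))
  i <- seq_len(nw); j <- i + window_points - 1L
  w <- window_points
  St  <- cs_t[j + 1L] - cs_t[i];   Sy  <- cs_y[j + 1L] - cs_y[i]
  Stt <- cs_tt[j + 1L] - cs_tt[i]; Sty <- cs_ty[j + 1L] - cs_ty[i]
  slope <- (w * Sty - St * Sy) / (w * Stt - St * St)
  best <- which.max(slope)   # which.max returns the first maximum
  list(rate = slope[best],
       t_mid = mean(t[best:(best + window_points - 1L)]),
       window = c(best, best + window_points - 1L))
}

#' Summarize maximal rates by condition
#'
#' @param traces list of \code{\link{fluorescence_trace}} objects.
#' @param window_points passed to \code{\link{max_rate}}.
#' @return data.frame ordered by condition label: \code{condition},
#'   \code{n}, \code{mean_rate}, \code{se_rate} (SD/sqrt(n); 0 and
#'   flagged by \code{single_trace} when n = 1), \code{additive_conc}.
#' @export
summarize_conditions <- function(traces, window_points = NULL) {
  if (length(traces) == 0) stop("summarize_conditions: empty trace list")
  rates <- vapply(traces, function(tr) max_rate(tr, window_points)$rate,
                  numeric(1))
  cond <- vapply(traces, function(tr) tr$condition, character(1))
  conc <- vapply(traces, function(tr) tr$additive_conc, numeric(1))
  out <- do.call(rbind, lapply(sort(unique(cond)), function(cd) {
    r <- rates[cond == cd]
    data.frame(condition = cd, n = length(r), mean_rate = mean(r),
               se_rate = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0,
               single_trace = length(r) == 1L,
               additive_conc = conc[cond == cd][1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a fluorescence trace from CSV
#'
#' Expected columns: \code{time_s}, \code{fluorescence}.
#'
#' @param path CSV file.
#' @param condition,additive_conc metadata for the trace.
#' @return a \code{\link{fluorescence_trace}}.
#' @export
read_trace_csv <- function(path, condition = basename(path),
                           additive_conc = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "fluorescence") %in% names(df)))
    stop("read_trace_csv: need columns time_s, fluorescence")
  fluorescence_trace(df$time_s, df$fluorescence, condition = condition,
                     additive_conc = additive_conc)
}
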