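#' Photoresponse descriptors
#'
#' Standardized descriptors extracted from response traces: peak suppression,
#' saturation time (T_sat, the time a response spends at or above 90% of the
#' full dark-current suppression), the recovery time constant (tau_rec, a
#' single exponential fitted to the late recovery of a non-saturating
#' response), and the Pepperberg dominant time constant (tau_D, the slope of
#' T_sat against the natural log of flash strength over the first four
#' saturating points of a half-log ladder).
#'
#' @name response_analysis
NULL

cross_time <- function(time, x, level, rising = TRUE) {
  # linear interpolation of the first crossing of `level`
  above <- x >= level
  if (rising) i <- which(!above[-length(above)] & above[-1])
  else i <- which(above[-length(above)] & !above[-1])
  if (!length(i)) return(NA_real_)
  i <- i[1]
  t0 <- time[i]; t1 <- time[i + 1]; x0 <- x[i]; x1 <- x[i + 1]
  t0 + (level - x0) / (x1 - x0) * (t1 - t0)
}

#' Saturation time of a response
#'
#' Length of the contiguous interval during which the suppression stays at or
#' above `threshold` of the full dark-current suppression capacity, with the
#' crossing times linearly interpolated. Traces that never reach the
#' threshold are classed "not saturating" and return `NA` (never 0).
#'
#' @param trace A `response_trace` (or any data frame with `time`, `deltaJ`).
#' @param threshold Saturation criterion as a fraction of the dark current
#'   (default 0.9).
#' @return Saturation time in seconds, or `NA_real_` with attribute
#'   `saturating = FALSE` for a non-saturating response.
#' @export
compute_tsat <- function(trace, threshold = 0.9) {
  dj <- trace$deltaJ; tt <- trace$time
  if (max(dj) < threshold) {
    return(structure(NA_real_, saturating = FALSE))
  }
  ipk <- which.max(dj)
  t_on <- cross_time(tt[seq_len(ipk)], dj[seq_len(ipk)], threshold, rising = TRUE)
  rest <- ipk:length(dj)
  t_off <- cross_time(tt[rest], dj[rest], threshold, rising = FALSE)
  if (is.na(t_off)) t_off <- tt[length(tt)]   # never recovered within horizon
  if (is.na(t_on)) t_on <- tt[1]
  structure(t_off - t_on, saturating = TRUE)
}

#' Recovery time constant of a non-saturating response
#'
#' Least-squares single-exponential time constant fitted over the window from
#' 50% to 99% recovery of the peak suppression (the operational "second half
#' of the recovery phase").
#'
#' @param trace A `response_trace`.
#' @param window Recovery-fraction window (default `c(0.5, 0.99)`).
#' @param sat_threshold Responses peaking at or above this fraction of the
#'   dark current are rejected as saturating.
#' @return Time constant in seconds.
#' @export
fit_tau_rec <- function(trace, window = c(0.5, 0.99), sat_threshold = 0.9) {
  dj <- trace$deltaJ; tt <- trace$time
  pk <- max(dj); ipk <- which.max(dj)
  if (pk >= sat_threshold)
    stop("response is saturating; use compute_tsat() / pepperberg_fit() instead",
         call. = FALSE)
  rest <- ipk:length(dj)
  t_hi <- cross_time(tt[rest], dj[rest], pk * (1 - window[1]), rising = FALSE)
  t_lo <- cross_time(tt[rest], dj[rest], pk * (1 - window[2]), rising = FALSE)
  if (is.na(t_hi)) stop("response has not recovered to the fit window", call. = FALSE)
  if (is.na(t_lo)) t_lo <- tt[length(tt)]
  sel <- tt >= t_hi & tt <= t_lo & dj > 0
  fit <- stats::lm(log(dj[sel]) ~ tt[sel])
  -1 / unname(stats::coef(fit)[2])
}

#' Pepperberg regression: dominant time constant of recovery
#'
#' Ordinary least-squares slope of saturation time against the natural
#' logarithm of flash strength over the first four saturating points.
#'
#' @param strengths Flash strengths (R* per flash), strictly increasing.
#' @param tsats Matching saturation times (s); `NA` for non-saturating points.
#' @param n_points Number of leading saturating points used (default 4).
#' @return A `pepperberg_fit` object; use [tidy()]/[glance()] or `$tau_D`.
#' @export
pepperberg_fit <- function(strengths, tsats, n_points = 4) {
  stopifnot(length(strengths) == length(tsats))
  if (any(diff(strengths) <= 0)) stop("strengths must be strictly increasing",
                                      call. = FALSE)
  ok <- which(!is.na(tsats))
  if (length(ok) < n_points)
    stop("need at least ", n_points, " saturating points for the Pepperberg ",
         "regression (got ", length(ok), ")", call. = FALSE)
  use <- ok[seq_len(n_points)]
  x <- log(strengths[use]); y <- tsats[use]
  fit <- stats::lm(y ~ x)
  # suppressWarnings: synthetic ladders can be exactly collinear
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(tau_D = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 strengths = strengths[use], tsats = y,
                 r_squared = r2, fit = fit),
            class = "pepperberg_fit")
}

#' @export
print.pepperberg_fit <- function(x, ...) {
  cat("Pepperberg regression over", length(x$tsats), "saturating flashes\n")
  cat("  tau_D =", signif(x$tau_D, 4), "s   (R^2 =", signif(x$r_squared, 4), ")\n")
  invisible(x)
}

#' Tidy a Pepperberg fit
#'
#' @param x A `pepperberg_fit`.
#' @param ... Unused.
#' @return One-row-per-term tibble (broom convention).
#' @importFrom generics tidy
#' @method tidy pepperberg_fit
#' @export
tidy.pepperberg_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit)$coefficients)
  tibble::tibble(term = c("intercept", "log_strength"),
                 estimate = s[, 1], std.error = s[, 2])
}

#' @rdname tidy.pepperberg_fit
#' @importFrom generics glance
#' @method glance pepperberg_fit
#' @export
glance.pepperberg_fit <- function(x, ...) {
  tibble::tibble(tau_D = x$tau_D, r.squared = x$r_squared,
                 n_points = length(x$tsats))
}

#' @export
generics::tidy

#' @export
generics::glance

#' Saturation times across a flash ladder
#'
#' Runs a flash ladder on a dark-equilibrated network and tabulates peak
#' suppression and saturation time per strength.
#'
#' @param network Dark-equilibrated `rod_network`.
#' @param strengths Flash strengths (R* per flash), ascending.
#' @param max_saturating Stop once this many saturating points have been
#'   collected (the Pepperberg regression needs the first four); `Inf` runs
#'   the whole ladder.
#' @param ... Passed to [run_protocol()].
#' @return Tibble with `strength`, `peak`, `tsat`, `saturating`.
#' @export
tsat_ladder <- function(network, strengths = pepperberg_strengths(),
                        max_saturating = Inf, ...) {
  rows <- list()
  n_sat <- 0
  for (s in strengths) {
    if (n_sat >= max_saturating) break
    tr <- run_protocol(network, stimulus_protocol("flash", s),
                       keep_species = FALSE, ...)
    ts <- compute_tsat(tr)
    n_sat <- n_sat + isTRUE(attr(ts, "saturating"))
    rows[[length(rows) + 1]] <-
      tibble::tibble(strength = s, peak = max(tr$deltaJ), tsat = as.numeric(ts),
                     saturating = isTRUE(attr(ts, "saturating")))
  }
  dplyr::bind_rows(rows)
}

#' Dominant time constant for one genotype
#'
#' @param network Dark-equilibrated `rod_network` (already mutant-scaled).
#' @param strengths Half-log flash ladder.
#' @param ... Passed to [run_protocol()].
#' @return A `pepperberg_fit`.
#' @export
tau_d <- function(network, strengths = pepperberg_strengths(), ...) {
  lad <- tsat_ladder(network, strengths, ...)
  pepperberg_fit(lad$strength, lad$tsat)
}

#' Normalized dominant-time-constant sweep across genotypes
#'
#' Applies each mutant, re-equilibrates, measures tau_D by the standardized
#' four-point Pepperberg procedure, and normalizes to the wild-type value.
#'
#' @param genotypes Named list of [mutant_spec()] (default [table1_genotypes()]).
#' @param params Parameter list.
#' @param strengths Half-log flash ladder shared by all genotypes.
#' @param ... Passed to [run_protocol()].
#' @return Tibble with `genotype`, `tau_d_s`, `tau_d_norm`.
#' @export
tau_d_table <- function(genotypes = table1_genotypes(),
                        params = default_params(),
                        strengths = pepperberg_strengths(), ...) {
  base <- build_rod_model(params)
  vals <- vapply(genotypes, function(g) {
    net <- apply_mutant(base, g)
    tau_d(net, strengths, ...)$tau_D
  }, numeric(1))
  wt <- if ("WT" %in% names(genotypes)) vals[["WT"]]
        else tau_d(base, strengths, ...)$tau_D
  tibble::tibble(genotype = names(genotypes), tau_d_s = unname(vals),
                 tau_d_norm = unname(vals) / wt)
}

#' Summed molecular-class trajectories
#'
#' Sums species trajectories into the classes tracked during a saturating
#' flash: free R* with 0-3 and 4-6 phosphates (including kinase-complexed
#' forms), their Arr-bound counterparts, monomeric Arr and Arr residing in
#' oligomers (2 per dimer + 4 per tetramer).
#'
#' @param trace A `response_trace` with species columns.
#' @return Tibble with `time` and one column per class.
#' @export
class_abundances <- function(trace) {
  need <- c("Rst0", "ArrB1", "Arr", "Arr_di")
  if (!all(need %in% names(trace)))
    stop("trace lacks species trajectories; rerun with keep_species = TRUE",
         call. = FALSE)
  gsum <- function(cols) rowSums(trace[, cols, drop = FALSE])
  low <- c(sprintf("Rst%d", 0:3), sprintf("RGt%d", 0:3),
           sprintf("RKpre%d", 0:3), sprintf("RKpost%d", 1:3))
  high <- c(sprintf("Rst%d", 4:6), sprintf("RGt%d", 4:6),
            sprintf("RKpre%d", 4:5), sprintf("RKpost%d", 4:6))
  tibble::tibble(
    time = trace$time,
    Rst_0_3P = gsum(low),
    Rst_4_6P = gsum(high),
    ArrB_1_3P = gsum(sprintf("ArrB%d", 1:3)),
    ArrB_4_6P = gsum(sprintf("ArrB%d", 4:6)),
    Arr_monomer = trace$Arr,
    Arr_oligomer = 2 * trace$Arr_di + 4 * trace$Arr_tetra
  )
}
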