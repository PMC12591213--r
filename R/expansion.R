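# Expansion-index kinetics: theoretical curve from hemispherical expander
# geometry versus empirical curve from hair-follicle density, and detection
# of the decoupling point that marks regenerative exhaustion.

#' Saline injection schedule for a tissue expander
#'
#' The default is the standard paradigm: 0.6 mL at implantation (day 0),
#' then 0.3 mL every 4 days, capped at a 3.0 mL total (reached at day 32).
#' An explicit schedule can be given as vectors of days and added volumes.
#'
#' @param initial volume (mL) injected at day 0.
#' @param addition volume (mL) per subsequent injection (regular schedule).
#' @param interval days between injections (regular schedule).
#' @param total total volume cap in mL (optional; \code{NULL} for no cap).
#' @param days,volumes explicit injection days (> 0, strictly increasing)
#'   and added volumes; overrides the regular schedule when given.
#' @return object of class \code{"injection_schedule"}: list with
#'   \code{initial}, \code{days}, \code{volumes}, \code{cap}.
#' @examples
#' sch <- injection_schedule()
#' cumulative_volume(sch, c(0, 4, 36))
#' @export
injection_schedule <- function(initial = 0.6, addition = 0.3, interval = 4,
                               total = 3.0, days = NULL, volumes = NULL) {
  stopifnot(initial > 0)
  if (is.null(days)) {
    if (is.null(total)) stop("a regular schedule needs a total volume cap")
    n_add <- max(0, floor((total - initial) / addition + 1e-9))
    days <- interval * seq_len(n_add)
    volumes <- rep(addition, n_add)
  } else {
    stopifnot(length(days) == length(volumes))
  }
  if (any(volumes <= 0)) stop("added volumes must be positive")
  if (is.unsorted(days, strictly = TRUE)) stop("injection days must be strictly increasing")
  cum <- initial + cumsum(volumes)
  if (!is.null(total) && any(cum > total + 1e-9)) {
    stop("cumulative volume exceeds the cap of ", total, " mL")
  }
  structure(list(initial = initial, days = as.numeric(days),
                 volumes = as.numeric(volumes), cap = total),
            class = "injection_schedule")
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat("Injection schedule: ", x$initial, " mL at day 0",
      if (length(x$days)) paste0(", then ", length(x$days), " additions to ",
                                 x$initial + sum(x$volumes), " mL by day ",
                                 max(x$days)), "\n", sep = "")
  invisible(x)
}

#' Cumulative expander volume at given days
#'
#' @param schedule an \code{"injection_schedule"}.
#' @param day numeric vector of days (>= 0).
#' @return cumulative volume in mL at each day.
#' @export
cumulative_volume <- function(schedule, day) {
  stopifnot(inherits(schedule, "injection_schedule"), all(day >= 0))
  vapply(day, function(d) {
    schedule$initial + sum(schedule$volumes[schedule$days <= d])
  }, numeric(1))
}

#' Theoretical expansion index from hemisphere geometry
#'
#' For a hemispherical expander, volume V = (2/3) pi r^3 and surface area
#' A = 2 pi r^2, so A is proportional to V^(2/3). The theoretical index is
#' the injected volume raised to the 2/3 power, normalized to the reference
#' day: \code{T(d) = (V(d) / V(ref))^(2/3)}. It is invariant to uniform
#' rescaling of all volumes.
#'
#' @param schedule an \code{"injection_schedule"}.
#' @param days days at which to evaluate.
#' @param ref_day reference day for normalization (default 4).
#' @return numeric vector T(d), with T(ref_day) = 1.
#' @examples
#' theoretical_index(injection_schedule(), days = c(4, 36))
#' @export
theoretical_index <- function(schedule, days, ref_day = 4) {
  vref <- cumulative_volume(schedule, ref_day)
  if (vref <= 0) stop("cumulative volume at the reference day is zero")
  (cumulative_volume(schedule, days) / vref)^(2 / 3)
}

#' Empirical expansion index from hair-follicle density
#'
#' Hair follicles neither regenerate nor disappear during expansion, so the
#' reciprocal of their areal density 1/alpha is proportional to the local
#' skin area. The empirical index is \code{E(d) = alpha(ref) / alpha(d)},
#' normalized to the reference day.
#'
#' @param counts data.frame with columns \code{day} and \code{density}
#'   (follicles per mm^2, > 0).
#' @param ref_day reference day (must be present in \code{counts}).
#' @return numeric vector E(d) aligned with \code{counts$day}.
#' @export
empirical_index <- function(counts, ref_day = 4) {
  stopifnot(is.data.frame(counts), all(c("day", "density") %in% names(counts)))
  if (any(counts$density <= 0)) stop("densities must be positive")
  i <- match(ref_day, counts$day)
  if (is.na(i)) stop("reference day ", ref_day, " not present in the counts")
  counts$density[i] / counts$density
}

#' Detect decoupling of empirical from theoretical expansion
#'
#' The decoupling day is the earliest observed day from which the empirical
#' index falls persistently short of the theoretical curve: the smallest d*
#' with \code{E(d) < (1 - delta) * T(d)} for d* and every later observed
#' day. The per-day shortfall is \code{1 - E/T}.
#'
#' @param days common observation days.
#' @param theoretical,empirical index values on those days.
#' @param delta tolerated relative shortfall (default 0.10).
#' @return list with \code{day} (the decoupling day, or \code{NA} if none)
#'   and \code{shortfall} (data.frame: day, shortfall, below).
#' @export
detect_decoupling <- function(days, theoretical, empirical, delta = 0.10) {
  stopifnot(length(days) == length(theoretical),
            length(days) == length(empirical), delta >= 0)
  o <- order(days)
  days <- days[o]; theoretical <- theoretical[o]; empirical <- empirical[o]
  below <- empirical < (1 - delta) * theoretical
  # persistently below: TRUE from some day onwards
  suffix_all <- rev(cumprod(rev(below))) > 0
  day <- if (any(suffix_all)) days[which(suffix_all)[1]] else NA_real_
  list(day = day,
       shortfall = data.frame(day = days, shortfall = 1 - empirical / theoretical,
                              below = below))
}

#' Expansion-index series with decoupling report
#'
#' Computes the theoretical and empirical expansion indices on the observed
#' days and flags the decoupling day signalling regenerative exhaustion.
#'
#' @param schedule an \code{"injection_schedule"}.
#' @param counts follicle-density table (columns \code{day},
#'   \code{density}).
#' @param ref_day normalization day (default 4).
#' @param delta decoupling tolerance (default 0.10).
#' @return object of class \code{"expansion_index"}: list with \code{series}
#'   (data.frame: day, volume_ml, theoretical, empirical, shortfall),
#'   \code{decoupling_day}, \code{ref_day}, \code{delta}.
#' @examples
#' counts <- data.frame(day = c(4, 12, 20, 28, 36),
#'                      density = c(12, 9, 7.2, 6, 5.9))
#' expansion_index(injection_schedule(), counts)
#' @export
expansion_index <- function(schedule, counts, ref_day = 4, delta = 0.10) {
  days <- counts$day
  tt <- theoretical_index(schedule, days, ref_day)
  ee <- empirical_index(counts, ref_day)
  dec <- detect_decoupling(days, tt, ee, delta)
  structure(list(
    series = data.frame(day = days,
                        volume_ml = cumulative_volume(schedule, days),
                        theoretical = tt, empirical = ee,
                        shortfall = 1 - ee / tt),
    decoupling_day = dec$day, ref_day = ref_day, delta = delta
  ), class = "expansion_index")
}

#' @export
print.expansion_index <- function(x, ...) {
  cat("Expansion index (reference day ", x$ref_day, ", delta = ", x$delta,
      ")\n", sep = "")
  print(x$series, row.names = FALSE, digits = 4)
  if (is.na(x$decoupling_day)) {
    cat("No decoupling detected.\n")
  } else {
    cat("Decoupling (regenerative exhaustion) from day ", x$decoupling_day,
        "\n", sep = "")
  }
  invisible(x)
}

#' Plot theoretical vs empirical expansion curves
#' @param x an \code{"expansion_index"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.expansion_index <- function(x, ...) {
  s <- x$series
  graphics::matplot(s$day, cbind(s$theoretical, s$empirical), type = "b",
                    pch = c(1, 16), lty = c(2, 1), col = c("red3", "blue3"),
                    xlab = "days post-expansion", ylab = "expansion index", ...)
  graphics::legend("topleft", c("theoretical", "empirical"), pch = c(1, 16),
                   lty = c(2, 1), col = c("red3", "blue3"), bty = "n")
  if (!is.na(x$decoupling_day)) {
    graphics::abline(v = x$decoupling_day, lty = 3)
  }
  invisible(x)
}
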