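# Folding kinetics: per-chain transition detection, the folded-count step
# function N_h(t), and the sigmoid saturation model
#
#   N_h(t) = h_max / (1 + exp(-k (t - t_half))),  k > 0,
#
# fitted by nonlinear least squares. The monotone-increasing convention is
# used (k = -lambda of the equivalent form with exp(+lambda (t - t_half));
# both are reported).

#' Detect stable helix-straightening transitions
#'
#' For each chain, the first entry into the single-helix state such that the
#' single-helix occupancy over the following persistence window is at least
#' \code{min_occupancy}. Chains never satisfying the criterion yield no
#' record. When a trajectory is supplied, the neighbour chains within the
#' contact cutoff and the size of the containing aggregate at the transition
#' moment are attached.
#'
#' @param states a \code{state_series}.
#' @param persistence_ns stability window after the candidate entry (ns).
#' @param min_occupancy minimum single-helix occupancy over the window.
#' @param traj optional \code{trajectory} for neighbour/aggregate context.
#' @param cutoff_nm contact cutoff for that context (nm).
#' @return data.frame with columns \code{chain}, \code{time_ns}, and (when
#'   \code{traj} is given) \code{neighbours} (comma-separated ids) and
#'   \code{aggregate_size}.
#' @export
detect_transitions <- function(states, persistence_ns = 50,
                               min_occupancy = 0.8, traj = NULL,
                               cutoff_nm = 0.5) {
  stopifnot(inherits(states, "state_series"))
  times <- states$times
  if (length(times) == 0L) stop("empty state series")
  dt <- if (length(times) > 1L) min(diff(times)) else persistence_ns
  if (persistence_ns < dt) stop("persistence window below frame interval")
  recs <- list()
  for (ch in rownames(states$labels)) {
    lab <- states$labels[ch, ]
    hit <- which(lab == "single-helix")
    found <- NA_real_
    for (f in hit) {
      win <- which(times >= times[f] & times < times[f] + persistence_ns)
      if (mean(lab[win] == "single-helix") >= min_occupancy) {
        found <- times[f]
        break
      }
    }
    if (!is.na(found)) {
      recs[[ch]] <- data.frame(chain = ch, time_ns = found,
                               stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) {
    out <- data.frame(chain = character(), time_ns = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
  }
  if (!is.null(traj) && nrow(out) > 0L) {
    out$neighbours <- vapply(seq_len(nrow(out)), function(i) {
      paste(neighbors_at_time(traj, out$chain[i], out$time_ns[i], cutoff_nm),
            collapse = ", ")
    }, "")
    out$aggregate_size <- vapply(seq_len(nrow(out)), function(i) {
      f <- which.min(abs(traj$times - out$time_ns[i]))
      comps <- .components(chain_contact_graph(traj, f, cutoff_nm))
      lengths(comps)[vapply(comps, function(x) out$chain[i] %in% x, TRUE)][1]
    }, 0L)
  }
  out[order(out$time_ns), , drop = FALSE]
}

#' Folded-count step function N_h(t)
#'
#' Number of transition events at or before each evaluation time
#' (right-continuous: a transition at t counts at t).
#'
#' @param transition_times numeric vector of transition times (ns), or a
#'   data.frame with a \code{time_ns} column as returned by
#'   \code{\link{detect_transitions}}.
#' @param times evaluation times (ns).
#' @return integer vector of \code{N_h} values, one per evaluation time.
#' @export
folded_count <- function(transition_times, times) {
  if (is.data.frame(transition_times)) {
    transition_times <- transition_times$time_ns
  }
  tt <- sort(transition_times)
  vapply(times, function(t) sum(tt <= t), 0L)
}

#' Fit the sigmoid folding-kinetics model
#'
#' Nonlinear least squares of \code{h_max / (1 + exp(-k (t - t_half)))} with
#' \code{k > 0}. Initialisation: \code{h_max} from the terminal count,
#' \code{t_half} from the half-terminal crossing, \code{k} from the 10--90
#' percent rise span; a small multi-start grid is tried on failure.
#'
#' @param times evaluation times (ns).
#' @param counts observed \code{N_h} values.
#' @return object of class \code{sigmoid_fit}: list with \code{h_max},
#'   \code{t_half} (ns), \code{k} (1/ns), \code{lambda} (= -k, the shape
#'   parameter of the decreasing-exponent form), \code{rss},
#'   \code{fitted_fn} (function of time), \code{fit} (the nls object).
#' @export
fit_sigmoid <- function(times, counts) {
  keep <- !is.na(times) & !is.na(counts)
  times <- times[keep]; counts <- counts[keep]
  if (length(unique(times)) < 4L) stop("need at least 4 distinct time points")
  if (max(counts) <= 0 || stats::sd(counts) == 0) {
    stop("degenerate flat series")
  }
  hmax0 <- max(counts)
  crossing <- function(level) {
    i <- which(counts >= level)[1]
    if (is.na(i)) max(times) else times[i]
  }
  t10 <- crossing(0.1 * hmax0); t90 <- crossing(0.9 * hmax0)
  k0 <- if (t90 > t10) 4.4 / (t90 - t10) else 4 / max(diff(range(times)), 1)
  th0 <- crossing(0.5 * hmax0)
  dat <- data.frame(t = times, y = counts)
  span <- diff(range(times))
  starts <- list(c(hmax0, th0, k0))
  for (fk in c(0.2, 5)) starts <- c(starts, list(c(hmax0, th0, k0 * fk)))
  for (dth in c(-span / 4, span / 4)) {
    starts <- c(starts, list(c(hmax0, th0 + dth, k0)))
  }
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ hmax / (1 + exp(-k * (t - thalf))), data = dat,
        start = list(hmax = s[1], thalf = s[2], k = s[3]),
        lower = c(hmax = 1e-8, thalf = -Inf, k = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("sigmoid fit failed to converge after restarts")
  p <- stats::coef(fit)
  fn <- function(t) p[["hmax"]] / (1 + exp(-p[["k"]] * (t - p[["thalf"]])))
  structure(list(h_max = p[["hmax"]], t_half = p[["thalf"]], k = p[["k"]],
                 lambda = -p[["k"]],
                 rss = sum(stats::residuals(fit)^2),
                 fitted_fn = fn, fit = fit),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid_fit: h_max %.4g, t_half %.4g ns, k %.4g /ns (rss %.4g)\n",
    x$h_max, x$t_half, x$k, x$rss))
  invisible(x)
}
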