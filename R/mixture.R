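with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Fit a lognormal mixture to corrected 4dTv values
#'
#' Paralogue-age distributions accumulate one peak per burst of
#' duplication; a lognormal mixture captures those peaks on the positive
#' 4dTv scale. The fit is a Gaussian mixture with unequal component
#' variances, estimated by EM on ln(values); the component count k is
#' chosen among `k_candidates` by minimum BIC (-2 log L + p ln n).
#' Saturated or undefined distances must be excluded before calling.
#' Each component's mode on the 4dTv scale is exp(mu - sigma^2).
#'
#' @param values positive corrected-4dTv values; n must be at least
#'   10 x max(k_candidates).
#' @param k_candidates integer vector of component counts to score.
#' @param seed integer seed; the fit is deterministic given (values, seed).
#' @param var_floor minimum log-space component variance; fits collapsing
#'   below it (e.g. all values identical) are rejected.
#' @return object of class `lognormal_mixture_fit` with fields k, weight,
#'   meanlog, sdlog, mode, loglik, bic, bic_table, n, seed.
#' @export
fit_lognormal_mixture <- function(values, k_candidates = 1:4, seed = 1L,
                                  var_floor = 1e-6) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("values must be positive and finite; offending index(es): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  n <- length(values)
  if (n < 10L * max(k_candidates))
    stop("need at least ", 10L * max(k_candidates), " values to consider k=",
         max(k_candidates), "; got ", n, call. = FALSE)
  lv <- log(values)
  if (stats::var(lv) < var_floor)
    stop("log-scale variance below the variance floor (", var_floor,
         "); the values are (nearly) identical and no mixture is ",
         "identifiable", call. = FALSE)
  fits <- with_seed(seed, lapply(k_candidates, function(k) {
    f <- tryCatch(
      suppressWarnings(mclust::Mclust(lv, G = k, modelNames = "V",
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f$parameters$mean))) return(NULL)
    sig2 <- f$parameters$variance$sigmasq
    if (length(sig2) == 1L) sig2 <- rep(sig2, k)
    if (any(sig2 < var_floor)) return(NULL)
    list(k = k, weight = f$parameters$pro, meanlog = f$parameters$mean,
         sdlog = sqrt(sig2), loglik = f$loglik, df = f$df)
  }))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok))
    stop("no mixture candidate could be fitted", call. = FALSE)
  bic <- vapply(fits, function(f)
    if (is.null(f)) NA_real_ else -2 * f$loglik + f$df * log(n), 0)
  best <- fits[[which.min(bic)]]
  ord <- order(best$meanlog)
  out <- list(k = best$k,
              weight = unname(best$weight[ord]),
              meanlog = unname(best$meanlog[ord]),
              sdlog = unname(best$sdlog[ord]),
              mode = unname(exp(best$meanlog[ord] - best$sdlog[ord]^2)),
              loglik = best$loglik,
              bic = min(bic, na.rm = TRUE),
              bic_table = data.frame(k = k_candidates, bic = bic),
              n = n, seed = as.integer(seed))
  class(out) <- "lognormal_mixture_fit"
  out
}

#' @export
print.lognormal_mixture_fit <- function(x, ...) {
  cat("Lognormal mixture fit: k = ", x$k, " (BIC ", round(x$bic, 1),
      ", n = ", x$n, ")\n", sep = "")
  for (i in seq_len(x$k))
    cat(sprintf("  component %d: weight %.3f, meanlog %.4f, sdlog %.4f,",
                i, x$weight[i], x$meanlog[i], x$sdlog[i]),
        sprintf(" mode %.4f\n", x$mode[i]))
  invisible(x)
}

#' Mixture density on the 4dTv scale
#'
#' @param fit a [fit_lognormal_mixture()] object.
#' @param x positive evaluation points.
#' @return density values.
#' @export
mixture_density <- function(fit, x) {
  stopifnot(inherits(fit, "lognormal_mixture_fit"))
  d <- numeric(length(x))
  for (i in seq_len(fit$k))
    d <- d + fit$weight[i] * stats::dlnorm(x, fit$meanlog[i], fit$sdlog[i])
  d
}

#' Local maxima of a fitted mixture density
#'
#' Evaluates the mixture density on a regular grid and reports every grid
#' point exceeding both neighbours; plateaus (runs of equal density)
#' contribute their midpoint. These local maxima are the "modes" used to
#' date duplication bursts.
#'
#' @param fit a [fit_lognormal_mixture()] object.
#' @param grid_min,grid_max,step evaluation grid in 4dTv units.
#' @return sorted numeric vector of maxima positions.
#' @export
density_local_maxima <- function(fit, grid_min = 0.01, grid_max = 1.5,
                                 step = 0.005) {
  x <- seq(grid_min, grid_max, by = step)
  d <- mixture_density(fit, x)
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  maxima <- numeric(0)
  for (j in seq_along(r$values)) {
    left_ok <- j > 1L && r$values[j] > r$values[j - 1L]
    right_ok <- j < length(r$values) && r$values[j] > r$values[j + 1L]
    if (left_ok && right_ok)
      maxima <- c(maxima, (x[starts[j]] + x[ends[j]]) / 2)
  }
  sort(maxima)
}

#' Plot a fitted mixture density over the 4dTv histogram
#'
#' Draws the normalized histogram of the values and overlays the fitted
#' mixture density with its local maxima marked. Both layers are on the
#' probability-density scale so their areas match.
#'
#' @param x a `lognormal_mixture_fit`.
#' @param values the corrected 4dTv values the fit was computed from.
#' @param config a [pipeline_config()] controlling the histogram range.
#' @param ... passed to [graphics::hist].
#' @return invisibly, the maxima positions.
#' @export
plot.lognormal_mixture_fit <- function(x, values,
                                       config = pipeline_config(), ...) {
  breaks <- seq(config$hist_min, config$hist_max, by = config$hist_width)
  inside <- values[values >= config$hist_min & values < config$hist_max]
  graphics::hist(inside, breaks = breaks, freq = FALSE,
                 col = "grey85", border = "white",
                 xlab = "corrected 4dTv", main = "", ...)
  xs <- seq(config$hist_min, config$hist_max, length.out = 400L)
  graphics::lines(xs, mixture_density(x, xs), lwd = 2)
  mx <- density_local_maxima(x, config$hist_min, config$hist_max, 0.005)
  graphics::abline(v = mx, lty = 2)
  invisible(mx)
}

#' Histogram of 4dTv values over a fixed range
#'
#' Bins values into half-open fixed-width bins [lo, hi) spanning
#' [hist_min, hist_max); values below or at/above the range are counted
#' in the underflow/overflow fields rather than silently dropped.
#'
#' @param values corrected 4dTv values (NA dropped with a count).
#' @param config a [pipeline_config()]; uses hist_min, hist_max,
#'   hist_width.
#' @return list with `bins` (data.frame bin_lo, bin_hi, count),
#'   `underflow`, `overflow`, `n_na`.
#' @export
histogram_4dtv <- function(values, config = pipeline_config()) {
  validate_config(config)
  n_na <- sum(is.na(values))
  values <- values[!is.na(values)]
  breaks <- seq(config$hist_min, config$hist_max, by = config$hist_width)
  if (abs(breaks[length(breaks)] - config$hist_max) > 1e-9)
    breaks <- c(breaks, config$hist_max)
  idx <- findInterval(values, breaks)
  nb <- length(breaks) - 1L
  counts <- tabulate(idx[idx >= 1L & idx <= nb &
                           values < config$hist_max], nbins = nb)
  list(bins = data.frame(bin_lo = breaks[-length(breaks)],
                         bin_hi = breaks[-1L], count = counts),
       underflow = sum(values < config$hist_min),
       overflow = sum(values >= config$hist_max),
       n_na = n_na)
}
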