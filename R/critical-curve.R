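#' Monte-Carlo calibration of the segmentation significance curve
#'
#' The segmentation splits a window of length `N` only when the maximal
#' Kolmogorov-Smirnov distance over admissible cuts, `D_max`, exceeds the
#' value expected by chance.  That null reference, `D_crit(N, alpha)`, is the
#' empirical `(1 - alpha)` quantile of `D_max` over `n_null` i.i.d. standard
#' Gaussian series of length `N`, scanned with exactly the same
#' minimum-length restriction `l0` as the segmenter itself, so calibration
#' and use are provably matched.  Values between calibrated lengths are
#' interpolated linearly in `log(N)` after a decreasing isotonic fit (the
#' null quantile shrinks as `N` grows).
#'
#' @param lengths Integer vector of series lengths to calibrate (each
#'   `>= 2 * l0`).
#' @param alpha Significance level in (0, 1).
#' @param l0 Minimum segment length used in the scan.
#' @param n_null Null replicates per length (>= 1000 recommended).
#' @param seed RNG seed.
#' @param cache_dir Optional directory; results are cached as JSON keyed by
#'   `(lengths, alpha, l0, n_null, seed)` and reloaded on repeat calls.
#' @return A `ks_critical_curve` object.
#' @seealso [default_critical_curve()] for the shipped pre-calibrated table,
#'   [critical_curve_fn()] to wrap a user-supplied analytic formula.
#' @export
calibrate_critical_curve <- function(lengths, alpha = 0.01, l0 = 33L,
                                     n_null = 2000L, seed = 1L,
                                     cache_dir = NULL) {
  lengths <- sort(unique(as.integer(lengths)))
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (any(lengths < 2L * l0)) abort("every calibrated length must be >= 2 * l0")
  key <- sprintf("kscrit_l0%d_a%g_null%d_seed%d_N%s.json", l0, alpha, n_null,
                 seed, paste(lengths, collapse = "-"))
  cache_file <- if (!is.null(cache_dir)) file.path(cache_dir, key) else NULL
  if (!is.null(cache_file) && file.exists(cache_file)) {
    cached <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
    return(new_critical_curve(tibble::as_tibble(cached$table), alpha, l0,
                              provenance = cached$provenance))
  }
  d_crit <- vapply(lengths, function(n) {
    set.seed(as.integer((seed + n) %% .Machine$integer.max))
    unname(quantile(null_dmax_cpp(n, l0, n_null), probs = 1 - alpha, type = 7))
  }, numeric(1))
  tab <- tibble::tibble(n = lengths, d_crit = monotone_decreasing(lengths, d_crit))
  prov <- list(method = "monte-carlo", n_null = n_null, seed = seed)
  if (!is.null(cache_file)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(table = tab, provenance = prov, alpha = alpha, l0 = l0),
                         cache_file, auto_unbox = TRUE, digits = NA)
  }
  new_critical_curve(tab, alpha, l0, provenance = prov)
}

# Decreasing isotonic fit (pool-adjacent-violators via stats::isoreg on -y),
# removing Monte-Carlo wiggles from the quantile-vs-length table.
monotone_decreasing <- function(x, y) {
  if (length(y) < 2L) return(y)
  -isoreg(x, -y)$yf
}

new_critical_curve <- function(table, alpha, l0, provenance = list(), fun = NULL) {
  structure(
    list(table = table, alpha = alpha, l0 = as.integer(l0),
         provenance = provenance, fun = fun),
    class = "ks_critical_curve"
  )
}

#' Wrap an analytic critical curve
#'
#' Users holding a closed-form significance curve (e.g. a published fitted
#' formula) can plug it in instead of the Monte-Carlo table.
#'
#' @param fun Function of the window length `n` returning `D_crit` in (0, 1].
#' @param alpha Nominal level the formula corresponds to.
#' @param l0 Minimum segment length the formula assumes.
#' @return A `ks_critical_curve`.
#' @export
critical_curve_fn <- function(fun, alpha, l0 = 33L) {
  stopifnot(is.function(fun))
  new_critical_curve(table = NULL, alpha = alpha, l0 = l0,
                     provenance = list(method = "user-supplied"), fun = fun)
}

#' The shipped default critical curve
#'
#' Loads the pre-calibrated Monte-Carlo table bundled with the package
#' (standard-Gaussian null, `l0 = 33`, lengths 66 to 23170, 400-3000
#' replicates per length; regenerable with [calibrate_critical_curve()]).
#'
#' @param alpha One of the calibrated levels 0.10, 0.05, 0.02, 0.01, 0.005.
#' @return A `ks_critical_curve` with `l0 = 33`.
#' @export
default_critical_curve <- function(alpha = 0.01) {
  path <- system.file("extdata", "ks_dmax_critical.csv", package = "sbpseg")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  avail <- sort(unique(tab$alpha))
  if (!any(abs(avail - alpha) < 1e-12)) {
    abort(sprintf("no shipped calibration at alpha = %g (available: %s); use calibrate_critical_curve()",
                  alpha, paste(avail, collapse = ", ")))
  }
  sub <- tab[abs(tab$alpha - alpha) < 1e-12, ]
  sub <- sub[order(sub$n), ]
  new_critical_curve(
    tibble::tibble(n = sub$n, d_crit = monotone_decreasing(sub$n, sub$d_crit)),
    alpha = alpha, l0 = sub$l0[1],
    provenance = list(method = "monte-carlo (shipped)", n_null = sub$n_null,
                      seed = sub$seed[1])
  )
}

#' Evaluate a critical curve
#'
#' @param curve A `ks_critical_curve`.
#' @param n Window length(s).
#' @return `D_crit(n, alpha)`, linearly interpolated in `log(n)` between
#'   calibrated lengths and clamped to the end values outside the calibrated
#'   range (constant extrapolation is conservative for large `n`).
#' @export
d_crit <- function(curve, n) {
  stopifnot(inherits(curve, "ks_critical_curve"))
  if (!is.null(curve$fun)) return(curve$fun(n))
  tab <- curve$table
  if (nrow(tab) == 1L) return(rep(tab$d_crit, length(n)))
  approx(log(tab$n), tab$d_crit, xout = log(n), rule = 2)$y
}

#' @export
print.ks_critical_curve <- function(x, ...) {
  cat(sprintf("<ks_critical_curve> alpha = %g, l0 = %d, %s\n", x$alpha, x$l0,
              x$provenance$method %||% "unknown provenance"))
  if (!is.null(x$table)) print(x$table, n = 5)
  invisible(x)
}
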