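# Double-logarithm (Hill) analysis of static quenching:
#   log10[(F0 - F)/F] = log10 K_A + n log10 [Q]
# The slope is the number of binding sites n, the intercept the log of the
# association constant K_A. Logarithms are base 10 throughout.

#' Double-logarithm transform of a titration series
#'
#' Builds the (log10\[Q\], log10((F0 - F)/F)) point set for the Hill
#' regression. Points with `F >= F0` (no net quenching, e.g. an initial
#' fluorescence-enhancement phase) and the `[Q] = 0` point are dropped and
#' recorded in the `"dropped"` attribute, since their transform is
#' undefined.
#'
#' @inheritParams quench_ratios
#' @return Data frame with columns `log10_Q`, `log10_quench`,
#'   `point_index` (index into the original series); attributes `dropped`
#'   (data frame of excluded points with reasons) and `temperature_K`.
#' @export
hill_transform <- function(series, policy = c("fixed", "max"), F0 = NULL,
                           fit_halfwidth_nm = 12) {
  ratios <- quench_ratios(series, policy = policy, F0 = F0,
                          fit_halfwidth_nm = fit_halfwidth_nm)
  q <- ratios$quencher_conc_M
  y <- ratios$ratio - 1           # (F0 - F)/F = F0/F - 1
  usable <- q > 0 & y > 0
  dropped <- data.frame(
    point_index = which(!usable),
    quencher_conc_M = q[!usable],
    reason = ifelse(q[!usable] == 0, "zero concentration", "F >= F0 (no quenching)")
  )
  if (sum(usable) < 3L) {
    stop("fewer than 3 usable points after dropping enhanced/zero points",
         call. = FALSE)
  }
  out <- data.frame(log10_Q = log10(q[usable]), log10_quench = log10(y[usable]),
                    point_index = which(usable))
  attr(out, "dropped") <- dropped
  attr(out, "temperature_K") <- attr(ratios, "temperature_K")
  out
}

#' Hill (double-logarithm) fit: association constant and site number
#'
#' Ordinary least-squares line through the double-logarithm points:
#' `K_A = 10^intercept` (reported in L/mol, the printed convention even for
#' `n != 1`) and `n = slope`.
#'
#' @param x A [titration_series] (transformed internally via
#'   [hill_transform()]) or a data frame as returned by it.
#' @param ... Passed to [hill_transform()] when `x` is a series.
#' @return An object of class `binding_result`: `K_A` (L/mol), `n`,
#'   `temperature_K`, `r_squared`, `points_used`, `dropped`.
#' @export
hill_fit <- function(x, ...) {
  if (inherits(x, "titration_series")) x <- hill_transform(x, ...)
  if (nrow(x) < 3L) stop("Hill fit needs at least 3 points", call. = FALSE)
  if (diff(range(x$log10_Q)) == 0) {
    stop("degenerate concentration range: all [Q] equal", call. = FALSE)
  }
  fit <- stats::lm(log10_quench ~ log10_Q, data = x)
  co <- stats::coef(fit)
  tK <- attr(x, "temperature_K")
  structure(
    list(K_A = unname(10^co[1]), n = unname(co[2]),
         temperature_K = if (is.null(tK)) NA_real_ else tK,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         points_used = x$point_index,
         dropped = attr(x, "dropped")),
    class = "binding_result"
  )
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("<binding_result> T = %g K: K_A = %.4g L/mol, n = %.3f, r2 = %.5f\n",
              x$temperature_K, x$K_A, x$n, x$r_squared))
  if (nrow(x$dropped)) {
    cat(sprintf("  dropped %d point(s): %s\n", nrow(x$dropped),
                paste(unique(x$dropped$reason), collapse = "; ")))
  }
  invisible(x)
}
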