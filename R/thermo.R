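# Van't Hoff thermodynamics of the binding equilibrium:
#   ln K_A = -dH/(R T) + dS/R          (linear in 1/T)
#   dG = dH - T dS = -R T ln K_A
# The signs of dH and dS indicate the dominant interaction force:
# both negative -> hydrogen bonds / van der Waals; dH < 0 with dS > 0 ->
# hydrophobic.

#' Universal gas constant, J/(mol K)
#' @export
R_GAS <- 8.314

#' Van't Hoff fit of association constants across temperature
#'
#' Ordinary least squares of `ln K_A` on `1/T`. The enthalpy change is
#' `-slope * R` (returned in kJ/mol), the entropy change `intercept * R`
#' (J/(mol K)).
#'
#' @param temperature_K Vector of distinct temperatures (K).
#' @param K_A Positive association constants (L/mol), same length.
#' @return A list with `delta_H` (kJ/mol), `delta_S` (J/(mol K)),
#'   `r_squared`, and the `(T, K_A)` pairs used.
#' @export
vant_hoff_fit <- function(temperature_K, K_A) {
  if (length(temperature_K) != length(K_A) || length(K_A) < 2L) {
    stop("need >= 2 (temperature, K_A) pairs", call. = FALSE)
  }
  if (anyDuplicated(temperature_K)) {
    stop("duplicate temperatures in van't Hoff fit", call. = FALSE)
  }
  if (any(K_A <= 0)) stop("K_A must be positive", call. = FALSE)
  x <- 1 / temperature_K
  y <- log(K_A)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (stats::var(y) == 0) 1 else suppressWarnings(summary(fit)$r.squared)
  list(delta_H = unname(-co[2] * R_GAS / 1000),
       delta_S = unname(co[1] * R_GAS),
       r_squared = r2,
       pairs = data.frame(temperature_K = temperature_K, K_A = K_A))
}

#' Gibbs energy from enthalpy and entropy
#'
#' `dG = dH - T dS`, with dH in kJ/mol and dS in J/(mol K); the result is
#' in kJ/mol. This is the primary dG pathway of the pipeline because it is
#' exact given (dH, dS).
#'
#' @param delta_H Enthalpy change, kJ/mol.
#' @param delta_S Entropy change, J/(mol K).
#' @param temperature_K Temperature(s), K (> 0). Vectorised.
#' @return Gibbs energy change(s), kJ/mol.
#' @export
gibbs_from_HS <- function(delta_H, delta_S, temperature_K) {
  if (any(temperature_K <= 0)) stop("temperature must be positive", call. = FALSE)
  delta_H - temperature_K * delta_S / 1000
}

#' Gibbs energy from the association constant
#'
#' `dG = -R T ln K_A` in kJ/mol. Reported alongside [gibbs_from_HS()] as a
#' consistency diagnostic; the two agree exactly only when K_A lies
#' exactly on the van't Hoff line.
#'
#' @param K_A Association constant(s), L/mol (> 0).
#' @param temperature_K Temperature(s), K (> 0).
#' @return Gibbs energy change(s), kJ/mol.
#' @export
gibbs_from_K <- function(K_A, temperature_K) {
  if (any(K_A <= 0)) stop("K_A must be positive", call. = FALSE)
  if (any(temperature_K <= 0)) stop("temperature must be positive", call. = FALSE)
  -R_GAS * temperature_K * log(K_A) / 1000
}

#' Classify the dominant interaction force from (dH, dS) signs
#'
#' Primary sign rules: `dH < 0 & dS < 0` indicates hydrogen bonding and
#' van der Waals forces (`"hbond_vdw"`); `dH < 0 & dS > 0` indicates
#' hydrophobic interaction (`"hydrophobic"`). With
#' `allow_extensions = TRUE`, the conventional extensions are applied when
#' the primary rules do not: `dH > 0 & dS > 0` -> hydrophobic;
#' `|dH| < eps_H_kJ & dS > 0` -> electrostatic; such calls are flagged as
#' extensions in `rule_applied`. Anything else is `"indeterminate"`.
#'
#' @param delta_H Enthalpy change, kJ/mol.
#' @param delta_S Entropy change, J/(mol K).
#' @param allow_extensions Apply the conventional extended rules (default
#'   `TRUE`).
#' @param eps_H_kJ Half-width of the "dH approximately 0" band in kJ/mol
#'   (default 5).
#' @return An object of class `force_class` with fields `label` and
#'   `rule_applied`.
#' @export
classify_forces <- function(delta_H, delta_S, allow_extensions = TRUE,
                            eps_H_kJ = 5) {
  if (!is.finite(delta_H) || !is.finite(delta_S)) {
    stop("delta_H and delta_S must be finite", call. = FALSE)
  }
  label <- "indeterminate"
  rule <- "no sign rule matched"
  if (delta_H < 0 && delta_S < 0) {
    label <- "hbond_vdw"
    rule <- "dH < 0 and dS < 0: hydrogen bond / van der Waals"
  } else if (delta_H < 0 && delta_S > 0) {
    label <- "hydrophobic"
    rule <- "dH < 0 and dS > 0: hydrophobic interaction"
  } else if (allow_extensions) {
    if (abs(delta_H) < eps_H_kJ && delta_S > 0) {
      label <- "electrostatic"
      rule <- "extension: dH ~ 0 and dS > 0: electrostatic"
    } else if (delta_H > 0 && delta_S > 0) {
      label <- "hydrophobic"
      rule <- "extension: dH > 0 and dS > 0: hydrophobic interaction"
    }
  }
  structure(list(label = label, rule_applied = rule), class = "force_class")
}

#' @export
print.force_class <- function(x, ...) {
  cat(sprintf("<force_class> %s (%s)\n", x$label, x$rule_applied))
  invisible(x)
}

#' Full thermodynamic analysis from per-temperature binding results
#'
#' Runs the van't Hoff fit over a set of [hill_fit()] results, computes dG
#' at every temperature by both pathways, and classifies the dominant
#' interaction force.
#'
#' @param binding_results List of `binding_result` objects at >= 2 distinct
#'   temperatures.
#' @param ... Passed to [classify_forces()].
#' @return An object of class `thermo_result`: `delta_H` (kJ/mol),
#'   `delta_S` (J/(mol K)), `delta_G_by_T` (named vector, kJ/mol, from
#'   dH - T dS), `delta_G_from_K` (named vector, -RT ln K_A),
#'   `gibbs_consistency_kJ` (their difference), `gas_constant`,
#'   `force_class`, `r_squared`.
#' @export
thermo_analysis <- function(binding_results, ...) {
  tK <- vapply(binding_results, `[[`, numeric(1), "temperature_K")
  KA <- vapply(binding_results, `[[`, numeric(1), "K_A")
  ord <- order(tK)
  tK <- tK[ord]; KA <- KA[ord]
  vh <- vant_hoff_fit(tK, KA)
  dG_hs <- gibbs_from_HS(vh$delta_H, vh$delta_S, tK)
  dG_k <- gibbs_from_K(KA, tK)
  names(dG_hs) <- names(dG_k) <- as.character(tK)
  structure(
    list(delta_H = vh$delta_H, delta_S = vh$delta_S,
         delta_G_by_T = dG_hs, delta_G_from_K = dG_k,
         gibbs_consistency_kJ = dG_hs - dG_k,
         gas_constant = R_GAS,
         force_class = classify_forces(vh$delta_H, vh$delta_S, ...),
         r_squared = vh$r_squared),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.2f kJ/mol, dS = %.2f J/(mol K), r2 = %.5f\n",
              x$delta_H, x$delta_S, x$r_squared))
  cat(sprintf("  dG(T): %s kJ/mol\n",
              paste(sprintf("%s K: %.2f", names(x$delta_G_by_T), x$delta_G_by_T),
                    collapse = "; ")))
  cat(sprintf("  force: %s\n", x$force_class$label))
  invisible(x)
}
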