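#' nucleoflux: light-gated nucleocytoplasmic transport and terminal mechanics
#'
#' Tools for quantifying how fast proteins shuttle between nucleus and
#' cytoplasm under optogenetic control, and for relating those rates to the
#' local mechanical stability of the protein terminus that threads the
#' nuclear pore first. The package covers five stages of the analysis:
#' synthetic data generation with known ground truth, image quantification,
#' kinetic model fitting, single-molecule force-ramp analysis, and the
#' transcription-factor disorder survey, plus static backbone hydrogen-bond
#' counting on structures.
#'
#' @keywords internal
#' @importFrom stats median mad rnorm rpois runif rlnorm density ks.test
#'   wilcox.test qnorm sd quantile coef setNames runmed nls.control optim
#' @importFrom utils read.csv write.csv read.delim write.table
"_PACKAGE"

#' Transport parameter bundle for one cell
#'
#' Collects the kinetic parameters of the two-compartment first-order
#' exchange model. During the recovery phase (light off) the compartment
#' concentrations relax as
#' \deqn{[N](t) = [N]_e - ([N]_e - [N]_0) e^{-kt}, \quad
#'       [C](t) = [C]_e + ([C]_0 - [C]_e) e^{-kt},}
#' with a single relaxation rate \eqn{k = k_I + k_E}, the sum of the active
#' import and export rate constants. Mass conservation links the two pools
#' through the relative nucleus-to-cytoplasm volume factor
#' \eqn{v = ([C]_0 - [C]_e) / ([N]_e - [N]_0)}, and the steady-state
#' accumulation ratio is \eqn{K_e = [N]_e/[C]_e = k_I/k_E} (import mode; the
#' export-mode ratio swaps the compartments so that \eqn{K_e = k_E/k_I}).
#'
#' Concentrations are normalized so that the volume-weighted total
#' \eqn{v\,[N] + [C] = 1} at all times, which fixes
#' \eqn{[C]_e = 1/(1 + v K_e)} and \eqn{[N]_e = K_e/(1 + v K_e)}.
#'
#' @param K_e steady-state accumulation ratio (dimensionless, > 0). Nucleus
#'   over cytoplasm for import mode, cytoplasm over nucleus for export mode.
#' @param k total relaxation rate in s^-1 (> 0); `k = k_I + k_E`.
#' @param v relative nucleus-to-cytoplasm volume factor (> 0).
#' @param mode `"import"` or `"export"`; decides how `k` splits into
#'   `k_I` and `k_E` (see [rates_from_fit()]).
#' @param N0 initial concentration of the accumulating compartment at the
#'   start of recovery (default 0: fully emptied).
#' @return An object of class `transport_params`: a list with `K_e`, `k`,
#'   `k_I`, `k_E`, `v`, `mode`, `N0`, `Ne`, `C0`, `Ce` (all in normalized
#'   concentration units; rates in s^-1).
#' @examples
#' p <- transport_params(K_e = 1.87, k = 4.94e-3)
#' p$k_I * 1000   # import rate in ks^-1
#' @export
transport_params <- function(K_e, k, v = 1, mode = c("import", "export"),
                             N0 = 0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(K_e), is.numeric(k), is.numeric(v), length(K_e) == 1,
            length(k) == 1, length(v) == 1)
  if (!is.finite(K_e) || K_e <= 0) stop("K_e must be finite and > 0")
  if (!is.finite(k) || k <= 0) stop("k must be finite and > 0")
  if (!is.finite(v) || v <= 0) stop("v must be finite and > 0")
  if (!is.finite(N0) || N0 < 0) stop("N0 must be finite and >= 0")
  rates <- rates_from_fit(K_e, k, mode)
  Ce <- 1 / (1 + v * K_e)
  Ne <- K_e * Ce
  if (N0 >= Ne && N0 > 0) stop("N0 must be below the steady-state level Ne")
  obj <- list(K_e = K_e, k = k, k_I = rates[["k_I"]], k_E = rates[["k_E"]],
              v = v, mode = mode,
              N0 = N0, Ne = Ne, C0 = 1 - v * N0, Ce = Ce)
  class(obj) <- "transport_params"
  obj
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf("Transport parameters (%s mode)\n", x$mode))
  cat(sprintf("  K_e = %.4g  k = %.4g s^-1 (k_I = %.4g, k_E = %.4g s^-1)\n",
              x$K_e, x$k, x$k_I, x$k_E))
  cat(sprintf("  v = %.4g  [N]: %.4g -> %.4g  [C]: %.4g -> %.4g\n",
              x$v, x$N0, x$Ne, x$C0, x$Ce))
  invisible(x)
}

#' Recovery-phase nucleus-to-cytoplasm concentration ratio
#'
#' Closed-form ratio of the accumulating over the depleting compartment
#' during the recovery phase, starting from a fully emptied accumulating
#' compartment:
#' \deqn{\frac{[N]}{[C]}(t) = \frac{K_e (1 - e^{-kt})}{1 + v K_e e^{-kt}}.}
#' The curve starts at 0, increases strictly monotonically, and approaches
#' `K_e` as `t` grows.
#'
#' @param t time since light off, seconds (vectorized, >= 0).
#' @param K_e steady-state accumulation ratio (> 0).
#' @param k total relaxation rate, s^-1 (> 0).
#' @param v relative volume factor (> 0), default 1.
#' @return numeric vector of ratios, same length as `t`.
#' @examples
#' ratio_recovery(200, K_e = 1.87, k = 4.94e-3)  # 0.692
#' @export
ratio_recovery <- function(t, K_e, k, v = 1) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  if (K_e <= 0 || k <= 0 || v <= 0) stop("K_e, k and v must be > 0")
  e <- exp(-k * t)
  K_e * (1 - e) / (1 + v * K_e * e)
}

#' Recovery-phase cytoplasm-to-nucleus ratio (export experiments)
#'
#' Export experiments track the inverse compartment ratio, which obeys the
#' same functional form as [ratio_recovery()] with `K_e` now the relative
#' cytoplasm-to-nucleus accumulation (`k_E/k_I`). Provided as a named mirror
#' so that export analyses read naturally.
#'
#' @inheritParams ratio_recovery
#' @return numeric vector of `[C]/[N]` ratios.
#' @export
export_ratio_recovery <- function(t, K_e, k, v = 1) {
  ratio_recovery(t, K_e, k, v)
}

#' Decompose the total exchange rate into import and export components
#'
#' From a fitted accumulation ratio and total rate, recover the individual
#' rate constants using \eqn{K_e = k_I/k_E} (import mode) and
#' \eqn{k = k_I + k_E}:
#' \deqn{k_I = k \frac{K_e}{1 + K_e}, \qquad k_E = \frac{k}{1 + K_e}.}
#' In export mode the roles are swapped (the fitted `K_e` is `k_E/k_I`).
#' The identity `k_I + k_E == k` holds exactly.
#'
#' @param K_e fitted accumulation ratio (> 0).
#' @param k total relaxation rate (> 0); any unit, the components inherit it.
#' @param mode `"import"` or `"export"`.
#' @return named numeric vector `c(k_I = , k_E = )` in the units of `k`.
#' @examples
#' rates_from_fit(1.87, 4.94)  # k_I = 3.22 in the same (ks^-1) units
#' @export
rates_from_fit <- function(K_e, k, mode = c("import", "export")) {
  mode <- match.arg(mode)
  if (K_e <= 0 || k <= 0) stop("K_e and k must be > 0")
  fast <- k * K_e / (1 + K_e)   # rate feeding the accumulating compartment
  slow <- k / (1 + K_e)
  if (mode == "import") c(k_I = fast, k_E = slow) else c(k_I = slow, k_E = fast)
}

#' Percent split between N- and C-terminal-entry construct groups
#'
#' Degree of asymmetry between constructs that enter the pore N-terminus
#' first versus C-terminus first, for either the accumulation ratio or a
#' rate constant: `100 * (mean(group_N) / mean(group_C) - 1)`. Positive when
#' the N-terminal-entry group is larger (faster), negative otherwise.
#'
#' @param group_N numeric values (per-cell estimates) for the N-term group;
#'   a single group mean is accepted.
#' @param group_C numeric values for the C-term group.
#' @return percent split (single number).
#' @examples
#' split_percent(3.22, 2.06)  # 56 percent import-rate split
#' @export
split_percent <- function(group_N, group_C) {
  if (length(group_N) == 0 || length(group_C) == 0) stop("empty group")
  mN <- mean(group_N)
  mC <- mean(group_C)
  if (!is.finite(mC) || mC <= 0) stop("group_C mean must be > 0")
  100 * (mN / mC - 1)
}

#' Two-sided Mann-Whitney comparison of two cell groups
#'
#' Wraps the two-tailed Mann-Whitney (Wilcoxon rank-sum) test with tie
#' correction, as used for all cross-construct comparisons, and reports the
#' group means with their standard errors alongside the test.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return list with `U` (rank-sum statistic for `a`), `p.value` (two-sided),
#'   `mean_a`, `sem_a`, `mean_b`, `sem_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = NULL, correct = TRUE))
  p <- if (is.nan(wt$p.value)) 1 else min(1, wt$p.value)
  list(U = unname(wt$statistic), p.value = p,
       mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)),
       mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)),
       n_a = length(a), n_b = length(b))
}
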