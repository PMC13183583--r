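# Freely jointed chain elasticity. Units: pN, nm, seconds throughout.

#' FJC constants
#'
#' Kuhn length and thermal energy used in all polymer-elasticity
#' conversions. The defaults (l_K = 1.1 nm, kT = 4.11 pN nm) correspond to
#' an unfolded polypeptide at the experimental temperature and are not
#' recomputed.
#'
#' @param l_K Kuhn length, nm.
#' @param kT thermal energy, pN nm.
#' @return object of class `fjc_constants`.
#' @export
fjc_constants <- function(l_K = 1.1, kT = 4.11) {
  if (l_K <= 0 || kT <= 0) stop("l_K and kT must be > 0")
  structure(list(l_K = l_K, kT = kT), class = "fjc_constants")
}

# Langevin factor coth(b) - 1/b, series near 0 for numerical stability.
.langevin <- function(b) {
  out <- numeric(length(b))
  small <- b < 1e-4
  out[small] <- b[small] / 3 - b[small]^3 / 45
  bb <- b[!small]
  out[!small] <- 1 / tanh(bb) - 1 / bb
  out
}

#' Freely-jointed-chain extension at a given force
#'
#' Equilibrium end-to-end extension of an unstructured chain of contour
#' length `dLc` under force `F`:
#' \deqn{x(F) = \Delta L_c \left[\coth\beta - 1/\beta\right], \quad
#'       \beta = F l_K / kT.}
#' Strictly increasing in `F`, linear in `dLc`, saturating at `dLc` for
#' large forces; the low-force limit `dLc * beta / 3` is evaluated by
#' series to stay numerically stable as `F` approaches 0.
#'
#' @param F force, pN (vectorized, > 0).
#' @param dLc contour length, nm (>= 0).
#' @param constants [fjc_constants()].
#' @return extension in nm.
#' @examples
#' fjc_extension(50, 65)   # ~60 nm
#' @export
fjc_extension <- function(F, dLc, constants = fjc_constants()) {
  if (any(F <= 0)) stop("F must be > 0 (extension -> 0 as F -> 0+)")
  if (any(dLc < 0)) stop("dLc must be >= 0")
  dLc * .langevin(F * constants$l_K / constants$kT)
}

#' Contour-length increment from a measured step size
#'
#' Inverts [fjc_extension()] at the unfolding force: a step of `step` nm
#' observed at force `F` corresponds to a released contour length
#' `step / (coth(beta) - 1/beta)`. Exact inverse of the forward formula at
#' the same force.
#'
#' @param step measured extension jump, nm (> 0).
#' @param F force at which the step occurred, pN (> 0).
#' @param constants [fjc_constants()].
#' @return contour-length increment, nm.
#' @examples
#' contour_from_step(60, 50)  # ~65 nm
#' @export
contour_from_step <- function(step, F, constants = fjc_constants()) {
  if (any(step < 0)) stop("step must be >= 0")
  if (any(F <= 0)) stop("F must be > 0")
  step / .langevin(F * constants$l_K / constants$kT)
}
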