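#' Single-fiber constitutive laws
#'
#' A fiber is a nonlinear spring whose state is its effective stretch
#' \eqn{\lambda} (deformed endpoint distance over relaxed length). Two
#' families of dimensionless force-stretch relations \eqn{S(\lambda)} are
#' implemented:
#'
#' * **Family 1** (stable, supercritical post-buckling):
#'   \eqn{S(\lambda) = \lambda^k - 1}, odd \eqn{k \ge 1}. Force and stiffness
#'   increase with stretch; stiffness decays to zero in the crushing limit
#'   \eqn{\lambda \to 0} but never becomes negative. `k = 1` is the linear,
#'   non-buckling spring.
#' * **Family 2** (unstable, subcritical buckling):
#'   \eqn{S(\lambda) = \lambda^k - \lambda^{k-2}}, odd \eqn{k \ge 5}.
#'   Stiffness becomes negative for \eqn{\lambda} below the critical stretch
#'   \eqn{\lambda^* = \sqrt{(k-2)/k}}, so a compressed fiber in
#'   \eqn{(0, \lambda^*)} is unstable and tends to collapse.
#'
#' The fiber energy is the antiderivative \eqn{W(\lambda) = \int_1^\lambda
#' S(t)\,dt}, normalized so \eqn{W(1) = 0}. All quantities are dimensionless
#' (forces are divided by a reference fiber stiffness coefficient).
#'
#' @param spec either a string of the form `"lin"`, `"1-3"`, `"1-5"`, `"1-7"`,
#'   `"2-5"`, `"2-7"` (family-exponent), or a family number `1`/`2` combined
#'   with the `k` argument.
#' @param k odd integer exponent; `k >= 1` for family 1, `k >= 5` for family 2.
#'
#' @return an object of class `fiber_law` with fields `family`, `k`, `label`.
#' @examples
#' law <- fiber_law("2-7")
#' fiber_force(law, c(0.5, 1, 2))
#' critical_stretch(law)
#' @export
fiber_law <- function(spec, k = NULL) {
  if (is.character(spec)) {
    stopifnot(length(spec) == 1L)
    if (spec == "lin") {
      family <- 1L; k <- 1L
    } else {
      parts <- strsplit(spec, "-", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("unknown law spec '", spec,
             "'; expected \"lin\" or \"<family>-<k>\" such as \"2-7\"")
      family <- as.integer(parts[1])
      k <- as.integer(parts[2])
    }
  } else {
    family <- as.integer(spec)
    if (is.null(k)) stop("exponent k required when family given numerically")
    k <- as.integer(k)
  }
  if (!family %in% c(1L, 2L)) stop("family must be 1 or 2")
  if (is.na(k) || k %% 2L != 1L) stop("exponent k must be an odd integer")
  if (family == 1L && k < 1L) stop("family 1 requires k >= 1")
  if (family == 2L && k < 5L) stop("family 2 requires k >= 5")
  structure(
    list(family = family, k = k,
         label = if (family == 1L && k == 1L) "lin"
                 else paste0(family, "-", k)),
    class = "fiber_law")
}

#' @export
print.fiber_law <- function(x, ...) {
  expr <- if (x$family == 1L) {
    if (x$k == 1L) "S(lambda) = lambda - 1"
    else sprintf("S(lambda) = lambda^%d - 1", x$k)
  } else {
    sprintf("S(lambda) = lambda^%d - lambda^%d", x$k, x$k - 2L)
  }
  cat(sprintf("<fiber_law %s> %s (family %d, %s buckling)\n",
              x$label, expr, x$family,
              if (x$family == 1L) "stable" else "unstable"))
  invisible(x)
}

check_lambda <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("stretch lambda must be finite and >= 0")
  lambda
}

#' Fiber force, energy and tangent stiffness
#'
#' Closed-form evaluation of the force \eqn{S(\lambda)}, the energy
#' \eqn{W(\lambda)} (with \eqn{W(1)=0}) and the tangent stiffness
#' \eqn{dS/d\lambda} of a single fiber. \eqn{\lambda = 0} is allowed and
#' evaluated by continuous limit (family 1: \eqn{S \to -1}; family 2:
#' \eqn{S \to 0}), so energies stay finite under total fiber collapse.
#'
#' @param law a [fiber_law()].
#' @param lambda vector of effective stretches, `lambda >= 0`.
#' @return numeric vector of the same length as `lambda`.
#' @examples
#' law <- fiber_law("1-3")
#' fiber_force(law, 2)    # 2^3 - 1 = 7
#' fiber_energy(law, 1)   # 0
#' @export
fiber_force <- function(law, lambda) {
  check_lambda(lambda)
  if (law$family == 1L) lambda^law$k - 1
  else lambda^law$k - lambda^(law$k - 2L)
}

#' @rdname fiber_force
#' @export
fiber_energy <- function(law, lambda) {
  check_lambda(lambda)
  k <- law$k
  if (law$family == 1L)
    lambda^(k + 1) / (k + 1) - lambda + k / (k + 1)
  else
    lambda^(k + 1) / (k + 1) - lambda^(k - 1) / (k - 1) +
      2 / ((k - 1) * (k + 1))
}

#' @rdname fiber_force
#' @export
fiber_stiffness <- function(law, lambda) {
  check_lambda(lambda)
  k <- law$k
  if (law$family == 1L) k * lambda^(k - 1)
  else k * lambda^(k - 1) - (k - 2) * lambda^(k - 3)
}

#' Critical stretch of the unstable compressive regime
#'
#' For family-2 laws the stiffness \eqn{dS/d\lambda} has a unique root
#' \eqn{\lambda^* = \sqrt{(k-2)/k}} in \eqn{(0,1)}: fibers compressed below
#' \eqn{\lambda^*} have negative stiffness and are unstable (subcritical
#' buckling collapse). Family-1 laws have positive stiffness everywhere and
#' no critical stretch.
#'
#' @param law a [fiber_law()].
#' @return the critical stretch, or `NA_real_` for family-1 laws.
#' @examples
#' critical_stretch(fiber_law("2-7"))  # sqrt(5/7), prints as 0.85
#' @export
critical_stretch <- function(law) {
  if (law$family == 1L) return(NA_real_)
  sqrt((law$k - 2) / law$k)
}
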