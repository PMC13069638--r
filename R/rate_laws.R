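#' Hill-type regulation strength
#'
#' `phi(a) = a^n / (a^n + j^n)` (default) maps an activator level `a >= 0` to
#' a saturating occupancy in `[0, 1)`, monotone nondecreasing in `a`, with
#' half-maximum at `a = j`. With `denominator = "j"` the raw lumped constant
#' `j` is used instead of `j^n`.
#'
#' @param a activator level(s), `>= 0`.
#' @param j half-saturation level, `> 0`.
#' @param n integer Hill coefficient, `>= 1`.
#' @param denominator `"jn"` or `"j"` (see [circuit()]).
#' @return numeric vector of regulation strengths.
#' @export
regulation_strength <- function(a, j, n, denominator = c("jn", "j")) {
  denominator <- match.arg(denominator)
  if (any(a < 0)) stop("activator level a must be >= 0")
  if (j <= 0) stop("half-saturation j must be > 0")
  if (n < 1 || n != round(n)) stop("Hill coefficient n must be a positive integer")
  an <- a^n
  den <- an + if (denominator == "jn") j^n else j
  out <- an / den
  out[a == 0] <- 0
  out
}

#' Rate contribution of a single regulation edge
#'
#' Activation edges contribute `+k (T - x) phi(a)`; inhibition edges
#' contribute `-k x phi(a)`. The capacity factor `(T - x)` caps the active
#' amount at the target's expression total `T`; the `x` factor makes
#' inhibition vanish with the active pool, so the rate is zero at `a = 0` and
#' finite everywhere.
#'
#' @param sign `+1` (activation) or `-1` (inhibition).
#' @param k maximal rate (1/time), `> 0`.
#' @param j,n,denominator as in [regulation_strength()].
#' @param a activator level, `>= 0`.
#' @param x target active amount, in `[0, total]`.
#' @param total target expression total.
#' @return the signed rate (1/time).
#' @export
rate_contribution <- function(sign, k, j, n, a, x, total,
                              denominator = c("jn", "j")) {
  denominator <- match.arg(denominator)
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (k <= 0) stop("rate k must be > 0")
  if (a < 0) stop("activator level a must be >= 0")
  if (x < 0 || x > total) stop("target activity x must lie in [0, total]")
  p <- regulation_strength(a, j, n, denominator)
  if (sign > 0) k * (total - x) * p else -k * x * p
}

#' Assemble the deterministic vector field of a circuit
#'
#' Returns `F(x)` summing all edge rate contributions, the optional
#' constitutive activation `basal (T - x)`, and first-order deactivation
#' `-d x` per node; the input node additionally sees the constant stimulation
#' level `s` through its dedicated `".stim"` edge. The returned closure is the
#' drift used by [steady_state()], [dose_response()] and
#' [simulate_langevin()].
#'
#' @param circ a `circuit`; every edge must carry complete `(k, j, n)`
#'   parameters (validated, with the offending edge named).
#' @return `function(x)` mapping a state vector (node order of
#'   `circ$nodes$name`) to its time derivative.
#' @export
assemble_rhs <- function(circ) {
  validate_circuit(circ)
  e <- circ$edges
  if (nrow(e)) {
    bad <- which(!is.finite(e$k) | !is.finite(e$j) | !is.finite(e$n))
    if (length(bad))
      stop("edge ", e$source[bad[1]], " -> ", e$target[bad[1]],
           " is missing kinetic parameters")
  }
  enc <- encode_circuit(circ)
  function(x) {
    x <- as.numeric(x)
    cpp_rhs(enc, x)
  }
}
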