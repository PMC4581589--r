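#' Restricted cubic spline specification
#'
#' Holds an ordered knot vector for a Harrell-parameterization restricted
#' cubic spline. The basis has one linear term plus `length(knots) - 2`
#' nonlinear terms; it is linear beyond the boundary knots and has a
#' continuous second derivative everywhere.
#'
#' @param knots numeric vector of at least 3 strictly increasing knot
#'   locations.
#' @param variable_name label used for basis column names.
#' @return an object of class `rcs_spec`.
#' @export
rcs_spec <- function(knots, variable_name = "x") {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) {
    stop("a restricted cubic spline needs at least 3 knots", call. = FALSE)
  }
  if (anyNA(knots) || any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing and non-missing", call. = FALSE)
  }
  structure(list(knots = knots, variable_name = variable_name),
            class = "rcs_spec")
}

#' Restricted cubic spline basis
#'
#' Evaluates the Harrell-convention restricted cubic spline basis: the first
#' column is the untransformed value, followed by `length(knots) - 2`
#' truncated-power terms restricted to be linear beyond the boundary knots.
#' Nonlinear terms are scaled by `(last knot - first knot)^2` so all columns
#' share the scale of `x`.
#'
#' @param x numeric vector at which to evaluate the basis.
#' @param spec an [rcs_spec()] (or a bare numeric knot vector).
#' @return numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns.
#' @export
rcs_basis <- function(x, spec) {
  if (!inherits(spec, "rcs_spec")) spec <- rcs_spec(spec)
  t <- spec$knots
  K <- length(t)
  scl <- (t[K] - t[1L])^2
  x <- as.numeric(x)
  out <- matrix(0, nrow = length(x), ncol = K - 1L)
  out[, 1L] <- x
  pc <- function(u) pmax(u, 0)^3
  denom <- t[K] - t[K - 1L]
  for (j in seq_len(K - 2L)) {
    out[, j + 1L] <- (pc(x - t[j]) -
                        pc(x - t[K - 1L]) * (t[K] - t[j]) / denom +
                        pc(x - t[K]) * (t[K - 1L] - t[j]) / denom) / scl
  }
  colnames(out) <- c(spec$variable_name,
                     paste0(spec$variable_name, "'", seq_len(K - 2L)))
  out
}
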