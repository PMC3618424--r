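#' Define a set of relative ion permeabilities
#'
#' Relative permeabilities to K+, Na+ and Cl-. Only ratios are physically
#' meaningful: the GHK voltage is invariant under uniform rescaling of all
#' three values. By convention the suite normalizes to the residual P_K of
#' SLO3-mutant non-capacitated sperm at pH 7.4, assigned 1.0.
#'
#' @param P_K,P_Na,P_Cl dimensionless relative permeabilities, each >= 0.
#' @return An object of class `"perm_set"`: a named numeric vector.
#' @export
#' @examples
#' perm_set(P_K = 1.6, P_Na = 0.13, P_Cl = 0.6)
perm_set <- function(P_K, P_Na = 0, P_Cl = 0) {
  p <- c(P_K = P_K, P_Na = P_Na, P_Cl = P_Cl)
  if (!is.numeric(p) || length(p) != 3L || anyNA(p) || any(!is.finite(p)))
    stop("permeabilities must be finite numbers", call. = FALSE)
  if (any(p < 0))
    stop("permeabilities must be >= 0 (got ",
         paste(names(p)[p < 0], collapse = ", "), " negative)", call. = FALSE)
  structure(p, class = "perm_set")
}

#' @export
print.perm_set <- function(x, digits = 3, ...) {
  cat("Relative permeabilities: P_K =", signif(x[["P_K"]], digits),
      " P_Na =", signif(x[["P_Na"]], digits),
      " P_Cl =", signif(x[["P_Cl"]], digits), "\n")
  invisible(x)
}

as_perm_set <- function(x) {
  if (inherits(x, "perm_set")) return(x)
  x <- unlist(x)
  if (is.null(names(x))) names(x) <- c("P_K", "P_Na", "P_Cl")
  perm_set(P_K = x[["P_K"]], P_Na = x[["P_Na"]], P_Cl = x[["P_Cl"]])
}
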