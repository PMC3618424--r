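# Condition registry: experimental conditions of the fluorimetry study and
# their ground-truth permeability presets, shipped as a YAML file under
# inst/extdata so users can supply their own registry.

#' Describe an experimental condition
#'
#' A condition is a combination of genotype, capacitation state, external
#' pH, pharmacological blocker and recording medium, optionally with a
#' mixed-population structure (a fraction of cells at a shifted membrane
#' potential, as happens when only part of a sperm sample reaches the
#' capacitated state).
#'
#' @param genotype `"wild-type"` or `"SLO3-mutant"`.
#' @param state `"non-capacitated"` or `"capacitated"`.
#' @param pH external pH label: `"7.4"`, `"7"` or `"8"`.
#' @param blocker `"none"`, `"amiloride"`, `"Ba"` or `"clofilium"`.
#' @param media `"normal"`, `"low-Na"`, `"low-Cl-44"` or `"low-Cl-5"`.
#' @param mixed_fraction fraction of the population in the first
#'   subpopulation, in \[0, 1\]; 0 disables the mixture.
#' @param subpop_offsets length-2 mV offsets of the two subpopulations
#'   relative to the condition's GHK voltage.
#' @return An object of class `"condition_spec"`.
#' @export
#' @examples
#' condition_spec("wild-type", "non-capacitated")
condition_spec <- function(genotype = c("wild-type", "SLO3-mutant"),
                           state = c("non-capacitated", "capacitated"),
                           pH = c("7.4", "7", "8"),
                           blocker = c("none", "amiloride", "Ba", "clofilium"),
                           media = c("normal", "low-Na", "low-Cl-44",
                                     "low-Cl-5"),
                           mixed_fraction = 0,
                           subpop_offsets = c(0, 0)) {
  genotype <- match.arg(genotype)
  state <- match.arg(state)
  pH <- match.arg(as.character(pH), c("7.4", "7", "8"))
  blocker <- match.arg(blocker)
  media <- match.arg(media)
  if (!is.numeric(mixed_fraction) || length(mixed_fraction) != 1L ||
      is.na(mixed_fraction) || mixed_fraction < 0 || mixed_fraction > 1)
    stop("mixed_fraction must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(subpop_offsets) || length(subpop_offsets) != 2L ||
      anyNA(subpop_offsets))
    stop("subpop_offsets must be two finite mV values", call. = FALSE)
  structure(list(genotype = genotype, state = state, pH = pH,
                 blocker = blocker, media = media,
                 mixed_fraction = mixed_fraction,
                 subpop_offsets = subpop_offsets),
            class = "condition_spec")
}

#' @export
format.condition_spec <- function(x, ...) {
  lab <- paste(x$genotype, x$state, paste0("pH", x$pH), sep = " / ")
  if (x$blocker != "none") lab <- paste(lab, x$blocker, sep = " / ")
  if (x$media != "normal") lab <- paste(lab, x$media, sep = " / ")
  lab
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("Condition:", format(x), "\n")
  if (x$mixed_fraction > 0)
    cat(sprintf("  mixed population: fraction %.2f at offsets %+.1f/%+.1f mV\n",
                x$mixed_fraction, x$subpop_offsets[1], x$subpop_offsets[2]))
  invisible(x)
}

#' Load the condition-preset registry
#'
#' @param path YAML registry path; defaults to the registry shipped with
#'   the package.
#' @return The parsed registry list.
#' @export
preset_registry <- function(path = system.file("extdata",
                                               "condition_presets.yaml",
                                               package = "ghkperm")) {
  yaml::read_yaml(path)
}

#' Ground-truth permeabilities for a condition
#'
#' Looks up the base permeability triple for the condition's genotype,
#' state and pH, then applies the blocker modifier: amiloride divides P_Na
#' by 6.5; Ba2+/clofilium replace the wild-type P_K by the SLO3-mutant
#' value for the same state and pH (removal of the SLO3 component). Media
#' substitutions affect the bath, not the permeabilities.
#'
#' @param spec a [condition_spec()].
#' @param registry registry list, see [preset_registry()].
#' @return A [perm_set()].
#' @export
#' @examples
#' preset_permeabilities(condition_spec("wild-type", "non-capacitated"))
preset_permeabilities <- function(spec, registry = preset_registry()) {
  stopifnot(inherits(spec, "condition_spec"))
  entry <- registry$base[[spec$genotype]][[spec$state]][[spec$pH]]
  if (is.null(entry)) {
    known <- unlist(lapply(names(registry$base), function(g)
      lapply(names(registry$base[[g]]), function(s)
        paste(g, s, names(registry$base[[g]][[s]]), sep = " / "))))
    stop("no preset for ", format(spec), "; known conditions:\n  ",
         paste(known, collapse = "\n  "), call. = FALSE)
  }
  p <- c(P_K = entry$P_K, P_Na = entry$P_Na, P_Cl = entry$P_Cl)
  blk <- registry$blockers[[spec$blocker]]
  if (!is.null(blk)) {
    if (!is.null(blk$P_Na_factor)) p[["P_Na"]] <- p[["P_Na"]] * blk$P_Na_factor
    if (isTRUE(blk$remove_slo3)) {
      mut <- registry$base[["SLO3-mutant"]][[spec$state]][[spec$pH]]
      p[["P_K"]] <- mut$P_K
    }
  }
  perm_set(P_K = p[["P_K"]], P_Na = p[["P_Na"]], P_Cl = p[["P_Cl"]])
}

#' Bath template for a condition
#'
#' @param spec a [condition_spec()].
#' @param K_out external K+, mM.
#' @param ... further arguments to [media_bath()].
#' @return A `"bath"` object with the condition's media substitutions.
#' @export
condition_bath <- function(spec, K_out = 5, ...) {
  stopifnot(inherits(spec, "condition_spec"))
  media_bath(K_out = K_out, media = spec$media, ...)
}
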