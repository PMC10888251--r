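#' @include AllClasses.R
NULL

#' Number of enzyme functional states
#' @param object a [RateSet] or [EnzymeParams]
#' @return integer, 2, 3 or 4
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @rdname nStates
#' @export
setMethod("nStates", "RateSet", function(object) object@nStates)

#' @rdname nStates
#' @export
setMethod("nStates", "EnzymeParams", function(object) object@nStates)

#' Rate constants of a rate set
#' @param object a [RateSet]
#' @return named numeric k_1..k_2n, 1/s
#' @export
setGeneric("rateConstants", function(object) standardGeneric("rateConstants"))

#' @rdname rateConstants
#' @export
setMethod("rateConstants", "RateSet", function(object) {
  stats::setNames(object@k, paste0("k", seq_along(object@k)))
})

#' Stationary occupancies
#' @param object a [SteadyState]
#' @return numeric p_1..p_n
#' @export
setGeneric("occupancies", function(object) standardGeneric("occupancies"))

#' @rdname occupancies
#' @export
setMethod("occupancies", "SteadyState", function(object) object@occupancies)

#' Net cycle flux
#' @param object a [SteadyState]
#' @return numeric J, 1/s per enzyme
#' @export
setGeneric("flux", function(object) standardGeneric("flux"))

#' @rdname flux
#' @export
setMethod("flux", "SteadyState", function(object) object@flux)

#' Sample rows of a table
#' @param object a [SampleTable]
#' @return data.frame, one row per recorded step
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname sampleData
#' @export
setMethod("sampleData", "SampleTable", function(object) object@data)

#' Run provenance of a table
#' @param object a [SampleTable]
#' @return named list (generator, arguments, seed)
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "SampleTable", function(object) object@provenance)

setMethod("show", "RateSet", function(object) {
  cat(sprintf("RateSet: %d-state reversible cycle\n", object@nStates))
  k <- rateConstants(object)
  cat(paste(sprintf("  %-3s %.6g 1/s", names(k), k), collapse = "\n"), "\n")
})

setMethod("show", "CycleEnvironment", function(object) {
  cat("CycleEnvironment\n")
  cat(sprintf("  [S] %.4g M   [P] %.4g M", object@substrate, object@product))
  if (!is.na(object@buffer)) cat(sprintf("   [B] %.4g M", object@buffer))
  if (!is.na(object@enzyme)) cat(sprintf("   [E] %.4g M", object@enzyme))
  cat(sprintf("\n  temperature: %s\n", object@temperature))
})

setMethod("show", "EnzymeParams", function(object) {
  cat(sprintf("EnzymeParams \"%s\" (%s)\n", object@name, object@fullName))
  cat(sprintf("  %d states, scheme %s, Keq convention \"%s\"\n",
              object@nStates, object@schemeVariant, object@keqConvention))
  if (length(object@secondOrder))
    cat("  second-order:",
        paste(sprintf("%s* = %.4g /(M s) [%s]", names(object@secondOrder),
                      object@secondOrder, object@bindingLigand), collapse = ", "),
        "\n")
  if (length(object@firstOrder))
    cat("  first-order:",
        paste(sprintf("%s = %.4g /s", names(object@firstOrder),
                      object@firstOrder), collapse = ", "), "\n")
  show(object@environment)
})

setMethod("show", "SteadyState", function(object) {
  n <- length(object@occupancies)
  cat(sprintf("SteadyState (%d states): J = %.6g 1/s\n", n, object@flux))
  cat("  p:", paste(sprintf("%.4g", object@occupancies), collapse = " "), "\n")
})

setMethod("show", "ThermoKinetic", function(object) {
  cat("ThermoKinetic\n")
  cat(sprintf("  Xtot/RT = %.4g   P = %.6g 1/s   (force sign %+d)\n",
              object@totalForce, object@entropyProduction, object@forceSign))
  cat(sprintf("  kcat = %.4g 1/s   KM = %.4g M   kcat/KM = %.4g /(M s)\n",
              object@kcat, object@km, object@specificity))
  cat(sprintf("  Kapp = %.4g   Kchem = %.4g   Shannon = %.4g nats\n",
              object@kApp, object@kChem, object@shannonEntropy))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: %s (shift %+g), %s draw, constraint %s, seed %d\n",
              object@distribution, object@shift, object@drawPolicy,
              object@constraint, object@seed))
  cat("  mask:", paste0("k", object@mask, collapse = " "), "\n")
})

setMethod("show", "SampleTable", function(object) {
  cat(sprintf("SampleTable: %d steps x %d columns (%s)\n",
              nrow(object@data), ncol(object@data),
              if (is.null(object@provenance$generator)) "unknown origin"
              else object@provenance$generator))
  if (nrow(object@data)) {
    utils::str(utils::head(object@data, 3), give.attr = FALSE, vec.len = 3)
  }
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: y = %.6g x %+.6g  (R^2 = %.6g, n = %d%s)\n",
              object@slope, object@intercept, object@rSquared, object@nPoints,
              if (object@throughOrigin) ", through origin" else ""))
})

setMethod("show", "AbmResult", function(object) {
  cat(sprintf("AbmResult: %d recorded ticks, %d species, %g clamp events\n",
              nrow(object@counts), ncol(object@counts), object@clampEvents))
  cat(sprintf("  net S->P conversions: %g\n", object@netConversions))
})
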