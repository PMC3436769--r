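#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' `samplingRate`, `channelSamples`, `channelLabel`, `epochLength`,
#' `stages`, `nEpochs`, `thresholds`, `emgBand` and `droppedSamples`
#' extract the corresponding components without touching slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelSamples", function(x) standardGeneric("channelSamples"))
#' @rdname accessors
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))
#' @rdname accessors
#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))
#' @rdname accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setGeneric("emgBand", function(x) standardGeneric("emgBand"))
#' @rdname accessors
#' @export
setGeneric("droppedSamples", function(x) standardGeneric("droppedSamples"))

#' @rdname accessors
setMethod("samplingRate", "RawChannel", function(x) x@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "EpochedSignal", function(x) x@samplingRate)
#' @rdname accessors
setMethod("channelSamples", "RawChannel", function(x) x@samples)
#' @rdname accessors
setMethod("channelSamples", "EpochedSignal", function(x) as.numeric(x@epochs))
#' @rdname accessors
setMethod("channelLabel", "RawChannel", function(x) x@label)
#' @rdname accessors
setMethod("epochLength", "EpochedSignal", function(x) x@epochLength)
#' @rdname accessors
setMethod("epochLength", "Hypnogram", function(x) x@epochLength)
#' @rdname accessors
setMethod("stages", "Hypnogram", function(x) x@stages)
#' @rdname accessors
setMethod("nEpochs", "EpochedSignal", function(x) ncol(x@epochs))
#' @rdname accessors
setMethod("nEpochs", "Hypnogram", function(x) length(x@stages))
#' @rdname accessors
setMethod("thresholds", "StagerConfig", function(x) x@thresholds)
#' @rdname accessors
setMethod("emgBand", "StagerConfig", function(x) x@emgBand)
#' @rdname accessors
setMethod("droppedSamples", "EpochedSignal", function(x) x@droppedSamples)

#' Extract one epoch's samples
#'
#' @param x an [EpochedSignal-class].
#' @param i epoch index (1-based).
#' @return numeric vector of the epoch's samples.
#' @export
setGeneric("epochSamples", function(x, i) standardGeneric("epochSamples"))

#' @rdname epochSamples
setMethod("epochSamples", "EpochedSignal", function(x, i) x@epochs[, i])

## show methods ---------------------------------------------------------------

setMethod("show", "RawChannel", function(object) {
  cat(sprintf("RawChannel '%s': %d samples @ %g Hz (%.1f s), unit %s\n",
              object@label, length(object@samples), object@samplingRate,
              length(object@samples) / object@samplingRate,
              object@physicalUnit))
})

setMethod("show", "EpochedSignal", function(object) {
  cat(sprintf(
    "EpochedSignal '%s': %d epochs of %g s @ %g Hz (%d samples dropped)\n",
    object@label, ncol(object@epochs), object@epochLength,
    object@samplingRate, object@droppedSamples))
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@stages, levels = STAGES))
  cat(sprintf("Hypnogram: %d epochs of %g s\n", length(object@stages),
              object@epochLength))
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
})

setMethod("show", "StagerConfig", function(object) {
  cat(sprintf("StagerConfig: EMG band %g-%g Hz, smoothing %s, highpass %g Hz\n",
              object@emgBand[1], object@emgBand[2],
              if (object@smoothing) "on" else "off", object@highpassHz))
  cat(sprintf("  23 thresholds, e.g. wake_emg_power=%.4g, wake_bei=%.4g, n3_dbi=%.4g\n",
              object@thresholds["wake_emg_power"],
              object@thresholds["wake_bei"], object@thresholds["n3_dbi"]))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport: %d epochs, overall agreement %.1f%%\n",
              sum(object@confusion), object@overallPercent))
  cat("  kappa:", paste(sprintf("%s=%.2f", STAGES, object@kappa),
                        collapse = " "), "\n")
})

setMethod("show", "SdbProfile", function(object) {
  cat(sprintf("SdbProfile '%s': RDI %g/h, stage fractions %s\n",
              object@severity, object@targetRdi,
              paste(sprintf("%s=%.3f", STAGES, object@stageFractions),
                    collapse = " ")))
})
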