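#' @import methods
NULL

#' Accessor generics
#'
#' Accessors for the core data classes: [RawSession-class],
#' [EpochSet-class], [FeatureTable-class], [ChannelImportanceReport-class]
#' and [EvaluationResult-class].
#'
#' @param x An object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname accessors
#' @export
setGeneric("fnirsData", function(x) standardGeneric("fnirsData"))

#' @rdname accessors
#' @export
setGeneric("sessionEvents", function(x) standardGeneric("sessionEvents"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("epochInfo", function(x) standardGeneric("epochInfo"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("epochLevels", function(x) standardGeneric("epochLevels"))

#' @rdname accessors
#' @export
setGeneric("featureWeights", function(x) standardGeneric("featureWeights"))

#' @rdname accessors
#' @export
setGeneric("channelWeights", function(x) standardGeneric("channelWeights"))

#' @rdname accessors
#' @export
setGeneric("channelRanking", function(x) standardGeneric("channelRanking"))

#' @rdname accessors
#' @export
setGeneric("testAccuracy", function(x) standardGeneric("testAccuracy"))

#' @rdname accessors
#' @export
setGeneric("trainAccuracy", function(x) standardGeneric("trainAccuracy"))
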