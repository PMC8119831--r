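#' Re-exported SummarizedExperiment accessors
#'
#' [ConnectomeExperiment-class] objects are SummarizedExperiments; these
#' accessors are re-exported so the container can be used without attaching
#' SummarizedExperiment.
#'
#' @name reexports
#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @rdname reexports
#' @importFrom SummarizedExperiment assayNames
#' @export
SummarizedExperiment::assayNames

#' @rdname reexports
#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @rdname reexports
#' @importFrom SummarizedExperiment rowData
#' @export
SummarizedExperiment::rowData
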