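## The 45 AAL base regions of one hemisphere (cortical + 6 subcortical:
## hippocampus, amygdala, caudate, putamen, pallidum, thalamus).  Bilateral
## substantia innominata is appended to give the 92-node scheme.
.AAL_BASE <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")

#' Construct a parcellation
#'
#' @param labels character vector of unique node labels.
#' @param hemisphere character vector of `"L"`/`"R"`, one per node.
#' @return a [Parcellation-class] object.
#' @examples
#' p <- parcellation(c("A_L", "A_R"), c("L", "R"))
#' nNodes(p)
#' @export
parcellation <- function(labels, hemisphere) {
    new("Parcellation", nodes = data.frame(
        index = seq_along(labels), label = as.character(labels),
        hemisphere = as.character(hemisphere)))
}

#' The default 92-node parcellation
#'
#' The AAL atlas parcellates each hemisphere into 45 regions (including six
#' subcortical regions); the bilateral substantia innominata (SI) is added,
#' giving 92 nodes in total.  Regions are ordered left/right interleaved
#' with the SI pair last; labels follow the AAL convention
#' (`"Caudate_L"`, `"Calcarine_L"`, ...).
#'
#' @return a [Parcellation-class] with 92 nodes.
#' @examples
#' p <- aalParcellation()
#' nNodes(p)                       # 92
#' "Caudate_L" %in% nodeLabels(p)  # TRUE
#' @export
aalParcellation <- function() {
    base <- c(.AAL_BASE, "Substantia_Innominata")
    labels <- as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
    parcellation(labels, rep(c("L", "R"), length(base)))
}

#' Number of nodes
#' @param x a [Parcellation-class] or [WeightedNetwork-class].
#' @return integer node count.
#' @rdname nNodes
#' @export
setMethod("nNodes", "Parcellation", function(x) nrow(x@nodes))

#' Node labels
#' @param x a [Parcellation-class] or [WeightedNetwork-class].
#' @return character vector of labels in node order.
#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "Parcellation", function(x) x@nodes$label)

#' Resolve node labels to indices
#'
#' @param parc a [Parcellation-class].
#' @param labels character vector of node labels.
#' @return integer indices; errors on any label absent from the scheme.
#' @export
matchNodes <- function(parc, labels) {
    idx <- match(labels, nodeLabels(parc))
    if (anyNA(idx))
        stop("unknown node label(s): ",
             paste(labels[is.na(idx)], collapse = ", "))
    idx
}

setMethod("show", "Parcellation", function(object) {
    nd <- object@nodes
    cat("Parcellation with", nrow(nd), "nodes (",
        sum(nd$hemisphere == "L"), "L /", sum(nd$hemisphere == "R"), "R )\n")
    cat("  first:", paste(utils::head(nd$label, 4), collapse = ", "), "...\n")
})
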