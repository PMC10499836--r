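#' @import methods
NULL

## Canonical atom-table columns used throughout the package. One row per
## atom; residues are identified by (chain, resno, insert) and carry their
## one-letter amino-acid code on every atom row.
.ATOM_COLS <- c("chain", "resno", "insert", "aa", "atom",
                "x", "y", "z", "occ", "b", "elem")

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.validAtomTable <- function(atoms) {
    if (!is.data.frame(atoms))
        return("'atoms' must be a data.frame")
    miss <- setdiff(.ATOM_COLS, names(atoms))
    if (length(miss))
        return(paste0("atom table lacks columns: ",
                      paste(miss, collapse = ", ")))
    if (nrow(atoms)) {
        if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
            return("atom coordinates must be finite")
        if (any(!nzchar(atoms$atom)))
            return("atom names must be non-empty")
        if (any(!atoms$aa %in% .AA1))
            return("amino-acid codes must be one of the 20 standard or X")
        key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom)
        if (anyDuplicated(key))
            return("atom names must be unique within a residue")
    }
    TRUE
}

#' ComplexStructure: one antibody-antigen pose
#'
#' Holds the atoms of a docked (or crystal) antibody-antigen complex as a
#' flat atom table together with the partner assignment: which chain
#' identifiers form the antibody and which form the antigen. The two chain
#' sets must be disjoint, non-empty, and jointly cover every chain present
#' in the atom table.
#'
#' @slot atoms data.frame with one row per atom and columns
#'   \code{chain, resno, insert, aa, atom, x, y, z, occ, b, elem};
#'   coordinates in Angstrom, \code{aa} a one-letter code (X = unknown).
#' @slot abChains character vector of antibody chain identifiers.
#' @slot agChains character vector of antigen chain identifiers.
#'
#' @seealso [readComplexPDB()], [makeToyComplex()], [mergeChains()]
#' @export
setClass("ComplexStructure",
    representation(atoms = "data.frame",
                   abChains = "character",
                   agChains = "character"))

setValidity("ComplexStructure", function(object) {
    msg <- .validAtomTable(object@atoms)
    if (!isTRUE(msg)) return(msg)
    ab <- object@abChains
    ag <- object@agChains
    if (!length(ab) || !length(ag))
        return("both antibody and antigen chain sets must be non-empty")
    if (length(intersect(ab, ag)))
        return("antibody and antigen chain sets must be disjoint")
    present <- unique(object@atoms$chain)
    if (nrow(object@atoms) && !setequal(present, c(ab, ag)))
        return("chain sets must jointly cover all chains in the structure")
    TRUE
})

#' MergedTemplate: chains of a pose merged into one template chain
#'
#' Result of [mergeChains()]: all chains of a complex concatenated into a
#' single chain with sequential residue numbering. Under the linker
#' strategy, blocks of unknown (X) residues without coordinates join
#' consecutive chains; under the gap strategy no placeholder residues are
#' inserted and a fixed residue-index gap separates consecutive chains.
#'
#' @slot residues data.frame with one row per merged-template residue
#'   position: \code{index} (merged residue number), \code{aa} (one-letter
#'   code, X for linkers), \code{chain}, \code{resno}, \code{insert}
#'   (originating residue key; NA for linker positions) and \code{linker}
#'   (logical).
#' @slot atoms atom table (see [ComplexStructure-class]) in which
#'   \code{chain} is the merged chain id and \code{resno} the merged index.
#' @slot strategy either \code{"linker"} or \code{"gap"}.
#' @slot mergedChainId single character, the chain id of the merged chain.
#'
#' @export
setClass("MergedTemplate",
    representation(residues = "data.frame",
                   atoms = "data.frame",
                   strategy = "character",
                   mergedChainId = "character"))

setValidity("MergedTemplate", function(object) {
    msg <- .validAtomTable(object@atoms)
    if (!isTRUE(msg)) return(msg)
    res <- object@residues
    need <- c("index", "aa", "chain", "resno", "insert", "linker")
    if (!all(need %in% names(res)))
        return("residue table lacks required columns")
    if (!object@strategy %in% c("linker", "gap"))
        return("strategy must be 'linker' or 'gap'")
    if (is.unsorted(res$index, strictly = TRUE))
        return("merged residue indices must be strictly increasing")
    real <- res[!res$linker, ]
    key <- paste(real$chain, real$resno, real$insert)
    if (anyDuplicated(key))
        return("index map must be injective on real residues")
    if (identical(object@strategy, "gap") && any(res$linker))
        return("gap strategy admits no linker positions")
    TRUE
})

#' TemplateFeatureBundle: poly-alanine template features for AF2-style input
#'
#' The feature bundle produced by [buildTemplateFeatures()]: an all-alanine
#' template sequence, a per-position atom mask restricted to the five
#' backbone/C-beta slots (N, CA, C, O, CB), the matching coordinates, and
#' the query-side inputs -- the true merged sequence (with X at linker
#' positions) and a single-row MSA equal to that sequence.
#'
#' @slot templateSequence all-alanine character string over template
#'   positions (X retained at linker positions, which carry no atoms).
#' @slot templateAatype character vector of per-position amino-acid class
#'   labels (all "A", "X" at linkers).
#' @slot atomMask numeric matrix (positions x 5), columns N, CA, C, O, CB;
#'   1 where a coordinate is present.
#' @slot coordinates numeric array (positions x 5 x 3), Angstrom; zero
#'   where the mask is zero.
#' @slot templateDomainNames character, the none-marker.
#' @slot querySequence true merged amino-acid sequence, X at linkers.
#' @slot msa character vector with exactly one row, equal to
#'   \code{querySequence}.
#'
#' @export
setClass("TemplateFeatureBundle",
    representation(templateSequence = "character",
                   templateAatype = "character",
                   atomMask = "matrix",
                   coordinates = "array",
                   templateDomainNames = "character",
                   querySequence = "character",
                   msa = "character"))

setValidity("TemplateFeatureBundle", function(object) {
    n <- nchar(object@templateSequence)
    if (length(object@templateAatype) != n)
        return("templateAatype length must match templateSequence")
    if (!identical(dim(object@atomMask), c(n, 5L)))
        return("atomMask must be positions x 5")
    if (!identical(dim(object@coordinates), c(n, 5L, 3L)))
        return("coordinates must be positions x 5 x 3")
    if (nchar(object@querySequence) != n)
        return("querySequence length must match template")
    if (length(object@msa) != 1L ||
        !identical(object@msa, object@querySequence))
        return("msa must be exactly one row equal to querySequence")
    qaa <- strsplit(object@querySequence, "")[[1]]
    if (any(object@atomMask[qaa == "X", ] != 0))
        return("X (linker) positions must have an all-zero atom mask")
    present <- apply(object@coordinates, c(1, 2),
                     function(v) any(v != 0))
    if (any(object@atomMask == 1 & !present & seq_len(n) > 0)) {
        ## mask may legitimately point at an atom lying exactly at the
        ## origin; tolerate only that corner case
        bad <- which(object@atomMask == 1 & !present)
        if (length(bad))
            warning("mask-active slots with all-zero coordinates detected")
    }
    TRUE
})

setMethod("show", "ComplexStructure", function(object) {
    nres <- nrow(unique(object@atoms[, c("chain", "resno", "insert")]))
    cat("ComplexStructure:", nres, "residues,",
        nrow(object@atoms), "atoms\n")
    cat("  antibody chains:", paste(object@abChains, collapse = ", "), "\n")
    cat("  antigen chains: ", paste(object@agChains, collapse = ", "), "\n")
})

setMethod("show", "MergedTemplate", function(object) {
    res <- object@residues
    cat("MergedTemplate (", object@strategy, " strategy): ",
        sum(!res$linker), " real + ", sum(res$linker),
        " linker residues\n", sep = "")
})

setMethod("show", "TemplateFeatureBundle", function(object) {
    cat("TemplateFeatureBundle:", nchar(object@templateSequence),
        "positions,", sum(object@atomMask), "mask-active atom slots\n")
})

#' Accessors for structural objects
#'
#' `atomTable()` returns the flat atom table of a [ComplexStructure-class]
#' or [MergedTemplate-class]; `antibodyChains()` / `antigenChains()` return
#' the partner chain identifiers; `residueTable()` returns the merged
#' residue table of a [MergedTemplate-class]; `linkerPositions()` the
#' merged indices occupied by artificial linker residues;
#' `mergeStrategy()` the strategy used; `querySequence()` the true merged
#' amino-acid sequence with X at linker positions.
#'
#' @param x a ComplexStructure, MergedTemplate or TemplateFeatureBundle.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("antibodyChains", function(x) standardGeneric("antibodyChains"))
#' @rdname accessors
#' @export
setGeneric("antigenChains", function(x) standardGeneric("antigenChains"))
#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))
#' @rdname accessors
#' @export
setGeneric("linkerPositions", function(x) standardGeneric("linkerPositions"))
#' @rdname accessors
#' @export
setGeneric("mergeStrategy", function(x) standardGeneric("mergeStrategy"))
#' @rdname accessors
#' @export
setGeneric("querySequence", function(x) standardGeneric("querySequence"))

setMethod("atomTable", "ComplexStructure", function(x) x@atoms)
setMethod("atomTable", "MergedTemplate", function(x) x@atoms)
setMethod("antibodyChains", "ComplexStructure", function(x) x@abChains)
setMethod("antigenChains", "ComplexStructure", function(x) x@agChains)
setMethod("residueTable", "MergedTemplate", function(x) x@residues)
setMethod("linkerPositions", "MergedTemplate",
          function(x) x@residues$index[x@residues$linker])
setMethod("mergeStrategy", "MergedTemplate", function(x) x@strategy)
setMethod("querySequence", "MergedTemplate", function(x) {
    res <- x@residues
    src <- if ("queryAa" %in% names(res)) res$queryAa else res$aa
    paste(src, collapse = "")
})
setMethod("querySequence", "TemplateFeatureBundle",
          function(x) x@querySequence)

#' CAPRI quality classes
#'
#' Ordered factor levels used for model quality:
#' Incorrect < Acceptable < Medium < High. A model is a *positive* when its
#' class is Acceptable or better.
#'
#' @param x character vector of class labels.
#' @return ordered factor with levels Incorrect < Acceptable < Medium < High.
#' @examples
#' capriFactor(c("High", "Incorrect")) >= "Acceptable"
#' @export
capriFactor <- function(x) {
    factor(x, levels = c("Incorrect", "Acceptable", "Medium", "High"),
           ordered = TRUE)
}

#' @rdname capriFactor
#' @param quality vector of class labels (character or capriFactor).
#' @export
isPositive <- function(quality) {
    capriFactor(as.character(quality)) >= "Acceptable"
}
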