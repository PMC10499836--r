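#' Merge the chains of a complex into a single template chain
#'
#' Connects all chains of a complex into one chain, as required before a
#' structure can serve as a single-chain ("monomer") template for
#' structure-conditioned inference. Two strategies are supported:
#' \describe{
#'   \item{linker}{consecutive chains are joined by artificial linkers of
#'     \code{linkerLength} unknown (X) residues that carry no coordinates;
#'     all residues are renumbered sequentially starting at 1, so the merged
#'     length is the sum of the chain lengths plus
#'     \code{linkerLength * (nChains - 1)}.}
#'   \item{gap}{no placeholder residues are inserted; the first residue of
#'     chain k+1 is numbered \code{gapSize + 1} beyond the last residue of
#'     chain k, leaving a residue-index gap at every chain boundary.}
#' }
#' Chains are concatenated antibody-first (in the order given at
#' construction: conventionally heavy then light), antigen last; pass
#' \code{chainOrder} to override. Sequential renumbering joins the two ends
#' of any unsolved loop inside a chain; a message lists such junctions.
#'
#' @param x a [ComplexStructure-class] with at least two chains.
#' @param strategy \code{"linker"} or \code{"gap"}.
#' @param linkerLength number of X residues per junction (default 50).
#' @param gapSize residue-index gap per junction for the gap strategy
#'   (default 200, applied at every chain boundary).
#' @param chainOrder optional explicit chain order; default antibody chains
#'   then antigen chains.
#' @param mergedChainId chain identifier of the merged chain (default "A").
#' @return a [MergedTemplate-class].
#' @examples
#' cx <- makeToyComplex(8, 8, seed = 1)
#' mt <- mergeChains(cx, "linker", linkerLength = 10)
#' residueTable(mt)[9:12, ]
#' @export
mergeChains <- function(x, strategy = c("linker", "gap"),
                        linkerLength = 50L, gapSize = 200L,
                        chainOrder = NULL, mergedChainId = "A") {
    strategy <- match.arg(strategy)
    atoms <- atomTable(x)
    if (is.null(chainOrder))
        chainOrder <- c(antibodyChains(x), antigenChains(x))
    chainOrder <- chainOrder[chainOrder %in% unique(atoms$chain)]
    if (length(chainOrder) < 2L)
        stop("nothing to merge: structure has a single chain")

    resRows <- list()
    atomRows <- list()
    nextIndex <- 1L
    for (k in seq_along(chainOrder)) {
        ch <- chainOrder[k]
        cat_ <- atoms[atoms$chain == ch, , drop = FALSE]
        rkey <- paste(cat_$resno, cat_$insert)
        ukey <- unique(rkey)
        resno <- cat_$resno[match(ukey, rkey)]
        insert <- cat_$insert[match(ukey, rkey)]
        aa <- cat_$aa[match(ukey, rkey)]
        n <- length(ukey)
        gaps <- which(diff(resno) > 1L)
        if (length(gaps))
            message("chain ", ch, ": sequential renumbering joins loop ",
                    "junction(s) after residue(s) ",
                    paste(resno[gaps], collapse = ", "))
        idx <- seq.int(nextIndex, length.out = n)
        resRows[[length(resRows) + 1L]] <- data.frame(
            index = idx, aa = aa, queryAa = aa, chain = ch, resno = resno,
            insert = insert, linker = FALSE, stringsAsFactors = FALSE)
        cat_$resno <- idx[match(rkey, ukey)]
        cat_$insert <- ""
        cat_$chain <- mergedChainId
        atomRows[[length(atomRows) + 1L]] <- cat_
        nextIndex <- nextIndex + n
        if (k < length(chainOrder)) {
            if (strategy == "linker") {
                lidx <- seq.int(nextIndex, length.out = linkerLength)
                resRows[[length(resRows) + 1L]] <- data.frame(
                    index = lidx, aa = "X", queryAa = "X",
                    chain = NA_character_, resno = NA_integer_,
                    insert = NA_character_, linker = TRUE,
                    stringsAsFactors = FALSE)
                nextIndex <- nextIndex + as.integer(linkerLength)
            } else {
                nextIndex <- nextIndex + as.integer(gapSize)
            }
        }
    }
    residues <- do.call(rbind, resRows)
    merged <- do.call(rbind, atomRows)
    rownames(residues) <- rownames(merged) <- NULL
    new("MergedTemplate", residues = residues, atoms = merged,
        strategy = strategy, mergedChainId = mergedChainId)
}

#' Map merged-template indices back to original residue keys
#'
#' Returns the (chain, resno, insert) key of the original residue occupying
#' a merged index, or NA rows for linker positions.
#'
#' @param mt a [MergedTemplate-class].
#' @param index merged indices to look up (default: all).
#' @return data.frame with columns index, chain, resno, insert.
#' @export
invertIndexMap <- function(mt, index = NULL) {
    res <- residueTable(mt)
    if (!is.null(index))
        res <- res[match(index, res$index), , drop = FALSE]
    res[, c("index", "chain", "resno", "insert")]
}
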