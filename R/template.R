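## Poly-alanine template preparation: stripping side chains, rebuilding
## missing C-beta atoms on glycines, and assembling the feature bundle fed
## to a structure-conditioned inference engine.

.FEATURE_SLOTS <- c("N", "CA", "C", "O", "CB")
.FEATURE_SCHEMA_VERSION <- 1L

#' Place an idealized C-beta atom from backbone coordinates
#'
#' Constructs a C-beta position with ideal tetrahedral geometry (bond
#' length about 1.52 Angstrom) from the N, CA and C positions of a residue.
#' The construction is a fixed linear combination of the local backbone
#' frame, so it is exactly equivariant under rigid motions of the residue.
#'
#' @param n,ca,c numeric length-3 vectors: backbone N, CA, C positions.
#' @return numeric length-3 vector, the constructed CB position.
#' @export
idealCB <- function(n, ca, c) {
    b <- ca - n
    cc <- c - ca
    a <- c(b[2] * cc[3] - b[3] * cc[2],
           b[3] * cc[1] - b[1] * cc[3],
           b[1] * cc[2] - b[2] * cc[1])
    -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Convert a merged template to poly-alanine
#'
#' Strips every real residue down to the alanine heavy-atom set
#' {N, CA, C, O, CB}, constructs the missing C-beta atom on glycines from
#' ideal backbone geometry (see [idealCB()]; the same construction repairs
#' any residue whose C-beta is absent), and relabels all real residues as
#' alanine. Linker (X) residues, which carry no atoms, are
#' untouched. Backbone coordinates are never moved. The operation is
#' idempotent.
#'
#' Residues lacking any of N, CA or C cannot receive a constructed CB and
#' are kept without one; a warning lists them.
#'
#' @param mt a [MergedTemplate-class].
#' @return a [MergedTemplate-class] with all real residues poly-alanine.
#' @export
toPolyAlanine <- function(mt) {
    atoms <- atomTable(mt)
    res <- residueTable(mt)
    atoms <- atoms[atoms$atom %in% .FEATURE_SLOTS, , drop = FALSE]
    real <- res[!res$linker, , drop = FALSE]
    failed <- character()
    newCB <- list()
    for (i in seq_len(nrow(real))) {
        idx <- real$index[i]
        ra <- atoms[atoms$resno == idx, , drop = FALSE]
        if ("CB" %in% ra$atom) next
        need <- c("N", "CA", "C")
        if (!all(need %in% ra$atom)) {
            failed <- c(failed, as.character(idx))
            next
        }
        g <- function(nm) unlist(ra[ra$atom == nm, c("x", "y", "z")],
                                 use.names = FALSE)
        cb <- idealCB(g("N"), g("CA"), g("C"))
        tmpl <- ra[ra$atom == "CA", , drop = FALSE]
        tmpl$atom <- "CB"
        tmpl$elem <- "C"
        tmpl$x <- cb[1]; tmpl$y <- cb[2]; tmpl$z <- cb[3]
        newCB[[length(newCB) + 1L]] <- tmpl
    }
    if (length(failed))
        warning("no CB constructed for residue(s) missing backbone atoms: ",
                paste(failed, collapse = ", "))
    if (length(newCB)) {
        atoms <- rbind(atoms, do.call(rbind, newCB))
        atoms <- atoms[order(atoms$resno,
                             match(atoms$atom, .FEATURE_SLOTS)), ,
                       drop = FALSE]
    }
    atoms$aa <- "A"
    res$aa[!res$linker] <- "A"
    rownames(atoms) <- NULL
    new("MergedTemplate", residues = res, atoms = atoms,
        strategy = mergeStrategy(mt), mergedChainId = mt@mergedChainId)
}

#' Build the poly-alanine template feature bundle
#'
#' Assembles the feature set consumed by structure-conditioned inference
#' from a poly-alanine merged template: the all-alanine template sequence
#' and per-position amino-acid labels, the atom mask restricted to the
#' N/CA/C/O/CB slots, the matching coordinates, the none-marker for
#' template domain names, and the query-side inputs -- the true merged
#' sequence (original amino acids, X at linker positions) and a
#' single-sequence MSA equal to it, encoding the deliberate absence of any
#' co-evolutionary signal.
#'
#' @param mt a poly-alanine [MergedTemplate-class] (see [toPolyAlanine()]);
#'   a template that still carries side-chain atoms is rejected.
#' @return a [TemplateFeatureBundle-class].
#' @export
buildTemplateFeatures <- function(mt) {
    atoms <- atomTable(mt)
    res <- residueTable(mt)
    if (any(!atoms$atom %in% .FEATURE_SLOTS) ||
        any(atoms$aa[atoms$resno %in% res$index[!res$linker]] != "A"))
        stop("template must be poly-alanine; run toPolyAlanine() first")
    n <- nrow(res)
    tseq <- ifelse(res$linker, "X", "A")
    mask <- matrix(0, n, 5L, dimnames = list(NULL, .FEATURE_SLOTS))
    coords <- array(0, dim = c(n, 5L, 3L))
    pos <- match(atoms$resno, res$index)
    slot <- match(atoms$atom, .FEATURE_SLOTS)
    if (anyNA(pos))
        stop("atom table refers to positions absent from the residue ",
             "table: length mismatch between template and query")
    for (i in seq_along(pos)) {
        mask[pos[i], slot[i]] <- 1
        coords[pos[i], slot[i], ] <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    }
    qseq <- querySequence(mt)
    new("TemplateFeatureBundle",
        templateSequence = paste(tseq, collapse = ""),
        templateAatype = tseq,
        atomMask = mask,
        coordinates = coords,
        templateDomainNames = "none",
        querySequence = qseq,
        msa = qseq)
}

#' Serialize / deserialize a template feature bundle
#'
#' `exportFeatures()` writes a [TemplateFeatureBundle-class] to a versioned
#' JSON document; `importFeatures()` reads it back. The round trip is
#' lossless to full double precision. This on-disk layout is owned by this
#' package (schema version 1); adapters targeting a particular inference
#' engine should consume it rather than any engine-internal format.
#'
#' @param bundle a [TemplateFeatureBundle-class].
#' @param path file path of the JSON document.
#' @return `exportFeatures()`: invisibly, `path`; `importFeatures()`: the
#'   reconstructed [TemplateFeatureBundle-class].
#' @export
exportFeatures <- function(bundle, path) {
    payload <- list(
        schema = "abag-template-features",
        version = .FEATURE_SCHEMA_VERSION,
        n_positions = nchar(bundle@templateSequence),
        template_sequence = bundle@templateSequence,
        template_aatype = bundle@templateAatype,
        atom_slots = .FEATURE_SLOTS,
        atom_mask = bundle@atomMask,
        coordinates = bundle@coordinates,
        template_domain_names = bundle@templateDomainNames,
        query_sequence = bundle@querySequence,
        msa = bundle@msa)
    json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
    writeLines(json, path)
    invisible(path)
}

#' @rdname exportFeatures
#' @export
importFeatures <- function(path) {
    p <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("schema error: unreadable ",
                                           "feature document: ",
                                           conditionMessage(e),
                                           call. = FALSE))
    if (!identical(p$schema, "abag-template-features"))
        stop("schema error: not a template feature document")
    n <- p$n_positions
    if (!is.numeric(n) || nchar(p$template_sequence) != n ||
        length(p$template_aatype) != n)
        stop("schema error: corrupt length field")
    mask <- matrix(as.numeric(p$atom_mask), n, 5L,
                   dimnames = list(NULL, .FEATURE_SLOTS))
    coords <- array(as.numeric(p$coordinates), dim = c(n, 5L, 3L))
    new("TemplateFeatureBundle",
        templateSequence = p$template_sequence,
        templateAatype = as.character(p$template_aatype),
        atomMask = mask,
        coordinates = coords,
        templateDomainNames = as.character(p$template_domain_names),
        querySequence = p$query_sequence,
        msa = as.character(p$msa))
}
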