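## PDB reading/writing, backed by bio3d. The package-internal atom table is
## a flat data.frame (one row per atom, one-letter aa codes); conversion to
## and from bio3d's pdb object happens only here.

.HEAVY_BACKBONE <- c("N", "CA", "C", "O")

.newComplex <- function(atoms, abChains, agChains) {
    rownames(atoms) <- NULL
    new("ComplexStructure", atoms = atoms,
        abChains = as.character(abChains), agChains = as.character(agChains))
}

.emptyAtomTable <- function() {
    data.frame(chain = character(), resno = integer(), insert = character(),
               aa = character(), atom = character(),
               x = numeric(), y = numeric(), z = numeric(),
               occ = numeric(), b = numeric(), elem = character(),
               stringsAsFactors = FALSE)
}

.guessElement <- function(atom) {
    ## first alphabetic character of the atom name; adequate for the heavy
    ## protein atoms this package handles
    sub("^[0-9]*([A-Za-z]).*$", "\\1", atom)
}

#' Read a docked antibody-antigen complex from a PDB file
#'
#' Parses ATOM records, resolves alternate locations to the highest
#' occupancy (ties broken by the alphabetically first altloc label), drops
#' hydrogen atoms by default (as typically done when preparing docking
#' inputs), and assigns the named chains to the antibody and antigen
#' partners.
#'
#' @param path path to a PDB-format file.
#' @param abChains character vector of antibody chain identifiers.
#' @param agChains character vector of antigen chain identifiers.
#' @param dropHydrogens drop hydrogen/deuterium atoms on read (default TRUE).
#' @param keepChains if TRUE (default) chains other than the requested ones
#'   are silently discarded; they never enter the structure.
#' @return a [ComplexStructure-class].
#' @examples
#' cx <- makeToyComplex(8, 8, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeComplexPDB(cx, f)
#' cx2 <- readComplexPDB(f, abChains = "H", agChains = "G")
#' @export
readComplexPDB <- function(path, abChains, agChains,
                           dropHydrogens = TRUE, keepChains = TRUE) {
    if (!file.exists(path))
        stop("file not found: ", path)
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e)
                        stop("PDB format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
    wanted <- c(abChains, agChains)
    missing <- setdiff(wanted, unique(at$chain))
    if (length(missing))
        stop("chain not found: ", paste(missing, collapse = ", "))
    at <- at[at$chain %in% wanted, , drop = FALSE]
    if (dropHydrogens) {
        elem <- ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                       .guessElement(at$elety), at$elesy)
        at <- at[!toupper(elem) %in% c("H", "D"), , drop = FALSE]
    }
    ## altloc resolution: highest occupancy, ties to first label
    at$alt[is.na(at$alt)] <- ""
    at$insert[is.na(at$insert)] <- ""
    if (any(nzchar(at$alt))) {
        key <- paste(at$chain, at$resno, at$insert, at$elety)
        ord <- order(key, -at$o, at$alt)
        at <- at[ord, , drop = FALSE]
        at <- at[!duplicated(paste(at$chain, at$resno, at$insert,
                                   at$elety)), , drop = FALSE]
        at <- at[order(match(paste(at$chain, at$resno, at$insert),
                             unique(paste(at$chain, at$resno,
                                          at$insert)))), , drop = FALSE]
    }
    aa <- suppressWarnings(bio3d::aa321(at$resid))
    aa[is.na(aa) | !aa %in% .AA1] <- "X"
    atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                        insert = at$insert, aa = aa, atom = at$elety,
                        x = at$x, y = at$y, z = at$z,
                        occ = ifelse(is.na(at$o), 1, at$o),
                        b = ifelse(is.na(at$b), 0, at$b),
                        elem = toupper(.guessElement(at$elety)),
                        stringsAsFactors = FALSE)
    .newComplex(atoms, abChains, agChains)
}

#' Write a structure to a PDB file
#'
#' Emits standard ATOM records with a TER record between chains. For a
#' [MergedTemplate-class], linker residues carry no atoms and are omitted
#' from the output by default; with \code{emitLinkerUNK = TRUE} they are
#' written as atom-less placeholder is impossible in PDB, so a single
#' zero-occupancy CA marker named UNK is emitted instead.
#'
#' @param x a [ComplexStructure-class] or [MergedTemplate-class].
#' @param path output file path.
#' @param emitLinkerUNK for merged templates, emit UNK CA markers at linker
#'   positions (default FALSE: linkers are skipped).
#' @return invisibly, \code{path}.
#' @export
writeComplexPDB <- function(x, path, emitLinkerUNK = FALSE) {
    atoms <- atomTable(x)
    if (!nrow(atoms))
        stop("no atoms to write")
    extra <- NULL
    if (is(x, "MergedTemplate") && emitLinkerUNK) {
        lp <- linkerPositions(x)
        if (length(lp))
            extra <- data.frame(chain = x@mergedChainId, resno = lp,
                                insert = "", aa = "X", atom = "CA",
                                x = 0, y = 0, z = 0, occ = 0, b = 0,
                                elem = "C", stringsAsFactors = FALSE)
    }
    if (!is.null(extra)) {
        atoms <- rbind(atoms, extra)
        atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
    }
    resid3 <- vapply(atoms$aa, function(a) {
        if (a == "X") "UNK" else bio3d::aa123(a)
    }, character(1))
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(atoms)),
                     resno = atoms$resno, resid = resid3,
                     insert = ifelse(nzchar(atoms$insert), atoms$insert, ""),
                     elety = atoms$atom, chain = atoms$chain,
                     o = atoms$occ, b = atoms$b)
    invisible(path)
}

#' Reduce a complex to backbone (and optionally C-beta) atoms
#'
#' Retains only N, CA, C, O atoms per residue, plus CB when
#' \code{includeCB} and the residue has one. Residues missing some backbone
#' atoms are kept with whatever exists (a message lists them). The residue
#' count is never changed. The operation is idempotent.
#'
#' @param x a [ComplexStructure-class].
#' @param includeCB also keep C-beta atoms (default TRUE).
#' @return a [ComplexStructure-class] with the reduced atom set.
#' @export
extractBackbone <- function(x, includeCB = TRUE) {
    keep <- .HEAVY_BACKBONE
    if (includeCB) keep <- c(keep, "CB")
    atoms <- atomTable(x)
    out <- atoms[atoms$atom %in% keep, , drop = FALSE]
    key <- function(d) unique(paste(d$chain, d$resno, d$insert))
    lost <- setdiff(key(atoms), key(out))
    if (length(lost))
        message("residues with no backbone atoms dropped entirely: ",
                paste(lost, collapse = "; "))
    bb <- out[out$atom %in% .HEAVY_BACKBONE, , drop = FALSE]
    partial <- names(which(table(paste(bb$chain, bb$resno, bb$insert)) < 4))
    if (length(partial))
        message(length(partial), " residue(s) retained with incomplete ",
                "backbone")
    .newComplex(out, antibodyChains(x), antigenChains(x))
}

## coordinates of one partner ("ab"/"ag"), optionally restricted to an
## atom-name set, returned as an n x 3 matrix with residue/atom keys
.partnerCoords <- function(cx, partner = c("ab", "ag"), atomNames = NULL) {
    partner <- match.arg(partner)
    chains <- if (partner == "ab") antibodyChains(cx) else antigenChains(cx)
    at <- atomTable(cx)
    at <- at[at$chain %in% chains, , drop = FALSE]
    if (!is.null(atomNames))
        at <- at[at$atom %in% atomNames, , drop = FALSE]
    at
}
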