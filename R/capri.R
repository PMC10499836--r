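## CAPRI-style model quality evaluation: native contacts, interface and
## ligand RMSD via Kabsch superposition, and quality classification.

.resKey <- function(at) paste(at$chain, at$resno, at$insert, sep = ":")

.coordMatrix <- function(at) {
    m <- as.matrix(at[, c("x", "y", "z")])
    rownames(m) <- NULL
    m
}

## squared distances between every row of a and every row of b
.cross2 <- function(a, b) {
    outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
}

#' Cross-partner residue contacts of a complex
#'
#' A residue pair (one antibody residue, one antigen residue) is a contact
#' when any pair of heavy atoms across the two partners lies within
#' \code{cutoff} Angstrom (closed interval: a pair exactly at the cutoff
#' counts). Contacts are never formed within a partner.
#'
#' @param cx a [ComplexStructure-class].
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5).
#' @return data.frame with columns \code{ab} and \code{ag} (residue keys
#'   \code{chain:resno:insert}), one row per contact pair, with the cutoff
#'   stored in \code{attr(, "cutoff")}.
#' @export
contactPairs <- function(cx, cutoff = 5.0) {
    abAt <- .partnerCoords(cx, "ab")
    agAt <- .partnerCoords(cx, "ag")
    abAt <- abAt[abAt$elem != "H", , drop = FALSE]
    agAt <- agAt[agAt$elem != "H", , drop = FALSE]
    if (!nrow(abAt) || !nrow(agAt))
        stop("both partners must have atoms")
    d2 <- .cross2(.coordMatrix(abAt), .coordMatrix(agAt))
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    pairs <- unique(data.frame(ab = .resKey(abAt)[hit[, 1]],
                               ag = .resKey(agAt)[hit[, 2]],
                               stringsAsFactors = FALSE))
    rownames(pairs) <- NULL
    attr(pairs, "cutoff") <- cutoff
    pairs
}

.pairKey <- function(pairs) paste(pairs$ab, pairs$ag, sep = "|")

#' Fraction of native contacts preserved in a model
#'
#' The fraction of the reference (crystal) cross-partner residue contacts,
#' at a heavy-atom cutoff of \code{cutoff} Angstrom, that are also present
#' in the model. Residues correspond by (chain, residue number, insertion
#' code); model and reference must share the same numbering.
#'
#' @param model,reference [ComplexStructure-class] objects with matching
#'   residue numbering.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return fraction in [0, 1].
#' @export
fnat <- function(model, reference, cutoff = 5.0) {
    ref <- contactPairs(reference, cutoff)
    if (!nrow(ref))
        stop("no native contacts in the reference at ", cutoff, " A")
    mod <- contactPairs(model, cutoff)
    length(intersect(.pairKey(ref), .pairKey(mod))) / nrow(ref)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimizing
#' the RMSD between \code{moving \%*\% R + t} and \code{fixed} over paired
#' coordinate rows.
#'
#' @param moving,fixed n x 3 coordinate matrices with paired rows, n >= 3
#'   and not collinear.
#' @return list with elements \code{R} (3 x 3 proper rotation,
#'   determinant +1), \code{t} (length-3 translation) and \code{rmsd}.
#' @export
kabschSuperpose <- function(moving, fixed) {
    moving <- as.matrix(moving); fixed <- as.matrix(fixed)
    if (nrow(moving) != nrow(fixed) || ncol(moving) != 3L)
        stop("paired n x 3 coordinate matrices required")
    n <- nrow(moving)
    if (n < 3L)
        stop("at least 3 paired atoms required for superposition")
    mc <- colMeans(moving); fc <- colMeans(fixed)
    X <- sweep(moving, 2, mc); Y <- sweep(fixed, 2, fc)
    C <- crossprod(X, Y)
    sv <- svd(C)
    xs <- svd(X, nu = 0, nv = 0)$d
    if (xs[2] < 1e-8 * max(xs[1], 1))
        stop("degenerate (collinear) geometry: superposition ill-defined")
    s <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
    t <- fc - as.vector(mc %*% R)
    fittedRmsd <- sqrt(mean(rowSums((X %*% R - Y)^2)))
    list(R = R, t = t, rmsd = fittedRmsd)
}

#' @rdname kabschSuperpose
#' @param transform result of `kabschSuperpose()`.
#' @param coords n x 3 matrix to transform.
#' @export
applySuperposition <- function(transform, coords) {
    sweep(as.matrix(coords) %*% transform$R, 2, -transform$t)
}

.atomSetNames <- function(atomSet = c("backbone", "CA")) {
    atomSet <- match.arg(atomSet)
    if (atomSet == "backbone") c("N", "CA", "C", "O") else "CA"
}

## atoms of cx matched one-to-one against atoms of ref by
## (chain, resno, insert, atom name); returns paired coordinate matrices
.pairedCoords <- function(model, reference, keys, atomNames) {
    sel <- function(cx) {
        at <- atomTable(cx)
        at <- at[at$atom %in% atomNames & .resKey(at) %in% keys, ,
                 drop = FALSE]
        at
    }
    mAt <- sel(model); rAt <- sel(reference)
    mKey <- paste(.resKey(mAt), mAt$atom)
    rKey <- paste(.resKey(rAt), rAt$atom)
    common <- intersect(mKey, rKey)
    if (!length(common))
        stop("no shared atoms between model and reference selection")
    list(model = .coordMatrix(mAt[match(common, mKey), , drop = FALSE]),
         reference = .coordMatrix(rAt[match(common, rKey), , drop = FALSE]))
}

#' Interface residues of a reference complex
#'
#' Residues of either partner having any cross-partner heavy atom within
#' \code{cutoff} Angstrom, evaluated on the reference structure only.
#'
#' @param reference a [ComplexStructure-class].
#' @param cutoff interface distance cutoff in Angstrom (default 10).
#' @return character vector of residue keys \code{chain:resno:insert}.
#' @export
interfaceResidues <- function(reference, cutoff = 10.0) {
    pairs <- contactPairs(reference, cutoff)
    unique(c(pairs$ab, pairs$ag))
}

#' Interface RMSD of a model against a reference
#'
#' RMSD over the backbone (or CA-only) atoms of the reference-defined
#' interface residues, after best-fit superposition of those same atoms.
#' The interface is defined on the reference alone: residues of either
#' partner with a cross-partner heavy atom within \code{interfaceCutoff}
#' Angstrom. By default the fit is joint over both partners' interface
#' atoms; \code{fit = "antigen"} restricts the superposition to
#' antigen-side interface atoms while still measuring over all interface
#' atoms.
#'
#' @param model,reference [ComplexStructure-class] objects with matching
#'   residue numbering.
#' @param interfaceCutoff interface definition cutoff in Angstrom
#'   (default 10).
#' @param atomSet \code{"backbone"} (N, CA, C, O) or \code{"CA"}.
#' @param fit \code{"joint"} (default) or \code{"antigen"}.
#' @return RMSD in Angstrom.
#' @export
interfaceRMSD <- function(model, reference, interfaceCutoff = 10.0,
                          atomSet = c("backbone", "CA"),
                          fit = c("joint", "antigen")) {
    fit <- match.arg(fit)
    atomNames <- .atomSetNames(atomSet)
    keys <- interfaceResidues(reference, interfaceCutoff)
    if (!length(keys))
        stop("empty interface at ", interfaceCutoff, " A")
    paired <- .pairedCoords(model, reference, keys, atomNames)
    if (fit == "joint") {
        kabschSuperpose(paired$model, paired$reference)$rmsd
    } else {
        agKeys <- intersect(keys, .resKey(.partnerCoords(reference, "ag")))
        agPaired <- .pairedCoords(model, reference, agKeys, atomNames)
        tr <- kabschSuperpose(agPaired$model, agPaired$reference)
        moved <- applySuperposition(tr, paired$model)
        sqrt(mean(rowSums((moved - paired$reference)^2)))
    }
}

#' Ligand RMSD of a model against a reference
#'
#' The antigen of the model is superposed onto the antigen of the
#' reference (best fit over the chosen atom set); the RMSD of the antibody
#' atoms is then reported in that frame, without refitting. This measures
#' how far the mobile partner (the antibody) sits from its native pose
#' relative to the antigen.
#'
#' @inheritParams interfaceRMSD
#' @return RMSD in Angstrom.
#' @export
ligandRMSD <- function(model, reference, atomSet = c("backbone", "CA")) {
    atomNames <- .atomSetNames(atomSet)
    agKeys <- intersect(.resKey(.partnerCoords(model, "ag")),
                        .resKey(.partnerCoords(reference, "ag")))
    abKeys <- intersect(.resKey(.partnerCoords(model, "ab")),
                        .resKey(.partnerCoords(reference, "ab")))
    if (!length(agKeys) || !length(abKeys))
        stop("both partners are required for ligand RMSD")
    agPaired <- .pairedCoords(model, reference, agKeys, atomNames)
    abPaired <- .pairedCoords(model, reference, abKeys, atomNames)
    tr <- kabschSuperpose(agPaired$model, agPaired$reference)
    moved <- applySuperposition(tr, abPaired$model)
    sqrt(mean(rowSums((moved - abPaired$reference)^2)))
}

#' CAPRI quality classification from fnat, iRMSD and lRMSD
#'
#' Applies the standard CAPRI class criteria (Lensink & Wodak):
#' \itemize{
#'   \item High: fnat >= 0.5 and (lRMSD <= 1.0 or iRMSD <= 1.0)
#'   \item Medium: fnat >= 0.3 and (lRMSD <= 5.0 or iRMSD <= 2.0)
#'   \item Acceptable: fnat >= 0.1 and (lRMSD <= 10.0 or iRMSD <= 4.0)
#'   \item Incorrect: otherwise
#' }
#' The classification is monotone: improving any single metric never
#' lowers the class.
#'
#' @param fnat fraction of native contacts in [0, 1] (vectorized).
#' @param irmsd interface RMSD, Angstrom.
#' @param lrmsd ligand RMSD, Angstrom.
#' @return ordered factor (see [capriFactor()]).
#' @examples
#' classifyCapri(0.6, 0.8, 0.5)   # High
#' classifyCapri(0.15, 3.5, 12.0) # Acceptable via the iRMSD branch
#' @export
classifyCapri <- function(fnat, irmsd, lrmsd) {
    stopifnot(length(fnat) == length(irmsd),
              length(fnat) == length(lrmsd))
    cls <- rep("Incorrect", length(fnat))
    cls[fnat >= 0.1 & (lrmsd <= 10.0 | irmsd <= 4.0)] <- "Acceptable"
    cls[fnat >= 0.3 & (lrmsd <= 5.0 | irmsd <= 2.0)] <- "Medium"
    cls[fnat >= 0.5 & (lrmsd <= 1.0 | irmsd <= 1.0)] <- "High"
    capriFactor(cls)
}

#' Fraction of template contacts conserved in a rebuilt model
#'
#' Given a model rebuilt from a docked template (e.g. by
#' structure-conditioned inference), the fraction of the template's
#' cross-partner contacts that are retained in the rebuilt model. The
#' template plays the role of the reference contact set; the computation
#' shares its contact engine with [fnat()].
#'
#' @param model the rebuilt [ComplexStructure-class].
#' @param template the docked template [ComplexStructure-class].
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return fraction in [0, 1].
#' @export
conservedContactFraction <- function(model, template, cutoff = 5.0) {
    tmpl <- contactPairs(template, cutoff)
    if (!nrow(tmpl))
        stop("template has no cross-partner contacts at ", cutoff, " A")
    fnat(model, template, cutoff)
}

#' Full CAPRI quality evaluation of one model
#'
#' Convenience wrapper computing fnat, interface RMSD, ligand RMSD and the
#' CAPRI class of a model against a reference in one call.
#'
#' @inheritParams interfaceRMSD
#' @param contactCutoff fnat contact cutoff, Angstrom (default 5).
#' @return one-row data.frame with columns \code{fnat}, \code{irmsd},
#'   \code{lrmsd}, \code{class}.
#' @export
evaluateQuality <- function(model, reference, contactCutoff = 5.0,
                            interfaceCutoff = 10.0,
                            atomSet = c("backbone", "CA")) {
    f <- fnat(model, reference, contactCutoff)
    i <- interfaceRMSD(model, reference, interfaceCutoff, atomSet)
    l <- ligandRMSD(model, reference, atomSet)
    data.frame(fnat = f, irmsd = i, lrmsd = l,
               class = as.character(classifyCapri(f, i, l)),
               stringsAsFactors = FALSE)
}

#' Apply a rigid transform to a whole complex or to one partner
#'
#' Rotates (about the origin) and translates the atoms of a complex; with
#' \code{partner} set, only the antibody or antigen atoms are moved, which
#' is how rigid-body decoys are generated.
#'
#' @param cx a [ComplexStructure-class].
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation vector.
#' @param partner \code{"both"} (default), \code{"ab"} or \code{"ag"}.
#' @param center optional length-3 vector about which to rotate (default:
#'   origin; commonly the moved partner's centroid).
#' @return the transformed [ComplexStructure-class].
#' @export
applyRigid <- function(cx, R = diag(3), t = c(0, 0, 0),
                       partner = c("both", "ab", "ag"), center = NULL) {
    partner <- match.arg(partner)
    at <- atomTable(cx)
    move <- switch(partner,
                   both = rep(TRUE, nrow(at)),
                   ab = at$chain %in% antibodyChains(cx),
                   ag = at$chain %in% antigenChains(cx))
    xyz <- .coordMatrix(at[move, , drop = FALSE])
    if (is.null(center)) center <- c(0, 0, 0)
    xyz <- sweep(sweep(xyz, 2, center) %*% R, 2, -(center + t))
    at$x[move] <- xyz[, 1]; at$y[move] <- xyz[, 2]; at$z[move] <- xyz[, 3]
    .newComplex(at, antibodyChains(cx), antigenChains(cx))
}

#' Uniformly random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (via quaternion sampling) using
#' the current RNG state, so results are reproducible under
#' \code{set.seed()}.
#'
#' @param angle optional rotation angle in degrees; when given, the axis is
#'   drawn uniformly on the sphere and the rotation has exactly this
#'   magnitude.
#' @return 3 x 3 proper rotation matrix.
#' @export
randomRotation <- function(angle = NULL) {
    if (is.null(angle)) {
        q <- stats::rnorm(4)
        q <- q / sqrt(sum(q^2))
    } else {
        ax <- stats::rnorm(3)
        ax <- ax / sqrt(sum(ax^2))
        half <- angle * pi / 360
        q <- c(cos(half), sin(half) * ax)
    }
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
}
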