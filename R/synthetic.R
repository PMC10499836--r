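## Deterministic generators: idealized toy complexes, rigid-body decoy
## ensembles spanning the CAPRI quality classes, and quality-correlated
## mock confidence metrics. These stand in for docking programs and for
## neural-network inference so the whole rescoring pipeline runs at desk
## scale; they are synthetic by construction and documented as such.

## Natural-extension-reference-frame placement: position atom D given the
## positions of A, B, C, the bond length C-D, the angle B-C-D and the
## dihedral A-B-C-D (degrees).
.nerf <- function(a, b, c, r, theta, chi) {
    theta <- theta * pi / 180
    chi <- chi * pi / 180
    cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                              u[3] * v[1] - u[1] * v[3],
                              u[1] * v[2] - u[2] * v[1])
    bc <- c - b
    bc <- bc / sqrt(sum(bc^2))
    n <- cross(b - a, bc)
    n <- n / sqrt(sum(n^2))
    m <- cbind(bc, cross(n, bc), n)
    d <- c(-r * cos(theta), r * sin(theta) * cos(chi),
           r * sin(theta) * sin(chi))
    as.vector(m %*% d) + c
}

## ideal backbone internal coordinates (Engh-Huber-like) and helical
## torsions phi=-57, psi=-47, omega=180
.IDEAL <- list(bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
               aNCAC = 111.2, aCACN = 116.2, aCNCA = 121.7, aCACO = 120.8,
               phi = -57, psi = -47, omega = 180)

## rotate a helix atom matrix into a canonical frame: centroid at the
## origin, principal (helix) axis along +x, first CA fixing the y side
.canonicalFrame <- function(xyz, ca) {
    ctr <- colMeans(ca)
    cc <- sweep(ca, 2, ctr)
    v1 <- svd(cc, nu = 0, nv = 3)$v[, 1]
    if (sum((ca[nrow(ca), ] - ca[1, ]) * v1) < 0) v1 <- -v1
    r1 <- cc[1, ] - sum(cc[1, ] * v1) * v1
    v2 <- r1 / sqrt(sum(r1^2))
    v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    sweep(xyz, 2, ctr) %*% cbind(v1, v2, v3)
}

## poly-alanine alpha helix of n residues; returns atom table rows for one
## chain (atoms N, CA, C, O, CB per residue)
.idealHelix <- function(n, chain) {
    g <- .IDEAL
    pos <- vector("list", n)
    N <- c(0, 0, 0)
    CA <- c(g$bNCA, 0, 0)
    C <- .nerf(c(0, -1, 0), N, CA, g$bCAC, g$aNCAC, 60)
    for (i in seq_len(n)) {
        O <- .nerf(N, CA, C, g$bCO, g$aCACO, g$psi + 180)
        CB <- idealCB(N, CA, C)
        pos[[i]] <- rbind(N = N, CA = CA, C = C, O = O, CB = CB)
        if (i < n) {
            N2 <- .nerf(N, CA, C, g$bCN, g$aCACN, g$psi)
            CA2 <- .nerf(CA, C, N2, g$bNCA, g$aCNCA, g$omega)
            C2 <- .nerf(C, N2, CA2, g$bCAC, g$aNCAC, g$phi)
            N <- N2; CA <- CA2; C <- C2
        }
    }
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
        p <- pos[[i]]
        data.frame(chain = chain, resno = i, insert = "", aa = "A",
                   atom = rownames(p), x = p[, 1], y = p[, 2], z = p[, 3],
                   occ = 1, b = 0,
                   elem = substr(rownames(p), 1, 1),
                   stringsAsFactors = FALSE)
    }))
    xyz <- .canonicalFrame(as.matrix(out[, c("x", "y", "z")]),
                           as.matrix(out[out$atom == "CA",
                                         c("x", "y", "z")]))
    out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
    out
}

#' Build an idealized toy antibody-antigen complex
#'
#' Constructs two poly-alanine alpha helices with ideal backbone geometry
#' (N, CA, C, O, CB per residue) packed side by side: the antigen helix is
#' spun about its own axis and shifted axially by seed-determined random
#' amounts, then slid toward the antibody until the closest heavy-atom
#' approach equals \code{approach} Angstrom. The parallel packing keeps
#' the contact seam running along the full helix length, guaranteeing at
#' least 3 native contact pairs at the 5 Angstrom cutoff. Output is
#' bitwise-deterministic for a fixed seed.
#'
#' @param nAb,nAg residues in the antibody ("H") and antigen ("G")
#'   chains, each >= 4 (defaults 12).
#' @param seed integer seed controlling the antigen orientation.
#' @param approach target closest heavy-atom distance in Angstrom
#'   (default 4).
#' @return a [ComplexStructure-class].
#' @export
makeToyComplex <- function(nAb = 12L, nAg = 12L, seed = 1L,
                           approach = 4.0) {
    stopifnot(nAb >= 4L, nAg >= 4L)
    ab <- .idealHelix(nAb, "H")
    ag <- .idealHelix(nAg, "G")
    set.seed(seed)
    ## spin about the helix (x) axis plus a small axial slide; the two
    ## helices stay parallel so the contact seam spans their full length
    spin <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(1, 0, 0,
                  0, cos(spin), -sin(spin),
                  0, sin(spin), cos(spin)), 3, 3, byrow = TRUE)
    axial <- c(stats::runif(1, -1.5, 1.5), 0, 0)
    agXyz <- as.matrix(ag[, c("x", "y", "z")])
    agXyz <- sweep(agXyz, 2, colMeans(agXyz))
    agXyz <- sweep(agXyz %*% R, 2, -axial)
    abXyz <- as.matrix(ab[, c("x", "y", "z")])
    ## slide the antigen along +y until the closest approach hits target
    dir <- c(0, 1, 0)
    minDist <- function(off) {
        shifted <- sweep(agXyz, 2, -(colMeans(abXyz) + off * dir))
        sqrt(min(.cross2(abXyz, shifted)))
    }
    lo <- 0; hi <- 60
    while (minDist(hi) < approach) hi <- hi + 20
    for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (minDist(mid) < approach) lo <- mid else hi <- mid
    }
    off <- hi
    build <- function(off) {
        shifted <- sweep(agXyz, 2, -(colMeans(abXyz) + off * dir))
        ag$x <- shifted[, 1]; ag$y <- shifted[, 2]; ag$z <- shifted[, 3]
        .newComplex(rbind(ab, ag), "H", "G")
    }
    cx <- build(off)
    ## tighten the packing until at least 3 residue contact pairs exist,
    ## never closer than a 2.6 A clash floor
    while (nrow(contactPairs(cx)) < 3L && minDist(off - 0.2) > 2.6) {
        off <- off - 0.2
        cx <- build(off)
    }
    cx
}

#' Default rigid-perturbation ladder for decoy generation
#'
#' Pairs of (rotation magnitude in degrees, translation magnitude in
#' Angstrom) applied to the antibody of a reference complex. The default
#' ladder was calibrated once on the toy complex so that decoy ensembles
#' span all four CAPRI quality classes, from unperturbed (High) to far
#' displaced (Incorrect), and is kept frozen.
#'
#' @return data.frame with columns \code{rot} (degrees) and \code{trans}
#'   (Angstrom).
#' @export
defaultLadder <- function() {
    data.frame(rot = c(0, 6, 14, 25, 35, 45, 60, 80, 100, 120),
               trans = c(0, 1.5, 4.5, 12, 18, 24, 30, 40, 50, 60))
}

#' Generate a rigid-body decoy ensemble with ground-truth quality
#'
#' Creates decoys of a reference complex by rigidly perturbing the
#' antibody (the antigen frame stays fixed, mirroring the ligand-RMSD
#' convention): for each model, a ladder entry supplies the rotation and
#' translation magnitudes, while the rotation axis and translation
#' direction are drawn at random. Each decoy is evaluated against the
#' reference with the CAPRI metrics, so the ensemble carries ground-truth
#' quality labels.
#'
#' @param reference a [ComplexStructure-class].
#' @param nModels number of decoys (default 50); ladder entries are
#'   cycled.
#' @param ladder data.frame with columns \code{rot}, \code{trans} (default
#'   [defaultLadder()]).
#' @param seed integer seed.
#' @param atomSet atom set for the RMSD metrics (default \code{"backbone"}).
#' @return list with \code{decoys} (list of [ComplexStructure-class]) and
#'   \code{metrics} (data.frame: model_id, rot, trans, fnat, irmsd, lrmsd,
#'   class).
#' @export
makeDecoys <- function(reference, nModels = 50L, ladder = defaultLadder(),
                       seed = 1L, atomSet = "backbone") {
    stopifnot(all(ladder$rot >= 0), all(ladder$trans >= 0))
    set.seed(seed)
    entries <- ladder[((seq_len(nModels) - 1L) %% nrow(ladder)) + 1L, ]
    abAt <- .partnerCoords(reference, "ab")
    center <- colMeans(.coordMatrix(abAt))
    decoys <- vector("list", nModels)
    rows <- vector("list", nModels)
    for (i in seq_len(nModels)) {
        R <- randomRotation(angle = entries$rot[i])
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        d <- applyRigid(reference, R, entries$trans[i] * dir,
                        partner = "ab", center = center)
        q <- evaluateQuality(d, reference, atomSet = atomSet)
        decoys[[i]] <- d
        rows[[i]] <- cbind(data.frame(model_id = sprintf("m%03d", i),
                                      rot = entries$rot[i],
                                      trans = entries$trans[i]), q)
    }
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
    list(decoys = decoys, metrics = metrics)
}

#' Mock confidence metrics correlated with true model quality
#'
#' Emulates the confidence output of structure-conditioned inference for a
#' decoy ensemble: a latent true-quality score, \code{-log(1 + lRMSD)}, is
#' standardized within the ensemble; each of the two metrics is then
#' \code{signalStrength * quality + noise}, with the two noise terms drawn
#' from a bivariate normal with cross-correlation \code{agreement} and SD
#' \code{noiseSd}, and the results squashed into [0, 1] by the logistic
#' function. With \code{signalStrength = 0} the metrics are pure noise.
#'
#' @param metrics decoy metrics data.frame from [makeDecoys()] (needs
#'   \code{model_id} and \code{lrmsd}).
#' @param signalStrength real >= 0 (default 1).
#' @param agreement cross-correlation of the two metrics' noise in [0, 1]
#'   (default 0.9; high agreement between the two confidence metrics is
#'   characteristic of good models).
#' @param noiseSd noise standard deviation > 0 (default 0.5).
#' @param seed integer seed.
#' @param systemId,method labels for the output records.
#' @return data.frame with columns \code{system_id}, \code{model_id},
#'   \code{method}, \code{plddt}, \code{ptmscore}.
#' @export
mockConfidences <- function(metrics, signalStrength = 1, agreement = 0.9,
                            noiseSd = 0.5, seed = 1L,
                            systemId = "sys1", method = "synthetic") {
    stopifnot(signalStrength >= 0, agreement >= 0, agreement <= 1,
              noiseSd > 0)
    set.seed(seed)
    n <- nrow(metrics)
    quality <- zscores(-log1p(metrics$lrmsd))
    e1 <- stats::rnorm(n)
    e2 <- agreement * e1 + sqrt(1 - agreement^2) * stats::rnorm(n)
    plddt <- stats::plogis(signalStrength * quality + noiseSd * e1)
    ptm <- stats::plogis(signalStrength * quality + noiseSd * e2)
    data.frame(system_id = systemId, model_id = metrics$model_id,
               method = method, plddt = plddt, ptmscore = ptm,
               stringsAsFactors = FALSE)
}

#' Generate a full synthetic labeled decoy benchmark
#'
#' Builds \code{nSystems} toy complexes, a rigid-body decoy ensemble for
#' each, mock confidence metrics with the requested signal strength, and a
#' signal-free mock docking score, then assembles the labeled decoy table
#' consumed by the enrichment analytics. The rebuilt-model variant of each
#' decoy is emulated by a small extra rigid jitter of the antibody (the
#' synthetic analogue of structural refinement), and its quality is
#' re-evaluated, so the two per-model quality labels are genuinely
#' distinct. Optionally writes reference/decoy PDB files and TSV tables to
#' \code{dir}.
#'
#' @param nSystems number of systems (default 20).
#' @param nModels decoys per system (default 50).
#' @param seed integer master seed; per-system seeds are derived from it.
#' @param signalStrength,agreement,noiseSd passed to [mockConfidences()].
#' @param rebuildJitter length-2 numeric c(rot degrees, trans Angstrom)
#'   jitter emulating the rebuild step (default c(2, 0.3)).
#' @param dir optional output directory for PDB/TSV artifacts.
#' @param writePDB when writing to \code{dir}, also write per-decoy PDB
#'   files (default FALSE: only references and tables).
#' @return list with \code{decoyTable} (the labeled decoy table: columns
#'   system_id, model_id, method, docking_score, composite,
#'   quality_docking, quality_af2, plus the underlying metrics),
#'   \code{confidences}, and \code{references} (list of toy complexes).
#' @export
makeBenchmark <- function(nSystems = 20L, nModels = 50L, seed = 1L,
                          signalStrength = 1, agreement = 0.9,
                          noiseSd = 0.5, rebuildJitter = c(2, 0.3),
                          dir = NULL, writePDB = FALSE) {
    tables <- vector("list", nSystems)
    confs <- vector("list", nSystems)
    refs <- vector("list", nSystems)
    for (s in seq_len(nSystems)) {
        sysSeed <- as.integer((as.numeric(seed) * 1000 + s) %% 2147483000)
        sysId <- sprintf("sys%03d", s)
        ref <- makeToyComplex(seed = sysSeed)
        dk <- makeDecoys(ref, nModels = nModels, seed = sysSeed + 1L)
        conf <- mockConfidences(dk$metrics, signalStrength, agreement,
                                noiseSd, seed = sysSeed + 2L,
                                systemId = sysId)
        scored <- suppressWarnings(compositeScores(conf))
        set.seed(sysSeed + 3L)
        dockingScore <- zscores(stats::rnorm(nModels))
        ## rebuilt-model variant: small extra rigid jitter, re-evaluated
        af2Class <- character(nModels)
        abCenter <- colMeans(.coordMatrix(.partnerCoords(ref, "ab")))
        for (i in seq_len(nModels)) {
            R <- randomRotation(angle = rebuildJitter[1])
            dirv <- stats::rnorm(3)
            dirv <- dirv / sqrt(sum(dirv^2))
            rb <- applyRigid(dk$decoys[[i]], R, rebuildJitter[2] * dirv,
                             partner = "ab", center = abCenter)
            q <- evaluateQuality(rb, ref)
            af2Class[i] <- q$class
        }
        tables[[s]] <- data.frame(
            system_id = sysId, model_id = dk$metrics$model_id,
            method = "synthetic",
            docking_score = dockingScore,
            composite = scored$composite,
            quality_docking = dk$metrics$class,
            quality_af2 = af2Class,
            fnat = dk$metrics$fnat, irmsd = dk$metrics$irmsd,
            lrmsd = dk$metrics$lrmsd,
            stringsAsFactors = FALSE)
        confs[[s]] <- conf
        refs[[s]] <- ref
        if (!is.null(dir)) {
            sysDir <- file.path(dir, sysId)
            dir.create(sysDir, recursive = TRUE, showWarnings = FALSE)
            writeComplexPDB(ref, file.path(sysDir, "reference.pdb"))
            if (writePDB)
                for (i in seq_len(nModels))
                    writeComplexPDB(dk$decoys[[i]],
                                    file.path(sysDir,
                                              paste0(dk$metrics$model_id[i],
                                                     ".pdb")))
        }
    }
    decoyTable <- do.call(rbind, tables)
    confidences <- do.call(rbind, confs)
    rownames(decoyTable) <- rownames(confidences) <- NULL
    if (!is.null(dir)) {
        utils::write.table(decoyTable, file.path(dir, "decoys.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        utils::write.table(confidences, file.path(dir, "confidences.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    list(decoyTable = decoyTable, confidences = confidences,
         references = refs)
}
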