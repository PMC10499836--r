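## Fixtures are built in code; oracles here are deliberately independent of
## the package's computation paths (brute-force loops, bio3d fits).

## a complex assembled from explicit residue specs:
## list(chain=, resno=, aa=, atoms=data.frame(atom, x, y, z))
buildComplex <- function(residues, abChains, agChains) {
    rows <- lapply(residues, function(r) {
        data.frame(chain = r$chain, resno = r$resno, insert = "",
                   aa = r$aa, atom = r$atoms$atom,
                   x = r$atoms$x, y = r$atoms$y, z = r$atoms$z,
                   occ = 1, b = 0,
                   elem = substr(r$atoms$atom, 1, 1),
                   stringsAsFactors = FALSE)
    })
    AbAgRescore:::.newComplex(do.call(rbind, rows), abChains, agChains)
}

## one residue with a single CA atom at a point
caResidue <- function(chain, resno, pos, aa = "A") {
    list(chain = chain, resno = resno, aa = aa,
         atoms = data.frame(atom = "CA",
                            x = pos[1], y = pos[2], z = pos[3]))
}

## brute-force O(n^2) cross-partner residue contact oracle
bruteContacts <- function(cx, cutoff = 5.0) {
    at <- atomTable(cx)
    at <- at[at$elem != "H", ]
    ab <- at[at$chain %in% antibodyChains(cx), ]
    ag <- at[at$chain %in% antigenChains(cx), ]
    key <- function(d) paste(d$chain, d$resno, d$insert, sep = ":")
    out <- character()
    for (ra in unique(key(ab))) {
        A <- as.matrix(ab[key(ab) == ra, c("x", "y", "z")])
        for (rg in unique(key(ag))) {
            B <- as.matrix(ag[key(ag) == rg, c("x", "y", "z")])
            hit <- FALSE
            for (i in seq_len(nrow(A)))
                for (j in seq_len(nrow(B)))
                    if (sqrt(sum((A[i, ] - B[j, ])^2)) <= cutoff)
                        hit <- TRUE
            if (hit) out <- c(out, paste(ra, rg, sep = "|"))
        }
    }
    sort(out)
}

## superposition oracle via bio3d's least-squares fit
bio3dFit <- function(moving, fixed) {
    xyzM <- as.vector(t(moving))
    xyzF <- as.vector(t(fixed))
    fitted <- bio3d::fit.xyz(fixed = xyzF, mobile = xyzM,
                             fixed.inds = seq_along(xyzF),
                             mobile.inds = seq_along(xyzM))
    matrix(fitted, ncol = 3, byrow = TRUE)
}

## exhaustive concordant-pair AUC oracle (half credit for ties)
bruteAUC <- function(pos, neg) {
    s <- 0
    for (p in pos)
        for (n in neg)
            s <- s + (p > n) + 0.5 * (p == n)
    s / (length(pos) * length(neg))
}

## random rigid transform of a whole complex (both partners jointly)
jointTransform <- function(cx) {
    R <- randomRotation()
    t <- stats::rnorm(3, sd = 20)
    applyRigid(cx, R, t)
}

rmsdOf <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
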