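polyalaFixture <- function(seed = 1, linkerLength = 10) {
    cx <- makeToyComplex(8, 8, seed = seed)
    mergeChains(cx, "linker", linkerLength = linkerLength)
}

test_that("toPolyAlanine leaves the alanine atom set, relabels residues, keeps linkers", {
    lys <- list(chain = "H", resno = 1, aa = "K",
                atoms = data.frame(
                    atom = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE",
                             "NZ"),
                    x = c(0, 1.46, 2.0, 1.5, 1.9, 3, 4, 5, 6),
                    y = c(0, 0, 1.3, 2.4, -1.3, -2, -3, -4, -5), z = 0))
    ag <- list(chain = "G", resno = 1, aa = "A",
               atoms = data.frame(atom = c("N", "CA", "C", "O", "CB"),
                                  x = c(0, 1.46, 2.0, 1.5, 1.9),
                                  y = c(8, 8, 9.3, 10.4, 6.7), z = 0))
    cx <- buildComplex(list(lys, ag), "H", "G")
    mt <- mergeChains(cx, "linker", linkerLength = 5)
    pa <- toPolyAlanine(mt)
    at <- atomTable(pa)
    expect_equal(sum(at$resno == 1), 5L)          # Lys stripped to 5 atoms
    expect_setequal(at$atom[at$resno == 1], c("N", "CA", "C", "O", "CB"))
    expect_true(all(at$aa == "A"))
    res <- residueTable(pa)
    expect_equal(res$aa[res$linker], rep("X", 5)) # linkers untouched
    expect_equal(res$queryAa[1], "K")             # query keeps the original
})

test_that("glycine gains an ideal C-beta; construction is rigid-equivariant", {
    gly <- list(chain = "H", resno = 1, aa = "G",
                atoms = data.frame(
                    atom = c("N", "CA", "C", "O"),
                    x = c(0.000, 1.458, 2.009, 1.383),
                    y = c(0.000, 0.000, 1.420, 2.411),
                    z = c(0, 0, 0, 0)))
    ag <- caResidue("G", 1, c(0, 8, 0))
    cx <- buildComplex(list(gly, ag), "H", "G")
    mt <- mergeChains(cx, "linker", linkerLength = 3)
    ## (the CA-only antigen stub legitimately warns: no CB constructible)
    pa <- suppressWarnings(toPolyAlanine(mt))
    at <- atomTable(pa)
    cb <- unlist(at[at$resno == 1 & at$atom == "CB", c("x", "y", "z")])
    ca <- unlist(at[at$resno == 1 & at$atom == "CA", c("x", "y", "z")])
    n <- unlist(at[at$resno == 1 & at$atom == "N", c("x", "y", "z")])
    c_ <- unlist(at[at$resno == 1 & at$atom == "C", c("x", "y", "z")])
    expect_equal(sqrt(sum((cb - ca)^2)), 1.522, tolerance = 0.02)
    ang <- function(a, b, c) {
        u <- a - b; v <- c - b
        acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    }
    ## tetrahedral placement: N-CA-CB and C-CA-CB near 110 degrees
    expect_equal(ang(n, ca, cb), 110, tolerance = 5)
    expect_equal(ang(c_, ca, cb), 110, tolerance = 5)

    ## equivariance: CB of a rotated residue equals rotated CB
    set.seed(42)
    for (i in 1:20) {
        R <- randomRotation()
        t <- rnorm(3, sd = 10)
        moved <- idealCB(as.vector(n %*% R + t), as.vector(ca %*% R + t),
                         as.vector(c_ %*% R + t))
        expect_equal(moved, as.vector(cb %*% R + t), tolerance = 1e-10,
                     ignore_attr = TRUE)
    }
})

test_that("toPolyAlanine is idempotent and never moves backbone atoms", {
    mt <- polyalaFixture()
    pa1 <- toPolyAlanine(mt)
    pa2 <- toPolyAlanine(pa1)
    expect_identical(atomTable(pa1), atomTable(pa2))
    bbIn <- atomTable(mt)
    bbIn <- bbIn[bbIn$atom %in% c("N", "CA", "C", "O"), c("x", "y", "z")]
    bbOut <- atomTable(pa1)
    bbOut <- bbOut[bbOut$atom %in% c("N", "CA", "C", "O"),
                   c("x", "y", "z")]
    expect_identical(bbIn, bbOut)  # bitwise equal
})

test_that("feature bundle satisfies the template/query contract", {
    ## 2-chain toy, lengths 3 and 2, linker 50 -> 55 positions
    mk <- function(chain, n, y, aa) lapply(seq_len(n), function(i)
        list(chain = chain, resno = i, aa = aa[i],
             atoms = data.frame(atom = c("N", "CA", "C", "O"),
                                x = c(0, 1.46, 2.0, 1.5) + 4 * i,
                                y = c(0, 0, 1.3, 2.4) + y, z = 0)))
    cx <- buildComplex(c(mk("H", 3, 0, c("K", "G", "F")),
                         mk("G", 2, 7, c("D", "W"))), "H", "G")
    mt <- toPolyAlanine(mergeChains(cx, "linker", linkerLength = 50))
    fb <- buildTemplateFeatures(mt)
    expect_equal(nchar(fb@templateSequence), 55L)
    activePositions <- sum(apply(fb@atomMask, 1, function(r) any(r == 1)))
    expect_equal(activePositions, 5L)
    ## mask-active slots: 5 per real residue, none missing a CB here
    expect_equal(sum(fb@atomMask), 5 * 5)
    expect_equal(fb@msa, fb@querySequence)
    q <- fb@querySequence
    expect_equal(substr(q, 1, 3), "KGF")
    expect_equal(substr(q, 54, 55), "DW")
    expect_true(all(strsplit(substr(q, 4, 53), "")[[1]] == "X"))
    expect_true(all(strsplit(fb@templateSequence, "")[[1]] %in% c("A", "X")))
    expect_equal(fb@templateDomainNames, "none")
    ## linker rows all-zero mask
    expect_true(all(fb@atomMask[4:53, ] == 0))
})

test_that("a residue missing backbone atoms is kept without CB, with a warning", {
    broken <- list(chain = "H", resno = 1, aa = "G",
                   atoms = data.frame(atom = c("CA", "O"),
                                      x = c(0, 1), y = 0, z = 0))
    ag <- caResidue("G", 1, c(0, 6, 0))
    cx <- buildComplex(list(broken, ag), "H", "G")
    mt <- mergeChains(cx, "linker", linkerLength = 2)
    expect_warning(pa <- toPolyAlanine(mt), "no CB constructed")
    expect_false("CB" %in% atomTable(pa)$atom[atomTable(pa)$resno == 1])
})

test_that("feature export/import round trips losslessly; corrupt files are schema errors", {
    mt <- toPolyAlanine(polyalaFixture(seed = 3, linkerLength = 6))
    fb <- buildTemplateFeatures(mt)
    f <- withr::local_tempfile(fileext = ".json")
    exportFeatures(fb, f)
    fb2 <- importFeatures(f)
    expect_equal(fb2@templateSequence, fb@templateSequence)
    expect_equal(fb2@atomMask, fb@atomMask)
    expect_equal(fb2@coordinates, fb@coordinates, tolerance = 1e-12)
    expect_equal(fb2@querySequence, fb@querySequence)
    expect_equal(fb2@msa, fb@msa)

    ## corrupt length field
    doc <- jsonlite::fromJSON(f)
    doc$n_positions <- 3
    writeLines(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE), f)
    expect_error(importFeatures(f), "schema error")
    ## not a feature document at all
    writeLines('{"foo": 1}', f)
    expect_error(importFeatures(f), "schema error")
})
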