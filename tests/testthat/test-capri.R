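twoPoint <- function(d) {
    buildComplex(list(caResidue("H", 1, c(0, 0, 0)),
                      caResidue("H", 2, c(-3.8, 0, 0)),
                      caResidue("G", 1, c(d, 0, 0)),
                      caResidue("G", 2, c(d + 3.8, 0, 0))),
                 "H", "G")
}

test_that("contact cutoff is a closed interval on heavy-atom distance", {
    expect_equal(nrow(contactPairs(twoPoint(4.9))), 1L)
    expect_equal(nrow(contactPairs(twoPoint(5.1))), 0L)
    expect_equal(nrow(contactPairs(twoPoint(5.0))), 1L)   # ties count
})

test_that("contact engine matches the brute-force all-pairs oracle", {
    set.seed(11)
    for (rep in 1:5) {
        ## two random 4x4 residue lattices, close enough to touch
        mk <- function(chain, z) lapply(1:16, function(i)
            caResidue(chain, i,
                      c((i - 1) %% 4 * 3.5 + rnorm(1, sd = 0.8),
                        (i - 1) %/% 4 * 3.5 + rnorm(1, sd = 0.8),
                        z + rnorm(1, sd = 0.8))))
        cx <- buildComplex(c(mk("H", 0), mk("G", 4.5)), "H", "G")
        got <- contactPairs(cx)
        gotKeys <- sort(paste(got$ab, got$ag, sep = "|"))
        expect_equal(gotKeys, bruteContacts(cx))
    }
})

test_that("fnat: identity gives 1, separation gives 0, partial overlap counts pairs", {
    cx <- makeToyComplex(10, 10, seed = 5)
    expect_equal(fnat(cx, cx), 1.0)
    far <- applyRigid(cx, diag(3), c(0, 50, 0), partner = "ab")
    expect_equal(fnat(far, cx), 0.0)
    ## a model preserving a known subset of native pairs
    ref <- buildComplex(c(
        lapply(1:4, function(i) caResidue("H", i, c(i * 3.5, 0, 0))),
        lapply(1:4, function(i) caResidue("G", i, c(i * 3.5, 4.5, 0)))),
        "H", "G")
    expect_equal(nrow(contactPairs(ref)), 4L)
    ## shift two antigen residues out of range -> 2 of 4 pairs kept
    mod <- buildComplex(c(
        lapply(1:4, function(i) caResidue("H", i, c(i * 3.5, 0, 0))),
        lapply(1:4, function(i)
            caResidue("G", i, c(i * 3.5, ifelse(i <= 2, 4.5, 30), 0)))),
        "H", "G")
    expect_equal(fnat(mod, ref), 0.5)
    expect_error(fnat(twoPoint(40), twoPoint(40)), "no native contacts")
})

test_that("Kabsch superposition recovers a known rigid transform", {
    set.seed(7)
    fixed <- matrix(rnorm(30, sd = 5), ncol = 3)
    th <- 37 * pi / 180
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    t <- c(5, -2, 1)
    moving <- sweep(fixed %*% t(R), 2, t)   # inverse-moved copy
    fit <- kabschSuperpose(moving, fixed)
    expect_equal(fit$rmsd, 0, tolerance = 1e-8)
    expect_equal(det(fit$R), 1, tolerance = 1e-10)
    expect_equal(applySuperposition(fit, moving), fixed,
                 tolerance = 1e-8, ignore_attr = TRUE)

    ## the fitted rmsd lower-bounds any random rigid placement
    moving2 <- fixed + matrix(rnorm(30, sd = 0.4), ncol = 3)
    best <- kabschSuperpose(moving2, fixed)$rmsd
    for (i in 1:1000) {
        Rr <- randomRotation()
        tr <- rnorm(3, sd = 2)
        trial <- rmsdOf(sweep(moving2 %*% Rr, 2, -tr), fixed)
        expect_gte(trial, best - 1e-10)
    }

    expect_error(kabschSuperpose(fixed[1:2, ], fixed[1:2, ]),
                 "at least 3")
    line <- cbind(1:5, 0, 0)
    expect_error(kabschSuperpose(line, line), "degenerate")
})

test_that("interface RMSD matches an independent bio3d-fit oracle", {
    ref <- makeToyComplex(10, 10, seed = 8)
    expect_equal(interfaceRMSD(applyRigid(ref, randomRotation(), c(3, 4, 5)),
                               ref), 0, tolerance = 1e-8)
    ## perturb one antibody interface residue
    mod <- ref
    at <- atomTable(mod)
    ikeys <- interfaceResidues(ref)
    abKey <- ikeys[startsWith(ikeys, "H")][1]
    sel <- paste(at$chain, at$resno, at$insert, sep = ":") == abKey
    at$x[sel] <- at$x[sel] + 1.5
    mod <- AbAgRescore:::.newComplex(at, "H", "G")
    got <- interfaceRMSD(mod, ref, atomSet = "backbone")
    ## oracle: brute-force selection + bio3d fit
    keys <- interfaceResidues(ref)
    pick <- function(cx) {
        a <- atomTable(cx)
        a <- a[a$atom %in% c("N", "CA", "C", "O") &
               paste(a$chain, a$resno, a$insert, sep = ":") %in% keys, ]
        a <- a[order(a$chain, a$resno, a$atom), ]
        as.matrix(a[, c("x", "y", "z")])
    }
    fitted <- bio3dFit(pick(mod), pick(ref))
    expect_equal(got, rmsdOf(fitted, pick(ref)), tolerance = 1e-6)
    ## CA-only differs from backbone on this asymmetric perturbation
    expect_false(isTRUE(all.equal(got,
                                  interfaceRMSD(mod, ref, atomSet = "CA"))))
})

test_that("ligand RMSD: antigen-frame fit, antibody measured without refit", {
    ref <- makeToyComplex(10, 10, seed = 9)
    expect_equal(ligandRMSD(ref, ref), 0, tolerance = 1e-10)
    shifted <- applyRigid(ref, diag(3), c(3, 0, 0), partner = "ab")
    expect_equal(ligandRMSD(shifted, ref), 3.0, tolerance = 1e-8)
    ## combined rotation fixture vs brute-force two-stage oracle
    set.seed(5)
    mod <- applyRigid(ref, randomRotation(angle = 20), rnorm(3),
                      partner = "ab",
                      center = c(5, 5, 5))
    mod <- applyRigid(mod, randomRotation(), rnorm(3, sd = 10)) # global
    got <- ligandRMSD(mod, ref)
    pick <- function(cx, p) {
        a <- atomTable(cx)
        ch <- if (p == "ab") antibodyChains(cx) else antigenChains(cx)
        a <- a[a$atom %in% c("N", "CA", "C", "O") & a$chain %in% ch, ]
        a <- a[order(a$chain, a$resno, a$atom), ]
        as.matrix(a[, c("x", "y", "z")])
    }
    ## oracle: fit antigen with bio3d, apply that transform to the antibody
    agM <- pick(mod, "ag"); agR <- pick(ref, "ag")
    allM <- rbind(agM, pick(mod, "ab"))
    xyzFit <- bio3d::fit.xyz(fixed = as.vector(t(agR)),
                             mobile = as.vector(t(allM)),
                             fixed.inds = seq_len(3 * nrow(agR)),
                             mobile.inds = seq_len(3 * nrow(agM)))
    moved <- matrix(xyzFit, ncol = 3, byrow = TRUE)
    abMoved <- moved[-seq_len(nrow(agM)), ]
    expect_equal(got, rmsdOf(abMoved, pick(ref, "ab")), tolerance = 1e-6)
})

test_that("CAPRI classification follows the standard criteria and is monotone", {
    expect_equal(as.character(classifyCapri(0.6, 0.8, 0.5)), "High")
    expect_equal(as.character(classifyCapri(0.05, 0.5, 0.5)), "Incorrect")
    expect_equal(as.character(classifyCapri(0.15, 3.5, 12.0)), "Acceptable")
    expect_equal(as.character(classifyCapri(0.35, 1.8, 6.0)), "Medium")
    ## monotone in each metric separately
    set.seed(3)
    for (i in 1:200) {
        f <- runif(1); ir <- runif(1, 0, 12); lr <- runif(1, 0, 15)
        base <- classifyCapri(f, ir, lr)
        expect_gte(as.integer(classifyCapri(min(f + 0.2, 1), ir, lr)),
                   as.integer(base))
        expect_gte(as.integer(classifyCapri(f, max(ir - 1, 0), lr)),
                   as.integer(base))
        expect_gte(as.integer(classifyCapri(f, ir, max(lr - 2, 0))),
                   as.integer(base))
    }
})

test_that("conserved contact fraction shares the contact engine with fnat", {
    tmpl <- makeToyComplex(10, 10, seed = 12)
    expect_equal(conservedContactFraction(tmpl, tmpl), 1.0)
    far <- applyRigid(tmpl, diag(3), c(60, 0, 0), partner = "ab")
    expect_equal(conservedContactFraction(far, tmpl), 0.0)
    ## a fixture retaining a known share of template contacts
    ref <- buildComplex(c(
        lapply(1:9, function(i)
            caResidue("H", i, c((i - 1) %% 3 * 4, (i - 1) %/% 3 * 4, 0))),
        lapply(1:9, function(i)
            caResidue("G", i, c((i - 1) %% 3 * 4, (i - 1) %/% 3 * 4, 4.6)))),
        "H", "G")
    n0 <- nrow(contactPairs(ref))
    expect_equal(n0, 9L)
    mod <- buildComplex(c(
        lapply(1:9, function(i)
            caResidue("H", i, c((i - 1) %% 3 * 4, (i - 1) %/% 3 * 4, 0))),
        lapply(1:9, function(i)
            caResidue("G", i, c((i - 1) %% 3 * 4, (i - 1) %/% 3 * 4,
                                ifelse(i <= 5, 4.6, 25))))),
        "H", "G")
    expect_equal(conservedContactFraction(mod, ref), 5 / 9)
    expect_equal(conservedContactFraction(mod, ref), fnat(mod, ref))
    expect_error(conservedContactFraction(ref, twoPoint(40)),
                 "no cross-partner contacts")
})

test_that("all quality metrics are invariant under joint rigid motions", {
    ref <- makeToyComplex(10, 10, seed = 21)
    mod <- applyRigid(ref, randomRotation(angle = 10), c(1.5, 0.5, 0),
                      partner = "ab", center = c(4, 0, 0))
    f0 <- fnat(mod, ref)
    i0 <- interfaceRMSD(mod, ref)
    l0 <- ligandRMSD(mod, ref)
    set.seed(99)
    for (k in 1:25) {
        mod2 <- jointTransform(mod)
        expect_equal(fnat(mod2, ref), f0, tolerance = 1e-9)
        expect_equal(interfaceRMSD(mod2, ref), i0, tolerance = 1e-8)
        expect_equal(ligandRMSD(mod2, ref), l0, tolerance = 1e-8)
    }
})
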