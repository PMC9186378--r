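test_that("cells identical to the reference mean give a zero profile", {
    set.seed(2)
    v <- matrix(rexp(100 * 4, 0.1), 100, 4)
    v <- cbind(v, v[, 1:4])   # test cells duplicate the reference cells
    e <- makeExpr(v)
    ord <- data.frame(chrom = "chr1", gene = geneIds(e))
    refs <- sampleIds(e)[1:4]
    prof <- inferCnvProfile(e, refs, ord, clip = Inf)
    # the duplicated cells sit exactly at the reference mean of themselves?
    # no: centering is by the reference mean, so the *mean over reference
    # cells* of the profile is exactly zero
    expect_lt(max(abs(colMeans(prof[refs, ]))), 1e-10)
    # a cell equal to every reference cell (all refs identical) is zero
    v2 <- matrix(rep(rexp(50, 0.1), 5), 50, 5)
    e2 <- makeExpr(v2)
    prof2 <- inferCnvProfile(e2, sampleIds(e2)[1:2],
                             data.frame(chrom = "chr1", gene = geneIds(e2)))
    expect_lt(max(abs(prof2)), 1e-12)
})

test_that("a planted noiseless segment yields the exact plateau", {
    nG <- 300
    ref <- matrix(rep(c(3, 3), each = nG), nG, 2)
    tumor <- ref[, 1]
    tumor[100:249] <- 2 * tumor[100:249] + 1   # log2 shift exactly +1
    v <- cbind(ref, tumor)
    e <- makeExpr(v, cells = c("r1", "r2", "t"))
    ord <- data.frame(chrom = "chr1", gene = geneIds(e))
    prof <- inferCnvProfile(e, c("r1", "r2"), ord)
    # interior plateau: windows fully inside the 150-gene segment
    expect_equal(unname(prof["t", 150:199]), rep(1, 50), tolerance = 1e-12)
    expect_equal(unname(prof["t", 1:49]), rep(0, 49), tolerance = 1e-12)
    # ramp at the segment edge: window half-covered
    expect_equal(unname(prof["t", 99]), 50 / 101, tolerance = 1e-12)
})

test_that("a unit spike spreads 1/101 over full interior windows", {
    nG <- 300
    ref <- matrix(1, nG, 2)
    tumor <- rep(1, nG)
    tumor[150] <- 2 * tumor[150] + 1     # E = +1 at one interior gene
    e <- makeExpr(cbind(ref, tumor), cells = c("r1", "r2", "t"))
    ord <- data.frame(chrom = "chr1", gene = geneIds(e))
    prof <- inferCnvProfile(e, c("r1", "r2"), ord)
    expect_equal(unname(prof["t", 100:200]), rep(1 / 101, 101),
                 tolerance = 1e-12)
    expect_equal(unname(prof["t", 99]), 0, tolerance = 1e-12)
    # an E = 101 spike gives CNV = 1 at every covered position (101/101)
    tumor2 <- rep(1, nG); tumor2[150] <- 2^(101 + 1) - 1
    e2 <- makeExpr(cbind(ref, tumor2), cells = c("r1", "r2", "t"))
    prof2 <- inferCnvProfile(e2, c("r1", "r2"), ord, clip = Inf)
    expect_equal(unname(prof2["t", 100:200]), rep(1, 101), tolerance = 1e-9)
})

test_that("profile matches the brute-force windowed mean on random fixtures", {
    set.seed(14)
    nG <- 300
    v <- matrix(rexp(nG * 6, 0.2), nG, 6)
    e <- makeExpr(v)
    chrom <- rep(c("chr1", "chr2"), c(180, 120))
    ord <- data.frame(chrom = chrom, gene = geneIds(e))
    refs <- sampleIds(e)[1:3]
    for (hw in c(7, 50)) {
        prof <- inferCnvProfile(e, refs, ord, halfWindow = hw, clip = Inf)
        lv <- log2(v + 1)
        E <- lv - rowMeans(lv[, 1:3])
        rownames(E) <- geneIds(e); colnames(E) <- sampleIds(e)
        want <- oracleWindowMean(E, chrom, hw)
        expect_equal(prof, want[rownames(prof), colnames(prof)],
                     tolerance = 1e-12)
    }
})

test_that("windows never span chromosomes and truncate with renormalization", {
    nG <- 60
    ref <- matrix(1, nG, 1)
    tumor <- rep(1, nG)
    tumor[30] <- 3    # E = +1 at the last gene of chr1
    e <- makeExpr(cbind(ref, tumor), cells = c("r", "t"))
    ord <- data.frame(chrom = rep(c("chr1", "chr2"), each = 30),
                      gene = geneIds(e))
    prof <- inferCnvProfile(e, "r", ord, halfWindow = 10)
    # chr2 positions see nothing of the chr1 spike
    expect_true(all(prof["t", 31:60] == 0))
    # truncated end window on chr1: 11 members at position 30
    expect_equal(unname(prof["t", 30]), 1 / 11, tolerance = 1e-12)
    expect_equal(unname(prof["t", 25]), 1 / 16, tolerance = 1e-12)
})

test_that("profile is translation-equivariant in a cell's centred values", {
    set.seed(5)
    v <- matrix(rexp(120 * 3, 0.2), 120, 3)
    e <- makeExpr(v)
    ord <- data.frame(chrom = "chr1", gene = geneIds(e))
    p1 <- inferCnvProfile(e, "c01", ord, halfWindow = 10, clip = Inf)
    # scale cell 3 by 4x: log2 values shift by +2 everywhere
    v2 <- v; v2[, 3] <- 4 * v2[, 3] + 3
    p2 <- inferCnvProfile(makeExpr(v2), "c01", ord, halfWindow = 10,
                          clip = Inf)
    expect_equal(unname(p2["c03", ] - p1["c03", ]),
                 rep(2, 120), tolerance = 1e-12)
})

test_that("gain/loss calls use the symmetric threshold", {
    expect_equal(unname(callGainLoss(c(0.3, 0, -0.3))),
                 c("gain", "neutral", "loss"))
    expect_equal(unname(callGainLoss(c(0.2, -0.2))),
                 c("neutral", "neutral"))  # strict comparisons
    m <- matrix(c(0.5, -0.5, 0.1, -0.1), 2)
    expect_equal(dim(callGainLoss(m)), dim(m))
    expect_error(callGainLoss(c(1, NA)), "finite")
})

test_that("input contract violations are reported with offenders", {
    e <- makeExpr(matrix(1:12, 4, 3))
    ord <- data.frame(chrom = "chr1", gene = c(geneIds(e), "ghost"))
    expect_error(inferCnvProfile(e, "c01", ord), "ghost")
    expect_error(inferCnvProfile(e, character(),
                                 data.frame(chrom = "chr1",
                                            gene = geneIds(e))),
                 "empty reference")
})
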