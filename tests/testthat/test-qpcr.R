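makeCt <- function(df, hk = "GAPDH") ctTable(df, hk)

test_that("delta-Ct subtracts the mean housekeeping Ct per sample", {
    d <- expand.grid(assay_id = c("GENE", "HK1", "HK2", "HK3"),
                     sample_id = "s1", replicate = 1L,
                     stringsAsFactors = FALSE)
    d$ct <- c(25, 20, 22, 24)
    dct <- deltaCt(ctTable(d, c("HK1", "HK2", "HK3")))
    expect_equal(unname(dct["GENE", "s1"]), 3)       # 25 - mean(20,22,24)
    expect_equal(unname(dct["HK1", "s1"]), -2)
    ## gene Ct equal to every housekeeping Ct -> 0
    d0 <- d; d0$ct <- 21
    expect_equal(unname(deltaCt(ctTable(d0, c("HK1", "HK2", "HK3")))["GENE", "s1"]), 0)
    ## single housekeeping gene reduces to pairwise subtraction
    dct1 <- deltaCt(ctTable(d, "HK1"))
    expect_equal(unname(dct1["GENE", "s1"]), 5)
})

test_that("replicates average before normalization and propagate SD", {
    d <- data.frame(assay_id = rep(c("GENE", "GAPDH"), each = 3),
                    sample_id = "s1", replicate = rep(1:3, 2),
                    ct = c(24, 25, 26, 20, 20, 20))
    dct <- deltaCt(makeCt(d))
    expect_equal(unname(dct["GENE", "s1"]), 5)
    expect_equal(unname(attr(dct, "replicate_sd")["GENE", "s1"]), 1)
})

test_that("housekeeping undetected in a sample is an error naming it", {
    d <- data.frame(assay_id = c("GENE", "GAPDH", "GENE", "GAPDH"),
                    sample_id = c("s1", "s1", "s2", "s2"),
                    replicate = 1L, ct = c(25, 20, 26, NA))
    expect_error(deltaCt(makeCt(d)), "s2")
})

test_that("relative expression fixes the reference at 100 and doubles per cycle", {
    dct <- matrix(c(5, 4, 6), 1, 3,
                  dimnames = list("GENE", c("ref", "lo", "hi")))
    rel <- relativeExpression(dct, "ref")
    expect_equal(unname(rel["GENE", ]), c(ref = 100, lo = 200, hi = 50),
                 ignore_attr = TRUE)
    ## one cycle below reference -> 200: doubling input abundance doubles it
    dct2 <- dct; dct2[, "lo"] <- dct2[, "lo"] - 1
    expect_equal(unname(relativeExpression(dct2, "ref")["GENE", "lo"]), 400)
    expect_error(relativeExpression(dct, "nope"), "not in the table")
})

test_that("undetected assays get relative expression 0 with a flag", {
    dct <- matrix(c(5, NA), 1, 2, dimnames = list("G", c("ref", "s2")))
    rel <- relativeExpression(dct, "ref")
    expect_equal(unname(rel["G", "s2"]), 0)
    expect_true(attr(rel, "undetected")["G", "s2"])
    dctBad <- matrix(c(NA, 5), 1, 2, dimnames = list("G", c("ref", "s2")))
    expect_error(relativeExpression(dctBad, "ref"), "reference")
})

test_that("the ddCt chain matches an independently coded oracle on random plates", {
    set.seed(71)
    for (rep in 1:5) {
        ab <- matrix(rlnorm(12, 0, 1.5), 3, 4,
                     dimnames = list(paste0("A", 1:3), paste0("s", 1:4)))
        ct <- generateCt(ab, noiseSd = 0.3, nReplicates = 3, seed = rep)
        rel <- relativeExpression(deltaCt(ct), "s1")
        oracle <- ddctOracle(ct, "s1")
        expect_equal(unname(rel[rownames(oracle), colnames(oracle)]),
                     unname(oracle), tolerance = 1e-12)
    }
})

test_that("relative expression is invariant to per-sample Ct offsets", {
    ab <- matrix(rlnorm(8, 0, 1), 2, 4,
                 dimnames = list(c("A1", "A2"), paste0("s", 1:4)))
    ct <- generateCt(ab, noiseSd = 0.1, nReplicates = 3, seed = 9)
    rel <- relativeExpression(deltaCt(ct), "s1")
    shifted <- ctValues(ct)
    offs <- c(s1 = 1.3, s2 = -0.7, s3 = 2.2, s4 = 0)
    shifted$ct <- shifted$ct + offs[shifted$sample_id]
    rel2 <- relativeExpression(deltaCt(ctTable(shifted, housekeepingAssays(ct))), "s1")
    expect_equal(as.numeric(rel2), as.numeric(rel))
})

test_that("group statistics report mean +- SD, Welch p and stars", {
    gs <- groupStats(c(441, 549, 495), c(100, 120, 110))
    expect_equal(gs$mean_a, 495)
    expect_equal(gs$sd_a, 54)
    expect_equal(gs$p_value,
                 t.test(c(441, 549, 495), c(100, 120, 110))$p.value)
    ## identical groups: fold 1, p = 1
    same <- groupStats(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$fold, 1)
    expect_equal(same$p_value, 1)
    expect_identical(same$stars, "")
    ## star thresholds
    starFor <- function(p) if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    expect_identical(starFor(0.009), "**")
    expect_identical(starFor(0.04), "*")
    expect_identical(starFor(0.2), "")
    expect_identical(groupStats(c(0, 0, 10), c(100, 95, 105))$stars,
                     starFor(groupStats(c(0, 0, 10), c(100, 95, 105))$p_value))
    ## degenerate zero variance
    deg <- groupStats(c(5, 5, 5), c(5, 5))
    expect_true(deg$degenerate)
    expect_equal(deg$p_value, 1)
    ## fold undefined when the denominator group mean is zero
    expect_true(is.na(groupStats(c(1, 2), c(0, 0))$fold))
})

test_that("Welch p-values agree with a permutation test on small samples", {
    set.seed(123)
    a <- c(495, 318, 126) * c(1.1, 0.9, 1.0)
    b <- c(30, 45, 12)
    welch <- groupStats(a, b)$p_value
    pooled <- c(a, b)
    perms <- combn(6, 3)
    tstat <- function(x, y) abs(mean(x) - mean(y)) /
        sqrt(var(x) / 3 + var(y) / 3)
    obs <- tstat(a, b)
    permT <- apply(perms, 2, function(ix) tstat(pooled[ix], pooled[-ix]))
    pPerm <- mean(permT >= obs - 1e-12)
    ## exact permutation p with n=3 per group is coarse (1/20 steps)
    expect_lt(abs(welch - pPerm), 0.15)
    expect_true((welch < 0.05) == (pPerm <= 0.05))
})

test_that("long and wide Ct readers agree", {
    longF <- tempfile(fileext = ".tsv")
    writeLines(c("assay_id\tsample_id\treplicate\tct",
                 "G1\ts1\t1\t24.0", "G1\ts1\t2\t24.2",
                 "G1\ts2\t1\t27.1", "G1\ts2\t2\tND",
                 "GAPDH\ts1\t1\t20.0", "GAPDH\ts1\t2\t20.1",
                 "GAPDH\ts2\t1\t19.9", "GAPDH\ts2\t2\t20.0"), longF)
    wideF <- tempfile(fileext = ".tsv")
    writeLines(c("assay_id\ts1\ts1\ts2\ts2",
                 "G1\t24.0\t24.2\t27.1\tND",
                 "GAPDH\t20.0\t20.1\t19.9\t20.0"), wideF)
    a <- readCtTable(longF, "GAPDH")
    b <- readCtWide(wideF, "GAPDH")
    expect_equal(deltaCt(a), deltaCt(b))
    expect_identical(housekeepingAssays(a), "GAPDH")
})
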