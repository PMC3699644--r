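test_that("the generator is reproducible from its seed", {
    a <- generateCounts(simulationConfig(seed = 42))
    b <- generateCounts(simulationConfig(seed = 42))
    expect_identical(exprValues(a$experiment), exprValues(b$experiment))
    expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
    c2 <- generateCounts(simulationConfig(seed = 43))
    expect_false(identical(exprValues(a$experiment), exprValues(c2$experiment)))
})

test_that("the zero-dispersion limit is noise-free", {
    sim <- generateCounts(simulationConfig(dispersion = 0, seed = 3))
    depths <- librarySizes(sim$experiment)
    tmpl <- as.matrix(as.data.frame(
        sim$truth[, paste0("mean_rpm_", classLabels(sim$experiment))]))
    mu <- sweep(tmpl, 2L, depths / 1e6, "*")
    expect_equal(unname(exprValues(sim$experiment)), unname(round(mu)))
})

test_that("infeasible archetype quotas are rejected", {
    expect_error(simulationConfig(nGenes = 10,
                                  quotas = c(pan_cec = 8, ubiquitous = 8)),
                 "exceed")
    expect_error(simulationConfig(quotas = c(unicorn = 5)), "unknown")
})

test_that("library depths and metadata mirror the configured design", {
    sim <- generateCounts(simulationConfig(seed = 8))
    ls <- librarySizes(sim$experiment)
    expect_true(all(ls >= 1.8e6 & ls <= 4.6e6))
    expect_setequal(unname(classLabels(sim$experiment)),
                    c("cec_young", "cec_old", "cec_culture", "stroma"))
    ## annotation carries the planted specificity verdicts
    spec <- geneSpecificity(sim$experiment)
    arch <- sim$truth$archetype
    expect_true(all(spec[arch == "ubiquitous"] == "ubiquitous"))
    expect_true(all(spec[arch == "ocular_non_cec"] == "restricted:retina"))
})

test_that("class mean RPMs converge to the truth table at extreme depth", {
    cfg <- simulationConfig(librarySizeRange = c(1e8, 1e8),
                            dispersion = 0.001, seed = 12)
    sim <- generateCounts(cfg)
    rpm <- rpmNormalize(sim$experiment)
    m <- classRpm(rpm)
    tmpl <- as.matrix(as.data.frame(sim$truth[, paste0("mean_rpm_", colnames(m))]))
    big <- tmpl >= 10
    expect_true(all(abs(m[big] - tmpl[big]) / tmpl[big] < 0.2))
})

test_that("planted pan-CEC genes pass the stroma-absent screen; ubiquitous never do", {
    passes <- 0L; total <- 0L; ubiq <- 0L
    for (i in 1:100) {
        sim <- generateCounts(simulationConfig(seed = 300 + i))
        rpm <- rpmNormalize(sim$experiment)
        sa <- stromaAbsentFilter(rpm)$gene_id
        pan <- sim$truth$gene_id[sim$truth$archetype == "pan_cec"]
        passes <- passes + sum(pan %in% sa)
        total <- total + length(pan)
        ubiq <- ubiq + sum(sim$truth$gene_id[sim$truth$archetype ==
                                             "ubiquitous"] %in% sa)
        ## on the noiseless templates the stroma-absent set is nested in the
        ## stable set (planted age folds lie within bounds)
        expect_true(all(sim$truth$expected_stable[sim$truth$expected_stroma_absent]))
    }
    expect_gte(passes / total, 0.95)
    expect_identical(ubiq, 0L)
})

test_that("the age criterion passes ~90% of unit-fold genes at default noise", {
    ## operating characteristic behind the stable filter's recall: two
    ## independent NB libraries at dispersion 0.1 put the rounded young/old
    ## fold of a true unit-fold gene outside [0.5, 2.0] about 10% of the time
    set.seed(2024)
    mu <- 600 * 3.2   # a pan-CEC gene at a mid-range depth
    r <- rnbinom(2e5, mu = mu, size = 10) / rnbinom(2e5, mu = mu, size = 10)
    fa <- roundHalfUp(r, 1)
    p <- mean(fa >= 0.5 & fa <= 2.0)
    expect_gt(p, 0.88)
    expect_lt(p, 0.92)
})

test_that("noiseless Ct plates recover abundance ratios exactly", {
    ab <- matrix(c(84, 16, 1, 1), 2, 2,
                 dimnames = list(c("SLC4A11", "CYYR1"), c("cec", "stroma")))
    ct <- generateCt(ab, noiseSd = 0, nReplicates = 3, seed = 5)
    rel <- relativeExpression(deltaCt(ct), "stroma")
    expect_equal(unname(rel["SLC4A11", "cec"]), 8400)
    expect_equal(unname(rel["CYYR1", "cec"]), 1600)
    expect_error(generateCt(matrix(c(1, -2), 1, 2)), "positive")
    ## same seed, same plate
    expect_identical(ctValues(generateCt(ab, seed = 7)),
                     ctValues(generateCt(ab, seed = 7)))
})

test_that("group fold estimates recover a planted 84-fold contrast", {
    est <- vapply(1:100, function(s) {
        ab <- matrix(c(rep(84, 3), rep(1, 3)), 1, 6,
                     dimnames = list("SLC4A11",
                                     c(paste0("cec", 1:3), paste0("str", 1:3))))
        ct <- generateCt(ab, noiseSd = 0.2, nReplicates = 3, seed = 7000 + s)
        rel <- relativeExpression(deltaCt(ct), "str1")
        groupStats(rel["SLC4A11", 1:3], rel["SLC4A11", 4:6])$fold
    }, numeric(1))
    expect_lt(abs(mean(est) - 84) / 84, 0.2)
    expect_gt(mean(abs(est - 84) / 84 <= 0.2), 0.9)
})
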