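test_that("the dominant eigenvalue crosses zero at the programmed bifurcation", {
    mod <- grnModel()
    eigAt <- function(p) grnDominantEigen(mod, p)[1L]
    expect_lt(eigAt(-0.4), -0.5)                  # strongly stable far away
    expect_lt(eigAt(-0.05), 0)
    expect_equal(eigAt(-0.01), -0.02, tolerance = 1e-3)  # slope eigenSlope * p
    expect_equal(eigAt(-1e-4), 0, tolerance = 1e-3)      # -> 0 from the left
    expect_null(grnDominantEigen(mod, 0.01))      # low state gone past the fold
})

test_that("noise-free trajectories settle to a fixed point", {
    mod <- grnModel()
    s <- simulateGrn(mod, p = -0.4, sigma = 0, nSamples = 50, seed = 1)
    expect_lte(max(apply(s, 1L, stats::sd)), 1e-6)
    expect_true(all(s > 0))
})

test_that("simulation is bit-identical under a fixed seed", {
    mod <- grnModel()
    a <- simulateGrn(mod, -0.1, sigma = 0.05, nSamples = 10, seed = 42)
    b <- simulateGrn(mod, -0.1, sigma = 0.05, nSamples = 10, seed = 42)
    expect_identical(a, b)
})

test_that("critical fluctuations grow near the bifurcation", {
    mod <- grnModel()
    ratios <- vapply(1:8, function(s) {
        far <- simulateGrn(mod, -0.45, sigma = 0.05, seed = s)
        near <- simulateGrn(mod, -0.05, sigma = 0.05, seed = s + 100L)
        stats::sd(near["n1", ]) / stats::sd(far["n1", ])
    }, numeric(1))
    expect_gt(stats::median(ratios), 1.5)
})

test_that("sweepAndScore validates its grid and shows the transition jump", {
    mod <- grnModel()
    expect_error(sweepAndScore(mod, pGrid = c(-0.1, 0)), "at least 3")
    expect_error(sweepAndScore(mod, pGrid = c(0, -0.1, 0.1)), "ascending")
    sw <- sweepAndScore(mod, pGrid = seq(-0.5, 0.1, by = 0.1), nSamples = 15,
                        sigma = 0.05, seed = 1)
    cv <- sw$curve[!is.na(sw$curve$score), ]
    # scores after the fold dwarf the pre-fold baseline
    expect_gt(max(cv$score[cv$p >= 0]), 5 * max(abs(cv$score[cv$p < 0])))
})

test_that("cohort generation is deterministic and honors its contract", {
    a <- generateCohort(seed = 9)
    b <- generateCohort(seed = 9)
    expect_identical(abundances(a$profile), abundances(b$profile))
    expect_identical(a$truth, b$truth)
    expect_identical(dim(a$profile), c(40L, 180L))
    expect_true(all(is.na(a$truth$transitionDay[a$truth$group == "control"])))
    expect_true(all(a$truth$transitionDay[a$truth$group != "control"] == 270))
    expect_error(generateCohort(dnbSize = 50, nTaxa = 40), "larger than taxa")
})

test_that("the programmed DNB ramp raises intra-block correlation and variance", {
    hits <- vapply(1:10, function(s) {
        coh <- generateCohort(seed = s)
        lat <- coh$latent
        ind <- sub("_d.*", "", colnames(lat))
        sym <- unique(ind[startsWith(ind, "sero") | startsWith(ind, "case")])
        ti <- coh$settings$transitionIndex
        pre <- c(); early <- c(); vpre <- c(); vearly <- c()
        for (i in sym) {
            cols <- which(ind == i)
            ramp <- cols[(ti - 3L):(ti - 1L)]
            first <- cols[1:3]
            blk <- lat[coh$dnbTaxa, , drop = FALSE]
            cr <- function(j) {
                cc <- stats::cor(t(blk[, j]))
                mean(cc[upper.tri(cc)])
            }
            pre <- c(pre, cr(ramp)); early <- c(early, cr(first))
            vpre <- c(vpre, mean(apply(blk[, ramp], 1, stats::var)))
            vearly <- c(vearly, mean(apply(blk[, first], 1, stats::var)))
        }
        mean(pre) > mean(early) && mean(vpre) > mean(vearly)
    }, logical(1))
    expect_gte(mean(hits), 0.5)    # holds for the median seed
})

test_that("control individuals have no day-dependent latent structure", {
    coh <- generateCohort(seed = 3)
    lat <- coh$latent
    ind <- sub("_d.*", "", colnames(lat))
    ctrl <- lat[, ind == "ctrl01"]
    # mean block abundance early vs late indistinguishable at generator scale
    blk <- colMeans(ctrl[coh$dnbTaxa, ])
    expect_lt(abs(mean(blk[1:4]) - mean(blk[9:12])), 1.5)
})
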