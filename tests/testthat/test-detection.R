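test_that("ratio rule matches the printed examples", {
    c1 <- detectTipping(1:3, c(1.0, 1.2, 2.0))
    expect_identical(firstSignal(c1), 3)          # 2.0 > 1.5 * 1.2
    c2 <- detectTipping(1:4, c(1, 1, 1, 1))
    expect_length(firstSignal(c2), 0L)
    c3 <- detectTipping(1:3, c(5, 1, 1.6))        # local rule, not global
    expect_identical(firstSignal(c3), 3)
    expect_error(detectTipping(c(1, 3, 2), c(1, 2, 3)), "strictly increasing")
    expect_error(detectTipping(1:2, c(1, NA)), "finite")
})

test_that("ratio rule is invariant to positive rescaling of the series", {
    set.seed(2)
    s <- abs(rnorm(10)) + 0.2
    a <- detectTipping(1:10, s)
    b <- detectTipping(1:10, s * 137)
    expect_identical(signalDays(a), signalDays(b))
})

test_that("the first time point can never fire", {
    cl <- detectTipping(c(5, 6), c(1, 100))
    expect_identical(signalDays(cl), 6)
    expect_true(validObject(cl))
})

test_that("deviation rule flags sharp moves in either direction only", {
    days <- 1:8
    flat <- c(1, 1.05, 0.95, 1.02, 0.99, 1.04, 1.01, 0.97)
    expect_length(firstSignal(detectTipping(days, flat, method = "deviation")), 0L)
    drop <- c(1, 1.05, 0.95, 1.02, 0.2, 1, 1, 1)
    expect_identical(firstSignal(detectTipping(days, drop, method = "deviation")), 5)
    rise <- c(1, 1.05, 0.95, 1.02, 2.5, 1, 1, 1)
    expect_identical(firstSignal(detectTipping(days, rise, method = "deviation")), 5)
    # needs three baseline points: day 3 cannot fire even on a huge move
    early <- c(1, 1.01, 50, 1, 1, 1, 1, 1)
    expect_false(3 %in% signalDays(detectTipping(days, early, method = "deviation")))
})

test_that("DNB calling keeps the ceiling of the fraction with deterministic ties", {
    sc20 <- stats::setNames(seq(0.01, 0.20, by = 0.01), sprintf("t%02d", 1:20))
    expect_length(dnbTaxa(identifyDnb(sc20)), 2L)
    sc11 <- stats::setNames(seq_len(11) / 11, paste0("x", 1:11))
    expect_length(dnbTaxa(identifyDnb(sc11)), 2L)   # ceiling(1.1)
    tie <- c(zeta = 1, beta = 0.5, alpha = 0.5, gamma = 0.1)
    got <- dnbTaxa(identifyDnb(tie, fraction = 0.5))
    expect_identical(got, c("zeta", "alpha"))       # lexicographic at the cutoff
    expect_error(identifyDnb(numeric(0)), "empty")
})

test_that("high-frequency species rule follows both group branches", {
    mk <- function(ind, taxa, group)
        new("DnbSet", individual = ind, day = 1, taxa = taxa,
            scores = rep(1, length(taxa)), fraction = length(taxa) / 10,
            nScored = 10L, group = group)
    t1 <- mk("d1", c("A", "B"), "T1D-case")
    t2 <- mk("d2", c("A", "C"), "T1D-case")
    ser <- lapply(1:11, function(i)
        mk(paste0("s", i), if (i <= 5) c("D", "E") else "E", "seroconverter"))
    hf <- highFrequencySpecies(c(list(t1, t2), ser))
    expect_true("A" %in% hf)        # in 2 T1D sets
    expect_false("B" %in% hf)       # in only 1 T1D set
    expect_true("D" %in% hf)        # in exactly 5 seroconverter sets
    expect_true("E" %in% hf)        # in all 11
    hf2 <- highFrequencySpecies(c(list(t1, t2), ser), seroMin = 6L)
    expect_false("D" %in% hf2)      # 5 of 11 now below threshold
})

test_that("dark species are DNBs without a group abundance shift", {
    set.seed(33)
    n <- 30
    grp <- rep(c("control", "seroconverter", "T1D-case"), each = n)
    cnt <- rbind(
        flat  = rpois(3 * n, 50),                                  # null taxon
        shift = rpois(3 * n, rep(c(20, 50, 110), each = n)),       # strong shift
        other = rpois(3 * n, 30))
    colnames(cnt) <- paste0("s", seq_len(3 * n))
    tp <- TaxonProfile(cnt, individual = paste0("i", seq_len(3 * n)),
                       day = 1, group = grp)
    dark <- darkSpecies(c("flat", "shift"), tp)
    expect_true("flat" %in% dark)
    expect_false("shift" %in% dark)
    expect_false("other" %in% dark)          # never returns non-DNB taxa
    expect_error(darkSpecies("flat", TaxonProfile(cnt,
        individual = paste0("i", seq_len(3 * n)), day = 1,
        group = c("a", rep("b", 3 * n - 1L)))), "fewer than 2")
})
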