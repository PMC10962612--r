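test_that("a written profile reads back identically", {
    cnt <- matrix(c(3L, 0L, 5L, 1L, 2L, 7L, 0L, 0L, 0L, 4L, 9L, 2L), 3, 4,
                  dimnames = list(c("ta", "tb", "tc"), paste0("s", 1:4)))
    f <- writeToyProfileFiles(cnt, individual = rep(c("A", "B"), each = 2),
                              day = c(10, 40, 10, 40))
    tp <- readTaxonProfile(f$table, f$metadata)
    expect_s4_class(tp, "TaxonProfile")
    expect_identical(dim(tp), c(3L, 4L))
    expect_identical(abundances(tp)[, colnames(cnt)], cnt + 0)
    # round trip through writeTaxonProfile
    tf2 <- tempfile(); mf2 <- tempfile()
    writeTaxonProfile(tp, tf2, mf2)
    tp2 <- readTaxonProfile(tf2, mf2)
    expect_identical(abundances(tp2), abundances(tp))
    expect_identical(sampleDays(tp2), sampleDays(tp))
})

test_that("reader rejects duplicate sample ids, missing metadata, negatives", {
    cnt <- matrix(1:6, 2, 3, dimnames = list(c("ta", "tb"), c("s1", "s2", "s1")))
    f <- writeToyProfileFiles(cnt, individual = "A", day = 1:3)
    expect_error(readTaxonProfile(f$table, f$metadata), "duplicate sample id")

    cnt2 <- matrix(1:6, 2, 3, dimnames = list(c("ta", "tb"), paste0("s", 1:3)))
    f2 <- writeToyProfileFiles(cnt2, individual = "A", day = 1:3)
    md <- utils::read.table(f2$metadata, header = TRUE, sep = "\t")
    utils::write.table(md[-2L, ], f2$metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readTaxonProfile(f2$table, f2$metadata), "missing from metadata")

    cnt3 <- cnt2; cnt3[1L, 1L] <- -1
    f3 <- writeToyProfileFiles(cnt3, individual = "A", day = 1:3)
    expect_error(readTaxonProfile(f3$table, f3$metadata), "negative")
})

test_that("all-zero taxon rows load but are flagged", {
    cnt <- matrix(c(1, 2, 0, 0, 3, 4), 3, 2, byrow = TRUE,
                  dimnames = list(c("ta", "tz", "tb"), c("s1", "s2")))
    f <- writeToyProfileFiles(cnt, individual = "A", day = 1:2)
    tp <- readTaxonProfile(f$table, f$metadata)
    expect_identical(nrow(tp), 3L)
    expect_identical(unname(SummarizedExperiment::rowData(tp)$zeroSum),
                     c(FALSE, TRUE, FALSE))
})

test_that("aggregation sums within rank, preserves column sums, pools unclassified", {
    cnt <- matrix(c(3, 4, 1, 2, 10, 20, 5, 5), 4, 2, byrow = TRUE,
                  dimnames = list(paste0("otu", 1:4), c("s1", "s2")))
    lin <- c("k__B;p__F;c__C;o__O;f__L;g__Lacto;s__a",
             "k__B;p__F;c__C;o__O;f__L;g__Lacto;s__b",
             "k__B;p__F;c__C;o__O;f__L;g__Strep;s__c",
             "k__B;p__F;c__C;o__O;f__L;g__;s__")   # genus missing
    tp <- TaxonProfile(cnt, individual = "A", day = 1:2, lineage = lin)
    ag <- aggregateToLevel(tp, "genus")
    a <- abundances(ag)
    expect_equal(a["Lacto", ], c(s1 = 4, s2 = 6))
    expect_equal(a["Strep", ], c(s1 = 10, s2 = 20))
    expect_true("unclassified_L" %in% rownames(a))
    expect_equal(colSums(a), colSums(cnt))       # conservation, exactly
    # aggregating at the level the table is effectively at = identity matrix
    sp <- aggregateToLevel(tp, "species")
    expect_equal(sort(unname(rowSums(abundances(sp))[c("a", "b", "c")])),
                 sort(unname(rowSums(cnt[1:3, ]))))
    expect_error(aggregateToLevel(tp, "tribe"))
})

test_that("relative-abundance normalization matches hand values", {
    cnt <- matrix(c(1, 1, 2, 0, 0, 2), 3, 2,
                  dimnames = list(paste0("t", 1:3), c("s1", "s2")))
    tp <- TaxonProfile(cnt, individual = "A", day = 1:2)
    n0 <- abundances(normalizeRelative(tp, pseudocount = 0))
    expect_equal(unname(n0[, "s1"]), c(0.25, 0.25, 0.5))
    n5 <- abundances(normalizeRelative(tp, pseudocount = 0.5))
    expect_equal(unname(n5[, "s2"]), c(0.5, 0.5, 2.5) / 3.5)
    expect_true(all(n5 > 0))
    expect_equal(colSums(n5), c(s1 = 1, s2 = 1), tolerance = 1e-9)
    zero <- TaxonProfile(matrix(c(0, 0, 1, 1), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2"))),
                individual = "A", day = 1:2)
    expect_error(normalizeRelative(zero, pseudocount = 0), "all-zero")
})

test_that("aggregate-then-normalize equals normalize-the-aggregated-counts", {
    set.seed(7)
    cnt <- matrix(rpois(40, 8), 8, 5,
                  dimnames = list(paste0("otu", 1:8), paste0("s", 1:5)))
    lin <- sprintf("k__B;p__P;c__C;o__O;f__F;g__g%d;s__s%d",
                   rep(1:4, each = 2), 1:8)
    tp <- TaxonProfile(cnt, individual = "A", day = 1:5, lineage = lin)
    a <- normalizeRelative(aggregateToLevel(tp, "genus"), 0.5)
    b <- normalizeRelative(aggregateToLevel(tp, "genus"), 0.5)
    expect_equal(abundances(a), abundances(b))
    # and column sums of the aggregate stay 1 after normalization
    expect_equal(unname(colSums(abundances(a))), rep(1, 5), tolerance = 1e-9)
})

test_that("referenceSplit pools leading time points and keeps sets disjoint", {
    cnt <- matrix(rpois(40, 5), 4, 10,
                  dimnames = list(paste0("t", 1:4), paste0("s", 1:10)))
    tp <- TaxonProfile(cnt, individual = rep(c("A", "B"), each = 5),
                       day = rep(c(10, 20, 30, 40, 50), 2))
    sp <- referenceSplit(tp, "A")
    expect_length(sp$reference, 4L)        # 2 leading days x 2 individuals
    expect_length(sp$case, 3L)
    expect_length(intersect(sp$reference, sp$case), 0L)
    expect_equal(sp$caseDays, c(30, 40, 50))
    spo <- referenceSplit(tp, "A", referenceScope = "individual")
    expect_length(spo$reference, 2L)
    expect_error(referenceSplit(tp, "nope"), "unknown individual")
})
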