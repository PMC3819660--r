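hitRow <- function(q, subj, identity, aln, evalue, bitscore = 500) {
    data.frame(query_id = q, subject_id = subj, identity = identity,
               aln_length = aln, mismatches = 0L, gap_opens = 0L,
               q_start = 1L, q_end = aln, s_start = 1L, s_end = aln,
               evalue = evalue, bitscore = bitscore,
               stringsAsFactors = FALSE)
}
noHits <- hitRow("dummy", "dummy", 0, 1L, 1)[0, ]

test_that("organelle thresholds are applied exactly, with the length gate", {
    lens <- c(cpIn = 500, cpIdOut = 500, cpCovOut = 500, mtIn = 500,
              mtIdOut = 500, mtCovOut = 500, short = 150, gate = 200,
              gatePlus = 201, none = 400)
    cp <- rbind(
        hitRow("cpIn", "cp", 96.2, 425, 1e-20),      # 85% coverage
        hitRow("cpIdOut", "cp", 94.9, 450, 1e-20),   # identity fails
        hitRow("cpCovOut", "cp", 99.0, 399, 1e-20),  # 79.8% coverage fails
        hitRow("short", "cp", 100, 150, 1e-30),      # length gate
        hitRow("gate", "cp", 100, 200, 1e-30),       # 200 nt is not > 200
        hitRow("gatePlus", "cp", 100, 201, 1e-30))   # 201 nt passes
    mt <- rbind(
        hitRow("cpIdOut", "mt", 81, 300, 1e-8),      # 60% coverage, rescue
        hitRow("mtIn", "mt", 80.0, 250, 1e-6),       # both at threshold
        hitRow("mtIdOut", "mt", 79.9, 400, 1e-20),
        hitRow("mtCovOut", "mt", 95, 249, 1e-20))    # 49.8% fails
    part <- classifyScaffolds(cp, mt, lens)
    cls <- classification(part)
    expect_identical(cls[["cpIn"]], "chloroplast")
    expect_identical(cls[["cpIdOut"]], "mitochondrion")
    expect_identical(cls[["cpCovOut"]], "nucleus")
    expect_identical(cls[["mtIn"]], "mitochondrion")
    expect_identical(cls[["mtIdOut"]], "nucleus")
    expect_identical(cls[["mtCovOut"]], "nucleus")
    expect_identical(cls[["short"]], "nucleus")
    expect_identical(cls[["gate"]], "nucleus")
    expect_identical(cls[["gatePlus"]], "chloroplast")
    expect_identical(cls[["none"]], "nucleus")

    # disjoint cover
    expect_identical(sort(names(cls)), sort(names(lens)))
    expect_identical(sum(table(cls)), length(lens))
})

test_that("e-value gate and chloroplast precedence hold", {
    lens <- c(a = 500, b = 500)
    cpWeak <- hitRow("a", "cp", 99, 450, 1e-4)   # e-value too large
    mtGood <- hitRow("a", "mt", 90, 300, 1e-10)
    part <- classifyScaffolds(cpWeak, mtGood, lens)
    expect_identical(classification(part)[["a"]], "mitochondrion")

    cpGood <- hitRow("b", "cp", 99, 450, 1e-10)
    mtAlso <- hitRow("b", "mt", 90, 300, 1e-10)
    part2 <- classifyScaffolds(cpGood, mtAlso, lens)
    expect_identical(classification(part2)[["b"]], "chloroplast")
    expect_identical(part2@conflicts$scaffold, "b")

    expect_error(classifyScaffolds(hitRow("zz", "cp", 99, 450, 1e-10),
                                   noHits, lens),
                 "unknown scaffold")
})

test_that("relaxing a threshold never shrinks an organelle class", {
    set.seed(77)
    n <- 60
    lens <- stats::setNames(sample(150:2000, n),
                            sprintf("s%02d", seq_len(n)))
    cp <- do.call(rbind, lapply(names(lens), function(q)
        hitRow(q, "cp", runif(1, 70, 100),
               as.integer(runif(1, 0.2, 1) * lens[[q]]),
               10^-runif(1, 2, 40))))
    strict <- classification(classifyScaffolds(cp, noHits, lens))
    relaxed <- classification(classifyScaffolds(
        cp, noHits, lens, cpIdentity = 85, cpCoverage = 60,
        maxEvalue = 1e-3))
    expect_true(all(names(strict)[strict == "chloroplast"] %in%
                    names(relaxed)[relaxed == "chloroplast"]))
})

test_that("best hit per scaffold decides (lowest e-value, then bitscore)", {
    lens <- c(a = 500)
    cp <- rbind(hitRow("a", "cp", 94, 450, 1e-30, bitscore = 800),
                hitRow("a", "cp", 99, 450, 1e-10, bitscore = 900))
    # best hit is the 1e-30 one, whose identity fails
    part <- classifyScaffolds(cp, noHits, lens)
    expect_identical(classification(part)[["a"]], "nucleus")
})

test_that("hit tables parse from outfmt-6 text and reject malformed rows", {
    f <- tempfile()
    writeLines(c("q1\tcp\t97.5\t400\t10\t1\t1\t400\t100\t499\t1e-30\t720",
                 "q2\tcp\t88.0\t150\t18\t0\t1\t150\t5\t154\t2e-9\t180"), f)
    hits <- readBlastHits(f)
    expect_equal(nrow(hits), 2L)
    expect_equal(hits$identity, c(97.5, 88.0))
    expect_equal(hits$evalue, c(1e-30, 2e-9))

    writeLines("q1\tcp\t97.5\t400", f)
    expect_error(readBlastHits(f), "line 1")
})

test_that("Venn regions enumerate correctly and sum to the union", {
    out <- sharedSets(list(p = c("a", "b", "c"), s = c("b", "c"),
                           l = c("b", "c", "d")))
    expect_equal(out$union, 4L)
    expect_equal(out$sharedAll, 2L)
    expect_equal(out$sharedFraction, 0.5)
    expect_equal(sum(out$regions$count), out$union)
    only_p <- out$regions$count[out$regions$p & !out$regions$s &
                                !out$regions$l]
    expect_equal(only_p, 1L)  # {a}
    only_l <- out$regions$count[!out$regions$p & !out$regions$s &
                                out$regions$l]
    expect_equal(only_l, 1L)  # {d}

    same <- sharedSets(list(x = c("a", "b"), y = c("a", "b")))
    expect_equal(same$sharedFraction, 1)
    disjoint <- sharedSets(list(x = "a", y = "b"))
    expect_equal(disjoint$sharedFraction, 0)
    expect_error(sharedSets(list(x = "a")), "at least 2")
    expect_error(sharedSets(list(x = character(), y = character())),
                 "empty")
})

test_that("per-class per-sample summary counts expressed scaffolds", {
    lens <- c(a = 500, b = 500, c = 500)
    cp <- hitRow("a", "cp", 99, 450, 1e-10)
    expr <- matrix(c(5, 0, 2, 3, 1, 0), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    part <- classifyScaffolds(cp, noHits, lens, expression = expr)
    s <- part@summary
    nuc1 <- s[s$class == "nucleus" & s$sample == "s1", ]
    expect_equal(nuc1$scaffolds, 1L)     # only c (b is zero in s1)
    expect_equal(nuc1$expression, 2)     # b + c = 0 + 2
    cp1 <- s[s$class == "chloroplast" & s$sample == "s1", ]
    expect_equal(cp1$expression, 5)
})
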