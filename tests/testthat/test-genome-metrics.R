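test_that("GC content matches direct base counting", {
    expect_equal(gcContent("ATGC"), 50.0)
    expect_equal(gcContent("GGCC"), 100.0)
    expect_equal(gcContent("ATGCN"), 50.0)  # ambiguity excluded
    ga <- GenomeAssembly("t", Biostrings::DNAStringSet(c(a = "AATT",
                                                         b = "GGGG")))
    expect_equal(gcContent(ga), 50.0)
    expect_error(gcContent("NNNN"), "unambiguous")
})

test_that("fragment ANI is exact on identical genomes and recovers targets", {
    gp <- makeGenomePair(30000, 1.0, seed = 2)
    self <- orthoAni(gp$genomeA, gp$genomeA)
    expect_equal(self$ani, 100.0)

    gp95 <- makeGenomePair(30000, 0.95, seed = 5)
    a <- orthoAni(gp95$genomeA, gp95$genomeB)
    expect_lt(abs(a$ani - 95), 1.0)
    expect_true(a$reciprocal)
    expect_gte(a$nFragmentsUsed, 1L)

    gp80 <- makeGenomePair(30000, 0.80, seed = 5)
    expect_lt(abs(orthoAni(gp80$genomeA, gp80$genomeB)$ani - 80), 1.5)
})

test_that("fragment ANI is symmetric and monotone in the divergence ladder", {
    anis <- vapply(c(0.85, 0.95, 0.99), function(t) {
        gp <- makeGenomePair(30000, t, seed = 17)
        orthoAni(gp$genomeA, gp$genomeB)$ani
    }, numeric(1))
    expect_true(all(diff(anis) > 0))

    gp <- makeGenomePair(30000, 0.9, seed = 18)
    fwd <- orthoAni(gp$genomeA, gp$genomeB)$ani
    rev <- orthoAni(gp$genomeB, gp$genomeA)$ani
    expect_lt(abs(fwd - rev), 0.2)
})

test_that("ANI errors on short genomes and unalignable pairs", {
    short <- GenomeAssembly("s", Biostrings::DNAStringSet(
        c(a = strrep("ACGT", 300))))
    expect_error(orthoAni(short, short), "2 x fragmentLen")
    g1 <- makeGenomePair(12000, 1.0, seed = 1)$genomeA
    g2 <- makeGenomePair(12000, 1.0, seed = 99)$genomeA  # unrelated
    expect_error(orthoAni(g1, g2), "undefined")
})

test_that("POCP equals the closed-form designed truth on synthetic proteomes", {
    pp <- makeProteomePair(4, 4, conservedPairs = 2, seed = 5)
    expect_equal(pocp(pp$proteomeA, pp$proteomeB), pp$truthPocp,
                 tolerance = 1e-9)

    ppAll <- makeProteomePair(5, 5, conservedPairs = 5, seed = 6)
    expect_equal(pocp(ppAll$proteomeA, ppAll$proteomeB), 100.0,
                 tolerance = 1e-9)

    ident <- makeProteomePair(6, 6, conservedPairs = 6,
                              conservedIdentity = 0.999, seed = 7)
    expect_equal(pocp(ident$proteomeA, ident$proteomeA), 100.0)

    # unrelated random proteomes share no qualifying hit
    ppNone <- makeProteomePair(20, 20, conservedPairs = 0,
                               proteinLength = 300, seed = 8)
    expect_equal(pocp(ppNone$proteomeA, ppNone$proteomeB), 0.0,
                 tolerance = 1e-9)

    expect_error(pocp(Biostrings::AAStringSet(), pp$proteomeB), "non-empty")
})

test_that("asymmetric proteome sizes use the (C1+C2)/(T1+T2) denominator", {
    pp <- makeProteomePair(2, 6, conservedPairs = 2, seed = 10)
    expect_equal(pocp(pp$proteomeA, pp$proteomeB), 100 * 4 / 8,
                 tolerance = 1e-9)
})

test_that("mash distance matches the closed form and its boundary cases", {
    gp <- makeGenomePair(20000, 1.0, seed = 3)
    s <- mashSketch(gp$genomeA)
    expect_equal(mashDistance(s, s), 0.0)

    # hand-built sketches with known Jaccard index 1/3 over the merged sketch
    h3 <- new("MashSketch", k = 21L, sketchSize = 6L,
              hashes = c(1, 2, 3, 4, 5, 6))
    h4 <- new("MashSketch", k = 21L, sketchSize = 6L,
              hashes = c(1, 2, 7, 8, 9, 10))
    # merged bottom-6 = {1,2,3,4,5,6}; shared = {1,2} -> j = 1/3
    expect_equal(mashDistance(h3, h4), mashOracle(1 / 3, 21),
                 tolerance = 1e-12)
    expect_equal(mashOracle(1 / 3, 21), log(2) / 21, tolerance = 1e-9)

    disj <- new("MashSketch", k = 21L, sketchSize = 6L,
                hashes = c(11, 12, 13, 14, 15, 16))
    expect_equal(mashDistance(h3, disj), 1.0)

    wrongK <- new("MashSketch", k = 15L, sketchSize = 4L,
                  hashes = c(1, 2, 3, 4))
    expect_error(mashDistance(h3, wrongK), "different k")
})

test_that("mash distance grows as ANI falls on the synthetic ladder", {
    ds <- vapply(c(0.99, 0.95, 0.90, 0.80), function(t) {
        gp <- makeGenomePair(20000, t, seed = 23)
        mashDistance(mashSketch(gp$genomeA), mashSketch(gp$genomeB))
    }, numeric(1))
    expect_true(all(diff(ds) > 0))
})

test_that("reference matching applies the strict 0.05 boundary", {
    gp97 <- makeGenomePair(20000, 0.97, seed = 25)
    gp80 <- makeGenomePair(20000, 0.80, seed = 26)
    refs <- list(near = gp97$genomeB, far = gp80$genomeB,
                 self = gp97$genomeA)
    hits <- matchReferenceSpecies(gp97$genomeA, refs)
    expect_true(all(c("self", "near") %in% hits$ref))
    expect_false("far" %in% hits$ref)
    expect_identical(hits$ref[1], "self")  # sorted ascending, d = 0 first
    expect_equal(hits$distance[1], 0.0)

    none <- matchReferenceSpecies(gp80$genomeA, list(far = gp97$genomeB))
    expect_identical(nrow(none), 0L)  # dark-species candidate
})

test_that("dDDH estimate is maximal for identical genomes, symmetric, monotone", {
    gp <- makeGenomePair(20000, 1.0, seed = 31)
    selfDdh <- ddhEstimate(gp$genomeA, gp$genomeA)
    expect_equal(selfDdh$distanceF2, 0.0)
    expect_equal(selfDdh$ddh, 100 * plogis(5.35), tolerance = 1e-9)

    gp99 <- makeGenomePair(20000, 0.99, seed = 32)
    gp85 <- makeGenomePair(20000, 0.85, seed = 32)
    d99 <- ddhEstimate(gp99$genomeA, gp99$genomeB)
    d85 <- ddhEstimate(gp85$genomeA, gp85$genomeB)
    expect_lt(d85$ddh, d99$ddh)
    expect_gt(d85$distanceF2, d99$distanceF2)

    swap <- ddhEstimate(gp99$genomeB, gp99$genomeA)
    expect_equal(swap$ddh, d99$ddh, tolerance = 0.5)
})

test_that("assembly statistics match brute-force N50 and the exact score", {
    contigs <- Biostrings::DNAStringSet(setNames(
        vapply(c(5000, 4000, 3000, 2000, 1000),
               function(n) strrep("A", n), ""),
        paste0("c", 1:5)))
    ga <- GenomeAssembly("t", contigs)
    st <- assemblyStats(ga, 97.65, 0.63)
    expect_identical(st$n50, 4000L)
    expect_identical(st$n50, n50Oracle(Biostrings::width(contigs)))
    expect_equal(st$qualityScore, 97.65 - 5 * 0.63, tolerance = 1e-12)

    one <- GenomeAssembly("m", Biostrings::DNAStringSet(
        c(c1 = strrep("ACGT", 250000))))
    expect_identical(assemblyStats(one, 100, 0)$n50, 1000000L)

    # randomized N50 agreement with the scanning oracle
    set.seed(42)
    for (i in 1:10) {
        w <- sample(500:5000, sample(3:12, 1))
        g <- GenomeAssembly("r", Biostrings::DNAStringSet(
            setNames(vapply(w, function(n) strrep("A", n), ""),
                     paste0("c", seq_along(w)))))
        expect_identical(assemblyStats(g, 90, 1)$n50, n50Oracle(w))
    }
})

test_that("quality score is linear: mean of scores equals score of means", {
    set.seed(7)
    comp <- runif(20, 80, 100)
    cont <- runif(20, 0, 4)
    g <- GenomeAssembly("x", Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 500))))
    scores <- vapply(seq_along(comp),
                     function(i) assemblyStats(g, comp[i], cont[i])$qualityScore,
                     numeric(1))
    expect_equal(mean(scores),
                 assemblyStats(g, mean(comp), mean(cont))$qualityScore,
                 tolerance = 1e-12)
})
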