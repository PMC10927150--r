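test_that("plate normalisation follows the background/vehicle arithmetic", {
    # toy plate: background {10, 10}, one vehicle well 110, one test 60
    plate <- data.frame(
        plate = "P1",
        well = c("B1", "B2", "V1", "T1"),
        drug = c("NONE", "NONE", "VEH", "DOX"),
        conc_uM = c(0, 0, 1, 1),
        rflu = c(10, 10, 110, 60),
        is_background = c(TRUE, TRUE, FALSE, FALSE))
    v <- normalizePlate(plate)
    expect_equal(v$viability[v$drug == "DOX"], (60 - 10) / (110 - 10))
    # well equal to background -> viability 0; equal to vehicle -> 1
    plate$rflu[4] <- 10
    expect_equal(normalizePlate(plate)$viability[2], 0)
    plate$rflu[4] <- 110
    expect_equal(normalizePlate(plate)$viability[2], 1)
})

test_that("plate normalisation is invariant to a constant plate offset", {
    plate <- simulateViabilityPlate(list(DOX = c(b = 2, c = 0.1, e = 1)),
                                    noiseSd = 0.01, seed = 8)
    shifted <- plate
    shifted$rflu <- shifted$rflu + 500
    expect_equal(normalizePlate(plate)$viability,
                 normalizePlate(shifted)$viability, tolerance = 1e-10)
})

test_that("normalisation errors name the offending condition", {
    plate <- data.frame(plate = "P1", well = c("B1", "T1"),
                        drug = c("NONE", "DOX"), conc_uM = c(0, 5),
                        rflu = c(10, 60),
                        is_background = c(TRUE, FALSE))
    expect_error(normalizePlate(plate), "5")
    plate2 <- data.frame(plate = "P1", well = c("B1", "V1", "T1"),
                         drug = c("NONE", "VEH", "DOX"),
                         conc_uM = c(0, 1, 1), rflu = c(100, 50, 80),
                         is_background = c(TRUE, FALSE, FALSE))
    expect_error(normalizePlate(plate2), "<= 0")
})

test_that("noiseless 4PL data are recovered to numerical precision", {
    conc <- c(50, 10, 5, 1, 0.5, 0.1, 0.05, 0.01)
    for (b in c(0.5, 1.5, 3, 5)) {
        for (cc in c(0, 0.2, 0.45)) {
            for (e in c(0.2, 2, 10)) {
                y <- rep(ll4(conc, b, cc, e), each = 4)
                x <- rep(conc, each = 4)
                fit <- fitLL4FixedUpper(x, y)
                expect_true(fit@converged)
                expect_lt(abs(fit@b - b) / b, 1e-6)
                expect_lt(abs(fit@c - cc), 1e-6)
                expect_lt(abs(fit@e - e) / e, 1e-6)
            }
        }
    }
})

test_that("flat viability yields a degenerate fit with undefined LD50", {
    conc <- rep(c(50, 10, 1, 0.1, 0.01), each = 4)
    fit <- fitLL4FixedUpper(conc, rep(1, length(conc)))
    expect_false(fit@converged)
    expect_true(is.na(fit@ld50))
    expect_error(fitLL4FixedUpper(c(1, 2, 3), c(1, 0.5, 0.2)),
                 "4 distinct")
})

test_that("LD50 has its closed form and agrees with bisection", {
    # c = 0: LD50 equals the inflection point exactly
    fit <- new("DoseResponseFit", b = 2, c = 0, d = 1, e = 3.7,
               ld50 = NA_real_, rss = 0, converged = TRUE,
               diagnostics = character())
    expect_equal(extractLD50(fit), 3.7)
    # closed form at (b = 1.5, c = 0.1, e = 2): 2 * (0.9/0.4 - 1)^(1/1.5)
    fit@b <- 1.5; fit@c <- 0.1; fit@e <- 2
    expect_equal(extractLD50(fit), 2 * (0.9 / 0.4 - 1)^(1 / 1.5),
                 tolerance = 1e-12)
    # floor above 50% kill: undefined
    fit@c <- 0.6
    expect_true(is.na(extractLD50(fit)))
    # bisection agreement to 1e-9 relative on random parameter draws
    set.seed(1)
    for (i in 1:50) {
        b <- runif(1, 0.5, 5); cc <- runif(1, 0, 0.45)
        e <- 10^runif(1, -2, 2)
        fit@b <- b; fit@c <- cc; fit@e <- e
        expect_equal(extractLD50(fit), oracleLd50Bisect(b, cc, e),
                     tolerance = 1e-9)
    }
})

test_that("fitted curves are monotone with the expected limits", {
    conc <- c(50, 10, 5, 1, 0.5, 0.1, 0.05, 0.01)
    y <- ll4(conc, 2, 0.3, 1.5)
    fit <- fitLL4FixedUpper(conc, y)
    grid <- 10^seq(-4, 4, length.out = 200)
    vals <- ll4(grid, fit@b, fit@c, fit@e)
    expect_true(all(diff(vals) < 1e-12))
    expect_equal(vals[1], 1, tolerance = 1e-3)
    expect_equal(vals[length(vals)], fit@c, tolerance = 1e-3)
})

test_that("LD50 summaries compare drugs with the Welch t test", {
    tab <- data.frame(
        drug = rep(c("DOX", "DNR"), each = 6),
        individual = rep(paste0("i", 1:3), times = 4),
        replicate = rep(rep(1:2, each = 3), 2),
        ld50 = c(1, 2, 3, 1, 2, 3, 4, 5, 6, 4, 5, 6))
    out <- summarizeLD50(tab, reference = "DOX")
    ref <- t.test(c(4, 5, 6), c(1, 2, 3))
    cmp <- out$comparisons[out$comparisons$drug == "DNR", ]
    expect_equal(cmp$t, unname(ref$statistic))
    expect_equal(cmp$p, ref$p.value)
    expect_equal(out$perDrug$median_ld50[out$perDrug$drug == "DOX"], 2)
    # identical vectors: no difference
    tab$ld50[tab$drug == "DNR"] <- tab$ld50[tab$drug == "DOX"]
    out2 <- summarizeLD50(tab)
    expect_equal(out2$comparisons$t, 0)
    expect_equal(out2$comparisons$p, 1)
    # single drug: medians only
    out3 <- summarizeLD50(tab[tab$drug == "DOX", ])
    expect_equal(nrow(out3$comparisons), 0)
    expect_equal(nrow(out3$perDrug), 1)
})

test_that("viability-stress correlation behaves at the extremes", {
    grid <- expand.grid(individual = paste0("i", 1:3),
                        drug = "DOX", conc_uM = c(0.1, 1, 10),
                        stringsAsFactors = FALSE)
    grid$viability <- seq(0.9, 0.1, length.out = nrow(grid))
    ldh <- rbind(
        data.frame(individual = grid$individual, drug = "VEH",
                   conc_uM = grid$conc_uM, ldh = 1),
        data.frame(individual = grid$individual, drug = "DOX",
                   conc_uM = grid$conc_uM, ldh = 2 - grid$viability))
    out <- correlateStress(grid, ldh)
    expect_equal(out$rho[out$drug == "DOX"], -1)
    # constant LDH: undefined correlation
    ldh$ldh[ldh$drug == "DOX"] <- 1
    out2 <- correlateStress(grid, ldh)
    expect_true(is.na(out2$rho[out2$drug == "DOX"]))
})
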