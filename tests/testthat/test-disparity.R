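# gender disparity ratios, bands, quintiles, group summaries, changes

mk_scores <- function(qci_male, qci_female, location = "L", year = 2019L) {
  data.frame(location = rep(location, 2L), year = year,
             sex = c("male", "female"), qci = c(qci_male, qci_female),
             stringsAsFactors = FALSE)
}

test_that("the worked global 2019 GDR falls in the optimal band", {
  g <- compute_gdr(mk_scores(93.6, 94.3, location = "Global"))
  expect_equal(g$gdr, 93.6 / 94.3, tolerance = 1e-12)
  expect_equal(round(g$gdr, 5), 0.99258)
  expect_equal(as.character(g$band), "[0.95,1.05]")
})

test_that("GDR is male over female QCI with band arithmetic", {
  expect_equal(compute_gdr(mk_scores(50, 50))$gdr, 1)
  expect_equal(as.character(compute_gdr(mk_scores(50, 50))$band),
               "[0.95,1.05]")
  g <- compute_gdr(mk_scores(30, 100))
  expect_equal(g$gdr, 0.3)
  expect_equal(as.character(g$band), "[0,0.5)")
  # female QCI of zero leaves the ratio undefined
  expect_message(g0 <- compute_gdr(mk_scores(10, 0)), "undefined")
  expect_true(is.na(g0$gdr))
  expect_error(compute_gdr(mk_scores(NA, NA)), "no overlapping")
})

test_that("swapping the sexes gives the reciprocal ratio", {
  set.seed(23)
  qm <- runif(20, 10, 100)
  qf <- runif(20, 10, 100)
  sc <- data.frame(location = rep(sprintf("l%02d", 1:20), each = 2),
                   year = 2019L, sex = c("male", "female"),
                   qci = as.vector(rbind(qm, qf)))
  sw <- sc
  sw$sex <- ifelse(sw$sex == "male", "female", "male")
  expect_equal(compute_gdr(sw)$gdr, 1 / compute_gdr(sc)$gdr)
})

test_that("band boundaries follow the pinned convention", {
  expect_equal(as.character(classify_gdr_band(1.00)), "[0.95,1.05]")
  expect_equal(as.character(classify_gdr_band(0.95)), "[0.95,1.05]")
  expect_equal(as.character(classify_gdr_band(1.05)), "[0.95,1.05]")
  expect_equal(as.character(classify_gdr_band(0.9499)), "[0.5,0.95)")
  expect_equal(as.character(classify_gdr_band(0.5)), "[0.5,0.95)")
  expect_equal(as.character(classify_gdr_band(0.4999)), "[0,0.5)")
  expect_equal(as.character(classify_gdr_band(1.0501)), "(1.05,1.5]")
  expect_equal(as.character(classify_gdr_band(1.5)), "(1.05,1.5]")
  expect_equal(as.character(classify_gdr_band(1.6)), "(1.5,Inf)")
  expect_error(classify_gdr_band(0), "domain")
  expect_error(classify_gdr_band(-1), "domain")
  expect_error(classify_gdr_band(Inf), "domain")
})

test_that("banding agrees with direct interval membership on random draws", {
  set.seed(12)
  g <- rlnorm(10000, 0, 0.5)
  got <- as.character(classify_gdr_band(g))
  direct <- ifelse(g >= 0 & g < 0.5, "[0,0.5)",
            ifelse(g >= 0.5 & g < 0.95, "[0.5,0.95)",
            ifelse(g >= 0.95 & g <= 1.05, "[0.95,1.05]",
            ifelse(g > 1.05 & g <= 1.5, "(1.05,1.5]", "(1.5,Inf)"))))
  expect_identical(got, direct)
})

test_that("band counts partition the locations with a defined GDR", {
  sc <- do.call(rbind, lapply(1:3, function(i)
    mk_scores(50, 50, location = paste0("l", i))))
  tab <- count_by_band(compute_gdr(sc), 2019)
  expect_equal(unname(tab["[0.95,1.05]"]), 3L)
  expect_equal(sum(tab), 3L)

  set.seed(31)
  n <- 40
  sc2 <- data.frame(location = rep(sprintf("l%02d", 1:n), each = 2),
                    year = 2019L, sex = c("male", "female"),
                    qci = runif(2 * n, 5, 100))
  g2 <- compute_gdr(sc2)
  tab2 <- count_by_band(g2, 2019)
  expect_equal(sum(tab2), sum(!is.na(g2$gdr)))
  expect_error(count_by_band(g2, 1990), "not present")
})

test_that("quintile ranking cuts near-equal groups, highest QCI in Q5", {
  sc <- data.frame(location = sprintf("l%02d", 1:10), year = 2019L,
                   sex = "both", qci = seq(5, 95, by = 10))
  q <- qci_quintiles(sc, 2019)
  expect_equal(as.vector(table(q$quintile)), rep(2L, 5))
  expect_equal(q$quintile[which.max(q$qci)], 5L)
  expect_equal(q$quintile[which.min(q$qci)], 1L)

  sc7 <- sc[1:7, ]
  q7 <- qci_quintiles(sc7, 2019)
  expect_equal(as.vector(table(q7$quintile)), c(2L, 1L, 1L, 1L, 2L))

  # all tied: assignment falls back to alphabetical order
  tied <- data.frame(location = c("e", "d", "c", "b", "a"), year = 2019L,
                     sex = "both", qci = 50)
  qt <- qci_quintiles(tied, 2019)
  expect_equal(qt$location, c("a", "b", "c", "d", "e"))
  expect_equal(qt$quintile, 1:5)

  expect_error(qci_quintiles(sc[1:4, ], 2019), "insufficient")
})

test_that("quintiles are invariant under monotone transforms of the QCI", {
  set.seed(41)
  sc <- data.frame(location = sprintf("l%02d", 1:23), year = 2019L,
                   sex = "both", qci = runif(23, 0, 100))
  ref <- qci_quintiles(sc, 2019)
  tr <- sc
  tr$qci <- sqrt(tr$qci) * 3 + 1
  got <- qci_quintiles(tr, 2019)
  expect_equal(got[c("location", "quintile")], ref[c("location", "quintile")])
})

test_that("group summaries prefer published group rows over member means", {
  sc <- data.frame(
    location = c("A", "B", "High income", "C"),
    year = 2019L, sex = "both", qci = c(40, 60, 97, 80))
  scheme <- data.frame(location = c("A", "B", "C"),
                       group = c("High income", "High income", "Low income"))
  auto <- group_summary(sc, scheme, 2019)
  expect_equal(auto$qci[auto$group == "High income"], 97)
  expect_equal(auto$source[auto$group == "High income"], "group_row")
  # no group-level row for Low income: unweighted member mean
  expect_equal(auto$qci[auto$group == "Low income"], 80)
  expect_equal(auto$source[auto$group == "Low income"], "member_mean")

  mm <- group_summary(sc, scheme, 2019, mode = "member_mean")
  expect_equal(mm$qci[mm$group == "High income"], 50)

  one <- group_summary(sc, data.frame(location = "C", group = "Solo"), 2019)
  expect_equal(one$qci, 80)

  expect_warning(
    group_summary(sc, data.frame(location = "Z", group = "Empty"), 2019),
    "omitted")
})

test_that("period change is end minus start, matching the printed table", {
  expect_equal(change_between(19.63, 7.51), -12.12)
  expect_equal(change_between(5, 5), 0)
  expect_equal(change_between(66.36, 90.20), 23.84)
  # antisymmetry
  set.seed(2)
  a <- rnorm(50)
  b <- rnorm(50)
  expect_equal(change_between(a, b), -change_between(b, a))
  expect_true(is.na(change_between(NA, 1)))
})
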