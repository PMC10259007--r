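test_that("within-group standardisation gives exact z-scores", {
  tab <- data.frame(id = 1:3, rtle = c(300, 310, 320), group = "G1")
  out <- standardize_rtle(tab)
  expect_equal(out$tle, c(-1, 0, 1)) # sd = 10 with the n-1 denominator

  st <- small_study()
  ph <- st$pheno
  for (g in unique(ph$group)) {
    expect_lt(abs(mean(ph$tle[ph$group == g])), 1e-12)
    expect_lt(abs(sd(ph$tle[ph$group == g]) - 1), 1e-12)
  }
  # idempotent: standardising the standardised phenotype changes nothing
  ph2 <- ph; ph2$rtle <- ph2$tle
  expect_equal(standardize_rtle(ph2)$tle, ph$tle, tolerance = 1e-12)
})

test_that("standardisation rejects singleton groups by name", {
  tab <- data.frame(id = 1:3, rtle = c(300, 310, 320),
                    group = c("G1", "G1", "G9"))
  expect_error(standardize_rtle(tab), "G9")
  tab$group <- NULL
  expect_error(standardize_rtle(tab), "required")
})

test_that("cumulative degree-minutes follow the closed forms", {
  const <- heating_curve("G1", t0 = 17, segments = data.frame(
    duration_h = Inf, rate_c_per_h = 0))
  tab <- data.frame(id = 1, rtle = 100, group = "G1")
  expect_equal(cumulative_degrees(tab, list(G1 = const))$ctu, 0)

  # +0.05 C/min linear: CTU at 120 min is 0.05 * 120 * 121 / 2
  lin <- heating_curve("G1", t0 = 10, segments = data.frame(
    duration_h = Inf, rate_c_per_h = 3))
  tab2 <- data.frame(id = 1, rtle = 120, group = "G1")
  expect_equal(cumulative_degrees(tab2, list(G1 = lin))$ctu, 363)

  # monotone in rTLE within a group (CTU is discretised to whole minutes,
  # so equal values are allowed only for fish lost in the same minute)
  st <- small_study()
  ph <- cumulative_degrees(st$pheno, st$sim$heating_curves)
  for (g in unique(ph$group)) {
    i <- which(ph$group == g)
    o <- i[order(ph$rtle[i])]
    expect_true(all(diff(ph$ctu[o]) >= 0))
    expect_equal(cor(ph$ctu[o], floor(ph$rtle[o]), method = "spearman"), 1)
  }
  expect_true(all(ph$ctu >= 0))

  short <- heating_curve("G1", t0 = 10, segments = data.frame(
    duration_h = 0.5, rate_c_per_h = 3))
  expect_error(cumulative_degrees(tab2, list(G1 = short)), "ends before")
  expect_error(cumulative_degrees(tab2, list()), "no heating curve")
})

test_that("harvest derivation and the 10-g filter follow the rules", {
  tab <- data.frame(id = c("a", "b", "c"),
                    bw2 = c(1000, 500, 800),
                    hgcw = c(787, 380, 630),
                    headw = c(115, 60, 90),
                    viscw = c(95, 49, 78),
                    fat_ant = c(4, 5, 6), fat_post = c(5, 5, 6))
  out <- derive_and_filter_harvest(tab)
  # yields: HGC% is the HGCW/BW2 ratio in percent, fat is the site mean
  expect_equal(out$table$hgc_pct[out$table$id == "a"], 78.7)
  expect_equal(out$table$fat_pct[out$table$id == "a"], 4.5)
  # record b: parts sum 489, discrepancy 11 g > 10 -> removed
  expect_equal(out$removed, "b")
  expect_equal(out$report$discrepancy_g, 11)
  # filtering never alters surviving records; removed + surviving = input
  expect_equal(nrow(out$table) + length(out$removed), nrow(tab))
  expect_equal(out$table[c("bw2", "hgcw")],
               tab[tab$id != "b", c("bw2", "hgcw")], ignore_attr = TRUE)
  expect_error(derive_and_filter_harvest(transform(tab, bw2 = c(0, 500, 800))),
               "zero")
})

test_that("descriptive statistics reproduce the printed group summaries", {
  gs <- read.delim(system.file("extdata", "challenge_group_summary.tsv",
                               package = "troutherm"))
  d <- descriptives(group_stats = data.frame(mean = gs$rtle_mean,
                                             sd = gs$rtle_sd,
                                             n = gs$n_assigned))
  expect_equal(d$pooled_n, 1327)
  expect_equal(round(d$pooled_mean, 1), 412.2)

  ts <- read.delim(system.file("extdata", "challenge_trait_summary.tsv",
                               package = "troutherm"))
  rt <- ts[ts$trait == "rTLE", ]
  expect_equal(round(cv_pct(rt$mean, rt$sd), 1), 13.6)

  expect_equal(descriptives(c(5))$sd, 0)
  expect_error(descriptives(c(0, 0)), "mean is zero")
  x <- rnorm(50, 10, 2)
  d2 <- descriptives(x)
  expect_equal(d2$cv, sd(x) / mean(x) * 100)
  expect_equal(d2$n, 50)
})
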