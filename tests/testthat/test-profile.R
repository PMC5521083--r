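# a small synthetic background table with known counts
toy_background <- function() {
  # 2 positions with ref C, 1 with ref G; plasma counts chosen by hand
  mk_background(data.table::data.table(
    pos = rep(c(10L, 20L, 30L), each = 3L),
    ref = rep(c("C", "C", "G"), each = 3L),
    alt = c("A", "G", "T", "A", "G", "T", "A", "C", "T"),
    category = "background",
    plasma_count = c(8L, 0L, 0L, 0L, 0L, 2L, 1L, 0L, 4L),
    plasma_depth = rep(c(50000L, 50000L, 40000L), each = 3L),
    plasma_vaf = 0,
    pbl_count = c(16L, 0L, 0L, 4L, 0L, 2L, 1L, 0L, 4L),
    pbl_depth = rep(c(50000L, 50000L, 40000L), each = 3L),
    pbl_vaf = 0
  ))
}

test_that("class rates are numerator/denominator by definition", {
  cr <- class_rates(toy_background(), "plasma")
  expect_equal(cr[class == "C>A", rate], 8 / 100000)
  expect_equal(cr[class == "C>T", rate], 2 / 100000)
  expect_equal(cr[class == "G>T", rate], 4 / 40000)
  expect_true(is.na(cr[class == "A>C", rate]))   # no A sites: missing
  # overall = all background alt bases / depth summed over eligible positions
  expect_equal(attr(cr, "overall"), 15 / 140000)
})

test_that("collapsing pools counts and handles degenerate members", {
  cr <- class_rates(toy_background(), "plasma")
  cc <- collapse_classes(cr)
  # C>A (8/1e5) + G>T (4/4e4) -> pooled 12/1.4e5
  expect_equal(cc[class == "C:G>A:T", numerator], 12)
  expect_equal(cc[class == "C:G>A:T", denominator], 140000)
  expect_equal(cc[class == "C:G>A:T", rate], 12 / 140000)
  # pooled rate over both members' counts
  expect_equal(cc[class == "C:G>T:A", rate], (2 + 1) / 140000)
  # classes with no eligible source sites stay missing after collapsing
  expect_true(is.na(cc[class == "T:A>C:G", rate]))
  # conservation of counts
  expect_equal(sum(cc$numerator), sum(cr$numerator))
  expect_equal(sum(cc$denominator), sum(cr$denominator))
  expect_identical(collapse_classes(cc), cc)   # idempotent
})

test_that("worked pooling example: 8/1e5 with 4/1e5 gives 6e-5", {
  tab <- mk_background(data.table::data.table(
    pos = rep(c(1L, 2L), each = 3L), ref = rep(c("C", "G"), each = 3L),
    alt = c("A", "G", "T", "A", "C", "T"), category = "background",
    plasma_count = c(8L, 0L, 0L, 0L, 0L, 4L),
    plasma_depth = rep(100000L, 6L), plasma_vaf = 0,
    pbl_count = 0L, pbl_depth = rep(100000L, 6L), pbl_vaf = 0
  ))
  cc <- collapse_classes(class_rates(tab, "plasma"))
  expect_equal(cc[class == "C:G>A:T", rate], 6e-5)
})

test_that("error-free fraction counts eligible positions without errors", {
  tab <- toy_background()
  # positions 20 and 30 have plasma errors at some allele? pos10: 8 errors;
  # pos20: 2; pos30: 5 -> none error-free
  expect_equal(error_free_fraction(tab, "plasma"), 0)
  tab2 <- copy(tab)[, plasma_count := 0L]
  expect_equal(error_free_fraction(mk_background(tab2), "plasma"), 1)
  tab3 <- copy(tab)
  tab3[pos != 10L, plasma_count := 0L]
  expect_equal(error_free_fraction(mk_background(tab3), "plasma"), 2 / 3)
  expect_error(error_free_fraction(mk_background(tab[category != "background"]),
                                   "plasma"), "no background")
})

test_that("context marginalization recovers class rates exactly", {
  cfg <- sim_config(seed = 51, ref_length = 14000, n_fragments = 9000,
                    snp_density = 0)
  coh <- simulate_cohort(cfg, n_pairs = 1, fna = FALSE)
  th <- filter_thresholds(min_depth_pair = 100)
  pu <- lapply(coh$subjects[[1]][c("plasma", "pbl")], function(s)
    build_pileup(filter_reads(s$reads, th), coh$reference, th))
  tab <- call_background(pu$plasma, pu$pbl, thresholds = th)
  ctx <- context_rates(tab, coh$reference, "pbl")
  marg <- ctx[, .(numerator = sum(numerator), denominator = sum(denominator)),
              by = class]
  cc <- collapse_classes(class_rates(tab, "pbl"))
  m <- merge(marg, cc[, .(class, num0 = numerator, den0 = denominator)], by = "class")
  # targets sit away from reference edges, so no positions are lost
  expect_equal(m$numerator, m$num0)
  expect_equal(m$denominator, m$den0)
})

test_that("reciprocal ratios reproduce printed-rate arithmetic", {
  rates <- rep(2e-5, 12)
  rates[4] <- 8.7e-5   # C>A
  rates[9] <- 5.4e-5   # G>T
  t1 <- mk_rate_table(rates)
  expect_equal(reciprocal_ratio(t1, c("C>A", "G>T")), 8.7 / 5.4, tolerance = 1e-12)
  expect_equal(round(reciprocal_ratio(t1, c("C>A", "G>T")), 2), 1.61)
  expect_equal(reciprocal_ratio(mk_rate_table(rep(3e-5, 12)), c("C>T", "G>A")), 1)
  # zero baseline -> missing
  r0 <- rates; r0[9] <- 0
  expect_true(is.na(reciprocal_ratio(mk_rate_table(r0), c("C>A", "G>T"))))
  # cohort aggregation returns mean/sd of per-sample ratios and pooled form
  t2 <- mk_rate_table(rates * 1.2)
  agg <- reciprocal_ratio_cohort(list(t1, t2), c("C>A", "G>T"))
  expect_equal(agg$mean, 8.7 / 5.4, tolerance = 1e-12)
  expect_equal(agg$sd, 0, tolerance = 1e-12)
  expect_equal(agg$pooled, (8.7e-5 * 1.1) / (5.4e-5 * 1.1), tolerance = 1e-12)
})

test_that("shear attribution implements its defining arithmetic", {
  r_pl <- rep(5e-5, 12); r_pb <- rep(5e-5, 12)
  r_pb[c(4, 9)] <- 2e-4   # C>A and G>T elevated so collapsed C:G>A:T = 2e-4
  att <- attribute_shear(mk_rate_table(r_pb), mk_rate_table(r_pl))
  expect_equal(att[class == "C:G>A:T", shear_fraction], 0.75)
  expect_equal(att[class == "C:G>A:T", shear_increase], 3.0)
  expect_equal(att[class == "T:A>C:G", shear_fraction], 0)
  expect_equal(att[class == "T:A>C:G", shear_increase], 0)
  # cohort wrapper averages per-subject values
  agg <- attribute_shear_cohort(list(mk_rate_table(r_pb), mk_rate_table(r_pb)),
                                list(mk_rate_table(r_pl), mk_rate_table(r_pl)))
  expect_equal(agg[class == "C:G>A:T", shear_fraction_mean], 0.75)
  expect_equal(agg[class == "C:G>A:T", shear_fraction_sd], 0)
})

test_that("hybrid-selection asymmetry matches the printed plasma rates", {
  rates <- rep(2e-5, 12)
  rates[4] <- 8.7e-5; rates[9] <- 5.4e-5
  hs <- attribute_hybsel(mk_rate_table(rates), "minus")
  expect_equal(hs[pair == "C>A/G>T", asymmetry], (8.7 - 5.4) / 8.7, tolerance = 1e-12)
  expect_equal(round(hs[pair == "C>A/G>T", asymmetry], 3), 0.379)
  # symmetric rates: asymmetry 0
  hs0 <- attribute_hybsel(mk_rate_table(rep(4e-5, 12)), "minus")
  expect_equal(hs0$asymmetry, c(0, 0))
  # pure hybrid-selection injection: baseline 0, asymmetry -> 1
  r1 <- rep(0, 12); r1[4] <- 5e-5
  hs1 <- attribute_hybsel(mk_rate_table(r1), "minus")
  expect_equal(hs1[pair == "C>A/G>T", asymmetry], 1)
  # plus-strand capture flips the excess side
  hsp <- attribute_hybsel(mk_rate_table(rates), "plus")
  expect_identical(hsp$excess_class, c("G>T", "G>A"))
})
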