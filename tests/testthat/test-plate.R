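test_that("the default plate map matches the control layout", {
  lib <- drug_library(n = 320, seed = 1)
  map <- build_plate_map(lib)
  expect_equal(sum(map$role == "negative_control"), 16)
  expect_equal(sum(map$role == "positive_control"), 16)
  expect_equal(sum(map$role == "test"), 320)
  expect_equal(sum(map$role == "empty"), 32)
  # controls split by row half in columns 2 and 23
  expect_true(all(map$role[map$well %in% c("A2", "H2", "A23", "H23")] ==
                    "negative_control"))
  expect_true(all(map$role[map$well %in% c("I2", "P2", "I23", "P23")] ==
                    "positive_control"))
  # column-wise scan from A2 to P23
  expect_equal(map$well[which(map$scan_order == 1)], "A2")
  expect_equal(map$well[which(map$scan_order == 352)], "P23")
  # test wells fill column-wise starting at A3
  expect_equal(map$compound[map$well == "A3"], "cmpd-001")
  expect_equal(map$compound[map$well == "B3"], "cmpd-002")
  # empty library leaves all test wells empty
  map0 <- build_plate_map(NULL)
  expect_equal(sum(map0$role == "test"), 0)
  expect_equal(sum(map0$role == "empty"), 352)
})

test_that("plate maps round-trip through delimited text", {
  map <- build_plate_map(drug_library(n = 10, seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_plate_map(map, path)
  back <- read_plate_map(path)
  expect_equal(as.data.frame(back), as.data.frame(map)[, colnames(back)])
})

test_that("drug libraries have unique labels and the requested mix", {
  lib <- drug_library(n = 100, seed = 2)
  expect_false(any(duplicated(lib$table$label)))
  expect_equal(nrow(lib$table), 100)
  expect_equal(sum(lib$table$active), sum(lib$table$class %in%
                                            c("slow_unbind", "fast_unbind")))
  expect_equal(mean(lib$table$active), 0.12, tolerance = 0.25)
  expect_error(drug_library(fractions = c(inert = 0.5, tonic = 0.1,
                                          slow_unbind = 0.1,
                                          fast_unbind = 0.1,
                                          gating_shift = 0.1)), "sum to 1")
})

# one small plate is shared by the simulation tests below: 8 compounds
# (2 per non-inert class) plus the 32 control wells
small_lib <- drug_library(n = 8, seed = 11,
                          fractions = c(inert = 0.25, tonic = 0.125,
                                        slow_unbind = 0.25,
                                        fast_unbind = 0.25,
                                        gating_shift = 0.125))
small_map <- build_plate_map(small_lib)
small_traces <- simulate_plate(small_map, seed = 7)
small_res <- run_screen(small_traces, small_map)

test_that("plate simulation is deterministic under a fixed seed", {
  again <- simulate_plate(small_map, seed = 7)
  expect_identical(small_traces[["A2"]]$F, again[["A2"]]$F)
  expect_identical(small_traces[["P23"]]$F, again[["P23"]]$F)
  other <- simulate_plate(small_map, seed = 8)
  expect_false(identical(small_traces[["A2"]]$F, other[["A2"]]$F))
})

test_that("vehicle wells show stable spiking and low sigma spread", {
  w <- small_res$wells
  neg <- w[w$role == "negative_control", ]
  expect_true(all(!neg$flagged))
  expect_true(all(neg$spike_count == 8))
  expect_lt(diff(range(neg$sigma)), 0.05)
  expect_lt(mean(neg$gamma), 0.05)          # inert: no use dependence
  expect_equal(mean(neg$mean_dff), 0.035, tolerance = 0.15)
})

test_that("screen analysis separates the drug classes", {
  w <- merge(small_res$wells, small_lib$table, by.x = "compound",
             by.y = "label", all.x = TRUE)
  agg <- aggregate(cbind(sigma, gamma) ~ class,
                   data = w[w$role == "test", ], FUN = mean)
  expect_gt(agg$gamma[agg$class == "slow_unbind"],
            max(agg$gamma[agg$class != "slow_unbind"]))
  expect_gt(agg$sigma[agg$class == "slow_unbind"],
            agg$sigma[agg$class == "inert"] + 0.05)
  expect_gt(agg$sigma[agg$class == "fast_unbind"],
            agg$sigma[agg$class == "inert"] + 0.01)
  # among the active classes the fast-unbinding one is the less monotone:
  # its alternation score exceeds the slow-unbinding class's
  alt <- aggregate(alternation ~ class, data = w[w$role == "test", ],
                   FUN = mean)
  expect_gt(alt$alternation[alt$class == "fast_unbind"],
            alt$alternation[alt$class == "slow_unbind"])
  # positive controls behave like the slow-unbinding class
  expect_gt(small_res$controls$pos_mean, small_res$controls$neg_mean + 0.05)
  expect_false(is.na(small_res$zprime))
})

test_that("screens without positive controls still call hits", {
  map2 <- small_map[small_map$role != "positive_control", ]
  attr(map2, "library") <- small_lib
  traces2 <- small_traces[names(small_traces) %in% map2$well]
  res2 <- run_screen(traces2, map2)
  expect_true(is.na(res2$zprime))
  expect_false(any(is.na(res2$wells$hit)))
  expect_gt(res2$n_hits, 0)                 # blockers still detected
})

test_that("flat wells are flagged and excluded from hit calling", {
  t <- (0:299) / 100
  flat <- list(A3 = fluorescence_trace("A3", t, rep(1000, 300),
                                       stim_times = seq(0.5, 1.2, 0.1)))
  map <- build_plate_map(drug_library(n = 1, seed = 1))
  res <- suppressWarnings(run_screen(flat, map))
  expect_true(res$wells$flagged[res$wells$well == "A3"])
  expect_false(any(res$wells$hit, na.rm = TRUE))
})
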