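test_that("array thresholds zero sub-threshold arrays and sum the survivors", {
  g <- default_geometry()
  map <- array(0, c(4, 16, 14))
  map[, 1:4, 1] <- 1          # facet 0, array 1 sums to 16
  map[, 5:8, 1] <- 0.2        # facet 0, array 2 sums to 3.2
  th <- apply_thresholds(map, g, daq_config(array_threshold = 5))
  expect_equal(th$array_sums[1, 1], 16)
  expect_equal(th$array_sums[2, 1], 0)      # 3.2 < 5 zeroed
  expect_equal(th$facet_sums[1], 16)
  # threshold 0 keeps everything
  th0 <- apply_thresholds(map, g, daq_config(array_threshold = 0))
  expect_equal(th0$facet_sums[1], 16 + 3.2)
  # inclusive comparison: an array exactly at threshold survives
  thx <- apply_thresholds(map, g, daq_config(array_threshold = 3.2))
  expect_equal(thx$facet_sums[1], 16 + 3.2)
  # all arrays below threshold: everything zero
  thz <- apply_thresholds(map, g, daq_config(array_threshold = 100))
  expect_true(all(thz$facet_sums == 0))
})

test_that("prompt windows, partner filtering and multiple rejection follow the trigger rules", {
  g <- default_geometry()
  cfg <- daq_config(coincidence_window = 2)
  # partner pair 1 ns apart -> one prompt
  s <- synthetic_singles(c(100, 101), c(0, 7))
  co <- find_coincidences(s, g, cfg)
  expect_identical(co$counts$n_prompt, 1L)
  expect_identical(nrow(co$events), 1L)
  # 3 ns apart -> none
  co <- find_coincidences(synthetic_singles(c(100, 103), c(0, 7)), g, cfg)
  expect_identical(co$counts$n_prompt, 0L)
  # adjacent (non-partner) facets -> rejected, counted
  co <- find_coincidences(synthetic_singles(c(100, 101), c(0, 1)), g, cfg)
  expect_identical(co$counts$n_prompt, 0L)
  expect_identical(co$counts$n_nonpartner, 1L)
  # three singles mutually in-window -> all discarded
  co <- find_coincidences(synthetic_singles(c(100, 101, 101.5),
                                            c(0, 7, 3)), g, cfg)
  expect_identical(co$counts$n_prompt, 0L)
  expect_gt(co$counts$n_multiple_discarded, 0)
  # unsorted timeline rejected
  bad <- synthetic_singles(c(100, 101), c(0, 7))
  bad$df <- bad$df[2:1, ]
  expect_error(find_coincidences(bad, g, cfg), "sorted")
})

test_that("primary/secondary assignment is order-invariant and keeps distributions aligned", {
  g <- default_geometry()
  cfg <- daq_config()
  d <- matrix(c(rep(1, 192), rep(2, 192)), 2, 192, byrow = TRUE)
  s12 <- synthetic_singles(c(100, 101), c(0, 7), fsum = c(50, 80), dist = d)
  co <- find_coincidences(s12, g, cfg)
  expect_identical(co$events$primary, 7L)   # larger facet sum
  expect_identical(co$events$secondary, 0L)
  expect_true(all(co$dist_primary == 2))
  expect_true(all(co$dist_secondary == 1))
  # swapping arrival order leaves the assignment unchanged
  s21 <- synthetic_singles(c(100, 101), c(7, 0), fsum = c(80, 50),
                           dist = d[2:1, ])
  co2 <- find_coincidences(s21, g, cfg)
  expect_identical(co2$events$primary, 7L)
  expect_identical(co2$events$secondary, 0L)
  expect_true(all(co2$dist_primary == 2))
})

test_that("12x16 distributions wrap facet neighbours modularly", {
  g <- default_geometry()
  # signals: facet f pixel (iu, iv) coded uniquely
  sig <- matrix(seq_len(14 * 64), 1, 14 * 64)
  d0 <- assemble_distribution(sig, 0L, g)
  m <- distribution_matrix(d0[1, ])
  expect_identical(dim(m), c(12L, 16L))
  # rows 1-4 from facet 13, 5-8 from facet 0, 9-12 from facet 1
  expect_equal(m[1, 1], sig[1, 13 * 64 + 1])
  expect_equal(m[5, 1], sig[1, 1])
  expect_equal(m[9, 1], sig[1, 64 + 1])
  # axial ordering: column j holds pixel row iv = j
  expect_equal(m[5, 2], sig[1, 5])    # iv = 2 -> offset 4 in array order
})

test_that("prompts partition exactly into trues, scatters and randoms", {
  g <- default_geometry()
  truth <- simulate_events(point_source("Na22", 3e6, c(5, 0, 0)), g,
                           physics_config(), n = 2500, seed = 13)
  set.seed(14)
  s <- build_singles(truth, g)
  co <- find_coincidences(s, g)
  cls <- classify_prompts(co)
  expect_identical(length(cls), nrow(co$events))
  expect_identical(sum(table(cls)), as.integer(co$counts$n_prompt))
  expect_gt(sum(cls == "true"), 0)
})

test_that("empty timelines yield no coincidences", {
  g <- default_geometry()
  co <- find_coincidences(synthetic_singles(numeric(0), integer(0)), g)
  expect_identical(co$counts$n_prompt, 0L)
  expect_identical(nrow(co$events), 0L)
})

test_that("random coincidence rate scales as the product of singles rates", {
  g <- default_geometry()
  # uncorrelated Poisson singles: randoms ~ window * S_i * S_j
  rate1 <- rep(2e4, 14)
  s1 <- poisson_singles(rate1, duration = 0.6, seed = 15)
  co1 <- find_coincidences(s1, g, daq_config())
  s2 <- poisson_singles(2 * rate1, duration = 0.6, seed = 16)
  co2 <- find_coincidences(s2, g, daq_config())
  # all prompts here are randoms; quadrupling expected when rates double
  ratio <- co2$counts$n_prompt / co1$counts$n_prompt
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.5)
})

test_that("intrinsic background produces threshold-passing singles on all facets", {
  g <- default_geometry()
  s <- simulate_intrinsic_singles(g, rate = 300, duration = 0.05, seed = 17)
  expect_gt(nrow(s$df), 50)
  expect_true(all(s$df$fsum > 0))
  expect_gt(length(unique(s$df$facet)), 8)
  expect_true(all(s$df$label == "intrinsic"))
})
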