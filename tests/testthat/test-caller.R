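test_that("caller recovers simulated events exactly (noise-free round trip)", {
  for (pct in c(3, 5, 10)) {
    fx <- fixture(pct)
    set <- simulate_colony_set(fx$cassette, fx$pair, 60,
                               mixture_preset(0.5, 0.1, 0.4), seed = pct)
    calls <- call_colony_set(set, fx$cassette)
    tr <- set$events
    expect_identical(calls$event_class, tr$event_class)
    expect_identical(calls$crossover_interval, tr$crossover_interval)
    expect_identical(calls$patch_alleles[!is.na(tr$patch_alleles)],
                     tr$patch_alleles[!is.na(tr$patch_alleles)])
    expect_identical(calls$deletion_size, tr$deletion_size)
    expect_identical(calls$left_bp, tr$left_bp)
    expect_identical(calls$right_bp, tr$right_bp)
    expect_identical(calls$microhomology_len, tr$microhomology_len)
    expect_identical(calls$breakpoint_ambiguity, calls$microhomology_len)
  }
})

test_that("unmodified or unanchorable products are UNRESOLVED", {
  fx <- fixture(5)
  expect_identical(call_junction(fx$cassette$sequence, fx$cassette)$event_class,
                   "UNRESOLVED")
  ev <- simulate_recombination_product(fx$cassette, fx$pair, 2)
  truncated <- substr(ev$product_sequence, 25, nchar(ev$product_sequence))
  expect_identical(call_junction(truncated, fx$cassette)$event_class,
                   "UNRESOLVED")
  # other records in a batch are unaffected
  calls <- call_colony_set(c(a = truncated, b = ev$product_sequence),
                           fx$cassette)
  expect_identical(calls$event_class, c("UNRESOLVED",
                                        "RECOMB_SINGLE_CROSSOVER"))
})

test_that("measure_microhomology matches the brute-force shift oracle", {
  # worked example: AAGATC xxxx GATC AA, deletion of xxxxGATC
  s <- "AAGATCTCTCGATCAA"
  r <- measure_microhomology(s, 6, 14)
  expect_identical(r$microhomology_len, 4L)
  expect_identical(r$left, 2L)          # leftmost placement: deletes TCTCGATC
  expect_identical(r$right, 10L)
  orc <- oracle_microhomology(s, 6, 14)
  expect_identical(r$microhomology_len, orc$len)

  # blunt junction
  fx <- fixture(5)
  sq <- fx$cassette$sequence
  set.seed(7)
  n_checked <- 0
  while (n_checked < 200) {
    l <- sample(1300:2500, 1); r <- l + sample(100:1300, 1)
    if (r > nchar(sq)) next
    m <- measure_microhomology(sq, l, r)
    o <- oracle_microhomology(sq, l, r)
    expect_identical(m$microhomology_len, o$len)
    expect_identical(m$left, o$left)
    expect_identical(m$right, o$right)
    n_checked <- n_checked + 1
  }
})

test_that("equivalent breakpoint placements yield identical calls", {
  fx <- fixture(5)
  sq <- fx$cassette$sequence
  set.seed(13)
  found <- 0
  while (found < 20) {
    l <- sample(1300:2400, 1); r <- l + sample(897:1400, 1)
    if (r > 2900) next
    m <- measure_microhomology(sq, l, r)
    if (m$microhomology_len == 0) next
    found <- found + 1
    ev_a <- simulate_nhej_deletion(fx$cassette, l, r)
    ev_b <- simulate_nhej_deletion(fx$cassette, m$left, m$right)
    expect_identical(ev_a$product_sequence, ev_b$product_sequence)
    ca <- call_junction(ev_a$product_sequence, fx$cassette)
    expect_identical(ca$left_breakpoint, m$left)
    expect_identical(ca$breakpoint_ambiguity, m$microhomology_len)
  }
})

test_that("locate_crossover agrees with the consistency-enumeration oracle", {
  expect_identical(locate_crossover(c(1L, 1L, 2L, 2L, 2L)), 2L)
  expect_identical(locate_crossover(c(2L, 2L, 2L)), 0L)
  expect_identical(locate_crossover(c(1L, 1L, 1L)), 3L)
  expect_identical(locate_crossover(c(1L, 2L, 1L, 2L)), "COMPLEX")
  expect_identical(locate_crossover(integer(0)), 0L)

  for (n in 0:6) {
    for (gv in all_genotype_vectors(n)) {
      expect_identical(locate_crossover(gv), oracle_locate(gv),
                       info = paste(gv, collapse = ","))
    }
  }
})

test_that("NHEJ topology classifies breakpoints against the Alu spans", {
  fx <- fixture(5)
  mk_call <- function(l, r, amb = 0L)
    structure(list(event_class = "NHEJ_DELETION", left_breakpoint = l,
                   right_breakpoint = r, breakpoint_ambiguity = amb),
              class = "junction_call")
  expect_identical(classify_nhej_topology(mk_call(1300L, 2700L), fx$cassette),
                   "both_Alus")
  expect_identical(classify_nhej_topology(mk_call(1100L, 2700L), fx$cassette),
                   "one_Alu")
  expect_identical(classify_nhej_topology(mk_call(1600L, 2950L), fx$cassette),
                   "no_Alu")
  # any_placement mode can rescue a breakpoint just left of the span
  expect_identical(
    classify_nhej_topology(mk_call(1195L, 2700L, amb = 10L), fx$cassette,
                           mode = "any_placement"), "both_Alus")
  expect_error(
    classify_nhej_topology(structure(list(event_class = "UNRESOLVED"),
                                     class = "junction_call"), fx$cassette),
    "NHEJ")
})

test_that("topology fractions match the geometric expectation", {
  fx <- fixture(5)
  set <- simulate_colony_set(fx$cassette, fx$pair, 400,
                             mixture_preset(0, 0, 1), seed = 17)
  calls <- call_colony_set(set, fx$cassette)
  # closed-form expectation under the detectability constraints: enumerate
  # the admissible uniform (left, right) lattice directly
  pa_s <- 2532L; sce_e <- 2600L; w <- c(897L, 1881L)
  lefts <- 1200:2532
  n_both <- n_one <- n_tot <- 0
  for (l in lefts) {
    r_lo <- max(sce_e, l + w[1]); r_hi <- min(2900L, l + w[2])
    if (r_lo > r_hi) next
    rs <- r_lo:r_hi
    l_in <- l >= 1200L && l < 1500L
    r_in <- rs >= 2600L & rs < 2900L
    n_tot <- n_tot + length(rs)
    n_both <- n_both + sum(l_in & r_in)
    n_one <- n_one + sum(xor(l_in, r_in))
  }
  p_both <- n_both / n_tot
  nh <- calls$event_class == "NHEJ_DELETION"
  obs <- mean(calls$topology[nh] == "both_Alus")
  # leftmost normalization and in-register relabelling jitter a few boundary
  # cases; allow 3 SD + slack
  expect_lt(abs(obs - p_both), 3 * sqrt(p_both * (1 - p_both) / 400) + 0.02)
})
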