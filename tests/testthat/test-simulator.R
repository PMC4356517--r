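# genotype a product's Alu span positionally (independent of the caller)
regenotype <- function(product, fx) {
  a1s <- fx$cassette$features$start[fx$cassette$features$name == "alu1"]
  sites <- fx$pair$diagnostic_sites
  span <- substr(product, a1s + 1, a1s + fx$pair$length)
  ch <- strsplit(span, "")[[1]]
  b1 <- strsplit(fx$pair$aligned1, "")[[1]][sites + 1]
  b2 <- strsplit(fx$pair$aligned2, "")[[1]][sites + 1]
  ifelse(ch[sites + 1] == b1, 1L, ifelse(ch[sites + 1] == b2, 2L, NA_integer_))
}

test_that("single-crossover products carry the requested allele pattern", {
  fx <- fixture(5)
  k <- length(fx$pair$diagnostic_sites)

  ev0 <- simulate_recombination_product(fx$cassette, fx$pair, 0)
  expect_identical(regenotype(ev0$product_sequence, fx), rep(2L, k))
  evk <- simulate_recombination_product(fx$cassette, fx$pair, k)
  expect_identical(regenotype(evk$product_sequence, fx), rep(1L, k))

  ev3 <- simulate_recombination_product(fx$cassette, fx$pair, 3)
  expect_identical(regenotype(ev3$product_sequence, fx),
                   c(rep(1L, 3), rep(2L, k - 3)))
  # deletion arithmetic: alu2.start - alu1.start = 2600 - 1200
  expect_identical(ev3$deletion_size, 1400L)
  expect_identical(nchar(ev3$product_sequence),
                   fx$cassette$length - ev3$deletion_size)
  expect_error(simulate_recombination_product(fx$cassette, fx$pair, k + 1),
               "interval_index")
})

test_that("complex chimeras require >= 2 switches and keep the patch pattern", {
  fx <- fixture(3)                      # 9 diagnostic sites
  k <- 9L
  al <- c(1L, 2L, 1L, rep(1L, k - 3))
  ev <- simulate_complex_chimera(fx$cassette, fx$pair, al)
  expect_identical(regenotype(ev$product_sequence, fx), al)
  expect_identical(ev$event_class, "RECOMB_COMPLEX_CHIMERA")

  al4 <- c(2L, 1L, 2L, 1L, rep(1L, k - 4))   # 3 switches
  expect_identical(sum(diff(al4) != 0), 3L)
  ev4 <- simulate_complex_chimera(fx$cassette, fx$pair, al4)
  expect_identical(regenotype(ev4$product_sequence, fx), al4)

  expect_error(
    simulate_complex_chimera(fx$cassette, fx$pair,
                             c(1L, 1L, rep(2L, k - 2))),
    "single-crossover")
})

test_that("NHEJ deletions measure emergent microhomology and keep lengths", {
  fx <- fixture(5)
  s <- fx$cassette$sequence
  # find breakpoints whose flanks share a 4-mer: s[l-3..l] == s[r-3..r]
  found <- NULL
  for (l in 1500:1600) {
    for (r in 2650:2750) {
      if (substr(s, l - 3, l) == substr(s, r - 3, r) &&
          substr(s, l + 1, l + 1) != substr(s, r + 1, r + 1) &&
          substr(s, l - 4, l - 4) != substr(s, r - 4, r - 4)) {
        found <- c(l, r); break
      }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))   # the fixture sequence contains such a pair
  ev <- simulate_nhej_deletion(fx$cassette, found[1], found[2])
  expect_identical(ev$microhomology_len, 4L)
  orc <- oracle_microhomology(s, found[1], found[2])
  expect_identical(ev$microhomology_len, orc$len)
  expect_identical(ev$left_breakpoint, orc$left)

  # 1-bp deletion and insertion bookkeeping
  ev1 <- simulate_nhej_deletion(fx$cassette, 1500, 1501)
  expect_identical(ev1$deletion_size, 1L)
  evtt <- simulate_nhej_deletion(fx$cassette, 1500, 2700, insertion = "TT")
  expect_identical(nchar(evtt$product_sequence),
                   fx$cassette$length - evtt$deletion_size + 2L)
  expect_error(simulate_nhej_deletion(fx$cassette, 100, 2700), "breakpoints")
})

test_that("selection filter implements the puro-resistance logic", {
  fx <- fixture(5)
  # single-crossover recombination with defaults is detectable
  ev <- simulate_recombination_product(fx$cassette, fx$pair, 7)
  expect_true(selection_filter(ev, fx$cassette))
  # small deletion inside neoR only: polyA retained -> not selectable
  expect_false(simulate_nhej_deletion(fx$cassette, 1600, 1800)$detectable)
  # deletion into puroR destroys the marker (outside window and flank broken)
  expect_false(
    selection_filter(
      structure(list(left_breakpoint = 1400L, right_breakpoint = 3000L,
                     deletion_size = 1600L), class = "repair_event"),
      fx$cassette))
  # size window: a spacer-spanning deletion below 897 bp is rejected
  expect_false(simulate_nhej_deletion(fx$cassette, 2500, 2650)$detectable)
})

test_that("colony sets respect the preset mixture and are reproducible", {
  fx <- fixture(10)
  # 100% single crossover
  s1 <- simulate_colony_set(fx$cassette, fx$pair, 50,
                            mixture_preset(1, 0, 0), seed = 5)
  expect_true(all(s1$events$event_class == "RECOMB_SINGLE_CROSSOVER"))
  expect_true(all(s1$events$detectable))

  # 44/56 recombination/NHEJ mixture: fractions within 3 binomial SDs
  n <- 1000L
  s2 <- simulate_colony_set(fx$cassette, fx$pair, n,
                            mixture_preset(0.44, 0, 0.56), seed = 6)
  frac <- mean(s2$events$event_class == "RECOMB_SINGLE_CROSSOVER")
  expect_lt(abs(frac - 0.44), 3 * sqrt(0.44 * 0.56 / n))

  # byte-identical outputs for the same seed
  d1 <- withr::local_tempdir()
  a <- simulate_colony_set(fx$cassette, fx$pair, 30,
                           mixture_preset(0.5, 0, 0.5), seed = 9)
  b <- simulate_colony_set(fx$cassette, fx$pair, 30,
                           mixture_preset(0.5, 0, 0.5), seed = 9)
  write_colony_set(a, file.path(d1, "a.fasta"), file.path(d1, "a.tsv"))
  write_colony_set(b, file.path(d1, "b.fasta"), file.path(d1, "b.tsv"))
  sums <- tools::md5sum(file.path(d1, c("a.fasta", "b.fasta", "a.tsv", "b.tsv")))
  expect_identical(unname(sums[1]), unname(sums[2]))
  expect_identical(unname(sums[3]), unname(sums[4]))
})

test_that("deletion-size conservation holds for every emitted event", {
  fx <- fixture(5)
  set <- simulate_colony_set(fx$cassette, fx$pair, 120,
                             mixture_preset(0.4, 0.1, 0.5), seed = 11)
  prod_len <- nchar(set$sequences)
  expect_true(all(prod_len + set$events$deletion_size == fx$cassette$length))
  expect_true(all(set$events$deletion_size ==
                    set$events$right_bp - set$events$left_bp))
})

test_that("uniform crossover preset gives uniform interval occupancy", {
  fx <- fixture(5)
  n_int <- length(fx$imap$starts)
  set.seed(123)
  draws <- replicate(10000, aluRepair:::draw_crossover_interval(fx$imap, 0))
  tab <- tabulate(draws + 1L, nbins = n_int)
  gof <- chi_square_gof(data.frame(observed = tab,
                                   expected = rep(10000 / n_int, n_int)))
  expect_gt(gof$p_value, 0.01)
})

test_that("5'-bias weight hits the requested first-segment probability", {
  fx <- fixture(5)
  w <- bias_weight_for_segment1(fx$imap, 0.6)
  set.seed(321)
  draws <- replicate(5000, aluRepair:::draw_crossover_interval(fx$imap, w))
  seg <- fx$imap$segment_of_interval[draws + 1L]
  expect_lt(abs(mean(seg == 0L) - 0.6), 3 * sqrt(0.6 * 0.4 / 5000))
})

test_that("microhomology-seeking NHEJ enriches junction microhomology", {
  fx <- fixture(5)
  plain <- simulate_colony_set(fx$cassette, fx$pair, 150,
                               mixture_preset(0, 0, 1), seed = 31)
  seek <- simulate_colony_set(fx$cassette, fx$pair, 150,
                              mixture_preset(0, 0, 1, mh_seeking = TRUE),
                              seed = 31)
  expect_gt(mean(seek$events$microhomology_len),
            mean(plain$events$microhomology_len))
})
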