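test_that("UI evaluates its defining formula on hand-built tables", {
  tab <- toy_table("ACACACA", depth = 100)
  pos <- data.frame(pos = c(2L, 4L, 6L), strand = "+")
  expect_equal(compute_ui(tab, pos)$ui, 0)  # zero numerator

  tab1 <- toy_table("AC", depth = 100,
                    overrides = list(list(pos = 2, C = 99, T = 1)))
  one <- compute_ui(tab1, data.frame(pos = 2L, strand = "+"))
  expect_equal(one$ui, 10.0)  # (0.01 / 1) * 1e3

  tab3 <- toy_table("ACACACA", depth = 100,
                    overrides = list(list(pos = 2, C = 99, T = 1),
                                     list(pos = 4, C = 98, T = 2),
                                     list(pos = 6, C = 97, T = 3)))
  expect_equal(compute_ui(tab3, pos)$ui, 20.0)  # mean(0.01,0.02,0.03)*1e3
})

test_that("unmeasured positions split the two denominator conventions", {
  tab <- toy_table("ACAC", depth = 100,
                   overrides = list(list(pos = 2, C = 90, T = 10),
                                    list(pos = 4, depth_total = 0, C = 0)))
  pos <- data.frame(pos = c(2L, 4L), strand = "+")
  expect_equal(compute_ui(tab, pos, "measured")$ui, 100)
  expect_equal(compute_ui(tab, pos, "genomic")$ui, 50)
  res <- compute_ui(tab, pos)
  expect_equal(res$n_positions, 2L)
  expect_equal(res$n_measured, 1L)

  none <- toy_table("AC", depth = 0)
  expect_error(compute_ui(none, data.frame(pos = 2L, strand = "+")),
               "no measurable")
})

test_that("UI is invariant to uniform depth rescaling at fixed fractions", {
  set.seed(9)
  sq <- random_seq(500)
  mk <- function(depth) {
    ov <- list()
    ch <- strsplit(sq, "", fixed = TRUE)[[1]]
    for (i in which(ch == "C")) {
      ov[[length(ov) + 1]] <- list(pos = i, C = depth - depth * 0.02,
                                   T = depth * 0.02)
    }
    toy_table(sq, depth = depth, overrides = ov)
  }
  pos <- find_context_positions(genome(sq), "NC:2")
  pos <- pos[pos$strand == "+", ]
  expect_equal(compute_ui(mk(100), pos)$ui, compute_ui(mk(1000), pos)$ui)
})

test_that("a single stratum reproduces the unstratified UI", {
  set.seed(10)
  sq <- random_seq(300)
  tab <- toy_table(sq, depth = 50,
                   overrides = list(list(pos = which(strsplit(sq, "")[[1]] == "C")[1],
                                         C = 49, T = 1)))
  pos <- find_context_positions(genome(sq), "NC:2")
  whole <- compute_ui(tab, pos)
  strat <- ui_stratified(tab, pos, rep("all", nrow(pos)))
  expect_length(strat, 1L)
  expect_equal(strat$all$ui, whole$ui)

  # empty strata are reported, not dropped
  lab <- rep("a", nrow(pos)); lab[1] <- "b"
  tab0 <- toy_table(sq, depth = 50)
  tab0$depth_total[pos$pos[1]] <- 0L
  strat2 <- ui_stratified(tab0, pos, lab)
  expect_true("b" %in% names(strat2))
  expect_true(is.na(strat2$b$ui))
})

test_that("subset UIs are deterministic, balanced and consistent", {
  set.seed(12)
  sq <- random_seq(3000)
  ch <- strsplit(sq, "", fixed = TRUE)[[1]]
  ov <- lapply(which(ch == "C"), function(i)
    list(pos = i, C = 95L, T = 5L))
  tab <- toy_table(sq, depth = 100, overrides = ov)
  pos <- find_context_positions(genome(sq), "NC:2")
  pos <- pos[pos$strand == "+", ]

  r1 <- ui_with_subset_error(tab, pos, k = 3, seed = 99)
  r2 <- ui_with_subset_error(tab, pos, k = 3, seed = 99)
  expect_identical(r1$subset_uis, r2$subset_uis)

  # uniform fraction: every subset UI equals f * 1e3 and sd ~ 0
  expect_true(all(abs(r1$subset_uis - 50) < 1e-9))
  expect_lt(r1$sd, 1e-9)
  expect_error(ui_with_subset_error(tab, pos, k = 1), "k must be")
})

test_that("percent uracilation profiles recount the table per position", {
  tab <- toy_table("AACGTT", depth = 100,
                   overrides = list(list(pos = 3, C = 95, T = 5),
                                    list(pos = 4, G = 80, A = 20)))
  prof <- percent_uracilation_profile(tab, 1, 6)
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$percent[prof$pos == 3], 5.0)
  expect_equal(prof$percent[prof$pos == 4], 20.0)
  expect_equal(prof$strand, c("+", "-"))

  none <- percent_uracilation_profile(toy_table("AATT", 10), 1, 4)
  expect_equal(nrow(none), 0L)

  # independent recount on a 50-bp fixture
  set.seed(14)
  sq <- random_seq(50)
  ch <- strsplit(sq, "", fixed = TRUE)[[1]]
  ov <- lapply(which(ch == "C"), function(i) list(pos = i, C = 90L, T = 10L))
  tabr <- toy_table(sq, depth = 100, overrides = ov)
  prof2 <- percent_uracilation_profile(tabr, 1, 50)
  expect_equal(nrow(prof2), sum(ch %in% c("C", "G")))
  expect_equal(sum(prof2$percent[prof2$strand == "+"]), 10 * sum(ch == "C"))
  expect_equal(sum(prof2$percent[prof2$strand == "-"]), 0)
})
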