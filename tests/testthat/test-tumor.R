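test_that("catalog loading normalizes VCF and TSV, skipping indels", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t101\t.\tC\tT\t.\tPASS\t.",
               "chr1\t201\t.\tG\tA\t.\tPASS\t.",
               "chr1\t301\t.\tCA\tC\t.\tPASS\t."), vcf)
  muts <- load_mutation_catalog(vcf)
  expect_equal(nrow(muts), 2L)
  expect_equal(muts$pos, c(101L, 201L))
  expect_equal(attr(muts, "n_skipped"), 1L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tsample_id",
               "chr1\t11\tC\tT\ts1",
               "chr1\t21\tC\tG\ts2",
               "chr1\t31\tC\tC\ts2"), tsv)   # ref == alt dropped
  mt <- load_mutation_catalog(tsv)
  expect_equal(nrow(mt), 2L)
  expect_equal(table(mt$sample_id)[["s1"]], 1L)

  # reference disagreement drops the record with a warning
  g <- genome(strrep("A", 400), name = "chr1", circular = FALSE)
  expect_warning(m2 <- load_mutation_catalog(vcf, g = g), "mismatch")
  expect_equal(nrow(m2), 0L)
})

test_that("ci95 reproduces the n/N normal approximation and bounds the rate", {
  ci <- ci95(25, 1000)
  expect_equal(ci, c(0.0152, 0.0348))
  expect_equal(ci95(0, 50), c(0, 0))
  # exact Poisson upper bound for a zero count is 3.689/N
  expect_equal(ci95(0, 50, "poisson_exact")[2], 3.688879 / 50, tolerance = 1e-5)
  for (n in c(1, 5, 40)) {
    for (meth in c("normal", "poisson_exact", "wilson")) {
      ci <- ci95(n, 100, meth)
      expect_lte(ci[1], n / 100)
      expect_gte(ci[2], n / 100)
    }
  }
  expect_error(ci95(5, 0), "N")
})

test_that("strand-bias machinery conserves counts and is label-equivariant", {
  set.seed(41)
  sim <- generate_genome(3e4, n_genes = 10, n_trna = 2, seed = 41)
  params <- sim_params(strand_bias_beta = 2, seed = 41)
  muts <- simulate_mutation_catalog(sim$genome, sim$map, params, 3000)

  res <- strand_bias_rates(muts, sim$genome, "TC:2", "replicative",
                           map = sim$map)
  pos <- find_context_positions(sim$genome, "TC:2")
  key <- paste(pos$pos, pos$strand)
  mkey <- paste(muts$pos, ifelse(muts$ref == "C", "+", "-"))
  expect_equal(sum(res$rates$n_mut), sum(mkey %in% key))   # conservation
  expect_equal(sum(res$rates$n_sites), nrow(pos))

  # swapping the ori/ter (and hence every LGST/LDST label) inverts the ratio
  flipped <- replichore_map(sim$map$ter, sim$map$ori)
  res2 <- strand_bias_rates(muts, sim$genome, "TC:2", "replicative",
                            map = flipped)
  expect_equal(res2$ratio, 1 / res$ratio, tolerance = 1e-12)

  # all mutations on one strand: ratio flagged, not fabricated
  one <- muts[muts$ref == "C", ]
  one <- one[replicative_role(one$pos, "+", sim$map, sim$genome) == "LGST", ]
  class(one) <- class(muts)
  r3 <- strand_bias_rates(one, sim$genome, "TC:2", "replicative", map = sim$map)
  expect_true(r3$zero_denominator)
  expect_true(is.na(r3$ratio))
})

test_that("transcriptional mode uses coding vs template strand labels", {
  set.seed(42)
  sim <- generate_genome(3e4, n_genes = 12, n_trna = 2, seed = 42)
  params <- sim_params(seed = 42)
  muts <- simulate_mutation_catalog(sim$genome, sim$map, params, 2000)
  res <- strand_bias_rates(muts, sim$genome, "NC:2", "transcriptional",
                           genes = sim$genes)
  expect_equal(res$rates$strand, c("Tx+", "Tx-"))
  expect_true(all(res$rates$n_sites > 0))
  expect_true(is.finite(res$ratio))
})

test_that("hairpin-binned rates normalize per bin and stay conserved", {
  set.seed(43)
  sim <- generate_genome(3e4, n_genes = 8, n_trna = 2,
                         n_planted_hairpins = 30, seed = 43)
  params <- sim_params(seed = 43)
  muts <- simulate_mutation_catalog(sim$genome, sim$map, params, 2000)
  asg <- assign_best_hairpin(sim$genome, scan_hairpins(sim$genome))
  rates <- hairpin_mutation_rates(muts, sim$genome, "NC:2", asg,
                                  bin_edges = c(4L, 8L, 12L), map = sim$map)
  both <- rates[rates$strand == "both", ]
  pos <- find_context_positions(sim$genome, "NC:2")
  expect_equal(sum(both$n_sites), nrow(pos))       # bins tile all sites
  expect_equal(sum(both$n_mut), nrow(muts))        # NC catches every C:G SNV
  lg <- rates[rates$strand == "LGST", ]
  ld <- rates[rates$strand == "LDST", ]
  expect_equal(lg$n_mut + ld$n_mut, both$n_mut)    # strand rows sum to both
  expect_true(all(rates$ci_lo[!is.na(rates$rate)] <=
                    rates$rate[!is.na(rates$rate)] + 1e-12))

  none <- muts[0, ]
  class(none) <- class(muts)
  expect_error(hairpin_mutation_rates(none, sim$genome, "NC:2", asg),
               NA)
})

test_that("expression deciles partition genes evenly and rank correctly", {
  set.seed(44)
  sim <- generate_genome(4e4, n_genes = 18, n_trna = 2, seed = 44)
  params <- sim_params(seed = 44)
  muts <- simulate_mutation_catalog(sim$genome, sim$map, params, 1500)
  res <- expression_binned_rates(muts, sim$genome, "NC:2", sim$genes)
  expect_equal(nrow(res), 10L)
  expect_false(is.unsorted(res$mean_expression))
  expect_true(all(res$n_sites > 0))

  ten <- sim$genes[1:10, ]
  r10 <- expression_binned_rates(muts, sim$genome, "NC:2", ten)
  expect_equal(nrow(r10), 10L)  # exactly one gene per bin
  expect_error(expression_binned_rates(muts, sim$genome, "NC:2",
                                       sim$genes[1:5, ]), "at least")
})
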