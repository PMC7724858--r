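test_that("call_snv applies the depth filter and Fisher threshold", {
  # below the 10x depth filter: never called, however strong the signal
  expect_null(call_snv(pileup_row(1, "A", A = 0, G = 9)))
  # no alternative reads: p = 1
  expect_null(call_snv(pileup_row(1, "A", A = 10)))
  # minimum calling alt count at depth 10 is 6
  called <- call_snv(pileup_row(1, "A", A = 4, G = 6))
  expect_equal(called$alt, "G")
  expect_equal(called$p_value, choose(14, 4) / choose(20, 10))
  expect_null(call_snv(pileup_row(1, "A", A = 5, G = 5)))
  expect_equal(snv_p_value(5, 10), 0.01625387, tolerance = 1e-6)
  # inconsistent counts are a data error
  expect_error(call_snv(list(chrom = "chr1", pos = 1, ref = "A", depth = 12,
                             A = 5, C = 0, G = 5, T = 0)), "sum to depth")
})

test_that("snv_p_value agrees with Fisher enumeration for all depths <= 30", {
  for (d in 1:30) {
    a <- 0:d
    ours <- snv_p_value(a, rep(d, d + 1))
    oracle <- vapply(a, function(ai) {
      oracle_fisher(matrix(c(ai, 0, d - ai, d), 2, 2), "one_sided")
    }, 0)
    expect_equal(ours, oracle, tolerance = 1e-10)
    # monotone non-increasing in alt count at fixed depth
    expect_true(all(diff(ours) <= 1e-12))
  }
  # the same holds up to depth 50 for the monotonicity property
  for (d in 31:50) {
    expect_true(all(diff(snv_p_value(0:d, rep(d, d + 1))) <= 1e-12))
  }
})

test_that("call_sample filters, validates and sorts", {
  empty <- call_sample(ref_pileup(0))
  expect_equal(nrow(empty), 0)
  # all depths < 10: nothing called
  low <- ref_pileup(5, depth = 9)
  low$G <- low$depth; low$A <- 0
  expect_equal(nrow(call_sample(low)), 0)
  # unsorted and duplicated input rejected
  pu <- ref_pileup(5)
  expect_error(call_sample(pu[c(2, 1, 3, 4, 5), ]), "sorted")
  dup <- rbind(pu, pu[5, ])
  expect_error(call_sample(dup[order(dup$pos), ]), "duplicate")
  # hom call and zygosity threshold
  pu2 <- rbind(pileup_row(1, "A", A = 0, T = 30),        # hom (fraction 1)
               pileup_row(2, "C", C = 15, G = 15),       # het (fraction .5)
               pileup_row(3, "G", G = 3, T = 27))        # fraction .9 -> hom
  calls <- call_sample(pu2)
  expect_equal(calls$zygosity, c("hom", "het", "hom"))
  expect_true(all(calls$p_value < 0.01))
})

test_that("noiseless synthetic pileups are recovered perfectly", {
  cfg <- sim_config(seed = 5, genome_length = 2000, n_genes = 0,
                    depth_mean = 30, error_rate = 0,
                    n_germline = 50, n_somatic = 10, cancer_fraction = 1,
                    het_fraction = 0)    # all hom -> alt count = depth
  gen <- synth_genome(cfg)
  truth <- synth_truth(cfg, gen$genome)
  blood <- synth_pileup(gen$genome, truth, cfg, "blood")
  calls <- call_sample(blood)
  # exactly the 50 planted hom sites (depth >= 10 at 30x essentially always)
  truth_keys <- paste0("chrS:", truth$germline_sites$pos, ":",
                       truth$germline_sites$ref, ">",
                       truth$germline_sites$alt)
  expect_setequal(variant_keys(calls), truth_keys)
  expect_equal(nrow(calls), 50)
})

test_that("germline and somatic set logic is coverage-gated subtraction", {
  # minimum calling alt count at depth 30 is 7 (p(7,30) ~ 0.0053)
  pu_para <- rbind(pileup_row(1, "A", A = 23, G = 7, depth = 30),
                   pileup_row(2, "C", C = 5, depth = 5),   # low coverage
                   pileup_row(3, "G", G = 30, depth = 30))
  pu_cancer <- rbind(pileup_row(1, "A", A = 23, G = 7, depth = 30),
                     pileup_row(2, "C", C = 10, T = 20, depth = 30),
                     pileup_row(3, "G", G = 10, A = 20, depth = 30))
  para_calls <- call_sample(pu_para)
  cancer_calls <- call_sample(pu_cancer)
  germ <- germline_set(para_calls)
  expect_equal(germ, "chr1:1:A>G")
  som <- somatic_set(cancer_calls, para_calls, pu_para)
  # pos 2 excluded (para depth 5 < 10); pos 3 kept; pos 1 shared
  expect_equal(som, "chr1:3:G>A")
  # subtraction identity: same calls -> empty somatic set
  expect_equal(somatic_set(para_calls, para_calls, pu_para), character(0))
  # germline and somatic sets of one individual are disjoint
  expect_length(intersect(germ, som), 0)
  expect_error(somatic_set(cancer_calls, para_calls, NULL), "pileup")
})

test_that("noiseless cancer/para pair recovers the planted somatic truth", {
  cfg <- sim_config(seed = 6, genome_length = 2000, n_genes = 0,
                    depth_mean = 30, error_rate = 0, n_germline = 20,
                    n_somatic = 15, cancer_fraction = 1)
  gen <- synth_genome(cfg)
  truth <- synth_truth(cfg, gen$genome)
  para <- synth_pileup(gen$genome, truth, cfg, "para")
  cancer <- synth_pileup(gen$genome, truth, cfg, "cancer")
  som <- somatic_set(call_sample(cancer), call_sample(para), para)
  truth_keys <- paste0("chrS:", truth$somatic_sites$pos, ":",
                       truth$somatic_sites$ref, ">",
                       truth$somatic_sites$alt)
  expect_setequal(som, truth_keys)
})

test_that("shared_germline is exact multi-set intersection", {
  expect_equal(shared_germline(list(c("a", "b"))), c("a", "b"))
  expect_equal(shared_germline(list("a", "b")), character(0))
  expect_error(shared_germline(list()), "non-empty")
  # 5 individuals sharing a planted core plus private keys
  core <- sprintf("chr1:%d:A>G", 1:30)
  withr::with_seed(9, {
    sets <- lapply(1:5, function(i) {
      sample(c(core, sprintf("chr9:%d:C>T", sample(1e6, 40))))
    })
  })
  expect_setequal(shared_germline(sets), core)
})

test_that("false-positive rate at 0.5% error and 30x is below 1e-4", {
  cfg <- sim_config(seed = 8, genome_length = 50000, n_genes = 0,
                    depth_mean = 30, error_rate = 0.005,
                    n_germline = 0, n_somatic = 0)
  gen <- synth_genome(cfg)
  truth <- synth_truth(cfg, gen$genome)
  calls <- call_sample(synth_pileup(gen$genome, truth, cfg, "blood"))
  expect_lt(nrow(calls) / 50000, 1e-4)
})

test_that("crossref_catalog joins and summarises non-benign entries", {
  keys <- sprintf("chr1:%d:A>G", 1:10)
  empty <- crossref_catalog(keys, data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), classification = character()))
  expect_equal(empty$n_non_benign, 0)
  expect_equal(empty$present_fraction, 0)
  catalog <- data.frame(chrom = "chr1", pos = c(1, 2, 3, 4),
                        ref = "A", alt = "G",
                        classification = c("pathogenic", "Benign",
                                           "risk factor",
                                           "Conflicting interpretations"),
                        stringsAsFactors = FALSE)
  res <- crossref_catalog(keys, catalog)
  expect_equal(res$present_fraction, 0.4)
  expect_equal(res$n_non_benign, 3)          # "Benign" is case-insensitive
  expect_equal(res$annotations$classification[1], "pathogenic")
  # malformed catalog lines are skipped with a warning
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1\tA\tG\tpathogenic", "broken line"), tf)
  expect_warning(res2 <- crossref_catalog(keys, tf), "malformed")
  expect_equal(res2$n_non_benign, 1)
})

test_that("VCF writing round-trips all fields", {
  reference <- "synthetic-genome"
  tf <- withr::local_tempfile(fileext = ".vcf")
  empty <- call_sample(ref_pileup(0))
  write_vcf(empty, reference, tf)
  expect_true(all(grepl("^#", readLines(tf))))   # header only
  expect_equal(nrow(read_vcf(tf)), 0)
  pu <- rbind(pileup_row(7, "A", A = 0, T = 30),
              pileup_row(9, "C", C = 15, G = 15))
  calls <- call_sample(pu)
  write_vcf(calls, reference, tf)
  back <- read_vcf(tf)
  expect_equal(back$chrom, calls$chrom)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$alt_count, calls$alt_count)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$p_value, calls$p_value, tolerance = 1e-5)
  expect_equal(back$zygosity, calls$zygosity)
  expect_error(write_vcf(calls[c(2, 1), ], reference, tf), "sorted")
})

test_that("variant keys round-trip through parse_variant_keys", {
  pu <- rbind(pileup_row(7, "A", A = 0, T = 30),
              pileup_row(9, "C", C = 15, G = 15))
  calls <- call_sample(pu)
  keys <- variant_keys(calls)
  back <- parse_variant_keys(keys)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$alt, calls$alt)
  expect_error(parse_variant_keys("chr1:x:A>G"), "malformed")
})
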