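test_that("all simulators are deterministic under a fixed seed", {
  cfg <- simulation_config(n_haplogroups = 2, n_per_group = 2,
                           seq_length = 300, seed = 1)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_alignment(simulate_haplogroup_sequences(cfg), f1)
  write_alignment(simulate_haplogroup_sequences(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  expect_identical(simulate_f2("disomic_allelic", 200, seed = 3),
                   simulate_f2("disomic_allelic", 200, seed = 3))
})

test_that("zero within-group divergence gives identical group members", {
  cfg <- simulation_config(n_haplogroups = 3, n_per_group = 4,
                           seq_length = 400, between_divergence = 0.1,
                           within_divergence = 0, seed = 2)
  aln <- simulate_haplogroup_sequences(cfg)
  groups <- attr(aln, "haplogroup")
  ss <- alignment_strings(aln)
  for (g in levels(groups)) {
    expect_length(unique(ss[groups == g]), 1)
  }
})

test_that("between-group p-distance matches the substitution-process expectation", {
  # Monte-Carlo oracle for the expected p-distance at total path 0.10
  p_exp <- oracle_jc_p(0.10, n_sites = 1e5)
  cfg <- simulation_config(n_haplogroups = 2, n_per_group = 3,
                           seq_length = 1000, between_divergence = 0.10,
                           within_divergence = 0, seed = 8)
  aln <- simulate_haplogroup_sequences(cfg)
  groups <- attr(aln, "haplogroup")
  a <- which(groups == "H1")[1]; b <- which(groups == "H2")[1]
  p_obs <- p_distance(aln[a, ], aln[b, ])$p
  se <- sqrt(p_exp * (1 - p_exp) / 1000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("saturating divergence requests are rejected", {
  expect_error(simulation_config(between_divergence = 15,
                                 within_divergence = 0.01),
               "saturated")
  expect_error(simulation_config(between_divergence = 0.01,
                                 within_divergence = 0.05),
               "between_divergence > within_divergence")
})

test_that("panel generation respects marker counts and cluster frequencies", {
  cfg0 <- simulation_config(n_accessions = 60, heterozygote_rate = 0, seed = 5)
  p0 <- simulate_panel(cfg0)
  expect_true(all(lengths(strsplit(p0$markers, ";")) == 2L))

  # binomial convergence at n = 1e4 with (0.5, 0.5) subgenome-1 frequencies
  cfg <- simulation_config(
    n_accessions = 1e4, heterozygote_rate = 0, seed = 6,
    cluster_spec = list(c1 = list(sub1 = c(A = 0.5, B = 0.5),
                                  sub2 = c(D = 1))))
  p <- simulate_panel(cfg)
  freq <- marker_frequencies(p)
  fA <- freq$frequency_pct[freq$marker == "A"] / 100
  expect_lt(abs(fA - 0.5), 3 * sqrt(0.25 / 1e4))

  expect_error(simulation_config(cluster_spec = list(c1 = list(
    sub1 = numeric(0), sub2 = c(D = 1)))), "empty frequency")
})

test_that("disjoint cluster alleles give perfect marker-cluster association", {
  cfg <- simulation_config(
    n_accessions = 1e4, heterozygote_rate = 0, seed = 7,
    cluster_spec = list(c1 = list(sub1 = c(A = 1), sub2 = c(D = 1)),
                        c2 = list(sub1 = c(B = 1), sub2 = c(D = 1))))
  panel <- simulate_panel(cfg)
  tab <- build_contingency(panel, c("A", "B"))
  expect_equal(cramers_v(tab)$V, 1)
})

test_that("heterozygotes appear on subgenome 1 at the configured rate", {
  cfg <- simulation_config(
    n_accessions = 5000, heterozygote_rate = 0.2, seed = 9,
    cluster_spec = list(c1 = list(sub1 = c(A = 0.5, B = 0.5),
                                  sub2 = c(D = 1))))
  p <- simulate_panel(cfg)
  n_het <- sum(lengths(strsplit(p$markers, ";")) == 3L)
  expect_lt(abs(n_het / 5000 - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
})

test_that("F2 simulation converges to the exact class distribution", {
  expect_equal(sum(simulate_f2("disomic_allelic", 0)), 0)

  for (name in names(segregation_models())) {
    d <- f2_class_distribution(segregation_models()[[name]])
    n <- 1e5
    obs <- simulate_f2(name, n, seed = 11)
    expect_equal(sum(obs), n)
    for (k in seq_len(4)) {
      p <- d$prob[k]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(obs[k] / n - p), 3 * se + 1e-12)
    }
  }

  # rare 'neither' class of the tetrasomic-nonallelic model at n = 1e6
  n <- 1e6
  obs <- simulate_f2("tetrasomic_nonallelic", n, seed = 12)
  p <- 1 / 1296
  expect_lt(abs(obs[["neither"]] / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("panel TSV round-trips through the reader", {
  cfg <- simulation_config(n_accessions = 20, seed = 13)
  p <- simulate_panel(cfg)
  f <- tempfile(fileext = ".tsv")
  write_panel(p, f)
  back <- read_panel(f)
  expect_equal(back$accession, p$accession)
  expect_equal(back$markers, p$markers)
  expect_error(read_panel({
    bad <- tempfile(); writeLines("a\tb\n1\t2", bad); bad
  }), "columns")
})
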