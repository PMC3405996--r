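test_that("p-distance counts mismatches and partitions transitions/transversions", {
  id <- p_distance(strrep("A", 100), strrep("A", 100))
  expect_equal(id$p, 0)
  expect_equal(id$L, 100)

  tv <- p_distance("ACGT", "ACGA")  # T<->A transversion
  expect_equal(tv$p, 0.25)
  expect_equal(tv$P, 0)
  expect_equal(tv$Q, 0.25)
  expect_equal(tv$L, 4)

  ts <- p_distance("ACGT", "GCGT")  # A<->G transition
  expect_equal(ts$P, 0.25)
  expect_equal(ts$Q, 0)

  gap <- p_distance("ACG-", "ACGT")
  expect_equal(gap$L, 3)
  expect_equal(gap$p, 0)

  expect_error(p_distance("----", "ACGT"), "no comparable sites")
  expect_error(p_distance("ACG", "ACGT"), "equal")
})

test_that("complete deletion masks columns gapped anywhere in the alignment", {
  others <- matrix(c("A", "-", "G", "T"), nrow = 1)
  pd <- p_distance("ACGT", "ACGA", deletion = "complete", others = others)
  expect_equal(pd$L, 3)
  expect_equal(pd$p, 1 / 3)
})

test_that("Jukes-Cantor matches the closed form and rejects saturation", {
  est <- jukes_cantor(0.1, 1000)
  expect_equal(round(est$d, 6), 0.107326)
  expect_equal(round(est$SE, 6), 0.010946)

  z <- jukes_cantor(0, 500)
  expect_equal(z$d, 0)
  expect_equal(z$SE, 0)

  expect_gt(jukes_cantor(0.749, 100)$d, jukes_cantor(0.74, 100)$d)
  expect_error(jukes_cantor(0.75, 100), "saturated")
  expect_gte(jukes_cantor(0.3, 100)$d, 0.3)  # correction inflates
})

test_that("Kimura 2P matches the closed form, its pure-transition limit, and dominates p", {
  expect_equal(round(kimura_2p(0.1, 0.05)$d, 6), 0.170181)
  expect_equal(kimura_2p(0, 0)$d, 0)
  for (P in c(0.05, 0.2, 0.4)) {
    expect_equal(kimura_2p(P, 0)$d, -0.5 * log(1 - 2 * P))
  }
  expect_error(kimura_2p(0.3, 0.4), "saturated")
  # correction never smaller than the raw proportion on the valid domain
  for (i in 1:20) {
    P <- runif(1, 0, 0.3); Q <- runif(1, 0, 0.25)
    if (1 - 2 * P - Q > 0 && 1 - 2 * Q > 0)
      expect_gte(kimura_2p(P, Q)$d, P + Q - 1e-12)
  }
})

test_that("JC and K2P are monotone in their raw proportions", {
  ps <- seq(0.01, 0.7, by = 0.01)
  ds <- vapply(ps, function(p) jukes_cantor(p, 100)$d, numeric(1))
  expect_true(all(diff(ds) > 0))
  dk <- vapply(ps / 2, function(q) kimura_2p(q, q / 2)$d, numeric(1))
  expect_true(all(diff(dk) > 0))
})

test_that("Nei-Gojobori reproduces the worked codon example", {
  ng <- nei_gojobori("TTTGGGAAA", "TTCGGGAAA")
  expect_equal(ng$S_sites, 5 / 3, tolerance = 1e-12)
  expect_equal(ng$Sd, 1)
  expect_equal(ng$Nd, 0)
  expect_equal(round(ng$Ks, 5), 1.20708)
  expect_equal(ng$Ka, 0)

  same <- nei_gojobori("ATGAAATTT", "ATGAAATTT")
  expect_equal(same$Ks, 0)
  expect_equal(same$Ka, 0)
})

test_that("Nei-Gojobori site counts are conserved and match a code-table oracle", {
  skip_if_not_installed("Biostrings")
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  expect_length(sense, 61)
  bases <- c("A", "C", "G", "T")
  for (cod in sense) {
    # oracle: one-step-neighbor enumeration over the standard code
    cc <- strsplit(cod, "")[[1]]
    s_expect <- 0
    for (pos in 1:3) for (nb in setdiff(bases, cc[pos])) {
      mut <- cc; mut[pos] <- nb
      mut_aa <- code[[paste(mut, collapse = "")]]
      if (mut_aa != "*" && mut_aa == code[[cod]]) s_expect <- s_expect + 1 / 3
    }
    got <- nei_gojobori(cod, cod)
    expect_equal(got$S_sites, s_expect, tolerance = 1e-12)
    expect_equal(got$S_sites + got$N_sites, 3)
  }
  # conservation on a multi-codon pair
  pair <- nei_gojobori("TTTGGGAAA", "TTAGGCAAT")
  expect_equal(pair$S_sites + pair$N_sites, 9)
})

test_that("multi-difference codons average over minimal pathways", {
  # TTT (Phe) vs GTA (Val): positions 1 and 3 differ.
  # path 1: TTT->GTT (F->V, nonsyn) -> GTA (V->V, syn)
  # path 2: TTT->TTA (F->L, nonsyn) -> GTA (L->V, nonsyn)
  # average: Sd = 0.5, Nd = 1.5
  ng <- nei_gojobori("TTT", "GTA")
  expect_equal(ng$Sd, 0.5)
  expect_equal(ng$Nd, 1.5)
})

test_that("group mean divergence equals the pair estimate for singletons and duplicates", {
  set.seed(7)
  s1 <- random_dna(600)
  s2 <- mutate_at(s1, sample(600, 60))
  A <- alignment(c(a = s1))
  B <- alignment(c(b = s2))
  pd <- p_distance(s1, s2)
  ref <- jukes_cantor(pd$p, pd$L)
  g1 <- group_mean_divergence(A, B)
  expect_equal(g1$mean_d, ref$d)
  expect_equal(g1$SE, ref$SE)

  A2 <- alignment(c(a1 = s1, a2 = s1))  # duplicated copies
  g2 <- group_mean_divergence(A2, B, seed = 1)
  expect_equal(g2$mean_d, ref$d)
})

test_that("bootstrap SE over sites agrees with the analytic per-pair SE", {
  set.seed(11)
  s1 <- random_dna(1000)
  s2 <- mutate_at(s1, sample(1000, 100))
  pd <- p_distance(s1, s2)
  analytic <- jukes_cantor(pd$p, pd$L)$SE
  g <- group_mean_divergence(alignment(c(a = s1)), alignment(c(b = s2)),
                             n_boot = 1000, seed = 5,
                             se_method = "bootstrap")
  expect_lt(abs(g$SE - analytic) / analytic, 0.2)
})

test_that("JC estimates recover the true simulated distance", {
  # pairs simulated under a per-site JC process at true distance 0.1
  L <- 10000; d_true <- 0.1
  p_branch <- 0.75 * (1 - exp(-4 * (d_true / 2) / 3))
  bases <- c("A", "C", "G", "T")
  ests <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    root <- sample(bases, L, replace = TRUE)
    evolve <- function(x) {
      hit <- runif(L) < p_branch
      x[hit] <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1),
                       character(1))
      x
    }
    pd <- p_distance(paste(evolve(root), collapse = ""),
                     paste(evolve(root), collapse = ""))
    jukes_cantor(pd$p, pd$L)$d
  }, numeric(1))
  se_mean <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - d_true), 2 * se_mean)
})
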