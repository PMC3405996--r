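panel_from <- function(markers, clusters) {
  data.frame(accession = sprintf("a%02d", seq_along(markers)),
             cluster = clusters, markers = markers,
             stringsAsFactors = FALSE)
}

test_that("contingency building applies the heterozygote/non-carrier exclusions", {
  p <- panel_from(c("A;D", "A;D", "B;D", "A;B;D", "D"),
                  c("c1", "c1", "c2", "c1", "c2"))
  tab <- build_contingency(p, c("A", "B"))
  # the dual-marker accession (A;B) and the non-carrier (D only) are excluded
  expect_equal(attr(tab, "excluded"), 2L)
  expect_equal(tab["A", "c1"], 2L)
  expect_equal(tab["B", "c2"], 1L)
  expect_equal(sum(tab), 3L)

  # with {A} as the only queried marker, the A;B accession carries exactly
  # one queried marker and is retained: counts are cluster sizes of A-bearers
  single <- build_contingency(p, c("A"))
  expect_equal(nrow(single), 1L)
  expect_equal(unname(single["A", "c1"]), 3L)

  expect_error(build_contingency(p, c("Z")), "empty table")
})

test_that("Cramer's V matches closed forms and is permutation invariant", {
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2))$V, 1)
  expect_equal(cramers_v(matrix(c(5, 5, 5, 5), 2))$V, 0)

  t22 <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  cv <- cramers_v(t22)
  expect_equal(cv$chi2, 7.2)
  expect_equal(cv$V, 0.6)

  set.seed(51)
  t <- matrix(rpois(12, 5) + 1L, 3, 4)
  v0 <- cramers_v(t, fisher_args = list(monte_carlo = TRUE, reps = 100))$V
  pr <- sample(3); pc <- sample(4)
  expect_equal(cramers_v(t[pr, pc],
                         fisher_args = list(monte_carlo = TRUE,
                                            reps = 100))$V, v0)
  expect_equal(cramers_v(t(t), fisher_args = list(monte_carlo = TRUE,
                                                  reps = 100))$V, v0)
})

test_that("V = 1 exactly iff rows concentrate in distinct columns", {
  perfect <- matrix(c(7, 0, 0, 0, 3, 0, 0, 0, 12), 3, byrow = TRUE)
  expect_equal(cramers_v(perfect)$V, 1)
  off <- perfect; off[1, 2] <- 1
  expect_lt(cramers_v(off)$V, 1)
})

test_that("Fisher's exact test reproduces the 2x2 published table and conventions", {
  t2 <- matrix(c(4, 0, 1, 5), 2, byrow = TRUE)
  fe <- fisher_exact(t2)
  expect_equal(round(fe$p_one_tailed, 4), 0.0238)
  expect_equal(round(fe$p_two_tailed, 4), 0.0476)
  expect_gte(fe$p_two_tailed, fe$p_one_tailed)

  expect_equal(fisher_exact(matrix(1, 2, 2))$p_two_tailed, 1)

  # table probabilities under fixed margins are a distribution
  rs <- c(4, 6); cs <- c(5, 5)
  supp <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  expect_equal(sum(dhyper(supp, cs[1], cs[2], rs[1])), 1)
})

test_that("Fisher's exact test agrees with the reference implementation", {
  set.seed(52)
  for (i in 1:10) {
    t <- matrix(rpois(4, 4), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    fe <- fisher_exact(t)
    ref <- stats::fisher.test(t)
    expect_equal(fe$p_two_tailed, ref$p.value, tolerance = 1e-8)
  }
  # r x c enumeration path
  t3 <- matrix(c(3, 1, 0, 1, 4, 1, 0, 1, 3), 3, byrow = TRUE)
  fe3 <- fisher_exact(t3)
  expect_equal(fe3$method, "enumeration")
  expect_equal(fe3$p_two_tailed, stats::fisher.test(t3)$p.value,
               tolerance = 1e-8)
})

test_that("Monte-Carlo Fisher approximates the enumerated p for larger tables", {
  t3 <- matrix(c(3, 1, 0, 1, 4, 1, 0, 1, 3), 3, byrow = TRUE)
  exact <- fisher_exact(t3)$p_two_tailed
  mc <- fisher_exact(t3, monte_carlo = TRUE, reps = 2e4, seed = 3,
                     max_tables = 1)
  expect_equal(mc$method, "monte_carlo")
  expect_lt(abs(mc$p_two_tailed - exact), 0.02)
})

test_that("marker frequencies are computed over 2N subgenome slots", {
  # 49 accessions: 23 homozygous A (46 slots of 98), 23 B, 2 C, 1 B;C het
  markers <- c(rep("A;D", 23), rep("B;D", 23), rep("C;D", 2), "B;C;D")
  p <- panel_from(markers, rep("c1", 49))
  fr <- marker_frequencies(p, subgenomes = list(sub1 = c("A", "B", "C"),
                                                sub2 = c("D")))
  get <- function(m) fr$frequency_pct[fr$marker == m]
  expect_equal(round(get("A"), 1), 46.9)   # 46 / 98
  expect_equal(get("B"), 100 * 47 / 98)
  expect_equal(get("C"), 100 * 5 / 98)
  expect_equal(get("D"), 100)
  # absent marker
  fr2 <- marker_frequencies(p, subgenomes = list(sub2 = c("E")))
  expect_equal(fr2$frequency_pct, 0)
})

test_that("delta-K summarises clustering log-likelihoods as second differences", {
  runs <- data.frame(
    K = rep(1:4, each = 3),
    lnP = c(-101, -100, -99, -51, -50, -49, -42, -40, -38, -39, -38, -37))
  dk <- delta_k(runs)
  expect_equal(dk$deltaK[dk$K == 3], 4)        # |(-38+40) - (-40+50)| / 2
  expect_true(is.na(dk$deltaK[dk$K == 1]))     # boundary K undefined

  # linear lnP -> all interior delta-K are zero
  lin <- data.frame(K = rep(1:4, each = 2),
                    lnP = rep(c(-40, -30, -20, -10), each = 2) + c(-1, 1))
  dl <- delta_k(lin)
  expect_equal(dl$deltaK[dl$K %in% 2:3], c(0, 0))

  expect_error(delta_k(data.frame(K = 1:4, lnP = 1:4)), "2 runs")
  # zero spread -> flagged undefined
  flat <- data.frame(K = rep(1:3, each = 2), lnP = c(1, 1, 5, 5, 6, 6))
  expect_true(is.na(delta_k(flat)$deltaK[2]))
})

test_that("cross scoring applies the pollen-tube and silique criteria", {
  expect_equal(score_cross(pollen_tubes = 19), "incompatible")
  expect_equal(score_cross(pollen_tubes = 20), "compatible")
  expect_equal(score_cross(pollen_tubes = 100), "compatible")
  expect_equal(score_cross(pollen_tubes = 15, stringent = TRUE), "compatible")
  expect_equal(score_cross(pollen_tubes = 9, stringent = TRUE), "incompatible")
  expect_equal(score_cross(silique_mm = 4.9), "incompatible")
  expect_equal(score_cross(silique_mm = 7), "compatible")
  expect_error(score_cross(pollen_tubes = -1), "negative")
  expect_error(score_cross(pollen_tubes = 5, silique_mm = 3), "exactly one")
  expect_error(score_cross(), "exactly one")
})
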