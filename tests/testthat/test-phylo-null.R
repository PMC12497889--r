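test_that("cophenetic distances are patristic path sums", {
  two <- ape::read.tree(text = "(A:1,B:2);")
  D <- cophenetic_matrix(two)
  expect_equal(D["A", "B"], 3)
  # ultrametric: all tips equidistant from the root, so all pairwise paths
  # through the root are equal
  tr <- simulate_tree(20, seed = 3)
  depths <- ape::node.depth.edgelength(tr)[1:20]
  expect_true(diff(range(depths)) < 1e-8)
  # triangle inequality on random pure-birth trees up to 8 tips
  for (s in 1:10) {
    tt <- simulate_tree(sample(3:8, 1), seed = 100 + s)
    DD <- cophenetic_matrix(tt)
    n <- nrow(DD)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_true(DD[i, j] <= DD[i, k] + DD[k, j] + 1e-12)
    }
  }
  noBL <- ape::read.tree(text = "(A,B);")
  expect_error(cophenetic_matrix(noBL), "branch length")
})

test_that("betaMNTD matches hand-computed examples", {
  D <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # single-taxon communities: 0.5 * (d + d) = d
  expect_equal(bmntd(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 0), D), 2)
  # x = {A}, y = {B: 0.5, C: 0.5}: 0.5 * (2 + (0.5*2 + 0.5*4)) = 2.5
  expect_equal(bmntd(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 1), D), 2.5)
  # identical supports: every taxon's nearest neighbour is itself
  expect_equal(bmntd(c(A = 2, B = 1, C = 0), c(A = 1, B = 5, C = 0), D), 0)
  expect_error(bmntd(c(A = 0, B = 0, C = 0), c(A = 1, B = 0, C = 0), D), "empty")
})

test_that("betaMNTD agrees exactly with the brute-force oracle", {
  set.seed(17)
  for (case in 1:200) {
    n_taxa <- sample(2:8, 1)
    n_samples <- sample(2:6, 1)
    tr <- simulate_tree(max(n_taxa, 2), seed = 1000 + case)
    D <- cophenetic_matrix(tr)
    m <- random_counts(n_samples, n_taxa)
    colnames(m) <- tr$tip.label[seq_len(n_taxa)]
    D <- D[colnames(m), colnames(m)]
    W <- relative_abundance(m)
    for (weighted in c(TRUE, FALSE)) {
      prod <- bmntd_matrix(m, D, weighted = weighted)
      for (a in 1:(n_samples - 1)) for (b in (a + 1):n_samples) {
        expect_equal(prod[a, b],
                     bmntd_bruteforce(W[a, ], W[b, ], D, weighted = weighted),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("betaMNTD agrees with picante's comdistnt", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(25, seed = 5)
  m <- random_counts(6, 25)
  colnames(m) <- tr$tip.label
  ours <- bmntd_matrix(m, tr, weighted = TRUE)
  ref <- as.matrix(picante::comdistnt(m, cophenetic_matrix(tr),
                                      abundance.weighted = TRUE))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("betaNTI is seeded, scale-invariant and flags degenerate pairs", {
  tr <- simulate_tree(30, seed = 7)
  m <- simulate_neutral(n_samples = 8, N = 500, m = 0.3, n_taxa = 30, seed = 8)
  b1 <- bnti_pairwise(m, tr, n_null = 199, seed = 9)
  b2 <- bnti_pairwise(m, tr, n_null = 199, seed = 9)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), choose(8, 2))

  # branch-length rescaling cancels in the z-score
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 13
  b3 <- bnti_pairwise(m, tr2, n_null = 199, seed = 9)
  expect_equal(b1$bnti, b3$bnti, tolerance = 1e-9)

  # identical communities: all null betaMNTD are 0, sd = 0, reported not fatal
  dup <- abundance_matrix(rbind(s1 = m[1, ], s2 = m[1, ]),
                          taxon_ids = colnames(m))
  expect_warning(bd <- bnti_pairwise(dup, tr, n_null = 49, seed = 1),
                 "degenerate")
  expect_true(bd$degenerate[1])
  expect_true(is.na(bd$bnti[1]))
})

test_that("Raup-Crick honours ties, identity pairs and ordering invariance", {
  # single-taxon metacommunity: every null BC equals BC_obs, ties at half
  # weight force rc = 0
  one <- abundance_matrix(matrix(c(10L, 20L), 2, 1,
                                 dimnames = list(c("a", "b"), "t1")))
  expect_equal(rc_bray(one, n_null = 99, seed = 1)$rc, 0)

  # identical pair on a diverse metacommunity: null BC almost surely > 0
  base <- simulate_neutral(n_samples = 12, N = 1000, m = 0.2, n_taxa = 60,
                           seed = 61)
  pair <- abundance_matrix(rbind(s1 = base[1, ], s2 = base[1, ]),
                           taxon_ids = colnames(base))
  rc_id <- rc_bray(pair, n_null = 199, seed = 2,
                   meta = list(occupancy = colSums(unclass(base) > 0),
                               abundance = colSums(unclass(base))))
  expect_lt(rc_id$rc, -0.95)

  # exactly invariant to taxon and sample order; seeded runs reproducible
  r1 <- rc_bray(base[1:4, ], n_null = 99, seed = 3)
  perm <- sample(ncol(base))
  shuffled <- abundance_matrix(unclass(base)[4:1, perm])
  r2 <- rc_bray(shuffled, n_null = 99, seed = 3)
  expect_equal(r1, r2)
  expect_identical(rc_bray(base[1:4, ], n_null = 99, seed = 3), r1)
  expect_true(all(abs(r1$rc) <= 1))
})

test_that("process classification applies the published thresholds exactly", {
  expect_equal(as.character(classify_process(3.1, NA)), "variable_selection")
  expect_equal(as.character(classify_process(-2.4, NA)), "homogeneous_selection")
  expect_equal(as.character(classify_process(-1.0, 0.97)), "dispersal_limitation")
  expect_equal(as.character(classify_process(0.5, -0.99)), "homogenizing_dispersal")
  expect_equal(as.character(classify_process(0, 0)), "undominated")
  # boundary cases: |bnti| = 2 and |rc| = 0.95 are stochastic/undominated
  expect_equal(as.character(classify_process(2, 0.95)), "undominated")
  expect_true(is.na(classify_process(1, NA)))
  expect_error(classify_process(0, 1.5), "rc must lie")
})

test_that("process summaries are normalised fractions per group", {
  pr <- factor(c("undominated", "undominated", "variable_selection", NA),
               levels = lakeassembly:::PROCESS_LEVELS)
  pairs <- data.frame(process = pr, group = c("g1", "g1", "g1", "g1"))
  s <- summarize_processes(pairs, grouping = "group")
  expect_equal(sum(s$fraction), 1)
  expect_equal(s$fraction[s$process == "undominated"], 2 / 3)
  expect_equal(unique(s$n_excluded), 1)

  all_und <- data.frame(process = factor(rep("undominated", 5),
                                         levels = lakeassembly:::PROCESS_LEVELS))
  s2 <- summarize_processes(all_und)
  expect_equal(s2$fraction, c(0, 0, 0, 0, 1))
})

test_that("assembly_analysis stays within declared groups", {
  tr <- simulate_tree(40, seed = 71)
  m <- simulate_neutral(n_samples = 8, N = 800, m = 0.3, n_taxa = 40, seed = 72)
  md <- data.frame(sample_id = rownames(m), lake = rep(c("L1", "L2"), each = 4))
  res <- assembly_analysis(m, tr, md, group_by = "lake", n_null = 99, seed = 73)
  expect_equal(nrow(res$pairs), 2 * choose(4, 2))
  # no cross-lake pairs
  il <- md$lake[match(res$pairs$sample_i, md$sample_id)]
  jl <- md$lake[match(res$pairs$sample_j, md$sample_id)]
  expect_true(all(il == jl))
  expect_true(all(abs(tapply(res$summary$fraction, res$summary$group, sum) - 1) < 1e-12))
})
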