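two_block_spec <- function() {
  plspm_spec(list(X = c("x1", "x2"), Y = c("y1", "y2")),
             data.frame(from = "X", to = "Y"))
}

test_that("model specification is validated", {
  expect_error(plspm_spec(list(X = "a", Y = character(0)),
                          data.frame(from = "X", to = "Y")), "nonempty")
  expect_error(plspm_spec(list(X = "a", Y = "a"),
                          data.frame(from = "X", to = "Y")), "more than one block")
  expect_error(plspm_spec(list(X = "a", Y = "b"),
                          data.frame(from = "X", to = "Z")), "unknown latent")
  expect_error(plspm_spec(list(X = "a", Y = "b"),
                          data.frame(from = c("X", "Y"), to = c("Y", "X"))),
               "cycle")
})

test_that("single-indicator two-LV model collapses to Pearson correlation", {
  set.seed(2)
  x <- rnorm(120)
  y <- 0.6 * x + rnorm(120)
  d <- data.frame(x = x, y = y)
  spec <- plspm_spec(list(X = "x", Y = "y"), data.frame(from = "X", to = "Y"))
  fit <- fit_plspm(d, spec)
  expect_equal(fit$paths$coefficient, cor(x, y), tolerance = 1e-10)
  # single-indicator blocks: communalities are 1, so gof = sqrt(mean R^2)
  expect_equal(fit$outer$communality, c(1, 1), tolerance = 1e-10)
  expect_equal(fit$gof, sqrt(mean(fit$r_squared)), tolerance = 1e-12)
  # gof identity holds in general
  expect_equal(fit$gof,
               sqrt(mean(fit$outer$communality) * mean(fit$r_squared)),
               tolerance = 1e-12)
})

test_that("saturated single-indicator model equals standardized OLS", {
  set.seed(3)
  d <- data.frame(a = rnorm(200))
  d$b <- 0.4 * d$a + rnorm(200)
  d$c <- 0.3 * d$a - 0.5 * d$b + rnorm(200)
  spec <- plspm_spec(list(A = "a", B = "b", C = "c"),
                     data.frame(from = c("A", "A", "B"), to = c("B", "C", "C")))
  fit <- fit_plspm(d, spec)
  ols <- coef(lm(scale(d$c) ~ scale(d$a) + scale(d$b)))
  expect_equal(unname(fit$path_matrix["C", c("A", "B")]), unname(ols[2:3]),
               tolerance = 1e-10)
})

test_that("latent scores are standardized and blocks are column-order invariant", {
  set.seed(4)
  n <- 150
  lv <- rnorm(n)
  d <- data.frame(x1 = lv + rnorm(n, 0, 0.4), x2 = lv + rnorm(n, 0, 0.4),
                  y1 = 0.5 * lv + rnorm(n), y2 = 0.5 * lv + rnorm(n))
  fit <- fit_plspm(d, two_block_spec())
  expect_equal(unname(apply(fit$scores, 2, sd)), c(1, 1), tolerance = 1e-12)
  spec_swapped <- plspm_spec(list(X = c("x2", "x1"), Y = c("y2", "y1")),
                             data.frame(from = "X", to = "Y"))
  fit2 <- fit_plspm(d, spec_swapped)
  expect_equal(fit$paths$coefficient, fit2$paths$coefficient, tolerance = 1e-9)
  expect_equal(fit$gof, fit2$gof, tolerance = 1e-9)
})

test_that("paths of a known linear structural model are recovered", {
  set.seed(5)
  n <- 500
  X <- rnorm(n)
  M <- 0.6 * X + rnorm(n, 0, 0.3)
  Y <- -0.4 * M + rnorm(n, 0, 0.3)
  mk <- function(lv, tag) {
    out <- sapply(1:3, function(k) lv + rnorm(n, 0, 0.3))
    colnames(out) <- paste0(tag, 1:3)
    out
  }
  d <- data.frame(mk(X, "x"), mk(M, "m"), mk(Y, "y"))
  spec <- plspm_spec(
    list(X = paste0("x", 1:3), M = paste0("m", 1:3), Y = paste0("y", 1:3)),
    data.frame(from = c("X", "M"), to = c("M", "Y"))
  )
  fit <- fit_plspm(d, spec)
  truth <- c(cor(X, M), -0.4 * sd(M) / sd(Y))
  expect_equal(fit$paths$coefficient[1], truth[1], tolerance = 0.1)
  expect_lt(abs(fit$paths$coefficient[2] - truth[2]), 0.1)
  # all three schemes land close to each other on clean data
  for (scheme in c("factor", "path")) {
    spec_s <- plspm_spec(spec$blocks, spec$paths[, 1:2], scheme = scheme)
    expect_equal(fit_plspm(d, spec_s)$paths$coefficient,
                 fit$paths$coefficient, tolerance = 0.02)
  }
})

test_that("indirect effects match the path-enumeration oracle", {
  # chain: X -> M (0.5), M -> Y (0.4) and no direct X -> Y edge
  P <- matrix(0, 3, 3, dimnames = list(c("X", "M", "Y"), c("X", "M", "Y")))
  P["M", "X"] <- 0.5
  P["Y", "M"] <- 0.4
  fake <- structure(list(
    path_matrix = P,
    spec = list(inner = P != 0)
  ), class = "plspm_fit")
  eff <- indirect_effects(fake)
  xy <- eff[eff$from == "X" & eff$to == "Y", ]
  expect_equal(xy$indirect, 0.2)
  expect_equal(xy$direct, 0)
  # diamond with a direct edge: enumeration oracle over simple paths
  P2 <- matrix(0, 4, 4,
               dimnames = list(c("X", "M1", "M2", "Y"), c("X", "M1", "M2", "Y")))
  P2["M1", "X"] <- 0.5; P2["M2", "X"] <- -0.3
  P2["Y", "M1"] <- 0.4; P2["Y", "M2"] <- 0.6; P2["Y", "X"] <- 0.2
  fake2 <- structure(list(path_matrix = P2, spec = list(inner = P2 != 0)),
                     class = "plspm_fit")
  eff2 <- indirect_effects(fake2)
  xy2 <- eff2[eff2$from == "X" & eff2$to == "Y", ]
  expect_equal(xy2$indirect, indirect_bruteforce(P2, "X", "Y"), tolerance = 1e-12)
  expect_equal(xy2$direct, 0.2)
  expect_equal(xy2$total, 0.2 + xy2$indirect)
  # no multi-step path: indirect effect is zero
  expect_equal(eff2[eff2$from == "M1" & eff2$to == "Y", "indirect"], 0)
})

test_that("bootstrap p-values are deterministic given a seed", {
  set.seed(6)
  n <- 80
  lv <- rnorm(n)
  d <- data.frame(x1 = lv + rnorm(n), x2 = lv + rnorm(n),
                  y1 = 0.6 * lv + rnorm(n), y2 = 0.6 * lv + rnorm(n))
  b1 <- bootstrap_paths(d, two_block_spec(), n_boot = 99, seed = 7)
  b2 <- bootstrap_paths(d, two_block_spec(), n_boot = 99, seed = 7)
  expect_identical(b1, b2)
  expect_true(all(b1$p_value >= 0 & b1$p_value <= 1))
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- data.frame(x1 = rnorm(50), x2 = rep(2, 50), y1 = rnorm(50), y2 = rnorm(50))
  expect_error(fit_plspm(d, two_block_spec()), "x2")
  d2 <- data.frame(x1 = rnorm(50), x2 = rnorm(50), y1 = rnorm(50), y2 = rnorm(50))
  d2$x1[3] <- NA
  expect_error(fit_plspm(d2, two_block_spec()), "missing")
  fit <- fit_plspm(d2, two_block_spec(), listwise = TRUE)
  expect_equal(fit$n, 49)
})

test_that("DOT export names every latent variable and edge", {
  set.seed(8)
  d <- data.frame(x = rnorm(60), y = rnorm(60))
  spec <- plspm_spec(list(X = "x", Y = "y"), data.frame(from = "X", to = "Y"))
  dot <- plspm_dot(fit_plspm(d, spec))
  expect_match(dot, "digraph")
  expect_match(dot, '"X" -> "Y"')
})
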