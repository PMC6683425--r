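test_that("sign-partitioned means average the stated subsets", {
  tbl <- tibble::tibble(mrna = c("a", "b", "c"), mirna = c("x", "y", "z"),
                        t_cc = c(0.2, 0.4, -0.3), n_cc = c(-0.1, -0.5, 0.6))
  m <- compute_sign_means(tbl)
  expect_equal(m$m_t_plus, 0.3)
  expect_equal(m$m_t_minus, 0.3)
  expect_equal(m$m_n_plus, 0.6)
  expect_equal(m$m_n_minus, 0.3)

  single <- tibble::tibble(mrna = "a", mirna = "x", t_cc = -0.5, n_cc = 0.5)
  ms <- compute_sign_means(single)
  expect_equal(ms$m_t_minus, 0.5)
  expect_equal(ms$m_n_plus, 0.5)
  expect_true(is.na(ms$m_t_plus))
  expect_true(is.na(ms$m_n_minus))
  expect_error(compute_lambdas(ms), class = "mwmm_config_error")

  const <- tibble::tibble(mrna = letters[1:4], mirna = LETTERS[1:4],
                          t_cc = rep(0.37, 4), n_cc = rep(-0.2, 4))
  expect_equal(compute_sign_means(const)$m_t_plus, 0.37)
})

test_that("lambda coefficients follow the mean-ratio definition", {
  mk <- function(tp, tm, np, nm) {
    tibble::tibble(m_t_plus = tp, m_t_minus = tm, m_n_plus = np, m_n_minus = nm)
  }
  expect_equal(compute_lambdas(mk(0.2, 0.3, 0.4, 0.3))$lambda1, 0.4) # 0.2/0.5
  l <- compute_lambdas(mk(0.25, 0.3, 0.4, 0.25))
  expect_equal(l$lambda1, 0.5) # symmetric means
  expect_equal(l$lambda1 + (1 - l$lambda1), 1)
  expect_true(l$lambda2 >= 0 && l$lambda2 <= 1)
})

test_that("the five desk-computable example weights match the reference pair", {
  t <- -0.092; n <- 0.271
  expect_lte(abs(edge_weight(t, n, "arithmetic_mean") - 0.182), 5e-4 + 1e-9)
  expect_lte(abs(edge_weight(t, n, "geometric_mean") - 0.158), 5e-4 + 1e-9)
  expect_lte(abs(edge_weight(t, n, "maximum_absolute") - 0.271), 5e-4 + 1e-9)
  expect_lte(abs(edge_weight(t, n, "all_negative") - 0.092), 5e-4 + 1e-9)
  expect_lte(abs(edge_weight(t, n, "all_positive") - 0.271), 5e-4 + 1e-9)
  # integrated weight with the back-solved lambda2 = (0.271-0.225)/0.179
  lam <- tibble::tibble(lambda1 = 0.5, lambda2 = 0.257)
  expect_lte(abs(edge_weight(t, n, "integrated_mean", lam) - 0.225), 5e-4 + 1e-9)
})

test_that("piecewise formulas refuse undefined inputs", {
  expect_error(edge_weight(0, 0.4, "integrated_mean",
                           tibble::tibble(lambda1 = 0.5, lambda2 = 0.5)),
               class = "mwmm_config_error")
  expect_error(edge_weight(0, 0.4, "all_negative"), class = "mwmm_config_error")
  expect_error(edge_weight(0.3, 0.2, "all_positive"), class = "mwmm_config_error")
  expect_error(edge_weight(-0.1, 0.4, "integrated_mean"),
               class = "mwmm_config_error") # missing lambdas
  expect_equal(edge_weight(0.3, 0.2, "arithmetic_mean"), 0.25) # abs formulas accept
})

test_that("symmetric pairs collapse all six formulas to the shared magnitude", {
  w <- c(0.15, 0.42, 0.9)
  tbl <- tibble::tibble(mrna = paste0("g", 1:3), mirna = paste0("m", 1:3),
                        t_cc = -w, n_cc = w)
  for (f in weight_formulas()) {
    got <- build_weighted_edges(tbl, f,
                                lambdas = if (f == "integrated_mean")
                                  tibble::tibble(lambda1 = 0.3, lambda2 = 0.7))
    expect_equal(got$weight, w, tolerance = 1e-12, label = f)
  }
})

test_that("weight invariants hold over many random sign-inverting records", {
  withr::local_seed(402)
  n <- 10000
  mag_t <- runif(n, 1e-6, 1)
  mag_n <- runif(n, 1e-6, 1)
  flip <- runif(n) < 0.5
  t_cc <- ifelse(flip, -mag_t, mag_t)
  n_cc <- ifelse(flip, mag_n, -mag_n)
  lam <- tibble::tibble(lambda1 = runif(1), lambda2 = runif(1))
  am <- edge_weight(t_cc, n_cc, "arithmetic_mean")
  gm <- edge_weight(t_cc, n_cc, "geometric_mean")
  mx <- edge_weight(t_cc, n_cc, "maximum_absolute")
  im <- edge_weight(t_cc, n_cc, "integrated_mean", lam)
  an <- edge_weight(t_cc, n_cc, "all_negative")
  ap <- edge_weight(t_cc, n_cc, "all_positive")
  eps <- 1e-12
  expect_true(all(gm <= am + eps))
  expect_true(all(am <= mx + eps))
  lo <- pmin(abs(t_cc), abs(n_cc)); hi <- pmax(abs(t_cc), abs(n_cc))
  expect_true(all(im >= lo - eps & im <= hi + eps)) # convex combination
  for (v in list(am, gm, mx, im, an, ap)) {
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("lambdas are invariant under row permutation and computed table-wide", {
  tbl <- example_correlation_rows()
  ed <- build_weighted_edges(tbl, "integrated_mean")
  lam <- attr(ed, "lambdas")
  withr::local_seed(7)
  shuffled <- tbl[sample(nrow(tbl)), ]
  lam2 <- attr(build_weighted_edges(shuffled, "integrated_mean"), "lambdas")
  expect_equal(lam, lam2, tolerance = 1e-12)
  expect_equal(nrow(ed), 10)
  # arithmetic weights reproduce the first-row reference value
  expect_equal(build_weighted_edges(tbl, "arithmetic_mean")$weight[1], 0.1815)
  expect_equal(nrow(build_weighted_edges(tbl[0, ], "arithmetic_mean")), 0)
})
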