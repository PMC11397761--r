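test_that("finite-population sample sizes match the published design", {
  des <- sample_size_fpc(N = 1874, p = 0.5, conf_level = 0.95, d = 0.05,
                         loss_fraction = 0.3)
  expect_equal(des$net_n, 319L)
  expect_equal(des$gross_n, 415L) # 319 * 1.3 = 414.7, rounded half up

  no_loss <- sample_size_fpc(N = 1874)
  expect_equal(no_loss$gross_n, no_loss$net_n)

  expect_error(sample_size_fpc(N = 100, d = 0), class = "canasta_domain_error")

  # monotone in N and confidence, antitone in margin
  n_by_N <- vapply(c(200, 500, 1000, 5000, 1e5),
                   function(N) sample_size_fpc(N)$net_n, integer(1))
  expect_true(all(diff(n_by_N) >= 0))
  n_by_conf <- vapply(c(0.8, 0.9, 0.95, 0.99),
                      function(cl) sample_size_fpc(1874, conf_level = cl)$net_n,
                      integer(1))
  expect_true(all(diff(n_by_conf) >= 0))
  n_by_d <- vapply(c(0.02, 0.05, 0.1),
                   function(d) sample_size_fpc(1874, d = d)$net_n, integer(1))
  expect_true(all(diff(n_by_d) <= 0))
})

test_that("stratified selection respects allocations and seeds", {
  frame <- data.frame(
    id = 1:100, domain = rep(c("a", "b", "c", "d"), each = 25),
    stringsAsFactors = FALSE
  )
  s <- stratified_select(frame, stratum = "domain",
                         allocation = c(a = 5, b = 5, c = 5, d = 5), seed = 3)
  expect_equal(nrow(s), 20)
  expect_true(all(table(s$domain) == 5))
  expect_false(any(duplicated(s$id)))

  s2 <- stratified_select(frame, stratum = "domain",
                          allocation = c(a = 5, b = 5, c = 5, d = 5), seed = 3)
  expect_identical(s, s2)

  prop <- stratified_select(frame, stratum = "domain", n = 40, seed = 9)
  expect_equal(nrow(prop), 40)

  expect_error(
    stratified_select(frame, stratum = "domain",
                      allocation = c(a = 30, b = 5, c = 5, d = 5)),
    regexp = "a", class = "canasta_domain_error"
  )
})

test_that("median and quartiles use linear interpolation", {
  mi <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(unlist(mi), c(median = 3, q1 = 2, q3 = 4))
  expect_equal(unlist(median_iqr(rep(7, 10))), c(median = 7, q1 = 7, q3 = 7))
  expect_error(median_iqr(numeric(0)), class = "canasta_domain_error")

  # sorting-based interpolation oracle on random samples
  quartile_oracle <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  set.seed(10)
  for (n in c(2, 5, 17, 100)) {
    x <- stats::rlnorm(n)
    mi <- median_iqr(x)
    expect_equal(mi$q1, quartile_oracle(x, 0.25))
    expect_equal(mi$median, quartile_oracle(x, 0.5))
    expect_equal(mi$q3, quartile_oracle(x, 0.75))
  }
})

test_that("Kruskal-Wallis H matches a direct rank computation and is robust", {
  set.seed(21)
  x <- c(stats::rnorm(12), stats::rnorm(15, 1))
  g <- rep(c("g1", "g2"), c(12, 15))
  kw <- kruskal_wallis(x, g)

  # brute-force rank oracle (no ties)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  H_direct <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  expect_equal(kw$H, H_direct, tolerance = 1e-12)
  expect_equal(kw$df, 1)
  expect_equal(kw$p, stats::pchisq(H_direct, 1, lower.tail = FALSE))

  # invariant under swapping group identities and monotone transforms
  g_swapped <- ifelse(g == "g1", "g2", "g1")
  expect_equal(kruskal_wallis(x, g_swapped)$H, kw$H)
  expect_equal(kruskal_wallis(exp(x), g)$H, kw$H)

  # all-identical values: H = 0, p = 1
  flat <- kruskal_wallis(rep(3, 9), rep(c("a", "b", "c"), 3))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)
})

test_that("Dunn post-hoc letters separate shifted groups and share otherwise", {
  set.seed(33)
  # groups far apart: all letters distinct
  x <- c(stats::rnorm(40, 0, 0.1), stats::rnorm(40, 5, 0.1),
         stats::rnorm(40, 10, 0.1))
  g <- rep(c("a1", "a2", "a3"), each = 40)
  gc <- group_comparison(x, g)
  expect_lt(gc$p, 0.001)
  expect_equal(length(unique(gc$summary$letter)), 3)

  # identical groups: everyone shares one letter
  y <- rep(stats::rnorm(30), 3)
  gy <- rep(c("b1", "b2", "b3"), each = 30)
  gcy <- group_comparison(y, gy)
  expect_true(all(gcy$summary$letter == "a"))
})

test_that("letter displays are consistent with the pairwise matrix", {
  set.seed(55)
  for (rep_i in 1:20) {
    k <- sample(3:5, 1)
    shift <- stats::runif(k, 0, 3)
    x <- unlist(lapply(shift, function(s) stats::rnorm(25, s)))
    g <- rep(paste0("g", seq_len(k)), each = 25)
    pw <- dunn_posthoc(x, g)
    lets <- compact_letters(pw, alpha = 0.05)
    for (i in seq_len(nrow(pw))) {
      shared <- intersect(strsplit(lets[[pw$group1[i]]], "")[[1]],
                          strsplit(lets[[pw$group2[i]]], "")[[1]])
      if (pw$p_adj[i] < 0.05) {
        expect_length(shared, 0)
      } else {
        expect_gt(length(shared), 0)
      }
    }
  }
})

test_that("post-hoc power separates a shifted group at n = 200 per group", {
  set.seed(77)
  n <- 200
  x <- c(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n, 1.5))
  g <- rep(c("c1", "c2", "shifted"), each = n)
  gc <- group_comparison(x, g)
  shifted_letter <- gc$summary$letter[gc$summary$group == "shifted"]
  others <- gc$summary$letter[gc$summary$group != "shifted"]
  expect_false(any(vapply(others, function(l) {
    length(intersect(strsplit(l, "")[[1]], strsplit(shifted_letter, "")[[1]])) > 0
  }, logical(1))))
})
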